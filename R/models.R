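#' Evidence-accumulation race models of distractor effects
#'
#' Constructors for the four trial-level choice models.  All four share the
#' same race dynamics (see [accumulator_params()]): pools of accumulators
#' receive noisy value-proportional input, a common feedforward inhibition
#' pool subtracts `f * mean(input)` from every pool, and the first
#' *choosable* pool (HV or LV) to reach the threshold determines the choice
#' and the reaction time.  The models differ in how the distractor value D
#' enters:
#'
#' * `mutual_inhibition_model()`: three pools (HV, LV, D).  The D pool
#'   accumulates and feeds the inhibition but can never be chosen, so large
#'   distractors slow everyone down and sharpen the HV/LV comparison.
#' * `divisive_normalisation_model()`: two pools (HV, LV) whose drifts are
#'   `d * V_i / (V_HV + V_LV + V_D)`; D acts only through the denominator
#'   and compresses the HV/LV drift difference.
#' * `dual_route_model()`: a mutual-inhibition route and a divisive-
#'   normalisation route accumulate independently in parallel; the first
#'   route to cross the threshold determines the outcome.
#' * `null_model()`: mutual-inhibition dynamics over the HV and LV pools
#'   only; the distractor is ignored entirely.
#'
#' Default parameter values are the ones used for the decision-space
#' simulations, chosen so that each model's overall accuracy over the
#' standard value grid is approximately 0.85.
#'
#' @param d,sigma Drift gain (s^-1) and input noise for the single-route
#'   models.
#' @param d_mutual,sigma_mutual,d_divnorm,sigma_divnorm Route-specific
#'   drift and noise for the dual route model.
#' @param f,threshold,t_nd,timeout,dt See [accumulator_params()].
#' @return An object of class `accumulator_model`.
#' @seealso [simulate_trials()], [run_decision_space()]
#' @examples
#' m <- mutual_inhibition_model()
#' simulate_trials(m, c(hv = 3, lv = 1, d = 2), n_reps = 5)
#' @name accumulator_models
NULL

new_accumulator_model <- function(kind, params, params_divnorm = NULL,
                                  two_option = FALSE) {
  structure(list(kind = kind, params = params,
                 params_divnorm = params_divnorm,
                 two_option = two_option),
            class = "accumulator_model")
}

#' @rdname accumulator_models
#' @export
mutual_inhibition_model <- function(d = 1.3, sigma = 1, f = 0.5,
                                    threshold = 1, t_nd = 0.3, timeout = 6,
                                    dt = 0.001) {
  new_accumulator_model("mutual",
    accumulator_params(d, sigma, f, threshold, t_nd, timeout, dt))
}

#' @rdname accumulator_models
#' @export
divisive_normalisation_model <- function(d = 5.5, sigma = 0.6, f = 0.5,
                                         threshold = 1, t_nd = 0.3,
                                         timeout = 6, dt = 0.001) {
  new_accumulator_model("divnorm",
    accumulator_params(d, sigma, f, threshold, t_nd, timeout, dt))
}

#' @rdname accumulator_models
#' @export
dual_route_model <- function(d_mutual = 0.8, sigma_mutual = 0.6,
                             d_divnorm = 1.0, sigma_divnorm = 0.6,
                             f = 0.5, threshold = 1, t_nd = 0.3,
                             timeout = 6, dt = 0.001) {
  new_accumulator_model(
    "dual",
    accumulator_params(d_mutual, sigma_mutual, f, threshold, t_nd, timeout, dt),
    accumulator_params(d_divnorm, sigma_divnorm, f, threshold, t_nd, timeout, dt))
}

#' @rdname accumulator_models
#' @export
null_model <- function(d = 1.3, sigma = 1, f = 0.5, threshold = 1,
                       t_nd = 0.3, timeout = 6, dt = 0.001) {
  new_accumulator_model("null",
    accumulator_params(d, sigma, f, threshold, t_nd, timeout, dt))
}

#' Construct an accumulator model by kind
#'
#' Programmatic interface used by the fitting routines: builds one of the
#' four models from a kind string and a flat named parameter list.
#'
#' @param kind One of `"mutual"`, `"divnorm"`, `"dual"`, `"null"`.
#' @param ... Passed to the matching constructor (see
#'   [accumulator_models]).
#' @return An `accumulator_model`.
#' @export
accumulator_model <- function(kind = c("mutual", "divnorm", "dual", "null"),
                              ...) {
  kind <- match.arg(kind)
  switch(kind,
         mutual = mutual_inhibition_model(...),
         divnorm = divisive_normalisation_model(...),
         dual = dual_route_model(...),
         null = null_model(...))
}

#' Read a model configuration file
#'
#' Builds an accumulator model from a YAML (or JSON-compatible) config
#' naming the model kind and any parameter fields, e.g.
#' `kind: mutual`, `d: 1.3`, `sigma: 1`.
#'
#' @param path Path to a YAML config file.
#' @return An `accumulator_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- cfg$kind %||% cfg$model
  if (is.null(kind))
    stop_config("model config must name the model 'kind'")
  args <- cfg[setdiff(names(cfg), c("kind", "model"))]
  do.call(accumulator_model, c(list(kind = kind), args))
}

#' Two-option reduction of a model
#'
#' Returns the variant of `model` that applies on trials where no
#' distractor is shown: the mutual inhibition model loses its D pool (and
#' so coincides with the null model), the divisive normalisation model
#' normalises by `HV + LV` only, and the dual route model combines the two
#' reduced routes.
#'
#' @param model An `accumulator_model`.
#' @return An `accumulator_model` that ignores the `d` column.
#' @export
two_option_model <- function(model) {
  stopifnot(inherits(model, "accumulator_model"))
  model$two_option <- TRUE
  model
}

#' @export
print.accumulator_model <- function(x, ...) {
  label <- c(mutual = "Mutual inhibition model (3 pools)",
             divnorm = "Divisive normalisation model (2 pools)",
             dual = "Dual route model (mutual inhibition + divisive normalisation)",
             null = "Null model (2 pools, distractor ignored)")[[x$kind]]
  if (isTRUE(x$two_option)) label <- paste(label, "[two-option variant]")
  cat(label, "\n")
  if (x$kind == "dual") {
    cat("Mutual inhibition route:\n  "); print(x$params)
    cat("Divisive normalisation route:\n  "); print(x$params_divnorm)
  } else {
    print(x$params)
  }
  invisible(x)
}

# Normalise `values` into a data.frame with columns hv, lv, d.
as_option_values <- function(values, model) {
  if (is.numeric(values) && is.null(dim(values))) {
    if (length(values) == 2L) values <- c(values, NA_real_)
    if (length(values) != 3L)
      stop_config("'values' must be (hv, lv) or (hv, lv, d)")
    values <- data.frame(hv = values[[1L]], lv = values[[2L]],
                         d = values[[3L]])
  }
  values <- as.data.frame(values)
  if (!all(c("hv", "lv") %in% names(values)))
    stop_config("'values' must contain columns 'hv' and 'lv'")
  if (!"d" %in% names(values)) values$d <- NA_real_
  if (anyNA(values$hv) || anyNA(values$lv))
    stop_config("'hv' and 'lv' must not be missing")
  if (any(values$hv < values$lv))
    stop_config("'hv' must be at least 'lv' on every trial")
  values[c("hv", "lv", "d")]
}

needs_distractor <- function(model) {
  !isTRUE(model$two_option) && model$kind %in% c("mutual", "divnorm", "dual")
}

# Drift matrix for a single-route kind; returns list(drift, sigma, params).
route_drift <- function(kind, params, vals, two_option) {
  d <- params$d
  if (kind == "mutual" && !two_option) {
    drift <- cbind(d * vals$hv, d * vals$lv, d * vals$d)
  } else if (kind == "divnorm") {
    sv <- if (two_option) vals$hv + vals$lv else vals$hv + vals$lv + vals$d
    if (any(sv == 0))
      stop_config("undefined divisive normalisation: option values sum to 0")
    drift <- cbind(d * vals$hv / sv, d * vals$lv / sv)
  } else {
    # null model, or the two-option reduction of the mutual model
    drift <- cbind(d * vals$hv, d * vals$lv)
  }
  drift
}

run_route <- function(kind, params, vals, two_option, cap = NULL) {
  drift <- route_drift(kind, params, vals, two_option)
  race_kernel(drift, params$sigma, params$f, params$threshold,
              params$timeout, params$dt, 2L, cap)
}

max_race_steps <- function(params) {
  as.integer(ceiling(params$timeout / params$dt - 1e-9))
}

#' Simulate trials from an accumulator model
#'
#' Runs the stochastic race for a set of option-value triples and returns a
#' trial table.  Uses R's global random number stream; call `set.seed()`
#' for reproducibility.
#'
#' @param model An `accumulator_model`.
#' @param values A numeric vector `(hv, lv[, d])` or a data frame with
#'   columns `hv`, `lv` and (for distractor-aware models) `d`.  `hv` must
#'   be at least `lv`; `d` is unconstrained.
#' @param n_reps Number of simulated repetitions of each value row.
#' @param cap_routes Dual route only: stop the divisive normalisation
#'   route once the mutual inhibition route has already decided earlier
#'   (the combined outcome is unaffected; only unneeded noise draws are
#'   skipped).  Set to `FALSE` to run both routes to their own completion,
#'   in which case the outcome equals the per-trial minimum of the two
#'   standalone routes driven by the same noise streams.
#' @param step_cap Optional integer vector (recycled over value rows
#'   before replication) limiting the number of accumulation steps
#'   simulated per trial; trials not decided within their cap are
#'   reported undecided.  Used by the likelihood machinery, which only
#'   needs each trial's outcome up to a known horizon.
#' @return A data frame with columns `trial`, `hv`, `lv`, `d`, `choice`
#'   (`"HV"`, `"LV"` or `"NONE"`), `rt` (seconds, including the
#'   non-decision time; `NA` when undecided), `decided`, and `route`
#'   (`"mutual"`, `"divnorm"`, or `NA`; non-`NA` only for the dual route
#'   model).
#' @examples
#' set.seed(1)
#' simulate_trials(dual_route_model(), c(hv = 3, lv = 1, d = 2), n_reps = 3)
#' @export
simulate_trials <- function(model, values, n_reps = 1, cap_routes = TRUE,
                            step_cap = NULL) {
  stopifnot(inherits(model, "accumulator_model"))
  vals <- as_option_values(values, model)
  if (needs_distractor(model) && anyNA(vals$d))
    stop_config(sprintf(
      "the %s model requires a distractor value on every trial; use two_option_model() for two-option trials",
      model$kind))
  if (!is.null(step_cap))
    step_cap <- as.integer(rep_len(step_cap, nrow(vals)))
  if (n_reps != 1) {
    idx <- rep(seq_len(nrow(vals)), each = n_reps)
    vals <- vals[idx, , drop = FALSE]
    rownames(vals) <- NULL
    if (!is.null(step_cap)) step_cap <- step_cap[idx]
  }
  n <- nrow(vals)
  two <- isTRUE(model$two_option)
  p <- model$params

  if (model$kind == "dual") {
    mi <- run_route("mutual", p, vals, two, step_cap)
    max_steps <- max_race_steps(p)
    cap <- step_cap
    if (cap_routes) {
      cap <- as.integer(ifelse(mi$decided, mi$step, max_steps))
      if (!is.null(step_cap)) cap <- pmin(cap, step_cap)
    }
    dn <- run_route("divnorm", model$params_divnorm, vals, two, cap)
    dn_wins <- dn$decided & (!mi$decided | dn$step < mi$step)
    tie <- dn$decided & mi$decided & dn$step == mi$step &
      dn$choice != mi$choice
    if (any(tie)) dn_wins[tie] <- stats::runif(sum(tie)) < 0.5
    decided <- mi$decided | dn$decided
    choice_id <- ifelse(dn_wins, dn$choice, mi$choice)
    step <- ifelse(dn_wins, dn$step, mi$step)
    route <- ifelse(!decided, NA_character_,
                    ifelse(dn_wins, "divnorm", "mutual"))
  } else {
    out <- run_route(model$kind, p, vals, two, step_cap)
    decided <- out$decided
    choice_id <- out$choice
    step <- out$step
    route <- rep(NA_character_, n)
  }

  data.frame(
    trial = seq_len(n),
    hv = vals$hv, lv = vals$lv, d = vals$d,
    choice = c("NONE", "HV", "LV")[choice_id + 1L],
    rt = ifelse(decided, step * p$dt + p$t_nd, NA_real_),
    decided = decided,
    route = route,
    stringsAsFactors = FALSE)
}

#' Simulate method for accumulator models
#'
#' Thin wrapper around [simulate_trials()] following the base
#' `simulate()` contract: `nsim` repetitions per value row, optional
#' `seed`.
#'
#' @param object An `accumulator_model`.
#' @param nsim Repetitions per value row.
#' @param seed Optional seed passed to `set.seed()`.
#' @param values As in [simulate_trials()].
#' @param ... Passed on to [simulate_trials()].
#' @return See [simulate_trials()].
#' @export
simulate.accumulator_model <- function(object, nsim = 1, seed = NULL,
                                       values, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_trials(object, values, n_reps = nsim, ...)
}
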