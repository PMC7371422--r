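#' Decision-space value grid
#'
#' Builds the Cartesian product of value-sum, value-difference and relative
#' distractor levels that spans the decision space used in the simulation
#' sweeps.  Each cell is converted to an option triple via
#' `hv = (sum + diff) / 2`, `lv = (sum - diff) / 2`, `d = hv + d_offset`.
#' Grid coordinates are rounded to 9 decimals so cells can be compared
#' exactly.
#'
#' @param sums Levels of `hv + lv`.  Default `seq(3, 5, by = 0.2)`.
#' @param diffs Levels of `hv - lv`; all must be positive.  Default
#'   `seq(0.6, 2, by = 0.2)`.
#' @param d_offsets Levels of `d - hv`.  Default `seq(-1.2, 4.8, by = 0.4)`.
#' @return A data frame of class `value_grid` with columns `sum`, `diff`,
#'   `d_minus_hv`, `hv`, `lv`, `d`; one row per cell (1408 with the
#'   defaults).
#' @examples
#' g <- value_grid()
#' nrow(g)  # 11 * 8 * 16
#' @export
value_grid <- function(sums = seq(3, 5, by = 0.2),
                       diffs = seq(0.6, 2, by = 0.2),
                       d_offsets = seq(-1.2, 4.8, by = 0.4)) {
  if (!length(sums) || !length(diffs) || !length(d_offsets))
    stop_config("all grid level vectors must be non-empty")
  if (any(diffs <= 0))
    stop_config("all 'diffs' must be positive (hv must exceed lv)")
  g <- expand.grid(sum = sums, diff = diffs, d_minus_hv = d_offsets,
                   KEEP.OUT.ATTRS = FALSE)
  g$sum <- round(g$sum, 9); g$diff <- round(g$diff, 9)
  g$d_minus_hv <- round(g$d_minus_hv, 9)
  g$hv <- round((g$sum + g$diff) / 2, 9)
  g$lv <- round((g$sum - g$diff) / 2, 9)
  g$d <- round(g$hv + g$d_minus_hv, 9)
  class(g) <- c("value_grid", "data.frame")
  g
}

#' Simulate a cohort over the decision space
#'
#' Runs `n_iter` trials of `model` in every grid cell and assigns the
#' iterations uniformly at random to `n_participants` simulated
#' participants, mimicking a cohort whose members each contribute trials
#' from the whole decision space.  Undecided trials are retained (flagged
#' `decided = FALSE`) so that the undecided fraction can be checked, but
#' their `accuracy` is `NA` and downstream analyses drop them.
#'
#' @param model An `accumulator_model`.
#' @param grid A [value_grid()].
#' @param n_iter Simulated trials per grid cell.
#' @param n_participants Number of simulated participants the iterations
#'   are shuffled into.
#' @return A data frame of class `decision_cohort`: `participant`, the
#'   grid columns, `choice`, `accuracy` (1 if HV chosen, 0 if LV, `NA` if
#'   undecided), `rt`, `decided`, `route`.  The undecided fraction is
#'   stored in `attr(, "undecided_fraction")`.
#' @examples
#' set.seed(1)
#' cohort <- run_decision_space(mutual_inhibition_model(),
#'                              value_grid(sums = 4, diffs = c(1, 2),
#'                                         d_offsets = c(0, 2)),
#'                              n_iter = 10, n_participants = 2)
#' mean(cohort$accuracy, na.rm = TRUE)
#' @export
run_decision_space <- function(model, grid = value_grid(), n_iter = 5000,
                               n_participants = 105) {
  stopifnot(inherits(model, "accumulator_model"))
  if (n_iter < 1 || n_participants < 1)
    stop_config("'n_iter' and 'n_participants' must be at least 1")
  idx <- rep(seq_len(nrow(grid)), each = n_iter)
  trials <- simulate_trials(model, grid[idx, c("hv", "lv", "d")])
  out <- data.frame(
    participant = sample(rep_len(seq_len(n_participants), length(idx))),
    sum = grid$sum[idx], diff = grid$diff[idx],
    d_minus_hv = grid$d_minus_hv[idx],
    hv = trials$hv, lv = trials$lv, d = trials$d,
    choice = trials$choice,
    accuracy = ifelse(trials$decided, as.integer(trials$choice == "HV"),
                      NA_integer_),
    rt = trials$rt, decided = trials$decided, route = trials$route,
    stringsAsFactors = FALSE)
  attr(out, "undecided_fraction") <- mean(!trials$decided)
  class(out) <- c("decision_cohort", "data.frame")
  out
}

#' Accuracy map over the decision space
#'
#' Mean accuracy among decided trials, binned by the native grid levels of
#' difficulty (rows, `diff = hv - lv`) and relative distractor value
#' (columns, `d_minus_hv`).  Empty bins are `NA`.
#'
#' @param cohort A `decision_cohort` (or any data frame with `diff`,
#'   `d_minus_hv`, `accuracy`, `decided` columns).
#' @return A numeric matrix with difficulty levels as rownames and
#'   `d - hv` levels as colnames.
#' @export
accuracy_map <- function(cohort) {
  ok <- cohort$decided & !is.na(cohort$accuracy)
  if (!any(ok)) stop_config("no decided trials to map")
  cohort <- cohort[ok, ]
  rows <- sort(unique(cohort$diff))
  cols <- sort(unique(cohort$d_minus_hv))
  m <- tapply(cohort$accuracy,
              list(factor(cohort$diff, levels = rows),
                   factor(cohort$d_minus_hv, levels = cols)),
              mean)
  matrix(m, nrow = length(rows), ncol = length(cols),
         dimnames = list(diff = rows, d_minus_hv = cols))
}

scale_drift <- function(model, factor) {
  model$params$d <- model$params$d * factor
  if (model$kind == "dual")
    model$params_divnorm$d <- model$params_divnorm$d * factor
  model
}

grid_accuracy <- function(model, grid, n_iter) {
  idx <- rep(seq_len(nrow(grid)), each = n_iter)
  trials <- simulate_trials(model, grid[idx, c("hv", "lv", "d")])
  mean(trials$choice[trials$decided] == "HV")
}

#' Check and calibrate overall grid accuracy
#'
#' Measures the overall accuracy of `model` over the grid and verifies it
#' against a target (conventionally 0.85).  If the measured accuracy falls
#' outside `target +/- tolerance`, a monotone bisection on a common drift
#' multiplier (noise held fixed) is run and the adjusted drift is reported
#' alongside the configured one.  Accuracy is monotone increasing in drift
#' at fixed noise, which makes the bisection well posed.
#'
#' @param model An `accumulator_model`.
#' @param grid A [value_grid()].
#' @param target Target accuracy, strictly between 0.5 and 1.
#' @param tolerance Acceptance half-width around the target.
#' @param n_iter Simulated trials per cell for each measurement.
#' @param factor_range Bracket of drift multipliers searched when
#'   adjustment is needed.
#' @param max_steps Bisection iterations.
#' @return A list of class `calibration`: `measured`, `target`, `pass`,
#'   `d` (configured drift), and when adjusted, `d_adjusted` and
#'   `factor`.
#' @export
calibrate_accuracy <- function(model, grid = value_grid(), target = 0.85,
                               tolerance = 0.02, n_iter = 100,
                               factor_range = c(0.2, 5), max_steps = 12) {
  stopifnot(inherits(model, "accumulator_model"))
  if (target <= 0.5 || target >= 1) {
    if (target == 1 && model$params$sigma == 0) {
      # noise-free: accuracy is exactly 1 wherever hv > lv
    } else {
      stop_config("'target' must lie strictly between 0.5 and 1")
    }
  }
  measured <- grid_accuracy(model, grid, n_iter)
  out <- list(measured = measured, target = target,
              pass = abs(measured - target) <= tolerance,
              d = model$params$d)
  class(out) <- "calibration"
  if (out$pass) return(out)
  acc_at <- function(fac) grid_accuracy(scale_drift(model, fac), grid, n_iter)
  lo <- factor_range[1]; hi <- factor_range[2]
  a_lo <- acc_at(lo); a_hi <- acc_at(hi)
  if ((a_lo - target) * (a_hi - target) > 0)
    stop_config(sprintf(
      "calibration target %.3f not bracketed by drift multipliers [%g, %g] (accuracy %.3f to %.3f)",
      target, lo, hi, a_lo, a_hi))
  for (i in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    a_mid <- acc_at(mid)
    if (abs(a_mid - target) <= tolerance / 2) { lo <- hi <- mid; break }
    if ((a_mid - target) * (a_lo - target) > 0) { lo <- mid; a_lo <- a_mid }
    else hi <- mid
  }
  fac <- (lo + hi) / 2
  out$factor <- fac
  out$d_adjusted <- model$params$d * fac
  out$measured_adjusted <- acc_at(fac)
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Grid accuracy %.4f against target %.3f: %s\n",
              x$measured, x$target, if (x$pass) "PASS" else "outside tolerance"))
  if (!is.null(x$d_adjusted))
    cat(sprintf("Adjusted drift: %.4f (configured %.4f), accuracy %.4f\n",
                x$d_adjusted, x$d, x$measured_adjusted))
  invisible(x)
}
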