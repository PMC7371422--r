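#' z-score a column
#'
#' Centres by the mean and scales by the sample standard deviation
#' (denominator `n - 1`).  All regressors entering the choice and gaze
#' GLMs are z-scored this way before fitting; interaction regressors are
#' products of already z-scored components and are not re-scored.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return A numeric vector with mean 0 and sample SD 1.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(x) {
  if (length(unique(stats::na.omit(x))) < 2L)
    stop_config("cannot z-score a constant column")
  (x - mean(x)) / stats::sd(x)
}

# --- GLM specification table ------------------------------------------------
# Terms are either derived quantities (hv_lv = hv - lv, ...) or direct
# columns of the records; "a:b" denotes the product of the z-scored
# components a and b.
glm_specs <- list(
  "1a" = list(type = "binomial",
              step1 = c("hv_lv", "d_hv", "hv_lv:d_hv")),
  "1b" = list(type = "binomial",
              step1 = c("hv_lv", "hv_p_lv", "d_hv", "hv_lv:d_hv")),
  "1c" = list(type = "multinomial",
              step1 = c("hv_lv", "d_hv", "hv_lv:d_hv")),
  "2a" = list(type = "stepwise", step1_family = "binomial",
              step1 = c("hv_lv", "hv_p_lv"), step2 = "d_hv"),
  "2b" = list(type = "stepwise", step1_family = "binomial",
              step1 = c("hv_lv", "hv_p_lv"), step2 = "d"),
  "2c" = list(type = "stepwise", step1_family = "binomial",
              step1 = "difficulty", step2 = "d_hv"),
  "2d" = list(type = "stepwise", step1_family = "binomial",
              step1 = "difficulty", step2 = "d"),
  "3a" = list(type = "binomial", step1 = c("hv_lv", "hv_p_lv")),
  "3b" = list(type = "binomial",
              step1 = c("mag_diff", "mag_sum", "prob_diff", "prob_sum")),
  "4"  = list(type = "binomial",
              step1 = c("subjdiff", "congruence", "d_hv", "subjdiff:d_hv")),
  "5"  = list(type = "binomial",
              step1 = c("hv_lv", "hv_p_lv", "d", "hv_lv:d", "hv_p_lv:d",
                        "hv_lv:hv_p_lv", "hv_lv:hv_p_lv:d")),
  "6a" = list(type = "binomial",
              step1 = c("gain_trial", "hv_lv", "d", "hv_lv:d", "abs_d",
                        "hv_lv:abs_d")),
  "6b" = list(type = "stepwise", step1_family = "binomial",
              step1 = c("gain_trial", "hv_lv", "hv_p_lv"), step2 = "d"),
  "6c" = list(type = "stepwise", step1_family = "binomial",
              step1 = c("gain_trial", "hv_lv", "hv_p_lv"), step2 = "abs_d"),
  "7"  = list(type = "linear", response = TRUE,
              step1 = c("hv_lv", "hv_p_lv", "d")),
  "8"  = list(type = "stepwise", step1_family = "linear", response = TRUE,
              step1 = c("fix_hv", "fix_lv", "fix_d"),
              step2 = c("hv", "lv", "d")),
  "9"  = list(type = "stepwise", step1_family = "binomial",
              step1 = c("hv_lv", "hv_p_lv", "d"),
              step2 = c("shift_d_hv", "shift_d_lv", "shift_hv_d",
                        "shift_lv_d", "shift_lv_hv", "shift_hv_lv"))
)

base_term <- function(name, s) {
  if (name %in% names(s)) return(as.numeric(s[[name]]))
  switch(name,
    hv_lv = s$hv - s$lv,
    hv_p_lv = s$hv + s$lv,
    d_hv = s$d - s$hv,
    abs_d = abs(s$d),
    mag_diff = s$mag_hv - s$mag_lv,
    mag_sum = s$mag_hv + s$mag_lv,
    prob_diff = s$prob_hv - s$prob_lv,
    prob_sum = s$prob_hv + s$prob_lv,
    gain_trial = as.numeric(s$valence == "gain"),
    congruence = as.numeric(sign(s$mag_hv - s$mag_lv) *
                              sign(s$prob_hv - s$prob_lv) >= 0),
    stop_config(sprintf("unknown regressor '%s' (not a derived term or a column of the records)", name))
  )
}

term_components <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

# z-score the base components over the mask, then form interaction products.
design_matrix <- function(terms, s) {
  comps <- term_components(terms)
  z <- lapply(comps, function(nm) {
    x <- base_term(nm, s)
    tryCatch(zscore(x),
             error = function(e)
               stop_config(sprintf("regressor '%s' is constant over the included trials", nm)))
  })
  names(z) <- comps
  X <- sapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, z[parts])
  })
  X <- matrix(X, nrow = nrow(s), dimnames = list(NULL, terms))
  cbind("(Intercept)" = 1, X)
}

fit_logistic <- function(X, y) {
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- fit$fitted.values
  ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  if (any(abs(fit$coefficients) > 15, na.rm = TRUE)) separation <- TRUE
  list(coef = fit$coefficients, fitted = p, loglik = ll,
       k = sum(!is.na(fit$coefficients)), converged = fit$converged,
       separation = separation)
}

fit_linear <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(coef = fit$coefficients, fitted = y - fit$residuals, loglik = ll,
       k = sum(!is.na(fit$coefficients)) + 1, converged = TRUE,
       separation = FALSE)
}

# Multinomial logit with HV as reference; coefficients reported on the
# ln(P_HV / P_j) scale, j in {LV, D}.
fit_multinomial <- function(X, choice) {
  y <- factor(choice, levels = c("HV", "LV", "D"))
  fit <- nnet::multinom(y ~ X[, -1, drop = FALSE], trace = FALSE,
                        maxit = 500)
  cf <- stats::coef(fit)   # rows LV, D: ln(P_j / P_HV)
  colnames(cf) <- colnames(X)
  cf <- -cf                # ln(P_HV / P_j)
  out <- as.vector(t(cf))
  names(out) <- paste0(rep(rownames(cf), each = ncol(cf)), "|",
                       colnames(cf))
  ll <- -fit$deviance / 2
  list(coef = out, fitted = stats::fitted(fit), loglik = ll,
       k = length(out), converged = fit$convergence == 0,
       separation = FALSE,
       d_intercept = cf["D", "(Intercept)"])
}

default_mask <- function(s, spec_id) {
  if (spec_id == "1c") return(s$choice %in% c("HV", "LV", "D"))
  if (spec_id %in% c("7", "8")) return(rep(TRUE, nrow(s)))
  !is.na(s$accuracy)
}

#' Fit a choice or gaze GLM per participant
#'
#' Fits one of the study's GLM specifications separately to every
#' participant and collects the coefficients.  Specification ids:
#'
#' * `"1a"`, `"1b"`: logistic accuracy on z(HV-LV), z(D-HV) (and
#'   z(HV+LV) in 1b) plus the (HV-LV)(D-HV) interaction.
#' * `"1c"`: multinomial choice (HV reference, contrasts `LV|` and `D|`),
#'   distractor choices retained; participants with fewer than 3
#'   distractor choices, or `|beta| > 10` on the `D|` intercept, are
#'   flagged excluded.
#' * `"2a"`-`"2d"`: stepwise; step 1 partials difficulty (and value-sum)
#'   terms out of accuracy by logistic regression, step 2 regresses the
#'   response-scale residuals on the distractor term by OLS.
#' * `"3a"`/`"3b"`: value-based versus attribute-based accuracy models.
#' * `"4"`, `"5"`, `"6a"`-`"6c"`: subjective-difficulty, value-sum and
#'   gain/loss (value vs salience) variants.
#' * `"7"`, `"8"`: linear models of fixation counts and (stepwise) gaze
#'   shifts; these need a `response` column name.
#' * `"9"`: stepwise logistic accuracy with step-2 directed gaze-shift
#'   regressors.
#'
#' All component regressors are z-scored within participant over the
#' included trials; interaction terms are products of z-scored components.
#' Trials where the distractor was chosen or no response was made are
#' excluded (except in `"1c"`), as are trials with missing regressors
#' (two-option trials, for distractor terms) unless `control_d = "mean"`
#' imputes the mean distractor value into control trials first.
#' Participants whose included accuracy is constant cannot be fitted and
#' are flagged excluded.
#'
#' @param records A multi-participant trial table (`decision_cohort`,
#'   `behaviour_records`, or any data frame with the needed columns).
#' @param spec Specification id (see above).
#' @param response Column name of the dependent variable for specs `"7"`
#'   and `"8"` (e.g. `"fix_d"`, `"shift_hv_d"`, or a shift-proportion
#'   column).
#' @param difficulty Optional per-trial difficulty vector (aligned with
#'   `records`) used by specs `"2c"`, `"2d"` (see
#'   [attribute_difficulty()]); stored as column `difficulty`.
#' @param subjdiff Optional per-trial subjective difficulty for spec
#'   `"4"`; defaults to `hv - lv`.
#' @param control_d `"exclude"` drops trials with missing distractor
#'   values; `"mean"` assigns the mean distractor value to them.
#' @param participant Name of the participant id column.
#' @return An object of class `drglm`: coefficient matrix (participants x
#'   regressors), per-participant diagnostics (`n`, `loglik`, `bic`,
#'   `converged`, `separation`, `excluded`, `reason`), and the row masks
#'   used.
#' @seealso [group_test()], [compare_bic()], [median_split()]
#' @export
fit_glm <- function(records, spec, response = NULL, difficulty = NULL,
                    subjdiff = NULL, control_d = c("exclude", "mean"),
                    participant = "participant") {
  spec_id <- as.character(spec)
  if (!spec_id %in% names(glm_specs))
    stop_config(sprintf("unknown GLM spec '%s'", spec_id))
  sp <- glm_specs[[spec_id]]
  control_d <- match.arg(control_d)
  records <- as.data.frame(records)
  if (!participant %in% names(records)) records[[participant]] <- 1L
  if (!is.null(difficulty)) records$difficulty <- difficulty
  if (!is.null(subjdiff)) records$subjdiff <- subjdiff
  if (spec_id == "4" && !"subjdiff" %in% names(records))
    records$subjdiff <- records$hv - records$lv
  if (isTRUE(sp$response) && is.null(response))
    stop_config(sprintf("GLM%s needs a 'response' column name", spec_id))
  if (control_d == "mean" && "d" %in% names(records)) {
    miss <- is.na(records$d)
    records$d[miss] <- mean(records$d[!miss])
  }

  all_terms <- c(sp$step1, sp$step2)
  needed <- term_components(all_terms)
  pids <- unique(records[[participant]])
  coefs <- list(); diags <- list(); masks <- list()

  for (pid in pids) {
    rows <- which(records[[participant]] == pid)
    s <- records[rows, , drop = FALSE]
    mask <- default_mask(s, spec_id)
    for (nm in needed) {
      v <- tryCatch(base_term(nm, s), error = function(e) e)
      if (inherits(v, "error")) stop(v)
      mask <- mask & !is.na(v)
    }
    if (!is.null(response)) mask <- mask & !is.na(s[[response]])
    s <- s[mask, , drop = FALSE]
    masks[[as.character(pid)]] <- rows[mask]

    res <- fit_one_glm(s, sp, spec_id, response)
    coefs[[as.character(pid)]] <- res$coef
    diags[[as.character(pid)]] <- data.frame(
      participant = pid, n = nrow(s), loglik = res$loglik,
      bic = res$k * log(max(nrow(s), 1)) - 2 * res$loglik,
      converged = res$converged, separation = res$separation,
      excluded = res$excluded, reason = res$reason,
      stringsAsFactors = FALSE)
  }

  cn <- unique(unlist(lapply(coefs, names)))
  B <- t(vapply(coefs, function(x) x[cn], numeric(length(cn))))
  rownames(B) <- names(coefs); colnames(B) <- cn
  structure(list(spec = spec_id, type = sp$type, response = response,
                 coefficients = B,
                 diagnostics = do.call(rbind, diags),
                 masks = masks),
            class = "drglm")
}

fit_one_glm <- function(s, sp, spec_id, response) {
  empty <- function(reason) {
    terms <- c("(Intercept)", sp$step1, if (!is.null(sp$step2)) sp$step2)
    list(coef = stats::setNames(rep(NA_real_, length(terms)), terms),
         loglik = NA_real_, k = NA_real_, converged = FALSE,
         separation = FALSE, excluded = TRUE, reason = reason)
  }
  if (nrow(s) < length(sp$step1) + 2L) return(empty("too few trials"))

  if (sp$type == "multinomial") {
    if (sum(s$choice == "D") < 3L)
      return(empty("fewer than 3 distractor choices"))
    X <- design_matrix(sp$step1, s)
    res <- fit_multinomial(X, s$choice)
    excluded <- abs(res$d_intercept) > 10
    return(c(res[c("coef", "loglik", "k", "converged", "separation")],
             list(excluded = excluded,
                  reason = if (excluded) "|beta| > 10 on D contrast intercept" else "")))
  }

  y <- if (isTRUE(sp$response)) as.numeric(s[[response]]) else s$accuracy
  fam1 <- sp$step1_family %||%
    (if (sp$type == "linear") "linear" else "binomial")
  if (fam1 == "binomial" && length(unique(y)) < 2L)
    return(empty("constant response"))

  X1 <- design_matrix(sp$step1, s)
  f1 <- if (fam1 == "binomial") fit_logistic(X1, y) else fit_linear(X1, y)

  if (sp$type != "stepwise") {
    return(c(f1[c("coef", "loglik", "k", "converged", "separation")],
             list(excluded = FALSE, reason = "")))
  }

  # Step 2: OLS of response-scale residuals on the step-2 regressors.
  resid1 <- y - f1$fitted
  X2 <- design_matrix(sp$step2, s)
  f2 <- fit_linear(X2, resid1)
  cf1 <- f1$coef
  names(cf1) <- c("step1_(Intercept)", paste0("step1_", sp$step1))
  cf2 <- f2$coef
  names(cf2) <- c("(Intercept)", sp$step2)
  list(coef = c(cf2, cf1), loglik = f1$loglik, k = f1$k,
       converged = f1$converged && f1$k > 0, separation = f1$separation,
       excluded = FALSE, reason = "")
}

#' @export
print.drglm <- function(x, ...) {
  cat(sprintf("GLM%s (%s), %d participants (%d excluded)\n", x$spec, x$type,
              nrow(x$coefficients), sum(x$diagnostics$excluded)))
  if (sum(!x$diagnostics$excluded) >= 2L) print(group_test(x))
  else print(x$coefficients)
  invisible(x)
}

#' @export
coef.drglm <- function(object, ...) object$coefficients

included_betas <- function(fit, term) {
  keep <- !fit$diagnostics$excluded
  b <- fit$coefficients[keep, term]
  b[!is.na(b)]
}

#' Group-level test of GLM coefficients
#'
#' One-sample two-sided t-tests of the per-participant coefficients
#' against zero, excluding participants flagged by the fitting rules.
#' With `paired_with`, a paired t-test of the coefficient difference
#' between two fits (e.g. hard vs easy halves) is run over the common
#' participants instead.
#'
#' @param fit A `drglm` object.
#' @param terms Regressor names (default: all non-intercept terms).
#' @param paired_with Optional second `drglm` for a paired contrast.
#' @return A data frame of class `group_stats`: `term`, `mean_beta`, `t`,
#'   `df`, `p`, `n`.  Zero-variance coefficient sets yield `NA` test
#'   statistics.
#' @export
group_test <- function(fit, terms = NULL, paired_with = NULL) {
  stopifnot(inherits(fit, "drglm"))
  if (is.null(terms))
    terms <- setdiff(colnames(fit$coefficients),
                     grep("Intercept|^step1_", colnames(fit$coefficients),
                          value = TRUE))
  rows <- lapply(terms, function(tm) {
    if (is.null(paired_with)) {
      b <- included_betas(fit, tm)
    } else {
      b1 <- included_betas(fit, tm); b2 <- included_betas(paired_with, tm)
      common <- intersect(names(b1), names(b2))
      b <- b1[common] - b2[common]
    }
    if (length(b) < 2L)
      stop_config("group test needs at least 2 included participants")
    if (stats::sd(b) == 0)
      return(data.frame(term = tm, mean_beta = mean(b), t = NA_real_,
                        df = length(b) - 1L, p = NA_real_, n = length(b)))
    tt <- stats::t.test(b)
    data.frame(term = tm, mean_beta = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(b))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Median split by difficulty
#'
#' Splits each participant's trials at their median difficulty.  Trials
#' strictly below the median are "hard"; trials at or above it (including
#' ties at the median) are "easy".
#'
#' @param records A trial table.
#' @param difficulty Per-trial difficulty, aligned with `records`;
#'   defaults to `hv - lv`.
#' @param participant Participant id column name.
#' @return `list(hard = , easy = )` of the two record subsets (each
#'   retaining a `difficulty` column).
#' @export
median_split <- function(records, difficulty = NULL,
                         participant = "participant") {
  records <- as.data.frame(records)
  if (!participant %in% names(records)) records[[participant]] <- 1L
  if (is.null(difficulty)) difficulty <- records$hv - records$lv
  if (anyNA(difficulty))
    stop_config("difficulty must be defined for every trial")
  records$difficulty <- difficulty
  hard <- logical(nrow(records))
  for (pid in unique(records[[participant]])) {
    i <- records[[participant]] == pid
    di <- difficulty[i]
    if (length(unique(di)) < 2L)
      stop_config("cannot median-split constant difficulty")
    hard[i] <- di < stats::median(di)
  }
  list(hard = records[hard, , drop = FALSE],
       easy = records[!hard, , drop = FALSE])
}

#' Attribute-weighted difficulty index
#'
#' Builds the per-trial subjective difficulty used when participants
#' weight reward magnitude and probability additively rather than
#' multiplying them into expected values: the GLM3b coefficients
#' `(w1..w4)` of the z-scored magnitude difference/sum and probability
#' difference/sum are applied back to the same z-scored attribute columns,
#' `Difficulty = w1 z(dMag) + w2 z(sMag) + w3 z(dProb) + w4 z(sProb)`.
#' Participants whose GLM3b did not converge get `NA` with a warning.
#'
#' @param fit3b A `drglm` from `fit_glm(records, "3b")`.
#' @param records The same trial table the GLM was fitted on.
#' @param participant Participant id column name.
#' @return A numeric vector aligned with `records` rows, suitable as the
#'   `difficulty` argument of [fit_glm()] spec `"2c"`/`"2d"` or
#'   [median_split()].
#' @export
attribute_difficulty <- function(fit3b, records,
                                 participant = "participant") {
  stopifnot(inherits(fit3b, "drglm"), fit3b$spec == "3b")
  records <- as.data.frame(records)
  if (!participant %in% names(records)) records[[participant]] <- 1L
  terms <- c("mag_diff", "mag_sum", "prob_diff", "prob_sum")
  out <- rep(NA_real_, nrow(records))
  for (pid in rownames(fit3b$coefficients)) {
    i <- which(records[[participant]] == pid)
    if (!length(i)) next
    dg <- fit3b$diagnostics[fit3b$diagnostics$participant == pid, ]
    w <- fit3b$coefficients[pid, terms]
    if (anyNA(w) || !dg$converged[1]) {
      warning(sprintf("GLM3b did not converge for participant %s; difficulty is NA", pid))
      next
    }
    mask_rows <- fit3b$masks[[pid]]
    s_mask <- records[mask_rows, , drop = FALSE]
    val <- numeric(length(i))
    for (j in seq_along(terms)) {
      x_all <- base_term(terms[j], records[i, , drop = FALSE])
      x_ref <- base_term(terms[j], s_mask)
      val <- val + w[j] * (x_all - mean(x_ref)) / stats::sd(x_ref)
    }
    out[i] <- val
  }
  out
}

#' Compare BIC between two GLM fits
#'
#' Per-participant BIC difference `BIC(fit_b) - BIC(fit_a)` (negative
#' values favour `fit_b`) with a paired group t-test.  Both fits must
#' have been computed on identical trial masks.
#'
#' @param fit_a,fit_b `drglm` objects fitted to the same records (e.g.
#'   the value-based spec `"3a"` and the attribute-based `"3b"`).
#' @return A list with `delta_bic` (named per participant), `mean_delta`,
#'   `t`, `df`, `p`.
#' @export
compare_bic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "drglm"), inherits(fit_b, "drglm"))
  common <- intersect(names(fit_a$masks), names(fit_b$masks))
  for (pid in common)
    if (!identical(fit_a$masks[[pid]], fit_b$masks[[pid]]))
      stop_config("trial masks differ between the two fits")
  da <- fit_a$diagnostics; db <- fit_b$diagnostics
  keep <- common[!da$excluded[match(common, da$participant)] &
                   !db$excluded[match(common, db$participant)]]
  delta <- db$bic[match(keep, db$participant)] -
    da$bic[match(keep, da$participant)]
  names(delta) <- keep
  if (stats::sd(delta) == 0) {
    return(list(delta_bic = delta, mean_delta = mean(delta), t = NA_real_,
                df = length(delta) - 1L, p = NA_real_))
  }
  tt <- stats::t.test(delta)
  list(delta_bic = delta, mean_delta = mean(delta),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
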