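#' Random-effects Bayesian model selection
#'
#' Group-level comparison of candidate models from per-participant
#' (approximate) log model evidences, treating the model identity as a
#' random effect across participants.  The population model frequencies
#' are given a Dirichlet prior `Dir(alpha0)` and estimated by the
#' variational scheme of Stephan et al. (2009, NeuroImage 46:1004-1017):
#' participant-wise model responsibilities and the Dirichlet pseudo-counts
#' are updated alternately until the pseudo-counts converge.  Reported
#' are the posterior Dirichlet parameters `alpha`, the estimated model
#' frequencies `Ef = alpha / sum(alpha)`, and the exceedance probability
#' `Xp` of each model -- the posterior probability that it is the most
#' frequent model in the population, estimated by Monte-Carlo sampling of
#' the posterior Dirichlet.
#'
#' @param evidence A participants x models numeric matrix of log model
#'   evidences (column names label the models), or a list of lists of
#'   `accumulator_fit` objects.
#' @param alpha0 Symmetric Dirichlet prior count (default 1).
#' @param n_samples Dirichlet samples for the exceedance probability.
#' @param max_iter,tol Convergence control for the variational updates.
#' @return An object of class `bms`: `alpha`, `ef`, `xp`, `iterations`.
#' @examples
#' L <- matrix(c(0, 0, 0, 0, -3, -4, -2, -5), ncol = 2)  # model 1 wins
#' bms(L, n_samples = 1e4)
#' @export
bms <- function(evidence, alpha0 = 1, n_samples = 1e5, max_iter = 500,
                tol = 1e-8) {
  L <- as.matrix(evidence)
  if (!all(is.finite(L))) stop_config("log evidences must be finite")
  n <- nrow(L); m <- ncol(L)
  if (m < 2L) stop_config("need at least two models to compare")
  if (is.null(colnames(L))) colnames(L) <- paste0("model", seq_len(m))

  alpha <- rep(alpha0, m)
  for (it in seq_len(max_iter)) {
    lu <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu); g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (it == max_iter)
      stop_config(sprintf(
        "BMS did not converge in %d iterations (last max change %.2e)",
        max_iter, delta))
  }
  ef <- alpha / sum(alpha)
  samp <- rdirichlet(n_samples, alpha)
  winner <- max.col(samp, ties.method = "random")
  xp <- tabulate(winner, nbins = m) / n_samples
  structure(list(alpha = stats::setNames(alpha, colnames(L)),
                 ef = stats::setNames(ef, colnames(L)),
                 xp = stats::setNames(xp, colnames(L)),
                 iterations = it),
            class = "bms")
}

#' @export
print.bms <- function(x, digits = 3, ...) {
  cat("Random-effects Bayesian model selection\n")
  out <- rbind(alpha = x$alpha, Ef = x$ef, Xp = x$xp)
  print(round(out, digits))
  invisible(x)
}

#' Collect an evidence matrix from accumulator fits
#'
#' Convenience helper: given a list (participants) of named lists
#' (models) of [fit_accumulator()] results, builds the participants x
#' models log-evidence matrix consumed by [bms()].
#'
#' @param fits List of named lists of `accumulator_fit` objects.
#' @return A numeric matrix.
#' @export
evidence_matrix <- function(fits) {
  models <- names(fits[[1]])
  t(vapply(fits, function(fl) {
    vapply(fl[models], function(f) f$evidence, numeric(1))
  }, numeric(length(models))))
}
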