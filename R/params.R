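#' Accumulator parameters
#'
#' Bundles the parameters of an evidence-accumulation race: the drift gain
#' `d` (per second), the input noise `sigma` (standard deviation of the
#' Gaussian input, per square-root second), the feedforward inhibition level
#' `f`, the decision threshold, the non-decision time `t_nd` added to every
#' crossing time, the accumulation timeout after which a trial is recorded
#' as undecided, and the Euler--Maruyama step size `dt`.
#'
#' Per step of length `dt`, pool `i` draws an input increment
#' `E_i ~ Normal(d * V_i * dt, sigma^2 * dt)`; the common inhibition is
#' `f * sum(E) / k` over the `k` pools, and each pool accumulates
#' `E_i - I`.  With this discretisation `d` and `sigma` keep per-second
#' units and results are insensitive to `dt` (halving `dt` changes grid
#' accuracies by less than Monte-Carlo error).
#'
#' @param d Drift gain, s^-1.  Must be positive.
#' @param sigma Input noise standard deviation, s^-1/2.  Non-negative.
#' @param f Feedforward inhibition level in `[0, 1]`.  Default 0.5.
#' @param threshold Decision threshold in evidence units.  Default 1.
#' @param t_nd Non-decision time in seconds, added to the crossing time.
#'   Default 0.3.
#' @param timeout Maximum accumulation time in seconds (excluding `t_nd`);
#'   trials with no crossing are undecided.  Default 6.
#' @param dt Integration step in seconds.  Default 0.001.
#' @return An object of class `accumulator_params`.
#' @examples
#' accumulator_params(d = 1.3, sigma = 1)
#' @export
accumulator_params <- function(d, sigma, f = 0.5, threshold = 1,
                               t_nd = 0.3, timeout = 6, dt = 0.001) {
  check_scalar(d, "d", lower = 0, strict_lower = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(f, "f", lower = 0, upper = 1)
  check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  check_scalar(t_nd, "t_nd", lower = 0)
  check_scalar(timeout, "timeout", lower = 0, strict_lower = TRUE)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (timeout <= t_nd)
    stop_config("'timeout' must exceed 't_nd'")
  structure(list(d = d, sigma = sigma, f = f, threshold = threshold,
                 t_nd = t_nd, timeout = timeout, dt = dt),
            class = "accumulator_params")
}

#' @export
print.accumulator_params <- function(x, ...) {
  cat(sprintf(
    "Accumulator parameters: d = %g /s, sigma = %g, f = %g, threshold = %g,\n  t_nd = %g s, timeout = %g s, dt = %g s\n",
    x$d, x$sigma, x$f, x$threshold, x$t_nd, x$timeout, x$dt))
  invisible(x)
}
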