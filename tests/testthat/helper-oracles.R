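# Independent Monte-Carlo oracle for the race dynamics, written as a
# rep-vectorised R stepper (structurally unlike the per-trial C++ kernel).
# `kind` selects how the distractor enters; returns the choice (1 = HV,
# 2 = LV, 0 = none) of each repetition.
oracle_race <- function(v, d, sigma, f = 0.5, kind = c("mutual", "divnorm", "null"),
                        n = 1000, dt = 0.005, threshold = 1, timeout = 6) {
  kind <- match.arg(kind)
  drift <- switch(kind,
                  mutual = d * v,
                  divnorm = d * v[1:2] / sum(v),
                  null = d * v[1:2])
  k <- length(drift)
  y <- matrix(0, n, k)
  choice <- integer(n)
  alive <- rep(TRUE, n)
  for (s in seq_len(floor(timeout / dt + 1e-9))) {
    na <- sum(alive)
    if (na == 0L) break
    E <- matrix(stats::rnorm(na * k, mean = rep(drift * dt, each = na),
                             sd = sigma * sqrt(dt)), na, k)
    y[alive, ] <- y[alive, ] + E - f * rowMeans(E)
    crossed_hv <- y[, 1] >= threshold & alive
    crossed_lv <- y[, 2] >= threshold & alive
    both <- crossed_hv & crossed_lv
    if (any(both)) {
      coin <- stats::runif(sum(both)) < 0.5
      crossed_hv[both] <- coin
      crossed_lv[both] <- !coin
    }
    choice[crossed_hv] <- 1L
    choice[crossed_lv] <- 2L
    alive <- alive & !crossed_hv & !crossed_lv
  }
  choice
}

# Two-sided binomial confidence bound check: is the observed proportion
# consistent (at `level`) with the oracle's proportion given both sample
# sizes?
props_agree <- function(x1, n1, x2, n2, level = 0.99) {
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  abs(x1 / n1 - x2 / n2) <= stats::qnorm(1 - (1 - level) / 2) * se + 1e-12
}

# Small multi-participant behaviour cohort used across GLM tests.
make_behaviour_cohort <- function(n_participants, generator,
                                  n_trials = 60, valence = "gain", ...) {
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    sched <- generate_schedule(n_two_option = n_trials, n_distractor = n_trials,
                               valence = valence)
    cbind(generate_behaviour(sched, generator, ...), participant = i)
  }))
}
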