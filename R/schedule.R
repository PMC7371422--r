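#' Task attribute levels
#'
#' The reward magnitudes and probabilities from which every option in the
#' multi-attribute task is composed.  Magnitudes are in currency units
#' (2 to 12) and probabilities in percent (12.5 to 87.5).
#'
#' @return Numeric vectors of levels.
#' @export
task_magnitudes <- function() c(2, 4, 6, 8, 10, 12)

#' @rdname task_magnitudes
#' @export
task_probabilities <- function() c(12.5, 25, 37.5, 50, 62.5, 75, 87.5)

all_option_combos <- function() {
  g <- expand.grid(mag = task_magnitudes(), prob = task_probabilities(),
                   KEEP.OUT.ATTRS = FALSE)
  g$ev <- g$mag * g$prob / 100
  g
}

#' Generate a synthetic task schedule
#'
#' Builds a randomly interleaved schedule of two-option and distractor
#' trials for the multi-attribute task.  Options are (magnitude,
#' probability) combinations with expected value `EV = magnitude *
#' probability` (negated on loss trials, where all outcomes are losses and
#' the higher-value option is the one losing least).  When matching is on
#' (the default), every two-option trial's (HV, LV) configuration equals,
#' attribute for attribute, the choosable pair of exactly one distractor
#' trial.  The relative distractor value is controlled directly: each
#' distractor trial draws a uniform `D - HV` offset, snapped to the
#' nearest attainable EV, so distractor values span the decision space
#' (including trials with `D < LV` and with `D > HV`) while staying
#' uncorrelated with difficulty.  Loss schedules are gain schedules with
#' all outcomes negated (the option losing least is HV).  A random 15%
#' of trials carry a catch-trial flag, which is bookkeeping only and never
#' enters any analysis.
#'
#' @param n_two_option,n_distractor Trial counts per type; must be equal
#'   while `match_pairs` is `TRUE`.
#' @param valence `"gain"` or `"loss"`.
#' @param match_pairs Match two-option configurations exactly to
#'   distractor-trial pairs.
#' @param catch_rate Proportion of trials flagged as catch trials.
#' @return A data frame of class `trial_schedule` with columns `trial`,
#'   `trial_type` (`"TWO_OPTION"`/`"DISTRACTOR"`), per-option magnitude,
#'   probability and EV columns (`mag_hv`, `prob_hv`, `ev_hv`, ...; the
#'   `*_d` columns are `NA` on two-option trials), screen quadrants
#'   (`quad_hv`, `quad_lv`, `quad_d`), `valence`, and `catch_trial`.
#' @examples
#' set.seed(1)
#' sched <- generate_schedule()
#' table(sched$trial_type)
#' @export
generate_schedule <- function(n_two_option = 150, n_distractor = 150,
                              valence = c("gain", "loss"),
                              match_pairs = TRUE, catch_rate = 0.15) {
  valence <- match.arg(valence)
  if (match_pairs && n_two_option != n_distractor)
    stop_config("matched schedules need n_two_option == n_distractor; set match_pairs = FALSE otherwise")
  combos <- all_option_combos()
  # Loss schedules are gain schedules with negated outcomes, so everything
  # is generated in gain space and mirrored at the end (which also swaps
  # the HV/LV roles: the option losing least is the higher-value one).
  sgn <- 1

  draw_pairs <- function(n) {
    t(replicate(n, {
      repeat {
        ij <- sample.int(nrow(combos), 2L)
        if (combos$ev[ij[1]] != combos$ev[ij[2]]) break
      }
      ij
    }))
  }
  pairs <- draw_pairs(n_distractor)
  ev <- matrix(sgn * combos$ev[pairs], ncol = 2)
  hv_col <- ifelse(ev[, 1] >= ev[, 2], 1L, 2L)
  hv_i <- pairs[cbind(seq_len(n_distractor), hv_col)]
  lv_i <- pairs[cbind(seq_len(n_distractor), 3L - hv_col)]
  ev_hv <- sgn * combos$ev[hv_i]
  ev_lv <- sgn * combos$ev[lv_i]

  # The relative distractor value D - HV is controlled directly: each
  # trial draws a uniform offset, symmetric within the room the EV range
  # leaves around that trial's HV, and snaps it to the nearest attainable
  # EV (ties between attribute combinations with the same EV are sampled
  # at random).  Symmetric conditional offsets keep the relative
  # distractor value uncorrelated with the pair values across the
  # schedule while spanning the decision space, including trials with
  # D < LV and D > HV.
  ev_min <- min(combos$ev); ev_max <- max(combos$ev)
  draw_d <- function() {
    room <- pmin(3.5, ev_max - ev_hv, ev_hv - ev_min)
    off <- stats::runif(n_distractor, -room, room)
    target <- ev_hv + sgn * off
    vapply(target, function(tg) {
      i <- which(abs(sgn * combos$ev - tg) ==
                   min(abs(sgn * combos$ev - tg)))
      if (length(i) > 1) i <- sample(i, 1)
      i
    }, integer(1))
  }
  d_i <- draw_d()
  if (n_distractor >= 10) {
    for (tries in 1:100) {
      ev_d <- sgn * combos$ev[d_i]
      if (any(ev_d > ev_hv) && any(ev_d < ev_lv)) break
      d_i <- draw_d()
    }
    if (!(any(sgn * combos$ev[d_i] > ev_hv) && any(sgn * combos$ev[d_i] < ev_lv)))
      stop_config("could not build a schedule covering D > HV and D < LV")
  }
  ev_d <- sgn * combos$ev[d_i]

  quads <- t(replicate(n_distractor, sample.int(4L, 3L)))
  distractor <- data.frame(
    trial_type = "DISTRACTOR",
    mag_hv = combos$mag[hv_i], prob_hv = combos$prob[hv_i], ev_hv = ev_hv,
    mag_lv = combos$mag[lv_i], prob_lv = combos$prob[lv_i], ev_lv = ev_lv,
    mag_d = combos$mag[d_i], prob_d = combos$prob[d_i], ev_d = ev_d,
    quad_hv = quads[, 1], quad_lv = quads[, 2], quad_d = quads[, 3],
    stringsAsFactors = FALSE)

  if (match_pairs) {
    two <- distractor[seq_len(n_two_option), ]
  } else {
    p2 <- draw_pairs(n_two_option)
    ev2 <- matrix(sgn * combos$ev[p2], ncol = 2)
    hc <- ifelse(ev2[, 1] >= ev2[, 2], 1L, 2L)
    h2 <- p2[cbind(seq_len(n_two_option), hc)]
    l2 <- p2[cbind(seq_len(n_two_option), 3L - hc)]
    two <- data.frame(
      trial_type = "DISTRACTOR",
      mag_hv = combos$mag[h2], prob_hv = combos$prob[h2],
      ev_hv = sgn * combos$ev[h2],
      mag_lv = combos$mag[l2], prob_lv = combos$prob[l2],
      ev_lv = sgn * combos$ev[l2],
      mag_d = NA, prob_d = NA, ev_d = NA,
      quad_hv = NA, quad_lv = NA, quad_d = NA,
      stringsAsFactors = FALSE)
  }
  two$trial_type <- "TWO_OPTION"
  two$mag_d <- NA_real_; two$prob_d <- NA_real_; two$ev_d <- NA_real_
  q2 <- t(replicate(n_two_option, sample.int(4L, 2L)))
  two$quad_hv <- q2[, 1]; two$quad_lv <- q2[, 2]; two$quad_d <- NA_integer_

  sched <- rbind(two, distractor)
  sched <- sched[sample.int(nrow(sched)), ]
  rownames(sched) <- NULL
  sched <- cbind(trial = seq_len(nrow(sched)), sched)
  if (valence == "loss") {
    flipped <- sched
    for (suffix in c("mag_", "prob_", "ev_", "quad_")) {
      flipped[[paste0(suffix, "hv")]] <- sched[[paste0(suffix, "lv")]]
      flipped[[paste0(suffix, "lv")]] <- sched[[paste0(suffix, "hv")]]
    }
    sched <- flipped
    for (col in c("ev_hv", "ev_lv", "ev_d")) sched[[col]] <- -sched[[col]]
  }
  sched$valence <- valence
  sched$catch_trial <- stats::runif(nrow(sched)) < catch_rate
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Logistic choice-generator coefficients
#'
#' A coefficient-based behaviour generator: accuracy on each trial is drawn
#' from `Bernoulli(plogis(intercept + hv_lv * z(HV-LV) + d_hv * z(D-HV) +
#' interaction * z(HV-LV) z(D-HV)))`, with the z-scores computed over the
#' trials on which each term is defined.  On distractor trials the
#' distractor itself is chosen with probability `lapse_d` (before the
#' HV/LV draw), which is how attentional-capture choices are injected.
#'
#' @param intercept,hv_lv,d_hv,interaction Logistic coefficients.
#' @param lapse_d Probability of a distractor choice on distractor trials.
#' @return An object of class `choice_coefficients`.
#' @export
choice_coefficients <- function(intercept = 0, hv_lv = 0, d_hv = 0,
                                interaction = 0, lapse_d = 0) {
  check_scalar(lapse_d, "lapse_d", lower = 0, upper = 1)
  structure(list(intercept = intercept, hv_lv = hv_lv, d_hv = d_hv,
                 interaction = interaction, lapse_d = lapse_d),
            class = "choice_coefficients")
}

#' Generate behaviour for a schedule
#'
#' Produces per-trial choices, reaction times and accuracies for a task
#' schedule, either from an accumulator model (distractor trials use the
#' full model, two-option trials its [two_option_model()] reduction, and
#' EVs are rescaled into the model's value range by `value_scale`), or
#' from a [choice_coefficients()] logistic generator.  Simulated responses
#' slower than `deadline` are recorded as misses (`choice = "NONE"`).
#'
#' @param schedule A [generate_schedule()] table.
#' @param generator An `accumulator_model` or a `choice_coefficients`
#'   object.
#' @param value_scale Multiplier mapping EVs into accumulator value units
#'   (model generators only).  The default 0.5 places task EVs (0.25 to
#'   10.5) in the range spanned by the decision-space grid.
#' @param deadline Response deadline in seconds.
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters for the
#'   coefficient generator (which does not model latencies mechanistically).
#' @return A data frame of class `behaviour_records`: the schedule columns
#'   plus `hv`, `lv`, `d` (EV-scale option values), `choice`
#'   (`"HV"`, `"LV"`, `"D"`, `"NONE"`), `rt` and `accuracy` (1/0 when HV
#'   or LV was chosen, otherwise `NA`).
#' @examples
#' set.seed(1)
#' sched <- generate_schedule(n_two_option = 20, n_distractor = 20)
#' beh <- generate_behaviour(sched, choice_coefficients(1, 1.5, lapse_d = 0.05))
#' mean(beh$accuracy, na.rm = TRUE)
#' @export
generate_behaviour <- function(schedule, generator, value_scale = 0.5,
                               deadline = 1.5, rt_meanlog = log(0.65),
                               rt_sdlog = 0.25) {
  n <- nrow(schedule)
  out <- as.data.frame(schedule)
  out$hv <- schedule$ev_hv; out$lv <- schedule$ev_lv; out$d <- schedule$ev_d
  is_dis <- schedule$trial_type == "DISTRACTOR"
  choice <- character(n); rt <- rep(NA_real_, n)

  if (inherits(generator, "choice_coefficients")) {
    hvlv <- out$hv - out$lv
    z1 <- if (length(unique(hvlv)) > 1) zscore(hvlv) else rep(0, n)
    z2 <- numeric(n)
    if (any(is_dis)) {
      dv <- (out$d - out$hv)[is_dis]
      z2[is_dis] <- if (length(unique(dv)) > 1) zscore(dv) else 0
    }
    eta <- generator$intercept + generator$hv_lv * z1 +
      generator$d_hv * z2 + generator$interaction * z1 * z2
    p <- invlogit(eta)
    if (all(p < 1e-8 | p > 1 - 1e-8))
      warning("generator probabilities are all 0 or 1; expect separation downstream")
    correct <- stats::runif(n) < p
    choice <- ifelse(correct, "HV", "LV")
    lapse <- is_dis & stats::runif(n) < generator$lapse_d
    choice[lapse] <- "D"
    rt <- pmin(stats::rlnorm(n, rt_meanlog, rt_sdlog), deadline * 0.99)
  } else if (inherits(generator, "accumulator_model")) {
    if (all(schedule$valence == "loss"))
      stop_config("loss schedules are not simulated by the accumulator models")
    vals <- data.frame(hv = out$hv * value_scale, lv = out$lv * value_scale,
                       d = out$d * value_scale)
    choice <- rep("NONE", n); rt <- rep(NA_real_, n)
    if (any(is_dis)) {
      sim <- simulate_trials(generator, vals[is_dis, ])
      choice[is_dis] <- sim$choice; rt[is_dis] <- sim$rt
    }
    if (any(!is_dis)) {
      sim2 <- simulate_trials(two_option_model(generator), vals[!is_dis, ])
      choice[!is_dis] <- sim2$choice; rt[!is_dis] <- sim2$rt
    }
    late <- !is.na(rt) & rt > deadline
    choice[late] <- "NONE"; rt[late] <- NA_real_
  } else {
    stop_config("'generator' must be an accumulator_model or choice_coefficients")
  }

  out$choice <- choice
  out$rt <- rt
  out$accuracy <- ifelse(choice == "HV", 1L,
                         ifelse(choice == "LV", 0L, NA_integer_))
  class(out) <- c("behaviour_records", "data.frame")
  out
}

behaviour_vocab <- list(
  trial_type = c("TWO_OPTION", "DISTRACTOR"),
  choice = c("HV", "LV", "D", "NONE"),
  valence = c("gain", "loss"))

mandatory_behaviour_cols <- c("trial_type", "ev_hv", "ev_lv", "choice")

validate_behaviour <- function(records) {
  for (col in mandatory_behaviour_cols)
    if (!col %in% names(records))
      stop_config(sprintf("behaviour table is missing mandatory column '%s'", col))
  for (col in intersect(names(behaviour_vocab), names(records))) {
    bad <- setdiff(unique(stats::na.omit(records[[col]])), behaviour_vocab[[col]])
    if (length(bad))
      stop_config(sprintf("invalid %s value(s): %s", col,
                          paste(bad, collapse = ", ")))
  }
  if (any(records$choice == "D" & records$trial_type == "TWO_OPTION",
          na.rm = TRUE))
    stop_config("distractor choice recorded on a TWO_OPTION trial")
  invisible(records)
}

#' Read and write behavioural trial tables
#'
#' CSV round-trip for behaviour records.  `read_behaviour()` validates the
#' mandatory columns (`trial_type`, `ev_hv`, `ev_lv`, `choice`) and the
#' categorical vocabularies, preserves unknown columns, and reconstructs
#' `hv`/`lv`/`d` and `accuracy` when absent.  Deposited data sets whose
#' column names differ can be ingested through `aliases`: a named
#' character vector (or path to a YAML file of the same shape) mapping
#' canonical names to the file's column names.
#'
#' @param path CSV file path.
#' @param aliases Optional named character vector `c(canonical = "file_col")`
#'   or path to a YAML file encoding that mapping.
#' @param records A behaviour table as produced by [generate_behaviour()].
#' @return `read_behaviour()` returns a validated `behaviour_records` data
#'   frame; `write_behaviour()` invisibly returns `path`.
#' @export
read_behaviour <- function(path, aliases = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(aliases)) {
    if (is.character(aliases) && is.null(names(aliases)) &&
        length(aliases) == 1L)
      aliases <- unlist(yaml::read_yaml(aliases))
    for (canon in names(aliases)) {
      old <- aliases[[canon]]
      if (old %in% names(records))
        names(records)[names(records) == old] <- canon
    }
  }
  validate_behaviour(records)
  if (!"hv" %in% names(records)) records$hv <- records$ev_hv
  if (!"lv" %in% names(records)) records$lv <- records$ev_lv
  if (!"d" %in% names(records) && "ev_d" %in% names(records))
    records$d <- records$ev_d
  if (!"accuracy" %in% names(records))
    records$accuracy <- ifelse(records$choice == "HV", 1L,
                               ifelse(records$choice == "LV", 0L, NA_integer_))
  class(records) <- c("behaviour_records", "data.frame")
  records
}

#' @rdname read_behaviour
#' @export
write_behaviour <- function(records, path) {
  validate_behaviour(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
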