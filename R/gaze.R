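#' Area-of-interest screen layout
#'
#' The eye-tracking task presents each option as a pair of stimuli in one
#' quadrant of a 1920 x 1080 screen; the eight stimulus positions are 291
#' pixels from the screen centre and equally separated, and each carries
#' a square axis-aligned AOI of 300 x 300 pixels.  `aoi_layout()` builds
#' the eight AOIs and maps the two positions of each occupied quadrant to
#' its option.
#'
#' @param assignment Named integer vector giving the quadrant (1-4) of
#'   each option, e.g. `c(hv = 1, lv = 2, d = 3)` (quadrants are numbered
#'   counter-clockwise from the upper right).  Options may be omitted
#'   (two-option trials).
#' @param screen Screen size in pixels.
#' @param radius Distance of stimulus centres from screen centre (px).
#' @param aoi_size AOI side length (px).
#' @return A data frame of class `aoi_layout`: `position`, `quadrant`,
#'   `x`, `y` (AOI centre), and `option` (`"HV"`, `"LV"`, `"D"` or `NA`
#'   for unoccupied positions).
#' @export
aoi_layout <- function(assignment = c(hv = 1, lv = 2, d = 3),
                       screen = c(1920, 1080), radius = 291,
                       aoi_size = 300) {
  names(assignment) <- tolower(names(assignment))
  if (anyDuplicated(assignment))
    stop_config("options must occupy distinct quadrants")
  # Two positions per quadrant at 22.5 degrees either side of its centre.
  quad_centre <- c(45, 135, 225, 315)
  angles <- as.vector(rbind(quad_centre - 22.5, quad_centre + 22.5))
  quadrant <- rep(1:4, each = 2)
  opt_map <- stats::setNames(rep(NA_character_, 4), 1:4)
  for (opt in names(assignment))
    opt_map[as.character(assignment[[opt]])] <- toupper(opt)
  out <- data.frame(
    position = seq_along(angles),
    quadrant = quadrant,
    x = screen[1] / 2 + radius * cospi(angles / 180),
    y = screen[2] / 2 + radius * sinpi(angles / 180),
    option = unname(opt_map[as.character(quadrant)]),
    stringsAsFactors = FALSE)
  attr(out, "aoi_size") <- aoi_size
  attr(out, "screen") <- screen
  class(out) <- c("aoi_layout", "data.frame")
  out
}

# Which AOI (row of layout) contains each sample; NA when outside all.
# With the standard geometry AOIs cannot overlap; should two ever overlap
# the nearest centre wins.
locate_samples <- function(samples, layout) {
  half <- attr(layout, "aoi_size") / 2
  hit <- rep(NA_integer_, nrow(samples))
  dist <- rep(Inf, nrow(samples))
  for (i in seq_len(nrow(layout))) {
    dx <- abs(samples$x - layout$x[i]); dy <- abs(samples$y - layout$y[i])
    inside <- dx <= half & dy <= half
    d2 <- dx^2 + dy^2
    take <- inside & d2 < dist
    hit[take] <- i; dist[take] <- d2[take]
  }
  hit
}

#' Detect fixations from gaze samples
#'
#' A fixation is a maximal run of consecutive valid samples inside one
#' AOI lasting more than `min_duration` (50 ms by default).  Invalid
#' samples break runs unless `bridge_samples` allows short invalid gaps
#' to be bridged (off by default).  Trials whose overall sample validity
#' falls below `validity_threshold` are excluded: an empty fixation table
#' is returned with `attr(, "excluded") = TRUE` and a reason.
#'
#' @param samples Data frame with `t` (seconds), `x`, `y` (pixels) and
#'   logical `validity`, time-ordered.
#' @param layout An [aoi_layout()].
#' @param min_duration Minimum dwell, seconds (exclusive).
#' @param validity_threshold Minimum fraction of valid samples for the
#'   trial to be analysed (0.85 by default; 0.70 in relaxed mode).
#' @param bridge_samples Number of consecutive invalid samples that may
#'   be bridged within a run (0 = conservative).
#' @return A data frame with one row per fixation: `option`, `onset`,
#'   `duration` (seconds); attributes `validity` and `excluded`.
#' @export
detect_fixations <- function(samples, layout, min_duration = 0.05,
                             validity_threshold = 0.85,
                             bridge_samples = 0) {
  stopifnot(all(c("t", "x", "y", "validity") %in% names(samples)))
  if (is.unsorted(samples$t)) stop_config("samples must be time-ordered")
  validity <- mean(samples$validity)
  empty <- data.frame(option = character(), onset = numeric(),
                      duration = numeric(), stringsAsFactors = FALSE)
  if (validity < validity_threshold) {
    attr(empty, "validity") <- validity
    attr(empty, "excluded") <- TRUE
    attr(empty, "reason") <- sprintf(
      "trial validity %.2f below threshold %.2f", validity,
      validity_threshold)
    return(empty)
  }
  hit <- locate_samples(samples, layout)
  opt <- layout$option[hit]
  state <- ifelse(samples$validity & !is.na(opt), opt, NA_character_)
  if (bridge_samples > 0) {
    run <- rle(is.na(state))
    pos <- cumsum(c(1, run$lengths))
    for (r in which(run$values & run$lengths <= bridge_samples)) {
      if (r == 1 || r == length(run$values)) next
      i0 <- pos[r]; i1 <- pos[r + 1] - 1
      before <- state[i0 - 1]; after <- state[i1 + 1]
      invalid_gap <- !samples$validity[i0:i1]
      if (all(invalid_gap) && identical(before, after))
        state[i0:i1] <- before
    }
  }
  dt_med <- stats::median(diff(samples$t))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- !is.na(runs$values)
  fix <- data.frame(option = runs$values[keep],
                    onset = samples$t[starts[keep]],
                    duration = runs$lengths[keep] * dt_med,
                    stringsAsFactors = FALSE)
  fix <- fix[fix$duration > min_duration, , drop = FALSE]
  rownames(fix) <- NULL
  attr(fix, "validity") <- validity
  attr(fix, "excluded") <- FALSE
  fix
}

#' Gaze features for the shift regressions
#'
#' Counts per-trial fixations on each option and transitions between
#' consecutive fixations, both directed (e.g. `shift_d_hv` = D-to-HV)
#' and bidirectional (`shift_b_hv_d = shift_hv_d + shift_d_hv`).
#'
#' @param fixations Time-ordered fixation table from
#'   [detect_fixations()].
#' @return A one-row data frame: `fix_hv`, `fix_lv`, `fix_d`, the six
#'   directed shift counts, the three bidirectional counts, and
#'   `n_shifts`.
#' @examples
#' f <- data.frame(option = c("D", "HV", "D", "LV"),
#'                 onset = 1:4 / 10, duration = 0.06)
#' gaze_features(f)
#' @export
gaze_features <- function(fixations) {
  cnt <- function(o) sum(fixations$option == o)
  seqs <- fixations$option
  from <- seqs[-length(seqs)]; to <- seqs[-1]
  if (length(seqs) < 2L) from <- to <- character(0)
  dir_cnt <- function(a, b) sum(from == a & to == b)
  out <- data.frame(
    fix_hv = cnt("HV"), fix_lv = cnt("LV"), fix_d = cnt("D"),
    shift_d_hv = dir_cnt("D", "HV"), shift_d_lv = dir_cnt("D", "LV"),
    shift_hv_d = dir_cnt("HV", "D"), shift_lv_d = dir_cnt("LV", "D"),
    shift_lv_hv = dir_cnt("LV", "HV"), shift_hv_lv = dir_cnt("HV", "LV"))
  out$shift_b_hv_lv <- out$shift_hv_lv + out$shift_lv_hv
  out$shift_b_hv_d <- out$shift_hv_d + out$shift_d_hv
  out$shift_b_lv_d <- out$shift_lv_d + out$shift_d_lv
  out$n_shifts <- length(from)
  # directed shift proportions over all shifts (the response used by the
  # directional variant of the shift regression)
  tot <- max(out$n_shifts, 1L)
  for (nm in c("shift_d_hv", "shift_d_lv", "shift_hv_d", "shift_lv_d"))
    out[[paste0("p_", nm)]] <-
      if (out$n_shifts > 0) out[[nm]] / tot else NA_real_
  out
}

#' Synthetic gaze policy
#'
#' Parameters of the synthetic gaze generator: a Markov chain over the
#' options present on a trial, with dwell times per fixation, a
#' value-attraction weight on transition probabilities, and a dedicated
#' coupling that makes leaving the distractor towards HV more likely when
#' the distractor is valuable (the structure probed by the shift
#' regressions).
#'
#' @param dwell_mean,dwell_sd Mean and SD of fixation dwell, seconds.
#' @param attract_weight Weight of an option's value in the transition
#'   softmax.
#' @param d_to_hv_coupling Added log-odds per value unit of D for the
#'   D-to-HV transition.
#' @param dropout Probability that a sample is invalid.
#' @return A list of class `gaze_policy`.
#' @export
gaze_policy <- function(dwell_mean = 0.25, dwell_sd = 0.08,
                        attract_weight = 0, d_to_hv_coupling = 0,
                        dropout = 0) {
  structure(list(dwell_mean = dwell_mean, dwell_sd = dwell_sd,
                 attract_weight = attract_weight,
                 d_to_hv_coupling = d_to_hv_coupling, dropout = dropout),
            class = "gaze_policy")
}

#' Generate synthetic gaze samples for one trial
#'
#' Simulates 300 Hz gaze samples during the decision phase of a trial:
#' fixations alternate between the options under the policy's Markov
#' chain, samples sit at the fixated AOI centre, and a `dropout` fraction
#' of samples is marked invalid (and displaced off-screen).
#'
#' @param values Named numeric vector of the option values present, e.g.
#'   `c(hv = 3, lv = 1, d = 2)`; omit `d` on two-option trials.
#' @param layout An [aoi_layout()] whose options cover `names(values)`.
#' @param policy A [gaze_policy()].
#' @param duration Decision-phase duration, seconds.
#' @param rate Sampling rate, Hz.
#' @return A samples data frame (`t`, `x`, `y`, `validity`) suitable for
#'   [detect_fixations()].
#' @export
generate_gaze <- function(values, layout, policy = gaze_policy(),
                          duration = 2, rate = 300) {
  opts <- toupper(names(values))
  present <- opts[opts %in% layout$option]
  if (!length(present)) stop_config("no option in 'values' appears in the layout")
  v <- as.numeric(values)[match(present, opts)]
  names(v) <- present

  trans_prob <- function(cur) {
    cand <- setdiff(present, cur)
    if (!length(cand)) return(stats::setNames(1, cur))
    lw <- policy$attract_weight * v[cand]
    if (identical(cur, "D") && "HV" %in% cand)
      lw[cand == "HV"] <- lw[cand == "HV"] + policy$d_to_hv_coupling * v[["D"]]
    w <- exp(lw - max(lw))
    stats::setNames(w / sum(w), cand)
  }

  cur <- sample(present, 1)
  t_now <- 0; fix_opt <- character(0); fix_dur <- numeric(0)
  while (t_now < duration) {
    dur <- max(0.03, stats::rnorm(1, policy$dwell_mean, policy$dwell_sd))
    fix_opt <- c(fix_opt, cur); fix_dur <- c(fix_dur, dur)
    t_now <- t_now + dur
    pr <- trans_prob(cur)
    cur <- sample(names(pr), 1, prob = pr)
  }
  fix_dur[length(fix_dur)] <- fix_dur[length(fix_dur)] -
    (t_now - duration)

  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  which_fix <- findInterval(t, cumsum(c(0, fix_dur)), rightmost.closed = TRUE)
  which_fix[which_fix > length(fix_opt)] <- length(fix_opt)
  opt_at <- fix_opt[which_fix]
  pos <- vapply(opt_at, function(o) {
    rows <- which(layout$option == o)
    r <- rows[1]
    c(layout$x[r], layout$y[r])
  }, numeric(2))
  valid <- stats::runif(n) >= policy$dropout
  data.frame(t = t,
             x = ifelse(valid, pos[1, ], -1e4),
             y = ifelse(valid, pos[2, ], -1e4),
             validity = valid)
}

#' Simulate a gaze experiment over a behaviour table
#'
#' Generates synthetic gaze for every distractor trial of a behaviour
#' table, extracts fixation features, and appends the feature columns
#' needed by the fixation and shift regressions (specs `"7"`-`"9"` of
#' [fit_glm()]).  Trials excluded by the validity criterion get `NA`
#' features.
#'
#' @param records A `behaviour_records` table.
#' @param policy A [gaze_policy()].
#' @param layout_for Function of a record row returning an
#'   [aoi_layout()]; the default assigns quadrants from the `quad_*`
#'   columns when present.
#' @param duration Decision-phase duration per trial, seconds.
#' @param validity_threshold Passed to [detect_fixations()].
#' @return `records` with the [gaze_features()] columns appended, plus
#'   `gaze_valid`.
#' @export
simulate_gaze_experiment <- function(records, policy = gaze_policy(),
                                     layout_for = NULL, duration = 2,
                                     validity_threshold = 0.85) {
  records <- as.data.frame(records)
  if (is.null(layout_for)) {
    layout_for <- function(row) {
      if (!is.null(row$quad_hv) && !is.na(row$quad_hv) &&
          !is.na(row$quad_d %||% NA))
        aoi_layout(c(hv = row$quad_hv, lv = row$quad_lv, d = row$quad_d))
      else aoi_layout()
    }
  }
  feat_names <- names(gaze_features(
    data.frame(option = "HV", onset = 0, duration = 0.06)))
  feats <- matrix(NA_real_, nrow(records), length(feat_names),
                  dimnames = list(NULL, feat_names))
  gaze_valid <- rep(NA, nrow(records))
  is_dis <- records$trial_type == "DISTRACTOR"
  for (i in which(is_dis)) {
    row <- records[i, ]
    lay <- layout_for(row)
    vals <- c(hv = row$hv, lv = row$lv, d = row$d)
    samples <- generate_gaze(vals, lay, policy, duration = duration)
    fix <- detect_fixations(samples, lay,
                            validity_threshold = validity_threshold)
    gaze_valid[i] <- !isTRUE(attr(fix, "excluded"))
    if (gaze_valid[i] && nrow(fix))
      feats[i, ] <- as.numeric(gaze_features(fix)[1, feat_names])
  }
  cbind(records, as.data.frame(feats), gaze_valid = gaze_valid)
}
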