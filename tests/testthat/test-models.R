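test_that("noise-free crossing times match the closed form for all models", {
  # mutual inhibition: y_HV rate = 1 * (3 - 0.5 * 6 / 3) = 2 /s
  out <- simulate_trials(mutual_inhibition_model(d = 1, sigma = 0),
                         c(hv = 3, lv = 1, d = 2))
  expect_equal(out$choice, "HV")
  expect_equal(out$rt, 0.5 + 0.3, tolerance = 1e-9)

  # divisive normalisation: rate = (3 - 0.5 * 4 / 2) / 6 = 1/3 /s
  out <- simulate_trials(divisive_normalisation_model(d = 1, sigma = 0),
                         c(hv = 3, lv = 1, d = 2))
  expect_equal(out$choice, "HV")
  expect_lte(abs(out$rt - 3.3), 0.001 + 1e-9)   # within one dt

  # null model on a pair: rate = 3 - 0.5 * 4 / 2 = 2 /s
  out <- simulate_trials(null_model(d = 1, sigma = 0), c(hv = 3, lv = 1))
  expect_equal(out$choice, "HV")
  expect_equal(out$rt, 0.8, tolerance = 1e-9)

  # dual route: mutual route crosses at 0.5 s, divnorm at 3.0 s
  out <- simulate_trials(
    dual_route_model(d_mutual = 1, sigma_mutual = 0,
                     d_divnorm = 1, sigma_divnorm = 0),
    c(hv = 3, lv = 1, d = 2))
  expect_equal(out$route, "mutual")
  expect_equal(out$rt, 0.8, tolerance = 1e-9)

  # dual route with a vanishing mutual drift: only the divnorm route moves
  out <- simulate_trials(
    dual_route_model(d_mutual = 1e-4, sigma_mutual = 0,
                     d_divnorm = 1, sigma_divnorm = 0),
    c(hv = 3, lv = 1, d = 2))
  expect_equal(out$route, "divnorm")
  expect_lte(abs(out$rt - 3.3), 0.001 + 1e-9)
})

test_that("vanishing drift with zero noise leaves the trial undecided", {
  out <- simulate_trials(mutual_inhibition_model(d = 1e-6, sigma = 0),
                         c(hv = 3, lv = 1, d = 2))
  expect_false(out$decided)
  expect_equal(out$choice, "NONE")
  expect_true(is.na(out$rt))

  # divnorm needing 30 s > 6 s timeout
  out <- simulate_trials(divisive_normalisation_model(d = 0.1, sigma = 0),
                         c(hv = 3, lv = 1, d = 2))
  expect_false(out$decided)
})

test_that("invalid configurations and values are rejected", {
  expect_error(accumulator_params(d = 1, sigma = 1, dt = 0), "'dt'")
  expect_error(accumulator_params(d = 0, sigma = 1), "'d'")
  expect_error(accumulator_params(d = 1, sigma = 1, f = 1.5), "'f'")
  expect_error(accumulator_params(d = 1, sigma = 1, timeout = 0.2),
               "timeout")
  expect_error(simulate_trials(mutual_inhibition_model(), c(hv = 3, lv = 1)),
               "distractor value")
  expect_error(simulate_trials(divisive_normalisation_model(),
                               c(hv = 2, lv = 1, d = -3)),
               "sum to 0")
  expect_error(simulate_trials(null_model(), c(hv = 1, lv = 2)),
               "at least")
})

test_that("the null model is invariant to the distractor value by construction", {
  vals1 <- data.frame(hv = c(3, 2.5), lv = c(1, 1.5), d = c(0, 0))
  vals2 <- transform(vals1, d = c(100, 7))
  set.seed(42); out1 <- simulate_trials(null_model(), vals1, n_reps = 20)
  set.seed(42); out2 <- simulate_trials(null_model(), vals2, n_reps = 20)
  expect_equal(out1[c("choice", "rt", "decided")],
               out2[c("choice", "rt", "decided")])
})

test_that("simulated accuracy matches an independent Monte-Carlo oracle", {
  n <- 4000
  set.seed(101)
  # mutual inhibition at the spec'd oracle condition
  sim <- simulate_trials(mutual_inhibition_model(d = 1.3, sigma = 1, dt = 0.005),
                         c(hv = 2.3, lv = 1.1, d = 2.0), n_reps = n)
  orc <- oracle_race(c(2.3, 1.1, 2.0), d = 1.3, sigma = 1, kind = "mutual",
                     n = n, dt = 0.005)
  expect_true(props_agree(sum(sim$choice == "HV"), sum(sim$decided),
                          sum(orc == 1), sum(orc > 0)))

  # null model
  sim <- simulate_trials(null_model(d = 1.3, sigma = 1, dt = 0.005),
                         c(hv = 2.5, lv = 1.5), n_reps = n)
  orc <- oracle_race(c(2.5, 1.5), d = 1.3, sigma = 1, kind = "null",
                     n = n, dt = 0.005)
  expect_true(props_agree(sum(sim$choice == "HV"), sum(sim$decided),
                          sum(orc == 1), sum(orc > 0)))

  # divisive normalisation
  sim <- simulate_trials(divisive_normalisation_model(dt = 0.005),
                         c(hv = 3, lv = 1, d = 2), n_reps = n)
  orc <- oracle_race(c(3, 1, 2), d = 5.5, sigma = 0.6, kind = "divnorm",
                     n = n, dt = 0.005)
  expect_true(props_agree(sum(sim$choice == "HV"), sum(sim$decided),
                          sum(orc == 1), sum(orc > 0)))
})

test_that("distractor value shifts accuracy in opposite directions across models", {
  set.seed(202)
  n <- 6000
  acc_at <- function(model, d_val) {
    sim <- simulate_trials(model, c(hv = 3, lv = 1, d = d_val), n_reps = n)
    mean(sim$choice[sim$decided] == "HV")
  }
  # divisive normalisation: accuracy non-increasing in D
  m <- divisive_normalisation_model(dt = 0.002)
  acc_dn <- vapply(c(0.1, 3, 6), function(dv) acc_at(m, dv), numeric(1))
  expect_lt(acc_dn[3], acc_dn[1])
  expect_true(all(diff(acc_dn) < 0.01))   # monotone within MC noise
  # mutual inhibition: accuracy non-decreasing in D
  m <- mutual_inhibition_model(dt = 0.002)
  acc_mi <- vapply(c(0.1, 3, 6), function(dv) acc_at(m, dv), numeric(1))
  expect_gt(acc_mi[3], acc_mi[1])
  expect_true(all(diff(acc_mi) > -0.01))
})

test_that("accuracy is non-decreasing in the value difference for every model", {
  set.seed(303)
  n <- 4000
  models <- list(mutual_inhibition_model(dt = 0.002),
                 divisive_normalisation_model(dt = 0.002),
                 dual_route_model(dt = 0.002),
                 null_model(dt = 0.002))
  for (m in models) {
    accs <- vapply(c(0.6, 1.3, 2.0), function(diff) {
      v <- c(hv = 2 + diff / 2, lv = 2 - diff / 2, d = 2.5)
      sim <- simulate_trials(m, v, n_reps = n)
      mean(sim$choice[sim$decided] == "HV")
    }, numeric(1))
    expect_gt(accs[3], accs[1])
    expect_true(all(diff(accs) > -0.01))
  }
})

test_that("the dual route outcome is the earlier of its two component routes", {
  grid <- value_grid(sums = c(3, 4.6), diffs = c(0.6, 1.6),
                     d_offsets = c(-1.2, 2, 4.8))
  vals <- grid[rep(seq_len(nrow(grid)), each = 30), c("hv", "lv", "d")]
  dual <- dual_route_model()
  set.seed(77)
  combined <- simulate_trials(dual, vals, cap_routes = FALSE)
  set.seed(77)
  mi <- simulate_trials(mutual_inhibition_model(d = 0.8, sigma = 0.6), vals)
  dn <- simulate_trials(divisive_normalisation_model(d = 1.0, sigma = 0.6), vals)
  dn_first <- dn$decided & (!mi$decided | (dn$rt < mi$rt))
  tie <- dn$decided & mi$decided & dn$rt == mi$rt
  expected_choice <- ifelse(dn_first, dn$choice, mi$choice)
  expected_rt <- ifelse(dn_first, dn$rt, mi$rt)
  free <- !tie
  expect_equal(combined$choice[free], expected_choice[free])
  expect_equal(combined$rt[free], expected_rt[free])
  expect_equal(combined$decided, mi$decided | dn$decided)
})

test_that("reaction times respect the non-decision time and timeout bounds", {
  set.seed(11)
  m <- mutual_inhibition_model(dt = 0.002)
  sim <- simulate_trials(m, c(hv = 2, lv = 1.8, d = 5), n_reps = 500)
  dec <- sim$decided
  expect_true(all(sim$rt[dec] > m$params$t_nd))
  expect_true(all(sim$rt[dec] <= m$params$timeout + m$params$t_nd))
  expect_true(all(is.na(sim$rt[!dec])))
  expect_true(all(sim$choice[!dec] == "NONE"))
  expect_false(any(sim$choice %in% "D"))
})

test_that("model configuration files round-trip through the constructor", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("kind: divnorm", "d: 4.2", "sigma: 0.7", "dt: 0.002"), cfg)
  m <- read_model_config(cfg)
  expect_equal(m$kind, "divnorm")
  expect_equal(m$params$d, 4.2)
  expect_equal(m$params$dt, 0.002)
  writeLines(c("d: 1"), cfg)
  expect_error(read_model_config(cfg), "kind")
})

test_that("the simulate method mirrors simulate_trials under a shared seed", {
  m <- mutual_inhibition_model()
  a <- simulate(m, nsim = 5, seed = 31, values = c(hv = 3, lv = 1, d = 2))
  set.seed(31)
  b <- simulate_trials(m, c(hv = 3, lv = 1, d = 2), n_reps = 5)
  expect_equal(a, b)
})

test_that("halving dt leaves accuracy unchanged within Monte-Carlo error", {
  set.seed(404)
  n <- 8000
  v <- c(hv = 2.6, lv = 1.4, d = 3)
  a1 <- simulate_trials(mutual_inhibition_model(dt = 0.004), v, n_reps = n)
  a2 <- simulate_trials(mutual_inhibition_model(dt = 0.002), v, n_reps = n)
  expect_true(props_agree(sum(a1$choice == "HV"), sum(a1$decided),
                          sum(a2$choice == "HV"), sum(a2$decided),
                          level = 0.999))
})
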