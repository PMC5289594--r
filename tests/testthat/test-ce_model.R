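zero_probs <- function(overrides = c()) {
  p <- stats::setNames(rep(0, 12), nmahesim:::TRANSITIONS)
  p[names(overrides)] <- overrides
  p
}

basic_costs <- list(maintenance = c(100, 200, 400), event = 1000,
                    oneoff = 0, per_cycle = 0)
basic_utils <- list(stage = c(1, 1, 1), event_decrement = 0)

test_that("run_markov handles degenerate chains exactly", {
  # identity transitions, utility 1, no events: LY = QALY = 1
  out <- run_markov(zero_probs(), basic_costs, basic_utils)
  expect_equal(out$ly, 1)
  expect_equal(out$qaly, 1)
  expect_equal(out$events, 0)
  expect_equal(sum(out$cycles), 12)
  # all-Death start: everything zero
  out2 <- run_markov(zero_probs(), basic_costs, basic_utils,
                     start = c(0, 0, 0, 1))
  expect_equal(out2$ly, 0)
  expect_equal(out2$qaly, 0)
  expect_equal(out2$total_cost, 0)
  expect_error(run_markov(zero_probs()[1:5], basic_costs, basic_utils),
               "missing")
})

test_that("run_markov reproduces a hand-computed two-cycle toy chain", {
  # start everyone Moderate; M->S 0.4, M->D 0.1; event in M 0.5, in S 0.2
  probs <- zero_probs(c(MS = 0.4, MD = 0.1, evM = 0.5, evS = 0.2))
  out <- run_markov(probs, basic_costs,
                    list(stage = c(0.8, 0.5, 0.2), event_decrement = 0.01),
                    cycles = 2, start = c(1, 0, 0, 0))
  # cycle 1: all in M; cycle 2: 0.5 M, 0.4 S, 0.1 D
  expect_equal(unname(out$cycles), c(1.5, 0.4, 0, 0.1))
  expect_equal(out$ly, 1.9 / 12)
  expect_equal(out$events, 1 * 0.5 + 0.5 * 0.5 + 0.4 * 0.2)
  want_qaly <- (1 * 0.8 + 0.5 * 0.8 + 0.4 * 0.5) / 12 - out$events * 0.01
  expect_equal(out$qaly, want_qaly)
  expect_equal(out$maintenance_cost, 100 * 1.5 + 200 * 0.4)
  expect_equal(out$event_cost, out$events * 1000)
})

test_that("cohort occupancy is conserved and matches the reference truth", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 20000, seed = 31)
  ref <- reference_outcomes(pop)
  # feed the model the true parameters with zero variance: the cohort
  # model should land close to the microsimulated incremental outcomes
  probs_usual <- ref$true_probs[, "Usual"]
  probs_new <- probs_usual * exp(ref$true_lnrr)
  probs_new[probs_new > 1] <- 1
  cu <- ref$true_cost_utility
  costs_u <- list(maintenance = unname(cu[1:3]), event = unname(cu["event_cost"]),
                  oneoff = 0, per_cycle = 60)
  costs_n <- costs_u; costs_n$per_cycle <- 350
  utils_ <- list(stage = unname(cu[c("util_Moderate", "util_Severe",
                                     "util_VerySevere")]),
                 event_decrement = unname(cu["event_decrement"]))
  mu <- run_markov(probs_usual, costs_u, utils_)
  mn <- run_markov(probs_new, costs_n, utils_)
  expect_equal(sum(mu$cycles), 12, tolerance = 1e-9)
  expect_equal(sum(mn$cycles), 12, tolerance = 1e-9)
  # structural approximation: cohort-vs-microsimulation gap stays moderate
  expect_lt(abs((mn$qaly - mu$qaly) - ref$incremental$delta_qaly), 0.02)
  expect_lt(abs((mn$total_cost - mu$total_cost) -
                  ref$incremental$delta_total_cost), 400)
})

test_that("draw_psa respects moments and degenerates to the means", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 3000, seed = 41)
  net <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 300),
                                seed = 19)
  ps <- model_parameter_set(net, "PUHAN")
  set.seed(1)
  d <- draw_psa(ps, 10000)
  m <- ps$baseline["SVS", "mean"]; s <- ps$baseline["SVS", "se"]
  expect_lt(abs(mean(d$baseline[, "SVS"]) - m), 4 * s / sqrt(10000))
  expect_lt(abs(sd(d$baseline[, "SVS"]) - s), 0.1 * s + 4 * s / sqrt(10000))
  ec <- ps$absolutes["event_cost", ]
  expect_lt(abs(mean(d$absolutes[, "event_cost"]) - ec["mean"]),
            4 * ec["se"] / sqrt(10000) + 1e-9)
  # zero-variance set: draws equal the means exactly
  ps0 <- ps
  ps0$baseline[, "se"] <- 0
  ps0$absolutes[, "se"] <- 0
  for (par in nmahesim:::TRANSITIONS) ps0$effects[[par]]$variance <- 0
  d0 <- draw_psa(ps0, 3)
  expect_equal(d0$baseline[1, ], d0$baseline[3, ])
  expect_equal(unname(d0$baseline[2, "MS"]), ps$baseline["MS", "mean"])
  expect_equal(unname(d0$lnrr[1, "SVS"]), ps$effects[["SVS"]]$point)
})

test_that("run_psa is deterministic, ordered and degenerate-safe", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 3000, seed = 41)
  net <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 300),
                                seed = 19)
  ps <- model_parameter_set(net, "SONG")
  psa <- run_psa(ps, n_iter = 150, seed = 7)
  psa2 <- run_psa(ps, n_iter = 150, seed = 7)
  expect_identical(psa$iterations, psa2$iterations)
  for (oc in colnames(psa$ci)) {
    expect_lte(psa$ci[1, oc], psa$means[oc])
    expect_gte(psa$ci[2, oc], psa$means[oc])
  }
  # zero-variance set: all iterations identical, zero-width intervals
  ps0 <- ps
  ps0$baseline[, "se"] <- 0
  ps0$absolutes[, "se"] <- 0
  for (par in nmahesim:::TRANSITIONS) ps0$effects[[par]]$variance <- 0
  psa0 <- run_psa(ps0, n_iter = 5, seed = 3)
  expect_equal(psa0$ci[1, "delta_qaly"], psa0$ci[2, "delta_qaly"])
  expect_equal(var(psa0$iterations$delta_qaly), 0)
})

test_that("vectorized PSA cohort agrees with the scalar Markov model", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 3000, seed = 41)
  net <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 300),
                                seed = 19)
  ps <- model_parameter_set(net, "SONG")
  psa <- run_psa(ps, 25, seed = 9)
  draws <- nmahesim:::with_seed(derive_seed(9, "psa", "New", "Usual"),
                                draw_psa(ps, 25))
  for (i in c(1, 12, 25)) {
    p0 <- draws$baseline[i, ]
    ab <- draws$absolutes[i, ]
    costs_c <- list(maintenance = ab[1:3], event = ab[["event_cost"]],
                    oneoff = 0, per_cycle = 60)
    costs_t <- costs_c
    costs_t$per_cycle <- 350
    utils_ <- list(stage = ab[c("util_Moderate", "util_Severe",
                                "util_VerySevere")],
                   event_decrement = ab[["event_decrement"]])
    comp <- run_markov(p0, costs_c, utils_)
    p1 <- p0 * exp(draws$lnrr[i, ])
    p1[p1 > 1] <- 1
    trt <- run_markov(p1, costs_t, utils_)
    expect_equal(psa$iterations$delta_qaly[i], trt$qaly - comp$qaly,
                 tolerance = 1e-12)
    expect_equal(psa$iterations$delta_total_cost[i],
                 trt$total_cost - comp$total_cost, tolerance = 1e-9)
  }
})

test_that("ceac counts positive net monetary benefit", {
  psa <- structure(list(iterations = data.frame(
    delta_qaly = c(0.1, 0.1, 0.1, 0.1),
    delta_total_cost = c(1000, 2000, 2500, 4000)
  )), class = "psa_result")
  # at 30,000/QALY the NMB signs are (+, +, +, -)
  expect_equal(ceac(psa, 30000)$probability, 0.75)
  expect_equal(ceac(psa, 0)$probability, 0)
  # monotone when all dQALY > 0
  curve <- ceac(psa, seq(0, 60000, 5000))
  expect_true(all(diff(curve$probability) >= 0))
})
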