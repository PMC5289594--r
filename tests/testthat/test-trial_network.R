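test_that("scenario definitions follow the heterogeneity table", {
  s1 <- scenario_spec(1)
  expect_true(all(s1$slots$filter == "none"))
  expect_equal(s1$n_per_arm, 500)
  s4 <- scenario_spec(4)
  expect_equal(which(s4$slots$filter != "none"), 8L)
  s7 <- scenario_spec(7)
  expect_equal(which(s7$slots$filter == "worse_health"), c(1L, 6L, 8L))
  s8 <- scenario_spec(8)
  expect_equal(which(s8$slots$filter == "worse_health_extreme"), c(1L, 6L, 8L))
  # fixed slot identities
  for (id in 1:8) {
    s <- scenario_spec(id)
    expect_equal(unlist(s$slots[1, c("treatment", "comparator")],
                        use.names = FALSE), c("Old", "No"))
    expect_equal(unlist(s$slots[6, c("treatment", "comparator")],
                        use.names = FALSE), c("New", "No"))
    expect_equal(unlist(s$slots[8, c("treatment", "comparator")],
                        use.names = FALSE), c("New", "Usual"))
  }
  expect_error(scenario_spec(9), "1..8")
  bad <- nmahesim:::DEFAULT_SLOT_CONTRASTS
  bad[[8]] <- c("New", "No")
  expect_error(scenario_spec(1, slot_contrasts = bad), "slot 8")
})

test_that("every scenario's network covers all six contrasts and connects", {
  pairs <- apply(combn(c("No", "Old", "Usual", "New"), 2), 2,
                 function(x) paste(sort(x), collapse = "-"))
  for (id in 1:8) {
    s <- scenario_spec(id)
    covered <- unique(apply(s$slots[, c("treatment", "comparator")], 1,
                            function(x) paste(sort(x), collapse = "-")))
    expect_setequal(covered, pairs)
  }
})

test_that("sample_trial arms are disjoint, sized and deterministic", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 4000, seed = 8)
  tr <- sample_trial(pop, c("New", "Usual"), n_per_arm = 500, seed = 31)
  expect_equal(tr$n_per_arm, 500)
  # total event exposure equals alive patient-cycles in each arm
  for (a in 1:2) {
    ev_n <- sum(tr$counts[[a]]$n[c("evM", "evS", "evVS")])
    expect_equal(ev_n %% 1, 0)
    expect_true(all(tr$counts[[a]]$r <= tr$counts[[a]]$n))
  }
  tr2 <- sample_trial(pop, c("New", "Usual"), n_per_arm = 500, seed = 31)
  expect_identical(tr$counts, tr2$counts)
  expect_error(sample_trial(pop, c("New", "Usual"), n_per_arm = 5000),
               "insufficient")
  expect_error(sample_trial(pop, c("New", "Gone")), "contrast")
})

test_that("worse-health tilt samples older, heavier, smokier patients", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 20000, seed = 17)
  # pool several weighted trials and compare characteristics to the roster
  idx <- unlist(lapply(1:10, function(i) {
    nmahesim:::with_seed(derive_seed(900, i),
      sample(nrow(pop$roster), 1000,
             prob = nmahesim:::filter_weights(pop$roster, "worse_health")))
  }))
  sub <- pop$roster[idx, ]
  n <- length(idx)
  expect_gt(mean(sub$age) - mean(pop$roster$age),
            3 * sd(pop$roster$age) / sqrt(n))
  expect_gt(mean(sub$smoker) - mean(pop$roster$smoker),
            3 * sd(pop$roster$smoker) / sqrt(n))
  expect_gt(mean(sub$bmi > 30), mean(pop$roster$bmi > 30))
  # the extreme variant shifts the same direction, further
  w_e <- nmahesim:::filter_weights(pop$roster, "worse_health_extreme")
  w_w <- nmahesim:::filter_weights(pop$roster, "worse_health")
  expect_true(all(w_e >= w_w))
  age_w <- weighted.mean(pop$roster$age, w_w)
  age_e <- weighted.mean(pop$roster$age, w_e)
  expect_gt(age_e, age_w)
  # age filters tilt the right tails
  w_y <- nmahesim:::filter_weights(pop$roster, "younger")
  expect_lt(weighted.mean(pop$roster$age, w_y), mean(pop$roster$age))
  w_o <- nmahesim:::filter_weights(pop$roster, "older")
  expect_gt(weighted.mean(pop$roster$age, w_o), mean(pop$roster$age))
  # a vacuous filter reduces to simple random sampling weights
  expect_true(all(nmahesim:::filter_weights(pop$roster, "none") == 1))
})

test_that("summarize_counts tallies a fixed path by hand", {
  # single patient: Moderate at cycle 1, Severe from cycle 2 onward
  paths <- list(stages = matrix(c(1L, rep(2L, 11)), 1),
                events = matrix(c(FALSE, TRUE, rep(FALSE, 10)), 1))
  cnt <- summarize_counts(paths)
  expect_equal(unname(cnt$r[["MS"]]), 1)
  expect_equal(unname(cnt$n[["MS"]]), 1)   # at risk in Moderate only cycle 1
  expect_equal(unname(cnt$n[["SVS"]]), 10) # Severe during cycles 2..11
  expect_equal(unname(cnt$r[["SVS"]]), 0)
  expect_equal(unname(cnt$n[["evM"]]), 1)
  expect_equal(unname(cnt$n[["evS"]]), 11)
  expect_equal(unname(cnt$r[["evS"]]), 1)
  # structural zero: never in Very Severe
  expect_equal(unname(cnt$n[["VSS"]]), 0)
})

test_that("trial_lnrr matches 2x2 arithmetic and applies the 0.5 correction", {
  res <- trial_lnrr(20, 100, 10, 100)
  expect_equal(res$delta, log(2), tolerance = 1e-12)
  expect_equal(res$v, 1 / 20 - 1 / 100 + 1 / 10 - 1 / 100, tolerance = 1e-12)
  expect_false(res$corrected)
  expect_equal(trial_lnrr(15, 80, 15, 80)$delta, 0)
  cor <- trial_lnrr(0, 100, 10, 100)
  expect_true(cor$corrected)
  expect_equal(cor$delta, log((0.5 / 100.5) / (10.5 / 100.5)), tolerance = 1e-12)
  expect_equal(cor$v, 1 / 0.5 - 1 / 100.5 + 1 / 10.5 - 1 / 100.5,
               tolerance = 1e-12)
  expect_false(trial_lnrr(1, 0, 2, 10)$estimable)
})

test_that("build_evidence_network is reproducible and exports flat tables", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 3000, seed = 5)
  net <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 200),
                                seed = 99)
  expect_equal(length(net$trials), 9)
  net2 <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 200),
                                 seed = 99)
  expect_identical(network_counts_df(net), network_counts_df(net2))
  cdf <- network_counts_df(net)
  expect_equal(nrow(cdf), 9 * 2 * 12)
  adf <- network_absolutes_df(net)
  expect_true(all(c("maint_Moderate", "util_Severe", "event_cost") %in%
                    adf$quantity))
  stem <- withr::local_tempfile()
  write_evidence_network(net, stem)
  expect_true(file.exists(paste0(stem, "_counts.csv")))
  back <- read.csv(paste0(stem, "_counts.csv"))
  expect_equal(back$r, cdf$r)
})

test_that("scenario-1 trial proportions are unbiased for the population", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 20000, seed = 23)
  truth <- reference_outcomes(pop)$true_probs
  # average the Usual-arm event-rate estimate over repeated trials
  p_hat <- replicate(60, {
    tr <- sample_trial(pop, c("New", "Usual"), n_per_arm = 500,
                       seed = sample.int(1e6, 1))
    tr$counts[[2]]$r[["evM"]] / tr$counts[[2]]$n[["evM"]]
  })
  expect_lt(abs(mean(p_hat) - truth["evM", "Usual"]),
            3 * sd(p_hat) / sqrt(length(p_hat)))
})
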