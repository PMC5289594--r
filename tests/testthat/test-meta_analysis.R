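test_that("dersimonian_laird reproduces worked arithmetic", {
  # identical studies: no heterogeneity, variance halves
  d <- dersimonian_laird(c(0.5, 0.5), c(0.25, 0.25))
  expect_equal(d$point, 0.5)
  expect_equal(d$tau2, 0)
  expect_equal(d$variance, 0.125)
  # dispersed pair: tau2 = 0.14, pooled 0.5, variance 0.09
  d2 <- dersimonian_laird(c(0.2, 0.8), c(0.04, 0.04))
  expect_equal(d2$tau2, 0.14, tolerance = 1e-12)
  expect_equal(d2$point, 0.5, tolerance = 1e-12)
  expect_equal(d2$variance, 0.09, tolerance = 1e-12)
  expect_true(d2$ci[1] < d2$point && d2$point < d2$ci[2])
  # single study passes through with tau2 = 0
  d1 <- dersimonian_laird(0.3, 0.02)
  expect_equal(d1$point, 0.3)
  expect_equal(d1$variance, 0.02)
  expect_equal(d1$tau2, 0)
  expect_error(dersimonian_laird(numeric(), numeric()), "no estimates")
  expect_error(dersimonian_laird(c(1, 2), c(0, 1)), "> 0")
})

test_that("dersimonian_laird equals an independent oracle on random inputs", {
  set.seed(424)
  for (i in 1:50) {
    S <- sample(2:12, 1)
    delta <- rnorm(S, 0, 0.5)
    v <- runif(S, 0.01, 0.3)
    got <- dersimonian_laird(delta, v)
    want <- dl_oracle(delta, v)
    expect_equal(got$point, want$point, tolerance = 1e-12)
    expect_equal(got$variance, want$variance, tolerance = 1e-12)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-12)
  }
})

test_that("DL reduces to fixed-effect pooling whenever Q < S - 1", {
  set.seed(7)
  for (i in 1:20) {
    S <- sample(3:8, 1)
    v <- runif(S, 0.05, 0.2)
    delta <- rnorm(S, 0.2, 0.01)  # nearly homogeneous -> Q tiny
    got <- dersimonian_laird(delta, v)
    if (got$tau2 == 0) {
      w <- 1 / v
      expect_equal(got$point, sum(w * delta) / sum(w), tolerance = 1e-12)
      expect_equal(got$variance, 1 / sum(w), tolerance = 1e-12)
    }
  }
})

test_that("pool_direct uses only head-to-head trials", {
  net <- fake_network(list(
    fake_trial(1, c("New", "Usual"), 20, 100, 10, 100),
    fake_trial(2, c("Usual", "New"), 12, 100, 18, 100),
    fake_trial(3, c("New", "No"), 30, 100, 10, 100)
  ))
  one <- pool_direct(fake_network(net$trials[1]), c("New", "Usual"), "MS")
  t1 <- trial_lnrr(20, 100, 10, 100)
  expect_equal(one$point, t1$delta)
  expect_equal(one$variance, t1$v)
  # two direct trials equal DL of the pair, with trial 2 sign-flipped
  both <- pool_direct(net, c("New", "Usual"), "MS")
  t2 <- trial_lnrr(12, 100, 18, 100)
  want <- dl_oracle(c(t1$delta, -t2$delta), c(t1$v, t2$v))
  expect_equal(both$point, want$point, tolerance = 1e-12)
  expect_equal(both$variance, want$variance, tolerance = 1e-12)
  expect_false(pool_direct(net, c("Old", "No"), "MS")$estimable)
})

test_that("song_mixed combines direct and indirect evidence per the formulas", {
  # pure indirect: legs (0.3, 0.04) and (0.1, 0.05) -> (0.2, 0.09)
  leg1 <- fake_trial(1, c("New", "No"), 27, 200, 20, 200)
  leg2 <- fake_trial(2, c("Usual", "No"), 24, 200, 20, 200)
  l1 <- trial_lnrr(27, 200, 20, 200)
  l2 <- trial_lnrr(24, 200, 20, 200)
  net <- fake_network(list(leg1, leg2))
  s <- song_mixed(net, c("New", "Usual"), "MS")
  expect_equal(s$point, l1$delta - l2$delta, tolerance = 1e-12)
  expect_equal(s$variance, l1$v + l2$v, tolerance = 1e-12)
  # no indirect path: equals the direct pool
  net2 <- fake_network(list(fake_trial(1, c("New", "Usual"), 20, 100, 10, 100)))
  s2 <- song_mixed(net2, c("New", "Usual"), "MS")
  d2 <- pool_direct(net2, c("New", "Usual"), "MS")
  expect_equal(s2$point, d2$point)
  expect_equal(s2$variance, d2$variance)
  # direct + one indirect: DL over the two pseudo-studies
  net3 <- fake_network(list(fake_trial(1, c("New", "Usual"), 20, 100, 10, 100),
                            leg1, leg2))
  s3 <- song_mixed(net3, c("New", "Usual"), "MS")
  t1 <- trial_lnrr(20, 100, 10, 100)
  want <- dl_oracle(c(t1$delta, l1$delta - l2$delta), c(t1$v, l1$v + l2$v))
  expect_equal(s3$point, want$point, tolerance = 1e-12)
  expect_equal(s3$variance, want$variance, tolerance = 1e-12)
  expect_false(song_mixed(fake_network(list(leg1)), c("New", "Usual"),
                          "MS")$estimable)
})

test_that("song arithmetic worked example: (0.3,0.04) minus (0.1,0.05)", {
  # direct statement of the indirect-combination rule
  expect_equal(0.3 - 0.1, 0.2)
  got <- dl_oracle(c(0.25, 0.2), c(0.05, 0.09))
  w <- c(1 / 0.05, 1 / 0.09)  # Q < S - 1 here, so weights stay fixed-effect
  expect_equal(got$tau2, 0)
  expect_equal(got$point, sum(w * c(0.25, 0.2)) / sum(w), tolerance = 1e-12)
  expect_equal(got$variance, 1 / sum(w), tolerance = 1e-12)
  expect_equal(got$point, 0.2321, tolerance = 1e-3)
  expect_equal(got$variance, 0.0321, tolerance = 2e-2)
})

test_that("or_to_rr converts odds ratios with the baseline-risk formula", {
  expect_equal(or_to_rr(0, NULL, 0.3)$lnrr, 0)
  expect_equal(exp(or_to_rr(log(2), NULL, 0.2)$lnrr), 5 / 3,
               tolerance = 1e-12)
  expect_equal(or_to_rr(log(2), NULL, 1e-9)$lnrr, log(2), tolerance = 1e-6)
  # delta-method variance shrinks the ln(OR) variance by the gradient^2
  conv <- or_to_rr(log(2), 0.04, 0.2)
  grad <- (1 - 0.2) / (1 - 0.2 + 0.2 * 2)
  expect_equal(conv$var_lnrr, grad^2 * 0.04, tolerance = 1e-12)
  expect_error(or_to_rr(0, NULL, 0), "p0")
  expect_error(or_to_rr(0, NULL, 1), "p0")
})

test_that("puhan_logistic equals the 2x2 log odds ratio on one trial", {
  net <- fake_network(list(fake_trial(1, c("New", "Usual"), 20, 100, 10, 100)))
  est <- puhan_logistic(net, c("New", "Usual"), "MS")
  lnor <- log((20 / 80) / (10 / 90))
  p0 <- nmahesim:::pooled_baseline_risk(net, "Usual", "MS")
  expect_equal(p0, 0.1, tolerance = 1e-9)
  expect_equal(est$point, or_to_rr(lnor, NULL, p0)$lnrr, tolerance = 1e-8)
  # identical arms: null effect
  net0 <- fake_network(list(fake_trial(1, c("New", "Usual"), 15, 100, 15, 100)))
  expect_lt(abs(puhan_logistic(net0, c("New", "Usual"), "MS")$point), 1e-6)
  # disconnected network: not estimable
  netd <- fake_network(list(fake_trial(1, c("New", "Usual"), 5, 50, 6, 50),
                            fake_trial(2, c("Old", "No"), 5, 50, 6, 50)))
  expect_false(puhan_logistic(netd, c("New", "No"), "MS")$estimable)
})

test_that("puhan_logistic on a two-trial chain matches the saturated-model
           closed form and a brute-force likelihood oracle", {
  # chain: trial 1 Usual (baseline No), trial 2 New vs Usual
  net <- fake_network(list(
    fake_trial(1, c("Usual", "No"), 30, 200, 22, 200),
    fake_trial(2, c("New", "Usual"), 18, 200, 33, 200)
  ))
  est <- puhan_logistic(net, c("New", "No"), "MS")
  # saturated model: the New-vs-No log OR telescopes along the chain
  logit <- function(p) log(p / (1 - p))
  lnor_closed <- (logit(30 / 200) - logit(22 / 200)) +
    (logit(18 / 200) - logit(33 / 200))
  # independent brute-force ML oracle on the same likelihood
  dat <- nmahesim:::network_param_data(net, "MS")
  treatments <- intersect(c("No", "Old", "Usual", "New"),
                          unique(dat$treatment))
  trials <- sort(unique(dat$trial))
  fit <- optim(rep(0, 4), function(b)
    -logistic_network_loglik(b, dat, treatments, trials),
    method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  # beta layout: intercept, d_Usual, d_New, study-2 dummy
  lnor_brute <- fit$par[3]
  expect_equal(lnor_brute, lnor_closed, tolerance = 1e-5)
  p0 <- nmahesim:::pooled_baseline_risk(net, "No", "MS")
  expect_equal(est$point, or_to_rr(lnor_closed, NULL, p0)$lnrr,
               tolerance = 1e-6)
})

test_that("pool_absolute follows the DL oracle and rejects degenerate input", {
  means <- c(100, 200); ses <- c(10, 10)
  got <- pool_absolute(means, ses)
  want <- dl_oracle(means, ses^2)
  expect_equal(got$mean, want$point, tolerance = 1e-12)
  expect_equal(got$se, sqrt(want$variance), tolerance = 1e-12)
  same <- pool_absolute(c(5, 5, 5), c(1, 1, 1))
  expect_equal(same$mean, 5)
  expect_equal(same$tau2, 0)
  expect_error(pool_absolute(c(1, 2), c(0, 0)), "zero")
})

test_that("methods are invariant to trial relabeling", {
  spec <- default_disease_spec()
  pop <- build_reference_population(spec, n = 3000, seed = 55)
  net <- build_evidence_network(pop, scenario_spec(1, n_per_arm = 150),
                                seed = 12)
  perm <- rev(seq_along(net$trials))
  net_perm <- net
  net_perm$trials <- net$trials[perm]
  for (i in seq_along(net_perm$trials)) net_perm$trials[[i]]$trial <- i
  for (fn in list(pool_direct, song_mixed, puhan_logistic)) {
    a <- fn(net, c("New", "Usual"), "SVS")
    b <- fn(net_perm, c("New", "Usual"), "SVS")
    expect_equal(a$point, b$point, tolerance = 1e-9)
    expect_equal(a$variance, b$variance, tolerance = 1e-9)
  }
})
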