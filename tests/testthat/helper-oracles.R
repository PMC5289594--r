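# Independent oracles and fixture builders used across the test suite.

# One-pass DerSimonian-Laird oracle, written independently of the package
# implementation (explicit loops, no shared helpers).
dl_oracle <- function(delta, v) {
  S <- length(delta)
  w <- numeric(S)
  for (i in 1:S) w[i] <- 1 / v[i]
  sw <- 0; swd <- 0; sw2 <- 0
  for (i in 1:S) { sw <- sw + w[i]; swd <- swd + w[i] * delta[i]; sw2 <- sw2 + w[i]^2 }
  fe <- swd / sw
  Q <- 0
  for (i in 1:S) Q <- Q + w[i] * (delta[i] - fe)^2
  tau2 <- 0
  if (S > 1 && Q >= S - 1) tau2 <- (Q - (S - 1)) / (sw - sw2 / sw)
  ws <- sws <- swsd <- 0
  for (i in 1:S) {
    wi <- 1 / (v[i] + tau2)
    sws <- sws + wi
    swsd <- swsd + wi * delta[i]
  }
  list(point = swsd / sws, variance = 1 / sws, tau2 = tau2)
}

# Deterministic Markov occupancy oracle: repeated multiplication with the
# one-cycle matrix, counting the occupancy at cycles 1..n_cycles.
occupancy_oracle <- function(M, start, n_cycles = 12) {
  occ <- start
  total <- numeric(length(start))
  for (cyc in seq_len(n_cycles)) {
    total <- total + occ
    if (cyc < n_cycles) occ <- as.numeric(occ %*% M)
  }
  total
}

# A minimal disease world with no characteristic heterogeneity, handy when a
# test needs a homogeneous roster or hand-computable dynamics.
flat_spec <- function(rdp_overrides = c(), int_modifiers = NULL,
                      maintenance = c(100, 200, 400), event_cost = 1000,
                      utilities = c(0.9, 0.6, 0.3), event_decrement = 0.01) {
  rdp <- stats::setNames(rep(0, 12), nmahesim:::TRANSITIONS)
  rdp[names(rdp_overrides)] <- rdp_overrides
  if (is.null(int_modifiers)) {
    int_modifiers <- data.frame(intervention = character(),
                                transition = character(), delta = numeric())
  }
  disease_spec(
    rdp = rdp,
    characteristic_modifiers = data.frame(factor = character(),
                                          level = character(),
                                          transition = character(),
                                          delta = numeric()),
    intervention_modifiers = int_modifiers,
    maintenance_cost = maintenance,
    event_cost = event_cost,
    intervention_costs = list(No = list(oneoff = 0, per_cycle = 0),
                              Old = list(oneoff = 250, per_cycle = 0),
                              Usual = list(oneoff = 0, per_cycle = 60),
                              New = list(oneoff = 0, per_cycle = 350)),
    utilities = utilities,
    event_decrement = event_decrement
  )
}

# Hand-built two-arm trial summary carrying identical counts for all 12
# parameters; lets meta-analysis tests state exact 2x2 tables.
fake_trial <- function(trial_id, contrast, r1, n1, r0, n0) {
  TR <- nmahesim:::TRANSITIONS
  counts <- list(
    list(r = stats::setNames(rep(r1, 12), TR), n = stats::setNames(rep(n1, 12), TR)),
    list(r = stats::setNames(rep(r0, 12), TR), n = stats::setNames(rep(n0, 12), TR))
  )
  lnrr <- nmahesim:::trial_lnrr_table(counts[[1]], counts[[2]])
  structure(list(trial = trial_id, contrast = contrast, filter = "none",
                 n_per_arm = n1, counts = counts, lnrr = lnrr,
                 absolutes = stats::setNames(list(list(), list()), contrast)),
            class = "trial_summary")
}

fake_network <- function(trials) {
  structure(list(trials = trials, scenario = NULL, seed = NA),
            class = "evidence_network")
}

# Log-likelihood of the fixed-effect logistic network model on arm-level
# counts, for the brute-force regression oracle.
logistic_network_loglik <- function(beta, dat, treatments, trials) {
  ll <- 0
  for (i in seq_len(nrow(dat))) {
    eta <- beta[1]
    ti <- match(dat$treatment[i], treatments)
    if (ti > 1) eta <- eta + beta[1 + (ti - 1)]
    si <- match(dat$trial[i], trials)
    if (si > 1) eta <- eta + beta[length(treatments) + (si - 1)]
    p <- 1 / (1 + exp(-eta))
    ll <- ll + dat$r[i] * log(p) + (dat$n[i] - dat$r[i]) * log(1 - p)
  }
  ll
}
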