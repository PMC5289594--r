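# Trial sampling: two-arm trials drawn from the reference population per
# heterogeneity scenario, summarized into the statistics that the
# meta-analysis methods consume.

# Contrast carried by each of the nine trial slots. Slots 1, 6 and 8 are
# fixed by the study design (Old-vs-No, New-vs-No, New-vs-Usual); the
# remaining assignment completes direct evidence on all six pairs.
DEFAULT_SLOT_CONTRASTS <- list(
  c("Old", "No"), c("Old", "No"), c("Usual", "No"), c("Usual", "Old"),
  c("New", "Old"), c("New", "No"), c("New", "No"), c("New", "Usual"),
  c("Usual", "Old")
)

SUBPOP_FILTERS <- c("none", "worse_health", "worse_health_extreme",
                    "younger", "older")

#' Heterogeneity scenario definitions
#'
#' Eight scenarios share the same nine-trial evidence network (500 patients
#' per arm) and differ only in which trials are drawn from a biased
#' subpopulation: scenario 1 draws all trials randomly; scenarios 2-4 bias a
#' single trial (1, 6 or 8 respectively) towards patients in worse health;
#' scenario 5 biases trial 1 (worse health) and trial 6 (younger); scenario 6
#' additionally biases trial 8 (older); scenario 7 biases trials 1, 6 and 8
#' all towards worse health; scenario 8 is the extreme-stress variant of
#' scenario 7.
#'
#' Filters tilt the trial's sampling weights towards a subpopulation (see
#' [sample_trial()]): `worse_health` over-samples patients with age > 55,
#' smoking or BMI > 30; `worse_health_extreme` doubles that shift;
#' `younger` over-samples age < 35; `older` over-samples age > 64.
#'
#' @param id scenario id in 1..8.
#' @param n_per_arm patients per arm (default 500).
#' @param slot_contrasts optional list of 9 contrasts overriding the default
#'   slot assignment (slots 1, 6, 8 must keep their fixed contrasts).
#' @return object of class `scenario_spec`: list with `id`, `n_per_arm` and
#'   `slots` (data-frame with trial, treatment, comparator, filter).
#' @export
scenario_spec <- function(id, n_per_arm = 500,
                          slot_contrasts = DEFAULT_SLOT_CONTRASTS) {
  if (length(id) != 1 || !id %in% 1:8) stop("scenario id must be in 1..8")
  stopifnot(length(slot_contrasts) == 9)
  fixed <- list(`1` = c("Old", "No"), `6` = c("New", "No"),
                `8` = c("New", "Usual"))
  for (s in names(fixed)) {
    if (!identical(slot_contrasts[[as.integer(s)]], fixed[[s]])) {
      stop("trial slot ", s, " must carry the contrast ",
           paste(fixed[[s]], collapse = " vs "))
    }
  }
  filters <- rep("none", 9)
  if (id == 2) filters[1] <- "worse_health"
  if (id == 3) filters[6] <- "worse_health"
  if (id == 4) filters[8] <- "worse_health"
  if (id == 5) { filters[1] <- "worse_health"; filters[6] <- "younger" }
  if (id == 6) {
    filters[1] <- "worse_health"; filters[6] <- "younger"; filters[8] <- "older"
  }
  if (id == 7) filters[c(1, 6, 8)] <- "worse_health"
  if (id == 8) filters[c(1, 6, 8)] <- "worse_health_extreme"
  slots <- data.frame(
    trial = 1:9,
    treatment = vapply(slot_contrasts, `[`, "", 1),
    comparator = vapply(slot_contrasts, `[`, "", 2),
    filter = filters,
    stringsAsFactors = FALSE
  )
  structure(list(id = id, n_per_arm = n_per_arm, slots = slots),
            class = "scenario_spec")
}

# Per-patient sampling weights under a subpopulation filter. Filters tilt
# the sampling distribution rather than excluding patients outright: flagged
# patients are over-sampled by the tilt factor, which shifts the trial's
# average health moderately (the paper's design reports biased but still
# overlapping trial populations — no parameter ever loses nominal coverage
# outside the extreme stress scenario). The extreme variant doubles the
# tilt.
FILTER_TILT <- 2
filter_weights <- function(roster, filter) {
  filter <- match.arg(filter, SUBPOP_FILTERS)
  flags <- cbind(roster$age > 55, roster$smoker, roster$bmi > 30)
  w <- rep(1, nrow(roster))
  switch(filter,
    none = w,
    worse_health = ifelse(rowSums(flags) >= 1, FILTER_TILT, 1),
    worse_health_extreme = ifelse(rowSums(flags) >= 1, FILTER_TILT, 1) *
      ifelse(rowSums(flags) >= 2, FILTER_TILT, 1),
    younger = ifelse(roster$age < 35, FILTER_TILT, 1),
    older = ifelse(roster$age > 64, FILTER_TILT, 1)
  )
}

#' Sample one two-arm trial from the reference population
#'
#' Patients are drawn without replacement within the trial (the two arms are
#' disjoint) but independently across trials, mirroring sampling from a
#' superpopulation. Each arm re-uses the patient's already-simulated
#' trajectory under that arm's intervention, and monthly records are
#' summarized into at-risk counts for the 12 effect-bearing parameters plus
#' arm-level means of costs and utility proxies.
#'
#' @param pop a [build_reference_population()] result.
#' @param contrast character(2): (treatment, comparator).
#' @param n_per_arm patients per arm.
#' @param filter one of `r toString(SUBPOP_FILTERS)`.
#' @param seed integer seed.
#' @param trial_id identifier stored in the summary.
#' @return object of class `trial_summary`: list with `trial`, `contrast`,
#'   `counts` (per parameter and arm: r, n), `lnrr` (per parameter: estimate,
#'   variance, continuity flag) and `absolutes` (per arm: mean/se/n of
#'   stage-wise maintenance cost and utility, event cost and decrement).
#' @export
sample_trial <- function(pop, contrast, n_per_arm = 500, filter = "none",
                         seed = 1L, trial_id = 1L) {
  stopifnot(inherits(pop, "reference_population"))
  if (!all(contrast %in% names(pop$paths))) {
    stop("unknown contrast: ", toString(contrast))
  }
  weights <- filter_weights(pop$roster, filter)
  if (sum(weights > 0) < 2 * n_per_arm) {
    stop("insufficient subpopulation: filter '", filter, "' leaves ",
         sum(weights > 0), " eligible patients, need ", 2 * n_per_arm)
  }
  idx <- with_seed(seed, sample(nrow(pop$roster), 2 * n_per_arm,
                                prob = weights))
  arms <- list(idx[seq_len(n_per_arm)], idx[n_per_arm + seq_len(n_per_arm)])
  counts <- lapply(1:2, function(a) {
    count_parameters(pop$paths[[contrast[a]]], arms[[a]])
  })
  lnrr <- trial_lnrr_table(counts[[1]], counts[[2]])
  absolutes <- lapply(1:2, function(a) {
    arm_absolutes(pop, contrast[a], arms[[a]])
  })
  names(absolutes) <- contrast
  structure(list(trial = trial_id, contrast = contrast, filter = filter,
                 n_per_arm = n_per_arm, counts = counts, lnrr = lnrr,
                 absolutes = absolutes),
            class = "trial_summary")
}

# Arm-level estimates of the absolute model quantities, from the monthly
# records of the sampled patients: per-stage maintenance cost and utility
# (mean over at-risk patient-cycles), event cost and utility decrement (mean
# over events), plus the arm's per-cycle baseline probabilities.
arm_absolutes <- function(pop, intervention, idx) {
  roster <- pop$roster[idx, , drop = FALSE]
  paths <- pop$paths[[intervention]]
  stages <- paths$stages[idx, , drop = FALSE]
  cu <- cost_utility_deltas(roster, pop$spec)
  spec <- pop$spec
  res <- list()
  for (st in 1:3) {
    cycles_in <- rowSums(stages == st)
    tot <- sum(cycles_in)
    nm <- STAGES[st]
    if (tot > 0) {
      maint_obs_mean <- spec$maintenance_cost[st] + cu$maintenance
      util_obs <- pmin(1, pmax(0, spec$utilities[st] + cu$utility))
      # weighted by time spent in stage; SE treats patient-cycles as units
      m <- sum(cycles_in * maint_obs_mean) / tot
      v_m <- sum(cycles_in * (maint_obs_mean - m)^2) / tot
      u <- sum(cycles_in * util_obs) / tot
      v_u <- sum(cycles_in * (util_obs - u)^2) / tot
      res[[paste0("maint_", nm)]] <- c(mean = m, se = sqrt(v_m / tot), n = tot)
      res[[paste0("util_", nm)]] <- c(mean = u, se = sqrt(v_u / tot), n = tot)
    } else {
      res[[paste0("maint_", nm)]] <- c(mean = NA, se = NA, n = 0)
      res[[paste0("util_", nm)]] <- c(mean = NA, se = NA, n = 0)
    }
  }
  n_events <- rowSums(paths$events[idx, , drop = FALSE])
  tot_ev <- sum(n_events)
  if (tot_ev > 0) {
    ec <- pmax(0, spec$event_cost + cu$event_cost)
    dec <- pmax(0, spec$event_decrement + cu$event_decrement)
    mec <- sum(n_events * ec) / tot_ev
    vec_ <- sum(n_events * (ec - mec)^2) / tot_ev
    mdec <- sum(n_events * dec) / tot_ev
    vdec <- sum(n_events * (dec - mdec)^2) / tot_ev
    res$event_cost <- c(mean = mec, se = sqrt(vec_ / tot_ev), n = tot_ev)
    res$event_decrement <- c(mean = mdec, se = sqrt(vdec / tot_ev), n = tot_ev)
  } else {
    res$event_cost <- c(mean = NA, se = NA, n = 0)
    res$event_decrement <- c(mean = NA, se = NA, n = 0)
  }
  res
}

#' Trial-level log relative risk
#'
#' `delta = log((r1/n1)/(r0/n0))` with within-trial variance
#' `v = 1/r1 - 1/n1 + 1/r0 - 1/n0`. When any cell is zero or complete
#' (r = 0 or r = n), 0.5 is added to all four cells first (continuity
#' correction) and the result is flagged.
#'
#' @param r1,n1 occurrences and exposure in the treatment arm.
#' @param r0,n0 occurrences and exposure in the comparator arm.
#' @return list `(delta, v, corrected)`, or `NULL`-like not-estimable signal
#'   (`estimable = FALSE`) if either exposure is zero.
#' @export
trial_lnrr <- function(r1, n1, r0, n0) {
  if (n1 <= 0 || n0 <= 0) {
    return(list(delta = NA_real_, v = NA_real_, corrected = FALSE,
                estimable = FALSE))
  }
  corrected <- r1 == 0 || r0 == 0 || r1 == n1 || r0 == n0
  if (corrected) {
    r1 <- r1 + 0.5; r0 <- r0 + 0.5; n1 <- n1 + 0.5; n0 <- n0 + 0.5
  }
  delta <- log((r1 / n1) / (r0 / n0))
  v <- 1 / r1 - 1 / n1 + 1 / r0 - 1 / n0
  list(delta = delta, v = v, corrected = corrected, estimable = TRUE)
}

trial_lnrr_table <- function(counts_trt, counts_ctl) {
  out <- data.frame(parameter = TRANSITIONS, delta = NA_real_, v = NA_real_,
                    corrected = FALSE, estimable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(TRANSITIONS)) {
    tr <- TRANSITIONS[i]
    res <- trial_lnrr(counts_trt$r[[tr]], counts_trt$n[[tr]],
                      counts_ctl$r[[tr]], counts_ctl$n[[tr]])
    out$delta[i] <- res$delta
    out$v[i] <- res$v
    out$corrected[i] <- res$corrected
    out$estimable[i] <- res$estimable
  }
  out
}

#' Summarize arm records into per-parameter counts
#'
#' Given the stage/event matrices of a set of patients, returns occurrence
#' counts `r` and at-risk exposures `n` for the 12 effect-bearing
#' parameters. Exposures are at-risk patient-cycles: for transitions, cycles
#' 1-11 spent in the origin stage; for events, alive cycles 1-12 in the
#' stage.
#'
#' @param paths list with `stages` and `events` matrices (as stored in a
#'   reference population).
#' @param idx optional row subset.
#' @return list with named vectors `r` and `n`.
#' @export
summarize_counts <- function(paths, idx = NULL) {
  count_parameters(paths, idx)
}

#' Build the nine-trial evidence network for a scenario
#'
#' @param pop a [build_reference_population()] result.
#' @param scenario a [scenario_spec()] (or a scenario id in 1..8).
#' @param seed integer seed; trial `t` uses the substream
#'   `derive_seed(seed, "trial", t)`.
#' @return object of class `evidence_network`: list of 9 `trial_summary`
#'   objects plus the scenario.
#' @export
build_evidence_network <- function(pop, scenario, seed = 1L) {
  if (is.numeric(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  trials <- lapply(seq_len(nrow(scenario$slots)), function(t) {
    row <- scenario$slots[t, ]
    sample_trial(pop, c(row$treatment, row$comparator),
                 n_per_arm = scenario$n_per_arm, filter = row$filter,
                 seed = derive_seed(seed, "trial", t), trial_id = t)
  })
  structure(list(trials = trials, scenario = scenario, seed = seed),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network: scenario", x$scenario$id, "with",
      length(x$trials), "trials\n")
  for (tr in x$trials) {
    cat(sprintf("  trial %d: %s vs %s%s\n", tr$trial, tr$contrast[1],
                tr$contrast[2],
                if (tr$filter != "none") paste0(" [", tr$filter, "]") else ""))
  }
  invisible(x)
}

#' Export / import an evidence network as flat CSV tables
#'
#' `network_counts_df()` returns the long count table (trial, arm, treatment,
#' filter, parameter, r, n); `network_absolutes_df()` the arm-level means
#' table. `write_evidence_network()` writes both as CSV files
#' (`<stem>_counts.csv`, `<stem>_absolutes.csv`).
#'
#' @param network an `evidence_network`.
#' @return data.frame (or, for the writer, the stem invisibly).
#' @export
network_counts_df <- function(network) {
  do.call(rbind, lapply(network$trials, function(tr) {
    do.call(rbind, lapply(1:2, function(a) {
      data.frame(trial = tr$trial, arm = a, treatment = tr$contrast[a],
                 filter = tr$filter, parameter = TRANSITIONS,
                 r = unname(tr$counts[[a]]$r), n = unname(tr$counts[[a]]$n),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' @rdname network_counts_df
#' @export
network_absolutes_df <- function(network) {
  do.call(rbind, lapply(network$trials, function(tr) {
    do.call(rbind, lapply(1:2, function(a) {
      ab <- tr$absolutes[[a]]
      data.frame(trial = tr$trial, arm = a, treatment = tr$contrast[a],
                 quantity = names(ab),
                 mean = vapply(ab, `[[`, 0.0, "mean"),
                 se = vapply(ab, `[[`, 0.0, "se"),
                 n = vapply(ab, `[[`, 0.0, "n"),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
}

#' @rdname network_counts_df
#' @param stem file path stem.
#' @export
write_evidence_network <- function(network, stem) {
  utils::write.csv(network_counts_df(network),
                   paste0(stem, "_counts.csv"), row.names = FALSE)
  utils::write.csv(network_absolutes_df(network),
                   paste0(stem, "_absolutes.csv"), row.names = FALSE)
  invisible(stem)
}
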