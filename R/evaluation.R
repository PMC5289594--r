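# Repetition orchestration and performance metrics: coverage, statistical
# power, bias and mean absolute deviation against the simulated truth.

HE_OUTCOMES <- c("delta_qaly", "delta_ly", "delta_events", "delta_total_cost")

#' Coverage, power, bias and MAD of a set of repeated estimates
#'
#' Coverage is the fraction of intervals containing the truth; power the
#' fraction of intervals excluding the null; bias the mean signed deviation
#' of the point estimates from the truth; MAD the mean absolute deviation.
#' With `relative = TRUE` (default) bias and MAD are expressed as a
#' percentage of the absolute true value; when the truth is zero the
#' absolute scale is used instead and the result flagged.
#'
#' @param estimates data.frame with columns `point`, `lo`, `hi` (one row per
#'   repetition).
#' @param truth true value.
#' @param null null value for the power computation (default 0).
#' @param relative report bias/MAD relative to `|truth|` in percent.
#' @return list with `coverage`, `power`, `bias`, `mad`, `relative`
#'   (whether the relative scale was actually used) and `n`.
#' @export
compute_metrics <- function(estimates, truth, null = 0, relative = TRUE) {
  stopifnot(is.data.frame(estimates),
            all(c("point", "lo", "hi") %in% names(estimates)))
  ok <- stats::complete.cases(estimates[, c("point", "lo", "hi")])
  est <- estimates[ok, ]
  if (!nrow(est)) stop("compute_metrics: no complete estimates")
  coverage <- mean(est$lo <= truth & truth <= est$hi)
  power <- mean(est$lo > null | est$hi < null)
  dev <- est$point - truth
  used_relative <- relative && truth != 0
  scale <- if (used_relative) 100 / abs(truth) else 1
  list(coverage = coverage, power = power,
       bias = mean(dev) * scale, mad = mean(abs(dev)) * scale,
       relative = used_relative, n = nrow(est))
}

#' Run one repetition of the trial-sampling / pooling / modeling pipeline
#'
#' Draws one nine-trial evidence network, pools it with every requested
#' method on identical trial data, and runs the probabilistic sensitivity
#' analysis with identical seeds across methods, so that any difference
#' between methods is attributable to the methods themselves.
#'
#' @param pop a [build_reference_population()] result.
#' @param scenario a [scenario_spec()] or scenario id.
#' @param methods subset of `r toString(METHODS)`.
#' @param rep_seed integer seed for this repetition.
#' @param contrast analysis contrast, default `c("New", "Usual")`.
#' @param psa_iters PSA iterations per method (study default 1,100).
#' @param glm_cfg a [glm_config()] for the Bayesian methods.
#' @param wtp_grid willingness-to-pay grid on which the repetition's CEAC is
#'   recorded.
#' @return object of class `repetition_record`: `parameters` (long
#'   data.frame: method, parameter, point, lo, hi on the ln(RR) scale),
#'   `he_outcomes` (method, outcome, point, lo, hi), `ceac` (method, wtp,
#'   probability), `failures` (methods that errored).
#' @export
run_repetition <- function(pop, scenario, methods = METHODS, rep_seed = 1L,
                           contrast = c("New", "Usual"), psa_iters = 1100,
                           glm_cfg = NULL,
                           wtp_grid = seq(0, 100000, by = 5000)) {
  if (is.numeric(scenario)) scenario <- scenario_spec(scenario)
  methods <- match.arg(methods, METHODS, several.ok = TRUE)
  network <- build_evidence_network(pop, scenario,
                                    seed = derive_seed(rep_seed, "network"))
  if (is.null(glm_cfg)) glm_cfg <- glm_config(seed = derive_seed(rep_seed, "glm"))
  params_rows <- list()
  he_rows <- list()
  ceac_rows <- list()
  failures <- character()
  for (m in methods) {
    res <- tryCatch({
      pset <- model_parameter_set(network, m, contrast,
                                  intervention_costs = pop$spec$intervention_costs,
                                  glm_cfg = glm_cfg)
      psa <- run_psa(pset, n_iter = psa_iters, seed = rep_seed)
      list(pset = pset, psa = psa)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, m)
      next
    }
    eff <- res$pset$effects
    params_rows[[m]] <- data.frame(
      method = m, parameter = TRANSITIONS,
      point = vapply(eff, function(e) e$point, 0.0),
      lo = vapply(eff, function(e) e$ci[1], 0.0),
      hi = vapply(eff, function(e) e$ci[2], 0.0),
      stringsAsFactors = FALSE, row.names = NULL)
    he_rows[[m]] <- data.frame(
      method = m, outcome = HE_OUTCOMES,
      point = unname(res$psa$means[HE_OUTCOMES]),
      lo = unname(res$psa$ci[1, HE_OUTCOMES]),
      hi = unname(res$psa$ci[2, HE_OUTCOMES]),
      stringsAsFactors = FALSE, row.names = NULL)
    cc <- ceac(res$psa, wtp_grid)
    ceac_rows[[m]] <- data.frame(method = m, cc, stringsAsFactors = FALSE)
  }
  structure(list(
    scenario = scenario$id, rep_seed = rep_seed, contrast = contrast,
    parameters = do.call(rbind, params_rows),
    he_outcomes = do.call(rbind, he_rows),
    ceac = do.call(rbind, ceac_rows),
    failures = failures), class = "repetition_record")
}

#' Score methods over repetitions
#'
#' Aggregates repetition records into the study's performance summaries:
#' per-parameter and per-health-economic-outcome coverage/power/bias/MAD per
#' method, band counts per method (coverage < 90% and > 98%; bias 1-2% and
#' > 2%; MAD 4-7% and > 7%), ranges over the four health-economic outcomes,
#' and the cross-repetition CEAC envelope (median and 2.5/97.5 percentiles
#' per willingness-to-pay value).
#'
#' Parameter-level metrics are computed on the relative-risk scale
#' (estimates and truths exponentiated; bias and MAD in percent of the true
#' RR); health-economic metrics are relative to the reference incremental
#' outcome.
#'
#' @param records list of [run_repetition()] results (same scenario).
#' @param reference a [reference_outcomes()] result carrying the truth.
#' @return object of class `performance_summary` with elements
#'   `parameter_metrics`, `he_metrics`, `parameter_bands`, `he_ranges`,
#'   `ceac_envelope`, `n_reps`.
#' @export
summarize_study <- function(records, reference) {
  stopifnot(length(records) >= 2, inherits(reference, "reference_outcomes"))
  scen <- unique(vapply(records, function(r) r$scenario, 0))
  if (length(scen) != 1) stop("records mix scenarios: ", toString(scen))
  all_params <- do.call(rbind, lapply(records, `[[`, "parameters"))
  all_he <- do.call(rbind, lapply(records, `[[`, "he_outcomes"))
  all_ceac <- do.call(rbind, lapply(records, `[[`, "ceac"))
  methods <- unique(all_params$method)

  param_rows <- list()
  for (m in methods) {
    for (par in TRANSITIONS) {
      sel <- all_params[all_params$method == m & all_params$parameter == par, ]
      est <- data.frame(point = exp(sel$point), lo = exp(sel$lo),
                        hi = exp(sel$hi))
      truth <- exp(reference$true_lnrr[[par]])
      met <- compute_metrics(est, truth, null = 1)
      param_rows[[length(param_rows) + 1L]] <- data.frame(
        method = m, parameter = par, coverage = met$coverage,
        power = met$power, bias = met$bias, mad = met$mad,
        stringsAsFactors = FALSE)
    }
  }
  parameter_metrics <- do.call(rbind, param_rows)

  truth_he <- c(delta_qaly = reference$incremental$delta_qaly,
                delta_ly = reference$incremental$delta_ly,
                delta_events = reference$incremental$delta_events,
                delta_total_cost = reference$incremental$delta_total_cost)
  he_rows <- list()
  for (m in unique(all_he$method)) {
    for (oc in HE_OUTCOMES) {
      sel <- all_he[all_he$method == m & all_he$outcome == oc, ]
      met <- compute_metrics(sel[, c("point", "lo", "hi")], truth_he[[oc]])
      he_rows[[length(he_rows) + 1L]] <- data.frame(
        method = m, outcome = oc, coverage = met$coverage, power = met$power,
        bias = met$bias, mad = met$mad, stringsAsFactors = FALSE)
    }
  }
  he_metrics <- do.call(rbind, he_rows)

  parameter_bands <- do.call(rbind, lapply(methods, function(m) {
    pm <- parameter_metrics[parameter_metrics$method == m, ]
    data.frame(
      method = m,
      coverage_below_90 = sum(pm$coverage < 0.90),
      coverage_above_98 = sum(pm$coverage > 0.98),
      bias_1_2 = sum(abs(pm$bias) >= 1 & abs(pm$bias) <= 2),
      bias_above_2 = sum(abs(pm$bias) > 2),
      mad_4_7 = sum(pm$mad >= 4 & pm$mad <= 7),
      mad_above_7 = sum(pm$mad > 7),
      stringsAsFactors = FALSE)
  }))

  he_ranges <- do.call(rbind, lapply(unique(he_metrics$method), function(m) {
    hm <- he_metrics[he_metrics$method == m, ]
    data.frame(method = m,
               coverage_min = min(hm$coverage), coverage_max = max(hm$coverage),
               power_min = min(hm$power), power_max = max(hm$power),
               bias_min = min(abs(hm$bias)), bias_max = max(abs(hm$bias)),
               mad_min = min(hm$mad), mad_max = max(hm$mad),
               stringsAsFactors = FALSE)
  }))

  ceac_envelope <- NULL
  if (!is.null(all_ceac)) {
    ceac_envelope <- do.call(rbind, lapply(split(
      all_ceac, list(all_ceac$method, all_ceac$wtp), drop = TRUE),
      function(g) {
        data.frame(method = g$method[1], wtp = g$wtp[1],
                   median = stats::median(g$probability),
                   p2.5 = unname(stats::quantile(g$probability, 0.025)),
                   p97.5 = unname(stats::quantile(g$probability, 0.975)),
                   stringsAsFactors = FALSE)
      }))
    ceac_envelope <- ceac_envelope[order(ceac_envelope$method,
                                         ceac_envelope$wtp), ]
    rownames(ceac_envelope) <- NULL
  }

  structure(list(scenario = scen, n_reps = length(records),
                 parameter_metrics = parameter_metrics,
                 he_metrics = he_metrics,
                 parameter_bands = parameter_bands,
                 he_ranges = he_ranges,
                 ceac_envelope = ceac_envelope),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Performance summary: scenario", x$scenario, "over", x$n_reps,
      "repetitions\n\nParameter band counts:\n")
  print(x$parameter_bands, row.names = FALSE)
  cat("\nHealth-economic outcome ranges:\n")
  print(x$he_ranges, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a full simulation study
#'
#' Convenience wrapper: builds (or accepts) the reference population, runs
#' `n_reps` repetitions of one scenario and summarizes performance.
#'
#' @param spec a [disease_spec()]; default the calibrated default world.
#' @param scenario scenario id or [scenario_spec()].
#' @param methods methods to compare.
#' @param n_reps repetitions (study default 1,000).
#' @param n_pop superpopulation size (study default 50,000).
#' @param psa_iters PSA iterations.
#' @param seed master seed.
#' @param pop optional pre-built reference population (overrides `spec`,
#'   `n_pop`).
#' @param glm_cfg optional [glm_config()] override for the Bayesian methods.
#' @param wtp_grid CEAC grid.
#' @param progress print one line per repetition.
#' @return list with `population` summary (`reference_outcomes`), `records`
#'   and `summary` (a `performance_summary`).
#' @export
run_study <- function(spec = default_disease_spec(), scenario = 1,
                      methods = METHODS, n_reps = 1000, n_pop = 50000,
                      psa_iters = 1100, seed = 1L, pop = NULL,
                      glm_cfg = NULL, wtp_grid = seq(0, 100000, by = 5000),
                      progress = FALSE) {
  stopifnot(n_reps >= 1)
  if (is.null(pop)) {
    pop <- build_reference_population(spec, n = n_pop,
                                      seed = derive_seed(seed, "population"))
  }
  reference <- reference_outcomes(pop)
  records <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- if (is.null(glm_cfg)) NULL else {
      glm_cfg$seed <- derive_seed(seed, "glm", i)
      glm_cfg
    }
    records[[i]] <- run_repetition(pop, scenario, methods,
                                   rep_seed = derive_seed(seed, "rep", i),
                                   psa_iters = psa_iters, glm_cfg = cfg,
                                   wtp_grid = wtp_grid)
    if (progress) message("repetition ", i, "/", n_reps, " done")
  }
  summary <- if (n_reps >= 2) summarize_study(records, reference) else NULL
  list(population = reference, records = records, summary = summary)
}
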