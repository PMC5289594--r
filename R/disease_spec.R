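# Disease world definition: reference disease progression (RDP), additive
# modifiers, costs and utilities.

#' Disease stages, transitions and interventions
#'
#' The simulated chronic disease has four stages (Moderate, Severe,
#' Very Severe, Death) plus a temporary within-cycle event. Twelve
#' effect-bearing parameters drive progression: three progression
#' probabilities (MS, MVS, SVS), three improvement probabilities (SM, VSS,
#' VSM), three death probabilities (MD, SD, VSD) and three per-stage event
#' probabilities (evM, evS, evVS). All are monthly probabilities.
#'
#' @name disease-structure
#' @keywords internal
NULL

STAGES <- c("Moderate", "Severe", "VerySevere", "Death")
TRANSITIONS <- c("MS", "MVS", "SVS", "SM", "VSS", "VSM",
                 "MD", "SD", "VSD", "evM", "evS", "evVS")
INTERVENTIONS <- c("No", "Old", "Usual", "New")

# origin stage (1=Moderate, 2=Severe, 3=VerySevere) of each transition
TRANSITION_FROM <- c(MS = 1L, MVS = 1L, SVS = 2L, SM = 2L, VSS = 3L, VSM = 3L,
                     MD = 1L, SD = 2L, VSD = 3L, evM = 1L, evS = 2L, evVS = 3L)
# destination stage of the nine stage-changing transitions
TRANSITION_TO <- c(MS = 2L, MVS = 3L, SVS = 3L, SM = 1L, VSS = 2L, VSM = 1L,
                   MD = 4L, SD = 4L, VSD = 4L)

CHARACTERISTIC_LEVELS <- list(
  gender = c("male", "female"),
  age_band = c("18-34", "35-64", "65+"),
  country = c("developed", "developing"),
  bmi_cat = c("<25", "25-30", ">30"),
  smoker = c("no", "yes")
)

#' Create a disease specification
#'
#' A `disease_spec` bundles everything that defines the simulated world: the
#' reference disease progression (baseline monthly probabilities of an
#' untreated base-case patient), additive probability modifiers keyed by
#' patient characteristic level and by intervention, and cost/utility
#' parameters with their own characteristic modifiers. Modification is
#' additive throughout: the effective probability of a transition for a given
#' patient and intervention is the RDP value plus the sum of all applicable
#' deltas, clamped to \[0, 1\].
#'
#' @param rdp named numeric vector of length 12 with baseline monthly
#'   probabilities for the transitions `r toString(TRANSITIONS)`.
#' @param characteristic_modifiers data.frame with columns `factor`, `level`,
#'   `transition`, `delta`: additive probability-point changes for patients at
#'   the given characteristic level (base-case levels carry no rows).
#' @param intervention_modifiers data.frame with columns `intervention`,
#'   `transition`, `delta`.
#' @param maintenance_cost numeric length 3: cost in euro per cycle spent in
#'   Moderate/Severe/Very Severe, for the base-case patient.
#' @param event_cost euro per event, base-case patient.
#' @param intervention_costs list per intervention with elements `oneoff`
#'   (euro at cycle 1) and `per_cycle` (euro per alive cycle).
#' @param utilities numeric length 3: yearly utility weight per alive stage,
#'   base-case patient.
#' @param event_decrement utility loss per event, base-case patient.
#' @param cost_utility_modifiers data.frame with columns `factor`, `level`,
#'   `quantity` (one of `"maintenance"`, `"event_cost"`, `"utility"`,
#'   `"event_decrement"`), `delta`: additive changes by characteristic level.
#'   Maintenance and utility deltas apply uniformly across alive stages.
#' @return an object of class `disease_spec`.
#' @seealso [default_disease_spec()], [read_disease_spec()]
#' @export
disease_spec <- function(rdp,
                         characteristic_modifiers,
                         intervention_modifiers,
                         maintenance_cost,
                         event_cost,
                         intervention_costs,
                         utilities,
                         event_decrement,
                         cost_utility_modifiers = empty_cu_modifiers()) {
  rdp <- rdp[TRANSITIONS]
  if (anyNA(rdp)) {
    stop("`rdp` must be a named vector covering all transitions: ",
         toString(TRANSITIONS))
  }
  if (any(rdp < 0 | rdp > 1)) stop("RDP probabilities must lie in [0, 1]")
  check_modifier_frame(characteristic_modifiers,
                       c("factor", "level", "transition", "delta"))
  check_modifier_frame(intervention_modifiers,
                       c("intervention", "transition", "delta"))
  check_modifier_frame(cost_utility_modifiers,
                       c("factor", "level", "quantity", "delta"))
  stopifnot(length(maintenance_cost) == 3, all(maintenance_cost >= 0),
            length(event_cost) == 1, event_cost >= 0,
            length(utilities) == 3, all(utilities >= 0), all(utilities <= 1),
            length(event_decrement) == 1, event_decrement >= 0)
  missing_iv <- setdiff(INTERVENTIONS, names(intervention_costs))
  if (length(missing_iv)) {
    stop("intervention_costs missing entries for: ", toString(missing_iv))
  }
  spec <- structure(list(
    rdp = rdp,
    characteristic_modifiers = characteristic_modifiers,
    intervention_modifiers = intervention_modifiers,
    maintenance_cost = stats::setNames(maintenance_cost, STAGES[1:3]),
    event_cost = unname(event_cost),
    intervention_costs = intervention_costs[INTERVENTIONS],
    utilities = stats::setNames(utilities, STAGES[1:3]),
    event_decrement = unname(event_decrement),
    cost_utility_modifiers = cost_utility_modifiers
  ), class = "disease_spec")
  spec
}

empty_cu_modifiers <- function() {
  data.frame(factor = character(), level = character(),
             quantity = character(), delta = numeric())
}

check_modifier_frame <- function(df, cols) {
  if (!is.data.frame(df) || !all(cols %in% names(df))) {
    stop("modifier table must be a data.frame with columns ", toString(cols))
  }
  if ("transition" %in% cols && nrow(df) &&
      !all(df$transition %in% TRANSITIONS)) {
    stop("unknown transition in modifier table")
  }
  if ("factor" %in% cols && nrow(df)) {
    bad <- !df$factor %in% names(CHARACTERISTIC_LEVELS)
    if (any(bad)) stop("unknown characteristic: ", toString(unique(df$factor[bad])))
    for (f in unique(df$factor)) {
      lv <- df$level[df$factor == f]
      if (!all(lv %in% CHARACTERISTIC_LEVELS[[f]])) {
        stop("unknown level for ", f, ": ", toString(setdiff(lv, CHARACTERISTIC_LEVELS[[f]])))
      }
    }
  }
  invisible(df)
}

#' Default calibrated disease specification
#'
#' The shipped default world. Its headline health-economic outcomes (QALY and
#' cost differences, ICERs between the four interventions) were calibrated by
#' numerical search so that the 50,000-patient reference simulation reproduces
#' the reference-outcome table of the study design this package implements
#' (QALY difference New minus Usual within 0.01, pairwise ICERs within 15%).
#' A user-supplied specification, e.g. a verbatim transcription of an external
#' reference disease progression table, supersedes these defaults via
#' [read_disease_spec()].
#'
#' Anchored values: the untreated base-case probability of moving from Severe
#' to Death is 10% per cycle; being female changes it by -2 percentage
#' points, age 35-64 by +4, and New Intervention by -3.
#'
#' @return a `disease_spec`.
#' @export
default_disease_spec <- function() {
  disease_spec(
    rdp = DEFAULT_RDP,
    characteristic_modifiers = DEFAULT_CHAR_MODIFIERS,
    intervention_modifiers = DEFAULT_INT_MODIFIERS,
    maintenance_cost = DEFAULT_MAINTENANCE_COST,
    event_cost = DEFAULT_EVENT_COST,
    intervention_costs = list(
      No = list(oneoff = 0, per_cycle = 0),
      Old = list(oneoff = 250, per_cycle = 0),
      Usual = list(oneoff = 0, per_cycle = 60),
      New = list(oneoff = 0, per_cycle = 350)
    ),
    utilities = DEFAULT_UTILITIES,
    event_decrement = DEFAULT_EVENT_DECREMENT,
    cost_utility_modifiers = DEFAULT_CU_MODIFIERS
  )
}

#' Read / write a disease specification as JSON
#'
#' The JSON schema mirrors the constructor arguments: blocks `rdp`,
#' `characteristic_modifiers`, `intervention_modifiers`, `costs`
#' (`maintenance`, `event`, `interventions`), `utilities` (`stage`,
#' `event_decrement`) and `cost_utility_modifiers`. Fields omitted from the
#' file fall back to the calibrated defaults, so a partial transcription of a
#' reference disease progression table can override only the probability
#' blocks.
#'
#' @param path file path.
#' @return `read_disease_spec()` returns a `disease_spec`;
#'   `write_disease_spec()` returns `path` invisibly.
#' @export
read_disease_spec <- function(path) {
  if (!file.exists(path)) stop("disease spec file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  def <- default_disease_spec()
  rdp <- def$rdp
  if (!is.null(raw$rdp)) {
    vals <- unlist(raw$rdp)
    unknown <- setdiff(names(vals), TRANSITIONS)
    if (length(unknown)) stop("unknown transitions in rdp block: ", toString(unknown))
    rdp[names(vals)] <- vals
  }
  pick <- function(x, fallback) if (is.null(x)) fallback else x
  ivc <- def$intervention_costs
  if (!is.null(raw$costs$interventions)) {
    for (nm in names(raw$costs$interventions)) {
      ivc[[nm]] <- utils::modifyList(ivc[[nm]], raw$costs$interventions[[nm]])
    }
  }
  disease_spec(
    rdp = rdp,
    characteristic_modifiers = pick(raw$characteristic_modifiers,
                                    def$characteristic_modifiers),
    intervention_modifiers = pick(raw$intervention_modifiers,
                                  def$intervention_modifiers),
    maintenance_cost = pick(unlist(raw$costs$maintenance),
                            unname(def$maintenance_cost)),
    event_cost = pick(raw$costs$event, def$event_cost),
    intervention_costs = ivc,
    utilities = pick(unlist(raw$utilities$stage), unname(def$utilities)),
    event_decrement = pick(raw$utilities$event_decrement, def$event_decrement),
    cost_utility_modifiers = pick(raw$cost_utility_modifiers,
                                  def$cost_utility_modifiers)
  )
}

#' @rdname read_disease_spec
#' @param spec a `disease_spec`.
#' @export
write_disease_spec <- function(spec, path) {
  stopifnot(inherits(spec, "disease_spec"))
  out <- list(
    rdp = as.list(spec$rdp),
    characteristic_modifiers = spec$characteristic_modifiers,
    intervention_modifiers = spec$intervention_modifiers,
    costs = list(
      maintenance = unname(spec$maintenance_cost),
      event = spec$event_cost,
      interventions = spec$intervention_costs
    ),
    utilities = list(
      stage = unname(spec$utilities),
      event_decrement = spec$event_decrement
    ),
    cost_utility_modifiers = spec$cost_utility_modifiers
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.disease_spec <- function(x, ...) {
  cat("Disease specification (4-stage monthly chronic disease model)\n")
  cat("  RDP:\n")
  print(round(x$rdp, 4))
  cat("  characteristic modifiers:", nrow(x$characteristic_modifiers), "rows\n")
  cat("  intervention modifiers:  ", nrow(x$intervention_modifiers), "rows\n")
  cat("  maintenance cost/cycle:  ", paste(x$maintenance_cost, collapse = " / "),
      "euro (M/S/VS)\n")
  cat("  event cost:", x$event_cost, "euro; utilities:",
      paste(x$utilities, collapse = " / "), "\n")
  invisible(x)
}
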