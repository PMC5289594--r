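# Numeric content of the default calibrated world. Probability values are in
# absolute probability points per monthly cycle. The Severe->Death anchor
# (RDP 0.10; female -0.02; age 35-64 +0.04; New Intervention -0.03) is fixed;
# the remaining values were obtained by least-squares calibration of the
# exact covariate-class cohort expectation against the target reference
# outcomes, then rounded to 0.5 probability points (see the methods
# vignette). Regenerate with tools/calibrate_default_spec.R.

mod_row <- function(factor, level, transition, delta) {
  data.frame(factor = factor, level = level, transition = transition,
             delta = delta, stringsAsFactors = FALSE)
}

DEFAULT_RDP <- c(
  MS  = 0.140, MVS = 0.059, SVS = 0.043,
  SM  = 0.249, VSS = 0.250, VSM = 0.248,
  MD  = 0.000, SD  = 0.100, VSD = 0.119,
  evM = 0.068, evS = 0.091, evVS = 0.470
)

DEFAULT_CHAR_MODIFIERS <- do.call(rbind, list(
  # gender: females die somewhat less at every stage
  mod_row("gender", "female", c("MD", "SD", "VSD"), c(-0.01, -0.02, -0.03)),
  # age bands: older patients progress, die and have events more often,
  # improve less; 18-34 is the base case
  mod_row("age_band", "35-64", c("MS", "MVS", "SVS"), c(0.02, 0.02, 0.02)),
  mod_row("age_band", "35-64", c("MD", "SD", "VSD"), c(0.02, 0.04, 0.06)),
  mod_row("age_band", "35-64", c("evM", "evS", "evVS"), c(0.01, 0.01, 0.01)),
  mod_row("age_band", "65+", c("MS", "MVS", "SVS"), c(0.04, 0.04, 0.04)),
  mod_row("age_band", "65+", c("MD", "SD", "VSD"), c(0.04, 0.08, 0.12)),
  mod_row("age_band", "65+", c("evM", "evS", "evVS"), c(0.02, 0.02, 0.02)),
  mod_row("age_band", "65+", c("SM", "VSS", "VSM"), c(-0.02, -0.02, -0.01)),
  # smoking: faster deterioration and more events
  mod_row("smoker", "yes", c("MS", "MVS", "SVS"), c(0.03, 0.03, 0.03)),
  mod_row("smoker", "yes", c("MD", "SD", "VSD"), c(0.02, 0.02, 0.02)),
  mod_row("smoker", "yes", c("evM", "evS", "evVS"), c(0.02, 0.02, 0.02)),
  # BMI categories (<25 is the base case)
  mod_row("bmi_cat", "25-30", c("MS", "MVS", "SVS"), c(0.01, 0.01, 0.01)),
  mod_row("bmi_cat", "25-30", c("evM", "evS", "evVS"), c(0.01, 0.01, 0.01)),
  mod_row("bmi_cat", ">30", c("MS", "MVS", "SVS"), c(0.03, 0.03, 0.03)),
  mod_row("bmi_cat", ">30", c("MD", "SD", "VSD"), c(0.02, 0.02, 0.02)),
  mod_row("bmi_cat", ">30", c("evM", "evS", "evVS"), c(0.02, 0.02, 0.02)),
  # developing country: slightly higher mortality and event risk
  mod_row("country", "developing", c("MD", "SD", "VSD"), c(0.01, 0.01, 0.01)),
  mod_row("country", "developing", c("evM", "evS", "evVS"), c(0.005, 0.005, 0.005))
))

DEFAULT_INT_MODIFIERS <- local({
  iv <- function(intervention, transition, delta) {
    data.frame(intervention = intervention, transition = transition,
               delta = delta, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # Old Intervention: fewer events, lower mortality
    iv("Old", c("evM", "evS", "evVS"), c(-0.034, -0.034, -0.034)),
    iv("Old", c("MD", "SD", "VSD"), c(-0.010, -0.020, -0.030)),
    # Usual Care: slower progression
    iv("Usual", c("MS", "MVS", "SVS"), c(-0.073, -0.003, -0.003)),
    # New Intervention: slower progression, more improvement, fewer events,
    # lower mortality (Severe->Death anchored at -0.03)
    iv("New", c("MS", "MVS", "SVS"), c(-0.045, -0.036, -0.034)),
    iv("New", c("SM", "VSS", "VSM"), c(0.020, 0.003, 0.002)),
    iv("New", c("evM", "evS", "evVS"), c(-0.061, -0.061, -0.061)),
    iv("New", c("MD", "SD", "VSD"), c(-0.015, -0.030, -0.045))
  ))
})

DEFAULT_MAINTENANCE_COST <- c(118, 239, 1546)
DEFAULT_EVENT_COST <- 2250
DEFAULT_UTILITIES <- c(0.893, 0.443, 0.443)
DEFAULT_EVENT_DECREMENT <- 0.0043

DEFAULT_CU_MODIFIERS <- do.call(rbind, list(
  data.frame(factor = "smoker", level = "yes", quantity = "maintenance",
             delta = 120, stringsAsFactors = FALSE),
  data.frame(factor = "bmi_cat", level = ">30", quantity = "maintenance",
             delta = 200, stringsAsFactors = FALSE),
  data.frame(factor = "age_band", level = "65+", quantity = "maintenance",
             delta = 160, stringsAsFactors = FALSE),
  data.frame(factor = "country", level = "developing", quantity = "event_cost",
             delta = -500, stringsAsFactors = FALSE),
  data.frame(factor = "smoker", level = "yes", quantity = "utility",
             delta = -0.06, stringsAsFactors = FALSE),
  data.frame(factor = "bmi_cat", level = ">30", quantity = "utility",
             delta = -0.10, stringsAsFactors = FALSE),
  data.frame(factor = "age_band", level = "65+", quantity = "utility",
             delta = -0.08, stringsAsFactors = FALSE),
  data.frame(factor = "smoker", level = "yes", quantity = "event_decrement",
             delta = 0.002, stringsAsFactors = FALSE),
  data.frame(factor = "bmi_cat", level = ">30", quantity = "event_decrement",
             delta = 0.002, stringsAsFactors = FALSE)
))
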