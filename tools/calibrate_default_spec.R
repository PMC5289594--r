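# Calibration of the default disease world: stage maintenance costs and
# utilities join the free parameters; the objective targets the
# per-intervention QALY and total-cost levels (which pin every pairwise
# ICER) plus the Usual/New occupancy rows. Run from the repo root and paste
# the rounded values into R/disease_defaults.R.
library(nmahesim)

cls <- nmahesim:::covariate_classes()
TR <- nmahesim:::TRANSITIONS
def <- default_disease_spec()
D <- t(vapply(seq_len(nrow(cls)), function(i) {
  roster <- nmahesim:::class_roster_row(cls[i, ])
  nmahesim:::characteristic_deltas(roster, def)[1, ]
}, numeric(12)))
colnames(D) <- TR
w <- cls$weight
cu <- lapply(seq_len(nrow(cls)), function(i) {
  nmahesim:::cost_utility_deltas(nmahesim:::class_roster_row(cls[i, ]), def)
})
maint_mod <- vapply(cu, function(x) x$maintenance, 0)
evcost_mod <- vapply(cu, function(x) x$event_cost, 0)
util_mod <- vapply(cu, function(x) x$utility, 0)
dec_mod <- vapply(cu, function(x) x$event_decrement, 0)

EVCOST <- def$event_cost; DEC <- def$event_decrement
IVC <- def$intervention_costs
start_vec <- c(5, 2, 1, 0) / 8

# par: 1-11 rdp (MS MVS SVS SM VSS VSM MD VSD evM evS evVS); SD=0.10
# 12-14 usual prog; 15-17 new prog; 18-20 new improvement
# 21 new event; 22 old event; 23 old death scale
# 24-26 maintenance (M S VS); 27-29 utilities (M S VS)
int_delta <- function(par, ivn) {
  d <- setNames(numeric(12), TR)
  if (ivn == "Old") {
    d[c("evM", "evS", "evVS")] <- -par[22]
    d[c("MD", "SD", "VSD")] <- par[23] * c(-0.01, -0.02, -0.03)
  } else if (ivn == "Usual") {
    d[c("MS", "MVS", "SVS")] <- -par[12:14]
  } else if (ivn == "New") {
    d[c("MS", "MVS", "SVS")] <- -par[15:17]
    d[c("SM", "VSS", "VSM")] <- par[18:20]
    d[c("evM", "evS", "evVS")] <- -par[21]
    d[c("MD", "SD", "VSD")] <- c(-0.015, -0.030, -0.045)
  }
  d
}

outcomes_iv <- function(par, ivn) {
  rdp <- setNames(c(par[1:7], 0.10, par[8], par[9:11]),
                  c("MS","MVS","SVS","SM","VSS","VSM","MD","SD","VSD","evM","evS","evVS"))[TR]
  P <- sweep(D, 2, rdp + int_delta(par, ivn), "+")
  P[P < 0] <- 0; P[P > 1] <- 1
  for (cols in list(c("MS","MVS","MD"), c("SVS","SM","SD"), c("VSS","VSM","VSD"))) {
    tot <- rowSums(P[, cols]); over <- tot > 1
    if (any(over)) P[over, cols] <- P[over, cols] / tot[over]
  }
  nc <- nrow(cls)
  occ <- matrix(rep(start_vec, each = nc), nc, 4)
  cycles <- matrix(0, nc, 4); events <- numeric(nc)
  for (cyc in 1:12) {
    cycles <- cycles + occ
    events <- events + occ[, 1] * P[, "evM"] + occ[, 2] * P[, "evS"] + occ[, 3] * P[, "evVS"]
    if (cyc < 12) {
      o1 <- occ[,1]*(1 - P[,"MS"] - P[,"MVS"] - P[,"MD"]) + occ[,2]*P[,"SM"] + occ[,3]*P[,"VSM"]
      o2 <- occ[,1]*P[,"MS"] + occ[,2]*(1 - P[,"SVS"] - P[,"SM"] - P[,"SD"]) + occ[,3]*P[,"VSS"]
      o3 <- occ[,1]*P[,"MVS"] + occ[,2]*P[,"SVS"] + occ[,3]*(1 - P[,"VSS"] - P[,"VSM"] - P[,"VSD"])
      o4 <- occ[,4] + occ[,1]*P[,"MD"] + occ[,2]*P[,"SD"] + occ[,3]*P[,"VSD"]
      occ <- cbind(o1, o2, o3, o4)
    }
  }
  MAINT <- par[24:26]; UTIL <- par[27:29]
  alive <- cycles[, 1:3] %*% rep(1, 3)
  maint <- cycles[, 1:3] %*% MAINT + alive * maint_mod
  qaly <- (cycles[, 1:3] %*% UTIL + alive * util_mod) / 12 - events * (DEC + dec_mod)
  evcost <- events * (EVCOST + evcost_mod)
  ivc <- IVC[[ivn]]
  ivcost <- ivc$oneoff + ivc$per_cycle * alive
  list(cycles = colSums(cycles * w), events = sum(events * w),
       qaly = sum(qaly * w), ly = sum(alive * w) / 12,
       total_cost = sum((maint + evcost + ivcost) * w))
}

qc_targets <- c(No_q = 0.4440, Old_q = 0.4746, Usual_q = 0.4854, New_q = 0.5397,
                No_c = 5551, Old_c = 5658, Usual_c = 6120, New_c = 7640)
occ_targets <- list(
  Usual = list(cycles = c(5.171, 2.477, 1.238, 3.114), events = 1.160),
  New = list(cycles = c(6.209, 2.313, 0.911, 2.567), events = 0.630))

softbox <- function(x, lo, hi) sum(pmax(0, lo - x)^2 + pmax(0, x - hi)^2) * 1e4

objective <- function(par) {
  pen <- softbox(par[1:3], 0.01, 0.30) +      # progression rdp
    softbox(par[4:6], 0.01, 0.25) +           # improvement rdp
    softbox(par[7], 0.005, 0.08) +            # MD
    softbox(par[8], 0.12, 0.40) +             # VSD
    softbox(par[9:11], 0.02, 0.45) +
    softbox(par[12:21], 0.002, 0.10) +
    softbox(par[22], 0.002, 0.10) + softbox(par[23], 0.2, 2.5) +
    softbox(par[24], 50, 400) + softbox(par[25], 200, 800) +
    softbox(par[26], 600, 1600) +
    softbox(par[27], 0.60, 0.95) + softbox(par[28], 0.35, 0.75) +
    softbox(par[29], 0.10, 0.50) +
    softbox(par[10] - par[9], 0, 1) + softbox(par[11] - par[10], 0, 1) +
    softbox(par[25] - par[24], 0, 1e9) + softbox(par[26] - par[25], 0, 1e9) +
    softbox(par[27] - par[28], 0, 1) + softbox(par[28] - par[29], 0, 1)
  out <- lapply(c(No = "No", Old = "Old", Usual = "Usual", New = "New"),
                function(ivn) outcomes_iv(par, ivn))
  q <- vapply(out, `[[`, 0.0, "qaly")
  cst <- vapply(out, `[[`, 0.0, "total_cost")
  err <- pen
  err <- err + sum(((q - qc_targets[1:4]) / 0.01)^2) * 1.0        # ~0.002 QALY accuracy
  err <- err + sum(((cst - qc_targets[5:8]) / 150)^2) * 1.0
  for (ivn in c("Usual", "New")) {
    tg <- occ_targets[[ivn]]
    err <- err + sum(((out[[ivn]]$cycles - tg$cycles) / 0.6)^2) * 1.0 +
      ((out[[ivn]]$events - tg$events) / 0.1)^2 * 1.0
  }
  err
}

report <- function(par, label) {
  cat("\n==", label, "==\n")
  qc <- sapply(c("No", "Old", "Usual", "New"), function(ivn) {
    out <- outcomes_iv(par, ivn)
    cat(sprintf("%6s cycles %s events %.3f qaly %.4f ly %.4f cost %.0f\n",
                ivn, paste(sprintf("%.3f", out$cycles), collapse = " "),
                out$events, out$qaly, out$ly, out$total_cost))
    c(q = out$qaly, c = out$total_cost)
  })
  icer <- function(a, b) (qc["c", a] - qc["c", b]) / (qc["q", a] - qc["q", b])
  cat(sprintf("dQALY NvU %.4f (0.054 +-0.01)\n", qc["q","New"] - qc["q","Usual"]))
  cat(sprintf("ICERs: NvU %.0f (28020) NvO %.0f (30440) UvO %.0f (42760) NvNo %.0f (21830) UvNo %.0f (13750) OvNo %.0f (3680)\n",
              icer("New","Usual"), icer("New","Old"), icer("Usual","Old"),
              icer("New","No"), icer("Usual","No"), icer("Old","No")))
  invisible(qc)
}

start0 <- c(0.16, 0.04, 0.15, 0.08, 0.08, 0.03, 0.03, 0.18,
            0.07, 0.15, 0.25,
            0.05, 0.02, 0.05, 0.06, 0.025, 0.06, 0.04, 0.04, 0.02,
            0.08, 0.05, 1.0,
            200, 400, 1000, 0.80, 0.55, 0.30)

set.seed(77001)
best <- NULL
for (s in 1:10) {
  st <- if (s == 1) start0 else {
    v <- start0 * exp(rnorm(29, 0, 0.25)); v
  }
  f <- tryCatch(optim(st, objective, method = "BFGS",
                      control = list(maxit = 600, reltol = 1e-12)),
                error = function(e) NULL)
  if (is.null(f)) next
  f <- optim(f$par, objective, method = "Nelder-Mead",
             control = list(maxit = 12000, reltol = 1e-13))
  f2 <- tryCatch(optim(f$par, objective, method = "BFGS",
                       control = list(maxit = 600)), error = function(e) f)
  if (f2$value < f$value) f <- f2
  cat("start", s, "obj:", f$value, "\n")
  if (is.null(best) || f$value < best$value) best <- f
}
cat("\nbest obj:", best$value, "\n")
report(best$par, "optimum")
cat("\npar:", paste(sprintf("%.5f", best$par), collapse = ", "), "\n")
rounded <- c(round(best$par[1:22] * 200) / 200, round(best$par[23] * 4) / 4,
             round(best$par[24:26]), round(best$par[27:29] * 200) / 200)
cat("\nrounded objective:", objective(rounded), "\n")
report(rounded, "rounded")
cat("\nrounded par:", paste(sprintf("%.4f", rounded), collapse = ", "), "\n")
saveRDS(list(best = best, rounded = rounded), "/root/pkg/scratch/calib3.rds")
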