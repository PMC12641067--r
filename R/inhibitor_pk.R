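#' Rifampicin total plasma concentration
#'
#' Closed-form one-compartment model with lag time, zero-order absorption of
#' duration `Tk0`, and linear elimination; multiple doses superpose.
#'
#' @param t Times (h, >= 0) at which to evaluate the concentration.
#' @param doses Dose events, see [dose_events()]; all must be rifampicin.
#' @param p A [rifampicin_params()] object.
#' @return Total plasma concentration (uM), same length as `t`.
#' @export
rifampicin_conc <- function(t, doses, p) {
  if (any(t < 0)) stop("t must be non-negative")
  if (nrow(doses) && !all(doses$drug == "rifampicin"))
    stop("all dose events must be rifampicin")
  conc <- numeric(length(t))
  k <- p$CL / p$V
  for (i in seq_len(nrow(doses))) {
    amt <- doses$amount[i] / p$MW * 1000  # mg -> umol
    conc <- conc + .rif_one_dose(t - doses$time[i], amt, p$Tlag, p$Tk0, p$V, k)
  }
  conc
}

# Single-dose zero-order-absorption profile; tau is time since dosing.
.rif_one_dose <- function(tau, amt_umol, Tlag, Tk0, V, k) {
  s <- tau - Tlag
  r0 <- amt_umol / Tk0                 # zero-order input rate, umol/h
  cmax_coef <- r0 / (k * V)
  out <- numeric(length(tau))
  dur <- pmin(s, Tk0)
  on <- s > 0
  # during input: (R0/kV)(1 - e^{-ks}); after: value at Tk0 decayed
  out[on] <- cmax_coef * (1 - exp(-k * dur[on])) *
    exp(-k * pmax(s[on] - Tk0, 0))
  out
}

#' Probenecid total plasma concentration
#'
#' Closed-form one-compartment model with first-order absorption (Bateman
#' function) and linear elimination; multiple doses superpose. Complete oral
#' bioavailability is assumed, consistent with apparent volume and clearance.
#' The degenerate case `ka == CL/V` is handled by the analytic limit
#' `(D/V) ka tau exp(-ka tau)`.
#'
#' @param t Times (h, >= 0).
#' @param doses Dose events, see [dose_events()]; all must be probenecid.
#' @param p A [probenecid_params()] object.
#' @return Total plasma concentration (uM), same length as `t`.
#' @export
probenecid_conc <- function(t, doses, p) {
  if (any(t < 0)) stop("t must be non-negative")
  if (nrow(doses) && !all(doses$drug == "probenecid"))
    stop("all dose events must be probenecid")
  conc <- numeric(length(t))
  k <- p$CL / p$V
  for (i in seq_len(nrow(doses))) {
    amt <- doses$amount[i] / p$MW * 1000
    conc <- conc + .bateman(t - doses$time[i], amt, p$ka, k, p$V)
  }
  conc
}

.bateman <- function(tau, amt_umol, ka, k, V) {
  out <- numeric(length(tau))
  on <- tau > 0
  s <- tau[on]
  if (abs(ka - k) < 1e-8 * ka) {
    out[on] <- (amt_umol / V) * ka * s * exp(-ka * s)
  } else {
    out[on] <- (amt_umol / V) * ka / (ka - k) * (exp(-k * s) - exp(-ka * s))
  }
  out
}

# ---- vectorized-across-subjects closed forms (internal) -------------------
# Subject parameters enter as vectors; returns an n_time x n_subj matrix of
# TOTAL concentrations. Dose schedules are shared across subjects.

.rif_conc_mat <- function(tgrid, dose_times, dose_amts, Tlag, Tk0, V, CL, MW) {
  nt <- length(tgrid); ns <- length(V)
  out <- matrix(0, nt, ns)
  k <- matrix(CL / V, nt, ns, byrow = TRUE)
  TlagM <- matrix(Tlag, nt, ns, byrow = TRUE)
  Tk0M <- matrix(Tk0, nt, ns, byrow = TRUE)
  coefM <- matrix(1 / (CL * Tk0), nt, ns, byrow = TRUE)  # 1/(kV Tk0)
  for (i in seq_along(dose_times)) {
    amt <- dose_amts[i] / MW * 1000
    s <- matrix(tgrid - dose_times[i], nt, ns) - TlagM
    on <- s > 0
    dur <- pmin(s, Tk0M)
    v <- amt * coefM * (1 - exp(-k * dur)) * exp(-k * pmax(s - Tk0M, 0))
    v[!on] <- 0
    out <- out + v
  }
  out
}

.prob_conc_mat <- function(tgrid, dose_times, dose_amts, ka, V, CL, MW) {
  nt <- length(tgrid); ns <- length(V)
  out <- matrix(0, nt, ns)
  kel <- CL / V
  kaM <- matrix(ka, nt, ns, byrow = TRUE)
  kM <- matrix(kel, nt, ns, byrow = TRUE)
  degen <- abs(kaM - kM) < 1e-8 * kaM
  fM <- matrix(ka / (V * ifelse(abs(ka - kel) < 1e-8 * ka, 1, ka - kel)),
               nt, ns, byrow = TRUE)
  for (i in seq_along(dose_times)) {
    amt <- dose_amts[i] / MW * 1000
    s <- matrix(tgrid - dose_times[i], nt, ns)
    on <- s > 0
    v <- amt * fM * (exp(-kM * s) - exp(-kaM * s))
    if (any(degen))
      v[degen] <- (amt * kaM * s * exp(-kaM * s) / matrix(V, nt, ns, byrow = TRUE))[degen]
    v[!on] <- 0
    out <- out + v
  }
  out
}
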