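#' Structural parameters of the rifampicin plasma model
#'
#' One-compartment disposition with a lag time, zero-order absorption over a
#' fixed duration, and linear elimination. Doses in mg are converted to umol
#' through the molecular weight, so concentrations are expressed in uM.
#'
#' @param Tlag Absorption lag time (h).
#' @param Tk0 Duration of the zero-order absorption window (h).
#' @param V Apparent volume of distribution (L).
#' @param CL Apparent clearance (L/h).
#' @param fu Unbound fraction in plasma (0-1]; the inhibition terms act on
#'   unbound concentration `fu * C`.
#' @param MW Molecular weight (g/mol).
#' @param Ki_u_OATP1B3 Unbound competitive inhibition constant against
#'   OATP1B3-mediated hepatic uptake of the biomarker (uM).
#' @return An object of class `rifampicin_params`.
#' @export
rifampicin_params <- function(Tlag = 0.56, Tk0 = 0.84, V = 35, CL = 6.7,
                              fu = 0.15, MW = 822.94, Ki_u_OATP1B3 = 0.009) {
  p <- list(Tlag = Tlag, Tk0 = Tk0, V = V, CL = CL, fu = fu, MW = MW,
            Ki_u_OATP1B3 = Ki_u_OATP1B3)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rifampicin parameters must be finite and strictly positive")
  if (fu > 1) stop("fu must lie in (0, 1]")
  structure(p, class = "rifampicin_params")
}

#' Structural parameters of the probenecid plasma model
#'
#' One-compartment disposition with first-order absorption (Bateman input)
#' and linear elimination. `X` is the fold reduction in biomarker hepatic
#' clearance during probenecid treatment, capturing its weak secondary
#' OATP1B3 effect; `X = 1` means no effect.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param V Apparent volume of distribution (L).
#' @param CL Apparent clearance (L/h).
#' @param fu Unbound fraction in plasma (0-1].
#' @param MW Molecular weight (g/mol).
#' @param Ki_u_OAT3 Unbound competitive inhibition constant against
#'   OAT3-mediated renal secretion of the biomarker (uM).
#' @param X Fold reduction in biomarker hepatic clearance while on
#'   probenecid (dimensionless, >= 1).
#' @return An object of class `probenecid_params`.
#' @export
probenecid_params <- function(ka = 1.1, V = 17, CL = 0.95, fu = 0.10,
                              MW = 285.36, Ki_u_OAT3 = 2.7, X = 1.7) {
  p <- list(ka = ka, V = V, CL = CL, fu = fu, MW = MW,
            Ki_u_OAT3 = Ki_u_OAT3, X = X)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all probenecid parameters must be finite and strictly positive")
  if (fu > 1) stop("fu must lie in (0, 1]")
  if (X < 1) stop("X must be >= 1 (fold reduction in hepatic clearance)")
  structure(p, class = "probenecid_params")
}

#' Structural parameters of the biomarker turnover model
#'
#' Zero-order synthesis into a single central compartment with parallel
#' first-order hepatobiliary and renal clearances. The pre-treatment steady
#' state is `ksyn / (CLh + CLR)`.
#'
#' @param ksyn Zero-order synthesis rate (umol/h).
#' @param Vc Central volume of distribution (L).
#' @param CLh Hepatobiliary clearance (L/h).
#' @param CLR Renal clearance (L/h).
#' @return An object of class `biomarker_params`.
#' @export
biomarker_params <- function(ksyn = 1.0, Vc = 4.8, CLh = 15, CLR = 0.31) {
  p <- list(ksyn = ksyn, Vc = Vc, CLh = CLh, CLR = CLR)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all biomarker parameters must be finite and strictly positive")
  structure(p, class = "biomarker_params")
}

#' Dose events
#'
#' @param drug `"rifampicin"` or `"probenecid"` (recycled).
#' @param time Dose times in hours from occasion start (non-decreasing).
#' @param amount Dose amounts in mg (> 0, recycled).
#' @return A data frame with columns `drug`, `time`, `amount`.
#' @export
dose_events <- function(drug, time, amount) {
  d <- data.frame(drug = as.character(drug), time = as.numeric(time),
                  amount = as.numeric(amount), stringsAsFactors = FALSE)
  if (!all(d$drug %in% c("rifampicin", "probenecid")))
    stop("drug must be 'rifampicin' or 'probenecid'")
  if (any(d$amount <= 0)) stop("dose amounts must be positive")
  if (is.unsorted(d$time)) stop("dose times must be non-decreasing")
  d
}

#' Pre-treatment steady-state biomarker concentration
#'
#' In the absence of inhibitors the turnover model sits at its steady state
#' `ksyn / (CLh + CLR)`.
#'
#' @param bp A [biomarker_params()] object.
#' @return Baseline plasma concentration (uM).
#' @export
baseline_concentration <- function(bp) {
  bp$ksyn / (bp$CLh + bp$CLR)
}

#' Convert a reported IIV percentage to a log-scale standard deviation
#'
#' Population tables conventionally report inter-individual variability as a
#' percentage. Under the default convention that percentage is 100 * omega,
#' the SD of the log-normal random effect. The exact coefficient-of-variation
#' convention `omega = sqrt(log(1 + (cv/100)^2))` is also available.
#'
#' @param cv_percent Reported IIV (%), non-negative.
#' @param convention `"omega_percent"` (default) or `"exact_cv"`.
#' @return omega, the SD of the log-scale random effect.
#' @export
cv_to_omega <- function(cv_percent, convention = c("omega_percent", "exact_cv")) {
  convention <- match.arg(convention)
  if (any(cv_percent < 0)) stop("cv_percent must be non-negative")
  switch(convention,
         omega_percent = cv_percent / 100,
         exact_cv = sqrt(log(1 + (cv_percent / 100)^2)))
}

# Canonical observable names used throughout the package (DVID codes 1-4).
.observables <- c("biomarker_plasma", "biomarker_urine",
                  "rifampicin_plasma", "probenecid_plasma")

#' Final population parameter estimates of the coupled models
#'
#' Returns the fixed effects, inter-individual variabilities and residual
#' error magnitudes of the final coupled rifampicin / probenecid / GCDCA-S
#' models, together with the configuration constants (unbound fractions and
#' molecular weights) needed to form unbound inhibitor concentrations from
#' total plasma concentrations. The unbound fractions are assumptions, not
#' estimates, and can be overridden.
#'
#' @param iiv_convention Convention used to map reported IIV percentages to
#'   log-scale SDs, see [cv_to_omega()].
#' @param fu_RIF,fu_PROB Unbound plasma fractions of rifampicin and
#'   probenecid (assumed constants).
#' @return A list of class `population_parameters` with elements
#'   `fixed` (named typical values), `iiv` (named log-scale SDs; parameters
#'   without IIV are absent), `residual` (per observable, proportional SD as
#'   a fraction and additive SD in observable units, plus a `fixed` flag for
#'   the additive component), `constants` (fu and MW values) and
#'   `fixed_flags` (parameters held fixed during estimation).
#' @export
default_population <- function(iiv_convention = c("omega_percent", "exact_cv"),
                               fu_RIF = 0.15, fu_PROB = 0.10) {
  iiv_convention <- match.arg(iiv_convention)
  iiv_pct <- c(V_PROB = 31, CL_PROB = 27, Ki_u_OAT3 = 32,
               Tlag_RIF = 46, Tk0_RIF = 77, CL_RIF = 18,
               ksyn = 61, CLR = 24)
  pop <- list(
    fixed = c(ka_PROB = 1.1, V_PROB = 17, CL_PROB = 0.95,
              Ki_u_OAT3 = 2.7, X = 1.7,
              Tlag_RIF = 0.56, Tk0_RIF = 0.84, V_RIF = 35, CL_RIF = 6.7,
              Ki_u_OATP1B3 = 0.009,
              ksyn = 1.0, Vc = 4.8, CLR = 0.31, CLh = 15),
    iiv = cv_to_omega(iiv_pct, iiv_convention),
    residual = list(
      biomarker_plasma  = list(prop = 0.45, add = 0,     add_fixed = TRUE),
      biomarker_urine   = list(prop = 0.29, add = 0,     add_fixed = TRUE),
      rifampicin_plasma = list(prop = 0.20, add = 0.2,   add_fixed = TRUE),
      probenecid_plasma = list(prop = 0.23, add = 0.001, add_fixed = TRUE)),
    constants = c(fu_RIF = fu_RIF, fu_PROB = fu_PROB,
                  MW_RIF = 822.94, MW_PROB = 285.36),
    fixed_flags = "Vc",
    iiv_convention = iiv_convention)
  class(pop) <- "population_parameters"
  pop
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population PK parameters (coupled inhibitor-biomarker models)\n")
  cat("Fixed effects:\n")
  print(round(x$fixed, 4))
  cat("IIV (omega, log-scale SD):\n")
  print(round(x$iiv, 4))
  cat("Residual error (proportional fraction / additive):\n")
  for (obs in names(x$residual))
    cat(sprintf("  %-18s prop %.3f  add %.4g%s\n", obs,
                x$residual[[obs]]$prop, x$residual[[obs]]$add,
                if (isTRUE(x$residual[[obs]]$add_fixed)) " (fixed)" else ""))
  cat("Constants:", paste(names(x$constants), signif(x$constants, 6),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Extract the three structural parameter objects for one individual (or the
# typical individual when ind is NULL) from a population_parameters object.
.structural_params <- function(pop, ind = NULL) {
  th <- if (is.null(ind)) pop$fixed else ind
  cs <- pop$constants
  list(
    rif = rifampicin_params(Tlag = th[["Tlag_RIF"]], Tk0 = th[["Tk0_RIF"]],
                            V = th[["V_RIF"]], CL = th[["CL_RIF"]],
                            fu = cs[["fu_RIF"]], MW = cs[["MW_RIF"]],
                            Ki_u_OATP1B3 = th[["Ki_u_OATP1B3"]]),
    prob = probenecid_params(ka = th[["ka_PROB"]], V = th[["V_PROB"]],
                             CL = th[["CL_PROB"]], fu = cs[["fu_PROB"]],
                             MW = cs[["MW_PROB"]], Ki_u_OAT3 = th[["Ki_u_OAT3"]],
                             X = th[["X"]]),
    bp = biomarker_params(ksyn = th[["ksyn"]], Vc = th[["Vc"]],
                          CLh = th[["CLh"]], CLR = th[["CLR"]]))
}
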