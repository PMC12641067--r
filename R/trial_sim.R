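# DVID codes of the dataset dialect
.dvid_codes <- c(biomarker_plasma = 1L, biomarker_urine = 2L,
                 rifampicin_plasma = 3L, probenecid_plasma = 4L)

# Simulate one occasion for a block of subjects sharing the design.
# ind is a parameter matrix [param x n]; returns model predictions (no
# residual error): biomarker plasma [n_bm x n], urine interval amounts
# [n_int x n], inhibitor plasma [n_inh x n].
.simulate_occasion_block <- function(occ, duration, pop, ind,
                                     scales = c(oatp1b3 = 1, oat3 = 1),
                                     grid_step = 0.05,
                                     probenecid_occasion = NULL) {
  n <- ncol(ind)
  cs <- pop$constants
  reg <- occ$regimen
  rd <- if (!is.null(reg)) reg[reg$drug == "rifampicin", , drop = FALSE] else NULL
  pd <- if (!is.null(reg)) reg[reg$drug == "probenecid", , drop = FALSE] else NULL
  has_rif <- !is.null(rd) && nrow(rd) > 0
  has_prob <- !is.null(pd) && nrow(pd) > 0
  if (is.null(probenecid_occasion)) probenecid_occasion <- has_prob

  ub <- if (is.null(occ$urine_intervals)) numeric(0) else as.numeric(occ$urine_intervals)
  C0 <- ind["ksyn", ] / (ind["CLh", ] + ind["CLR", ])
  if (!has_rif && !has_prob && !probenecid_occasion) {
    # steady state: constant concentration, linear urine accumulation
    bm <- matrix(C0, length(occ$biomarker_times), n, byrow = TRUE)
    ur <- if (length(ub)) {
      w <- occ$urine_intervals[, 2] - occ$urine_intervals[, 1]
      outer(w, C0 * ind["CLR", ])
    } else matrix(0, 0, n)
    inh <- matrix(0, length(occ$inhibitor_times), n)
    return(list(biomarker = bm, urine = ur, inhibitor = inh))
  }

  grid <- .make_grid(duration, grid_step, rd, pd,
                     pop$fixed[["Tlag_RIF"]], pop$fixed[["Tk0_RIF"]],
                     extra = c(occ$biomarker_times, ub))
  crif <- if (has_rif)
    .rif_conc_mat(grid, rd$time, rd$amount, ind["Tlag_RIF", ], ind["Tk0_RIF", ],
                  ind["V_RIF", ], ind["CL_RIF", ], cs[["MW_RIF"]])
  else matrix(0, length(grid), n)
  cprob <- if (has_prob)
    .prob_conc_mat(grid, pd$time, pd$amount, ind["ka_PROB", ], ind["V_PROB", ],
                   ind["CL_PROB", ], cs[["MW_PROB"]])
  else matrix(0, length(grid), n)

  Xeff <- if (probenecid_occasion) ind["X", ] else rep(1, n)
  mh <- 1 / (matrix(Xeff, length(grid), n, byrow = TRUE) *
               (1 + scales[["oatp1b3"]] * cs[["fu_RIF"]] *
                  sweep(crif, 2, ind["Ki_u_OATP1B3", ], "/")))
  mr <- 1 / (1 + scales[["oat3"]] * cs[["fu_PROB"]] *
               sweep(cprob, 2, ind["Ki_u_OAT3", ], "/"))
  clh <- sweep(mh, 2, ind["CLh", ], "*")
  clr <- sweep(mr, 2, ind["CLR", ], "*")
  Vc <- ind["Vc", 1]
  kel <- (clh + clr) / Vc
  fr <- clr / (clh + clr)
  sol <- .solve_turnover_grid(grid, kel, fr, ind["ksyn", ], Vc, C0)

  ibm <- match(occ$biomarker_times, grid)
  bm <- sol$C[ibm, , drop = FALSE]
  ur <- if (length(ub)) {
    i0 <- match(occ$urine_intervals[, 1], grid)
    i1 <- match(occ$urine_intervals[, 2], grid)
    sol$A_renal[i1, , drop = FALSE] - sol$A_renal[i0, , drop = FALSE]
  } else matrix(0, 0, n)
  inh <- if (length(occ$inhibitor_times)) {
    if (has_rif)
      .rif_conc_mat(occ$inhibitor_times, rd$time, rd$amount, ind["Tlag_RIF", ],
                    ind["Tk0_RIF", ], ind["V_RIF", ], ind["CL_RIF", ], cs[["MW_RIF"]])
    else
      .prob_conc_mat(occ$inhibitor_times, pd$time, pd$amount, ind["ka_PROB", ],
                     ind["V_PROB", ], ind["CL_PROB", ], cs[["MW_PROB"]])
  } else matrix(0, 0, n)
  list(biomarker = bm, urine = ur, inhibitor = inh)
}

#' Simulate a clinical trial
#'
#' Draws one set of individual parameters per subject (shared across
#' occasions, as in a cross-over design), simulates each occasion with the
#' coupled structural models, reads plasma concentrations at the design's
#' sampling times and urine amounts over its collection intervals, and
#' optionally adds residual error.
#'
#' @param design A [study_design()] object.
#' @param pop Population parameters, see [default_population()].
#' @param with_residual Add residual unexplained variability?
#' @param seed Optional integer seed for reproducibility.
#' @param n_subjects Override the design's subject count (e.g., for VPCs).
#' @param grid_step Solver grid spacing (h).
#' @return A data frame of observation records with columns `ID`, `OCC`,
#'   `TIME`, `EVID` (0), `DVID` (1 biomarker plasma uM, 2 biomarker urine
#'   umol, 3 rifampicin plasma uM, 4 probenecid plasma uM), `DV`, `AMT`
#'   (`NA`), `DRUG` (`NA`), `USTART` (urine interval start, `DVID == 2`
#'   rows only).
#' @export
simulate_trial <- function(design, pop = default_population(),
                           with_residual = TRUE, seed = NULL,
                           n_subjects = design$n_subjects, grid_step = 0.05) {
  if (!inherits(design, "study_design")) stop("design must be a study_design")
  for (occ in design$occasions)
    if (!is.null(occ$urine_intervals) && !("CLR" %in% names(pop$fixed)))
      stop("design requests urine sampling but population lacks CLR")
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects
  ind <- .sample_individuals(pop, n)
  recs <- vector("list", length(design$occasions))
  for (io in seq_along(design$occasions)) {
    occ <- design$occasions[[io]]
    blk <- .simulate_occasion_block(occ, design$duration, pop, ind,
                                    grid_step = grid_step)
    reg <- occ$regimen
    inh_dvid <- if (!is.null(reg) && any(reg$drug == "rifampicin")) 3L else 4L
    rows <- list()
    if (length(occ$biomarker_times))
      rows$bm <- data.frame(ID = rep(seq_len(n), each = length(occ$biomarker_times)),
                            OCC = io, TIME = rep(occ$biomarker_times, n),
                            EVID = 0L, DVID = 1L, DV = as.vector(blk$biomarker),
                            AMT = NA_real_, DRUG = NA_character_,
                            USTART = NA_real_)
    if (!is.null(occ$urine_intervals) && nrow(occ$urine_intervals))
      rows$ur <- data.frame(ID = rep(seq_len(n), each = nrow(occ$urine_intervals)),
                            OCC = io, TIME = rep(occ$urine_intervals[, 2], n),
                            EVID = 0L, DVID = 2L, DV = as.vector(blk$urine),
                            AMT = NA_real_, DRUG = NA_character_,
                            USTART = rep(occ$urine_intervals[, 1], n))
    if (length(occ$inhibitor_times))
      rows$inh <- data.frame(ID = rep(seq_len(n), each = length(occ$inhibitor_times)),
                             OCC = io, TIME = rep(occ$inhibitor_times, n),
                             EVID = 0L, DVID = inh_dvid, DV = as.vector(blk$inhibitor),
                             AMT = NA_real_, DRUG = NA_character_,
                             USTART = NA_real_)
    recs[[io]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (with_residual) {
    for (obs in names(.dvid_codes)) {
      sel <- out$DVID == .dvid_codes[[obs]]
      if (any(sel))
        out$DV[sel] <- apply_residual(out$DV[sel], obs, pop$residual)
    }
  }
  out[order(out$ID, out$OCC, out$TIME, out$DVID), , drop = FALSE]
}

#' Non-compartmental metrics for one subject-occasion
#'
#' Linear-trapezoid AUC of the biomarker plasma points inside the window,
#' cumulative amount excreted in urine (Ae) over intervals inside the
#' window, and observed renal clearance `CLR_obs = Ae / AUC`.
#'
#' @param records Observation records of a single subject and occasion.
#' @param window Numeric `c(start, end)` (h).
#' @return A list with `auc` (uM*h), `ae` (umol or `NA` if no urine data),
#'   `clr_obs` (L/h or `NA`).
#' @export
nca <- function(records, window = c(0, 24)) {
  if (length(window) != 2 || window[2] <= window[1]) stop("empty NCA window")
  pl <- records[records$DVID == 1L & records$TIME >= window[1] &
                  records$TIME <= window[2], , drop = FALSE]
  if (nrow(pl) < 2)
    stop("need at least two plasma points in the window for AUC")
  pl <- pl[order(pl$TIME), ]
  auc <- sum(diff(pl$TIME) * (utils::head(pl$DV, -1) + utils::tail(pl$DV, -1)) / 2)
  ur <- records[records$DVID == 2L & !is.na(records$USTART) &
                  records$USTART >= window[1] & records$TIME <= window[2], ,
                drop = FALSE]
  ae <- if (nrow(ur)) sum(ur$DV) else NA_real_
  clr <- if (!is.na(ae)) {
    if (auc <= 0) {
      warning("AUC is zero; CLR_obs undefined")
      NA_real_
    } else ae / auc
  } else NA_real_
  list(auc = auc, ae = ae, clr_obs = clr)
}

#' Visual-predictive-check percentile bands
#'
#' Simulates `n_sim` individuals under the design (residual error included)
#' and summarizes each observable at each sampling time by simulated
#' percentiles (default median and 90% prediction interval).
#'
#' @param design A [study_design()].
#' @param pop Population parameters.
#' @param n_sim Number of simulated individuals (>= 100).
#' @param seed Optional seed.
#' @param probs Percentiles to report.
#' @param with_residual Include residual error (default `TRUE`).
#' @param grid_step Solver grid spacing (h).
#' @return Data frame with columns `OCC`, `DVID`, `TIME` and one column per
#'   requested percentile (`p5`, `p50`, `p95` by default).
#' @export
vpc <- function(design, pop = default_population(), n_sim = 1000, seed = NULL,
                probs = c(0.05, 0.5, 0.95), with_residual = TRUE,
                grid_step = 0.05) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  sim <- simulate_trial(design, pop, with_residual = with_residual,
                        seed = seed, n_subjects = n_sim, grid_step = grid_step)
  key <- interaction(sim$OCC, sim$DVID, sim$TIME, drop = TRUE)
  qs <- t(vapply(split(sim$DV, key),
                 function(v) stats::quantile(v, probs, names = FALSE),
                 numeric(length(probs))))
  u <- !duplicated(key)
  meta <- sim[u, c("OCC", "DVID", "TIME")]
  out <- cbind(meta[match(levels(key), as.character(key[u])), ], qs)
  names(out)[4:(3 + length(probs))] <- paste0("p", round(probs * 100))
  out <- out[order(out$OCC, out$DVID, out$TIME), ]
  rownames(out) <- NULL
  out
}
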