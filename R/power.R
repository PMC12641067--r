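# ---- power calculation for DDI-study design -------------------------------
#
# Hypothetical inhibitors are assumed to share the PK of rifampicin
# (OATP1B3) or probenecid (OAT3); their potency is varied by scaling the
# I/Ki ratio by a factor Y relative to the fitted drug. Each simulated
# subject contributes a paired (cross-over) metric ratio: plasma AUC ratio
# over 0-24 h for OATP1B3, observed renal-clearance ratio (Ae/AUC over the
# sampling day) for OAT3. A one-sample two-sided t-test of the mean
# log-ratio against zero gives the rejection decision per replicate trial.

#' Define a power-analysis scenario
#'
#' @param target `"OATP1B3"` (plasma AUC ratio metric, rifampicin-like
#'   inhibitor, single 600 mg dose design) or `"OAT3"` (renal clearance
#'   ratio metric, probenecid-like inhibitor, multi-dose cross-over design).
#' @param Y Potency scale(s) on I/Ki relative to the reference inhibitor
#'   (`Y = 1` reproduces rifampicin/probenecid; `Y = 0` is the null).
#' @param n Sample sizes to test.
#' @param alpha Significance level(s) of the paired t-test.
#' @param replicates Simulated trials per (Y, n) combination.
#' @param power_threshold Power level defining the minimal sample size.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(target = c("OATP1B3", "OAT3"), Y = 1,
                           n = c(5, 10, 15, 20, 25, 30),
                           alpha = c(0.01, 0.05), replicates = 1000,
                           power_threshold = 0.8) {
  target <- match.arg(target)
  if (any(Y < 0)) stop("Y must be >= 0")
  if (any(n < 2)) stop("sample sizes must be >= 2")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  structure(list(target = target, Y = Y, n = n, alpha = alpha,
                 replicates = replicates, power_threshold = power_threshold,
                 metric = if (target == "OATP1B3") "AUCR" else "CLR_ratio"),
            class = "power_scenario")
}

# Simulate n_total paired log metric ratios under a scenario (vectorized
# across subjects; chunked to bound memory).
.simulate_log_ratios <- function(target, Y, n_total, pop, with_residual = TRUE,
                                 grid_step = 0.1, chunk = 5000L) {
  out <- numeric(0)
  designs <- builtin_designs()
  if (target == "OATP1B3") {
    occ <- designs$rif600$occasions[[2]]
    dur <- designs$rif600$duration
    tpl <- occ$biomarker_times
    window_w <- NULL
  } else {
    occ <- designs$study3$occasions[[2]]
    dur <- designs$study3$duration
    tpl <- occ$biomarker_times
    ui <- occ$urine_intervals
  }
  scales <- if (target == "OATP1B3") c(oatp1b3 = Y, oat3 = 1)
            else c(oatp1b3 = 1, oat3 = Y)
  res <- pop$residual
  while (length(out) < n_total) {
    n <- min(chunk, n_total - length(out))
    ind <- .sample_individuals(pop, n)
    C0 <- ind["ksyn", ] / (ind["CLh", ] + ind["CLR", ])
    # hypothetical selective inhibitor: no probenecid X effect on CLh
    blk <- .simulate_occasion_block(occ, dur, pop, ind, scales = scales,
                                    grid_step = grid_step,
                                    probenecid_occasion = FALSE)
    Ct <- blk$biomarker                       # treatment occasion
    Cc <- matrix(C0, length(tpl), n, byrow = TRUE)  # control occasion
    if (with_residual) {
      op <- options(gcdcaspk.quiet = TRUE); on.exit(options(op), add = TRUE)
      Ct <- matrix(apply_residual(as.vector(Ct), "biomarker_plasma", res),
                   nrow(Ct), n)
      Cc <- matrix(apply_residual(as.vector(Cc), "biomarker_plasma", res),
                   nrow(Cc), n)
    }
    w <- diff(tpl)
    auc_t <- colSums((Ct[-1, , drop = FALSE] + Ct[-nrow(Ct), , drop = FALSE]) / 2 * w)
    auc_c <- colSums((Cc[-1, , drop = FALSE] + Cc[-nrow(Cc), , drop = FALSE]) / 2 * w)
    if (target == "OATP1B3") {
      lr <- log(auc_t / auc_c)
    } else {
      At <- blk$urine
      wid <- ui[, 2] - ui[, 1]
      Ac <- outer(wid, C0 * ind["CLR", ])
      if (with_residual) {
        At <- matrix(apply_residual(as.vector(At), "biomarker_urine", res),
                     nrow(At), n)
        Ac <- matrix(apply_residual(as.vector(Ac), "biomarker_urine", res),
                     nrow(Ac), n)
      }
      clr_t <- colSums(At) / auc_t
      clr_c <- colSums(Ac) / auc_c
      lr <- log(clr_t / clr_c)
    }
    bad <- !is.finite(lr)
    if (any(bad)) {
      message(sum(bad), " subject(s) with undefined metric ratio resampled")
      lr <- lr[!bad]
    }
    out <- c(out, lr)
  }
  out[seq_len(n_total)]
}

#' Paired metric ratio for one simulated subject
#'
#' Simulates one subject's control and treatment occasions with shared
#' random effects and residual error, and returns the DDI metric ratio:
#' plasma AUC ratio (0-24 h) for an OATP1B3 scenario, observed
#' renal-clearance ratio for an OAT3 scenario.
#'
#' @param scenario A [power_scenario()] (its first `Y` value is used).
#' @param pop Population parameters.
#' @param with_residual Include residual error?
#' @param grid_step Solver grid spacing (h).
#' @return Dimensionless ratio (treatment / control).
#' @export
subject_metric_ratio <- function(scenario, pop = default_population(),
                                 with_residual = TRUE, grid_step = 0.05) {
  unname(exp(.simulate_log_ratios(scenario$target, scenario$Y[1], 1L, pop,
                                  with_residual = with_residual,
                                  grid_step = grid_step)))
}

#' Simulation-based power curves
#'
#' For every combination of potency scale `Y`, sample size `n` and
#' significance level `alpha`, simulates `replicates` cross-over trials,
#' applies a two-sided one-sample t-test to the subjects' log metric ratios,
#' and estimates power as the rejection fraction. Also reports the smallest
#' tested `n` reaching the scenario's power threshold.
#'
#' @param scenario A [power_scenario()].
#' @param pop Population parameters.
#' @param seed Optional seed.
#' @param grid_step Solver grid spacing (h).
#' @return A `power_grid` list: `grid` (data frame with `target`, `Y`, `n`,
#'   `alpha`, `power`, `mc_se`) and `minimal_n` (data frame with `target`,
#'   `Y`, `alpha`, `n_min`; `NA` when the threshold is not reached on the
#'   tested grid).
#' @export
power_curve <- function(scenario, pop = default_population(), seed = NULL,
                        grid_step = 0.1) {
  if (!inherits(scenario, "power_scenario")) stop("need a power_scenario")
  if (!is.null(seed)) set.seed(seed)
  reps <- scenario$replicates
  rows <- list()
  for (Y in scenario$Y) {
    for (n in scenario$n) {
      lr <- .simulate_log_ratios(scenario$target, Y, n * reps, pop,
                                 grid_step = grid_step)
      M <- matrix(lr, n, reps)
      mu <- colMeans(M)
      sd <- sqrt(colSums((M - matrix(mu, n, reps, byrow = TRUE))^2) / (n - 1))
      tstat <- mu / (sd / sqrt(n))
      pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
      for (alpha in scenario$alpha) {
        pw <- mean(pval < alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          target = scenario$target, Y = Y, n = n, alpha = alpha,
          power = pw, mc_se = sqrt(pw * (1 - pw) / reps))
      }
    }
  }
  grid <- do.call(rbind, rows)
  mn <- do.call(rbind, lapply(split(grid, interaction(grid$Y, grid$alpha)),
    function(d) {
      hit <- d$n[d$power >= scenario$power_threshold]
      data.frame(target = d$target[1], Y = d$Y[1], alpha = d$alpha[1],
                 n_min = if (length(hit)) min(hit) else NA_integer_)
    }))
  rownames(mn) <- NULL
  structure(list(grid = grid, minimal_n = mn,
                 power_threshold = scenario$power_threshold),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Simulated power grid (threshold", x$power_threshold, ")\n")
  print(x$grid, row.names = FALSE)
  cat("Minimal n reaching threshold:\n")
  print(x$minimal_n, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of the DDI metrics to the biomarker synthesis rate
#'
#' Simulates the typical individual with the synthesis rate multiplied by
#' each fold change, alongside the transporter inhibition of the scenario,
#' and reports plasma AUC over the sampling day and observed renal clearance
#' (Ae/AUC). Because the turnover model is linear in `ksyn`, plasma AUC
#' scales with the fold change while the renal-clearance metric cancels it;
#' an inhibitor that also perturbed synthesis would therefore bias AUC-based
#' DDI classification but not the renal-clearance metric.
#'
#' @param folds Positive fold changes applied to `ksyn`.
#' @param target `"OATP1B3"`, `"OAT3"` or `"none"` (inhibition scenario).
#' @param Y Potency scale of the inhibitor.
#' @param pop Population parameters.
#' @param grid_step Solver grid spacing (h).
#' @return Data frame with `fold`, `auc` (uM*h), `clr_obs` (L/h).
#' @export
ksyn_perturbation <- function(folds = c(0.5, 1, 2),
                              target = c("none", "OATP1B3", "OAT3"), Y = 1,
                              pop = default_population(), grid_step = 0.05) {
  target <- match.arg(target)
  if (any(folds <= 0)) stop("fold changes must be positive")
  designs <- builtin_designs()
  sp <- .structural_params(pop)
  if (target == "OATP1B3") {
    occ <- designs$rif600$occasions[[2]]
    dur <- designs$rif600$duration
    scales <- c(oatp1b3 = Y, oat3 = 1)
    regim <- list(rifampicin = occ$regimen)
    window <- c(0, 24)
  } else if (target == "OAT3") {
    occ <- designs$study3$occasions[[2]]
    dur <- designs$study3$duration
    scales <- c(oatp1b3 = 1, oat3 = Y)
    regim <- list(probenecid = occ$regimen)
    window <- .prob_sampling_offset + c(0, 24)
  } else {
    dur <- 24
    scales <- c(oatp1b3 = 1, oat3 = 1)
    regim <- list()
    window <- c(0, 24)
  }
  out <- lapply(folds, function(f) {
    bp <- biomarker_params(ksyn = pop$fixed[["ksyn"]] * f,
                           Vc = pop$fixed[["Vc"]], CLh = pop$fixed[["CLh"]],
                           CLR = pop$fixed[["CLR"]])
    s <- solve_biomarker(dur, regim, bp, sp$rif, sp$prob, scales = scales,
                         probenecid_occasion = FALSE, grid_step = grid_step,
                         extra_times = window)
    inw <- s$time >= window[1] & s$time <= window[2]
    tt <- s$time[inw]; cc <- s$conc[inw]
    auc <- sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
    ae <- s$amount_urine[s$time == window[2]] - s$amount_urine[s$time == window[1]]
    data.frame(fold = f, auc = auc, clr_obs = ae / auc)
  })
  do.call(rbind, out)
}
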