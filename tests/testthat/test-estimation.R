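# Mixed-effects estimation machinery.

make_subject_records <- function(pop, eta = c(0, 0, 0), seed = 1,
                                 with_residual = FALSE) {
  # one study-3-like subject simulated at a fixed eta
  popi <- pop
  popi$fixed["ksyn"] <- pop$fixed[["ksyn"]] * exp(eta[1])
  popi$fixed["CLR"] <- pop$fixed[["CLR"]] * exp(eta[2])
  popi$fixed["Ki_u_OAT3"] <- pop$fixed[["Ki_u_OAT3"]] * exp(eta[3])
  popi$iiv[] <- 0
  des <- builtin_designs()$study3
  des$n_subjects <- 1
  sim <- quiet_sim(simulate_trial(des, popi, with_residual = with_residual,
                                  seed = seed))
  doses <- gcdcaspk:::.dose_rows(des)
  doses <- doses[doses$ID == 1, ]
  d <- rbind(sim, doses)
  d[order(d$ID, d$OCC, d$TIME, d$EVID), ]
}

test_that("eta = 0 minimizes the individual objective for typical-value data", {
  pop <- default_population()
  rec <- make_subject_records(pop)
  f0 <- individual_nll(rec, c(0, 0, 0), pop)
  for (j in 1:3) for (s in c(-0.3, 0.3)) {
    eta <- numeric(3); eta[j] <- s
    expect_gt(individual_nll(rec, eta, pop), f0)
  }
})

test_that("individual likelihood is invariant to record reordering", {
  pop <- default_population()
  rec <- make_subject_records(pop, eta = c(0.2, -0.1, 0.1),
                              with_residual = TRUE, seed = 3)
  f1 <- individual_nll(rec, c(0.1, 0, 0), pop)
  shuffled <- rec[sample(nrow(rec)), ]
  shuffled <- shuffled[order(shuffled$ID, shuffled$OCC, shuffled$TIME,
                             shuffled$EVID), ]
  expect_equal(individual_nll(shuffled, c(0.1, 0, 0), pop), f1,
               tolerance = 1e-12)
})

test_that("empirical Bayes recovers the generating random effects at low noise", {
  pop <- default_population()
  pop$residual$biomarker_plasma$prop <- 0.02
  pop$residual$biomarker_urine$prop <- 0.02
  eta_true <- c(0.4, -0.25, 0.3)
  rec <- make_subject_records(pop, eta = eta_true, with_residual = TRUE,
                              seed = 4)
  eb <- empirical_bayes(rec, pop)
  expect_equal(unname(eb), eta_true, tolerance = 0.12)
})

test_that("a subject with no observations sits at the prior mode", {
  pop <- default_population()
  rec <- make_subject_records(pop)
  rec <- rec[rec$EVID == 1, ]  # doses only
  eb <- empirical_bayes(rec, pop)
  expect_equal(unname(eb), c(0, 0, 0), tolerance = 1e-6)
})

test_that("EBE magnitudes shrink when the residual noise grows", {
  pop <- default_population()
  pop$residual$biomarker_plasma$prop <- 0.05
  pop$residual$biomarker_urine$prop <- 0.05
  eta_true <- c(0.5, -0.3, 0.2)
  rec <- make_subject_records(pop, eta = eta_true, with_residual = FALSE)
  eb_tight <- empirical_bayes(rec, pop)
  popN <- pop
  popN$residual$biomarker_plasma$prop <- 2.0
  popN$residual$biomarker_urine$prop <- 2.0
  eb_noisy <- empirical_bayes(rec, popN)
  expect_true(all(abs(eb_noisy) <= abs(eb_tight) + 1e-8))
})

test_that("population fit recovers the truth on a low-variability ensemble", {
  pop_true <- pop_low_noise()
  td <- tempfile()
  dats <- list()
  for (j in 1:2) {
    g <- quiet_sim(generate_study(c("study1", "study3")[j], pop_true,
                                  seed = 40 + j, out_dir = td))
    dats[[j]] <- read_dataset(g$dataset)
  }
  fit <- fit_population(dats, pop_true,
                        fit_control(iter.max = 40, eval.max = 250))
  est <- fit$stages$biomarker$par
  expect_equal(est[["ksyn"]], 1.0, tolerance = 0.1)
  expect_equal(est[["CLh"]], 15, tolerance = 0.1)
  expect_equal(est[["CLR"]], 0.31, tolerance = 0.1)
  expect_equal(est[["Ki_u_OATP1B3"]], 0.009, tolerance = 0.2)
  expect_equal(est[["Ki_u_OAT3"]], 2.7, tolerance = 0.2)
  expect_equal(fit$strategy, "sequential-IPP (Laplace)")
  expect_true(is.finite(fit$ofv))
  # inhibitor stages recover their own parameters
  expect_equal(fit$stages$rifampicin$par[["CL_RIF"]], 6.7, tolerance = 0.15)
  expect_equal(fit$stages$probenecid$par[["CL_PROB"]], 0.95, tolerance = 0.15)
  unlink(td, recursive = TRUE)

  # goodness-of-fit table: record count preserved, residuals calibrated
  g <- gof(dats, fit)
  nobs <- sum(vapply(dats, function(d) sum(d$EVID == 0 & d$DVID %in% 1:2), 0L))
  expect_equal(nrow(g), nobs)
  expect_true(all(c("PRED", "IPRED", "WRES", "IWRES") %in% names(g)))
  expect_lt(abs(mean(g$IWRES)), 0.5)
  expect_lt(mean(abs(g$IWRES)), 3)
})

test_that("perfect data yields zero residuals in the GOF table", {
  pop0 <- pop_deterministic()
  td <- tempfile()
  g <- generate_study("study1", pop0, seed = 50, with_residual = FALSE,
                      out_dir = td)
  d <- read_dataset(g$dataset)
  # evaluate GOF at the truth without refitting
  fit <- list(estimates = pop0, ebes = list(), stages = list())
  class(fit) <- "fit_result"
  tab <- gof(d, fit)
  expect_equal(nrow(tab), sum(d$EVID == 0 & d$DVID %in% 1:2))
  expect_lt(max(abs(tab$DV - tab$PRED)) / max(tab$DV), 0.01)
  unlink(td, recursive = TRUE)
})
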