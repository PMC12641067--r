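# Trial simulation, NCA metrics and VPC bands.

test_that("built-in designs match the published study structure", {
  d <- builtin_designs()
  expect_setequal(names(d), c("study1", "study2", "study3", "rif300", "rif600"))
  expect_equal(d$study1$n_subjects, 6)
  expect_equal(d$study1$duration, 24)
  expect_equal(length(d$study1$occasions[[1]]$biomarker_times), 8)
  expect_equal(d$study2$n_subjects, 6)
  expect_equal(max(d$study2$occasions[[1]]$biomarker_times) -
                 min(d$study2$occasions[[1]]$biomarker_times), 168)
  # four probenecid doses per full dosing day
  reg <- d$study2$occasions[[2]]$regimen
  day3 <- reg$time[reg$time >= 13 + 48 & reg$time < 13 + 72]
  expect_equal(length(day3), 4)
  expect_equal(d$study3$n_subjects, 12)
  expect_equal(nrow(d$study3$occasions[[1]]$urine_intervals), 3)
  expect_equal(d$rif300$occasions[[2]]$regimen$amount, 300)
})

test_that("deterministic simulation hits the steady-state baseline everywhere", {
  pop0 <- pop_deterministic()
  sim <- simulate_trial(builtin_designs()$study1, pop0, with_residual = FALSE)
  C0 <- 1.0 / 15.31
  ctrl <- sim[sim$OCC == 1 & sim$DVID == 1, ]
  expect_equal(ctrl$DV, rep(C0, nrow(ctrl)), tolerance = 1e-10)
  # bookkeeping: 6 subjects x 2 occasions x 8 sampling times
  expect_equal(nrow(sim[sim$DVID == 1, ]), 6 * 2 * 8)
  expect_equal(nrow(sim[sim$DVID == 3, ]), 6 * 9)
  # repeated identical call is identical (no hidden state)
  sim2 <- simulate_trial(builtin_designs()$study1, pop0, with_residual = FALSE)
  expect_identical(sim, sim2)
})

test_that("urine interval amounts telescope to the cumulative amount", {
  pop0 <- pop_deterministic()
  des <- builtin_designs()$study3
  sim <- simulate_trial(des, pop0, with_residual = FALSE)
  ur <- sim[sim$ID == 1 & sim$OCC == 2 & sim$DVID == 2, ]
  s <- solve_biomarker(des$duration,
                       list(probenecid = des$occasions[[2]]$regimen),
                       extra_times = c(13, 37))
  total <- s$amount_urine[s$time == 37] - s$amount_urine[s$time == 13]
  expect_equal(sum(ur$DV), total, tolerance = 1e-8)
})

test_that("rifampicin treatment raises the biomarker then lets it return toward baseline", {
  pop0 <- pop_deterministic()
  sim <- simulate_trial(builtin_designs()$rif600, pop0, with_residual = FALSE,
                        n_subjects = 1)
  tr <- sim[sim$OCC == 2 & sim$DVID == 1, ]
  expect_gt(max(tr$DV), 2 * tr$DV[1])
  expect_lt(tr$DV[tr$TIME == 24], max(tr$DV))
})

test_that("nca computes trapezoid AUC, Ae and observed renal clearance", {
  C0 <- 0.0653
  rec <- data.frame(ID = 1, OCC = 1, TIME = c(0, 6, 12, 24), EVID = 0,
                    DVID = 1, DV = C0, AMT = NA, DRUG = NA, USTART = NA)
  m <- nca(rec, c(0, 24))
  expect_equal(m$auc, C0 * 24, tolerance = 1e-12)
  expect_equal(m$auc, 1.568, tolerance = 1e-3)
  ur <- data.frame(ID = 1, OCC = 1, TIME = 24, EVID = 0, DVID = 2,
                   DV = 0.486, AMT = NA, DRUG = NA, USTART = 0)
  m2 <- nca(rbind(rec, ur), c(0, 24))
  expect_equal(m2$clr_obs, 0.486 / 1.5672, tolerance = 1e-3)
  expect_equal(m2$clr_obs, 0.310, tolerance = 1e-2)
  expect_error(nca(rec[1, ], c(0, 24)), "at least two")
  expect_error(nca(rec, c(5, 5)), "window")
})

test_that("error-free control NCA recovers the generating renal clearance", {
  pop0 <- pop_deterministic()
  des <- builtin_designs()$study3
  sim <- simulate_trial(des, pop0, with_residual = FALSE)
  sub <- sim[sim$ID == 3 & sim$OCC == 1, ]
  m <- nca(sub, c(13, 37))
  expect_equal(m$clr_obs, 0.31, tolerance = 1e-10)
})

test_that("vpc bands collapse onto the typical prediction without variability and widen with noise", {
  pop0 <- pop_deterministic()
  b0 <- vpc(builtin_designs()$study1, pop0, n_sim = 100)
  expect_equal(b0$p5, b0$p95, tolerance = 1e-12)
  ctrl <- b0[b0$OCC == 1 & b0$DVID == 1, ]
  expect_equal(ctrl$p50, rep(1.0 / 15.31, nrow(ctrl)), tolerance = 1e-8)

  pop <- default_population()
  popW <- pop
  popW$residual$biomarker_plasma$prop <- 0.9
  quiet_sim({
    b1 <- vpc(builtin_designs()$study1, pop, n_sim = 400, seed = 5)
    b2 <- vpc(builtin_designs()$study1, popW, n_sim = 400, seed = 5)
  })
  s1 <- b1[b1$DVID == 1, ]; s2 <- b2[b2$DVID == 1, ]
  expect_gt(mean(s2$p95 - s2$p5), mean(s1$p95 - s1$p5))
})
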