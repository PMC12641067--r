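# Structural models: closed-form inhibitor PK and the biomarker turnover ODE.

test_that("rifampicin closed form reproduces its defining cases", {
  p <- rifampicin_params()
  d <- dose_events("rifampicin", 0, 600)
  # zero before the lag time
  expect_identical(rifampicin_conc(c(0, 0.3, 0.56), d, p), c(0, 0, 0))
  # end of the zero-order input window: (D/Tk0)/(kV) (1 - e^{-k Tk0})
  k <- p$CL / p$V
  amt <- 600 / p$MW * 1000
  expect_equal(rifampicin_conc(p$Tlag + p$Tk0, d, p),
               (amt / p$Tk0) / (k * p$V) * (1 - exp(-k * p$Tk0)),
               tolerance = 1e-12)
  expect_equal(rifampicin_conc(1.40, d, p), 19.24, tolerance = 2e-4)
  # mass balance: cumulative eliminated amount approaches the dose
  tt <- seq(0, 400, by = 0.02)
  cc <- rifampicin_conc(tt, d, p)
  expect_equal(sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2) * p$CL, amt,
               tolerance = 1e-4)
  expect_lt(rifampicin_conc(400, d, p), 1e-25)
  expect_error(rifampicin_conc(1, dose_events("probenecid", 0, 500), p),
               "rifampicin")
})

test_that("probenecid Bateman superposition matches its analytic peak and is linear", {
  p <- probenecid_params()
  d <- dose_events("probenecid", 0, 500)
  expect_identical(probenecid_conc(c(0, 0.0), d, p), c(0, 0))
  k <- p$CL / p$V
  tmax <- log(p$ka / k) / (p$ka - k)
  expect_equal(tmax, 2.854, tolerance = 1e-3)
  expect_equal(probenecid_conc(tmax, d, p), 87.9, tolerance = 1e-3)
  # two doses superpose as time-shifted single-dose curves
  d2 <- dose_events("probenecid", c(0, 6), 500)
  tt <- seq(0, 24, by = 0.5)
  expect_equal(probenecid_conc(tt, d2, p),
               probenecid_conc(tt, d, p) +
                 c(rep(0, sum(tt < 6)), probenecid_conc(tt[tt >= 6] - 6, d, p)),
               tolerance = 1e-12)
})

test_that("degenerate ka == k absorption uses the analytic limit", {
  p_eq <- probenecid_params(ka = 1.1, V = 17, CL = 1.1 * 17)
  d <- dose_events("probenecid", 0, 500)
  amt <- 500 / p_eq$MW * 1000
  tt <- c(0.5, 1, 3)
  expect_equal(probenecid_conc(tt, d, p_eq),
               (amt / p_eq$V) * p_eq$ka * tt * exp(-p_eq$ka * tt),
               tolerance = 1e-9)
  # continuity: a tiny perturbation of ka moves the curve only slightly
  p_near <- probenecid_params(ka = 1.1 * (1 + 1e-7), V = 17, CL = 1.1 * 17)
  expect_equal(probenecid_conc(tt, d, p_near), probenecid_conc(tt, d, p_eq),
               tolerance = 1e-5)
})

test_that("closed-form inhibitor concentrations match the numerical ODE oracle", {
  # rifampicin: piecewise-constant input ODE integrated with lsoda
  p <- rifampicin_params()
  d <- dose_events("rifampicin", 0, 600)
  amt <- 600 / p$MW * 1000
  k <- p$CL / p$V
  rhs <- function(t, y, parms) {
    inp <- if (t > p$Tlag && t <= p$Tlag + p$Tk0) amt / p$Tk0 else 0
    list(inp / p$V - k * y)
  }
  tt <- sort(c(seq(0.01, 24, length.out = 100), p$Tlag, p$Tlag + p$Tk0))
  num <- deSolve::lsoda(c(C = 0), c(0, tt), rhs, NULL, rtol = 1e-11,
                        atol = 1e-14, hmax = 0.01)[-1, "C"]
  cf <- rifampicin_conc(tt, d, p)
  expect_lt(max(abs(cf - num)) / max(num), 1e-6)

  # probenecid: multi-dose Bateman vs two-state absorption ODE
  pp <- probenecid_params()
  reg <- probenecid_regimen(1)
  kp <- pp$CL / pp$V
  amts <- reg$amount / pp$MW * 1000
  rhs2 <- function(t, y, parms) list(c(-pp$ka * y[1], pp$ka * y[1] / pp$V - kp * y[2]))
  ev <- data.frame(var = "A", time = reg$time, value = amts, method = "add")
  tt2 <- sort(unique(c(seq(0.1, 36, length.out = 100), reg$time + 1e-9)))
  num2 <- deSolve::lsoda(c(A = 0, C = 0), sort(unique(c(0, tt2, reg$time))),
                         rhs2, NULL, rtol = 1e-11, atol = 1e-14,
                         events = list(data = ev))
  num2 <- num2[match(tt2, num2[, "time"]), "C"]
  cf2 <- probenecid_conc(tt2, reg, pp)
  expect_lt(max(abs(cf2 - num2)) / max(num2), 1e-6)
})

test_that("clearance multipliers implement competitive inhibition and the X factor", {
  rp <- rifampicin_params(); pp <- probenecid_params()
  m0 <- clearance_multipliers(0, 0, rp, pp, probenecid_occasion = FALSE)
  expect_identical(unlist(m0), c(hepatic = 1, renal = 1))
  m1 <- clearance_multipliers(0, 10, rp, probenecid_params(Ki_u_OAT3 = 2.7))
  expect_equal(m1$renal, 1 / (1 + 10 / 2.7), tolerance = 1e-12)
  expect_equal(m1$renal, 0.2126, tolerance = 1e-4)
  m2 <- clearance_multipliers(0, 0, rp, pp, probenecid_occasion = TRUE)
  expect_equal(m2$hepatic, 1 / 1.7, tolerance = 1e-12)
  # potency scale zero removes the interaction
  m3 <- clearance_multipliers(5, 5, rp, pp, scale_oatp1b3 = 0, scale_oat3 = 0)
  expect_identical(unlist(m3), c(hepatic = 1, renal = 1))
  expect_error(clearance_multipliers(-1, 0, rp, pp), "non-negative")
})

test_that("baseline steady state is ksyn/(CLh+CLR) with the expected limits", {
  bp <- biomarker_params()
  expect_equal(baseline_concentration(bp), 1.0 / 15.31, tolerance = 1e-12)
  expect_equal(baseline_concentration(bp), 0.0653, tolerance = 1e-3)
  bp2 <- biomarker_params(ksyn = 2.0)
  expect_equal(baseline_concentration(bp2), 2 * baseline_concentration(bp))
  bp3 <- biomarker_params(CLR = 1e-9)
  expect_equal(baseline_concentration(bp3), 1.0 / 15, tolerance = 1e-9)
})

test_that("undisturbed biomarker stays at steady state and accumulates urine linearly", {
  s <- solve_biomarker(24)
  C0 <- baseline_concentration(biomarker_params())
  expect_lt(max(abs(s$conc - C0)) / C0, 1e-8)
  expect_equal(s$amount_urine[s$time == 24], C0 * 0.31 * 24, tolerance = 1e-8)
  expect_equal(s$amount_urine[1], 0)
  expect_true(all(diff(s$amount_urine) >= 0))
})

test_that("hypothetical complete hepatic shutdown drives the concentration to ksyn/CLR", {
  bp <- biomarker_params(CLh = 1e-9)
  s <- solve_biomarker(2000, bp = bp, grid_step = 1)
  expect_equal(s$conc[s$time == 2000], bp$ksyn / bp$CLR, tolerance = 1e-4)
  expect_equal(bp$ksyn / bp$CLR, 3.226, tolerance = 1e-3)
})

test_that("biomarker solution is linear in ksyn and mass-balanced", {
  d <- dose_events("rifampicin", 0, 600)
  reg <- list(rifampicin = d)
  s1 <- solve_biomarker(24, reg)
  s2 <- solve_biomarker(24, reg, bp = biomarker_params(ksyn = 2.0))
  expect_equal(s2$conc, 2 * s1$conc, tolerance = 1e-10)
  expect_equal(s2$amount_urine, 2 * s1$amount_urine, tolerance = 1e-10)
  bp <- biomarker_params()
  mb <- bp$ksyn * 24 -
    (bp$Vc * (s1$conc[nrow(s1)] - s1$conc[1]) +
       s1$amount_urine[nrow(s1)] + s1$amount_hepatic[nrow(s1)])
  expect_lt(abs(mb) / (bp$ksyn * 24), 1e-6)
})

test_that("grid solver agrees with the adaptive ODE solution", {
  reg <- list(rifampicin = dose_events("rifampicin", 0, 600))
  sg <- solve_biomarker(24, reg, grid_step = 0.01)
  so <- solve_biomarker(24, reg, grid_step = 0.01, method = "ode")
  expect_lt(max(abs(sg$conc - so$conc)) / max(so$conc), 5e-4)
  expect_lt(abs(sg$amount_urine[nrow(sg)] - so$amount_urine[nrow(so)]) /
              so$amount_urine[nrow(so)], 5e-4)
})

test_that("stronger inhibition moves exposure and excretion in the expected directions", {
  reg_r <- list(rifampicin = dose_events("rifampicin", 0, 600))
  aucs <- sapply(c(0, 0.05, 0.3, 1), function(y) {
    s <- solve_biomarker(24, reg_r, scales = c(oatp1b3 = y, oat3 = 1))
    trapz(s$time, s$conc)
  })
  expect_true(all(diff(aucs) > 0))
  reg_p <- list(probenecid = probenecid_regimen(1))
  frac <- sapply(c(0, 0.3, 1), function(y) {
    s <- solve_biomarker(37, reg_p, scales = c(oatp1b3 = 1, oat3 = y),
                         probenecid_occasion = FALSE)
    s$amount_urine[nrow(s)] / trapz(s$time, s$conc)
  })
  expect_true(all(diff(frac) < 0))
})

test_that("solver input errors are reported", {
  expect_error(solve_biomarker(-1), "positive")
  expect_error(biomarker_params(ksyn = -1), "positive")
  expect_error(rifampicin_params(fu = 1.5), "fu")
  expect_error(probenecid_params(X = 0.5), "X")
  expect_error(dose_events("rifampicin", c(2, 1), 600), "non-decreasing")
})
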