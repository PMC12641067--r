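# Dataset dialect I/O and validation.

test_that("datasets round-trip losslessly through CSV", {
  pop <- default_population()
  g <- quiet_sim(generate_study("study1", pop, seed = 9, out_dir = tempdir(),
                                basename = "rt"))
  back <- read_dataset(g$dataset)
  expect_equal(back$DV, g$data$DV, tolerance = 1e-12)
  expect_identical(back$ID, g$data$ID)
  expect_identical(back$DVID, g$data$DVID)
  expect_identical(back$DRUG[!is.na(back$DRUG)],
                   g$data$DRUG[!is.na(g$data$DRUG)])
  unlink(c(g$dataset, g$sidecar))
})

test_that("schema violations are rejected with row-numbered messages", {
  ok <- data.frame(ID = 1L, OCC = 1L, TIME = 1, EVID = 0L, DVID = 1L,
                   DV = 0.1, AMT = NA_real_, DRUG = NA_character_,
                   USTART = NA_real_)
  expect_silent(validate_dataset(ok))
  bad <- ok; bad$AMT <- 100
  expect_error(validate_dataset(bad), "both DV and AMT.*1")
  bad2 <- ok; bad2$DVID <- 2L
  expect_error(validate_dataset(bad2), "USTART")
  bad3 <- rbind(ok, transform(ok, TIME = 0.5))
  expect_error(validate_dataset(bad3), "sorted")
  bad4 <- ok[, setdiff(names(ok), "DVID")]
  expect_error(validate_dataset(bad4), "missing dataset column")
  bad5 <- ok; bad5$DVID <- 7L
  expect_error(validate_dataset(bad5), "bad DVID")
  dose_bad <- ok; dose_bad$EVID <- 1L; dose_bad$DV <- NA; dose_bad$AMT <- 500
  expect_error(validate_dataset(dose_bad), "DRUG")
})

test_that("generated studies match the published sample counts", {
  pop <- default_population()
  g1 <- quiet_sim(generate_study("study1", pop, seed = 11, out_dir = tempdir(),
                                 basename = "c1"))
  d1 <- g1$data
  # 48 biomarker plasma records per occasion, ~51 rifampicin records on occ 2
  expect_equal(sum(d1$EVID == 0 & d1$DVID == 1 & d1$OCC == 1), 48)
  expect_equal(sum(d1$EVID == 0 & d1$DVID == 1 & d1$OCC == 2), 48)
  expect_equal(sum(d1$EVID == 0 & d1$DVID == 3), 54)
  expect_equal(sum(d1$EVID == 1), 6)
  g2 <- quiet_sim(generate_study("study2", pop, seed = 12, out_dir = tempdir(),
                                 basename = "c2"))
  d2 <- g2$data
  expect_equal(sum(d2$EVID == 0 & d2$DVID == 1 & d2$OCC == 2), 66)
  expect_equal(sum(d2$EVID == 0 & d2$DVID == 2 & d2$OCC == 1), 54)
  expect_equal(sum(d2$EVID == 0 & d2$DVID == 4), 36)
  g3 <- quiet_sim(generate_study("study3", pop, seed = 13, out_dir = tempdir(),
                                 basename = "c3"))
  d3 <- g3$data
  expect_equal(sum(d3$EVID == 0 & d3$DVID == 1 & d3$OCC == 1), 108)
  expect_equal(sum(d3$EVID == 0 & d3$DVID == 2 & d3$OCC == 1), 36)
  unlink(c(g1$dataset, g1$sidecar, g2$dataset, g2$sidecar,
           g3$dataset, g3$sidecar))
})

test_that("generation is reproducible and the sidecar carries the truth", {
  pop <- default_population()
  t1 <- file.path(tempdir(), "ga"); t2 <- file.path(tempdir(), "gb")
  ga <- quiet_sim(generate_study("study1", pop, seed = 77, out_dir = t1))
  gb <- quiet_sim(generate_study("study1", pop, seed = 77, out_dir = t2))
  expect_identical(readLines(ga$dataset), readLines(gb$dataset))
  side <- read_config(ga$sidecar)
  expect_identical(side$pop$fixed, pop$fixed)
  expect_identical(side$seed, 77L)
  gc2 <- quiet_sim(generate_study("study1", pop, seed = 78, out_dir = t2))
  expect_false(identical(readLines(ga$dataset), readLines(gc2$dataset)))
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("residual-free, IIV-free generation equals the analytic baseline", {
  pop0 <- pop_deterministic()
  g <- generate_study("study1", pop0, seed = 5, with_residual = FALSE,
                      out_dir = tempdir(), basename = "det")
  ctrl <- g$data[g$data$EVID == 0 & g$data$DVID == 1 & g$data$OCC == 1, ]
  expect_equal(ctrl$DV, rep(1.0 / 15.31, nrow(ctrl)), tolerance = 1e-9)
  unlink(c(g$dataset, g$sidecar))
})

test_that("ensembles produce one dataset per seed with a manifest", {
  td <- file.path(tempdir(), "ens")
  m <- quiet_sim(generate_ensemble(1:3, designs = "study1", out_dir = td))
  expect_equal(nrow(m), 3)
  expect_true(all(file.exists(m$dataset)))
  man <- utils::read.csv(file.path(td, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_setequal(man$seed, 1:3)
  # different seeds give different residual draws
  expect_false(identical(readLines(m$dataset[1]), readLines(m$dataset[2])))
  unlink(td, recursive = TRUE)
})

test_that("study-3 baseline variability reflects the synthesis-rate IIV", {
  pop <- default_population()
  des <- builtin_designs()$study3
  set.seed(21)
  ind <- gcdcaspk:::.sample_individuals(pop, 200)
  base <- ind["ksyn", ] / (ind["CLh", ] + ind["CLR", ])
  cv <- sd(log(base))
  # baseline is ksyn/(CLh+CLR) with CLR << CLh, so log-scale SD ~ omega_ksyn
  expect_equal(cv, 0.61, tolerance = 0.15)
})
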