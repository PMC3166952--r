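test_that("genotype sampling respects the configured class distribution", {
  cfg <- PRTSimConfig(c("2" = 1), nCases = 4, nControls = 6, seed = 1)
  g <- sampleGenotypes(cfg)
  expect_equal(nrow(g), 10L)
  expect_true(all(g$true_cn == 2L))
  expect_equal(sum(g$status == "case"), 4L)

  empty <- PRTSimConfig(c("2" = 1), nCases = 0, nControls = 0, seed = 1)
  expect_equal(nrow(sampleGenotypes(empty)), 0L)

  # control-panel frequencies: empirical mean near 502/252 = 1.992
  cfg2 <- PRTSimConfig(controlFreq252(), nControls = 252, seed = 3)
  g2 <- sampleGenotypes(cfg2)
  # 3 x multinomial SE of the mean (population SD 0.718)
  expect_lt(abs(mean(g2$true_cn) - 1.992), 3 * 0.718 / sqrt(252))
})

test_that("invalid configurations are rejected", {
  expect_error(PRTSimConfig(c("2" = 0.9), seed = 1), "sum to 1")
  expect_error(PRTSimConfig(c("2" = 1.5, "3" = -0.5), seed = 1), "negative")
  expect_error(PRTSimConfig(c(0.5, 0.5), seed = 1), "named")
  expect_error(PRTSimConfig(c("2" = 1), sigma0 = -0.1), "sigma0")
  expect_error(PRTSimConfig(c("2" = 1), systems = character(0)), "system")
})

test_that("same seed gives byte-identical peak tables", {
  cfg <- PRTSimConfig(c("1" = 0.3, "2" = 0.7), nCases = 15, nControls = 15,
                      seed = 11)
  pk1 <- generatePeakTable(sampleGenotypes(cfg), cfg)
  pk2 <- generatePeakTable(sampleGenotypes(cfg), cfg)
  expect_identical(serialiseTable(pk1), serialiseTable(pk2))
})

test_that("noiseless generation inverts exactly through the caller", {
  for (seed in c(2, 17, 301)) {
    cfg <- PRTSimConfig(c("0" = 0.1, "1" = 0.2, "2" = 0.4, "3" = 0.2,
                          "4" = 0.1),
                        nCases = 20, nControls = 20,
                        sigma0 = 0, sigmaFloor = 0, seed = seed)
    g <- sampleGenotypes(cfg)
    calls <- callCopyNumbers(generatePeakTable(g, cfg))
    expect_equal(unname(combinedValue(calls)[g$sample_id]),
                 as.numeric(g$true_cn), tolerance = 1e-10)
    expect_identical(unname(integerCall(calls)[g$sample_id]), g$true_cn)
  }
})

test_that("recovered class spread matches the generating noise model", {
  # single-class cohort at sigma0 = 0.10: class SD should come back near
  # 0.10 * sqrt(2) = 0.141 through the full pipeline
  cfg <- PRTSimConfig(c("2" = 1), nControls = 1000, sigma0 = 0.10,
                      sigmaFloor = 0, seed = 5)
  calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
  s <- classStatistics(calls)
  sdEst <- s$sd[s$integer_cn == 2]
  expect_lt(abs(sdEst - 0.1414), 3 * 0.1414 / sqrt(2 * 1000) + 0.005)
})

test_that("an injected case shift moves case means as configured", {
  cfg <- PRTSimConfig(c("2" = 1), nCases = 500, nControls = 500,
                      biasShift = -0.12, sigma0 = 0.10, sigmaFloor = 0,
                      seed = 8)
  g <- sampleGenotypes(cfg)
  calls <- callCopyNumbers(generatePeakTable(g, cfg))
  cv <- combinedValue(calls)
  st <- sampleStatus(calls)
  expect_lt(abs(mean(cv[st == "case"]) - 1.88), 0.02)
  expect_lt(abs(mean(cv[st == "control"]) - 2.00), 0.02)
})

test_that("peak tables round-trip through TSV and the export dialect parses", {
  cfg <- PRTSimConfig(c("2" = 1), nControls = 5, seed = 4)
  pk <- generatePeakTable(sampleGenotypes(cfg), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePeakTable(pk, f)
  back <- readPeakTable(f)
  expect_equal(back$test_area, pk$test_area, tolerance = 1e-9)
  expect_identical(back$sample_id, pk$sample_id)

  # minimal fragment-analysis export: <sample>_<system> key
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_name\ttest_area\tref_area",
               "S1_CCL3C\t5100\t5000",
               "STD2_R1_CCL3C\t5000\t5000"), f2)
  gm <- readPeakTable(f2)
  expect_identical(gm$sample_id, c("S1", "STD2_R1"))
  expect_identical(gm$system, c("CCL3C", "CCL3C"))
  expect_identical(gm$is_standard, c(FALSE, TRUE))
  expect_identical(gm$standard_cn, c(NA_integer_, 2L))
})
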