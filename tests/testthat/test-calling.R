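test_that("peak-area ratios are computed and invalid records flagged", {
  r <- computeRatio(c(5000, 0, 7500), c(5000, 5000, 5000))
  expect_equal(as.numeric(r), c(1, 0, 1.5))
  expect_equal(attr(r, "n_invalid"), 0L)

  bad <- computeRatio(c(5000, -1, 100, NA), c(0, 5000, 5000, 5000))
  expect_true(all(is.na(bad[c(1, 2, 4)])))
  expect_equal(attr(bad, "n_invalid"), 3L)
})

test_that("calibration recovers exact lines and matches the OLS oracle", {
  # standards exactly on ratio = 0.5 * CN, in triplicate
  pk <- peakTableFromRatios(rep(c(0.5, 1, 1.5, 2), each = 3),
                            rep(1:4, each = 3))
  cal <- fitCalibration(pk)
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$n_points, 12L)

  # jittered standards: coefficients equal the normal-equations oracle
  set.seed(42)
  for (i in 1:5) {
    cn <- rep(1:4, each = 3)
    ratio <- 0.47 * cn + 0.03 + rnorm(12, 0, 0.02)
    cal <- fitCalibration(peakTableFromRatios(ratio, cn))
    oracle <- olsOracle(cn, ratio)
    expect_lt(abs(cal$slope - oracle["slope"]), 1e-12)
    expect_lt(abs(cal$intercept - oracle["intercept"]), 1e-12)
  }
})

test_that("rank-deficient or inverted calibrations are rejected", {
  oneLevel <- peakTableFromRatios(rep(1, 3), rep(2L, 3))
  expect_error(fitCalibration(oneLevel), "calibrated")

  # a second healthy plate survives while the deficient one is dropped
  healthy <- peakTableFromRatios(rep(c(0.5, 1, 1.5, 2), each = 3),
                                 rep(1:4, each = 3), plate = "P02")
  expect_warning(cal <- fitCalibration(rbind(oneLevel, healthy)),
                 "failed")
  expect_equal(nrow(cal), 1L)
  expect_equal(cal$plate, "P02")
  expect_equal(attr(cal, "failed")$reason, "fewer than 2 distinct CN levels")

  # negative slope (ratio decreasing in CN) is not a usable calibration
  inverted <- peakTableFromRatios(rep(c(2, 1.5, 1, 0.5), each = 3),
                                  rep(1:4, each = 3))
  expect_error(suppressWarnings(fitCalibration(inverted)), "calibrated")
})

test_that("calibrated values invert the fitted line, negatives retained", {
  expect_equal(calibrateValue(1.0, 0.5, 0), 2.0)
  expect_equal(calibrateValue(0.0, 0.5, 0.02), -0.04)
  expect_error(calibrateValue(1, -0.5, 0), "positive")
})

test_that("system combination is the mean of present values", {
  expect_equal(combineSystems(c(1.9, 2.1, 2.0)), 2.0)
  expect_equal(combineSystems(c(2.021)), 2.021)
  expect_equal(combineSystems(c(NA, 1.8, 2.2)), 2.0)
  expect_true(is.na(combineSystems(c(NA_real_, NA_real_))))
})

test_that("integer assignment rounds to nearest, ties away, clamps at 0", {
  n <- assignInteger(c(2.021, -0.033, 2.5, 1.49, 1.51, 0.5, NA))
  expect_identical(as.integer(n), c(2L, 0L, 3L, 1L, 2L, 1L, NA))
  expect_identical(attr(n, "boundary"),
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("integer call is invariant to system permutation", {
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(3, sample(0:5, 1), 0.2)
    expect_identical(assignInteger(combineSystems(v)),
                     assignInteger(combineSystems(sample(v))))
  }
})

test_that("concordance categories are nested around the consensus integer", {
  expect_equal(classifyConcordance(c(2.2, 1.8, 2.4), 2L), "concordant_05")
  expect_equal(classifyConcordance(c(2.6, 1.9, 2.0), 2L), "concordant_075")
  expect_equal(classifyConcordance(c(3.0, 1.9, 2.0), 2L), "discordant")
  expect_equal(classifyConcordance(c(2.1), 2L), "concordant_05")
  expect_equal(classifyConcordance(c(NA_real_, NA_real_), NA_integer_),
               "missing")
  # nesting property: within-0.5 implies within-0.75
  set.seed(13)
  for (i in 1:50) {
    v <- 2 + runif(3, -1, 1)
    lab <- classifyConcordance(v, 2L)
    if (lab == "concordant_05") {
      expect_true(all(abs(v - 2) <= 0.75))
    }
  }
})

test_that("discordant samples are unresolved unless externally resolved", {
  m <- rbind(CCL3C = c(3.0, 2.2), CCL4A = c(1.9, 1.8),
             LTR61A = c(2.0, 2.1))
  colnames(m) <- c("D1", "OK1")
  cs <- PRTCallSet(m, status = "control")
  expect_identical(unname(integerCall(cs)), c(NA_integer_, 2L))
  expect_equal(as.character(concordance(cs)),
               c("discordant", "concordant_05"))

  res <- data.frame(sample_id = "D1", integer_call = 2L)
  cs2 <- PRTCallSet(m, status = "control", resolution = res)
  expect_identical(unname(integerCall(cs2)), c(2L, 2L))
  # still reported discordant; only the integer is externally supplied
  expect_equal(as.character(concordance(cs2))[1], "discordant")
})

test_that("samples with every system failed are reported missing", {
  pk <- peakTableFromRatios(rep(c(0.5, 1, 1.5, 2), each = 3),
                            rep(1:4, each = 3),
                            unkRatios = c(1.0, 0.8), unkIds = c("A", "B"))
  pk$ref_area[pk$sample_id == "B"] <- 0    # dead trace
  calls <- callCopyNumbers(pk)
  expect_identical(unname(integerCall(calls)["A"]), 2L)
  expect_true(is.na(integerCall(calls)["B"]))
  expect_equal(as.character(concordance(calls)["B"]), "missing")
  expect_equal(unname(nSystemsUsed(calls)["B"]), 0L)
})

test_that("realistic noise keeps most samples concordant within 0.5", {
  cfg <- PRTSimConfig(controlFreq252(), nControls = 600,
                      sigma0 = 0.10, seed = 21)
  calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
  frac05 <- mean(concordance(calls) == "concordant_05")
  expect_gte(frac05, 0.80)
})

test_that("inter-plate duplicate runs of a sample agree", {
  # noiseless: identical integer calls for both runs
  cfg0 <- PRTSimConfig(c("1" = 0.3, "2" = 0.4, "3" = 0.3),
                       nControls = 60, plateSize = 60, nDuplicates = 20,
                       sigma0 = 0, sigmaFloor = 0, seed = 14)
  g <- sampleGenotypes(cfg0)
  pk <- generatePeakTable(g, cfg0)
  dup <- !pk$is_standard & pk$plate == "P02"
  expect_gt(sum(dup), 0)
  pk$sample_id[dup] <- paste0(pk$sample_id[dup], "_rep2")
  calls <- callCopyNumbers(pk)
  ids <- sub("_rep2$", "", grep("_rep2$", colnames(calls), value = TRUE))
  expect_identical(unname(integerCall(calls)[paste0(ids, "_rep2")]),
                   unname(integerCall(calls)[ids]))

  # noisy: run-to-run difference in combined value stays below 4 * sigma0
  # (the sample-level error component is shared between runs)
  cfg <- PRTSimConfig(c("1" = 0.3, "2" = 0.4, "3" = 0.3),
                      nControls = 100, plateSize = 100, nDuplicates = 50,
                      sigma0 = 0.10, seed = 15)
  g <- sampleGenotypes(cfg)
  pk <- generatePeakTable(g, cfg)
  dup <- !pk$is_standard & pk$plate == "P02"
  pk$sample_id[dup] <- paste0(pk$sample_id[dup], "_rep2")
  calls <- callCopyNumbers(pk)
  ids <- sub("_rep2$", "", grep("_rep2$", colnames(calls), value = TRUE))
  d <- abs(combinedValue(calls)[paste0(ids, "_rep2")] -
             combinedValue(calls)[ids])
  expect_gte(mean(d < 4 * 0.10), 0.99)
})

test_that("call tables serialise with unresolved and missing labels", {
  m <- rbind(CCL3C = c(3.0, 2.2, NA), CCL4A = c(1.9, 1.8, NA),
             LTR61A = c(2.0, 2.1, NA))
  colnames(m) <- c("D1", "OK1", "M1")
  cs <- PRTCallSet(m, status = "control")
  tab <- callTable(cs)
  expect_identical(tab$integer_call, c("unresolved", "2", "missing"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCallTable(cs, f)
  back <- utils::read.delim(f, colClasses = "character")
  expect_identical(back$sample_id, c("D1", "OK1", "M1"))
})
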