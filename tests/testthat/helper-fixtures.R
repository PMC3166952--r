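# Shared fixtures and independent oracles for the test suite.

# Control copy-number class frequencies of the Crohn's-study control panel
# (counts 4, 49, 149, 45, 5 for CN 0-4 out of 252).
controlFreq252 <- function() {
  c("0" = 4, "1" = 49, "2" = 149, "3" = 45, "4" = 5) / 252
}

# Closed-form ordinary-least-squares oracle (normal equations), kept
# independent of the lm()-based implementation it checks.
olsOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Minimal hand-built peak table: one plate, one system, standards with
# prescribed ratios plus optional unknowns (ratio -> areas with ref 5000).
peakTableFromRatios <- function(stdRatios, stdCN, unkRatios = numeric(0),
                                unkIds = sprintf("U%02d", seq_along(unkRatios)),
                                system = "CCL3C", plate = "P01") {
  ref <- 5000
  std <- data.frame(
    sample_id = sprintf("STD%d_R%d", stdCN, seq_along(stdCN)),
    cohort = "standard", status = "reference",
    system = system, plate = plate,
    test_area = stdRatios * ref, ref_area = ref,
    is_standard = TRUE, standard_cn = stdCN,
    stringsAsFactors = FALSE
  )
  if (!length(unkRatios)) return(std)
  unk <- data.frame(
    sample_id = unkIds, cohort = "control_cohort", status = "control",
    system = system, plate = plate,
    test_area = unkRatios * ref, ref_area = ref,
    is_standard = FALSE, standard_cn = NA_integer_,
    stringsAsFactors = FALSE
  )
  rbind(std, unk)
}

# Serialise a data.frame the same way the TSV writers do, for
# byte-identity comparisons without touching disk.
serialiseTable <- function(df) {
  tc <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, tc, sep = "\t", quote = FALSE, row.names = FALSE)
  close(tc)
  paste(out, collapse = "\n")
}
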