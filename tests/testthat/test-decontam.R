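test_that("NTConly flags OTUs present in both NTCs and specimens", {
  m <- rbind(only_spec = c(5L, 3L, 0L),
             both = c(2L, 0L, 1L),
             only_ntc = c(0L, 0L, 4L))
  colnames(m) <- c("sp1", "sp2", "ntc1")
  meta <- toy_metadata(colnames(m), c("specimen", "specimen", "ntc"),
                       copies = c(1000, 2000, 1))
  rep <- identify_ntconly(m, meta)
  expect_identical(rep$is_contaminant, c(FALSE, TRUE, FALSE))
  expect_equal(rep$max_ntc_proportion, c(0, 1 / 5, 4 / 5))
  expect_error(identify_ntconly(m[, 1:2], meta), "NTC")
})

test_that("NTConly equals a brute-force presence double loop", {
  withr::with_seed(21, {
    for (rep_i in 1:5) {
      m <- random_count_table(50, 20, max_count = 3)
      roles <- sample(c(rep("ntc", 4), rep("specimen", 16)))
      meta <- toy_metadata(colnames(m), roles, copies = 1000)
      got <- identify_ntconly(m, meta)
      oracle <- vapply(seq_len(nrow(m)), function(i) {
        in_ntc <- FALSE; in_spec <- FALSE
        for (j in seq_len(ncol(m))) {
          if (m[i, j] > 0 && roles[j] == "ntc") in_ntc <- TRUE
          if (m[i, j] > 0 && roles[j] == "specimen") in_spec <- TRUE
        }
        in_ntc && in_spec
      }, logical(1))
      expect_identical(got$is_contaminant, oracle)
    }
  })
})

test_that("frequency p-value hits its exact limits", {
  c6 <- c(10, 30, 100, 300, 1000, 3000)
  expect_equal(frequency_pvalue(1000 / c6 / 1e4, c6), 0)
  expect_equal(frequency_pvalue(rep(0.05, 6), c6), 1)
  expect_true(is.na(frequency_pvalue(c(0.1, 0.2, 0.3), c(1, 2, 3))))
})

test_that("frequency p-value detects simulated contaminants", {
  hits <- withr::with_seed(31, {
    sapply(1:200, function(i) {
      conc <- exp(runif(20, log(600), log(50000)))
      f <- 1000 / conc * rlnorm(20, 0, 0.1)
      frequency_pvalue(f, conc) < 0.05
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("frequency p-value is invariant to concentration rescaling", {
  withr::with_seed(41, {
    conc <- exp(runif(12, 5, 11))
    f <- rlnorm(12, -4, 1)
    expect_equal(frequency_pvalue(f, conc),
                 frequency_pvalue(f, conc * 1234.5), tolerance = 1e-12)
  })
})

test_that("prevalence p-value equals the exact hypergeometric tail", {
  expect_equal(prevalence_pvalue(0, 5, 3, 10), 1)
  expect_equal(prevalence_pvalue(2, 2, 0, 8), 1 / 45)
  expect_gt(prevalence_pvalue(5, 10, 50, 100), 0.5)

  # exhaustive enumeration oracle over all tables with n_ntc + n_spec <= 12
  enum_oracle <- function(k1, n1, k2, n2) {
    K <- k1 + k2
    js <- max(0, K - n2):min(K, n1)
    probs <- choose(n1, js) * choose(n2, K - js) / choose(n1 + n2, K)
    sum(probs[js >= k1])
  }
  for (n1 in 1:4) {
    for (n2 in 1:(12 - n1)) {
      for (k1 in 0:n1) {
        for (k2 in 0:n2) {
          expect_equal(prevalence_pvalue(k1, n1, k2, n2),
                       enum_oracle(k1, n1, k2, n2), tolerance = 1e-12)
        }
      }
    }
  }
  # and agrees with the one-sided Fisher exact test
  expect_equal(prevalence_pvalue(3, 6, 2, 9),
               stats::fisher.test(matrix(c(3, 2, 3, 7), 2),
                                  alternative = "greater")$p.value)
})

test_that("Fisher combination follows the chi-square(4) tail", {
  expect_equal(combined_pvalue(1, 1), 1)
  x <- -2 * (log(0.01) + log(0.01))
  expect_equal(combined_pvalue(0.01, 0.01), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(combined_pvalue(0.01, 0.01), 1.02e-3, tolerance = 1e-2)
  expect_equal(combined_pvalue(NA, 0.03), 0.03)
  expect_equal(combined_pvalue(0.2, NA), 0.2)
  expect_true(is.na(combined_pvalue(NA, NA)))
})

test_that("the decision rule is strict and re-callable", {
  m <- rbind(a = c(10L, 0L, 5L), b = c(8L, 2L, 1L), c = c(0L, 9L, 9L))
  colnames(m) <- c("sp1", "sp2", "ntc1")
  meta <- toy_metadata(colnames(m), c("specimen", "specimen", "ntc"),
                       copies = c(700, 900, 1))
  rep <- identify_contaminants(m, meta, method = "prevalence", threshold = 0.1)
  # manual thresholding at the boundary
  rep$p_prev <- c(0.05, 0.1, 0.5)
  out <- call_contaminants(rep, 0.1)
  expect_identical(out$is_contaminant, c(TRUE, FALSE, FALSE))
  none <- call_contaminants(rep, 0)
  expect_false(any(none$is_contaminant))
  expect_equal(glance(none)$n_contaminants, 0)
})

test_that("max-proportion subtraction clips, preserves and re-closes", {
  props <- cbind(sp1 = c(0.5, 0.3, 0.2), ntc1 = c(0.5, 0.25, 0.25))
  rownames(props) <- c("x", "y", "z")
  report <- tibble::tibble(otu_id = c("x", "y", "z"),
                           max_ntc_proportion = c(0.5, 0, 0),
                           p_freq = NA_real_, p_prev = NA_real_,
                           p_comb = NA_real_,
                           is_contaminant = c(TRUE, FALSE, FALSE))
  attr(report, "method") <- "ntconly"
  meta <- toy_metadata(colnames(props), c("specimen", "ntc"), copies = 1000)

  raw <- subtract_contaminants(props, report, meta, renormalize = FALSE)
  expect_equal(unname(raw[, "sp1"]), c(0, 0.3, 0.2))
  norm <- subtract_contaminants(props, report, meta, renormalize = TRUE)
  expect_equal(unname(norm[, "sp1"]), c(0, 0.6, 0.4))
  expect_equal(norm[, "ntc1"], props[, "ntc1"]) # controls untouched

  # p = 0.30, m = 0.10 -> 0.20; p = 0.05, m = 0.10 -> clipped at 0
  p2 <- cbind(s = c(0.30, 0.05, 0.65), n = c(0.1, 0.1, 0.8))
  rownames(p2) <- c("x", "y", "z")
  rep2 <- report
  rep2$max_ntc_proportion <- c(0.1, 0.1, 0)
  rep2$is_contaminant <- c(TRUE, TRUE, FALSE)
  meta2 <- toy_metadata(c("s", "n"), c("specimen", "ntc"), copies = 1000)
  raw2 <- subtract_contaminants(p2, rep2, meta2, renormalize = FALSE)
  expect_equal(unname(raw2[, "s"]), c(0.2, 0, 0.65))
})

test_that("subtraction contract holds on random tables", {
  withr::with_seed(51, {
    for (i in 1:10) {
      m <- random_count_table(25, 8)
      roles <- c("ntc", "ntc", rep("specimen", 6))
      meta <- toy_metadata(colnames(m), roles, copies = 1000)
      props <- to_proportions(m)
      rep <- identify_ntconly(m, meta)
      raw <- subtract_contaminants(props, rep, meta, renormalize = FALSE)
      expect_true(all(raw >= 0))
      keep <- !rep$is_contaminant
      spec <- roles == "specimen"
      expect_equal(raw[keep, spec], props[keep, spec])
      expect_true(all(raw[, spec] <= props[, spec] + 1e-12))
      closed <- subtract_contaminants(props, rep, meta, renormalize = TRUE)
      ok <- !degenerate_samples(closed)[spec]
      expect_true(all(abs(colSums(closed[, spec, drop = FALSE])[ok] - 1) < 1e-9))
    }
  })
})

test_that("shift report counts complete removals per positive specimen", {
  props <- cbind(s1 = c(0.6, 0.4), s2 = c(0.2, 0.8), s3 = c(0.5, 0.5),
                 s4 = c(0.1, 0.9), n1 = c(0.3, 0.7))
  rownames(props) <- c("o1", "o2")
  tax <- tibble::tibble(otu_id = c("o1", "o2"), genus = c("Staph", "Morax"),
                        species = c("a", "c"))
  meta <- toy_metadata(colnames(props), c(rep("specimen", 4), "ntc"),
                       copies = 1000)
  after <- props
  after["o1", c("s1", "s2", "s3")] <- 0 # zeroed in 3 of 4 positives
  rep <- shift_report(props, list(ntconly = after), tax, meta)
  s <- rep$summary
  expect_equal(s$fraction_completely_removed[s$taxon == "Staph"], 0.75)
  expect_equal(s$fraction_completely_removed[s$taxon == "Morax"], 0)
  expect_equal(s$n_positive[s$taxon == "Staph"], 4)

  noop <- shift_report(props, list(none = props), tax, meta)
  expect_true(all(noop$summary$fraction_completely_removed == 0))
  expect_equal(noop$profiles$before, noop$profiles$after)
  expect_s3_class(tidy(rep), "tbl_df")
})

test_that("NTConly removes spill-over-affected true taxa more than combined", {
  # directional: a Staphylococcus-like true taxon reaches the NTCs through
  # well-to-well spill-over, so presence-based removal zeroes it while the
  # statistical classifier spares it
  deltas <- sapply(1:10, function(s) {
    co <- small_cohort(s)
    ev_n <- decontam_eval(co, "ntconly")
    ev_c <- decontam_eval(co, "combined")
    props <- to_proportions(ev_n$gated$counts)
    cleaned <- list(
      ntconly = subtract_contaminants(props, ev_n$report, co$metadata),
      combined = subtract_contaminants(props, ev_c$report, co$metadata))
    rep <- shift_report(props, cleaned, co$taxonomy, co$metadata)
    s <- rep$summary[rep$summary$taxon == "Staphylococcus", ]
    s$fraction_completely_removed[s$method == "ntconly"] -
      s$fraction_completely_removed[s$method == "combined"]
  })
  expect_gte(mean(deltas, na.rm = TRUE), 0)
  expect_gt(sum(deltas > 0, na.rm = TRUE), sum(deltas < 0, na.rm = TRUE))
})
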