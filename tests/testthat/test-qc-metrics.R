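test_that("Shannon index matches its closed form", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(0, 1, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)))
  expect_equal(shannon_index(c(2, 1, 1)), shannon_index(c(0.5, 0.25, 0.25)))
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Shannon is maximal at the uniform distribution", {
  withr::with_seed(3, {
    for (i in 1:20) {
      k <- sample(2:40, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      expect_lte(shannon_index(p), log(k) + 1e-12)
    }
  })
})

test_that("pairwise R2 equals the OLS coefficient of determination", {
  counts <- rbind(A = c(50, 40), B = c(30, 40), C = c(20, 20))
  colnames(counts) <- c("S1", "S2")
  meta <- toy_metadata(c("S1", "S2"), "specimen", copies = 1000,
                       repeat_group = "g")
  r2 <- pairwise_r2(to_proportions(counts), meta)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$r_squared, 4 / 7, tolerance = 1e-12)
  # independent least-squares oracle
  fit <- lm(c(0.4, 0.4, 0.2) ~ c(0.5, 0.3, 0.2))
  expect_equal(r2$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  expect_true(r2$same_run)

  ident <- cbind(S1 = c(3L, 1L), S2 = c(3L, 1L))
  rownames(ident) <- c("A", "B")
  expect_equal(pairwise_r2(to_proportions(ident), meta)$r_squared, 1)
})

test_that("R2 record counts follow k(k-1)/2 and flags zero variance", {
  m <- random_count_table(10, 7, seed = 2)
  meta <- toy_metadata(colnames(m), "specimen", copies = 1000,
                       repeat_group = NA)
  meta$repeat_group <- c("q", "q", "q", "q", "d", "d", NA)
  r2 <- pairwise_r2(to_proportions(m), meta)
  expect_equal(sum(r2$repeat_group == "q"), 6)
  expect_equal(sum(r2$repeat_group == "d"), 1)

  # symmetry and invariance to OTU ordering
  perm <- sample(nrow(m))
  r2p <- pairwise_r2(to_proportions(m[perm, ]), meta)
  expect_equal(r2$r_squared, r2p$r_squared)

  flat <- m; flat[, 1] <- 5L
  r2f <- pairwise_r2(to_proportions(flat), meta)
  expect_true(any(r2f$undefined))
  expect_true(all(is.na(r2f$r_squared[r2f$undefined])))
})

test_that("spurious OTU classification uses the grand total strictly", {
  m <- rbind(OTUa = c(1L, 1L, 2L), OTUb = c(3L, 2L, 0L), OTUc = c(9L, 0L, 0L))
  colnames(m) <- paste0("S", 1:3)
  expect_identical(spurious_otus(m, 5), "OTUa") # 4 < 5; 5 survives
  st <- spurious_otu_stats(m, 5, groups = c("g", "g", "h"))
  expect_equal(st$per_sample$spurious_count, c(1L, 1L, 1L))
  expect_equal(st$per_group$frequency[st$per_group$group == "g"], 1)

  # two samples each carrying 3 distinct spurious OTUs -> frequency 3
  m2 <- matrix(1L, nrow = 6, ncol = 2,
               dimnames = list(paste0("sp", 1:6), c("A", "B")))
  m2[1:3, 2] <- 0L; m2[4:6, 1] <- 0L
  st2 <- spurious_otu_stats(m2, 5, groups = c("x", "x"))
  expect_equal(st2$per_group$frequency, 3)

  # invariant to sample order and to an all-zero OTU row
  expect_identical(spurious_otus(m[, c(3, 1, 2)], 5), spurious_otus(m, 5))
  expect_identical(spurious_otus(rbind(m, zero = 0L), 5)[1], "OTUa")
})

test_that("qc_table counts OTUs, reads and spurious detections", {
  counts <- toy_counts()
  meta <- toy_metadata(colnames(counts), "specimen", copies = 1000)
  qc <- qc_table(counts, meta)
  expect_equal(qc$read_count, c(8L, 4L, 7L))
  expect_equal(qc$otu_count, c(3L, 2L, 3L))
  expect_equal(qc$shannon[2], shannon_index(c(1, 3) / 4))
  expect_error(qc_table(counts, meta[-1, ]), "S1")
})

test_that("qc correlations flag undefined inputs and use the ln scale", {
  qc <- tibble::tibble(age_days = c(1, 10, 100), copies_per_ul = c(5, 5, 5),
                       read_count = c(1000, 2000, 3000), shannon = c(1, 2, 3))
  res <- qc_correlations(qc)
  expect_true(all(res$undefined[res$term != "r_reads_shannon"]))

  qc2 <- tibble::tibble(age_days = c(0, 3, 10, 80),
                        copies_per_ul = c(10, 100, 1000, 10000),
                        read_count = c(900, 1100, 1000, 1050),
                        shannon = c(3, 2.2, 1.5, 0.6))
  res2 <- qc_correlations(qc2)
  expect_equal(res2$estimate[res2$term == "r_age_biomass"],
               cor(log(qc2$age_days + 1), log(qc2$copies_per_ul + 1)))
  expect_lt(res2$estimate[res2$term == "r_biomass_shannon"], 0)
})

test_that("biomass gate is strict at the cutoff and exempts controls", {
  meta <- toy_metadata(c("a", "b", "c", "d"),
                       c("specimen", "specimen", "ntc", "specimen"),
                       copies = c(501, 500, 10, NA))
  g <- biomass_gate(meta, 500)
  expect_equal(g$status, c("retained", "excluded", "control", "missing"))
})
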