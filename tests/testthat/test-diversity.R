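test_that("Bray-Curtis matches its definition", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 0, 1), c(1, 1, 1)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("Bray-Curtis is a bounded symmetric dissimilarity", {
  withr::with_seed(3, {
    for (i in 1:20) {
      k <- sample(2:30, 1)
      x <- rgamma(k, 1); y <- rgamma(k, 1)
      expect_equal(bray_curtis(x, y), bray_curtis(y, x))
      expect_gte(bray_curtis(x, y), 0)
      expect_lte(bray_curtis(x, y), 1)
      expect_equal(bray_curtis(x, x), 0)
    }
  })
})

test_that("the distance matrix agrees with the pairwise operation and vegan", {
  m <- random_count_table(15, 6, seed = 7)
  p <- to_proportions(m)
  d <- as.matrix(bray_curtis_dist(p))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d[i, j], bray_curtis(p[, i], p[, j]), tolerance = 1e-12)
    }
  }
  expect_equal(unname(d), unname(as.matrix(vegan::vegdist(t(p), "bray"))),
               tolerance = 1e-12)
  expect_warning(bray_curtis_dist(m), "counts")
})

test_that("PCoA reproduces Euclidean configurations", {
  d2 <- as.dist(matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"),
                                                         c("a", "b"))))
  res <- pcoa(d2, k = 1)
  expect_equal(sort(unname(res$points[, 1])), c(-1, 1))

  withr::with_seed(29, {
    pts <- matrix(rnorm(20), ncol = 2)
  })
  d <- dist(pts)
  fit <- pcoa(d, k = 2)
  expect_equal(as.matrix(dist(fit$points)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-10)
  expect_equal(sum(fit$prop_var), 1, tolerance = 1e-9)
})

test_that("an equidistant triple yields two equal eigenvalues", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  fit <- pcoa(d, k = 2)
  eig <- fit$eigenvalues[fit$eigenvalues > 1e-8]
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  dd <- as.matrix(dist(fit$points))
  expect_equal(unname(dd[upper.tri(dd)]), rep(1, 3), tolerance = 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("PERMANOVA separates tight clusters and is seed-deterministic", {
  pts <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
               matrix(rnorm(20, 10, 0.01), ncol = 2))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 10)
  fit <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(fit$p_value, 1 / 200)
  fit2 <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(fit$p_value, fit2$p_value)
  # invariant to renaming group labels
  fit3 <- permanova(d, ifelse(g == "a", "x", "y"), n_perm = 199, seed = 5)
  expect_equal(fit3$pseudo_f, fit$pseudo_f)
  expect_equal(fit3$p_value, fit$p_value)
  expect_error(permanova(d, rep("a", 20)), "two groups")
})

test_that("pseudo-F matches brute-force enumeration for N <= 8", {
  withr::with_seed(37, {
    pts <- matrix(rnorm(16), ncol = 2)
  })
  d2 <- as.matrix(dist(pts))^2
  brute_f <- function(lab) {
    N <- 8; a <- 2
    sst <- sum(d2) / (2 * N)
    ssw <- 0
    for (lev in unique(lab)) {
      idx <- which(lab == lev)
      s <- 0
      for (i in idx) for (j in idx) s <- s + d2[i, j]
      ssw <- ssw + s / (2 * length(idx))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (N - a))
  }
  combos <- utils::combn(8, 4)
  for (c_i in sample(ncol(combos), 12)) {
    lab <- rep("b", 8); lab[combos[, c_i]] <- "a"
    fit <- permanova(dist(pts), lab, n_perm = 1, seed = 1)
    expect_equal(fit$pseudo_f, brute_f(lab), tolerance = 1e-10)
  }
  # cross-check against the reference implementation in vegan
  lab <- rep(c("a", "b"), each = 4)
  ad <- vegan::adonis2(dist(pts) ~ lab, permutations = 2)
  expect_equal(permanova(dist(pts), lab, n_perm = 1, seed = 1)$pseudo_f,
               ad$F[1], tolerance = 1e-10)
})

test_that("complete linkage merges by furthest neighbour", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 5
  dend <- complete_linkage(d)
  expect_equal(dend$height, c(1, 5))
  expect_equal(unname(cut_clusters(dend, 0.5)), c(1, 2, 3)) # below first merge
  expect_equal(unname(cut_clusters(dend, 2)), c(1, 1, 2))
  expect_equal(unname(cut_clusters(dend, 5)), c(1, 1, 1)) # at/after last merge
  expect_error(complete_linkage(matrix(0, 1, 1)), "two samples")
})

test_that("complete-linkage merge heights are monotone", {
  withr::with_seed(43, {
    for (i in 1:10) {
      p <- to_proportions(random_count_table(20, 10))
      h <- complete_linkage(bray_curtis_dist(p))$height
      expect_true(all(diff(h) >= -1e-12))
    }
  })
})
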