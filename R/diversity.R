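#' Bray-Curtis dissimilarity between two profiles
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; 0 for identical profiles,
#' 1 for disjoint supports, and bounded in \[0, 1\] for non-negative input.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("profiles must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) abort("Bray-Curtis is undefined for two all-zero profiles")
  sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix over samples
#'
#' Computes all pairwise Bray-Curtis dissimilarities between the sample
#' columns. Proportion input is expected (the analysis works on compositional
#' data); raw counts are accepted with a warning.
#'
#' @param profiles OTUs x samples matrix of proportions (or counts).
#' @return A `dist` object over samples.
#' @export
bray_curtis_dist <- function(profiles) {
  if (max(colSums(profiles)) > 1 + 1e-6) {
    warn("input looks like counts; Bray-Curtis is normally computed on proportions")
  }
  cs <- colSums(profiles)
  if (any(cs == 0)) {
    abort(sprintf("all-zero sample column(s): %s",
                  paste(colnames(profiles)[cs == 0], collapse = ", ")))
  }
  # BC(x, y) = L1(x, y) / (sum x + sum y)
  man <- dist(t(profiles), method = "manhattan")
  denom <- as.dist(outer(cs, cs, "+"))
  man / denom
}

#' Principal coordinate analysis
#'
#' Classical (metric) multidimensional scaling by Gower double-centering and
#' eigendecomposition, so that Euclidean distances between the returned
#' coordinates approximate the input dissimilarities. Axes with negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped with a warning reporting their magnitude; the
#' per-axis share of variance is `lambda_i / sum(positive lambda)`.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Number of coordinates to return (<= n - 1).
#' @return A `pcoa_result` with `points` (n x k' matrix), `eigenvalues`,
#'   `prop_var`, and `negative_magnitude`.
#' @export
pcoa <- function(d, k = 2) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm))) abort("dissimilarity matrix must be symmetric")
  n <- nrow(dm)
  if (k > n - 1) abort("k must be at most n - 1")
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-8]
  neg <- eig[eig < -1e-8]
  if (length(neg) > 0) {
    warn(sprintf("%d negative eigenvalue(s) dropped (largest magnitude %.3g)",
                 length(neg), max(abs(neg))))
  }
  pts <- fit$points
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = eig,
                 prop_var = pos / sum(pos),
                 negative_magnitude = if (length(neg)) max(abs(neg)) else 0),
            class = "pcoa_result")
}

#' @export
tidy.pcoa_result <- function(x, ...) {
  as_tibble(x$points, rownames = "sample_id")
}

#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(n_axes = ncol(x$points),
         prop_var_1 = x$prop_var[1],
         prop_var_2 = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_,
         negative_magnitude = x$negative_magnitude)
}

permanova_ss <- function(d2, groups) {
  N <- nrow(d2)
  lev <- unique(groups)
  Z <- matrix(0, N, length(lev))
  Z[cbind(seq_len(N), match(groups, lev))] <- 1
  within_g <- colSums((d2 %*% Z) * Z) / (2 * colSums(Z))
  c(total = sum(d2) / (2 * N), within = sum(within_g))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based one-factor PERMANOVA: with `SS_total = (1/N) sum_{i<j} d^2`
#' and `SS_within = sum_g (1/n_g) sum_{i<j in g} d^2`, the pseudo-F statistic
#' is `(SS_between / (a - 1)) / (SS_within / (N - a))`, and its p-value is the
#' permutation tail `(1 + #(F_perm >= F_obs)) / (1 + n_perm)` under random
#' relabeling of the group assignments.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample (>= 2 groups).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed making the permutation p-value
#'   reproducible.
#' @return A `permanova` object; [glance()] gives pseudo-F and p.
#' @export
permanova <- function(d, groups, n_perm = 1000, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm), n_perm >= 1)
  a <- length(unique(groups))
  if (a < 2) abort("PERMANOVA needs at least two groups")
  N <- nrow(dm)
  d2 <- dm^2
  run <- function() {
    ss <- permanova_ss(d2, groups)
    f_obs <- ((ss["total"] - ss["within"]) / (a - 1)) /
      (ss["within"] / (N - a))
    f_perm <- vapply(seq_len(n_perm), function(b) {
      g <- sample(groups)
      ssb <- permanova_ss(d2, g)
      ((ssb["total"] - ssb["within"]) / (a - 1)) / (ssb["within"] / (N - a))
    }, numeric(1))
    list(f = unname(f_obs),
         p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
         ss_total = unname(ss["total"]), ss_within = unname(ss["within"]))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(pseudo_f = res$f, p_value = res$p, n_perm = n_perm,
                 n_groups = a, n_samples = N,
                 ss_total = res$ss_total, ss_within = res$ss_within),
            class = "permanova")
}

#' @export
glance.permanova <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, p_value = x$p_value, n_perm = x$n_perm,
         n_groups = x$n_groups, n_samples = x$n_samples)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble(term = c("between", "within", "total"),
         sum_of_squares = c(x$ss_total - x$ss_within, x$ss_within,
                            x$ss_total),
         df = c(x$n_groups - 1, x$n_samples - x$n_groups,
                x$n_samples - 1))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p_value, x$n_perm))
  invisible(x)
}

#' Complete-linkage (furthest neighbour) hierarchical clustering
#'
#' Agglomerative clustering with max-distance linkage; merge heights are
#' non-decreasing. Use [cut_clusters()] to obtain the partition at a given
#' dissimilarity height (the study cuts a Bray-Curtis dendrogram at 0.99 for
#' primary clusters and 0.90 for sub-clusters).
#'
#' @param d A `dist` or symmetric dissimilarity matrix over >= 2 samples.
#' @return An `hclust` object.
#' @export
complete_linkage <- function(d) {
  dm <- as.dist(d)
  if (attr(dm, "Size") < 2) abort("clustering needs at least two samples")
  hclust(dm, method = "complete")
}

#' Cut a dendrogram at a dissimilarity height
#'
#' Returns the partition induced by removing all merges above height `h`.
#'
#' @param dend An `hclust` object.
#' @param h Cut height.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(dend, h) {
  cutree(dend, h = h)
}
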