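#' Bayesian-style multiplicative zero replacement
#'
#' Replaces zero parts of each sample composition with a small count-informed
#' pseudo-proportion and rescales the nonzero parts so the column still sums
#' to 1 and the ratios among originally-nonzero parts are preserved. For a
#' column with library size `N`, `D` parts and `Z` zeros, each zero becomes
#' `delta = alpha / (N + alpha * D)` and each nonzero part is multiplied by
#' `1 - Z * delta`.
#'
#' @param props OTUs x samples proportion matrix (columns sum to 1).
#' @param n_reads Library sizes of the source count table, one per column.
#' @param alpha Prior strength (default 0.5, a Jeffreys-like pseudo-count).
#' @return Strictly positive proportion matrix.
#' @export
replace_zeros <- function(props, n_reads, alpha = 0.5) {
  stopifnot(is.matrix(props), length(n_reads) == ncol(props), alpha > 0)
  D <- nrow(props)
  out <- props
  for (j in seq_len(ncol(props))) {
    x <- props[, j]
    if (all(x == 0)) {
      abort(sprintf("column '%s' is all-zero and cannot be zero-replaced",
                    colnames(props)[j]))
    }
    if (abs(sum(x) - 1) > 1e-6) {
      abort(sprintf("column '%s' does not sum to 1", colnames(props)[j]))
    }
    zero <- x == 0
    Z <- sum(zero)
    if (Z == 0) next
    delta <- alpha / (n_reads[j] + alpha * D)
    x[zero] <- delta
    x[!zero] <- x[!zero] * (1 - Z * delta)
    out[, j] <- x
  }
  out
}

#' Isometric log-ratio pivot coordinate
#'
#' The first ilr coordinate with the part of interest as pivot:
#' `z = sqrt((D - 1) / D) * ln(x_pivot / g(x_others))` where `g` is the
#' geometric mean of the remaining parts. It contrasts one taxon against the
#' rest of the composition, is scale-invariant, and is invariant to permuting
#' the non-pivot parts.
#'
#' @param x Strictly positive composition vector (D >= 2), or a matrix whose
#'   columns are compositions.
#' @param pivot Index (or row name, for matrices) of the pivot part.
#' @return Numeric scalar, or a named vector over samples for matrix input.
#' @export
ilr_pivot <- function(x, pivot) {
  if (is.matrix(x)) {
    if (is.character(pivot)) pivot <- match(pivot, rownames(x))
    return(vapply(seq_len(ncol(x)), function(j) ilr_pivot(x[, j], pivot),
                  numeric(1)) |> setNames(colnames(x)))
  }
  D <- length(x)
  if (D < 2) abort("a composition needs at least two parts")
  if (any(x <= 0)) {
    abort("zero or negative parts: apply replace_zeros() first")
  }
  if (is.character(pivot)) pivot <- match(pivot, names(x))
  sqrt((D - 1) / D) * (log(x[[pivot]]) - mean(log(x[-pivot])))
}

#' One-way ANOVA with Tukey HSD intervals on a pivot coordinate
#'
#' Fits a single-factor analysis of variance to ilr pivot coordinates grouped
#' by, e.g., extraction kit, and computes Tukey Honest Significant Difference
#' simultaneous confidence intervals for all pairwise group differences. A
#' pair differs significantly at the chosen level iff its interval excludes
#' zero.
#'
#' @param values Numeric responses (pivot coordinates).
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return A `pivot_anova` object; [tidy()] returns the Tukey interval table,
#'   [glance()] the F statistic, degrees of freedom and p-value.
#' @export
pivot_anova_tukey <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("each group needs at least two observations")
  df <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  ss <- an[["Sum Sq"]]
  if (all(ss < 1e-12)) {
    # all observations identical: no signal, no noise
    f <- 0; p <- 1
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    tuk <- tibble(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                  estimate = 0, conf_low = 0, conf_high = 0,
                  adj_p_value = 1, significant = FALSE)
  } else {
    f <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit, conf.level = conf_level)$g
    tuk <- tibble(contrast = rownames(tk),
                  estimate = unname(tk[, "diff"]),
                  conf_low = unname(tk[, "lwr"]),
                  conf_high = unname(tk[, "upr"]),
                  adj_p_value = unname(tk[, "p adj"]),
                  significant = unname(tk[, "lwr"] > 0 | tk[, "upr"] < 0))
  }
  structure(list(f_statistic = f, p_value = p,
                 df_between = nlevels(g) - 1,
                 df_within = length(values) - nlevels(g),
                 conf_level = conf_level, tukey = tuk),
            class = "pivot_anova")
}

#' @export
tidy.pivot_anova <- function(x, ...) x$tukey

#' @export
glance.pivot_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}

#' @export
print.pivot_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$tukey)
  invisible(x)
}
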