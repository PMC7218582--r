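#' Frequency-based contaminant p-value
#'
#' Contaminant DNA contributes a roughly constant number of reads per library,
#' so a contaminant OTU's relative frequency is inversely proportional to
#' specimen biomass, while a true taxon's frequency is independent of it. In
#' (ln concentration, ln frequency) space two one-parameter models are fit by
#' least squares: the contaminant-free null `ln f = b0` and the contaminant
#' model `ln f = -ln c + b0'` (fixed slope -1). With `SSR_null` and `SSR_cont`
#' their residual sums of squares over the n samples where the OTU is present
#' and the concentration positive, the p-value is
#' `Pr(F_{n-1, n-1} >= SSR_null / SSR_cont)`; small p is contaminant-like.
#'
#' @param freqs OTU relative frequencies (proportions), one per sample.
#' @param concs Matching biomass concentrations (16S copies/ul).
#' @param min_n Minimum number of positive samples required (default 4);
#'   below it the OTU is ineligible for frequency evidence and `NA` is
#'   returned.
#' @return A p-value in \[0, 1\], or `NA`.
#' @export
frequency_pvalue <- function(freqs, concs, min_n = 4) {
  stopifnot(length(freqs) == length(concs))
  keep <- !is.na(freqs) & !is.na(concs) & freqs > 0 & concs > 0
  n <- sum(keep)
  if (n < min_n) return(NA_real_)
  lf <- log(freqs[keep])
  lc <- log(concs[keep])
  ssr_null <- sum((lf - mean(lf))^2)
  y <- lf + lc # residualizing the fixed slope -1
  ssr_cont <- sum((y - mean(y))^2)
  if (ssr_cont == 0 && ssr_null == 0) return(NA_real_)
  if (ssr_cont == 0) return(0)
  pf(ssr_null / ssr_cont, n - 1, n - 1, lower.tail = FALSE)
}

#' Prevalence-based contaminant p-value
#'
#' One-sided Fisher exact test (hypergeometric tail) for OTU presence being
#' enriched in no-template controls relative to biological specimens; small p
#' is contaminant-like.
#'
#' @param k_ntc,n_ntc Number of NTCs where the OTU is present, and total NTCs.
#' @param k_spec,n_spec Likewise for biological specimens.
#' @return A p-value in \[0, 1\].
#' @export
prevalence_pvalue <- function(k_ntc, n_ntc, k_spec, n_spec) {
  stopifnot(k_ntc >= 0, k_ntc <= n_ntc, k_spec >= 0, k_spec <= n_spec,
            n_ntc >= 1, n_spec >= 1)
  # P(X >= k_ntc), X ~ Hypergeometric: draws of size n_ntc from a pool of
  # n_ntc + n_spec samples of which k_ntc + k_spec are positive
  phyper(k_ntc - 1, k_ntc + k_spec, n_ntc + n_spec - k_ntc - k_spec, n_ntc,
         lower.tail = FALSE)
}

#' Combine frequency and prevalence evidence (Fisher's method)
#'
#' `X = -2 (ln p_freq + ln p_prev)` referred to a chi-square with 4 degrees of
#' freedom. A missing component passes the other through unchanged.
#'
#' @param p_freq,p_prev Component p-values in (0, 1\], or `NA`.
#' @return Combined p-value, or `NA` when both components are missing.
#' @export
combined_pvalue <- function(p_freq, p_prev) {
  if (is.na(p_freq) && is.na(p_prev)) return(NA_real_)
  if (is.na(p_freq)) return(p_prev)
  if (is.na(p_prev)) return(p_freq)
  x <- -2 * (log(p_freq) + log(p_prev))
  pchisq(x, df = 4, lower.tail = FALSE)
}

#' Identify potential contaminants from NTC presence alone
#'
#' The "NTConly" rule: an OTU is a potential contaminant iff it is detected
#' (count > 0) in at least one no-template control \emph{and} at least one
#' biological specimen. For every OTU the maximum proportion observed across
#' the NTC columns is recorded (0 for OTUs absent from all NTCs); this is the
#' amount later subtracted by [subtract_contaminants()].
#'
#' @param counts OTUs x samples count matrix (post-denoise, post-gate).
#' @param metadata Sample metadata with a `role` column.
#' @return A `contam_report` tibble (otu_id, max_ntc_proportion, p_freq,
#'   p_prev, p_comb, is_contaminant) with attributes `method` and `threshold`.
#' @export
identify_ntconly <- function(counts, metadata) {
  cols <- decontam_columns(counts, metadata)
  props <- to_proportions(counts)
  in_ntc <- rowSums(counts[, cols$ntc, drop = FALSE] > 0) > 0
  in_spec <- rowSums(counts[, cols$spec, drop = FALSE] > 0) > 0
  report <- tibble(
    otu_id = rownames(counts),
    max_ntc_proportion = unname(apply(props[, cols$ntc, drop = FALSE], 1, max)),
    p_freq = NA_real_, p_prev = NA_real_, p_comb = NA_real_,
    is_contaminant = unname(in_ntc & in_spec))
  new_contam_report(report, method = "ntconly", threshold = NA_real_)
}

decontam_columns <- function(counts, metadata) {
  meta <- metadata[match(colnames(counts), metadata$sample_id), ]
  ntc <- which(meta$role == "ntc")
  spec <- which(meta$role == "specimen")
  if (length(ntc) < 1) abort("no NTC columns in the table")
  if (length(spec) < 1) abort("no specimen columns in the table")
  list(ntc = ntc, spec = spec, meta = meta)
}

new_contam_report <- function(report, method, threshold) {
  attr(report, "method") <- method
  attr(report, "threshold") <- threshold
  class(report) <- c("contam_report", class(report))
  report
}

#' Identify potential contaminants
#'
#' Runs the requested contaminant-identification method on a (denoised,
#' biomass-gated) count table:
#' \describe{
#'   \item{ntconly}{presence in >= 1 NTC and >= 1 specimen
#'     ([identify_ntconly()]); `threshold` is ignored.}
#'   \item{frequency}{[frequency_pvalue()] against the specimens' measured
#'     copies/ul.}
#'   \item{prevalence}{[prevalence_pvalue()] of presence in NTCs vs specimens.}
#'   \item{combined}{Fisher combination of the two ([combined_pvalue()]).}
#' }
#' Statistical methods flag an OTU iff its p-value is strictly below
#' `threshold`. All NTC columns form one control pool.
#'
#' @param counts OTUs x samples count matrix (post-denoise, post-gate).
#' @param metadata Sample metadata (`role`, `copies_per_ul`).
#' @param method One of `"combined"`, `"frequency"`, `"prevalence"`,
#'   `"ntconly"`.
#' @param threshold Classifier threshold on the p-value (default 0.1).
#' @param min_freq_n Minimum positive samples for frequency evidence.
#' @return A `contam_report` tibble; see [identify_ntconly()].
#' @export
identify_contaminants <- function(counts, metadata,
                                  method = c("combined", "frequency",
                                             "prevalence", "ntconly"),
                                  threshold = 0.1, min_freq_n = 4) {
  method <- match.arg(method)
  if (method == "ntconly") return(identify_ntconly(counts, metadata))
  if (threshold < 0 || threshold >= 1) {
    abort("threshold must lie in [0, 1); 0 flags nothing")
  }
  cols <- decontam_columns(counts, metadata)
  props <- to_proportions(counts)
  spec_props <- props[, cols$spec, drop = FALSE]
  spec_conc <- cols$meta$copies_per_ul[cols$spec]
  n_ntc <- length(cols$ntc); n_spec <- length(cols$spec)
  k_ntc <- rowSums(counts[, cols$ntc, drop = FALSE] > 0)
  k_spec <- rowSums(counts[, cols$spec, drop = FALSE] > 0)

  p_freq <- vapply(seq_len(nrow(counts)), function(i) {
    frequency_pvalue(spec_props[i, ], spec_conc, min_n = min_freq_n)
  }, numeric(1))
  p_prev <- vapply(seq_len(nrow(counts)), function(i) {
    prevalence_pvalue(k_ntc[i], n_ntc, k_spec[i], n_spec)
  }, numeric(1))
  p_comb <- vapply(seq_len(nrow(counts)), function(i) {
    combined_pvalue(p_freq[i], p_prev[i])
  }, numeric(1))
  p_used <- switch(method, frequency = p_freq, prevalence = p_prev,
                   combined = p_comb)
  report <- tibble(
    otu_id = rownames(counts),
    max_ntc_proportion = unname(apply(props[, cols$ntc, drop = FALSE], 1, max)),
    p_freq = p_freq, p_prev = p_prev, p_comb = p_comb,
    is_contaminant = !is.na(p_used) & p_used < threshold)
  new_contam_report(report, method = method, threshold = threshold)
}

#' Re-apply the contaminant decision rule at a new threshold
#'
#' @param report A `contam_report`.
#' @param threshold New threshold in (0, 1); 0 flags nothing. Ignored for the
#'   `ntconly` method, whose presence rule has no threshold.
#' @return The re-thresholded `contam_report`.
#' @export
call_contaminants <- function(report, threshold = 0.1) {
  method <- attr(report, "method")
  if (method == "ntconly") return(report)
  p_used <- switch(method, frequency = report$p_freq,
                   prevalence = report$p_prev, combined = report$p_comb)
  report$is_contaminant <- !is.na(p_used) & p_used < threshold
  attr(report, "threshold") <- threshold
  report
}

#' @export
glance.contam_report <- function(x, ...) {
  tibble(method = attr(x, "method"), threshold = attr(x, "threshold"),
         n_otus = nrow(x), n_contaminants = sum(x$is_contaminant))
}

#' Remove contaminants by max-proportion subtraction
#'
#' For every flagged OTU its maximum NTC proportion `m_j` is subtracted from
#' each specimen column, clipping at zero: `q_ij = max(0, p_ij - m_j)`.
#' Unflagged OTUs are untouched before re-closure. With `renormalize = TRUE`
#' (default) each specimen column is re-closed to sum 1, preserving the ratios
#' among the surviving values; columns that become all-zero are flagged
#' degenerate and left all-zero. Control (NTC/mock) columns pass through
#' unchanged.
#'
#' @param props OTUs x samples proportion matrix.
#' @param report A `contam_report` computed on the same OTU axis.
#' @param metadata Optional sample metadata; when given, only specimen columns
#'   are decontaminated, otherwise all columns are.
#' @param renormalize Re-close specimen columns to sum 1 (default `TRUE`).
#' @return Proportion matrix with a `degenerate` attribute.
#' @export
subtract_contaminants <- function(props, report, metadata = NULL,
                                  renormalize = TRUE) {
  if (!setequal(report$otu_id, rownames(props)) ||
      nrow(report) != nrow(props)) {
    abort("report and proportion table disagree on the OTU axis")
  }
  m <- report$max_ntc_proportion[match(rownames(props), report$otu_id)]
  flagged <- report$is_contaminant[match(rownames(props), report$otu_id)]
  target <- if (is.null(metadata)) {
    rep(TRUE, ncol(props))
  } else {
    meta <- metadata[match(colnames(props), metadata$sample_id), ]
    !is.na(meta$role) & meta$role == "specimen"
  }
  out <- props
  sub <- out[, target, drop = FALSE]
  sub[flagged, ] <- pmax(0, sub[flagged, , drop = FALSE] - m[flagged])
  degenerate <- setNames(rep(FALSE, ncol(props)), colnames(props))
  if (renormalize) {
    tot <- colSums(sub)
    zero <- tot == 0
    sub <- sweep(sub, 2, ifelse(zero, 1, tot), "/")
    degenerate[colnames(sub)[zero]] <- TRUE
  } else {
    degenerate[colnames(sub)[colSums(sub) == 0]] <- TRUE
  }
  out[, target] <- sub
  attr(out, "degenerate") <- degenerate
  out
}

#' Pre/post decontamination shift report
#'
#' Summarises, per taxon (genus by default) and per decontamination method,
#' the per-specimen proportions before and after contaminant removal and the
#' fraction of initially-positive specimens from which the taxon was
#' completely removed (post-method proportion exactly 0).
#'
#' @param before OTUs x samples proportion matrix prior to decontamination.
#' @param after_by_method Named list of post-decontamination proportion
#'   matrices sharing axes with `before`.
#' @param taxonomy Taxonomy tibble mapping every OTU to a genus.
#' @param metadata Optional metadata; when given, only specimen columns enter
#'   the report.
#' @param level `"genus"` (member-OTU proportions summed) or `"otu"`.
#' @param positives_only Restrict each taxon's records to specimens where it
#'   was initially present (default `TRUE`).
#' @return A `shift_report` list with tibbles `summary` (taxon x method) and
#'   `profiles` (per-specimen before/after pairs, for plotting).
#' @export
shift_report <- function(before, after_by_method, taxonomy, metadata = NULL,
                         level = c("genus", "otu"), positives_only = TRUE) {
  level <- match.arg(level)
  stopifnot(is.list(after_by_method), length(names(after_by_method)) > 0)
  unmapped <- setdiff(rownames(before), taxonomy$otu_id)
  if (length(unmapped) > 0) {
    abort(sprintf("taxonomy does not map OTU(s): %s",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  cols <- if (is.null(metadata)) {
    colnames(before)
  } else {
    meta <- metadata[match(colnames(before), metadata$sample_id), ]
    colnames(before)[!is.na(meta$role) & meta$role == "specimen"]
  }
  rollup <- function(p) {
    p <- p[, cols, drop = FALSE]
    if (level == "otu") return(p)
    key <- taxonomy$genus[match(rownames(p), taxonomy$otu_id)]
    rowsum(p, key)
  }
  b <- rollup(before)
  b <- b[rowSums(b) > 0, , drop = FALSE] # taxa absent everywhere are omitted
  profiles <- list(); summaries <- list()
  for (mth in names(after_by_method)) {
    a <- rollup(after_by_method[[mth]])[rownames(b), , drop = FALSE]
    for (tx in rownames(b)) {
      pos <- b[tx, ] > 0
      idx <- if (positives_only) which(pos) else seq_along(pos)
      if (length(idx) == 0) next
      profiles[[length(profiles) + 1]] <- tibble(
        level = level, taxon = tx, method = mth,
        sample_id = colnames(b)[idx],
        before = unname(b[tx, idx]), after = unname(a[tx, idx]))
      summaries[[length(summaries) + 1]] <- tibble(
        level = level, taxon = tx, method = mth,
        n_positive = sum(pos),
        fraction_completely_removed =
          if (sum(pos) == 0) NA_real_ else
            sum(a[tx, pos] == 0) / sum(pos))
    }
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 profiles = dplyr::bind_rows(profiles)),
            class = "shift_report")
}

#' @export
tidy.shift_report <- function(x, ...) x$summary

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report>\n")
  print(x$summary, n = 20)
  invisible(x)
}
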