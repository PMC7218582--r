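#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over the positive parts, natural logarithm. Count
#' vectors are closed internally; matrices are treated column-wise (one sample
#' per column).
#'
#' @param p Proportion or count vector, or an OTUs x samples matrix.
#' @return A numeric scalar (vector input) or named vector (matrix input).
#' @export
shannon_index <- function(p) {
  if (is.matrix(p)) {
    return(vapply(seq_len(ncol(p)), function(j) shannon_index(p[, j]),
                  numeric(1)) |> setNames(colnames(p)))
  }
  if (any(p < 0)) abort("negative entries in a composition")
  s <- sum(p)
  if (s == 0) abort("Shannon index is undefined for an all-zero vector")
  p <- p[p > 0] / s
  -sum(p * log(p))
}

#' Per-sample quality-control records
#'
#' Computes, for every library, the read count, number of detected OTUs,
#' Shannon diversity of the closed profile, and the number of detected
#' spurious OTUs (OTUs whose total count over the whole table is below
#' `min_total`), joined to the biomass and age metadata.
#'
#' @param counts OTUs x samples count matrix.
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @param min_total Spurious-OTU threshold on the grand total (default 5).
#' @return A tibble with one row per sample.
#' @export
qc_table <- function(counts, metadata, min_total = 5) {
  validate_count_table(counts)
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("metadata missing for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  spur <- spurious_otus(counts, min_total)
  reads <- colSums(counts)
  tibble(
    sample_id = colnames(counts),
    read_count = as.integer(reads),
    otu_count = as.integer(colSums(counts > 0)),
    shannon = vapply(seq_len(ncol(counts)), function(j) {
      if (reads[j] == 0) 0 else shannon_index(counts[, j])
    }, numeric(1)),
    spurious_count = as.integer(colSums(counts[spur, , drop = FALSE] > 0))
  ) |>
    left_join(metadata[, c("sample_id", "role", "copies_per_ul", "age_days",
                           "run_id", "repeat_group")],
              by = "sample_id")
}

#' Spurious OTU identifiers
#'
#' An OTU is spurious iff its total read count across \emph{all} samples of the
#' table (specimens and controls together) is below `min_total`.
#'
#' @inheritParams qc_table
#' @return Character vector of spurious OTU ids.
#' @export
spurious_otus <- function(counts, min_total = 5) {
  if (min_total < 1) abort("min_total must be >= 1")
  rownames(counts)[rowSums(counts) < min_total]
}

#' Spurious-OTU statistics per sample and per group
#'
#' @inheritParams qc_table
#' @param groups Optional named grouping of samples (e.g. low/high biomass);
#'   a character vector parallel to `colnames(counts)`.
#' @return A list with `otu_ids` (the spurious set), `per_sample` (tibble of
#'   spurious detections per sample) and, when `groups` is given, `per_group`
#'   with the per-specimen frequency (total spurious detections / number of
#'   samples in the group).
#' @export
spurious_otu_stats <- function(counts, min_total = 5, groups = NULL) {
  spur <- spurious_otus(counts, min_total)
  per_sample <- tibble(
    sample_id = colnames(counts),
    spurious_count = as.integer(colSums(counts[spur, , drop = FALSE] > 0)))
  out <- list(otu_ids = spur, per_sample = per_sample)
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(counts))
    out$per_group <- per_sample |>
      mutate(group = as.character(groups)) |>
      group_by(.data$group) |>
      summarise(n_samples = dplyr::n(),
                frequency = sum(.data$spurious_count) / dplyr::n(),
                .groups = "drop")
  }
  out
}

#' Pairwise reproducibility of technical repeats
#'
#' For every repeat group with at least two libraries present in the
#' proportion table, computes the squared Pearson correlation of the two
#' profiles over all OTUs (union support: zeros included). This equals the
#' coefficient of determination of the simple linear regression with
#' intercept, and is symmetric in the two libraries. Duplicates contribute 1
#' record, triplicates 3, quadruplicates 6.
#'
#' @param props OTUs x samples proportion matrix (see [to_proportions()]).
#' @param metadata Sample metadata with `repeat_group` and `run_id`.
#' @return A tibble with columns repeat_group, sample_1, sample_2, r_squared,
#'   same_run, undefined (TRUE when one profile has zero variance).
#' @export
pairwise_r2 <- function(props, metadata) {
  meta <- metadata[match(colnames(props), metadata$sample_id), ]
  has_group <- !is.na(meta$repeat_group)
  groups <- split(seq_len(ncol(props))[has_group], meta$repeat_group[has_group])
  recs <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < 2) next
    for (a in seq_along(cols)[-length(cols)]) {
      for (b in (a + 1):length(cols)) {
        i <- cols[a]; j <- cols[b]
        x <- props[, i]; y <- props[, j]
        undef <- sd(x) == 0 || sd(y) == 0
        recs[[length(recs) + 1]] <- tibble(
          repeat_group = g,
          sample_1 = colnames(props)[i],
          sample_2 = colnames(props)[j],
          r_squared = if (undef) NA_real_ else cor(x, y)^2,
          same_run = identical(meta$run_id[i], meta$run_id[j]),
          undefined = undef)
      }
    }
  }
  if (length(recs) == 0) {
    return(tibble(repeat_group = character(), sample_1 = character(),
                  sample_2 = character(), r_squared = numeric(),
                  same_run = logical(), undefined = logical()))
  }
  dplyr::bind_rows(recs)
}

#' Correlations between biomass and QC metrics
#'
#' Pearson (default) correlations between participant age, specimen biomass,
#' read counts and Shannon diversity, with age, copies/ul and read counts on
#' the `ln(x + 1)` scale. Pairwise complete observations; fewer than 3
#' complete pairs, or a zero-variance margin, yields an `undefined` flag
#' rather than a number.
#'
#' @param qc A tibble from [qc_table()] (columns age_days, copies_per_ul,
#'   read_count, shannon).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with columns term, estimate, n, undefined.
#' @export
qc_correlations <- function(qc, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  lncopies <- log(qc$copies_per_ul + 1)
  pairs <- list(
    r_age_biomass = cbind(log(qc$age_days + 1), lncopies),
    r_biomass_reads = cbind(lncopies, log(qc$read_count + 1)),
    r_biomass_shannon = cbind(lncopies, qc$shannon))
  dplyr::bind_rows(lapply(names(pairs), function(nm) {
    xy <- pairs[[nm]][complete.cases(pairs[[nm]]), , drop = FALSE]
    n <- nrow(xy)
    undef <- n < 3 || sd(xy[, 1]) == 0 || sd(xy[, 2]) == 0
    tibble(term = nm,
           estimate = if (undef) NA_real_ else
             cor(xy[, 1], xy[, 2], method = method),
           n = n, undefined = undef)
  }))
}

#' Biomass gate on qPCR copy numbers
#'
#' Specimens are retained iff `copies_per_ul > cutoff` (strictly); NTCs and
#' mocks are never gated and are carried as controls; specimens with a missing
#' measurement are listed separately.
#'
#' @param metadata Sample metadata tibble.
#' @param cutoff Copies/ul threshold (default 500).
#' @return Tibble with columns sample_id, role, copies_per_ul and status
#'   (`retained`, `excluded`, `control`, `missing`).
#' @export
biomass_gate <- function(metadata, cutoff = 500) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  metadata |>
    mutate(status = dplyr::case_when(
      .data$role != "specimen" ~ "control",
      is.na(.data$copies_per_ul) ~ "missing",
      .data$copies_per_ul > cutoff ~ "retained",
      TRUE ~ "excluded")) |>
    select("sample_id", "role", "copies_per_ul", "status")
}
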