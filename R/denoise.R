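#' Remove spurious OTUs (denoising step 1)
#'
#' Drops OTUs whose total read count over the whole table (all specimens and
#' controls) is below `min_total`; every retained cell is untouched and the
#' sample set is unchanged. Spurious totals are defined on the full pre-gate
#' dataset, so this step must run before [exclude_low_biomass()].
#'
#' @param counts OTUs x samples count matrix.
#' @param min_total Threshold on the grand total (default 5; strictly
#'   "less than", so an OTU totalling exactly `min_total` survives).
#' @return List with `counts` (filtered matrix) and `removed` (OTU ids).
#' @export
remove_spurious_otus <- function(counts, min_total = 5) {
  validate_count_table(counts)
  removed <- spurious_otus(counts, min_total)
  keep <- setdiff(rownames(counts), removed)
  list(counts = counts[keep, , drop = FALSE], removed = removed)
}

#' Exclude low-biomass specimens (denoising step 2)
#'
#' Drops specimen columns whose measured biomass is at or below `cutoff`
#' copies/ul (retain iff strictly greater). NTC and mock columns are always
#' retained as controls, and the OTU axis is untouched (rows may become
#' all-zero).
#'
#' @param counts OTUs x samples count matrix.
#' @param metadata Sample metadata covering every specimen column.
#' @param cutoff Copies/ul threshold (default 500).
#' @return List with `counts` (filtered matrix) and `excluded` (sample ids).
#' @export
exclude_low_biomass <- function(counts, metadata, cutoff = 500) {
  validate_count_table(counts)
  meta <- metadata[match(colnames(counts), metadata$sample_id), ]
  is_spec <- !is.na(meta$role) & meta$role == "specimen"
  uncovered <- colnames(counts)[is.na(meta$role) |
                                  (is_spec & is.na(meta$copies_per_ul))]
  if (length(uncovered) > 0) {
    abort(sprintf("specimen(s) lacking usable metadata: %s",
                  paste(uncovered, collapse = ", ")))
  }
  drop <- is_spec & meta$copies_per_ul <= cutoff
  list(counts = counts[, !drop, drop = FALSE],
       excluded = colnames(counts)[drop])
}
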