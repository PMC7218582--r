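#' Background (unexpected-taxon) proportion of mock-community samples
#'
#' For each sample column, sums the proportions of OTUs whose genus is not
#' part of the mock reference composition. Matching is at genus level via the
#' taxonomy map; every detected OTU must be mapped.
#'
#' @param props OTUs x samples proportion matrix.
#' @param reference A `mock_reference` (see [builtin_mock()]).
#' @param taxonomy Taxonomy tibble covering all detected OTUs.
#' @return Tibble with columns sample_id, background_proportion.
#' @export
background_proportion <- function(props, reference, taxonomy) {
  detected <- rownames(props)[rowSums(props) > 0]
  unmapped <- setdiff(detected, taxonomy$otu_id)
  if (length(unmapped) > 0) {
    abort(sprintf("taxonomy does not map detected OTU(s): %s",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  genus <- taxonomy$genus[match(rownames(props), taxonomy$otu_id)]
  is_background <- !(genus %in% reference$genus)
  tibble(sample_id = colnames(props),
         background_proportion =
           unname(colSums(props[is_background, , drop = FALSE])))
}

#' Expected versus observed mock composition
#'
#' Per sample and per expected mock taxon, the observed proportion (member
#' OTUs summed at genus level) against the theoretical proportion, with the
#' log2 observed/expected ratio. Taxa expected but undetected are reported
#' with observed 0 (log2 ratio `-Inf`), not as errors; unexpected genera are
#' listed with `expected_in_mock = FALSE`.
#'
#' @inheritParams background_proportion
#' @return Tibble with columns sample_id, taxon, expected, observed,
#'   log2_ratio, expected_in_mock.
#' @export
composition_agreement <- function(props, reference, taxonomy) {
  detected <- rownames(props)[rowSums(props) > 0]
  unmapped <- setdiff(detected, taxonomy$otu_id)
  if (length(unmapped) > 0) {
    abort(sprintf("taxonomy does not map detected OTU(s): %s",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  genus <- taxonomy$genus[match(rownames(props), taxonomy$otu_id)]
  by_genus <- rowsum(props, genus)
  out <- list()
  for (j in seq_len(ncol(props))) {
    obs <- setNames(by_genus[, j], rownames(by_genus))
    expected <- setNames(reference$proportion, reference$genus)
    got <- setNames(rep(0, length(expected)), names(expected))
    hit <- intersect(names(obs), names(expected))
    got[hit] <- obs[hit]
    extra <- setdiff(names(obs)[obs > 0], names(expected))
    out[[j]] <- dplyr::bind_rows(
      tibble(sample_id = colnames(props)[j], taxon = names(expected),
             expected = unname(expected), observed = unname(got),
             log2_ratio = log2(unname(got) / unname(expected)),
             expected_in_mock = TRUE),
      tibble(sample_id = colnames(props)[j], taxon = extra,
             expected = NA_real_, observed = unname(obs[extra]),
             log2_ratio = NA_real_, expected_in_mock = FALSE))
  }
  dplyr::bind_rows(out)
}
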