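# small deterministic fixtures, built in code

toy_counts <- function() {
  m <- matrix(c(2, 0, 2,
                0, 0, 0,
                1, 1, 1,
                5, 0, 0,
                0, 3, 4), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("OTU", 1:5), paste0("S", 1:3)))
  storage.mode(m) <- "integer"
  m
}

toy_metadata <- function(sample_id, role, copies = NA, age = NA, run = "run01",
                         repeat_group = NA) {
  tibble::tibble(
    sample_id = sample_id, role = role,
    copies_per_ul = rep_len(as.numeric(copies), length(sample_id)),
    age_days = rep_len(as.numeric(age), length(sample_id)),
    run_id = rep_len(run, length(sample_id)),
    well = paste0("P01_A", sprintf("%02d", seq_along(sample_id))),
    repeat_group = rep_len(as.character(repeat_group), length(sample_id)),
    buffer = "primestore", kit = "kit_qs")
}

random_count_table <- function(n_otu, n_sample, max_count = 20, seed = NULL) {
  draw <- function() {
    matrix(rpois(n_otu * n_sample, max_count / 4), nrow = n_otu,
           dimnames = list(paste0("OTU", seq_len(n_otu)),
                           paste0("S", seq_len(n_sample))))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# shared cohorts: generating the default cohort is cheap but repeated use in
# the acceptance suite adds up, so cache per configuration
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed, ...) {
  key <- paste0("s", seed, "_", rlang::hash(list(...)))
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(sim_config(seed = seed, ...))
  }
  .cohort_cache[[key]]
}

small_cohort <- function(seed) {
  cached_cohort(seed, n_specimens = 30, n_ntc = 4, n_mock_high = 4,
                n_mock_low = 4)
}

# classifier performance against the generator's truth labels
decontam_eval <- function(cohort, method, threshold = 0.1) {
  md <- cohort$metadata
  den <- remove_spurious_otus(cohort$counts)
  gated <- exclude_low_biomass(den$counts, md)
  rep <- identify_contaminants(gated$counts, md, method = method,
                               threshold = threshold)
  flagged <- rep$otu_id[rep$is_contaminant]
  origin <- cohort$truth$otus
  spec_cols <- intersect(colnames(gated$counts),
                         md$sample_id[md$role == "specimen"])
  present_spec <- rownames(gated$counts)[
    rowSums(gated$counts[, spec_cols, drop = FALSE] > 0) > 0]
  contam <- intersect(origin$otu_id[origin$origin == "reagent_contaminant"],
                      rownames(gated$counts))
  true_present <- intersect(origin$otu_id[origin$origin == "true_taxon"],
                            present_spec)
  list(sensitivity = length(intersect(flagged, contam)) / length(contam),
       fpr = length(intersect(flagged, true_present)) / length(true_present),
       report = rep, gated = gated)
}
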