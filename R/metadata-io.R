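SAMPLE_ROLES <- c("specimen", "ntc", "mock")
BUFFERS <- c("primestore", "stgg", "none")
KITS <- c("kit_qs", "kit_zb", "none")

#' Read per-sample metadata
#'
#' Fixed-column TSV with columns `sample_id`, `role` (specimen/ntc/mock),
#' `copies_per_ul` (16S rRNA gene copies per microlitre by qPCR),
#' `age_days` (participant age at specimen collection), `run_id`, `well`,
#' `repeat_group` (shared by technical repeats of one specimen), `buffer`
#' (primestore/stgg/none) and `kit` (kit_qs/kit_zb/none). Empty fields encode
#' missing values; a `copies_per_ul` of exactly 0 is legal and distinct from
#' missing.
#'
#' @param path TSV path.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE,
                   na.strings = "")
  needed <- c("sample_id", "role", "copies_per_ul", "age_days", "run_id",
              "well", "repeat_group", "buffer", "kit")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    sample_id = df$sample_id,
    role = df$role,
    copies_per_ul = as.numeric(df$copies_per_ul),
    age_days = as.numeric(df$age_days),
    run_id = df$run_id,
    well = df$well,
    repeat_group = df$repeat_group,
    buffer = df$buffer,
    kit = df$kit
  )
  validate_sample_metadata(out)
}

validate_sample_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample_id in metadata")
  bad_role <- setdiff(unique(meta$role), SAMPLE_ROLES)
  if (length(bad_role) > 0) {
    abort(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")))
  }
  if (any(meta$role == "ntc" & !is.na(meta$repeat_group))) {
    abort("NTC samples must not carry a repeat_group")
  }
  if (any(meta$copies_per_ul < 0, na.rm = TRUE)) {
    abort("copies_per_ul must be non-negative")
  }
  meta
}

#' Write per-sample metadata
#' @param meta Tibble as returned by [read_sample_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a taxonomy map
#'
#' TSV with columns `otu_id`, `genus`, `species`. Unclassifiable OTUs may carry
#' any label (commonly `"unclassified"`); each OTU appears once.
#'
#' @param path TSV path.
#' @return Tibble with columns otu_id, genus, species.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE,
                   na.strings = "")
  needed <- c("otu_id", "genus", "species")
  if (!all(needed %in% colnames(df))) {
    abort("taxonomy must have columns otu_id, genus, species")
  }
  if (anyDuplicated(df$otu_id)) abort("duplicated otu_id in taxonomy")
  as_tibble(df[, needed])
}

#' Write a taxonomy map
#' @param taxonomy Tibble with columns otu_id, genus, species.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a mock-community reference composition
#'
#' Two-column TSV (`taxon`, `proportion`); proportions must be positive and sum
#' to 1 (± 1e-6).
#'
#' @param path TSV path.
#' @param name Reference name to attach (defaults to the file name).
#' @return A `mock_reference` tibble with columns taxon, genus, proportion.
#' @export
read_mock_reference <- function(path, name = basename(path)) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("taxon", "proportion") %in% colnames(df))) {
    abort("mock reference must have columns taxon, proportion")
  }
  new_mock_reference(name, df$taxon, as.numeric(df$proportion))
}

new_mock_reference <- function(name, taxon, proportion) {
  if (any(proportion <= 0)) abort("mock reference proportions must be > 0")
  if (abs(sum(proportion) - 1) > 1e-6) {
    abort(sprintf("mock reference proportions sum to %.6f, not 1", sum(proportion)))
  }
  out <- tibble(taxon = taxon,
                genus = vapply(strsplit(taxon, " "), `[`, character(1), 1),
                proportion = proportion)
  attr(out, "mock_name") <- name
  class(out) <- c("mock_reference", class(out))
  out
}
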