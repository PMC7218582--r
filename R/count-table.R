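#' Read an OTU count table
#'
#' Reads a tab-separated OTU-by-sample count table. The first column holds OTU
#' identifiers (header cell `otu_id`), the remaining header cells are sample
#' identifiers, and the body holds non-negative integer read counts.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is sample-by-OTU and is transposed on
#'   read so that the returned matrix is always OTUs x samples.
#' @return An integer matrix with OTU ids as rownames and sample ids as
#'   colnames.
#' @details Identifiers are treated case-sensitively and must be unique on both
#'   axes; duplicated or malformed entries are hard errors naming the offending
#'   id or cell. The reader is loss-free: `write_count_table()` followed by
#'   `read_count_table()` reproduces the matrix exactly.
#' @export
read_count_table <- function(path, transpose = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    abort("count table must have an id column and at least one sample column")
  }
  ids <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated row id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicated column id(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-integer or negative count '%s' at row '%s', column '%s'",
                  body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                  samples[bad[1, 2]]))
  }
  counts <- matrix(as.integer(num), nrow = length(ids),
                   dimnames = list(ids, samples))
  if (transpose) counts <- t(counts)
  counts
}

#' Write an OTU count table
#'
#' @param counts Integer matrix, OTUs x samples, with dimnames.
#' @param path Output TSV path.
#' @param id_column Header for the id column (default `"otu_id"`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "otu_id") {
  validate_count_table(counts)
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_table <- function(counts) {
  if (!is.matrix(counts)) abort("count table must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count table must carry OTU rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicated OTU ids")
  if (anyDuplicated(colnames(counts))) abort("duplicated sample ids")
  if (any(counts < 0)) abort("negative counts are not allowed")
  invisible(counts)
}

#' Close a count table to per-sample proportions
#'
#' Divides every sample column by its library size so each column sums to 1.
#' All-zero columns cannot be closed; they are left all-zero and flagged in the
#' `"degenerate"` attribute of the result.
#'
#' @param counts Numeric matrix, OTUs x samples.
#' @return A double matrix of the same shape; attribute `degenerate` is a named
#'   logical vector over samples.
#' @export
to_proportions <- function(counts) {
  validate_count_table(counts)
  totals <- colSums(counts)
  degenerate <- totals == 0
  props <- sweep(counts, 2, ifelse(degenerate, 1, totals), "/")
  storage.mode(props) <- "double"
  attr(props, "degenerate") <- setNames(degenerate, colnames(counts))
  props
}

#' Which samples of a proportion table are degenerate (all-zero source)?
#'
#' @param props A matrix produced by [to_proportions()].
#' @return Named logical vector.
#' @export
degenerate_samples <- function(props) {
  flag <- attr(props, "degenerate")
  if (is.null(flag)) flag <- setNames(colSums(props) == 0, colnames(props))
  flag
}
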