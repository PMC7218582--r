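#' Run the full QC / denoise / decontamination pipeline
#'
#' Orchestrates the stages in the analysis order: load or simulate the cohort,
#' per-sample QC and replicate reproducibility, spurious-OTU removal
#' (denoise), biomass gate, contaminant identification and max-proportion
#' subtraction per requested method, beta-diversity summaries, and mock
#' evaluation when mock samples are present. Every threshold and seed is
#' recorded in a machine-readable run summary; re-running with the same
#' config reproduces all outputs.
#'
#' @param config A YAML file path or an equivalent nested list. Recognised
#'   blocks (all optional except one of `simulate` / `inputs`):
#'   \describe{
#'     \item{simulate}{arguments for [sim_config()].}
#'     \item{inputs}{paths `counts`, `metadata` and optionally `taxonomy`.}
#'     \item{denoise}{`min_total_reads` (default 5).}
#'     \item{gate}{`biomass_cutoff` (default 500).}
#'     \item{decontam}{`methods` (default `c("ntconly", "combined")`),
#'       `threshold` (default 0.1), `renormalize` (default `TRUE`).}
#'     \item{diversity}{`group` metadata column for PERMANOVA (default
#'       `"role"`), `n_permutations` (default 1000), `cut` (default 0.99),
#'       `subcut` (default 0.90).}
#'     \item{mock}{`reference`: a built-in mock name.}
#'     \item{seed}{integer driving the permutation tests (and the simulation
#'       when `simulate` omits its own seed).}
#'   }
#' @param out_dir Output directory for the artifact set (created if needed);
#'   `NULL` skips file output.
#' @return The run summary list (invisibly when writing files).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("config must be a YAML path or a list")
  seed <- cfg$seed %||% 1L
  summary <- list(parameters = list(seed = seed))

  # --- stage: inputs --------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(scfg)
    counts <- cohort$counts
    metadata <- cohort$metadata
    taxonomy <- cohort$taxonomy
    summary$parameters$simulate <- sim_args
  } else if (!is.null(cfg$inputs)) {
    for (field in c("counts", "metadata")) {
      if (is.null(cfg$inputs[[field]])) {
        abort(sprintf("stage inputs: config field 'inputs.%s' is missing", field))
      }
    }
    cohort <- NULL
    counts <- read_count_table(cfg$inputs$counts)
    metadata <- read_sample_metadata(cfg$inputs$metadata)
    taxonomy <- if (!is.null(cfg$inputs$taxonomy)) {
      read_taxonomy(cfg$inputs$taxonomy)
    } else NULL
  } else {
    abort("config needs a 'simulate' or an 'inputs' block")
  }

  # --- stage: qc ------------------------------------------------------------
  min_total <- cfg$denoise$min_total_reads %||% 5
  qc <- qc_table(counts, metadata, min_total = min_total)
  r2 <- pairwise_r2(to_proportions(counts), metadata)
  summary$qc <- list(n_samples = ncol(counts), n_otus = nrow(counts),
                     correlations = as.list(setNames(
                       qc_correlations(qc)$estimate,
                       qc_correlations(qc)$term)))

  # --- stage: denoise -------------------------------------------------------
  den <- remove_spurious_otus(counts, min_total = min_total)
  summary$parameters$min_total_reads <- min_total
  summary$denoise <- list(n_otus_removed = length(den$removed),
                          n_otus_kept = nrow(den$counts))
  if (nrow(den$counts) == 0) {
    abort("stage gate: no OTUs remain after denoising")
  }

  # --- stage: gate ----------------------------------------------------------
  cutoff <- cfg$gate$biomass_cutoff %||% 500
  gated <- exclude_low_biomass(den$counts, metadata, cutoff = cutoff)
  summary$parameters$biomass_cutoff <- cutoff
  summary$gate <- list(n_samples_excluded = length(gated$excluded),
                       n_samples_kept = ncol(gated$counts))

  # --- stage: decontam ------------------------------------------------------
  methods <- cfg$decontam$methods %||% c("ntconly", "combined")
  threshold <- cfg$decontam$threshold %||% 0.1
  renormalize <- cfg$decontam$renormalize %||% TRUE
  summary$parameters$decontam <- list(methods = methods, threshold = threshold,
                                      renormalize = renormalize)
  props <- to_proportions(gated$counts)
  reports <- list(); cleaned <- list()
  for (m in methods) {
    rep_m <- identify_contaminants(gated$counts, metadata, method = m,
                                   threshold = threshold)
    reports[[m]] <- rep_m
    cleaned[[m]] <- subtract_contaminants(props, rep_m, metadata,
                                          renormalize = renormalize)
  }
  summary$decontam <- lapply(reports, function(r) {
    list(n_contaminants = sum(r$is_contaminant))
  })
  flagged <- lapply(reports, function(r) r$otu_id[r$is_contaminant])
  if (all(c("ntconly", "combined") %in% names(flagged))) {
    ncomb <- length(flagged$combined)
    summary$decontam$overlap_combined_in_ntconly <-
      if (ncomb == 0) NA else
        length(intersect(flagged$combined, flagged$ntconly)) / ncomb
  }
  shifts <- if (!is.null(taxonomy) && length(cleaned) > 0) {
    shift_report(props, cleaned, taxonomy, metadata)
  } else NULL

  # --- stage: diversity -----------------------------------------------------
  div_group <- cfg$diversity$group %||% "role"
  n_perm <- cfg$diversity$n_permutations %||% 1000
  cut_h <- cfg$diversity$cut %||% 0.99
  subcut_h <- cfg$diversity$subcut %||% 0.90
  summary$parameters$diversity <- list(group = div_group,
                                       n_permutations = n_perm,
                                       cut = cut_h, subcut = subcut_h)
  meta_g <- metadata[match(colnames(props), metadata$sample_id), ]
  labels <- meta_g[[div_group]]
  d <- bray_curtis_dist(props)
  div <- NULL
  if (length(unique(labels)) >= 2 && ncol(props) >= 3) {
    pm <- permanova(d, labels, n_perm = n_perm, seed = seed)
    dend <- complete_linkage(d)
    div <- list(permanova = pm,
                clusters = cut_clusters(dend, cut_h),
                subclusters = cut_clusters(dend, subcut_h))
    summary$diversity <- list(pseudo_f = pm$pseudo_f, p_value = pm$p_value,
                              n_clusters = max(div$clusters),
                              n_subclusters = max(div$subclusters))
  }

  # --- stage: mock evaluation ----------------------------------------------
  mock_tbl <- NULL
  if (!is.null(cfg$mock$reference) && !is.null(taxonomy) &&
      any(metadata$role == "mock")) {
    ref <- builtin_mock(cfg$mock$reference)
    mock_cols <- intersect(colnames(counts),
                           metadata$sample_id[metadata$role == "mock"])
    mock_props <- to_proportions(counts[, mock_cols, drop = FALSE])
    mock_tbl <- background_proportion(mock_props, ref, taxonomy)
    summary$mock <- list(reference = cfg$mock$reference,
                         mean_background = mean(mock_tbl$background_proportion))
  }

  # --- artifacts ------------------------------------------------------------
  result <- list(summary = summary, qc = qc, reproducibility = r2,
                 counts_denoised = den$counts, counts_gated = gated$counts,
                 reports = reports, cleaned = cleaned, shifts = shifts,
                 diversity = div, mock = mock_tbl, cohort = cohort)
  class(result) <- "lbqc_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(gated$counts, file.path(out_dir, "counts_filtered.tsv"))
    write_sample_metadata(metadata, file.path(out_dir, "metadata.tsv"))
    utils::write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(r2, file.path(out_dir, "reproducibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    for (m in names(reports)) {
      utils::write.table(reports[[m]],
                         file.path(out_dir, sprintf("contaminants_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
    if (!is.null(shifts)) {
      utils::write.table(shifts$summary, file.path(out_dir, "shifts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    return(invisible(result))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lbqc_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<lbqc_run> %d OTUs x %d samples; %d spurious OTUs removed; %d samples gated out\n",
              s$qc$n_otus, s$qc$n_samples, s$denoise$n_otus_removed,
              s$gate$n_samples_excluded))
  for (m in names(x$reports)) {
    cat(sprintf("  %-10s %d potential contaminants\n", m,
                sum(x$reports[[m]]$is_contaminant)))
  }
  invisible(x)
}
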