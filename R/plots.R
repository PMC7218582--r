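#' Plot a principal coordinate ordination
#'
#' @param object A `pcoa_result` from [pcoa()].
#' @param colour Optional vector of group labels, one per sample.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  pv <- object$prop_var
  p <- ggplot(df, aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(colour)) {
    df$group <- colour
    p <- ggplot(df, aes(x = .data$PCo1, y = .data$PCo2,
                        colour = .data$group))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PCo1 (%.1f%%)", 100 * pv[1]),
         y = sprintf("PCo2 (%.1f%%)", 100 * pv[2])) +
    theme_bw()
}

#' Plot pre/post decontamination shifts
#'
#' Per-specimen before/after proportion pairs for each taxon and method, in
#' the style of the shift panels used to compare decontamination approaches.
#'
#' @param object A `shift_report`.
#' @param taxa Optional subset of taxa to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shift_report <- function(object, taxa = NULL, ...) {
  df <- object$profiles
  if (!is.null(taxa)) df <- df[df$taxon %in% taxa, ]
  df_long <- tidyr::pivot_longer(df, c("before", "after"),
                                 names_to = "stage", values_to = "proportion")
  df_long$stage <- factor(df_long$stage, levels = c("before", "after"))
  ggplot(df_long, aes(x = .data$stage, y = .data$proportion,
                      colour = .data$method, group = interaction(
                        .data$sample_id, .data$method))) +
    ggplot2::geom_line(alpha = 0.25) +
    geom_point(alpha = 0.5, size = 1) +
    facet_wrap(~taxon, scales = "free_y") +
    labs(x = NULL, y = "proportion") +
    theme_bw()
}

#' Biomass against QC metrics
#'
#' Scatter plots of read count, Shannon diversity and OTU count against
#' specimen biomass (both axes on the natural-log scale where appropriate),
#' coloured by sample role.
#'
#' @param qc A tibble from [qc_table()].
#' @return A ggplot.
#' @export
plot_biomass_qc <- function(qc) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(qc, ln_copies = log(.data$copies_per_ul + 1),
                  ln_reads = log(.data$read_count + 1)),
    c("ln_reads", "shannon", "otu_count"),
    names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$ln_copies, y = .data$value,
                 colour = .data$role)) +
    geom_point(alpha = 0.6, size = 1) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "ln(16S copies/ul + 1)", y = NULL) +
    theme_bw()
}
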