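#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Occupancy-abundance plot of a neutral-model fit
#'
#' Observed occupancy against log10 mean relative abundance, with the
#' fitted neutral curve and its confidence band; points coloured by
#' partition (above / fit / below prediction).
#'
#' @param object An `ncm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- dplyr::arrange(object$taxa, .data$p)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq_obs,
                                     colour = .data$partition),
                        size = 1, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$freq_pred), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "blue",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "blue",
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(above = "cyan3", fit = "black",
                                            below = "red")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  title = sprintf("Neutral model: Nm = %.0f, R² = %.2f",
                                  object$Nm, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Violin plot of a per-sample index by habitat
#'
#' @param values Named numeric vector or `sample_id`/`value` data frame.
#' @param metadata Sample metadata.
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_alpha_violin <- function(values, metadata, ylab = "Shannon index (bits)") {
  v <- as_value_vector(values)
  metadata <- validate_metadata(metadata)
  df <- tibble::tibble(value = unname(v),
                       habitat = metadata$habitat[match(names(v),
                                                        metadata$sample_id)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$habitat, y = .data$value,
                                   fill = .data$habitat)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' NMDS ordination plot coloured by habitat
#'
#' @param ord Result of [nmds_ordination()].
#' @param metadata Sample metadata.
#' @return A ggplot.
#' @export
plot_nmds <- function(ord, metadata) {
  metadata <- validate_metadata(metadata)
  df <- dplyr::left_join(ord$points,
                         metadata[, c("sample_id", "habitat")],
                         by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nmds1, y = .data$nmds2,
                                   colour = .data$habitat)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("NMDS (stress = %.3f)", ord$stress)) +
    ggplot2::theme_minimal()
}

#' Heatmap of microbial codes
#'
#' @param code A code matrix from [microbial_code()].
#' @return A ggplot tile map (individuals x core taxa).
#' @export
plot_code_heatmap <- function(code) {
  df <- tibble::as_tibble(code, rownames = "individual_id")
  df <- tidyr::pivot_longer(df, -"individual_id",
                            names_to = "taxon", values_to = "share")
  df$taxon <- factor(df$taxon, levels = colnames(code))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$individual_id,
                                   fill = .data$share)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "core share") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
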