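#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_vline
#'   labs theme_minimal autoplot scale_color_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a dyad-anchored motif profile
#'
#' @param object a `motif_profile` tibble.
#' @param flank restrict the x axis to `+-flank` bp (default: full profile).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.motif_profile <- function(object, flank = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(flank)) df <- df[abs(df$offset) <= flank, , drop = FALSE]
  ggplot(df, aes(x = .data$offset, y = .data$count)) +
    geom_line(color = "#2c7fb8") +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    labs(x = "distance from dyad (bp)", y = "motif base pairs",
         title = attr(object, "tf_name")) +
    theme_minimal()
}

#' Plot an enrichment run: scores by rank, colored by FDR
#'
#' @param object a `nuc_enrichment_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nuc_enrichment_run <- function(object, ...) {
  df <- as_tibble(object$table)
  df$order <- rank(-df$score, ties.method = "first")
  ggplot(df, aes(x = .data$order, y = .data$score,
                 color = -log10(pmax(.data$q_value, 1e-300)))) +
    geom_point() +
    scale_color_viridis_c(name = "-log10 q") +
    labs(x = "TF rank", y = "enrichment score (odds ratio)",
         title = sprintf("Motif enrichment on NRs vs NDRs (%s)",
                         object$params$mode)) +
    theme_minimal()
}

#' Plot a clustering result in its 2-D embedding
#'
#' @param object a `nuc_clusters` (needs `embed = TRUE`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nuc_clusters <- function(object, ...) {
  if (is.null(object$embedding)) abort("clustering was run without an embedding")
  df <- as_tibble(object$assignments)
  df$x <- object$embedding[, 1]
  df$y <- object$embedding[, 2]
  df$cluster_lab <- ifelse(df$outlier, "outlier", as.character(df$cluster))
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$cluster_lab)) +
    geom_point(size = 2) +
    labs(x = "t-SNE 1", y = "t-SNE 2", color = "cluster",
         title = "TF binding-mode clusters") +
    theme_minimal()
}

#' Plot the dyad-aligned occupancy profile
#'
#' @param occupancy tibble (offset, occupancy) from [occupancy_profile()].
#' @return a ggplot.
#' @export
plot_occupancy <- function(occupancy) {
  ggplot(occupancy, aes(x = .data$offset, y = .data$occupancy)) +
    geom_line(color = "#d95f0e") +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    labs(x = "distance from dyad (bp)", y = "mean fragment coverage",
         title = "Nucleosome occupancy around called dyads") +
    theme_minimal()
}

#' Plot a dinucleotide frequency profile
#'
#' @param profile tibble from [dinuc_profile()].
#' @param dinuc_class label for the title.
#' @return a ggplot.
#' @export
plot_dinuc <- function(profile, dinuc_class = "WW") {
  ggplot(profile, aes(x = .data$offset, y = .data$freq)) +
    geom_line(color = "#31a354") +
    labs(x = "distance from dyad (bp)", y = "dinucleotide frequency",
         title = sprintf("%s dinucleotide profile", dinuc_class)) +
    theme_minimal()
}
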