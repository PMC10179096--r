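#' Plot sample PCA coordinates
#'
#' Scatter of the first two principal components, coloured by developmental
#' timepoint and shaped by species, with variance-explained percentages on
#' the axes.
#'
#' @param object A `fiber_pca` from [sample_pca()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiber_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = factor(.data$dpa),
                               shape = .data$species)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * (ve[2] %||% 0)),
      colour = "DPA", shape = "Species"
    ) +
    ggplot2::theme_minimal()
}

#' Plot z-scored expression trends by group
#'
#' Draws the z-scored RPKM profile of each gene over the time course,
#' facetted by a grouping column of the trend assignment (elongation group
#' by default), with the group mean overlaid.
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param trends Trend assignment tibble from [assign_trends()].
#' @param group_col Column of `trends` to facet by.
#' @param species Species whose profiles to draw (mean across accessions).
#' @param max_genes Per-group cap on plotted gene lines.
#' @return A ggplot object.
#' @export
plot_trend_profiles <- function(rpkm, trends,
                                group_col = "elongation_group",
                                species = "Gb", max_genes = 50) {
  prof <- rpkm |>
    dplyr::filter(.data$species == !!species) |>
    dplyr::group_by(.data$gene_id, .data$dpa) |>
    dplyr::summarise(rpkm = mean(.data$rpkm), .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(z = zscore_profile(.data$rpkm)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(
      trends |>
        dplyr::select("gene_id", group = dplyr::all_of(group_col)),
      by = "gene_id"
    ) |>
    dplyr::filter(.data$group != "none")
  keep <- prof |>
    dplyr::distinct(.data$group, .data$gene_id) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_head(n = max_genes) |>
    dplyr::ungroup()
  prof <- dplyr::semi_join(prof, keep, by = c("group", "gene_id"))
  ggplot2::ggplot(prof, ggplot2::aes(.data$dpa, .data$z,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Days post-anthesis", y = "z-scored RPKM") +
    ggplot2::theme_minimal()
}

#' Boxplot of a trait by genotype carrier group at one marker
#'
#' Mirrors how introgression effects are reported: donor carriers (Gb/Gb or
#' Gb/Gh) against Gh/Gh non-carriers, per environment.
#'
#' @param genotypes Genotype call tibble (`line`, `marker`, call/genotype).
#' @param phenotypes Phenotype tibble.
#' @param marker Marker id to plot.
#' @param trait Trait column name.
#' @return A ggplot object.
#' @export
plot_genotype_boxplot <- function(genotypes, phenotypes, marker, trait) {
  grp <- group_lines_by_genotype(genotypes, marker)
  d <- phenotypes |>
    dplyr::mutate(group = dplyr::case_when(
      .data$line %in% grp$carrier ~ "Gb carrier",
      .data$line %in% grp$noncarrier ~ "Gh/Gh",
      .default = NA_character_
    )) |>
    dplyr::filter(!is.na(.data$group))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data[[trait]],
                                  fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~environment) +
    ggplot2::labs(x = NULL, y = trait, title = marker) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
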