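#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `"permanova"` object.
#' @param ... Unused.
#' @return One-row tibble with the pseudo-F, degrees of freedom and
#'   permutation p-value.
#' @export
tidy.permanova <- function(x, ...) {
  tibble(term = "groups",
         df = x$n_groups - 1,
         df_residual = x$n - x$n_groups,
         pseudo_f = x$pseudo_f,
         p_value = x$p)
}

#' @rdname tidy.permanova
#' @return For `glance`: one-row tibble with sizes and permutation count.
#' @export
glance.permanova <- function(x, ...) {
  tibble(n = x$n, n_groups = x$n_groups,
         n_permutations = x$n_permutations,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Tidy a CCA ordination
#'
#' @param x A `"cca_ordination"` object.
#' @param ... Unused.
#' @return Tibble per constrained axis: eigenvalue and fraction of
#'   constrained inertia.
#' @export
tidy.cca_ordination <- function(x, ...) {
  tibble(axis = names(x$eigenvalues),
         eigenvalue = unname(x$eigenvalues),
         constrained_fraction = unname(x$constrained_fraction))
}

#' @rdname tidy.cca_ordination
#' @return For `glance`: one-row tibble with inertias and sample count.
#' @export
glance.cca_ordination <- function(x, ...) {
  tibble(n_samples = x$n_samples,
         n_axes = length(x$eigenvalues),
         total_inertia = x$total_inertia,
         constrained_inertia = x$constrained_inertia,
         constrained_proportion = x$constrained_inertia / x$total_inertia)
}

#' Ordination plot for a CCA fit
#'
#' Site scores on the first two constrained axes, with axis labels carrying
#' each axis' share of the constrained inertia.
#'
#' @param object A `"cca_ordination"` object.
#' @param colour Optional vector (length = retained samples) mapped to
#'   point colour, e.g. a depth-layer factor.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cca_ordination <- function(object, colour = NULL, ...) {
  sc <- as.data.frame(object$site_scores)
  if (ncol(sc) < 2) abort("need at least two constrained axes to plot.")
  names(sc)[1:2] <- c("CCA1", "CCA2")
  pct <- 100 * object$constrained_fraction
  sc$colour <- if (is.null(colour)) "sample" else colour
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$CCA1, y = .data$CCA2,
                                   colour = .data$colour)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("CCA1 (%.1f%% of constrained inertia)", pct[1]),
      y = sprintf("CCA2 (%.1f%% of constrained inertia)", pct[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Abundance heatmap of an RPKM matrix
#'
#' Taxa-by-sample tiles on a capped RPKM scale, rows and columns ordered by
#' the average-linkage dendrograms used for ecological clustering.
#'
#' @param rpkm_mat Numeric matrix, taxa in rows, samples in columns.
#' @param cap Upper display cap for the fill scale (default the 95th
#'   percentile of nonzero values).
#' @return A ggplot object.
#' @export
plot_abundance_heatmap <- function(rpkm_mat, cap = NULL) {
  if (is.null(cap)) {
    nz <- rpkm_mat[rpkm_mat > 0]
    cap <- if (length(nz)) unname(quantile(nz, 0.95)) else 1
  }
  ord_t <- average_linkage(bray_curtis(rpkm_mat, "taxa"))$order
  ord_s <- average_linkage(bray_curtis(rpkm_mat, "samples"))$order
  df <- as_tibble(as.table(rpkm_mat), .name_repair = "minimal") %>%
    setNames(c("taxon", "sample", "rpkm")) %>%
    mutate(taxon = factor(.data$taxon, levels = rownames(rpkm_mat)[ord_t]),
           sample = factor(.data$sample,
                           levels = colnames(rpkm_mat)[ord_s]),
           rpkm = pmin(.data$rpkm, cap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$taxon,
                                   fill = .data$rpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RPKM (capped)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
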