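#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` between the rows (`axis =
#' "taxa"`) or columns (`axis = "samples"`) of a non-negative abundance
#' matrix. A pair of all-zero vectors is defined as distance 0, with a
#' warning.
#'
#' @param mat Numeric matrix, taxa in rows and samples in columns.
#' @param axis Compare `"taxa"` (rows) or `"samples"` (columns).
#' @return A `stats::dist` object with labels.
#' @export
bray_curtis <- function(mat, axis = c("taxa", "samples")) {
  axis <- match.arg(axis)
  if (any(mat < 0)) abort("abundances must be non-negative.")
  m <- if (axis == "taxa") mat else t(mat)
  if (nrow(m) < 2) abort("need at least 2 items on the chosen axis.")
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    warn("all-zero vector pair(s); their Bray-Curtis distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param dist A `stats::dist` object (e.g. from [bray_curtis()]) with at
#'   least 2 items.
#' @return A `stats::hclust` tree; merge heights are the unweighted mean
#'   pairwise dissimilarities between merged clusters.
#' @export
average_linkage <- function(dist) {
  if (attr(dist, "Size") < 2) abort("need at least 2 items to cluster.")
  hclust(dist, method = "average")
}

#' Cut a dendrogram at a dissimilarity height (strict)
#'
#' Flat clusters are the maximal subtrees all of whose merge heights are
#' strictly below `height` (so cutting at exactly a merge's height splits
#' that merge).
#'
#' @param hc A `stats::hclust` object.
#' @param height Non-negative dissimilarity.
#' @return Tibble `label`, `cluster` (integer ids in leaf order of first
#'   appearance).
#' @export
cut_dendrogram <- function(hc, height) {
  if (height < 0) abort("`height` must be >= 0.")
  n <- length(hc$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rep_of_merge <- integer(nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    mem <- function(x) if (x < 0) -x else rep_of_merge[x]
    a <- mem(hc$merge[m, 1])
    b <- mem(hc$merge[m, 2])
    rep_of_merge[m] <- a
    if (hc$height[m] < height) parent[find(b)] <- find(a)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots[hc$order]))
  tibble(label = hc$labels, cluster = ids)
}

#' Identify ecological clusters of taxa and samples
#'
#' Taxa and samples are each clustered by average linkage on Bray-Curtis
#' distances; the taxon dendrogram is cut below `taxon_cut` and the sample
#' dendrogram below `sample_cut` (strictly, per the "< 0.8" / "< 0.7"
#' definitions). Every (taxon-clade, sample-clade) block is then screened
#' for elevated abundance: a block is kept when its median RPKM is at
#' least `elevation_min` times the global median of nonzero RPKM values.
#' Surviving blocks are labelled `A`, `B`, ... in descending elevation.
#'
#' @param rpkm_mat Numeric matrix of RPKM values, taxa in rows, samples in
#'   columns (high-recruitment samples only, per the upstream split).
#' @param taxon_cut,sample_cut Dendrogram cut heights (defaults 0.8, 0.7).
#' @param elevation_min Elevation factor over the global nonzero median
#'   (default 4).
#' @param min_taxa,min_samples Minimum block dimensions (default 2 each).
#' @return Tibble per cluster: `cluster`, `taxa` and `samples`
#'   (list-columns), `n_taxa`, `n_samples`, `block_median`, `elevation`.
#'   Empty when no block passes (or the matrix is all zero).
#' @export
ecological_clusters <- function(rpkm_mat, taxon_cut = 0.8,
                                sample_cut = 0.7, elevation_min = 4,
                                min_taxa = 2, min_samples = 2) {
  nz <- rpkm_mat[rpkm_mat > 0]
  empty <- tibble(cluster = character(), taxa = list(), samples = list(),
                  n_taxa = integer(), n_samples = integer(),
                  block_median = numeric(), elevation = numeric())
  if (!length(nz)) return(empty)
  global_med <- median(nz)
  tx <- cut_dendrogram(average_linkage(bray_curtis(rpkm_mat, "taxa")),
                       taxon_cut)
  sm <- cut_dendrogram(average_linkage(bray_curtis(rpkm_mat, "samples")),
                       sample_cut)
  blocks <- list()
  for (tc in unique(tx$cluster)) {
    taxa <- tx$label[tx$cluster == tc]
    if (length(taxa) < min_taxa) next
    for (sc in unique(sm$cluster)) {
      smp <- sm$label[sm$cluster == sc]
      if (length(smp) < min_samples) next
      bm <- median(rpkm_mat[taxa, smp])
      if (bm >= elevation_min * global_med) {
        nt <- length(taxa)
        ns <- length(smp)
        blocks[[length(blocks) + 1L]] <- tibble(
          taxa = list(taxa), samples = list(smp),
          n_taxa = nt, n_samples = ns,
          block_median = bm, elevation = bm / global_med)
      }
    }
  }
  if (!length(blocks)) return(empty)
  out <- bind_rows(blocks) %>% arrange(dplyr::desc(.data$elevation))
  out$cluster <- LETTERS[seq_len(nrow(out))]
  out[c("cluster", "taxa", "samples", "n_taxa", "n_samples",
        "block_median", "elevation")]
}

# distance-based sums of squares for one labelling
.permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

.permanova_f <- function(d2, groups) {
  a <- length(unique(groups))
  n <- nrow(d2)
  ss <- .permanova_ss(d2, groups)
  ((ss["total"] - ss["within"]) / (a - 1)) / (ss["within"] / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from distance sums of squares: total SS is the sum of squared
#' distances over pairs divided by N, within-group SS sums the analogous
#' per-group quantities, and `F = (SS_between / (a - 1)) / (SS_within /
#' (N - a))`. The p-value is `(1 + #permuted F >= observed F) / (1 +
#' n_perm)` under uniform unrestricted permutation of the group labels, so
#' it can never fall below `1 / (n_perm + 1)`. Fixing `seed` makes the
#' p-value exactly reproducible.
#'
#' @param dist A `stats::dist` or symmetric matrix of dissimilarities.
#' @param groups Group labels, at least 2 groups each of size >= 2.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `"permanova"`; see [tidy.permanova()] and
#'   [glance.permanova()].
#' @export
permanova <- function(dist, groups, n_perm = 9999, seed = NULL) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) {
    abort(paste0("every group needs >= 2 members; too small: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  f_obs <- .permanova_f(d2, groups)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    if (.permanova_f(d2, sample(groups)) >= f_obs) n_ge <- n_ge + 1L
  }
  structure(list(
    pseudo_f = unname(f_obs),
    p = (1 + n_ge) / (1 + n_perm),
    n_permutations = n_perm,
    n = nrow(d),
    n_groups = length(sizes),
    groups = groups,
    seed = seed
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("One-way PERMANOVA (", x$n, " items, ", x$n_groups, " groups)\n",
      "  pseudo-F = ", format(x$pseudo_f, digits = 4),
      ",  p = ", format(x$p, digits = 4),
      "  (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Runs [permanova()] on every pair of groups (permuting labels within the
#' pair's subset only) and multiplies each p-value by the number of pairs,
#' capped at 1.
#'
#' @inheritParams permanova
#' @return Tibble per pair: `group_a`, `group_b`, `pseudo_f`, `p`,
#'   `p_bonferroni`.
#' @export
pairwise_permanova <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  if (!is.null(seed)) set.seed(seed)
  levs <- sort(unique(groups))
  prs <- t(combn(levs, 2))
  out <- purrr::map_dfr(seq_len(nrow(prs)), function(i) {
    sel <- groups %in% prs[i, ]
    fit <- permanova(d[sel, sel], groups[sel], n_perm = n_perm)
    tibble(group_a = prs[i, 1], group_b = prs[i, 2],
           pseudo_f = fit$pseudo_f, p = fit$p)
  })
  out$p_bonferroni <- pmin(1, out$p * nrow(prs))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment preserving input order; values must lie in `[0, 1]`.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Welch two-sample t-test (unequal variances, two-sided)
#'
#' @param x,y Numeric samples, each of size >= 2; at least one must have
#'   nonzero variance.
#' @return One-row tibble `t`, `df` (Welch-Satterthwaite), `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs n >= 2.")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("both samples have zero variance.")
  }
  fit <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
}

.env_bins <- list(
  temperature = list(
    breaks = c(10, 20),
    labels = c("<10", "10-20", ">20"),
    # printed ranges are closed on their printed endpoints
    assign = function(x) ifelse(x < 10, "<10",
                         ifelse(x <= 20, "10-20", ">20"))
  ),
  oxygen = list(
    labels = c("<110", "110-159", "160-200", ">200"),
    # gap (159, 160): values go to the nearer printed edge, ties down
    assign = function(x) ifelse(x < 110, "<110",
                         ifelse(x <= 159.5, "110-159",
                         ifelse(x <= 200, "160-200", ">200")))
  ),
  phosphate = list(
    labels = c("BDL", "<0.5", "0.5-2.0", ">2.0"),
    assign = function(x) ifelse(x < 0.5, "<0.5",
                         ifelse(x <= 2.0, "0.5-2.0", ">2.0"))
  ),
  nitrate = list(
    labels = c("BDL", "<0.5", "0.5-1.9", "2.0-5.0", ">5.0"),
    # gap (1.9, 2.0): nearer printed edge, ties down
    assign = function(x) ifelse(x < 0.5, "<0.5",
                         ifelse(x <= 1.95, "0.5-1.9",
                         ifelse(x <= 5.0, "2.0-5.0", ">5.0")))
  )
)

#' Bin environmental measurements into the PERMANOVA groups
#'
#' Temperature (3 groups: under 10, 10-20, over 20 degrees C), oxygen
#' (4: under 110, 110-159, 160-200, over 200 umol/kg), phosphate (4: BDL,
#' under 0.5, 0.5-2.0, over 2.0 uM) and nitrate (5: BDL, under 0.5,
#' 0.5-1.9, 2.0-5.0, over 5.0 uM). Printed
#' ranges are closed on their printed endpoints; values falling in a gap
#' between printed ranges (oxygen 159-160, nitrate 1.9-2.0) go to the
#' nearer range, ties downward. Nutrient columns may be character with the
#' `"BDL"` sentinel (below detection limit, distinct from missing); `NA`
#' stays unbinned so the sample drops out of that variable's test.
#' Negative concentrations are rejected.
#'
#' @param metadata Tibble with a `sample` column and any of `temperature`,
#'   `oxygen`, `phosphate`, `nitrate`.
#' @return Tibble `sample` plus one `<variable>_bin` factor column per
#'   recognized variable present.
#' @export
bin_environment <- function(metadata) {
  out <- tibble(sample = metadata$sample)
  for (v in names(.env_bins)) {
    if (!v %in% names(metadata)) next
    raw <- metadata[[v]]
    is_bdl <- !is.na(raw) & raw == "BDL"
    num <- suppressWarnings(as.numeric(ifelse(is_bdl, NA, raw)))
    if (v %in% c("phosphate", "nitrate") && any(num < 0, na.rm = TRUE)) {
      abort(paste0("negative ", v, " concentration."))
    }
    bin <- rep(NA_character_, length(raw))
    bin[is_bdl] <- "BDL"
    ok <- !is_bdl & !is.na(num)
    bin[ok] <- .env_bins[[v]]$assign(num[ok])
    out[[paste0(v, "_bin")]] <- factor(bin,
                                       levels = .env_bins[[v]]$labels)
  }
  out
}

#' Canonical correspondence analysis of community data
#'
#' Constrained ordination of a samples-by-taxa abundance matrix on
#' z-standardized environmental variables. Samples with any missing value
#' in the requested variables are dropped (with a message), mirroring the
#' complete-case handling of the recruitment analysis; collinear variables
#' are aliased out by the underlying fit with a warning.
#'
#' @param abundance Numeric matrix or data frame, samples in rows, taxa in
#'   columns (non-negative; all-zero rows are dropped).
#' @param env Tibble/data frame of environmental variables for the same
#'   samples (row-matched), numeric columns only; `variables` selects a
#'   subset.
#' @param variables Optional character vector of env columns to use
#'   (default: all numeric columns, minimum 2).
#' @return Object of class `"cca_ordination"` wrapping the fit, with
#'   eigenvalues, the fraction of constrained inertia per axis, and site
#'   scores; see [tidy.cca_ordination()] and [glance.cca_ordination()].
#' @export
cca_ordination <- function(abundance, env, variables = NULL) {
  comm <- as.matrix(abundance)
  env <- as.data.frame(env)
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  }
  if (length(variables) < 2) abort("need at least 2 env variables.")
  env <- env[variables]
  complete <- stats::complete.cases(env)
  if (!all(complete)) {
    inform(paste0("dropping ", sum(!complete),
                  " sample(s) with incomplete metadata"))
  }
  comm <- comm[complete, , drop = FALSE]
  env <- env[complete, , drop = FALSE]
  nonzero <- rowSums(comm) > 0
  comm <- comm[nonzero, , drop = FALSE]
  env <- env[nonzero, , drop = FALSE]
  envz <- as.data.frame(scale(env))
  fit <- vegan::cca(comm ~ ., data = envz)
  aliased <- tryCatch(stats::alias(fit), error = function(e) NULL)
  if (!is.null(aliased)) {
    warn("collinear environmental variable(s) aliased out of the fit")
  }
  eig <- fit$CCA$eig
  structure(list(
    fit = fit,
    eigenvalues = eig,
    constrained_fraction = eig / sum(eig),
    total_inertia = fit$tot.chi,
    constrained_inertia = fit$CCA$tot.chi,
    site_scores = vegan::scores(fit, display = "sites",
                                choices = seq_along(eig)),
    n_samples = nrow(comm),
    variables = variables
  ), class = "cca_ordination")
}

#' @export
print.cca_ordination <- function(x, ...) {
  cat("CCA: ", x$n_samples, " samples, ", length(x$eigenvalues),
      " constrained axes\n", sep = "")
  cat("  constrained / total inertia: ",
      format(x$constrained_inertia / x$total_inertia, digits = 3), "\n",
      sep = "")
  cat("  axis share of constrained inertia: ",
      paste(format(x$constrained_fraction, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
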