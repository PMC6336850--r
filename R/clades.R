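#' Count distinct single-copy marker hits per genome
#'
#' @param hits Tibble of marker hits with columns `genome` and `marker`
#'   (extra columns such as scores are ignored).
#' @param marker_list Character vector of valid marker ids (e.g. the 120
#'   GTDB single-copy marker accessions). Hits to markers outside the list
#'   are dropped with a warning.
#' @param genomes Optional character vector of all candidate genomes, so
#'   genomes without hits report 0.
#' @return Tibble `genome`, `n_markers` (distinct markers with >= 1 hit).
#' @export
count_markers <- function(hits, marker_list, genomes = NULL) {
  unknown <- setdiff(unique(hits$marker), marker_list)
  if (length(unknown)) {
    warn(paste0("ignoring hits to ", length(unknown),
                " unknown marker(s): ",
                paste(head(unknown, 5), collapse = ", ")))
    hits <- hits[hits$marker %in% marker_list, , drop = FALSE]
  }
  counts <- hits %>%
    distinct(.data$genome, .data$marker) %>%
    count(.data$genome, name = "n_markers")
  if (!is.null(genomes)) {
    counts <- tibble(genome = genomes) %>%
      left_join(counts, by = "genome") %>%
      mutate(n_markers = dplyr::coalesce(.data$n_markers, 0L))
  }
  counts
}

#' Retain genomes with enough single-copy markers
#'
#' @param counts Tibble from [count_markers()].
#' @param min_markers Inclusive threshold (default 60, i.e. half of the 120
#'   concatenated markers).
#' @return Character vector of retained genome ids.
#' @export
marker_gate <- function(counts, min_markers = 60) {
  counts$genome[counts$n_markers >= min_markers]
}

#' Relative root-to-node depths of a rooted tree
#'
#' Depth of a node is the sum of branch lengths from the root; relative
#' depth divides by a normalization constant over root-to-leaf depths
#' (default the mean, so leaves average 1 and a relative depth of 1.2 means
#' 20% past the average tip). A tree of all-zero branch lengths yields all
#' zero depths.
#'
#' @param tree A rooted `ape::phylo`.
#' @param normalization `"mean"` (default), `"max"` or `"median"` leaf
#'   depth.
#' @return Tibble `node` (ape node number), `label` (tip label or `NA`),
#'   `is_tip`, `depth`, `relative_depth`.
#' @export
relative_depths <- function(tree,
                            normalization = c("mean", "max", "median")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(tree, "phylo"))
  # structural root check (a basal polytomy is still a valid rooted tree
  # here: the root node anchors the depth measure)
  n_roots <- sum(!(seq_len(length(tree$tip.label) + tree$Nnode) %in%
                     tree$edge[, 2]))
  if (n_roots != 1) abort("tree must have a single root.")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0.")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  norm <- switch(normalization,
                 mean = mean(depth[seq_len(ntip)]),
                 max = max(depth[seq_len(ntip)]),
                 median = median(depth[seq_len(ntip)]))
  rel <- if (norm > 0) depth / norm else rep(0, length(depth))
  tibble(node = seq_along(depth),
         label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
         is_tip = seq_along(depth) <= ntip,
         depth = depth, relative_depth = rel)
}

#' Cut a rooted tree into subclades at a relative root-distance threshold
#'
#' Subclades are the maximal clades whose stem edge crosses the threshold:
#' the clade's MRCA has relative depth >= `threshold` while its parent is
#' strictly shallower. Leaves on paths that never reach the threshold are
#' returned as singleton `unplaced` labels rather than being forced into a
#' neighbouring clade.
#'
#' @inheritParams relative_depths
#' @param threshold Positive relative depth (default 1.2).
#' @return Tibble `genome`, `subclade`, `mrca_node`, `mrca_depth`
#'   (relative). Subclades are labelled `SC1`, `SC2`, ... in tree traversal
#'   order; unplaced leaves get `unplaced:<tip>`. The MRCA table is
#'   attached as attribute `"mrca"`.
#' @export
cut_subclades <- function(tree, threshold = 1.2,
                          normalization = c("mean", "max", "median")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be > 0.")
  }
  rd <- relative_depths(tree, normalization)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (all(rd$depth == 0)) {
    # star of zero branches: a single clade containing every leaf
    out <- tibble(genome = tree$tip.label, subclade = "SC1",
                  mrca_node = root, mrca_depth = 0)
    attr(out, "mrca") <- tibble(subclade = "SC1", node = root,
                                relative_depth = 0,
                                parent_relative_depth = NA_real_)
    return(out)
  }
  parent <- rep(NA_integer_, nrow(rd))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rel <- rd$relative_depth
  crossing <- which(!is.na(parent) & rel >= threshold &
                      rel[parent] < threshold)

  # preorder so labels follow the drawing order of the tree
  ord <- unique(c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2]))
  crossing <- crossing[order(match(crossing, ord))]

  rows <- list(); mrca_rows <- list(); lab_i <- 0L
  placed <- logical(ntip)
  for (nd in crossing) {
    lab_i <- lab_i + 1L
    lab <- paste0("SC", lab_i)
    tips <- if (nd <= ntip) nd else
      .tips_under(tree, nd)
    placed[tips] <- TRUE
    rows[[lab]] <- tibble(genome = tree$tip.label[tips], subclade = lab,
                          mrca_node = nd, mrca_depth = rel[nd])
    mrca_rows[[lab]] <- tibble(subclade = lab, node = nd,
                               relative_depth = rel[nd],
                               parent_relative_depth =
                                 if (nd == root) NA_real_ else
                                   rel[parent[nd]])
  }
  un <- which(!placed)
  if (length(un)) {
    rows[["__unplaced"]] <- tibble(
      genome = tree$tip.label[un],
      subclade = paste0("unplaced:", tree$tip.label[un]),
      mrca_node = un, mrca_depth = rel[un])
  }
  out <- bind_rows(rows)
  attr(out, "mrca") <- if (length(mrca_rows)) bind_rows(mrca_rows) else
    tibble(subclade = character(), node = integer(),
           relative_depth = numeric(), parent_relative_depth = numeric())
  out
}

# tip indices in the clade rooted at an internal node
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, tree = tree))
}

#' Estimate average amino-acid identity between two proteomes
#'
#' Orthologs are reciprocal best hits under local alignment (BLOSUM62,
#' affine gaps), kept when percent identity is at least `min_id` and the
#' alignment covers at least `min_cov` of the shorter protein (CompareM-like
#' defaults). AAI is the mean percent identity over retained orthologs; no
#' retained orthologs gives a no-estimate result (`aai = NA`).
#'
#' @param proteome_a,proteome_b Named character vectors or `AAStringSet`s.
#' @param min_id Minimum ortholog percent identity (default 30).
#' @param min_cov Minimum alignment coverage of the shorter protein
#'   (default 0.7).
#' @return One-row tibble `aai` (percent or `NA`), `n_orthologs`.
#' @export
estimate_aai <- function(proteome_a, proteome_b, min_id = 30,
                         min_cov = 0.7) {
  a <- Biostrings::AAStringSet(proteome_a)
  b <- Biostrings::AAStringSet(proteome_b)
  if (!length(a) || !length(b)) abort("both proteomes must be non-empty.")
  if (is.null(names(a))) names(a) <- paste0("a", seq_along(a))
  if (is.null(names(b))) names(b) <- paste0("b", seq_along(b))
  score <- matrix(-Inf, length(a), length(b))
  pidm <- covm <- matrix(0, length(a), length(b))
  for (j in seq_along(b)) {
    aln <- Biostrings::pairwiseAlignment(
      a, b[[j]], type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    score[, j] <- Biostrings::score(aln)
    pidm[, j] <- Biostrings::pid(aln)
    covm[, j] <- Biostrings::nchar(aln) /
      pmin(Biostrings::width(a), Biostrings::width(b)[j])
  }
  best_b_for_a <- max.col(score, ties.method = "first")
  best_a_for_b <- apply(score, 2, which.max)
  orth <- which(best_a_for_b[best_b_for_a] == seq_along(a))
  keep <- orth[pidm[cbind(orth, best_b_for_a[orth])] >= min_id &
                 covm[cbind(orth, best_b_for_a[orth])] >= min_cov]
  if (!length(keep)) {
    return(tibble(aai = NA_real_, n_orthologs = 0L))
  }
  tibble(aai = mean(pidm[cbind(keep, best_b_for_a[keep])]),
         n_orthologs = length(keep))
}

#' Check ANI/AAI support of a subclade assignment
#'
#' For each subclade, the fraction of within-subclade genome pairs whose
#' ANI and AAI exceed the cutoffs (strict >, per the "> 70%" support
#' criterion). A subclade is flagged supported when both fractions reach
#' the quorum; singletons are trivially supported and flagged as such.
#'
#' @param assignment Tibble `genome`, `subclade` (as from
#'   [cut_subclades()]).
#' @param ani,aai Long pair tibbles with id columns (`query`/`ref` or
#'   `a`/`b`) and an `ani` / `aai` value column. Missing pairs count as
#'   failing.
#' @param ani_min,aai_min Percent cutoffs (default 70).
#' @param quorum Fraction of within pairs that must exceed each cutoff
#'   (default 0.9).
#' @return Tibble per subclade: sizes, support fractions, `supported`,
#'   `note`.
#' @export
support_check <- function(assignment, ani, aai, ani_min = 70, aai_min = 70,
                          quorum = 0.9) {
  lookup <- function(tab, value_col) {
    idc <- intersect(c("query", "ref", "a", "b"), names(tab))
    key1 <- paste(tab[[idc[1]]], tab[[idc[2]]])
    key2 <- paste(tab[[idc[2]]], tab[[idc[1]]])
    setNames(rep(tab[[value_col]], 2), c(key1, key2))
  }
  ani_l <- lookup(ani, "ani")
  aai_l <- lookup(aai, "aai")
  purrr::map_dfr(split(assignment$genome, assignment$subclade),
                 function(gs) {
    if (length(gs) == 1) {
      return(tibble(n = 1L, n_pairs = 0L, ani_support = 1,
                    aai_support = 1, supported = TRUE,
                    note = "supported (singleton)"))
    }
    prs <- t(combn(sort(gs), 2))
    key <- paste(prs[, 1], prs[, 2])
    av <- unname(ani_l[key]); bv <- unname(aai_l[key])
    fa <- mean(!is.na(av) & av > ani_min)
    fb <- mean(!is.na(bv) & bv > aai_min)
    tibble(n = length(gs), n_pairs = nrow(prs), ani_support = fa,
           aai_support = fb,
           supported = fa >= quorum && fb >= quorum, note = NA_character_)
  }, .id = "subclade")
}
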