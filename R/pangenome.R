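#' All-vs-all protein similarity scores
#'
#' Local-alignment scores (BLOSUM62, affine gaps) for every ordered protein
#' pair sharing at least one seed k-mer, plus the self-score of every
#' protein. Scores are symmetric; the self rows (`a == b`) carry each
#' node's self-score for minbit normalization.
#'
#' @param proteins Tibble with `protein_id`, `genome`, `sequence` (as from
#'   [simulate_trait_proteins()]) or a named character vector (genome then
#'   taken from names as `<genome>|<protein>` or set to `NA`).
#' @param k Seed k-mer length in residues (default 4); pairs sharing no
#'   k-mer get no edge.
#' @return Tibble `a`, `b`, `score` including self rows, with the
#'   protein-to-genome map attached as attribute `"genomes"`.
#' @export
score_pairs <- function(proteins, k = 4) {
  if (!is.data.frame(proteins)) {
    ids <- names(proteins)
    proteins <- tibble(protein_id = ids, genome = NA_character_,
                       sequence = unname(proteins))
  }
  if (!nrow(proteins)) abort("empty protein set.")
  if (any(!nzchar(proteins$sequence))) abort("empty sequence in input.")
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  n <- length(seqs)
  kmer_sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  aa <- Biostrings::AAStringSet(seqs)
  self <- tibble(a = names(seqs), b = names(seqs),
                 score = vapply(seq_len(n), function(i) {
                   Biostrings::score(Biostrings::pairwiseAlignment(
                     aa[[i]], aa[[i]], type = "local",
                     substitutionMatrix = "BLOSUM62",
                     gapOpening = 11, gapExtension = 1))
                 }, numeric(1)))
  edges <- list()
  if (n > 1) {
    prs <- t(combn(n, 2))
    share <- vapply(seq_len(nrow(prs)), function(r) {
      any(kmer_sets[[prs[r, 1]]] %in% kmer_sets[[prs[r, 2]]])
    }, logical(1))
    prs <- prs[share, , drop = FALSE]
    if (nrow(prs)) {
      sc <- vapply(seq_len(nrow(prs)), function(r) {
        Biostrings::score(Biostrings::pairwiseAlignment(
          aa[[prs[r, 1]]], aa[[prs[r, 2]]], type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11,
          gapExtension = 1))
      }, numeric(1))
      edges <- list(tibble(a = names(seqs)[prs[, 1]],
                           b = names(seqs)[prs[, 2]], score = sc))
    }
  }
  out <- bind_rows(c(list(self), edges))
  attr(out, "genomes") <- setNames(proteins$genome, proteins$protein_id)
  out
}

#' Filter a similarity graph by minbit
#'
#' `minbit(a, b) = score(a, b) / min(self(a), self(b))`; edges below the
#' threshold (default 0.5) are removed and retained edges are re-weighted
#' by their minbit value. Self rows pass trivially with minbit 1. Edges
#' touching a node with no self-score are dropped with a warning.
#'
#' @param graph Edge tibble from [score_pairs()] (self rows required).
#' @param minbit Threshold in `[0, 1]` (default 0.5).
#' @return Tibble `a`, `b`, `minbit` of retained non-self edges.
#' @export
minbit_filter <- function(graph, minbit = 0.5) {
  selves <- graph[graph$a == graph$b, ]
  self_of <- setNames(selves$score, selves$a)
  edges <- graph[graph$a != graph$b, , drop = FALSE]
  known <- edges$a %in% names(self_of) & edges$b %in% names(self_of)
  if (any(!known)) {
    warn(paste0("dropping ", sum(!known),
                " edge(s) touching nodes without self-scores"))
    edges <- edges[known, , drop = FALSE]
  }
  mb <- edges$score / pmin(self_of[edges$a], self_of[edges$b])
  out <- tibble(a = edges$a, b = edges$b, minbit = unname(mb))
  out <- out[out$minbit >= minbit, , drop = FALSE]
  attr(out, "nodes") <- names(self_of)
  attr(out, "genomes") <- attr(graph, "genomes")
  out
}

#' Markov clustering of a weighted similarity graph
#'
#' Canonical MCL: the weighted adjacency matrix (with self-loops set to
#' each node's maximum incident edge weight) is column-normalized, then
#' expansion (matrix squaring) and inflation (elementwise power, column
#' re-normalization) alternate until the matrix changes by less than `tol`
#' or `max_iter` is reached. Entries below `prune` are zeroed each
#' iteration. Clusters are the connected components of the converged
#' matrix's nonzero structure; every node lands in exactly one cluster.
#'
#' @param edges Tibble `a`, `b` and a weight column (`minbit` or `score`
#'   or `weight`), e.g. from [minbit_filter()].
#' @param inflation Inflation exponent (default 2, the pangenome default).
#' @param max_iter,tol Convergence controls.
#' @param prune Entries below this are zeroed each iteration.
#' @param nodes Optional character vector of all node ids (so isolated
#'   nodes become singleton clusters); defaults to attribute `"nodes"` of
#'   `edges`, else ids seen in the edges.
#' @return Tibble `protein_id`, `cluster` (`PC00001`, ...); attribute
#'   `"converged"` reports convergence.
#' @export
markov_cluster <- function(edges, inflation = 2, max_iter = 200,
                           tol = 1e-8, prune = 1e-10, nodes = NULL) {
  wcol <- intersect(c("minbit", "weight", "score"), names(edges))[1]
  if (is.na(wcol)) abort("no weight column (minbit/weight/score) found.")
  if (is.null(nodes)) nodes <- attr(edges, "nodes")
  if (is.null(nodes)) nodes <- unique(c(edges$a, edges$b))
  nodes <- sort(unique(nodes))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
    w <- edges[[wcol]]
    M[cbind(ia, ib)] <- w
    M[cbind(ib, ia)] <- w
  }
  loop <- apply(M, 1, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) {
    warn("MCL did not converge within `max_iter`; interpreting current matrix")
  }
  adj <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable cluster ids ordered by first member
  first <- tapply(seq_along(comp), comp, min)
  relabel <- rank(first)
  out <- tibble(protein_id = names(comp),
                cluster = sprintf("PC%05d", relabel[as.character(comp)]))
  attr(out, "converged") <- converged
  out
}

#' Genome presence/absence of protein clusters
#'
#' @param clusters Tibble `protein_id`, `cluster` from [markov_cluster()].
#' @param genomes Named character vector mapping protein id to genome (as
#'   attached by [score_pairs()]), or a tibble `protein_id`, `genome`.
#' @return Long tibble `cluster` (as `family`), `genome`, `present`.
#' @export
cluster_presence <- function(clusters, genomes) {
  if (is.data.frame(genomes)) {
    genomes <- setNames(genomes$genome, genomes$protein_id)
  }
  tab <- clusters %>%
    mutate(genome = unname(genomes[.data$protein_id])) %>%
    distinct(family = .data$cluster, .data$genome) %>%
    mutate(present = TRUE)
  tidyr::expand_grid(family = unique(tab$family),
                     genome = unique(unname(genomes))) %>%
    left_join(tab, by = c("family", "genome")) %>%
    mutate(present = dplyr::coalesce(.data$present, FALSE))
}

#' Classify protein clusters by clade/subclade frequency criteria
#'
#' For each cluster (gene family), occurrence frequencies are computed per
#' clade and per subclade and the enrichment category assigned with
#' precedence core > clade-core > subclade-unique > none:
#' * `core` — present in >= 70% of the genomes of *both* clades;
#' * `<clade>-core` — >= 70% within one clade and <= 30% in the other;
#' * `unique-<subclade>` — >= 70% within the subclade and <= 10% of all
#'   other genomes.
#'
#' @param presence Long tibble `family`, `genome`, `present` (logical),
#'   e.g. from [cluster_presence()] or [simulate_presence_matrix()].
#' @param labels Tibble `genome`, `clade` (exactly two levels), `subclade`;
#'   every genome in `presence` must be labeled.
#' @param core_min,other_max,unique_max The 0.70 / 0.30 / 0.10 criteria.
#' @return Tibble per family: `family`, `category`, per-clade frequencies
#'   (`freq_<clade>`), and for unique calls the subclade frequency.
#' @export
classify_clusters <- function(presence, labels, core_min = 0.7,
                              other_max = 0.3, unique_max = 0.1) {
  unlabeled <- setdiff(unique(presence$genome), labels$genome)
  if (length(unlabeled)) {
    abort(paste0("genome(s) without clade/subclade labels: ",
                 paste(head(unlabeled, 5), collapse = ", ")))
  }
  clades <- sort(unique(labels$clade))
  if (length(clades) != 2) abort("`labels$clade` must have exactly 2 levels.")
  tab <- presence %>% left_join(labels, by = "genome")
  per_clade <- tab %>%
    group_by(.data$family, .data$clade) %>%
    summarise(freq = mean(.data$present), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "clade", values_from = "freq")
  per_sub <- tab %>%
    group_by(.data$family, .data$subclade) %>%
    summarise(freq_in = mean(.data$present), n = dplyr::n(),
              .groups = "drop")
  totals <- tab %>%
    group_by(.data$family) %>%
    summarise(n_present = sum(.data$present), n_total = dplyr::n(),
              .groups = "drop")
  per_sub <- per_sub %>%
    left_join(totals, by = "family") %>%
    mutate(freq_out = (.data$n_present - .data$freq_in * .data$n) /
             (.data$n_total - .data$n))

  purrr::map_dfr(unique(presence$family), function(fam) {
    fc <- per_clade[per_clade$family == fam, ]
    f1 <- fc[[clades[1]]]; f2 <- fc[[clades[2]]]
    category <- "none"
    unique_sub <- NA_character_
    if (f1 >= core_min && f2 >= core_min) {
      category <- "core"
    } else if (f1 >= core_min && f2 <= other_max) {
      category <- paste0(clades[1], "-core")
    } else if (f2 >= core_min && f1 <= other_max) {
      category <- paste0(clades[2], "-core")
    } else {
      fs <- per_sub[per_sub$family == fam, ]
      ok <- which(fs$freq_in >= core_min & fs$freq_out <= unique_max)
      if (length(ok)) {
        j <- ok[order(-fs$freq_in[ok], fs$subclade[ok])][1]
        category <- paste0("unique-", fs$subclade[j])
        unique_sub <- fs$subclade[j]
      }
    }
    tibble(family = fam, category = category,
           !!paste0("freq_", clades[1]) := f1,
           !!paste0("freq_", clades[2]) := f2,
           unique_subclade = unique_sub)
  })
}
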