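#' Simulate a genome set along a phylogeny
#'
#' Evolves one nucleotide sequence per tip of a rooted tree from a random
#' ancestor, under a uniform-rate, site-independent substitution model
#' (Jukes-Cantor) with no indels. Branch lengths are expected substitutions
#' per site. The returned divergence table records, for every pair of tips,
#' the patristic path length and the closed-form expected per-site identity
#' `1/4 + 3/4 * exp(-4 d / 3)`, which downstream ANI estimation should
#' recover.
#'
#' @param tree A rooted `ape::phylo` tree with uniquely named tips (tip
#'   labels become genome ids) and non-negative branch lengths.
#' @param ancestor_length Length in bp of the ancestral sequence (must be
#'   positive; use at least 10x the ANI fragment length so fragment mapping
#'   is exercised).
#' @param completeness,contamination Optional numeric vectors (recycled) of
#'   CheckM-style quality estimates to attach to the genomes. Defaults draw
#'   completeness from U(70, 100) and contamination from U(0, 3).
#' @param seed Integer seed; identical seed and arguments give identical
#'   output.
#'
#' @return A list with `genomes`, a tibble with one row per tip (`genome`,
#'   `contigs` list-column of character vectors, `total_length`, `gc`,
#'   `completeness`, `contamination`), and `divergence`, a tibble of all
#'   unordered tip pairs (`a`, `b`, `path_length`, `expected_identity`).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((g1:0.01,g2:0.01):0.02,g3:0.03);")
#' sim <- simulate_genome_set(tr, ancestor_length = 2000, seed = 1)
#' sim$divergence
simulate_genome_set <- function(tree, ancestor_length = 200000,
                                completeness = NULL, contamination = NULL,
                                seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(ancestor_length) || length(ancestor_length) != 1 ||
      ancestor_length <= 0) {
    abort("`ancestor_length` must be a single positive number.")
  }
  tips <- tree$tip.label
  if (is.null(tips) || anyDuplicated(tips) || any(!nzchar(tips))) {
    abort("tree tips must be uniquely and non-trivially named.")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("tree must carry non-negative branch lengths.")
  }
  set.seed(seed)
  L <- as.integer(ancestor_length)
  ntip <- length(tips)
  root <- ntip + 1L

  # preorder edge traversal so parents are evolved before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    chd <- tr$edge[e, 2]
    seqs[[chd]] <- .evolve_jc(seqs[[par]], tr$edge.length[e])
  }

  bases <- c("A", "C", "G", "T")
  contigs <- lapply(seq_len(ntip), function(i) {
    paste(bases[seqs[[i]]], collapse = "")
  })
  gc <- vapply(seq_len(ntip), function(i) {
    100 * mean(seqs[[i]] == 2L | seqs[[i]] == 3L)
  }, numeric(1))
  compl <- if (is.null(completeness)) runif(ntip, 70, 100) else
    rep_len(completeness, ntip)
  contam <- if (is.null(contamination)) runif(ntip, 0, 3) else
    rep_len(contamination, ntip)

  genomes <- tibble(
    genome = tips,
    contigs = lapply(contigs, identity),
    total_length = L,
    gc = gc,
    completeness = compl,
    contamination = contam
  )

  # pairwise patristic distances -> expected per-site identity (Jukes-Cantor)
  dmat <- ape::cophenetic.phylo(tree)[tips, tips, drop = FALSE]
  pairs <- t(combn(tips, 2))
  d <- dmat[cbind(pairs[, 1], pairs[, 2])]
  divergence <- tibble(
    a = pairs[, 1], b = pairs[, 2],
    path_length = d,
    expected_identity = 0.25 + 0.75 * exp(-4 * d / 3)
  )
  list(genomes = genomes, divergence = divergence)
}

# one Jukes-Cantor branch: each site changes with prob (3/4)(1 - e^{-4b/3}),
# uniformly to one of the three other bases
.evolve_jc <- function(seq, b) {
  if (b <= 0) return(seq)
  p_change <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- which(runif(length(seq)) < p_change)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    seq[hit] <- (seq[hit] - 1L + shift) %% 4L + 1L
  }
  seq
}

#' Write simulated genomes to FASTA files
#'
#' One file per genome, named `<genome>.fna`, contigs named
#' `<genome>_c<index>`.
#'
#' @param genomes Genome tibble from [simulate_genome_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome_fasta <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(nrow(genomes)), function(i) {
    ctg <- genomes$contigs[[i]]
    names(ctg) <- paste0(genomes$genome[i], "_c", seq_along(ctg))
    path <- file.path(dir, paste0(genomes$genome[i], ".fna"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ctg), path)
    path
  }, character(1))
  invisible(paths)
}

#' Simulate a pair of diverged proteomes
#'
#' Emits two protein sets where protein `i` of the second set is the first
#' set's protein with each residue substituted independently at the given
#' per-site rate (uniform over the other 19 residues). Useful for exercising
#' amino-acid identity estimation against a known divergence.
#'
#' @param n_proteins Number of proteins per proteome.
#' @param protein_length Length of each protein in residues.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of two named character vectors, `a` and `b`.
#' @export
simulate_proteome_pair <- function(n_proteins = 20, protein_length = 200,
                                   divergence = 0.1, seed = 1) {
  stopifnot(divergence >= 0, divergence < 1)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- vapply(seq_len(n_proteins), function(i) {
    paste(sample(aa, protein_length, replace = TRUE), collapse = "")
  }, character(1))
  b <- vapply(a, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < divergence)
    for (j in hit) v[j] <- sample(setdiff(aa, v[j]), 1)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(a) <- paste0("p", seq_len(n_proteins))
  names(b) <- names(a)
  list(a = a, b = b)
}
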