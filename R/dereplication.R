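#' Filter genomes on assembly quality estimates
#'
#' Keeps genomes strictly more complete than `min_completeness` percent and
#' strictly less contaminated than `max_contamination` percent (the gate is
#' strict on both sides). Genomes with a missing estimate are excluded with
#' a warning.
#'
#' @param genomes Tibble with at least `genome`, `completeness` and
#'   `contamination` columns (percent).
#' @param min_completeness,max_contamination Percent thresholds (defaults
#'   50 and 5).
#' @return The filtered tibble, input order preserved.
#' @export
#' @examples
#' g <- tibble::tibble(genome = c("a", "b"),
#'                     completeness = c(80, 50), contamination = c(1, 0))
#' quality_filter(g)  # keeps only "a": 50 is not > 50
quality_filter <- function(genomes, min_completeness = 50,
                           max_contamination = 5) {
  missing <- is.na(genomes$completeness) | is.na(genomes$contamination)
  if (any(missing)) {
    warn(paste0("excluding ", sum(missing),
                " genome(s) with missing quality estimates: ",
                paste(genomes$genome[missing], collapse = ", ")))
  }
  genomes[!missing &
            genomes$completeness > min_completeness &
            genomes$contamination < max_contamination, , drop = FALSE]
}

.contigs_of <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x$contigs[[1]]
  } else if (is.character(x)) {
    x
  } else {
    abort("genome must be a one-row genome tibble or a character vector of contigs.")
  }
}

# exact k-mer index: k-mer string -> start positions
.kmer_index <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(list())
  split(seq_len(n), substring(seq, seq_len(n), k:(n + k - 1L)))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) {
           paste(rev(strsplit(x, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# place one fragment against one reference contig index by modal seed
# diagonal; ungapped per-site identity over the covered window
.place_fragment <- function(frag, ref_raw, idx, k, seed_step, min_cov) {
  fl <- nchar(frag)
  if (fl < k) return(NULL)
  starts <- seq.int(1L, fl - k + 1L, by = seed_step)
  seeds <- substring(frag, starts, starts + k - 1L)
  offs <- integer(0)
  hits <- idx[seeds]
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (!is.null(h)) offs <- c(offs, h - starts[i])
  }
  if (!length(offs)) return(NULL)
  off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  lo <- max(1L, 1L + off)
  hi <- min(length(ref_raw), fl + off)
  covered <- hi - lo + 1L
  if (covered < min_cov * fl) return(NULL)
  frag_raw <- charToRaw(frag)
  matches <- sum(frag_raw[(lo - off):(hi - off)] == ref_raw[lo:hi])
  c(identity = matches / covered, covered = covered)
}

# one direction: chop query into frag_len windows, map each onto reference
.ani_direction <- function(query_contigs, ref_contigs, frag_len, k,
                           seed_step, min_cov) {
  frags <- unlist(lapply(query_contigs, function(ctg) {
    L <- nchar(ctg)
    if (L < frag_len) return(character(0))
    starts <- seq.int(1L, L - frag_len + 1L, by = frag_len)
    substring(ctg, starts, starts + frag_len - 1L)
  }))
  if (!length(frags)) frags <- query_contigs  # genome shorter than frag_len
  ref_idx <- lapply(ref_contigs, .kmer_index, k = k)
  ref_raw <- lapply(ref_contigs, charToRaw)
  ids <- numeric(0)
  for (fr in frags) {
    cand <- list(fr, .revcomp(fr))
    best <- NULL
    for (f2 in cand) {
      for (ci in seq_along(ref_contigs)) {
        pl <- .place_fragment(f2, ref_raw[[ci]], ref_idx[[ci]], k,
                              seed_step, min_cov)
        if (!is.null(pl) &&
            (is.null(best) || pl["identity"] > best["identity"])) {
          best <- pl
        }
      }
      if (!is.null(best)) break  # forward strand placed; skip revcomp
    }
    if (!is.null(best)) ids <- c(ids, best["identity"])
  }
  list(ani = if (length(ids)) 100 * mean(ids) else NA_real_,
       fragments_total = length(frags), fragments_mapped = length(ids))
}

#' Estimate pairwise average nucleotide identity by fragment mapping
#'
#' The query is chopped into non-overlapping windows (default 1500 bp), each
#' window is located in the reference by shared 16-mer seeding (modal
#' diagonal over sampled seeds, both strands) and scored by ungapped
#' per-site identity; windows whose best placement covers less than
#' `min_cov` of the window are left unmapped and excluded. ANI is the mean
#' identity over mapped windows, computed in both directions and
#' symmetrized as their mean. Zero mapped fragments in both directions gives
#' a no-estimate result (`ani = NA`), distinct from 0.
#'
#' @param query,reference One-row genome tibbles (with a `contigs`
#'   list-column) or character vectors of contig sequences.
#' @param frag_len Fragment window length in bp (default 1500).
#' @param k Seed k-mer size (default 16; must not exceed `frag_len`).
#' @param seed_step Spacing of sampled seed k-mers within a fragment.
#' @param min_cov Minimum fraction of a fragment its placement must cover
#'   (default 0.8).
#' @return A one-row tibble: `query`, `ref`, `ani` (symmetrized, percent),
#'   the directional `ani_qr`/`ani_rq`, and fragment totals.
#' @export
estimate_ani <- function(query, reference, frag_len = 1500, k = 16,
                         seed_step = 20, min_cov = 0.8) {
  if (frag_len < k) abort("`frag_len` must be at least `k`.")
  qc <- .contigs_of(query)
  rc <- .contigs_of(reference)
  if (!length(qc) || !length(rc) || !sum(nchar(qc)) || !sum(nchar(rc))) {
    abort("both genomes must be non-empty.")
  }
  qr <- .ani_direction(qc, rc, frag_len, k, seed_step, min_cov)
  rq <- .ani_direction(rc, qc, frag_len, k, seed_step, min_cov)
  both <- c(qr$ani, rq$ani)
  tibble(
    query = if (is.data.frame(query)) query$genome else "query",
    ref = if (is.data.frame(reference)) reference$genome else "ref",
    ani = if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE),
    ani_qr = qr$ani, ani_rq = rq$ani,
    fragments_total = qr$fragments_total + rq$fragments_total,
    fragments_mapped = qr$fragments_mapped + rq$fragments_mapped
  )
}

#' All-vs-all ANI table for a genome set
#'
#' @param genomes Genome tibble (as from [simulate_genome_set()]).
#' @inheritParams estimate_ani
#' @return Long tibble of all unordered pairs, as [estimate_ani()] rows.
#' @export
ani_matrix <- function(genomes, frag_len = 1500, k = 16, seed_step = 20,
                       min_cov = 0.8) {
  stopifnot(nrow(genomes) >= 2)
  pairs <- t(combn(seq_len(nrow(genomes)), 2))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    estimate_ani(genomes[pairs[i, 1], ], genomes[pairs[i, 2], ],
                 frag_len = frag_len, k = k, seed_step = seed_step,
                 min_cov = min_cov)
  })
}

#' Group redundant genomes at an ANI threshold
#'
#' Genomes joined by an edge whenever their symmetrized ANI meets the
#' threshold (default 98.5, inclusive per ">= 98.5% ANI"). Under the default
#' single-linkage semantics groups are the connected components of that
#' graph (transitive closure); `method = "clique"` instead peels maximal
#' cliques greedily, largest first. Pairs with no estimate count as below
#' threshold; genomes in no pair become singletons.
#'
#' @param ani Long ANI tibble with `query`, `ref`, `ani` columns.
#' @param threshold Percent ANI in (0, 100].
#' @param ids Optional character vector of all genome ids (to include
#'   singletons absent from `ani`); defaults to ids seen in `ani`.
#' @param method `"single"` (connected components) or `"clique"`.
#' @return Tibble `genome`, `group` (integer group ids).
#' @export
group_redundant <- function(ani, threshold = 98.5, ids = NULL,
                            method = c("single", "clique")) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 100) {
    abort("`threshold` must lie in (0, 100].")
  }
  if (is.null(ids)) ids <- unique(c(ani$query, ani$ref))
  keep <- !is.na(ani$ani) & ani$ani >= threshold
  edges <- ani[keep, c("query", "ref")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = ids))
  if (method == "single") {
    comp <- igraph::components(g)$membership
    return(tibble(genome = names(comp), group = as.integer(comp)))
  }
  membership <- setNames(rep(NA_integer_, length(ids)), ids)
  gid <- 0L
  remaining <- g
  while (igraph::vcount(remaining) > 0) {
    cl <- igraph::largest_cliques(remaining)[[1]]
    nm <- sort(names(cl))
    gid <- gid + 1L
    membership[nm] <- gid
    remaining <- igraph::delete_vertices(remaining, names(cl))
  }
  tibble(genome = names(membership), group = membership)
}

#' Select the representative of a redundancy group
#'
#' Highest completeness first; ties broken by lowest contamination, then by
#' largest total length, then lexicographically smallest id.
#'
#' @param members Tibble of the group's genomes with `genome`,
#'   `completeness`, `contamination` and (optionally) `total_length`.
#' @return The representative genome id (length-1 character).
#' @export
select_representative <- function(members) {
  if (!nrow(members)) abort("empty group has no representative.")
  if (!"total_length" %in% names(members)) members$total_length <- 0
  ord <- order(-members$completeness, members$contamination,
               -members$total_length, members$genome)
  members$genome[ord[1]]
}

#' Dereplicate a genome set end to end
#'
#' Quality gate, all-vs-all fragment ANI, redundancy grouping at the
#' threshold, and per-group representative selection.
#'
#' @param genomes Genome tibble with `contigs`, `completeness`,
#'   `contamination` (and `total_length`).
#' @inheritParams estimate_ani
#' @inheritParams group_redundant
#' @inheritParams quality_filter
#' @return Tibble `genome`, `group`, `is_representative`, with the ANI
#'   table attached as attribute `"ani"`.
#' @export
dereplicate <- function(genomes, frag_len = 1500, k = 16, threshold = 98.5,
                        min_completeness = 50, max_contamination = 5,
                        method = c("single", "clique")) {
  method <- match.arg(method)
  kept <- quality_filter(genomes, min_completeness, max_contamination)
  if (nrow(kept) < 2) {
    out <- tibble(genome = kept$genome,
                  group = seq_len(nrow(kept)),
                  is_representative = TRUE)
    attr(out, "ani") <- tibble()
    return(out)
  }
  ani <- ani_matrix(kept, frag_len = frag_len, k = k)
  groups <- group_redundant(ani, threshold = threshold, ids = kept$genome,
                            method = method)
  reps <- groups %>%
    left_join(kept, by = "genome") %>%
    group_by(.data$group) %>%
    summarise(representative = select_representative(dplyr::pick(
      dplyr::everything())), .groups = "drop")
  out <- groups %>%
    left_join(reps, by = "group") %>%
    mutate(is_representative = .data$genome == .data$representative) %>%
    select("genome", "group", "is_representative")
  attr(out, "ani") <- ani
  out
}
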