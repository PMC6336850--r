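#' Classify proteorhodopsin function and spectral tuning
#'
#' Maps each query onto the numbering of the bundled reference
#' ([pr_reference()]) by global alignment and reads the residues at the
#' diagnostic columns: 97 (proton acceptor), 108 (proton donor) and 105
#' (spectral tuning). A sequence is called proton-pumping when position 97
#' is aspartate (D) and position 108 is lysine or glutamate (K/E); tuning
#' is blue for glutamine (Q) at 105, green for methionine (M), otherwise
#' indeterminate. A gap at a diagnostic column leaves that field
#' indeterminate (residue `"-"`).
#'
#' @param proteins Named character vector or `AAStringSet` of rhodopsin
#'   sequences. Sequences shorter than half the reference are rejected.
#' @param reference Reference sequence defining the column numbering.
#' @return Tibble per protein: `protein_id`, `residue_97`, `residue_108`,
#'   `residue_105`, `is_proton_pumping`, `tuning`.
#' @export
#' @examples
#' s <- pr_reference()  # the reference itself carries D97 / K108 / Q105
#' classify_rhodopsin(c(ref = s))
classify_rhodopsin <- function(proteins, reference = pr_reference()) {
  seqs <- as.character(Biostrings::AAStringSet(proteins))
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))
  short <- nchar(seqs) < nchar(reference) / 2
  if (any(short)) {
    abort(paste0("sequence(s) too short to map onto the reference: ",
                 paste(names(seqs)[short], collapse = ", ")))
  }
  purrr::map_dfr(names(seqs), function(id) {
    res <- .residues_at(seqs[[id]], reference, c(97L, 108L, 105L))
    if (any(res == "-")) {
      inform(paste0(id, ": gap at a diagnostic column; field(s) left ",
                    "indeterminate"))
    }
    tibble(
      protein_id = id,
      residue_97 = res[1], residue_108 = res[2], residue_105 = res[3],
      is_proton_pumping = res[1] == "D" && res[2] %in% c("K", "E"),
      tuning = if (res[3] == "Q") "blue" else if (res[3] == "M") "green"
               else "indeterminate"
    )
  })
}

# residues of `query` at reference columns, via global alignment
.residues_at <- function(query, reference, positions) {
  aln <- Biostrings::pairwiseAlignment(
    query, reference, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_col <- cumsum(sub != "-")
  vapply(positions, function(p) {
    i <- which(ref_col == p & sub != "-")[1]
    if (is.na(i)) "-" else pat[i]
  }, character(1))
}

#' Scan for ATP-synthase c-ring Na+-coupling motifs
#'
#' Scans each protein for the two diagnostic second-helix motifs of the
#' A-type ATP-synthase rotor subunit: `LPESxxI` (MGIIa-type) and `LPETIxL`
#' (MGIIb-type), where `x` is any residue. Overlapping matches resolve to
#' the first occurrence; a sequence matching both motifs is reported as
#' `"conflict"` rather than raising an error.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @return Tibble per protein: `protein_id`, `motif_class` (`"MGIIa-type"`,
#'   `"MGIIb-type"`, `"none"` or `"conflict"`), `match_position` (1-based
#'   start of the first match, `NA` when none).
#' @export
#' @examples
#' scan_cring_motif(c(x = "MALPESAAIKW", y = "MALPETIGLKW"))
scan_cring_motif <- function(proteins) {
  seqs <- as.character(Biostrings::AAStringSet(proteins))
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))
  pos_a <- regexpr("LPES..I", seqs)
  pos_b <- regexpr("LPETI.L", seqs)
  tibble(
    protein_id = names(seqs),
    motif_class = dplyr::case_when(
      pos_a > 0 & pos_b > 0 ~ "conflict",
      pos_a > 0 ~ "MGIIa-type",
      pos_b > 0 ~ "MGIIb-type",
      TRUE ~ "none"
    ),
    match_position = dplyr::case_when(
      pos_a > 0 & pos_b > 0 ~ pmin(as.integer(pos_a), as.integer(pos_b)),
      pos_a > 0 ~ as.integer(pos_a),
      pos_b > 0 ~ as.integer(pos_b),
      TRUE ~ NA_integer_
    )
  )
}

#' Call extracellular peptidases from HMM, localization and signal tables
#'
#' A peptidase HMM hit is called extracellular when its bitscore reaches
#' `score_min` (the `hmmsearch -T 75` floor) and either its subcellular
#' localization is extracellular or outer membrane, or the localization is
#' unknown but a translocation signal peptide is predicted. Proteins
#' missing from the localization table are treated as unknown. Duplicate
#' rows for one protein and family keep the maximum score with a warning.
#' All candidates are returned with their boolean so calls can be audited.
#'
#' @param hits Tibble `protein_id`, `merops_family`, `hmm_score`.
#' @param localization Tibble `protein_id`, `localization` (values such as
#'   `"extracellular"`, `"outer membrane"`, `"unknown"`, `"cytoplasmic"`).
#' @param signal Tibble `protein_id`, `has_signal_peptide` (logical).
#' @param score_min Bitscore floor (default 75).
#' @return Tibble per candidate hit with `localization`,
#'   `has_signal_peptide` and `is_extracellular_call`.
#' @export
call_extracellular_peptidases <- function(hits, localization, signal,
                                          score_min = 75) {
  dup <- hits %>% count(.data$protein_id, .data$merops_family) %>%
    filter(n > 1)
  if (nrow(dup)) {
    warn(paste0("duplicate hit rows for ", nrow(dup),
                " protein/family pair(s); keeping max score"))
    hits <- hits %>%
      group_by(.data$protein_id, .data$merops_family) %>%
      summarise(hmm_score = max(.data$hmm_score), .groups = "drop")
  }
  hits %>%
    left_join(localization, by = "protein_id") %>%
    left_join(signal, by = "protein_id") %>%
    mutate(
      localization = dplyr::coalesce(.data$localization, "unknown"),
      has_signal_peptide = dplyr::coalesce(.data$has_signal_peptide, FALSE),
      is_extracellular_call = .data$hmm_score >= score_min &
        (.data$localization %in% c("extracellular", "outer membrane") |
           (.data$localization == "unknown" & .data$has_signal_peptide))
    )
}

#' Detect the archaeal flagellum operon by gene co-localization
#'
#' A genome is called flagellated when one contig carries FlaH, FlaI and
#' FlaJ (KO K07331-K07333) plus at least one archaeal flagellin (PF01917)
#' with the whole component set spanning at most `window` gene indices.
#' Found components and the best span are reported for every genome so
#' partial operons can be inspected.
#'
#' @param genes Tibble `genome`, `contig`, `gene_index`, `protein_id`.
#' @param annotations Tibble `protein_id`, `type`, `value` with KO rows
#'   (`value` `"K07331"`-`"K07333"`) and HMM rows (`value` `"PF01917"`).
#' @param window Maximum gene-index span of the component set (default 10).
#' @return Tibble per genome: `genome`, `is_present`, `contig`,
#'   `span_start`, `span_end`, `components` (comma-separated found set).
#' @export
detect_flagellum_operon <- function(genes, annotations, window = 10) {
  comp_of <- c(K07331 = "FlaH", K07332 = "FlaI", K07333 = "FlaJ",
               PF01917 = "flagellin")
  ann <- annotations %>%
    filter(.data$value %in% names(comp_of)) %>%
    mutate(component = comp_of[.data$value]) %>%
    select("protein_id", "component") %>%
    distinct()
  tab <- genes %>% inner_join(ann, by = "protein_id",
                              relationship = "many-to-many")
  purrr::map_dfr(unique(genes$genome), function(g) {
    gt <- tab[tab$genome == g, , drop = FALSE]
    found <- sort(unique(gt$component))
    best <- NULL
    for (ctg in unique(gt$contig)) {
      ct <- gt[gt$contig == ctg, , drop = FALSE]
      need <- c("FlaH", "FlaI", "FlaJ")
      if (!all(need %in% ct$component) || !"flagellin" %in% ct$component)
        next
      core_idx <- vapply(need, function(cp) {
        min(ct$gene_index[ct$component == cp])
      }, numeric(1))
      fl_idx <- ct$gene_index[ct$component == "flagellin"]
      spans <- vapply(fl_idx, function(fi) {
        diff(range(c(core_idx, fi)))
      }, numeric(1))
      j <- which.min(spans)
      if (spans[j] <= window &&
          (is.null(best) || spans[j] < best$span)) {
        best <- list(contig = ctg, span = spans[j],
                     lo = min(core_idx, fl_idx[j]),
                     hi = max(core_idx, fl_idx[j]))
      }
    }
    tibble(
      genome = g,
      is_present = !is.null(best),
      contig = if (is.null(best)) NA_character_ else best$contig,
      span_start = if (is.null(best)) NA_integer_ else as.integer(best$lo),
      span_end = if (is.null(best)) NA_integer_ else as.integer(best$hi),
      components = paste(found, collapse = ",")
    )
  })
}

#' Per-subclade trait occurrence fractions
#'
#' Cell (subclade, trait) is the fraction of the subclade's genomes
#' carrying the trait, scaled 0-1 so that 1 means every genome in the
#' subclade possesses it.
#'
#' @param trait_calls Tibble `genome`, `trait`, `present` (logical).
#' @param assignment Tibble `genome`, `subclade`; every genome in
#'   `trait_calls` must be assigned.
#' @return Long tibble `subclade`, `trait`, `fraction`.
#' @export
occurrence_matrix <- function(trait_calls, assignment) {
  missing <- setdiff(unique(trait_calls$genome), assignment$genome)
  if (length(missing)) {
    abort(paste0("genome(s) without a subclade assignment: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(genome = unique(assignment$genome),
                             trait = unique(trait_calls$trait)) %>%
    left_join(trait_calls, by = c("genome", "trait")) %>%
    mutate(present = dplyr::coalesce(.data$present, FALSE)) %>%
    left_join(assignment[c("genome", "subclade")], by = "genome")
  grid %>%
    group_by(.data$subclade, .data$trait) %>%
    summarise(fraction = mean(.data$present), .groups = "drop")
}

#' Heatmap of per-subclade trait occurrence
#'
#' @param occurrence Long tibble from [occurrence_matrix()].
#' @return A ggplot object (tiles scaled 0-1).
#' @export
plot_occurrence <- function(occurrence) {
  ggplot2::ggplot(occurrence,
                  ggplot2::aes(x = .data$trait, y = .data$subclade,
                               fill = .data$fraction)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1),
                                 name = "fraction of genomes") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
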