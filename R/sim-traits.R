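# Synthetic reference rhodopsin used to define the diagnostic alignment
# columns (97: proton acceptor, 108: proton donor, 105: spectral tuning).
# This is a synthetic stand-in with the canonical residues planted at the
# canonical positions, not a database sequence.
.pr_reference_string <- paste0(
  "GMCCPKDPQIVYKTGIYFKCFCWIPWKSFQPFLSVSWTARGCGLGYCAAHHADRDARWTI",
  "YSQWFDVMVGIEAPHYATGTIDMHVHVLFYMAGDSIDIEFAGISQAFKSCSLCELWKMRI",
  "DCQVWLMQENKACLKQANFGMKWCVAVEHLEPENIPPYWTIGTLVHVDITVGAWLKELCK",
  "HNCQNMRERKPFRKYPNADQMTKWFVSNGGWEYKICPRDIFKFQHISIMQDWCWEKSFMC",
  "SDQANGKAM"
)

#' Bundled synthetic proteorhodopsin reference
#'
#' The reference sequence whose coordinates define the diagnostic residue
#' positions 97 (proton acceptor, canonically D), 108 (proton donor,
#' canonically K or E) and 105 (spectral tuning, Q for blue / M for green).
#' It is a synthetic sequence carrying the canonical residues at those
#' positions; queries are mapped onto its numbering by global alignment.
#'
#' @return A single character string of length 249.
#' @export
pr_reference <- function() .pr_reference_string

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_protein <- function(len) {
  paste(sample(.aa_alphabet, len, replace = TRUE), collapse = "")
}

.cring_motifs <- c(MGIIa = "LPES..I", MGIIb = "LPETI.L")

# a random background sequence guaranteed to contain neither c-ring motif
.clean_background <- function(len) {
  repeat {
    s <- .random_protein(len)
    if (!any(vapply(.cring_motifs, grepl, logical(1), x = s))) return(s)
  }
}

#' Simulate trait-bearing proteins, gene coordinates and annotations
#'
#' Emits, for a plan of planted traits, the protein sequences, gene
#' coordinate table and upstream annotation tables the trait classifiers
#' consume, together with the expected call for each planted trait.
#'
#' Recognised `kind` values and their plan columns:
#' * `"rhodopsin"` — `residue_97`, `residue_108`, `residue_105`: a mutated
#'   copy of [pr_reference()] with those residues planted at the diagnostic
#'   columns.
#' * `"cring"` — `motif_class` in `"MGIIa"` (plants `LPESxxI`), `"MGIIb"`
#'   (plants `LPETIxL`) or `"none"`.
#' * `"peptidase"` — `hmm_score`, `localization`, `signal_peptide`
#'   (logical): annotation rows for a MEROPS-family HMM hit plus
#'   localization and signal-peptide calls.
#' * `"operon"` — `layout` in `"colocalized"` (FlaH/I/J + flagellin at
#'   consecutive indices on one contig), `"split_contigs"` (flagellin on
#'   another contig) or `"distant"` (flagellin far outside the window).
#'
#' @param trait_plan Tibble with columns `genome`, `kind` and the
#'   kind-specific columns above. An empty plan yields empty trait tables.
#' @param n_filler_genes Background genes added per genome so operon indices
#'   sit in realistic context.
#' @param seed Integer seed.
#' @return A list of tibbles: `proteins` (`protein_id`, `genome`,
#'   `sequence`), `genes` (`genome`, `contig`, `gene_index`, `start`, `end`,
#'   `strand`, `protein_id`), `annotations` (`protein_id`, `genome`, `type`,
#'   `value`, `score`), and `truth` (planted expectations per trait row).
#' @export
simulate_trait_proteins <- function(trait_plan, n_filler_genes = 5,
                                    seed = 1) {
  known <- c("rhodopsin", "cring", "peptidase", "operon")
  if (nrow(trait_plan) && !all(trait_plan$kind %in% known)) {
    abort(paste("unknown trait kind:",
                setdiff(unique(trait_plan$kind), known)[1]))
  }
  set.seed(seed)
  ref <- strsplit(.pr_reference_string, "")[[1]]
  diag_pos <- c(97L, 105L, 108L)

  proteins <- list(); genes <- list(); annos <- list(); truth <- list()
  pid <- 0L
  next_id <- function() {
    pid <<- pid + 1L
    sprintf("prot%05d", pid)
  }
  genomes <- unique(trait_plan$genome)

  for (g in genomes) {
    rows <- trait_plan[trait_plan$genome == g, , drop = FALSE]
    g_genes <- list()
    idx <- 0L
    add_gene <- function(id, contig = "ctg1", index = NULL) {
      idx <<- if (is.null(index)) idx + 1L else as.integer(index)
      g_genes[[length(g_genes) + 1L]] <<- tibble(
        genome = g, contig = contig, gene_index = idx,
        start = (idx - 1L) * 1200L + 1L, end = idx * 1200L - 200L,
        strand = sample(c("+", "-"), 1), protein_id = id)
    }
    for (f in seq_len(n_filler_genes)) {
      id <- next_id()
      proteins[[id]] <- tibble(protein_id = id, genome = g,
                               sequence = .clean_background(150))
      add_gene(id)
    }
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, ]
      kind <- row$kind
      if (kind == "rhodopsin") {
        id <- next_id()
        v <- ref
        mut <- setdiff(which(runif(length(v)) < 0.03), diag_pos)
        for (j in mut) v[j] <- sample(setdiff(.aa_alphabet, v[j]), 1)
        v[97] <- row$residue_97
        v[108] <- row$residue_108
        v[105] <- row$residue_105
        proteins[[id]] <- tibble(protein_id = id, genome = g,
                                 sequence = paste(v, collapse = ""))
        add_gene(id)
        annos[[length(annos) + 1L]] <- tibble(
          protein_id = id, genome = g, type = "HMM", value = "PF01036",
          score = round(runif(1, 100, 300), 1))
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = id, genome = g, kind = kind,
          expected = NA_character_,
          expected_pumping = row$residue_97 == "D" &
            row$residue_108 %in% c("K", "E"),
          expected_tuning = dplyr::case_when(
            row$residue_105 == "Q" ~ "blue",
            row$residue_105 == "M" ~ "green",
            TRUE ~ "indeterminate"))
      } else if (kind == "cring") {
        id <- next_id()
        bg <- .clean_background(90)
        if (row$motif_class %in% c("MGIIa", "MGIIb")) {
          x2 <- function(n) paste(sample(.aa_alphabet, n, replace = TRUE),
                                  collapse = "")
          motif <- if (row$motif_class == "MGIIa") {
            paste0("LPES", x2(2), "I")
          } else {
            paste0("LPETI", x2(1), "L")
          }
          at <- sample.int(nchar(bg) - 6L, 1)
          s <- paste0(substr(bg, 1, at - 1), motif,
                      substr(bg, at + 7, nchar(bg)))
          # planting can collide with flanking residues; retry until clean
          hits <- vapply(.cring_motifs, grepl, logical(1), x = s)
          if (sum(hits) != 1 || !hits[row$motif_class]) {
            s <- paste0(.clean_background(40), motif, .clean_background(40))
          }
        } else {
          s <- bg
        }
        proteins[[id]] <- tibble(protein_id = id, genome = g, sequence = s)
        add_gene(id)
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = id, genome = g, kind = kind,
          expected = if (row$motif_class == "none") "none" else
            paste0(row$motif_class, "-type"),
          expected_pumping = NA, expected_tuning = NA_character_)
      } else if (kind == "peptidase") {
        id <- next_id()
        proteins[[id]] <- tibble(protein_id = id, genome = g,
                                 sequence = .clean_background(250))
        add_gene(id)
        annos[[length(annos) + 1L]] <- tibble(
          protein_id = id, genome = g, type = "HMM",
          value = "MER_S08", score = row$hmm_score)
        annos[[length(annos) + 1L]] <- tibble(
          protein_id = id, genome = g, type = "localization",
          value = row$localization, score = NA_real_)
        annos[[length(annos) + 1L]] <- tibble(
          protein_id = id, genome = g, type = "signal_peptide",
          value = if (isTRUE(row$signal_peptide)) "Y" else "N",
          score = NA_real_)
        expected <- row$hmm_score >= 75 &&
          (row$localization %in% c("extracellular", "outer membrane") ||
             (row$localization == "unknown" && isTRUE(row$signal_peptide)))
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = id, genome = g, kind = kind,
          expected = as.character(expected),
          expected_pumping = NA, expected_tuning = NA_character_)
      } else if (kind == "operon") {
        kos <- c("K07331", "K07332", "K07333")
        ids <- character(4)
        for (i in 1:3) {
          ids[i] <- next_id()
          proteins[[ids[i]]] <- tibble(protein_id = ids[i], genome = g,
                                       sequence = .clean_background(200))
          add_gene(ids[i])
          annos[[length(annos) + 1L]] <- tibble(
            protein_id = ids[i], genome = g, type = "KO", value = kos[i],
            score = NA_real_)
        }
        ids[4] <- next_id()
        proteins[[ids[4]]] <- tibble(protein_id = ids[4], genome = g,
                                     sequence = .clean_background(120))
        if (row$layout == "colocalized") {
          add_gene(ids[4])
        } else if (row$layout == "split_contigs") {
          add_gene(ids[4], contig = "ctg2", index = 1L)
        } else if (row$layout == "distant") {
          add_gene(ids[4], index = idx + 25L)
        } else {
          abort(paste("unknown operon layout:", row$layout))
        }
        annos[[length(annos) + 1L]] <- tibble(
          protein_id = ids[4], genome = g, type = "HMM", value = "PF01917",
          score = round(runif(1, 80, 200), 1))
        truth[[length(truth) + 1L]] <- tibble(
          protein_id = ids[4], genome = g, kind = kind,
          expected = as.character(row$layout == "colocalized"),
          expected_pumping = NA, expected_tuning = NA_character_)
      }
    }
    genes[[g]] <- bind_rows(g_genes)
  }

  empty_anno <- tibble(protein_id = character(), genome = character(),
                       type = character(), value = character(),
                       score = numeric())
  list(
    proteins = if (length(proteins)) bind_rows(proteins) else
      tibble(protein_id = character(), genome = character(),
             sequence = character()),
    genes = if (length(genes)) bind_rows(genes) else
      tibble(genome = character(), contig = character(),
             gene_index = integer(), start = integer(), end = integer(),
             strand = character(), protein_id = character()),
    annotations = if (length(annos)) bind_rows(annos) else empty_anno,
    truth = if (length(truth)) bind_rows(truth) else
      tibble(protein_id = character(), genome = character(),
             kind = character(), expected = character(),
             expected_pumping = logical(), expected_tuning = character())
  )
}
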