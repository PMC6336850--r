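test_that("rhodopsin residue rules map to function and tuning", {
  ref <- pr_reference()
  plant <- function(r97, r108, r105) {
    v <- strsplit(ref, "")[[1]]
    v[97] <- r97; v[108] <- r108; v[105] <- r105
    paste(v, collapse = "")
  }
  calls <- classify_rhodopsin(c(
    deq = plant("D", "E", "Q"),
    dkm = plant("D", "K", "M"),
    aeq = plant("A", "E", "Q")))
  expect_equal(calls$is_proton_pumping, c(TRUE, TRUE, FALSE))
  expect_equal(calls$tuning, c("blue", "green", "blue"))
  expect_equal(calls$residue_97, c("D", "D", "A"))
  # too-short sequence rejected
  expect_error(classify_rhodopsin(c(x = substr(ref, 1, 40))), "short")
})

test_that("rhodopsin mapping survives background mutations", {
  plan <- tibble::tibble(
    genome = paste0("g", 1:30), kind = "rhodopsin",
    residue_97 = sample(c("D", "D", "D", "A"), 30, replace = TRUE),
    residue_108 = sample(c("K", "E", "Q"), 30, replace = TRUE),
    residue_105 = sample(c("Q", "M", "L"), 30, replace = TRUE))
  sim <- simulate_trait_proteins(plan, seed = 17)
  rh <- sim$truth[sim$truth$kind == "rhodopsin", ]
  seqs <- setNames(
    sim$proteins$sequence[match(rh$protein_id, sim$proteins$protein_id)],
    rh$protein_id)
  calls <- classify_rhodopsin(seqs)
  expect_equal(calls$is_proton_pumping, rh$expected_pumping)
  expect_equal(calls$tuning, rh$expected_tuning)
})

test_that("c-ring motif scan matches its published examples", {
  calls <- scan_cring_motif(c(a = "MALPESAAIKW", b = "MALPETIGLKW",
                              c = "MAAAAAA"))
  expect_equal(calls$motif_class,
               c("MGIIa-type", "MGIIb-type", "none"))
  expect_equal(calls$match_position, c(3L, 3L, NA_integer_))
  both <- scan_cring_motif(c(x = "LPESAAILPETIALAA"))
  expect_equal(both$motif_class, "conflict")
})

test_that("c-ring scan agrees with a position-wise oracle", {
  set.seed(31)
  reduced <- c("L", "P", "E", "S", "T", "I", "A")
  for (i in 1:400) {
    len <- sample(7:12, 1)
    s <- paste(sample(reduced, len, replace = TRUE), collapse = "")
    got <- scan_cring_motif(setNames(s, "q"))
    want <- oracle_cring(s)
    expect_equal(got$motif_class, want$class, label = s)
    if (want$class %in% c("MGIIa-type", "MGIIb-type")) {
      expect_equal(got$match_position, want$pos, label = s)
    }
  }
})

test_that("extracellular peptidase logic combines score, location, signal", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    merops_family = "S08",
    hmm_score = c(80, 80, 74, 80, 80))
  loc <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4"),
    localization = c("extracellular", "unknown", "extracellular",
                     "cytoplasmic"))
  sp <- tibble::tibble(protein_id = c("p2", "p3"),
                       has_signal_peptide = c(TRUE, TRUE))
  calls <- call_extracellular_peptidases(hits, loc, sp)
  got <- setNames(calls$is_extracellular_call, calls$protein_id)
  expect_true(got[["p1"]])    # score + extracellular
  expect_true(got[["p2"]])    # unknown + signal peptide
  expect_false(got[["p3"]])   # below the bitscore floor
  expect_false(got[["p4"]])   # cytoplasmic
  expect_false(got[["p5"]])   # no localization row -> unknown, no SP

  dup <- dplyr::bind_rows(hits[1, ], hits[1, ])
  expect_warning(call_extracellular_peptidases(dup, loc, sp), "duplicate")
})

test_that("flagellum operon requires co-localization within the window", {
  genes <- tibble::tibble(
    genome = "g",
    contig = c(rep("c1", 4)),
    gene_index = 4:7,
    protein_id = paste0("p", 1:4))
  ann <- tibble::tibble(
    protein_id = paste0("p", 1:4),
    type = c("KO", "KO", "KO", "HMM"),
    value = c("K07331", "K07332", "K07333", "PF01917"))
  call <- detect_flagellum_operon(genes, ann)
  expect_true(call$is_present)
  expect_equal(c(call$span_start, call$span_end), c(4L, 7L))

  # flagellin on another contig: absent, components still listed
  genes2 <- genes
  genes2$contig[4] <- "c2"
  call2 <- detect_flagellum_operon(genes2, ann)
  expect_false(call2$is_present)
  expect_match(call2$components, "flagellin")

  # flagellin 27 genes away: outside the default 10-gene window
  genes3 <- genes
  genes3$gene_index <- c(1L, 2L, 3L, 30L)
  expect_false(detect_flagellum_operon(genes3, ann)$is_present)
  expect_true(detect_flagellum_operon(genes3, ann, window = 29)$is_present)
})

test_that("occurrence matrix scales 0-1 and ignores genome order", {
  calls <- tibble::tibble(
    genome = paste0("g", 1:4),
    trait = "pr",
    present = c(TRUE, TRUE, FALSE, FALSE))
  assign <- tibble::tibble(genome = paste0("g", 1:4), subclade = "S1")
  occ <- occurrence_matrix(calls, assign)
  expect_equal(occ$fraction, 0.5)
  occ_all <- occurrence_matrix(dplyr::mutate(calls, present = TRUE), assign)
  expect_equal(occ_all$fraction, 1.0)
  occ_none <- occurrence_matrix(dplyr::mutate(calls, present = FALSE),
                                assign)
  expect_equal(occ_none$fraction, 0.0)
  shuffled <- occurrence_matrix(calls[c(3, 1, 4, 2), ], assign)
  expect_equal(shuffled, occ)
  expect_true(all(occ$fraction >= 0 & occ$fraction <= 1))
  expect_error(occurrence_matrix(calls, assign[1:2, ]), "without")
})

test_that("all four classifiers recover planted labels at scale", {
  set.seed(53)
  n <- 130
  plan <- dplyr::bind_rows(
    tibble::tibble(genome = sprintf("r%03d", 1:n), kind = "rhodopsin",
                   residue_97 = sample(c("D", "A"), n, TRUE),
                   residue_108 = sample(c("K", "E", "T"), n, TRUE),
                   residue_105 = sample(c("Q", "M", "V"), n, TRUE)),
    tibble::tibble(genome = sprintf("c%03d", 1:n), kind = "cring",
                   motif_class = sample(c("MGIIa", "MGIIb", "none"), n,
                                        TRUE)),
    tibble::tibble(genome = sprintf("p%03d", 1:n), kind = "peptidase",
                   hmm_score = sample(c(60, 74, 75, 90), n, TRUE),
                   localization = sample(c("extracellular",
                                           "outer membrane", "unknown",
                                           "cytoplasmic"), n, TRUE),
                   signal_peptide = sample(c(TRUE, FALSE), n, TRUE)),
    tibble::tibble(genome = sprintf("o%03d", 1:n), kind = "operon",
                   layout = sample(c("colocalized", "split_contigs",
                                     "distant"), n, TRUE)))
  sim <- simulate_trait_proteins(plan, n_filler_genes = 2, seed = 53)
  expect_gte(nrow(sim$truth), 500)

  seq_of <- setNames(sim$proteins$sequence, sim$proteins$protein_id)

  rh <- sim$truth[sim$truth$kind == "rhodopsin", ]
  rc <- classify_rhodopsin(seq_of[rh$protein_id])
  expect_identical(rc$is_proton_pumping, rh$expected_pumping)
  expect_identical(rc$tuning, rh$expected_tuning)

  cr <- sim$truth[sim$truth$kind == "cring", ]
  cc <- scan_cring_motif(seq_of[cr$protein_id])
  expect_identical(cc$motif_class, cr$expected)

  pe <- sim$truth[sim$truth$kind == "peptidase", ]
  ann <- sim$annotations
  hits <- dplyr::filter(ann, .data$type == "HMM",
                        .data$protein_id %in% pe$protein_id)
  hits <- tibble::tibble(protein_id = hits$protein_id,
                         merops_family = hits$value,
                         hmm_score = hits$score)
  loc <- dplyr::filter(ann, .data$type == "localization")
  loc <- tibble::tibble(protein_id = loc$protein_id,
                        localization = loc$value)
  sp <- dplyr::filter(ann, .data$type == "signal_peptide")
  sp <- tibble::tibble(protein_id = sp$protein_id,
                       has_signal_peptide = sp$value == "Y")
  pc <- call_extracellular_peptidases(hits, loc, sp)
  expect_identical(as.character(pc$is_extracellular_call[
    match(pe$protein_id, pc$protein_id)]), pe$expected)

  op <- sim$truth[sim$truth$kind == "operon", ]
  oc <- detect_flagellum_operon(sim$genes, sim$annotations)
  got <- setNames(oc$is_present, oc$genome)[op$genome]
  expect_identical(as.character(unname(got)), op$expected)
})
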