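#' Simulate a gene-family presence/absence matrix with planted enrichment
#'
#' Each (family, genome) cell is an independent Bernoulli draw whose
#' probability is set per family and per group of genomes. The generator also
#' records, for every family, the enrichment category its *expected*
#' frequencies imply under the pangenome criteria (core in >= 70% of both
#' clades; clade-core >= 70% in one clade and <= 30% in the other;
#' subclade-unique >= 70% in the subclade and <= 10% of all other genomes),
#' so classifier recovery can be scored against ground truth.
#'
#' @param labels Tibble with columns `genome`, `clade` (exactly two levels)
#'   and `subclade`.
#' @param freq_plan Tibble with columns `family`, `group`, `p`: `group`
#'   matches a subclade label or, failing that, a clade label; every genome
#'   must be covered for every family. Probabilities must lie in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `presence`, a long tibble (`family`, `genome`,
#'   `present`), and `truth`, a tibble per family with the planted
#'   `category` and the expected per-clade frequencies.
#' @export
simulate_presence_matrix <- function(labels, freq_plan, seed = 1) {
  stopifnot(all(c("genome", "clade", "subclade") %in% names(labels)),
            all(c("family", "group", "p") %in% names(freq_plan)))
  if (any(freq_plan$p < 0 | freq_plan$p > 1)) {
    abort("occurrence probabilities must lie in [0, 1].")
  }
  set.seed(seed)
  fams <- unique(freq_plan$family)
  grid <- tidyr::expand_grid(family = fams, genome = labels$genome) %>%
    left_join(labels, by = "genome")
  by_sub <- freq_plan %>% rename(subclade = "group", p_sub = "p")
  by_clade <- freq_plan %>% rename(clade = "group", p_clade = "p")
  grid <- grid %>%
    left_join(by_sub, by = c("family", "subclade")) %>%
    left_join(by_clade, by = c("family", "clade")) %>%
    mutate(p = dplyr::coalesce(.data$p_sub, .data$p_clade))
  if (anyNA(grid$p)) {
    abort("`freq_plan` does not cover every (family, genome).")
  }
  presence <- grid %>%
    mutate(present = runif(dplyr::n()) < .data$p) %>%
    select("family", "genome", "present")

  truth <- grid %>%
    group_by(.data$family) %>%
    summarise(category = .planted_category(.data$p, .data$clade,
                                           .data$subclade),
              .groups = "drop")
  clade_freq <- grid %>%
    group_by(.data$family, .data$clade) %>%
    summarise(freq = mean(.data$p), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "clade", values_from = "freq",
                       names_prefix = "freq_")
  truth <- left_join(truth, clade_freq, by = "family")
  list(presence = presence, truth = truth)
}

# planted-label logic written against expected frequencies; deliberately a
# separate code path from classify_clusters() so tests exercise both
.planted_category <- function(p, clade, subclade) {
  clades <- sort(unique(clade))
  f_clade <- vapply(clades, function(cl) mean(p[clade == cl]), numeric(1))
  if (all(f_clade >= 0.7)) return("core")
  hi <- f_clade >= 0.7
  if (length(clades) == 2 && sum(hi) == 1 && f_clade[!hi] <= 0.3) {
    return(paste0(clades[hi], "-core"))
  }
  for (sc in sort(unique(subclade))) {
    inside <- subclade == sc
    if (mean(p[inside]) >= 0.7 && mean(p[!inside]) <= 0.1) {
      return(paste0("unique-", sc))
    }
  }
  "none"
}

#' Simulate read recruitment across environmental samples
#'
#' Draws per-sample environmental covariates, computes each genome's
#' expected share of the metagenome from a log-linear response (share
#' proportional to `exp(sum(beta * z))` times the genome's length share,
#' with a baseline of `target_fraction / n_genomes` per genome when all
#' coefficients are zero), and emits independent Poisson read counts --
#' the genome set's summed fraction is free to rise in samples where taxa
#' bloom, as in real recruitment data. Per-sample sequencing totals are
#' recorded in a manifest so relative fractions and RPKM have their
#' denominators.
#' Phosphate and nitrate carry a below-detection-limit state (`"BDL"`,
#' distinct from missing, which is `NA`).
#'
#' @param genomes Tibble with columns `genome` and `total_length`.
#' @param n_samples Number of samples.
#' @param depth Expected total reads per sample (vector recycled); must be
#'   non-negative.
#' @param read_length Read length in bp (used for total-bp accounting).
#' @param coefficients Optional tibble (`genome`, `variable`, `beta`) of
#'   log-linear responses to the z-scored covariates; missing pairs default
#'   to 0.
#' @param target_fraction Baseline summed relative fraction of the genome
#'   set per sample under all-zero coefficients (default 0.01). Per-sample
#'   totals are capped at 0.9 of the sample.
#' @param bdl_prob Probability that a nutrient measurement is below the
#'   detection limit.
#' @param missing_prob Probability that a nutrient measurement is missing.
#' @param seed Integer seed.
#' @return A list: `counts` (long tibble genome x sample), `env` (metadata
#'   tibble; nutrient columns are character with `"BDL"`), `manifest`
#'   (`sample`, `total_reads`, `total_bp`), and `truth` with expected counts
#'   and true RPKM per cell.
#' @export
simulate_community <- function(genomes, n_samples = 40, depth = 1e6,
                               read_length = 100, coefficients = NULL,
                               target_fraction = 0.01, bdl_prob = 0.1,
                               missing_prob = 0.05, seed = 1) {
  if (any(depth < 0)) abort("`depth` must be non-negative.")
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  depth <- rep_len(depth, n_samples)

  env_num <- tibble(
    sample = samples,
    depth_m = round(runif(n_samples, 5, 200)),
    temperature = round(runif(n_samples, 2, 30), 1),
    oxygen = round(runif(n_samples, 50, 250), 1),
    salinity = round(runif(n_samples, 30, 40), 2),
    chlorophyll = round(runif(n_samples, 0.01, 2), 3),
    phosphate = round(runif(n_samples, 0.05, 3), 2),
    nitrate = round(runif(n_samples, 0.05, 8), 2)
  )
  # z-scored covariates drive the responses; BDL/missingness is applied to
  # the *reported* values afterwards so truth stays exact
  covars <- c("depth_m", "temperature", "oxygen", "salinity",
              "chlorophyll", "phosphate", "nitrate")
  z <- scale(as.matrix(env_num[covars]))

  beta <- matrix(0, nrow(genomes), length(covars),
                 dimnames = list(genomes$genome, covars))
  if (!is.null(coefficients)) {
    bad <- setdiff(coefficients$variable, covars)
    if (length(bad)) abort(paste("unknown covariate:", bad[1]))
    beta[cbind(coefficients$genome, coefficients$variable)] <-
      coefficients$beta
  }
  eta <- beta %*% t(z)                     # genome x sample
  lenshare <- genomes$total_length / mean(genomes$total_length)
  frac <- (target_fraction / nrow(genomes)) * exp(eta) * lenshare
  over <- colSums(frac) > 0.9
  if (any(over)) frac[, over] <- sweep(frac[, over, drop = FALSE], 2,
                                       colSums(frac[, over, drop = FALSE]),
                                       "/") * 0.9
  lambda <- sweep(frac, 2, depth, "*")
  dimnames(lambda) <- list(genomes$genome, samples)
  counts_mat <- matrix(rpois(length(lambda), lambda), nrow(genomes),
                       n_samples, dimnames = list(genomes$genome, samples))

  manifest <- tibble(sample = samples,
                     total_reads = round(depth),
                     total_bp = round(depth) * read_length)

  env <- env_num
  for (v in c("phosphate", "nitrate")) {
    x <- format(env[[v]], trim = TRUE)
    u <- runif(n_samples)
    x[u < bdl_prob] <- "BDL"
    x[u >= bdl_prob & u < bdl_prob + missing_prob] <- NA
    env[[v]] <- x
  }

  long <- function(m, value) {
    as_tibble(as.table(m), .name_repair = "minimal") %>%
      setNames(c("genome", "sample", value))
  }
  true_rpkm <- sweep(lambda / (genomes$total_length / 1000), 2,
                     manifest$total_bp / 1e6, "/")
  truth <- long(lambda, "expected_reads") %>%
    left_join(long(true_rpkm, "true_rpkm"), by = c("genome", "sample"))

  list(counts = long(counts_mat, "reads"),
       env = env, manifest = manifest, truth = truth)
}

#' Simulate read-alignment records with planted filter labels
#'
#' Draws per-record identity and aligned fraction, quantizes them to
#' integer mismatch (NM) and aligned-base counts so that the emitted values
#' are exactly representable in SAM, and plants the pass/fail label under
#' the recruitment filter (identity >= `min_id` and aligned fraction >=
#' `min_aln`, both inclusive).
#'
#' @param n_records Number of records.
#' @param contigs Character vector of target contig names to sample from.
#' @param read_length Read length in bp.
#' @param identity_range,fraction_range Uniform ranges the raw identity and
#'   aligned fraction are drawn from (clipped to `[0, 1]`).
#' @param min_id,min_aln Thresholds used for the planted label.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `contig`, `identity`, `aligned_fraction`,
#'   `read_length`, `nm`, `aligned_length`, and logical `planted_pass`.
#' @export
simulate_alignment_records <- function(n_records = 1000, contigs = "c1",
                                       read_length = 100,
                                       identity_range = c(0.85, 1),
                                       fraction_range = c(0.5, 1),
                                       min_id = 0.95, min_aln = 0.75,
                                       seed = 1) {
  if (any(identity_range < 0 | identity_range > 1) ||
      any(fraction_range < 0 | fraction_range > 1)) {
    abort("identity and aligned-fraction ranges must lie in [0, 1].")
  }
  set.seed(seed)
  frac_raw <- runif(n_records, fraction_range[1], fraction_range[2])
  id_raw <- runif(n_records, identity_range[1], identity_range[2])
  aln_len <- pmax(1L, as.integer(round(frac_raw * read_length)))
  nm <- as.integer(round((1 - id_raw) * aln_len))
  identity <- 1 - nm / aln_len
  fraction <- aln_len / read_length
  tibble(
    read_id = sprintf("r%06d", seq_len(n_records)),
    contig = sample(contigs, n_records, replace = TRUE),
    identity = identity,
    aligned_fraction = fraction,
    read_length = as.integer(read_length),
    nm = nm,
    aligned_length = aln_len,
    planted_pass = identity >= min_id & fraction >= min_aln
  )
}
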