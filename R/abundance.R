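#' Read a minimal SAM text file into an alignment tibble
#'
#' Parses the required SAM columns plus the `NM` tag. Per the recruitment
#' pipeline's conventions, identity is `1 - NM / alignment_length` and the
#' aligned fraction is `alignment_length / read_length`, where the
#' alignment length sums the CIGAR `M`, `=` and `X` operations and the read
#' length additionally counts insertions and soft clips. Unmapped records
#' (flag 0x4 or `*` reference) are skipped; records without an `NM` tag are
#' skipped with a counted warning.
#'
#' @param path Path to a SAM text file.
#' @param sample Optional sample id to attach (defaults to the file name
#'   without extension).
#' @return Tibble `read_id`, `contig`, `identity`, `aligned_fraction`,
#'   `read_length`, `sample`.
#' @export
read_sam_minimal <- function(path, sample = NULL) {
  if (is.null(sample)) {
    sample <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  rows <- purrr::map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) || f[3] == "*") return(NULL)
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (!length(nm)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    nm <- as.integer(sub("^NM:i:", "", nm[1]))
    ops <- .cigar_ops(f[6])
    aln_len <- sum(ops$len[ops$op %in% c("M", "=", "X")])
    read_len <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
    if (aln_len == 0 || read_len == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tibble(read_id = f[1], contig = f[3],
           identity = 1 - nm / aln_len,
           aligned_fraction = aln_len / read_len,
           read_length = read_len)
  })
  if (skipped) {
    warn(paste0("skipped ", skipped, " malformed SAM record(s)"))
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(read_id = character(), contig = character(),
                  identity = numeric(), aligned_fraction = numeric(),
                  read_length = integer())
  }
  out$sample <- sample
  out
}

.cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = len, op = op)
}

#' Write alignment records as a minimal SAM file
#'
#' Emits one line per record with a CIGAR of `<aligned>M<soft>S` and an
#' `NM` tag chosen so that [read_sam_minimal()] recovers the record's
#' identity and aligned fraction exactly.
#'
#' @param records Tibble with `read_id`, `contig`, `aligned_length`, `nm`,
#'   `read_length` (as from [simulate_alignment_records()]).
#' @param path Output path.
#' @param contig_lengths Optional named vector for `@SQ` header lines.
#' @return Invisibly, `path`.
#' @export
write_sam_minimal <- function(records, path, contig_lengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  soft <- records$read_length - records$aligned_length
  cigar <- ifelse(soft > 0,
                  sprintf("%dM%dS", records$aligned_length, soft),
                  sprintf("%dM", records$aligned_length))
  body <- sprintf("%s\t0\t%s\t1\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                  records$read_id, records$contig, cigar, records$nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter alignment records on identity and aligned fraction
#'
#' Keeps records with identity >= `min_id` and aligned fraction >=
#' `min_aln` (both inclusive), then retains a single best placement per
#' read (highest identity; ties resolved by the lexicographically first
#' contig). Records with missing fields are skipped with a counted
#' warning. The operation is idempotent.
#'
#' @param records Alignment tibble (`read_id`, `contig`, `identity`,
#'   `aligned_fraction`, optionally `sample`).
#' @param min_id,min_aln Inclusive thresholds (defaults 0.95 and 0.75).
#' @return The filtered tibble, one row per retained read (per sample).
#' @export
filter_alignments <- function(records, min_id = 0.95, min_aln = 0.75) {
  bad <- is.na(records$identity) | is.na(records$aligned_fraction) |
    records$identity < 0 | records$identity > 1 |
    records$aligned_fraction < 0 | records$aligned_fraction > 1
  if (any(bad)) {
    warn(paste0("skipped ", sum(bad), " malformed alignment record(s)"))
    records <- records[!bad, , drop = FALSE]
  }
  kept <- records[records$identity >= min_id &
                    records$aligned_fraction >= min_aln, , drop = FALSE]
  if (!"sample" %in% names(kept)) kept$sample <- "sample1"
  kept %>%
    group_by(.data$sample, .data$read_id) %>%
    arrange(dplyr::desc(.data$identity), .data$contig, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
}

#' Count recruited reads per genome and sample
#'
#' @param filtered Filtered alignment tibble from [filter_alignments()].
#' @param contig_map Tibble `contig`, `genome`; every contig seen must map
#'   to exactly one genome, otherwise an error lists the offenders.
#' @return Tibble `genome`, `sample`, `reads`, complete over all genomes in
#'   the map (zero counts included).
#' @export
count_reads <- function(filtered, contig_map) {
  if (anyDuplicated(contig_map$contig)) {
    abort("`contig_map` maps some contig to more than one genome.")
  }
  unknown <- setdiff(unique(filtered$contig), contig_map$contig)
  if (length(unknown)) {
    abort(paste0("contig(s) absent from the contig map: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  if (!"sample" %in% names(filtered)) filtered$sample <- "sample1"
  samples <- unique(filtered$sample)
  if (!length(samples)) samples <- "sample1"
  counts <- filtered %>%
    left_join(contig_map, by = "contig") %>%
    count(.data$genome, .data$sample, name = "reads")
  tidyr::expand_grid(genome = unique(contig_map$genome),
                     sample = samples) %>%
    left_join(counts, by = c("genome", "sample")) %>%
    mutate(reads = as.integer(dplyr::coalesce(.data$reads, 0L)))
}

#' Relative fraction of each genome in each sample
#'
#' `fraction = reads recruited to the genome / total reads in the sample`.
#' Samples with zero total reads get `NA` fractions and a warning.
#'
#' @param counts Tibble `genome`, `sample`, `reads`.
#' @param manifest Tibble `sample`, `total_reads`.
#' @return `counts` with a `fraction` column added.
#' @export
relative_fraction <- function(counts, manifest) {
  out <- counts %>% left_join(manifest[c("sample", "total_reads")],
                              by = "sample")
  zero <- !is.na(out$total_reads) & out$total_reads == 0
  if (any(zero)) {
    warn(paste0("sample(s) with zero total reads flagged: ",
                paste(unique(out$sample[zero]), collapse = ", ")))
  }
  out %>%
    mutate(fraction = ifelse(.data$total_reads > 0,
                             .data$reads / .data$total_reads, NA_real_)) %>%
    select(-"total_reads")
}

#' Reads per kilobase of genome per megabase of metagenome (RPKM)
#'
#' `rpkm = (reads / (genome length in bp / 1000)) /
#' (total bp in metagenome / 1e6)`.
#'
#' @param counts Tibble `genome`, `sample`, `reads`.
#' @param genome_lengths Tibble `genome`, `total_length` (bp, > 0).
#' @param manifest Tibble `sample`, `total_bp` (> 0).
#' @return `counts` with an `rpkm` column added.
#' @export
#' @examples
#' rpkm(tibble::tibble(genome = "g", sample = "s", reads = 100),
#'      tibble::tibble(genome = "g", total_length = 2e6),
#'      tibble::tibble(sample = "s", total_bp = 1e9))  # 5e-05
rpkm <- function(counts, genome_lengths, manifest) {
  if (any(genome_lengths$total_length <= 0)) {
    abort("genome lengths must be positive.")
  }
  if (any(manifest$total_bp <= 0)) {
    abort("per-sample total bp must be positive.")
  }
  counts %>%
    left_join(genome_lengths[c("genome", "total_length")], by = "genome") %>%
    left_join(manifest[c("sample", "total_bp")], by = "sample") %>%
    mutate(rpkm = (.data$reads / (.data$total_length / 1000)) /
             (.data$total_bp / 1e6)) %>%
    select(-"total_length", -"total_bp")
}

#' Split samples into high and low recruitment classes
#'
#' A sample is `"high"` when the genome set's summed relative fraction
#' reaches the threshold (default 0.005, i.e. 0.5% of the sample's reads;
#' inclusive).
#'
#' @param fractions Tibble `genome`, `sample`, `fraction` from
#'   [relative_fraction()].
#' @param threshold Summed-fraction cutoff (default 0.005).
#' @return Tibble `sample`, `total_fraction`, `class`.
#' @export
split_high_low <- function(fractions, threshold = 0.005) {
  fractions %>%
    group_by(.data$sample) %>%
    summarise(total_fraction = sum(.data$fraction), .groups = "drop") %>%
    mutate(class = ifelse(!is.na(.data$total_fraction) &
                            .data$total_fraction >= threshold,
                          "high", "low"))
}
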