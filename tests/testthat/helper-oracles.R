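# Independent oracles used to check the package's implementations.
# These deliberately re-derive each quantity by the most literal route.

# naive average-linkage agglomeration: returns the merge heights and the
# flat clusters obtainable at any cut, via explicit mean-of-pairs updates
oracle_upgma_clusters <- function(dmat, cut) {
  labels <- rownames(dmat)
  clusters <- as.list(labels)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    if (best_d >= cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, sort)
}

# literal step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# position-by-position c-ring motif scan (no regular expressions)
oracle_cring <- function(s) {
  v <- strsplit(s, "")[[1]]
  hit_a <- NA_integer_
  hit_b <- NA_integer_
  for (i in seq_len(max(0, length(v) - 6))) {
    w <- v[i:(i + 6)]
    if (is.na(hit_a) && w[1] == "L" && w[2] == "P" && w[3] == "E" &&
        w[4] == "S" && w[7] == "I") {
      hit_a <- i
    }
    if (is.na(hit_b) && w[1] == "L" && w[2] == "P" && w[3] == "E" &&
        w[4] == "T" && w[5] == "I" && w[7] == "L") {
      hit_b <- i
    }
  }
  if (!is.na(hit_a) && !is.na(hit_b)) {
    list(class = "conflict", pos = min(hit_a, hit_b))
  } else if (!is.na(hit_a)) {
    list(class = "MGIIa-type", pos = hit_a)
  } else if (!is.na(hit_b)) {
    list(class = "MGIIb-type", pos = hit_b)
  } else {
    list(class = "none", pos = NA_integer_)
  }
}

# pseudo-F recomputed from first principles for one labelling
oracle_permanova_f <- function(dmat, groups) {
  n <- nrow(dmat)
  a <- length(unique(groups))
  ss_tot <- sum(dmat[upper.tri(dmat)]^2) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# brute-force connected components under an ANI threshold
oracle_components <- function(ids, ani, threshold) {
  grp <- seq_along(ids)
  names(grp) <- ids
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(ani))) {
      if (is.na(ani$ani[r]) || ani$ani[r] < threshold) next
      a <- ani$query[r]
      b <- ani$ref[r]
      if (grp[a] != grp[b]) {
        grp[grp == grp[b]] <- grp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(grp), grp)
}

# fraction of planted two-clade tree structure: deep clade stems, shallow
# internal structure, shallow outgroup leaves pulling the mean tip depth
# down so the clade MRCAs sit past 1.2 relative depth
planted_two_clade_tree <- function() {
  ape::read.tree(text = paste0(
    "(((a1:0.1,a2:0.1):0.1,(a3:0.1,a4:0.1):0.1):5.0,",
    "((b1:0.1,b2:0.1):0.1,(b3:0.1,b4:0.1):0.1):5.0,",
    "o1:0.3,o2:0.3,o3:0.3,o4:0.3);"))
}

planted_five_clade_tree <- function() {
  clade <- function(p) {
    sprintf("((%s1:0.05,%s2:0.05):0.05,%s3:0.1):5.0", p, p, p)
  }
  ape::read.tree(text = paste0(
    "(", paste(vapply(letters[1:5], clade, character(1)), collapse = ","),
    ",out1:0.3,out2:0.3,out3:0.3,out4:0.3,out5:0.3);"))
}

rpkm_matrix_from_sim <- function(sim, genomes) {
  rp <- rpkm(sim$counts, genomes, sim$manifest)
  wide <- tidyr::pivot_wider(rp[c("genome", "sample", "rpkm")],
                             names_from = "sample", values_from = "rpkm")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$genome
  m
}
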