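test_that("Bray-Curtis matches its formula and bounds", {
  m <- matrix(c(2, 1, 1, 3), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  d <- as.matrix(bray_curtis(m, "taxa"))
  expect_equal(d["t1", "t2"], 3 / 7)

  same <- matrix(c(1, 1, 2, 2), 2, 2,
                 dimnames = list(c("a", "b"), NULL))
  expect_equal(as.matrix(bray_curtis(same, "taxa"))["a", "b"], 0)

  disjoint <- matrix(c(1, 0, 0, 1), 2, 2,
                     dimnames = list(c("a", "b"), NULL))
  expect_equal(as.matrix(bray_curtis(disjoint, "taxa"))["a", "b"], 1)

  expect_error(bray_curtis(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  zz <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_warning(dz <- bray_curtis(zz, "taxa"), "all-zero")
  expect_equal(as.matrix(dz)["a", "b"], 0)

  set.seed(4)
  r <- matrix(rpois(60, 4), 6, 10,
              dimnames = list(paste0("t", 1:6), NULL))
  dr <- as.matrix(bray_curtis(r, "taxa"))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_equal(dr, t(dr))
  expect_true(all(diag(dr) == 0))
})

test_that("average linkage agrees with a brute-force oracle at small n", {
  # forced merges on a 3-item matrix
  dm <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(as.dist(dm))
  expect_equal(sort(hc$height), c(0.1, 0.9))

  set.seed(8)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    dm <- matrix(0, n, n, dimnames = list(paste0("i", 1:n),
                                          paste0("i", 1:n)))
    dm[upper.tri(dm)] <- runif(n * (n - 1) / 2)
    dm <- dm + t(dm)
    hc <- average_linkage(as.dist(dm))
    for (cut in c(0.3, 0.6, 0.9)) {
      got <- cut_dendrogram(hc, cut)
      got_sets <- unname(lapply(split(got$label, got$cluster), sort))
      want_sets <- oracle_upgma_clusters(dm, cut)
      expect_setequal(
        vapply(got_sets, paste, character(1), collapse = ","),
        vapply(want_sets, paste, character(1), collapse = ","))
    }
  }
  expect_error(average_linkage(dist(matrix(1, 1))), "at least 2")
})

test_that("dendrogram cutting is strict and hits its edge cases", {
  dm <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("x", "y"),
                                                      c("x", "y")))
  hc <- average_linkage(as.dist(dm))
  expect_equal(hc$height, 0.4)
  # cutting exactly at a merge height splits that merge (strict <)
  at <- cut_dendrogram(hc, 0.4)
  expect_equal(length(unique(at$cluster)), 2)
  above <- cut_dendrogram(hc, 0.4 + 1e-9)
  expect_equal(length(unique(above$cluster)), 1)
  zero <- cut_dendrogram(hc, 0)
  expect_equal(length(unique(zero$cluster)), 2)
})

test_that("PERMANOVA matches enumeration, bounds and an independent fit", {
  # n = 6, two groups of 3: p equals the exhaustive assignment fraction
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  x[4:6, ] <- x[4:6, ] + 1.5
  dm <- as.matrix(dist(x))
  gr <- rep(c("a", "b"), each = 3)
  f_obs <- oracle_permanova_f(dm, gr)
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep("b", 6)
    g[idx] <- "a"
    oracle_permanova_f(dm, g)
  })
  exact_p <- mean(f_all >= f_obs - 1e-12)
  fit <- permanova(dm, gr, n_perm = 9999, seed = 2)
  expect_equal(fit$pseudo_f, f_obs, tolerance = 1e-10)
  se <- sqrt(exact_p * (1 - exact_p) / 9999)
  expect_lt(abs(fit$p - exact_p), 4 * se + 2e-4)

  # p floor and seed reproducibility
  expect_gte(fit$p, 1 / (9999 + 1))
  fit2 <- permanova(dm, gr, n_perm = 999, seed = 31)
  fit3 <- permanova(dm, gr, n_perm = 999, seed = 31)
  expect_identical(fit2$p, fit3$p)

  # pseudo-F agrees with vegan's adonis2 on a larger example
  set.seed(6)
  y <- matrix(rpois(90, 6), 18, 5)
  dy <- vegan::vegdist(y)
  gy <- rep(c("u", "v", "w"), each = 6)
  ours <- permanova(dy, gy, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dy ~ gy, permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)

  # perfect separation: observed F is the maximum over all assignments and
  # p approaches the minimal attainable value (2 of the 20 distinct splits
  # reproduce the separating partition)
  z <- rbind(matrix(0, 3, 2), matrix(10, 3, 2)) + rnorm(12, sd = 1e-3)
  dz2 <- as.matrix(dist(z))
  fz <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("b", 6)
    g[idx] <- "a"
    oracle_permanova_f(dz2, g)
  })
  fitz <- permanova(dz2, gr, n_perm = 999, seed = 7)
  expect_equal(fitz$pseudo_f, max(fz), tolerance = 1e-9)
  expect_lt(fitz$p, 0.2)

  # group-size guards
  expect_error(permanova(dm, c("a", "a", "a", "a", "a", "b")), ">= 2")
  expect_error(permanova(dm, rep("a", 6)), "2 groups")
})

test_that("tidy and glance summarise a PERMANOVA fit", {
  set.seed(10)
  x <- matrix(rnorm(24), 12, 2)
  fit <- permanova(dist(x), rep(c("a", "b"), each = 6), n_perm = 99,
                   seed = 3)
  td <- tidy(fit)
  expect_equal(td$df, 1)
  expect_equal(td$df_residual, 10)
  gl <- glance(fit)
  expect_equal(gl$n_permutations, 99)
  expect_equal(gl$seed, 3)
})

test_that("pairwise PERMANOVA applies the Bonferroni multiplier", {
  set.seed(11)
  x <- rbind(matrix(rnorm(12), 6, 2),
             matrix(rnorm(12, 4), 6, 2),
             matrix(rnorm(12, 8), 6, 2))
  gr <- rep(c("a", "b", "c"), each = 6)
  res <- pairwise_permanova(dist(x), gr, n_perm = 199, seed = 5)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 3))
  expect_true(all(res$p_bonferroni >= res$p))
})

test_that("BH adjustment matches the closed form and a naive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(12)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Welch t-test handles the degenerate and calibrated cases", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")

  # null calibration and power at n = 50
  set.seed(13)
  reps <- 600
  p_null <- replicate(reps, welch_t(rnorm(50), rnorm(50))$p)
  rate <- mean(p_null < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  p_alt <- replicate(200, welch_t(rnorm(50), rnorm(50, 1))$p)
  expect_gt(mean(p_alt < 0.05), 0.99)
})

test_that("environmental binning reproduces the printed group edges", {
  md <- tibble::tibble(
    sample = paste0("s", 1:8),
    temperature = c(9.9, 10, 15, 20, 20.1, NA, 3, 25),
    oxygen = c(109, 110, 159, 159.4, 159.6, 160, 200, 201),
    phosphate = c("BDL", "0.4", "0.5", "2.0", "2.1", NA, "0.1", "1"),
    nitrate = c("BDL", "0.4", "1.9", "1.94", "1.96", "2.0", "5.0", "5.1"))
  b <- bin_environment(md)
  expect_equal(as.character(b$temperature_bin),
               c("<10", "10-20", "10-20", "10-20", ">20", NA, "<10", ">20"))
  expect_equal(as.character(b$oxygen_bin),
               c("<110", "110-159", "110-159", "110-159", "160-200",
                 "160-200", "160-200", ">200"))
  expect_equal(as.character(b$phosphate_bin),
               c("BDL", "<0.5", "0.5-2.0", "0.5-2.0", ">2.0", NA, "<0.5",
                 "0.5-2.0"))
  expect_equal(as.character(b$nitrate_bin),
               c("BDL", "<0.5", "0.5-1.9", "0.5-1.9", "2.0-5.0", "2.0-5.0",
                 "2.0-5.0", ">5.0"))
  # every measured value maps to exactly one bin
  expect_true(all(!is.na(b$oxygen_bin)))
  expect_error(bin_environment(tibble::tibble(sample = "x",
                                              phosphate = "-1")),
               "negative")
})

test_that("CCA separates signal from null environmental structure", {
  g <- tibble::tibble(genome = paste0("g", 1:8), total_length = 2e6)

  # null: coefficients all zero -> little constrained inertia
  fracs <- vapply(1:3, function(s) {
    sim <- simulate_community(g, n_samples = 50, depth = 2e5, seed = s)
    m <- rpkm_matrix_from_sim(sim, g)
    cc <- cca_ordination(t(m), sim$env[c("temperature", "oxygen")])
    cc$constrained_inertia / cc$total_inertia
  }, numeric(1))
  expect_lt(mean(fracs), 0.1)

  # one strong gradient -> axis 1 dominates the constrained inertia
  co <- tibble::tibble(genome = paste0("g", 1:4),
                       variable = "temperature", beta = 2)
  sim1 <- simulate_community(g, n_samples = 50, depth = 2e5,
                             coefficients = co, seed = 21)
  m1 <- rpkm_matrix_from_sim(sim1, g)
  cc1 <- cca_ordination(t(m1), sim1$env[c("temperature", "oxygen")])
  expect_gt(cc1$constrained_fraction[1], 0.9)

  # axis scores are orthogonal in the fit's weighted metric
  w <- rowSums(t(m1)[rownames(cc1$site_scores), ]) /
    sum(t(m1)[rownames(cc1$site_scores), ])
  sc <- vegan::scores(cc1$fit, display = "lc",
                      choices = seq_along(cc1$eigenvalues))
  cross <- t(sc) %*% diag(w) %*% sc
  expect_lt(abs(cross[1, 2]), 1e-8)
})

test_that("ecological clusters recover planted blocks and reject noise", {
  g <- tibble::tibble(genome = paste0("g", 1:10), total_length = 2e6)
  co <- tibble::tibble(genome = paste0("g", 1:3),
                       variable = "temperature", beta = 3)
  sim <- simulate_community(g, n_samples = 40, depth = 2e5,
                            coefficients = co, seed = 11)
  m <- rpkm_matrix_from_sim(sim, g)
  ec <- ecological_clusters(m)
  expect_gte(nrow(ec), 1)
  expect_setequal(ec$taxa[[1]], paste0("g", 1:3))
  # the cluster's samples are warm ones
  warm <- sim$env$sample[sim$env$temperature >
                           median(sim$env$temperature)]
  expect_gt(mean(ec$samples[[1]] %in% warm), 0.9)

  # two disjoint planted blocks -> two clusters with disjoint taxa
  co2 <- dplyr::bind_rows(
    tibble::tibble(genome = paste0("g", 1:3), variable = "temperature",
                   beta = 3),
    tibble::tibble(genome = paste0("g", 4:6), variable = "oxygen",
                   beta = 3))
  sim2 <- simulate_community(g, n_samples = 40, depth = 2e5,
                             coefficients = co2, seed = 22)
  m2 <- rpkm_matrix_from_sim(sim2, g)
  ec2 <- ecological_clusters(m2)
  expect_gte(nrow(ec2), 2)
  expect_equal(length(intersect(ec2$taxa[[1]], ec2$taxa[[2]])), 0)

  # a flat matrix yields no elevated block; all-zero yields empty
  flat <- matrix(5, 6, 8, dimnames = list(paste0("t", 1:6),
                                          paste0("s", 1:8)))
  expect_equal(nrow(suppressWarnings(ecological_clusters(flat))), 0)
  zero <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4),
                                          paste0("s", 1:4)))
  expect_equal(nrow(ecological_clusters(zero)), 0)
})
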