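test_that("VCF reader applies GT semantics and drops bad records", {
  p <- write_toy_vcf(tempfile(fileext = ".vcf"))
  expect_warning(g <- read_vcf(p), "non-biallelic")
  expect_equal(attr(g, "n_dropped_multiallelic"), 1)
  expect_equal(ncol(g$dosage), 2)                    # triallelic s2 gone
  expect_equal(unname(g$dosage[, "s1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosage[, "s3"]), c(NA, NA, 2L))  # half call -> NA
  expect_equal(attr(g, "n_half_calls"), 1)
  expect_equal(g$samples$location, c("a", "a", "b"))
  # a sample without location mapping is fatal
  suppressWarnings(
    expect_error(read_vcf(p, locations = data.frame(sample = "a_i01",
                                                    location = "a")),
                 "no location mapping"))
})

test_that("quality filters apply the documented rules in order", {
  # individuals: > 30% missing removed, exactly 30% retained
  set.seed(1)
  d <- matrix(rbinom(10 * 40, 2, 0.4), 10, 40)
  d[1, 1:13] <- NA    # 32.5% missing -> out
  d[2, 1:12] <- NA    # 30.0% missing -> retained
  g <- geno_matrix(d, snps = data.frame(id = paste0("s", 1:40),
                                        locus = paste0("l", 1:40),
                                        chrom = "c", pos = 1:40),
                   samples = data.frame(id = paste0("i", 1:10),
                                        location = rep(c("a", "b"), 5)))
  gf <- apply_quality_filters(g, min_mac = 0)
  expect_false("i1" %in% gf$samples$id)
  expect_true("i2" %in% gf$samples$id)

  # MAC: alt allele seen in exactly 2 copies -> removed (2 < 3)
  d2 <- matrix(0L, 10, 3)
  d2[, 1] <- rep(c(0L, 1L), 5)         # MAC 5: kept
  d2[1, 2] <- 2L                       # MAC 2: removed
  d2[1:4, 3] <- 1L                     # MAC 4: kept
  g2 <- geno_matrix(d2, snps = data.frame(id = paste0("s", 1:3),
                                          locus = paste0("l", 1:3),
                                          chrom = "c", pos = 1:3),
                    samples = data.frame(id = paste0("i", 1:10),
                                         location = "a"))
  g2f <- apply_quality_filters(g2, max_obs_het = 1)
  expect_equal(g2f$snps$id, c("s1", "s3"))
  expect_equal(attr(g2f, "filter_report")$snps_mac, 1)

  # depth: only the one extreme-depth SNP removed at the 99th percentile
  set.seed(2)
  d3 <- matrix(rbinom(20 * 100, 2, 0.5), 20, 100)
  depth <- c(rep(30, 99), 5000)
  g3 <- geno_matrix(d3, snps = data.frame(id = paste0("s", 1:100),
                                          locus = paste0("l", 1:100),
                                          chrom = "c", pos = 1:100,
                                          depth = depth),
                    samples = data.frame(id = paste0("i", 1:20),
                                         location = "a"))
  g3f <- apply_quality_filters(g3, min_mac = 0, max_obs_het = 1)
  rep3 <- attr(g3f, "filter_report")
  expect_equal(rep3$snps_depth, 1)
  expect_false("s100" %in% g3f$snps$id)
  # cutoff is the linear-interpolation 99th percentile of retained SNPs
  expect_equal(rep3$depth_cutoff, unname(quantile(depth, 0.99)))

  # observed heterozygosity > 0.7 removed
  d4 <- matrix(rep(c(0L, 2L), 10), 10, 2)
  d4[, 2] <- 1L                        # all het
  g4 <- geno_matrix(d4, snps = data.frame(id = c("s1", "s2"),
                                          locus = c("l1", "l2"),
                                          chrom = "c", pos = 1:2),
                    samples = data.frame(id = paste0("i", 1:10),
                                         location = "a"))
  g4f <- apply_quality_filters(g4, min_mac = 0)
  expect_equal(g4f$snps$id, "s1")
})

test_that("thinning keeps one SNP per locus, deterministically per seed", {
  sim <- simulate_landscape(tiny_cfg(seed = 6, n_neutral = 90,
                                     n_adaptive = 0, snps_per_locus = 3))
  g <- sim$geno
  t1 <- thin_one_snp_per_locus(g, seed = 1)
  t1b <- thin_one_snp_per_locus(g, seed = 1)
  t2 <- thin_one_snp_per_locus(g, seed = 2)
  expect_equal(ncol(t1$dosage), 30)
  expect_identical(t1$snps$id, t1b$snps$id)
  expect_false(identical(t1$snps$id, t2$snps$id))
  expect_equal(anyDuplicated(t1$snps$locus), 0)
})

test_that("population allele frequencies match hand counts", {
  # 3 pops x 4 SNPs toy, frequencies of the global minor allele
  d <- rbind(c(0L, 2L, 1L, 0L),
             c(0L, 2L, 1L, 0L),
             c(2L, 2L, 2L, 0L),
             c(0L, 1L, 2L, 0L),
             c(NA, 2L, 0L, 1L),
             c(0L, 2L, 1L, NA))
  g <- geno_matrix(d, snps = data.frame(id = paste0("s", 1:4),
                                        locus = paste0("l", 1:4),
                                        chrom = "c", pos = 1:4),
                   samples = data.frame(id = paste0("i", 1:6),
                                        location = rep(c("a", "b", "c"),
                                                       each = 2)))
  pf <- pop_allele_freqs(g)
  # SNP1: global alt = 2/10 -> minor is alt; freqs 0/4, 2/4, 0/2
  expect_true(pf$minor_is_alt[["s1"]])
  expect_equal(pf$freq["a", "s1"], 0)
  expect_equal(pf$freq["b", "s1"], 1 / 2)
  expect_equal(pf$freq["c", "s1"], 0)
  # SNP2: global alt 11/12 -> minor is REF; pop b ref freq = 1/4
  expect_false(pf$minor_is_alt[["s2"]])
  expect_equal(pf$freq["b", "s2"], 1 / 4)
  expect_equal(pf$freq["c", "s2"], 0)
  # all-missing cell flagged missing
  d[5:6, 2] <- NA
  g2 <- geno_matrix(d, snps = g$snps, samples = g$samples)
  expect_true(is.na(pop_allele_freqs(g2)$freq["c", "s2"]))
})

test_that("diversity statistics match closed forms", {
  # 2 diploids, genotypes 0 and 2 at one SNP: Ho = 0, unbiased He = 2/3
  d <- cbind(c(0L, 2L))
  g <- geno_matrix(d, snps = data.frame(id = "s1", locus = "l1",
                                        chrom = "c", pos = 1),
                   samples = data.frame(id = c("i1", "i2"), location = "a"))
  ds <- diversity_stats(g)
  expect_equal(ds$Ho, 0)
  expect_equal(ds$He, 2 * 0.5 * 0.5 * (4 / 3))
  expect_equal(ds$pi, 2 / 3)    # 2*2*2/(4*3)
  # monomorphic locus contributes zero; bounds hold on simulated data
  sim <- make_block_sim(seed = 3, n_neutral = 60, n_adaptive = 0)
  dv <- diversity_stats(sim$geno)
  expect_true(all(dv$Ho >= 0 & dv$Ho <= 1))
  expect_true(all(dv$He >= 0 & dv$He <= 1))
  expect_true(all(dv$pi >= 0 & dv$pi <= 1))
  # single-individual location skipped with a warning
  g3 <- sim$geno
  g3$samples$location[1] <- "lonely"
  expect_warning(diversity_stats(geno_matrix(g3$dosage, g3$snps,
                                             g3$samples)), "skipped")
})


test_that("Weir-Cockerham theta agrees with the literal-formula oracle", {
  # 2 pops x 2 loci toy with unequal sample sizes and heterozygotes
  d <- rbind(c(0L, 1L), c(1L, 1L), c(0L, 0L),     # pop a, n = 3
             c(2L, 1L), c(2L, 2L), c(1L, 2L), c(2L, 2L))  # pop b, n = 4
  g <- geno_matrix(d, snps = data.frame(id = c("s1", "s2"),
                                        locus = c("l1", "l2"),
                                        chrom = "c", pos = 1:2),
                   samples = data.frame(id = paste0("i", 1:7),
                                        location = rep(c("a", "b"),
                                                       c(3, 4))))
  got <- pairwise_fst(g)
  p_a <- colMeans(d[1:3, ]) / 2;  p_b <- colMeans(d[4:7, ]) / 2
  h_a <- colMeans(d[1:3, ] == 1); h_b <- colMeans(d[4:7, ] == 1)
  want <- wc_oracle_pair(c(3, 3), c(4, 4), p_a, p_b, h_a, h_b)
  expect_equal(got$theta["a", "b"], want, tolerance = 1e-12)

  # limits: identical frequency draws -> theta ~ 0; opposite fixation -> 1
  set.seed(8)
  f <- matrix(runif(200, 0.2, 0.8), 2, 100, byrow = TRUE)
  f[2, ] <- f[1, ]
  gg <- sample_genotypes(
    matrix(f[1, ], 2, 100, byrow = TRUE,
           dimnames = list(c("a", "b"), paste0("s", 1:100))),
    15, seed = 3)
  expect_lt(abs(pairwise_fst(gg)$theta[1, 2]), 0.02)
  dfix <- rbind(matrix(0L, 5, 20), matrix(2L, 5, 20))
  gfix <- geno_matrix(dfix, snps = data.frame(id = paste0("s", 1:20),
                                              locus = paste0("l", 1:20),
                                              chrom = "c", pos = 1:20),
                      samples = data.frame(id = paste0("i", 1:10),
                                           location = rep(c("a", "b"),
                                                          each = 5)))
  expect_equal(pairwise_fst(gfix)$theta[1, 2], 1)
})

test_that("AMOVA matches an explicit double-loop sums-of-squares oracle", {
  sim <- make_block_sim(seed = 5, K = 3, per = 1, n_ind = 5,
                        n_neutral = 40, n_adaptive = 0)
  g <- sim$geno
  got <- amova_phi_st(g)
  # oracle: explicit pairwise squared distances and group sums
  d <- g$dosage; n <- nrow(d); loc <- g$samples$location
  d2 <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(d[i, ]) & !is.na(d[j, ])
    d2[i, j] <- d2[j, i] <- sum((d[i, ok] - d[j, ok])^2) * ncol(d) / sum(ok)
  }
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (l in unique(loc)) {
    i <- which(loc == l)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  G <- length(unique(loc))
  ms_a <- (ss_tot - ss_w) / (G - 1); ms_w <- ss_w / (n - G)
  n0 <- (n - sum(table(loc)^2) / n) / (G - 1)
  s2a <- max(0, (ms_a - ms_w) / n0)
  expect_equal(got$phi_st, s2a / (s2a + ms_w), tolerance = 1e-12)
  # two populations fixed for opposite alleles -> Phi = 1
  dfix <- rbind(matrix(0L, 4, 10), matrix(2L, 4, 10))
  gfix <- geno_matrix(dfix, snps = data.frame(id = paste0("s", 1:10),
                                              locus = paste0("l", 1:10),
                                              chrom = "c", pos = 1:10),
                      samples = data.frame(id = paste0("i", 1:8),
                                           location = rep(c("a", "b"),
                                                          each = 4)))
  expect_equal(amova_phi_st(gfix)$phi_st, 1)
  # all identical individuals is a zero-variance error
  gsame <- geno_matrix(matrix(1L, 6, 5),
                       snps = data.frame(id = paste0("s", 1:5),
                                         locus = paste0("l", 1:5),
                                         chrom = "c", pos = 1:5),
                       samples = data.frame(id = paste0("i", 1:6),
                                            location = rep(c("a", "b"),
                                                           each = 3)))
  expect_error(amova_phi_st(gsame), "zero-variance")
})

test_that("statistics are invariant to individual and SNP permutation", {
  sim <- make_block_sim(seed = 7, n_neutral = 60, n_adaptive = 0, per = 3,
                        K = 3, n_ind = 6)
  g <- sim$geno
  set.seed(1)
  pi_ <- sample(nrow(g$dosage)); ps <- sample(ncol(g$dosage))
  gp <- geno_matrix(g$dosage[pi_, ps], snps = g$snps[ps, ],
                    samples = g$samples[pi_, ])
  expect_equal(pairwise_fst(gp)$theta, pairwise_fst(g)$theta,
               tolerance = 1e-12)
  expect_equal(amova_phi_st(gp)$phi_st, amova_phi_st(g)$phi_st,
               tolerance = 1e-12)
  a <- diversity_stats(g); b <- diversity_stats(gp)
  expect_equal(a[order(a$location), ], b[order(b$location), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("theta and Phi_ST track the divergence knob monotonically", {
  phis <- c(30, 8, 3, 1)
  stats <- sapply(1:10, function(s) {
    th <- sapply(phis, function(ph) {
      sim <- make_block_sim(seed = s * 100, phi = ph, n_neutral = 80,
                            n_adaptive = 0, K = 3, per = 3, n_ind = 8)
      c(pairwise_fst(sim$geno)$mean_pairwise,
        amova_phi_st(sim$geno)$phi_st)
    })
    c(cor(seq_along(phis), th[1, ], method = "spearman"),
      cor(seq_along(phis), th[2, ], method = "spearman"))
  })
  expect_gt(mean(stats[1, ]), 0.9)   # theta increases as phi decreases
  expect_gt(mean(stats[2, ]), 0.9)   # Phi_ST likewise
})
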