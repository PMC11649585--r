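# Shared fixtures, all generated in code.

# Small landscape config for fast end-to-end tests.
tiny_cfg <- function(seed = 1, ...) {
  args <- list(nrow = 24, ncol = 24, n_populations = 20, n_individuals = 10,
               n_neutral = 200, n_adaptive = 10, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Block-structured distance matrix: K groups of `per` locations, small
# within-group and large between-group distances. Gives clean, known
# cluster structure for the population-structure and concordance tests.
block_distance <- function(K = 4, per = 5, within = 1, between = 8) {
  n <- K * per
  g <- rep(seq_len(K), each = per)
  D <- matrix(between, n, n)
  for (k in seq_len(K)) D[g == k, g == k] <- within
  diag(D) <- 0
  ids <- paste0("pop_", sprintf("%02d", seq_len(n)))
  dimnames(D) <- list(ids, ids)
  list(D = D, groups = g, ids = ids)
}

# Frequencies + genotypes over a block-structured landscape. Adaptive loci
# follow an environmental variable aligned with the blocks plus noise, so
# structure and clines are both recoverable.
make_block_sim <- function(seed = 1, K = 4, per = 5, n_ind = 10,
                           n_neutral = 200, n_adaptive = 10, beta = 2,
                           sigma2 = 1.5, phi = 2,
                           within = 1, between = 8, n_env = 3,
                           adaptive_layers = 1) {
  bl <- block_distance(K, per, within, between)
  n <- K * per
  set.seed(seed + 5000)
  pops <- data.frame(id = bl$ids, row = seq_len(n), col = seq_len(n),
                     x = seq_len(n) * 10, y = rep(1, n))
  env <- sapply(seq_len(n_env), function(j)
    as.numeric(scale(bl$groups * (j == 1) + rnorm(n, sd = 0.6))))
  colnames(env) <- paste0("env_", seq_len(n_env))
  rownames(env) <- bl$ids
  cfg <- sim_config(n_populations = n, n_individuals = n_ind,
                    n_neutral = n_neutral, n_adaptive = n_adaptive,
                    beta = beta, adaptive_layers = adaptive_layers,
                    n_env_layers = n_env, sigma2 = sigma2, phi = phi,
                    seed = seed)
  sim <- simulate_allele_frequencies(pops, bl$D, env, cfg)
  geno <- sample_genotypes(sim$freqs, n_ind, seed = seed + 1)
  list(freqs = sim$freqs, truth = sim$truth, geno = geno, env = env,
       groups = bl$groups, pops = pops, D = bl$D)
}

# Hand-written 3-record VCF exercising triallelic and half-call handling.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a_i01", "a_i02", "b_i01"), collapse = "\t"),
    paste(c("loc1", "10", "s1", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("loc1", "35", "s2", "G", "C,T", ".", "PASS", ".", "GT",
            "0/1", "0/2", "0/0"), collapse = "\t"),
    paste(c("loc2", "10", "s3", "A", "C", ".", "PASS", ".", "GT",
            "./.", "./1", "1/1"), collapse = "\t")), path)
  path
}
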