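# Diversity and differentiation statistics: He/Ho/pi, Weir-Cockerham theta,
# distance-based AMOVA.

#' Per-location genetic diversity
#'
#' Per sampling location: observed heterozygosity `Ho` (mean fraction of
#' heterozygous genotypes), unbiased expected heterozygosity
#' `He = mean(2*p*q * 2n/(2n-1))`, and nucleotide diversity over variant
#' sites `pi` (mean pairwise difference per site, the unbiased
#' `2*n_ref*n_alt / (m*(m-1))` with `m` called alleles). Monomorphic sites
#' contribute zero. Locations with fewer than 2 genotyped individuals are
#' skipped with a warning.
#'
#' @param g a [geno_matrix()]
#' @return data.frame (location, n, Ho, He, pi)
#' @export
diversity_stats <- function(g) {
  locs <- sort(unique(g$samples$location))
  rows <- lapply(locs, function(l) {
    d <- g$dosage[g$samples$location == l, , drop = FALSE]
    n_ind <- nrow(d)
    if (n_ind < 2) return(NULL)
    n <- colSums(!is.na(d))              # called individuals per SNP
    ok <- n >= 2
    if (!any(ok)) return(NULL)
    d <- d[, ok, drop = FALSE]; n <- n[ok]
    alt <- colSums(d, na.rm = TRUE)
    m <- 2 * n                            # called alleles
    p <- alt / m
    ho <- mean(colSums(d == 1, na.rm = TRUE) / n)
    he <- mean(2 * p * (1 - p) * m / (m - 1))
    pi <- mean(2 * alt * (m - alt) / (m * (m - 1)))
    data.frame(location = l, n = n_ind, Ho = ho, He = he, pi = pi)
  })
  skipped <- locs[vapply(rows, is.null, logical(1))]
  if (length(skipped))
    warning("location(s) skipped (fewer than 2 genotyped individuals): ",
            paste(skipped, collapse = ", "))
  do.call(rbind, rows)
}

# Weir & Cockerham (1984) per-locus variance components for one pair or set
# of populations. Returns the a, b, c components per locus (rows = loci).
wc_components <- function(d, loc) {
  locs <- sort(unique(loc))
  r <- length(locs)
  L <- ncol(d)
  n_i <- sapply(locs, function(l) colSums(!is.na(d[loc == l, , drop = FALSE])))
  p_i <- sapply(locs, function(l) {
    dd <- d[loc == l, , drop = FALSE]
    colSums(dd, na.rm = TRUE) / (2 * colSums(!is.na(dd)))
  })
  h_i <- sapply(locs, function(l) {
    dd <- d[loc == l, , drop = FALSE]
    colSums(dd == 1, na.rm = TRUE) / colSums(!is.na(dd))
  })
  if (L == 1) { n_i <- rbind(n_i); p_i <- rbind(p_i); h_i <- rbind(h_i) }
  nbar <- rowMeans(n_i)
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  cbind(a = a, b = b, c = c_)
}

#' Pairwise Weir-Cockerham theta between sampling locations
#'
#' Multi-locus theta per pair as the ratio of summed variance components
#' `sum(a) / sum(a + b + c)` over loci (ratio-of-sums, the standard
#' variance-component practice). Negative pair values are retained, not
#' truncated. The overall mean is reported both as the average of pairwise
#' values (the printed-style summary) and as the global ratio-of-sums over
#' all locations.
#'
#' @param g a [geno_matrix()]
#' @return list: `theta` ([pairwise_matrix()] kind "genetic"),
#'   `mean_pairwise` (average of pairwise values), `overall`
#'   (all-location ratio-of-sums), `components` (per-locus a, b, c for the
#'   all-location model)
#' @export
pairwise_fst <- function(g) {
  loc <- g$samples$location
  locs <- sort(unique(loc))
  if (length(locs) < 2) stop("need at least 2 locations")
  K <- length(locs)
  th <- matrix(0, K, K, dimnames = list(locs, locs))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    sel <- loc %in% c(locs[i], locs[j])
    ni <- sum(loc == locs[i]); nj <- sum(loc == locs[j])
    if (ni < 2 || nj < 2) { th[i, j] <- th[j, i] <- NA; next }
    d <- g$dosage[sel, , drop = FALSE]
    l2 <- loc[sel]
    # drop loci not called in both members of the pair or monomorphic
    called <- sapply(c(locs[i], locs[j]), function(l)
      colSums(!is.na(d[l2 == l, , drop = FALSE])) > 0)
    poly <- apply(d, 2, function(x) {
      x <- x[!is.na(x)]; length(unique(x)) > 1 || any(x == 1) })
    use <- rowSums(called) == 2 & poly
    if (!any(use)) { th[i, j] <- th[j, i] <- NA; next }
    comp <- wc_components(d[, use, drop = FALSE], l2)
    th[i, j] <- th[j, i] <- sum(comp[, "a"]) / sum(comp)
  }
  comp_all <- wc_components(g$dosage, loc)
  comp_all <- comp_all[rowSums(is.na(comp_all)) == 0 &
                         rowSums(abs(comp_all)) > 0, , drop = FALSE]
  list(theta = pairwise_matrix(th, "genetic"),
       mean_pairwise = mean(th[upper.tri(th)], na.rm = TRUE),
       overall = sum(comp_all[, "a"]) / sum(comp_all),
       components = comp_all)
}

#' One-level AMOVA on dosage distances
#'
#' Partitions molecular variance among vs within sampling locations from
#' squared Euclidean distances on dosages (missing values excluded pairwise;
#' each squared distance is the mean squared difference over shared SNPs
#' scaled to the full SNP count). `Phi_ST = sigma2_among / sigma2_total`;
#' negative variance components are floored at zero with a note.
#'
#' @param g a [geno_matrix()]
#' @return list: `phi_st`, `pct_among` (= 100 * Phi_ST), `sigma2_among`,
#'   `sigma2_within`, `ss` (sums of squares), `df`
#' @export
amova_phi_st <- function(g) {
  loc <- g$samples$location
  locs <- sort(unique(loc))
  if (length(locs) < 2) stop("need at least 2 locations")
  d2 <- squared_dosage_dist(g$dosage)
  N <- nrow(d2); G <- length(locs)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (l in locs) {
    i <- which(loc == l)
    ss_within <- ss_within + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1; df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_g <- as.vector(table(loc))
  n0 <- (N - sum(n_g^2) / N) / (G - 1)
  s2_within <- ms_within
  s2_among <- (ms_among - ms_within) / n0
  if (s2_among < 0) {
    message("negative among-location variance component floored at 0")
    s2_among <- 0
  }
  tot <- s2_among + s2_within
  if (tot <= 0) stop("zero-variance input: all individuals identical")
  phi <- s2_among / tot
  list(phi_st = phi, pct_among = 100 * phi,
       sigma2_among = s2_among, sigma2_within = s2_within,
       ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within))
}

# Squared Euclidean dosage distance, missing-pairwise-deleted and rescaled
# to the full SNP count.
squared_dosage_dist <- function(d) {
  n <- nrow(d); L <- ncol(d)
  out <- matrix(0, n, n)
  dm <- d; dm[is.na(dm)] <- 0
  obs <- (!is.na(d)) + 0
  # sum over shared SNPs of (x - y)^2 via the polarization identity
  cross <- tcrossprod(dm)
  sq <- dm^2
  shared <- tcrossprod(obs)
  sum_x2 <- sq %*% t(obs)   # x^2 summed over loci where the partner is called

  out <- sum_x2 + t(sum_x2) - 2 * cross
  out <- ifelse(shared > 0, out * L / shared, NA)
  diag(out) <- 0
  out
}
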