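# Genotype container, VCF I/O and the quality-filter cascade.

#' Genotype matrix container
#'
#' Individuals x SNPs alternate-allele dosages (0/1/2, `NA` = missing) with
#' per-SNP metadata (RAD-locus ID, chromosome, 1-based position, mean depth
#' if available) and per-individual metadata (sample ID, sampling location).
#'
#' @param dosage integer matrix, entries in {0,1,2,NA}
#' @param snps data.frame with columns id, locus, chrom, pos and optionally
#'   depth
#' @param samples data.frame with columns id, location
#' @return object of class `geno_matrix`
#' @export
geno_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or missing")
  if (nrow(dosage) != nrow(samples))
    stop("sample metadata does not match dosage rows")
  if (ncol(dosage) != nrow(snps))
    stop("SNP metadata does not match dosage columns")
  if (any(is.na(samples$location) | samples$location == ""))
    stop("every individual needs a sampling location")
  if (any(is.na(snps$locus) | snps$locus == ""))
    stop("locus IDs must be non-empty")
  if (is.null(snps$depth)) snps$depth <- NA_real_
  rownames(dosage) <- samples$id
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%d loci, %d locations, %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$locus)),
              length(unique(x$samples$location)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

subset_geno <- function(g, ind = NULL, snp = NULL) {
  ind <- ind %||% seq_len(nrow(g$dosage))
  snp <- snp %||% seq_len(ncol(g$dosage))
  geno_matrix(g$dosage[ind, snp, drop = FALSE],
              snps = g$snps[snp, , drop = FALSE],
              samples = g$samples[ind, , drop = FALSE])
}

#' Read a VCF into a genotype matrix
#'
#' Keeps biallelic GT records only; dosage is the count of alternate alleles.
#' Half-calls (e.g. `./1`) become missing and non-biallelic records are
#' dropped, both with logged counts. The RAD-locus ID is taken from the
#' CHROM column (the convention of de novo RAD assemblies, one "chromosome"
#' per locus). Mean depth per SNP is computed from the DP format field when
#' present.
#'
#' @param path VCF file (v4.x, plain text)
#' @param locations data.frame mapping `sample` to `location`; a missing
#'   mapping for any VCF sample is fatal. If `NULL`, sample names of the
#'   form `<pop>_i<k>` are parsed for the location.
#' @return a [geno_matrix()]; attributes `n_dropped_multiallelic` and
#'   `n_half_calls` carry the logged counts
#' @export
read_vcf <- function(path, locations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT) & fix$ALT != "." &
    !grepl(",", fix$REF) & nchar(fix$REF) > 0
  n_multi <- sum(!biallelic)
  if (n_multi > 0) {
    warning(n_multi, " non-biallelic record(s) dropped")
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  al1 <- substr(gt, 1, 1); al2 <- substr(gt, 3, 3)
  half <- xor(al1 == ".", al2 == ".")
  n_half <- sum(half, na.rm = TRUE)
  dosage <- (al1 == "1") + (al2 == "1")
  dosage[al1 == "." | al2 == "." | is.na(gt)] <- NA
  dosage <- t(dosage)  # vcfR is SNP x sample
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  depth <- if (!is.null(dp)) rowMeans(dp, na.rm = TRUE) else NA_real_
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, locus = fix$CHROM, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), depth = as.numeric(depth))
  samp <- colnames(gt)
  if (is.null(locations)) {
    loc <- sub("_i[0-9]+$", "", samp)
    if (any(loc == samp))
      stop("cannot infer locations from sample names; supply `locations`")
  } else {
    loc <- locations$location[match(samp, locations$sample)]
    if (any(is.na(loc)))
      stop("no location mapping for sample(s): ",
           paste(samp[is.na(loc)], collapse = ", "))
  }
  g <- geno_matrix(dosage, snps = snps,
                   samples = data.frame(id = samp, location = loc))
  attr(g, "n_dropped_multiallelic") <- n_multi
  attr(g, "n_half_calls") <- n_half
  g
}

#' Write a genotype matrix as a GT-only VCF v4.2
#'
#' @param g a [geno_matrix()]
#' @param path output file
#' @param seed seed recorded in the header (provenance of simulated data)
#' @return invisibly, `path`
#' @export
write_vcf <- function(g, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genoscaper synthetic landscape generator",
               if (!is.null(seed)) paste0("##genoscaperSeed=", seed),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$id), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- g$dosage
  body <- vapply(seq_len(ncol(d)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$id[j], "A", "T", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Apply the post-assembly VCF quality filters
#'
#' The documented order is fixed: (1) individuals with more than
#' `max_ind_missing` missing data removed; (2) SNPs with minor-allele count
#' below `min_mac` removed; (3) SNPs whose mean depth exceeds the
#' `depth_quantile` quantile of the retained SNP set removed (skipped with a
#' note when no depth is available); (4) SNPs with observed heterozygosity
#' above `max_obs_het` removed. Optionally (5) a per-location call-rate
#' screen (`min_loc_call_rate`, default off) mirroring the assembly-level
#' r-filter.
#'
#' @param g a [geno_matrix()]
#' @param max_ind_missing maximum tolerated missing fraction per individual
#'   (individuals at exactly the threshold are retained)
#' @param min_mac minimum minor-allele count
#' @param depth_quantile depth cutoff quantile (linear-interpolation type 7)
#' @param max_obs_het maximum per-SNP observed heterozygosity
#' @param min_loc_call_rate optional minimum fraction of genotyped
#'   individuals per location required at every location (`NULL` = off)
#' @return filtered [geno_matrix()]; attribute `filter_report` lists counts
#'   removed per rule, in order
#' @export
apply_quality_filters <- function(g, max_ind_missing = 0.30, min_mac = 3,
                                  depth_quantile = 0.99, max_obs_het = 0.7,
                                  min_loc_call_rate = NULL) {
  report <- list()
  # 1. individuals
  miss <- rowMeans(is.na(g$dosage))
  keep_ind <- miss <= max_ind_missing
  report$individuals_missing <- sum(!keep_ind)
  if (!any(keep_ind))
    stop("all individuals removed by the missing-data rule")
  g <- subset_geno(g, ind = which(keep_ind))
  # 2. minor allele count
  alt <- colSums(g$dosage, na.rm = TRUE)
  called <- 2 * colSums(!is.na(g$dosage))
  mac <- pmin(alt, called - alt)
  keep <- mac >= min_mac
  report$snps_mac <- sum(!keep)
  if (!any(keep)) stop("all SNPs removed by the minor-allele-count rule")
  g <- subset_geno(g, snp = which(keep))
  # 3. excessive depth, 99th percentile computed on the retained SNP set
  if (all(is.na(g$snps$depth))) {
    report$snps_depth <- 0L
    report$depth_note <- "no depth available; rule skipped"
  } else {
    cut <- quantile(g$snps$depth, depth_quantile, na.rm = TRUE, type = 7)
    keep <- is.na(g$snps$depth) | g$snps$depth <= cut
    report$snps_depth <- sum(!keep)
    report$depth_cutoff <- unname(cut)
    if (!any(keep)) stop("all SNPs removed by the depth rule")
    g <- subset_geno(g, snp = which(keep))
  }
  # 4. observed heterozygosity
  het <- colMeans(g$dosage == 1, na.rm = TRUE)
  keep <- het <= max_obs_het | is.nan(het)
  report$snps_obs_het <- sum(!keep)
  if (!any(keep)) stop("all SNPs removed by the heterozygosity rule")
  g <- subset_geno(g, snp = which(keep))
  # 5. optional per-location call-rate screen
  if (!is.null(min_loc_call_rate)) {
    loc <- g$samples$location
    rate <- rowsum(1 - is.na(g$dosage), loc) /
      as.vector(table(loc)[sort(unique(loc))])
    keep <- apply(rate >= min_loc_call_rate, 2, all)
    report$snps_loc_call_rate <- sum(!keep)
    if (!any(keep)) stop("all SNPs removed by the call-rate rule")
    g <- subset_geno(g, snp = which(keep))
  }
  attr(g, "filter_report") <- report
  g
}

#' Thin to one random SNP per RAD locus
#'
#' Many downstream analyses assume unlinked loci; this keeps exactly one SNP
#' per locus ID, chosen uniformly at random, deterministically under `seed`.
#'
#' @param g a [geno_matrix()]
#' @param seed integer seed
#' @return thinned [geno_matrix()]
#' @export
thin_one_snp_per_locus <- function(g, seed = 1) {
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_len(ncol(g$dosage)), g$snps$locus),
                       function(i) if (length(i) == 1) i else sample(i, 1)),
                use.names = FALSE)
  subset_geno(g, snp = sort(idx))
}

#' Per-location minor-allele frequency matrix
#'
#' The minor allele is defined globally on the dataset given (post-filter);
#' per location, the frequency of that allele among called genotypes.
#'
#' @param g a [geno_matrix()]
#' @return list: `freq` (locations x SNPs; `NA` where a location has no
#'   calls), `n_alleles` (called allele counts per cell), `minor_is_alt`
#'   (logical per SNP)
#' @export
pop_allele_freqs <- function(g) {
  loc <- g$samples$location
  locs <- sort(unique(loc))
  d <- g$dosage
  alt_tot <- colSums(d, na.rm = TRUE)
  called_tot <- 2 * colSums(!is.na(d))
  minor_is_alt <- alt_tot / called_tot <= 0.5
  alt <- rowsum(ifelse(is.na(d), 0L, d), loc)[locs, , drop = FALSE]
  n2 <- 2 * rowsum((!is.na(d)) + 0L, loc)[locs, , drop = FALSE]
  freq_alt <- ifelse(n2 > 0, alt / n2, NA_real_)
  freq <- sweep(freq_alt, 2, minor_is_alt, function(f, m) ifelse(m, f, 1 - f))
  freq <- ifelse(n2 > 0, freq, NA_real_)
  rownames(freq) <- rownames(n2) <- locs
  colnames(freq) <- colnames(n2) <- g$snps$id
  list(freq = freq, n_alleles = n2, minor_is_alt = minor_is_alt)
}
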