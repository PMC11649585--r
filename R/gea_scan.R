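# Redundancy-analysis genome scan: VIF screen, constrained ordination,
# permutation tests for axis significance, the 3-standard-deviation outlier
# rule, and merging with externally supplied candidate lists.

#' Iterative variance-inflation-factor screen
#'
#' Drops the highest-VIF predictor until all `VIF_j = 1 / (1 - R2_j)`
#' (predictor j regressed on the others) fall below the threshold.
#' Perfectly collinear predictors (infinite VIF) are dropped first.
#'
#' @param env data.frame/matrix of standardized predictors (>= 2 columns)
#' @param threshold VIF cutoff (default 10)
#' @return list: `retained` (column names), `vif` (final VIF values),
#'   `dropped` (in drop order)
#' @export
vif_screen <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) stop("need at least 2 predictors")
  dropped <- character(0)
  vif_of <- function(df) {
    vapply(seq_along(df), function(j) {
      # perfect fits are expected for collinear inputs and handled below
      r2 <- suppressWarnings(
        summary(lm(df[[j]] ~ ., data = df[-j]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  repeat {
    if (ncol(env) == 1) break
    v <- vif_of(env)
    if (all(v < threshold)) break
    worst <- which.max(v)
    dropped <- c(dropped, names(env)[worst])
    env <- env[-worst]
  }
  v <- if (ncol(env) >= 2) vif_of(env) else setNames(1, names(env))
  list(retained = names(env), vif = setNames(v, names(env)),
       dropped = dropped)
}

#' Fit a redundancy analysis of dosages on environmental predictors
#'
#' The response (individual dosages, mean-imputed and centered — or a
#' population frequency matrix) is regressed column-wise on the centered
#' predictors; the fitted values are eigen-decomposed. Eigenvalues are
#' variances explained per constrained axis (non-increasing) and
#' constrained + residual variance equals total variance.
#'
#' @param y individuals x SNPs matrix (missing values mean-imputed) or a
#'   [geno_matrix()]
#' @param env predictor data.frame/matrix at the same rows; standardized
#'   internally
#' @return list of class `rda_fit`: `eigenvalues`, `loadings` (SNP x axis),
#'   `site_scores`, `constrained_variance`, `total_variance`, plus the
#'   pieces needed to refit under permutation
#' @export
rda_fit <- function(y, env) {
  if (inherits(y, "geno_matrix")) y <- y$dosage
  y <- as.matrix(y); storage.mode(y) <- "double"
  if (is.null(colnames(y))) colnames(y) <- paste0("snp_", seq_len(ncol(y)))
  mu <- colMeans(y, na.rm = TRUE)
  idx <- which(is.na(y), arr.ind = TRUE)
  if (nrow(idx)) y[idx] <- mu[idx[, 2]]
  X <- scale(as.matrix(env))
  n <- nrow(y)
  if (n != nrow(X)) stop("response and predictors differ in rows")
  if (n <= ncol(X)) stop("need more rows than predictors")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("predictors are rank deficient (rank ", qx$rank, " < ",
            ncol(X), ")")
  Yc <- scale(y, scale = FALSE)
  Q1 <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  fitted <- Q1 %*% crossprod(Q1, Yc)
  sv <- svd(fitted)
  k <- qx$rank
  eig <- sv$d[seq_len(k)]^2 / (n - 1)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(y)
  colnames(loadings) <- paste0("RDA", seq_len(k))
  structure(list(
    eigenvalues = eig,
    loadings = loadings,
    site_scores = sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                            k, k),
    constrained_variance = sum(fitted^2) / (n - 1),
    total_variance = sum(Yc^2) / (n - 1),
    Q1 = Q1, Yc = Yc, y = y, env = X, n = n), class = "rda_fit")
}

#' Permutation significance of sequential RDA axes
#'
#' Rows of the response are permuted, the ordination refit, and each
#' sequential eigenvalue compared with its null distribution;
#' `p_k = (1 + #permuted lambda_k >= lambda_k) / (n_perm + 1)`.
#'
#' @param rda an [rda_fit()]
#' @param n_perm permutations (default 199)
#' @param seed integer seed
#' @param alpha significance level flagging axes (default 0.05)
#' @return list: `p` per axis, `significant` (indices with p <= alpha)
#' @export
significant_axes <- function(rda, n_perm = 199, seed = 1, alpha = 0.05) {
  set.seed(as.integer(seed))
  k <- length(rda$eigenvalues)
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    Yp <- rda$Yc[sample.int(rda$n), , drop = FALSE]
    d <- svd(rda$Q1 %*% crossprod(rda$Q1, Yp), nu = 0, nv = 0)$d
    lam <- d[seq_len(k)]^2 / (rda$n - 1)
    exceed <- exceed + (lam >= rda$eigenvalues)
  }
  p <- (1 + exceed) / (n_perm + 1)
  list(p = p, significant = which(p <= alpha), alpha = alpha)
}

#' Detect outlier loci on significant RDA axes
#'
#' Loadings are z-scored per significant axis; loci with `|z| > sd_threshold`
#' on at least one significant axis are flagged as potentially adaptive and
#' annotated with the environmental variable most correlated (absolute
#' Pearson) with their dosage vector.
#'
#' @param rda an [rda_fit()]
#' @param axes output of [significant_axes()] (or integer axis indices)
#' @param sd_threshold the outlier rule (default 3)
#' @param env_names names for the annotation (default from the fit)
#' @return list of class `scan_result`: `outliers` (data.frame: locus, axis,
#'   z, env), `z` (SNP x axis z-scores on significant axes), `axes`
#' @export
detect_outliers <- function(rda, axes, sd_threshold = 3, env_names = NULL) {
  sig <- if (is.list(axes)) axes$significant else as.integer(axes)
  if (length(sig) == 0)
    return(structure(list(outliers = data.frame(locus = character(0),
                                                axis = integer(0),
                                                z = numeric(0),
                                                env = character(0)),
                          z = NULL, axes = integer(0)),
                     class = "scan_result"))
  L <- rda$loadings[, sig, drop = FALSE]
  z <- scale(L)
  flag <- abs(z) > sd_threshold
  idx <- which(rowSums(flag) > 0)
  env_names <- env_names %||% colnames(rda$env) %||%
    paste0("env_", seq_len(ncol(rda$env)))
  out <- do.call(rbind, lapply(idx, function(i) {
    ax <- which.max(abs(z[i, ]))
    cors <- abs(suppressWarnings(cor(rda$y[, i], rda$env)))
    cors[is.na(cors)] <- 0
    data.frame(locus = rownames(rda$loadings)[i],
               axis = sig[ax], z = z[i, ax],
               env = env_names[which.max(cors)])
  }))
  structure(list(outliers = out %||% data.frame(),
                 z = z, axes = sig, sd_threshold = sd_threshold),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", nrow(x$outliers), "outlier loci on axes",
      paste(x$axes, collapse = ", "), "\n")
  invisible(x)
}

#' Merge scan outliers with externally supplied candidate lists
#'
#' Union of candidate loci with per-method provenance (e.g. an external
#' Bayesian F-model outlier list alongside the ordination scan).
#'
#' @param scan a `scan_result` (or character vector of locus IDs)
#' @param ... named character vectors of locus IDs from other methods
#' @param universe all valid locus IDs; unknown IDs are rejected
#' @return list: `candidates` (data.frame locus x methods flags),
#'   `counts` (per method), `n_union`, `overlap` (pairwise overlap counts)
#' @export
merge_candidates <- function(scan, ..., universe = NULL) {
  lists <- list(...)
  scan_ids <- if (inherits(scan, "scan_result")) scan$outliers$locus
  else as.character(scan)
  lists <- c(list(rda = scan_ids), lists)
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("external candidate lists must be named")
  if (!is.null(universe)) {
    for (nm in names(lists)) {
      bad <- setdiff(lists[[nm]], universe)
      if (length(bad))
        stop("unknown locus ID(s) in '", nm, "': ",
             paste(head(bad, 5), collapse = ", "))
    }
  }
  all_ids <- unique(unlist(lists))
  flags <- sapply(lists, function(l) all_ids %in% l)
  if (length(all_ids) == 1) flags <- t(flags)
  df <- data.frame(locus = all_ids, flags, row.names = NULL)
  counts <- vapply(lists, function(l) length(unique(l)), integer(1))
  ov <- outer(seq_along(lists), seq_along(lists), Vectorize(function(i, j)
    length(intersect(lists[[i]], lists[[j]]))))
  dimnames(ov) <- list(names(lists), names(lists))
  list(candidates = df, counts = counts, n_union = length(all_ids),
       overlap = ov)
}
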