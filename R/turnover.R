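# Gradient-forest-style turnover: per-SNP ensembles of regression trees on
# environmental predictors, R2-weighted permutation importance, and
# density-standardized cumulative turnover functions along each gradient.
#
# Trees are grown with rpart on bootstrap resamples; predictor randomness
# is injected per tree (random subspace) rather than per split. Conditional
# permutation importance shares credit between predictors correlated above
# the configured threshold by permuting within strata of the most
# correlated companion predictor.

#' Fit the turnover-forest model
#'
#' For each SNP an ensemble of `n_trees` regression trees is grown on
#' bootstrap resamples with a random predictor subspace per tree. SNPs with
#' positive out-of-bag R2 are retained; per-predictor importance is the
#' SNP-averaged product of the SNP's R2 and its normalized (conditional)
#' permutation importance, with non-retained SNPs contributing zero. Split improvements are collected
#' per predictor with their threshold values for [cumulative_turnover()].
#'
#' @param freqs populations x SNPs allele-frequency matrix (candidate loci)
#' @param env populations x predictors data.frame
#' @param n_trees trees per SNP (default 2000; reduce for exploratory runs)
#' @param corr_threshold absolute-correlation threshold above which
#'   predictor importances are shared conditionally (default 0.7)
#' @param seed integer seed; the model is deterministic given the seed
#' @param mtry predictors per tree (default ceiling(p / 3))
#' @param min_pops minimum populations required (default 15)
#' @return object of class `turnover_model`: `snp_r2`, `retained`,
#'   `importance` (per predictor), `splits` (data.frame: snp, predictor,
#'   threshold, improve), `env`
#' @export
fit_turnover <- function(freqs, env, n_trees = 2000, corr_threshold = 0.7,
                         seed = 1, mtry = NULL, min_pops = 15) {
  freqs <- as.matrix(freqs)
  env <- as.data.frame(env)
  n <- nrow(freqs)
  if (n < min_pops)
    stop("need at least ", min_pops, " populations (got ", n, ")")
  p <- ncol(env)
  mtry <- mtry %||% max(1L, ceiling(p / 3))
  set.seed(as.integer(seed))
  cmat <- abs(suppressWarnings(cor(env)))
  cmat[is.na(cmat)] <- 0
  snp_names <- colnames(freqs) %||% paste0("snp_", seq_len(ncol(freqs)))
  imp_raw <- matrix(0, ncol(freqs), p,
                    dimnames = list(snp_names, names(env)))
  r2 <- setNames(numeric(ncol(freqs)), snp_names)
  splits <- list()
  ctrl <- rpart::rpart.control(minsplit = 4, minbucket = 2, cp = 1e-4,
                               maxsurrogate = 0, maxcompete = 0, xval = 0)
  for (s in seq_len(ncol(freqs))) {
    y <- freqs[, s]
    ok <- !is.na(y)
    ys <- y[ok]; Xs <- env[ok, , drop = FALSE]
    ns <- length(ys)
    if (ns < min_pops || sd(ys) == 0) { r2[s] <- -Inf; next }
    oob_sum <- numeric(ns); oob_n <- numeric(ns)
    err_diff <- numeric(p)      # per-tree OOB error increase when permuted
    var_y <- var(ys)
    snp_splits <- list()
    for (t in seq_len(n_trees)) {
      bag <- sample.int(ns, ns, replace = TRUE)
      oob <- setdiff(seq_len(ns), unique(bag))
      vars <- sample.int(p, mtry)
      df <- data.frame(y = ys[bag], Xs[bag, vars, drop = FALSE])
      fit <- rpart::rpart(y ~ ., data = df, control = ctrl)
      if (nrow(fit$frame) > 1) {
        fr <- fit$frame[fit$frame$var != "<leaf>", , drop = FALSE]
        # with maxcompete = maxsurrogate = 0, fit$splits holds exactly one
        # primary split per internal node, in frame order
        snp_splits[[length(snp_splits) + 1]] <- data.frame(
          predictor = as.character(fr$var),
          threshold = unname(fit$splits[, "index"]),
          improve = fr$dev - unsplit_dev(fit, fr))
      }
      if (length(oob) >= 2) {
        nd <- Xs[oob, vars, drop = FALSE]
        pr <- predict(fit, newdata = nd)
        oob_sum[oob] <- oob_sum[oob] + pr
        oob_n[oob] <- oob_n[oob] + 1
        err_base <- mean((ys[oob] - pr)^2)
        for (v in vars) {
          nd2 <- nd
          nd2[[names(env)[v]]] <- permute_conditional(
            Xs[oob, , drop = FALSE], v, cmat, corr_threshold)
          pr2 <- predict(fit, newdata = nd2)
          # trees without v contribute an exact zero, so summing over the
          # trees that carry v and dividing by the full tree count is the
          # standard all-trees permutation average
          err_diff[v] <- err_diff[v] + mean((ys[oob] - pr2)^2) - err_base
        }
      }
    }
    seen <- oob_n > 0
    if (!any(seen)) { r2[s] <- -Inf; next }
    pred <- oob_sum[seen] / oob_n[seen]
    sse <- sum((ys[seen] - pred)^2)
    sst <- sum((ys[seen] - mean(ys[seen]))^2)
    r2[s] <- 1 - sse / sst
    # error increase on the R2 scale, floored at zero
    imp_raw[s, ] <- pmax(0, err_diff / n_trees / var_y)
    if (length(snp_splits)) {
      sdf <- do.call(rbind, snp_splits)
      sdf$snp <- snp_names[s]
      splits[[length(splits) + 1]] <- sdf
    }
  }
  retained <- which(r2 > 0)
  if (length(retained) == 0) {
    warning("no SNP with positive out-of-bag R2; empty turnover model")
    importance <- setNames(rep(0, p), names(env))
  } else {
    norm <- imp_raw[retained, , drop = FALSE]
    rs <- rowSums(norm)
    norm[rs > 0, ] <- norm[rs > 0, , drop = FALSE] / rs[rs > 0]
    # averaged over every fitted SNP; SNPs without predictive value
    # contribute zero, so pure-noise panels give near-zero importance
    importance <- colSums(norm * r2[retained]) / length(r2)
  }
  splits <- if (length(splits)) do.call(rbind, splits) else
    data.frame(predictor = character(0), threshold = numeric(0),
               improve = numeric(0), snp = character(0))
  structure(list(snp_r2 = r2, retained = snp_names[retained],
                 importance = importance, splits = splits, env = env,
                 n_trees = n_trees, corr_threshold = corr_threshold,
                 seed = seed),
            class = "turnover_model")
}

# Deviance of the children of each internal node (for split improvement).
unsplit_dev <- function(fit, fr) {
  vapply(rownames(fr), function(nd) {
    kids <- c(2 * as.numeric(nd), 2 * as.numeric(nd) + 1)
    sum(fit$frame$dev[match(as.character(kids), rownames(fit$frame))],
        na.rm = TRUE)
  }, numeric(1))
}

# Permute a predictor; when companions correlate above the threshold,
# permute within quartile strata of the most correlated companion
# (conditional-importance convention).
permute_conditional <- function(X, v, cmat, corr_threshold) {
  x <- X[[v]]
  comp <- which(cmat[v, ] >= corr_threshold & seq_len(ncol(X)) != v)
  if (length(comp) == 0 || length(x) < 8) return(sample(x))
  cv <- comp[which.max(cmat[v, comp])]
  strata <- cut(rank(X[[cv]], ties.method = "first"),
                breaks = 4, labels = FALSE)
  out <- x
  for (g in unique(strata)) {
    i <- which(strata == g)
    out[i] <- x[i][sample.int(length(i))]
  }
  out
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("turnover_model:", length(x$retained), "of", length(x$snp_r2),
      "SNPs retained (positive OOB R2)\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Cumulative turnover function along one predictor
#'
#' Split improvements are binned at observed split thresholds,
#' density-standardized by the data density along the gradient, cumulatively
#' summed, and rescaled so the terminal value equals the predictor's
#' R2-weighted importance.
#'
#' @param model a [fit_turnover()] model
#' @param predictor predictor name
#' @param n_bins number of bins over the predictor range (default 50)
#' @return data.frame (threshold, cumulative), a monotone step function
#'   starting at 0 and ending at the predictor's importance
#' @export
cumulative_turnover <- function(model, predictor, n_bins = 50) {
  if (!predictor %in% names(model$importance))
    stop("predictor not in model: ", predictor)
  imp <- model$importance[[predictor]]
  x <- model$env[[predictor]]
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  sp <- model$splits[model$splits$predictor == predictor &
                       model$splits$snp %in% model$retained, , drop = FALSE]
  if (imp <= 0 || nrow(sp) == 0) {
    return(data.frame(threshold = br, cumulative = 0))
  }
  bin_of <- function(v) pmin(pmax(findInterval(v, br,
                                               rightmost.closed = TRUE), 1),
                             n_bins)
  imp_bins <- tapply(pmax(sp$improve, 0), bin_of(sp$threshold), sum)
  raw <- numeric(n_bins)
  raw[as.integer(names(imp_bins))] <- imp_bins
  dens <- tabulate(bin_of(x), nbins = n_bins)
  std <- ifelse(dens > 0, raw / pmax(dens, 1), 0)
  cum <- cumsum(std)
  if (max(cum) > 0) cum <- cum / max(cum) * imp
  data.frame(threshold = br, cumulative = c(0, cum))
}
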