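# Generalized dissimilarity modeling: site-pair assembly, monotone
# I-spline regression with a negative-exponential link fit by IRLS +
# non-negative least squares, predictor transformation, model comparison,
# and genomic offset under changed environments.

#' Bray-Curtis dissimilarity between frequency rows
#'
#' @param freqs sites x loci matrix of allele frequencies
#' @return symmetric matrix of Bray-Curtis dissimilarities in `[0, 1]`
#' @export
bray_curtis <- function(freqs) {
  f <- as.matrix(freqs)
  n <- nrow(f)
  out <- matrix(0, n, n, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(f[i, ]) & !is.na(f[j, ])
    s <- sum(f[i, ok] + f[j, ok])
    out[i, j] <- out[j, i] <- if (s == 0) 0 else
      sum(abs(f[i, ok] - f[j, ok])) / s
  }
  out
}

#' Assemble the GDM site-pair table
#'
#' Response = Bray-Curtis dissimilarity on (candidate-locus) allele
#' frequencies by default; any pairwise matrix (an externally computed
#' genetic distance, e.g. scaled F_ST) can be passed instead. Each matrix
#' predictor (geographic distance, habitat resistance, ...) is attached as
#' a pairwise-distance column.
#'
#' @param freqs sites x loci allele-frequency matrix (rows named by site),
#'   or `NULL` when `response` is given
#' @param env sites x predictors data.frame/matrix (rows aligned with
#'   `freqs`)
#' @param matrix_predictors named list of [pairwise_matrix()] objects
#'   aligned to the same sites
#' @param response optional precomputed site x site dissimilarity matrix in
#'   `[0, 1]` overriding the Bray-Curtis default
#' @param weights per-pair weights (default 1)
#' @return list of class `site_pair_table`: `pairs` (one row per unordered
#'   pair), `env_names`, `matrix_names`, `sites`
#' @export
assemble_site_pairs <- function(freqs, env, matrix_predictors = list(),
                                response = NULL, weights = NULL) {
  env <- as.data.frame(env)
  sites <- rownames(env) %||% rownames(freqs) %||%
    paste0("site_", seq_len(nrow(env)))
  rownames(env) <- sites
  D <- if (is.null(response)) bray_curtis(freqs) else as.matrix(response)
  if (any(D < -1e-9 | D > 1 + 1e-9, na.rm = TRUE))
    stop("response dissimilarities must lie in [0, 1]")
  n <- nrow(env)
  if (nrow(D) != n) stop("response does not match sites")
  for (nm in names(matrix_predictors))
    if (nrow(matrix_predictors[[nm]]) != n)
      stop("matrix predictor '", nm, "' does not match sites")
  ij <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- data.frame(s1 = sites[ij[, 1]], s2 = sites[ij[, 2]],
                      distance = D[ij],
                      weight = weights %||% 1)
  for (p in names(env)) {
    pairs[[paste0(p, "_s1")]] <- env[ij[, 1], p]
    pairs[[paste0(p, "_s2")]] <- env[ij[, 2], p]
  }
  for (m in names(matrix_predictors))
    pairs[[m]] <- as.matrix(matrix_predictors[[m]])[ij]
  structure(list(pairs = pairs, env_names = names(env),
                 matrix_names = names(matrix_predictors) %||% character(0),
                 sites = sites, env = env,
                 matrix_predictors = matrix_predictors),
            class = "site_pair_table")
}

# I-spline design matrix for a site-pair table given per-predictor bases.
# Env predictors contribute |I(x1) - I(x2)| per basis function; matrix
# predictors contribute I(d) on the raw pairwise distance.
gdm_design <- function(sp, bases, predictors) {
  blocks <- lapply(predictors, function(p) {
    b <- bases[[p]]
    if (p %in% sp$env_names) {
      abs(ispline_eval(b, sp$pairs[[paste0(p, "_s1")]]) -
            ispline_eval(b, sp$pairs[[paste0(p, "_s2")]]))
    } else {
      ispline_eval(b, sp$pairs[[p]])
    }
  })
  X <- do.call(cbind, c(list(intercept = rep(1, nrow(sp$pairs))), blocks))
  colnames(X) <- c("intercept", unlist(lapply(predictors, function(p)
    paste0(p, "_I", seq_len(bases[[p]]$n_basis)))))
  X
}

gdm_deviance <- function(y, mu, w = 1) {
  eps <- 1e-9
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(w * (t1 + t2))
}

#' Fit a generalized dissimilarity model
#'
#' Model: `d_hat = 1 - exp(-eta)`, `eta = alpha + sum_j sum_k beta_jk *
#' |I_jk(x1_j) - I_jk(x2_j)|` (matrix predictors enter their splines on the
#' raw pairwise distance), all coefficients and the intercept non-negative.
#' Fitting is iteratively reweighted least squares with an inner
#' non-negative least-squares solve and binomial-type deviance; convergence
#' at relative deviance change < 1e-6 (max 100 iterations). Predictors
#' whose coefficients are all zero are reported as not selected.
#'
#' @param sp a [assemble_site_pairs()] table
#' @param predictors predictor names to include (default: all env + matrix)
#' @param n_knots,order I-spline knots (at evenly spaced quantiles) and
#'   order per predictor
#' @return object of class `gdm_model`: `intercept`, `coefficients` (named
#'   list per predictor), `heights` (spline height = coefficient sum),
#'   `bases`, deviances and `pct_deviance_explained`, `selected`,
#'   `converged`
#' @export
fit_gdm <- function(sp, predictors = NULL, n_knots = 3, order = 2) {
  stopifnot(inherits(sp, "site_pair_table"))
  predictors <- predictors %||% c(sp$env_names, sp$matrix_names)
  bad <- setdiff(predictors, c(sp$env_names, sp$matrix_names))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  bases <- lapply(setNames(predictors, predictors), function(p) {
    vals <- if (p %in% sp$env_names)
      c(sp$pairs[[paste0(p, "_s1")]], sp$pairs[[paste0(p, "_s2")]])
    else sp$pairs[[p]]
    ispline_basis_for(vals, n_knots = n_knots, order = order)
  })
  X <- gdm_design(sp, bases, predictors)
  y <- sp$pairs$distance
  w <- sp$pairs$weight
  if (nrow(X) < 2 * ncol(X))
    warning("fewer than 2x more site pairs than coefficients")
  coefs <- c(max(1e-4, -log(1 - min(mean(y), 0.99))), numeric(ncol(X) - 1))
  eta <- as.vector(X %*% coefs)
  dev <- gdm_deviance(y, 1 - exp(-eta), w)
  null_dev <- gdm_deviance(y, mean(y), w)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(100)) {
    mu <- 1 - exp(-eta)
    mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    dmu <- exp(-eta)                     # d mu / d eta
    V <- mu_c * (1 - mu_c)
    z <- eta + (y - mu) / pmax(dmu, 1e-8)
    ww <- w * dmu^2 / V
    sw <- sqrt(ww)
    fit <- pracma::lsqnonneg(sw * X, sw * z)
    coefs_new <- fit$x
    eta_new <- as.vector(X %*% coefs_new)
    dev_new <- gdm_deviance(y, 1 - exp(-eta_new), w)
    step_ok <- is.finite(dev_new)
    if (step_ok) {
      # relative to the null deviance so a near-perfect fit also terminates
      rel <- abs(dev - dev_new) / max(dev, 1e-6 * null_dev, 1e-12)
      coefs <- coefs_new; eta <- eta_new; dev <- dev_new
      trace <- c(trace, dev)
      if (rel < 1e-6) { converged <- TRUE; break }
    } else break
  }
  if (!converged && length(trace) >= 100)
    warning("GDM IRLS did not converge in 100 iterations")
  co <- setNames(vector("list", length(predictors)), predictors)
  at <- 1
  for (p in predictors) {
    nb <- bases[[p]]$n_basis
    co[[p]] <- coefs[at + seq_len(nb)]
    at <- at + nb
  }
  heights <- vapply(co, sum, numeric(1))
  structure(list(intercept = coefs[1], coefficients = co,
                 heights = heights, bases = bases,
                 predictors = predictors,
                 env_names = intersect(predictors, sp$env_names),
                 matrix_names = intersect(predictors, sp$matrix_names),
                 null_deviance = null_dev, deviance = dev,
                 pct_deviance_explained = 100 * (1 - dev / null_dev),
                 selected = names(heights)[heights > 1e-8],
                 converged = converged, trace = trace),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("gdm_model: %.2f%% deviance explained; intercept %.3f\n",
              x$pct_deviance_explained, x$intercept))
  cat("spline heights:\n")
  print(round(x$heights, 4))
  if (length(setdiff(x$predictors, x$selected)))
    cat("not selected:", paste(setdiff(x$predictors, x$selected),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Predict pairwise dissimilarities from a fitted GDM
#'
#' @param model a [fit_gdm()] model
#' @param sp a [assemble_site_pairs()] table carrying the model's predictors
#' @return vector of predicted dissimilarities in `[0, 1)` aligned with
#'   `sp$pairs`
#' @export
predict_gdm <- function(model, sp) {
  X <- gdm_design(sp, model$bases, model$predictors)
  coefs <- c(model$intercept, unlist(model$coefficients[model$predictors]))
  1 - exp(-as.vector(X %*% coefs))
}

#' GDM-predicted dissimilarity matrix among sites
#'
#' @param model a [fit_gdm()] model
#' @param env sites x predictors table
#' @param matrix_predictors named list of aligned [pairwise_matrix()]
#'   objects for the model's matrix predictors
#' @return symmetric matrix of predicted dissimilarities
#' @export
predict_gdm_matrix <- function(model, env, matrix_predictors = list()) {
  env <- as.data.frame(env)[, model$env_names, drop = FALSE]
  n <- nrow(env)
  sp <- assemble_site_pairs(NULL, env,
                            matrix_predictors =
                              matrix_predictors[model$matrix_names],
                            response = matrix(0, n, n))
  pred <- predict_gdm(model, sp)
  out <- matrix(0, n, n)
  out[upper.tri(out)] <- pred
  out <- out + t(out)
  ids <- rownames(env) %||% paste0("site_", seq_len(n))
  dimnames(out) <- list(ids, ids)
  out
}

#' Transform environmental rasters through the fitted splines
#'
#' Per cell and predictor `j`: `f_j(x) = sum_k beta_jk * I_jk(x)`, monotone
#' in `x` with range `[0, height_j]`. Zero-coefficient predictors yield
#' all-zero layers. Nodata propagates.
#'
#' @param model a [fit_gdm()] model
#' @param env_stack named list of [grid_raster()] layers covering the
#'   model's environmental predictors
#' @return named list of transformed [grid_raster()] layers
#' @export
transform_predictors <- function(model, env_stack) {
  missing_p <- setdiff(model$env_names, names(env_stack))
  if (length(missing_p))
    stop("raster stack lacks predictor(s): ",
         paste(missing_p, collapse = ", "))
  out <- list()
  for (p in model$env_names) {
    r <- env_stack[[p]]
    v <- as.vector(r$values)
    f <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    f[ok] <- as.vector(ispline_eval(model$bases[[p]], v[ok]) %*%
                         model$coefficients[[p]])
    out[[p]] <- grid_raster(matrix(f, nrow(r$values)), xll = r$xll,
                            yll = r$yll, cellsize = r$cellsize, crs = r$crs)
  }
  out
}

#' Transform a table of environmental values through the fitted splines
#'
#' @param model a [fit_gdm()] model
#' @param env sites/cells x predictors table
#' @return matrix of transformed values (columns = env predictors)
#' @export
transform_env_table <- function(model, env) {
  env <- as.data.frame(env)
  sapply(model$env_names, function(p)
    as.vector(ispline_eval(model$bases[[p]], env[[p]]) %*%
                model$coefficients[[p]]))
}

#' Genomic offset between current and future environments
#'
#' `offset(cell) = 1 - exp(-sum_j |f_j(x_future) - f_j(x_current)|)`; the
#' intercept is excluded so identical climates give exactly zero. Values in
#' `[0, 1)`; nodata propagates.
#'
#' @param model a [fit_gdm()] model
#' @param current,future aligned named raster stacks
#' @return offset [grid_raster()]
#' @export
genomic_offset <- function(model, current, future) {
  fc <- transform_predictors(model, current)
  ff <- transform_predictors(model, future)
  acc <- matrix(0, nrow(fc[[1]]$values), ncol(fc[[1]]$values))
  for (p in model$env_names) {
    check_same_grid(fc[[p]], ff[[p]])
    acc <- acc + abs(ff[[p]]$values - fc[[p]]$values)
  }
  r1 <- fc[[1]]
  grid_raster(1 - exp(-acc), xll = r1$xll, yll = r1$yll,
              cellsize = r1$cellsize, crs = r1$crs)
}

#' Compare GDM predictor configurations
#'
#' Refits the model on each predictor subset against the same response and
#' tabulates percent deviance explained; the best-fitting model is flagged.
#'
#' @param sp a [assemble_site_pairs()] table
#' @param subsets named list of predictor-name vectors
#' @return data.frame (model, n_predictors, pct_deviance_explained, best)
#'   with the fitted models in attribute `models`
#' @export
compare_models <- function(sp, subsets) {
  fits <- lapply(subsets, function(pr) fit_gdm(sp, predictors = pr))
  dev <- vapply(fits, function(f) f$pct_deviance_explained, numeric(1))
  out <- data.frame(model = names(subsets),
                    n_predictors = vapply(subsets, length, integer(1)),
                    pct_deviance_explained = dev,
                    best = seq_along(dev) == which.max(dev),
                    row.names = NULL)
  attr(out, "models") <- fits
  out
}
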