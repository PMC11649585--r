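test_that("I-spline basis hits its boundary values and is monotone", {
  b <- ispline_basis(c(0, 0.4, 1), order = 2)
  expect_equal(b$n_basis, 3)
  v0 <- ispline_eval(b, 0)
  v1 <- ispline_eval(b, 1)
  expect_equal(unname(v0[1, ]), c(0, 0, 0))
  expect_equal(unname(v1[1, ]), c(1, 1, 1))
  # clamping outside the knot range
  expect_equal(ispline_eval(b, -5), v0)
  expect_equal(ispline_eval(b, 7), v1)
  # monotone non-decreasing over a fine grid
  g <- ispline_eval(b, seq(0, 1, length.out = 400))
  expect_true(all(diff(g[, 1]) >= -1e-12))
  expect_true(all(diff(g[, 2]) >= -1e-12))
  expect_true(all(diff(g[, 3]) >= -1e-12))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("I-splines equal the naive quadrature of their M-splines", {
  b <- ispline_basis(c(-1, 0.3, 2), order = 2)
  Tm <- genoscaper:::aug_knots(b$knots, b$order)
  xs <- seq(-1, 2, length.out = 23)
  got <- ispline_eval(b, xs)
  # oracle: dense trapezoid integration of the M-spline, independent path
  grid <- seq(-1, 2, length.out = 20001)
  M <- genoscaper:::mspline_eval(grid, Tm, b$order)
  h <- diff(grid)[1]
  for (i in seq_len(b$n_basis)) {
    cumI <- c(0, cumsum((M[-1, i] + M[-nrow(M), i]) / 2 * h))
    want <- approx(grid, cumI, xout = xs)$y
    expect_equal(got[, i], want, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("site-pair assembly produces Bray-Curtis responses", {
  f <- rbind(a = c(0.2, 0.8, 0.5), b = c(0.2, 0.8, 0.5),
             c = c(1, 0, 0))
  env <- data.frame(t1 = c(0, 1, 2), t2 = c(5, 5, 4),
                    row.names = c("a", "b", "c"))
  sp <- assemble_site_pairs(f, env)
  expect_equal(nrow(sp$pairs), 3)               # n(n-1)/2
  d_ab <- sp$pairs$distance[sp$pairs$s1 == "a" & sp$pairs$s2 == "b"]
  expect_equal(d_ab, 0)                         # identical rows
  # orthogonal frequency vectors -> Bray-Curtis 1
  f2 <- rbind(a = c(1, 0), b = c(0, 1))
  sp2 <- assemble_site_pairs(f2, env[1:2, ])
  expect_equal(sp2$pairs$distance, 1)
  expect_error(assemble_site_pairs(NULL, env, response = matrix(2, 3, 3)),
               "\\[0, 1\\]")
})


test_that("GDM recovers known spline heights and drops the inactive predictor", {
  tr <- simulate_gdm_truth(1)
  sp <- assemble_site_pairs(NULL, tr$env, response = tr$D)
  fit <- fit_gdm(sp)
  expect_gt(fit$pct_deviance_explained, 99)
  expect_equal(unname(fit$heights["p1"]), 0.5, tolerance = 0.05 / 0.5)
  expect_equal(unname(fit$heights["p2"]), 1.0, tolerance = 0.05)
  expect_lt(unname(fit$heights["p3"]), 0.05)
  expect_false("p3" %in% fit$selected || fit$heights["p3"] >= 0.05)
  # predictions stay inside [0, 1)
  pr <- predict_gdm(fit, sp)
  expect_true(all(pr >= 0 & pr < 1))
})

test_that("degenerate and invariance properties of the GDM fit", {
  tr <- simulate_gdm_truth(2, n_sites = 30)
  # all responses equal: intercept-only model, all beta 0
  spc <- assemble_site_pairs(NULL, tr$env,
                             response = 0.3 * (1 - diag(30)))
  fitc <- fit_gdm(spc)
  expect_true(all(unlist(fitc$coefficients) < 1e-6))
  expect_equal(1 - exp(-fitc$intercept), 0.3, tolerance = 1e-4)
  # deviance explained invariant to affine rescaling of a raw predictor
  sp1 <- assemble_site_pairs(NULL, tr$env, response = tr$D)
  env2 <- tr$env; env2$p1 <- env2$p1 * 37 - 5
  sp2 <- assemble_site_pairs(NULL, env2, response = tr$D)
  f1 <- fit_gdm(sp1); f2 <- fit_gdm(sp2)
  expect_equal(f1$pct_deviance_explained, f2$pct_deviance_explained,
               tolerance = 1e-6)
  # adding an irrelevant noise predictor barely changes the fit
  deltas <- sapply(1:10, function(s) {
    t2 <- simulate_gdm_truth(s + 10, n_sites = 12, noise = 0.02)
    e2 <- t2$env; set.seed(s); e2$junk <- rnorm(12)
    spa <- assemble_site_pairs(NULL, t2$env, response = t2$D)
    spb <- assemble_site_pairs(NULL, e2, response = t2$D)
    fit_gdm(spb)$pct_deviance_explained -
      fit_gdm(spa)$pct_deviance_explained
  })
  expect_lt(mean(abs(deltas)), 1)
})

test_that("spline transforms, the 1-predictor identity, and offset behave", {
  tr <- simulate_gdm_truth(3)
  sp <- assemble_site_pairs(NULL, tr$env, response = tr$D)
  fit <- fit_gdm(sp)
  # raster transform: zero-coefficient predictor -> all-zero layer;
  # value at the max knot equals the spline height
  mk <- function(v) grid_raster(matrix(v, 1))
  stack <- list(p1 = mk(tr$env$p1), p2 = mk(tr$env$p2), p3 = mk(tr$env$p3))
  tf <- transform_predictors(fit, stack)
  expect_equal(max(tf$p3$values), 0, tolerance = 1e-8)
  expect_equal(max(tf$p2$values),
               unname(fit$heights["p2"]), tolerance = 1e-8)
  expect_true(all(diff(tf$p1$values[1, order(tr$env$p1)]) >= -1e-12))
  # 1-predictor case: |f(x1) - f(x2)| equals eta - alpha
  fit1 <- fit_gdm(sp, predictors = "p2")
  ft <- transform_env_table(fit1, tr$env)
  i <- 5; j <- 17
  spij <- assemble_site_pairs(NULL, tr$env[c(i, j), ],
                              response = matrix(0, 2, 2))
  eta_ij <- -log(1 - predict_gdm(fit1, spij))
  expect_equal(unname(abs(ft[i, "p2"] - ft[j, "p2"])),
               unname(eta_ij - fit1$intercept), tolerance = 1e-8)
  # offset: zero when future = current, in [0, 1), monotone in shift size
  off0 <- genomic_offset(fit, stack, stack)
  expect_true(all(off0$values == 0))
  shift <- function(s) {
    st <- stack
    st$p2$values <- st$p2$values + s
    genomic_offset(fit, stack, st)$values
  }
  o1 <- shift(0.1); o2 <- shift(0.3)
  expect_true(all(o2 >= o1 - 1e-12))
  expect_true(all(o2 >= 0 & o2 < 1))
  # nodata propagates
  st2 <- stack; st2$p1$values[1, 3] <- NA
  offn <- genomic_offset(fit, st2, st2)
  expect_true(is.na(offn$values[1, 3]))
})

test_that("model comparison is monotone for nested predictor sets", {
  tr <- simulate_gdm_truth(4, n_sites = 40, noise = 0.03)
  # attach a matrix predictor correlated with p1
  set.seed(9)
  xy <- data.frame(id = rownames(tr$env), x = tr$env$p1 * 10 + rnorm(40),
                   y = rnorm(40))
  geo <- geographic_distance_matrix(xy)
  sp <- assemble_site_pairs(NULL, tr$env,
                            matrix_predictors = list(geographic = geo),
                            response = tr$D)
  cmp <- compare_models(sp, list(
    p1 = "p1", p12 = c("p1", "p2"), p123 = c("p1", "p2", "p3"),
    all = c("p1", "p2", "p3", "geographic")))
  dev <- cmp$pct_deviance_explained
  expect_true(all(diff(dev[1:3]) >= -1e-6))     # nested monotone
  expect_gte(dev[4], dev[3] - 1e-6)
  expect_equal(sum(cmp$best), 1)
  # duplicated predictor adds nothing
  sp2 <- assemble_site_pairs(NULL, cbind(tr$env, p1b = tr$env$p1),
                             response = tr$D)
  d1 <- fit_gdm(sp2, predictors = c("p1", "p2", "p3"))
  d2 <- fit_gdm(sp2, predictors = c("p1", "p1b", "p2", "p3"))
  expect_equal(d1$pct_deviance_explained, d2$pct_deviance_explained,
               tolerance = 0.01)
})
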