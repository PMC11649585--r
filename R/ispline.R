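# Monotone I-spline basis (integrated M-splines, Ramsay 1988).
#
# M-splines of order k are non-negative piecewise polynomials of degree
# k - 1 integrating to 1; I-splines are their running integrals, hence
# monotone non-decreasing from 0 (at/below the first knot) to 1 (at/above
# the last). Basis values are computed by exact piecewise Gauss-Legendre
# integration of the M-spline recursion, so they are closed-form up to
# machine precision.

#' I-spline basis definition
#'
#' @param knots sorted knot positions; the default convention is 3 knots at
#'   the min / median / max of the observed predictor values, giving 3 basis
#'   functions at order 2
#' @param order spline order (2 = piecewise quadratic I-splines, default)
#' @return list of class `ispline_basis` with `knots`, `order`, `n_basis`
#' @export
ispline_basis <- function(knots, order = 2) {
  knots <- sort(as.numeric(knots))
  if (length(knots) < 2) stop("need at least 2 knots")
  if (any(duplicated(knots))) knots <- unique(knots)
  if (length(knots) < 2) stop("degenerate knot vector")
  structure(list(knots = knots, order = order,
                 n_basis = length(knots) + order - 2),
            class = "ispline_basis")
}

# Augmented knot vector for M-splines of order k.
aug_knots <- function(knots, k) {
  c(rep(knots[1], k - 1), knots, rep(knots[length(knots)], k - 1))
}

# M-spline basis matrix: length(x) rows, (length(T) - k) columns, order k
# over augmented knots T.
mspline_eval <- function(x, T, k) {
  n <- length(T) - k
  if (k == 1) {
    out <- sapply(seq_len(n), function(i) {
      upper_closed <- i == max(which(T[-length(T)] < T[length(T)]))
      inside <- x >= T[i] & (x < T[i + 1] | (upper_closed & x <= T[i + 1]))
      ifelse(inside & T[i + 1] > T[i], 1 / (T[i + 1] - T[i]), 0)
    })
    return(matrix(out, nrow = length(x)))
  }
  lower <- mspline_eval(x, T, k - 1)
  out <- matrix(0, length(x), n)
  for (i in seq_len(n)) {
    denom <- (k - 1) * (T[i + k] - T[i])
    if (denom <= 0) next
    out[, i] <- k * ((x - T[i]) * lower[, i] +
                       (T[i + k] - x) * lower[, i + 1]) / denom
  }
  out
}

#' Evaluate the I-spline basis
#'
#' Values are in `[0, 1]`, each basis function monotone non-decreasing,
#' identically 0 at/below the first knot and 1 at/above the last. Inputs
#' outside the knot range are clamped.
#'
#' @param basis an [ispline_basis()]
#' @param x numeric vector
#' @return matrix length(x) x n_basis
#' @export
ispline_eval <- function(basis, x) {
  stopifnot(inherits(basis, "ispline_basis"))
  kn <- basis$knots; k <- basis$order
  xc <- pmin(pmax(x, kn[1]), kn[length(kn)])
  # I_i(x) = running integral of the order-k M-spline; integrated exactly
  # piecewise with 3-point Gauss-Legendre (exact for degree <= 5 >= k - 1).
  Tm <- aug_knots(kn, k)
  n <- length(Tm) - k
  gn <- c(0.1127016653792583, 0.5, 0.8872983346207417)
  gw <- c(5 / 18, 8 / 18, 5 / 18)
  breaks <- kn
  # cumulative integral of each basis function at the segment breaks
  cum <- matrix(0, length(breaks), n)
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; b <- breaks[s + 1]
    seg <- (b - a) * as.vector(gw %*% mspline_eval(a + (b - a) * gn, Tm, k))
    cum[s + 1, ] <- cum[s, ] + seg
  }
  out <- matrix(0, length(xc), n)
  seg_of <- pmin(findInterval(xc, breaks, rightmost.closed = TRUE),
                 length(breaks) - 1)
  for (s in sort(unique(seg_of))) {
    sel <- which(seg_of == s)
    a <- breaks[s]
    h <- xc[sel] - a
    part <- matrix(0, length(sel), n)
    for (g in seq_along(gn)) {
      part <- part + gw[g] * mspline_eval(a + h * gn[g], Tm, k)
    }
    out[sel, ] <- cum[rep(s, length(sel)), , drop = FALSE] + h * part
  }
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- paste0("I", seq_len(n))
  out
}

#' Default basis for a predictor: knots at min / median / max
#'
#' @param x observed predictor values
#' @param n_knots number of knots (default 3, at the 0/50/100 percentiles)
#' @param order spline order
#' @return an [ispline_basis()]
#' @export
ispline_basis_for <- function(x, n_knots = 3, order = 2) {
  qs <- quantile(x, probs = seq(0, 1, length.out = n_knots), na.rm = TRUE,
                 type = 7)
  if (length(unique(qs)) < 2)
    qs <- c(qs[1], qs[1] + 1e-8)
  ispline_basis(unique(qs), order = order)
}
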