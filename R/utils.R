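# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vectorize the upper triangle of a square matrix
#'
#' Row/column order is fixed (column-major upper triangle) so that paired
#' matrices vectorize consistently.
#' @param m square matrix
#' @return numeric vector of the strictly-upper-triangle entries
#' @keywords internal
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

#' Construct a tagged pairwise distance matrix
#'
#' A `pairwise_matrix` is an ordinary symmetric numeric matrix with location
#' IDs as dimnames and a `kind` attribute (geographic, environmental,
#' least_cost, commute or genetic). Genetic matrices may hold slightly
#' negative entries (Weir-Cockerham theta); all other kinds must be
#' non-negative.
#'
#' @param m symmetric numeric matrix, zero diagonal
#' @param kind one of "geographic", "environmental", "least_cost", "commute",
#'   "genetic"
#' @param ids optional location IDs (defaults to existing dimnames)
#' @return the matrix with class `pairwise_matrix` and a `kind` attribute
#' @export
pairwise_matrix <- function(m, kind, ids = NULL) {
  kind <- match.arg(kind,
    c("geographic", "environmental", "least_cost", "commute", "genetic"))
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("pairwise matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    stop("pairwise matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-10)) stop("pairwise matrix must have zero diagonal")
  if (kind != "genetic" && any(m[is.finite(m)] < -1e-10))
    stop("negative distances in a '", kind, "' matrix")
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  structure(m, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix (", attr(x, "kind"), "), ", nrow(x), " locations\n",
      sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

# Align two or more pairwise matrices on shared, identically ordered IDs.
check_aligned <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (nrow(m) != nrow(mats[[1]]))
      stop("pairwise matrices differ in size")
    if (!is.null(ids) && !is.null(rownames(m)) && !identical(rownames(m), ids))
      stop("pairwise matrices are not aligned on the same locations")
  }
  invisible(TRUE)
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper over [mclust::adjustedRandIndex()]; 1 for identical
#' partitions (up to relabeling), ~0 in expectation for independent ones.
#'
#' @param a,b integer/factor label vectors of equal length
#' @return scalar ARI
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# Deterministic child seeds below 2^31 derived from one master seed.
derive_seed <- function(seed, i) {
  (as.integer(seed) * 1009L + as.integer(i) * 9973L) %% 2147483647L
}
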