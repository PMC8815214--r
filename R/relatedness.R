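#' Standardized genetic relationship matrix
#'
#' Computes the standardized GRM
#' `G = (1/p) * sum_s w_s w_s'` with
#' `w_s = (x_s - 2 phat_s) / sqrt(2 phat_s (1 - phat_s))`, where `phat_s` is
#' the sample allele frequency of SNP `s` and `p` the number of retained
#' (polymorphic, non-excluded) SNPs. A centered-only variant
#' (`method = "centered"`) divides the unscaled centered cross-product by the
#' mean diagonal normalizer `2 sum phat (1 - phat)`.
#'
#' @param panel A [genotype_panel()] or a dosage matrix
#'   (individuals x SNPs).
#' @param exclude Integer indices of SNPs to drop before computing the GRM
#'   (e.g. a candidate SNP, though candidates are normally never part of the
#'   background panel).
#' @param method `"standardized"` (default) or `"centered"`.
#' @return A `relatedness_model`: list with `grm`, `n_snps_used`, `ids`, and
#'   a cache for the (lazily computed) eigendecomposition.
#' @export
compute_grm <- function(panel, exclude = integer(0),
                        method = c("standardized", "centered")) {
  method <- match.arg(method)
  X <- if (inherits(panel, "genotype_panel")) panel$dosages else as.matrix(panel)
  if (length(exclude)) X <- X[, -exclude, drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite dosages in GRM input")
  n <- nrow(X)
  phat <- colMeans(X) / 2
  poly <- phat > 0 & phat < 1
  if (sum(poly) < 2L) stop("fewer than 2 polymorphic SNPs; cannot compute GRM")
  X <- X[, poly, drop = FALSE]
  phat <- phat[poly]
  p <- ncol(X)
  W <- sweep(X, 2L, 2 * phat, "-")
  if (method == "standardized") {
    W <- sweep(W, 2L, sqrt(2 * phat * (1 - phat)), "/")
    G <- tcrossprod(W) / p
  } else {
    G <- tcrossprod(W) / sum(2 * phat * (1 - phat))
  }
  structure(
    list(grm = G, n_snps_used = p,
         ids = rownames(X) %||% sprintf("ind%05d", seq_len(n)),
         cache = new.env(parent = emptyenv())),
    class = "relatedness_model"
  )
}

#' Construct a relatedness model from an existing GRM matrix
#'
#' @param grm Symmetric n x n matrix.
#' @param ids Optional sample ids.
#' @param n_snps_used Number of SNPs that entered the matrix, if known.
#' @return A `relatedness_model`.
#' @export
as_relatedness_model <- function(grm, ids = NULL, n_snps_used = NA_integer_) {
  grm <- as.matrix(grm)
  if (max(abs(grm - t(grm))) > 1e-8) stop("GRM must be symmetric")
  grm <- (grm + t(grm)) / 2
  structure(
    list(grm = grm, n_snps_used = n_snps_used,
         ids = ids %||% rownames(grm) %||% sprintf("ind%05d", seq_len(nrow(grm))),
         cache = new.env(parent = emptyenv())),
    class = "relatedness_model"
  )
}

#' @export
print.relatedness_model <- function(x, ...) {
  cat(sprintf("<relatedness_model> n = %d, SNPs used = %s\n",
              nrow(x$grm), format(x$n_snps_used)))
  invisible(x)
}

#' Eigendecomposition of a relatedness model
#'
#' Computed once on first use and cached. Eigenvalues are returned in
#' nonincreasing order; values in `[-1e-8, 0)` are clamped to zero, larger
#' negative values raise an error (they indicate corrupt input).
#'
#' @param model A `relatedness_model`.
#' @return List with `values` and orthonormal `vectors`.
#' @export
grm_eigen <- function(model) {
  stopifnot(inherits(model, "relatedness_model"))
  if (is.null(model$cache$eigen)) {
    e <- eigen(model$grm, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(1, abs(e$values[1]))) {
      stop("GRM has substantially negative eigenvalues; input looks corrupt")
    }
    e$values[e$values < 0] <- 0
    model$cache$eigen <- e
  }
  model$cache$eigen
}

#' Top principal components from a relatedness model
#'
#' The first `k` eigenvectors of the GRM scaled by the square root of their
#' eigenvalues. Sign convention: within each component the loading of
#' largest magnitude is positive; exact ties (e.g. an identity GRM) fall
#' back to the first loading being non-negative.
#'
#' @param model A `relatedness_model`.
#' @param k Number of components, `k < n` (default 5).
#' @return Numeric matrix n x k with columns `PC1..PCk`.
#' @export
top_pcs <- function(model, k = 5L) {
  e <- grm_eigen(model)
  n <- nrow(model$grm)
  if (k >= n) stop("k must be smaller than the number of individuals")
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(V, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- model$ids
  scores
}
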