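# Variant weights and region-level genetic-similarity kernels.

#' Rare-variant weighting schemes
#'
#' Per-variant weights entering the region kernel
#' \eqn{K_m = G_m W_m G_m^T / p_m}:
#' \describe{
#'   \item{uniform}{\eqn{w_j = 1}: every variant contributes equally, the
#'     infinitesimal/common-variant regime.}
#'   \item{wss}{\eqn{w_j = 1/\sqrt{MAF_j (1 - MAF_j)}}, the weighted-sum
#'     statistic form; the inverse binomial standard deviation up-weights
#'     rare variants.}
#'   \item{beta}{\eqn{w_j = dbeta(MAF_j; shape1, shape2)^2} with defaults
#'     (1, 25), i.e. \eqn{(25 (1-MAF_j)^{24})^2}; set `squared = FALSE` for
#'     the unsquared density.}
#' }
#' Both non-uniform schemes are strictly decreasing in MAF on (0, 0.5].
#'
#' @param maf minor allele frequencies in (0, 0.5]; zero MAF is an error —
#'   monomorphic variants must be excluded (or the MAF clamped, see
#'   [compute_maf()]) before weighting.
#' @param scheme weighting scheme.
#' @param shape1,shape2 beta-density parameters for `scheme = "beta"`.
#' @param squared square the beta density (default `TRUE`).
#' @return Numeric vector of strictly positive weights.
#' @examples
#' variant_weights(c(0.5, 0.01), "wss")
#' @export
variant_weights <- function(maf, scheme = c("uniform", "wss", "beta"),
                            shape1 = 1, shape2 = 25, squared = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform") return(rep(1, length(maf)))
  if (any(maf <= 0 | maf > 0.5))
    stop("MAF must lie in (0, 0.5] for '", scheme,
         "' weights; exclude monomorphic variants first")
  switch(scheme,
         wss = 1 / sqrt(maf * (1 - maf)),
         beta = {
           w <- dbeta(maf, shape1, shape2)
           if (squared) w^2 else w
         })
}

#' Eigen-design of a positive semi-definite kernel
#'
#' Decomposes `K = Q diag(lambda) Q^T`, retains eigenpairs with
#' `lambda > rel_tol * max(lambda)`, and returns the design
#' `Z = Q diag(sqrt(lambda))` so that `Z Z^T` reconstructs `K` up to the
#' discarded mass and `Z^T Z = diag(lambda)` exactly.  Truncation removes the
#' numerically null directions so `Z` has full column rank, which the
#' variational updates require.
#'
#' @param K symmetric p.s.d. matrix.
#' @param rel_tol relative eigenvalue threshold (default 1e-8).
#' @return List with `Q`, `lambda` and `Z`.  A zero kernel yields an empty
#'   (zero-column) design.
#' @export
kernel_to_design <- function(K, rel_tol = 1e-8) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel is not symmetric")
  K <- (K + t(K)) / 2
  ee <- eigen(K, symmetric = TRUE)
  lmax <- max(ee$values, 0)
  keep <- ee$values > rel_tol * lmax & ee$values > 0
  lambda <- ee$values[keep]
  Q <- ee$vectors[, keep, drop = FALSE]
  list(Q = Q, lambda = lambda,
       Z = Q %*% diag(sqrt(lambda), length(lambda)))
}

#' Build a weighted region kernel and its eigen-design
#'
#' Forms the genetic-similarity kernel of one region,
#' \eqn{K_m = A \,\mathrm{diag}(w)\, A^T / p_m}, where `A` is the (optionally
#' column-mean-centred) region dosage matrix after per-variant mean
#' imputation of missing genotypes, `w` the variant weights and `p_m` the
#' number of variants.  The eigen-design is computed from the thin factor
#' \eqn{B = A \,\mathrm{diag}(\sqrt w)/\sqrt{p_m}} via SVD (cost `n p_m^2`
#' instead of `n^3`).
#'
#' @param G dosage matrix (samples x variants) or [genotype_matrix()].
#' @param maf per-variant MAF used for the weights; defaults to MAFs of `G`.
#'   Supply founder-based MAFs to avoid family-induced frequency inflation.
#' @param weights a scheme name for [variant_weights()] or a numeric vector.
#' @param center column-mean-centre the dosages (default `TRUE`, standard
#'   GRM practice).
#' @param rel_tol eigenvalue truncation (see [kernel_to_design()]).
#' @param name region label.
#' @return List of class `region_kernel`: `K`, `Q`, `lambda`,
#'   `Z = Q diag(sqrt(lambda))`, the weights `w`, variant IDs, column centres
#'   and the train-side projector `P = B^T Q diag(lambda^{-1/2})` used for
#'   cross-kernel prediction.  Returns `NULL` (with a warning) if every
#'   variant in the region is monomorphic.
#' @export
region_kernel <- function(G, maf = NULL, weights = "wss", center = TRUE,
                          rel_tol = 1e-8, name = NULL) {
  A <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (anyNA(A)) {                     # per-variant mean imputation
    mu <- colMeans(A, na.rm = TRUE)
    idx <- which(is.na(A), arr.ind = TRUE)
    A[idx] <- mu[idx[, 2]]
  }
  poly <- apply(A, 2, function(x) length(unique(x)) > 1)
  if (!any(poly)) {
    warning("region ", name %||% "", " has only monomorphic variants; unusable")
    return(NULL)
  }
  if (!all(poly)) {     # monomorphic variants carry no signal and no weight
    A <- A[, poly, drop = FALSE]
    if (!is.null(maf)) maf <- maf[poly]
  }
  if (is.null(maf)) maf <- pmax(.fold_maf(colMeans(A) / 2), 1 / (2 * nrow(A)))
  w <- if (is.character(weights)) variant_weights(maf, weights) else
    rep_len(as.numeric(weights), ncol(A))
  names(w) <- colnames(A)
  p_m <- ncol(A)
  centers <- if (center) colMeans(A) else rep(0, p_m)
  Ac <- sweep(A, 2, centers)
  B <- sweep(Ac, 2, sqrt(w / p_m), `*`)
  sv <- svd(B)
  lmax <- max(sv$d^2, 0)
  keep <- sv$d^2 > rel_tol * lmax & sv$d > 0
  lambda <- sv$d[keep]^2
  Q <- sv$u[, keep, drop = FALSE]
  structure(list(name = name, K = tcrossprod(B),
                 Q = Q, lambda = lambda,
                 Z = Q %*% diag(sqrt(lambda), length(lambda)),
                 w = w, p_m = p_m, centers = centers,
                 variant_ids = colnames(A), center = center,
                 P = crossprod(B, Q) %*% diag(1 / sqrt(lambda), length(lambda))),
            class = "region_kernel")
}

#' @method print region_kernel
#' @export
print.region_kernel <- function(x, ...) {
  cat(sprintf("region_kernel '%s': %d variants, rank %d\n",
              x$name %||% "?", x$p_m, length(x$lambda)))
  invisible(x)
}

# Build all region kernels for a fit; returns only usable regions.
build_region_kernels <- function(G, regions, weights, center, maf_ref,
                                 rel_tol = 1e-8) {
  out <- list()
  for (nm in names(regions)) {
    vids <- intersect(regions[[nm]], colnames(G$dosages))
    if (!length(vids)) next
    sub <- G$dosages[, vids, drop = FALSE]
    # exclusion is by sample polymorphism; weights use the (clamped)
    # reference MAF, which may come from founders only
    poly <- .fold_maf(colMeans(sub, na.rm = TRUE) / 2) > 0
    if (!any(poly)) {
      warning("region '", nm, "' dropped: all variants monomorphic")
      next
    }
    rk <- region_kernel(sub[, poly, drop = FALSE],
                        maf = pmax(maf_ref[vids][poly], 1 / (2 * nrow(sub))),
                        weights = weights, center = center,
                        rel_tol = rel_tol, name = nm)
    if (!is.null(rk)) out[[nm]] <- rk
  }
  out
}
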