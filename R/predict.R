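# Prediction for new individuals.
#
# Region and familial contributions are Gaussian-process conditional means
# under the trained variational posteriors: for a kernel component with
# design Z = Q Lambda^(1/2) and posterior factor mean M, a new individual
# with train-test cross-kernel row k* receives k* Q Lambda^(-1/2) M.  For a
# training individual, k* is that row of K and the formula returns the
# fitted component exactly.  New individuals outside every training family
# receive zero familial and environmental contributions — family-design
# information only transfers within families.

#' Region effect for new individuals
#'
#' Conditional-mean prediction of one region's genetic effect:
#' \eqn{\hat g^*_m = \phi_m K^*_m Q_m \Lambda_m^{-1/2} M_m}, where the
#' cross-kernel \eqn{K^*_m = A_{new} \mathrm{diag}(w) A_{train}^T / p_m} uses
#' the training weighting/centering transforms, and \eqn{\phi_m} is the
#' region's posterior inclusion probability (model-averaged, not
#' hard-thresholded).
#'
#' @param fit a [famlmm()] fit whose region kernels were built from
#'   genotypes (via [region_kernel()]).
#' @param genotypes [genotype_matrix()] (or dosage matrix) for the new
#'   individuals; variants are matched by ID, absent variants are imputed at
#'   the training mean (zero contribution after centring).
#' @param region region name.
#' @return Numeric vector of predicted region effects.
#' @export
cross_region_effect <- function(fit, genotypes, region) {
  rk <- fit$kernels$regions[[region]]
  if (is.null(rk)) stop("region '", region, "' not in fit")
  if (is.null(rk$P)) stop("region '", region,
                          "' was supplied as a bare design; no cross-kernel info")
  st_r <- fit$state$regions[[region]]
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  A <- matrix(rep(rk$centers, each = nrow(d)), nrow(d), rk$p_m,
              dimnames = list(rownames(d), rk$variant_ids))
  hit <- intersect(rk$variant_ids, colnames(d))
  if (length(hit) < rk$p_m) {
    dropped <- setdiff(rk$variant_ids, colnames(d))
    message(sprintf("region '%s': %d training variant(s) missing from request, imputed at training mean",
                    region, length(dropped)))
  }
  A[, hit] <- d[, hit]
  if (anyNA(A)) {
    idx <- which(is.na(A), arr.ind = TRUE)
    A[idx] <- rk$centers[idx[, 2]]
  }
  Ac <- sweep(A, 2, rk$centers)
  B <- sweep(Ac, 2, sqrt(rk$w / rk$p_m), `*`)
  as.numeric(st_r$phi * B %*% (rk$P %*% st_r$M))
}

#' Familial contributions for new individuals
#'
#' For a new individual belonging to a training family, the genetic
#' surrogate is the kinship-conditional mean
#' \eqn{\hat g_f^* = K^*_{gf} Q_{gf} \Lambda_{gf}^{-1/2} M_{gf}} with
#' \eqn{K^*_{gf}} the expected-relatedness rows between the new individual
#' and the training members of its family (computed on the merged pedigree),
#' and the environmental surrogate is the family's fitted shared
#' environmental effect.  Individuals outside every training family receive
#' exactly zero for both.
#'
#' @param fit a [famlmm()] fit with familial kernels.
#' @param ids new individuals' IDs.
#' @param pedigree merged [pedigree()] containing both the training
#'   individuals and the new ones (with their parent links); used for the
#'   kinship rows.  May be omitted when only the environmental term is
#'   needed.
#' @param families family ID per new individual; defaults to lookup in
#'   `pedigree`.  Individuals whose family is not a training family are
#'   treated as unrelated.
#' @return Data frame with columns `gf` and `ef`.
#' @export
familial_effect <- function(fit, ids, pedigree = NULL, families = NULL) {
  n_new <- length(ids)
  out <- data.frame(gf = numeric(n_new), ef = numeric(n_new),
                    row.names = ids)
  gf <- fit$kernels$gf
  ef <- fit$kernels$ef
  if (is.null(gf) && is.null(ef)) return(out)
  if (is.null(families)) {
    if (is.null(pedigree)) stop("need either 'pedigree' or 'families'")
    families <- pedigree$fam[match(ids, pedigree$id)]
    if (anyNA(families))
      stop("new individual(s) absent from the merged pedigree: ",
           paste(ids[is.na(families)], collapse = ", "))
  }
  st <- fit$state

  if (!is.null(ef)) {
    col <- match(families, ef$fams)
    inside <- !is.na(col)
    out$ef[inside] <- st$ef$M[col[inside]]
  }

  if (!is.null(gf) && !is.null(pedigree)) {
    blocks <- gf$blocks
    names(blocks) <- vapply(blocks, `[[`, "", "fam")
    for (i in seq_len(n_new)) {
      blk <- blocks[[families[i]]]
      if (is.null(blk)) next                    # not a training family
      if (ids[i] %in% blk$ids) {                # training individual itself
        kstar <- kinship_matrix(
          .family_ped(pedigree, families[i]),
          ids = c(ids[i], blk$ids))[1, -1, drop = TRUE]
      } else {
        fam_ped <- .family_ped(pedigree, families[i])
        if (!ids[i] %in% fam_ped$id)
          stop("individual '", ids[i],
               "' is not in the merged pedigree for family ", families[i])
        kstar <- kinship_matrix(fam_ped,
                                ids = c(ids[i], blk$ids))[1, -1, drop = TRUE]
      }
      out$gf[i] <- sum(kstar %*% blk$W * st$gf$M[blk$cols])
    }
  }
  out
}

.family_ped <- function(ped, fam) {
  sub <- ped[ped$fam == fam, , drop = FALSE]
  class(sub) <- c("pedigree", "data.frame")
  sub
}

#' Predict outcomes for new individuals
#'
#' Combines the training mean, model-averaged isolated-variant effects,
#' region conditional means and (for members of training families) the two
#' familial surrogates:
#' \deqn{\hat Y^* = \bar y + X^* E[\Gamma\beta] + \sum_m \hat g^*_m + \hat g_f^* + \hat e_f^*.}
#' Prediction on the training samples themselves reproduces the fitted
#' values.
#'
#' @param object a [famlmm()] fit.
#' @param genotypes [genotype_matrix()] or dosage matrix for the new
#'   individuals (used for region effects, and for `X` columns when
#'   `X = NULL`).
#' @param X optional matrix of isolated-variant dosages matching the
#'   training `X` columns by name; defaults to looking the columns up in
#'   `genotypes`.  Missing columns are imputed at the training mean.
#' @param pedigree merged [pedigree()] with the new individuals' links (see
#'   [familial_effect()]).
#' @param families family ID per new individual (alternative to
#'   `pedigree` when only the environmental surrogate is needed).
#' @param type `"response"` for predicted outcomes, `"components"` for the
#'   per-component breakdown.
#' @param ... unused.
#' @return Named numeric vector, or a data frame of components.
#' @export
predict.famlmm <- function(object, genotypes = NULL, X = NULL,
                           pedigree = NULL, families = NULL,
                           type = c("response", "components"), ...) {
  type <- match.arg(type)
  st <- object$state
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    if (!is.null(genotypes)) as.matrix(genotypes) else NULL
  ids <- rownames(d) %||% rownames(X) %||%
    (if (!is.null(families)) names(families)) %||% NULL
  n_new <- if (!is.null(d)) nrow(d) else if (!is.null(X)) nrow(as.matrix(X))
  else length(families %||% ids)
  if (is.null(n_new) || n_new == 0) stop("cannot determine new individuals")
  if (is.null(ids)) ids <- paste0("new", seq_len(n_new))

  comp <- data.frame(row.names = ids)

  # isolated variants
  comp$fixed <- numeric(n_new)
  if (st$p > 0) {
    Xn <- if (!is.null(X)) as.matrix(X) else d
    if (is.null(Xn))
      stop("fit has fixed effects but no genotypes/X supplied")
    M <- matrix(rep(object$x_centers, each = n_new), n_new, st$p,
                dimnames = list(ids, object$x_names))
    hit <- intersect(object$x_names, colnames(Xn))
    M[, hit] <- Xn[, hit]
    if (anyNA(M)) {
      idx <- which(is.na(M), arr.ind = TRUE)
      M[idx] <- object$x_centers[idx[, 2]]
    }
    comp$fixed <- as.numeric(sweep(M, 2, object$x_centers) %*%
                               (st$psi * st$Mb))
  }

  for (nm in names(st$regions)) {
    comp[[paste0("region_", nm)]] <- if (!is.null(d))
      cross_region_effect(object, d, nm) else numeric(n_new)
  }

  fe <- if (!is.null(pedigree) || !is.null(families)) {
    familial_effect(object, ids, pedigree = pedigree, families = families)
  } else data.frame(gf = numeric(n_new), ef = numeric(n_new))
  comp$gf <- fe$gf
  comp$ef <- fe$ef

  if (type == "components") return(comp)
  setNames(object$y_mean + rowSums(comp), ids)
}
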