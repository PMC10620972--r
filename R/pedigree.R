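# Pedigrees, kinship and family-design kernels.
#
# A pedigree is a data frame (fam, id, father, mother, mz) kept in
# topological order: every parent precedes its children.  Founders have NA
# parents.  Monozygotic twins are declared through a shared mz-group label
# rather than duplicated genotype rows, which keeps the kinship builder
# declarative (the MZ rule is a post-processing step on the relationship
# matrix).

#' Construct and validate a pedigree
#'
#' @param records data frame with columns `fam`, `id`, `father`, `mother` and
#'   optionally `mz` (monozygotic-twin group label, `NA` when not a twin).
#'   Missing parents are `NA` or `"0"`.
#' @return A topologically sorted data frame of class `pedigree`.
#' @details Validation enforces: unique individual IDs, every named parent
#'   present in the pedigree, acyclicity (no individual is its own ancestor;
#'   a cycle aborts with the offending IDs listed) and that members of an MZ
#'   group share both parents.
#' @export
pedigree <- function(records) {
  ped <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("fam", "id", "father", "mother") %in% colnames(ped)))
    stop("pedigree needs columns fam, id, father, mother")
  if (!"mz" %in% colnames(ped)) ped$mz <- NA_character_
  for (cc in c("fam", "id", "father", "mother", "mz"))
    ped[[cc]] <- as.character(ped[[cc]])
  ped$father[ped$father %in% c("0", "")] <- NA
  ped$mother[ped$mother %in% c("0", "")] <- NA
  ped$mz[ped$mz %in% c("0", "")] <- NA
  if (anyDuplicated(ped$id))
    stop("duplicate individual ID in pedigree: ",
         ped$id[duplicated(ped$id)][1])
  parents <- stats::na.omit(c(ped$father, ped$mother))
  absent <- setdiff(parents, ped$id)
  if (length(absent))
    stop("parent(s) referenced but absent from pedigree: ",
         paste(unique(absent), collapse = ", "))

  # Kahn topological sort; leftovers form a cycle.
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order)], collapse = ", "))
  ped <- ped[order, , drop = FALSE]
  rownames(ped) <- NULL

  for (grp in unique(stats::na.omit(ped$mz))) {
    members <- ped[!is.na(ped$mz) & ped$mz == grp, , drop = FALSE]
    if (nrow(members) > 1) {
      same <- length(unique(members$father)) == 1 &&
        length(unique(members$mother)) == 1
      if (!same)
        stop("MZ group '", grp, "' members do not share both parents")
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  nfo <- sum(is.na(x$father) & is.na(x$mother))
  cat(sprintf("pedigree: %d individuals (%d founders) in %d families\n",
              nrow(x), nfo, length(unique(x$fam))))
  if (any(!is.na(x$mz)))
    cat(sprintf("  MZ groups: %d\n", length(unique(stats::na.omit(x$mz)))))
  invisible(x)
}

#' Read / write PED-style pedigree files
#'
#' Whitespace-delimited columns: family, individual, father, mother and an
#' optional MZ-group label; `0` denotes a missing (founder) parent.
#'
#' @param path file path.
#' @return [read_pedigree()] returns a [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- max(utils::count.fields(path))
  tab <- read.table(path, stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = c("NA", ""),
                    col.names = paste0("V", seq_len(nf)))
  if (ncol(tab) < 4) stop("pedigree file needs >= 4 columns")
  colnames(tab)[1:4] <- c("fam", "id", "father", "mother")
  if (ncol(tab) >= 5) colnames(tab)[5] <- "mz"
  pedigree(tab)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$fam, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ifelse(is.na(ped$mz), "0", ped$mz))
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

founder_ids <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Expected additive relationship matrix from a pedigree
#'
#' Computes the theoretical (expected) relatedness by the standard recursion
#' over a topological order: founders are mutually unrelated with diagonal 1,
#' \eqn{A_{ii} = 1 + A_{f_i m_i}/2} and \eqn{A_{ij} = (A_{f_i j} + A_{m_i j})/2}
#' for a non-founder `i` and any earlier `j`.  Members of an MZ group are set
#' identical: their mutual entry equals the diagonal.
#'
#' The default scale is the additive relationship \eqn{2\phi} (diagonal 1 for
#' non-inbred individuals); any constant rescaling is absorbed by the
#' associated variance component, so model fits are invariant to the choice.
#' `scale = "phi"` returns kinship coefficients \eqn{\phi}.
#'
#' @param ped a [pedigree()].
#' @param ids optional IDs selecting/ordering rows and columns of the result
#'   (kinship is always computed on the full pedigree first).
#' @param scale `"relationship"` (2phi, default) or `"phi"`.
#' @return Symmetric p.s.d. matrix with dimnames `ids`.
#' @export
kinship_matrix <- function(ped, ids = NULL, scale = c("relationship", "phi")) {
  scale <- match.arg(scale)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (i in seq_len(n)) {
    if (is.na(fi[i]) && is.na(mi[i])) {
      A[i, i] <- 1
    } else {
      js <- seq_len(i - 1)
      af <- if (!is.na(fi[i])) A[fi[i], js] else numeric(i - 1)
      am <- if (!is.na(mi[i])) A[mi[i], js] else numeric(i - 1)
      if (i > 1) {
        A[i, js] <- (af + am) / 2
        A[js, i] <- A[i, js]
      }
      cross <- if (!is.na(fi[i]) && !is.na(mi[i])) A[fi[i], mi[i]] else 0
      A[i, i] <- 1 + cross / 2
    }
  }
  # MZ rule: identical genomes within a group.
  for (grp in unique(stats::na.omit(ped$mz))) {
    idx <- which(!is.na(ped$mz) & ped$mz == grp)
    if (length(idx) > 1)
      A[idx, idx] <- A[idx[1], idx[1]]
  }
  if (scale == "phi") A <- A / 2
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("IDs not in pedigree: ", paste(miss, collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Shared-environment block kernel
#'
#' The shared-environment kernel is block diagonal with an all-ones block per
#' family: members of a family are exchangeable carriers of one common
#' environmental effect.  Its exact eigen-design has one column per family,
#' the 0/1 family-membership indicator (`Z Z^T = K` with eigenvalue equal to
#' the family size), so no truncation is ever needed.
#'
#' @param fam family labels, or a [pedigree()] (optionally subset via `ids`).
#' @param ids optional IDs selecting/ordering individuals.
#' @return List with dense `K`, sparse indicator design `Z`, eigenvalues
#'   `lambda` (family sizes) and the family labels `fams` (column order of
#'   `Z`).
#' @export
env_kernel <- function(fam, ids = NULL) {
  if (inherits(fam, "pedigree")) {
    ped <- fam
    if (is.null(ids)) ids <- ped$id
    fam <- ped$fam[match(ids, ped$id)]
    if (anyNA(fam)) stop("IDs not in pedigree")
  } else if (!is.null(ids)) {
    names(fam) <- names(fam) %||% ids
    fam <- fam[ids]
  }
  fam <- as.character(fam)
  fams <- unique(fam)
  Z <- Matrix::sparseMatrix(i = seq_along(fam), j = match(fam, fams),
                            x = 1, dims = c(length(fam), length(fams)),
                            dimnames = list(ids, fams))
  K <- as.matrix(Matrix::tcrossprod(Z))
  list(K = K, Z = Z, lambda = as.numeric(table(factor(fam, levels = fams))),
       fams = fams)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Family-design random-effect bases
#'
#' Builds the two family-design surrogates used by [famlmm()]: the genetic
#' surrogate from the expected relationship matrix and the environmental
#' surrogate from the block-of-ones kernel.  Both kernels are block diagonal
#' by family (individuals in different families are unrelated), so the
#' eigendecomposition is carried out family by family and assembled into one
#' sparse design \eqn{Z = Q \Lambda^{1/2}} with \eqn{Z^T Z = \Lambda}
#' diagonal, exactly the structure the variational updates exploit.
#'
#' @param ped a [pedigree()] covering at least `ids`.
#' @param ids individual IDs (row order of the designs); defaults to all
#'   pedigree members.
#' @param rel_tol relative eigenvalue truncation threshold.
#' @return List with elements `gf` (sparse `Z`, eigenvalues `lambda`, and a
#'   per-family list `blocks` carrying the projector `W = Q diag(lambda^-1/2)`
#'   and member IDs used for out-of-sample prediction) and `ef` (indicator
#'   design, see [env_kernel()]).
#' @export
familial_designs <- function(ped, ids = NULL, rel_tol = 1e-8) {
  if (is.null(ids)) ids <- ped$id
  miss <- setdiff(ids, ped$id)
  if (length(miss)) stop("IDs not in pedigree: ", paste(miss, collapse = ", "))
  fam <- ped$fam[match(ids, ped$id)]
  fams <- unique(fam)

  blocks <- vector("list", length(fams))
  trip_i <- trip_j <- trip_x <- vector("list", length(fams))
  lam_all <- vector("list", length(fams))
  col0 <- 0L
  for (k in seq_along(fams)) {
    members <- ids[fam == fams[k]]
    sub <- ped[ped$fam == fams[k], , drop = FALSE]
    class(sub) <- c("pedigree", "data.frame")
    Kf <- kinship_matrix(sub, ids = members)
    ee <- eigen(Kf, symmetric = TRUE)
    keep <- ee$values > rel_tol * max(ee$values, 0) & ee$values > 0
    lam <- ee$values[keep]
    Q <- ee$vectors[, keep, drop = FALSE]
    Zb <- Q %*% diag(sqrt(lam), length(lam))
    blocks[[k]] <- list(fam = fams[k], ids = members,
                        W = Q %*% diag(1 / sqrt(lam), length(lam)),
                        cols = col0 + seq_along(lam))
    trip_i[[k]] <- rep(match(members, ids), times = length(lam))
    trip_j[[k]] <- rep(col0 + seq_along(lam), each = length(members))
    trip_x[[k]] <- as.numeric(Zb)
    lam_all[[k]] <- lam
    col0 <- col0 + length(lam)
  }
  Zgf <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x),
                              dims = c(length(ids), col0),
                              dimnames = list(ids, NULL))
  ef <- env_kernel(fam, ids = ids)
  list(gf = list(Z = Zgf, lambda = unlist(lam_all), blocks = blocks,
                 fams = fams),
       ef = ef,
       ids = ids, fam = fam)
}
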