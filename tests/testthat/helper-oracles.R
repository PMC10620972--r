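# Independent oracles and fixture builders shared across test files.
# Each oracle is deliberately implemented by a different route than the
# package code it checks.

# --- kinship by exhaustive inheritance-pattern enumeration -------------------
# Every non-founder draws one of 2 alleles from each parent; enumerating all
# 4^(#non-founders) inheritance patterns and counting identical-by-descent
# allele matches gives the exact expected relationship 2*phi, independently
# of the tabular recursion used by kinship_matrix().  MZ group members copy
# the genome of the group's first member.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  nf_idx <- which(!(is.na(fi) & is.na(mi)))
  stopifnot(length(nf_idx) <= 6)
  founders <- which(is.na(fi) & is.na(mi))
  # founder alleles are globally distinct labels
  alle <- matrix(0L, n, 2)
  alle[founders, 1] <- seq_along(founders) * 2L - 1L
  alle[founders, 2] <- seq_along(founders) * 2L

  mz_first <- rep(NA_integer_, n)
  for (grp in unique(stats::na.omit(ped$mz))) {
    idx <- which(!is.na(ped$mz) & ped$mz == grp)
    if (length(idx) > 1) mz_first[idx[-1]] <- idx[1]
  }

  npat <- 4^length(nf_idx)
  acc <- matrix(0, n, n)
  for (pat in 0:(npat - 1)) {
    a <- alle
    bits <- pat
    for (i in nf_idx) {
      pf <- bits %% 2L; bits <- bits %/% 2L
      pm <- bits %% 2L; bits <- bits %/% 2L
      a[i, 1] <- a[fi[i], pf + 1L]
      a[i, 2] <- a[mi[i], pm + 1L]
      if (!is.na(mz_first[i])) a[i, ] <- a[mz_first[i], ]
    }
    for (i in seq_len(n)) for (j in i:n) {
      m <- sum(outer(a[i, ], a[j, ], `==`)) / 4
      acc[i, j] <- acc[i, j] + m
      acc[j, i] <- acc[i, j]
    }
  }
  A <- 2 * acc / npat
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# --- exact posterior by enumeration over (gamma, r) --------------------------
# Fixed-variance toy: y = X diag(gamma) beta + r Z U + eps with
# beta ~ N(0, sb2 I), U ~ N(0, su2 I).  For each of the 2^p * 2 binary
# configurations the model is linear-Gaussian, so the marginal likelihood
# and the posterior mean of the signal are closed-form; mixing over
# configurations gives the exact posterior predictive mean and the exact
# log marginal likelihood.
oracle_enumeration <- function(y, X, Z, theta0, wp, sb2, su2, se2) {
  n <- length(y)
  p <- ncol(X)
  ldmvnorm0 <- function(y, S) {
    ch <- chol(S)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, y, transpose = TRUE)^2))
  }
  configs <- expand.grid(rep(list(0:1), p + 1))
  logw <- numeric(nrow(configs))
  means <- matrix(0, nrow(configs), n)
  for (c_i in seq_len(nrow(configs))) {
    g <- as.numeric(configs[c_i, 1:p])
    r <- as.numeric(configs[c_i, p + 1])
    Ssig <- sb2 * tcrossprod(X %*% diag(g, p)) + r * su2 * tcrossprod(Z)
    S <- Ssig + se2 * diag(n)
    logw[c_i] <- ldmvnorm0(y, S) +
      sum(g * log(theta0) + (1 - g) * log(1 - theta0)) +
      r * log(wp) + (1 - r) * log(1 - wp)
    means[c_i, ] <- as.numeric(Ssig %*% solve(S, y))
  }
  wmax <- max(logw)
  w <- exp(logw - wmax)
  list(mean = colSums(means * w) / sum(w),
       log_ml = wmax + log(sum(w)))
}

# --- generalized-ridge / GLS closed form -------------------------------------
# With all inclusion indicators clamped at 1 and variances fixed, the joint
# posterior of the coefficients is Gaussian with mean solving one ridge
# system; the mean-field CAVI fixed point must reproduce it.
oracle_ridge <- function(y, design_list, prior_prec, se2) {
  C <- do.call(cbind, design_list)
  P <- diag(unlist(prior_prec))
  solve(crossprod(C) / se2 + P, crossprod(C, y) / se2)
}

# --- small random fixtures ---------------------------------------------------
rand_psd_design <- function(n, k) {
  B <- matrix(rnorm(n * max(k, 1)), n)
  kd <- kernel_to_design(tcrossprod(B))
  list(Z = kd$Z, lambda = kd$lambda, Q = kd$Q)
}

# a random small problem with optional X, regions, and familial designs
rand_problem <- function(n = 20, p = 3, n_regions = 2, family_size = 4,
                         with_fam = TRUE) {
  X <- if (p > 0) matrix(rnorm(n * p), n, dimnames =
                           list(NULL, paste0("x", seq_len(p)))) else NULL
  regions <- lapply(seq_len(n_regions), function(m) {
    kd <- rand_psd_design(n, sample(2:4, 1))
    list(Z = kd$Z, lambda = kd$lambda, name = paste0("r", m))
  })
  names(regions) <- vapply(regions, `[[`, "", "name")
  gf <- ef <- NULL
  if (with_fam) {
    fam <- rep(seq_len(ceiling(n / family_size)), each = family_size)[1:n]
    ids <- paste0("s", seq_len(n))
    ek <- env_kernel(as.character(fam), ids = ids)
    ef <- list(Z = ek$Z, lambda = ek$lambda)
    kd <- rand_psd_design(n, 3)
    gf <- list(Z = kd$Z, lambda = kd$lambda)
  }
  y <- rnorm(n)
  list(y = y, X = X, kernels = list(regions = regions, gf = gf, ef = ef))
}

quiet_fit <- function(...) suppressWarnings(famlmm(...))

nuclear_blocks <- function(n_fam, k = 2)
  list(list(structure = sprintf("nuclear-%d-offspring", k), n = n_fam))
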