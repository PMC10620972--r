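# Coordinate-ascent variational inference for the family-based Bayesian
# linear mixed model
#
#   y = X G(gamma) beta + sum_m Z_m r_m U_m + Z_gf U_gf + Z_ef U_ef + eps
#
# with beta_j ~ N(0, sigma_beta2), gamma_j ~ Bern(theta0), U_m ~ N(0, I s2_m),
# r_m ~ Bern(wp), U_gf ~ N(0, I s2_gf), U_ef ~ N(0, I s2_ef),
# eps ~ N(0, I s2_eps) and inverse-gamma priors on every variance.
#
# The mean-field factorisation follows q(beta) x prod q(gamma_j) x
# prod q(U_m) q(r_m) x q(U_gf) q(U_ef) x IG factors.  Every update below is
# the exact conditional-conjugate CAVI solution, so the ELBO is
# non-decreasing sweep over sweep; all designs satisfy Z^T Z = diag(lambda),
# making the Gaussian factor covariances diagonal.

.clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
.B_FLOOR <- 1e-12

#' Hyperparameters of the family-based Bayesian linear mixed model
#'
#' @param theta0 prior inclusion probability of an isolated variant effect
#'   (spike-and-slab Bernoulli), default 0.1.
#' @param sigma_beta2 slab variance of included fixed effects; fixed, not
#'   learned (the model's parameter list carries no factor for it).  Default
#'   1 on the scale of the centred outcome.
#' @param region_prob prior inclusion probability of a region effect,
#'   default 0.1 (mirroring `theta0`; the model text gives it no value).
#' @param a_region,b_region inverse-gamma prior (shape, rate) for each
#'   region variance, default (0.1, 0.1).
#' @param a_gf,b_gf,a_ef,b_ef,a_eps,b_eps inverse-gamma priors for the
#'   genetic-familial, shared-environment and residual variances; defaults
#'   (0.1, 0.1).
#' @return List of class `famlmm_hyper`.
#' @export
famlmm_hyper <- function(theta0 = 0.1, sigma_beta2 = 1, region_prob = 0.1,
                         a_region = 0.1, b_region = 0.1,
                         a_gf = 0.1, b_gf = 0.1,
                         a_ef = 0.1, b_ef = 0.1,
                         a_eps = 0.1, b_eps = 0.1) {
  h <- list(theta0 = theta0, sigma_beta2 = sigma_beta2,
            region_prob = region_prob,
            a_region = a_region, b_region = b_region,
            a_gf = a_gf, b_gf = b_gf, a_ef = a_ef, b_ef = b_ef,
            a_eps = a_eps, b_eps = b_eps)
  stopifnot(theta0 > 0, theta0 < 1, region_prob > 0, region_prob < 1,
            sigma_beta2 > 0,
            all(unlist(h[grep("^[ab]_", names(h))]) > 0))
  class(h) <- "famlmm_hyper"
  h
}

#' Fitting controls for [famlmm()]
#'
#' @param max_sweeps maximum number of full coordinate-ascent sweeps.
#' @param rel_tol convergence threshold on the relative ELBO change.
#' @param beta_block_cap largest joint Gaussian block for `q(beta)`.  With
#'   more retained variants than this, the fixed-effect posterior is updated
#'   in blocks of this size (a finer mean-field factorisation) with a
#'   warning.
#' @param clamp_inclusion fix all inclusion probabilities at 1 (no
#'   spike-and-slab selection); used for conjugate-limit checks.
#' @param phi_init initial region-inclusion probability (default 0.95, a
#'   warm start).  The factorised posterior `q(U_m) q(r_m)` has two basins
#'   for a predictive region — one with the region switched off before its
#'   effect is ever estimated — and coordinate ascent cannot leave a basin;
#'   starting near inclusion lets the first sweeps estimate each region's
#'   effect from data before the (exact) inclusion updates prune it.
#'   Set to the prior `region_prob` for a cold start.
#' @param fixed_variances optional list with any of `residual`, `regions`
#'   (scalar or per-region vector), `gf`, `ef`: the named variances are held
#'   at the given values instead of receiving inverse-gamma updates.
#' @param seed optional integer recorded in the fit (the coordinate ascent
#'   itself is deterministic).
#' @param verbose print the ELBO every 10 sweeps.
#' @return List of class `famlmm_control`.
#' @export
famlmm_control <- function(max_sweeps = 1000, rel_tol = 1e-5,
                           beta_block_cap = 5000,
                           clamp_inclusion = FALSE,
                           phi_init = 0.95,
                           fixed_variances = NULL,
                           seed = NULL, verbose = FALSE) {
  structure(list(max_sweeps = max_sweeps, rel_tol = rel_tol,
                 beta_block_cap = beta_block_cap,
                 clamp_inclusion = clamp_inclusion,
                 phi_init = phi_init,
                 fixed_variances = fixed_variances,
                 seed = seed, verbose = verbose),
            class = "famlmm_control")
}

# ---- variational state ------------------------------------------------------

# Builds the engine state: data, hyper, control and all q-distribution
# parameters at their initial values (psi = theta0, phi = region_prob, zero
# means, prior (co)variances, IG factors at the prior, and the residual IG
# rate seeded from the phenotype variance by method of moments).
famlmm_init_state <- function(yc, Xc, regions, gf, ef, hyper, control) {
  n <- length(yc)
  p <- if (is.null(Xc)) 0L else ncol(Xc)
  fv <- control$fixed_variances %||% list()
  st <- list(n = n, yc = yc, hyper = hyper, control = control,
             clamp = isTRUE(control$clamp_inclusion))

  if (p > 0) {
    st$Xc <- Xc
    st$XtX <- crossprod(Xc)
    cap <- control$beta_block_cap
    if (p > cap) {
      warning(sprintf(
        "%d fixed-effect variants exceed the joint-posterior cap (%d); using blockwise q(beta) updates",
        p, cap))
      st$blocks <- split(seq_len(p), ceiling(seq_len(p) / cap))
    } else st$blocks <- list(seq_len(p))
    st$psi <- rep(if (st$clamp) 1 else hyper$theta0, p)
    st$Mb <- numeric(p)
    st$Sb <- lapply(st$blocks, function(ix)
      diag(hyper$sigma_beta2, length(ix)))
  }
  st$p <- p

  fixed_reg <- fv$regions
  st$regions <- lapply(seq_along(regions), function(m) {
    r <- regions[[m]]
    k <- length(r$lambda)
    fixed <- !is.null(fixed_reg)
    val <- if (fixed) rep_len(fixed_reg, length(regions))[m] else NA_real_
    list(name = r$name %||% names(regions)[m] %||% paste0("region", m),
         Z = as.matrix(r$Z), lambda = r$lambda, k = k,
         M = numeric(k),
         s = rep(if (fixed) val else hyper$b_region / hyper$a_region, k),
         phi = if (st$clamp) 1 else
           .clip01(control$phi_init %||% hyper$region_prob),
         a = hyper$a_region, b = hyper$b_region,
         fixed = fixed, value = val)
  })
  names(st$regions) <- vapply(st$regions, `[[`, "", "name")

  init_fam <- function(comp, a0, b0, fixed_val) {
    if (is.null(comp)) return(NULL)
    k <- length(comp$lambda)
    fixed <- !is.null(fixed_val)
    list(Z = comp$Z, lambda = comp$lambda, k = k, M = numeric(k),
         s = rep(if (fixed) fixed_val else b0 / a0, k),
         a = a0, b = b0, fixed = fixed, value = fixed_val %||% NA_real_)
  }
  st$gf <- init_fam(gf, hyper$a_gf, hyper$b_gf, fv$gf)
  st$ef <- init_fam(ef, hyper$a_ef, hyper$b_ef, fv$ef)

  st$eps <- if (!is.null(fv$residual)) {
    list(fixed = TRUE, value = fv$residual, a = NA, b = NA)
  } else {
    list(fixed = FALSE, value = NA,
         a = hyper$a_eps,
         b = hyper$a_eps * max(stats::var(yc), 1e-8))
  }
  st$elbo_trace <- numeric(0)
  st
}

.tau <- function(x) if (x$fixed) 1 / x$value else x$a / x$b
.elog_inv <- function(x) if (x$fixed) -log(x$value) else digamma(x$a) - log(x$b)

# fitted mean of each component under q
.fit_fixed <- function(st) {
  if (st$p == 0) return(numeric(st$n))
  as.numeric(st$Xc %*% (st$psi * st$Mb))
}
.fit_region <- function(r) r$phi * as.numeric(r$Z %*% r$M)
.fit_fam <- function(f, n) if (is.null(f)) numeric(n) else
  as.numeric(f$Z %*% f$M)

# E||X Gamma beta||^2 and the variance of the fixed-effect component under q
.fixed_moments <- function(st) {
  if (st$p == 0) return(list(mean = numeric(st$n), var = 0))
  psi <- st$psi; Mb <- st$Mb
  vpm <- psi * Mb
  mean_fix <- as.numeric(st$Xc %*% vpm)
  dG <- diag(st$XtX)
  t1 <- as.numeric(crossprod(vpm, st$XtX %*% vpm)) - sum(psi^2 * dG * Mb^2)
  t2 <- 0
  for (bi in seq_along(st$blocks)) {
    ix <- st$blocks[[bi]]
    S <- st$Sb[[bi]]
    pb <- psi[ix]
    Gbb <- st$XtX[ix, ix, drop = FALSE]
    t2 <- t2 + sum(outer(pb, pb) * Gbb * S) - sum(pb^2 * diag(Gbb) * diag(S))
  }
  t3 <- sum(psi * dG * (Mb^2 + .sb_diag(st)))
  list(mean = mean_fix, var = t1 + t2 + t3 - sum(mean_fix^2))
}

.sb_diag <- function(st) {
  d <- numeric(st$p)
  for (bi in seq_along(st$blocks)) d[st$blocks[[bi]]] <- diag(st$Sb[[bi]])
  d
}

# Expected residual sum of squares E_q || y - fitted ||^2
.expected_rss <- function(st) {
  fx <- .fixed_moments(st)
  tot <- fx$mean
  v <- fx$var
  for (r in st$regions) {
    tot <- tot + .fit_region(r)
    lm2 <- sum(r$lambda * r$M^2)
    v <- v + r$phi * (1 - r$phi) * lm2 + r$phi * sum(r$lambda * r$s)
  }
  for (f in list(st$gf, st$ef)) {
    if (!is.null(f)) {
      tot <- tot + .fit_fam(f, st$n)
      v <- v + sum(f$lambda * f$s)
    }
  }
  sum((st$yc - tot)^2) + v
}

# ---- one full coordinate-ascent sweep --------------------------------------

# Updates, in fixed order, q(beta), each q(gamma_j), each (q(U_m), q(r_m))
# pair, q(U_gf), q(U_ef), then all inverse-gamma factors.  Returns the
# updated state.
cavi_sweep <- function(st) {
  n <- st$n
  hy <- st$hyper
  tau <- .tau(st$eps)

  fit_fix <- .fit_fixed(st)
  fit_reg <- lapply(st$regions, .fit_region)
  fit_gf <- .fit_fam(st$gf, n)
  fit_ef <- .fit_fam(st$ef, n)
  reg_sum <- Reduce(`+`, fit_reg, numeric(n))

  # --- q(beta): joint Gaussian per block --------------------------------
  if (st$p > 0) {
    F_nofix <- st$yc - reg_sum - fit_gf - fit_ef
    for (bi in seq_along(st$blocks)) {
      ix <- st$blocks[[bi]]
      other_fix <- fit_fix -
        as.numeric(st$Xc[, ix, drop = FALSE] %*% (st$psi[ix] * st$Mb[ix]))
      Fb <- F_nofix - other_fix
      pb <- st$psi[ix]
      Abb <- st$XtX[ix, ix, drop = FALSE] * outer(pb, pb)
      diag(Abb) <- pb * diag(st$XtX)[ix]
      prec <- tau * Abb + diag(1 / hy$sigma_beta2, length(ix))
      cf <- tryCatch(chol(prec), error = function(e)
        stop("numerical error updating q(beta): ", conditionMessage(e)))
      S <- chol2inv(cf)
      Mbb <- as.numeric(
        tau * S %*% (pb * crossprod(st$Xc[, ix, drop = FALSE], Fb)))
      if (any(!is.finite(Mbb)))
        stop("non-finite value while updating q(beta)")
      st$Sb[[bi]] <- S
      st$Mb[ix] <- Mbb
      fit_fix <- other_fix +
        as.numeric(st$Xc[, ix, drop = FALSE] %*% (pb * Mbb))
    }

    # --- q(gamma_j): sequential Bernoulli updates -----------------------
    if (!st$clamp) {
      XtF <- as.numeric(crossprod(st$Xc, F_nofix))
      dG <- diag(st$XtX)
      sdiag <- .sb_diag(st)
      vpm <- st$psi * st$Mb
      XtXvpm <- as.numeric(st$XtX %*% vpm)
      blk_of <- integer(st$p)
      for (bi in seq_along(st$blocks)) blk_of[st$blocks[[bi]]] <- bi
      lo0 <- qlogis(.clip01(hy$theta0))
      for (j in seq_len(st$p)) {
        crossM <- st$Mb[j] * (XtXvpm[j] - dG[j] * vpm[j])
        bi <- blk_of[j]
        ix <- st$blocks[[bi]]
        jl <- match(j, ix)
        Srow <- st$Sb[[bi]][jl, ]
        crossS <- sum(st$psi[ix] * st$XtX[j, ix] * Srow) -
          st$psi[j] * dG[j] * sdiag[j]
        lo <- lo0 + tau * (st$Mb[j] * XtF[j] - crossM - crossS -
                             0.5 * dG[j] * (st$Mb[j]^2 + sdiag[j]))
        if (!is.finite(lo)) stop("non-finite value while updating q(gamma)")
        new_psi <- .clip01(plogis(lo))
        delta <- (new_psi - st$psi[j]) * st$Mb[j]
        XtXvpm <- XtXvpm + st$XtX[, j] * delta
        vpm[j] <- new_psi * st$Mb[j]
        st$psi[j] <- new_psi
      }
      fit_fix <- as.numeric(st$Xc %*% vpm)
    }
  }

  # --- regions: (q(U_m), q(r_m)) pairs ----------------------------------
  R <- st$yc - fit_fix - reg_sum - fit_gf - fit_ef
  lo_r0 <- qlogis(.clip01(hy$region_prob))
  for (m in seq_along(st$regions)) {
    r <- st$regions[[m]]
    Fm <- R + fit_reg[[m]]
    tau_m <- .tau(r)
    ZtF <- as.numeric(crossprod(r$Z, Fm))
    r$s <- 1 / (tau * r$phi * r$lambda + tau_m)
    r$M <- tau * r$phi * r$s * ZtF
    if (any(!is.finite(r$M)))
      stop("non-finite value while updating q(U) for region ", r$name)
    if (!st$clamp) {
      gain <- tau * (sum(r$M * ZtF) -
                       0.5 * sum(r$lambda * (r$M^2 + r$s)))
      if (!is.finite(gain))
        stop("non-finite value while updating q(r) for region ", r$name)
      r$phi <- .clip01(plogis(lo_r0 + gain))
    }
    new_fit <- .fit_region(r)
    R <- Fm - new_fit
    fit_reg[[m]] <- new_fit
    st$regions[[m]] <- r
  }

  # --- familial surrogates ----------------------------------------------
  for (nm in c("gf", "ef")) {
    f <- st[[nm]]
    if (is.null(f)) next
    Ff <- R + .fit_fam(f, n)
    tau_f <- .tau(f)
    ZtF <- as.numeric(crossprod(f$Z, Ff))
    f$s <- 1 / (tau * f$lambda + tau_f)
    f$M <- tau * f$s * ZtF
    if (any(!is.finite(f$M)))
      stop("non-finite value while updating q(U_", nm, ")")
    R <- Ff - .fit_fam(f, n)
    st[[nm]] <- f
  }

  # --- inverse-gamma factors --------------------------------------------
  for (m in seq_along(st$regions)) {
    r <- st$regions[[m]]
    if (!r$fixed) {
      r$a <- st$hyper$a_region + r$k / 2
      r$b <- max(st$hyper$b_region + 0.5 * (sum(r$M^2) + sum(r$s)), .B_FLOOR)
      st$regions[[m]] <- r
    }
  }
  for (nm in c("gf", "ef")) {
    f <- st[[nm]]
    if (!is.null(f) && !f$fixed) {
      f$a <- st$hyper[[paste0("a_", nm)]] + f$k / 2
      f$b <- max(st$hyper[[paste0("b_", nm)]] +
                   0.5 * (sum(f$M^2) + sum(f$s)), .B_FLOOR)
      st[[nm]] <- f
    }
  }
  if (!st$eps$fixed) {
    st$eps$a <- st$hyper$a_eps + n / 2
    st$eps$b <- max(st$hyper$b_eps + 0.5 * .expected_rss(st), .B_FLOOR)
  }
  st
}

# ---- evidence lower bound ---------------------------------------------------

# E_q[log p(y, xi)] - E_q[log q(xi)].  Components whose variance is held
# fixed contribute through the likelihood only (their IG prior/entropy terms
# are constants and are omitted); clamped inclusion indicators likewise.
compute_elbo <- function(st) {
  n <- st$n
  hy <- st$hyper
  tau <- .tau(st$eps)
  L <- -n / 2 * log(2 * pi) + n / 2 * .elog_inv(st$eps) -
    tau / 2 * .expected_rss(st)

  ig_terms <- function(x, a0, b0) {
    if (x$fixed) return(0)
    el <- log(x$b) - digamma(x$a)        # E[log sigma2]
    prior <- a0 * log(b0) - lgamma(a0) - (a0 + 1) * el - b0 * x$a / x$b
    entropy <- x$a + log(x$b) + lgamma(x$a) - (1 + x$a) * digamma(x$a)
    prior + entropy
  }
  bern_terms <- function(prob, prior) {
    prob <- .clip01(prob)
    sum(prob * log(prior) + (1 - prob) * log(1 - prior)) -
      sum(prob * log(prob) + (1 - prob) * log(1 - prob))
  }

  if (st$p > 0) {
    trS <- sum(.sb_diag(st))
    L <- L - st$p / 2 * log(2 * pi * hy$sigma_beta2) -
      (sum(st$Mb^2) + trS) / (2 * hy$sigma_beta2)
    for (S in st$Sb)
      L <- L + 0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus)
    L <- L + st$p / 2 * (1 + log(2 * pi))
    if (!st$clamp) L <- L + bern_terms(st$psi, hy$theta0)
  }

  for (r in st$regions) {
    if (r$k == 0) next
    tau_m <- .tau(r)
    L <- L - r$k / 2 * log(2 * pi) + r$k / 2 * .elog_inv(r) -
      tau_m / 2 * (sum(r$M^2) + sum(r$s))
    L <- L + 0.5 * sum(log(r$s)) + r$k / 2 * (1 + log(2 * pi))
    if (!st$clamp) L <- L + bern_terms(r$phi, hy$region_prob)
    L <- L + ig_terms(r, hy$a_region, hy$b_region)
  }
  for (nm in c("gf", "ef")) {
    f <- st[[nm]]
    if (is.null(f) || f$k == 0) next
    tau_f <- .tau(f)
    L <- L - f$k / 2 * log(2 * pi) + f$k / 2 * .elog_inv(f) -
      tau_f / 2 * (sum(f$M^2) + sum(f$s))
    L <- L + 0.5 * sum(log(f$s)) + f$k / 2 * (1 + log(2 * pi))
    L <- L + ig_terms(f, hy[[paste0("a_", nm)]], hy[[paste0("b_", nm)]])
  }
  L <- L + ig_terms(st$eps, hy$a_eps, hy$b_eps)
  if (!is.finite(L)) stop("non-finite ELBO")
  L
}

# ---- fitting loop -----------------------------------------------------------

famlmm_engine <- function(yc, Xc, regions, gf, ef, hyper, control) {
  st <- famlmm_init_state(yc, Xc, regions, gf, ef, hyper, control)
  elbo <- compute_elbo(st)
  trace <- elbo
  stop_reason <- "max_sweeps"
  for (sweep in seq_len(control$max_sweeps)) {
    st <- cavi_sweep(st)
    new_elbo <- compute_elbo(st)
    trace <- c(trace, new_elbo)
    if (control$verbose && sweep %% 10 == 0)
      message(sprintf("sweep %4d  ELBO %.6f", sweep, new_elbo))
    if (abs(new_elbo - elbo) / (abs(new_elbo) + 1e-12) < control$rel_tol) {
      stop_reason <- "converged"
      elbo <- new_elbo
      break
    }
    elbo <- new_elbo
  }
  if (stop_reason == "max_sweeps")
    warning("famlmm did not converge within ", control$max_sweeps, " sweeps")
  st$elbo_trace <- trace
  st$convergence <- list(sweeps = length(trace) - 1, stop_reason = stop_reason,
                         elbo = elbo)
  st
}

#' Fit a family-based Bayesian linear mixed model
#'
#' Fits, by coordinate-ascent mean-field variational Bayes, the model
#' \deqn{y = X\Gamma\beta + \sum_m Z_m r_m U_m + Z_{gf} U_{gf} + Z_{ef} U_{ef} + \epsilon,}
#' where the columns of `X` are isolated (typically pre-screened common)
#' variants under a spike-and-slab prior, each genetic region contributes a
#' random effect whose covariance is the weighted similarity kernel
#' \eqn{K_m = G_m W_m G_m^T/p_m}, and the family design contributes two
#' surrogates for unmeasured predictors: a genetic one built from the
#' expected relationship matrix and an environmental one from the
#' block-of-ones family kernel.  All kernels enter through truncated
#' eigen-designs \eqn{Z = Q\Lambda^{1/2}}.
#'
#' The outcome is mean-centred internally (the model carries no intercept);
#' the training mean is stored and restored by [predict.famlmm()].
#'
#' @param y numeric outcome vector; names (or `sample_ids`) identify
#'   individuals for pedigree matching.
#' @param X optional matrix of isolated-variant dosages / covariates
#'   (columns named).  Columns are mean-centred when `center = TRUE`.
#' @param genotypes a [genotype_matrix()] over the training samples, used
#'   with `regions` to build region kernels.
#' @param regions a [region_map()] naming each region's variants.
#' @param pedigree a [pedigree()] covering the training samples; enables the
#'   two family-design surrogates.
#' @param kernels optional pre-built kernel set: a list with elements
#'   `regions` (list of objects with `Z`, `lambda` — e.g. from
#'   [region_kernel()]), `gf` and `ef` (each with `Z`, `lambda`).  Overrides
#'   `genotypes`/`regions`/`pedigree`.
#' @param weights variant-weighting scheme for the region kernels
#'   (see [variant_weights()]).
#' @param center mean-centre dosage columns before kernel construction.
#' @param maf_reference MAF reference population for the weights:
#'   `"founders"` when a pedigree is available (`"auto"`, the default,
#'   chooses this), else all samples.
#' @param sample_ids individual IDs when `y` is unnamed.
#' @param hyper a [famlmm_hyper()] object.
#' @param control a [famlmm_control()] object.
#' @return An object of class `famlmm`; see [summary.famlmm()],
#'   [predict.famlmm()], [coef.famlmm()].
#' @examples
#' set.seed(1)
#' ped <- build_pedigrees(list(list(structure = "nuclear-2", n = 30)))
#' sim <- simulate_env_only(ped, sigma_a2 = 1, sigma2 = 1, seed = 2)
#' fit <- famlmm(sim$phenotypes$y, pedigree = ped,
#'               sample_ids = sim$phenotypes$id,
#'               control = famlmm_control(max_sweeps = 50))
#' summary(fit)
#' @export
famlmm <- function(y, X = NULL, genotypes = NULL, regions = NULL,
                   pedigree = NULL, kernels = NULL,
                   weights = c("wss", "uniform", "beta"),
                   center = TRUE,
                   maf_reference = c("auto", "founders", "all"),
                   sample_ids = NULL,
                   hyper = famlmm_hyper(), control = famlmm_control()) {
  weights <- if (is.character(weights)) match.arg(weights) else weights
  maf_reference <- match.arg(maf_reference)
  cl <- match.call()
  y_names <- names(y)
  y <- as.numeric(unlist(y))
  n <- length(y)
  ids <- sample_ids %||% y_names %||%
    (if (!is.null(genotypes)) rownames(genotypes$dosages)) %||%
    paste0("sample", seq_len(n))
  if (length(ids) != n) stop("sample_ids length does not match y")
  names(y) <- ids
  if (!all(is.finite(y))) stop("outcome contains non-finite values")

  y_mean <- mean(y)
  yc <- y - y_mean

  # fixed-effect design
  x_centers <- NULL
  Xc <- NULL
  if (!is.null(X)) {
    Xc <- as.matrix(X)
    if (nrow(Xc) != n) stop("X has ", nrow(Xc), " rows, expected ", n)
    if (is.null(colnames(Xc))) colnames(Xc) <- paste0("x", seq_len(ncol(Xc)))
    if (anyNA(Xc)) {                     # column-mean imputation
      mu <- colMeans(Xc, na.rm = TRUE)
      idx <- which(is.na(Xc), arr.ind = TRUE)
      Xc[idx] <- mu[idx[, 2]]
    }
    keep <- apply(Xc, 2, function(col) stats::var(col) > 0)
    Xc <- Xc[, keep, drop = FALSE]
    if (ncol(Xc) == 0) Xc <- NULL
  }
  if (!is.null(Xc)) {
    x_centers <- if (center) colMeans(Xc) else rep(0, ncol(Xc))
    names(x_centers) <- colnames(Xc)
    Xc <- sweep(Xc, 2, x_centers)
  }

  # kernel set
  if (!is.null(kernels)) {
    if (length(kernels$regions) && is.null(names(kernels$regions)))
      names(kernels$regions) <- vapply(seq_along(kernels$regions), function(m)
        kernels$regions[[m]]$name %||% paste0("region", m), "")
  } else {
    kernels <- list(regions = list(), gf = NULL, ef = NULL)
    if (!is.null(genotypes) && !is.null(regions)) {
      gsub <- genotypes
      if (!identical(rownames(gsub$dosages), ids)) {
        miss <- setdiff(ids, rownames(gsub$dosages))
        if (length(miss)) stop("samples missing from genotypes: ",
                               paste(head(miss, 5), collapse = ", "))
        gsub <- gsub[ids, ]
      }
      use_founders <- maf_reference == "founders" ||
        (maf_reference == "auto" && !is.null(pedigree))
      maf_ref <- if (use_founders && !is.null(pedigree)) {
        compute_maf(gsub, "founders", pedigree)
      } else gsub$maf
      kernels$regions <- build_region_kernels(gsub, regions, weights, center,
                                              maf_ref)
    }
    if (!is.null(pedigree)) {
      fd <- familial_designs(pedigree, ids)
      kernels$gf <- fd$gf
      kernels$ef <- fd$ef
      kernels$fam <- fd$fam
      kernels$pedigree <- pedigree
    }
  }

  if (!is.null(control$seed)) set.seed(control$seed)
  st <- famlmm_engine(yc, Xc, kernels$regions, kernels$gf, kernels$ef,
                      hyper, control)

  fit <- structure(list(
    call = cl, n = n, sample_ids = ids, y = y, y_mean = y_mean,
    x_names = colnames(Xc), x_centers = x_centers,
    kernels = kernels, state = st,
    elbo = st$elbo_trace, convergence = st$convergence,
    hyper = hyper, control = control,
    weights_scheme = if (is.character(weights)) weights else "custom",
    center = center), class = "famlmm")
  fit$fitted_components <- .component_table(fit)
  fit
}

# per-sample posterior-mean component breakdown on the training data
.component_table <- function(fit) {
  st <- fit$state
  n <- st$n
  out <- data.frame(row.names = fit$sample_ids)
  out$fixed <- .fit_fixed(st)
  for (r in st$regions) out[[paste0("region_", r$name)]] <- .fit_region(r)
  out$gf <- .fit_fam(st$gf, n)
  out$ef <- .fit_fam(st$ef, n)
  out
}
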