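# Evaluation pipeline: train/test splitting, marginal pre-screening,
# metrics, a gBLUP ridge baseline and replicated benchmarking.

#' Random train/test split
#'
#' Uniformly random split at the individual level (`round(fraction * n)`
#' test samples) or at the family level, which never separates members of
#' one family (`round(fraction * n_families)` whole families go to test) —
#' the regime probing out-of-family generalisation.
#'
#' @param ids individual IDs.
#' @param pedigree a [pedigree()], required for `unit = "family"`.
#' @param fraction test fraction in (0, 1); default 0.2.
#' @param unit `"individual"` or `"family"`.
#' @param seed integer seed.
#' @return List of class `split_plan` with `train`, `test`, `unit`,
#'   `fraction`, `seed`.
#' @export
train_test_split <- function(ids, pedigree = NULL, fraction = 0.2,
                             unit = c("individual", "family"), seed = 1) {
  unit <- match.arg(unit)
  if (fraction <= 0 || fraction >= 1)
    stop("test fraction must lie in (0, 1)")
  set.seed(seed)
  if (unit == "individual") {
    test <- sort(sample(ids, round(fraction * length(ids))))
  } else {
    if (is.null(pedigree)) stop("family-unit split requires a pedigree")
    fam <- pedigree$fam[match(ids, pedigree$id)]
    if (anyNA(fam)) stop("IDs missing from pedigree")
    fams <- unique(fam)
    test_fams <- sample(fams, round(fraction * length(fams)))
    test <- sort(ids[fam %in% test_fams])
  }
  structure(list(train = setdiff(ids, test), test = test,
                 unit = unit, fraction = fraction, seed = seed),
            class = "split_plan")
}

# Profile ML for the null model y ~ N(mu, s2g K + s2e I) via the
# eigendecomposition of K; returns delta = s2g/s2e and the eigen basis.
.null_varcomp <- function(y, K) {
  n <- length(y)
  K <- (K + t(K)) / 2
  ee <- tryCatch(eigen(K, symmetric = TRUE), error = function(e) {
    warning("kinship eigendecomposition failed; adding 1e-8 jitter")
    eigen(K + diag(1e-8, n), symmetric = TRUE)
  })
  lam <- pmax(ee$values, 0)
  yr <- as.numeric(crossprod(ee$vectors, y))
  ones_r <- as.numeric(crossprod(ee$vectors, rep(1, n)))
  nll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (delta * lam + 1)
    mu <- sum(w * ones_r * yr) / sum(w * ones_r^2)
    r <- yr - mu * ones_r
    s2e <- sum(w * r^2) / n
    0.5 * (n * log(s2e) - sum(log(w)))
  }
  opt <- optimize(nll, c(-12, 8))
  delta <- exp(opt$minimum)
  w <- 1 / (delta * lam + 1)
  mu <- sum(w * ones_r * yr) / sum(w * ones_r^2)
  s2e <- sum(w * (yr - mu * ones_r)^2) / length(y)
  list(delta = delta, s2e = s2e, s2g = delta * s2e,
       Q = ee$vectors, lambda = lam, w = w, yr = yr, ones_r = ones_r)
}

#' Marginal single-variant pre-screen
#'
#' Screens variants one at a time with a generalized-least-squares linear
#' model that accounts for family correlation: the null variance components
#' of \eqn{V = \sigma_g^2 K_{gf} + \sigma_e^2 I} are estimated once by
#' maximum likelihood (eigen-rotation), then each variant gets a GLS slope
#' t-test (two-sided, `n - 2` df).  Variants with `p <= threshold` are
#' retained; the screen reduces to ordinary least squares when
#' `K_gf` is the identity.
#'
#' @param G [genotype_matrix()] or dosage matrix (training samples only —
#'   screening belongs inside the training set).
#' @param y outcome for the same samples.
#' @param K_gf kinship/relationship matrix; identity when `NULL`.
#' @param threshold retention p-value threshold (default 0.1).
#' @return List with `retained` (variant IDs), `pvalues` and the null
#'   variance components `varcomp`.
#' @export
marginal_prescreen <- function(G, y, K_gf = NULL, threshold = 0.1) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  n <- length(y)
  stopifnot(nrow(d) == n)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  if (is.null(K_gf)) K_gf <- diag(n)
  vc <- .null_varcomp(y, K_gf)
  w <- vc$w
  Xr <- crossprod(vc$Q, d)              # rotated dosages
  yr <- vc$yr; ones <- vc$ones_r

  # per-variant weighted regression on [1, x] in the rotated basis
  s11 <- sum(w * ones^2)
  s1y <- sum(w * ones * yr)
  s1x <- as.numeric(crossprod(Xr * w, ones))
  sxx <- as.numeric(colSums(w * Xr^2))
  sxy <- as.numeric(crossprod(Xr * w, yr))
  syy <- sum(w * yr^2)
  det <- s11 * sxx - s1x^2
  ok <- det > 1e-12 * pmax(s11 * sxx, 1e-300)
  beta <- ifelse(ok, (s11 * sxy - s1x * s1y) / det, 0)
  alpha <- ifelse(ok, (sxx * s1y - s1x * sxy) / det, s1y / s11)
  rss <- syy - alpha * s1y - beta * sxy
  df <- n - 2
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 * s11 / pmax(det, 1e-300))
  tstat <- ifelse(ok & se > 0, beta / se, 0)
  pv <- 2 * pt(-abs(tstat), df)
  pv[!ok] <- 1
  names(pv) <- colnames(d)
  list(retained = colnames(d)[pv <= threshold], pvalues = pv,
       varcomp = vc[c("s2g", "s2e", "delta")])
}

#' Pearson correlation and RMSE of predictions
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return List with `r` and `rmse`.  `r` is `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
pearson_rmse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3)
  rmse <- sqrt(mean((predicted - observed)^2))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(list(r = NA_real_, rmse = rmse))
  }
  list(r = cor(predicted, observed), rmse = rmse)
}

#' gBLUP ridge baseline
#'
#' Genotype-only genomic BLUP with a single overall genomic relationship
#' matrix (centred cross-product over all measured variants) and no
#' family-design surrogates.  The variance ratio is estimated by maximum
#' likelihood on the training samples; test predictions are the usual
#' kernel-ridge conditional mean
#' \eqn{\hat y^* = \bar y + K_{*t} (K_{tt} + I/\delta)^{-1} (y - \bar y)}.
#'
#' @param y_train training outcomes.
#' @param G_train,G_test dosage matrices (same variant columns).
#' @return List with `predictions` for the test rows, the fitted `delta`
#'   and the GRM used.
#' @export
gblup <- function(y_train, G_train, G_test) {
  tr <- if (inherits(G_train, "genotype_matrix")) G_train$dosages else
    as.matrix(G_train)
  te <- if (inherits(G_test, "genotype_matrix")) G_test$dosages else
    as.matrix(G_test)
  ctr <- colMeans(tr)
  p <- ncol(tr)
  Bt <- sweep(tr, 2, ctr) / sqrt(p)
  Bs <- sweep(te, 2, ctr) / sqrt(p)
  Ktt <- tcrossprod(Bt)
  vc <- .null_varcomp(y_train, Ktt)
  mu <- mean(y_train)
  if (vc$delta < 1e-8) {
    pred <- rep(mu, nrow(te))
  } else {
    alpha <- solve(Ktt + diag(1 / vc$delta, nrow(Ktt)), y_train - mu)
    pred <- mu + as.numeric(Bs %*% crossprod(Bt, alpha))
  }
  list(predictions = setNames(pred, rownames(te)), delta = vc$delta,
       varcomp = vc[c("s2g", "s2e")])
}

#' Replicated benchmark of family-aware prediction
#'
#' Runs the full evaluation loop `n_replicates` times: simulate a study from
#' a [run_scenario()] preset, split 80/20, optionally pre-screen common
#' variants inside the training set, fit each method, predict the test
#' samples and record Pearson correlation and RMSE.  Replicate `k` uses seed
#' `seed + k`, recorded per row.  Failed replicates are skipped and counted.
#'
#' @param preset scenario preset (see [run_scenario()]).
#' @param n_replicates number of replicates (default 20).
#' @param methods subset of `"famlmm"` (the family-based model) and
#'   `"gblup"` (genotype-only ridge baseline).
#' @param seed base seed.
#' @param overrides scenario overrides (see [run_scenario()]).
#' @param split_fraction,split_unit passed to [train_test_split()].
#' @param prescreen apply the GLS marginal screen (threshold 0.1) to common
#'   variants (MAF >= 0.05) to form the isolated-effect design `X`.
#' @param hyper,control passed to [famlmm()].
#' @return Object of class `famlmm_benchmark`: per-replicate data frame and
#'   a median/quartile summary per method.
#' @export
replicate_experiment <- function(preset, n_replicates = 20,
                                 methods = c("famlmm", "gblup"),
                                 seed = 1, overrides = list(),
                                 split_fraction = 0.2,
                                 split_unit = "individual",
                                 prescreen = TRUE,
                                 hyper = famlmm_hyper(),
                                 control = famlmm_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  failures <- 0L
  for (k in seq_len(n_replicates)) {
    rep_seed <- seed + k
    res <- tryCatch(
      .one_replicate(preset, rep_seed, methods, overrides,
                     split_fraction, split_unit, prescreen, hyper, control),
      error = function(e) {
        warning(sprintf("replicate %d failed: %s", k, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { failures <- failures + 1L; next }
    res$replicate <- k
    res$seed <- rep_seed
    rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all replicates failed")
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$method), function(df) {
    data.frame(method = df$method[1],
               r_median = median(df$r, na.rm = TRUE),
               r_q1 = quantile(df$r, 0.25, na.rm = TRUE, names = FALSE),
               r_q3 = quantile(df$r, 0.75, na.rm = TRUE, names = FALSE),
               rmse_median = median(df$rmse, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  structure(list(replicates = reps, summary = agg, preset = preset,
                 failures = failures, n_replicates = n_replicates),
            class = "famlmm_benchmark")
}

.one_replicate <- function(preset, rep_seed, methods, overrides,
                           split_fraction, split_unit, prescreen,
                           hyper, control) {
  sim <- run_scenario(preset, overrides = overrides, seed = rep_seed)
  ids <- sim$phenotypes$id
  y <- setNames(sim$phenotypes$y, ids)
  plan <- train_test_split(ids, sim$pedigree, fraction = split_fraction,
                           unit = split_unit, seed = rep_seed)
  y_tr <- y[plan$train]
  G_tr <- sim$genotypes[plan$train, ]
  G_te <- sim$genotypes[plan$test, ]

  out <- list()
  for (m in methods) {
    if (m == "famlmm") {
      X_tr <- NULL
      if (prescreen) {
        common <- colnames(G_tr$dosages)[G_tr$maf >= 0.05]
        if (length(common)) {
          Kt <- kinship_matrix(sim$pedigree, ids = plan$train)
          sc <- marginal_prescreen(G_tr[, common], y_tr, Kt, threshold = 0.1)
          if (length(sc$retained))
            X_tr <- G_tr$dosages[, sc$retained, drop = FALSE]
        }
      }
      fit <- famlmm(y_tr, X = X_tr, genotypes = G_tr,
                    regions = sim$region_map, pedigree = sim$pedigree,
                    hyper = hyper, control = control)
      pred <- predict(fit, genotypes = G_te, pedigree = sim$pedigree)
    } else {
      pred <- gblup(y_tr, G_tr, G_te)$predictions
    }
    met <- pearson_rmse(pred, y[plan$test])
    out[[m]] <- data.frame(method = m, r = met$r, rmse = met$rmse)
  }
  do.call(rbind, out)
}

#' @method print famlmm_benchmark
#' @export
print.famlmm_benchmark <- function(x, ...) {
  cat(sprintf("famlmm benchmark: preset '%s', %d replicates (%d failed)\n",
              x$preset, x$n_replicates, x$failures))
  print(x$summary, digits = 3)
  invisible(x)
}
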