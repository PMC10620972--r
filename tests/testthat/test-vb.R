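# Variational inference engine: initialisation contract, conjugate closed
# forms, ELBO properties and invariances.

test_that("initial state follows the stated contract", {
  pr <- rand_problem(n = 15, p = 3, n_regions = 2)
  hy <- famlmm_hyper()
  st <- famlmm:::famlmm_init_state(pr$y - mean(pr$y), pr$X,
                                   pr$kernels$regions, pr$kernels$gf,
                                   pr$kernels$ef, hy, famlmm_control())
  expect_equal(st$psi, rep(hy$theta0, 3))
  expect_equal(st$Mb, rep(0, 3))
  expect_true(all(vapply(st$regions, function(r) all(r$M == 0), TRUE)))
  # residual IG rate seeded from the phenotype variance (method of moments)
  expect_equal(st$eps$b / st$eps$a, var(pr$y - mean(pr$y)))
})

test_that("a model without fixed-effect variants still fits", {
  set.seed(2)
  pr <- rand_problem(n = 16, p = 0, n_regions = 1)
  fit <- quiet_fit(pr$y, kernels = pr$kernels,
                   control = famlmm_control(max_sweeps = 30))
  expect_equal(fit$state$p, 0L)
  expect_length(coef(fit), 0)
  expect_true(all(diff(fit$elbo) >= -1e-8))
})

test_that("fits are deterministic: identical inputs give identical results", {
  set.seed(4)
  pr <- rand_problem(n = 18, p = 2, n_regions = 2)
  f1 <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels,
                  control = famlmm_control(max_sweeps = 25, seed = 7))
  f2 <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels,
                  control = famlmm_control(max_sweeps = 25, seed = 7))
  expect_identical(f1$elbo, f2$elbo)
  expect_identical(f1$state$Mb, f2$state$Mb)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("a zero outcome leaves all posterior means at zero after one sweep", {
  pr <- rand_problem(n = 12, p = 2, n_regions = 2)
  y0 <- rep(0, 12)
  fit <- quiet_fit(y0, X = pr$X, kernels = pr$kernels,
                   control = famlmm_control(max_sweeps = 1))
  st <- fit$state
  expect_equal(st$Mb, rep(0, 2))
  for (r in st$regions) {
    expect_equal(r$M, rep(0, r$k))
    expect_lte(r$phi, fit$hyper$region_prob + 1e-12)
  }
  expect_equal(st$gf$M, rep(0, st$gf$k))
})

test_that("single-region update reproduces the conjugate closed form", {
  set.seed(9)
  n <- 14
  kd <- rand_psd_design(n, 3)
  y <- rnorm(n)
  yc <- y - mean(y)
  s2r <- 0.7; s2e <- 0.4
  fit <- quiet_fit(y, kernels = list(regions = list(
                     list(Z = kd$Z, lambda = kd$lambda, name = "r1")),
                     gf = NULL, ef = NULL),
                   control = famlmm_control(max_sweeps = 1,
                                            clamp_inclusion = TRUE,
                                            fixed_variances = list(
                                              residual = s2e, regions = s2r)))
  M_expected <- solve(crossprod(kd$Z) / s2e + diag(3) / s2r,
                      crossprod(kd$Z, yc) / s2e)
  expect_equal(fit$state$regions[[1]]$M, as.numeric(M_expected),
               tolerance = 1e-10)
})

test_that("ELBO is non-decreasing on random fixtures, including blockwise q(beta)", {
  set.seed(101)
  for (i in 1:12) {
    pr <- rand_problem(n = sample(10:30, 1), p = sample(0:4, 1),
                       n_regions = sample(1:3, 1),
                       with_fam = i %% 2 == 0)
    fit <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels,
                     control = famlmm_control(max_sweeps = 30,
                                              rel_tol = 1e-12))
    expect_true(all(diff(fit$elbo) >= -1e-8), label = paste("fixture", i))
  }
  # forcing tiny beta blocks exercises the blockwise factorisation
  pr <- rand_problem(n = 25, p = 6, n_regions = 1)
  fit <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels,
                   control = famlmm_control(max_sweeps = 30, rel_tol = 1e-12,
                                            beta_block_cap = 2))
  expect_true(all(diff(fit$elbo) >= -1e-8))
})

test_that("with clamped inclusion and fixed variances CAVI reaches the ridge solution", {
  set.seed(33)
  n <- 22
  pr <- rand_problem(n = n, p = 3, n_regions = 2)
  s2e <- 0.5
  fit <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels, center = TRUE,
                   control = famlmm_control(max_sweeps = 20000, rel_tol = 0,
                                            clamp_inclusion = TRUE,
                                            fixed_variances = list(
                                              residual = s2e, regions = 0.8,
                                              gf = 0.6, ef = 0.9)))
  st <- fit$state
  yc <- pr$y - mean(pr$y)
  Xc <- sweep(pr$X, 2, colMeans(pr$X))
  designs <- c(list(Xc), lapply(st$regions, `[[`, "Z"),
               list(as.matrix(st$gf$Z), as.matrix(st$ef$Z)))
  prec <- c(rep(1 / fit$hyper$sigma_beta2, 3),
            rep(1 / 0.8, sum(vapply(st$regions, `[[`, 0L, "k"))),
            rep(1 / 0.6, st$gf$k), rep(1 / 0.9, st$ef$k))
  theta <- oracle_ridge(yc, designs, prec, s2e)
  got <- c(st$Mb, unlist(lapply(st$regions, `[[`, "M")), st$gf$M, st$ef$M)
  expect_equal(got, as.numeric(theta), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ELBO is bounded by the exact log marginal likelihood", {
  set.seed(55)
  n <- 10
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  kd <- rand_psd_design(n, 2)
  y <- 0.8 * X[, 1] + as.numeric(kd$Z %*% rnorm(2)) + rnorm(n, 0, 0.6)
  y <- y - mean(y)
  s2e <- 0.36
  hy <- famlmm_hyper(theta0 = 0.3, region_prob = 0.3)
  fit <- quiet_fit(y, X = X, center = FALSE,
                   kernels = list(regions = list(
                     list(Z = kd$Z, lambda = kd$lambda, name = "r1")),
                     gf = NULL, ef = NULL), hyper = hy,
                   control = famlmm_control(max_sweeps = 500, rel_tol = 1e-12,
                                            fixed_variances = list(
                                              residual = s2e, regions = 1)))
  oracle <- oracle_enumeration(y, X, kd$Z, theta0 = 0.3, wp = 0.3,
                               sb2 = 1, su2 = 1, se2 = s2e)
  expect_lte(fit$convergence$elbo, oracle$log_ml + 1e-8)
  # converged fixed point: one extra sweep barely moves the ELBO
  ne <- length(fit$elbo)
  expect_lt(abs(fit$elbo[ne] - fit$elbo[ne - 1]), 1e-8)
})

test_that("posterior summaries are invariant to variant and region order", {
  set.seed(77)
  pr <- rand_problem(n = 20, p = 4, n_regions = 3, with_fam = FALSE)
  ctrl <- famlmm_control(max_sweeps = 200, rel_tol = 1e-10)
  f1 <- quiet_fit(pr$y, X = pr$X, kernels = pr$kernels, control = ctrl)
  perm_x <- c(3, 1, 4, 2); perm_r <- c(2, 3, 1)
  f2 <- quiet_fit(pr$y, X = pr$X[, perm_x],
                  kernels = list(regions = pr$kernels$regions[perm_r],
                                 gf = NULL, ef = NULL), control = ctrl)
  expect_equal(coef(f2)[colnames(pr$X)], coef(f1), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(vapply(f2$state$regions, `[[`, 0, "phi")[names(pr$kernels$regions)],
               vapply(f1$state$regions, `[[`, 0, "phi"), tolerance = 1e-8)
  expect_equal(fitted(f2), fitted(f1), tolerance = 1e-8)
})

test_that("null phenotypes leave regions excluded with negligible variance share", {
  set.seed(404)
  phis <- numeric(0); fracs <- numeric(0)
  for (i in 1:5) {
    sim <- run_scenario("env-only", overrides = list(scale = 0.04,
                                                 env_fraction = 0.01),
                        seed = 1000 + i)
    yn <- setNames(rnorm(nrow(sim$pedigree)), sim$pedigree$id)
    fit <- quiet_fit(yn, genotypes = sim$genotypes, regions = sim$region_map,
                     pedigree = sim$pedigree)
    sm <- summary(fit)
    phis <- c(phis, mean(sm$regions$phi))
    reg_rows <- grepl("^gene", sm$varcomp$component)
    fracs <- c(fracs, sum(sm$varcomp$fraction[reg_rows]))
  }
  expect_lt(median(phis), famlmm_hyper()$region_prob + 0.1)
  expect_lt(median(fracs), 0.05)
})
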