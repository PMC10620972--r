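# Family-aware prediction: cross-kernel region effects, familial
# conditional means and their composition.

make_region_fit <- function(seed = 21, n_fam = 12, center = TRUE) {
  set.seed(seed)
  ped <- build_pedigrees(nuclear_blocks(n_fam))
  founders <- simulate_founders(2 * n_fam + 4, 12, seed = seed)
  G <- gene_drop(ped, founders, seed = seed + 1)
  rmap <- region_map(list(gA = colnames(G$dosages)[1:6],
                          gB = colnames(G$dosages)[7:12]))
  y <- setNames(rnorm(nrow(ped)) + rowSums(G$dosages[, 1:3]) * 0.4, ped$id)
  fit <- quiet_fit(y, genotypes = G, regions = rmap, pedigree = ped,
                   center = center,
                   control = famlmm_control(max_sweeps = 300))
  list(fit = fit, ped = ped, G = G, y = y, rmap = rmap)
}

test_that("predicting the training samples reproduces the fitted values", {
  mf <- make_region_fit()
  pr <- predict(mf$fit, genotypes = mf$G, pedigree = mf$ped)
  expect_equal(pr, fitted(mf$fit), tolerance = 1e-8)
})

test_that("a duplicated genotype row receives the training sample's region effect", {
  mf <- make_region_fit()
  i <- 7
  dup <- mf$G$dosages[i, , drop = FALSE]
  rownames(dup) <- "clone"
  for (rg in names(mf$rmap)) {
    g_train <- mf$fit$fitted_components[[paste0("region_", rg)]][i]
    expect_equal(cross_region_effect(mf$fit, dup, rg), g_train,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(cross_region_effect(mf$fit, dup, "nope"), "not in fit")
})

test_that("an excluded region contributes exactly zero", {
  mf <- make_region_fit()
  fit <- mf$fit
  fit$state$regions[["gA"]]$phi <- 0
  expect_equal(cross_region_effect(fit, mf$G$dosages[1:3, ], "gA"),
               rep(0, 3))
})

test_that("region cross-kernel matches the hand-evaluated formula on a toy", {
  A_tr <- matrix(c(0, 2, 1, 0), 2, 2,
                 dimnames = list(c("t1", "t2"), c("v1", "v2")))
  rk <- region_kernel(A_tr, maf = c(0.3, 0.4), weights = "wss",
                      center = FALSE, name = "g")
  y <- c(1, -1)
  fit <- quiet_fit(y, sample_ids = c("t1", "t2"), center = FALSE,
                   kernels = list(regions = list(rk), gf = NULL, ef = NULL),
                   control = famlmm_control(max_sweeps = 50))
  st <- fit$state$regions[[1]]
  A_new <- matrix(c(2, 0), 1, 2, dimnames = list("n1", c("v1", "v2")))
  Kstar <- A_new %*% diag(rk$w) %*% t(A_tr) / 2
  by_hand <- st$phi * Kstar %*% rk$Q %*% diag(1 / sqrt(rk$lambda),
                                              length(rk$lambda)) %*% st$M
  expect_equal(cross_region_effect(fit, A_new, "g"), as.numeric(by_hand),
               tolerance = 1e-8)
})

test_that("familial terms transfer only within training families", {
  mf <- make_region_fit()
  fit <- mf$fit; ped <- mf$ped

  # an unrelated new subject: both surrogates exactly zero
  new_ped <- pedigree(rbind(as.data.frame(ped),
                            data.frame(fam = "famX", id = "stranger",
                                       father = NA, mother = NA, mz = NA)))
  fe <- familial_effect(fit, "stranger", pedigree = new_ped)
  expect_identical(fe$gf, 0)
  expect_identical(fe$ef, 0)

  # a new full sibling of family 3 inherits that family's fitted
  # environmental effect
  f3 <- "fam0003"
  new_ped2 <- pedigree(rbind(
    as.data.frame(ped),
    data.frame(fam = f3, id = "newsib", father = paste0(f3, "_f1"),
               mother = paste0(f3, "_f2"), mz = NA)))
  fe2 <- familial_effect(fit, "newsib", pedigree = new_ped2)
  ef_train <- fit$fitted_components$ef[ped$fam == f3]
  expect_equal(rep(fe2$ef, sum(ped$fam == f3)), ef_train, tolerance = 1e-10)
})

test_that("an MZ co-twin receives its twin's fitted genetic familial effect", {
  set.seed(31)
  ped <- build_pedigrees(list(list(structure = "twin", n = 10,
                                   mz_fraction = 1)))
  founders <- simulate_founders(30, 8, seed = 3)
  G <- gene_drop(ped, founders, seed = 4)
  y <- setNames(rnorm(nrow(ped)), ped$id)
  fit <- quiet_fit(y, pedigree = ped, control = famlmm_control(max_sweeps = 200))
  new_ped <- pedigree(rbind(
    as.data.frame(ped),
    data.frame(fam = "fam0002", id = "cotwin", father = "fam0002_f1",
               mother = "fam0002_f2", mz = "fam0002_mz")))
  fe <- familial_effect(fit, "cotwin", pedigree = new_ped)
  twin_gf <- fit$fitted_components$gf[fit$sample_ids == "fam0002_c1"]
  expect_equal(fe$gf, twin_gf, tolerance = 1e-8)
})

test_that("all-zero genotypes for an unrelated subject predict the training mean", {
  mf <- make_region_fit(center = FALSE)
  zero <- matrix(0, 1, ncol(mf$G$dosages),
                 dimnames = list("z1", colnames(mf$G$dosages)))
  pr <- predict(mf$fit, genotypes = zero,
                families = setNames("famZZ", "z1"))
  expect_equal(unname(pr), mf$fit$y_mean, tolerance = 1e-10)
})

test_that("centred predictions are linear in the posterior means", {
  mf <- make_region_fit()
  fit2 <- mf$fit
  fit2$state$Mb <- 2 * fit2$state$Mb
  for (m in seq_along(fit2$state$regions))
    fit2$state$regions[[m]]$M <- 2 * fit2$state$regions[[m]]$M
  fit2$state$gf$M <- 2 * fit2$state$gf$M
  fit2$state$ef$M <- 2 * fit2$state$ef$M
  p1 <- predict(mf$fit, genotypes = mf$G, pedigree = mf$ped)
  p2 <- predict(fit2, genotypes = mf$G, pedigree = mf$ped)
  expect_equal(p2 - mf$fit$y_mean, 2 * (p1 - mf$fit$y_mean),
               tolerance = 1e-10)
})

test_that("out-of-family predictions ignore the familial decomposition", {
  mf <- make_region_fit()
  fit2 <- mf$fit
  fit2$state$gf$M <- rnorm(length(fit2$state$gf$M))   # arbitrary re-allocation
  fit2$state$ef$M <- rnorm(length(fit2$state$ef$M))
  out <- mf$G$dosages[1:4, ]
  rownames(out) <- paste0("o", 1:4)
  fam_out <- setNames(rep("famNEW", 4), rownames(out))
  expect_equal(predict(mf$fit, genotypes = out, families = fam_out),
               predict(fit2, genotypes = out, families = fam_out))
})

test_that("variants missing from a request are imputed at the training mean", {
  mf <- make_region_fit()
  partial <- mf$G$dosages[1:2, 1:4]        # drop most variants
  expect_message(g <- cross_region_effect(mf$fit, partial, "gA"),
                 "imputed at training mean")
  expect_true(all(is.finite(g)))
})
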