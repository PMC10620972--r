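# Variant weights, region kernels and eigen-designs.

test_that("MAF computation handles references and clamping", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1,
                              dimnames = list(paste0("s", 1:3), "v1")))
  expect_equal(unname(compute_maf(g)), 0.5)
  g0 <- genotype_matrix(matrix(0, 3, 1,
                               dimnames = list(paste0("s", 1:3), "v1")))
  expect_equal(unname(compute_maf(g0)), 0)
  expect_equal(unname(compute_maf(g0, clamp = TRUE)), 1 / 6)

  # founders-only reference excludes the child
  ped <- pedigree(data.frame(fam = "F", id = c("p1", "p2", "kid"),
                             father = c(NA, NA, "p1"),
                             mother = c(NA, NA, "p2")))
  g3 <- genotype_matrix(matrix(c(1, 1, 2), 3, 1,
                               dimnames = list(c("p1", "p2", "kid"), "v1")))
  expect_equal(unname(compute_maf(g3, "founders", ped)), 0.5)
  expect_error(compute_maf(g3, "founders"), "pedigree")
})

test_that("weight schemes match their closed forms and up-weight rare variants", {
  expect_equal(variant_weights(0.5, "uniform"), 1)
  expect_equal(variant_weights(0.5, "wss"), 2)
  # squared beta(1, 25) density at maf 0.5: (25 * 0.5^24)^2
  expect_equal(variant_weights(0.5, "beta"), (25 * 0.5^24)^2)
  expect_equal(variant_weights(0.1, "beta", squared = FALSE),
               25 * 0.9^24)

  maf <- seq(0.001, 0.5, length.out = 200)
  for (scheme in c("wss", "beta")) {
    w <- variant_weights(maf, scheme)
    expect_true(all(diff(w) < 0))          # strictly decreasing in MAF
    expect_true(all(w > 0))
    expect_error(variant_weights(c(0.2, 0), scheme), "exclude monomorphic")
  }
})

test_that("region kernel matches hand-computed cases", {
  G <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "v1"))
  rk <- region_kernel(G, weights = 1, center = TRUE)
  expect_equal(rk$K, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  rk0 <- region_kernel(G, weights = 1, center = FALSE)
  expect_equal(rk0$K, matrix(c(0, 0, 0, 4), 2), ignore_attr = TRUE)

  expect_warning(rk_na <- region_kernel(matrix(1, 3, 2), weights = 1),
                 "monomorphic")
  expect_null(rk_na)
})

test_that("region kernels are symmetric p.s.d. with consistent eigen-designs", {
  set.seed(11)
  for (i in 1:5) {
    G <- matrix(rbinom(30 * 6, 2, runif(6, 0.05, 0.5)), 30, 6,
                dimnames = list(paste0("s", 1:30), paste0("v", 1:6)))
    rk <- region_kernel(G, weights = sample(c("wss", "uniform", "beta"), 1))
    expect_equal(rk$K, t(rk$K))
    ev <- eigen(rk$K, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-10 * max(ev))
    # Z^T Z = diag(lambda); Z Z^T reconstructs K
    expect_equal(crossprod(rk$Z), diag(rk$lambda, length(rk$lambda)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(tcrossprod(rk$Z), rk$K, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("missing dosages are mean-imputed before kernel construction", {
  G <- matrix(c(0, 1, 2, NA, 0, 2, 1, 1), 4, 2,
              dimnames = list(paste0("s", 1:4), c("v1", "v2")))
  Gi <- G; Gi[4, 1] <- 1                  # column mean of (0,1,2)
  expect_equal(region_kernel(G, weights = 1)$K,
               region_kernel(Gi, weights = 1)$K)
})

test_that("kernel eigen-design retains mass and flags degenerate input", {
  kd <- kernel_to_design(diag(2))
  expect_equal(sort(kd$lambda), c(1, 1))
  expect_equal(tcrossprod(kd$Z), diag(2), tolerance = 1e-12)

  kd1 <- kernel_to_design(matrix(1, 2, 2))
  expect_equal(kd1$lambda, 2)
  expect_equal(abs(kd1$Z[, 1]), c(1, 1), tolerance = 1e-12)

  set.seed(3)
  B <- matrix(rnorm(25), 5)
  K <- tcrossprod(B)
  kd5 <- kernel_to_design(K, rel_tol = 1e-8)
  expect_lt(norm(tcrossprod(kd5$Z) - K, "F") / norm(K, "F"), 1e-8 * 5)

  expect_equal(length(kernel_to_design(matrix(0, 3, 3))$lambda), 0)
  expect_error(kernel_to_design(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})
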