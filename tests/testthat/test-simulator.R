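# Study simulator: founders, pedigree structures, gene dropping and the
# phenotype-generation models.

test_that("founder genotypes hit their target frequency and reproduce by seed", {
  g <- simulate_founders(10000, 3, maf_sampler = function(p) rep(0.5, p),
                         seed = 12)
  expect_true(all(abs(g$maf - 0.5) < 0.01))
  g2 <- simulate_founders(50, 20, seed = 99)
  g3 <- simulate_founders(50, 20, seed = 99)
  expect_identical(g2$dosages, g3$dosages)
  expect_error(simulate_founders(10, 5,
                                 maf_sampler = function(p) rep(0, p)),
               "outside")
  expect_error(maf_spectrum(rare_range = c(0, 0.01)), "strictly positive")
})

test_that("pedigree structures have the stated member counts", {
  counts <- c("trio" = 3, "nuclear-2-offspring" = 4,
              "nuclear-4-offspring" = 6, "half-sib-5" = 5, "twin" = 4,
              "threegen-grandparent" = 5, "threegen-avuncular" = 6,
              "threegen-sibling" = 6, "threegen-double-cousin" = 10)
  for (s in names(counts)) {
    ped <- build_pedigrees(list(list(structure = s, n = 3)))
    expect_equal(nrow(ped), 3 * counts[[s]], label = s)
    expect_equal(length(unique(ped$fam)), 3)
  }
  expect_error(build_pedigrees(list(list(structure = "hexagon", n = 1))),
               "unknown pedigree structure")
  tw <- build_pedigrees(list(list(structure = "twin", n = 4,
                                  mz_fraction = 0.5)))
  expect_equal(length(unique(na.omit(tw$mz))), 2)  # half the pairs are MZ
})

test_that("gene dropping is Mendelian and preserves MZ identity", {
  ped <- build_pedigrees(nuclear_blocks(5, k = 4))
  founders <- genotype_matrix(matrix(c(rep(0, 10), rep(2, 10)), 10, 2,
                                     dimnames = list(paste0("f", 1:10),
                                                     c("v0", "v2"))),
                              validate = FALSE)
  G <- gene_drop(ped, founders, seed = 8)
  kids <- ped$id[!is.na(ped$father)]
  expect_true(all(G$dosages[kids, "v0"] == 0))   # 0 x 0 -> 0
  expect_true(all(G$dosages[kids, "v2"] == 2))   # 2 x 2 -> 2

  tw <- build_pedigrees(list(list(structure = "twin", n = 6,
                                  mz_fraction = 1)))
  Gt <- gene_drop(tw, simulate_founders(20, 15, seed = 2), seed = 3)
  expect_identical(Gt$dosages[paste0(unique(tw$fam), "_c1"), ],
                   Gt$dosages[paste0(unique(tw$fam), "_c2"), ],
                   ignore_attr = TRUE)
})

test_that("gene dropping preserves allele frequency in expectation", {
  ped <- build_pedigrees(nuclear_blocks(300, k = 2))
  founders <- simulate_founders(600, 10, seed = 5)
  G <- gene_drop(ped, founders, seed = 6)
  kids <- ped$id[!is.na(ped$father)]
  f_kid <- colMeans(G$dosages[kids, ]) / 2
  f_founder <- colMeans(founders$dosages) / 2
  # binomial SE over 2 * n_offspring transmitted alleles
  se <- sqrt(f_founder * (1 - f_founder) / (2 * length(kids)))
  expect_true(all(abs(f_kid - f_founder) < 3 * pmax(se, 1e-3) + 0.02))
})

test_that("environment-only phenotypes realise the intraclass correlation", {
  ped <- build_pedigrees(nuclear_blocks(1000, k = 2))
  within_r <- function(sim) {
    y <- setNames(sim$phenotypes$y, sim$phenotypes$id)
    ymat <- sapply(split(ped$id, ped$fam), function(m) y[m])  # members x fam
    pairs <- combn(4, 2)
    mean(apply(pairs, 2, function(ij) cor(ymat[ij[1], ], ymat[ij[2], ])))
  }
  s_null <- simulate_env_only(ped, sigma_a2 = 0, sigma2 = 1, seed = 2)
  expect_lt(abs(within_r(s_null)), 0.05)
  s_half <- simulate_env_only(ped, sigma_a2 = 1, sigma2 = 1, seed = 3)
  expect_lt(abs(within_r(s_half) - 0.5), 0.05)
  # components sum exactly to the outcome
  tr <- s_half$truth$components
  expect_identical(tr$env + tr$eps, s_half$phenotypes$y)
})

test_that("repeated family draws reproduce the env-only covariance", {
  ped1 <- build_pedigrees(nuclear_blocks(1))
  ys <- sapply(1:2000, function(s)
    simulate_env_only(ped1, 1, 1, seed = s)$phenotypes$y)
  emp <- tcrossprod(ys - rowMeans(ys)) / (ncol(ys) - 1)
  expect_lt(max(abs(emp - (matrix(1, 4, 4) + diag(4)))), 0.2)
})

test_that("genetic-only simulation hits variance targets and hides one gene", {
  sim0 <- run_scenario("genetic-common", overrides = list(scale = 0.08), seed = 31)
  # hidden variants never appear among measured genotypes
  expect_length(intersect(colnames(sim0$hidden_genotypes$dosages),
                          colnames(sim0$genotypes$dosages)), 0)
  expect_length(sim0$region_map, 2)
  tr <- sim0$truth$components
  y <- sim0$phenotypes$y
  for (cmp in setdiff(colnames(tr), "id")) {
    target <- sim0$truth$variance_targets[[if (cmp == "eps") "eps" else cmp]]
    expect_lt(abs(var(tr[[cmp]]) / var(y) - target), 0.05, label = cmp)
  }
  expect_equal(unname(rowSums(as.matrix(tr[, setdiff(colnames(tr), "id")]))),
               y, tolerance = 1e-12)

  # h = 0: pure noise, no association with any true component
  ped <- build_pedigrees(nuclear_blocks(50))
  G <- gene_drop(ped, simulate_founders(100, 30, seed = 1), seed = 2)
  rmap <- region_map(split(colnames(G$dosages), rep(1:3, each = 10)))
  s0 <- simulate_genetic_only(G, rmap, h_total = 0, seed = 3)
  expect_true(all(s0$truth$components[, names(rmap)] == 0))
  expect_error(simulate_genetic_only(G, rmap, h_total = 1), "h_total")
})

test_that("combined model splits variance equally between factors", {
  sim <- run_scenario("combined", overrides = list(scale = 0.3), seed = 17)
  tr <- sim$truth$components
  y <- sim$phenotypes$y
  env_share <- var(tr$env) / var(y)
  gen_share <- var(rowSums(as.matrix(tr[, paste0("gene", 1:3)]))) / var(y)
  expect_lt(abs(env_share - 0.2), 0.05)
  # component cross-covariances add sampling noise to the genetic sum
  expect_lt(abs(gen_share - 0.2), 0.08)
  expect_lt(abs(env_share - gen_share), 0.1)
})

test_that("scenario-2 disease models satisfy their defining inequalities", {
  for (p in c("S1", "S2", "S3")) {
    sim <- run_scenario(p, overrides = list(scale = 0.02), seed = 7)
    v <- sim$truth$variance_targets
    meas <- setdiff(names(sim$region_map), character(0))
    unm <- sim$truth$unmeasured
    s_meas <- sum(v[meas])
    if (p == "S1") expect_equal(unname(v[unm]), s_meas)        # s_u^2 = sum s_m^2
    if (p == "S2") expect_gt(v[["env"]], s_meas)               # env dominant
    if (p == "S3") expect_gt(unname(v[unm]), v[["env"]] + s_meas)
  }
  expect_error(run_scenario("S1", overrides = list(pedigree = "circle")),
               "unknown scenario-2 pedigree")
})

test_that("simulated studies are reproducible bit-for-bit from the seed", {
  a <- run_scenario("genetic-rare-beta", overrides = list(scale = 0.03), seed = 77)
  b <- run_scenario("genetic-rare-beta", overrides = list(scale = 0.03), seed = 77)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
})
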