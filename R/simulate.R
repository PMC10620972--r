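# Pedigree-based study simulator: founder genotypes, family structures,
# Mendelian gene dropping and the phenotype-generation models used for
# method validation.
#
# Founders are synthetic Hardy-Weinberg draws over a configurable MAF
# spectrum with an explicit rare-variant fraction (real founder panels from
# sequencing studies are not distributable).  Loci segregate independently
# (no linkage), which suffices for the unlinked-region phenotype models
# simulated here.

#' MAF spectrum sampler for founder simulation
#'
#' Mixture sampler: a fraction of variants is rare with MAF uniform on
#' `rare_range`, the rest common with MAF uniform on `common_range`.
#'
#' @param rare_fraction fraction of rare variants (default 0.4, emulating
#'   exome-sequencing gene regions where rare sites outnumber common ones
#'   but common sites dominate after polymorphism filtering).
#' @param rare_range,common_range MAF ranges (defaults (0.001, 0.01) and
#'   (0.05, 0.5)); lower bounds must be positive.
#' @return A function of `p` returning `p` MAFs.
#' @export
maf_spectrum <- function(rare_fraction = 0.4, rare_range = c(0.001, 0.01),
                         common_range = c(0.05, 0.5)) {
  stopifnot(rare_fraction >= 0, rare_fraction <= 1)
  if (min(rare_range) <= 0 || min(common_range) <= 0)
    stop("MAF sampler ranges must be strictly positive")
  function(p) {
    rare <- runif(p) < rare_fraction
    ifelse(rare, runif(p, rare_range[1], rare_range[2]),
           runif(p, common_range[1], common_range[2]))
  }
}

#' Simulate founder genotypes
#'
#' Draws per-variant target MAFs from `maf_sampler` and genotypes as
#' independent Binomial(2, maf) dosages (Hardy-Weinberg equilibrium).
#' Variants realised monomorphic are redrawn up to 10 times, then dropped.
#'
#' @param n number of founders.
#' @param p number of variants.
#' @param maf_sampler a function of `p` (see [maf_spectrum()]).
#' @param seed integer seed.
#' @return A [genotype_matrix()] of up to `p` polymorphic variants with
#'   target MAFs in `attr(, "target_maf")`.
#' @export
simulate_founders <- function(n, p, maf_sampler = maf_spectrum(), seed = 1) {
  stopifnot(n >= 1, p >= 1)
  set.seed(seed)
  maf <- maf_sampler(p)
  if (any(maf <= 0 | maf > 0.5))
    stop("maf_sampler produced frequencies outside (0, 0.5]")
  d <- vapply(maf, function(q) rbinom(n, 2, q), numeric(n))
  d <- matrix(d, nrow = n)
  for (attempt in 1:10) {
    mono <- apply(d, 2, function(x) length(unique(x)) == 1)
    if (!any(mono)) break
    d[, mono] <- vapply(maf[mono], function(q) rbinom(n, 2, q), numeric(n))
  }
  mono <- apply(d, 2, function(x) length(unique(x)) == 1)
  if (any(mono)) {
    d <- d[, !mono, drop = FALSE]
    maf <- maf[!mono]
  }
  # keep the minor-allele coding convention when draws near maf 0.5
  # realise a frequency above one half
  flip <- colMeans(d) / 2 > 0.5
  d[, flip] <- 2 - d[, flip]
  dimnames(d) <- list(sprintf("founder%04d", seq_len(n)),
                      sprintf("v%05d", seq_len(ncol(d))))
  g <- genotype_matrix(d)
  attr(g, "target_maf") <- setNames(maf, colnames(d))
  g
}

# ---- pedigree construction --------------------------------------------------

# Each structure is a template: member roles with parent roles (NA = founder).
.ped_templates <- list(
  "trio" = data.frame(
    role = c("f1", "f2", "c1"),
    father = c(NA, NA, "f1"), mother = c(NA, NA, "f2")),
  "half-sib-5" = data.frame(               # one shared parent, two mates
    role = c("p", "m1", "m2", "c1", "c2"),
    father = c(NA, NA, NA, "p", "p"), mother = c(NA, NA, NA, "m1", "m2")),
  "threegen-grandparent" = data.frame(     # grandparent - parent - child
    role = c("g1", "g2", "p1", "s1", "k1"),
    father = c(NA, NA, "g1", NA, "p1"), mother = c(NA, NA, "g2", NA, "s1")),
  "threegen-avuncular" = data.frame(       # uncle/aunt in generation 2
    role = c("g1", "g2", "a1", "p1", "s1", "k1"),
    father = c(NA, NA, "g1", "g1", NA, "p1"),
    mother = c(NA, NA, "g2", "g2", NA, "s1")),
  "threegen-sibling" = data.frame(         # sibling pair in generation 3
    role = c("g1", "g2", "p1", "s1", "k1", "k2"),
    father = c(NA, NA, "g1", NA, "p1", "p1"),
    mother = c(NA, NA, "g2", NA, "s1", "s1")),
  "threegen-double-cousin" = data.frame(   # two sib pairs intermarry
    role = c("a1", "a2", "b1", "b2", "pa1", "pa2", "pb1", "pb2", "c1", "c2"),
    father = c(NA, NA, NA, NA, "a1", "a1", "b1", "b1", "pa1", "pa2"),
    mother = c(NA, NA, NA, NA, "a2", "a2", "b2", "b2", "pb1", "pb2"))
)

.nuclear_template <- function(k) {
  data.frame(role = c("f1", "f2", paste0("c", seq_len(k))),
             father = c(NA, NA, rep("f1", k)),
             mother = c(NA, NA, rep("f2", k)))
}

#' Build pedigrees from structure blocks
#'
#' Supported structures and their member counts: `trio` (3),
#' `nuclear-2-offspring` (4), `nuclear-4-offspring` (6, and generally
#' `nuclear-<k>-offspring`), `half-sib-5` (5: one shared parent, two mates,
#' one offspring per mate pair), `twin` (4: a nuclear family whose offspring
#' pair may be flagged monozygotic), `threegen-grandparent` (5),
#' `threegen-avuncular` (6), `threegen-sibling` (6) and
#' `threegen-double-cousin` (10).
#'
#' @param blocks list of blocks, each a list with `structure`, `n` (number
#'   of families) and, for `twin`, an optional `mz_fraction` (default 0.5;
#'   the first `round(mz_fraction * n)` twin pairs are monozygotic).
#' @return A [pedigree()] with families `fam0001`, `fam0002`, ...
#' @examples
#' ped <- build_pedigrees(list(list(structure = "half-sib-5", n = 30)))
#' nrow(ped)  # 150
#' @export
build_pedigrees <- function(blocks) {
  recs <- list()
  fam_i <- 0L
  for (blk in blocks) {
    structure_name <- blk$structure
    count <- blk$n
    if (!is.numeric(count) || count < 1 || count != round(count))
      stop("block count must be a positive integer")
    nm <- sub("^nuclear-([0-9]+)(-offspring)?$", "nuclear-\\1", structure_name)
    if (grepl("^nuclear-[0-9]+$", nm)) {
      tpl <- .nuclear_template(as.integer(sub("nuclear-", "", nm)))
      mz <- rep(NA, count)
    } else if (structure_name == "twin") {
      tpl <- .nuclear_template(2)
      frac <- blk$mz_fraction %||% 0.5
      mz <- rep(FALSE, count)
      if (count > 0) mz[seq_len(round(frac * count))] <- TRUE
    } else if (structure_name %in% names(.ped_templates)) {
      tpl <- .ped_templates[[structure_name]]
      mz <- rep(NA, count)
    } else {
      stop("unknown pedigree structure: '", structure_name, "'")
    }
    for (i in seq_len(count)) {
      fam_i <- fam_i + 1L
      fam <- sprintf("fam%04d", fam_i)
      id <- paste0(fam, "_", tpl$role)
      rec <- data.frame(
        fam = fam, id = id,
        father = ifelse(is.na(tpl$father), NA, paste0(fam, "_", tpl$father)),
        mother = ifelse(is.na(tpl$mother), NA, paste0(fam, "_", tpl$mother)),
        mz = NA_character_, stringsAsFactors = FALSE)
      if (structure_name == "twin" && isTRUE(mz[i]))
        rec$mz[tpl$role %in% c("c1", "c2")] <- paste0(fam, "_mz")
      recs[[length(recs) + 1]] <- rec
    }
  }
  pedigree(do.call(rbind, recs))
}

#' Drop genes through a pedigree
#'
#' Mendelian transmission: each founder's dosage is split into two allele
#' draws (dosage 1 is a heterozygote), and each offspring receives one
#' uniformly random allele from each parent, independently per variant.
#' Members of a monozygotic group share one genome.  When pedigree founders
#' outnumber the founder pool, pool rows are assigned by sampling with
#' replacement; otherwise founders receive distinct random pool rows.
#'
#' @param ped a [pedigree()].
#' @param founders a [genotype_matrix()] founder pool.
#' @param seed integer seed.
#' @return A [genotype_matrix()] for every pedigree member, rows in pedigree
#'   order.
#' @export
gene_drop <- function(ped, founders, seed = 1) {
  set.seed(seed)
  d <- founders$dosages
  p <- ncol(d)
  n <- nrow(ped)
  fo <- is.na(ped$father) & is.na(ped$mother)
  nf <- sum(fo)
  rows <- if (nf > nrow(d)) sample.int(nrow(d), nf, replace = TRUE)
  else sample.int(nrow(d), nf)

  A1 <- matrix(0L, n, p)
  A2 <- matrix(0L, n, p)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  fidx <- 0L
  mz_done <- list()
  for (i in seq_len(n)) {
    grp <- ped$mz[i]
    if (!is.na(grp) && !is.null(mz_done[[grp]])) {
      src <- mz_done[[grp]]
      A1[i, ] <- A1[src, ]
      A2[i, ] <- A2[src, ]
      next
    }
    if (fo[i]) {
      fidx <- fidx + 1L
      dos <- d[rows[fidx], ]
      A1[i, ] <- as.integer(dos >= 1)     # het -> one of each allele
      A2[i, ] <- as.integer(dos == 2)
    } else {
      pick_f <- rbinom(p, 1, 0.5)
      pick_m <- rbinom(p, 1, 0.5)
      A1[i, ] <- pick_f * A1[fi[i], ] + (1 - pick_f) * A2[fi[i], ]
      A2[i, ] <- pick_m * A1[mi[i], ] + (1 - pick_m) * A2[mi[i], ]
    }
    if (!is.na(grp)) mz_done[[grp]] <- i
  }
  out <- A1 + A2
  dimnames(out) <- list(ped$id, colnames(d))
  genotype_matrix(out, founders$variants, validate = FALSE)
}

# ---- phenotype models -------------------------------------------------------

#' Shared-environment-only phenotype model
#'
#' Simulates `Y_ij = alpha_i + eps_ij` with family effects
#' `alpha_i ~ N(0, sigma_a2)` shared by all members of family `i` and
#' independent residuals `eps_ij ~ N(0, sigma2)`; equivalently
#' `Y ~ N(0, K_ef sigma_a2 + I sigma2)`.  The fraction of outcome variance
#' from shared environment (the intraclass correlation) is
#' `sigma_a2 / (sigma_a2 + sigma2)`.
#'
#' @param ped a [pedigree()].
#' @param sigma_a2,sigma2 shared-environment and residual variances.
#' @param seed integer seed.
#' @return List with `phenotypes` (data frame `id`, `y`) and `truth`
#'   (per-individual components and the variance partition).  Components sum
#'   exactly to `y`.
#' @export
simulate_env_only <- function(ped, sigma_a2 = 1, sigma2 = 1, seed = 1) {
  stopifnot(sigma_a2 >= 0, sigma2 >= 0)
  set.seed(seed)
  fams <- unique(ped$fam)
  alpha <- setNames(rnorm(length(fams), 0, sqrt(sigma_a2)), fams)
  env <- alpha[ped$fam]
  eps <- rnorm(nrow(ped), 0, sqrt(sigma2))
  y <- as.numeric(env + eps)
  list(phenotypes = data.frame(id = ped$id, y = y, stringsAsFactors = FALSE),
       truth = list(components = data.frame(id = ped$id, env = as.numeric(env),
                                            eps = eps),
                    variance = c(sigma_a2 = sigma_a2, sigma2 = sigma2),
                    env_fraction = sigma_a2 / (sigma_a2 + sigma2)))
}

# Draw one component ~ N(0, K sigma2) from a kernel factor (or iid noise for
# B = NULL) and rescale to an exact sample-variance target.
.draw_scaled <- function(B, target_var, n) {
  raw <- if (is.null(B)) rnorm(n) else as.numeric(B %*% rnorm(ncol(B)))
  v <- stats::var(raw)
  if (v <= 0 || target_var <= 0) return(numeric(n))
  raw * sqrt(target_var / v)
}

#' Genetic-only phenotype model with an unmeasured causal gene
#'
#' `Y = sum_m g_m + eps` over three causal regions with
#' `g_m ~ N(0, K_m sigma_m2)`; the region kernels use the requested causal
#' weight scheme.  One causal region is unmeasured: its variants are removed
#' from the exported genotypes.  Component draws are rescaled so realised
#' sample-variance fractions hit the targets exactly: total heritability
#' `h_total`, of which `unmeasured_fraction` sits on the unmeasured region
#' and the remainder splits equally over the measured causal regions.
#'
#' @param genotypes [genotype_matrix()] for all individuals (e.g. from
#'   [gene_drop()]).
#' @param regions a [region_map()] of the 3 causal regions.
#' @param weights causal weight scheme (`"uniform"`, `"beta"`, `"wss"`).
#' @param h_total total heritability in `[0, 1)`.
#' @param unmeasured_fraction fraction of heritability on the unmeasured
#'   region.
#' @param unmeasured region name to hide; randomly chosen when `NULL`.
#' @param seed integer seed.
#' @return List of class `famlmm_sim`: measured `genotypes`,
#'   `hidden_genotypes`, measured `region_map`, `phenotypes`, `truth`.
#' @export
simulate_genetic_only <- function(genotypes, regions,
                                  weights = c("uniform", "beta", "wss"),
                                  h_total = 0.6, unmeasured_fraction = 0.5,
                                  unmeasured = NULL, seed = 1) {
  weights <- match.arg(weights)
  if (h_total < 0 || h_total >= 1) stop("h_total must lie in [0, 1)")
  set.seed(seed)
  nm <- names(regions)
  if (is.null(unmeasured)) unmeasured <- sample(nm, 1)
  if (!unmeasured %in% nm) stop("unknown unmeasured region: ", unmeasured)
  n <- nrow(genotypes$dosages)

  meas <- setdiff(nm, unmeasured)
  targets <- setNames(rep(h_total * (1 - unmeasured_fraction) / length(meas),
                          length(nm)), nm)
  targets[unmeasured] <- h_total * unmeasured_fraction

  comps <- matrix(0, n, length(nm),
                  dimnames = list(rownames(genotypes$dosages), nm))
  for (r in nm) {
    rk <- region_kernel(genotypes$dosages[, regions[[r]], drop = FALSE],
                        weights = weights, center = TRUE, name = r)
    comps[, r] <- .draw_scaled(rk$Z, targets[r], n)
  }
  eps <- .draw_scaled(NULL, 1 - h_total, n)
  y <- rowSums(comps) + eps

  hidden_ids <- regions[[unmeasured]]
  keep <- setdiff(colnames(genotypes$dosages), hidden_ids)
  structure(list(
    genotypes = genotypes[, keep],
    hidden_genotypes = genotypes[, intersect(hidden_ids,
                                             colnames(genotypes$dosages))],
    region_map = region_map(regions[meas]),
    phenotypes = data.frame(id = rownames(genotypes$dosages), y = y,
                            stringsAsFactors = FALSE),
    truth = list(components = data.frame(id = rownames(genotypes$dosages),
                                         comps, eps = eps,
                                         check.names = FALSE),
                 variance_targets = c(targets, eps = 1 - h_total),
                 unmeasured = unmeasured, h_total = h_total,
                 weights = weights)), class = "famlmm_sim")
}

#' Combined environmental and genetic phenotype model
#'
#' `Y = alpha + sum_m g_m + eps` with family-shared environmental effects
#' and three causal regions (unweighted kernels `K_m = G_m G_m^T / p_m`),
#' one of them unmeasured.  In the equal-contribution mode the
#' shared-environment variance equals the total causal-region variance
#' (`sigma_a2 = sum_m sigma_m2`), i.e. each factor explains half of
#' `total_explained`; the genetic half splits equally over the three causal
#' regions.  Component draws are variance-rescaled as in
#' [simulate_genetic_only()].
#'
#' @param ped a [pedigree()] aligned with `genotypes`.
#' @param genotypes [genotype_matrix()] for all individuals.
#' @param regions a [region_map()] of the 3 causal regions.
#' @param total_explained total variance fraction explained by environment
#'   plus genetics, in `[0, 1)`.
#' @param variance optional named fractions (`env`, and one per region)
#'   overriding the equal-contribution split; must sum to
#'   `total_explained`.
#' @param weights causal kernel weights (default `"uniform"`).
#' @param unmeasured,seed see [simulate_genetic_only()].
#' @return List of class `famlmm_sim` (as in [simulate_genetic_only()], plus
#'   an `env` truth component).
#' @export
simulate_combined <- function(ped, genotypes, regions, total_explained = 0.4,
                              variance = NULL,
                              weights = "uniform",
                              unmeasured = NULL, seed = 1) {
  if (total_explained < 0 || total_explained >= 1)
    stop("total_explained must lie in [0, 1)")
  set.seed(seed)
  nm <- names(regions)
  if (is.null(unmeasured)) unmeasured <- sample(nm, 1)
  n <- nrow(genotypes$dosages)
  if (is.null(variance)) {
    variance <- c(env = total_explained / 2,
                  setNames(rep(total_explained / 2 / length(nm), length(nm)),
                           nm))
  } else if (abs(sum(variance) - total_explained) > 1e-8) {
    stop("variance fractions must sum to total_explained")
  }

  fams <- unique(ped$fam)
  alpha <- rnorm(length(fams))
  env_raw <- alpha[match(ped$fam, fams)]
  env <- if (variance["env"] > 0)
    env_raw * sqrt(variance["env"] / stats::var(env_raw)) else numeric(n)

  comps <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  for (r in nm) {
    rk <- region_kernel(genotypes$dosages[, regions[[r]], drop = FALSE],
                        weights = weights, center = TRUE, name = r)
    comps[, r] <- .draw_scaled(rk$Z, variance[r], n)
  }
  eps <- .draw_scaled(NULL, 1 - total_explained, n)
  y <- env + rowSums(comps) + eps

  meas <- setdiff(nm, unmeasured)
  keep <- setdiff(colnames(genotypes$dosages), regions[[unmeasured]])
  structure(list(
    genotypes = genotypes[, keep],
    hidden_genotypes = genotypes[, intersect(regions[[unmeasured]],
                                             colnames(genotypes$dosages))],
    region_map = region_map(regions[meas]),
    phenotypes = data.frame(id = ped$id, y = y, stringsAsFactors = FALSE),
    truth = list(components = data.frame(id = ped$id, env = env, comps,
                                         eps = eps, check.names = FALSE),
                 variance_targets = c(variance, eps = 1 - total_explained),
                 unmeasured = unmeasured,
                 total_explained = total_explained)), class = "famlmm_sim")
}

#' @method print famlmm_sim
#' @export
print.famlmm_sim <- function(x, ...) {
  cat(sprintf("famlmm_sim: %d individuals, %d measured variants, %d measured regions\n",
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              length(x$region_map)))
  if (!is.null(x$truth$unmeasured))
    cat("  unmeasured causal region:", x$truth$unmeasured, "\n")
  invisible(x)
}

# ---- scenario presets -------------------------------------------------------

.scenario1_blocks <- list(list(structure = "half-sib-5", n = 30),
                          list(structure = "nuclear-2-offspring", n = 177),
                          list(structure = "nuclear-4-offspring", n = 197))

.scale_blocks <- function(blocks, scale) {
  lapply(blocks, function(b) { b$n <- max(1L, round(b$n * scale)); b })
}

#' Instantiate a full simulation design
#'
#' Presets reproduce the study designs used for validation:
#' \describe{
#'   \item{env-only}{Two-generation mixed pedigrees (30 half-sib, 177
#'     two-offspring and 197 four-offspring nuclear families; 2040
#'     individuals from an 808-founder pool), environment-only phenotypes;
#'     `env_fraction` sweeps 0.25-0.75.}
#'   \item{genetic-common / genetic-rare-beta / genetic-rare-wss}{Same pedigrees, genetic-only phenotypes at 60%
#'     total heritability with one of three causal genes unmeasured, causal
#'     weights uniform / squared-beta(1,25) / WSS respectively.}
#'   \item{combined}{Same pedigrees, combined model: environment and genetics
#'     contribute equally to `total_explained` (default 0.4).}
#'   \item{S1/S2/S3}{Pedigree-structure scenarios (default: 510 twin
#'     families, half monozygotic; set `overrides$pedigree` to `"trio"` or
#'     `"threegen"` for 680 trios or the 24 avuncular / 30 double-cousin /
#'     42 grandparent / 278 sibling three-generation mix), combined model at
#'     heritability `h_total` (default 0.4) with disease-model variance
#'     splits S1: no shared environment, unmeasured = measured genetic
#'     variance; S2: environment dominant (0.6/0.1/0.1/0.2 of `h_total` for
#'     env/region1/region2/unmeasured); S3: unmeasured dominant
#'     (0.2/0.1/0.1/0.6).}
#' }
#'
#' @param preset one of `"env-only"`, `"genetic-common"`, `"genetic-rare-beta"`, `"genetic-rare-wss"`, `"combined"`,
#'   `"S1"`, `"S2"`, `"S3"`.
#' @param overrides named list of desk-scale overrides: `scale` (multiplies
#'   family counts), `blocks`, `founders_n`, `variants_per_gene`,
#'   `env_fraction`, `h_total`, `unmeasured_fraction`, `total_explained`,
#'   `pedigree` (scenario-2 structure), `rare_fraction`.
#' @param seed integer seed controlling founders, gene dropping and
#'   phenotypes.
#' @return A list of class `famlmm_sim` with `genotypes`, `pedigree`,
#'   `region_map`, `phenotypes`, `truth` and the instantiated `config`.
#' @examples
#' sim <- run_scenario("env-only", overrides = list(scale = 0.05), seed = 1)
#' @export
run_scenario <- function(preset = c("env-only", "genetic-common", "genetic-rare-beta", "genetic-rare-wss",
                                    "combined", "S1", "S2", "S3"),
                         overrides = list(), seed = 1) {
  preset <- match.arg(preset)
  ov <- overrides
  scale <- ov$scale %||% 1
  founders_n <- ov$founders_n %||% max(16L, round(808 * scale))
  vpg <- ov$variants_per_gene %||% 50
  genes <- paste0("gene", 1:3)

  blocks <- ov$blocks %||% if (preset %in% c("S1", "S2", "S3")) {
    switch(ov$pedigree %||% "twin",
           twin = list(list(structure = "twin", n = max(2L, round(510 * scale)),
                            mz_fraction = 0.5)),
           trio = list(list(structure = "trio", n = max(2L, round(680 * scale)))),
           threegen = .scale_blocks(
             list(list(structure = "threegen-avuncular", n = 24),
                  list(structure = "threegen-double-cousin", n = 30),
                  list(structure = "threegen-grandparent", n = 42),
                  list(structure = "threegen-sibling", n = 278)), scale),
           stop("unknown scenario-2 pedigree: ", ov$pedigree))
  } else .scale_blocks(.scenario1_blocks, scale)

  ped <- build_pedigrees(blocks)
  sampler <- maf_spectrum(rare_fraction = ov$rare_fraction %||% 0.4)
  founders <- simulate_founders(founders_n, vpg * 3, sampler, seed = seed)
  G <- gene_drop(ped, founders, seed = seed + 1)
  vids <- colnames(G$dosages)
  rmap <- region_map(setNames(
    split(vids, rep(genes, each = vpg, length.out = length(vids))), genes))

  config <- list(preset = preset, blocks = blocks, founders_n = founders_n,
                 variants_per_gene = vpg, seed = seed)

  sim <- switch(preset,
    `env-only` = {
      envf <- ov$env_fraction %||% 0.5
      s <- simulate_env_only(ped, sigma_a2 = envf, sigma2 = 1 - envf,
                             seed = seed + 2)
      structure(list(genotypes = G, hidden_genotypes = NULL,
                     region_map = rmap, phenotypes = s$phenotypes,
                     truth = s$truth), class = "famlmm_sim")
    },
    `genetic-common` = ,
    `genetic-rare-beta` = ,
    `genetic-rare-wss` = {
      w <- c(`genetic-common` = "uniform", `genetic-rare-beta` = "beta",
             `genetic-rare-wss` = "wss")[[preset]]
      simulate_genetic_only(G, rmap, weights = w,
                            h_total = ov$h_total %||% 0.6,
                            unmeasured_fraction = ov$unmeasured_fraction %||% 0.5,
                            seed = seed + 2)
    },
    combined = simulate_combined(ped, G, rmap,
                             total_explained = ov$total_explained %||% 0.4,
                             seed = seed + 2),
    S1 = ,
    S2 = ,
    S3 = {
      h <- ov$h_total %||% 0.4
      v <- switch(preset,
                  S1 = c(0, 0.25, 0.25, 0.5),
                  S2 = c(0.6, 0.1, 0.1, 0.2),
                  S3 = c(0.2, 0.1, 0.1, 0.6)) * h
      names(v) <- c("env", genes)
      # the last-listed gene plays the unmeasured role
      simulate_combined(ped, G, rmap, total_explained = h,
                        variance = v, unmeasured = genes[3], seed = seed + 2)
    })
  sim$pedigree <- ped
  sim$config <- config
  sim
}
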