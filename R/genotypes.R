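# Genotype container and file formats.
#
# Dosages are stored sample x variant as minor-allele counts in {0, 1, 2};
# missing genotypes are NA (imputation happens downstream, at kernel-building
# time, so the I/O layer stays lossless).  Positions follow the 1-based .bim
# convention; all conversion to 0-based indices happens here and only here.

#' Construct a genotype matrix
#'
#' Bundles a dosage matrix with variant metadata and per-variant minor allele
#' frequencies.  Dosages count copies of the minor allele (0, 1 or 2, `NA`
#' for missing).
#'
#' @param dosages numeric matrix, samples in rows (rownames = individual IDs),
#'   variants in columns (colnames = variant IDs).
#' @param variants optional data frame of variant metadata with columns
#'   `id`, `chr`, `pos`, `a1`, `a2`; defaults are synthesized from column
#'   names.
#' @param validate check dosage domain and ID uniqueness.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants` and `maf`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3,
#'   dimnames = list(paste0("s", 1:3), c("v1", "v2"))))
#' g$maf
#' @export
genotype_matrix <- function(dosages, variants = NULL, validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(dosages), chr = "1",
                           pos = seq_len(ncol(dosages)),
                           a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  if (validate) {
    if (anyDuplicated(rownames(dosages)))
      stop("duplicate sample IDs in genotype matrix")
    if (anyDuplicated(colnames(dosages)))
      stop("duplicate variant IDs in genotype matrix")
    bad <- which(!(dosages %in% c(0, 1, 2) | is.na(dosages)))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(dosages)) + 1
      j <- ((bad[1] - 1) %/% nrow(dosages)) + 1
      stop(sprintf(
        "invalid dosage %g for sample '%s', variant '%s' (must be 0, 1, 2 or NA)",
        dosages[bad[1]], rownames(dosages)[i], colnames(dosages)[j]))
    }
    if (!identical(as.character(variants$id), colnames(dosages)))
      stop("variant metadata IDs do not match dosage column names")
  }
  structure(list(dosages = dosages, variants = variants,
                 maf = .fold_maf(colMeans(dosages, na.rm = TRUE) / 2)),
            class = "genotype_matrix")
}

.fold_maf <- function(f) {
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.4g - %.4g; missing: %d\n",
              min(x$maf), max(x$maf), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample / variant indices (any usual matrix index type).
#' @param ... unused.
#' @return A `genotype_matrix` over the selected samples and variants, with
#'   MAFs recomputed on the subset.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  d <- x$dosages[i, j, drop = FALSE]
  v <- x$variants[match(colnames(d), x$variants$id), , drop = FALSE]
  rownames(v) <- NULL
  genotype_matrix(d, v, validate = FALSE)
}

#' Compute minor allele frequencies
#'
#' MAF is the folded allele frequency, `min(f, 1 - f)` with
#' `f = mean(dosage) / 2`, computed either over all samples or over pedigree
#' founders only.  Founder-based frequencies avoid the inflation induced by
#' sampling many relatives from a few families.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param reference `"all"` samples or pedigree `"founders"` only.
#' @param pedigree a [pedigree()], required when `reference = "founders"`.
#' @param clamp if `TRUE`, frequencies are floored at `1/(2 n_ref)` so that
#'   downstream variant weights stay finite for variants that are monomorphic
#'   in the reference but present in the sample.
#' @return Named numeric vector of MAFs in `[0, 0.5]`.
#' @export
compute_maf <- function(G, reference = c("all", "founders"), pedigree = NULL,
                        clamp = FALSE) {
  reference <- match.arg(reference)
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (reference == "founders") {
    if (is.null(pedigree))
      stop("founders reference requires a pedigree")
    fo <- pedigree$id[is.na(pedigree$father) & is.na(pedigree$mother)]
    keep <- rownames(d) %in% fo
    if (!any(keep))
      stop("no pedigree founders found among genotyped samples")
    d <- d[keep, , drop = FALSE]
  }
  maf <- .fold_maf(colMeans(d, na.rm = TRUE) / 2)
  if (clamp) maf <- pmax(maf, 1 / (2 * nrow(d)))
  maf
}

# ---- dosage TSV -------------------------------------------------------------

#' Read / write a dosage TSV
#'
#' The text dosage format is a tab-separated table with a header row of
#' variant IDs, one row per sample, and the individual ID in the first
#' column.  Values are minor-allele counts (0/1/2) or `NA`.  Columns whose
#' allele frequency exceeds 0.5 are assumed to count the major allele and are
#' flipped to minor-allele counts; the flipped variant IDs are recorded in
#' `attr(, "flipped")`.
#'
#' @param path file path.
#' @return [read_dosage()] returns a [genotype_matrix()].
#' @export
read_dosage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty dosage file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop(sprintf("ragged dosage TSV: row %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  header <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[`, "", 1)
  vals <- vapply(fields[-1], function(f) suppressWarnings(as.numeric(f[-1])),
                 numeric(length(header)))
  d <- if (length(header) == 1) matrix(vals, ncol = 1) else t(vals)
  dimnames(d) <- list(ids, header)
  bad <- which(!(d %in% c(0, 1, 2) | is.na(d)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(d)) + 1
    j <- ((bad[1] - 1) %/% nrow(d)) + 1
    stop(sprintf("invalid dosage '%s' at row %d (sample '%s'), column '%s'",
                 fields[[i + 1]][j + 1], i, ids[i], header[j]))
  }
  f <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  g <- genotype_matrix(d)
  attr(g, "flipped") <- colnames(d)[flip]
  g
}

#' @rdname read_dosage
#' @param G a [genotype_matrix()].
#' @export
write_dosage <- function(G, path) {
  d <- G$dosages
  header <- paste(c("id", colnames(d)), collapse = "\t")
  body <- vapply(seq_len(nrow(d)), function(i)
    paste(c(rownames(d)[i], format(d[i, ], trim = TRUE)), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------

# 2-bit codes in a .bed byte, SNP-major: 00 = hom A1 (2 copies of A1),
# 01 = missing, 10 = het, 11 = hom A2.  Dosage counts the A1 allele.
.plink_decode_table <- function() {
  codes <- c(2, NA, 1, 0)
  tab <- matrix(0, 256, 4)
  for (b in 0:255)
    tab[b + 1, ] <- codes[(bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)) + 1]
  tab
}

#' Read / write PLINK binary genotypes
#'
#' Reads a `.bed`/`.bim`/`.fam` triple sharing `prefix`.  Only SNP-major bed
#' files (the modern layout) are supported.  A1 is taken as the counted
#' allele; variants whose A1 frequency exceeds 0.5 are flipped to
#' minor-allele dosage and recorded in `attr(, "flipped")`.
#'
#' @param prefix path prefix of the `.bed`, `.bim` and `.fam` files.
#' @return [read_plink()] returns a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing PLINK file(s): ",
                            paste(missing, collapse = ", "))
  fam <- read.table(paths[3], stringsAsFactors = FALSE)
  bim <- read.table(paths[2], stringsAsFactors = FALSE)
  colnames(bim)[1:6] <- c("chr", "id", "cm", "pos", "a1", "a2")
  if (anyDuplicated(bim$id))
    stop("duplicate variant ID in .bim: ",
         bim$id[duplicated(bim$id)][1])
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed magic bytes in ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * p)
    stop(sprintf(".bed payload has %d bytes, expected %d",
                 length(raw) - 3, bpv * p))
  tab <- .plink_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = p)
  d <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    vals <- t(tab[body[, j] + 1, , drop = FALSE])  # 4 x bpv, sample-major
    d[, j] <- vals[seq_len(n)]
  }
  dimnames(d) <- list(as.character(fam[[2]]), bim$id)
  f <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    d[, flip] <- 2 - d[, flip]
    a1 <- bim$a1
    bim$a1[flip] <- bim$a2[flip]
    bim$a2[flip] <- a1[flip]
  }
  g <- genotype_matrix(d, bim[, c("id", "chr", "pos", "a1", "a2")])
  attr(g, "flipped") <- bim$id[flip]
  attr(g, "fam") <- fam
  g
}

#' @rdname read_plink
#' @param G a [genotype_matrix()].
#' @param family_ids optional family IDs for the `.fam` file (defaults to the
#'   individual IDs).
#' @export
write_plink <- function(G, prefix, family_ids = NULL) {
  d <- G$dosages
  n <- nrow(d); p <- ncol(d)
  if (is.null(family_ids)) family_ids <- rownames(d)
  fam <- data.frame(family_ids, rownames(d), 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  v <- G$variants
  bim <- data.frame(v$chr, v$id, 0, v$pos, v$a1, v$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, p)
  code[d == 2] <- 0L
  code[d == 1] <- 2L
  code[is.na(d)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  out <- raw(3 + bpv * p)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  shifts <- c(0L, 2L, 4L, 6L)
  for (j in seq_len(p)) {
    cj <- c(code[, j], integer(pad))
    m <- matrix(cj, nrow = 4)
    bytes <- as.integer(colSums(m * 2^shifts))
    out[3 + (j - 1) * bpv + seq_len(bpv)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read genotypes in a supported format
#'
#' Thin dispatcher over [read_plink()] and [read_dosage()].
#'
#' @param path file path (for `dosage-tsv`) or prefix (for `plink-bed`).
#' @param format one of `"plink-bed"`, `"dosage-tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink-bed", "dosage-tsv")) {
  format <- match.arg(format)
  switch(format,
         "plink-bed" = read_plink(path),
         "dosage-tsv" = read_dosage(path))
}

# ---- region map and phenotypes ---------------------------------------------

#' Read a region map
#'
#' Two-column tab-separated file mapping region name to variant ID, one pair
#' per row.  Regions keep file order; duplicated pairs are dropped.  When
#' `variant_ids` is supplied, unknown variants are removed (and counted in
#' `attr(, "report")`); regions left empty are dropped with a warning.
#'
#' @param path file path.
#' @param variant_ids optional character vector of known variant IDs.
#' @return Named list of character vectors (class `region_map`).
#' @export
read_region_map <- function(path, variant_ids = NULL) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("region", "variant"))
  region_map(split(tab$variant, factor(tab$region, levels = unique(tab$region))),
             variant_ids = variant_ids)
}

#' @rdname read_region_map
#' @param regions named list of variant-ID vectors.
#' @export
region_map <- function(regions, variant_ids = NULL) {
  regions <- lapply(regions, function(v) unique(as.character(v)))
  skipped <- character(0)
  if (!is.null(variant_ids)) {
    regions <- lapply(regions, function(v) {
      skipped <<- c(skipped, setdiff(v, variant_ids))
      intersect(v, variant_ids)
    })
  }
  empty <- lengths(regions) == 0
  if (any(empty))
    warning("dropping region(s) with no resolvable variants: ",
            paste(names(regions)[empty], collapse = ", "))
  out <- regions[!empty]
  class(out) <- "region_map"
  attr(out, "report") <- list(skipped_variants = skipped,
                              dropped_regions = names(regions)[empty])
  out
}

#' @method print region_map
#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d regions, sizes %s\n", length(x),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}

#' Read a phenotype / covariate table
#'
#' Tab-separated table with a header; the first column is the individual ID,
#' the second the quantitative outcome, remaining columns are covariates.
#'
#' @param path file path.
#' @return A data frame with at least columns `id` and `y`.
#' @export
read_phenotypes <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  colnames(tab)[1:2] <- c("id", "y")
  tab$id <- as.character(tab$id)
  if (!all(is.finite(tab$y)))
    stop("non-finite outcome value for individual '",
         tab$id[!is.finite(tab$y)][1], "'")
  if (anyDuplicated(tab$id))
    stop("duplicate individual ID in phenotype file: ",
         tab$id[duplicated(tab$id)][1])
  tab
}

#' Inner-join phenotypes to genotyped samples
#'
#' @param phenotypes data frame from [read_phenotypes()].
#' @param G a [genotype_matrix()].
#' @return List with the matched phenotype table, the subset genotype matrix
#'   and the IDs dropped from either side.
#' @export
align_samples <- function(phenotypes, G) {
  common <- intersect(rownames(G$dosages), phenotypes$id)
  dropped <- list(genotyped_only = setdiff(rownames(G$dosages), common),
                  phenotyped_only = setdiff(phenotypes$id, common))
  if (length(dropped$genotyped_only) || length(dropped$phenotyped_only))
    message(sprintf("align_samples: %d genotyped-only, %d phenotyped-only IDs dropped",
                    length(dropped$genotyped_only), length(dropped$phenotyped_only)))
  list(phenotypes = phenotypes[match(common, phenotypes$id), , drop = FALSE],
       genotypes = G[common, ], dropped = dropped)
}
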