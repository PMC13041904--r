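#' Configuration for a synthetic single-cell eQTL cohort
#'
#' Defines the cohort structure emulated by [simulate_cohort()]: donor and
#' variant counts, an LD block model, per-cell-type cell counts, and a grid of
#' injected cis effects with their cross-cell-type sharing patterns. Defaults
#' mirror a single-tissue single-cell eQTL cohort of ~129 donors with a few
#' dozen cells per donor and cell type.
#'
#' @param n_donors,n_variants,n_genes,n_cell_types cohort dimensions (all >= 1).
#' @param cells_per_donor_per_type named vector `c(mean=, dispersion=)`; the
#'   number of cells a donor contributes to a cell type is drawn
#'   NB(mean, dispersion) (dispersion = NB size parameter).
#' @param maf_range allele-frequency range, within (0, 0.5]; per-variant MAFs
#'   are drawn uniformly from it.
#' @param ld_block_size,ld_rho variants are organized in blocks of
#'   `ld_block_size` with pairwise latent (haplotype-level) correlation
#'   `ld_rho` in \[0, 1).
#' @param effect_grid data.frame with columns `pattern` (one of "null",
#'   "global", "category", "specific", "dynamic"), `beta` (log-scale allelic
#'   effect), `slope` (per-quantile change of the allelic effect along
#'   pseudotime; nonzero only for "dynamic"), and `weight` (fraction of genes
#'   assigned the row). Effect sizes are free parameters chosen for test
#'   power.
#' @param nb_dispersion NB dispersion of per-cell counts
#'   (variance = mu + dispersion * mu^2).
#' @param donor_sd SD of the per-gene donor random intercept (log scale).
#' @param pseudotime_model "uniform" (flat on \[0, 30\]) or "bimodal" (two
#'   modes at 8 and 22, emulating cells piling up at trajectory termini).
#' @param frac_inf_pseudotime fraction of cells assigned infinite pseudotime
#'   (cells off the inferred trajectory, removed by downstream analyses).
#' @param pseudotime_quantiles number of pseudotime quantile bins the dynamic
#'   effect slope is expressed in (default 6).
#' @param variant_spacing bp between adjacent variants on the single
#'   synthetic chromosome.
#' @param base_expr_range range of per-UMI expression rates genes are drawn
#'   from (log-uniform).
#' @param seed single top-level integer seed; per-stage child streams are
#'   derived from it deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_donors = 129L, n_variants = 400L, n_genes = 120L,
                       n_cell_types = 4L,
                       cells_per_donor_per_type = c(mean = 40, dispersion = 8),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L, ld_rho = 0.8,
                       effect_grid = default_effect_grid(),
                       nb_dispersion = 0.4, donor_sd = 0.25,
                       pseudotime_model = c("uniform", "bimodal"),
                       frac_inf_pseudotime = 0.01,
                       pseudotime_quantiles = 6L,
                       variant_spacing = 4000L,
                       base_expr_range = c(1e-4, 5e-3),
                       seed = 1L) {
  pseudotime_model <- match.arg(pseudotime_model)
  cfg <- list(
    n_donors = as.integer(n_donors), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    cells_per_donor_per_type = cells_per_donor_per_type,
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, effect_grid = effect_grid,
    nb_dispersion = nb_dispersion, donor_sd = donor_sd,
    pseudotime_model = pseudotime_model,
    frac_inf_pseudotime = frac_inf_pseudotime,
    pseudotime_quantiles = as.integer(pseudotime_quantiles),
    variant_spacing = as.integer(variant_spacing),
    base_expr_range = base_expr_range,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_donors >= 1, n_variants >= 1, n_genes >= 1, n_cell_types >= 1,
              cells_per_donor_per_type[["mean"]] > 0,
              cells_per_donor_per_type[["dispersion"]] > 0,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2],
              ld_rho >= 0, ld_rho < 1,
              nb_dispersion > 0, donor_sd >= 0,
              frac_inf_pseudotime >= 0, frac_inf_pseudotime < 1,
              pseudotime_quantiles >= 2,
              all(c("pattern", "beta", "slope", "weight") %in%
                    colnames(effect_grid)))
  })
  if (cfg$n_variants < cfg$ld_block_size)
    stop("n_variants (", cfg$n_variants, ") must be >= ld_block_size (",
         cfg$ld_block_size, ")")
  # cell types cycle through the four standard lung cell categories
  cfg$cell_types <- data.frame(
    cell_type = sprintf("ct%02d", seq_len(cfg$n_cell_types)),
    category = rep(c("epithelial", "immune", "endothelial", "stromal"),
                   length.out = cfg$n_cell_types),
    stringsAsFactors = FALSE
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default grid of injected cis effects
#'
#' Half the genes are null; the rest split between globally shared,
#' category-shared, cell-type-specific, and pseudotime-dynamic effects.
#' @return data.frame with columns pattern, beta, slope, weight.
#' @export
default_effect_grid <- function() {
  data.frame(
    pattern = c("null", "global", "category", "specific", "dynamic"),
    beta    = c(0,      0.5,      0.5,        0.5,        0.25),
    slope   = c(0,      0,        0,          0,          0.15),
    weight  = c(0.50,   0.15,     0.10,       0.15,       0.10),
    stringsAsFactors = FALSE
  )
}

#' Simulate donor genotypes with block LD under Hardy-Weinberg equilibrium
#'
#' Two haplotypes per donor are drawn from a latent Gaussian with
#' compound-symmetric correlation `ld_rho` inside each LD block and
#' thresholded at the allele frequency, so genotype frequencies follow
#' Hardy-Weinberg at each variant while dosage r^2 is elevated within blocks.
#'
#' @param config a [sim_config()].
#' @return `genotype_matrix`: list with `dosage` (donor x variant matrix of
#'   alternative-allele dosages in 0..2), `variants` (variant_id, chrom, pos,
#'   ref, alt, maf (generative), emp_maf (realized, folded), impq (imputation
#'   quality score), block) and `donors`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "genotypes"))
  n <- config$n_donors; V <- config$n_variants
  maf <- runif(V, config$maf_range[1], config$maf_range[2])
  block <- ceiling(seq_len(V) / config$ld_block_size)
  thr <- qnorm(maf)
  dosage <- matrix(0L, n, V)
  for (hap in 1:2) {
    u <- matrix(rnorm(n * max(block)), n, max(block))
    z <- sqrt(config$ld_rho) * u[, block, drop = FALSE] +
      sqrt(1 - config$ld_rho) * matrix(rnorm(n * V), n, V)
    dosage <- dosage + (z < rep(thr, each = n))
  }
  storage.mode(dosage) <- "integer"
  donors <- sprintf("D%03d", seq_len(n))
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(V)),
    chrom = "chr1",
    pos = 10000L + config$variant_spacing * seq_len(V),
    ref = "A", alt = "G",
    maf = maf,
    emp_maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
    impq = round(runif(V, 0.6, 1), 4),
    block = block,
    stringsAsFactors = FALSE
  )
  dimnames(dosage) <- list(donors, variants$variant_id)
  structure(list(dosage = dosage, variants = variants, donors = donors),
            class = "genotype_matrix")
}

#' Construct a cell-level expression table
#'
#' Bundles a gene x cell count matrix with per-cell metadata and gene
#' annotation. For externally supplied data a mismatch of more than 1%
#' between `n_umi` and the column sums raises a warning.
#'
#' @param counts gene x cell matrix (coerced to sparse).
#' @param meta data.frame with columns cell_id, donor, cell_type, n_umi,
#'   pct_mito, pseudotime.
#' @param genes data.frame with columns gene_id, chrom, tss, strand.
#' @return object of class `cell_table`.
#' @export
cell_table <- function(counts, meta, genes) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  stopifnot(ncol(counts) == nrow(meta), nrow(counts) == nrow(genes),
            all(c("cell_id", "donor", "cell_type", "n_umi", "pct_mito",
                  "pseudotime") %in% colnames(meta)),
            all(c("gene_id", "chrom", "tss", "strand") %in% colnames(genes)))
  cs <- Matrix::colSums(counts)
  bad <- abs(cs - meta$n_umi) > pmax(1, 0.01 * pmax(cs, meta$n_umi))
  if (any(bad))
    warning(sum(bad), " cells have n_umi differing from column sums by > 1%")
  dimnames(counts) <- list(genes$gene_id, meta$cell_id)
  structure(list(counts = counts, meta = meta, genes = genes),
            class = "cell_table")
}

#' Simulate per-cell counts with injected cis-eQTL effects
#'
#' Per-cell UMI counts for each gene are drawn from a negative binomial whose
#' log mean is `base + beta * dosage + slope * centered_quantile * dosage +
#' donor_intercept + log(size factor)`, where `beta` follows the gene's
#' sharing pattern across cell types and `slope` makes the allelic effect
#' drift along pseudotime quantiles. Each gene's causal variant is the one
#' nearest its TSS. Recorded `n_umi` equals the realized column sum.
#'
#' @param config a [sim_config()].
#' @param genotypes output of [simulate_genotypes()].
#' @return list with `cells` (a [cell_table()]) and `truth` (data.frame of
#'   gene_id, variant_id, cell_type, pattern, true_beta, true_slope; null
#'   entries have both effects 0).
#' @export
simulate_cells <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            nrow(genotypes$dosage) == config$n_donors)
  set.seed(child_seed(config$seed, "cells"))
  G <- config$n_genes; K <- config$n_cell_types; n <- config$n_donors
  Q <- config$pseudotime_quantiles
  cts <- config$cell_types

  pos <- genotypes$variants$pos
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(G)),
    chrom = "chr1",
    tss = as.integer(round(seq(min(pos), max(pos), length.out = G))),
    strand = rep(c("+", "-"), length.out = G),
    stringsAsFactors = FALSE
  )
  causal <- vapply(genes$tss, function(t) which.min(abs(pos - t)), 1L)

  # assign grid rows to genes in proportion to weights (exact counts)
  w <- config$effect_grid$weight / sum(config$effect_grid$weight)
  counts_per <- diff(round(cumsum(c(0, w)) * G))
  pat_idx <- rep(seq_len(nrow(config$effect_grid)), times = counts_per)
  target_ct <- ((seq_len(G) - 1L) %% K) + 1L  # affected cell type, cycling

  truth <- do.call(rbind, lapply(seq_len(G), function(g) {
    row <- config$effect_grid[pat_idx[g], ]
    beta_k <- rep(0, K); slope_k <- rep(0, K)
    if (row$pattern %in% c("global", "dynamic")) {
      beta_k[] <- row$beta; slope_k[] <- row$slope
    } else if (row$pattern == "category") {
      beta_k[cts$category == cts$category[target_ct[g]]] <- row$beta
    } else if (row$pattern == "specific") {
      beta_k[target_ct[g]] <- row$beta
    }
    data.frame(gene_id = genes$gene_id[g],
               variant_id = genotypes$variants$variant_id[causal[g]],
               cell_type = cts$cell_type, pattern = row$pattern,
               true_beta = beta_k, true_slope = slope_k,
               stringsAsFactors = FALSE)
  }))

  # cells per donor x cell type
  cpd <- config$cells_per_donor_per_type
  ncell <- matrix(rnbinom(n * K, mu = cpd[["mean"]], size = cpd[["dispersion"]]),
                  n, K)
  donor_idx <- rep(rep(seq_len(n), K), times = as.vector(ncell))
  ct_idx <- rep(rep(seq_len(K), each = n), times = as.vector(ncell))
  N <- length(donor_idx)
  if (N == 0) stop("no cells simulated; increase cells_per_donor_per_type")

  pt <- switch(config$pseudotime_model,
    uniform = runif(N, 0, 30),
    bimodal = pmin(30, pmax(0, rnorm(N, sample(c(8, 22), N, TRUE), 2.5))))
  if (config$frac_inf_pseudotime > 0) {
    inf_cells <- runif(N) < config$frac_inf_pseudotime
    pt[inf_cells] <- Inf
  }
  # centered quantile bin within cell type (dynamic effects are expressed in
  # quantile units, matching the downstream interaction model)
  qc <- rep(0, N)
  for (k in seq_len(K)) {
    idx <- which(ct_idx == k & is.finite(pt))
    if (length(idx) >= Q) {
      r <- rank(pt[idx], ties.method = "first")
      qc[idx] <- (floor((r - 1) * Q / length(idx)) + 1) - (Q + 1) / 2
    }
  }
  sf <- rlnorm(N, log(2000), 0.35)
  pct_mito <- rbeta(N, 2, 38)
  base <- exp(runif(G, log(config$base_expr_range[1]),
                    log(config$base_expr_range[2])))
  u <- matrix(rnorm(G * n, 0, config$donor_sd), G, n)

  beta_mat <- matrix(truth$true_beta, nrow = K)   # K x G (truth is ct-major)
  slope_mat <- matrix(truth$true_slope, nrow = K)
  counts <- matrix(0L, G, N)
  for (g in seq_len(G)) {
    dos <- genotypes$dosage[, causal[g]][donor_idx]
    eta <- log(base[g]) +
      beta_mat[cbind(ct_idx, g)] * dos +
      slope_mat[cbind(ct_idx, g)] * qc * dos +
      u[g, donor_idx]
    counts[g, ] <- rnbinom(N, mu = sf * exp(eta),
                           size = 1 / config$nb_dispersion)
  }
  meta <- data.frame(
    cell_id = sprintf("c%06d", seq_len(N)),
    donor = genotypes$donors[donor_idx],
    cell_type = cts$cell_type[ct_idx],
    n_umi = colSums(counts),
    pct_mito = round(pct_mito, 5),
    pseudotime = pt,
    stringsAsFactors = FALSE
  )
  list(cells = cell_table(counts, meta, genes), truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()] and [simulate_cells()].
#' Deterministic under a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genotypes`, `cells`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genotypes <- simulate_genotypes(config)
  sc <- simulate_cells(config, genotypes)
  list(config = config, genotypes = genotypes, cells = sc$cells,
       truth = sc$truth)
}

#' Write a simulated cohort to standard on-disk formats
#'
#' Emits `genotypes.vcf` (VCF v4.2 with GT and DS), `counts.mtx` +
#' `features.tsv` + `barcodes.tsv`, cell metadata (`cells.tsv`), a TSS table
#' (`tss.tsv`), a chromatin-state track (`states.bed`, BED4, 0-based
#' half-open, 15 ChromHMM-style labels), an ATAC-peak track (`peaks.bed`,
#' BED4 with group labels), and the ground truth (`truth.tsv`). All files are
#' plain text; [read_fixture()] reproduces the matrices exactly.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- sim$genotypes
  set.seed(child_seed(sim$config$seed, "fixture"))

  ## VCF
  dos <- t(gt$dosage)  # variant x donor
  gt_str <- matrix(c("0/0", "0/1", "1/1")[round(dos) + 1], nrow(dos))
  body <- matrix(paste0(gt_str, ":", formatC(dos, format = "g", digits = 17)),
                 nrow(dos))
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$donors), collapse = "\t"),
    paste(gt$variants$chrom, gt$variants$pos, gt$variants$variant_id,
          gt$variants$ref, gt$variants$alt, ".", "PASS",
          sprintf("MAF=%s;R2=%s", signif(gt$variants$maf, 6),
                  gt$variants$impq),
          "GT:DS", apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(vcf, file.path(dir, "genotypes.vcf"))

  ## counts
  Matrix::writeMM(sim$cells$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(sim$cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sim$cells$counts), file.path(dir, "barcodes.tsv"))
  write.table(sim$cells$meta, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tss <- with(sim$cells$genes,
              data.frame(gene_id = gene_id, chrom = chrom, tss_pos = tss,
                         strand = strand))
  write.table(tss, file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## annotation tracks (synthetic): chromatin states tile the chromosome,
  ## peaks are scattered windows with group labels
  span <- max(gt$variants$pos) + 10000L
  starts <- seq(0L, span, by = 2000L)
  states <- data.frame(
    chrom = "chr1", start = starts, end = pmin(starts + 2000L, span + 2000L),
    label = sample(chromhmm15_labels(), length(starts), replace = TRUE))
  write.table(states, file.path(dir, "states.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pk_start <- sort(sample.int(span, min(200L, max(10L, span %/% 10000L))))
  peaks <- data.frame(
    chrom = "chr1", start = pk_start, end = pk_start + 500L,
    label = sample(c("cell-type-specific", "multi-category", "other"),
                   length(pk_start), replace = TRUE, prob = c(.4, .3, .3)))
  write.table(peaks, file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

# The 15 ChromHMM core-model state mnemonics.
chromhmm15_labels <- function() {
  c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG", "7_Enh",
    "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk", "12_EnhBiv",
    "13_ReprPC", "14_ReprPCWk", "15_Quies")
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `genotypes` (a `genotype_matrix`; `maf`/`impq` from the
#'   VCF INFO field, `emp_maf` recomputed), `cells` (a [cell_table()]) and
#'   `truth`.
#' @export
read_fixture <- function(dir) {
  v <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS")
  dosage <- t(apply(ds, 1, as.numeric))
  colnames(dosage) <- colnames(ds)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, element = "MAF")
  impq <- vcfR::extract.info(v, element = "R2")
  dosage <- t(dosage)  # donor x variant
  colnames(dosage) <- fix$ID
  variants <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = as.numeric(info),
    emp_maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
    impq = as.numeric(impq), stringsAsFactors = FALSE)
  genotypes <- structure(
    list(dosage = dosage, variants = variants, donors = rownames(dosage)),
    class = "genotype_matrix")

  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes_id <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.table(file.path(dir, "cells.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  tss <- read.table(file.path(dir, "tss.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = genes_id, stringsAsFactors = FALSE)
  genes <- merge(genes, data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                                   tss = tss$tss_pos, strand = tss$strand),
                 by = "gene_id", sort = FALSE)
  dimnames(counts) <- list(genes_id, barcodes)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  list(genotypes = genotypes, cells = cell_table(counts, meta, genes),
       truth = truth)
}
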