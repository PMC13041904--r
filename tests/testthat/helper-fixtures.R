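# Shared small fixtures, built once per test run.

.fixture_env <- new.env()

# A modest cohort with injected effects, reused by several files.
small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    cfg <- sim_config(n_donors = 80, n_variants = 80, n_genes = 30,
                      n_cell_types = 2,
                      cells_per_donor_per_type = c(mean = 15, dispersion = 8),
                      seed = 101)
    .fixture_env$small_sim <- simulate_cohort(cfg)
  }
  .fixture_env$small_sim
}

small_pb <- function() {
  if (is.null(.fixture_env$small_pb))
    .fixture_env$small_pb <- pseudobulk(small_sim()$cells, min_donors = 40)
  .fixture_env$small_pb
}

# Wrap a bare dosage matrix as a genotype_matrix with evenly spaced
# positions (used to feed hand-constructed dosages into the mappers).
make_genotypes <- function(dosage, pos = NULL, maf = NULL, impq = NULL) {
  V <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%04d", seq_len(V))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("D%03d", seq_len(nrow(dosage)))
  emp <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  structure(list(
    dosage = dosage,
    variants = data.frame(
      variant_id = colnames(dosage), chrom = "chr1",
      pos = pos %||% (1000L * seq_len(V)),
      ref = "A", alt = "G",
      maf = maf %||% emp, emp_maf = emp,
      impq = impq %||% rep(1, V), stringsAsFactors = FALSE),
    donors = rownames(dosage)), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal cell_table from per-cell gene counts and metadata vectors.
make_cells <- function(counts, donor, cell_type,
                       pseudotime = rep(1, length(donor))) {
  counts <- as.matrix(counts)
  meta <- data.frame(
    cell_id = sprintf("c%05d", seq_along(donor)),
    donor = donor, cell_type = cell_type,
    n_umi = colSums(counts), pct_mito = 0.05, pseudotime = pseudotime,
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(counts) %||%
                        sprintf("g%03d", seq_len(nrow(counts))),
                      chrom = "chr1",
                      tss = 1000L * seq_len(nrow(counts)), strand = "+",
                      stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene_id
  cell_table(counts, meta, genes)
}

# Simulate a locus: genotypes with block LD, two traits with chosen causal
# variants, and per-variant marginal summary statistics.
sim_locus <- function(n = 4000, V = 40, causal1 = 20, causal2 = 20,
                      b1 = 0.3, b2 = 0.25, seed = 1) {
  set.seed(seed)
  maf <- runif(V, 0.1, 0.5)
  blk <- ceiling(seq_len(V) / 8)
  G <- matrix(0L, n, V)
  for (hap in 1:2) {
    u <- matrix(rnorm(n * max(blk)), n, max(blk))
    z <- sqrt(0.8) * u[, blk] + sqrt(0.2) * matrix(rnorm(n * V), n, V)
    G <- G + (z < rep(qnorm(maf), each = n))
  }
  y1 <- if (is.na(causal1)) rnorm(n) else b1 * G[, causal1] + rnorm(n)
  y2 <- if (is.na(causal2)) rnorm(n) else b2 * G[, causal2] + rnorm(n)
  ss <- function(y) t(sapply(seq_len(V), function(j)
    summary(lm(y ~ G[, j]))$coefficients[2, 1:2]))
  s1 <- ss(y1); s2 <- ss(y2)
  list(G = G, maf = maf, n = n,
       s1 = data.frame(id = paste0("v", 1:V), beta = s1[, 1], se = s1[, 2]),
       s2 = data.frame(id = paste0("v", 1:V), beta = s2[, 1], se = s2[, 2]))
}

# Redraw a genotype cohort with the same per-variant MAFs and LD blocks as
# an existing genotype_matrix (e.g. a larger GWAS panel on shared variants).
regen_genotypes <- function(variants, n, ld_rho = 0.8, seed = 1,
                            prefix = "G") {
  set.seed(seed)
  V <- nrow(variants)
  blk <- variants$block
  thr <- qnorm(variants$maf)
  dosage <- matrix(0L, n, V)
  for (hap in 1:2) {
    u <- matrix(rnorm(n * max(blk)), n, max(blk))
    z <- sqrt(ld_rho) * u[, blk, drop = FALSE] +
      sqrt(1 - ld_rho) * matrix(rnorm(n * V), n, V)
    dosage <- dosage + (z < rep(thr, each = n))
  }
  dimnames(dosage) <- list(sprintf("%s%04d", prefix, seq_len(n)),
                           variants$variant_id)
  dosage
}

# Closed-form OLS oracle: full design (intercept + covariates + dosage),
# coded independently of the package's residualization path.
ols_oracle <- function(y, g, C = NULL) {
  X <- cbind(1, C, g)
  XtX <- crossprod(X)
  bh <- solve(XtX, crossprod(X, y))
  res <- y - X %*% bh
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  j <- ncol(X)
  t <- unname(bh[j] / se[j])
  list(beta = unname(bh[j]), se = unname(se[j]), t = t,
       p = 2 * pt(-abs(t), df), df = df)
}
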