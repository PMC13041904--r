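test_that("nominal pass matches the closed-form OLS oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(20:50, 1)
    k <- sample(0:min(20, n - 5), 1)
    C <- if (k > 0) matrix(rnorm(n * k), n,
                           dimnames = list(NULL, paste0("c", 1:k)))
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (sd(g) == 0) next
    y <- rnorm(n)
    gt <- make_genotypes(matrix(g, n, 1), pos = 500L)
    expr <- matrix(y, 1, n, dimnames = list("g1", rownames(gt$dosage)))
    gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = 500L,
                     strand = "+")
    if (!is.null(C)) rownames(C) <- rownames(gt$dosage)
    rec <- map_nominal(expr, gt, C, gi,
                       filter = variant_filter(min_maf = 1e-9))
    o <- ols_oracle(y, g, C)
    expect_equal(rec$beta, o$beta, tolerance = 1e-10)
    expect_equal(rec$se, o$se, tolerance = 1e-10)
    expect_equal(rec$p_nominal, o$p, tolerance = 1e-10)
    expect_equal(attr(rec, "df"), o$df)
  }
})

test_that("dosage orthogonal to the phenotype gives beta 0, p 1", {
  n <- 24
  g <- rep(0:2, each = n / 3)
  y <- rep(c(-1, 0, 1), n / 3)          # orthogonal to g and to 1
  y <- residualize(y)                    # center
  y <- y - sum(y * (g - mean(g))) / sum((g - mean(g))^2) * (g - mean(g))
  gt <- make_genotypes(matrix(g, n, 1), pos = 100L)
  expr <- matrix(y, 1, n, dimnames = list("g1", rownames(gt$dosage)))
  gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100L, strand = "+")
  rec <- map_nominal(expr, gt, NULL, gi,
                     filter = variant_filter(min_maf = 1e-9))
  expect_lt(abs(rec$beta), 1e-12)
  expect_equal(rec$p_nominal, 1, tolerance = 1e-12)
})

test_that("the cis window is inclusive at exactly 1 Mb from the TSS", {
  n <- 40
  set.seed(2)
  dos <- sapply(1:3, function(i) rbinom(n, 2, 0.4))
  tss <- 2e6L
  gt <- make_genotypes(dos, pos = c(tss - 1e6L, tss + 1e6L, tss + 1e6L + 1L))
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", rownames(gt$dosage)))
  gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = tss, strand = "+")
  rec <- map_nominal(expr, gt, NULL, gi,
                     filter = variant_filter(min_maf = 1e-9))
  expect_setequal(rec$variant_id, c("v0001", "v0002"))
  expect_equal(sort(abs(rec$tss_distance)), c(1e6, 1e6))
})

test_that("monomorphic variants are skipped with a log message", {
  n <- 30
  dos <- cbind(rbinom(n, 2, 0.4), rep(1L, n))
  gt <- make_genotypes(dos, pos = c(100L, 200L), maf = c(0.4, 0.3))
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", rownames(gt$dosage)))
  gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = 150L, strand = "+")
  expect_message(rec <- map_nominal(expr, gt, NULL, gi,
                                    filter = variant_filter(min_maf = 1e-9)),
                 "monomorphic")
  expect_equal(rec$variant_id, "v0001")
})

test_that("rank-deficient covariates raise an error", {
  sim <- small_sim()
  pb <- small_pb()
  ct <- names(pb$cell_types)[1]
  donors <- pb$cell_types[[ct]]$donors
  C <- cbind(a = rnorm(length(donors)))
  C <- cbind(C, b = 2 * C[, 1])
  rownames(C) <- donors
  expect_error(map_nominal(pb$cell_types[[ct]]$normalized, sim$genotypes,
                           C, pb$gene_info), "rank-deficient")
})

test_that("flipping ref/alt coding flips beta's sign exactly", {
  sim <- small_sim()
  pb <- small_pb()
  ct <- names(pb$cell_types)[1]
  rec1 <- map_nominal(pb$cell_types[[ct]]$normalized, sim$genotypes, NULL,
                      pb$gene_info)
  gt2 <- sim$genotypes
  gt2$dosage <- 2 - gt2$dosage
  rec2 <- map_nominal(pb$cell_types[[ct]]$normalized, gt2, NULL,
                      pb$gene_info)
  expect_equal(rec1$beta, -rec2$beta, tolerance = 1e-12)
  expect_equal(rec1$p_nominal, rec2$p_nominal, tolerance = 1e-12)
})

test_that("permutation pass: single-variant null gives uniform minima", {
  set.seed(4)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  gt <- make_genotypes(matrix(g, n, 1), pos = 100L)
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", rownames(gt$dosage)))
  gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100L, strand = "+")
  eg <- map_permutation(expr, gt, NULL, gi, n_perm = 5000, seed = 10,
                        filter = variant_filter(min_maf = 1e-9))
  expect_gte(eg$beta_shape1, 0.8); expect_lte(eg$beta_shape1, 1.25)
  expect_gte(eg$beta_shape2, 0.8); expect_lte(eg$beta_shape2, 1.25)
})

test_that("permutation pass is deterministic and refuses tiny n_perm", {
  sim <- small_sim()
  pb <- small_pb()
  ct <- names(pb$cell_types)[1]
  expr <- pb$cell_types[[ct]]$normalized[1:5, , drop = FALSE]
  e1 <- map_permutation(expr, sim$genotypes, NULL, pb$gene_info,
                        n_perm = 150, seed = 42)
  e2 <- map_permutation(expr, sim$genotypes, NULL, pb$gene_info,
                        n_perm = 150, seed = 42)
  expect_identical(e1, e2)
  expect_error(map_permutation(expr, sim$genotypes, NULL, pb$gene_info,
                               n_perm = 50), "refusing")
  # both permutation schemes agree on a covariate-free design
  e3 <- map_permutation(expr, sim$genotypes, NULL, pb$gene_info,
                        n_perm = 150, seed = 42, permute = "phenotype")
  expect_equal(e1$p_beta_adjusted, e3$p_beta_adjusted, tolerance = 0.15)
})

test_that("Storey q-values: edge cases and monotonicity", {
  # all p = 1: no eGenes
  eg <- data.frame(gene_id = paste0("g", 1:30), p_beta_adjusted = 1)
  called <- call_egenes(eg)
  expect_equal(sum(called$egene), 0)
  # monotone in p
  set.seed(8)
  p <- runif(200)^2
  q <- storey_qvalue(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # fewer than 20 genes: BH-equivalent fallback with warning
  expect_warning(q2 <- storey_qvalue(runif(10)), "pi0 = 1")
  expect_equal(attr(q2, "pi0"), 1)
})

test_that("NB mapper approaches the Poisson limit and skips zero genes", {
  set.seed(13)
  n <- 80
  g <- rbinom(n, 2, 0.4)
  lib <- rep(5000, n)
  mu <- exp(log(lib) - 4 + 0.3 * g)
  y <- rpois(n, mu)                      # dispersion-free counts
  raw <- rbind(g1 = y, g0 = rep(0L, n))
  colnames(raw) <- sprintf("D%03d", 1:n)
  gt <- make_genotypes(matrix(g, n, 1), pos = 100L)
  gi <- data.frame(gene_id = c("g1", "g0"), chrom = "chr1",
                   tss = c(100L, 100L), strand = "+")
  expect_message(rec <- map_nb(raw, gt, NULL, gi, lib_size = setNames(lib,
                               colnames(raw)),
                               filter = variant_filter(min_maf = 1e-9)),
                 "all-zero")
  pois <- glm(y ~ g + offset(log(lib)), family = poisson())
  zp <- summary(pois)$coefficients["g", "z value"]
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$z_stat / zp - 1), 0.01)
})

test_that("NB mapper recovers a known log-scale effect", {
  set.seed(17)
  n <- 100
  hits <- 0; total <- 200
  for (r in seq_len(total)) {
    g <- rbinom(n, 2, 0.3)
    if (sd(g) == 0) { total <- total - 1; next }
    lib <- round(exp(rnorm(n, log(2e4), 0.2)))
    mu <- exp(log(lib) - 6 + 0.5 * g)
    y <- rnbinom(n, mu = mu, size = 3)
    raw <- rbind(g1 = y)
    colnames(raw) <- sprintf("D%03d", 1:n)
    gt <- make_genotypes(matrix(g, n, 1), pos = 100L)
    gi <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100L,
                     strand = "+")
    rec <- map_nb(raw, gt, NULL, gi,
                  lib_size = setNames(lib, colnames(raw)),
                  filter = variant_filter(min_maf = 1e-9))
    if (abs(rec$beta - 0.5) <= 3 * rec$se) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("type-I error is controlled on a null cohort", {
  grid <- data.frame(pattern = "null", beta = 0, slope = 0, weight = 1)
  cfg <- sim_config(n_donors = 60, n_variants = 40, n_genes = 40,
                    n_cell_types = 1, effect_grid = grid,
                    cells_per_donor_per_type = c(mean = 10, dispersion = 8),
                    seed = 77)
  sim <- simulate_cohort(cfg)
  pb <- pseudobulk(sim$cells, min_donors = 40, min_fraction = 0)
  ct <- names(pb$cell_types)[1]
  nom <- map_nominal(pb$cell_types[[ct]]$normalized, sim$genotypes, NULL,
                     pb$gene_info)
  ks <- suppressWarnings(ks.test(nom$p_nominal, "punif"))
  expect_gt(ks$p.value, 0.01)
})
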