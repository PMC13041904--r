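# build a cell_table with a single gene following the NBME generative model
sim_dynamic_cells <- function(n_donors = 120, cells = 6, beta = 0.3,
                              slope = 0, donor_sd = 0.3, theta = 2,
                              maf = 0.3, seed = 1, n_inf = 0) {
  set.seed(seed)
  donors <- sprintf("D%03d", seq_len(n_donors))
  dos_d <- rbinom(n_donors, 2, maf)
  N <- n_donors * cells
  donor <- rep(donors, each = cells)
  pt <- runif(N, 0, 30)
  if (n_inf > 0) pt[sample(N, n_inf)] <- Inf
  q <- rep(NA_real_, N)
  fin <- is.finite(pt)
  q[fin] <- floor((rank(pt[fin], ties.method = "first") - 1) * 6 /
                    sum(fin)) + 1
  qc <- ifelse(fin, q - 3.5, 0)
  sf <- round(exp(rnorm(N, log(2000), 0.3)))
  u <- rep(rnorm(n_donors, 0, donor_sd), each = cells)
  dos <- rep(dos_d, each = cells)
  mu <- sf / 2000 * exp(-1 + beta * dos + slope * qc * dos + u)
  y <- rnbinom(N, mu = mu, size = theta)
  filler <- rnbinom(N, mu = sf / 10, size = 5)  # keeps n_umi > 0
  counts <- rbind(gene = y, filler = filler)
  meta <- data.frame(cell_id = sprintf("c%05d", 1:N), donor = donor,
                     cell_type = "AT2", n_umi = colSums(counts),
                     pct_mito = 0.05, pseudotime = pt,
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gene", "filler"), chrom = "chr1",
                      tss = c(1000L, 5000L), strand = "+",
                      stringsAsFactors = FALSE)
  gt <- make_genotypes(matrix(dos_d, n_donors, 1,
                              dimnames = list(donors, "v0001")),
                       pos = 1000L)
  list(cells = cell_table(counts, meta, genes), genotypes = gt)
}

test_that("quantile bins have equal counts and drop infinite pseudotime", {
  mkcells <- function(n, n_inf = 0) {
    pt <- c(runif(n), rep(Inf, n_inf))
    make_cells(matrix(1L, 1, n + n_inf),
               donor = rep("d1", n + n_inf),
               cell_type = "AT2", pseudotime = pt)
  }
  a <- assign_quantiles(mkcells(600))
  expect_equal(unname(table(a$quantile)), rep(100L, 6), ignore_attr = TRUE)
  a2 <- assign_quantiles(mkcells(601))
  expect_equal(sort(as.vector(table(a2$quantile))), c(100, 100, 100, 100,
                                                      100, 101))
  a3 <- assign_quantiles(mkcells(600, n_inf = 10))
  expect_equal(sum(!is.na(a3$quantile)), 600)
  expect_equal(sum(is.na(a3$quantile)), 10)
  expect_error(assign_quantiles(mkcells(5)), "fewer than Q")
})

test_that("quantile assignment is invariant to monotone transforms", {
  set.seed(3)
  cells <- make_cells(matrix(1L, 1, 200), donor = rep("d1", 200),
                      cell_type = "AT2", pseudotime = runif(200, 0, 30))
  a1 <- assign_quantiles(cells)
  cells2 <- cells
  cells2$meta$pseudotime <- exp(cells$meta$pseudotime / 5)
  a2 <- assign_quantiles(cells2)
  expect_equal(a1$quantile, a2$quantile)
})

test_that("NBME estimates match the glmmTMB oracle", {
  skip_if_not_installed("glmmTMB")
  sd <- sim_dynamic_cells(n_donors = 100, cells = 8, beta = 0.3,
                          slope = 0.15, seed = 5)
  a <- assign_quantiles(sd$cells)
  rec <- fit_interaction(sd$cells, sd$genotypes, "gene", "v0001", a)
  idx <- match(a$cell_id, colnames(sd$cells$counts))
  df <- data.frame(y = as.integer(sd$cells$counts["gene", idx]),
                   dos = sd$genotypes$dosage[a$donor, "v0001"],
                   qc = a$quantile - mean(a$quantile),
                   numi = sd$cells$meta$n_umi[idx], donor = a$donor)
  tmb <- glmmTMB::glmmTMB(y ~ dos * qc + offset(log(numi)) + (1 | donor),
                          family = glmmTMB::nbinom2, data = df)
  cf <- summary(tmb)$coefficients$cond["dos:qc", ]
  expect_equal(rec$beta_interaction, unname(cf[1]), tolerance = 1e-3)
  expect_equal(rec$se_interaction, unname(cf[2]), tolerance = 1e-3)
  expect_equal(rec$p_interaction, unname(cf[4]), tolerance = 1e-2)
  # AGHQ refinement stays close to the Laplace fit
  rec9 <- fit_interaction(sd$cells, sd$genotypes, "gene", "v0001", a,
                          re_mode = "aghq")
  expect_equal(rec9$beta_interaction, rec$beta_interaction,
               tolerance = 5e-3)
})

test_that("zero donor variance reduces to the fixed-effect NB GLM", {
  sd <- sim_dynamic_cells(n_donors = 100, cells = 6, beta = 0.4,
                          slope = 0.1, donor_sd = 0, seed = 7)
  a <- assign_quantiles(sd$cells)
  rec <- fit_interaction(sd$cells, sd$genotypes, "gene", "v0001", a)
  expect_lt(rec$sigma, 0.05)
  idx <- match(a$cell_id, colnames(sd$cells$counts))
  y <- as.integer(sd$cells$counts["gene", idx])
  dos <- sd$genotypes$dosage[a$donor, "v0001"]
  qc <- a$quantile - mean(a$quantile)
  numi <- sd$cells$meta$n_umi[idx]
  glmfit <- suppressWarnings(
    MASS::glm.nb(y ~ dos * qc + offset(log(numi))))
  expect_equal(rec$beta_interaction,
               unname(coef(glmfit)["dos:qc"]), tolerance = 1e-3)
  # fixed-effect oracle with observed-information Wald SEs (the mixed
  # model quantifies curvature, not Fisher-scoring expected information)
  mu <- fitted(glmfit); th <- glmfit$theta
  w <- (y + th) * th * mu / (mu + th)^2
  Xf <- cbind(1, dos, qc, dos * qc)
  se_obs <- sqrt(diag(solve(t(Xf) %*% (Xf * w))))[4]
  z_obs <- coef(glmfit)["dos:qc"] / se_obs
  p_glm <- unname(2 * pnorm(-abs(z_obs)))
  expect_lt(abs(rec$p_interaction / p_glm - 1), 0.10)
})

test_that("trend classification handles the canonical shapes", {
  tiny <- rep(1e-4, 6)
  lin <- classify_trend(c(1, 2, 3, 4, 5, 6), tiny)
  expect_equal(lin$trend_class, "linear")
  expect_lt(lin$p_linear, 1e-10)
  quad <- classify_trend(c(4, 1, 0, 0, 1, 4), tiny)
  expect_equal(quad$trend_class, "quadratic")
  none <- classify_trend(rep(2, 6), tiny)
  expect_equal(none$trend_class, "none")
  # fewer than 4 usable points: none, flagged via n_used
  few <- classify_trend(c(1, 2, NA, NA, NA, 6), c(tiny[1:2], NA, NA, NA,
                                                  tiny[6]))
  expect_equal(few$trend_class, "none")
  expect_equal(few$n_used, 3)
})

test_that("per-quantile effects recover a constant allelic effect", {
  covered <- integer(0)
  for (s in 1:6) {
    sd <- sim_dynamic_cells(n_donors = 80, cells = 12, beta = 0.5,
                            slope = 0, seed = 100 + s)
    a <- assign_quantiles(sd$cells)
    pq <- per_quantile_effects(sd$cells, sd$genotypes, "gene", "v0001", a,
                               min_cells = 30)
    ok <- !is.na(pq$beta)
    covered <- c(covered, abs(pq$beta[ok] - 0.5) <= 3 * pq$se[ok])
  }
  expect_gte(mean(covered), 0.90)
})

test_that("a sign-flipping effect is detected at the trajectory ends", {
  flips <- 0
  for (s in 1:6) {
    sd <- sim_dynamic_cells(n_donors = 100, cells = 12, beta = 0,
                            slope = 0.4, seed = 200 + s)
    a <- assign_quantiles(sd$cells)
    pq <- per_quantile_effects(sd$cells, sd$genotypes, "gene", "v0001", a,
                               min_cells = 30)
    if (!is.na(pq$beta[1]) && !is.na(pq$beta[6]) &&
        sign(pq$beta[1]) != sign(pq$beta[6])) flips <- flips + 1
  }
  expect_gte(flips / 6, 0.90)
})

test_that("quantiles without alternative-allele carriers yield NA", {
  # donors partition cleanly into quantiles (constant pseudotime per donor)
  sd <- sim_dynamic_cells(n_donors = 60, cells = 10, beta = 0.4,
                          maf = 0.3, seed = 11)
  sd$cells$meta$pseudotime <- rep(seq_len(60) / 2, each = 10)
  a <- assign_quantiles(sd$cells)
  q3_donors <- unique(a$donor[!is.na(a$quantile) & a$quantile == 3])
  gt <- sd$genotypes
  gt$dosage[q3_donors, 1] <- 0L
  expect_message(
    pq <- per_quantile_effects(sd$cells, gt, "gene", "v0001", a,
                               min_cells = 10),
    "no dosage variation")
  expect_true(is.na(pq$beta[3]))
  expect_gt(sum(!is.na(pq$beta)), 0)
})

test_that("regulon trends flag linear and quadratic activity shapes", {
  set.seed(21)
  n <- 600
  cells <- make_cells(matrix(1L, 1, n), donor = rep("d1", n),
                      cell_type = "AT2", pseudotime = runif(n, 0, 30))
  a <- assign_quantiles(cells)
  q <- a$quantile
  act <- rbind(lin = q + rnorm(n, 0, 0.1),
               par = -(q - 3.5)^2 + rnorm(n, 0, 0.1),
               flat = rep(1, n),
               noise = rnorm(n))
  colnames(act) <- a$cell_id
  rt <- regulon_trends(act, a)
  expect_true(rt$significant[rt$regulon_id == "lin"])
  expect_lt(rt$p_linear[rt$regulon_id == "lin"], 1e-10)
  par_row <- rt[rt$regulon_id == "par", ]
  expect_lt(par_row$p_quadratic, 1e-10)
  expect_lt(par_row$quad_coef, 0)
  expect_false(rt$significant[rt$regulon_id == "flat"])
  expect_equal(rt$p_linear[rt$regulon_id == "flat"], 1)
})

test_that("regulon trend test is calibrated under the null", {
  set.seed(23)
  n <- 300
  cells <- make_cells(matrix(1L, 1, n), donor = rep("d1", n),
                      cell_type = "AT2", pseudotime = runif(n, 0, 30))
  a <- assign_quantiles(cells)
  act <- matrix(rnorm(1000 * n), 1000, n,
                dimnames = list(paste0("r", 1:1000), a$cell_id))
  rt <- regulon_trends(act, a)
  fp <- mean(rt$significant)
  # two tests at 0.05 each, so the family-wise flag rate sits near 0.1
  expect_gt(fp, 0.03); expect_lt(fp, 0.17)
  expect_lt(abs(mean(rt$p_linear < 0.05) - 0.05), 0.03)
})

test_that("gene-list overlaps count intersections exactly", {
  genes <- sprintf("g%03d", 1:494)
  other <- c(sprintf("g%03d", 1:10), sprintf("x%03d", 1:26))
  ov <- overlap_summary(genes, list(gwas = other, none = "zzz",
                                    self = genes))
  expect_equal(ov$gwas$n_overlap, 10)
  expect_equal(ov$none$n_overlap, 0)
  expect_equal(ov$self$n_overlap, 494)
  expect_equal(ov$n_dynamic, 494)
})
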