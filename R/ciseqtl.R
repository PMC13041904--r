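#' Variant inclusion filter for eQTL mapping
#'
#' @param min_maf minimum in-sample minor allele frequency (exclusive,
#'   default 0.05).
#' @param min_impq minimum imputation quality R^2 (exclusive, default 0.3).
#' @param cis_window cis window around the TSS in bp (inclusive at exactly
#'   +/- `cis_window`; default 1e6).
#' @return list of class `variant_filter`.
#' @export
variant_filter <- function(min_maf = 0.05, min_impq = 0.3,
                           cis_window = 1e6) {
  stopifnot(min_maf > 0, min_impq > 0, cis_window > 0)
  structure(list(min_maf = min_maf, min_impq = min_impq,
                 cis_window = cis_window), class = "variant_filter")
}

# Align expression, genotypes and covariates on shared donors; residualize
# both phenotype and dosage against the covariates (plus intercept), the
# Frisch-Waugh projection that makes per-variant OLS exact.
prepare_cis_inputs <- function(expr, genotypes, covariates, gene_info,
                               filter) {
  donors <- intersect(colnames(expr), rownames(genotypes$dosage))
  if (!is.null(covariates)) donors <- intersect(donors, rownames(covariates))
  n <- length(donors)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < k + 3) stop("need at least 2 more donors than model parameters")
  C <- if (k) covariates[donors, , drop = FALSE] else NULL
  if (k && qr(cbind(1, C))$rank < k + 1) stop("rank-deficient covariates")

  v <- genotypes$variants
  maf <- pmin(colMeans(genotypes$dosage[donors, , drop = FALSE]) / 2,
              1 - colMeans(genotypes$dosage[donors, , drop = FALSE]) / 2)
  impq <- v$impq %||% rep(1, nrow(v))
  pass <- maf > filter$min_maf & impq > filter$min_impq
  mono <- apply(genotypes$dosage[donors, , drop = FALSE], 2, sd) == 0
  if (any(pass & mono))
    message(sum(pass & mono), " monomorphic-in-sample variants skipped")
  pass <- pass & !mono

  G <- genotypes$dosage[donors, pass, drop = FALSE]
  Gr <- residualize(G, C)
  Y <- t(expr[, donors, drop = FALSE])
  Yr <- residualize(Y, C)
  genes <- intersect(rownames(expr), gene_info$gene_id)
  gi <- gene_info[match(genes, gene_info$gene_id), , drop = FALSE]
  list(donors = donors, df = n - k - 2L, Gr = Gr, Yr = Yr,
       variants = v[pass, , drop = FALSE], maf = maf[pass], genes = gi)
}

# Signed TSS distance in the direction of transcription.
tss_dist <- function(pos, tss, strand) {
  sgn <- ifelse(strand == "-", -1, 1)
  sgn * (pos - tss)
}

#' Nominal cis-eQTL pass (linear model)
#'
#' For each gene and each variant within the cis window of its TSS, fits an
#' ordinary least-squares model of the normalized phenotype on allele dosage
#' with covariates, and reports the dosage effect. Computation residualizes
#' phenotype and dosage against the covariates once and then performs exact
#' per-variant OLS (Frisch-Waugh), with two-sided p from the t distribution
#' on n - (covariates + 2) degrees of freedom.
#'
#' @param expr gene x donor phenotype matrix (normalized pseudo-bulk).
#' @param genotypes a `genotype_matrix` (dosage = alternative-allele count).
#' @param covariates donor x k covariate matrix (or NULL).
#' @param gene_info data.frame with gene_id, tss, strand (and chrom).
#' @param filter a [variant_filter()].
#' @return data.frame with gene_id, variant_id, tss_distance, beta, se,
#'   t_stat, p_nominal, maf — one row per tested (gene, cis variant) pair.
#' @export
map_nominal <- function(expr, genotypes, covariates = NULL, gene_info,
                        filter = variant_filter()) {
  pr <- prepare_cis_inputs(expr, genotypes, covariates, gene_info, filter)
  gss <- colSums(pr$Gr^2)
  res <- lapply(seq_len(nrow(pr$genes)), function(i) {
    g <- pr$genes[i, ]
    d <- tss_dist(pr$variants$pos, g$tss, g$strand)
    S <- which(abs(d) <= filter$cis_window)
    if (!length(S)) return(NULL)
    y <- pr$Yr[, g$gene_id]
    yy <- sum(y^2)
    xy <- as.vector(crossprod(pr$Gr[, S, drop = FALSE], y))
    beta <- xy / gss[S]
    rss <- pmax(yy - beta * xy, 0)
    se <- sqrt(rss / pr$df / gss[S])
    t_stat <- ifelse(se > 0, beta / se, 0)
    data.frame(gene_id = g$gene_id, variant_id = pr$variants$variant_id[S],
               tss_distance = d[S], beta = beta, se = se, t_stat = t_stat,
               p_nominal = 2 * pt(-abs(t_stat), pr$df), maf = pr$maf[S],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "df") <- pr$df
  out
}

# ML fit of a Beta distribution to permutation minimum p-values:
# method-of-moments start, then direct likelihood maximization.
fit_beta_ml <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  m <- mean(p); v <- var(p)
  if (v <= 0) v <- 1e-6
  c0 <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * c0, (1 - m) * c0), 1e-3))
  nll <- function(par) -sum(dbeta(p, exp(par[1]), exp(par[2]), log = TRUE))
  fit <- optim(start, nll, method = "L-BFGS-B", lower = -10, upper = 10)
  exp(fit$par)
}

#' Permutation pass with Beta approximation
#'
#' For each gene, the covariate-residualized phenotype is permuted across
#' donors `n_perm` times (dosage residuals held fixed) and the minimum cis
#' p-value recorded per permutation. A Beta(shape1, shape2) distribution is
#' fitted to the permutation minima by maximum likelihood and the gene-level
#' adjusted p-value is its CDF at the top nominal p. Alternatively
#' (`permute = "phenotype"`), raw phenotypes are permuted and re-residualized
#' each round.
#'
#' @inheritParams map_nominal
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; fixed seed gives identical records.
#' @param permute "residual" (fast, FastQTL-style) or "phenotype".
#' @return data.frame, one row per gene: gene_id, top variant and its
#'   nominal statistics, beta_shape1/2, p_perm_empirical =
#'   (1 + #\{min p <= observed\})/(1 + n_perm), p_beta_adjusted.
#' @export
map_permutation <- function(expr, genotypes, covariates = NULL, gene_info,
                            filter = variant_filter(), n_perm = 1000L,
                            seed = 1L, permute = c("residual", "phenotype")) {
  permute <- match.arg(permute)
  if (n_perm < 100) stop("n_perm < 100: Beta fit unstable; refusing")
  pr <- prepare_cis_inputs(expr, genotypes, covariates, gene_info, filter)
  n <- length(pr$donors); df <- pr$df
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  # unit-scaled residual dosages: correlations come from a single crossprod
  Gs <- sweep(pr$Gr, 2, sqrt(colSums(pr$Gr^2)), "/")
  C <- if (is.null(covariates)) NULL else covariates[pr$donors, , drop = FALSE]
  r2p <- function(r) {
    r2 <- pmin(r^2, 1 - 1e-14)
    2 * pt(-abs(r * sqrt(df / (1 - r2))), df)
  }
  res <- lapply(seq_len(nrow(pr$genes)), function(i) {
    g <- pr$genes[i, ]
    d <- tss_dist(pr$variants$pos, g$tss, g$strand)
    S <- which(abs(d) <= filter$cis_window)
    if (!length(S)) return(NULL)
    y <- pr$Yr[, g$gene_id]
    ys <- y / sqrt(sum(y^2))
    r_obs <- as.vector(crossprod(Gs[, S, drop = FALSE], ys))
    p_obs <- r2p(r_obs)
    # top variant: lowest p, then largest |t| (== largest |r|), then id
    ord <- order(p_obs, -abs(r_obs), pr$variants$variant_id[S])
    top <- ord[1]
    if (permute == "residual") {
      # re-projecting the permuted residuals onto the covariate-orthogonal
      # subspace keeps the permuted statistics on the same df as the
      # observed one (plain entry permutation leaves the subspace and
      # deflates the permuted correlations, making adjusted p too small)
      Yp <- residualize(matrix(y[perms], n, n_perm), C)
    } else {
      Yp <- residualize(matrix(t(expr[g$gene_id, pr$donors])[perms],
                               n, n_perm), C)
    }
    Yp <- sweep(Yp, 2, sqrt(colSums(Yp^2)), "/")
    rmax <- apply(abs(crossprod(Gs[, S, drop = FALSE], Yp)), 2, max)
    minp <- r2p(rmax)
    shp <- fit_beta_ml(minp)
    data.frame(gene_id = g$gene_id,
               top_variant = pr$variants$variant_id[S][top],
               beta_top = (sum(y^2) / sum(pr$Gr[, S[top]]^2))^0.5 *
                 sign(r_obs[top]) * abs(r_obs[top]),
               p_nominal_top = p_obs[top],
               n_cis_variants = length(S),
               beta_shape1 = shp[1], beta_shape2 = shp[2],
               p_perm_empirical = (1 + sum(minp <= p_obs[top])) / (1 + n_perm),
               p_beta_adjusted = pbeta(p_obs[top], shp[1], shp[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "df") <- df
  out
}

#' Call eGenes with Storey q-values
#'
#' Computes Storey q-values over the Beta-adjusted gene-level p-values, with
#' pi0 estimated at a single lambda = 0.5; with fewer than 20 genes, pi0
#' falls back to 1 (Benjamini-Hochberg-equivalent) with a warning.
#'
#' @param egenes output of [map_permutation()].
#' @param alpha eGene significance threshold on the q-value (default 0.05).
#' @return input with columns `q_value` and logical `egene` appended;
#'   attribute `pi0` records the null-proportion estimate.
#' @export
call_egenes <- function(egenes, alpha = 0.05) {
  q <- storey_qvalue(egenes$p_beta_adjusted)
  egenes$q_value <- as.numeric(q)
  egenes$egene <- egenes$q_value < alpha
  attr(egenes, "pi0") <- attr(q, "pi0")
  egenes
}

#' Nominal cis-eQTL pass by negative-binomial regression
#'
#' The count-based alternative mapper: per (gene, cis variant), a NB GLM with
#' log link of the raw pseudo-bulk counts on dosage and covariates, with the
#' log donor library size as offset; Wald test on the dosage coefficient and
#' per-gene dispersion by maximum likelihood. Non-converging fits fall back
#' to Poisson and are flagged.
#'
#' @param raw gene x donor matrix of raw pseudo-bulk counts.
#' @param genotypes,covariates,gene_info,filter as in [map_nominal()].
#' @param lib_size optional named donor library sizes (default: column sums
#'   of `raw`).
#' @return data.frame of per-pair records with columns gene_id, variant_id,
#'   tss_distance, beta, se, z_stat, p_nominal, maf, model ("nb"/"poisson").
#' @export
map_nb <- function(raw, genotypes, covariates = NULL, gene_info,
                   filter = variant_filter(), lib_size = NULL) {
  pr <- prepare_cis_inputs(log1p(raw), genotypes, covariates, gene_info,
                           filter)
  donors <- pr$donors
  if (is.null(lib_size)) lib_size <- colSums(raw[, donors, drop = FALSE])
  off <- log(lib_size[donors])
  C <- if (is.null(covariates)) NULL else covariates[donors, , drop = FALSE]
  G <- genotypes$dosage[donors, pr$variants$variant_id, drop = FALSE]
  res <- lapply(seq_len(nrow(pr$genes)), function(i) {
    g <- pr$genes[i, ]
    d <- tss_dist(pr$variants$pos, g$tss, g$strand)
    S <- which(abs(d) <= filter$cis_window)
    y <- raw[g$gene_id, donors]
    if (!length(S)) return(NULL)
    if (all(y == 0)) {
      message("gene ", g$gene_id, " all-zero; skipped")
      return(NULL)
    }
    do.call(rbind, lapply(S, function(j) {
      X <- cbind(dosage = G[, j], C)
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ X + offset(off))),
        error = function(e) NULL)
      model <- "nb"
      if (is.null(fit) || !fit$converged) {
        fit <- suppressWarnings(
          stats::glm(y ~ X + offset(off), family = stats::poisson()))
        model <- "poisson"
      }
      cf <- summary(fit)$coefficients[2, ]  # dosage is the first X column
      data.frame(gene_id = g$gene_id, variant_id = pr$variants$variant_id[j],
                 tss_distance = d[j], beta = cf[1], se = cf[2],
                 z_stat = cf[3], p_nominal = cf[4], maf = pr$maf[j],
                 model = model, stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  do.call(rbind, res)
}
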