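#' Harmonize two summary-statistics tables to a common allele orientation
#'
#' Joins on variant id and flips the sign of the second table's effect when
#' its effect/other alleles are swapped relative to the first; variants with
#' incompatible alleles are dropped with a message.
#'
#' @param ss1,ss2 data.frames with columns id, a1 (effect allele), a2,
#'   beta, se (others carried through with suffixes).
#' @return merged data.frame with beta_1/se_1 and harmonized beta_2/se_2.
#' @export
harmonize_alleles <- function(ss1, ss2) {
  m <- merge(ss1, ss2, by = "id", suffixes = c("_1", "_2"))
  same <- m$a1_1 == m$a1_2 & m$a2_1 == m$a2_2
  swap <- m$a1_1 == m$a2_2 & m$a2_1 == m$a1_2
  bad <- !(same | swap)
  if (any(bad)) {
    message(sum(bad), " variants with incompatible alleles dropped")
    m <- m[!bad, , drop = FALSE]; same <- same[!bad]; swap <- swap[!bad]
  }
  m$beta_2[swap] <- -m$beta_2[swap]
  m$a1_2 <- m$a1_1; m$a2_2 <- m$a2_1
  m
}

#' Define colocalization loci around GWAS top SNPs
#'
#' For each GWAS top SNP, collects the variants within +/- `window` bp
#' (boundaries inclusive) present in both the GWAS and eQTL summary
#' statistics; loci without any shared variant are dropped with a message.
#'
#' @param gwas data.frame with id, chrom, pos (and summary stats).
#' @param top_snps data.frame with id, chrom, pos of the GWAS lead SNPs.
#' @param eqtl data.frame of eQTL summary stats with an `id` column.
#' @param window half-width in bp (default 1e5).
#' @return named list (per top SNP) of character vectors of shared variant
#'   ids.
#' @export
define_loci <- function(gwas, top_snps, eqtl, window = 1e5) {
  shared <- intersect(gwas$id, eqtl$id)
  loci <- lapply(seq_len(nrow(top_snps)), function(i) {
    hit <- gwas$chrom == top_snps$chrom[i] &
      abs(gwas$pos - top_snps$pos[i]) <= window
    intersect(gwas$id[hit], shared)
  })
  names(loci) <- top_snps$id
  empty <- lengths(loci) == 0
  if (any(empty))
    message(sum(empty), " loci without shared eQTL variants dropped")
  loci[!empty]
}

# Wakefield log approximate Bayes factor for one trait.
wakefield_labf <- function(beta, se, W) {
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)
}

# coloc's internal estimator of the phenotype SD from summary statistics:
# var(beta_j) ~ sdY^2 / (2 n maf_j (1 - maf_j)), fitted through the origin.
estimate_sdY <- function(se, maf, n) {
  oneover <- 1 / se^2
  nvx <- 2 * n * maf * (1 - maf)
  sqrt(coef(lm(nvx ~ oneover - 1))[[1]])
}

#' Approximate-Bayes-factor colocalization for one locus
#'
#' Computes per-variant Wakefield log-ABFs for each trait and the posterior
#' probabilities of the five single-causal-variant hypotheses (H0: no
#' association; H1/H2: association with trait 1/2 only; H3: two distinct
#' causal variants; H4: one shared causal variant), summing Bayes factors in
#' log space. Prior variances follow the conventional defaults: quantitative
#' traits W = (0.15 sdY)^2 with sdY estimated from the summary statistics
#' when not supplied; case-control traits W = 0.2^2 on the log-odds scale.
#'
#' @param beta1,se1,beta2,se2 aligned per-variant effects and SEs.
#' @param snp optional variant ids.
#' @param type1,type2 "quant" or "cc" per trait.
#' @param sdY1,sdY2 phenotype SDs (quant traits; estimated from `maf` and
#'   `n` when NULL).
#' @param maf,n1,n2 per-variant MAFs and sample sizes for sdY estimation.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @return list: pp (PP.H0..PP.H4, summing to 1), n_variants, top_shared
#'   (variant with the largest H4 contribution), labf1, labf2. PP.H4 is
#'   invariant to trait order.
#' @export
coloc_abf <- function(beta1, se1, beta2, se2, snp = NULL,
                      type1 = "quant", type2 = "quant",
                      sdY1 = NULL, sdY2 = NULL, maf = NULL,
                      n1 = NULL, n2 = NULL,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  ok <- is.finite(beta1) & is.finite(se1) & is.finite(beta2) &
    is.finite(se2) & se1 > 0 & se2 > 0
  if (any(!ok)) message(sum(!ok), " variants with non-finite stats dropped")
  beta1 <- beta1[ok]; se1 <- se1[ok]; beta2 <- beta2[ok]; se2 <- se2[ok]
  snp <- (snp %||% paste0("v", seq_along(ok)))[ok]
  if (!length(beta1)) stop("no usable variants at locus")
  W_for <- function(type, sdY, se, n) {
    if (type == "cc") return(0.2^2)
    if (is.null(sdY)) {
      if (is.null(maf) || is.null(n))
        stop("quant trait needs sdY or (maf, n)")
      sdY <- estimate_sdY(se, maf[ok], n)
    }
    (0.15 * sdY)^2
  }
  l1 <- wakefield_labf(beta1, se1, W_for(type1, sdY1, se1, n1))
  l2 <- wakefield_labf(beta2, se2, W_for(type2, sdY2, se2, n2))
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  # sum over ordered pairs i != j of exp(l1_i + l2_j)
  s3 <- s1 + s2 + log1p(-exp(pmin(s12 - s1 - s2, 0)))
  if (!is.finite(s3)) s3 <- -Inf
  lh <- c(H0 = 0,
          H1 = log(p1) + s1, H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  # priors: H0 gets no per-SNP prior term beyond the complement; use the
  # standard normalization over the five hypothesis sums
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  h4_contrib <- l1 + l2
  list(pp = pp, n_variants = length(beta1),
       top_shared = snp[which.max(h4_contrib)],
       labf1 = setNames(l1, snp), labf2 = setNames(l2, snp))
}

#' Colocalization over a set of loci
#'
#' @param loci output of [define_loci()].
#' @param gwas,eqtl summary-statistics data.frames with id, beta, se (plus
#'   maf/n columns on the eQTL side if sdY must be estimated).
#' @param gwas_type,eqtl_type trait types as in [coloc_abf()].
#' @param pph4 reporting threshold (default 0.70).
#' @param ... forwarded to [coloc_abf()].
#' @return data.frame per locus with PP.H0..PP.H4, n_variants, top shared
#'   variant and `colocalized` (PP.H4 >= pph4).
#' @export
coloc_scan <- function(loci, gwas, eqtl, gwas_type = "cc",
                       eqtl_type = "quant", pph4 = 0.70, ...) {
  do.call(rbind, lapply(names(loci), function(lid) {
    ids <- loci[[lid]]
    gi <- gwas[match(ids, gwas$id), ]
    ei <- eqtl[match(ids, eqtl$id), ]
    cl <- coloc_abf(ei$beta, ei$se, gi$beta, gi$se, snp = ids,
                    type1 = eqtl_type, type2 = gwas_type,
                    maf = ei$maf, n1 = ei$n[1], ...)
    data.frame(locus = lid, t(cl$pp), n_variants = cl$n_variants,
               top_shared = cl$top_shared,
               colocalized = cl$pp[["PP.H4"]] >= pph4,
               stringsAsFactors = FALSE)
  }))
}

# Out-of-fold predictions for a weight vector fitted by `fit_fun(train)`.
cv_predictions <- function(X, y, k_folds, fit_fun, folds) {
  pred <- numeric(length(y))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    w <- fit_fun(X[tr, , drop = FALSE], y[tr])
    pred[!tr] <- X[!tr, , drop = FALSE] %*% w
  }
  pred
}

# Model fitters returning a weight vector over standardized dosages. Each
# penalized model's lambda is tuned once on the full data by cv.glmnet and
# then held fixed across CV folds and permutations; with a single cis
# variant all models reduce to the univariate predictor.
twas_fitters <- function(X, y) {
  top_snp <- function(Xt, yt) {
    b <- as.vector(crossprod(Xt, yt)) / colSums(Xt^2)
    t2 <- b^2 * colSums(Xt^2)
    w <- numeric(ncol(Xt)); j <- which.max(t2); w[j] <- b[j]; w
  }
  if (ncol(X) < 2)
    return(list(`top-snp` = top_snp, ridge = top_snp, lasso = top_snp,
                `elastic-net` = top_snp))
  pen <- function(alpha) {
    lam <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = 5)$lambda.min
    function(Xt, yt)
      as.vector(coef(glmnet::glmnet(Xt, yt, alpha = alpha,
                                    lambda = lam)))[-1]
  }
  list(`top-snp` = top_snp, ridge = pen(0), lasso = pen(1),
       `elastic-net` = pen(0.5))
}

#' Train cis expression-prediction weights for TWAS
#'
#' Fits four weight models on standardized cis dosages against the
#' covariate-residualized phenotype — top SNP, ridge (a BLUP surrogate with
#' CV-chosen penalty), lasso and elastic-net — scores each by k-fold
#' cross-validated R^2, and selects the best. The gene is retained when (i)
#' a permutation test of the best cv R^2 (refitting on permuted phenotypes)
#' gives p < 0.05, standing in for a cis-heritability filter, and (ii) the
#' correlation test of out-of-fold predictions against observations gives
#' p < 0.05.
#'
#' @param X donor x cis-variant dosage matrix.
#' @param y phenotype vector (residualized beforehand if covariates exist).
#' @param covariates optional donor x k matrix regressed out of `y` first.
#' @param k_folds cross-validation folds (default 5).
#' @param n_perm_h2 permutations for the heritability surrogate test
#'   (default 30; 0 skips the filter).
#' @param seed RNG seed (folds and permutations).
#' @return list of class `twas_model`: weights (named by variant),
#'   model_type, cv_r2, cv_p, heritability_p, retained, cv_r2_all.
#' @export
train_weights <- function(X, y, covariates = NULL, k_folds = 5L,
                          n_perm_h2 = 30L, seed = 1L) {
  set.seed(seed)
  if (!is.null(covariates)) y <- residualize(y, covariates)
  y <- as.vector(scale(y))
  sds <- apply(X, 2, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  n <- length(y)
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  fitters <- twas_fitters(X, y)
  r2 <- function(pred) {
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  preds <- lapply(fitters, function(f) cv_predictions(X, y, k_folds, f,
                                                      folds))
  cv_r2 <- vapply(preds, r2, 0)
  best <- names(which.max(cv_r2))
  if (max(cv_r2) <= 0) {
    message("all models have cv R^2 <= 0; gene dropped")
    return(structure(list(weights = NULL, model_type = NA_character_,
                          cv_r2 = max(cv_r2), cv_p = NA_real_,
                          heritability_p = NA_real_, retained = FALSE,
                          cv_r2_all = cv_r2), class = "twas_model"))
  }
  ct <- stats::cor.test(preds[[best]], y, alternative = "greater")
  h2_p <- NA_real_
  if (n_perm_h2 > 0) {
    null_r2 <- vapply(seq_len(n_perm_h2), function(i) {
      yp <- sample(y)
      r2p <- 1 - sum((yp - cv_predictions(X, yp, k_folds, fitters[[best]],
                                          folds))^2) /
        sum((yp - mean(yp))^2)
      r2p
    }, 0)
    h2_p <- (1 + sum(null_r2 >= cv_r2[best])) / (1 + n_perm_h2)
  }
  w <- fitters[[best]](X, y)
  names(w) <- colnames(X)
  retained <- ct$p.value < 0.05 && (n_perm_h2 == 0 || h2_p < 0.05) &&
    any(w != 0)
  structure(list(weights = w, model_type = best, cv_r2 = cv_r2[[best]],
                 cv_p = ct$p.value, heritability_p = h2_p,
                 retained = retained, cv_r2_all = cv_r2),
            class = "twas_model")
}

#' TWAS association from GWAS z-scores and an LD reference
#'
#' z_twas = w' z / sqrt(w' R w), with R the in-sample variant correlation
#' matrix regularized as (1 - eps) R + eps I; two-sided p from the standard
#' normal.
#'
#' @param weights named weight vector (a `twas_model$weights`).
#' @param z named GWAS z-scores.
#' @param R variant correlation matrix (from the reference dosages), with
#'   dimnames; only variants shared with `weights` are used.
#' @param eps ridge regularization (default 0.01).
#' @return list: z, p, n_variants; z is NA when the quadratic form is not
#'   positive.
#' @export
twas_associate <- function(weights, z, R, eps = 0.01) {
  ids <- intersect(names(weights), intersect(names(z), rownames(R)))
  if (!length(ids)) stop("no shared variants between weights, z and LD")
  w <- weights[ids]; zz <- z[ids]
  Rr <- (1 - eps) * R[ids, ids, drop = FALSE] + eps * diag(length(ids))
  denom <- as.numeric(t(w) %*% Rr %*% w)
  if (denom <= 0)
    return(list(z = NA_real_, p = NA_real_, n_variants = length(ids)))
  zt <- sum(w * zz) / sqrt(denom)
  list(z = zt, p = 2 * pnorm(-abs(zt)), n_variants = length(ids))
}

#' TWAS over many genes with FDR
#'
#' @param models named list of `twas_model`s (per gene); non-retained models
#'   are skipped.
#' @param z named GWAS z-scores.
#' @param R LD correlation matrix with dimnames.
#' @param eps regularization forwarded to [twas_associate()].
#' @return data.frame gene_id, z, p, fdr (BH across genes).
#' @export
twas_scan <- function(models, z, R, eps = 0.01) {
  keep <- names(models)[vapply(models, function(m) isTRUE(m$retained),
                               TRUE)]
  res <- do.call(rbind, lapply(keep, function(g) {
    a <- twas_associate(models[[g]]$weights, z, R, eps)
    data.frame(gene_id = g, z = a$z, p = a$p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(res)
  res$fdr <- p.adjust(res$p, "BH")
  res
}
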