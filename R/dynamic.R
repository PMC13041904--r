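#' Assign pseudotime quantile bins
#'
#' Cells with finite pseudotime (optionally restricted to the trajectory
#' cell types) are ranked and split into Q equal-count bins (sizes differ by
#' at most 1; ties broken by stable cell order). Cells with infinite
#' pseudotime get a missing quantile — they are off the trajectory and are
#' excluded from state-dependent models. The assignment is invariant to any
#' monotone transformation of pseudotime.
#'
#' @param cells a [cell_table()].
#' @param Q number of quantiles (default 6).
#' @param cell_types optional character vector restricting to trajectory
#'   cell types (e.g. the AT2 -> transitional -> AT1 branch).
#' @return data.frame cell_id, donor, cell_type, pseudotime, quantile
#'   (integer 1..Q or NA).
#' @export
assign_quantiles <- function(cells, Q = 6L, cell_types = NULL) {
  meta <- cells$meta
  if (!is.null(cell_types)) meta <- meta[meta$cell_type %in% cell_types, ]
  fin <- is.finite(meta$pseudotime)
  if (sum(fin) < Q)
    stop("fewer than Q = ", Q, " cells with finite pseudotime")
  qb <- rep(NA_integer_, nrow(meta))
  r <- rank(meta$pseudotime[fin], ties.method = "first")
  qb[fin] <- as.integer(floor((r - 1) * Q / sum(fin)) + 1L)
  data.frame(cell_id = meta$cell_id, donor = meta$donor,
             cell_type = meta$cell_type, pseudotime = meta$pseudotime,
             quantile = qb, stringsAsFactors = FALSE)
}

# Gauss-Hermite nodes/weights (physicists' convention) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, logw = log(sqrt(pi)) + 2 * log(abs(e$vectors[1, ])))
}

# NB log-likelihood terms in eta = log mu, dispersion theta (size).
nb_ll <- function(y, eta, theta) {
  mu <- exp(eta)
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta) + y * eta - (y + theta) * log(mu + theta)
}

# Per-donor concave 1-D Newton for the random-intercept modes given fixed
# (beta, theta, sigma); eta0 excludes u. Returns modes and curvatures.
nbme_modes <- function(y, eta0, theta, sigma, donor_idx, n_donor, u0) {
  u <- u0
  for (it in 1:40) {
    eta <- eta0 + u[donor_idx]
    mu <- exp(eta)
    w <- (y + theta) * mu / (mu + theta)
    grad <- rowsum(y - w, donor_idx, reorder = FALSE)[, 1] - u / sigma^2
    hess <- rowsum(w * theta / (mu + theta), donor_idx,
                   reorder = FALSE)[, 1] + 1 / sigma^2
    step <- grad / hess
    step <- pmin(pmax(step, -2), 2)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  eta <- eta0 + u[donor_idx]
  mu <- exp(eta)
  h <- rowsum((y + theta) * theta * mu / (mu + theta)^2, donor_idx,
              reorder = FALSE)[, 1] + 1 / sigma^2
  list(u = u, h = h)
}

#' Negative-binomial mixed-effects regression with a donor random intercept
#'
#' Fits counts ~ NB(mu, theta) with log mu = X beta + offset + u_donor,
#' u_donor ~ N(0, sigma^2). The 1-D random-effect integral per donor is
#' handled by a Laplace approximation around the per-donor mode (found by a
#' concave Newton iteration, vectorized across donors) or by adaptive
#' Gauss-Hermite quadrature; dispersion and the random-effect SD are
#' estimated jointly by maximum marginal likelihood. `re_mode = "fixed"`
#' replaces the random intercept by donor fixed effects (a slower reference
#' mode used as an oracle in testing).
#'
#' @param y integer counts per cell.
#' @param X fixed-effects design matrix (no intercept column; one is added).
#' @param offset per-cell log offset (e.g. log nUMI).
#' @param donor donor label per cell.
#' @param re_mode "laplace" (default), "aghq" or "fixed".
#' @param nodes Gauss-Hermite nodes for `re_mode = "aghq"` (default 9).
#' @return list with `coefficients` (data.frame term/estimate/se/z/p for the
#'   intercept and X columns), `theta`, `sigma`, `logLik`, `converged`.
#' @export
nbme_fit <- function(y, X, offset, donor, re_mode = c("laplace", "aghq",
                                                      "fixed"), nodes = 9L) {
  re_mode <- match.arg(re_mode)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (re_mode == "fixed") {
    dn <- factor(donor)
    XX <- if (nlevels(dn) > 1) cbind(X, stats::model.matrix(~dn)[, -1])
      else X
    fit <- suppressWarnings(MASS::glm.nb(y ~ XX + offset(offset)))
    cf <- summary(fit)$coefficients[seq_len(ncol(X) + 1), , drop = FALSE]
    return(list(coefficients = data.frame(
      term = c("(Intercept)", colnames(X)), estimate = cf[, 1],
      se = cf[, 2], z = cf[, 3], p = cf[, 4], row.names = NULL),
      theta = fit$theta, sigma = NA_real_, logLik = as.numeric(stats::logLik(fit)),
      converged = fit$converged))
  }

  dn <- factor(donor)
  donor_idx <- as.integer(dn)
  D <- nlevels(dn)
  Xf <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xf)
  gh <- if (re_mode == "aghq") gauss_hermite(nodes)

  # warm-started modes shared across objective evaluations
  u_env <- new.env(); u_env$u <- rep(0, D)
  rs <- function(v) rowsum(v, donor_idx, reorder = FALSE)[, 1]

  # Laplace objective with exact analytic gradient: the value uses the
  # envelope identity at the per-donor mode; the -0.5 log h term needs the
  # total derivative, including the mode shift du/dpsi = (d2f/du dpsi)/h.
  eval_laplace <- function(par, want_grad = TRUE) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1]); sigma <- exp(par[p + 2])
    eta0 <- as.vector(Xf %*% beta) + offset
    md <- nbme_modes(y, eta0, theta, sigma, donor_idx, D, u_env$u)
    u_env$u <- md$u
    uu <- md$u; h <- md$h
    eta <- eta0 + uu[donor_idx]
    mu <- exp(eta); den <- mu + theta
    value <- sum(nb_ll(y, eta, theta)) +
      sum(dnorm(uu, 0, sigma, log = TRUE)) +
      D * 0.5 * log(2 * pi) - 0.5 * sum(log(h))
    if (!want_grad) return(list(value = value))
    s <- y - (y + theta) * mu / den
    w <- (y + theta) * theta * mu / den^2
    tt <- (y + theta) * theta * mu * (theta - mu) / den^3
    Td <- rs(tt)
    Mw <- rowsum(Xf * w, donor_idx, reorder = FALSE)
    Mt <- rowsum(Xf * tt, donor_idx, reorder = FALSE)
    g_beta <- colSums(Xf * s) -
      0.5 * colSums((Mt - Mw * (Td / h)) / h)
    dll_dth <- digamma(y + theta) - digamma(theta) + 1 + log(theta) -
      log(den) - (y + theta) / den
    ds_dth <- -mu * (mu - y) / den^2
    dw_dth <- mu * ((y + 2 * theta) * den - 2 * theta * (y + theta)) / den^3
    du_dth <- rs(ds_dth) / h
    dh_dth <- rs(dw_dth) + Td * du_dth
    g_lth <- theta * (sum(dll_dth) - 0.5 * sum(dh_dth / h))
    du_dsg <- 2 * uu / (sigma^3 * h)
    dh_dsg <- -2 / sigma^3 + Td * du_dsg
    g_lsg <- sigma * (sum(uu^2 / sigma^3 - 1 / sigma) -
                        0.5 * sum(dh_dsg / h))
    list(value = value, grad = c(g_beta, g_lth, g_lsg))
  }

  marg_ll_aghq <- function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1]); sigma <- exp(par[p + 2])
    eta0 <- as.vector(Xf %*% beta) + offset
    md <- nbme_modes(y, eta0, theta, sigma, donor_idx, D, u_env$u)
    u_env$u <- md$u
    s2h <- sqrt(2 / md$h)
    lk <- vapply(seq_along(gh$nodes), function(k) {
      uk <- md$u + s2h * gh$nodes[k]
      rs(nb_ll(y, eta0 + uk[donor_idx], theta)) +
        dnorm(uk, 0, sigma, log = TRUE) + gh$logw[k] + gh$nodes[k]^2
    }, numeric(D))
    sum(apply(lk, 1, logsumexp) + log(s2h))
  }

  # starting values: Poisson GLM betas, moment dispersion, modest sigma
  start_fit <- suppressWarnings(
    stats::glm.fit(Xf, y, offset = offset, family = stats::poisson()))
  mu0 <- pmax(start_fit$fitted.values, 1e-8)
  disp <- max(mean(((y - mu0)^2 - mu0) / mu0^2), 0.01)
  par0 <- c(start_fit$coefficients, log(1 / disp), log(0.3))
  lower <- c(rep(-Inf, p), log(1e-4), log(1e-4))
  upper <- c(rep(Inf, p), log(1e6), log(5))
  cache <- new.env(); cache$par <- NULL
  memo <- function(par) {
    if (!identical(par, cache$par)) {
      cache$par <- par
      cache$ev <- eval_laplace(par)
    }
    cache$ev
  }
  opt <- tryCatch(
    if (re_mode == "laplace") {
      optim(par0, fn = function(par) -memo(par)$value,
            gr = function(par) -memo(par)$grad,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300))
    } else {
      optim(par0, fn = function(par) -marg_ll_aghq(par),
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300))
    },
    error = function(e) NULL)
  if (is.null(opt))
    return(list(coefficients = data.frame(
      term = c("(Intercept)", colnames(X)), estimate = NA_real_,
      se = NA_real_, z = NA_real_, p = NA_real_, row.names = NULL),
      theta = NA, sigma = NA, logLik = NA, converged = FALSE))
  H <- if (re_mode == "laplace") {
    # Hessian by central differences of the analytic gradient
    hh <- 1e-5 * pmax(1, abs(opt$par))
    Hm <- vapply(seq_along(opt$par), function(k) {
      e <- numeric(length(opt$par)); e[k] <- hh[k]
      (-eval_laplace(opt$par + e)$grad + eval_laplace(opt$par - e)$grad) /
        (2 * hh[k])
    }, numeric(length(opt$par)))
    (Hm + t(Hm)) / 2
  } else {
    tryCatch(optimHess(opt$par, function(par) -marg_ll_aghq(par)),
             error = function(e) NULL)
  }
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    # a collapsed variance component (sigma -> 0, no donor heterogeneity)
    # leaves a near-flat log-sigma direction that would contaminate the
    # inverted curvature; treat it as pinned at the boundary, so the fit
    # degenerates cleanly to the fixed-effect NB GLM
    free <- c(rep(TRUE, p),
              opt$par[p + 1] > lower[p + 1] + 1e-6 &
                opt$par[p + 1] < upper[p + 1] - 1e-6,
              exp(opt$par[p + 2]) > 0.01 &
                opt$par[p + 2] < upper[p + 2] - 1e-6)
    Vc <- tryCatch(solve(H[free, free, drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(Vc)) {
      dv <- diag(Vc)[seq_len(p)]
      se <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  est <- opt$par[seq_len(p)]
  z <- est / se
  list(coefficients = data.frame(term = colnames(Xf), estimate = est,
                                 se = se, z = z, p = 2 * pnorm(-abs(z)),
                                 row.names = NULL),
       theta = exp(opt$par[p + 1]), sigma = exp(opt$par[p + 2]),
       logLik = -opt$value, converged = opt$convergence == 0)
}

# Cell-level design pieces for one (gene, variant) pair, aligned on the
# quantile assignment; drops zero-UMI cells.
dynamic_design <- function(cells, genotypes, gene_id, variant_id,
                           assignment, covariates = NULL) {
  a <- assignment[!is.na(assignment$quantile), , drop = FALSE]
  idx <- match(a$cell_id, colnames(cells$counts))
  y <- as.integer(cells$counts[gene_id, idx])
  numi <- cells$meta$n_umi[idx]
  keep <- numi > 0
  dos <- genotypes$dosage[a$donor, variant_id]
  C <- if (!is.null(covariates)) covariates[a$cell_id, , drop = FALSE]
  list(y = y[keep], dosage = as.numeric(dos)[keep],
       quantile = a$quantile[keep], donor = a$donor[keep],
       offset = log(numi[keep]),
       covariates = if (!is.null(C)) C[keep, , drop = FALSE])
}

#' Genotype x pseudotime interaction test for one eQTL
#'
#' Fits the NB mixed-effects model of per-cell UMI counts on dosage, the
#' (centered) quantile pseudotime treated as continuous, their interaction,
#' and any cell-level covariates, with log nUMI offset and donor random
#' intercept, then Wald-tests the interaction coefficient. Centering the
#' quantile decorrelates the main and interaction terms without changing
#' the interaction estimate.
#'
#' @param cells a [cell_table()].
#' @param genotypes a `genotype_matrix`.
#' @param gene_id,variant_id the tested pair.
#' @param assignment output of [assign_quantiles()].
#' @param covariates optional cell x k matrix (rownames = cell ids).
#' @param re_mode,nodes see [nbme_fit()].
#' @param center center the quantile covariate (default TRUE).
#' @return one-row data.frame: gene_id, variant_id, beta_interaction,
#'   se_interaction, p_interaction, beta_genotype, sigma, theta, converged.
#' @export
fit_interaction <- function(cells, genotypes, gene_id, variant_id,
                            assignment, covariates = NULL,
                            re_mode = "laplace", nodes = 9L, center = TRUE) {
  d <- dynamic_design(cells, genotypes, gene_id, variant_id, assignment,
                      covariates)
  qc <- if (center) d$quantile - mean(d$quantile) else d$quantile
  X <- cbind(dosage = d$dosage, quantile = qc,
             dosage_x_quantile = d$dosage * qc, d$covariates)
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("singular design")
  fit <- nbme_fit(d$y, X, d$offset, d$donor, re_mode = re_mode,
                  nodes = nodes)
  cf <- fit$coefficients
  i <- match("dosage_x_quantile", cf$term)
  data.frame(gene_id = gene_id, variant_id = variant_id,
             beta_interaction = cf$estimate[i], se_interaction = cf$se[i],
             p_interaction = cf$p[i],
             beta_genotype = cf$estimate[match("dosage", cf$term)],
             sigma = fit$sigma, theta = fit$theta,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Interaction scan over a list of eQTL pairs
#'
#' Runs [fit_interaction()] for each (gene, variant) pair and appends a
#' Benjamini-Hochberg FDR over the interaction p-values; dynamic eQTLs are
#' those with `fdr < alpha`.
#'
#' @inheritParams fit_interaction
#' @param pairs data.frame with gene_id, variant_id.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame of per-pair records with `fdr` and logical `dynamic`.
#' @export
dynamic_scan <- function(cells, genotypes, pairs, assignment,
                         covariates = NULL, re_mode = "laplace",
                         alpha = 0.05) {
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    tryCatch(
      fit_interaction(cells, genotypes, pairs$gene_id[i],
                      pairs$variant_id[i], assignment, covariates,
                      re_mode = re_mode),
      error = function(e)
        data.frame(gene_id = pairs$gene_id[i],
                   variant_id = pairs$variant_id[i],
                   beta_interaction = NA_real_, se_interaction = NA_real_,
                   p_interaction = NA_real_, beta_genotype = NA_real_,
                   sigma = NA_real_, theta = NA_real_, converged = FALSE,
                   stringsAsFactors = FALSE))))
  res$fdr <- p.adjust(res$p_interaction, "BH")
  res$dynamic <- !is.na(res$fdr) & res$fdr < alpha
  res
}

#' Per-quantile allelic effects
#'
#' Fits the NB model (no interaction term) separately within each
#' pseudotime quantile's cells, with the same covariates, offset and donor
#' random intercept, returning the allelic effect trajectory along the
#' trajectory. Quantiles with fewer than `min_cells` cells or without
#' dosage variation (e.g. no carriers of the alternative allele) yield NA.
#'
#' @inheritParams fit_interaction
#' @param min_cells minimum cells per quantile (default 50).
#' @return data.frame quantile, n_cells, beta, se, p.
#' @export
per_quantile_effects <- function(cells, genotypes, gene_id, variant_id,
                                 assignment, covariates = NULL,
                                 re_mode = "laplace", min_cells = 50L) {
  d <- dynamic_design(cells, genotypes, gene_id, variant_id, assignment,
                      covariates)
  Q <- max(assignment$quantile, na.rm = TRUE)
  do.call(rbind, lapply(seq_len(Q), function(q) {
    sel <- d$quantile == q
    na_row <- data.frame(quantile = q, n_cells = sum(sel), beta = NA_real_,
                         se = NA_real_, p = NA_real_)
    if (sum(sel) < min_cells || sd(d$dosage[sel]) == 0) {
      message("quantile ", q, ": insufficient cells or no dosage variation")
      return(na_row)
    }
    X <- cbind(dosage = d$dosage[sel], d$covariates[sel, , drop = FALSE])
    fit <- tryCatch(nbme_fit(d$y[sel], X, d$offset[sel], d$donor[sel],
                             re_mode = re_mode),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(na_row)
    cf <- fit$coefficients
    i <- match("dosage", cf$term)
    data.frame(quantile = q, n_cells = sum(sel), beta = cf$estimate[i],
               se = cf$se[i], p = cf$p[i])
  }))
}

# Guard WLS p-values against exact fits (zero residual variance).
wls_term_p <- function(fit, term) {
  cf <- summary(fit)$coefficients
  est <- cf[term, "Estimate"]
  p <- cf[term, "Pr(>|t|)"]
  if (is.na(p) || is.nan(p)) p <- if (abs(est) < 1e-10) 1 else 0
  c(estimate = unname(est), p = unname(p))
}

#' Classify the shape of an allelic-effect trajectory
#'
#' Weighted least squares (weights 1/se^2) of the per-quantile effects on
#' the quantile index: a linear model tests the slope, a quadratic model
#' tests the curvature. The trajectory is "linear" if only the slope is
#' significant at `alpha`, "quadratic" if only the curvature, "both" if
#' both, "none" otherwise (including fewer than 4 usable quantiles).
#'
#' @param beta_q,se_q per-quantile effect estimates and SEs (NA allowed).
#' @param alpha significance level (default 0.05).
#' @return list: trend_class, p_linear, p_quadratic, n_used.
#' @export
classify_trend <- function(beta_q, se_q, alpha = 0.05) {
  ok <- is.finite(beta_q) & is.finite(se_q) & se_q > 0
  if (sum(ok) < 4)
    return(list(trend_class = "none", p_linear = NA_real_,
                p_quadratic = NA_real_, n_used = sum(ok)))
  q <- seq_along(beta_q)[ok]; b <- beta_q[ok]; w <- 1 / se_q[ok]^2
  p_lin <- wls_term_p(lm(b ~ q, weights = w), "q")["p"]
  p_quad <- wls_term_p(lm(b ~ q + I(q^2), weights = w), "I(q^2)")["p"]
  cls <- if (p_lin < alpha && p_quad < alpha) "both"
    else if (p_lin < alpha) "linear"
    else if (p_quad < alpha) "quadratic"
    else "none"
  list(trend_class = cls, p_linear = unname(p_lin),
       p_quadratic = unname(p_quad), n_used = sum(ok))
}

#' Regulon-activity trends along pseudotime quantiles
#'
#' Per regulon, regresses per-cell activity on the quantile index with
#' linear and quadratic models; the highest-order term of each model is
#' tested and a regulon is flagged significant when either p < alpha.
#'
#' @param activity regulon x cell matrix (colnames = cell ids).
#' @param assignment output of [assign_quantiles()].
#' @param alpha significance level (default 0.05).
#' @return data.frame regulon_id, per-quantile mean activity (activity_q1
#'   ...), p_linear, p_quadratic, quad_coef, significant.
#' @export
regulon_trends <- function(activity, assignment, alpha = 0.05) {
  a <- assignment[!is.na(assignment$quantile), ]
  idx <- match(a$cell_id, colnames(activity))
  q <- a$quantile
  Q <- max(q)
  do.call(rbind, lapply(rownames(activity), function(rg) {
    y <- as.numeric(activity[rg, idx])
    means <- tapply(y, q, mean)
    if (sd(y) == 0) {
      pl <- pq <- 1; qc <- 0
    } else {
      pl <- summary(lm(y ~ q))$coefficients["q", "Pr(>|t|)"]
      sq <- summary(lm(y ~ q + I(q^2)))$coefficients
      pq <- sq["I(q^2)", "Pr(>|t|)"]; qc <- sq["I(q^2)", "Estimate"]
    }
    out <- data.frame(regulon_id = rg, t(means), p_linear = pl,
                      p_quadratic = pq, quad_coef = qc,
                      significant = pl < alpha || pq < alpha,
                      stringsAsFactors = FALSE, row.names = NULL)
    colnames(out)[2:(Q + 1)] <- paste0("activity_q", seq_len(Q))
    out
  }))
}

#' Overlap between dynamic eQTL genes and other gene lists
#'
#' @param dynamic_genes character vector (e.g. genes with a significant
#'   interaction).
#' @param gene_lists named list of character vectors (e.g. colocalized or
#'   TWAS susceptibility genes, regulon targets).
#' @return list per input list: `n_overlap` and `genes` (the intersection);
#'   plus `n_dynamic`.
#' @export
overlap_summary <- function(dynamic_genes, gene_lists) {
  res <- lapply(gene_lists, function(g) {
    ov <- intersect(dynamic_genes, g)
    list(n_overlap = length(ov), genes = ov)
  })
  c(res, list(n_dynamic = length(unique(dynamic_genes))))
}
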