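#' Panel of per-cell-type effect estimates
#'
#' Bundles the "strong" subset (per-cell-type top eQTLs, union across cell
#' types) and a "random" subset of tested pairs used to learn the error
#' correlation and mixture weights. Untested (gene, variant, cell type)
#' entries are NA.
#'
#' @param strong_beta,strong_se (gene, variant)-row x cell-type matrices.
#' @param random_beta,random_se same layout for the random subset.
#' @return object of class `effect_panel`.
#' @export
effect_panel <- function(strong_beta, strong_se, random_beta = strong_beta,
                         random_se = strong_se) {
  stopifnot(all(dim(strong_beta) == dim(strong_se)),
            all(dim(random_beta) == dim(random_se)),
            ncol(strong_beta) == ncol(random_beta),
            all(random_se > 0, na.rm = TRUE),
            all(strong_se > 0, na.rm = TRUE))
  structure(list(strong = list(beta = as.matrix(strong_beta),
                               se = as.matrix(strong_se)),
                 random = list(beta = as.matrix(random_beta),
                               se = as.matrix(random_se)),
                 cell_types = colnames(strong_beta) %||%
                   paste0("ct", seq_len(ncol(strong_beta)))),
            class = "effect_panel")
}

#' Assemble an effect panel from per-cell-type eQTL results
#'
#' The strong set is the union over cell types of each cell type's top eQTL
#' (gene, top variant) pairs; the random set is a seeded draw from all
#' tested pairs. Effects and errors are looked up in the nominal records of
#' every cell type (NA where a pair was not tested).
#'
#' @param egenes named list (per cell type) of [map_permutation()] outputs.
#' @param nominal named list (per cell type) of [map_nominal()] outputs.
#' @param random_size number of random tested pairs (default 10000, capped
#'   at the number available).
#' @param seed RNG seed for the random draw.
#' @param egene_only if TRUE, restrict the strong set to rows of genes
#'   flagged as eGenes (requires `q_value` columns).
#' @return an [effect_panel()] with row names "gene_id:variant_id".
#' @export
build_effect_panel <- function(egenes, nominal, random_size = 10000L,
                               seed = 1L, egene_only = FALSE) {
  stopifnot(identical(names(egenes), names(nominal)))
  key <- function(d) paste(d$gene_id, d$variant_id, sep = ":")
  strong_keys <- sort(unique(unlist(lapply(egenes, function(e) {
    if (egene_only) e <- e[e$egene, , drop = FALSE]
    paste(e$gene_id, e$top_variant, sep = ":")
  }))))
  all_keys <- sort(unique(unlist(lapply(nominal, key))))
  set.seed(seed)
  rand_keys <- sample(all_keys, min(random_size, length(all_keys)))
  lookup <- function(keys) {
    b <- s <- matrix(NA_real_, length(keys), length(nominal),
                     dimnames = list(keys, names(nominal)))
    for (ct in names(nominal)) {
      idx <- match(keys, key(nominal[[ct]]))
      b[, ct] <- nominal[[ct]]$beta[idx]
      s[, ct] <- nominal[[ct]]$se[idx]
    }
    list(beta = b, se = s)
  }
  st <- lookup(strong_keys); rd <- lookup(rand_keys)
  effect_panel(st$beta, st$se, rd$beta, rd$se)
}

# Clip a symmetric matrix to positive semi-definite by eigenvalue flooring.
psd_clip <- function(M, floor = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

# Canonical + data-driven unit covariance patterns for K cell types.
canonical_covs <- function(K, Z_strong = NULL, n_pc = 3L) {
  U <- list(identity = diag(K), shared = matrix(1, K, K))
  for (k in seq_len(K))
    U[[paste0("singleton_", k)]] <- {
      m <- matrix(0, K, K); m[k, k] <- 1; m
    }
  if (!is.null(Z_strong)) {
    Zc <- Z_strong[complete.cases(Z_strong), , drop = FALSE]
    if (nrow(Zc) > K) {
      sv <- svd(scale(Zc, scale = FALSE), nu = 0, nv = min(n_pc, K))
      for (p in seq_len(ncol(sv$v))) {
        u <- tcrossprod(sv$v[, p])
        U[[paste0("pca_", p)]] <- u / max(diag(u))
      }
      full <- psd_clip(crossprod(Zc) / nrow(Zc))
      U$pca_full <- full / max(diag(full))
    }
  }
  U
}

# Per-row log-likelihood matrix under each mixture component, grouping rows
# by missingness pattern so each component needs one Cholesky per pattern.
component_loglik <- function(Z, V, sigmas) {
  n <- nrow(Z); J <- length(sigmas)
  L <- matrix(-Inf, n, J)
  pat <- apply(!is.na(Z), 1, function(r) paste(as.integer(r), collapse = ""))
  for (p in unique(pat)) {
    rows <- which(pat == p)
    o <- which(strsplit(p, "")[[1]] == "1")
    if (!length(o)) { L[rows, ] <- 0; next }
    Zo <- t(Z[rows, o, drop = FALSE])
    for (j in seq_len(J)) {
      Om <- (V + sigmas[[j]])[o, o, drop = FALSE]
      R <- tryCatch(chol(Om), error = function(e) chol(psd_clip(Om, 1e-6)))
      q <- backsolve(R, Zo, transpose = TRUE)
      L[rows, j] <- -0.5 * (length(o) * log(2 * pi) +
                              2 * sum(log(diag(R))) + colSums(q^2))
    }
  }
  L
}

#' Fit the empirical-Bayes effect-sharing model
#'
#' A self-contained multi-condition shrinkage model in the spirit of
#' multivariate adaptive shrinkage: z-scores of true effects are modelled as
#' a mixture of zero-mean multivariate normals whose covariances are
#' canonical patterns (null, identity, per-cell-type singletons, rank-1
#' equal effects) plus data-driven patterns (top principal components of the
#' strong-set z-scores, eigenvalue-clipped to PSD), each expanded over a
#' geometric scale grid. Mixture weights are estimated by EM on the random
#' subset; the residual error correlation V is estimated from near-null
#' random rows (all |z| < 2). The marginal log-likelihood is non-decreasing
#' over EM iterations by construction and asserted.
#'
#' @param panel an [effect_panel()].
#' @param n_pc number of data-driven principal-component patterns.
#' @param grid_length length of the geometric scale grid (default 20); the
#'   grid spans 0.1 to 2 x the largest observed |z|.
#' @param max_iter,tol EM controls.
#' @return object of class `eb_model`: error correlation `V`, component
#'   covariances `sigmas`, weights `pi` (summing to 1), `loglik` trace.
#' @export
fit_eb_model <- function(panel, n_pc = 3L, grid_length = 20L,
                         max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(panel, "effect_panel"))
  K <- ncol(panel$random$beta)
  Zr <- panel$random$beta / panel$random$se
  Zs <- panel$strong$beta / panel$strong$se

  nearnull <- which(apply(abs(Zr) < 2, 1, all))
  V <- if (length(nearnull) >= 20 && K > 1) {
    Vc <- stats::cor(Zr[nearnull, , drop = FALSE],
                     use = "pairwise.complete.obs")
    Vc[is.na(Vc)] <- 0; diag(Vc) <- 1
    as.matrix(psd_clip(0.95 * Vc + 0.05 * diag(K), 1e-4))
  } else diag(K)

  zmax <- max(abs(c(Zr, Zs)), na.rm = TRUE)
  grid <- exp(seq(log(0.1), log(max(2 * zmax, 0.5)),
                  length.out = grid_length))
  U <- canonical_covs(K, Zs, n_pc)
  sigmas <- c(list(null = matrix(0, K, K)),
              unlist(lapply(names(U), function(nm)
                setNames(lapply(grid, function(s) s^2 * U[[nm]]),
                         paste0(nm, "_s", seq_along(grid)))),
                recursive = FALSE))
  L <- component_loglik(Zr, V, sigmas)
  J <- length(sigmas)
  pi_j <- rep(1 / J, J)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    A <- sweep(L, 2, log(pi_j), "+")
    m <- apply(A, 1, max)
    w <- exp(A - m)
    rs <- rowSums(w)
    ll <- sum(m + log(rs))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-6)
      stop("EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    pi_new <- colMeans(w / rs)
    if (length(ll_trace) > 1 &&
        abs(diff(utils::tail(ll_trace, 2))) < tol * abs(ll)) break
    pi_j <- pi_new
  }
  structure(list(V = V, sigmas = sigmas, pi = pi_j / sum(pi_j),
                 grid = grid, loglik = ll_trace,
                 cell_types = panel$cell_types),
            class = "eb_model")
}

#' Posterior effect summaries and local false sign rates
#'
#' For each (gene, variant) row and cell type, computes the posterior mean,
#' posterior SD and lfsr of the effect under the fitted mixture, on the
#' original effect-size scale. lfsr = min(P(effect <= 0 | data),
#' P(effect >= 0 | data)); mass on exactly-zero components counts toward
#' both signs. Missing entries are imputed from the conditional posterior
#' given the observed cell types (their effect scale taken as the column
#' median standard error).
#'
#' @param model an `eb_model`.
#' @param panel an [effect_panel()].
#' @param subset "strong" (default) or "random".
#' @return object of class `shrunken_effects`: list of row x cell-type
#'   matrices `posterior_mean`, `posterior_sd`, `lfsr`, plus `rows`.
#' @export
posterior_summaries <- function(model, panel, subset = c("strong", "random")) {
  subset <- match.arg(subset)
  dat <- panel[[subset]]
  Z <- dat$beta / dat$se
  n <- nrow(Z); K <- ncol(Z); J <- length(model$sigmas)
  V <- model$V
  L <- component_loglik(Z, V, model$sigmas)
  A <- sweep(L, 2, log(pmax(model$pi, 1e-300)), "+")
  W <- exp(A - apply(A, 1, max)); W <- W / rowSums(W)

  post_mean <- post_m2 <- zero_mass <- neg <- matrix(0, n, K)
  pat <- apply(!is.na(Z), 1, function(r) paste(as.integer(r), collapse = ""))
  for (p in unique(pat)) {
    rows <- which(pat == p)
    o <- which(strsplit(p, "")[[1]] == "1")
    Zo <- Z[rows, o, drop = FALSE]
    if (!length(o)) { zero_mass[rows, ] <- 1; next }
    for (j in seq_len(J)) {
      S <- model$sigmas[[j]]
      wj <- W[rows, j]
      if (all(wj < 1e-12)) next
      if (all(S == 0)) { zero_mass[rows, ] <- zero_mass[rows, ] + wj; next }
      Oinv <- solve((V + S)[o, o, drop = FALSE])
      Aj <- S[, o, drop = FALSE] %*% Oinv            # K x |o|
      mu <- Zo %*% t(Aj)                             # rows x K
      Pv <- pmax(diag(S - Aj %*% S[o, , drop = FALSE]), 0)
      sdv <- sqrt(Pv)
      for (k in seq_len(K)) {
        if (sdv[k] < 1e-10) {
          zero_mass[rows, k] <- zero_mass[rows, k] + wj
        } else {
          post_mean[rows, k] <- post_mean[rows, k] + wj * mu[, k]
          post_m2[rows, k] <- post_m2[rows, k] + wj * (mu[, k]^2 + Pv[k])
          neg[rows, k] <- neg[rows, k] + wj * pnorm(0, mu[, k], sdv[k])
        }
      }
    }
  }
  pos <- pmax(1 - zero_mass - neg, 0)
  lfsr <- pmin(pmin(neg, pos) + zero_mass, 1)
  sd_z <- sqrt(pmax(post_m2 - post_mean^2, 0))
  scale_se <- dat$se
  for (k in seq_len(K))
    scale_se[is.na(scale_se[, k]), k] <- median(dat$se[, k], na.rm = TRUE)
  out <- list(posterior_mean = post_mean * scale_se,
              posterior_sd = sd_z * scale_se,
              lfsr = lfsr,
              rows = rownames(dat$beta) %||% seq_len(n),
              cell_types = model$cell_types)
  dimnames(out$posterior_mean) <- dimnames(out$posterior_sd) <-
    dimnames(out$lfsr) <- list(out$rows, out$cell_types)
  structure(out, class = "shrunken_effects")
}

#' Classify eQTLs by cross-cell-type sharing
#'
#' An eQTL row is cell-type-specific when significant (lfsr < alpha) in
#' exactly one cell type, category-shared when significant in two or more
#' cell types all of one cell category, and cross-category-shared when its
#' significant cell types span two or more categories.
#'
#' @param effects a `shrunken_effects`.
#' @param category_map named character vector mapping every cell type to one
#'   of "endothelial", "epithelial", "immune", "stromal".
#' @param alpha lfsr significance threshold (default 0.05).
#' @return data.frame with row id, class, n_significant and the significant
#'   cell types (comma-separated).
#' @export
classify_sharing <- function(effects, category_map, alpha = 0.05) {
  cts <- effects$cell_types
  if (!all(cts %in% names(category_map)))
    stop("unmapped cell types: ",
         paste(setdiff(cts, names(category_map)), collapse = ", "))
  sig <- !is.na(effects$lfsr) & effects$lfsr < alpha
  cls <- apply(sig, 1, function(s) {
    if (!any(s)) return("non-significant")
    if (sum(s) == 1) return("cell-type-specific")
    if (length(unique(category_map[cts[s]])) == 1) return("category-shared")
    "cross-category-shared"
  })
  data.frame(row = effects$rows, class = cls,
             n_significant = rowSums(sig),
             significant_cell_types =
               apply(sig, 1, function(s) paste(cts[s], collapse = ",")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise effect-size sharing between cell types
#'
#' For each ordered pair (A, B), among rows significant (lfsr < alpha) in
#' both cell types, the fraction whose posterior means are in the same
#' allelic direction with a B/A fold change inside `fold` (boundaries
#' inclusive; a zero posterior mean in either cell type fails the rule).
#'
#' @param effects a `shrunken_effects`.
#' @param alpha lfsr threshold (default 0.05).
#' @param fold fold-change bounds (default c(0.5, 2)).
#' @return cell type x cell type matrix; diagonal 1; NA where no rows are
#'   jointly significant.
#' @export
pairwise_sharing <- function(effects, alpha = 0.05, fold = c(0.5, 2)) {
  K <- length(effects$cell_types)
  sig <- !is.na(effects$lfsr) & effects$lfsr < alpha
  M <- effects$posterior_mean
  out <- matrix(NA_real_, K, K,
                dimnames = list(effects$cell_types, effects$cell_types))
  diag(out) <- 1
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    rows <- which(sig[, a] & sig[, b])
    if (!length(rows)) next
    ma <- M[rows, a]; mb <- M[rows, b]
    ratio <- mb / ma
    out[a, b] <- mean(ma != 0 & mb != 0 & sign(ma) == sign(mb) &
                        ratio >= fold[1] & ratio <= fold[2])
  }
  out
}
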