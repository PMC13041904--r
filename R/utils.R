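# Internal numeric helpers shared across modules.

#' @importFrom stats qnorm pnorm pt pbeta dbeta rnorm runif rbinom rnbinom
#'   rbeta rlnorm p.adjust prcomp lm coef sd var cor complete.cases
#'   fisher.test chisq.test wilcox.test optim optimHess quantile median
#'   setNames rexp dnbinom dnorm pchisq rmultinom residuals
#' @importFrom utils write.table read.table head
NULL

# log(sum(exp(x))) without overflow; returns -Inf for empty x
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Rank-based inverse-normal transform with offset (r - 0.5)/n; ties share
# their average rank so tied inputs map to equal quantiles.
inverse_normal <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

# Storey q-values with pi0 estimated at a single lambda (default 0.5).
# With fewer than `min_genes` p-values pi0 falls back to 1 (BH-equivalent).
storey_qvalue <- function(p, lambda = 0.5, min_genes = 20) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m < min_genes) {
    warning("fewer than ", min_genes, " p-values; using pi0 = 1")
    pi0 <- 1
  } else {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    if (pi0 <= 0) pi0 <- 1 / m  # all p below lambda; keep q-values positive
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))[ro]
  attr(q, "pi0") <- pi0
  q
}

# Derive a child RNG seed from a top-level seed and a stage label;
# stays below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483587L)
}

# Residualize columns of y against covariate matrix X (intercept added).
residualize <- function(y, covariates = NULL) {
  n <- if (is.matrix(y)) nrow(y) else length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qr.resid(qr(X), y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
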