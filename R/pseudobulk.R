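#' Cell types qualifying for pseudo-bulk eQTL mapping
#'
#' A cell type qualifies when at least `min_donors` donors each contribute at
#' least `min_cells` cells of that type — the standard inclusion rule for
#' per-cell-type pseudo-bulk mapping.
#'
#' @param cells a [cell_table()].
#' @param min_donors minimum number of qualifying donors (default 40).
#' @param min_cells minimum cells a donor must contribute (default 5).
#' @return character vector of qualifying cell types, with attribute
#'   `donors`: a named list of the qualifying donors per cell type.
#' @export
qualify_cell_types <- function(cells, min_donors = 40L, min_cells = 5L) {
  stopifnot(inherits(cells, "cell_table"), nrow(cells$meta) > 0)
  tab <- table(cells$meta$cell_type, cells$meta$donor)
  ok_donors <- apply(tab >= min_cells, 1, function(x) colnames(tab)[x],
                     simplify = FALSE)
  keep <- names(ok_donors)[lengths(ok_donors) >= min_donors]
  structure(keep, donors = ok_donors[keep])
}

#' Genes expressed in a minimum fraction of all cells
#'
#' Retains genes with a nonzero count in at least `min_fraction` of all cells
#' in the dataset (the threshold is inclusive).
#'
#' @param cells a [cell_table()].
#' @param min_fraction minimum fraction of cells with nonzero counts
#'   (default 0.10).
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(cells, min_fraction = 0.10) {
  stopifnot(inherits(cells, "cell_table"))
  nnz <- Matrix::rowSums(cells$counts > 0)
  keep <- cells$genes$gene_id[nnz >= min_fraction * ncol(cells$counts)]
  if (!length(keep)) warning("no genes pass the expression filter")
  keep
}

#' Normalize a pseudo-bulk count matrix
#'
#' Step 1: per-donor library-size normalization (counts / column total x
#' 10,000, then log1p). Step 2: per-gene rank-based inverse-normal transform
#' across donors with offset (r - 0.5)/n; ties receive equal transformed
#' values. The result has mean ~0, variance ~1 per gene and preserves the
#' donor rank order of the step-1 values.
#'
#' @param raw gene x donor matrix of summed counts.
#' @param scale_factor library scale (default 1e4).
#' @return gene x donor matrix of transformed values. Donors with zero total
#'   counts are dropped with a warning.
#' @export
pseudobulk_normalize <- function(raw, scale_factor = 1e4) {
  raw <- as.matrix(raw)
  tot <- colSums(raw)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " donors with zero total counts excluded")
    raw <- raw[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  step1 <- log1p(sweep(raw, 2, tot, "/") * scale_factor)
  t(apply(step1, 1, inverse_normal))
}

#' Aggregate cells into per-cell-type pseudo-bulk matrices
#'
#' Sums counts per (cell type, donor) over the qualifying cell types, donors
#' and filtered genes, then normalizes each matrix with
#' [pseudobulk_normalize()].
#'
#' @param cells a [cell_table()].
#' @param min_donors,min_cells qualification thresholds, see
#'   [qualify_cell_types()].
#' @param min_fraction gene expression filter, see [filter_genes()].
#' @return `pseudobulk_set`: list with `cell_types` (named list, each with
#'   `raw` and `normalized` gene x donor matrices and `donors`), `genes`
#'   (retained gene ids) and `gene_info`.
#' @export
pseudobulk <- function(cells, min_donors = 40L, min_cells = 5L,
                       min_fraction = 0.10) {
  cts <- qualify_cell_types(cells, min_donors, min_cells)
  if (!length(cts)) stop("no cell type qualifies")
  genes <- filter_genes(cells, min_fraction)
  gidx <- match(genes, cells$genes$gene_id)
  out <- lapply(cts, function(ct) {
    donors <- attr(cts, "donors")[[ct]]
    sel <- cells$meta$cell_type == ct & cells$meta$donor %in% donors
    sub <- cells$counts[gidx, sel, drop = FALSE]
    grp <- factor(cells$meta$donor[sel], levels = sort(donors))
    raw <- sapply(levels(grp), function(d)
      Matrix::rowSums(sub[, grp == d, drop = FALSE]))
    rownames(raw) <- genes
    list(raw = raw, normalized = pseudobulk_normalize(raw),
         donors = levels(grp))
  })
  names(out) <- cts
  structure(list(cell_types = out, genes = genes,
                 gene_info = cells$genes[gidx, , drop = FALSE]),
            class = "pseudobulk_set")
}

#' Build eQTL mapping covariates
#'
#' Produces, per cell type, a donor x covariate matrix of centered donor age,
#' genotype principal components (computed on LD-pruned, standardized
#' dosages) and expression factors (top principal components of the
#' normalized pseudo-bulk matrix, the usual stand-in for latent-factor
#' methods such as PEER).
#'
#' @param pb a `pseudobulk_set`.
#' @param genotypes a `genotype_matrix`.
#' @param age named numeric vector of donor ages.
#' @param n_gpcs number of genotype PCs (default 3).
#' @param n_factors number of expression factors; a single count or a named
#'   vector per cell type. `0` gives age + genotype PCs only.
#' @param prune_r2 LD-pruning threshold used before genotype PCA.
#' @return named list of donor x covariate matrices (columns centered).
#' @export
build_covariates <- function(pb, genotypes, age, n_gpcs = 3L, n_factors = 5L,
                             prune_r2 = 0.9) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  kept <- ld_prune(genotypes, r2 = prune_r2)
  X <- genotypes$dosage[, kept, drop = FALSE]
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  gpc_all <- prcomp(scale(X), center = FALSE)$x
  if (n_gpcs > ncol(gpc_all)) {
    warning("requested ", n_gpcs, " genotype PCs; only ", ncol(gpc_all),
            " available")
    n_gpcs <- ncol(gpc_all)
  }
  if (is.null(names(n_factors)))
    n_factors <- setNames(rep(n_factors[1], length(pb$cell_types)),
                          names(pb$cell_types))
  out <- lapply(names(pb$cell_types), function(ct) {
    donors <- pb$cell_types[[ct]]$donors
    m <- n_factors[[ct]]
    cov <- cbind(age = as.numeric(age[donors]))
    if (n_gpcs > 0)
      cov <- cbind(cov, gpc_all[match(donors, rownames(genotypes$dosage)),
                                seq_len(n_gpcs), drop = FALSE])
    if (m > 0) {
      epc <- prcomp(t(pb$cell_types[[ct]]$normalized))$x
      if (m > ncol(epc)) {
        warning("cell type ", ct, ": only ", ncol(epc),
                " expression factors available")
        m <- ncol(epc)
      }
      ef <- epc[, seq_len(m), drop = FALSE]
      colnames(ef) <- paste0("expPC", seq_len(m))
      cov <- cbind(cov, ef)
    }
    rownames(cov) <- donors
    scale(cov, center = TRUE, scale = FALSE)
  })
  names(out) <- names(pb$cell_types)
  out
}

#' Choose the expression-factor count that saturates eGene discovery
#'
#' Runs eGene discovery at each candidate factor count and returns, per cell
#' type, the smallest count whose discovery is within `tol` of the grid
#' maximum (the "plateau" rule used to tune latent-factor covariates).
#'
#' @param pb a `pseudobulk_set`.
#' @param genotypes a `genotype_matrix`.
#' @param age named donor ages.
#' @param grid integer vector of candidate factor counts.
#' @param n_gpcs genotype PCs to include.
#' @param n_perm,seed,alpha forwarded to the permutation pass and eGene call.
#' @param tol plateau tolerance (default 0.02: within 2% of the maximum).
#' @param filter a [variant_filter()].
#' @return named integer vector (chosen count per cell type) with attribute
#'   `egenes`: the discovery counts per cell type x grid value.
#' @export
optimize_factor_count <- function(pb, genotypes, age, grid, n_gpcs = 3L,
                                  n_perm = 200L, seed = 1L, alpha = 0.05,
                                  tol = 0.02, filter = variant_filter()) {
  if (!length(grid)) stop("empty factor-count grid")
  grid <- sort(unique(as.integer(grid)))
  counts <- sapply(grid, function(m) {
    covs <- build_covariates(pb, genotypes, age, n_gpcs = n_gpcs,
                             n_factors = m)
    vapply(names(pb$cell_types), function(ct) {
      eg <- map_permutation(pb$cell_types[[ct]]$normalized, genotypes,
                            covs[[ct]], pb$gene_info, filter = filter,
                            n_perm = n_perm, seed = seed)
      sum(call_egenes(eg, alpha = alpha)$q_value < alpha)
    }, 0L)
  })
  counts <- matrix(counts, nrow = length(pb$cell_types),
                   dimnames = list(names(pb$cell_types), grid))
  chosen <- apply(counts, 1, function(x) grid[which(x >= (1 - tol) * max(x))[1]])
  structure(chosen, egenes = counts)
}
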