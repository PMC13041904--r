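#' LD-prune variants with a sliding window
#'
#' plink-style `--indep-pairwise`: a window of `window` variants slides in
#' steps of `step`; within each window, while any retained pair has dosage
#' r^2 above `r2`, the lower-MAF member of the pair is removed (ties: the
#' variant at the later position). Output is deterministic and depends only
#' on variant order, positions, MAFs and dosages — not donor order.
#'
#' @param genotypes a `genotype_matrix`.
#' @param window window size in variants (default 250).
#' @param step window step in variants (default 50).
#' @param r2 pruning threshold (default 0.9, exclusive).
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window = 250L, step = 50L, r2 = 0.9) {
  v <- genotypes$variants
  X <- genotypes$dosage
  maf <- v$emp_maf %||% pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  V <- ncol(X)
  keep <- rep(TRUE, V)
  sds <- apply(X, 2, sd)
  starts <- unique(c(seq(1L, max(1L, V - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, V)
    idx <- idx[keep[idx] & sds[idx] > 0]
    if (length(idx) < 2) next
    R2 <- suppressWarnings(cor(X[, idx, drop = FALSE]))^2
    diag(R2) <- 0
    repeat {
      hit <- which(R2 > r2, arr.ind = TRUE)
      if (!nrow(hit)) break
      hit <- hit[1, ]
      pair <- idx[c(hit[1], hit[2])]
      drop_local <- if (maf[pair[1]] < maf[pair[2]]) hit[1]
        else if (maf[pair[2]] < maf[pair[1]]) hit[2]
        else hit[which.max(c(v$pos[pair[1]], v$pos[pair[2]]))]
      keep[idx[drop_local]] <- FALSE
      R2[drop_local, ] <- 0; R2[, drop_local] <- 0
    }
  }
  v$variant_id[keep]
}

# GRanges from a BED-like data.frame (0-based half-open) and from 1-based
# SNP positions; a SNP at 1-based position p overlaps [start, end) iff
# start <= p - 1 < end, which GRanges' 1-based closed arithmetic preserves
# under start+1.
bed_granges <- function(bed) {
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(bed$start + 1L, bed$end),
                         label = bed$label)
}

snp_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
}

#' Read a BED4 annotation track
#'
#' @param path BED file (chrom, start, end, label; 0-based half-open).
#' @return data.frame with columns chrom, start, end, label.
#' @export
read_bed4 <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:4]
  colnames(bed) <- c("chrom", "start", "end", "label")
  stopifnot(all(bed$start < bed$end))
  bed
}

#' Enrichment of eQTL SNPs in annotation labels
#'
#' Per label, a two-sided Fisher's exact test on the 2x2 table of
#' (eQTL vs background) x (inside vs outside the label's intervals), with
#' Benjamini-Hochberg FDR across labels. Both SNP sets are expected to be
#' LD-pruned; the background is typically the pruned non-eQTL SNPs. Zero
#' cells give unconditional odds ratios of 0 or Inf.
#'
#' @param eqtl_snps,background_snps data.frames with chrom, pos (1-based).
#' @param track data.frame chrom/start/end/label (see [read_bed4()]).
#' @return data.frame per label: counts a (eQTL in), b (eQTL out), c
#'   (background in), d (background out), odds_ratio = (a d)/(b c), p, fdr,
#'   significant (fdr < 0.05), direction.
#' @export
enrichment_test <- function(eqtl_snps, background_snps, track) {
  if (!nrow(background_snps)) stop("empty background SNP set")
  labels <- sort(unique(track$label))
  qg <- snp_granges(eqtl_snps); bg <- snp_granges(background_snps)
  res <- do.call(rbind, lapply(labels, function(lb) {
    tg <- bed_granges(track[track$label == lb, , drop = FALSE])
    a <- sum(IRanges::overlapsAny(qg, tg))
    b <- length(qg) - a
    cc <- sum(IRanges::overlapsAny(bg, tg))
    d <- length(bg) - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    or <- (a * d) / (b * cc)  # unconditional ratio; 0/Inf kept as-is
    data.frame(label = lb, a = a, b = b, c = cc, d = d, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- p.adjust(res$p, "BH")
  res$significant <- res$fdr < 0.05
  res$direction <- ifelse(res$odds_ratio >= 1, "enrichment", "depletion")
  res
}

#' Compare TSS distances of shared vs cell-type-specific eQTL SNPs
#'
#' Computes signed TSS distances (in the direction of transcription, so the
#' sign flips with gene strand while |distance| is unchanged) for each SNP
#' and its target gene, and tests whether shared eQTL SNPs sit closer to the
#' TSS than cell-type-specific ones with a one-sided Mann-Whitney U test on
#' |distance| (alternative: shared < specific).
#'
#' @param specific_snps,shared_snps data.frames with pos, gene_id.
#' @param tss data.frame gene_id, tss_pos, strand.
#' @return list with `distances` (per class, signed), medians of |distance|,
#'   and `p` from the one-sided test.
#' @export
tss_distance_compare <- function(specific_snps, shared_snps, tss) {
  dist1 <- function(snps) {
    idx <- match(snps$gene_id, tss$gene_id)
    drop <- is.na(idx)
    if (any(drop)) message(sum(drop), " SNPs without a TSS dropped")
    tss_dist(snps$pos[!drop], tss$tss_pos[idx[!drop]],
             tss$strand[idx[!drop]])
  }
  ds <- dist1(specific_snps); dh <- dist1(shared_snps)
  test <- wilcox.test(abs(dh), abs(ds), alternative = "less", exact = FALSE)
  list(distances = list(specific = ds, shared = dh),
       median_abs = c(specific = median(abs(ds)), shared = median(abs(dh))),
       p = test$p.value)
}

#' Overlap of eQTL SNP classes with grouped ATAC peaks
#'
#' Assigns each SNP to at most one peak group with precedence
#' cell-type-specific > multi-category > other (SNPs overlapping no peak are
#' excluded), forms the eQTL-class x peak-group contingency table and tests
#' it with Pearson's chi-square (no continuity correction).
#'
#' @param specific_snps,shared_snps data.frames with chrom, pos.
#' @param peaks data.frame chrom/start/end/label with labels among
#'   "cell-type-specific", "multi-category", "other".
#' @return list with `table` (2 x up-to-3), `proportions` per class,
#'   `statistic`, `p`; a warning is raised when an expected cell count
#'   is below 1.
#' @export
atac_overlap_test <- function(specific_snps, shared_snps, peaks) {
  precedence <- c("cell-type-specific", "multi-category", "other")
  assign_group <- function(snps) {
    gr <- snp_granges(snps)
    grp <- rep(NA_character_, length(gr))
    for (lb in rev(precedence)) {  # higher precedence overwrites lower
      pk <- peaks[peaks$label == lb, , drop = FALSE]
      if (nrow(pk)) grp[IRanges::overlapsAny(gr, bed_granges(pk))] <- lb
    }
    grp[!is.na(grp)]
  }
  tab <- rbind(specific = table(factor(assign_group(specific_snps),
                                       levels = precedence)),
               shared = table(factor(assign_group(shared_snps),
                                     levels = precedence)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected cell count < 1; chi-square test unreliable")
  list(table = tab, proportions = tab / rowSums(tab),
       statistic = unname(ct$statistic), p = ct$p.value)
}
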