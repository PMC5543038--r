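#' Quality-control thresholds
#'
#' Defaults follow common practice for array-genotyped wild populations:
#' individuals and SNPs below 95% call rate are removed, heterozygosity
#' outliers at 1% FDR, duplicate-level identity-by-state at 0.95, minor
#' allele frequency at 0.10, and at least 20 phenotyped individuals in
#' every genotype-by-temperature-class cell.
#'
#' @param min_call_rate Minimum fraction of non-missing calls (SNPs and
#'   individuals).
#' @param min_maf Minimum minor allele frequency (computed on non-missing
#'   calls).
#' @param het_fdr FDR level for heterozygosity outlier removal.
#' @param max_ibs Pairwise mean IBS at or above which one member of the
#'   pair is removed.
#' @param min_cell Minimum distinct phenotyped individuals per
#'   genotype-by-class cell.
#' @param mds_dims,mds_mult Multidimensional-scaling outlier rule (axes
#'   retained; robust-SD multiplier), see [mds_outliers()].
#' @return List of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.10,
                          het_fdr = 0.01, max_ibs = 0.95, min_cell = 20L,
                          mds_dims = 2L, mds_mult = 6) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            het_fdr > 0, het_fdr < 1,
            max_ibs >= 0, max_ibs <= 1, min_cell >= 0)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 het_fdr = het_fdr, max_ibs = max_ibs,
                 min_cell = as.integer(min_cell),
                 mds_dims = as.integer(mds_dims), mds_mult = mds_mult),
            class = "qc_thresholds")
}

.qc_step <- function(report, name, removed, threshold) {
  report$steps[[length(report$steps) + 1L]] <-
    list(filter = name, removed = removed, threshold = threshold)
  report
}

#' Tabulate a QC report
#'
#' @param report A QC report list returned by the filter functions.
#' @return Data frame with one row per filter stage.
#' @export
qc_report_table <- function(report) {
  do.call(rbind, lapply(report$steps, function(s) {
    data.frame(filter = s$filter, n_removed = length(s$removed),
               threshold = as.character(s$threshold),
               removed = paste(s$removed, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Minor allele frequency per SNP
#'
#' Computed on non-missing calls only: min(f, 1 - f) with f the alternate
#' allele frequency.
#'
#' @param G Genotype matrix, individuals x SNPs.
#' @return Numeric vector, one value per SNP (`NaN` for all-missing SNPs).
#' @export
snp_maf <- function(G) {
  alt <- colSums(G, na.rm = TRUE)
  called <- colSums(!is.na(G))
  f <- alt / (2 * called)
  pmin(f, 1 - f)
}

#' SNP-level quality-control cascade
#'
#' Removes, in order: SNPs with missing or duplicated (chromosome,
#' position); monomorphic SNPs; SNPs with call rate below threshold; SNPs
#' with MAF below threshold.  Hardy-Weinberg deviation is deliberately not
#' a filter: a trait under directional selection may hold causal loci out
#' of equilibrium, so HWE-violating but otherwise clean SNPs survive.
#'
#' @param G Genotype matrix, individuals x SNPs (0/1/2/`NA`).
#' @param info SNP info data frame (`snp`, `chr`, `pos`).
#' @param thr A [qc_thresholds()] object.
#' @return List `genotypes`, `info` (filtered, positions sorted within
#'   chromosome) and `report`.
#' @export
snp_filters <- function(G, info, thr = qc_thresholds()) {
  stopifnot(ncol(G) == nrow(info), ncol(G) >= 1L)
  report <- list(steps = list())

  key <- paste(info$chr, info$pos)
  bad_pos <- is.na(info$chr) | is.na(info$pos) | duplicated(key) |
    duplicated(key, fromLast = TRUE)
  bad_pos[is.na(info$chr) | is.na(info$pos)] <- TRUE
  report <- .qc_step(report, "position", info$snp[bad_pos],
                     "missing or duplicated (chr,pos)")
  keep <- !bad_pos

  ## monomorphic = only one allele observed among called genotypes
  altf <- colSums(G, na.rm = TRUE) / (2 * pmax(colSums(!is.na(G)), 1L))
  mono <- keep & (colSums(!is.na(G)) == 0L | altf == 0 | altf == 1)
  report <- .qc_step(report, "monomorphic", info$snp[mono], "1 allele")
  keep <- keep & !mono

  cr <- colMeans(!is.na(G))
  low_cr <- keep & cr < thr$min_call_rate
  report <- .qc_step(report, "snp_call_rate", info$snp[low_cr],
                     paste0("<", thr$min_call_rate))
  keep <- keep & !low_cr

  maf <- snp_maf(G)
  low_maf <- keep & (is.na(maf) | maf < thr$min_maf)
  report <- .qc_step(report, "maf", info$snp[low_maf],
                     paste0("<", thr$min_maf))
  keep <- keep & !low_maf

  info2 <- info[keep, , drop = FALSE]
  ord <- order(info2$chr, info2$pos)
  info2 <- info2[ord, , drop = FALSE]
  rownames(info2) <- NULL
  list(genotypes = G[, info2$snp, drop = FALSE], info = info2,
       report = report)
}

#' Individual-level quality-control cascade
#'
#' Removes, in order: individuals with call rate below threshold;
#' heterozygosity outliers (per-individual observed heterozygosity
#' z-scored against the sample, two-sided normal p-values,
#' Benjamini-Hochberg at the FDR level); then for every pair with mean IBS
#' at or above the duplicate threshold, the member with the lower call rate
#' (ties: the lexicographically larger id) is removed.
#'
#' @param G Genotype matrix, individuals x SNPs.
#' @param thr A [qc_thresholds()] object.
#' @return List `ids` (survivors, in input order) and `report`.
#' @export
individual_filters <- function(G, thr = qc_thresholds()) {
  stopifnot(nrow(G) >= 2L)
  report <- list(steps = list())
  ids <- rownames(G)

  cr <- rowMeans(!is.na(G))
  low <- cr < thr$min_call_rate
  report <- .qc_step(report, "ind_call_rate", ids[low],
                     paste0("<", thr$min_call_rate))
  keep <- !low

  het <- rowMeans(G[, , drop = FALSE] == 1L, na.rm = TRUE)
  hk <- het[keep]
  if (stats::sd(hk) > 0) {
    z <- (hk - mean(hk)) / stats::sd(hk)
    pv <- 2 * stats::pnorm(-abs(z))
    padj <- stats::p.adjust(pv, method = "BH")
    flag <- names(hk)[padj < thr$het_fdr]
  } else {
    flag <- character(0)
  }
  report <- .qc_step(report, "heterozygosity",
                     flag, paste0("BH FDR <", thr$het_fdr))
  keep <- keep & !(ids %in% flag)

  Gk <- G[keep, , drop = FALSE]
  drop_ibs <- character(0)
  if (nrow(Gk) >= 2L) {
    ibs <- ibs_matrix(Gk)$ibs
    crk <- cr[keep]
    pair <- which(upper.tri(ibs) & ibs >= thr$max_ibs, arr.ind = TRUE)
    if (nrow(pair)) {
      for (r in seq_len(nrow(pair))) {
        a <- rownames(ibs)[pair[r, 1]]
        b <- colnames(ibs)[pair[r, 2]]
        if (a %in% drop_ibs || b %in% drop_ibs) next
        drop_ibs <- c(drop_ibs,
                      if (crk[a] < crk[b]) a
                      else if (crk[b] < crk[a]) b
                      else max(a, b))
      }
    }
  }
  report <- .qc_step(report, "ibs_duplicates", drop_ibs,
                     paste0(">=", thr$max_ibs))
  keep <- keep & !(ids %in% drop_ibs)

  list(ids = ids[keep], report = report)
}

#' Genotype-by-class support filter
#'
#' Retains a SNP only if all three genotypes occur and every of the nine
#' genotype-by-temperature-class cells contains at least `min_cell`
#' distinct phenotyped individuals (an individual breeding in two classes
#' counts once in each).
#'
#' @param G Genotype matrix, individuals x SNPs.
#' @param records Phenotype records with columns `id` and `class`.
#' @param thr A [qc_thresholds()] object.
#' @return Character vector of surviving SNP ids.
#' @export
genotype_class_support <- function(G, records, thr = qc_thresholds()) {
  if (!"class" %in% names(records) || anyNA(records$class)) {
    stop("validation error: every phenotype record needs a temperature class")
  }
  ic <- unique(records[, c("id", "class")])
  ic <- ic[ic$id %in% rownames(G), , drop = FALSE]
  cls <- factor(as.character(ic$class),
                levels = c("cold", "intermediate", "warm"))
  keep <- vapply(colnames(G), function(s) {
    g <- G[ic$id, s]
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 3L) return(FALSE)
    tab <- table(factor(g[ok], levels = 0:2), cls[ok])
    all(tab >= thr$min_cell)
  }, logical(1))
  colnames(G)[keep]
}
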