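#' Pedigree numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' method: founders have \eqn{A_{ii} = 1}; for an individual with parents s
#' and d, \eqn{A_{ij} = (A_{sj} + A_{dj})/2} for earlier j and
#' \eqn{A_{ii} = 1 + A_{sd}/2}.  Unknown parents contribute zero.  Dense;
#' intended for desk-scale pedigrees (use [a_inverse()] inside model fits).
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`), parents before
#'   offspring.
#' @return A symmetric numeric matrix with dimnames `ped$id`.
#' @export
a_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Pedigree inbreeding coefficients
#'
#' F of an individual is the kinship between its parents, computed by the
#' recursive kinship algorithm with memoisation (no dense matrix), so it
#' scales to the multi-thousand-individual pedigrees used in simulation.
#'
#' @param ped Pedigree data frame, parents before offspring.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(parent = emptyenv(), size = 4L * n)
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + kin(si[i], di[i]))
    } else {
      # j is the later individual: recurse through j's parents
      0.5 * (kin(i, si[j]) + kin(i, di[j]))
    }
    memo[[key]] <- v
    v
  }
  Fi <- vapply(seq_len(n), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else kin(si[i], di[i])
  }, 0)
  names(Fi) <- ped$id
  Fi
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's direct rules: with Mendelian-sampling variance
#' \eqn{d_i = 1}, \eqn{3/4 - F_p/4} or \eqn{1/2 - (F_s + F_d)/4} for 0, 1
#' or 2 known parents, add \eqn{1/d_i} at (i,i), \eqn{-1/(2 d_i)} at
#' (i, parent) and \eqn{1/(4 d_i)} between parents.  Also returns
#' \eqn{\log|A| = \sum \log d_i}, needed by the REML likelihood.
#'
#' @param ped Pedigree data frame, parents before offspring.
#' @return List with `Ainv` (sparse symmetric [Matrix::Matrix]) and
#'   `logdet` (log determinant of A).
#' @export
a_inverse <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  Fi <- inbreeding(ped)
  Fs <- ifelse(is.na(si), 0, Fi[ifelse(is.na(si), 1L, si)])
  Fd <- ifelse(is.na(di), 0, Fi[ifelse(is.na(di), 1L, di)])
  npar <- (!is.na(si)) + (!is.na(di))
  d <- ifelse(npar == 2L, 0.5 - 0.25 * (Fs + Fd),
              ifelse(npar == 1L, 0.75 - 0.25 * ifelse(is.na(si), Fd, Fs), 1))
  ii <- jj <- integer(0)
  xx <- numeric(0)
  alpha <- 1 / d
  add <- function(i, j, x) {
    ii <<- c(ii, pmin(i, j))
    jj <<- c(jj, pmax(i, j))
    xx <<- c(xx, x)
  }
  add(seq_len(n), seq_len(n), alpha)
  ks <- which(!is.na(si))
  add(ks, si[ks], -0.5 * alpha[ks])
  kd <- which(!is.na(di))
  add(kd, di[kd], -0.5 * alpha[kd])
  kb <- which(npar == 2L)
  add(si[kb], si[kb], 0.25 * alpha[kb])
  add(di[kb], di[kb], 0.25 * alpha[kb])
  add(si[kb], di[kb], 0.25 * alpha[kb])
  k1 <- which(npar == 1L)
  p1 <- ifelse(is.na(si[k1]), di[k1], si[k1])
  add(p1, p1, 0.25 * alpha[k1])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = TRUE,
                               dimnames = list(ped$id, ped$id))
  list(Ainv = Ainv, logdet = sum(log(d)))
}

#' Identity-by-state similarity and distance
#'
#' Pairwise mean fraction of shared alleles over SNPs called in both
#' individuals: per SNP, share \eqn{= 1 - |g_i - g_j| / 2}.  The genetic
#' distance is `1 - IBS`.
#'
#' @param G Genotype matrix, individuals x SNPs, entries 0/1/2/`NA`.
#' @return List with `ibs` and `distance` (symmetric matrices, diagonal 1
#'   and 0).
#' @export
ibs_matrix <- function(G) {
  stopifnot(nrow(G) >= 2L, ncol(G) >= 1L)
  Gz <- G
  Gz[is.na(Gz)] <- 0
  M <- !is.na(G)                              # called indicator
  storage.mode(Gz) <- "double"
  storage.mode(M) <- "double"
  njoint <- tcrossprod(M)                     # jointly called SNP counts
  if (any(njoint == 0)) {
    bad <- which(njoint == 0, arr.ind = TRUE)[1, ]
    stop("no jointly called SNPs for pair ", rownames(G)[bad[1]], " / ",
         rownames(G)[bad[2]])
  }
  # sum over joint SNPs of |g_i - g_j| = sum g_i^2 + g_j^2 - 2 g_i g_j only
  # for 0/2 pairs; with 0/1/2 entries |a-b| != via squares, so accumulate
  # per dosage level instead: |a-b| = a + b - 2*min(a,b).
  lev <- function(x) {
    L <- (Gz >= x) * M
    L
  }
  # min(a,b) summed = sum_k [a>=k][b>=k] for k = 1, 2
  minsum <- tcrossprod(lev(1)) + tcrossprod(lev(2))
  asum <- Gz %*% t(M)                         # sum of g_i over joint SNPs
  absdiff <- asum + t(asum) - 2 * minsum
  ibs <- 1 - absdiff / (2 * njoint)
  diag(ibs) <- 1
  list(ibs = ibs, distance = 1 - ibs)
}

#' Classical metric MDS with robust outlier flagging
#'
#' Double-centers the squared distance matrix, extracts the leading
#' eigenvectors scaled by root eigenvalues, and flags as outliers the
#' individuals whose coordinate deviates from the axis mean by more than
#' `mult` robust standard deviations (median absolute deviation scaled by
#' 1.4826) on any retained axis.  Used to screen genotyped individuals for
#' clusters of genetically dissimilar birds before association analysis.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param dims Number of retained axes (default 2).
#' @param mult Robust-SD multiplier (default 6).
#' @return List with `coords` (n x dims), `eigenvalues`, and `outliers`
#'   (character ids).  Warns when negative eigenvalue mass exceeds 20% of
#'   the total (non-Euclidean distances).
#' @export
mds_outliers <- function(D, dims = 2L, mult = 6) {
  stopifnot(isSymmetric(unname(D)))
  n <- nrow(D)
  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  neg <- sum(abs(e$values[e$values < 0]))
  tot <- sum(abs(e$values))
  if (tot > 0 && neg / tot > 0.2) {
    warning("negative eigenvalue mass ", signif(neg / tot, 3),
            " of total: distances are strongly non-Euclidean")
  }
  k <- min(dims, sum(e$values > 1e-12 * max(abs(e$values), 1)))
  coords <- if (k > 0) {
    e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(D)
  out <- logical(n)
  offd <- D[upper.tri(D)]
  degenerate <- length(offd) && diff(range(offd)) < 1e-12
  # with all pairwise distances equal the embedding axes are arbitrary
  # (tied eigenvalues), so per-axis screening is meaningless: no outliers
  if (!degenerate) {
    for (j in seq_len(ncol(coords))) {
      x <- coords[, j]
      s <- stats::mad(x)
      if (s > 0) out <- out | abs(x - mean(x)) > mult * s
    }
  }
  list(coords = coords, eigenvalues = e$values,
       outliers = rownames(D)[out])
}
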