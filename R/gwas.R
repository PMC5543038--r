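## Per-SNP association scan.  The default engine ("null-fixed") estimates
## variance components once under the no-SNP model and holds them fixed for
## every SNP, solving each SNP's GLS through a Woodbury identity on the
## record-level covariance:
##   V^-1 = R^-1 - R^-1 Z (G^-1 + Z' R^-1 Z)^-1 Z' R^-1
## with Z = [Z_a Z_pe] and G = diag(V_A A, V_PE I).  The q x q inner matrix
## is sparse and factored once, so each SNP costs a handful of triangular
## solves.  The slow engine ("per-snp") refits REML per SNP.

.fixed_vc_context <- function(data, ped, theta, residuals, response) {
  n <- nrow(data)
  y <- data[[response]]
  rinv_of <- function(idx) {
    if (residuals == "heterogeneous") {
      vres <- theta$vres
      1 / vres[as.integer(droplevels(data$class))[idx]]
    } else {
      rep(1 / theta$vres[1], length(idx))
    }
  }
  ja <- match(data$id, ped$ids)
  qa <- length(ped$ids)
  uid <- unique(data$id)
  qp <- length(uid)
  jp <- match(data$id, uid)
  Ginv <- rbind(
    cbind(ped$Ainv / theta$va,
          Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(qa, qp))),
    cbind(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(qp, qa)),
          Matrix::Diagonal(qp) / theta$vpe)
  )
  Ginv <- Matrix::forceSymmetric(Ginv)

  make_solver <- function(idx) {
    ni <- length(idx)
    Z <- Matrix::sparseMatrix(
      i = rep(seq_len(ni), 2L),
      j = c(ja[idx], qa + jp[idx]),
      x = 1, dims = c(ni, qa + qp))
    rinv <- rinv_of(idx)
    ZtR <- Matrix::t(Z * rinv)
    Cq <- Matrix::forceSymmetric(Ginv + ZtR %*% Z)
    CH <- Matrix::Cholesky(Cq, LDL = FALSE, perm = TRUE)
    vsolve <- function(M) {
      RM <- M * rinv
      RM - as.matrix(Z %*% Matrix::solve(CH, ZtR %*% M)) * rinv
    }
    list(vsolve = vsolve, y = y[idx], rinv = rinv, idx = idx)
  }
  full <- make_solver(seq_len(n))
  list(full = full, make_solver = make_solver, n = n)
}

## GLS fit + Wald tests + adjusted marginal r2 for one design, given the
## Woodbury solver of the record subset.
.gls_snp <- function(solver, X, blocks, theta, class_sub, residuals) {
  VX <- solver$vsolve(X)
  XtVX <- crossprod(X, VX)
  Xty <- crossprod(VX, solver$y)
  ok <- TRUE
  beta <- cov <- NULL
  tryCatch({
    if (rcond(XtVX) < 1e-10) stop("ill-conditioned design")
    R <- chol(XtVX)
    cov <- chol2inv(R)
    beta <- cov %*% Xty
  }, error = function(e) ok <<- FALSE)
  if (!ok) return(NULL)
  n <- length(solver$y)
  res <- list()
  for (b in names(blocks)) {
    idx <- blocks[[b]]
    Vb <- cov[idx, idx, drop = FALSE]
    bb <- beta[idx]
    st <- tryCatch(max(0, as.numeric(t(bb) %*% solve(Vb, bb))),
                   error = function(e) NA_real_)
    res[[b]] <- list(stat = st, df = length(idx),
                     p = stats::pchisq(st, length(idx), lower.tail = FALSE))
  }
  fitted <- as.numeric(X %*% beta)
  vf <- stats::var(fitted) * (n - 1) / n
  mean_vres <- if (residuals == "heterogeneous") {
    mean(theta$vres[as.integer(class_sub)])
  } else {
    theta$vres[1]
  }
  p_fix <- ncol(X) - 1L
  r2 <- vf / (vf + theta$va + theta$vpe + mean_vres)
  r2a <- 1 - (1 - r2) * (n - 1) / (n - p_fix - 1)
  res$r2m_adj <- r2a
  res
}

#' Genome-wide association scan (main effect and interaction)
#'
#' For every SNP, fits the animal model with the SNP genotype as a 3-level
#' fixed factor (main-effect model) and additionally with the 4-df
#' SNP-by-temperature-class interaction block (interaction model), and
#' reports Wald chi-square tests plus adjusted marginal r-squared for both.
#' Records of individuals with a missing call at a SNP are dropped for that
#' SNP only.
#'
#' With `vc_mode = "null-fixed"` (default, fast) variance components are
#' REML-estimated once under the no-SNP null and held fixed across SNPs;
#' `"per-snp"` refits REML for every SNP and model (slow, exact).
#'
#' @param data Centered phenotype records (columns `id`, response, `class`,
#'   `age_class`).
#' @param G Genotype matrix, individuals x SNPs.
#' @param info SNP info (`snp`, `chr`, `pos`), rows matching `G` columns.
#' @param ped A [ped_precision()] object.
#' @param residuals `"heterogeneous"` (class-stratified) or
#'   `"homogeneous"`.
#' @param vc_mode `"null-fixed"` or `"per-snp"`.
#' @param response Response column name.
#' @param null_fit Optional pre-computed no-SNP [reml_fit()] on the same
#'   records and residual structure; skips the internal null REML (useful
#'   when scanning many phenotype replicates against components estimated
#'   once).
#' @return Data frame (class `"gwas_result"`): per SNP id, chr, pos, maf,
#'   n, stat/df/p for the main effect and the interaction, adjusted
#'   marginal r2 for both models, and a `converged` flag.  The null-model
#'   fit is attached as attribute `"null_fit"`.
#' @export
run_scan <- function(data, G, info, ped,
                     residuals = c("heterogeneous", "homogeneous"),
                     vc_mode = c("null-fixed", "per-snp"),
                     response = "centered", null_fit = NULL) {
  residuals <- match.arg(residuals)
  vc_mode <- match.arg(vc_mode)
  stopifnot(ncol(G) == nrow(info))
  data <- data[data$id %in% rownames(G), , drop = FALSE]
  ord <- order(info$chr, info$pos)
  info <- info[ord, , drop = FALSE]
  G <- G[, info$snp, drop = FALSE]

  if (is.null(null_fit)) {
    null_fit <- reml_fit(data, ped, response = response, snp = NULL,
                         residuals = residuals, se = FALSE)
  } else {
    stopifnot(inherits(null_fit, "reml_fit"),
              null_fit$residuals == residuals)
  }
  theta <- null_fit$theta
  ctx <- if (vc_mode == "null-fixed") {
    .fixed_vc_context(data, ped, theta, residuals, response)
  } else NULL

  base_des <- .build_design(data)
  X0 <- base_des$X
  cls <- data$class
  maf <- snp_maf(G[unique(data$id)[unique(data$id) %in% rownames(G)], ,
                   drop = FALSE])

  out <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    snp_id <- info$snp[j]
    g <- G[data$id, snp_id]
    okrec <- !is.na(g)
    row <- list(snp = snp_id, chr = info$chr[j], pos = info$pos[j],
                maf = maf[snp_id], n = sum(okrec),
                stat_main = NA_real_, df_main = 2L, p_main = NA_real_,
                stat_int = NA_real_, df_int = 4L,
                p_interaction = NA_real_,
                r2m_main = NA_real_, r2m_interaction = NA_real_,
                converged = FALSE)
    if (vc_mode == "null-fixed") {
      solver <- if (all(okrec)) ctx$full else ctx$make_solver(which(okrec))
      dsub <- data[okrec, , drop = FALSE]
      gs <- g[okrec]
      S <- cbind(snp_g1 = as.numeric(gs == 1L),
                 snp_g2 = as.numeric(gs == 2L))
      I4 <- cbind(snp_g1.int = S[, 1] * (dsub$class == "intermediate"),
                  snp_g1.warm = S[, 1] * (dsub$class == "warm"),
                  snp_g2.int = S[, 2] * (dsub$class == "intermediate"),
                  snp_g2.warm = S[, 2] * (dsub$class == "warm"))
      Xb <- X0[okrec, , drop = FALSE]
      main <- .gls_snp(solver, cbind(Xb, S),
                       list(snp = ncol(Xb) + 1:2), theta,
                       dsub$class, residuals)
      int <- .gls_snp(solver, cbind(Xb, S, I4),
                      list(snp = ncol(Xb) + 1:2,
                           interaction = ncol(Xb) + 3:6), theta,
                      dsub$class, residuals)
      if (!is.null(main) && !is.null(int)) {
        row$stat_main <- main$snp$stat
        row$p_main <- main$snp$p
        row$r2m_main <- main$r2m_adj
        row$stat_int <- int$interaction$stat
        row$p_interaction <- int$interaction$p
        row$r2m_interaction <- int$r2m_adj
        row$converged <- TRUE
      }
    } else {
      gvec <- G[, snp_id]
      warm <- list(va = theta$va, vpe = theta$vpe, vres = theta$vres)
      fm <- tryCatch(
        reml_fit(data, ped, response = response, snp = gvec,
                 residuals = residuals, se = FALSE, start = warm,
                 restarts = 0L),
        error = function(e) NULL)
      fi <- tryCatch(
        reml_fit(data, ped, response = response, snp = gvec,
                 interaction = TRUE, residuals = residuals, se = FALSE,
                 start = warm, restarts = 0L),
        error = function(e) NULL)
      if (!is.null(fm) && !is.null(fi)) {
        wm <- wald_test(fm, "snp")
        wi <- wald_test(fi, "interaction")
        row$stat_main <- wm$statistic
        row$p_main <- wm$p
        row$r2m_main <- marginal_r2(fm)$r2m_adj
        row$stat_int <- wi$statistic
        row$p_interaction <- wi$p
        row$r2m_interaction <- marginal_r2(fi)$r2m_adj
        row$converged <- fm$converged && fi$converged
      }
    }
    out[[j]] <- row
  }
  res <- do.call(rbind, lapply(out, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("gwas_result", "data.frame")
  attr(res, "null_fit") <- null_fit
  res
}

#' Bonferroni threshold
#'
#' @param M Number of tests (>= 1).
#' @param alpha Family-wise error rate.
#' @return `alpha / M`.
#' @export
bonferroni <- function(M, alpha = 0.05) {
  stopifnot(M >= 1)
  alpha / M
}

#' Effective number of independent tests under LD
#'
#' Sliding-window correction: per chromosome (SNPs in position order),
#' Keff = 1 + sum over SNPs j >= 2 of sqrt(1 - r2max_j), where r2max_j is
#' the largest squared Pearson genotype correlation between SNP j and its
#' preceding min(window - 1, j - 1) SNPs; chromosome contributions add.
#' Independent SNPs give Keff = M, perfect LD gives Keff = 1 per
#' chromosome.
#'
#' @param G Genotype matrix, individuals x SNPs.
#' @param info SNP info (`snp`, `chr`, `pos`).
#' @param window Sliding-window size in SNPs (default 20).
#' @return List `keff`, `M`, `reduction` (= (M - Keff)/M) and the
#'   per-chromosome contributions.
#' @export
keff <- function(G, info, window = 20L) {
  stopifnot(ncol(G) == nrow(info), window >= 2L)
  sds <- apply(G, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("zero-variance SNP in keff: ",
         paste(utils::head(info$snp[!is.finite(sds) | sds == 0]),
               collapse = ", "), " (should have been removed by QC)")
  }
  per_chr <- vapply(split(seq_len(nrow(info)), info$chr), function(ix) {
    ix <- ix[order(info$pos[ix])]
    m <- length(ix)
    k <- 1
    if (m >= 2L) {
      for (j in 2:m) {
        prev <- ix[max(1L, j - window + 1L):(j - 1L)]
        r2 <- vapply(prev, function(pj) {
          gi <- G[, ix[j]]
          gj <- G[, pj]
          ok <- !is.na(gi) & !is.na(gj)
          if (stats::sd(gi[ok]) == 0 || stats::sd(gj[ok]) == 0) {
            stop("zero-variance SNP in keff: ",
                 info$snp[ix[j]], " / ", info$snp[pj])
          }
          stats::cor(gi[ok], gj[ok])^2
        }, 0)
        k <- k + sqrt(max(0, 1 - max(r2)))
      }
    }
    k
  }, 0)
  M <- ncol(G)
  K <- sum(per_chr)
  list(keff = K, M = M, reduction = (M - K) / M, per_chr = per_chr)
}

#' Genomic inflation factor
#'
#' Converts p-values back to chi-square quantiles at the stated degrees of
#' freedom and reports lambda = median observed / median of the null
#' chi-square distribution.  Lambda near 1 indicates calibrated tests;
#' values above ~1.05 indicate inflation.
#'
#' @param p P-values (`NA`s dropped).
#' @param df Degrees of freedom of the test.
#' @return Lambda (numeric).
#' @export
genomic_inflation <- function(p, df) {
  p <- p[!is.na(p)]
  if (length(p) < 20L) stop("need >= 20 valid p-values")
  chi <- stats::qchisq(p, df = df, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = df, lower.tail = FALSE)
}

#' Compare main-effect and interaction models by adjusted marginal r2
#'
#' Restricts to SNPs where either term is significant at `alpha` and
#' reports, per SNP, the adjusted marginal r2 of both models and the
#' fraction of the subset where the interaction model explains more.
#'
#' @param results A [run_scan()] result.
#' @param alpha Significance level for subset membership (default 0.05).
#' @return List `table` (subset rows with both r2 values), `fraction`
#'   (share favoring the interaction model; `NA` for an empty subset) and
#'   `n_subset`.
#' @export
compare_models <- function(results, alpha = 0.05) {
  need <- c("snp", "p_main", "p_interaction", "r2m_main",
            "r2m_interaction")
  stopifnot(all(need %in% names(results)))
  sig <- !is.na(results$p_main) & !is.na(results$p_interaction) &
    (results$p_main < alpha | results$p_interaction < alpha)
  tab <- results[sig, need, drop = FALSE]
  tab$favors_interaction <- tab$r2m_interaction > tab$r2m_main
  if (!nrow(tab)) {
    message("no SNP significant at alpha = ", alpha,
            ": empty comparison table")
    return(list(table = tab, fraction = NA_real_, n_subset = 0L))
  }
  list(table = tab, fraction = mean(tab$favors_interaction),
       n_subset = nrow(tab))
}

#' Tables for Manhattan and QQ plots
#'
#' @param results A [run_scan()] result.
#' @param which `"p_main"` or `"p_interaction"`.
#' @return List `manhattan` (snp, chr, pos, neg_log10_p) and `qq`
#'   (expected vs observed -log10 quantiles).
#' @export
plot_tables <- function(results, which = c("p_interaction", "p_main")) {
  which <- match.arg(which)
  p <- results[[which]]
  ok <- !is.na(p)
  man <- data.frame(snp = results$snp[ok], chr = results$chr[ok],
                    pos = results$pos[ok], neg_log10_p = -log10(p[ok]))
  ps <- sort(p[ok])
  qq <- data.frame(
    expected = -log10(stats::ppoints(length(ps))),
    observed = -log10(ps))
  list(manhattan = man, qq = qq)
}
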