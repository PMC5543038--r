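#' Wald chi-square test for a fixed-effect block
#'
#' Tests the SNP main-effect block (2 df: genotype factor levels g1, g2) or
#' the SNP-by-class interaction block (4 df with three classes) of a fitted
#' model: statistic = b' Cov(b)^-1 b with the GLS coefficient covariance,
#' p from the upper chi-square tail.
#'
#' @param fit A [reml_fit()] object.
#' @param term `"snp"` or `"interaction"`.
#' @return List `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, term = c("snp", "interaction")) {
  term <- match.arg(term)
  idx <- fit$blocks[[term]]
  if (is.null(idx)) stop("term '", term, "' not present in the model spec")
  b <- fit$beta[idx]
  V <- fit$beta_cov[idx, idx, drop = FALSE]
  stat <- tryCatch(as.numeric(t(b) %*% solve(V, b)),
                   error = function(e) {
                     stop("aliased block: singular covariance for ", term)
                   })
  stat <- max(stat, 0)
  df <- length(idx)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Likelihood-ratio test for one variance component
#'
#' Compares a full and a reduced REML fit differing by exactly one variance
#' component under identical fixed effects: chi-square = 2 * (logLik_full -
#' logLik_reduced), clipped at zero, referred to a 1-df chi-square
#' (the plain convention; the 50:50 boundary mixture is available via
#' `mixture = TRUE`).
#'
#' @param fit_full,fit_reduced [reml_fit()] objects (or their restricted
#'   log-likelihoods as numbers).
#' @param mixture Use the 50:50 chi-square(0):chi-square(1) mixture null.
#' @return List `chi2`, `df`, `p`.
#' @export
lrt_component <- function(fit_full, fit_reduced, mixture = FALSE) {
  ll <- function(x) if (inherits(x, "reml_fit")) x$loglik else as.numeric(x)
  if (inherits(fit_full, "reml_fit") && inherits(fit_reduced, "reml_fit")) {
    if (fit_full$p != fit_reduced$p) {
      stop("usage error: fits must share the same fixed effects")
    }
    nv <- function(f) length(f$vc)
    if (nv(fit_full) - nv(fit_reduced) != 1L) {
      stop("usage error: reduced model must drop exactly one component")
    }
  }
  chi2 <- max(0, 2 * (ll(fit_full) - ll(fit_reduced)))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (mixture) p <- p / 2
  list(chi2 = chi2, df = 1L, p = p)
}

#' Narrow-sense heritability from variance components
#'
#' h2 = V_A / (V_A + V_PE + V_res[group]); the standard error comes from a
#' first-order delta method on the component covariance when available.
#'
#' @param vc Either a [reml_fit()] object or a named numeric vector with
#'   `V_A`, `V_PE` and the residual component(s).
#' @param group Residual group name (e.g. `"cold"`); needed only when the
#'   fit has stratified residuals.
#' @param vc_cov Optional component covariance matrix when `vc` is a plain
#'   vector.
#' @return List `h2`, `se` (`NA` when no covariance is available).
#' @export
heritability <- function(vc, group = NULL, vc_cov = NULL) {
  if (inherits(vc, "reml_fit")) {
    vc_cov <- vc$vc_cov
    vc <- vc$vc
  }
  nm <- names(vc)
  res_names <- grep("^V_res", nm, value = TRUE)
  rn <- if (!is.null(group)) {
    cand <- c(paste0("V_res.", group), group)
    hit <- cand[cand %in% nm]
    if (!length(hit)) stop("no residual component for group '", group, "'")
    hit[1]
  } else {
    if (length(res_names) != 1L) {
      stop("multiple residual groups: specify `group`")
    }
    res_names
  }
  use <- c("V_A", "V_PE", rn)
  if (!all(use %in% nm)) stop("vc must contain V_A, V_PE and ", rn)
  v <- vc[use]
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance: heritability undefined")
  h2 <- as.numeric(v["V_A"] / tot)
  se <- NA_real_
  if (!is.null(vc_cov) && all(use %in% rownames(vc_cov))) {
    g <- c((tot - v["V_A"]) / tot^2, -v["V_A"] / tot^2, -v["V_A"] / tot^2)
    S <- vc_cov[use, use]
    se <- sqrt(max(0, as.numeric(t(g) %*% S %*% g)))
  }
  list(h2 = h2, se = se)
}

#' Marginal r-squared of the fixed effects, with complexity adjustment
#'
#' The variance explained by the fixed effects alone relative to the total
#' modeled variance: r2m = var(X beta) / (var(X beta) + V_A + V_PE +
#' mean over records of V_res[group]).  The adjusted value applies the
#' classical Wherry correction 1 - (1 - r2m)(n - 1)/(n - p - 1) with p the
#' number of non-intercept fixed-effect columns, so richer models pay for
#' their extra terms when compared.
#'
#' @param fit A [reml_fit()] object.
#' @return List `r2m`, `r2m_adj`, `p` (non-intercept columns).
#' @export
marginal_r2 <- function(fit) {
  n <- fit$n
  p <- sum(colnames(fit$X) != "(Intercept)")
  if (n <= p + 1) stop("marginal r2 undefined: n <= p + 1")
  vf <- stats::var(fit$fitted_fixed) * (n - 1) / n
  vres <- fit$vc[grep("^V_res", names(fit$vc))]
  mean_vres <- if (length(vres) == 1L) {
    as.numeric(vres)
  } else {
    sum(vres * fit$group_n[sub("^V_res\\.", "", names(vres))]) /
      sum(fit$group_n)
  }
  denom <- vf + sum(fit$vc[intersect(c("V_A", "V_PE"), names(fit$vc))]) +
    mean_vres
  r2 <- vf / denom
  r2a <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2m = r2, r2m_adj = r2a, p = p)
}
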