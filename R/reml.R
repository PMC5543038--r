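## Repeated-measures animal model, fitted by REML through the mixed-model
## equations (MME):
##
##   y = X beta + Z_a a + Z_pe pe + e
##   a  ~ N(0, V_A * A)      (A = pedigree numerator relationship matrix)
##   pe ~ N(0, V_PE * I)     (one level per phenotyped individual)
##   e  ~ N(0, diag(V_res[group_j]))  (residual group = temperature class)
##
## The restricted log-likelihood is evaluated from the sparse MME
## coefficient matrix C = W' R^-1 W + diag(0, A^-1/V_A, I/V_PE):
##
##   -2 l_R = (n - p) log 2pi + log|R| + log|G| + log|C| + y' P y
##
## with y'Py = y'R^-1 y - sol' rhs.  A^-1 is sparse (Henderson rules), so a
## likelihood evaluation costs one sparse Cholesky of C; the symbolic
## factorization is computed once and updated numerically per evaluation.

## Precision-structure helper bundling what reml_fit needs of the pedigree.
#' Pedigree precision structure for model fitting
#'
#' Precomputes the sparse inverse numerator relationship matrix and its log
#' determinant for use in [reml_fit()] and [run_scan()].
#'
#' @param ped Pedigree data frame, parents before offspring.
#' @return List of class `"ped_precision"`: `ids`, `Ainv`, `logdet`.
#' @export
ped_precision <- function(ped) {
  ai <- a_inverse(ped)
  structure(list(ids = ped$id, Ainv = ai$Ainv, logdet = ai$logdet),
            class = "ped_precision")
}

## Build the fixed-effects design for one record table.  Base covariates:
## intercept + age (2-level factor).  Optional SNP genotype as an unordered
## 3-level factor (columns g1, g2 vs reference g0) and optional
## SNP-by-class interaction coded as the 4 treatment-contrast products
## (g1, g2) x (intermediate, warm); the class main effect is deliberately
## absent because year/area centering removes it (see vignette).
.build_design <- function(data, snp = NULL, interaction = FALSE,
                          fixed = NULL) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(fixed)) {
    Xf <- stats::model.matrix(fixed, data)
    keep <- colnames(Xf) != "(Intercept)"
    X <- cbind(X, Xf[, keep, drop = FALSE])
  } else if ("age_class" %in% names(data)) {
    X <- cbind(X, age_older = as.numeric(data$age_class == "older"))
  }
  blocks <- list()
  if (!is.null(snp)) {
    g <- snp
    S <- cbind(snp_g1 = as.numeric(g == 1L), snp_g2 = as.numeric(g == 2L))
    blocks$snp <- ncol(X) + seq_len(2L)
    X <- cbind(X, S)
    if (interaction) {
      cl <- data$class
      I4 <- cbind(
        snp_g1.int = S[, 1] * (cl == "intermediate"),
        snp_g1.warm = S[, 1] * (cl == "warm"),
        snp_g2.int = S[, 2] * (cl == "intermediate"),
        snp_g2.warm = S[, 2] * (cl == "warm")
      )
      blocks$interaction <- ncol(X) + seq_len(4L)
      X <- cbind(X, I4)
    }
  }
  ## drop aliased columns (rank deficiency), keeping track for the blocks
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep]
    for (b in names(blocks)) {
      if (any(blocks[[b]] %in% setdiff(seq_len(ncol(X)), keep))) {
        stop("aliased levels in ", b, " block: ",
             paste(intersect(colnames(X)[blocks[[b]]], dropped),
                   collapse = ", "))
      }
      blocks[[b]] <- match(blocks[[b]], keep)
    }
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, blocks = blocks)
}

## Assemble the REML evaluation engine.  Returns closures sharing
## precomputed per-group cross-product blocks so one likelihood evaluation
## is a sparse Cholesky update plus two triangular solves.
.reml_engine <- function(y, X, data_id, ped, groups, animal = TRUE,
                         pe = TRUE) {
  n <- length(y)
  p <- ncol(X)
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix")
  Wparts <- list(Xs)
  qa <- 0L
  qp <- 0L
  if (animal) {
    stopifnot(inherits(ped, "ped_precision"))
    ja <- match(data_id, ped$ids)
    if (anyNA(ja)) {
      stop("phenotyped individuals missing from pedigree: ",
           paste(unique(data_id[is.na(ja)]), collapse = ", "))
    }
    qa <- length(ped$ids)
    Wparts$Za <- Matrix::sparseMatrix(i = seq_len(n), j = ja, x = 1,
                                      dims = c(n, qa))
  }
  if (pe) {
    uid <- unique(data_id)
    qp <- length(uid)
    Wparts$Zp <- Matrix::sparseMatrix(i = seq_len(n),
                                      j = match(data_id, uid), x = 1,
                                      dims = c(n, qp))
  }
  W <- do.call(cbind, unname(Wparts))
  dimC <- p + qa + qp

  grp_idx <- lapply(groups, identity)
  G <- length(grp_idx)
  Mg <- lapply(grp_idx, function(ix) {
    Matrix::forceSymmetric(Matrix::crossprod(W[ix, , drop = FALSE]))
  })
  vg <- lapply(grp_idx, function(ix) {
    as.numeric(Matrix::crossprod(W[ix, , drop = FALSE], y[ix]))
  })
  yty_g <- vapply(grp_idx, function(ix) sum(y[ix]^2), 0)
  ng <- vapply(grp_idx, length, 0L)

  ## penalty patterns (A^-1 and I embedded in the C layout)
  pad <- function(M, at) {
    k <- nrow(M)
    idx <- at + seq_len(k)
    T <- methods::as(M, "TsparseMatrix")
    Matrix::sparseMatrix(i = T@i + 1L + at, j = T@j + 1L + at, x = T@x,
                         dims = c(dimC, dimC), symmetric = FALSE)
  }
  Pa <- if (animal) pad(Matrix::triu(ped$Ainv), p) else NULL
  Pp <- if (pe) {
    Matrix::sparseMatrix(i = p + qa + seq_len(qp), j = p + qa + seq_len(qp),
                         x = 1, dims = c(dimC, dimC))
  } else NULL

  buildC <- function(theta) {
    ## theta: list(va, vpe, vres = numeric(G))
    C <- Reduce(`+`, Map(function(M, v) M / v, Mg, as.list(theta$vres)))
    C <- methods::as(C, "generalMatrix")
    C <- Matrix::triu(C)
    if (animal) C <- C + Pa / theta$va
    if (pe) C <- C + Pp / theta$vpe
    Matrix::forceSymmetric(C, uplo = "U")
  }

  sym <- NULL   # symbolic factorization, computed on first use

  factorC <- function(C) {
    if (is.null(sym)) {
      sym <<- Matrix::Cholesky(C, LDL = FALSE, super = FALSE, perm = TRUE)
      sym
    } else {
      Matrix::update(sym, C)
    }
  }

  const <- (n - p) * log(2 * pi)

  neg2ll <- function(theta) {
    if (any(unlist(theta) <= 0)) return(Inf)
    C <- buildC(theta)
    CH <- tryCatch(factorC(C), error = function(e) NULL)
    if (is.null(CH)) return(Inf)
    rhs <- Reduce(`+`, Map(`/`, vg, as.list(theta$vres)))
    sol <- as.numeric(Matrix::solve(CH, rhs))
    yry <- sum(yty_g / theta$vres)
    yPy <- yry - sum(sol * rhs)
    logdetC <- 2 * as.numeric(Matrix::determinant(CH, sqrt = TRUE)$modulus)
    logdetR <- sum(ng * log(theta$vres))
    logdetG <- 0
    if (animal) logdetG <- logdetG + qa * log(theta$va) + ped$logdet
    if (pe) logdetG <- logdetG + qp * log(theta$vpe)
    const + logdetR + logdetG + logdetC + yPy
  }

  solve_at <- function(theta) {
    C <- buildC(theta)
    CH <- factorC(C)
    rhs <- Reduce(`+`, Map(`/`, vg, as.list(theta$vres)))
    sol <- as.numeric(Matrix::solve(CH, rhs))
    Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                               dims = c(dimC, p))
    Cinv_p <- Matrix::solve(CH, Ep)
    beta_cov <- as.matrix(Cinv_p[seq_len(p), , drop = FALSE])
    beta <- sol[seq_len(p)]
    a <- if (animal) stats::setNames(sol[p + seq_len(qa)], ped$ids) else NULL
    pe_v <- if (pe) sol[p + qa + seq_len(qp)] else NULL
    list(beta = beta, beta_cov = (beta_cov + t(beta_cov)) / 2,
         a = a, pe = pe_v)
  }

  list(neg2ll = neg2ll, solve_at = solve_at, n = n, p = p, qa = qa, qp = qp,
       G = G, W = W, ng = ng)
}

.theta_pack <- function(par, animal, pe, G) {
  i <- 0L
  va <- if (animal) exp(par[i <- i + 1L]) else NULL
  vpe <- if (pe) exp(par[i <- i + 1L]) else NULL
  list(va = va, vpe = vpe, vres = exp(par[i + seq_len(G)]))
}

#' Fit the repeated-measures animal model by REML
#'
#' Maximizes the restricted likelihood of the model described above over
#' log-parameterized variance components with the PORT optimizer (`nlminb`)
#' plus perturbed restarts, then computes fixed effects by GLS at the
#' optimum.  Residual variances are either pooled (`residuals =
#' "homogeneous"`) or stratified by the `class` column (`"heterogeneous"`).
#'
#' @param data Phenotype records: columns `id`, the response, and any
#'   covariates; `class` (factor cold/intermediate/warm) when heterogeneous
#'   residuals or an interaction are requested.
#' @param ped A [ped_precision()] object (or `NULL` with `animal = FALSE`).
#' @param response Name of the response column (e.g. `"centered"`).
#' @param snp Optional named genotype vector (0/1/2 by individual id) for
#'   the SNP fixed effect; records of individuals with a missing call are
#'   dropped (complete-case per SNP).
#' @param interaction Add the SNP-by-class interaction block (requires
#'   `snp`).
#' @param residuals `"homogeneous"` or `"heterogeneous"`.
#' @param animal Include the additive genetic effect (default `TRUE`).
#' @param pe Include the permanent-environment effect (default `TRUE`).
#' @param fixed Optional one-sided formula of additional fixed effects
#'   evaluated in `data` (replaces the default age term).
#' @param se Compute standard errors of variance components by numerical
#'   differentiation of the restricted likelihood (default `TRUE`).
#' @param start Optional named list of starting values
#'   (`va`, `vpe`, `vres`).
#' @param restarts Number of perturbed restarts (default 2).
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `"reml_fit"`; see Details.  Key fields:
#'   `vc` (named variance components), `vc_cov`, `beta`, `beta_cov`,
#'   `blocks`, `loglik` (restricted), `converged`, `boundary`, `n`, `p`.
#' @export
reml_fit <- function(data, ped = NULL, response = "centered", snp = NULL,
                     interaction = FALSE, residuals = "heterogeneous",
                     animal = TRUE, pe = TRUE, fixed = NULL, se = TRUE,
                     start = NULL, restarts = 2L,
                     control = list(rel.tol = 1e-12, iter.max = 500L,
                                    eval.max = 1000L)) {
  residuals <- match.arg(residuals, c("heterogeneous", "homogeneous"))
  stopifnot(response %in% names(data), "id" %in% names(data))
  if (interaction && is.null(snp)) stop("interaction requires a SNP term")

  keep <- rep(TRUE, nrow(data))
  gvec <- NULL
  if (!is.null(snp)) {
    gvec <- snp[data$id]
    keep <- !is.na(gvec)
  }
  data <- data[keep, , drop = FALSE]
  if (!is.null(snp)) gvec <- gvec[keep]
  y <- data[[response]]
  if (anyNA(y)) stop("missing response values")

  if (residuals == "heterogeneous" || interaction) {
    if (!"class" %in% names(data)) {
      stop("heterogeneous residuals require a 'class' column on every record")
    }
  }
  groups <- if (residuals == "heterogeneous") {
    split(seq_along(y), droplevels(as.factor(data$class)))
  } else {
    list(all = seq_along(y))
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("each residual group needs at least 2 records")
  }

  des <- .build_design(data, snp = gvec, interaction = interaction,
                       fixed = fixed)
  eng <- .reml_engine(y, des$X, data$id, ped, groups, animal = animal,
                      pe = pe)
  G <- eng$G
  vy <- stats::var(y)
  s0 <- list(va = vy / 3, vpe = vy / 3, vres = rep(vy / 2, G))
  if (!is.null(start)) s0[names(start)] <- start
  par0 <- log(unlist(s0[c(if (animal) "va", if (pe) "vpe", "vres")],
                     use.names = FALSE))
  obj <- function(par) eng$neg2ll(.theta_pack(par, animal, pe, G))

  lower <- log(vy) - 20
  upper <- log(vy) + 10
  best <- NULL
  set_starts <- c(0, seq_len(restarts))
  for (k in set_starts) {
    p0 <- if (k == 0) par0 else par0 + (k %% 2 * 2 - 1) * k * 0.7
    opt <- tryCatch(
      stats::nlminb(p0, obj, lower = lower, upper = upper,
                    control = control),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("REML optimization failed from all starts")
  ## polish: restart from the optimum with the tightest tolerances nlminb
  ## accepts, so closed-form oracles are matched to ~1e-9
  pol <- tryCatch(
    stats::nlminb(best$par, obj, lower = lower, upper = upper,
                  control = list(rel.tol = 1e-15, x.tol = 1e-14,
                                 iter.max = 200L)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$objective <= best$objective) best <- pol
  ## Newton polish on the log scale.  Near the optimum the objective is too
  ## flat for value comparisons (differences sink below evaluation noise),
  ## so iterate on the finite-difference gradient directly, inside a small
  ## trust region around the nlminb solution, and only fall back if the
  ## curvature is not positive definite.
  np <- length(best$par)
  grad_norm <- Inf
  par_n <- best$par
  for (it in 1:6) {
    ## Richardson-extrapolated central differences: kills the O(h^2)
    ## truncation term, so a larger h keeps roundoff noise low too
    h <- 1e-3
    g <- numeric(np)
    Hd <- matrix(0, np, np)
    f0 <- obj(par_n)
    fp <- fm <- numeric(np)
    for (i in seq_len(np)) {
      ei <- replace(numeric(np), i, h)
      fp[i] <- obj(par_n + ei)
      fm[i] <- obj(par_n - ei)
      g1 <- (fp[i] - fm[i]) / (2 * h)
      g2 <- (obj(par_n + 2 * ei) - obj(par_n - 2 * ei)) / (4 * h)
      g[i] <- (4 * g1 - g2) / 3
      Hd[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    }
    grad_norm <- max(abs(g))
    if (np > 1L) {
      for (i in 1:(np - 1L)) {
        for (j in (i + 1L):np) {
          eij <- replace(numeric(np), c(i, j), h)
          Hd[i, j] <- Hd[j, i] <-
            (obj(par_n + eij) - fp[i] - fp[j] + f0) / h^2
        }
      }
    }
    ok_H <- tryCatch({ chol(Hd); TRUE }, error = function(e) FALSE)
    if (!ok_H) break
    step <- -solve(Hd, g)
    if (!all(is.finite(step))) break
    smax <- max(abs(step))
    if (smax > 0.05) step <- step * (0.05 / smax)   # trust region
    par_n <- pmin(pmax(par_n + step, lower), upper)
    if (max(abs(step)) < 1e-10) break
  }
  fn <- obj(par_n)
  if (is.finite(fn) && fn <= best$objective + 1e-8 * max(1, abs(best$objective))) {
    best$par <- par_n
    best$objective <- min(fn, best$objective)
  }
  theta <- .theta_pack(best$par, animal, pe, G)
  ## nlminb's "singular convergence" is routine at tight tolerances near a
  ## flat optimum; trust the polished gradient instead of the return code
  converged <- is.finite(best$objective) &&
    (best$convergence == 0 || grad_norm < 1e-3 * max(1, abs(best$objective)))
  boundary <- c(
    if (animal) c(va = theta$va < vy * 1e-5),
    if (pe) c(vpe = theta$vpe < vy * 1e-5),
    stats::setNames(theta$vres < vy * 1e-5,
                    paste0("vres.", names(groups)))
  )

  sol <- eng$solve_at(theta)
  vc <- c(if (animal) c(V_A = theta$va),
          if (pe) c(V_PE = theta$vpe),
          stats::setNames(theta$vres, paste0("V_res.", names(groups))))

  vc_cov <- NULL
  if (se) {
    np <- length(best$par)
    h <- pmax(abs(best$par) * 1e-4, 1e-5)
    H <- matrix(NA_real_, np, np)
    f0 <- best$objective
    fp <- fm <- numeric(np)
    for (i in seq_len(np)) {
      ei <- replace(numeric(np), i, h[i])
      fp[i] <- obj(best$par + ei)
      fm[i] <- obj(best$par - ei)
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    }
    for (i in seq_len(np)) {
      for (j in seq_len(np)) {
        if (i < j) {
          eij <- replace(numeric(np), c(i, j), h[c(i, j)])
          fpp <- obj(best$par + eij)
          H[i, j] <- H[j, i] <-
            (fpp - fp[i] - fp[j] + f0) / (h[i] * h[j])
        }
      }
    }
    ## delta back to natural scale: d V / d log V = V
    Hn <- tryCatch({
      Sl <- 2 * solve(H)                    # cov of log components
      D <- diag(exp(best$par), np)
      D %*% Sl %*% D
    }, error = function(e) NULL)
    if (!is.null(Hn)) {
      dimnames(Hn) <- list(names(vc), names(vc))
      vc_cov <- Hn
    }
  }

  structure(list(
    vc = vc, vc_cov = vc_cov, theta = theta,
    beta = stats::setNames(sol$beta, colnames(des$X)),
    beta_cov = sol$beta_cov, blocks = des$blocks,
    X = des$X, fitted_fixed = as.numeric(des$X %*% sol$beta),
    ranef = list(a = sol$a, pe = sol$pe),
    loglik = -0.5 * best$objective,
    converged = converged, boundary = boundary,
    residuals = residuals, animal = animal, pe = pe,
    groups = names(groups),
    group_n = vapply(groups, length, 0L),
    n = eng$n, p = eng$p,
    data_id = data$id
  ), class = "reml_fit")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the restricted log-likelihood of the model of [reml_fit()] at
#' user-supplied components without optimizing — useful for profile plots,
#' grid checks and constrained comparisons (e.g. a heterogeneous model with
#' all residual groups forced equal).
#'
#' @inheritParams reml_fit
#' @param theta Named list `va`, `vpe`, `vres` (lengths matching the model;
#'   omit components excluded by `animal`/`pe`).
#' @return The restricted log-likelihood (numeric).
#' @export
reml_loglik <- function(data, ped = NULL, theta, response = "centered",
                        residuals = "heterogeneous", animal = TRUE,
                        pe = TRUE, fixed = NULL) {
  residuals <- match.arg(residuals, c("heterogeneous", "homogeneous"))
  y <- data[[response]]
  groups <- if (residuals == "heterogeneous") {
    split(seq_along(y), droplevels(as.factor(data$class)))
  } else {
    list(all = seq_along(y))
  }
  des <- .build_design(data, fixed = fixed)
  eng <- .reml_engine(y, des$X, data$id, ped, groups, animal = animal,
                      pe = pe)
  theta$vres <- rep(theta$vres, length.out = eng$G)
  -0.5 * eng$neg2ll(theta)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML animal-model fit:", x$n, "records,", x$p, "fixed-effect df\n")
  cat("  residuals:", x$residuals, "\n")
  cat("  restricted logLik:", format(x$loglik, digits = 8),
      if (!x$converged) "(NOT converged)", "\n")
  cat("  variance components:\n")
  se <- if (!is.null(x$vc_cov)) sqrt(pmax(diag(x$vc_cov), 0)) else
    rep(NA_real_, length(x$vc))
  for (i in seq_along(x$vc)) {
    cat(sprintf("    %-12s %8.3f  (SE %s)%s\n", names(x$vc)[i], x$vc[i],
                ifelse(is.na(se[i]), "n/a", sprintf("%.3f", se[i])),
                if (isTRUE(x$boundary[i])) " [boundary]" else ""))
  }
  invisible(x)
}
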