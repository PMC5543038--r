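test_that("REML equals closed-form ANOVA estimators on balanced data", {
  set.seed(42)
  k <- 5
  q <- 30
  id <- rep(sprintf("i%02d", 1:q), each = k)
  y <- rep(rnorm(q, 0, 2), each = k) + rnorm(q * k, 0, 1.5) + 10
  d <- data.frame(id = id, y = y)
  fit <- reml_fit(d, ped = NULL, response = "y",
                  residuals = "homogeneous", animal = FALSE, pe = TRUE,
                  fixed = ~1, se = FALSE)
  gm <- tapply(y, id, mean)
  MSB <- k * sum((gm - mean(y))^2) / (q - 1)
  MSW <- sum((y - gm[id])^2) / (q * (k - 1))
  truth <- c((MSB - MSW) / k, MSW)
  est <- unname(fit$vc[c("V_PE", "V_res.all")])
  expect_lt(max(abs(est - truth) / truth), 1e-8)
})

test_that("REML matches a 2-D grid-search likelihood oracle", {
  # 30 records, 2 residual groups, fixed effects only (no a, no pe)
  set.seed(11)
  n <- 30
  cls <- factor(rep(c("cold", "warm"), c(14, 16)),
                levels = c("cold", "intermediate", "warm"))
  x <- rnorm(n)
  y <- 2 + 0.5 * x + rnorm(n, 0, ifelse(cls == "cold", 1.4, 0.7))
  d <- data.frame(id = sprintf("r%02d", 1:n), y = y, x = x, class = cls)
  fit <- reml_fit(d, ped = NULL, response = "y", residuals = "heterogeneous",
                  animal = FALSE, pe = FALSE, fixed = ~x, se = FALSE)

  # independent oracle: dense restricted likelihood on a refining grid
  X <- cbind(1, x)
  restll <- function(v1, v2) {
    V <- diag(ifelse(cls == "cold", v1, v2))
    Vi <- diag(1 / diag(V))
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    -0.5 * as.numeric(sum(log(diag(V))) + determinant(XtViX)$modulus[1] +
                        t(r) %*% Vi %*% r + (n - 2) * log(2 * pi))
  }
  rng1 <- seq(0.1, 5, by = 0.05)
  g <- outer(rng1, rng1, Vectorize(restll))
  top <- arrayInd(which.max(g), dim(g))
  fine1 <- seq(rng1[top[1]] - 0.06, rng1[top[1]] + 0.06, by = 1e-3)
  fine2 <- seq(rng1[top[2]] - 0.06, rng1[top[2]] + 0.06, by = 1e-3)
  gf <- outer(fine1, fine2, Vectorize(restll))
  topf <- arrayInd(which.max(gf), dim(gf))
  oracle <- c(fine1[topf[1]], fine2[topf[2]])
  est <- unname(fit$vc[c("V_res.cold", "V_res.warm")])
  expect_lt(max(abs(est - oracle)), 2e-3)
  expect_equal(fit$loglik, restll(est[1], est[2]), tolerance = 1e-8)
})

test_that("restricted likelihood is invariant to design reparameterization", {
  w <- small_world(seed = 3, n_founders = 40, n_snps = 4)
  d <- w$centered
  f1 <- reml_fit(d, w$ped_prec, se = FALSE)
  d2 <- d
  d2$age_class <- factor(d2$age_class, levels = c("older", "first"))
  f2 <- reml_fit(d2, w$ped_prec, se = FALSE,
                 fixed = ~age_class)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("heterogeneous fit at equal components reproduces the homogeneous
          likelihood", {
  w <- small_world(seed = 4, n_founders = 40, n_snps = 4)
  d <- w$centered
  hom <- reml_fit(d, w$ped_prec, residuals = "homogeneous", se = FALSE)
  th <- hom$theta
  ll_het <- reml_loglik(d, w$ped_prec,
                        theta = list(va = th$va, vpe = th$vpe,
                                     vres = rep(th$vres, 3)),
                        residuals = "heterogeneous")
  expect_equal(ll_het, hom$loglik, tolerance = 1e-6)
})

test_that("Wald test reduces correctly and rejects missing terms", {
  fake <- structure(list(
    beta = c("(Intercept)" = 1, snp_g1 = 0, snp_g2 = 0),
    beta_cov = diag(c(1, 2, 3)),
    blocks = list(snp = 2:3)), class = "reml_fit")
  wt <- wald_test(fake, "snp")
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p, 1)
  expect_equal(wt$df, 2L)

  fake$beta <- c(1, 0.8, 0)
  fake$blocks <- list(snp = 2L)
  wt1 <- wald_test(fake, "snp")
  expect_equal(wt1$statistic, 0.8^2 / 2)   # squared z-test, 1 df
  expect_equal(wt1$df, 1L)
  expect_error(wald_test(fake, "interaction"), "not present")
})

test_that("interaction Wald p-values are calibrated under the null", {
  # fixed known components, fresh phenotype per replicate; GLS through the
  # same Woodbury path the scan uses
  w <- small_world(seed = 19, n_founders = 60, n_snps = 30,
                   mean_records = 2, maf_range = c(0.3, 0.5),
                   sd_year = 0, beta_temp = 0, n_areas = 1, sd_area = 0)
  d <- w$centered
  d$raw <- d$laying_date
  th <- list(va = 10.8, vpe = 3, vres = c(14.5, 14.5, 14.5))
  ctx <- gxewas:::.fixed_vc_context(d, w$ped_prec, th, "heterogeneous",
                                    "raw")
  A <- a_matrix(w$pedigree)
  ids <- w$pedigree$id
  Za <- outer(d$id, ids, "==") * 1
  uid <- unique(d$id)
  Zp <- outer(d$id, uid, "==") * 1
  L <- chol(10.8 * A)
  ps <- numeric(400)
  set.seed(55)
  X0 <- matrix(1, nrow(d), 1)
  solver0 <- ctx$make_solver(seq_len(nrow(d)))
  for (r in seq_len(400)) {
    yv <- as.numeric(Za %*% (t(L) %*% rnorm(length(ids)))) +
      as.numeric(Zp %*% rnorm(length(uid), 0, sqrt(3))) +
      rnorm(nrow(d), 0, sqrt(14.5))
    solver <- solver0
    solver$y <- yv
    g <- w$genotypes[d$id, 1 + (r %% 25)]
    S <- cbind(g == 1, g == 2) * 1
    I4 <- cbind(S[, 1] * (d$class == "intermediate"),
                S[, 1] * (d$class == "warm"),
                S[, 2] * (d$class == "intermediate"),
                S[, 2] * (d$class == "warm"))
    res <- gxewas:::.gls_snp(solver, cbind(X0, S, I4),
                             list(interaction = 4:7), th, d$class,
                             "heterogeneous")
    ps[r] <- if (is.null(res)) NA else res$interaction$p
  }
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(genomic_inflation(ps, 4) - 1), 0.15)
})

test_that("likelihood-ratio arithmetic matches the chi-square tail", {
  same <- list(loglik = -100)
  expect_equal(lrt_component(-100, -100)$chi2, 0)
  expect_equal(lrt_component(-100, -100)$p, 1)
  expect_equal(lrt_component(-95.305, -100)$chi2, 9.39)
  expect_equal(round(lrt_component(-95.305, -100)$p, 3), 0.002)
  expect_lt(lrt_component(-79.05, -100)$p, 0.001)   # chi2 = 41.9
  f1 <- structure(list(loglik = -10, p = 2, vc = c(a = 1, b = 1, c = 1)),
                  class = "reml_fit")
  f2 <- structure(list(loglik = -11, p = 3, vc = c(a = 1, b = 1)),
                  class = "reml_fit")
  expect_error(lrt_component(f1, f2), "same fixed effects")
})

test_that("heritability arithmetic and delta-method SE", {
  expect_equal(round(heritability(c(V_A = 10.8, V_PE = 3.00,
                                    V_res = 14.5))$h2, 2), 0.38)
  expect_equal(round(heritability(c(V_A = 3.75, V_PE = 8.24,
                                    V_res = 15.4))$h2, 2), 0.14)
  expect_equal(round(heritability(c(V_A = 9.69, V_PE = 2.27,
                                    V_res = 11.9))$h2, 2), 0.41)
  expect_equal(heritability(c(V_A = 5, V_PE = 0, V_res = 0))$h2, 1)
  expect_error(heritability(c(V_A = 0, V_PE = 0, V_res = 0)), "undefined")
  # delta method against a small parametric bootstrap of the ratio
  vc <- c(V_A = 10, V_PE = 3, V_res = 14)
  S <- diag(c(2, 1, 1))
  dimnames(S) <- list(names(vc), names(vc))
  se <- heritability(vc, vc_cov = S)$se
  set.seed(2)
  draws <- rmvn_chol(5000, vc, S)
  h2d <- draws[, 1] / rowSums(draws)
  expect_equal(se, sd(h2d), tolerance = 0.05)
})

test_that("marginal r2 recovers a constructed fixed-effect share", {
  set.seed(21)
  q <- 1000
  id <- rep(sprintf("i%04d", 1:q), each = 2)
  x <- rep(rbinom(q, 1, 0.5), each = 2)
  y <- 4 * x + rep(rnorm(q, 0, 2), each = 2) + rnorm(2 * q, 0, sqrt(8))
  d <- data.frame(id = id, y = y, x = x)
  fit <- reml_fit(d, NULL, response = "y", residuals = "homogeneous",
                  animal = FALSE, pe = TRUE, fixed = ~x, se = FALSE)
  r2 <- marginal_r2(fit)
  # construction: var(Xb) = 4, total = 4 + 4 + 8 -> 0.25
  expect_lt(abs(r2$r2m - 0.25), 0.05)
  expect_lt(abs(r2$r2m_adj - r2$r2m), 0.01)

  fit0 <- fit
  fit0$fitted_fixed <- rep(mean(y), length(y))
  r20 <- marginal_r2(fit0)
  expect_equal(r20$r2m, 0)
  expect_lte(r20$r2m_adj, 0)
})

test_that("REML recovers simulation components at desk scale", {
  h2s <- sapply(1:4, function(s) {
    cfg <- sim_config(n_founders = 120, n_generations = 3,
                      offspring_per_pair = 3, n_snps = 2,
                      n_phenotyped = 500, mean_records = 1.5,
                      V_A = 10.8, V_PE = 3.0, V_res = 14.5, seed = 100 + s)
    d <- simulate_dataset(cfg)
    pc <- center_phenotypes(d$phenotypes, d$classification)
    fit <- reml_fit(pc, ped_precision(d$pedigree),
                    residuals = "homogeneous", se = FALSE)
    heritability(fit)$h2
  })
  expect_lt(abs(mean(h2s) - 10.8 / 28.3), 0.1)
})
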