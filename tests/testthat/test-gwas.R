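test_that("bonferroni threshold arithmetic", {
  expect_equal(bonferroni(1, 0.05), 0.05)
  expect_equal(bonferroni(20, 0.05), 2.5e-3)
  expect_equal(bonferroni(384081, 0.05), 0.05 / 384081)
  expect_equal(bonferroni(384081, 0.05), 1.3018e-7, tolerance = 1e-4)
  expect_error(bonferroni(0))
})

test_that("keff limiting values, bounds and oracle recomputation", {
  set.seed(33)
  n <- 120
  # exactly orthogonal columns: balanced factorial patterns
  g1 <- rep(c(0L, 2L), each = n / 2)
  g2 <- rep(c(0L, 2L), times = n / 2)
  g3 <- rep(c(0L, 1L, 2L, 1L), times = n / 4)
  G_ind <- cbind(a = g1, b = g2, c = g3)
  stopifnot(abs(cor(G_ind)[upper.tri(diag(3))]) < 1e-12)
  info3 <- data.frame(snp = colnames(G_ind), chr = "c1", pos = 1:3 * 100)
  expect_equal(keff(G_ind, info3)$keff, 3)

  G_dup <- cbind(a = g1, b = g1, c = g1)
  expect_equal(keff(G_dup, info3)$keff, 1)

  # brute-force oracle on random data, including the window bound
  m <- 40
  G <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
  colnames(G) <- sprintf("s%02d", 1:m)
  info <- data.frame(snp = colnames(G),
                     chr = rep(c("c1", "c2"), each = m / 2),
                     pos = rep(seq_len(m / 2) * 1000, 2))
  w <- 7L
  oracle <- 0
  for (ch in c("c1", "c2")) {
    idx <- which(info$chr == ch)
    oracle <- oracle + 1
    for (j in 2:length(idx)) {
      prev <- idx[max(1, j - w + 1):(j - 1)]
      r2m <- max(cor(G[, idx[j]], G[, prev])^2)
      oracle <- oracle + sqrt(1 - r2m)
    }
  }
  k <- keff(G, info, window = w)
  expect_equal(k$keff, oracle, tolerance = 1e-12)
  expect_gte(k$keff, 1)
  expect_lte(k$keff, m)
  expect_equal(k$reduction, (m - oracle) / m)

  # monotone non-increasing as LD strengthens
  mk_ld <- function(rho, seed = 50) {
    set.seed(seed)
    base <- rbinom(n, 2, 0.4)
    sapply(1:10, function(j) {
      flip <- runif(n) > rho
      ifelse(flip, rbinom(n, 2, 0.4), base)
    })
  }
  infoL <- data.frame(snp = sprintf("l%02d", 1:10), chr = "c1",
                      pos = 1:10 * 50)
  ks <- sapply(c(0, 0.5, 0.9), function(r) {
    Gl <- mk_ld(r)
    colnames(Gl) <- infoL$snp
    keff(Gl, infoL)$keff
  })
  expect_true(all(diff(ks) < 0))
  expect_error(keff(cbind(z = rep(1L, n)),
                    data.frame(snp = "z", chr = "c1", pos = 1L)),
               "zero-variance")
})

test_that("genomic inflation factor behaves", {
  set.seed(61)
  p <- runif(1e4)
  expect_lt(abs(genomic_inflation(p, 4) - 1), 0.03)
  expect_equal(genomic_inflation(rep(0.5, 30), 4), 1)
  expect_equal(genomic_inflation(rep(0.5, 30), 2), 1)
  expect_error(genomic_inflation(runif(5), 2), ">= 20")
})

test_that("model comparison table and degenerate subset", {
  res <- data.frame(
    snp = sprintf("s%d", 1:4),
    p_main = c(0.01, 0.2, 0.5, NA),
    p_interaction = c(0.2, 0.01, 0.6, 0.01),
    r2m_main = c(0.05, 0.02, 0.01, 0.10),
    r2m_interaction = c(0.04, 0.06, 0.02, 0.20))
  cmp <- compare_models(res, alpha = 0.05)
  expect_equal(cmp$n_subset, 2L)             # s1, s2 (s4 has missing main p)
  expect_equal(cmp$fraction, 0.5)
  expect_message(cmp0 <- compare_models(res, alpha = 1e-6), "empty")
  expect_equal(cmp0$n_subset, 0L)
  expect_true(is.na(cmp0$fraction))
})

test_that("scan engines agree and detect a planted interaction", {
  eff <- causal_effect(cold = c(0, 0, 3), intermediate = c(0, 0, 0),
                       warm = c(0, 0, -3))
  w <- small_world(seed = 30, n_founders = 80, n_snps = 25,
                   n_phen = 200, mean_records = 2,
                   maf_range = c(0.3, 0.5),
                   causal = list(snp00010 = eff))
  d <- w$centered
  scan_nf <- run_scan(d, w$genotypes, w$info, w$ped_prec,
                      residuals = "heterogeneous", vc_mode = "null-fixed")
  expect_equal(nrow(scan_nf), 25L)
  expect_true(all(scan_nf$df_main == 2L & scan_nf$df_int == 4L))
  ok <- scan_nf$converged
  expect_true(all(scan_nf$p_main[ok] > 0 & scan_nf$p_main[ok] <= 1))

  # slow exact engine on a subset: p-values must agree with the fast path
  sub <- scan_nf$snp[ok][1:10]
  info_sub <- w$info[match(sub, w$info$snp), ]
  scan_ps <- run_scan(d, w$genotypes[, sub, drop = FALSE], info_sub,
                      w$ped_prec, residuals = "heterogeneous",
                      vc_mode = "per-snp")
  m_nf <- scan_nf[match(scan_ps$snp, scan_nf$snp), ]
  both <- scan_ps$converged
  expect_gt(cor(m_nf$p_interaction[both], scan_ps$p_interaction[both],
                method = "spearman"), 0.99)
  expect_lt(max(abs(m_nf$p_interaction[both] -
                      scan_ps$p_interaction[both])), 0.02)

  # the class-reversing causal SNP: interaction beats the main effect
  row <- scan_nf[scan_nf$snp == "snp00010", ]
  expect_lt(row$p_interaction, row$p_main)
  expect_equal(which.min(scan_nf$p_interaction),
               which(scan_nf$snp == "snp00010"))
})

test_that("records with missing calls are dropped per SNP only", {
  w <- small_world(seed = 44, n_founders = 60, n_snps = 6,
                   mean_records = 2, maf_range = c(0.3, 0.5))
  G <- w$genotypes
  some <- unique(w$centered$id)[1:5]
  G[some, 2] <- NA_integer_
  scan <- run_scan(w$centered, G, w$info, w$ped_prec,
                   residuals = "heterogeneous")
  full_n <- scan$n[scan$snp == w$info$snp[1]]
  red_n <- scan$n[scan$snp == w$info$snp[2]]
  expect_lt(red_n, full_n)
  expect_true(scan$converged[scan$snp == w$info$snp[2]])
})
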