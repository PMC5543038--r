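test_that("pedigree simulation obeys structure and determinism", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    offspring_per_pair = 2, seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4L)
  off <- ped[ped$generation == 1L, ]
  expect_equal(length(unique(off$sire)), 1L)
  expect_equal(length(unique(off$dam)), 1L)
  expect_true(all(is.na(ped$sire[ped$generation == 0L])))

  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)
  cfg3 <- sim_config(n_founders = 2, n_generations = 1,
                     offspring_per_pair = 2, seed = 6)
  # sexes of offspring are random, so a different seed changes something
  ped3a <- simulate_pedigree(sim_config(n_founders = 40, n_generations = 2,
                                        offspring_per_pair = 2, seed = 1))
  ped3b <- simulate_pedigree(sim_config(n_founders = 40, n_generations = 2,
                                        offspring_per_pair = 2, seed = 2))
  expect_false(identical(ped3a, ped3b))
  expect_error(sim_config(n_founders = 1), "n_founders")
})

test_that("pedigree relatedness matches the independent kinship oracle", {
  ped <- random_ped(20, 3, 2, seed = 9)
  A <- a_matrix(ped)
  last <- ped$id[ped$generation == max(ped$generation)]
  # mean additive relatedness among last-generation individuals
  idx <- t(combn(last, 2))
  mean_A <- mean(A[idx])
  mean_oracle <- mean(apply(idx, 1, function(p) {
    2 * oracle_kinship(ped, p[1], p[2])
  }))
  expect_equal(mean_A, mean_oracle, tolerance = 1e-12)
})

test_that("founder allele frequencies hit the configured MAF", {
  cfg <- sim_config(n_founders = 1000, n_generations = 1,
                    offspring_per_pair = 1, n_snps = 12,
                    maf_range = c(0.3, 0.3), ld_r = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  founders <- ped$id[ped$generation == 0L]
  f <- colMeans(gen$genotypes[founders, ]) / 2
  maf <- pmin(f, 1 - f)
  # binomial sd of an allele frequency at 2000 draws is ~0.0102
  expect_true(all(abs(maf - 0.3) < 0.03))
})

test_that("gene dropping is Mendelian and LD behaves", {
  cfg <- sim_config(n_founders = 1000, n_generations = 1,
                    offspring_per_pair = 1, n_snps = 60,
                    n_chromosomes = 1, ld_r = 0, seed = 8)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  founders <- ped$id[ped$generation == 0L]
  G <- gen$genotypes[founders, ]
  r_adj <- sapply(seq_len(ncol(G) - 1L), function(j) {
    cor(G[, j], G[, j + 1L])
  })
  expect_true(all(abs(r_adj) < 0.1))      # independence limit

  cfg2 <- cfg
  cfg2$ld_r <- 0.6
  gen2 <- simulate_genotypes(ped, cfg2)
  G2 <- gen2$genotypes[founders, ]
  r_adj2 <- sapply(seq_len(ncol(G2) - 1L), function(j) {
    cor(G2[, j], G2[, j + 1L])
  })
  expect_gt(mean(r_adj2), mean(r_adj) + 0.2)  # LD parameter acts

  # a parent homozygous for the alternate allele transmits at least 1 copy
  off <- ped[!is.na(ped$sire), ]
  s <- off$sire[1]
  hom <- which(gen$genotypes[s, ] == 2L)
  skip_if(length(hom) == 0)
  kids <- off$id[off$sire == s]
  expect_true(all(gen$genotypes[kids, hom] >= 1L))
})

test_that("temperature simulation covers the window and reproduces", {
  cfg <- sim_config(n_years = 17, seed = 2)
  tm <- simulate_temperatures(cfg)
  years <- sort(unique(as.integer(format(tm$date, "%Y"))))
  expect_length(years, 17L)
  wm <- sapply(years, function(y) window_mean(tm, y))
  names(wm) <- years
  cls <- classify_years(wm)
  expect_equal(as.integer(table(cls$years$class)[c("cold", "intermediate",
                                                   "warm")]),
               c(6L, 6L, 5L))
  expect_identical(tm, simulate_temperatures(cfg))
  cfg$n_years <- 2L
  expect_error(simulate_temperatures(cfg), "terciles")
})

test_that("phenotype generator reproduces its stated variance structure", {
  cfg <- sim_config(n_founders = 500, n_generations = 3,
                    offspring_per_pair = 3, n_snps = 2,
                    n_phenotyped = 1500, mean_records = 1.3,
                    V_A = 10.8, V_PE = 3.0, V_res = 14.5, seed = 12)
  d <- simulate_dataset(cfg)
  tr <- d$truth
  ids <- unique(d$phenotypes$id)
  expect_true(all(abs(var(tr$a[ids]) / 10.8 - 1) < 0.15))
  expect_true(all(abs(var(tr$pe[ids]) / 3.0 - 1) < 0.15))
  # reconstruct residuals from the truth record by record
  ph <- d$phenotypes
  e <- ph$laying_date - cfg$mu - tr$year_eff[as.character(ph$year)] -
    tr$area_eff[ph$area] -
    ifelse(ph$age_class == "first", cfg$age_effect, 0) -
    tr$pe[ph$id] - tr$a[ph$id]
  expect_lt(abs(var(e) / 14.5 - 1), 0.15)
})

test_that("generated breeding values have covariance V_A * A", {
  ped <- ped_sibs()
  A <- a_matrix(ped)
  R <- 2000L
  set.seed(31)
  draws <- replicate(R, gxewas:::.breeding_values(ped, 1))
  emp <- tcrossprod(draws - rowMeans(draws)) / (R - 1)
  expect_lt(max(abs(emp - A)), 0.12)
  expect_lt(mean(abs(emp - A)), 0.05)
})

test_that("degenerate phenotype config collapses to the mean", {
  cfg <- sim_config(n_founders = 20, n_generations = 1,
                    offspring_per_pair = 2, n_snps = 2,
                    V_A = 0, V_PE = 0, V_res = 0, age_effect = 0,
                    beta_temp = 0, sd_year = 0, sd_area = 0, seed = 4)
  d <- simulate_dataset(cfg)
  expect_true(all(abs(d$phenotypes$laying_date - cfg$mu) < 1e-12))
})

test_that("causal SNPs must exist in the genotype matrix", {
  cfg <- sim_config(n_founders = 10, n_generations = 1,
                    offspring_per_pair = 2, n_snps = 5,
                    causal = list(nope = causal_effect()), seed = 1)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  tmp <- simulate_temperatures(cfg)
  expect_error(simulate_phenotypes(ped, gen, tmp, cfg), "causal SNP")
})
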