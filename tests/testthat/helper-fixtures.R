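# Fixtures built in code; no binary data anywhere in the repo.

# id sire dam sex generation, parents before offspring
ped_df <- function(...) {
  m <- matrix(c(...), ncol = 5, byrow = TRUE)
  d <- data.frame(id = m[, 1], sire = m[, 2], dam = m[, 3], sex = m[, 4],
                  generation = as.integer(m[, 5]),
                  stringsAsFactors = FALSE)
  d$sire[d$sire == "-"] <- NA
  d$dam[d$dam == "-"] <- NA
  d
}

# founder pair, two full sibs, and an offspring of the full sibs (inbred)
ped_sibs <- function() {
  ped_df(
    "s1", "-", "-", "M", 0,
    "d1", "-", "-", "F", 0,
    "o1", "s1", "d1", "M", 1,
    "o2", "s1", "d1", "F", 1,
    "x1", "o1", "o2", "F", 2
  )
}

# random multi-generation pedigree for oracle comparisons
random_ped <- function(n_founders, n_gen, off, seed) {
  simulate_pedigree(sim_config(n_founders = n_founders,
                               n_generations = n_gen,
                               offspring_per_pair = off, seed = seed))
}

# small complete analysis world (records carry class + centered response)
small_world <- function(seed = 1, n_founders = 80, n_snps = 40,
                        n_phen = NULL, mean_records = 2, V_res = c(14, 14, 14),
                        maf_range = c(0.25, 0.5), causal = list(), ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 2,
                    offspring_per_pair = 3, n_snps = n_snps,
                    n_phenotyped = n_phen, mean_records = mean_records,
                    V_res = V_res, maf_range = maf_range, causal = causal,
                    seed = seed, ...)
  d <- simulate_dataset(cfg)
  d$centered <- center_phenotypes(d$phenotypes, d$classification)
  d$ped_prec <- ped_precision(d$pedigree)
  d
}

rmvn_chol <- function(n, mu, S) {
  L <- chol(S)
  matrix(stats::rnorm(n * length(mu)), n) %*% L +
    matrix(mu, n, length(mu), byrow = TRUE)
}

# independent recursive kinship (path-counting style), deliberately written
# differently from the package's tabular/recursive implementations
oracle_kinship <- function(ped, i, j) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  s <- stats::setNames(ped$sire, ped$id)
  d <- stats::setNames(ped$dam, ped$id)
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (a == b) {
      sa <- s[[a]]; da <- d[[a]]
      return(0.5 * (1 + f(sa, da)))
    }
    if (pos[[a]] < pos[[b]]) { t <- a; a <- b; b <- t }
    0.5 * (f(s[[a]], b) + f(d[[a]], b))
  }
  f(i, j)
}
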