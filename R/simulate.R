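#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents and alternating sexes.  In
#' each subsequent generation, females and males of the previous generation
#' are paired at random, monogamously; every pair produces
#' `offspring_per_pair` offspring of random sex.  The result is a pedigree
#' data frame with parents preceding offspring, suitable for
#' [a_matrix()] / [a_inverse()].
#'
#' @param config A [sim_config()] object.
#' @return A data frame with columns `id`, `sire`, `dam` (`NA` = unknown),
#'   `sex` (`"F"`/`"M"`) and `generation` (integer, founders 0).
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  id <- sprintf("F%04d", seq_len(nf))
  ped <- data.frame(
    id = id, sire = NA_character_, dam = NA_character_,
    sex = rep_len(c("F", "M"), nf), generation = 0L,
    stringsAsFactors = FALSE
  )
  prev <- ped
  for (g in seq_len(config$n_generations)) {
    fem <- prev$id[prev$sex == "F"]
    mal <- prev$id[prev$sex == "M"]
    npair <- min(length(fem), length(mal))
    if (npair < 1L) break
    dams <- sample(fem, npair)
    sires <- sample(mal, npair)
    noff <- npair * config$offspring_per_pair
    off <- data.frame(
      id = sprintf("G%d_%04d", g, seq_len(noff)),
      sire = rep(sires, each = config$offspring_per_pair),
      dam = rep(dams, each = config$offspring_per_pair),
      sex = sample(c("F", "M"), noff, replace = TRUE),
      generation = g,
      stringsAsFactors = FALSE
    )
    ped <- rbind(ped, off)
    prev <- off
  }
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree data frame
#'
#' Checks id uniqueness, that every named parent exists and precedes its
#' offspring (no cycles), and that sires are male and dams female when sex
#' is recorded.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`, optionally `sex`).
#' @return The pedigree, invisibly; errors describe the violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("structural error: duplicated pedigree ids")
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    if (!all(par[known] %in% ped$id)) {
      stop("structural error: ", col, " ids not in pedigree: ",
           paste(setdiff(par[known], ped$id), collapse = ", "))
    }
    if (any(pos[par[known]] >= pos[known])) {
      stop("structural error: parents must precede offspring (cycle?)")
    }
  }
  if ("sex" %in% names(ped)) {
    sx <- ped$sex
    names(sx) <- ped$id
    s <- ped$sire[!is.na(ped$sire)]
    d <- ped$dam[!is.na(ped$dam)]
    if (any(sx[s] != "M")) stop("structural error: sire with sex != M")
    if (any(sx[d] != "F")) stop("structural error: dam with sex != F")
  }
  invisible(ped)
}

## Founder haplotype block: first-order Markov chain along each chromosome.
## Adjacent SNPs k-1, k on one haplotype are Bernoulli with frequencies
## f[k-1], f[k] and target correlation r; transition probabilities are the
## unique pair satisfying the marginal and the correlation, clamped to [0,1]
## when f's are too unequal for the requested r.
.founder_haplotypes <- function(n_hap, freq, chrom, r) {
  m <- length(freq)
  H <- matrix(0L, n_hap, m)
  for (k in seq_len(m)) {
    f <- freq[k]
    if (k == 1L || chrom[k] != chrom[k - 1L] || r == 0) {
      H[, k] <- as.integer(stats::runif(n_hap) < f)
    } else {
      fp <- freq[k - 1L]
      cv <- r * sqrt(fp * (1 - fp) * f * (1 - f))
      p1 <- min(1, max(0, f + cv * (1 - fp) / (fp * (1 - fp))))
      p0 <- min(1, max(0, f - cv / (1 - fp)))
      prev <- H[, k - 1L]
      H[, k] <- as.integer(stats::runif(n_hap) < ifelse(prev == 1L, p1, p0))
    }
  }
  H
}

## One meiosis: recombine the parent's two haplotypes with a single uniform
## crossover per chromosome and a random starting phase.
.meiosis <- function(h1, h2, chrom_index_list) {
  gam <- integer(length(h1))
  for (idx in chrom_index_list) {
    m <- length(idx)
    cut <- sample.int(m + 1L, 1L) - 1L        # 0..m SNPs from the first arm
    first <- sample(c(TRUE, FALSE), 1L)       # which haplotype starts
    take1 <- c(rep(first, cut), rep(!first, m - cut))
    gam[idx] <- ifelse(take1, h1[idx], h2[idx])
  }
  gam
}

#' Simulate genotypes down a pedigree
#'
#' Founder haplotypes carry allele frequencies drawn from the configured MAF
#' range with first-order Markov linkage disequilibrium between adjacent
#' SNPs; non-founders receive haplotypes by Mendelian gene dropping with one
#' uniform crossover per chromosome per meiosis.  Genotypes count alternate
#' alleles (0/1/2); optionally calls are masked missing completely at
#' random.
#'
#' @param pedigree Pedigree data frame from [simulate_pedigree()].
#' @param config A [sim_config()] object.
#' @return A list with `genotypes` (individuals x SNPs integer matrix,
#'   dimnames set, `NA` = missing) and `info` (data frame `snp`, `chr`,
#'   `pos`, `ref`, `alt`).
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_pedigree(pedigree)
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "genotypes"))
  m <- config$n_snps
  nchr <- min(config$n_chromosomes, m)
  chrom <- sort(rep_len(seq_len(nchr), m))
  pos <- integer(m)
  for (c in seq_len(nchr)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(2e8L, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  info <- data.frame(
    snp = sprintf("snp%05d", seq_len(m)),
    chr = paste0("chr", chrom), pos = pos, ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )
  freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  chrom_idx <- split(seq_len(m), chrom)

  n <- nrow(pedigree)
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  rownames(hap1) <- rownames(hap2) <- pedigree$id
  founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  nf <- sum(founder)
  H <- .founder_haplotypes(2L * nf, freq, chrom, config$ld_r)
  hap1[founder, ] <- H[seq_len(nf), , drop = FALSE]
  hap2[founder, ] <- H[nf + seq_len(nf), , drop = FALSE]
  for (i in which(!founder)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    hap1[i, ] <- .meiosis(hap1[s, ], hap2[s, ], chrom_idx)
    hap2[i, ] <- .meiosis(hap1[d, ], hap2[d, ], chrom_idx)
  }
  G <- hap1 + hap2
  if (config$missing_rate > 0) {
    G[stats::runif(length(G)) < config$missing_rate] <- NA_integer_
  }
  colnames(G) <- info$snp
  list(genotypes = G, info = info)
}

#' Simulate daily spring temperatures
#'
#' Each simulated year gets a daily mean-temperature series covering March 1
#' to April 30 (so the March 11 - April 20 classification window is always
#' complete).  Year window means are drawn uniformly across the configured
#' range; daily values scatter around the year mean with the configured
#' day-to-day standard deviation.
#'
#' @param config A [sim_config()] object; `n_years` must be at least 3.
#' @return A data frame with columns `date` (`Date`) and `temp_c`.
#' @export
simulate_temperatures <- function(config) {
  validate_sim_config(config)
  if (config$n_years < 3L) {
    stop("configuration error: n_years must be >= 3 (terciles undefined)")
  }
  set.seed(substream_seed(config$seed, "temperatures"))
  years <- 2000L + seq_len(config$n_years) - 1L
  yr_mean <- stats::runif(config$n_years, config$temp_range[1],
                          config$temp_range[2])
  out <- lapply(seq_along(years), function(i) {
    days <- seq(as.Date(sprintf("%d-03-01", years[i])),
                as.Date(sprintf("%d-04-30", years[i])), by = "day")
    data.frame(date = days,
               temp_c = yr_mean[i] + stats::rnorm(length(days), 0,
                                                  config$temp_day_sd))
  })
  do.call(rbind, out)
}

## Generative breeding values: founders ~ N(0, V_A); offspring = midparent +
## Mendelian sampling N(0, V_A/2 * (1 - mean parental inbreeding)).
## Inbreeding coefficients come from the pedigree kinship recursion.
.breeding_values <- function(pedigree, V_A) {
  n <- nrow(pedigree)
  Fi <- inbreeding(pedigree)
  a <- numeric(n)
  names(a) <- pedigree$id
  if (V_A == 0) return(a)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) {
      a[i] <- stats::rnorm(1, 0, sqrt(V_A))
    } else if (is.na(s) || is.na(d)) {
      p <- if (is.na(s)) d else s
      Fp <- Fi[p]
      a[i] <- 0.5 * a[p] + stats::rnorm(1, 0, sqrt(V_A * (0.75 - 0.25 * Fp)))
    } else {
      msv <- V_A * 0.5 * (1 - 0.5 * (Fi[s] + Fi[d]))
      a[i] <- 0.5 * (a[s] + a[d]) + stats::rnorm(1, 0, sqrt(msv))
    }
  }
  a
}

#' Simulate repeated laying-date records
#'
#' Generates phenotypes under the repeated-measures animal model: record
#' value = mu + year effect + area effect + age effect + per-class causal
#' SNP effect + permanent environment + breeding value + residual, with the
#' residual standard deviation determined by the record year's temperature
#' class.  Breeding values are generated generatively down the pedigree
#' (founders from N(0, V_A), offspring as midparent plus Mendelian
#' sampling).  Year effects track window temperature with slope `beta_temp`
#' plus independent noise, so cold springs delay laying as in wild tit
#' populations.
#'
#' @param pedigree Pedigree from [simulate_pedigree()].
#' @param genotypes List from [simulate_genotypes()] (or `NULL` when no
#'   causal SNPs are configured).
#' @param temps Temperature series from [simulate_temperatures()].
#' @param config A [sim_config()] object.
#' @return A list with `phenotypes` (data frame `id`, `year`, `area`,
#'   `laying_date`, `age_class`), `classification` (the year tercile table,
#'   see [classify_years()]), and `truth` (breeding values `a`, permanent
#'   environment `pe`, year/area effects) for parameter-recovery checks.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, temps, config) {
  validate_pedigree(pedigree)
  validate_sim_config(config)
  for (cs in names(config$causal)) {
    if (is.null(genotypes) || !cs %in% colnames(genotypes$genotypes)) {
      stop("configuration error: causal SNP '", cs,
           "' absent from genotype matrix")
    }
  }
  set.seed(substream_seed(config$seed, "phenotypes"))

  years <- sort(unique(as.integer(format(temps$date, "%Y"))))
  wm <- vapply(years, function(y) window_mean(temps, y), 0)
  names(wm) <- years
  cls <- classify_years(stats::setNames(wm, years))
  class_of_year <- stats::setNames(cls$years$class, cls$years$year)

  females <- pedigree$id[pedigree$sex == "F"]
  if (!is.null(config$n_phenotyped) &&
      config$n_phenotyped < length(females)) {
    # prefer later generations: those are the birds with records in a
    # long-running nest-box study
    ord <- order(-pedigree$generation[match(females, pedigree$id)])
    females <- sort(females[ord][seq_len(config$n_phenotyped)])
  }

  a <- .breeding_values(pedigree, config$V_A)
  pe <- stats::setNames(stats::rnorm(length(females), 0, sqrt(config$V_PE)),
                        females)
  year_eff <- config$beta_temp * (wm - mean(wm)) +
    stats::rnorm(length(years), 0, config$sd_year)
  names(year_eff) <- years
  area_ids <- sprintf("area%d", seq_len(config$n_areas))
  area_eff <- stats::setNames(stats::rnorm(config$n_areas, 0, config$sd_area),
                              area_ids)
  area_of <- stats::setNames(sample(area_ids, length(females), replace = TRUE),
                             females)

  nrec <- pmin(config$n_years,
               1L + stats::rpois(length(females),
                                 max(0, config$mean_records - 1)))
  rec_id <- rep(females, nrec)
  ## warm springs carry more breeding records (weight exp(slope * temp))
  yr_w <- exp(config$year_weight_temp * (wm - mean(wm)))
  rec_year <- unlist(lapply(seq_along(females), function(i) {
    sort(sample(years, nrec[i], prob = yr_w))
  }), use.names = FALSE)
  rec_class <- as.character(class_of_year[as.character(rec_year)])
  first_year <- stats::setNames(
    vapply(split(rec_year, rec_id), min, 0L)[unique(rec_id)], unique(rec_id))
  age_class <- ifelse(rec_year == first_year[rec_id], "first", "older")

  snp_eff <- numeric(length(rec_id))
  cls_levels <- c("cold", "intermediate", "warm")
  for (cs in names(config$causal)) {
    eff <- config$causal[[cs]]
    g <- genotypes$genotypes[rec_id, cs]
    ok <- !is.na(g)
    snp_eff[ok] <- snp_eff[ok] +
      eff[cbind(match(rec_class[ok], cls_levels), g[ok] + 1L)]
  }

  resid_sd <- sqrt(config$V_res)[match(rec_class, cls_levels)]
  y <- config$mu + year_eff[as.character(rec_year)] +
    area_eff[area_of[rec_id]] +
    ifelse(age_class == "first", config$age_effect, 0) +
    snp_eff + pe[rec_id] + a[rec_id] +
    stats::rnorm(length(rec_id), 0, resid_sd)

  phen <- data.frame(
    id = rec_id, year = rec_year, area = unname(area_of[rec_id]),
    laying_date = unname(y), age_class = age_class,
    stringsAsFactors = FALSE
  )
  list(phenotypes = phen, classification = cls,
       truth = list(a = a, pe = pe, year_eff = year_eff,
                    area_eff = area_eff, window_means = wm))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running pedigree, genotype, temperature and phenotype
#' simulation from one config.
#'
#' @param config A [sim_config()] object.
#' @return A list with `pedigree`, `genotypes`, `info`, `temperatures`,
#'   `phenotypes`, `classification`, `truth`.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  tmp <- simulate_temperatures(config)
  phe <- simulate_phenotypes(ped, gen, tmp, config)
  list(pedigree = ped, genotypes = gen$genotypes, info = gen$info,
       temperatures = tmp, phenotypes = phe$phenotypes,
       classification = phe$classification, truth = phe$truth)
}
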