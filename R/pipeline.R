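#' Pipeline configuration
#'
#' One declarative object tying the stages together.  Any field of
#' [sim_config()] can be supplied under `sim`, any [qc_thresholds()] field
#' under `qc`.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim List of [sim_config()] overrides (the demo default simulates
#'   500 phenotyped females and 2000 SNPs).
#' @param qc List of [qc_thresholds()] overrides.
#' @param residuals `"heterogeneous"` or `"homogeneous"`.
#' @param vc_mode `"null-fixed"` or `"per-snp"`.
#' @param alpha Significance level for thresholds and model comparison.
#' @param keff_window Sliding-window size for the LD-adjusted correction.
#' @param run_mds Run IBS/MDS outlier screening (quadratic in individuals;
#'   on by default).
#' @param seed Root seed for the whole run.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "gxewas_run", sim = list(),
                            qc = list(), residuals = "heterogeneous",
                            vc_mode = "null-fixed", alpha = 0.05,
                            keff_window = 20L, run_mds = TRUE, seed = 1L) {
  sim_defaults <- list(n_founders = 150, n_generations = 3,
                       offspring_per_pair = 3, n_snps = 2000,
                       n_phenotyped = 500, seed = seed)
  sim_defaults[names(sim)] <- sim
  scfg <- do.call(sim_config, sim_defaults)
  qcfg <- do.call(qc_thresholds, qc)
  residuals <- match.arg(residuals, c("heterogeneous", "homogeneous"))
  vc_mode <- match.arg(vc_mode, c("null-fixed", "per-snp"))
  stopifnot(alpha > 0, alpha < 1, keff_window >= 2)
  structure(list(out_dir = out_dir, sim = scfg, qc = qcfg,
                 residuals = residuals, vc_mode = vc_mode, alpha = alpha,
                 keff_window = as.integer(keff_window),
                 run_mds = isTRUE(run_mds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate -> qc -> classify/center -> relatedness -> gwas -> h2 ->
#' compare, writing every artifact (plus a manifest recording the config
#' and the failing stage on error) under `config$out_dir`.  Identical
#' configs give byte-identical result tables.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package = "gxewas",
                   version = as.character(utils::packageVersion("gxewas")),
                   seed = config$seed,
                   residuals = config$residuals, vc_mode = config$vc_mode,
                   alpha = config$alpha, stage = "start",
                   sim = unclass(config$sim)[
                     setdiff(names(config$sim), "causal")],
                   qc = unclass(config$qc))
  save_manifest <- function() {
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  stage <- function(name, expr) {
    manifest$stage <<- name
    save_manifest()
    expr
  }
  res <- list()

  res$data <- stage("simulate", {
    d <- simulate_dataset(config$sim)
    write_plink_text(d$genotypes, d$info, art("genotypes"))
    write_csv_table(d$pedigree, art("pedigree.csv"))
    write_csv_table(d$phenotypes, art("phenotypes.csv"))
    write_csv_table(transform(d$temperatures, date = format(date)),
                    art("temperatures.csv"))
    d
  })
  d <- res$data

  res$qc <- stage("qc", {
    sf <- snp_filters(d$genotypes, d$info, config$qc)
    indf <- individual_filters(sf$genotypes, config$qc)
    G <- sf$genotypes[indf$ids, , drop = FALSE]
    rep_tab <- rbind(qc_report_table(sf$report),
                     qc_report_table(indf$report))
    list(genotypes = G, info = sf$info, report = rep_tab)
  })

  res$classes <- stage("classify", {
    years <- sort(unique(d$phenotypes$year))
    wm <- vapply(years, function(y) window_mean(d$temperatures, y), 0)
    names(wm) <- years
    cls <- classify_years(wm)
    write_csv_table(cls$years, art("classification.csv"))
    phen <- center_phenotypes(d$phenotypes, cls)
    phen <- phen[phen$id %in% rownames(res$qc$genotypes), , drop = FALSE]
    write_csv_table(phen, art("phenotypes_centered.csv"))
    list(classification = cls, phenotypes = phen)
  })
  phen <- res$classes$phenotypes

  res$qc$class_snps <- stage("class-support", {
    keep <- genotype_class_support(res$qc$genotypes, phen, config$qc)
    res$qc$report <- rbind(
      res$qc$report,
      data.frame(filter = "genotype_class_support",
                 n_removed = ncol(res$qc$genotypes) - length(keep),
                 threshold = paste0(">=", config$qc$min_cell, " per cell"),
                 removed = "", stringsAsFactors = FALSE))
    utils::write.table(res$qc$report, art("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    keep
  })
  Gq <- res$qc$genotypes[, res$qc$class_snps, drop = FALSE]
  infoq <- res$qc$info[res$qc$info$snp %in% res$qc$class_snps, ,
                       drop = FALSE]

  res$relatedness <- stage("relatedness", {
    pedp <- ped_precision(d$pedigree)
    out <- list(ped = pedp)
    if (config$run_mds && nrow(Gq) >= 3L) {
      ib <- ibs_matrix(Gq)
      md <- mds_outliers(ib$distance, config$qc$mds_dims,
                         config$qc$mds_mult)
      utils::write.table(
        data.frame(id = rownames(md$coords), md$coords,
                   outlier = rownames(md$coords) %in% md$outliers),
        art("mds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      out$mds <- md
      keep_ids <- setdiff(rownames(Gq), md$outliers)
      Gq <- Gq[keep_ids, , drop = FALSE]
      phen <- phen[phen$id %in% keep_ids, , drop = FALSE]
    }
    out
  })

  res$gwas <- stage("gwas", {
    if (ncol(Gq) == 0L) {
      warning("no SNPs left after QC; skipping scan")
      NULL
    } else {
      scan <- run_scan(phen, Gq, infoq, res$relatedness$ped,
                       residuals = config$residuals,
                       vc_mode = config$vc_mode)
      write_gwas_tsv(scan, art("gwas_results.tsv"))
      ke <- keff(Gq, infoq, config$keff_window)
      mt <- data.frame(
        M = ke$M, alpha = config$alpha,
        bonferroni = bonferroni(ke$M, config$alpha),
        keff = ke$keff, keff_threshold = config$alpha / ke$keff,
        reduction = ke$reduction)
      utils::write.table(mt, art("multiple_testing.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      lam <- c(main = genomic_inflation(scan$p_main, 2),
               interaction = genomic_inflation(scan$p_interaction, 4))
      for (w in c("p_main", "p_interaction")) {
        pt <- plot_tables(scan, w)
        utils::write.table(pt$manhattan,
                           art(paste0("manhattan_", w, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(pt$qq, art(paste0("qq_", w, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(scan = scan, multiple_testing = mt, lambda = lam)
    }
  })

  res$h2 <- stage("h2", {
    tab <- h2_by_class(d$phenotypes, res$classes$classification,
                       res$relatedness$ped)
    utils::write.table(tab, art("h2_by_class.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  res$compare <- stage("compare", {
    if (is.null(res$gwas)) NULL else {
      cmp <- compare_models(res$gwas$scan, config$alpha)
      utils::write.table(
        data.frame(n_subset = cmp$n_subset, fraction = cmp$fraction),
        art("model_comparison.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      cmp
    }
  })

  manifest$stage <- "done"
  save_manifest()
  invisible(res)
}

#' Per-class heritability table
#'
#' Fits one repeated-measures animal model per temperature class on raw
#' laying dates with age, year (factor), area and year-by-area fixed
#' effects, homogeneous residuals within the class, and reports the
#' variance components, heritability with delta-method SE, and the 1-df
#' likelihood-ratio test of the additive genetic variance.
#'
#' @param phenotypes Raw phenotype records (`id`, `year`, `area`,
#'   `laying_date`, `age_class`).
#' @param classification A [classify_years()] result.
#' @param ped A [ped_precision()] object.
#' @return Data frame, one row per class.
#' @export
h2_by_class <- function(phenotypes, classification, ped) {
  cmap <- stats::setNames(classification$years$class,
                          classification$years$year)
  phenotypes$class <- cmap[as.character(phenotypes$year)]
  rows <- lapply(c("cold", "intermediate", "warm"), function(cl) {
    sub <- phenotypes[phenotypes$class == cl, , drop = FALSE]
    if (nrow(sub) < 30L) {
      return(data.frame(class = cl, n_obs = nrow(sub),
                        n_ind = length(unique(sub$id)), V_A = NA, se_V_A = NA,
                        V_PE = NA, V_res = NA, h2 = NA, se_h2 = NA,
                        lrt_chi2 = NA, lrt_p = NA))
    }
    nyear <- length(unique(sub$year))
    narea <- length(unique(sub$area))
    fx <- if (nyear > 1L && narea > 1L) {
      ~ age_class + factor(year) * factor(area)
    } else if (nyear > 1L) {
      ~ age_class + factor(year)
    } else if (narea > 1L) {
      ~ age_class + factor(area)
    } else {
      ~ age_class
    }
    full <- reml_fit(sub, ped, response = "laying_date",
                     residuals = "homogeneous", fixed = fx)
    red <- reml_fit(sub, ped, response = "laying_date",
                    residuals = "homogeneous", fixed = fx, animal = FALSE,
                    se = FALSE)
    lrt <- lrt_component(full, red)
    h <- heritability(full)
    seV <- if (!is.null(full$vc_cov)) {
      sqrt(pmax(diag(full$vc_cov), 0))
    } else {
      rep(NA_real_, 3)
    }
    data.frame(class = cl, n_obs = full$n,
               n_ind = length(unique(sub$id)),
               V_A = unname(full$vc["V_A"]), se_V_A = seV[1],
               V_PE = unname(full$vc["V_PE"]),
               V_res = unname(full$vc[grep("^V_res", names(full$vc))]),
               h2 = h$h2, se_h2 = h$se,
               lrt_chi2 = lrt$chi2, lrt_p = lrt$p)
  })
  do.call(rbind, rows)
}
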