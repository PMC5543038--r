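test_that("snp filter cascade removes the right SNPs in order", {
  G <- cbind(
    mono = rep(0L, 100),
    lowcr = c(rep(NA_integer_, 6), rep(1L, 47), rep(0L, 47)),
    okcr = c(rep(NA_integer_, 4), rep(1L, 48), rep(0L, 48)),
    maf175 = c(rep(0L, 70), rep(1L, 25), rep(2L, 5)),
    lowmaf = c(rep(0L, 95), rep(1L, 5)),
    dup1 = c(rep(0L, 50), rep(1L, 50)),
    dup2 = c(rep(0L, 50), rep(1L, 50))
  )
  rownames(G) <- sprintf("i%03d", 1:100)
  info <- data.frame(snp = colnames(G), chr = "chr1",
                     pos = c(10L, 20L, 30L, 40L, 50L, 60L, 60L),
                     ref = "A", alt = "G")
  out <- snp_filters(G, info, qc_thresholds())
  expect_setequal(out$info$snp, c("okcr", "maf175"))
  tab <- qc_report_table(out$report)
  expect_equal(tab$n_removed[tab$filter == "position"], 2L)       # dup pair
  expect_equal(tab$n_removed[tab$filter == "monomorphic"], 1L)
  expect_equal(tab$n_removed[tab$filter == "snp_call_rate"], 1L)  # 0.95 < cr
  expect_equal(tab$n_removed[tab$filter == "maf"], 1L)
  # MAF arithmetic: (25 + 2*5) / 200 = 0.175, retained at >= 0.10
  expect_equal(unname(snp_maf(G[, "maf175", drop = FALSE])), 0.175)
  # idempotence
  out2 <- snp_filters(out$genotypes, out$info, qc_thresholds())
  expect_identical(out2$info, out$info)
  expect_identical(out2$genotypes, out$genotypes)
})

test_that("HWE deviation is never a removal reason", {
  # strongly HWE-violating SNP (all heterozygous) but clean otherwise
  G <- cbind(hwe = rep(1L, 60), anchor = rep(c(0L, 1L, 2L), 20))
  rownames(G) <- sprintf("i%02d", 1:60)
  info <- data.frame(snp = colnames(G), chr = "chr1", pos = c(1L, 2L),
                     ref = "A", alt = "G")
  out <- snp_filters(G, info, qc_thresholds())
  expect_true("hwe" %in% out$info$snp)
})

test_that("individual filters: call rate, heterozygosity FDR, IBS", {
  set.seed(22)
  n <- 200
  m <- 400
  f <- runif(m, 0.2, 0.5)
  G <- sapply(f, function(p) rbinom(n, 2, p))
  rownames(G) <- sprintf("i%03d", 1:n)
  # 5 spiked extreme-heterozygosity individuals
  spiked <- sprintf("i%03d", 1:5)
  G[spiked, ] <- 1L
  # one low-call-rate individual
  G["i010", seq(1, m, by = 2)] <- NA_integer_
  # an exact duplicate pair (i020 copied into i021, i021 given lower cr)
  G["i021", ] <- G["i020", ]
  G["i021", 1:4] <- NA_integer_
  out <- individual_filters(G, qc_thresholds())
  tab <- qc_report_table(out$report)
  expect_equal(tab$removed[tab$filter == "ind_call_rate"], "i010")
  het_removed <- strsplit(tab$removed[tab$filter == "heterozygosity"],
                          ";")[[1]]
  expect_setequal(het_removed, spiked)
  expect_equal(tab$removed[tab$filter == "ibs_duplicates"], "i021")
  expect_setequal(out$ids, setdiff(rownames(G),
                                   c("i010", spiked, "i021")))

  # all-identical heterozygosity: nothing flagged by the FDR step
  base_row <- c(rep(1L, 10), rep(0L, 5), rep(2L, 5))
  G2 <- t(sapply(1:10, function(s) base_row[(seq(0, 19) + s) %% 20 + 1]))
  rownames(G2) <- letters[1:10]
  out2 <- individual_filters(G2, qc_thresholds())
  tab2 <- qc_report_table(out2$report)
  expect_equal(tab2$n_removed[tab2$filter == "heterozygosity"], 0L)
})

test_that("pairwise IBS 1 removes one member of a duplicate pair", {
  G <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L),
             c = c(2L, 1L, 0L, 0L))
  out <- individual_filters(G, qc_thresholds())
  # identical call rates: lexicographically larger id dropped
  expect_setequal(out$ids, c("a", "c"))
})

test_that("genotype-class support requires all cells filled", {
  set.seed(9)
  n <- 260
  ids <- sprintf("i%03d", 1:n)
  records <- data.frame(
    id = rep(ids, 2),
    class = factor(rep(c("cold", "intermediate", "warm"), length.out = 2 * n),
                   levels = c("cold", "intermediate", "warm")))
  G <- cbind(
    common = rbinom(n, 2, 0.5),
    nohom = pmin(rbinom(n, 2, 0.5), 1L),    # no homozygous-alt anywhere
    rare = rbinom(n, 2, 0.10)               # hom-alt cell far below 20
  )
  rownames(G) <- ids
  keep <- genotype_class_support(G, records, qc_thresholds(min_cell = 20))
  expect_true("common" %in% keep)
  expect_false("nohom" %in% keep)
  # Hardy-Weinberg expectation: 0.01 * ~87 individuals per class << 20
  expect_false("rare" %in% keep)

  # boundary: cells of exactly the threshold are retained
  g <- rep(0:2, each = 60)
  recs <- data.frame(id = sprintf("x%03d", 1:180),
                     class = rep(c("cold", "intermediate", "warm"), 60))
  Gx <- matrix(g, ncol = 1, dimnames = list(recs$id, "s"))
  expect_equal(genotype_class_support(Gx, recs,
                                      qc_thresholds(min_cell = 20)), "s")
  recs$class[1] <- NA
  expect_error(genotype_class_support(Gx, recs, qc_thresholds()),
               "temperature class")
})
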