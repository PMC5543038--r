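#' Read PLINK text genotypes (.ped / .map)
#'
#' Parses the classic whitespace-delimited PLINK 1.07 text pair: each .ped
#' row is FID IID PAT MAT SEX PHENO followed by two allele calls per SNP;
#' the .map gives chromosome, SNP id, genetic position and base-pair
#' position.  Alleles are recoded to 0/1/2 alternate-allele counts with the
#' minor allele as alternate (ties broken toward the alphabetically later
#' allele); `0 0` is a missing call.
#'
#' @param ped_path,map_path File paths.
#' @return List `genotypes` (individuals x SNPs, dimnames set) and `info`
#'   (`snp`, `chr`, `pos`, `ref`, `alt`).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    stop("format error: .ped line ", bad, " has ", lens[bad],
         " fields, expected ", want, " for ", m, " SNPs")
  }
  ids <- vapply(toks, `[`, "", 2L)
  A1 <- matrix("", n, m)
  A2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    g <- toks[[i]][-(1:6)]
    A1[i, ] <- g[seq(1L, 2L * m, by = 2L)]
    A2[i, ] <- g[seq(2L, 2L * m, by = 2L)]
  }
  G <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp))
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    a <- c(A1[, j], A2[, j])
    obs <- a[a != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop("format error: SNP ", map$snp[j], " has ", length(alleles),
           " alleles (", paste(alleles, collapse = "/"), ")")
    }
    if (length(alleles) == 0L) {
      ref[j] <- "N"; alt[j] <- "N"
      next
    }
    if (length(alleles) == 1L) {
      ref[j] <- alleles; alt[j] <- "N"
      G[, j] <- ifelse(A1[, j] == "0" | A2[, j] == "0", NA_integer_, 0L)
      next
    }
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele is alt; tie -> alphabetically later allele
    alt_j <- if (cnt[2] < cnt[1]) alleles[2] else
      if (cnt[1] < cnt[2]) alleles[1] else alleles[2]
    ref[j] <- setdiff(alleles, alt_j)
    alt[j] <- alt_j
    miss <- A1[, j] == "0" | A2[, j] == "0"
    G[, j] <- (A1[, j] == alt_j) + (A2[, j] == alt_j)
    G[miss, j] <- NA_integer_
  }
  info <- data.frame(snp = map$snp, chr = as.character(map$chr),
                     pos = as.integer(map$pos), ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  list(genotypes = G, info = info)
}

#' Write PLINK text genotypes (.ped / .map)
#'
#' Inverse of [read_plink_text()] up to allele-label convention: genotype 0
#' becomes `ref ref`, 1 `ref alt`, 2 `alt alt`, missing `0 0`.  Family and
#' parent fields are written as unknown, sex as 0, phenotype as -9.
#'
#' @param G Genotype matrix, individuals x SNPs (0/1/2/`NA`).
#' @param info SNP info data frame (`snp`, `chr`, `pos`, `ref`, `alt`),
#'   rows matching the columns of `G`.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The two file paths, invisibly.
#' @export
write_plink_text <- function(G, info, prefix) {
  stopifnot(ncol(G) == nrow(info))
  map <- data.frame(chr = info$chr, snp = info$snp, cm = 0, pos = info$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(G)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(G))) {
    g <- G[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, info$alt, info$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, info$alt, info$ref))
    writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}
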