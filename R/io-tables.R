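#' Read the pedigree CSV
#'
#' Expected columns: `id`, `sire`, `dam`, optionally `sex` and
#' `generation`.  Empty, `"0"`, `"NA"` or missing parent fields mean
#' unknown.
#'
#' @param path CSV path (comma-separated, header row, UTF-8).
#' @return Pedigree data frame (validated).
#' @export
read_pedigree_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(d))) {
    stop("validation error: pedigree CSV needs columns ",
         paste(need, collapse = ", "))
  }
  for (col in c("sire", "dam")) {
    v <- trimws(d[[col]])
    v[v %in% c("", "0", "NA")] <- NA_character_
    d[[col]] <- v
  }
  if ("generation" %in% names(d)) d$generation <- as.integer(d$generation)
  validate_pedigree(d)
  d
}

#' Read the phenotype CSV
#'
#' Expected columns: `id`, `year`, `area`, `laying_date`, `age_class`.
#' `laying_date` is either a numeric day-of-year or an ISO date (converted
#' to day-of-year).  `age_class` must be the two-level coding
#' `first` / `older`.  Duplicate (id, year) rows are rejected with their
#' line numbers.
#'
#' @param path CSV path.
#' @return Phenotype data frame with `laying_date` as numeric day-of-year.
#' @export
read_phenotype_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "year", "area", "laying_date", "age_class")
  if (!all(need %in% names(d))) {
    stop("validation error: phenotype CSV needs columns ",
         paste(need, collapse = ", "))
  }
  d$id <- as.character(d$id)
  d$year <- as.integer(d$year)
  d$area <- as.character(d$area)
  ld <- d$laying_date
  if (is.character(ld)) {
    # each value is either a bare day-of-year or an ISO date
    num <- suppressWarnings(as.numeric(ld))
    need <- is.na(num) & !is.na(ld)
    if (any(need)) {
      dt <- suppressWarnings(as.Date(ld[need], format = "%Y-%m-%d"))
      if (anyNA(dt)) {
        stop("validation error: unparseable laying_date values: ",
             paste(utils::head(ld[need][is.na(dt)]), collapse = ", "))
      }
      num[need] <- as.numeric(strftime(dt, "%j"))
    }
    d$laying_date <- num
  } else {
    d$laying_date <- as.numeric(ld)
  }
  bad_age <- !d$age_class %in% c("first", "older")
  if (any(bad_age)) {
    stop("validation error: unknown age labels (want first/older): ",
         paste(unique(d$age_class[bad_age]), collapse = ", "))
  }
  key <- paste(d$id, d$year)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    lines <- which(key == dup) + 1L   # +1 for header
    stop("validation error: duplicate (id, year) phenotype rows at lines ",
         paste(lines, collapse = ", "))
  }
  d
}

#' Read the daily temperature CSV
#'
#' Expected columns: `date` (ISO), `temp_c`.
#'
#' @param path CSV path.
#' @return Data frame with `date` as `Date` and numeric `temp_c`.
#' @export
read_temperature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "temp_c") %in% names(d))) {
    stop("validation error: temperature CSV needs columns date, temp_c")
  }
  dt <- as.Date(d$date)
  if (anyNA(dt)) {
    stop("validation error: unparseable dates: ",
         paste(utils::head(d$date[is.na(dt)]), collapse = ", "))
  }
  data.frame(date = dt, temp_c = as.numeric(d$temp_c))
}

#' Write the project CSV tables
#'
#' @param x Data frame (pedigree, phenotypes, temperatures, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a GWAS result table as TSV
#'
#' @param res A [run_scan()] result data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble and cross-check a dataset
#'
#' Bundles the parts and enforces the cross-index invariants: every
#' phenotyped id must be genotyped (or explicitly listed in `ungenotyped`)
#' and every genotyped id must appear in the pedigree.
#'
#' @param genotypes,info,pedigree,phenotypes,temperatures The parts.
#' @param ungenotyped Ids allowed to carry phenotypes without genotypes.
#' @return List of class `"gxe_dataset"`.
#' @export
make_dataset <- function(genotypes, info, pedigree, phenotypes,
                         temperatures, ungenotyped = character(0)) {
  miss_g <- setdiff(unique(phenotypes$id),
                    c(rownames(genotypes), ungenotyped))
  if (length(miss_g)) {
    stop("validation error: phenotyped ids without genotypes: ",
         paste(utils::head(miss_g), collapse = ", "))
  }
  miss_p <- setdiff(rownames(genotypes), pedigree$id)
  if (length(miss_p)) {
    stop("validation error: genotyped ids absent from pedigree: ",
         paste(utils::head(miss_p), collapse = ", "))
  }
  structure(list(genotypes = genotypes, info = info, pedigree = pedigree,
                 phenotypes = phenotypes, temperatures = temperatures),
            class = "gxe_dataset")
}
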