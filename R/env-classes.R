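#' Spring-window mean temperature for one year
#'
#' Arithmetic mean of the daily mean temperatures for March 11 to April 20
#' (inclusive, 41 days) of the given year.  The window is defined by
#' calendar dates, not day-of-year, so leap years need no special handling.
#' Missing days are an error, never imputed.
#'
#' @param temps Data frame with columns `date` (`Date` or parseable
#'   character) and `temp_c`.
#' @param year Integer calendar year.
#' @return The window mean in degrees C.
#' @export
window_mean <- function(temps, year) {
  stopifnot(all(c("date", "temp_c") %in% names(temps)))
  dates <- as.Date(temps$date)
  if (anyDuplicated(dates[!is.na(dates)])) {
    stop("data error: duplicated dates in temperature series")
  }
  want <- seq(as.Date(sprintf("%d-03-11", year)),
              as.Date(sprintf("%d-04-20", year)), by = "day")
  idx <- match(want, dates)
  if (anyNA(idx)) {
    stop("data error: missing temperature days: ",
         paste(format(want[is.na(idx)]), collapse = ", "))
  }
  mean(temps$temp_c[idx])
}

#' Classify years into temperature terciles
#'
#' Years are sorted by ascending window mean (ties broken by year) and
#' partitioned into cold, intermediate and warm classes whose sizes are the
#' balanced split of n into three parts with remainders assigned to the
#' colder classes first: 17 years split 6/6/5, 18 split 6/6/6.  This
#' convention reproduces the class-year counts of a 17-year study
#' (6 cold, 6 intermediate, 5 warm).
#'
#' @param window_means Named numeric vector of per-year window means; names
#'   are the years.
#' @return A list of class `"year_classification"` with `years` (data frame
#'   `year`, `window_mean`, `class`) and `boundaries` (33rd and 67th
#'   percentile of the window means, for reporting).
#' @export
classify_years <- function(window_means) {
  n <- length(window_means)
  if (n < 3L) stop("configuration error: need >= 3 years for terciles")
  if (any(!is.finite(window_means))) {
    stop("configuration error: non-finite window means")
  }
  yrs <- as.integer(names(window_means))
  ord <- order(window_means, yrs)
  n1 <- ceiling(n / 3)
  n2 <- ceiling((n - n1) / 2)
  cls <- rep(c("cold", "intermediate", "warm"), c(n1, n2, n - n1 - n2))
  out <- data.frame(year = yrs[ord],
                    window_mean = unname(window_means[ord]),
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  structure(list(years = out,
                 boundaries = stats::quantile(window_means, c(1, 2) / 3,
                                              names = FALSE)),
            class = "year_classification")
}

#' Center laying dates by year and area and attach temperature classes
#'
#' Subtracts from each record the mean laying date of its year-by-area cell,
#' removing among-year and among-area variation before association analysis.
#' Singleton cells are allowed (centered value 0) but reported in the
#' `singletons` attribute.
#'
#' @param records Phenotype data frame with columns `id`, `year`, `area`,
#'   `laying_date` and optionally `age_class`.
#' @param classification A [classify_years()] result covering every record
#'   year.
#' @return The records with added columns `centered` (days) and `class`.
#' @export
center_phenotypes <- function(records, classification) {
  stopifnot(all(c("id", "year", "area", "laying_date") %in% names(records)))
  if (anyNA(records$year) || anyNA(records$area)) {
    stop("validation error: every record needs year and area")
  }
  cell <- interaction(records$year, records$area, drop = TRUE)
  mu <- tapply(records$laying_date, cell, mean)
  out <- records
  out$centered <- records$laying_date - as.numeric(mu[cell])
  cmap <- stats::setNames(classification$years$class,
                          classification$years$year)
  cl <- cmap[as.character(records$year)]
  if (anyNA(cl)) {
    stop("validation error: unclassified record years: ",
         paste(unique(records$year[is.na(cl)]), collapse = ", "))
  }
  out$class <- factor(as.character(cl),
                      levels = c("cold", "intermediate", "warm"))
  singles <- names(table(cell))[table(cell) == 1L]
  attr(out, "singletons") <- singles
  out
}
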