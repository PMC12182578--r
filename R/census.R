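#' Population groups mapped by the pipeline
#'
#' Group codes used throughout: total population and the four age groups
#' 0-14, 15-59, 60-64 and 65+. The 60-64 group is derived from the census
#' columns `a60plus` and `a65plus` (see [derive_a60_64()]).
#' @export
POP_GROUPS <- c("total", "a0_14", "a15_59", "a60_64", "a65plus")

CENSUS_COUNT_COLS <- c("total", "a0_14", "a15_59", "a60plus", "a65plus")

validate_census <- function(census) {
  req <- c("zone_id", CENSUS_COUNT_COLS)
  miss <- setdiff(req, names(census))
  if (length(miss))
    stop("census table missing column(s): ", paste(miss, collapse = ", "))
  for (col in CENSUS_COUNT_COLS)
    if (any(census[[col]] < 0, na.rm = TRUE))
      stop("negative counts in column ", col)
  bad <- which(census$a65plus > census$a60plus)
  if (length(bad))
    stop("a65plus exceeds a60plus for zone(s): ",
         paste(census$zone_id[bad], collapse = ", "),
         " (violates census logic)")
  census
}

#' Read a census table from CSV
#'
#' Expected columns: `zone_id, name, level, parent_id, total, a0_14,
#' a15_59, a60plus, a65plus`. Counts must be nonnegative with
#' `a65plus <= a60plus` in every row.
#'
#' @param path CSV file path.
#' @return data.frame (a census table).
#' @export
read_census <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_census(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a census table to CSV
#' @param census Census table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE)
  invisible(path)
}

#' Attach the 60-64 age group
#'
#' The census publishes 60+ and 65+; the mapped groups use 60-64, so
#' `a60_64 = a60plus - a65plus` per zone.
#'
#' @param census Census table with `a60plus` and `a65plus` columns.
#' @return The table with an `a60_64` column appended (or replaced).
#' @export
derive_a60_64 <- function(census) {
  census <- validate_census(census)
  census$a60_64 <- census$a60plus - census$a65plus
  census
}
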