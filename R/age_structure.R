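#' Sum the four age-group population grids
#'
#' Cell-wise sum; a cell that is nodata in any input is nodata in the
#' output. This summed grid is the denominator for age-structure
#' proportions (the direct-total grid stays a separate, independently
#' estimated product).
#'
#' @param grids Named list of the four age-group population `grid`s.
#' @return A population `grid`.
#' @export
sum_age_groups <- function(grids) {
  stopifnot(length(grids) >= 2)
  tmpl <- grids[[1]]
  for (g in grids[-1]) stopifnot_coregistered(tmpl, g, "age-group grids")
  ok <- Reduce(`&`, lapply(grids, grid_valid))
  s <- Reduce(`+`, lapply(grids, function(g) g$values))
  s[!ok] <- tmpl$nodata
  out <- tmpl
  out$values <- s
  out
}

#' Per-cell age-group proportion
#'
#' Ratio of a group grid to the summed-ages total, defined where the total
#' is valid and positive; nodata where the total is zero (no population,
#' proportion undefined) or where either grid is nodata.
#'
#' @param group_grid Age-group population `grid`.
#' @param total_sum_grid Summed-ages grid from [sum_age_groups()].
#' @return A proportion `grid` with values in `[0, 1]`.
#' @export
proportions <- function(group_grid, total_sum_grid) {
  stopifnot_coregistered(group_grid, total_sum_grid,
                         "group and total grids")
  nodata <- -9999
  ok <- grid_valid(group_grid) & grid_valid(total_sum_grid) &
    total_sum_grid$values > 0
  p <- matrix(nodata, nrow(group_grid$values), ncol(group_grid$values))
  p[ok] <- group_grid$values[ok] / total_sum_grid$values[ok]
  new_grid(p, x_origin = group_grid$x_origin,
           y_origin = group_grid$y_origin,
           cell_size = group_grid$cell_size, crs_id = group_grid$crs_id,
           nodata = nodata)
}

#' Consistency between direct-total and summed-ages grids, by region
#'
#' For each unit at `level` (city by default): Pearson correlation and RMSE
#' (persons/ha) between the two total-population estimates over the unit's
#' cells valid in both grids. Units with fewer than `min_cells` valid cells
#' are skipped with a warning; a unit where either grid is constant has
#' undefined correlation, reported as `NA`. Summaries are the mean and IQR
#' (25th-75th percentile, linear interpolation) across units.
#'
#' @param total_direct Direct total-population `grid`.
#' @param total_sum Summed-ages `grid`.
#' @param zones A `zone_map`.
#' @param level Admin level to compare within (default `"city"`).
#' @param min_cells Minimum valid cells per unit (default 3).
#' @return List with `by_unit` (data.frame `zone_id`, `n_cells`, `r`,
#'   `rmse`) and `summary` (mean and IQR of each metric).
#' @export
consistency_by_region <- function(total_direct, total_sum, zones,
                                  level = "city", min_cells = 3) {
  stopifnot_coregistered(total_direct, total_sum, "the two total grids")
  stopifnot_coregistered(total_direct, zones$labels, "grid and zones")
  ids <- zones_at_level(zones, level)
  fine <- sort(unique(as.vector(zones$labels$values)))
  fine <- fine[fine > 0]
  anc <- ancestor_at_level(zones, fine, level)
  lab <- c(0, anc)[match(zones$labels$values, c(0, fine))]
  ok <- grid_valid(total_direct) & grid_valid(total_sum) & lab > 0
  rows <- lapply(ids, function(id) {
    sel <- ok & lab == id
    n <- sum(sel)
    if (n < min_cells) {
      warning("unit ", id, " has ", n, " valid cell(s); skipped")
      return(data.frame(zone_id = id, n_cells = n, r = NA_real_,
                        rmse = NA_real_))
    }
    a <- total_direct$values[sel]; b <- total_sum$values[sel]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
    data.frame(zone_id = id, n_cells = n, r = r,
               rmse = sqrt(mean((a - b)^2)))
  })
  by_unit <- do.call(rbind, rows)
  summ <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x),
      q25 = stats::quantile(x, 0.25, type = 7, names = FALSE),
      q75 = stats::quantile(x, 0.75, type = 7, names = FALSE))
  }
  list(by_unit = by_unit,
       summary = list(r = summ(by_unit$r), rmse = summ(by_unit$rmse)))
}
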