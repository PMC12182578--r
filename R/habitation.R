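#' Inhabited-zone mask
#'
#' A cell is an inhabited candidate when it has any built-up area or any
#' building height and is not covered by water:
#' `(builtup_frac > 0 OR building_height > 0) AND water == 0`. The
#' inequality is strict, with no epsilon. All density modelling and
#' allocation happen inside this mask; population outside it is zero.
#'
#' @param stack Named list of covariate `grid`s; needs `builtup_frac`,
#'   `building_height` and `water`.
#' @return A 0/1 `grid` (1 = inhabited candidate).
#' @export
compute_mask <- function(stack) {
  need <- c("builtup_frac", "building_height", "water")
  miss <- setdiff(need, names(stack))
  if (length(miss))
    stop("covariate stack missing layer(s): ", paste(miss, collapse = ", "))
  b <- stack$builtup_frac; h <- stack$building_height; w <- stack$water
  stopifnot_coregistered(b, h, "builtup_frac and building_height")
  stopifnot_coregistered(b, w, "builtup_frac and water")
  m <- (b$values > 0 | h$values > 0) & w$values == 0
  new_grid(m + 0, x_origin = b$x_origin, y_origin = b$y_origin,
           cell_size = b$cell_size, crs_id = b$crs_id, nodata = -1)
}

#' Per-zone inhabited area
#'
#' Counts inhabited cells per zone and converts to hectares
#' (`cell_size^2 / 1e4`); at 100-m cells, area in ha equals the cell count.
#' Zones with no inhabited cell get area 0 and are flagged — they cannot
#' receive population, so a positive census count there is a conservation
#' problem the caller must surface.
#'
#' @param mask Inhabited mask from [compute_mask()].
#' @param zones A `zone_map` co-registered with the mask.
#' @return data.frame with `zone_id`, `area_ha`, `n_cells`, `uninhabited`.
#' @export
inhabited_area <- function(mask, zones) {
  cnt <- zonal_aggregate(mask, zones, stat = "sum")
  n <- cnt$value
  n[is.na(n)] <- 0
  ha_per_cell <- mask$cell_size^2 / 1e4
  data.frame(zone_id = cnt$zone_id, area_ha = n * ha_per_cell,
             n_cells = n, uninhabited = n == 0)
}
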