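#' Predict the per-cell weighting layer
#'
#' Applies a fitted density model to every cell's covariates to get a
#' relative population weight, clamped at zero (tree-ensemble regression on
#' nonnegative targets is already nonnegative; the clamp is a guard), and
#' sets weights outside the inhabited mask to exactly zero so no population
#' can be allocated there.
#'
#' @param model A `density_model`.
#' @param stack Named list of covariate `grid`s.
#' @param mask Inhabited mask from [compute_mask()].
#' @return A `grid` of weights.
#' @export
predict_weights <- function(model, stack, mask) {
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss))
    stop("covariate stack missing layer(s): ", paste(miss, collapse = ", "))
  tmpl <- stack[[model$covariates[1]]]
  stopifnot_coregistered(tmpl, mask, "stack and mask")
  idx <- which(mask$values > 0)
  w <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  if (length(idx)) {
    newdata <- as.data.frame(lapply(stack[model$covariates],
                                    function(g) g$values[idx]))
    w[idx] <- pmax(0, predict_density(model, newdata))
  }
  new_grid(w, x_origin = tmpl$x_origin, y_origin = tmpl$y_origin,
           cell_size = tmpl$cell_size, crs_id = tmpl$crs_id,
           nodata = -9999)
}

#' Allocate census counts to grid cells
#'
#' Dasymetric allocation with the mass-preserving (pycnophylactic)
#' contract: within each source zone, its census count is split over the
#' zone's inhabited cells proportionally to the weighting layer, and a
#' final largest-weight residual correction makes the zone sum match the
#' count to machine precision. Zones present in the zone map but absent
#' from the census become nodata; cells outside the study area are nodata;
#' inhabited-mask-false cells inside censused zones get 0.
#'
#' Fallback: a zone with a positive count but all-zero weights is allocated
#' uniformly over its inhabited cells; if it has no inhabited cells the
#' count is reported as unallocatable (and the zone left nodata).
#'
#' @param census Census table containing `group`'s counts.
#' @param weights Weighting layer from [predict_weights()].
#' @param zones A `zone_map` whose labels are the census's zone ids.
#' @param mask Inhabited mask.
#' @param group Group code (column of `census`).
#' @return A `grid` of persons per cell (= persons/ha at 100-m cells), with
#'   attribute `"unallocatable"`: data.frame of zones whose count could not
#'   be placed.
#' @export
allocate <- function(census, weights, zones, mask, group = "total") {
  if (!group %in% names(census)) stop("census lacks group column ", group)
  stopifnot_coregistered(weights, mask, "weights and mask")
  stopifnot_coregistered(weights, zones$labels, "weights and zone labels")
  lab <- zones$labels$values
  zone_ids <- sort(unique(as.vector(lab))); zone_ids <- zone_ids[zone_ids > 0]
  nodata <- -9999
  out <- matrix(nodata, nrow(lab), ncol(lab))
  counts <- census[[group]][match(zone_ids, census$zone_id)]
  unalloc <- list()
  inmask <- mask$values > 0
  wv <- weights$values
  cells_by_zone <- split(seq_along(lab), lab)
  cells_by_zone[["0"]] <- NULL
  for (k in seq_along(zone_ids)) {
    zid <- zone_ids[k]
    cells <- cells_by_zone[[as.character(zid)]]
    p <- counts[k]
    if (is.na(p)) next                       # no census row -> nodata zone
    out[cells] <- 0
    icells <- cells[inmask[cells]]
    if (!length(icells)) {
      if (p > 0)
        unalloc[[length(unalloc) + 1L]] <-
          data.frame(zone_id = zid, count = p,
                     reason = "no inhabited cells")
      next
    }
    w <- wv[icells]
    sw <- sum(w)
    if (sw <= 0) {
      w <- rep(1, length(icells))            # uniform fallback
      sw <- length(icells)
    }
    v <- p * w / sw
    # residual correction on the heaviest cell: exact zone sum
    v[which.max(w)] <- v[which.max(w)] + (p - sum(v))
    out[icells] <- v
  }
  g <- new_grid(out, x_origin = weights$x_origin,
                y_origin = weights$y_origin, cell_size = weights$cell_size,
                crs_id = weights$crs_id, nodata = nodata)
  attr(g, "unallocatable") <- if (length(unalloc)) do.call(rbind, unalloc)
    else data.frame(zone_id = integer(0), count = numeric(0),
                    reason = character(0))
  g
}

#' Run the dasymetric mapping for every population group
#'
#' One independent weighting-and-allocation pass per group: the direct
#' total-population grid and the four age-group grids are produced by
#' separate models, so the direct total and the sum of the age grids are
#' two distinct estimates of the same surface (their agreement is the
#' second validation).
#'
#' @param census Census table (with `a60_64`).
#' @param models Named list of `density_model`s, one per group in `groups`.
#' @param stack Covariate stack.
#' @param mask Inhabited mask.
#' @param zones Zone map matching the census's zone ids.
#' @param groups Groups to map (default [POP_GROUPS]).
#' @return Named list of population `grid`s.
#' @export
run_group_mappings <- function(census, models, stack, mask, zones,
                               groups = POP_GROUPS) {
  miss <- setdiff(groups, names(models))
  if (length(miss))
    stop("no fitted model for group(s): ", paste(miss, collapse = ", "))
  out <- lapply(groups, function(g) {
    w <- predict_weights(models[[g]], stack, mask)
    allocate(census, w, zones, mask, group = g)
  })
  names(out) <- groups
  out
}
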