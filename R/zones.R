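#' Construct a zone map
#'
#' A `zone_map` pairs an integer label grid (0 = outside the study area)
#' with a unit table describing the administrative hierarchy. Every township
#' has a county parent, every county a city parent, every city a province
#' parent (parent of a province is `NA`).
#'
#' @param labels Integer `grid` of zone labels (0 outside study area).
#' @param units data.frame with columns `zone_id`, `name`, `level`
#'   (one of province/city/county/township) and `parent_id`.
#' @return An object of class `zone_map`.
#' @export
new_zone_map <- function(labels, units) {
  stopifnot(is_grid(labels))
  req <- c("zone_id", "name", "level", "parent_id")
  if (!all(req %in% names(units)))
    stop("units table must have columns ", paste(req, collapse = ", "))
  bad <- setdiff(units$level, c("province", "city", "county", "township"))
  if (length(bad)) stop("unknown admin level(s): ", paste(bad, collapse = ", "))
  lv <- c(city = "province", county = "city", township = "county")
  for (l in names(lv)) {
    kids <- units[units$level == l, ]
    if (!nrow(kids)) next
    # parent links are validated when declared; a level that is present in
    # the table makes its children's links mandatory
    must <- lv[[l]] %in% units$level
    if (must && anyNA(kids$parent_id))
      stop("broken hierarchy: every ", l, " needs a ", lv[[l]], " parent")
    decl <- kids[!is.na(kids$parent_id), ]
    if (nrow(decl)) {
      par <- units[match(decl$parent_id, units$zone_id), ]
      if (anyNA(par$zone_id) || any(par$level != lv[[l]]))
        stop("broken hierarchy: every ", l, " needs a ", lv[[l]], " parent")
    }
  }
  pos <- setdiff(unique(as.vector(labels$values)), 0)
  if (!all(pos %in% units$zone_id))
    stop("labels contain zone ids missing from the unit table: ",
         paste(setdiff(pos, units$zone_id), collapse = ", "))
  structure(list(labels = labels, units = units), class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d cells; units: %s\n",
              nrow(x$labels$values), ncol(x$labels$values),
              paste(sprintf("%d %s", table(x$units$level)[c("province",
                "city", "county", "township")],
                c("province", "city", "county", "township")),
                collapse = ", ")))
  invisible(x)
}

#' Zone ids at a given administrative level
#' @param zones A `zone_map`.
#' @param level Admin level name.
#' @return Integer vector of zone ids.
#' @export
zones_at_level <- function(zones, level) {
  if (!level %in% zones$units$level)
    stop("level '", level, "' absent from hierarchy")
  zones$units$zone_id[zones$units$level == level]
}

#' Ancestor zone id at a coarser level
#'
#' Walks `parent_id` links from each id until reaching `level`.
#'
#' @param zones A `zone_map`.
#' @param zone_ids Integer vector of zone ids.
#' @param level Target (coarser or equal) admin level.
#' @return Integer vector of ancestor ids, `NA` where no ancestor exists.
#' @export
ancestor_at_level <- function(zones, zone_ids, level) {
  u <- zones$units
  out <- zone_ids
  for (k in seq_len(4)) {             # hierarchy depth is at most 4
    i <- match(out, u$zone_id)
    done <- !is.na(i) & u$level[i] == level
    if (all(done | is.na(out))) break
    out[!done] <- u$parent_id[match(out[!done], u$zone_id)]
  }
  i <- match(out, u$zone_id)
  out[is.na(i) | u$level[i] != level] <- NA_integer_
  out
}

#' Relabel a zone map at a coarser level
#'
#' Replaces every cell's township (or other fine) label by its ancestor at
#' `level`, producing the zone map a coarse-source run allocates over.
#'
#' @param zones A `zone_map`.
#' @param level Target admin level.
#' @return A `zone_map` whose labels are ids at `level`; the unit table is
#'   restricted to `level` and its ancestors.
#' @export
coarsen_zone_map <- function(zones, level) {
  ids <- sort(unique(as.vector(zones$labels$values)))
  ids <- ids[ids > 0]
  anc <- ancestor_at_level(zones, ids, level)
  map <- c(0, anc)[match(zones$labels$values, c(0, ids))]
  map[is.na(map)] <- 0
  lab <- zones$labels
  lab$values <- matrix(map, nrow(lab$values), ncol(lab$values))
  keep_lv <- c("province", "city", "county", "township")
  keep_lv <- keep_lv[seq_len(match(level, keep_lv))]
  new_zone_map(lab, zones$units[zones$units$level %in% keep_lv, ])
}

#' Build a labeled polygon set
#'
#' Lightweight vector carrier: one closed ring per zone plus the hierarchy
#' attributes [rasterize_zones()] needs. Multi-ring zones are supported by
#' `NA`-separated vertex runs, the convention `mgcv::in.out` uses.
#'
#' @param polygons List of two-column matrices (x, y vertices; first vertex
#'   need not be repeated at the end).
#' @param zone_id,name,level,parent_id Per-polygon attributes, recycled
#'   rules not applied — lengths must match `polygons`.
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(polygons, zone_id, name = as.character(zone_id),
                        level = "township", parent_id = NA_integer_) {
  n <- length(polygons)
  stopifnot(length(zone_id) == n)
  level <- rep_len(level, n); parent_id <- rep_len(parent_id, n)
  name <- rep_len(name, n)
  structure(list(polygons = polygons,
                 attrs = data.frame(zone_id = zone_id, name = name,
                                    level = level, parent_id = parent_id)),
            class = "polygon_set")
}

#' Rasterize labeled polygons onto a template lattice
#'
#' Each cell is labeled by the polygon containing its center; cells outside
#' all polygons get 0. A center claimed by more than one polygon is assigned
#' to the polygon earliest in file order when the claim comes from a shared
#' boundary; genuinely overlapping polygons at the same level raise an error
#' listing the offending ids. A polygon capturing no cell center triggers a
#' warning.
#'
#' @param polys A `polygon_set`.
#' @param template A `grid` defining the target lattice.
#' @param units Optional unit table for the resulting `zone_map`; by default
#'   built from the polygon attributes.
#' @return A `zone_map`.
#' @export
rasterize_zones <- function(polys, template, units = NULL) {
  stopifnot(inherits(polys, "polygon_set"), is_grid(template))
  cc <- cell_centers(template)
  pts <- cbind(as.vector(cc$x), as.vector(cc$y))
  lab <- integer(nrow(pts))
  claimed_by <- vector("list", nrow(pts))
  inside <- vector("list", length(polys$polygons))
  for (k in seq_along(polys$polygons)) {
    ring <- polys$polygons[[k]]
    inside[[k]] <- mgcv::in.out(rbind(ring, ring[1, , drop = FALSE]), pts)
    take <- inside[[k]] & lab == 0L
    lab[take] <- k
    if (!any(inside[[k]]))
      warning("polygon for zone ", polys$attrs$zone_id[k],
              " captures no cell center")
  }
  # multi-claim cells: boundary touch vs genuine same-level overlap
  eps <- 1e-6 * template$cell_size
  jit <- rbind(c(eps, eps), c(-eps, eps), c(eps, -eps), c(-eps, -eps))
  offenders <- character(0)
  for (k in seq_along(inside)) for (j in seq_len(k - 1L)) {
    if (polys$attrs$level[k] != polys$attrs$level[j]) next
    both <- which(inside[[k]] & inside[[j]])
    if (!length(both)) next
    for (cell in both) {
      p4 <- sweep(jit, 2L, pts[cell, ], `+`)
      rk <- polys$polygons[[k]]; rj <- polys$polygons[[j]]
      in_k <- mgcv::in.out(rbind(rk, rk[1, , drop = FALSE]), p4)
      in_j <- mgcv::in.out(rbind(rj, rj[1, , drop = FALSE]), p4)
      if (any(in_k & in_j)) {
        offenders <- c(offenders, sprintf("%s/%s", polys$attrs$zone_id[j],
                                          polys$attrs$zone_id[k]))
        break
      }
    }
  }
  if (length(offenders))
    stop("overlapping polygons at same level: ",
         paste(unique(offenders), collapse = ", "))
  ids <- polys$attrs$zone_id
  labels <- new_grid(matrix(c(0L, ids)[lab + 1L],
                            nrow(template$values), ncol(template$values)),
                     x_origin = template$x_origin,
                     y_origin = template$y_origin,
                     cell_size = template$cell_size,
                     crs_id = template$crs_id, nodata = -1)
  if (is.null(units)) units <- polys$attrs
  new_zone_map(labels, units)
}
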