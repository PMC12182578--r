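#' Configuration for a synthetic landscape
#'
#' Bundles every knob of the synthetic world generator: lattice size,
#' administrative hierarchy (cities split into counties split into
#' townships, all rectangular and contiguous), covariate field structure
#' (spatial correlation length, urban cores), water coverage, density noise
#' and the per-group age-structure gradients.
#'
#' Defaults describe the test-scale world the package's own validation runs
#' on: 400 x 400 cells of 100 m (a 40 km x 40 km extent), a
#' 4 x 5 x 10 hierarchy (200 townships), 8% water, and additive density
#' noise of 1.5 persons/ha — about 17% of the noise-free cell-density SD,
#' the low-noise regime under which township density is recoverable from
#' the covariates.
#'
#' @param n_rows,n_cols Lattice size in cells.
#' @param cell_size Cell edge (m); 100 m makes persons/cell = persons/ha.
#' @param n_cities,counties_per_city,townships_per_county Hierarchy counts.
#' @param corr_len Correlation length (cells) of the smooth covariate
#'   fields.
#' @param urban_cores_per_city Number of urban-core kernels per city.
#' @param urban_decay Gaussian decay scale (cells) of urban cores.
#' @param water_fraction Fraction of cells covered by water, in `[0, 1]`.
#' @param density_noise_sd SD (persons/ha) of additive cell-density noise.
#' @param age_gradient Named list, one numeric triple `(bx, by, bu)` per age
#'   group: log-share gradients along easting, northing and urbanity. These
#'   produce the smooth spatial age-structure variation the per-group
#'   mapping is meant to recover.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 400, n_cols = 400, cell_size = 100,
                             n_cities = 4, counties_per_city = 5,
                             townships_per_county = 10,
                             corr_len = 12, urban_cores_per_city = 2,
                             urban_decay = 18, water_fraction = 0.08,
                             density_noise_sd = 1.5,
                             age_gradient = list(
                               a0_14   = c(bx =  0.30, by =  0.00, bu = -0.5),
                               a15_59  = c(bx =  0.00, by =  0.00, bu =  0.9),
                               a60_64  = c(bx =  0.00, by =  0.15, bu = -0.2),
                               a65plus = c(bx = -0.25, by =  0.20, bu = -0.9)),
                             seed = 1L) {
  stopifnot(n_rows >= 4, n_cols >= 4, cell_size > 0,
            n_cities >= 1, counties_per_city >= 1,
            townships_per_county >= 1,
            water_fraction >= 0, water_fraction <= 1,
            density_noise_sd >= 0)
  stopifnot(setequal(names(age_gradient),
                     c("a0_14", "a15_59", "a60_64", "a65plus")))
  structure(as.list(environment()), class = "landscape_config")
}

COVARIATE_NAMES <- c("builtup_frac", "building_height", "ntl", "dist_road",
                     "poi_density", "elevation", "slope", "water")

# near-square factorization k = a * b with a <= b
near_square <- function(k) {
  a <- floor(sqrt(k))
  while (k %% a != 0) a <- a - 1
  c(a, k %/% a)
}

build_hierarchy <- function(cfg) {
  nr <- cfg$n_rows; nc <- cfg$n_cols
  tshape <- near_square(cfg$townships_per_county)
  if (nc < cfg$n_cities * tshape[2] || nr < cfg$counties_per_city * tshape[1])
    stop("hierarchy counts exceed grid capacity")
  next_id <- 1L
  units <- list()
  add_unit <- function(name, level, parent) {
    id <- next_id; next_id <<- next_id + 1L
    units[[length(units) + 1L]] <<- data.frame(
      zone_id = id, name = name, level = level, parent_id = parent)
    id
  }
  prov <- add_unit("province_1", "province", NA_integer_)
  lab <- matrix(0L, nr, nc)
  city_cols <- split_sizes(nc, cfg$n_cities)
  c0 <- 0L
  for (ci in seq_len(cfg$n_cities)) {
    city <- add_unit(sprintf("city_%d", ci), "city", prov)
    ccols <- (c0 + 1L):(c0 + city_cols[ci]); c0 <- c0 + city_cols[ci]
    cty_rows <- split_sizes(nr, cfg$counties_per_city)
    r0 <- 0L
    for (ki in seq_len(cfg$counties_per_city)) {
      county <- add_unit(sprintf("county_%d_%d", ci, ki), "county", city)
      crows <- (r0 + 1L):(r0 + cty_rows[ki]); r0 <- r0 + cty_rows[ki]
      trows <- split_sizes(length(crows), tshape[1])
      tr0 <- 0L
      ti <- 0L
      for (a in seq_len(tshape[1])) {
        rr <- crows[(tr0 + 1L):(tr0 + trows[a])]; tr0 <- tr0 + trows[a]
        tcols <- split_sizes(length(ccols), tshape[2])
        tc0 <- 0L
        for (b in seq_len(tshape[2])) {
          ti <- ti + 1L
          cc <- ccols[(tc0 + 1L):(tc0 + tcols[b])]; tc0 <- tc0 + tcols[b]
          tw <- add_unit(sprintf("township_%d_%d_%d", ci, ki, ti),
                         "township", county)
          lab[rr, cc] <- tw
        }
      }
    }
  }
  list(labels = lab, units = do.call(rbind, units))
}

#' Generate a synthetic landscape
#'
#' Produces the eight co-registered covariate grids (fraction built-up,
#' building height, nighttime light, distance to road, POI density,
#' elevation, slope, water) and the hierarchical zone map. Covariates are
#' smoothed random fields on which Gaussian urban-core kernels raise
#' built-up fraction, building height, nighttime light and POI density
#' jointly, mirroring the correlated covariate structure of real cities;
#' slope is derived from the elevation field by finite differences; water
#' follows a low-elevation-biased smooth field thresholded at the requested
#' areal fraction.
#'
#' @param cfg A [landscape_config()].
#' @return List with `stack` (named list of covariate `grid`s), `zones`
#'   (a `zone_map`) and `urbanity` (the latent urban intensity field used
#'   by the truth generator, unit-scaled).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  h <- build_hierarchy(cfg)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  with_seed(cfg$seed, {
    f <- function() smooth_field(nr, nc, cfg$corr_len)
    # latent urbanity: per-city core kernels + smooth background
    u <- 0.35 * f()
    city_cols <- split_sizes(nc, cfg$n_cities)
    c0 <- cumsum(c(0, city_cols))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (ci in seq_len(cfg$n_cities)) {
      for (k in seq_len(cfg$urban_cores_per_city)) {
        cr <- stats::runif(1, 0.15 * nr, 0.85 * nr)
        cc <- stats::runif(1, c0[ci] + 0.15 * city_cols[ci],
                           c0[ci] + 0.85 * city_cols[ci])
        amp <- stats::runif(1, 0.8, 1.4)
        u <- u + amp * exp(-((rows - cr)^2 + (cols - cc)^2) /
                             (2 * cfg$urban_decay^2))
      }
    }
    un <- unit_scale(u)
    elevation <- 800 + 350 * f() - 300 * un
    # slope (degrees) from central differences of elevation
    gx <- (elevation[, c(2:nc, nc)] - elevation[, c(1, 1:(nc - 1))]) /
      (2 * cfg$cell_size)
    gy <- (elevation[c(2:nr, nr), ] - elevation[c(1, 1:(nr - 1)), ]) /
      (2 * cfg$cell_size)
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    wfield <- 0.7 * f() - 0.5 * unit_scale(elevation)
    water <- matrix(0, nr, nc)
    if (cfg$water_fraction > 0)
      water[wfield >= stats::quantile(wfield, 1 - cfg$water_fraction)] <- 1
    braw <- u + 0.30 * f()
    bthr <- stats::quantile(braw, 0.55)
    builtup <- pmin(1, pmax(0, (braw - bthr) /
                              (stats::quantile(braw, 0.995) - bthr)))
    height <- 25 * builtup^1.3 * exp(0.3 * f())
    height[builtup == 0] <- 0
    ntl <- 60 * un^1.5 + 1.5 * abs(f())
    dist_road <- 3000 * exp(-3 * un) * exp(0.4 * f())
    poi <- 8 * un^2 * exp(0.5 * f())
    mk <- function(v) new_grid(matrix(v, nr, nc), x_origin = 0,
                               y_origin = nr * cfg$cell_size,
                               cell_size = cfg$cell_size,
                               crs_id = "SYNTH_METERS", nodata = -9999)
    stack <- list(builtup_frac = mk(builtup), building_height = mk(height),
                  ntl = mk(ntl), dist_road = mk(dist_road),
                  poi_density = mk(poi), elevation = mk(elevation),
                  slope = mk(slope), water = mk(water))
    zones <- new_zone_map(
      new_grid(h$labels, x_origin = 0, y_origin = nr * cfg$cell_size,
               cell_size = cfg$cell_size, crs_id = "SYNTH_METERS",
               nodata = -1),
      h$units)
    list(stack = stack, zones = zones, urbanity = mk(un))
  })
}

#' Generate per-group true population surfaces
#'
#' Cell density for the base (total-like) surface is a nonlinear function of
#' the covariates — increasing in built-up fraction, building height, POI
#' density and nighttime light; decaying with slope and distance to road —
#' plus additive Gaussian noise truncated at zero. Density is identically
#' zero outside the inhabited candidate area (water, or no built-up and no
#' building). Age-group surfaces split the base surface with per-cell
#' shares from a softmax over smooth spatial gradients (see
#' [landscape_config()]); the reported `total` surface is defined as the
#' exact cell-wise sum of the four group surfaces.
#'
#' @param land Result of [generate_landscape()].
#' @param cfg The same [landscape_config()].
#' @return List with `pop` (named list of `grid`s: total plus the four
#'   groups), `shares` (list of share matrices) and `base_density`.
#' @export
generate_true_population <- function(land, cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  s <- lapply(land$stack, function(g) g$values)
  nr <- nrow(s$builtup_frac); nc <- ncol(s$builtup_frac)
  inhab <- (s$builtup_frac > 0 | s$building_height > 0) & s$water == 0
  d <- (0.15 + 28 * s$builtup_frac^1.5 + 0.9 * s$building_height +
          2.2 * s$poi_density + 0.06 * s$ntl) *
    exp(-s$slope / 25) * exp(-s$dist_road / 2500)
  with_seed(cfg$seed + 1L, {
    if (cfg$density_noise_sd > 0)
      d <- d + matrix(stats::rnorm(nr * nc, sd = cfg$density_noise_sd),
                      nr, nc)
    d <- pmax(d, 0)
    d[!inhab] <- 0
    x <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
    y <- matrix(seq_len(nr) / nr, nr, nc)
    un <- land$urbanity$values
    base <- log(c(a0_14 = 0.179, a15_59 = 0.634, a60_64 = 0.052,
                  a65plus = 0.135))
    groups <- c("a0_14", "a15_59", "a60_64", "a65plus")
    eta <- lapply(groups, function(g) {
      b <- cfg$age_gradient[[g]]
      base[[g]] + b[["bx"]] * x + b[["by"]] * y + b[["bu"]] * un +
        0.10 * smooth_field(nr, nc, cfg$corr_len)
    })
    names(eta) <- groups
    emax <- Reduce(pmax, eta)
    ee <- lapply(eta, function(e) exp(e - emax))
    denom <- Reduce(`+`, ee)
    shares <- lapply(ee, function(e) e / denom)
    pop <- lapply(shares, function(sh) d * sh)
    pop$total <- Reduce(`+`, pop[groups])   # exact cell-wise sum
    tmpl <- land$stack$builtup_frac
    mk <- function(v) new_grid(matrix(v, nr, nc), x_origin = tmpl$x_origin,
                               y_origin = tmpl$y_origin,
                               cell_size = tmpl$cell_size,
                               crs_id = tmpl$crs_id, nodata = -9999)
    list(pop = lapply(pop[POP_GROUPS], mk), shares = shares,
         base_density = mk(d))
  })
}

#' Tabulate a census from true population surfaces
#'
#' Sums the true group surfaces over the zones of the requested
#' administrative level, then rebuilds the published census schema: the
#' table's `a60plus` is `a60_64 + a65plus` and `total` is the exact sum of
#' the three published age groups, so the real-census identities hold
#' exactly in synthetic tables.
#'
#' @param truth Result of [generate_true_population()].
#' @param zones A `zone_map`.
#' @param level Admin level to tabulate at.
#' @return Census table (data.frame) with zone metadata, the five published
#'   count columns and the derived `a60_64`.
#' @export
tabulate_census <- function(truth, zones, level = "township") {
  ids <- zones_at_level(zones, level)
  lab_fine <- zones$labels$values
  fine_ids <- sort(unique(as.vector(lab_fine))); fine_ids <- fine_ids[fine_ids > 0]
  anc <- ancestor_at_level(zones, fine_ids, level)
  lab <- c(0, anc)[match(lab_fine, c(0, fine_ids))]
  groups <- c("a0_14", "a15_59", "a60_64", "a65plus")
  sums <- lapply(groups, function(g) {
    v <- truth$pop[[g]]$values
    agg <- tapply(v[lab > 0], lab[lab > 0], sum)
    out <- as.numeric(agg[as.character(ids)])
    out[is.na(out)] <- 0
    out
  })
  names(sums) <- groups
  u <- zones$units[match(ids, zones$units$zone_id), ]
  data.frame(zone_id = ids, name = u$name, level = u$level,
             parent_id = u$parent_id,
             total = sums$a0_14 + sums$a15_59 + sums$a60_64 + sums$a65plus,
             a0_14 = sums$a0_14, a15_59 = sums$a15_59,
             a60plus = sums$a60_64 + sums$a65plus,
             a65plus = sums$a65plus, a60_64 = sums$a60_64,
             row.names = NULL)
}
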