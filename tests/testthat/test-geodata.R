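test_that("grid write/read round-trips values, transform and nodata", {
  g <- new_grid(matrix(1, 3, 3), cell_size = 100, crs_id = "SYNTH")
  p <- file.path(tempdir(), "ones.asc")
  write_grid(g, p)
  h <- read_grid(p)
  expect_identical(h$values, g$values)
  expect_identical(c(h$x_origin, h$y_origin, h$cell_size),
                   c(g$x_origin, g$y_origin, g$cell_size))
  expect_identical(h$crs_id, "SYNTH")
  expect_identical(h$nodata, g$nodata)

  # a nodata-coded cell is invalid after read
  g2 <- new_grid(matrix(c(5, -1, 2, 3), 2, 2), cell_size = 1, nodata = -1)
  p2 <- file.path(tempdir(), "nd.asc")
  write_grid(g2, p2)
  h2 <- read_grid(p2)
  expect_identical(sum(grid_valid(h2)), 3L)
  expect_false(grid_valid(h2)[2, 1])

  # continuous covariate grid: exact round trip at 64-bit precision
  w <- small_world()
  g3 <- w$land$stack$ntl
  p3 <- file.path(tempdir(), "cov.asc")
  write_grid(g3, p3)
  expect_identical(read_grid(p3)$values, g3$values)
})

test_that("read_grid refuses missing files and missing CRS", {
  expect_error(read_grid(file.path(tempdir(), "nope.asc")), "not found")
  g <- new_grid(matrix(0, 2, 2), cell_size = 1)
  p <- file.path(tempdir(), "nocrs.asc")
  write_grid(g, p)
  file.remove(paste0(p, ".prj"))
  expect_error(read_grid(p), "CRS missing")
  expect_identical(read_grid(p, crs_id = "X")$crs_id, "X")
})

test_that("rasterize_zones labels cells by center containment", {
  tmpl <- new_grid(matrix(0, 4, 4), x_origin = 0, y_origin = 4,
                   cell_size = 1)
  # one polygon covering the whole template
  ps <- polygon_set(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))),
                    zone_id = 7L)
  zm <- rasterize_zones(ps, tmpl)
  expect_true(all(zm$labels$values == 7))

  # two half planes -> 8 cells each, matching a point-in-polygon oracle
  left <- cbind(c(0, 2, 2, 0), c(0, 0, 4, 4))
  right <- cbind(c(2, 4, 4, 2), c(0, 0, 4, 4))
  ps2 <- polygon_set(list(left, right), zone_id = c(1L, 2L))
  zm2 <- rasterize_zones(ps2, tmpl)
  expect_identical(sum(zm2$labels$values == 1), 8L)
  expect_identical(sum(zm2$labels$values == 2), 8L)
  cc <- cell_centers(tmpl)
  ora <- mgcv::in.out(rbind(left, left[1, ]),
                      cbind(as.vector(cc$x), as.vector(cc$y)))
  expect_identical(as.vector(zm2$labels$values) == 1, ora)

  # polygon missing every center: warning, no cells labeled
  tiny <- cbind(c(0.6, 0.9, 0.9, 0.6), c(0.6, 0.6, 0.9, 0.9))
  expect_warning(zm3 <- rasterize_zones(
    polygon_set(list(left, tiny), zone_id = c(1L, 3L)), tmpl),
    "captures no cell center")
  expect_identical(sum(zm3$labels$values == 3), 0L)
})

test_that("overlapping same-level polygons are rejected with their ids", {
  tmpl <- new_grid(matrix(0, 4, 4), x_origin = 0, y_origin = 4,
                   cell_size = 1)
  a <- cbind(c(0, 3, 3, 0), c(0, 0, 4, 4))
  b <- cbind(c(1, 4, 4, 1), c(0, 0, 4, 4))
  expect_error(rasterize_zones(polygon_set(list(a, b),
                                           zone_id = c(11L, 12L)), tmpl),
               "overlapping.*11/12")
})

test_that("zonal_aggregate matches constants, hand sums and a loop oracle", {
  lab <- matrix(c(1, 1, 2, 2), 2, 2)
  zm <- flat_zone_map(lab, cell_size = 1)
  g7 <- new_grid(matrix(7, 2, 2), cell_size = 1)
  expect_equal(zonal_aggregate(g7, zm, "mean")$value[1:2], c(7, 7))

  gv <- new_grid(matrix(c(1, 2, 10, -9999), 2, 2), cell_size = 1)
  s <- zonal_aggregate(gv, zm, "sum")
  expect_equal(s$value[s$zone_id == 1], 3)
  expect_equal(s$value[s$zone_id == 2], 10)

  # random 50x50, 12 random zones, against the brute-force loop
  set.seed(99)
  rg <- new_grid(matrix(rnorm(2500), 50, 50), cell_size = 1)
  rl <- matrix(sample.int(12, 2500, replace = TRUE), 50, 50)
  rz <- flat_zone_map(rl, cell_size = 1)
  fast <- zonal_aggregate(rg, rz, "mean")
  slow <- oracle_zonal(rg, rz, "mean")
  expect_equal(fast$value, slow$value, tolerance = 1e-12)

  expect_error(zonal_aggregate(new_grid(matrix(0, 3, 3), cell_size = 1),
                               rz, "sum"), "co-registered")
})

test_that("zonal sums conserve the grid total and flag empty zones as NA", {
  set.seed(4)
  lab <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
  reg <- lab; reg[1, 1] <- 5              # register zone 5 in the units
  zm <- flat_zone_map(reg, cell_size = 1)
  lab[1, 1] <- 0                          # ...but give it no cells
  zm$labels$values <- lab + 0
  g <- new_grid(matrix(runif(400), 20, 20), cell_size = 1)
  s <- zonal_aggregate(g, zm, "sum")
  inside <- sum(g$values[lab > 0])
  expect_equal(sum(s$value[s$zone_id %in% 1:4]), inside, tolerance = 1e-12)
  expect_true(is.na(s$value[s$zone_id == 5]))
})

test_that("census reading validates logic and derives the 60-64 group", {
  cen <- data.frame(zone_id = 1:3, name = c("a", "b", "c"),
                    level = "township", parent_id = NA,
                    total = c(200, 0, 50), a0_14 = c(40, 0, 10),
                    a15_59 = c(120, 0, 30), a60plus = c(100, 0, 10),
                    a65plus = c(60, 0, 10))
  p <- file.path(tempdir(), "census.csv")
  write_census(cen, p)
  got <- derive_a60_64(read_census(p))
  expect_equal(got$a60_64, c(40, 0, 0))

  bad <- cen; bad$a65plus[1] <- 150
  pb <- file.path(tempdir(), "bad.csv")
  write_census(bad, pb)
  expect_error(read_census(pb), "zone.*1")
})

test_that("synthetic township a60_64 equals the truth-surface sums", {
  w <- small_world()
  cen <- derive_a60_64(w$census[setdiff(names(w$census), "a60_64")])
  ora <- oracle_zonal(w$truth$pop$a60_64, w$land$zones, "sum")
  ora$value[is.na(ora$value)] <- 0
  keep <- match(cen$zone_id, ora$zone_id)
  expect_equal(cen$a60_64, ora$value[keep], tolerance = 1e-9)
})
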