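test_that("agreement metrics read bias off the OLS slope", {
  a <- c(10, 25, 40, 80, 120)
  m1 <- agreement_metrics(a, a)
  expect_equal(c(m1$r2, m1$slope, m1$rmse), c(1, 1, 0), tolerance = 1e-12)
  m2 <- agreement_metrics(a, 0.5 * a)
  expect_equal(m2$slope, 0.5, tolerance = 1e-12)
  expect_equal(m2$r2, 1, tolerance = 1e-12)   # proportional, just biased
  expect_gt(m2$rmse, 0)
})

test_that("city size classes use left-closed official breaks", {
  got <- city_size_class(c(0.4e6, 0.5e6, 1.0e6, 4.9e6, 10e6, 12e6))
  expect_identical(as.character(got),
                   c("small", "medium", "large", "large", "extremely_large",
                     "extremely_large"))
  expect_identical(as.character(city_size_class(9.99e6)), "very_large")
})

test_that("stratified metrics partition the townships by city class", {
  w <- small_world()
  set.seed(2)
  # force a spread of city sizes by scaling the census counts per city
  cen <- w$census
  city <- ancestor_at_level(w$land$zones, cen$zone_id, "city")
  scale <- ifelse(city == min(city), 40, 9000)
  est <- cen$total * scale * runif(nrow(cen), 0.8, 1.2)
  scatter <- data.frame(group = "total", zone_id = cen$zone_id,
                        actual = cen$total * scale, estimated = est)
  ct <- data.frame(zone_id = w$census_city$zone_id,
                   total = tapply(cen$total * scale, city,
                                  sum)[as.character(w$census_city$zone_id)])
  strat <- stratify_by_city_size(scatter, w$land$zones, ct)
  expect_identical(sum(strat$n), nrow(cen))
  filled <- strat[strat$n >= 3, ]
  expect_true(all(is.finite(filled$r2)))
})

test_that("spatial variation SD matches hand values and invariances", {
  lab <- matrix(c(1, 1, 2, 2), 1, 4)
  zm <- flat_zone_map(lab, cell_size = 100)
  pr <- new_grid(matrix(c(0.2, 0.4, 0.3, 0.3), 1, 4), cell_size = 100)
  v <- spatial_variation(pr, zm, "township")
  expect_equal(v$by_unit$sd[v$by_unit$zone_id == 1], 0.1)   # ddof = 0
  expect_equal(v$by_unit$sd[v$by_unit$zone_id == 2], 0)

  # uniform proportions give all-zero SDs
  pu <- new_grid(matrix(0.25, 1, 4), cell_size = 100)
  expect_true(all(spatial_variation(pu, zm, "township")$by_unit$sd == 0))

  # invariant to adding nodata cells
  pr2 <- pr; pr2$values[1, 3] <- pr2$nodata
  v2 <- spatial_variation(pr2, zm, "township")
  expect_equal(v2$by_unit$sd[v2$by_unit$zone_id == 1], 0.1)
  # unit 2 now has a single valid cell -> excluded
  expect_false(2 %in% v2$by_unit$zone_id)
})

test_that("county-share baseline has county-constant proportions", {
  w <- small_world()
  mp <- small_mapping()
  ages <- setdiff(POP_GROUPS, "total")
  base <- baseline_county_share_product(mp$pop$total, w$census_county,
                                        w$land$zones, ages)
  # shares multiply the total: cell algebra
  lab <- w$land$zones$labels$values
  cty <- matrix(ancestor_at_level(w$land$zones, as.integer(round(lab)),
                                  "county"), nrow(lab))
  k <- w$census_county$zone_id[1]
  share <- w$census_county$a0_14[1] / (w$census_county$a0_14[1] +
    w$census_county$a15_59[1] + w$census_county$a60_64[1] +
    w$census_county$a65plus[1])
  sel <- !is.na(cty) & cty == k & grid_valid(mp$pop$total)
  expect_equal(base$a0_14$values[sel], mp$pop$total$values[sel] * share,
               tolerance = 1e-12)
  # groups sum back to the total cell-wise
  bsum <- Reduce(`+`, lapply(base, function(g) g$values))
  expect_equal(bsum[sel], mp$pop$total$values[sel], tolerance = 1e-9)
  # county-extent SD of baseline proportions is ~0
  bprop <- proportions(base$a65plus, sum_age_groups(base))
  v <- spatial_variation(bprop, w$land$zones, "county")
  expect_lt(max(v$by_unit$sd), 1e-12)
})

test_that("coarse-source validation reproduces trivial agreements", {
  # estimated == actual and estimated == 0.5 * actual by construction
  a <- c(5, 9, 14, 30)
  expect_equal(agreement_metrics(a, a)$r2, 1, tolerance = 1e-12)
  m <- agreement_metrics(a, a / 2)
  expect_equal(m$slope, 0.5, tolerance = 1e-12)
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("mapping from county data is less accurate than from townships", {
  w <- small_world()
  cv <- suppressWarnings(coarse_source_validation(
    w$census, w$census_county, w$land$stack, w$mask, w$land$zones,
    groups = c("total", "a65plus"), split_seed = 5, model_seed = 6,
    trees = c(60, 150), depths = c(10, 20), filter_min_rows = 200))
  expect_identical(nrow(cv$report), 2L)
  # the coarse-source grids still conserve county counts exactly
  sums <- zonal_aggregate(cv$pop_grids$total,
                          coarsen_zone_map(w$land$zones, "county"), "sum")
  act <- w$census_county$total[match(sums$zone_id,
                                     w$census_county$zone_id)]
  ok <- !is.na(sums$value) & act > 0
  expect_lt(max(abs(sums$value[ok] - act[ok]) / act[ok]), 1e-9)
  # township-source agreement is exact by conservation; county-source not
  expect_true(all(cv$report$r2 < 1))
  expect_true(all(cv$report$rmse > 0))
})
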