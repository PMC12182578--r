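# shared fixtures, built once per test run and cached across test files

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# small world: 120x120 cells, 2 cities x 3 counties x 4 townships = 24
small_cfg <- function(seed = 42L)
  landscape_config(n_rows = 120, n_cols = 120, n_cities = 2,
                   counties_per_city = 3, townships_per_county = 4,
                   corr_len = 6, urban_decay = 8, seed = seed)

small_world <- function() cached("small_world", {
  cfg <- small_cfg()
  land <- generate_landscape(cfg)
  truth <- generate_true_population(land, cfg)
  mask <- compute_mask(land$stack)
  list(cfg = cfg, land = land, truth = truth, mask = mask,
       census = tabulate_census(truth, land$zones, "township"),
       census_county = tabulate_census(truth, land$zones, "county"),
       census_city = tabulate_census(truth, land$zones, "city"),
       areas = inhabited_area(mask, land$zones),
       covs = aggregate_covariates(land$stack, land$zones, mask))
})

small_models <- function() cached("small_models", {
  w <- small_world()
  tab <- build_training_table(w$census, w$covs, w$areas)
  fit <- suppressWarnings(
    fit_density_models(tab, split_seed = 5, model_seed = 6,
                       trees = c(60, 150), depths = c(10, 20)))
  list(table = tab, fit = fit)
})

small_mapping <- function() cached("small_mapping", {
  w <- small_world(); m <- small_models()
  pop <- run_group_mappings(w$census, m$fit$models, w$land$stack, w$mask,
                            w$land$zones)
  ages <- setdiff(POP_GROUPS, "total")
  total_sum <- sum_age_groups(pop[ages])
  props <- lapply(pop[ages], proportions, total_sum_grid = total_sum)
  list(pop = pop, total_sum = total_sum, props = props)
})

# study-condition world: the generator defaults (400x400, 200 townships)
default_world <- function() cached("default_world", {
  cfg <- landscape_config()
  land <- generate_landscape(cfg)
  truth <- generate_true_population(land, cfg)
  mask <- compute_mask(land$stack)
  list(cfg = cfg, land = land, truth = truth, mask = mask,
       census = tabulate_census(truth, land$zones, "township"),
       census_county = tabulate_census(truth, land$zones, "county"),
       areas = inhabited_area(mask, land$zones),
       covs = aggregate_covariates(land$stack, land$zones, mask))
})

default_table <- function() cached("default_table", {
  w <- default_world()
  build_training_table(w$census, w$covs, w$areas)
})

# allocation-oriented fixture at study scale; compact candidate lists keep
# it fast (tuning protocol is exercised separately at full grid)
default_mapping <- function() cached("default_mapping", {
  w <- default_world()
  fit <- suppressWarnings(
    fit_density_models(default_table(), split_seed = 1, model_seed = 2,
                       trees = c(100, 400), depths = c(20, 40)))
  pop <- run_group_mappings(w$census, fit$models, w$land$stack, w$mask,
                            w$land$zones)
  ages <- setdiff(POP_GROUPS, "total")
  total_sum <- sum_age_groups(pop[ages])
  props <- lapply(pop[ages], proportions, total_sum_grid = total_sum)
  list(fit = fit, pop = pop, total_sum = total_sum, props = props)
})

# --- brute-force loop oracles (kept deliberately dumb) ------------------

oracle_zonal <- function(grid, zones, stat, restrict = NULL) {
  lab <- zones$labels$values
  ids <- sort(unique(zones$units$zone_id))
  out <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    acc <- numeric(0)
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
      if (lab[i, j] != ids[k]) next
      v <- grid$values[i, j]
      if (is.na(v) || v == grid$nodata) next
      if (!is.null(restrict) && !restrict[i, j]) next
      acc <- c(acc, v)
    }
    if (length(acc))
      out[k] <- switch(stat, sum = sum(acc), mean = mean(acc),
                       count = length(acc))
  }
  data.frame(zone_id = ids, value = out)
}

oracle_masked_count <- function(mask, zones) {
  lab <- zones$labels$values
  ids <- sort(unique(zones$units$zone_id))
  vapply(ids, function(id) {
    n <- 0
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab)))
      if (lab[i, j] == id && mask$values[i, j] > 0) n <- n + 1
    n
  }, numeric(1))
}

oracle_r2 <- function(obs, pred) {
  ssr <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  1 - ssr / sst
}

# 4-unit hierarchy helper for hand-built grids: one province/city/county,
# townships labeled 1..k on a supplied label matrix
flat_zone_map <- function(lab_matrix, cell_size = 100) {
  k <- max(lab_matrix)
  tw <- seq_len(k)
  units <- rbind(
    data.frame(zone_id = k + 3, name = "prov", level = "province",
               parent_id = NA_integer_),
    data.frame(zone_id = k + 2, name = "city", level = "city",
               parent_id = k + 3),
    data.frame(zone_id = k + 1, name = "cty", level = "county",
               parent_id = k + 2),
    data.frame(zone_id = tw, name = paste0("tw", tw), level = "township",
               parent_id = k + 1))
  new_zone_map(new_grid(lab_matrix + 0, cell_size = cell_size,
                        nodata = -1), units)
}
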