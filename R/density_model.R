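#' Default hyperparameter candidate lists
#'
#' The grid-search candidates for the random-forest weighting model:
#' 13 tree counts x 9 maximum depths = 117 combinations, each scored by
#' 5-fold cross-validated RMSE.
#' @export
RF_CANDIDATE_TREES <- c(5, 10, 20, 40, 60, 80, 100, 150, 200, 400, 600,
                        800, 1000)

#' @rdname RF_CANDIDATE_TREES
#' @export
RF_CANDIDATE_DEPTHS <- c(10, 20, 40, 50, 60, 70, 80, 90, 100)

#' Aggregate covariates to administrative zones
#'
#' Covariate value per zone is the mean over that zone's inhabited cells
#' (matching the inhabited-area denominator of the density target);
#' `cells = "all"` switches to the all-cell mean.
#'
#' @param stack Named list of covariate `grid`s.
#' @param zones A `zone_map`.
#' @param mask Inhabited mask from [compute_mask()].
#' @param cells `"inhabited"` (default) or `"all"`.
#' @return data.frame: `zone_id` plus one column per covariate. Zones with
#'   no contributing cells hold `NA`.
#' @export
aggregate_covariates <- function(stack, zones, mask,
                                 cells = c("inhabited", "all")) {
  cells <- match.arg(cells)
  restrict <- if (cells == "inhabited") mask$values > 0 else NULL
  cols <- lapply(stack, function(g)
    zonal_aggregate(g, zones, stat = "mean", restrict_to = restrict)$value)
  ids <- zonal_aggregate(stack[[1]], zones, stat = "count")$zone_id
  out <- data.frame(zone_id = ids)
  for (nm in names(stack)) out[[nm]] <- cols[[nm]]
  out
}

#' Build the per-zone training table
#'
#' One row per zone with positive inhabited area: the covariate aggregates,
#' the inhabited area, and the per-group population density
#' `D = count / area` in persons/ha, untransformed (no log). Zones with
#' zero inhabited area but positive population are excluded with a warning;
#' rows with missing covariate aggregates are excluded with a message.
#'
#' @param census Census table (with `a60_64`, see [derive_a60_64()]).
#' @param covariates Output of [aggregate_covariates()].
#' @param areas Output of [inhabited_area()].
#' @return data.frame with covariate columns, `area_ha` and one
#'   `density_<group>` column per mapped group.
#' @export
build_training_table <- function(census, covariates, areas) {
  ids <- intersect(census$zone_id, intersect(covariates$zone_id,
                                             areas$zone_id))
  cen <- census[match(ids, census$zone_id), ]
  cov <- covariates[match(ids, covariates$zone_id), ]
  ar <- areas[match(ids, areas$zone_id), ]
  drop0 <- ar$area_ha <= 0
  if (any(drop0 & cen$total > 0))
    warning(sum(drop0 & cen$total > 0),
            " zone(s) with population but zero inhabited area excluded")
  covnames <- setdiff(names(cov), "zone_id")
  badcov <- rowSums(is.na(cov[covnames])) > 0
  if (any(badcov & !drop0))
    message(sum(badcov & !drop0), " row(s) with missing covariate ",
            "aggregates excluded")
  keep <- !drop0 & !badcov
  out <- data.frame(zone_id = ids[keep])
  out[covnames] <- cov[keep, covnames]
  out$area_ha <- ar$area_ha[keep]
  for (g in intersect(POP_GROUPS, names(cen)))
    out[[paste0("density_", g)]] <- cen[[g]][keep] / out$area_ha
  if (any(!is.finite(as.matrix(out[grep("^density_", names(out))]))))
    stop("non-finite density in training table")
  out
}

#' Keep zones in the middle 99% of the density distribution
#'
#' Drops 0.5% in each tail: rows with density strictly between the 0.5th
#' and 99.5th empirical percentiles (linear-interpolation quantiles) of the
#' requested group's density are retained. With fewer than `min_rows` rows
#' the filter is skipped with a warning — tail trimming is meaningless on
#' tiny samples.
#'
#' @param table Training table from [build_training_table()].
#' @param group Group code (see [POP_GROUPS]).
#' @param lower,upper Tail probabilities (defaults 0.005 / 0.995).
#' @param min_rows Minimum rows for the filter to engage (default 200).
#' @return Filtered training table.
#' @export
filter_middle_99 <- function(table, group, lower = 0.005, upper = 0.995,
                             min_rows = 200) {
  d <- table[[paste0("density_", group)]]
  if (is.null(d)) stop("no density column for group ", group)
  if (nrow(table) < min_rows) {
    warning("fewer than ", min_rows, " rows; middle-99% filter skipped")
    return(table)
  }
  q <- stats::quantile(d, c(lower, upper), type = 7, names = FALSE)
  if (q[1] == q[2]) return(table)      # degenerate distribution: keep all
  table[d > q[1] & d < q[2], , drop = FALSE]
}

#' Seeded train/test split
#'
#' Shuffles rows under `seed` and takes `floor(fraction * n)` for training,
#' the remainder for testing; disjoint and exhaustive.
#'
#' @param table Training table.
#' @param fraction Training fraction (default 0.85).
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, fraction = 0.85, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  ord <- with_seed(seed, sample.int(n))
  n_train <- floor(fraction * n)
  list(train = table[sort(ord[seq_len(n_train)]), , drop = FALSE],
       test = table[sort(ord[-seq_len(n_train)]), , drop = FALSE])
}

rf_formula <- function(group, covnames) {
  stats::as.formula(paste(paste0("density_", group), "~",
                          paste(covnames, collapse = " + ")))
}

#' Grid-search a random forest density model
#'
#' Evaluates every (number of trees, maximum depth) combination of the
#' candidate lists by 5-fold cross-validated RMSE on the training rows
#' (fold assignment is a seeded random partition shared across
#' combinations), picks the minimum-RMSE combination (ties broken by fewer
#' trees, then shallower depth) and refits it on the full training set.
#' Every covariate is a split candidate at every node (`mtry = p`, the
#' usual regression-forest convention when the predictor set is small and
#' curated). Importances are impurity-based, normalized to sum to 1.
#'
#' @param train Training rows (from [split_train_test()]).
#' @param group Group code.
#' @param seed Integer seed driving fold assignment and tree growing.
#' @param trees,depths Candidate lists; defaults are [RF_CANDIDATE_TREES]
#'   and [RF_CANDIDATE_DEPTHS].
#' @param covariates Covariate column names; defaults to the eight stack
#'   layers present in `train`.
#' @param n_folds Cross-validation folds (default 5).
#' @return A `density_model`: the fitted ranger forest plus the tuning
#'   record (`cv_table` of all combinations, `n_trees`, `max_depth`,
#'   `cv_rmse`, normalized `importance`, seeds).
#' @export
tune_and_fit <- function(train, group, seed = 1L,
                         trees = RF_CANDIDATE_TREES,
                         depths = RF_CANDIDATE_DEPTHS,
                         covariates = NULL, n_folds = 5) {
  if (!nrow(train)) stop("empty training set")
  y <- train[[paste0("density_", group)]]
  if (is.null(y) || any(!is.finite(y))) stop("non-finite or missing target")
  if (is.null(covariates))
    covariates <- intersect(COVARIATE_NAMES, names(train))
  fml <- rf_formula(group, covariates)
  dat <- train[c(paste0("density_", group), covariates)]
  n <- nrow(dat)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  grid <- expand.grid(n_trees = trees, max_depth = depths,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_rmse <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sse <- 0
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      fit <- ranger::ranger(fml, data = dat[!hold, , drop = FALSE],
                            num.trees = grid$n_trees[i],
                            max.depth = grid$max_depth[i],
                            mtry = length(covariates),
                            seed = seed + f, num.threads = 1)
      pred <- stats::predict(fit, dat[hold, , drop = FALSE],
                             num.threads = 1)$predictions
      sse <- sse + sum((pred - dat[hold, 1])^2)
    }
    grid$cv_rmse[i] <- sqrt(sse / n)
  }
  best <- grid[order(grid$cv_rmse, grid$n_trees, grid$max_depth), ][1, ]
  forest <- ranger::ranger(fml, data = dat, num.trees = best$n_trees,
                           max.depth = best$max_depth,
                           mtry = length(covariates), seed = seed,
                           num.threads = 1, importance = "impurity")
  imp <- forest$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(group = group, forest = forest, covariates = covariates,
                 n_trees = best$n_trees, max_depth = best$max_depth,
                 cv_rmse = best$cv_rmse, cv_table = grid,
                 importance = imp, model_seed = seed),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> group %s: %d trees, depth %d, CV RMSE %.3f\n",
              x$group, x$n_trees, x$max_depth, x$cv_rmse))
  invisible(x)
}

predict_density <- function(model, newdata) {
  stats::predict(model$forest, newdata[model$covariates],
                 num.threads = 1)$predictions
}

#' Held-out goodness-of-fit
#'
#' Standard R-squared (`1 - SS_res / SS_tot`) and RMSE (persons/ha) of the
#' model on held-out rows.
#'
#' @param model A `density_model`.
#' @param test Held-out rows.
#' @return List with `r2`, `rmse` and `n`.
#' @export
evaluate_on_test <- function(model, test) {
  if (!nrow(test)) stop("empty test set")
  y <- test[[paste0("density_", model$group)]]
  pred <- predict_density(model, test)
  list(r2 = r_squared(y, pred),
       rmse = sqrt(mean((pred - y)^2)), n = length(y))
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Fit tuned density models for several groups
#'
#' Full per-group protocol: middle-99% density filter (per group, on that
#' group's density), one shared seeded 85/15 train/test split of the
#' group's candidate rows, grid-search tuning, and held-out evaluation.
#' Models are fitted independently per group and never shared.
#'
#' @param table Training table from [build_training_table()].
#' @param groups Groups to fit (default [POP_GROUPS]).
#' @param split_seed,model_seed Seeds for the split and the forests.
#' @param trees,depths Candidate lists passed to [tune_and_fit()].
#' @param filter_min_rows Passed to [filter_middle_99()].
#' @return List with `models` (named list of `density_model`) and `report`
#'   (data.frame per group: tuned parameters, CV RMSE, held-out R2/RMSE,
#'   row counts).
#' @export
fit_density_models <- function(table, groups = POP_GROUPS,
                               split_seed = 1L, model_seed = 2L,
                               trees = RF_CANDIDATE_TREES,
                               depths = RF_CANDIDATE_DEPTHS,
                               filter_min_rows = 200) {
  models <- list()
  rep_rows <- list()
  for (g in groups) {
    cand <- filter_middle_99(table, g, min_rows = filter_min_rows)
    sp <- split_train_test(cand, fraction = 0.85, seed = split_seed)
    m <- tune_and_fit(sp$train, g, seed = model_seed, trees = trees,
                      depths = depths)
    ev <- evaluate_on_test(m, sp$test)
    models[[g]] <- m
    rep_rows[[g]] <- data.frame(
      group = g, n_candidate = nrow(cand), n_train = nrow(sp$train),
      n_test = nrow(sp$test), n_trees = m$n_trees,
      max_depth = m$max_depth, cv_rmse = m$cv_rmse, test_r2 = ev$r2,
      test_rmse = ev$rmse)
  }
  list(models = models, report = do.call(rbind, rep_rows),
       split_seed = split_seed, model_seed = model_seed)
}

#' Covariate importances and partial dependence
#'
#' Returns the normalized impurity importances and, per covariate, a
#' partial-dependence curve: the mean model prediction over the training
#' rows as that covariate is swept over `n_points` equally spaced values
#' between its 1st and 99th percentiles.
#'
#' @param model A `density_model`.
#' @param train Training rows the model was fitted on.
#' @param n_points Sweep resolution (default 20).
#' @return List with `importance` (named, sums to 1) and `pdp` (data.frame
#'   `covariate`, `value`, `yhat`).
#' @export
importance_and_pdp <- function(model, train, n_points = 20) {
  curves <- lapply(model$covariates, function(cv) {
    rng <- stats::quantile(train[[cv]], c(0.01, 0.99), names = FALSE)
    xs <- seq(rng[1], rng[2], length.out = n_points)
    yh <- vapply(xs, function(v) {
      d <- train
      d[[cv]] <- v
      mean(predict_density(model, d))
    }, numeric(1))
    data.frame(covariate = cv, value = xs, yhat = yh)
  })
  list(importance = model$importance, pdp = do.call(rbind, curves))
}
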