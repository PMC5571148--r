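#' Regional sweep grid for one stressor
#'
#' An evenly spaced grid between the configured regional quantiles of the
#' observed stressor values (default 1st-99th percentile, which excludes
#' extreme outliers), extended where necessary so that every supplied
#' reference-site observation lies inside the grid, and clipped to declared
#' natural bounds (e.g. a toxic-pressure fraction in [0, 1]).
#'
#' @param env site-by-variable matrix of all modelled sites (native units).
#' @param stressor variable name.
#' @param sweep_quantiles length-2 quantile pair clamping the range.
#' @param sweep_points number of grid points.
#' @param ref_values optional observed values (e.g. at reference sites) the
#'   grid must cover.
#' @param bounds optional length-2 numeric natural bounds for the variable.
#' @return strictly increasing numeric vector of length `sweep_points`.
#' @export
sweep_grid <- function(env, stressor, sweep_quantiles = c(0.01, 0.99),
                       sweep_points = 1001L, ref_values = NULL,
                       bounds = NULL) {
  x <- as.matrix(env)[, stressor]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no observed values for '", stressor, "'",
                       call. = FALSE)
  q <- stats::quantile(x, sweep_quantiles, names = FALSE)
  lo <- q[1]; hi <- q[2]
  if (!is.null(ref_values)) {
    rv <- ref_values[!is.na(ref_values)]
    if (length(rv)) {
      lo <- min(lo, min(rv))
      hi <- max(hi, max(rv))
    }
  }
  if (!is.null(bounds)) {
    lo <- max(lo, bounds[1])
    hi <- min(hi, bounds[2])
  }
  if (!(hi > lo)) {
    stop("zero-width sweep range for '", stressor, "'", call. = FALSE)
  }
  seq(lo, hi, length.out = sweep_points)
}

#' Site-specific stressor-response curve of relative species richness
#'
#' Sweeps one stressor over a grid while holding every other variable at
#' the site's observed value, computes each pooled species' occurrence
#' probability from its averaged model, sums the probabilities into an
#' expected species richness, and normalizes by the expected richness at
#' the site's observed conditions, so that relative species richness (RSR)
#' equals 1 at the point of departure.
#'
#' @param site_id site identifier (must have complete values for all kept
#'   predictors).
#' @param stressor swept variable (one of the kept predictors).
#' @param sdms named list of `averaged_sdm` objects.
#' @param dataset the [survey_dataset].
#' @param screened the `screened_predictors` carrying standardization.
#' @param grid native-unit sweep grid (as from [sweep_grid]).
#' @param all_species_mode if `TRUE`, stack every modelled species instead
#'   of only the species observed at the site.
#' @param auc_exclude optional AUC cutoff; species below it are left out of
#'   the pool.
#' @return an object of class `response_curve` with fields `site_id`,
#'   `stressor`, `grid`, `rsr`, `point_of_departure` (observed value, RSR
#'   1), `richness_at_reference`, `species_pool`.
#' @export
site_response <- function(site_id, stressor, sdms, dataset, screened,
                          grid, all_species_mode = FALSE,
                          auc_exclude = NA_real_) {
  if (!site_id %in% rownames(dataset$env)) {
    stop("unknown site '", site_id, "'", call. = FALSE)
  }
  if (!stressor %in% screened$kept) {
    stop("'", stressor, "' is not a kept predictor", call. = FALSE)
  }
  env_row <- dataset$env[site_id, screened$kept, drop = FALSE]
  if (anyNA(env_row)) {
    stop("site '", site_id, "' has missing values in kept predictors",
         call. = FALSE)
  }
  pool <- names(sdms)
  if (!all_species_mode) {
    present <- colnames(dataset$occ)[dataset$occ[site_id, ] == 1]
    pool <- intersect(pool, present)
  }
  if (!is.na(auc_exclude)) {
    pool <- pool[vapply(sdms[pool], function(s) s$auc >= auc_exclude,
                        logical(1))]
  }
  if (!length(pool)) {
    stop("empty species pool for site '", site_id, "'", call. = FALSE)
  }
  z_obs <- standardize_env(env_row, screened)
  s_obs <- env_row[1, stressor]

  # matrix of standardized rows: the swept column runs over the grid, all
  # other columns are pinned at the site's observed (standardized) values
  Zg <- matrix(rep(z_obs, each = length(grid)), nrow = length(grid),
               dimnames = list(NULL, colnames(z_obs)))
  Zg[, stressor] <- (grid - screened$center[stressor]) /
    screened$scale[stressor]

  rich_ref <- 0
  rich_grid <- numeric(length(grid))
  for (sp in pool) {
    rich_ref <- rich_ref + predict(sdms[[sp]], z_obs)
    rich_grid <- rich_grid + predict(sdms[[sp]], Zg)
  }
  if (rich_ref < 1e-6) {
    stop("degenerate normalization at site '", site_id,
         "': expected richness below 1e-6", call. = FALSE)
  }
  structure(
    list(site_id = site_id, stressor = stressor, grid = grid,
         rsr = rich_grid / rich_ref,
         point_of_departure = c(value = unname(s_obs), rsr = 1),
         richness_at_reference = unname(rich_ref),
         species_pool = pool),
    class = "response_curve"
  )
}

#' Evaluate a site's RSR directly at arbitrary stressor values
#'
#' Bypasses the grid: recomputes the stacked occurrence probabilities at
#' the requested native-unit values. Used to check normalization (RSR = 1
#' at the observed value) and for closed-form comparisons.
#'
#' @inheritParams site_response
#' @param at numeric vector of native-unit stressor values.
#' @return numeric vector of RSR values.
#' @export
rsr_at <- function(site_id, stressor, sdms, dataset, screened, at,
                   all_species_mode = FALSE, auc_exclude = NA_real_) {
  curve <- site_response(site_id, stressor, sdms, dataset, screened,
                         grid = if (length(at) >= 2) sort(at) else
                           c(at, at + 1),
                         all_species_mode = all_species_mode,
                         auc_exclude = auc_exclude)
  # recompute in the requested order
  env_row <- dataset$env[site_id, screened$kept, drop = FALSE]
  z_obs <- standardize_env(env_row, screened)
  Zg <- matrix(rep(z_obs, each = length(at)), nrow = length(at),
               dimnames = list(NULL, colnames(z_obs)))
  Zg[, stressor] <- (at - screened$center[stressor]) /
    screened$scale[stressor]
  rich <- numeric(length(at))
  for (sp in curve$species_pool) rich <- rich + predict(sdms[[sp]], Zg)
  rich / curve$richness_at_reference
}

#' Response curves for every reference site and stressor
#'
#' Builds one shared sweep grid per stressor-role variable (covering all
#' reference sites' observed values) and one curve per reference site.
#' Curves are computed for every kept variable with a stressor role;
#' whether a variable ultimately supports an EVD is decided downstream.
#'
#' @param dataset a [survey_dataset].
#' @param sdms fitted models from [fit_sdms].
#' @param screened the screening result.
#' @param config an [evd_config].
#' @return a named list (by stressor) of lists of `response_curve` objects
#'   keyed by reference site id; sites with incomplete predictor values are
#'   skipped with a message.
#' @export
response_curves <- function(dataset, sdms, screened,
                            config = evd_config()) {
  stressors <- intersect(stressor_variables(dataset), screened$kept)
  if (!length(stressors)) {
    stop("no stressor-role variable survived screening", call. = FALSE)
  }
  modelled <- attr(sdms, "modelled_sites")
  if (is.null(modelled)) modelled <- rownames(dataset$env)
  ref <- dataset$reference_ids
  usable <- ref[ref %in% modelled]
  skipped <- setdiff(ref, usable)
  if (length(skipped)) {
    message(length(skipped),
            " reference site(s) skipped (incomplete predictor values): ",
            paste(skipped, collapse = ", "))
  }
  # a reference site hosting none of the modelled species cannot be
  # stacked; drop it here rather than aborting the regional analysis
  if (!config$all_species_mode) {
    pool_n <- vapply(usable, function(sid) {
      present <- colnames(dataset$occ)[dataset$occ[sid, ] == 1]
      length(intersect(names(sdms), present))
    }, integer(1))
    empty <- usable[pool_n == 0L]
    if (length(empty)) {
      message(length(empty),
              " reference site(s) skipped (no modelled species observed): ",
              paste(empty, collapse = ", "))
      usable <- setdiff(usable, empty)
    }
  }
  if (length(usable) < 2L) {
    stop("fewer than two usable reference sites remain", call. = FALSE)
  }
  env_mod <- dataset$env[modelled, , drop = FALSE]
  out <- lapply(stressors, function(sv) {
    grid <- sweep_grid(env_mod, sv,
                       sweep_quantiles = config$sweep_quantiles,
                       sweep_points = config$sweep_points,
                       ref_values = dataset$env[usable, sv],
                       bounds = config$bounds[[sv]])
    curves <- lapply(usable, function(sid) {
      site_response(sid, sv, sdms, dataset, screened, grid,
                    all_species_mode = config$all_species_mode,
                    auc_exclude = config$auc_exclude)
    })
    names(curves) <- usable
    curves
  })
  names(out) <- stressors
  out
}

#' Response curves as a long-format data frame
#' @param curves result of [response_curves] (or one stressor's list).
#' @return data frame (site_id, stressor, grid_value, rsr).
#' @export
curves_to_table <- function(curves) {
  if (inherits(curves, "response_curve")) curves <- list(list(curves))
  if (!is.null(curves$site_id)) curves <- list(curves)
  rows <- list()
  for (group in curves) {
    if (inherits(group, "response_curve")) group <- list(group)
    for (cv in group) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = cv$site_id, stressor = cv$stressor,
        grid_value = cv$grid, rsr = cv$rsr,
        pod_value = cv$point_of_departure[["value"]],
        richness_at_reference = cv$richness_at_reference,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
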