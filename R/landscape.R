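#' Specification of a virtual monitoring landscape
#'
#' Describes a synthetic region with known truth: environmental variables
#' with chosen marginal distributions (optionally correlated through a
#' Gaussian copula), species with known quadratic-logit occurrence
#' responses on the standardized scale, Bernoulli presence/absence sampling
#' with optional imperfect detection, and a rule for picking reference
#' sites. Because the generating model is written on the standardized scale
#' of the marginals' theoretical moments, every site's true response curve
#' and true critical stressor level are available in closed form.
#'
#' @param n_sites number of monitoring sites.
#' @param variables named list; each element is a list with `dist`
#'   (`"uniform"`, `"normal"` or `"lognormal"`), its parameters
#'   (`min`/`max`, `mean`/`sd`, or `meanlog`/`sdlog`) and a `role` (see
#'   [survey_dataset]).
#' @param species list; each element has `b0` (intercept), `linear` and
#'   `quadratic` (named numeric vectors over variable names, standardized
#'   scale; omitted names mean zero).
#' @param n_reference number of reference sites (< `n_sites`).
#' @param reference_rule `"low_stress_quantile"` (the `n_reference` sites
#'   with the smallest mean directional standardized stress over
#'   stressor-role variables) or `"random"`.
#' @param detection per-species detection probability in (0, 1]; scalar or
#'   vector.
#' @param correlation optional positive-definite correlation matrix over
#'   the variables (Gaussian copula).
#' @param seed integer seed; generation is fully reproducible given it.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_sites, variables, species, n_reference,
                           reference_rule = c("low_stress_quantile",
                                              "random"),
                           detection = 1, correlation = NULL, seed = 1L) {
  reference_rule <- match.arg(reference_rule)
  stopifnot(n_sites >= 3, n_reference >= 2)
  if (n_reference >= n_sites) {
    stop("n_reference must be smaller than n_sites", call. = FALSE)
  }
  if (is.null(names(variables)) || any(!nzchar(names(variables)))) {
    stop("variables must be a named list", call. = FALSE)
  }
  for (v in names(variables)) {
    d <- variables[[v]]
    if (!d$dist %in% c("uniform", "normal", "lognormal")) {
      stop("unknown distribution for '", v, "': ", d$dist, call. = FALSE)
    }
    if (!d$role %in% role_levels) {
      stop("unknown role for '", v, "': ", d$role, call. = FALSE)
    }
  }
  if (any(detection <= 0 | detection > 1)) {
    stop("detection must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (nrow(correlation) != length(variables) ||
        ncol(correlation) != length(variables)) {
      stop("correlation matrix must be square over the variables",
           call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("correlation matrix is not positive definite", call. = FALSE)
    }
  }
  if (is.null(names(species))) {
    names(species) <- sprintf("sp%02d", seq_along(species))
  }
  structure(
    list(n_sites = as.integer(n_sites), variables = variables,
         species = species, n_reference = as.integer(n_reference),
         reference_rule = reference_rule, detection = detection,
         correlation = correlation, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

# Theoretical mean and standard deviation of a marginal; the generating
# model standardizes with these, so truth does not depend on the sample.
marginal_moments <- function(d) {
  switch(d$dist,
         uniform = c(mean = (d$min + d$max) / 2,
                     sd = (d$max - d$min) / sqrt(12)),
         normal = c(mean = d$mean, sd = d$sd),
         lognormal = {
           m <- exp(d$meanlog + d$sdlog^2 / 2)
           c(mean = m, sd = m * sqrt(exp(d$sdlog^2) - 1))
         })
}

marginal_quantile <- function(d, u) {
  switch(d$dist,
         uniform = stats::qunif(u, d$min, d$max),
         normal = stats::qnorm(u, d$mean, d$sd),
         lognormal = stats::qlnorm(u, d$meanlog, d$sdlog))
}

# True occurrence probabilities for an env matrix in native units.
true_probabilities <- function(spec, env) {
  vars <- names(spec$variables)
  Z <- sapply(vars, function(v) {
    mm <- marginal_moments(spec$variables[[v]])
    (env[, v] - mm["mean"]) / mm["sd"]
  })
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, vars))
  P <- sapply(spec$species, function(sp) {
    bl <- stats::setNames(numeric(length(vars)), vars)
    bq <- stats::setNames(numeric(length(vars)), vars)
    bl[names(sp$linear)] <- sp$linear
    if (!is.null(sp$quadratic)) bq[names(sp$quadratic)] <- sp$quadratic
    stats::plogis(sp$b0 + drop(Z %*% bl) + drop((Z^2) %*% bq))
  })
  if (is.null(dim(P))) {
    P <- matrix(P, nrow = 1, dimnames = list(NULL, names(spec$species)))
  }
  rownames(P) <- rownames(env)
  P
}

#' Generate a virtual monitoring dataset
#'
#' Draws the environmental matrix from the spec's marginals (through a
#' Gaussian copula if a correlation matrix is given), computes every
#' species' true occurrence probability from its quadratic-logit generating
#' model, samples presence/absence as Bernoulli(probability x detection),
#' and selects reference sites by the configured rule. Site coordinates are
#' drawn uniformly on the unit square (arbitrary units) so that mapping
#' outputs can be exercised.
#'
#' @param spec a [landscape_spec].
#' @return an object of class `virtual_landscape`: a list with `dataset`
#'   (a [survey_dataset]), `spec`, and `true_prob` (site-by-species matrix
#'   of generating occurrence probabilities).
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  n <- spec$n_sites
  vars <- names(spec$variables)
  p <- length(vars)
  if (!is.null(spec$correlation)) {
    L <- chol(spec$correlation)
    U <- stats::pnorm(matrix(stats::rnorm(n * p), n, p) %*% L)
  } else {
    U <- matrix(stats::runif(n * p), n, p)
  }
  env <- sapply(seq_along(vars), function(j) {
    marginal_quantile(spec$variables[[vars[j]]], U[, j])
  })
  colnames(env) <- vars
  ids <- sprintf("S%05d", seq_len(n))
  rownames(env) <- ids
  prob <- true_probabilities(spec, env)
  det <- rep(spec$detection, length.out = length(spec$species))
  occ <- matrix(0L, n, length(spec$species),
                dimnames = list(ids, names(spec$species)))
  for (j in seq_along(spec$species)) {
    occ[, j] <- stats::rbinom(n, 1L, prob[, j] * det[j])
  }
  coords <- data.frame(site_id = ids,
                       x = stats::runif(n), y = stats::runif(n),
                       stringsAsFactors = FALSE)
  roles <- vapply(spec$variables, function(d) d$role, character(1))
  ref <- select_reference_sites(spec, env, roles)
  ds <- survey_dataset(env = env, occ = occ, reference_ids = ref,
                       roles = roles, coords = coords)
  structure(list(dataset = ds, spec = spec, true_prob = prob),
            class = "virtual_landscape")
}

select_reference_sites <- function(spec, env, roles) {
  ids <- rownames(env)
  if (spec$reference_rule == "random") {
    return(sample(ids, spec$n_reference))
  }
  stress_vars <- names(roles)[roles != "covariate"]
  score <- rowMeans(sapply(stress_vars, function(v) {
    mm <- marginal_moments(spec$variables[[v]])
    z <- (env[, v] - mm["mean"]) / mm["sd"]
    switch(roles[[v]],
           stressor_increase = z,
           stressor_decrease = -z,
           stressor_both = abs(z))
  }))
  ids[order(score)[seq_len(spec$n_reference)]]
}

#' True stressor-response curve of a virtual site
#'
#' The exact relative-species-richness curve implied by the generating
#' coefficients (no fitting): same stacking and normalization rules as
#' [site_response], with the species pool defaulting to the species
#' actually observed at the site.
#'
#' @param landscape a `virtual_landscape`.
#' @param site_id site identifier.
#' @param stressor swept variable.
#' @param grid native-unit grid.
#' @param all_species_mode stack every species instead of only those
#'   observed at the site.
#' @return a `response_curve` object (usable with [invert_curve]).
#' @export
true_response_curve <- function(landscape, site_id, stressor, grid,
                                all_species_mode = FALSE) {
  spec <- landscape$spec
  ds <- landscape$dataset
  env_row <- ds$env[site_id, , drop = FALSE]
  pool <- names(spec$species)
  if (!all_species_mode) {
    pool <- pool[ds$occ[site_id, pool] == 1]
  }
  if (!length(pool)) {
    stop("empty species pool for site '", site_id, "'", call. = FALSE)
  }
  sub <- spec
  sub$species <- spec$species[pool]
  rich_ref <- sum(true_probabilities(sub, env_row))
  env_grid <- matrix(rep(env_row, each = length(grid)),
                     nrow = length(grid),
                     dimnames = list(NULL, colnames(env_row)))
  env_grid[, stressor] <- grid
  rich <- rowSums(true_probabilities(sub, env_grid))
  structure(
    list(site_id = site_id, stressor = stressor, grid = grid,
         rsr = rich / rich_ref,
         point_of_departure = c(value = unname(env_row[1, stressor]),
                                rsr = 1),
         richness_at_reference = rich_ref,
         species_pool = pool),
    class = "response_curve"
  )
}

#' True critical stressor level of a virtual site
#'
#' First crossing of 1 - T on the exact generating-model curve, located on
#' a grid ten times denser than the pipeline default so that the truth's
#' interpolation error is negligible against the estimate's.
#'
#' @inheritParams true_response_curve
#' @param T impact threshold.
#' @param direction stress direction.
#' @param sweep_quantiles,sweep_points regional sweep settings the dense
#'   truth grid is derived from.
#' @param bounds optional natural bounds for the variable.
#' @return one-row data frame as from [invert_curve].
#' @export
true_critical_level <- function(landscape, site_id, stressor, T,
                                direction,
                                sweep_quantiles = c(0.01, 0.99),
                                sweep_points = 1001L, bounds = NULL,
                                all_species_mode = FALSE) {
  ds <- landscape$dataset
  grid <- sweep_grid(ds$env, stressor,
                     sweep_quantiles = sweep_quantiles,
                     sweep_points = 10L * sweep_points,
                     ref_values = ds$env[ds$reference_ids, stressor],
                     bounds = bounds)
  curve <- true_response_curve(landscape, site_id, stressor, grid,
                               all_species_mode = all_species_mode)
  invert_curve(curve, T = T, direction = direction)
}

#' A ready-made virtual landscape emulating a regional fish survey
#'
#' Four environmental gradients patterned on a freshwater biomonitoring
#' region: a 0-100 habitat-quality index (stressful when it decreases), a
#' lognormal nutrient concentration and a bounded toxic-pressure fraction
#' (stressful when they increase), and a pH-like variable stressful in both
#' directions. Species niches are drawn once from the stated seed:
#' intercepts span common to rare (so some species fall under the
#' occurrence filter), linear responses are biased against stress, and
#' roughly half the niches carry a negative quadratic term (unimodal
#' optima of varying breadth).
#'
#' @param n_sites number of sites (default 2000).
#' @param n_species number of species (default 30).
#' @param n_reference number of reference sites (default 18).
#' @param seed integer seed for both niche drawing and generation.
#' @return a [landscape_spec].
#' @export
default_landscape_spec <- function(n_sites = 2000L, n_species = 30L,
                                   n_reference = 18L, seed = 1L) {
  variables <- list(
    habitat = list(dist = "uniform", min = 20, max = 100,
                   role = "stressor_decrease"),
    totp = list(dist = "lognormal", meanlog = log(0.12), sdlog = 0.8,
                role = "stressor_increase"),
    toxicity = list(dist = "uniform", min = 0.005, max = 0.35,
                    role = "stressor_increase"),
    ph = list(dist = "normal", mean = 7.6, sd = 0.7,
              role = "stressor_both")
  )
  set.seed(seed + 1000L)
  bias <- c(habitat = 0.5, totp = -0.5, toxicity = -0.5, ph = 0)
  species <- lapply(seq_len(n_species), function(i) {
    b0 <- stats::runif(1, -4.5, 0.5)
    lin <- numeric(0); quad <- numeric(0)
    for (v in names(variables)) {
      if (stats::runif(1) < 0.75) {
        lin[v] <- stats::rnorm(1, bias[[v]], 0.6)
        if (v == "ph" || stats::runif(1) < 0.5) {
          quad[v] <- -stats::runif(1, 0.1, 1.0)
        }
      }
    }
    list(b0 = b0, linear = lin, quadratic = quad)
  })
  names(species) <- sprintf("sp%02d", seq_len(n_species))
  landscape_spec(n_sites = n_sites, variables = variables,
                 species = species, n_reference = n_reference,
                 reference_rule = "low_stress_quantile",
                 detection = 1, seed = seed)
}
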