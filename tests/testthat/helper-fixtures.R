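# Fixtures are built in code; nothing is read from disk.

# Hand-built averaged model with explicit coefficients.
make_sdm <- function(predictors, intercept = 0,
                     linear = stats::setNames(numeric(length(predictors)),
                                              predictors),
                     quadratic = stats::setNames(
                       numeric(length(predictors)), predictors),
                     species = "sp") {
  lin <- stats::setNames(numeric(length(predictors)), predictors)
  quad <- stats::setNames(numeric(length(predictors)), predictors)
  lin[names(linear)] <- linear
  quad[names(quadratic)] <- quadratic
  structure(
    list(species = species, predictors = predictors,
         intercept = intercept, linear = lin, quadratic = quad,
         n_models_averaged = 1L, best_aic = NA_real_,
         n_presences = NA_integer_, n_sites = NA_integer_,
         n_candidates = NA_integer_, n_excluded = 0L, auc = 1),
    class = "averaged_sdm")
}

# Hand-built response curve.
make_curve <- function(grid, rsr, pod_value, site_id = "A",
                       stressor = "s1", richness = 10) {
  structure(
    list(site_id = site_id, stressor = stressor, grid = grid, rsr = rsr,
         point_of_departure = c(value = pod_value, rsr = 1),
         richness_at_reference = richness,
         species_pool = "sp"),
    class = "response_curve")
}

# Minimal consistent 6-site dataset with two variables and three species.
tiny_dataset <- function() {
  env <- matrix(c(1, 2, 3, 4, 5, 6,
                  10, 20, 30, 40, 50, 60), ncol = 2,
                dimnames = list(paste0("s", 1:6), c("v1", "v2")))
  occ <- matrix(c(1, 0, 1, 0, 1, 0,
                  0, 1, 0, 1, 0, 1,
                  1, 1, 1, 0, 0, 0), ncol = 3,
                dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  survey_dataset(env, occ, reference_ids = c("s1", "s2"),
                 roles = c(v1 = "stressor_increase", v2 = "covariate"))
}

# A screened_predictors object with chosen standardization, bypassing the
# data-driven constructor (for tests that control the scale directly).
make_screened <- function(kept, center, scale) {
  structure(
    list(kept = kept,
         dropped = data.frame(variable = character(0), vif = numeric(0)),
         center = stats::setNames(center, kept),
         scale = stats::setNames(scale, kept),
         n_sites = NA_integer_, vif_limit = 5),
    class = "screened_predictors")
}

# Independent Newton-Raphson logistic maximizer (own code path, used as
# the brute-force oracle against the package's IRLS fits).
oracle_logit <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  list(beta = beta, ll = ll, aic = 2 * ncol(X) - 2 * ll)
}

# Small fitted virtual landscape shared by several files; cheap enough to
# rebuild per file (a few seconds).
small_landscape <- function(seed = 11L, n_sites = 400L, n_species = 12L) {
  generate_landscape(default_landscape_spec(
    n_sites = n_sites, n_species = n_species, n_reference = 10L,
    seed = seed))
}
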