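# A two-variable dataset with hand-set standardization so curve values can
# be computed in closed form.
curve_dataset <- function(n = 40, seed = 21) {
  set.seed(seed)
  env <- cbind(s1 = runif(n, 0, 10), cov = rnorm(n))
  rownames(env) <- sprintf("s%02d", seq_len(n))
  occ <- matrix(1L, n, 2, dimnames = list(rownames(env), c("up", "down")))
  survey_dataset(env, occ, reference_ids = rownames(env)[1:3],
                 roles = c(s1 = "stressor_increase", cov = "covariate"))
}

test_that("sweep grids follow the regional quantiles, cover reference values and respect bounds", {
  set.seed(31)
  env <- cbind(v = runif(5000, 0, 100))
  rownames(env) <- paste0("s", 1:5000)
  g <- sweep_grid(env, "v", c(0.01, 0.99), 101L)
  q <- quantile(env[, "v"], c(0.01, 0.99), names = FALSE)
  expect_equal(g[1], q[1])
  expect_equal(g[101], q[2])
  expect_equal(g[1], 1, tolerance = 0.5)    # empirical 1st pctile of U(0,100)
  expect_equal(g[101], 99, tolerance = 0.5)
  expect_equal(length(g), 101L)
  expect_true(all(diff(g) > 0))

  g2 <- sweep_grid(env, "v", c(0, 1), 11L)
  expect_equal(g2[1], min(env[, "v"]))
  expect_equal(g2[11], max(env[, "v"]))

  # an observed reference value outside the quantile span stretches the grid
  g3 <- sweep_grid(env, "v", c(0.01, 0.99), 11L,
                   ref_values = c(0.001, 99.999))
  expect_lte(g3[1], 0.001)
  expect_gte(g3[11], 99.999)

  # declared natural bounds clip the grid
  g4 <- sweep_grid(env, "v", c(0, 1), 11L, bounds = c(10, 50))
  expect_equal(range(g4), c(10, 50))

  expect_error(sweep_grid(cbind(v = rep(3, 10)), "v", c(0.01, 0.99), 11L),
               "zero-width")
})

test_that("a flat species gives RSR identically 1 and opposite responses cancel", {
  d <- curve_dataset()
  scr <- make_screened(c("s1", "cov"), center = c(5, 0), scale = c(2, 1))
  grid <- seq(0, 10, length.out = 21)

  flat <- list(up = make_sdm(c("s1", "cov"), species = "up"))
  cv <- site_response("s01", "s1", flat, d, scr, grid)
  expect_equal(cv$rsr, rep(1, 21))

  # mirrored pair: +b and -b on the swept variable, all else symmetric;
  # plogis(z) + plogis(-z) is constant so the stack cancels exactly
  pair <- list(
    up = make_sdm(c("s1", "cov"), linear = c(s1 = 1.3), species = "up"),
    down = make_sdm(c("s1", "cov"), linear = c(s1 = -1.3),
                    species = "down"))
  cv2 <- site_response("s01", "s1", pair, d, scr, grid)
  expect_equal(cv2$rsr, rep(1, 21), tolerance = 1e-12)
})

test_that("a single monotone logit matches its closed form at chosen grid points", {
  d <- curve_dataset()
  ctr <- 5; scl <- 2; b0 <- 0.4; b1 <- -1.1
  scr <- make_screened(c("s1", "cov"), center = c(ctr, 0), scale = c(scl, 1))
  sdm <- list(up = make_sdm(c("s1", "cov"), intercept = b0,
                            linear = c(s1 = b1), species = "up"))
  grid <- c(1, 5, 9)
  cv <- site_response("s01", "s1", sdm, d, scr, grid)
  s_obs <- d$env["s01", "s1"]
  eta <- function(s) b0 + b1 * (s - ctr) / scl
  expect_equal(cv$rsr, plogis(eta(grid)) / plogis(eta(s_obs)),
               tolerance = 1e-12)
  expect_equal(cv$point_of_departure[["value"]], unname(s_obs))
  expect_equal(cv$richness_at_reference, unname(plogis(eta(s_obs))))
})

test_that("RSR is exactly 1 at the observed stressor value", {
  d <- curve_dataset()
  scr <- make_screened(c("s1", "cov"), center = c(5, 0), scale = c(2, 1))
  sdms <- list(
    up = make_sdm(c("s1", "cov"), intercept = 0.2,
                  linear = c(s1 = 0.8, cov = 0.3),
                  quadratic = c(s1 = -0.4), species = "up"),
    down = make_sdm(c("s1", "cov"), intercept = -0.5,
                    linear = c(s1 = -0.6), species = "down"))
  for (sid in c("s01", "s02", "s03")) {
    s_obs <- d$env[sid, "s1"]
    expect_equal(rsr_at(sid, "s1", sdms, d, scr, at = s_obs), 1,
                 tolerance = 1e-9)
  }
})

test_that("curves are isolated per site and expected richness is pool-monotone", {
  d <- curve_dataset()
  scr <- make_screened(c("s1", "cov"), center = c(5, 0), scale = c(2, 1))
  sdms <- list(
    up = make_sdm(c("s1", "cov"), linear = c(s1 = 0.9, cov = 0.7),
                  species = "up"),
    down = make_sdm(c("s1", "cov"), linear = c(s1 = -0.5, cov = -0.2),
                    species = "down"))
  grid <- seq(1, 9, length.out = 15)
  cv <- site_response("s01", "s1", sdms, d, scr, grid)

  # perturbing another site's covariate must not move this site's curve
  d2 <- d
  d2$env["s07", "cov"] <- d2$env["s07", "cov"] + 100
  cv2 <- site_response("s01", "s1", sdms, d2, scr, grid)
  expect_identical(cv$rsr, cv2$rsr)

  # unnormalized richness drops pointwise when a species leaves the pool
  rich_full <- cv$rsr * cv$richness_at_reference
  cv_one <- site_response("s01", "s1", sdms["up"], d, scr, grid)
  rich_one <- cv_one$rsr * cv_one$richness_at_reference
  expect_true(all(rich_one < rich_full))
})

test_that("sweeping in native units equals sweeping in standardized units", {
  ls <- small_landscape(seed = 19, n_sites = 250, n_species = 8)
  d <- ls$dataset
  cfg <- evd_config(min_occurrences = 10, sweep_points = 61)
  scr <- screen_predictors(d$env, vif_limit = cfg$vif_limit)
  sdms <- fit_sdms(d, scr, cfg)
  sid <- d$reference_ids[1]
  grid <- sweep_grid(d$env, "totp", cfg$sweep_quantiles, 61L)
  cv <- site_response(sid, "totp", sdms, d, scr, grid)

  # the same probabilities arise from standardizing the grid first and
  # evaluating the averaged models directly
  z_obs <- standardize_env(d$env[sid, , drop = FALSE], scr)
  zg <- (grid - scr$center["totp"]) / scr$scale["totp"]
  rich <- rep(0, length(grid))
  rich_ref <- 0
  for (sp in cv$species_pool) {
    Z <- matrix(rep(z_obs, each = length(grid)), nrow = length(grid),
                dimnames = list(NULL, colnames(z_obs)))
    Z[, "totp"] <- zg
    rich <- rich + predict(sdms[[sp]], Z)
    rich_ref <- rich_ref + predict(sdms[[sp]], z_obs)
  }
  expect_equal(cv$rsr, rich / rich_ref, tolerance = 1e-12)
})

test_that("response_curves spans all reference sites and stressors with one grid each", {
  ls <- small_landscape(seed = 23, n_sites = 250, n_species = 8)
  cfg <- evd_config(min_occurrences = 10, sweep_points = 41)
  scr <- screen_predictors(ls$dataset$env, vif_limit = cfg$vif_limit)
  sdms <- fit_sdms(ls$dataset, scr, cfg)
  curves <- suppressMessages(response_curves(ls$dataset, sdms, scr, cfg))
  expect_setequal(names(curves),
                  intersect(stressor_variables(ls$dataset), scr$kept))
  for (sv in names(curves)) {
    expect_true(all(names(curves[[sv]]) %in% ls$dataset$reference_ids))
    expect_gte(length(curves[[sv]]), 2L)
    grids <- vapply(curves[[sv]], function(cv) cv$grid, numeric(41))
    expect_true(all(grids == grids[, 1]))
    pods <- vapply(curves[[sv]],
                   function(cv) cv$point_of_departure[["value"]],
                   numeric(1))
    expect_true(all(pods >= grids[1, 1] & pods <= grids[41, 1]))
    for (cv in curves[[sv]]) expect_true(all(cv$rsr > 0))
  }
})
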