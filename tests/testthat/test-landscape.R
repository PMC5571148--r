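flat_spec <- function(n_sites = 2000, detection = 1, seed = 55) {
  landscape_spec(
    n_sites = n_sites,
    variables = list(v = list(dist = "uniform", min = 0, max = 1,
                              role = "stressor_increase")),
    species = list(flat = list(b0 = 0, linear = numeric(0),
                               quadratic = numeric(0))),
    n_reference = 5, detection = detection, seed = seed)
}

test_that("generation is reproducible and honours detection", {
  l1 <- generate_landscape(flat_spec())
  l2 <- generate_landscape(flat_spec())
  expect_identical(l1$dataset$env, l2$dataset$env)
  expect_identical(l1$dataset$occ, l2$dataset$occ)
  expect_identical(l1$dataset$reference_ids, l2$dataset$reference_ids)

  # flat species (all beta = 0): prevalence ~ 0.5 * detection within
  # 3 binomial standard errors at n = 2000
  for (det in c(1, 0.6)) {
    l <- generate_landscape(flat_spec(detection = det, seed = 56))
    p <- 0.5 * det
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(l$dataset$occ[, "flat"]) - p), 3 * se)
  }
})

test_that("a strongly negative niche shows declining prevalence across quartiles", {
  spec <- landscape_spec(
    n_sites = 2000,
    variables = list(v = list(dist = "uniform", min = 0, max = 1,
                              role = "stressor_increase")),
    species = list(dec = list(b0 = 0, linear = c(v = -2),
                              quadratic = numeric(0))),
    n_reference = 5, seed = 57)
  l <- generate_landscape(spec)
  qt <- cut(l$dataset$env[, "v"], quantile(l$dataset$env[, "v"], 0:4 / 4),
            include.lowest = TRUE)
  prev <- tapply(l$dataset$occ[, "dec"], qt, mean)
  expect_true(all(diff(prev) < 0))
})

test_that("invalid specs are rejected", {
  expect_error(landscape_spec(10, list(v = list(dist = "beta", role = "covariate")),
                              list(), 2), "unknown distribution")
  expect_error(landscape_spec(
    10, list(v = list(dist = "uniform", min = 0, max = 1,
                      role = "stressor_increase")),
    list(sp = list(b0 = 0)), n_reference = 10), "n_reference")
  bad_corr <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(landscape_spec(
    100,
    list(a = list(dist = "normal", mean = 0, sd = 1,
                  role = "stressor_increase"),
         b = list(dist = "normal", mean = 0, sd = 1, role = "covariate")),
    list(sp = list(b0 = 0, linear = c(a = 1))), 5,
    correlation = bad_corr), "positive definite")
  expect_error(generate_landscape(structure(list(), class = "landscape_spec")))
})

test_that("true curves match closed forms and true critical levels match root finding", {
  spec <- landscape_spec(
    n_sites = 500,
    variables = list(v = list(dist = "uniform", min = 0, max = 10,
                              role = "stressor_increase")),
    species = list(dec = list(b0 = 1, linear = c(v = -1.5),
                              quadratic = numeric(0))),
    n_reference = 4, seed = 58)
  l <- generate_landscape(spec)
  # pick a reference site where the species is present
  sid <- l$dataset$reference_ids[l$dataset$occ[l$dataset$reference_ids,
                                               "dec"] == 1][1]
  mm_mean <- 5; mm_sd <- 10 / sqrt(12)
  s_obs <- l$dataset$env[sid, "v"]
  eta <- function(s) 1 - 1.5 * (s - mm_mean) / mm_sd
  grid <- c(2, 5, 8)
  cv <- true_response_curve(l, sid, "v", grid)
  expect_equal(cv$rsr, plogis(eta(grid)) / plogis(eta(s_obs)),
               tolerance = 1e-12)

  # flat species: RSR identically one, censored in every direction
  lf <- generate_landscape(flat_spec(n_sites = 300))
  sidf <- lf$dataset$reference_ids[1]
  cvf <- true_response_curve(lf, sidf, "v", seq(0.1, 0.9, 0.1))
  expect_equal(cvf$rsr, rep(1, 9))
  lvf <- true_critical_level(lf, sidf, "v", T = 0.05,
                             direction = "increase", sweep_points = 101)
  expect_true(lvf$censored)

  # analytic inversion of the logistic ratio as the oracle
  T <- 0.05
  target <- (1 - T) * plogis(eta(s_obs))
  root <- uniroot(function(s) plogis(eta(s)) - target,
                  interval = c(s_obs, 10), tol = 1e-12)$root
  lv <- true_critical_level(l, sid, "v", T = 0.05, direction = "increase",
                            sweep_points = 1001)
  span <- diff(range(l$dataset$env[, "v"]))
  expect_lt(abs(lv$level - root), 1e-4 * span)
})

test_that("reference sites sit at the low-stress end of the landscape", {
  spec <- default_landscape_spec(n_sites = 400, n_species = 10, seed = 60)
  l <- generate_landscape(spec)
  ds <- l$dataset
  # directional stress score recomputed here from the marginals
  score <- rep(0, nrow(ds$env))
  for (v in names(spec$variables)) {
    d <- spec$variables[[v]]
    if (d$role == "covariate") next
    mm <- evdist:::marginal_moments(d)
    z <- (ds$env[, v] - mm["mean"]) / mm["sd"]
    score <- score + switch(d$role, stressor_increase = z,
                            stressor_decrease = -z,
                            stressor_both = abs(z))
  }
  ref_scores <- score[rownames(ds$env) %in% ds$reference_ids]
  expect_lte(max(ref_scores), min(score[!rownames(ds$env) %in%
                                          ds$reference_ids]))
})

test_that("fitted curves converge to the true curves as the site count grows", {
  fit_vs_truth <- function(n_sites, seed = 71) {
    ls <- generate_landscape(default_landscape_spec(
      n_sites = n_sites, n_species = 10, n_reference = 8, seed = seed))
    cfg <- evd_config(min_occurrences = 10, sweep_points = 101)
    scr <- screen_predictors(ls$dataset$env, vif_limit = cfg$vif_limit)
    sdms <- fit_sdms(ls$dataset, scr, cfg)
    sid <- ls$dataset$reference_ids[1]
    grid <- sweep_grid(ls$dataset$env, "totp", cfg$sweep_quantiles, 101L,
                       ref_values = ls$dataset$env[sid, "totp"])
    est <- site_response(sid, "totp", sdms, ls$dataset, scr, grid)
    tru <- true_response_curve(ls, sid, "totp", grid)
    pool <- intersect(est$species_pool, tru$species_pool)
    # compare on the common pool so the gap reflects estimation error only
    est2 <- site_response(sid, "totp", sdms[pool], ls$dataset, scr, grid)
    tru2 <- true_response_curve(ls, sid, "totp", grid)
    tru2$rsr <- {
      sub <- ls$spec; sub$species <- ls$spec$species[pool]
      env_row <- ls$dataset$env[sid, , drop = FALSE]
      ref <- sum(evdist:::true_probabilities(sub, env_row))
      eg <- matrix(rep(env_row, each = length(grid)), nrow = length(grid),
                   dimnames = list(NULL, colnames(env_row)))
      eg[, "totp"] <- grid
      rowSums(evdist:::true_probabilities(sub, eg)) / ref
    }
    mean(abs(est2$rsr - tru2$rsr))
  }
  err_small <- fit_vs_truth(200)
  err_big <- fit_vs_truth(2000)
  expect_lt(err_big, err_small)
  expect_lt(err_big, 0.05)
})
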