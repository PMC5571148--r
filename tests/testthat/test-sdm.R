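test_that("the occurrence filter counts presences exactly", {
  set.seed(9)
  occ <- matrix(0L, 50, 4, dimnames = list(paste0("s", 1:50),
                                           c("rare", "edge", "mid", "com")))
  occ[sample(50, 19), "rare"] <- 1L
  occ[sample(50, 20), "edge"] <- 1L
  occ[sample(50, 30), "mid"] <- 1L
  occ[, "com"] <- 1L
  expect_equal(filter_species(occ, 20), c("edge", "mid", "com"))
  expect_equal(filter_species(occ, 0), colnames(occ))
  expect_equal(filter_species(occ, 20, species_universe = c("mid", "rare")),
               "mid")
  expect_error(filter_species(occ, 51), "no species")
})

test_that("enumeration yields 3^p candidates and never a quadratic without its linear term", {
  for (p in 1:8) {
    preds <- paste0("v", seq_len(p))
    grid <- enumerate_terms(preds)
    expect_equal(nrow(grid), 3L^p)
    expect_equal(anyDuplicated(grid), 0L)
  }
  # audit the realized designs at p = 3: a squared column implies the
  # plain column, and parameter counts match the states
  preds <- c("a", "b", "c")
  Z <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, preds))
  grid <- enumerate_terms(preds)
  expect_equal(nrow(grid), 27L)
  for (r in seq_len(nrow(grid))) {
    d <- evdist:::term_design(Z, grid[r, ])
    for (v in preds) {
      if (paste0(v, "_sq") %in% colnames(d)) {
        expect_true(v %in% colnames(d))
      }
    }
    expect_equal(ncol(d), sum(grid[r, ] >= 1) + sum(grid[r, ] == 2))
  }
})

test_that("logistic fits reproduce closed forms", {
  # intercept-only: beta0 = log-odds of prevalence; AIC by hand
  y <- c(rep(1, 30), rep(0, 70))
  m <- fit_logistic(y, matrix(numeric(0), 100, 0))
  expect_equal(unname(m$coefficients), log(30 / 70), tolerance = 1e-8)
  expect_equal(m$log_likelihood, 30 * log(0.3) + 70 * log(0.7),
               tolerance = 1e-8)
  expect_equal(m$aic, 2 * 1 - 2 * (30 * log(0.3) + 70 * log(0.7)),
               tolerance = 1e-8)

  # single binary predictor: beta1 is exactly the log odds ratio of the
  # 2x2 table (a, b, c, d all positive)
  a <- 12; b <- 8; c <- 5; d <- 25   # (x=1,y=1), (x=1,y=0), (x=0,y=1), (x=0,y=0)
  x <- c(rep(1, a + b), rep(0, c + d))
  y2 <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  m2 <- fit_logistic(y2, cbind(x = x))
  expect_equal(unname(m2$coefficients["x"]), log(a * d / (b * c)),
               tolerance = 1e-7)
  expect_equal(unname(m2$coefficients["(Intercept)"]), log(c / d),
               tolerance = 1e-7)

  expect_error(fit_logistic(rep(1, 10), cbind(rnorm(10))), "single class")
})

test_that("Akaike-weight averaging follows the arithmetic, absent terms entering as zeros", {
  mk <- function(aic, states, coefs) {
    structure(list(states = states, coefficients = coefs,
                   log_likelihood = NA_real_, aic = aic, aicc = aic,
                   k = length(coefs), converged = TRUE),
              class = "candidate_model")
  }
  preds <- "x"
  cands <- list(
    mk(100.0, c(x = 1L), c(`(Intercept)` = 0.5, x = 2.0)),
    mk(101.0, c(x = 2L), c(`(Intercept)` = 0.2, x = 1.0, x_sq = -0.5)),
    mk(102.0, c(x = 0L), c(`(Intercept)` = 0.9)),
    mk(104.0, c(x = 1L), c(`(Intercept)` = 9.9, x = 9.9)))  # outside the set
  avg <- average_models(cands, preds, delta_aic = 2)
  w <- exp(-c(0, 0.5, 1)); w <- w / sum(w)
  expect_equal(avg$n_models_averaged, 3L)
  expect_equal(avg$weights, w, tolerance = 1e-12)
  expect_equal(unname(avg$linear["x"]), w[1] * 2 + w[2] * 1 + w[3] * 0)
  expect_equal(unname(avg$quadratic["x"]), w[2] * -0.5)
  expect_equal(avg$intercept, sum(w * c(0.5, 0.2, 0.9)))

  # equal-AIC pair averages 50/50; a singleton set is the identity
  avg2 <- average_models(cands[c(1, 1)], preds, delta_aic = 2)
  expect_equal(avg2$weights, c(0.5, 0.5))
  avg3 <- average_models(cands[1], preds, delta_aic = 2)
  expect_equal(unname(avg3$linear["x"]), 2.0)
  expect_equal(avg3$intercept, 0.5)

  # conditional averaging divides by the weight mass of the term
  avg4 <- average_models(cands[1:3], preds, delta_aic = 2,
                         full_average = FALSE)
  expect_equal(unname(avg4$linear["x"]),
               (w[1] * 2 + w[2] * 1) / (w[1] + w[2]))
})

test_that("occurrence prediction is the inverse-logit of the averaged predictor", {
  s <- make_sdm("x")
  expect_equal(unname(predict(s, c(x = 0))), 0.5)
  expect_equal(unname(predict(s, c(x = 5))), 0.5)
  s2 <- make_sdm("x", intercept = 0, linear = c(x = 1))
  expect_equal(unname(predict(s2, c(x = 0))), 0.5)
  expect_equal(unname(predict(s2, c(x = 50))), 1, tolerance = 1e-12)
  # known niche: peak of b0 + b1' x^2 (b1 = 0, b1' = -2) sits at x = 0
  s3 <- make_sdm("x", intercept = 1, quadratic = c(x = -2))
  xx <- seq(-2, 2, by = 0.01)
  p <- predict(s3, cbind(x = xx))
  expect_equal(xx[which.max(p)], 0)
  expect_equal(max(p), plogis(1))
})

test_that("AUC counts concordant pairs and ignores monotone rescaling", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3)
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(auc_score(scores, labels), 5 / 6)
  expect_equal(auc_score(c(1, 1, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")

  set.seed(5)
  sc <- runif(40); lb <- rbinom(40, 1, 0.4)
  a0 <- auc_score(sc, lb)
  expect_equal(auc_score(qlogis(sc), lb), a0)
  expect_equal(auc_score(sc^3 + 10, lb), a0)
  # cross-check against pROC on the same scores
  skip_if_not_installed("pROC")
  expect_equal(a0, as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                  direction = "<"))))
})

test_that("best model and averaged coefficients match a brute-force oracle (p = 2, n = 300)", {
  set.seed(404)
  n <- 300
  Z <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- -0.3 + 1.1 * Z[, "x1"] - 0.8 * Z[, "x1"]^2 + 0.6 * Z[, "x2"]
  y <- rbinom(n, 1, plogis(eta))

  fit <- fit_species_sdm(y, Z, config = evd_config(delta_aic = 2))

  # independent path: own enumeration, own Newton maximizer, own averaging
  states_grid <- expand.grid(x1 = 0:2, x2 = 0:2)
  oracle <- lapply(seq_len(nrow(states_grid)), function(i) {
    st <- unlist(states_grid[i, ])
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    for (v in c("x1", "x2")) {
      if (st[v] >= 1) X <- cbind(X, Z[, v, drop = FALSE])
      if (st[v] == 2) {
        q <- Z[, v, drop = FALSE]^2
        colnames(q) <- paste0(v, "_sq")
        X <- cbind(X, q)
      }
    }
    c(list(states = st, X = X), oracle_logit(y, X))
  })
  aics <- vapply(oracle, function(o) o$aic, numeric(1))
  best <- min(aics)
  expect_equal(fit$best_aic, best, tolerance = 1e-6)

  sel <- which(aics - best <= 2)
  w <- exp(-(aics[sel] - best) / 2); w <- w / sum(w)
  lin <- c(x1 = 0, x2 = 0); quad <- c(x1 = 0, x2 = 0); b0 <- 0
  for (i in seq_along(sel)) {
    o <- oracle[[sel[i]]]
    beta <- setNames(o$beta, colnames(o$X))
    b0 <- b0 + w[i] * beta[["(Intercept)"]]
    for (v in c("x1", "x2")) {
      if (o$states[v] >= 1) lin[v] <- lin[v] + w[i] * beta[[v]]
      if (o$states[v] == 2) {
        quad[v] <- quad[v] + w[i] * beta[[paste0(v, "_sq")]]
      }
    }
  }
  expect_equal(fit$n_models_averaged, length(sel))
  expect_equal(fit$intercept, unname(b0), tolerance = 1e-6)
  expect_equal(fit$linear, lin, tolerance = 1e-6)
  expect_equal(fit$quadratic, quad, tolerance = 1e-6)
})

test_that("a known quadratic-logit niche is recovered within 3 SE and its term set sits in the confidence set", {
  # single large fit: truth recovered within 3 standard errors
  set.seed(515)
  n <- 2000
  Z <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  truth <- c(`(Intercept)` = -0.2, x1 = 0.9, x1_sq = -0.7, x2 = 0.5)
  eta <- truth["(Intercept)"] + truth["x1"] * Z[, "x1"] +
    truth["x1_sq"] * Z[, "x1"]^2 + truth["x2"] * Z[, "x2"]
  y <- rbinom(n, 1, plogis(eta))
  g <- glm(y ~ Z[, "x1"] + I(Z[, "x1"]^2) + Z[, "x2"],
           family = binomial())
  se <- summary(g)$coefficients[, "Std. Error"]
  ours <- fit_logistic(y, cbind(x1 = Z[, "x1"], x1_sq = Z[, "x1"]^2,
                                x2 = Z[, "x2"]))
  expect_true(all(abs(ours$coefficients - truth) <= 3 * se))

  # across 50 seeded replicates the generating term set lies inside the
  # delta-AIC <= 2 confidence set at least 90% of the time
  hits <- 0L
  for (seed in 1:50) {
    set.seed(1000 + seed)
    n <- 400
    Z <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    eta <- -0.2 + 1.0 * Z[, "x1"] - 0.9 * Z[, "x1"]^2 + 0.8 * Z[, "x2"]
    y <- rbinom(n, 1, plogis(eta))
    grid <- enumerate_terms(c("x1", "x2"))
    aics <- apply(grid, 1, function(st) {
      fit_logistic(y, evdist:::term_design(Z, st))$aic
    })
    target <- which(grid[, "x1"] == 2L & grid[, "x2"] == 1L)
    if (aics[target] - min(aics) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})
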