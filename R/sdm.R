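#' Species eligible for distribution modelling
#'
#' Returns the species with at least `min_occurrences` presences among the
#' modelled sites, optionally intersected with a species universe (by
#' default modelling is restricted to species observed at reference sites;
#' the all-species analysis variant lifts that restriction).
#'
#' @param occ 0/1 site-by-species matrix (modelled sites only).
#' @param min_occurrences minimum number of presences.
#' @param species_universe optional character vector restricting the result.
#' @return character vector of species names.
#' @export
filter_species <- function(occ, min_occurrences,
                           species_universe = NULL) {
  counts <- colSums(occ)
  keep <- colnames(occ)[counts >= min_occurrences]
  if (!is.null(species_universe)) {
    keep <- intersect(keep, species_universe)
  }
  if (!length(keep)) {
    stop("no species passes the occurrence filter (threshold ",
         min_occurrences, ")", call. = FALSE)
  }
  keep
}

#' Enumerate all candidate term assignments
#'
#' Every predictor is independently absent (0), linear (1), or
#' linear + quadratic (2); a quadratic term is only allowed together with
#' its linear term, which the three-state coding enforces by construction.
#' The enumeration therefore has exactly 3^p candidates, including the
#' intercept-only model, in a fixed order (first predictor cycling fastest).
#'
#' @param predictors character vector of predictor names.
#' @return integer matrix with one row per candidate and one column per
#'   predictor, entries in {0, 1, 2}.
#' @export
enumerate_terms <- function(predictors) {
  p <- length(predictors)
  if (p < 1L) stop("at least one predictor is required", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(0:2), p), KEEP.OUT.ATTRS = FALSE))
  storage.mode(grid) <- "integer"
  colnames(grid) <- predictors
  rownames(grid) <- NULL
  grid
}

# Design matrix (without intercept) for one term assignment.
term_design <- function(Z, states) {
  cols <- list()
  nms <- character(0)
  for (j in seq_along(states)) {
    if (states[j] >= 1L) {
      cols[[length(cols) + 1L]] <- Z[, j]
      nms <- c(nms, colnames(Z)[j])
    }
    if (states[j] == 2L) {
      cols[[length(cols) + 1L]] <- Z[, j]^2
      nms <- c(nms, paste0(colnames(Z)[j], "_sq"))
    }
  }
  if (!length(cols)) {
    m <- matrix(numeric(0), nrow = nrow(Z), ncol = 0)
  } else {
    m <- do.call(cbind, cols)
    colnames(m) <- nms
  }
  m
}

#' Fit one logistic candidate model
#'
#' Maximum-likelihood logistic regression (logit link, binomial error) of a
#' binary occurrence vector on a set of term columns, by iteratively
#' reweighted least squares (convergence when the deviance change drops
#' below 1e-8, at most 100 iterations). Records the log-likelihood,
#' the number of estimated parameters k (intercept included) and
#' AIC = 2k - 2 logLik.
#'
#' @param y binary 0/1 response over sites.
#' @param design numeric matrix of term columns (standardized scale),
#'   without the intercept; zero columns give the intercept-only model.
#' @param states optional integer vector recording the per-predictor term
#'   states this design realizes (carried through for averaging).
#' @param coef_cap absolute coefficient magnitude beyond which the fit is
#'   flagged as separated (`converged = FALSE`).
#' @return a list of class `candidate_model` with fields `states`,
#'   `coefficients` (named, `(Intercept)` first), `log_likelihood`, `aic`,
#'   `aicc`, `k`, `converged`.
#' @export
fit_logistic <- function(y, design, states = NULL, coef_cap = 15) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("response must be binary 0/1", call. = FALSE)
  }
  n1 <- sum(y)
  if (n1 == 0 || n1 == length(y)) {
    stop("response has a single class; cannot fit a logistic model",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design)
  k <- ncol(X)
  if (length(y) < k + 1L) {
    stop(sprintf("too few sites (%d) for %d parameters", length(y), k),
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # guard the log for fitted values pushed to the boundary
  mu <- pmin(pmax(mu, .Machine$double.eps), 1 - .Machine$double.eps)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  n <- length(y)
  aic <- 2 * k - 2 * ll
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  converged <- isTRUE(fit$converged) && !anyNA(beta) &&
    all(abs(beta) <= coef_cap)
  structure(
    list(states = states, coefficients = beta, log_likelihood = ll,
         aic = aic, aicc = aicc, k = k, converged = converged),
    class = "candidate_model"
  )
}

#' Average coefficients over the AIC confidence set
#'
#' Ranks converged candidates by AIC (or AICc), forms the confidence set of
#' models within `delta_aic` units of the best, and averages each
#' coefficient with Akaike weights w_i proportional to exp(-delta_i / 2),
#' normalized over the set. With `full_average = TRUE` (the default) a term
#' absent from a model contributes zero to the average (shrinkage
#' averaging); otherwise the term is averaged only over models containing
#' it (conditional averaging).
#'
#' @param candidates list of `candidate_model` objects for one species.
#' @param predictors character vector of predictor names (defines the
#'   averaged coefficient layout).
#' @param delta_aic width of the confidence set.
#' @param full_average logical, see above.
#' @param use_aicc rank and weight by AICc instead of AIC.
#' @return a list with `intercept`, `linear` and `quadratic` (named numeric
#'   vectors over `predictors`), `n_models_averaged`, `best_aic`, `weights`.
#' @export
average_models <- function(candidates, predictors, delta_aic = 2,
                           full_average = TRUE, use_aicc = FALSE) {
  if (!length(candidates)) {
    stop("no candidate models to average", call. = FALSE)
  }
  ok <- vapply(candidates, function(m) isTRUE(m$converged), logical(1))
  cand <- candidates[ok]
  if (!length(cand)) {
    stop("no converged candidate models", call. = FALSE)
  }
  crit <- vapply(cand, function(m) if (use_aicc) m$aicc else m$aic,
                 numeric(1))
  best <- min(crit)
  sel <- which(crit - best <= delta_aic)
  delta <- crit[sel] - best
  w <- exp(-delta / 2)
  w <- w / sum(w)
  p <- length(predictors)
  lin <- stats::setNames(numeric(p), predictors)
  quad <- stats::setNames(numeric(p), predictors)
  lin_w <- stats::setNames(numeric(p), predictors)   # weight mass of models with the term
  quad_w <- stats::setNames(numeric(p), predictors)
  b0 <- 0
  for (i in seq_along(sel)) {
    m <- cand[[sel[i]]]
    b0 <- b0 + w[i] * m$coefficients[["(Intercept)"]]
    st <- m$states
    for (j in seq_len(p)) {
      v <- predictors[j]
      if (st[j] >= 1L) {
        lin[v] <- lin[v] + w[i] * m$coefficients[[v]]
        lin_w[v] <- lin_w[v] + w[i]
      }
      if (st[j] == 2L) {
        quad[v] <- quad[v] + w[i] * m$coefficients[[paste0(v, "_sq")]]
        quad_w[v] <- quad_w[v] + w[i]
      }
    }
  }
  if (!full_average) {
    lin <- ifelse(lin_w > 0, lin / lin_w, 0)
    quad <- ifelse(quad_w > 0, quad / quad_w, 0)
    names(lin) <- names(quad) <- predictors
  }
  list(intercept = b0, linear = lin, quadratic = quad,
       n_models_averaged = length(sel), best_aic = best,
       weights = stats::setNames(w, NULL))
}

#' Fit and average the distribution model of one species
#'
#' Enumerates all 3^p term assignments over the kept predictors, fits each
#' by maximum likelihood, discards non-converged or separated candidates,
#' averages coefficients over the AIC confidence set and scores the
#' averaged model by in-sample AUC.
#'
#' @param y binary presence/absence vector over modelled sites.
#' @param Z standardized site-by-predictor matrix.
#' @param species species name carried into the result.
#' @param config an [evd_config].
#' @return an object of class `averaged_sdm`.
#' @export
fit_species_sdm <- function(y, Z, species = "species",
                            config = evd_config()) {
  predictors <- colnames(Z)
  assignments <- enumerate_terms(predictors)
  n <- nrow(Z)
  cands <- vector("list", nrow(assignments))
  n_skipped <- 0L
  for (r in seq_len(nrow(assignments))) {
    st <- assignments[r, ]
    k <- 1L + sum(st >= 1L) + sum(st == 2L)
    if (n < k + 1L) { n_skipped <- n_skipped + 1L; next }
    cands[[r]] <- fit_logistic(y, term_design(Z, st), states = st,
                               coef_cap = config$coef_cap)
  }
  cands <- cands[!vapply(cands, is.null, logical(1))]
  n_excluded <- sum(!vapply(cands, function(m) m$converged, logical(1)))
  avg <- average_models(cands, predictors,
                        delta_aic = config$delta_aic,
                        full_average = config$full_average,
                        use_aicc = config$use_aicc)
  sdm <- structure(
    list(species = species,
         predictors = predictors,
         intercept = avg$intercept,
         linear = avg$linear,
         quadratic = avg$quadratic,
         n_models_averaged = avg$n_models_averaged,
         best_aic = avg$best_aic,
         n_presences = as.integer(sum(y)),
         n_sites = n,
         n_candidates = nrow(assignments),
         n_excluded = n_excluded + n_skipped,
         auc = NA_real_),
    class = "averaged_sdm"
  )
  sdm$auc <- auc_score(predict(sdm, Z), y)
  sdm
}

#' Predict occurrence probability from an averaged model
#'
#' Inverse-logit of the averaged linear predictor
#' b0 + sum_j (beta_j z_j + beta'_j z_j^2) evaluated on the standardized
#' scale.
#'
#' @param object an `averaged_sdm`.
#' @param newdata standardized matrix (or single named row) covering all
#'   predictors of the model.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.averaged_sdm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  missing <- setdiff(object$predictors, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- as.matrix(newdata[, object$predictors, drop = FALSE])
  eta <- object$intercept +
    drop(Z %*% object$linear[object$predictors]) +
    drop((Z^2) %*% object$quadratic[object$predictors])
  stats::plogis(eta)
}

#' @export
print.averaged_sdm <- function(x, ...) {
  cat(sprintf(
    "Averaged SDM for '%s': %d presences of %d sites, AUC %.3f, %d model(s) averaged (best AIC %.2f)\n",
    x$species, x$n_presences, x$n_sites, x$auc, x$n_models_averaged,
    x$best_aic))
  cm <- rbind(linear = x$linear, quadratic = x$quadratic)
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  print(round(cm, 4))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' presence receives a higher score than a randomly chosen absence, with
#' ties counted one half. Invariant under any strictly monotone transform
#' of the scores.
#'
#' @param scores numeric predicted scores.
#' @param labels binary 0/1 observed outcomes.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit averaged distribution models for all eligible species
#'
#' Applies the occurrence filter, standardizes the kept predictors over the
#' modelled sites and fits one averaged model per species. Species present
#' at every modelled site (no absences) cannot be modelled and are dropped
#' with a message.
#'
#' @param dataset a [survey_dataset].
#' @param screened a `screened_predictors` object.
#' @param config an [evd_config].
#' @param species_universe optional restriction of the species pool; the
#'   default restricts to species observed at reference sites unless
#'   `config$all_species_mode` is set.
#' @return a named list of `averaged_sdm` objects, with attributes
#'   `modelled_sites` (site ids used) and `n_dropped_sites` (incomplete
#'   rows removed).
#' @export
fit_sdms <- function(dataset, screened, config = evd_config(),
                     species_universe = NULL) {
  env <- dataset$env
  complete <- stats::complete.cases(env[, screened$kept, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(n_dropped,
            " site(s) dropped from fitting: missing values in kept predictors")
  }
  sites <- rownames(env)[complete]
  Z <- standardize_env(env[sites, , drop = FALSE], screened)
  occ <- dataset$occ[sites, , drop = FALSE]
  if (is.null(species_universe) && !config$all_species_mode) {
    ref <- intersect(dataset$reference_ids, sites)
    species_universe <-
      colnames(dataset$occ)[colSums(dataset$occ[ref, , drop = FALSE]) > 0]
  }
  species <- filter_species(occ, config$min_occurrences, species_universe)
  degenerate <- species[colSums(occ[, species, drop = FALSE]) == nrow(occ)]
  if (length(degenerate)) {
    message(length(degenerate),
            " species present at every modelled site dropped: ",
            paste(degenerate, collapse = ", "))
    species <- setdiff(species, degenerate)
  }
  if (!length(species)) stop("no modellable species remain", call. = FALSE)
  sdms <- lapply(species, function(sp) {
    fit_species_sdm(occ[, sp], Z, species = sp, config = config)
  })
  names(sdms) <- species
  attr(sdms, "modelled_sites") <- sites
  attr(sdms, "n_dropped_sites") <- n_dropped
  sdms
}

#' Coefficient table of averaged models on both scales
#'
#' One row per species and predictor with the averaged linear and quadratic
#' coefficients on the standardized scale and their exact algebraic
#' back-transform to native units, plus per-species intercepts, AUC,
#' presence counts and the size of the averaged model set.
#'
#' @param sdms named list of `averaged_sdm` objects (as from [fit_sdms]).
#' @param screened the `screened_predictors` used for fitting (supplies the
#'   standardization parameters for the native-scale back-transform).
#' @return a data frame.
#' @export
sdm_coefficients <- function(sdms, screened) {
  rows <- lapply(sdms, function(s) {
    m <- screened$center[s$predictors]
    sd <- screened$scale[s$predictors]
    bl <- s$linear[s$predictors]
    bq <- s$quadratic[s$predictors]
    a_quad <- bq / sd^2
    a_lin <- bl / sd - 2 * bq * m / sd^2
    a0 <- s$intercept - sum(bl * m / sd) + sum(bq * m^2 / sd^2)
    data.frame(
      species = s$species,
      variable = c("(Intercept)", s$predictors),
      linear_std = c(s$intercept, unname(bl)),
      quadratic_std = c(NA_real_, unname(bq)),
      linear_native = c(a0, unname(a_lin)),
      quadratic_native = c(NA_real_, unname(a_quad)),
      auc = s$auc,
      n_presences = s$n_presences,
      n_models_averaged = s$n_models_averaged,
      best_aic = s$best_aic,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
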