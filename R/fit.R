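#' Fit ecosystem vulnerability distributions to a survey dataset
#'
#' The front door of the package: runs the full analysis on a
#' [survey_dataset] and returns one classed object holding every stage's
#' result. The stages are (i) sequential VIF screening of the environmental
#' variables and standardization of the kept set; (ii) per-species
#' quadratic-logit distribution models fitted by all-subsets enumeration
#' with AIC-confidence-set coefficient averaging; (iii) site-specific
#' stressor-response curves of relative species richness for every
#' reference site and stressor; (iv) inversion of each curve at the impact
#' threshold into critical stressor levels and assembly into per-stressor
#' (and per-direction) vulnerability distributions; (v) overlay of each
#' supported EVD with the regional stressor distribution, site
#' classification and stressor ranking.
#'
#' @param data a [survey_dataset].
#' @param config an [evd_config].
#' @return an object of class `evd_fit` with components `screened`, `sdms`,
#'   `curves`, `levels`, `evds` (list keyed `stressor.direction`),
#'   `suitability`, `reports`, `ranking`, `dataset`, `config`, and a `log`
#'   of record counts.
#' @seealso [summary.evd_fit()], [plot.evd_fit()], [coef.evd_fit()]
#' @export
#' @examples
#' ls <- generate_landscape(default_landscape_spec(n_sites = 400,
#'                                                 n_species = 12,
#'                                                 seed = 7))
#' fit <- evd_fit(ls$dataset,
#'                evd_config(min_occurrences = 10, sweep_points = 201))
#' fit$ranking
evd_fit <- function(data, config = evd_config()) {
  stopifnot(inherits(data, "survey_dataset"))
  stopifnot(inherits(config, "evd_config"))
  candidates <- colnames(data$env)
  complete <- stats::complete.cases(data$env)
  env_mod <- data$env[complete, , drop = FALSE]
  screened <- screen_predictors(env_mod, candidates,
                                vif_limit = config$vif_limit)
  sdms <- fit_sdms(data, screened, config)
  curves <- response_curves(data, sdms, screened, config)

  levels_all <- list()
  evds <- list()
  suitability <- list()
  for (sv in names(curves)) {
    role <- data$roles[[sv]]
    lv <- invert_all(curves[[sv]], role, T = config$threshold_T)
    levels_all[[sv]] <- lv
    for (d in role_directions(role)) {
      key <- paste(sv, d, sep = ".")
      lv_d <- lv[lv$direction == d, , drop = FALSE]
      evds[[key]] <- build_evd(lv_d, stressor = sv, direction = d)
      suitability[[key]] <- evd_suitability(
        curves[[sv]], lv_d, T = config$threshold_T, direction = d,
        censored_cutoff = config$censored_cutoff,
        complex_cutoff = config$complex_cutoff)
    }
  }
  levels <- do.call(rbind, levels_all)
  rownames(levels) <- NULL

  reports <- list()
  for (key in names(evds)) {
    if (evds[[key]]$supported) {
      reports[[key]] <- classify_sites(evds[[key]], data$env)
    }
  }
  # worst-case combination for both-direction stressors, alongside the
  # two directional reports
  both_vars <- names(data$roles)[data$roles == "stressor_both"]
  for (sv in intersect(both_vars, names(curves))) {
    ki <- paste(sv, "increase", sep = "."); kd <- paste(sv, "decrease",
                                                        sep = ".")
    if (!is.null(reports[[ki]]) && !is.null(reports[[kd]])) {
      reports[[paste(sv, "both", sep = ".")]] <-
        combine_directions(reports[[ki]], reports[[kd]])
    }
  }
  ranking <- if (length(reports)) rank_stressors(reports) else NULL

  structure(
    list(dataset = data, config = config, screened = screened,
         sdms = sdms, curves = curves, levels = levels, evds = evds,
         suitability = unlist(suitability), reports = reports,
         ranking = ranking,
         log = list(
           n_sites = nrow(data$env),
           n_modelled_sites = length(attr(sdms, "modelled_sites")),
           n_dropped_sites = attr(sdms, "n_dropped_sites"),
           n_species_total = ncol(data$occ),
           n_species_modelled = length(sdms),
           n_reference = length(data$reference_ids),
           n_predictors_kept = length(screened$kept),
           n_predictors_dropped = nrow(screened$dropped)
         )),
    class = "evd_fit"
  )
}

#' @export
print.evd_fit <- function(x, ...) {
  lg <- x$log
  cat("Ecosystem vulnerability analysis\n")
  cat(sprintf(
    "  %d sites (%d reference), %d/%d species modelled, %d predictors kept\n",
    lg$n_sites, lg$n_reference, lg$n_species_modelled, lg$n_species_total,
    lg$n_predictors_kept))
  cat(sprintf("  impact threshold: %.0f%% richness loss\n",
              100 * x$config$threshold_T))
  supported <- vapply(x$evds, function(e) e$supported, logical(1))
  cat(sprintf("  EVDs: %d derived (%d supported)\n",
              length(x$evds), sum(supported)))
  if (!is.null(x$ranking)) {
    cat("  stressor ranking (top 3):\n")
    top <- utils::head(x$ranking, 3)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %d. %s (%s): %.1f%% impacted, %.1f%% at risk\n",
                  top$rank[i], top$stressor[i], top$direction[i],
                  100 * top$f_impacted[i], 100 * top$f_risk[i]))
    }
  }
  invisible(x)
}

#' @export
summary.evd_fit <- function(object, ...) {
  x <- object
  print(x)
  aucs <- vapply(x$sdms, function(s) s$auc, numeric(1))
  cat(sprintf(
    "\n  SDM accuracy: median AUC %.3f; %.0f%% of models with AUC > 0.7\n",
    stats::median(aucs), 100 * mean(aucs > 0.7)))
  cat("\n  EVD summaries:\n")
  for (key in names(x$evds)) {
    e <- x$evds[[key]]
    flag <- x$suitability[[key]]
    if (e$supported) {
      cat(sprintf("    %-24s [%0.4g, %0.4g], %d/%d uncensored (%s)\n",
                  key, e$range[1], e$range[2], e$n_uncensored,
                  e$n_reference, flag))
    } else {
      cat(sprintf("    %-24s unsupported: all sites censored (%s)\n",
                  key, flag))
    }
  }
  if (!is.null(x$ranking)) {
    cat("\n  full ranking:\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}

#' Averaged SDM coefficients of a fitted analysis
#' @param object an `evd_fit`.
#' @param ... unused.
#' @return data frame from [sdm_coefficients] (standardized and native
#'   scales).
#' @export
coef.evd_fit <- function(object, ...) {
  sdm_coefficients(object$sdms, object$screened)
}

#' Predict occurrence probabilities at new environmental conditions
#' @param object an `evd_fit`.
#' @param newdata matrix or data frame of native-unit environmental values
#'   covering the kept predictors; defaults to the fitted sites.
#' @param species species subset (default: all modelled).
#' @param ... unused.
#' @return site-by-species matrix of occurrence probabilities.
#' @export
predict.evd_fit <- function(object, newdata = NULL, species = NULL, ...) {
  if (is.null(newdata)) newdata <- object$dataset$env
  Z <- standardize_env(newdata, object$screened)
  if (is.null(species)) species <- names(object$sdms)
  out <- sapply(species, function(sp) predict(object$sdms[[sp]], Z))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = nrow(Z),
                  dimnames = list(rownames(Z), species))
  }
  out
}

#' Plot a fitted EVD analysis
#'
#' Three displays: `"curves"` draws the reference sites'
#' stressor-response curves with their points of departure and the
#' regional variability band; `"evd"` draws the empirical exceedance
#' (vulnerability) distribution with the regional median and band;
#' `"ranking"` draws the stacked not-at-risk / at-risk / impacted fractions
#' per stressor.
#'
#' @param x an `evd_fit`.
#' @param type one of `"curves"`, `"evd"`, `"ranking"`.
#' @param stressor stressor to plot (for `"curves"` and `"evd"`); default
#'   is the first available.
#' @param direction stress direction for `"evd"`.
#' @param ... passed to the underlying base-graphics calls.
#' @return invisibly, `x`.
#' @export
plot.evd_fit <- function(x, type = c("curves", "evd", "ranking"),
                         stressor = NULL, direction = NULL, ...) {
  type <- match.arg(type)
  if (type == "ranking") {
    plot_ranking(x, ...)
    return(invisible(x))
  }
  if (is.null(stressor)) stressor <- names(x$curves)[1]
  if (type == "curves") {
    plot_response_curves(x, stressor, ...)
  } else {
    keys <- names(x$evds)[startsWith(names(x$evds),
                                     paste0(stressor, "."))]
    if (!is.null(direction)) {
      keys <- paste(stressor, direction, sep = ".")
    }
    supported <- keys[vapply(keys, function(k)
      isTRUE(x$evds[[k]]$supported), logical(1))]
    if (!length(supported)) {
      stop("no supported EVD for '", stressor, "'", call. = FALSE)
    }
    plot_evd_curve(x, supported[1], ...)
  }
  invisible(x)
}

plot_response_curves <- function(x, stressor, ...) {
  curves <- x$curves[[stressor]]
  if (is.null(curves)) stop("no curves for '", stressor, "'",
                            call. = FALSE)
  grid <- curves[[1]]$grid
  band <- stats::quantile(x$dataset$env[, stressor],
                          x$config$band_quantiles, na.rm = TRUE)
  rng <- range(vapply(curves, function(cv) range(cv$rsr), numeric(2)))
  graphics::plot(NA, xlim = range(grid), ylim = rng,
                 xlab = stressor, ylab = "relative species richness", ...)
  graphics::rect(band[1], rng[1] - 1, band[2], rng[2] + 1,
                 col = grDevices::adjustcolor("grey85", 0.6), border = NA)
  for (cv in curves) {
    graphics::lines(cv$grid, cv$rsr, col = "grey30")
    graphics::points(cv$point_of_departure[["value"]], 1, pch = 19,
                     col = "steelblue")
  }
  graphics::abline(h = 1 - x$config$threshold_T, lty = 2, col = "firebrick")
}

plot_evd_curve <- function(x, key, ...) {
  e <- x$evds[[key]]
  vals <- x$dataset$env[, e$stressor]
  grid <- seq(min(vals, e$range[1], na.rm = TRUE),
              max(vals, e$range[2], na.rm = TRUE), length.out = 512)
  graphics::plot(grid, e$exceedance(grid), type = "s",
                 xlab = e$stressor,
                 ylab = "fraction of reference sites exceeded",
                 main = key, ylim = c(0, 1), ...)
  graphics::abline(v = stats::median(vals, na.rm = TRUE), col = "steelblue")
  band <- stats::quantile(vals, x$config$band_quantiles, na.rm = TRUE)
  graphics::abline(v = band, lty = 3)
}

plot_ranking <- function(x, ...) {
  if (is.null(x$ranking)) stop("no ranking available", call. = FALSE)
  rk <- x$ranking
  m <- t(as.matrix(rk[, c("f_impacted", "f_risk", "f_not")]))
  colnames(m) <- paste(rk$stressor, rk$direction, sep = "\n")
  graphics::barplot(m, col = c("firebrick", "goldenrod", "seagreen"),
                    ylab = "fraction of regional sites",
                    legend.text = c("impacted", "at risk", "not at risk"),
                    args.legend = list(x = "topright", bg = "white"), ...)
}
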