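#' Analysis configuration
#'
#' Collects every tunable parameter of an EVD analysis in one validated
#' object. Defaults follow common practice in community-level distribution
#' modelling: a 5% richness-loss impact threshold, a minimum of 20 presences
#' per modelled species, a VIF limit of 5 for collinearity screening, and a
#' two-AIC-unit confidence set for coefficient averaging.
#'
#' @param threshold_T fraction of relative species richness lost that defines
#'   the critical stressor level; strictly between 0 and 1.
#' @param min_occurrences minimum number of presences a species needs among
#'   modelled sites to receive a distribution model.
#' @param vif_limit variance inflation factor above (or at) which a predictor
#'   is removed during sequential screening.
#' @param delta_aic width of the AIC confidence set: models within
#'   `delta_aic` units of the best AIC contribute to the averaged
#'   coefficients.
#' @param sweep_points number of grid points for stressor sweeps (>= 3).
#' @param sweep_quantiles length-2 numeric, regional quantiles that clamp the
#'   sweep range (outlier exclusion); strictly ordered within [0, 1].
#' @param band_quantiles length-2 numeric, quantiles of the regional stressor
#'   distribution shown as the variability band on plots.
#' @param all_species_mode logical; if `TRUE`, response curves stack all
#'   modelled species at every reference site instead of only the species
#'   observed there (the "all species" EVD variant).
#' @param full_average logical; `TRUE` (default) averages coefficients over
#'   the whole confidence set treating a term as zero in models where it is
#'   absent (shrinkage/full averaging); `FALSE` averages only over models
#'   containing the term (conditional averaging).
#' @param use_aicc logical; use the small-sample corrected AICc instead of
#'   AIC for ranking and weighting.
#' @param auc_exclude optional AUC cutoff; species whose averaged model scores
#'   below it are dropped from curve stacking. `NA` (default) disables the
#'   filter, which mirrors its role as a robustness check rather than a
#'   primary selection rule.
#' @param coef_cap maximum absolute coefficient magnitude (standardized
#'   scale) beyond which a candidate fit is treated as separated and excluded
#'   from the confidence set.
#' @param censored_cutoff advisory fraction of censored reference sites above
#'   which an EVD is flagged `low_response`.
#' @param complex_cutoff advisory fraction of reference-site curves with two
#'   or more threshold crossings above which an EVD is flagged
#'   `complex_response`.
#' @param bounds named list of length-2 numeric vectors giving natural bounds
#'   for variables (e.g. a toxic-pressure fraction bounded to [0, 1]); sweep
#'   grids are clipped to these bounds.
#' @param random_seed integer seed governing all stochastic stages (data
#'   synthesis; fitting itself is deterministic).
#'
#' @return an object of class `evd_config` (a validated list).
#' @export
#' @examples
#' cfg <- evd_config(threshold_T = 0.10, sweep_points = 501)
#' cfg$threshold_T
evd_config <- function(threshold_T = 0.05,
                       min_occurrences = 20L,
                       vif_limit = 5,
                       delta_aic = 2,
                       sweep_points = 1001L,
                       sweep_quantiles = c(0.01, 0.99),
                       band_quantiles = c(0.05, 0.95),
                       all_species_mode = FALSE,
                       full_average = TRUE,
                       use_aicc = FALSE,
                       auc_exclude = NA_real_,
                       coef_cap = 15,
                       censored_cutoff = 0.5,
                       complex_cutoff = 0.25,
                       bounds = list(),
                       random_seed = 1L) {
  stopifnot(is.numeric(threshold_T), length(threshold_T) == 1L)
  if (!(threshold_T > 0 && threshold_T < 1)) {
    stop("threshold_T must lie strictly between 0 and 1", call. = FALSE)
  }
  min_occurrences <- as.integer(min_occurrences)
  if (is.na(min_occurrences) || min_occurrences < 0L) {
    stop("min_occurrences must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(vif_limit) || vif_limit <= 1) {
    stop("vif_limit must be a number greater than 1", call. = FALSE)
  }
  if (!is.numeric(delta_aic) || delta_aic < 0) {
    stop("delta_aic must be non-negative", call. = FALSE)
  }
  sweep_points <- as.integer(sweep_points)
  if (is.na(sweep_points) || sweep_points < 3L) {
    stop("sweep_points must be an integer >= 3", call. = FALSE)
  }
  check_q <- function(q, nm) {
    if (!is.numeric(q) || length(q) != 2L || anyNA(q) ||
        q[1] >= q[2] || q[1] < 0 || q[2] > 1) {
      stop(nm, " must be two strictly ordered values within [0, 1]",
           call. = FALSE)
    }
  }
  check_q(sweep_quantiles, "sweep_quantiles")
  check_q(band_quantiles, "band_quantiles")
  if (length(bounds)) {
    if (is.null(names(bounds)) || any(!nzchar(names(bounds)))) {
      stop("bounds must be a named list", call. = FALSE)
    }
    ok <- vapply(bounds, function(b) {
      is.numeric(b) && length(b) == 2L && !anyNA(b) && b[1] < b[2]
    }, logical(1))
    if (!all(ok)) {
      stop("each bounds entry must be a length-2 increasing numeric vector",
           call. = FALSE)
    }
  }
  structure(
    list(
      threshold_T = as.numeric(threshold_T),
      min_occurrences = min_occurrences,
      vif_limit = as.numeric(vif_limit),
      delta_aic = as.numeric(delta_aic),
      sweep_points = sweep_points,
      sweep_quantiles = as.numeric(sweep_quantiles),
      band_quantiles = as.numeric(band_quantiles),
      all_species_mode = isTRUE(all_species_mode),
      full_average = isTRUE(full_average),
      use_aicc = isTRUE(use_aicc),
      auc_exclude = as.numeric(auc_exclude),
      coef_cap = as.numeric(coef_cap),
      censored_cutoff = as.numeric(censored_cutoff),
      complex_cutoff = as.numeric(complex_cutoff),
      bounds = bounds,
      random_seed = as.integer(random_seed)
    ),
    class = "evd_config"
  )
}

#' @export
print.evd_config <- function(x, ...) {
  cat("EVD analysis configuration\n")
  cat(sprintf("  impact threshold T      : %g (%.0f%% richness loss)\n",
              x$threshold_T, 100 * x$threshold_T))
  cat(sprintf("  min occurrences/species : %d\n", x$min_occurrences))
  cat(sprintf("  VIF limit               : %g\n", x$vif_limit))
  cat(sprintf("  AIC confidence set      : delta <= %g (%s)\n",
              x$delta_aic, if (x$use_aicc) "AICc" else "AIC"))
  cat(sprintf("  sweep grid              : %d points over quantiles [%g, %g]\n",
              x$sweep_points, x$sweep_quantiles[1], x$sweep_quantiles[2]))
  cat(sprintf("  averaging               : %s\n",
              if (x$full_average) "full (absent terms = 0)" else "conditional"))
  cat(sprintf("  species pool            : %s\n",
              if (x$all_species_mode) "all modelled species" else
                "species observed at each site"))
  invisible(x)
}

# Build an evd_config from a plain list (e.g. a YAML `parameters:` section),
# accepting only known fields and falling back to defaults otherwise.
config_from_list <- function(params) {
  if (is.null(params)) return(evd_config())
  known <- names(formals(evd_config))
  extra <- setdiff(names(params), known)
  if (length(extra)) {
    stop("unknown configuration fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(evd_config, params)
}
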