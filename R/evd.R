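#' Invert a response curve at the impact threshold
#'
#' Starting from the point of departure (observed value, RSR = 1) and
#' moving along the chosen stress direction, finds the first grid interval
#' in which RSR crosses 1 - T and locates the critical stressor level by
#' linear interpolation. If the curve never reaches 1 - T before the grid
#' end, the site is censored at the grid endpoint.
#'
#' @param curve a `response_curve`.
#' @param T impact threshold (fraction of richness lost).
#' @param direction `"increase"` or `"decrease"`.
#' @return a one-row data frame (class retained) with columns `site_id`,
#'   `stressor`, `direction`, `level`, `censored`, `rsr_at_level`.
#' @export
invert_curve <- function(curve, T, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  target <- 1 - T
  path <- directional_path(curve, direction)
  s <- path$s; r <- path$r
  level <- NA_real_; censored <- TRUE; rsr_lvl <- NA_real_
  if (length(s) >= 2L) {
    below <- which(r[-1] <= target & r[-length(r)] > target)
    if (length(below)) {
      i <- below[1]
      frac <- (r[i] - target) / (r[i] - r[i + 1])
      level <- s[i] + frac * (s[i + 1] - s[i])
      censored <- FALSE
      rsr_lvl <- target
    }
  }
  if (censored) {
    level <- s[length(s)]
    rsr_lvl <- r[length(r)]
  }
  data.frame(site_id = curve$site_id, stressor = curve$stressor,
             direction = direction, level = level, censored = censored,
             rsr_at_level = rsr_lvl, stringsAsFactors = FALSE)
}

# Curve restated as a path leaving the point of departure in the stress
# direction: first element is (observed value, RSR = 1), then the grid
# points strictly beyond it, ordered outward.
directional_path <- function(curve, direction) {
  s0 <- curve$point_of_departure[["value"]]
  if (direction == "increase") {
    idx <- which(curve$grid > s0)
    s <- c(s0, curve$grid[idx])
    r <- c(1, curve$rsr[idx])
  } else {
    idx <- which(curve$grid < s0)
    s <- c(s0, rev(curve$grid[idx]))
    r <- c(1, rev(curve$rsr[idx]))
  }
  list(s = s, r = r)
}

# Number of crossings of the 1 - T level along the directional path
# (sign changes of RSR - (1 - T), either way).
count_crossings <- function(curve, T, direction) {
  path <- directional_path(curve, direction)
  d <- path$r - (1 - T)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(diff(sign(d)) != 0)
}

#' Assemble an ecosystem vulnerability distribution
#'
#' Collects the critical levels of all reference sites for one stressor and
#' direction into an empirical vulnerability distribution. The exceedance
#' function gives, at stressor value s, the fraction of reference sites
#' whose critical level has been passed when moving along the stress
#' direction; censored sites stay in the denominator but never count as
#' exceeded, so censoring dilutes rather than inflates risk. If every site
#' is censored the stressor is flagged unsupported (no usable EVD).
#'
#' @param levels data frame of per-site critical levels (rows from
#'   [invert_curve] for one stressor/direction).
#' @param stressor stressor name (defaults to the one in `levels`).
#' @param direction stress direction (defaults to the one in `levels`).
#' @return an object of class `evd` with fields `stressor`, `direction`,
#'   `levels`, `n_reference`, `supported`, `range` (native-unit min/max of
#'   uncensored levels, `NA` if unsupported) and `exceedance` (a
#'   vectorized function of native-unit stressor values).
#' @export
build_evd <- function(levels, stressor = NULL, direction = NULL) {
  levels <- as.data.frame(levels)
  if (is.null(stressor)) stressor <- unique(levels$stressor)
  if (is.null(direction)) direction <- unique(levels$direction)
  stopifnot(length(stressor) == 1L, length(direction) == 1L)
  if (nrow(levels) < 2L) {
    stop("an EVD needs at least two reference sites", call. = FALSE)
  }
  n_ref <- nrow(levels)
  unc <- levels$level[!levels$censored]
  supported <- length(unc) > 0L
  rng <- if (supported) range(unc) else c(NA_real_, NA_real_)
  exceed <- if (direction == "increase") {
    function(s) vapply(s, function(si) sum(unc <= si) / n_ref, numeric(1))
  } else {
    function(s) vapply(s, function(si) sum(unc >= si) / n_ref, numeric(1))
  }
  structure(
    list(stressor = stressor, direction = direction, levels = levels,
         n_reference = n_ref, n_uncensored = length(unc),
         supported = supported, range = rng, exceedance = exceed),
    class = "evd"
  )
}

#' @export
print.evd <- function(x, ...) {
  cat(sprintf("EVD for %s (%s direction): %d reference sites, %d uncensored\n",
              x$stressor, x$direction, x$n_reference, x$n_uncensored))
  if (x$supported) {
    cat(sprintf("  critical-level range: [%.4g, %.4g]\n",
                x$range[1], x$range[2]))
  } else {
    cat("  unsupported: every reference site is censored\n")
  }
  invisible(x)
}

#' Advisory suitability classification of a stressor's EVD
#'
#' Flags a stressor whose reference-site curves barely respond (a high
#' fraction of censored sites: `low_response`, the conductivity-like case)
#' or respond non-monotonically (many curves crossing the threshold more
#' than once: `complex_response`, the total-nitrogen-like case). The flag
#' is advisory: EVD emission proceeds unless every site is censored.
#'
#' @param curves list of `response_curve` objects (one per reference site).
#' @param levels data frame of critical levels for the same sites and
#'   direction.
#' @param T impact threshold.
#' @param direction stress direction.
#' @param censored_cutoff censored-site fraction above which the flag is
#'   `low_response`.
#' @param complex_cutoff multi-crossing curve fraction above which the flag
#'   is `complex_response`.
#' @return one of `"supported"`, `"low_response"`, `"complex_response"`.
#' @export
evd_suitability <- function(curves, levels, T, direction,
                            censored_cutoff = 0.5, complex_cutoff = 0.25) {
  frac_cens <- mean(levels$censored)
  if (frac_cens > censored_cutoff) return("low_response")
  crossings <- vapply(curves, count_crossings, integer(1),
                      T = T, direction = direction)
  if (mean(crossings >= 2L) > complex_cutoff) return("complex_response")
  "supported"
}

#' Critical levels for all reference curves of one stressor
#'
#' Convenience wrapper: inverts every reference site's curve in each
#' direction spawned by the variable's role.
#'
#' @param curves named list of `response_curve` objects for one stressor.
#' @param role the variable's role (decides the direction set).
#' @param T impact threshold.
#' @return data frame of critical levels (all sites x directions).
#' @export
invert_all <- function(curves, role, T) {
  dirs <- role_directions(role)
  if (!length(dirs)) {
    stop("covariate-role variables do not yield an EVD", call. = FALSE)
  }
  rows <- lapply(dirs, function(d) {
    do.call(rbind, lapply(curves, invert_curve, T = T, direction = d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exceedance curve of an EVD on a grid
#' @param evd an `evd` object.
#' @param grid native-unit stressor values.
#' @return data frame (stressor, direction, grid_value, exceedance).
#' @export
evd_exceedance_table <- function(evd, grid) {
  data.frame(stressor = evd$stressor, direction = evd$direction,
             grid_value = grid, exceedance = evd$exceedance(grid),
             stringsAsFactors = FALSE)
}
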