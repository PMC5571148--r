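#' Overlay an EVD with the regional stressor distribution
#'
#' Projects every regional site's observed stressor value on the stress
#' axis (for decrease-direction stressors, "more stress" means a lower
#' value) and compares it with the EVD range: before the range the stressor
#' is not limiting (`not_at_risk`), inside the range (endpoints inclusive)
#' the site is `at_risk`, and beyond the range the predicted richness loss
#' exceeds the threshold (`impacted`). Sites with a missing stressor value
#' are excluded and counted.
#'
#' @param evd a supported `evd` object.
#' @param env site-by-variable matrix of the regional sites (native units).
#' @return an object of class `overlay_report` with per-site
#'   classifications, the summary fractions `(f_not, f_risk, f_impacted)`
#'   and the EVD range.
#' @export
classify_sites <- function(evd, env) {
  if (!isTRUE(evd$supported)) {
    stop("EVD for '", evd$stressor, "' (", evd$direction,
         ") is unsupported (all reference sites censored)", call. = FALSE)
  }
  env <- as.matrix(env)
  if (!evd$stressor %in% colnames(env)) {
    stop("env lacks the stressor column '", evd$stressor, "'",
         call. = FALSE)
  }
  values <- env[, evd$stressor]
  ok <- !is.na(values)
  n_missing <- sum(!ok)
  sgn <- if (evd$direction == "increase") 1 else -1
  u <- sgn * values[ok]
  u_lo <- min(sgn * evd$range)
  u_hi <- max(sgn * evd$range)
  cls <- ifelse(u < u_lo, "not_at_risk",
                ifelse(u <= u_hi, "at_risk", "impacted"))
  classification <- data.frame(
    site_id = rownames(env)[ok], stressor = evd$stressor,
    direction = evd$direction, value = values[ok],
    classification = cls, stringsAsFactors = FALSE)
  n <- nrow(classification)
  fr <- c(f_not = sum(cls == "not_at_risk") / n,
          f_risk = sum(cls == "at_risk") / n,
          f_impacted = sum(cls == "impacted") / n)
  structure(
    list(stressor = evd$stressor, direction = evd$direction,
         classification = classification, fractions = fr,
         n_sites = n, n_missing = n_missing, evd_range = evd$range),
    class = "overlay_report"
  )
}

#' @export
print.overlay_report <- function(x, ...) {
  cat(sprintf(
    "Overlay for %s (%s): %d sites (%d missing excluded)\n",
    x$stressor, x$direction, x$n_sites, x$n_missing))
  cat(sprintf("  EVD range [%.4g, %.4g]\n", x$evd_range[1], x$evd_range[2]))
  cat(sprintf("  not at risk %.1f%% | at risk %.1f%% | impacted %.1f%%\n",
              100 * x$fractions["f_not"], 100 * x$fractions["f_risk"],
              100 * x$fractions["f_impacted"]))
  invisible(x)
}

#' Combine two directional overlays into a worst-case report
#'
#' For variables stressful in both directions (e.g. pH) the two directional
#' classifications are merged per site by severity
#' (impacted > at_risk > not_at_risk), yielding a single report usable in
#' the ranking alongside single-direction stressors. The directional
#' reports remain available separately.
#'
#' @param report_inc,report_dec the two directional `overlay_report`s of
#'   one stressor.
#' @return an `overlay_report` with `direction = "both"`.
#' @export
combine_directions <- function(report_inc, report_dec) {
  stopifnot(report_inc$stressor == report_dec$stressor)
  sev <- c(not_at_risk = 1L, at_risk = 2L, impacted = 3L)
  a <- report_inc$classification
  b <- report_dec$classification
  common <- intersect(a$site_id, b$site_id)
  a <- a[match(common, a$site_id), ]
  b <- b[match(common, b$site_id), ]
  worst <- ifelse(sev[a$classification] >= sev[b$classification],
                  a$classification, b$classification)
  classification <- data.frame(
    site_id = common, stressor = report_inc$stressor, direction = "both",
    value = a$value, classification = worst, stringsAsFactors = FALSE)
  n <- nrow(classification)
  fr <- c(f_not = sum(worst == "not_at_risk") / n,
          f_risk = sum(worst == "at_risk") / n,
          f_impacted = sum(worst == "impacted") / n)
  structure(
    list(stressor = report_inc$stressor, direction = "both",
         classification = classification, fractions = fr,
         n_sites = n,
         n_missing = max(report_inc$n_missing, report_dec$n_missing),
         evd_range = c(NA_real_, NA_real_)),
    class = "overlay_report"
  )
}

#' Rank stressors by the severity of their regional overlay
#'
#' Orders stressors by the fraction of impacted sites (descending), then by
#' the fraction at risk, then alphabetically. A stressor whose regional
#' values never reach the EVD range (`f_risk = f_impacted = 0`) is labelled
#' not identified: its EVD and the regional distribution do not overlap.
#'
#' @param reports list of `overlay_report` objects.
#' @return data frame (stressor, direction, f_not, f_risk, f_impacted,
#'   rank, identified) in rank order.
#' @export
rank_stressors <- function(reports) {
  if (!length(reports)) stop("no overlay reports to rank", call. = FALSE)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(stressor = r$stressor, direction = r$direction,
               f_not = unname(r$fractions["f_not"]),
               f_risk = unname(r$fractions["f_risk"]),
               f_impacted = unname(r$fractions["f_impacted"]),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-df$f_impacted, -df$f_risk, df$stressor, df$direction)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  df$identified <- df$f_risk > 0 | df$f_impacted > 0
  rownames(df) <- NULL
  df
}

#' Geo-referenced site classification table
#'
#' Joins the per-site classifications of every supported stressor with the
#' site coordinates, for mapping which locations sit below, within or above
#' the EVD ranges. Sites without coordinates are omitted with a count.
#'
#' @param reports list of `overlay_report` objects.
#' @param dataset the [survey_dataset] (supplies coordinates).
#' @return data frame (site_id, x, y, stressor, direction, classification);
#'   empty with a warning if no site has coordinates.
#' @export
site_map_table <- function(reports, dataset) {
  empty <- data.frame(site_id = character(0), x = numeric(0),
                      y = numeric(0), stressor = character(0),
                      direction = character(0),
                      classification = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(dataset$coords) || !nrow(dataset$coords)) {
    warning("no site coordinates available; site map table skipped")
    return(empty)
  }
  rows <- lapply(reports, function(r) {
    cl <- r$classification
    m <- merge(dataset$coords, cl[c("site_id", "stressor", "direction",
                                    "classification")], by = "site_id")
    m
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty)
  n_dropped <- sum(vapply(reports,
                          function(r) sum(!r$classification$site_id %in%
                                            dataset$coords$site_id),
                          numeric(1)))
  if (n_dropped > 0) {
    message(n_dropped,
            " site classification(s) without coordinates omitted from the map table")
  }
  rownames(out) <- NULL
  out[order(out$stressor, out$direction, out$site_id), ]
}
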