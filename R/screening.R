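#' Variance inflation factor of one variable against the others
#'
#' VIF = 1 / (1 - R^2), where R^2 comes from the ordinary least-squares
#' regression of the target variable on all other candidate variables.
#' Returns `Inf` when the target is an exact linear combination of the
#' others (R^2 = 1 within numerical tolerance).
#'
#' @param env numeric matrix of site-by-variable values with no missing
#'   values among the rows used.
#' @param variable name of the target column.
#' @param candidates optional character vector restricting the predictor
#'   pool; defaults to all columns of `env`.
#' @return a single numeric VIF (possibly `Inf`).
#' @export
vif <- function(env, variable, candidates = colnames(env)) {
  env <- as.matrix(env)
  if (!variable %in% candidates) {
    stop("variable '", variable, "' is not among the candidates",
         call. = FALSE)
  }
  others <- setdiff(candidates, variable)
  if (!length(others)) return(1)
  if (anyNA(env[, candidates])) {
    stop("missing values among modelled sites; drop incomplete rows first",
         call. = FALSE)
  }
  p <- length(others)
  if (nrow(env) < p + 2L) {
    stop(sprintf(
      "unidentifiable regression: %d sites for %d predictors (need >= %d)",
      nrow(env), p, p + 2L), call. = FALSE)
  }
  y <- env[, variable]
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    stop("variable '", variable, "' has zero variance", call. = FALSE)
  }
  X <- cbind(1, env[, others, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

#' Sequential VIF screening of candidate predictors
#'
#' Repeatedly removes the single candidate with the highest VIF while any
#' VIF is at or above `vif_limit`, then records per-variable
#' standardization parameters (mean and sample standard deviation over the
#' modelled sites). Ties in the maximum VIF -- e.g. an exactly duplicated
#' pair, both at `Inf` -- are broken by removing the variable that appears
#' later in the candidate order, so screening is deterministic and
#' column-order invariant up to that documented rule.
#'
#' @param env numeric site-by-variable matrix (modelled sites only, no
#'   missing values among the candidates).
#' @param candidates character vector of columns to screen; defaults to all.
#' @param vif_limit removal threshold (default 5).
#' @return an object of class `screened_predictors` with fields `kept`
#'   (ordered as in `candidates`), `dropped` (data frame of variable and VIF
#'   at removal), `center` and `scale` (named numeric vectors for the kept
#'   variables), and `n_sites`.
#' @export
screen_predictors <- function(env, candidates = colnames(env),
                              vif_limit = 5) {
  env <- as.matrix(env)
  absent <- setdiff(candidates, colnames(env))
  if (length(absent)) {
    stop("candidates absent from env: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  current <- candidates
  dropped <- data.frame(variable = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    if (!length(current)) {
      stop("all candidate predictors were eliminated; no model is possible",
           call. = FALSE)
    }
    if (length(current) == 1L) break
    vifs <- vapply(current, function(v) vif(env, v, current), numeric(1))
    if (max(vifs) < vif_limit) break
    # ties: the later variable in the input order goes
    worst <- max(vifs)
    tied <- which(vifs == worst)
    out_idx <- tied[length(tied)]
    dropped <- rbind(dropped, data.frame(variable = current[out_idx],
                                         vif = worst,
                                         stringsAsFactors = FALSE))
    current <- current[-out_idx]
  }
  ctr <- colMeans(env[, current, drop = FALSE])
  scl <- apply(env[, current, drop = FALSE], 2, stats::sd)
  if (any(scl <= 0)) {
    stop("zero-variance column(s): ",
         paste(current[scl <= 0], collapse = ", "), call. = FALSE)
  }
  final_vif <- if (length(current) > 1L) {
    vapply(current, function(v) vif(env, v, current), numeric(1))
  } else {
    stats::setNames(1, current)
  }
  structure(
    list(kept = current, dropped = dropped,
         center = ctr, scale = scl, n_sites = nrow(env),
         vif_limit = vif_limit),
    class = "screened_predictors",
    final_vif = final_vif
  )
}

#' @export
print.screened_predictors <- function(x, ...) {
  cat(sprintf("Predictor screening (VIF limit %g, %d sites)\n",
              x$vif_limit, x$n_sites))
  cat("  kept   :", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:",
        paste(sprintf("%s (VIF %.3g)", x$dropped$variable, x$dropped$vif),
              collapse = ", "), "\n")
  } else {
    cat("  dropped: none\n")
  }
  invisible(x)
}

#' Standardize environmental columns with stored parameters
#'
#' Centres and scales the kept columns with the mean and sample (n - 1)
#' standard deviation recorded at screening time, so that sweep grids and
#' new sites are projected onto exactly the scale the models were fitted on.
#'
#' @param env matrix or data frame holding at least the kept columns.
#' @param screened a `screened_predictors` object.
#' @return numeric matrix of standardized values, columns ordered as
#'   `screened$kept`.
#' @export
standardize_env <- function(env, screened) {
  env <- as.matrix(env)
  missing <- setdiff(screened$kept, colnames(env))
  if (length(missing)) {
    stop("env lacks kept column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- env[, screened$kept, drop = FALSE]
  sweep(sweep(z, 2, screened$center[screened$kept]), 2,
        screened$scale[screened$kept], "/")
}

#' Invert a standardization back to native units
#' @param z standardized matrix with columns among `screened$kept`.
#' @param screened a `screened_predictors` object.
#' @return matrix in native units.
#' @export
unstandardize_env <- function(z, screened) {
  z <- as.matrix(z)
  vars <- colnames(z)
  sweep(sweep(z, 2, screened$scale[vars], "*"), 2,
        -screened$center[vars], "-")
}

#' Screening report as a data frame
#' @param screened a `screened_predictors` object.
#' @return data frame with columns variable, status, vif (final VIF for kept
#'   variables, VIF at removal for dropped ones).
#' @export
screening_report <- function(screened) {
  kept_vif <- if (length(screened$kept) > 1L) {
    # final VIFs are recomputable only with the data; stored at screen time
    attr(screened, "final_vif")
  } else NULL
  df_kept <- data.frame(variable = screened$kept, status = "kept",
                        vif = if (is.null(kept_vif)) NA_real_ else
                          kept_vif[screened$kept],
                        stringsAsFactors = FALSE)
  df_drop <- if (nrow(screened$dropped)) {
    data.frame(variable = screened$dropped$variable, status = "dropped",
               vif = screened$dropped$vif, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(0), status = character(0),
               vif = numeric(0), stringsAsFactors = FALSE)
  }
  rbind(df_kept, df_drop)
}
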