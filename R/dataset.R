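#' Survey dataset: joined environment, occurrence and reference-site tables
#'
#' The single observational input of an EVD analysis: a site-by-environment
#' matrix, a site-by-species presence/absence matrix on the identical site
#' index, a set of reference-site identifiers, and a role for every
#' environmental variable. Roles distinguish variables whose increase is
#' stressful (`stressor_increase`, e.g. nutrient loads or toxic pressure),
#' whose decrease is stressful (`stressor_decrease`, e.g. a habitat-quality
#' index), whose departure in either direction is stressful
#' (`stressor_both`, e.g. pH), and natural covariates (`covariate`, e.g.
#' drainage area) that are modelled but never swept into an EVD.
#'
#' @param env numeric matrix or data frame of environmental values, one row
#'   per site; row names (or a `site_id` column) identify sites.
#' @param occ matrix or data frame of 0/1 species occurrences on the same
#'   site index.
#' @param reference_ids character vector of reference-site identifiers; at
#'   least two (a vulnerability distribution over one site is degenerate).
#' @param roles named character vector mapping every environmental variable
#'   to one of `"stressor_increase"`, `"stressor_decrease"`,
#'   `"stressor_both"`, `"covariate"`.
#' @param coords optional data frame with columns `site_id`, `x`, `y`
#'   (arbitrary coordinate system, passed through for the site map table).
#'
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(env, occ, reference_ids, roles, coords = NULL) {
  env <- as_site_matrix(env, "env")
  occ <- as_site_matrix(occ, "occ")
  if (anyDuplicated(rownames(env))) {
    stop("duplicate site_id in env table: ",
         paste(unique(rownames(env)[duplicated(rownames(env))]),
               collapse = ", "), call. = FALSE)
  }
  if (!identical(sort(rownames(env)), sort(rownames(occ)))) {
    only_env <- setdiff(rownames(env), rownames(occ))
    only_occ <- setdiff(rownames(occ), rownames(env))
    stop("env and occ site universes differ. Only in env: ",
         paste(utils::head(only_env, 10), collapse = ", "),
         "; only in occ: ",
         paste(utils::head(only_occ, 10), collapse = ", "), call. = FALSE)
  }
  occ <- occ[rownames(env), , drop = FALSE]
  bad <- which(!(occ %in% c(0, 1)) | is.na(occ))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(occ))
    stop(sprintf(
      "occurrence values must be 0 or 1; first offending cell: site '%s', species '%s', value %s",
      rownames(occ)[i[1]], colnames(occ)[i[2]], occ[bad[1]]), call. = FALSE)
  }
  reference_ids <- as.character(reference_ids)
  orphan <- setdiff(reference_ids, rownames(env))
  if (length(orphan)) {
    stop("reference ids not present among sites: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (length(reference_ids) < 2L) {
    stop("at least two reference sites are required", call. = FALSE)
  }
  roles <- validate_roles(roles, colnames(env))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("site_id", "x", "y")
    if (!all(need %in% names(coords))) {
      stop("coords must have columns site_id, x, y", call. = FALSE)
    }
    coords <- coords[coords$site_id %in% rownames(env), need]
  }
  structure(
    list(env = env, occ = occ, reference_ids = reference_ids,
         roles = roles, coords = coords),
    class = "survey_dataset"
  )
}

as_site_matrix <- function(x, what) {
  if (is.data.frame(x)) {
    if ("site_id" %in% names(x)) {
      ids <- as.character(x$site_id)
      x <- x[setdiff(names(x), "site_id")]
      m <- as.matrix(x)
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
    }
  } else {
    m <- as.matrix(x)
  }
  if (is.null(rownames(m))) {
    stop(what, " table must carry site identifiers (row names or a site_id column)",
         call. = FALSE)
  }
  if (!is.numeric(m)) {
    stop(what, " table must be numeric", call. = FALSE)
  }
  m
}

role_levels <- c("stressor_increase", "stressor_decrease",
                 "stressor_both", "covariate")

validate_roles <- function(roles, variables) {
  roles <- unlist(roles)
  if (is.null(names(roles)) || any(!nzchar(names(roles)))) {
    stop("roles must be a named vector (variable -> role)", call. = FALSE)
  }
  bad_role <- setdiff(unique(roles), role_levels)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         "; valid roles are ", paste(role_levels, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(names(roles), variables)
  if (length(absent)) {
    stop("role assigned to variable(s) absent from env: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(variables, names(roles))
  if (length(missing)) {
    stop("every environmental variable needs a role; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(roles))) {
    stop("each variable must have exactly one role", call. = FALSE)
  }
  if (!any(roles != "covariate")) {
    stop("no stressors configured: at least one variable needs a stressor role",
         call. = FALSE)
  }
  roles[variables]
}

#' Names of the stressor-role variables of a dataset
#' @param dataset a `survey_dataset`.
#' @return character vector of variable names with a stressor role.
#' @export
stressor_variables <- function(dataset) {
  names(dataset$roles)[dataset$roles != "covariate"]
}

# Stress directions spawned by a variable's role: increase, decrease or both.
role_directions <- function(role) {
  switch(role,
         stressor_increase = "increase",
         stressor_decrease = "decrease",
         stressor_both = c("increase", "decrease"),
         covariate = character(0))
}

#' Load a survey dataset from delimited-text tables
#'
#' Reads a wide site-by-environment table, a wide site-by-species 0/1 table
#' and a plain-text list of reference-site identifiers, validates their
#' mutual consistency and returns a [survey_dataset]. Repeated rows for the
#' same `site_id` (repeat samplings) are collapsed to the per-site median for
#' environmental variables and to the maximum (ever observed = present) for
#' occurrences; coordinates collapse to the median.
#'
#' @param env_table path to a CSV with a `site_id` column, optional `x`/`y`
#'   coordinate columns, and one column per environmental variable.
#' @param occ_table path to a CSV with a `site_id` column and one 0/1 column
#'   per species.
#' @param reference_list path to a text file with one reference `site_id`
#'   per line (or a single-column CSV headed `site_id`).
#' @param roles named character vector or list, variable -> role; see
#'   [survey_dataset].
#' @return a validated [survey_dataset].
#' @export
load_dataset <- function(env_table, occ_table, reference_list, roles) {
  for (f in c(env_table, occ_table, reference_list)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  env_raw <- utils::read.csv(env_table, check.names = FALSE,
                             stringsAsFactors = FALSE)
  occ_raw <- utils::read.csv(occ_table, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!"site_id" %in% names(env_raw)) {
    stop("env table lacks a site_id column", call. = FALSE)
  }
  if (!"site_id" %in% names(occ_raw)) {
    stop("occ table lacks a site_id column", call. = FALSE)
  }
  ref_lines <- readLines(reference_list, warn = FALSE)
  ref_lines <- trimws(ref_lines)
  ref_lines <- ref_lines[nzchar(ref_lines)]
  ref_lines <- setdiff(ref_lines, "site_id")

  coord_cols <- intersect(c("x", "y"), names(env_raw))
  env_c <- collapse_sites(env_raw, fun = function(v) stats::median(v))
  occ_c <- collapse_sites(occ_raw, fun = function(v) max(v))
  coords <- NULL
  if (length(coord_cols) == 2L) {
    coords <- env_c[c("site_id", "x", "y")]
    env_c <- env_c[setdiff(names(env_c), coord_cols)]
  } else if (length(coord_cols) == 1L) {
    env_c <- env_c[setdiff(names(env_c), coord_cols)]
  }
  survey_dataset(env = env_c, occ = occ_c, reference_ids = ref_lines,
                 roles = roles, coords = coords)
}

# Collapse repeated site_id rows with the supplied per-column summary.
# NA-tolerant: the summary sees only the non-missing values; an all-missing
# group stays missing.
collapse_sites <- function(df, fun) {
  ids <- as.character(df$site_id)
  vars <- setdiff(names(df), "site_id")
  uid <- unique(ids)
  out <- data.frame(site_id = uid, stringsAsFactors = FALSE)
  for (v in vars) {
    col <- df[[v]]
    if (!is.numeric(col)) {
      col <- suppressWarnings(as.numeric(col))
    }
    out[[v]] <- vapply(uid, function(id) {
      vals <- col[ids == id]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(NA_real_)
      fun(vals)
    }, numeric(1))
  }
  out
}

#' Write a table to delimited text with lossless numeric precision
#'
#' All tabular outputs of the pipeline go through this writer. Numeric
#' columns are serialized with 17 significant digits so that a read/write
#' round trip reproduces every double bit-for-bit.
#'
#' @param records a data frame (non-empty schema).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  if (!ncol(records)) stop("refusing to write a table with no columns",
                           call. = FALSE)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a table written by [write_table]
#' @param path file path.
#' @return a data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    stop("required artifact not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Survey dataset\n")
  cat(sprintf("  sites      : %d (%d reference)\n",
              nrow(x$env), length(x$reference_ids)))
  cat(sprintf("  variables  : %d (%d with a stressor role)\n",
              ncol(x$env), sum(x$roles != "covariate")))
  cat(sprintf("  species    : %d\n", ncol(x$occ)))
  if (!is.null(x$coords)) {
    cat(sprintf("  coordinates: %d sites\n", nrow(x$coords)))
  }
  invisible(x)
}

#' @export
summary.survey_dataset <- function(object, ...) {
  prev <- colMeans(object$occ)
  cat("Survey dataset summary\n")
  print(object)
  cat("  species prevalence (fraction of sites):\n")
  print(summary(prev))
  cat("  variable roles:\n")
  print(object$roles)
  invisible(object)
}
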