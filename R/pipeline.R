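#' Staged analysis pipeline with plain-text artifacts
#'
#' Runs the analysis as a sequence of stages -- `simulate` (optional),
#' `screen`, `fit`, `curves`, `evd`, `overlay` -- each of which reads the
#' previous stage's CSV artifacts from the output directory and writes its
#' own, so any stage can be rerun in isolation and every intermediate is
#' inspectable and diffable. Numeric columns are serialized losslessly, so
#' a staged rerun reproduces the monolithic run bit-for-bit.
#'
#' The configuration is a YAML file (or equivalent list) with sections:
#' \describe{
#'   \item{data}{paths `env`, `occ`, `reference` and a `roles` map, for
#'     observed datasets.}
#'   \item{synthetic}{alternatively, `n_sites`, `n_species`, `n_reference`
#'     for a virtual landscape generated by [default_landscape_spec] with
#'     the run seed.}
#'   \item{parameters}{any field of [evd_config].}
#' }
#'
#' @param config path to a YAML configuration file, or an equivalent list.
#' @param outdir output directory (created if needed).
#' @param stages which stages to run, in order; default all applicable.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "screen", "fit", "curves",
                                    "evd", "overlay")) {
  cfg <- load_run_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(cfg$synthetic)) stages <- setdiff(stages, "simulate")
  for (st in stages) {
    run_stage(st, cfg, outdir)
  }
  write_manifest(cfg, outdir)
  invisible(outdir)
}

#' Run one pipeline stage from cached artifacts
#' @param stage one of `"simulate"`, `"screen"`, `"fit"`, `"curves"`,
#'   `"evd"`, `"overlay"`.
#' @param config configuration path or list (see [run_pipeline]).
#' @param outdir output directory holding the upstream artifacts.
#' @return the output directory, invisibly.
#' @export
run_stage <- function(stage, config, outdir) {
  cfg <- load_run_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(cfg, outdir),
         screen = stage_screen(cfg, outdir),
         fit = stage_fit(cfg, outdir),
         curves = stage_curves(cfg, outdir),
         evd = stage_evd(cfg, outdir),
         overlay = stage_overlay(cfg, outdir),
         stop("unknown stage '", stage, "'", call. = FALSE))
  invisible(outdir)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  if (is.null(config$data) && is.null(config$synthetic)) {
    stop("config needs a 'data' or a 'synthetic' section", call. = FALSE)
  }
  config$parameters <- config_from_list(config$parameters)
  config
}

run_log <- function(outdir, ...) {
  line <- paste0(...)
  message(line)
  cat(line, "\n", sep = "", file = file.path(outdir, "run.log"),
      append = TRUE)
}

# ---- dataset resolution -------------------------------------------------

pipeline_dataset <- function(cfg, outdir) {
  if (!is.null(cfg$synthetic)) {
    env_f <- file.path(outdir, "env.csv")
    if (!file.exists(env_f)) {
      stop("missing upstream artifact '", env_f,
           "'; run the simulate stage first", call. = FALSE)
    }
    roles <- yaml::read_yaml(file.path(outdir, "roles.yaml"))
    load_dataset(env_f, file.path(outdir, "occ.csv"),
                 file.path(outdir, "reference_sites.txt"),
                 roles = unlist(roles))
  } else {
    load_dataset(cfg$data$env, cfg$data$occ, cfg$data$reference,
                 roles = unlist(cfg$data$roles))
  }
}

stage_simulate <- function(cfg, outdir) {
  syn <- cfg$synthetic
  spec <- default_landscape_spec(
    n_sites = syn$n_sites %||% 2000L,
    n_species = syn$n_species %||% 30L,
    n_reference = syn$n_reference %||% 18L,
    seed = cfg$parameters$random_seed)
  ls <- generate_landscape(spec)
  ds <- ls$dataset
  env_df <- data.frame(site_id = rownames(ds$env), ds$env,
                       check.names = FALSE, stringsAsFactors = FALSE)
  env_df <- merge(env_df, ds$coords, by = "site_id", sort = TRUE)
  write_table(env_df, file.path(outdir, "env.csv"))
  occ_df <- data.frame(site_id = rownames(ds$occ), ds$occ,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_table(occ_df, file.path(outdir, "occ.csv"))
  writeLines(sort(ds$reference_ids),
             file.path(outdir, "reference_sites.txt"))
  yaml::write_yaml(as.list(ds$roles), file.path(outdir, "roles.yaml"))
  run_log(outdir, "simulate: ", nrow(ds$env), " sites, ", ncol(ds$occ),
          " species, ", length(ds$reference_ids), " reference sites (seed ",
          cfg$parameters$random_seed, ")")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_screen <- function(cfg, outdir) {
  ds <- pipeline_dataset(cfg, outdir)
  complete <- stats::complete.cases(ds$env)
  screened <- screen_predictors(ds$env[complete, , drop = FALSE],
                                colnames(ds$env),
                                vif_limit = cfg$parameters$vif_limit)
  write_table(screening_report(screened),
              file.path(outdir, "screening.csv"))
  write_table(data.frame(variable = screened$kept,
                         center = unname(screened$center),
                         scale = unname(screened$scale),
                         n_sites = screened$n_sites,
                         stringsAsFactors = FALSE),
              file.path(outdir, "standardization.csv"))
  run_log(outdir, "screen: kept ", length(screened$kept), " of ",
          ncol(ds$env), " variables (",
          paste(screened$dropped$variable, collapse = ", "),
          if (nrow(screened$dropped)) " dropped" else "none dropped", ")")
}

read_screened <- function(outdir) {
  std <- read_table(file.path(outdir, "standardization.csv"))
  scr <- read_table(file.path(outdir, "screening.csv"))
  dropped <- scr[scr$status == "dropped", c("variable", "vif")]
  structure(
    list(kept = std$variable,
         dropped = dropped,
         center = stats::setNames(std$center, std$variable),
         scale = stats::setNames(std$scale, std$variable),
         n_sites = std$n_sites[1],
         vif_limit = NA_real_),
    class = "screened_predictors"
  )
}

stage_fit <- function(cfg, outdir) {
  ds <- pipeline_dataset(cfg, outdir)
  screened <- read_screened(outdir)
  sdms <- fit_sdms(ds, screened, cfg$parameters)
  write_table(sdm_coefficients(sdms, screened),
              file.path(outdir, "sdm_coefficients.csv"))
  aucs <- vapply(sdms, function(s) s$auc, numeric(1))
  run_log(outdir, "fit: ", length(sdms), " species modelled over ",
          length(attr(sdms, "modelled_sites")), " sites (",
          attr(sdms, "n_dropped_sites"),
          " incomplete sites dropped); median AUC ",
          sprintf("%.3f", stats::median(aucs)))
}

read_sdms <- function(outdir, screened) {
  tab <- read_table(file.path(outdir, "sdm_coefficients.csv"))
  kept <- screened$kept
  out <- lapply(split(tab, tab$species), function(d) {
    ic <- d[d$variable == "(Intercept)", ]
    terms <- d[d$variable != "(Intercept)", ]
    lin <- stats::setNames(numeric(length(kept)), kept)
    quad <- stats::setNames(numeric(length(kept)), kept)
    lin[terms$variable] <- terms$linear_std
    quad[terms$variable] <- terms$quadratic_std
    structure(
      list(species = d$species[1], predictors = kept,
           intercept = ic$linear_std, linear = lin, quadratic = quad,
           n_models_averaged = ic$n_models_averaged,
           best_aic = ic$best_aic, n_presences = ic$n_presences,
           n_sites = NA_integer_, n_candidates = NA_integer_,
           n_excluded = NA_integer_, auc = ic$auc),
      class = "averaged_sdm")
  })
  out[unique(tab$species)]
}

stage_curves <- function(cfg, outdir) {
  ds <- pipeline_dataset(cfg, outdir)
  screened <- read_screened(outdir)
  sdms <- read_sdms(outdir, screened)
  complete <- stats::complete.cases(ds$env[, screened$kept, drop = FALSE])
  attr(sdms, "modelled_sites") <- rownames(ds$env)[complete]
  curves <- response_curves(ds, sdms, screened, cfg$parameters)
  write_table(curves_to_table(curves),
              file.path(outdir, "response_curves.csv"))
  run_log(outdir, "curves: ", length(curves), " stressor(s) x ",
          length(curves[[1]]), " reference site(s), ",
          cfg$parameters$sweep_points, " grid points")
}

read_curves <- function(outdir) {
  tab <- read_table(file.path(outdir, "response_curves.csv"))
  out <- list()
  for (sv in unique(tab$stressor)) {
    sub <- tab[tab$stressor == sv, ]
    curves <- lapply(split(sub, sub$site_id), function(d) {
      d <- d[order(d$grid_value), ]
      structure(
        list(site_id = d$site_id[1], stressor = sv, grid = d$grid_value,
             rsr = d$rsr,
             point_of_departure = c(value = d$pod_value[1], rsr = 1),
             richness_at_reference = d$richness_at_reference[1],
             species_pool = NULL),
        class = "response_curve")
    })
    out[[sv]] <- curves[unique(sub$site_id)]
  }
  out
}

stage_evd <- function(cfg, outdir) {
  ds <- pipeline_dataset(cfg, outdir)
  curves <- read_curves(outdir)
  T <- cfg$parameters$threshold_T
  levels_all <- list(); exceed_all <- list(); suit <- character(0)
  for (sv in names(curves)) {
    role <- ds$roles[[sv]]
    lv <- invert_all(curves[[sv]], role, T = T)
    levels_all[[sv]] <- lv
    for (d in role_directions(role)) {
      key <- paste(sv, d, sep = ".")
      lv_d <- lv[lv$direction == d, , drop = FALSE]
      e <- build_evd(lv_d, sv, d)
      suit[key] <- evd_suitability(curves[[sv]], lv_d, T, d,
                                   cfg$parameters$censored_cutoff,
                                   cfg$parameters$complex_cutoff)
      if (e$supported) {
        grid <- curves[[sv]][[1]]$grid
        exceed_all[[key]] <- evd_exceedance_table(e, grid)
      }
    }
  }
  levels <- do.call(rbind, levels_all); rownames(levels) <- NULL
  write_table(levels, file.path(outdir, "critical_levels.csv"))
  if (length(exceed_all)) {
    write_table(do.call(rbind, exceed_all),
                file.path(outdir, "evd_exceedance.csv"))
  }
  write_table(data.frame(evd = names(suit), suitability = unname(suit),
                         stringsAsFactors = FALSE),
              file.path(outdir, "evd_suitability.csv"))
  run_log(outdir, "evd: ", length(suit), " stressor-direction EVD(s); ",
          sum(levels$censored), "/", nrow(levels), " site levels censored")
}

stage_overlay <- function(cfg, outdir) {
  ds <- pipeline_dataset(cfg, outdir)
  levels <- read_table(file.path(outdir, "critical_levels.csv"))
  reports <- list()
  for (sv in unique(levels$stressor)) {
    for (d in unique(levels$direction[levels$stressor == sv])) {
      lv <- levels[levels$stressor == sv & levels$direction == d, ]
      e <- build_evd(lv, sv, d)
      if (e$supported) {
        reports[[paste(sv, d, sep = ".")]] <- classify_sites(e, ds$env)
      }
    }
  }
  both_vars <- names(ds$roles)[ds$roles == "stressor_both"]
  for (sv in both_vars) {
    ki <- paste(sv, "increase", sep = ".")
    kd <- paste(sv, "decrease", sep = ".")
    if (!is.null(reports[[ki]]) && !is.null(reports[[kd]])) {
      reports[[paste(sv, "both", sep = ".")]] <-
        combine_directions(reports[[ki]], reports[[kd]])
    }
  }
  if (!length(reports)) {
    stop("no supported EVD; overlay stage has nothing to classify",
         call. = FALSE)
  }
  cls <- do.call(rbind, lapply(reports, function(r) r$classification))
  rownames(cls) <- NULL
  write_table(cls, file.path(outdir, "overlay_classification.csv"))
  ranking <- rank_stressors(reports)
  write_table(ranking, file.path(outdir, "ranking.csv"))
  map_tab <- tryCatch(site_map_table(reports, ds),
                      warning = function(w) NULL)
  if (!is.null(map_tab) && nrow(map_tab)) {
    write_table(map_tab, file.path(outdir, "site_map.csv"))
  }
  run_log(outdir, "overlay: ", length(reports), " report(s); top stressor ",
          ranking$stressor[1], " (", ranking$direction[1], "), impacted ",
          sprintf("%.1f%%", 100 * ranking$f_impacted[1]))
}

write_manifest <- function(cfg, outdir) {
  digests <- list()
  if (!is.null(cfg$data)) {
    files <- unlist(cfg$data[c("env", "occ", "reference")])
    digests <- as.list(tools::md5sum(files))
  } else {
    files <- file.path(outdir, c("env.csv", "occ.csv",
                                 "reference_sites.txt"))
    digests <- as.list(tools::md5sum(files[file.exists(files)]))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("evdist")),
    seed = cfg$parameters$random_seed,
    parameters = unclass(cfg$parameters),
    input_digests = digests
  )
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))
}
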