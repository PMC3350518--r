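# Configuration, orchestration, logging and report generation for
# reproducible end-to-end runs: simulate/load -> sdm -> gdm -> rad ->
# maps, all artefacts written under one output directory.

#' Default run configuration
#'
#' The configuration has exactly one data source: either a `simulate`
#' block (grid, pool and survey parameters) or a `data` block (paths to
#' samples/abundance/grid CSVs). Per-stage seeds are derived from the
#' mandatory global seed by fixed offsets so stages can be re-run
#' independently.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, out_dir = "results/run") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(n_lon = 50, n_lat = 50, n_sites = 39,
                    n_species = 493, n_archetypes = 12,
                    area_range = c(160, 2500)),
    data = NULL,
    stages = c("sdm", "gdm", "rad"),
    sdm = list(n_top = 4, min_occurrences = 10, learning_rate = 0.05,
               n_trees = 300, tree_depth = 2, bag_fraction = 0.5,
               n_folds = 10),
    gdm = list(predictors = c("depth", "mud", "sand", "carbonate",
                              "temperature_mean", "salinity_mean",
                              "nitrate_mean", "phosphate_mean",
                              "temperature_sd", "salinity_sd"),
               n_basis = 3, anchor_count = 300),
    rad = list(
      abundance_candidates = c("carbonate", "sand", "mud", "gravel",
                               "nitrate_mean", "depth"),
      richness_candidates = c("log_N_scale", "N_scale", "nitrate_mean",
                              "sand", "sand:nitrate_mean"),
      evenness_candidates = c("N_scale", "N_scale2", "N_scale3",
                              "S_scale", "S_scale2"),
      reference_area = 1000, n_draws = 200)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; a `seed` is mandatory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config error: seed is mandatory")
  cfg <- default_run_config(seed = raw$seed)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, raw)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: seed is mandatory")
  has_sim <- !is.null(cfg$simulate)
  has_data <- !is.null(cfg$data)
  if (has_sim == has_data)
    stop("config error: exactly one of 'simulate' or 'data' must be given")
  bad <- setdiff(cfg$stages, c("sdm", "gdm", "rad"))
  if (length(bad) > 0)
    stop("config error: unknown stage ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Semantic hash of a configuration
#'
#' MD5 of the canonical (recursively name-sorted) JSON serialisation, so
#' the hash changes iff a semantic field changes.
#'
#' @param config A `run_config` or plain list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sort_rec(unclass(config)), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

run_stage <- function(name, log_path, expr) {
  pipeline_log(log_path, "stage ", name, ": start")
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  pipeline_log(log_path, "stage ", name, ": done")
  res
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (simulate or load, then sdm,
#' gdm, rad and their maps), writing every artefact under the output
#' directory: the dataset and grid CSVs plus truth JSON (simulated
#' runs); per-species SDM summaries (covariate, percent influence,
#' sign, AUC) and probability maps; the GDM model JSON (intercept,
#' sorted magnitudes, percent deviance explained), dissimilarity and
#' RGB composition map CSVs; and the RAD coefficient tables (term,
#' coefficient, SE, AIC trace, theta per component) with the six map
#' products (N, S, evenness and their CVs). A `report.json` records the
#' stage summaries, package version, config hash and wall time.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  seeds <- list(simulate = config$seed, sdm = config$seed + 101,
                gdm = config$seed + 202, rad = config$seed + 303,
                maps = config$seed + 404)
  pipeline_log(log_path, "run_pipeline seed=", config$seed,
               " hash=", config_hash(config))
  report <- list(package_version = as.character(utils::packageVersion("deepbenthos")),
                 config_hash = config_hash(config), seed = config$seed,
                 seeds = seeds, stages = list())

  # ---- data ----
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    dat <- run_stage("simulate", log_path, {
      spec <- grid_spec(n_lon = sim$n_lon, n_lat = sim$n_lat)
      env <- generate_environment(spec, seed = seeds$simulate)
      pool <- generate_species_pool(
        species_pool_params(n_species = sim$n_species,
                            n_archetypes = sim$n_archetypes),
        seed = seeds$simulate + 1)
      sv <- simulate_survey(pool, env, n_sites = sim$n_sites,
                            area_range = sim$area_range,
                            seed = seeds$simulate + 2)
      data_dir <- file.path(out, "data")
      write_survey(sv$dataset, data_dir)
      write_grid(env, file.path(data_dir, "grid.csv"))
      write_truth(sv$truth, file.path(data_dir, "truth.json"))
      list(dataset = sv$dataset, env = env, truth = sv$truth)
    })
    dataset <- dat$dataset; env <- dat$env
  } else {
    dat <- run_stage("load", log_path, {
      dataset <- load_survey(config$data$samples, config$data$abundance,
                             config$data$species)
      env <- load_grid(config$data$grid)
      list(dataset = dataset, env = env)
    })
    dataset <- dat$dataset; env <- dat$env
  }
  covs <- attach_covariates(dataset, env)
  report$stages$data <- list(n_sites = nrow(dataset$samples),
                             n_species = ncol(dataset$abundance),
                             singleton_fraction = singleton_fraction(dataset))

  # ---- sdm ----
  if ("sdm" %in% config$stages) {
    report$stages$sdm <- run_stage("sdm", log_path, {
      p <- config$sdm
      sdm_dir <- file.path(out, "sdm")
      dir.create(sdm_dir, showWarnings = FALSE)
      occ <- colSums(dataset$abundance > 0)
      eligible <- names(occ)[occ >= p$min_occurrences &
                               occ <= nrow(dataset$samples) - 2]
      chosen <- head(eligible[order(-occ[eligible])], p$n_top)
      summaries <- list()
      for (sp in chosen) {
        y <- as.numeric(dataset$abundance[, sp] > 0)
        m <- fit_abt(covs, y, n_folds = p$n_folds, seed = seeds$sdm,
                     learning_rate = p$learning_rate, n_trees = p$n_trees,
                     tree_depth = p$tree_depth,
                     bag_fraction = p$bag_fraction)
        tab <- abt_summary(m)
        jsonlite::write_json(
          list(species = sp, auc = attr(tab, "auc"), influence = tab),
          file.path(sdm_dir, paste0(sp, "_summary.json")),
          auto_unbox = TRUE, digits = NA)
        write.csv(predict_abt_map(m, env),
                  file.path(sdm_dir, paste0(sp, "_map.csv")),
                  row.names = FALSE)
        summaries[[sp]] <- list(auc = attr(tab, "auc"),
                                top = tab$covariate[which.max(tab$percent_influence)])
      }
      summaries
    })
  }

  # ---- gdm ----
  if ("gdm" %in% config$stages) {
    report$stages$gdm <- run_stage("gdm", log_path, {
      p <- config$gdm
      gdm_dir <- file.path(out, "gdm")
      dir.create(gdm_dir, showWarnings = FALSE)
      pa <- presence_absence(dataset)
      keep <- rowSums(pa) > 0
      if (any(!keep))
        pipeline_log(log_path, "gdm: dropping ", sum(!keep),
                     " site(s) with zero presences")
      d <- sorensen_dissimilarity(pa[keep, , drop = FALSE])
      preds <- intersect(p$predictors, names(covs))
      model <- fit_gdm(d, covs[keep, , drop = FALSE],
                       predictors = preds, n_basis = p$n_basis)
      mags <- sort(gdm_magnitudes(model), decreasing = TRUE)
      jsonlite::write_json(
        list(intercept = model$intercept,
             zero_distance_dissimilarity = 1 - exp(-model$intercept),
             deviance_explained = model$deviance_explained,
             magnitudes = as.list(mags), converged = model$converged),
        file.path(gdm_dir, "model.json"), auto_unbox = TRUE, digits = NA)
      write.csv(as.data.frame(d), file.path(gdm_dir, "dissimilarity.csv"))
      rgb_map <- composition_rgb_map(model, env,
                                     anchor_count = p$anchor_count,
                                     seed = seeds$gdm)
      write.csv(rgb_map, file.path(gdm_dir, "composition_map.csv"),
                row.names = FALSE)
      list(deviance_explained = model$deviance_explained,
           intercept = model$intercept,
           zero_distance_dissimilarity = 1 - exp(-model$intercept))
    })
  }

  # ---- rad ----
  if ("rad" %in% config$stages) {
    report$stages$rad <- run_stage("rad", log_path, {
      p <- config$rad
      rad_dir <- file.path(out, "rad")
      dir.create(rad_dir, showWarnings = FALSE)
      comp <- survey_rad_components(dataset)
      N <- vapply(comp, `[[`, integer(1), "N")
      S <- vapply(comp, `[[`, integer(1), "S")
      eta <- vapply(comp, `[[`, numeric(1), "evenness")
      areas <- dataset$samples$area_swept_m2

      ab_fit <- forward_select_aic(
        function(tm) fit_abundance_model(N, covs[tm], areas),
        candidates = p$abundance_candidates)

      scN <- rad_scaled_covariates(N, S, areas)
      rich_covs <- cbind(covs, scN)
      rich_fit <- forward_select_aic(
        function(tm) fit_richness_model(S, N, expand_interactions(rich_covs, tm)),
        candidates = p$richness_candidates)

      rank_fit <- fit_rank_curve(comp)
      ev_fit <- forward_select_aic(
        function(tm) fit_evenness_model(eta, scN, terms = tm),
        candidates = p$evenness_candidates)

      models <- rad_model_set(ab_fit, rich_fit, rank_fit, ev_fit)
      jsonlite::write_json(rad_table(models), file.path(rad_dir, "models.json"),
                           auto_unbox = TRUE, digits = NA)
      maps <- predict_rad_maps(models, env, reference_area = p$reference_area,
                               n_draws = p$n_draws, seed = seeds$maps)
      write.csv(maps, file.path(rad_dir, "maps.csv"), row.names = FALSE)
      list(abundance_terms = ab_fit$terms_selected,
           richness_terms = rich_fit$terms_selected,
           evenness_terms = ev_fit$terms_selected,
           abundance_theta = ab_fit$theta)
    })
  }

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(log_path, "run complete in ",
               sprintf("%.1f", report$wall_time_s), " s")
  invisible(report)
}

#' Expand interaction terms into product columns
#'
#' Builds the design columns named by `terms` from a covariate frame:
#' plain terms are copied, `"a:b"` terms become the product of the two
#' mains. Used to hand candidate sets with interactions to the
#' component-model fitters.
#'
#' @param df Data frame holding the main-effect columns.
#' @param terms Character vector of term names.
#' @return Data frame with one column per term (NULL when empty).
#' @export
expand_interactions <- function(df, terms) {
  if (length(terms) == 0) return(NULL)
  out <- list()
  for (tm in terms) {
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      out[[tm]] <- df[[parts[1]]] * df[[parts[2]]]
    } else out[[tm]] <- df[[tm]]
  }
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Coefficient tables of a fitted RAD model set
#'
#' One block per component with term, coefficient, standard error, the
#' forward-selection AIC trace and the dispersion theta where present.
#'
#' @param models A `rad_model_set`.
#' @return Nested list ready for JSON serialisation.
#' @export
rad_table <- function(models) {
  block <- function(m) {
    if (is.null(m)) return(NULL)
    se <- sqrt(pmax(diag(m$vcov), 0))
    list(terms = data.frame(term = names(m$coefficients),
                            coefficient = unname(m$coefficients),
                            se = unname(se)),
         aic = m$aic,
         aic_trace = if (!is.null(m$selection)) m$selection else NULL,
         theta = m$theta, theta_se = m$theta_se)
  }
  list(total_abundance = block(models$abundance),
       species_richness = block(models$richness),
       rank_curve = block(models$rank_curve),
       species_evenness = block(models$evenness))
}
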