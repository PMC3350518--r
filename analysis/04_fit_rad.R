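#!/usr/bin/env Rscript
# Community structure: decompose each sample's rank abundance
# distribution into total abundance N, richness S | N and relative
# abundances n | N, S; fit the component models with forward-AIC term
# selection and report the coefficient tables.
# Requires the artefacts of 01_simulate_survey.R.

library(deepbenthos)

data_dir <- "results/data"
out <- "results/rad"
if (!file.exists(file.path(data_dir, "samples.csv")))
  stop("run analysis/01_simulate_survey.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dataset <- load_survey(file.path(data_dir, "samples.csv"),
                       file.path(data_dir, "abundance.csv"),
                       file.path(data_dir, "species.csv"))
env <- load_grid(file.path(data_dir, "grid.csv"))
covs <- attach_covariates(dataset, env)

comp <- survey_rad_components(dataset)
N <- vapply(comp, `[[`, integer(1), "N")
S <- vapply(comp, `[[`, integer(1), "S")
eta <- vapply(comp, `[[`, numeric(1), "evenness")
areas <- dataset$samples$area_swept_m2
cat(sprintf("site totals N: %d-%d; richness S: %d-%d; evenness: %.2f-%.2f\n\n",
            min(N), max(N), min(S), max(S), min(eta), max(eta)))

# total abundance: NB with log(area) effort term, environment by
# forward AIC
ab_fit <- forward_select_aic(
  function(tm) fit_abundance_model(N, covs[tm], areas),
  candidates = c("carbonate", "sand", "mud", "gravel", "nitrate_mean",
                 "depth"))
cat("== total abundance (N) ==\n"); print(ab_fit)
cat("selected terms:", paste(ab_fit$terms_selected, collapse = ", "), "\n\n")

# richness: truncated NB conditional on N through area-scaled terms
sc <- rad_scaled_covariates(N, S, areas)
rich_frame <- cbind(covs, sc)
rich_fit <- forward_select_aic(
  function(tm) fit_richness_model(S, N, expand_interactions(rich_frame, tm)),
  candidates = c("log_N_scale", "N_scale", "nitrate_mean", "sand",
                 "sand:nitrate_mean"))
cat("== species richness (S | N) ==\n"); print(rich_fit)

# relative abundances: shared multinomial rank curve
rank_fit <- fit_rank_curve(comp)
cat("== rank curve (n | N, S) ==\n"); print(rank_fit)

# evenness: gamma regression on community structure only
ev_fit <- forward_select_aic(
  function(tm) fit_evenness_model(eta, sc, terms = tm),
  candidates = c("N_scale", "N_scale2", "N_scale3", "S_scale", "S_scale2"))
cat("== species evenness ==\n"); print(ev_fit)

models <- rad_model_set(ab_fit, rich_fit, rank_fit, ev_fit)
jsonlite::write_json(rad_table(models), file.path(out, "models.json"),
                     auto_unbox = TRUE, digits = NA)
cat("\ncoefficient tables written to", file.path(out, "models.json"), "\n")
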