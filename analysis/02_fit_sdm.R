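#!/usr/bin/env Rscript
# Single-species distribution models: aggregated boosted regression
# trees for the most frequently occurring species, with the per-species
# influence/sign/AUC summary table and gridded probability maps.
# Requires the artefacts of 01_simulate_survey.R.

library(deepbenthos)

data_dir <- "results/data"
out <- "results/sdm"
if (!file.exists(file.path(data_dir, "samples.csv")))
  stop("run analysis/01_simulate_survey.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dataset <- load_survey(file.path(data_dir, "samples.csv"),
                       file.path(data_dir, "abundance.csv"),
                       file.path(data_dir, "species.csv"))
env <- load_grid(file.path(data_dir, "grid.csv"))
covs <- attach_covariates(dataset, env)

occ <- colSums(presence_absence(dataset))
n_sites <- nrow(dataset$samples)
# frequent species only: enough presences for 10-fold stratification
chosen <- names(sort(occ[occ >= 8 & occ <= n_sites - 4], decreasing = TRUE))
chosen <- head(chosen, 4)
cat("modelling", length(chosen), "frequent species:",
    paste(chosen, collapse = ", "), "\n\n")

for (sp in chosen) {
  y <- as.numeric(dataset$abundance[, sp] > 0)
  m <- fit_abt(covs, y, n_folds = 10, seed = 20260924,
               learning_rate = 0.05, n_trees = 300)
  tab <- abt_summary(m)
  tab <- tab[order(-tab$percent_influence), ]
  cat(sprintf("== %s (%d presences) AUC = %.3f ==\n", sp, sum(y),
              attr(tab, "auc")))
  print(head(transform(tab, percent_influence = round(percent_influence, 2)),
             6), row.names = FALSE)
  cat("\n")
  jsonlite::write_json(list(species = sp, auc = attr(tab, "auc"),
                            influence = tab),
                       file.path(out, paste0(sp, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  write.csv(predict_abt_map(m, env),
            file.path(out, paste0(sp, "_map.csv")), row.names = FALSE)
}
cat("summaries and probability maps written under", out, "\n")
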