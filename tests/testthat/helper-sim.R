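# shared simulation helpers for the test suite

# pairwise dissimilarities generated from a known GDM: one active
# predictor with a linear turnover function of magnitude `mag`, one
# inactive predictor; observed d_ij are binomial proportions with
# denominator m around the model mean
sim_gdm_data <- function(n = 100, a0 = 0.891, mag = 0.95, m = 120, seed = 1) {
  set.seed(seed)
  covs <- data.frame(x = runif(n), z = runif(n))
  f <- mag * covs$x
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  mu <- 1 - exp(-(a0 + abs(f[pairs[, 1]] - f[pairs[, 2]])))
  d <- matrix(0, n, n)
  d[pairs] <- rbinom(nrow(pairs), m, mu) / m
  d <- d + t(d)
  list(d = d, covs = covs)
}

# binary response driven by a single covariate with strong contrast
sim_single_signal <- function(n = 300, seed = 1) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- rbinom(n, 1, plogis(-4 + 8 * X$x1))
  list(X = X, y = y)
}

# rank-cell count vectors drawn from the multinomial rank-curve model
# (cells NOT re-sorted: cell r is rank r by construction)
sim_rank_components <- function(beta, gamma, n_sites = 200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_sites), function(i) {
    S <- sample(3:12, 1)
    N <- sample(50:400, 1)
    z <- (seq_len(S) - 1) / (S - 1)
    p <- exp(beta * z + gamma * z^2)
    p <- p / sum(p)
    cc <- as.integer(rmultinom(1, N, p))
    structure(list(N = N, S = S, n = cc / N, area = 1, evenness = 0),
              class = "rad_components")
  })
}

# all ordered compositions of N into S non-negative cells; for S = 0 the
# single degenerate empty outcome (the composition component is a point
# mass there)
enum_compositions <- function(N, S) {
  if (S == 0) return(list(integer(0)))
  if (S == 1) return(list(N))
  out <- list()
  for (c1 in 0:N)
    for (rest in enum_compositions(N - c1, S - 1))
      out <- c(out, list(c(c1, rest)))
  out
}

# a small known RAD model set on one environmental covariate, with
# coefficient scales echoing deep-sea sled data
known_rad_models <- function() {
  moments <- list(N_scale = c(0.5, 0.3), log_N_scale = c(-1, 0.8),
                  S_scale = c(0.02, 0.01))
  ab <- component_model("nb_abundance",
                        c("(Intercept)" = -1.36, carbonate = 0.073,
                          log_area = 0.089),
                        theta = 1.73, terms = c("carbonate", "log_area"))
  ri <- component_model("truncated_nb_richness",
                        c("(Intercept)" = 1.8, log_N_scale = 0.31,
                          nitrate_mean = -0.08),
                        theta = 8, terms = c("log_N_scale", "nitrate_mean"),
                        cap = 60)
  rc <- component_model("multinomial_rank_curve", c(beta = -3, gamma = 0.5))
  ev <- component_model("gamma_evenness",
                        c("(Intercept)" = 1.25, N_scale = 1.17,
                          N_scale2 = -1.48, S_scale = -0.63),
                        terms = c("N_scale", "N_scale2", "S_scale"),
                        moments = moments, dispersion = 0.12)
  rad_model_set(ab, ri, rc, ev)
}

# covariates and areas for RAD recovery simulations
rad_sim_frame <- function(n, seed) {
  set.seed(seed)
  data.frame(carbonate = runif(n, 20, 80),
             nitrate_mean = runif(n, 5, 35),
             area = runif(n, 160, 2500))
}

# small environment + survey for fast integration-style tests
small_survey <- function(seed = 1, n_lon = 15, n_lat = 15, n_sites = 30,
                         n_species = 120) {
  env <- generate_environment(grid_spec(n_lon = n_lon, n_lat = n_lat),
                              seed = seed)
  pool <- generate_species_pool(
    species_pool_params(n_species = n_species, n_archetypes = 8),
    seed = seed + 1)
  sv <- simulate_survey(pool, env, n_sites = n_sites, seed = seed + 2)
  list(env = env, pool = pool, dataset = sv$dataset, truth = sv$truth)
}
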