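# Synthetic deep-sea survey generator: environmental grids, species
# pools with archetype responses, and sled-sample datasets with recorded
# ground truth for parameter-recovery validation.

#' Specify a regular lon/lat grid
#'
#' @param n_lon,n_lat Number of cells in each direction (>= 2).
#' @param lon_range,lat_range Extents in decimal degrees (WGS84).
#' @return A `grid_spec` list; `cell_size` is the lon spacing.
#' @export
grid_spec <- function(n_lon = 50, n_lat = 50,
                      lon_range = c(146, 146.5), lat_range = c(-44.5, -44)) {
  if (n_lon < 2 || n_lat < 2) stop("grid dimensions must be at least 2")
  cell_size <- diff(lon_range) / n_lon
  if (cell_size <= 0) stop("lon_range must be increasing")
  if (diff(lat_range) <= 0) stop("lat_range must be increasing")
  structure(list(n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
                 lon_range = lon_range, lat_range = lat_range,
                 cell_size = cell_size),
            class = "grid_spec")
}

#' Default parameters of the environment generator
#'
#' Controls the depth ramp and seamounts, the depth-driven oceanographic
#' mean layers, the depth-unimodal standard-deviation layers, the
#' sediment composition fields and the fished patch. All values can be
#' overridden through the `env_params` argument of
#' [generate_environment()].
#'
#' @return Named list of generator parameters.
#' @export
default_env_params <- function() {
  list(
    depth_range = c(150, 1850),     # offshore ramp, m (positive down)
    n_seamounts = 6,
    seamount_height = c(200, 300),  # m of elevation above the ramp
    seamount_sigma = c(0.015, 0.03),# cone width, degrees
    noise_sd = list(depth = 15, temperature_mean = 0.15, salinity_mean = 0.01,
                    oxygen_mean = 2, nitrate_mean = 0.5, phosphate_mean = 0.05,
                    sd_layers = 0.04, carbonate = 4),
    # mean layers: value = a + b * t + noise, t = scaled depth in [0,1]
    mean_profiles = list(
      temperature_mean = c(12.5, -10.5),
      salinity_mean    = c(35.15, -0.75),
      oxygen_mean      = c(168, 62),
      nitrate_mean     = c(6, 28),
      phosphate_mean   = c(0.45, 1.9)),
    # sd layers: base + amp * exp(-(depth - peak)^2 / (2 * width^2))
    sd_profiles = list(
      temperature_sd = c(0.15, 0.55), salinity_sd = c(0.02, 0.06),
      oxygen_sd = c(1.5, 4.5), nitrate_sd = c(0.3, 0.9),
      phosphate_sd = c(0.03, 0.09)),
    sd_peak_depth = 800, sd_peak_width = 300,
    carbonate_range = c(20, 80),    # west -> east gradient
    sediment_field_scale = 2.5,     # wavelengths per domain in latent fields
    fished_fraction = 0.15)
}

# smooth latent field: sum of low-frequency sinusoids with random
# phases/orientations; u, v are coordinates scaled to [0, 1]
latent_field <- function(u, v, scale, n_waves = 4) {
  z <- numeric(length(u))
  for (k in seq_len(n_waves)) {
    ang <- runif(1, 0, 2 * pi)
    freq <- runif(1, 0.5, scale)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    z <- z + amp * sin(2 * pi * freq * (u * cos(ang) + v * sin(ang)) + phase)
  }
  z / sqrt(n_waves)
}

#' Generate a synthetic environmental grid
#'
#' Builds one layer per covariate of [covariate_vocabulary()]: depth is a
#' smooth offshore ramp with cone-shaped seamounts whose peaks fall at
#' intermediate depths; oceanographic mean layers are monotone functions
#' of depth plus noise (so they are strongly correlated with depth, as on
#' a real continental margin); standard-deviation layers are unimodal in
#' depth with a peak at intermediate depths and are not linearly
#' correlated with depth; the sand/gravel/mud fractions are normalised
#' exponentials of three latent smooth fields and sum to 100 in every
#' cell; carbonate follows an independent west-to-east gradient; and the
#' fished layer is a single rectangular patch.
#'
#' @param spec A [grid_spec()].
#' @param env_params Named list overriding entries of
#'   [default_env_params()].
#' @param seed Integer seed; the draw order is fixed, so the same spec
#'   and seed always give identical layers.
#' @return An `environmental_grid`.
#' @export
generate_environment <- function(spec = grid_spec(),
                                 env_params = list(), seed = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  p <- default_env_params()
  unknown <- setdiff(names(env_params), names(p))
  if (length(unknown) > 0)
    stop("unknown covariate name or parameter: ", paste(unknown, collapse = ", "))
  p[names(env_params)] <- env_params
  set.seed(seed)

  lon_c <- spec$lon_range[1] + (seq_len(spec$n_lon) - 0.5) * diff(spec$lon_range) / spec$n_lon
  lat_c <- spec$lat_range[1] + (seq_len(spec$n_lat) - 0.5) * diff(spec$lat_range) / spec$n_lat
  cells <- expand.grid(lon = lon_c, lat = lat_c)
  n <- nrow(cells)
  u <- (cells$lon - spec$lon_range[1]) / diff(spec$lon_range)
  v <- (cells$lat - spec$lat_range[1]) / diff(spec$lat_range)

  # 1. depth: ramp deepening southwards (v = 0 is the southern edge)
  ramp <- p$depth_range[1] + (p$depth_range[2] - p$depth_range[1]) * (1 - v)
  depth <- ramp + rnorm(n, 0, p$noise_sd$depth)
  # seamounts: cones subtracted where the ramp is deep enough that the
  # peak lands at intermediate depth (~700-1400 m)
  for (k in seq_len(p$n_seamounts)) {
    h <- runif(1, p$seamount_height[1], p$seamount_height[2])
    sig <- runif(1, p$seamount_sigma[1], p$seamount_sigma[2])
    target_peak <- runif(1, 700, 1400)
    base_depth <- target_peak + h
    vk <- 1 - (base_depth - p$depth_range[1]) / (p$depth_range[2] - p$depth_range[1])
    ck_lon <- runif(1, spec$lon_range[1], spec$lon_range[2])
    ck_lat <- spec$lat_range[1] + vk * diff(spec$lat_range)
    d2 <- (cells$lon - ck_lon)^2 + (cells$lat - ck_lat)^2
    depth <- depth - h * exp(-d2 / (2 * sig^2))
  }
  depth <- pmax(depth, 100)
  t_depth <- (depth - p$depth_range[1]) / (p$depth_range[2] - p$depth_range[1])

  layers <- list(depth = depth)
  # 2. oceanographic mean layers, draw order fixed by profile list order
  for (nm in names(p$mean_profiles)) {
    ab <- p$mean_profiles[[nm]]
    layers[[nm]] <- ab[1] + ab[2] * t_depth + rnorm(n, 0, p$noise_sd[[nm]])
  }
  # 3. sd layers: unimodal bump at intermediate depth
  for (nm in names(p$sd_profiles)) {
    ba <- p$sd_profiles[[nm]]
    bump <- exp(-(depth - p$sd_peak_depth)^2 / (2 * p$sd_peak_width^2))
    layers[[nm]] <- pmax(ba[1] + ba[2] * bump +
                           rnorm(n, 0, p$noise_sd$sd_layers * (ba[1] + ba[2])),
                         0.001)
  }
  # 4. sediments: softmax of three latent smooth fields, closed to 100
  lat_fields <- vapply(1:3, function(k)
    latent_field(u, v, p$sediment_field_scale), numeric(n))
  expf <- exp(lat_fields)
  sed <- 100 * expf / rowSums(expf)
  layers$sand <- sed[, 1]; layers$gravel <- sed[, 2]; layers$mud <- sed[, 3]
  # 5. carbonate: independent west-east gradient
  cr <- p$carbonate_range
  layers$carbonate <- pmin(pmax(cr[1] + (cr[2] - cr[1]) * u +
                                  rnorm(n, 0, p$noise_sd$carbonate), 0), 100)
  # 6. fished: one rectangular patch covering ~fished_fraction of cells
  side <- sqrt(p$fished_fraction)
  u0 <- runif(1, 0, 1 - side); v0 <- runif(1, 0, 1 - side)
  layers$fished <- as.numeric(u >= u0 & u < u0 + side & v >= v0 & v < v0 + side)

  cells <- cbind(data.frame(cell_id = seq_len(n)), cells,
                 as.data.frame(layers))
  environmental_grid(cells, spec$cell_size)
}

#' Parameters of the synthetic species pool
#'
#' Species are grouped into archetypes. Each archetype has a Gaussian
#' depth niche (optimum and width on a standardised depth axis) plus
#' linear responses to sediment covariates; a species' logit-scale
#' response equals its archetype response plus independent jitter. The
#' occurrence probability at any covariate value is capped at
#' `max_occ_prob`, reflecting the low detectability of deep-sea
#' megabenthos even in suitable habitat.
#'
#' @param n_species Number of species in the regional pool.
#' @param n_archetypes Number of archetypes (<= `n_species`).
#' @param base_logit Mean archetype peak logit: controls how rare species
#'   are at their depth optimum.
#' @param logit_sd Spread of archetype peak logits.
#' @param jitter_sd Within-archetype jitter of all response coefficients.
#' @param niche_width Range of archetype depth-niche widths on the
#'   standardised depth axis (1 unit = 500 m); narrower niches give
#'   stronger depth turnover and more single-capture species.
#' @param max_occ_prob Cap on the occurrence probability, in (0, 1].
#' @param rank_slope Slope beta of the decreasing rank-proportion curve
#'   used to allocate a site's individuals among its present species;
#'   larger beta gives steeper, less even rank-abundance curves.
#' @param abundance_coefs Named coefficients of the negative-binomial
#'   site-total-abundance model on the log scale (intercept plus any
#'   covariate from the vocabulary).
#' @param log_area_coef Coefficient of log(swept area) in the abundance
#'   model.
#' @param theta Negative-binomial dispersion of site totals.
#' @return A `species_pool_params` list.
#' @export
species_pool_params <- function(n_species = 493, n_archetypes = 12,
                                base_logit = -2.55, logit_sd = 1.2,
                                jitter_sd = 0.6, niche_width = c(0.2, 0.45),
                                max_occ_prob = 0.6,
                                rank_slope = 5,
                                abundance_coefs = c(intercept = 2.6,
                                                    carbonate = 0.073),
                                log_area_coef = 0.089, theta = 1.73) {
  if (n_archetypes > n_species)
    stop("n_archetypes must not exceed n_species")
  if (max_occ_prob <= 0 || max_occ_prob > 1)
    stop("max_occ_prob must lie in (0, 1]")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (theta <= 0) stop("theta must be positive")
  structure(list(n_species = as.integer(n_species),
                 n_archetypes = as.integer(n_archetypes),
                 base_logit = base_logit, logit_sd = logit_sd,
                 jitter_sd = jitter_sd, niche_width = niche_width,
                 max_occ_prob = max_occ_prob,
                 rank_slope = rank_slope, abundance_coefs = abundance_coefs,
                 log_area_coef = log_area_coef, theta = theta),
            class = "species_pool_params")
}

# fixed reference scaling of covariates for occurrence responses, so the
# pool does not depend on any particular grid realisation
occ_feature_scaling <- function() {
  list(depth = c(centre = 1000, scale = 500),
       mud = c(centre = 33, scale = 20),
       carbonate = c(centre = 50, scale = 25))
}

#' Generate a synthetic species pool
#'
#' Assigns each species to exactly one archetype and draws its
#' logit-scale response coefficients as the archetype response plus
#' Gaussian jitter. Depth optima of the archetypes are spread over the
#' sampled depth range so the pool exhibits depth-structured
#' compositional turnover.
#'
#' @param params A [species_pool_params()].
#' @param seed Integer seed.
#' @return A `species_pool` with per-species coefficients on the features
#'   (1, depth, depth^2, mud, carbonate), the archetype assignment and
#'   the occurrence cap.
#' @export
generate_species_pool <- function(params = species_pool_params(), seed = 1) {
  stopifnot(inherits(params, "species_pool_params"))
  set.seed(seed)
  K <- params$n_archetypes
  # archetype Gaussian depth niches on the standardised depth axis
  opt <- runif(K, -1.6, 1.6)          # optima ~ 200..1800 m
  width <- runif(K, params$niche_width[1], params$niche_width[2])
  peak <- rnorm(K, params$base_logit, params$logit_sd)
  # eta = peak - (depth_s - opt)^2 / (2 width^2) + linear sediment terms
  arch <- cbind(intercept = peak - opt^2 / (2 * width^2),
                depth = opt / width^2,
                depth2 = -1 / (2 * width^2),
                mud = rnorm(K, 0, 0.5),
                carbonate = rnorm(K, 0, 0.5))
  assignment <- if (K == params$n_species) seq_len(K) else
    sample(rep_len(seq_len(K), params$n_species))
  coefs <- arch[assignment, , drop = FALSE] +
    matrix(rnorm(params$n_species * ncol(arch), 0, params$jitter_sd),
           params$n_species)
  rownames(coefs) <- sprintf("sp%03d", seq_len(params$n_species))
  structure(list(params = params, archetypes = arch,
                 assignment = assignment, coefs = coefs,
                 scaling = occ_feature_scaling(),
                 species_id = rownames(coefs)),
            class = "species_pool")
}

#' Occurrence probabilities of a species pool at given covariates
#'
#' @param pool A `species_pool`.
#' @param covariates Data frame with `depth`, `mud` and `carbonate`
#'   columns (raw units).
#' @return Matrix, rows = sites/cells, columns = species; probabilities
#'   capped at the pool's `max_occ_prob`.
#' @export
occurrence_probability <- function(pool, covariates) {
  stopifnot(inherits(pool, "species_pool"))
  sc <- pool$scaling
  ds <- (covariates$depth - sc$depth["centre"]) / sc$depth["scale"]
  X <- cbind(1, ds, ds^2,
             (covariates$mud - sc$mud["centre"]) / sc$mud["scale"],
             (covariates$carbonate - sc$carbonate["centre"]) / sc$carbonate["scale"])
  eta <- X %*% t(pool$coefs)
  p <- pmin(plogis(eta), pool$params$max_occ_prob)
  dimnames(p) <- list(rownames(covariates), pool$species_id)
  p
}

#' Simulate an epibenthic sled survey
#'
#' Sites are placed on distinct grid cells; each site's total abundance
#' is drawn from a negative binomial with log link on the configured
#' covariates plus log(swept area); species presence is Bernoulli with
#' the pool's (capped) occurrence probabilities; and the site total is
#' allocated to the present species by a multinomial whose rank
#' proportions decrease as exp(-beta * (r-1)/(S-1)). Species allocated a
#' zero count are undetected, which reproduces the high singleton
#' fraction typical of deep-sea sled data.
#'
#' @param pool A `species_pool`.
#' @param env An `environmental_grid`.
#' @param n_sites Number of sled samples (>= 2).
#' @param area_range Range of swept areas, m^2 (drawn uniformly).
#' @param seed Integer seed.
#' @return List with `dataset` (a `survey_dataset`) and `truth` (a
#'   `truth_record` that fully determines regeneration; see
#'   [regenerate_survey()]).
#' @export
simulate_survey <- function(pool, env, n_sites = 39,
                            area_range = c(160, 2500), seed = 1) {
  stopifnot(inherits(pool, "species_pool"), inherits(env, "environmental_grid"))
  if (pool$params$n_species < 1) stop("empty species pool")
  if (n_sites < 2) stop("n_sites must be at least 2")
  if (n_sites > nrow(env$cells)) stop("n_sites exceeds the grid cell count")
  set.seed(seed)
  par <- pool$params

  cell_idx <- sample.int(nrow(env$cells), n_sites)
  cells <- env$cells[cell_idx, , drop = FALSE]
  areas <- runif(n_sites, area_range[1], area_range[2])
  covs <- cells[, env$layers, drop = FALSE]
  rownames(covs) <- NULL

  # site totals: NB log link on configured covariates + log(swept area)
  beta <- par$abundance_coefs
  eta_N <- rep(beta[["intercept"]], n_sites)
  for (nm in setdiff(names(beta), "intercept"))
    eta_N <- eta_N + beta[[nm]] * covs[[nm]]
  eta_N <- eta_N + par$log_area_coef * log(areas)
  mu_N <- exp(eta_N)
  N <- rnbinom(n_sites, mu = mu_N, size = par$theta)

  p_occ <- occurrence_probability(pool, covs)
  present <- matrix(rbinom(length(p_occ), 1, p_occ), nrow = n_sites)
  counts <- matrix(0L, n_sites, par$n_species,
                   dimnames = list(sprintf("site%02d", seq_len(n_sites)),
                                   pool$species_id))
  for (i in seq_len(n_sites)) {
    pres <- which(present[i, ] == 1)
    S_pres <- length(pres)
    if (S_pres == 0 || N[i] == 0) next
    z <- if (S_pres == 1) 0 else (seq_len(S_pres) - 1) / (S_pres - 1)
    q <- exp(-par$rank_slope * z)
    q <- q / sum(q)
    # rank order among present species is a fresh random permutation
    ord <- sample(S_pres)
    counts[i, pres[ord]] <- as.integer(rmultinom(1, N[i], q))
  }

  samples <- data.frame(site_id = rownames(counts),
                        lon = cells$lon, lat = cells$lat,
                        depth_m = cells$depth,
                        area_swept_m2 = areas,
                        fished = cells$fished,
                        stringsAsFactors = FALSE)
  dataset <- survey_dataset(samples, counts)
  truth <- structure(list(pool = pool, grid_cell_idx = cell_idx,
                          n_sites = n_sites, area_range = area_range,
                          seed = seed, mu_N = mu_N, N = N,
                          env_fingerprint = nrow(env$cells)),
                     class = "truth_record")
  list(dataset = dataset, truth = truth)
}

#' Regenerate a survey from its truth record
#'
#' Repeats [simulate_survey()] with the stored pool, parameters and
#' seed; the result is identical to the original draw.
#'
#' @param truth A `truth_record`.
#' @param env The same `environmental_grid` used for the original draw.
#' @return As [simulate_survey()].
#' @export
regenerate_survey <- function(truth, env) {
  stopifnot(inherits(truth, "truth_record"))
  if (nrow(env$cells) != truth$env_fingerprint)
    stop("grid does not match the truth record")
  simulate_survey(truth$pool, env, n_sites = truth$n_sites,
                  area_range = truth$area_range, seed = truth$seed)
}

#' Write a truth record as JSON
#'
#' @param truth A `truth_record`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  out <- list(
    seed = truth$seed, n_sites = truth$n_sites,
    area_range = truth$area_range, grid_cell_idx = truth$grid_cell_idx,
    pool_params = unclass(truth$pool$params),
    archetype_assignment = truth$pool$assignment,
    species_coefs = as.data.frame(truth$pool$coefs))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fraction of observed species caught in exactly one sample
#'
#' @param dataset A `survey_dataset` (or count matrix).
#' @return Singletons / species observed at least once.
#' @export
singleton_fraction <- function(dataset) {
  occ <- colSums(presence_absence(dataset) > 0)
  occ <- occ[occ > 0]
  if (length(occ) == 0) return(NA_real_)
  mean(occ == 1)
}
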