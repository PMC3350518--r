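# RAD decomposition, component models, factorized likelihood, selection
# and prediction maps

test_that("decompose_rad matches hand arithmetic and exclusion rules", {
  r <- decompose_rad(c(5, 3, 1, 1), area = 1)
  expect_identical(r$N, 10L)
  expect_identical(r$S, 4L)
  expect_equal(r$n, c(0.5, 0.3, 0.1, 0.1))

  z <- decompose_rad(c(0, 0, 0), area = 2)
  expect_identical(z$N, 0L)
  expect_identical(z$S, 0L)
  expect_length(z$n, 0)
  expect_identical(z$evenness, 0)

  e <- decompose_rad(c(5, 3), countable = c(TRUE, FALSE), area = 1)
  expect_identical(e$N, 5L)
  expect_identical(e$S, 1L)

  expect_error(decompose_rad(c(-1, 2)), "negative")
  expect_error(decompose_rad(c(1, 2), area = 0), "positive")
})

test_that("decompose_rad conserves countable totals exactly", {
  set.seed(31)
  for (r in 1:10) {
    counts <- rpois(20, 3)
    countable <- rbinom(20, 1, 0.8) == 1
    rc <- decompose_rad(counts, countable, area = 1)
    expect_equal(round(rc$n * rc$N), sort(counts[countable][counts[countable] > 0],
                                          decreasing = TRUE))
    expect_identical(rc$N, sum(as.integer(counts[countable])))
  }
})

test_that("evenness matches closed forms and depends only on ratios", {
  expect_equal(compute_evenness(rep(1 / 3, 3)), 0)
  expect_equal(compute_evenness(c(1, 0.5, 0.25) / 1.75), 2 * log(2),
               tolerance = 1e-10)
  expect_identical(compute_evenness(1), 0)
  expect_equal(compute_evenness(c(0.8, 0.2)), abs(log(0.8) - log(0.2)))
  expect_error(compute_evenness(c(0.5, 0.5, 0)), "zero proportion")

  # geometric RADs: evenness is invariant to N (ratios only)
  g1 <- decompose_rad(c(64, 32, 16, 8), area = 1)
  g2 <- decompose_rad(c(640, 320, 160, 80), area = 1)
  expect_equal(g1$evenness, g2$evenness, tolerance = 1e-10)
})

test_that("nb abundance model: intercept-only MLE equals the sample mean", {
  set.seed(32)
  N <- rnbinom(200, mu = 40, size = 2)
  m <- fit_abundance_model(N)
  expect_equal(exp(unname(m$coefficients[1])), mean(N), tolerance = 1e-6)
  expect_error(fit_abundance_model(rep(0L, 10)), "all-zero")
})

test_that("nb abundance model recovers generating coefficients", {
  truth <- c(-1.36, 0.073, 0.089)
  covered <- matrix(NA, 5, 3)
  for (r in 1:5) {
    set.seed(300 + r)
    carb <- runif(500, 20, 80); areas <- runif(500, 160, 2500)
    mu <- exp(truth[1] + truth[2] * carb + truth[3] * log(areas))
    N <- rnbinom(500, mu = mu, size = 1.73)
    m <- fit_abundance_model(N, data.frame(carbonate = carb), areas)
    ci <- component_confint(m)
    covered[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  expect_gte(mean(covered), 0.8)
})

test_that("near-Poisson data yields a large estimated theta", {
  hits <- vapply(1:5, function(r) {
    set.seed(330 + r)
    N <- rpois(400, 30)  # theta -> infinity limit of the NB
    m <- fit_abundance_model(N)
    m$theta > 50
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("truncated richness model reduces to plain NB when truncation vanishes", {
  set.seed(33)
  x <- rnorm(400)
  S <- rnbinom(400, mu = exp(1.2 + 0.3 * x), size = 5)
  bigN <- rep(100000L, 400)
  mt <- fit_richness_model(S, bigN, data.frame(x = x), cap = 100000)
  mp <- suppressWarnings(MASS::glm.nb(S ~ x))
  expect_lt(max(abs(mt$coefficients - coef(mp))), 1e-3)
  expect_lt(abs(mt$theta - mp$theta) / mp$theta, 0.01)
  expect_error(fit_richness_model(c(5, 10), c(4, 20)), "exceeds")
})

test_that("truncated richness model recovers coefficients under binding truncation", {
  truth <- c(2.2, 0.4)
  covered <- matrix(NA, 5, 2)
  for (r in 1:5) {
    set.seed(340 + r)
    n <- 400
    x <- rnorm(n)
    mu <- exp(truth[1] + truth[2] * x)
    upper <- pmax(rpois(n, 12), 2)  # truncation binds: mean near upper
    S <- vapply(seq_len(n), function(i) {
      s <- 0:upper[i]
      sample(s, 1, prob = dtruncnb(s, mu[i], 4, upper[i]))
    }, integer(1))
    m <- fit_richness_model(S, upper, data.frame(x = x), cap = max(upper))
    ci <- component_confint(m)
    covered[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  expect_gte(mean(covered), 0.7)
})

test_that("predicted richness never exceeds the conditioning abundance", {
  set.seed(34)
  x <- rnorm(120)
  N <- pmax(rpois(120, 20), 1)
  S <- pmin(rpois(120, 10), N)
  m <- fit_richness_model(S, N, data.frame(x = x))
  pred <- predict_richness(m, data.frame(x = x), N)
  expect_true(all(pred <= pmin(N, m$cap) + 1e-9))
})

test_that("rank curve: uniform data give near-zero slope, probs sum to 1", {
  m0 <- fit_rank_curve(sim_rank_components(0, 0, 200, seed = 35))
  expect_lt(abs(m0$coefficients["beta"]), 0.15)

  m1 <- fit_rank_curve(sim_rank_components(-3, 0.5, 200, seed = 36))
  expect_lt(abs(m1$coefficients["beta"] - (-3)), 0.4)

  for (S in c(2, 5, 11))
    expect_equal(sum(deepbenthos:::rank_curve_probs(S, -2.3, 0.4)), 1)
  expect_error(fit_rank_curve(list(decompose_rad(c(5, 0, 0)))),
               "at least two species")
})

test_that("gamma evenness regression recovers a known quadratic response", {
  covered <- matrix(NA, 5, 5)
  truth <- c(1.25, 1.17, -1.48, -0.63, 0.37)
  for (r in 1:5) {
    set.seed(350 + r)
    n <- 400
    Ns <- runif(n, -1, 1); Ss <- runif(n, -1, 1)
    sc <- data.frame(N_scale = Ns, N_scale2 = Ns^2, N_scale3 = Ns^3,
                     S_scale = Ss, S_scale2 = Ss^2)
    attr(sc, "moments") <- list(N_scale = c(0, 1), log_N_scale = c(0, 1),
                                S_scale = c(0, 1))
    mu <- exp(truth[1] + truth[2] * Ns + truth[3] * Ns^2 +
                truth[4] * Ss + truth[5] * Ss^2)
    eta <- rgamma(n, shape = 8, rate = 8 / mu)
    m <- fit_evenness_model(eta, sc, terms = c("N_scale", "N_scale2",
                                               "S_scale", "S_scale2"))
    ci <- component_confint(m)
    covered[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  expect_gte(mean(covered), 0.8)
})

test_that("rad_loglik equals the sum of its three parts and respects nesting", {
  models <- known_rad_models()
  smp <- decompose_rad(c(12, 6, 3, 2, 1), area = 1000)
  covs <- data.frame(carbonate = 50, nitrate_mean = 20)
  ll <- rad_loglik(smp, models, covs)
  parts <- attr(ll, "components")
  expect_equal(as.numeric(ll), sum(parts))
  expect_length(parts, 3)
  expect_error(rad_loglik(structure(list(N = 2L, S = 5L, n = rep(0.2, 5),
                                         area = 1, evenness = 0),
                                    class = "rad_components"),
                          models, covs), "S <= N")

  # nesting: a covariate can only increase the maximised log-likelihood
  set.seed(37)
  carb <- runif(300, 20, 80)
  N <- rnbinom(300, mu = exp(1 + 0.03 * carb), size = 2)
  m0 <- fit_abundance_model(N)
  m1 <- fit_abundance_model(N, data.frame(carbonate = carb))
  expect_gte(m1$loglik, m0$loglik - 1e-8)
})

test_that("forward selection obeys the hierarchy rule and never worsens AIC", {
  set.seed(38)
  covs <- data.frame(a = runif(300), b = runif(300), c = runif(300))
  N <- rnbinom(300, mu = exp(2 + 1.5 * covs$a * covs$b), size = 3)
  fit_fun <- function(tm) fit_abundance_model(
    N, deepbenthos:::expand_interactions(covs, tm))
  sel <- forward_select_aic(fit_fun, c("a", "b", "c", "a:b"))
  base <- fit_fun(character(0))
  expect_lte(sel$aic, base$aic)
  # the interaction may only appear after both mains
  tr <- sel$selection$term
  if ("a:b" %in% tr)
    expect_true(all(match(c("a", "b"), tr) < match("a:b", tr)))

  # pure noise: base model returned unchanged
  set.seed(39)
  N2 <- rnbinom(200, mu = 20, size = 2)
  noise <- data.frame(u = runif(200), v = runif(200))
  sel2 <- forward_select_aic(function(tm) fit_abundance_model(N2, noise[tm]),
                             c("u", "v"))
  if (length(sel2$terms_selected) == 0)
    expect_equal(sel2$aic, fit_abundance_model(N2)$aic)
  expect_lte(sel2$aic, fit_abundance_model(N2)$aic)
})

test_that("the true abundance covariate is always selected first", {
  firsts <- vapply(1:5, function(r) {
    set.seed(380 + r)
    covs <- data.frame(carbonate = runif(500, 20, 80), v1 = runif(500),
                       v2 = runif(500), v3 = runif(500), v4 = runif(500),
                       v5 = runif(500))
    N <- rnbinom(500, mu = exp(0.5 + 0.05 * covs$carbonate), size = 1.73)
    sel <- forward_select_aic(function(tm) fit_abundance_model(N, covs[tm]),
                              candidates = names(covs))
    length(sel$terms_selected) >= 1 && sel$terms_selected[1] == "carbonate"
  }, logical(1))
  expect_identical(sum(firsts), 5L)
})

test_that("simulated components refit close to the generating models", {
  models <- known_rad_models()
  frame <- rad_sim_frame(300, seed = 40)
  sim <- simulate_rad_components(models, frame[c("carbonate", "nitrate_mean")],
                                 frame$area, seed = 41)
  expect_true(all(sim$S <= pmin(sim$N, models$richness$cap)))

  m_ab <- fit_abundance_model(sim$N, frame["carbonate"], frame$area)
  ci <- component_confint(m_ab)
  truth_ab <- models$abundance$coefficients
  cover_ab <- truth_ab >= ci[, 1] & truth_ab <= ci[, 2]

  sc <- rad_scaled_covariates(sim$N, sim$S, frame$area,
                              moments = models$evenness$moments)
  m_ri <- fit_richness_model(sim$S, sim$N,
                             cbind(frame["nitrate_mean"], sc["log_N_scale"]),
                             cap = models$richness$cap)
  m_ev <- fit_evenness_model(sim$evenness, sc,
                             terms = models$evenness$terms)
  ci_ev <- component_confint(m_ev)
  truth_ev <- models$evenness$coefficients
  cover_ev <- truth_ev >= ci_ev[, 1] & truth_ev <= ci_ev[, 2]
  expect_gte(mean(c(cover_ab, cover_ev)), 0.5)
  expect_true(m_ri$converged)
})

test_that("rad maps: zero covariance gives zero CV, bootstrap mean is consistent", {
  s <- small_survey(seed = 42, n_lon = 10, n_lat = 10, n_sites = 40,
                    n_species = 150)
  covs <- attach_covariates(s$dataset, s$env)
  comp <- survey_rad_components(s$dataset)
  N <- vapply(comp, `[[`, integer(1), "N")
  S <- vapply(comp, `[[`, integer(1), "S")
  eta <- vapply(comp, `[[`, numeric(1), "evenness")
  areas <- s$dataset$samples$area_swept_m2

  m_ab <- fit_abundance_model(N, covs["carbonate"], areas)
  sc <- rad_scaled_covariates(N, S, areas)
  m_ri <- fit_richness_model(S, N, sc["log_N_scale"])
  m_rc <- fit_rank_curve(comp)
  m_ev <- fit_evenness_model(eta, sc, terms = c("N_scale", "S_scale"))
  models <- rad_model_set(m_ab, m_ri, m_rc, m_ev)

  maps <- predict_rad_maps(models, s$env, reference_area = 1000,
                           n_draws = 400, seed = 43)
  expect_identical(nrow(maps), 100L)
  expect_true(all(maps$N_cv >= 0 & maps$S_cv >= 0 & maps$evenness_cv >= 0))

  # bootstrap consistency: mean over draws near the plug-in prediction
  draws <- vapply(1:400, function(b) 0, numeric(1))  # recompute via seed
  set.seed(43)
  co <- MASS::mvrnorm(400, m_ab$coefficients, m_ab$vcov)
  gridcovs <- grid_covariates(s$env)
  plug <- predict_abundance(m_ab, gridcovs, rep(1000, 100))
  boots <- vapply(1:400, function(b)
    predict_abundance(m_ab, gridcovs, rep(1000, 100), coefficients = co[b, ]),
    numeric(100))
  mc_se <- apply(boots, 1, sd) / sqrt(400)
  expect_gt(mean(abs(rowMeans(boots) - plug) <= 3 * mc_se + 0.02 * plug), 0.9)

  # degenerate covariance: CV identically zero
  zero <- models
  zero$abundance$vcov[] <- 0
  zero$richness$vcov[] <- 0
  zero$evenness$vcov[] <- 0
  maps0 <- predict_rad_maps(zero, s$env, n_draws = 60, seed = 44)
  expect_equal(max(maps0$N_cv), 0)
  expect_equal(max(maps0$S_cv), 0)
  expect_equal(max(maps0$evenness_cv), 0)
})
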