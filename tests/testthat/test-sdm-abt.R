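# boosted regression trees, aggregation, influence, sign and AUC

test_that("auc matches hand-counted example and handles edge rankings", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(auc(10:1, c(rep(0, 5), rep(1, 5))), 0)
  expect_equal(auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)  # all tied
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(8)
  for (r in 1:10) {
    s <- rnorm(40)
    y <- rbinom(40, 1, plogis(s))
    if (length(unique(y)) < 2) next
    a0 <- auc(s, y)
    expect_equal(auc(exp(s), y), a0)
    expect_equal(auc(qlogis(plogis(s)), y), a0)
    expect_equal(auc(s * 100 - 3, y), a0)
  }
})

test_that("fit_brt shrinks to the base rate and separates separable data", {
  set.seed(1)
  n <- 200
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- as.numeric(X$x1 > 0.5)

  tiny <- fit_brt(X, y, learning_rate = 1e-5, n_trees = 10, seed = 1)
  expect_lt(max(abs(predict(tiny, X) - mean(y))), 1e-3)

  sep <- fit_brt(X, y, learning_rate = 0.2, n_trees = 150, seed = 1)
  expect_equal(auc(predict(sep, X), y), 1.0)

  expect_error(fit_brt(X, rep(1, n)), "constant response")
  expect_error(fit_brt(X, y, learning_rate = 0), "learning_rate")
  expect_error(fit_brt(X, y, learning_rate = 1.5), "learning_rate")
})

test_that("pure-noise labels yield no systematic held-out gain", {
  set.seed(2)
  gains <- vapply(1:8, function(r) {
    n <- 120
    X <- data.frame(x1 = runif(n), x2 = runif(n))
    y <- rbinom(n, 1, 0.5)
    tr <- seq_len(80)
    m <- fit_brt(X[tr, ], y[tr], learning_rate = 0.05, n_trees = 100,
                 seed = r, validation = list(X = X[-tr, ], y = y[-tr]))
    p0 <- mean(y[tr])
    null_dev <- -2 * mean(y[-tr] * log(p0) + (1 - y[-tr]) * log(1 - p0))
    null_dev - min(m$valid_deviance)
  }, numeric(1))
  expect_lt(mean(gains), 0.05)
})

test_that("abt aggregation is the exact mean of fold probabilities", {
  sim <- sim_single_signal(n = 150, seed = 3)
  m <- fit_abt(sim$X, sim$y, n_folds = 10, seed = 3,
               learning_rate = 0.1, n_trees = 60)
  expect_length(m$fold_models, 10)
  expect_true(all(m$best_trees >= 1 & m$best_trees <= 60))
  agg <- predict(m, sim$X)
  byhand <- rowMeans(vapply(m$fold_models, function(f) predict(f, sim$X),
                            numeric(nrow(sim$X))))
  expect_identical(agg, byhand)
  expect_true(all(agg >= 0 & agg <= 1))
  expect_error(fit_abt(sim$X[1:5, ], sim$y[1:5], n_folds = 10),
               "fewer rows than folds")
})

test_that("relative influence sums to 100, zeroes unused covariates, finds the signal", {
  sim <- sim_single_signal(n = 300, seed = 4)
  X <- sim$X
  X$constant <- 1  # can never be split on
  m <- fit_abt(X, sim$y, n_folds = 10, seed = 4, learning_rate = 0.05,
               n_trees = 120, tree_depth = 1)
  infl <- relative_influence(m)$percent
  expect_equal(sum(infl), 100, tolerance = 1e-6)
  expect_true(all(infl >= 0))
  expect_identical(unname(infl["constant"]), 0)
  expect_gt(infl["x1"], 80)
})

test_that("partial dependence labels match the generative shape", {
  sim <- sim_single_signal(n = 300, seed = 5)
  m <- fit_abt(sim$X, sim$y, n_folds = 10, seed = 5, learning_rate = 0.05,
               n_trees = 120, tree_depth = 1)
  expect_identical(classify_sign(partial_dependence(m, "x1")), "+")
  expect_error(partial_dependence(m, "nope"), "unknown covariate")

  # binary covariate: curve takes exactly two values
  set.seed(6)
  Xb <- data.frame(b = rbinom(200, 1, 0.5), x = runif(200))
  yb <- rbinom(200, 1, plogis(-2 + 3 * Xb$b))
  mb <- fit_abt(Xb, yb, n_folds = 5, seed = 6, learning_rate = 0.1,
                n_trees = 60)
  pd <- partial_dependence(mb, "b")
  expect_identical(nrow(pd), 2L)

  # flat curve classification
  expect_identical(classify_sign(data.frame(x = 1:5, p = rep(0.3, 5))), "flat")
  # interior peak exceeding both endpoints
  expect_identical(classify_sign(data.frame(x = 1:5,
                                            p = c(0.1, 0.3, 0.6, 0.3, 0.1))),
                   "peak")
})

test_that("grid prediction needs every covariate and respects [0,1]", {
  s <- small_survey(seed = 7, n_lon = 10, n_lat = 10, n_sites = 40,
                    n_species = 150)
  covs <- attach_covariates(s$dataset, s$env)
  occ <- colSums(s$dataset$abundance > 0)
  usable <- occ[occ >= 3 & occ <= nrow(s$dataset$samples) - 3]
  sp <- names(usable)[which.min(abs(usable - nrow(s$dataset$samples) / 2))]
  y <- as.numeric(s$dataset$abundance[, sp] > 0)
  m <- fit_abt(covs, y, n_folds = 5, seed = 7, learning_rate = 0.1,
               n_trees = 40)
  map <- predict_abt_map(m, s$env)
  expect_identical(nrow(map), 100L)
  expect_true(all(map$probability >= 0 & map$probability <= 1))

  cells2 <- s$env$cells
  cells2$depth <- NULL
  grid2 <- environmental_grid(cells2, s$env$cell_size)
  expect_error(predict(m, grid2), "missing covariate layer")

  # all-identical cells give a constant map
  cells3 <- s$env$cells[rep(1, 20), ]
  cells3$cell_id <- 1:20
  grid3 <- environmental_grid(cells3, s$env$cell_size)
  expect_equal(diff(range(predict(m, grid3))), 0)
})

test_that("abt recovers depth-band species against the simulation truth", {
  s <- small_survey(seed = 9, n_lon = 20, n_lat = 20, n_sites = 120,
                    n_species = 80)
  covs <- attach_covariates(s$dataset, s$env)
  pa <- presence_absence(s$dataset)
  occ <- colSums(pa)
  # a mid-occurrence species with a clear niche
  sp <- names(sort(occ[occ >= 20 & occ <= 90], decreasing = TRUE))[1]
  y <- as.numeric(pa[, sp])
  m <- fit_abt(covs, y, n_folds = 10, seed = 9, learning_rate = 0.05,
               n_trees = 150)
  # generative depth band of the species from the truth record
  k <- match(sp, s$pool$species_id)
  sc <- s$pool$scaling$depth
  dgrid <- data.frame(depth = seq(150, 1850, by = 25), mud = 33,
                      carbonate = 50)
  p_true <- occurrence_probability(s$pool, dgrid)[, k]
  band <- range(dgrid$depth[p_true > 0.5 * max(p_true)])
  map <- predict(m, s$env)
  inside <- s$env$cells$depth >= band[1] & s$env$cells$depth <= band[2]
  if (sum(inside) > 5 && sum(!inside) > 5)
    expect_gt(mean(map[inside]), mean(map[!inside]))
  # and the model ranks held-in data well
  expect_gt(auc(predict(m, covs), y), 0.7)
})
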