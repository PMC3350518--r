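# Sorensen dissimilarity, I-splines, GDM fitting and composition maps

# brute-force set-based Sorensen oracle for one pair of binary rows
sorensen_oracle_pair <- function(r1, r2) {
  s1 <- which(r1 > 0); s2 <- which(r2 > 0)
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); cc <- length(setdiff(s2, s1))
  1 - 2 * a / (2 * a + b + cc)
}

test_that("sorensen matches hand counts and the set-count oracle", {
  m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))  # {A,B,C} vs {B,C,D}
  d <- sorensen_dissimilarity(m)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  ident <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  expect_equal(sorensen_dissimilarity(ident)["a", "b"], 0)
  disj <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(sorensen_dissimilarity(disj)["a", "b"], 1)

  set.seed(11)
  for (r in 1:20) {
    mm <- matrix(rbinom(60, 1, 0.45), 6, 10)
    while (any(rowSums(mm) == 0)) mm <- matrix(rbinom(60, 1, 0.45), 6, 10)
    d <- sorensen_dissimilarity(mm)
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(d[i, j], sorensen_oracle_pair(mm[i, ], mm[j, ]))
  }

  bad <- rbind(s1 = c(1, 0), empty = c(0, 0))
  expect_error(sorensen_dissimilarity(bad), "empty")
})

test_that("sorensen agrees with vegan's binary Bray-Curtis", {
  set.seed(12)
  mm <- matrix(rbinom(80, 1, 0.5), 8, 10)
  mm[rowSums(mm) == 0, 1] <- 1
  d <- sorensen_dissimilarity(mm)
  dv <- as.matrix(vegan::vegdist(mm, method = "bray", binary = TRUE))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12)
})

test_that("ispline basis is monotone, pinned at the knots, in [0,1]", {
  knots <- c(0, 0.4, 1)
  expect_equal(as.numeric(ispline_basis(0, knots)), c(0, 0, 0))
  expect_equal(as.numeric(ispline_basis(1, knots)), c(1, 1, 1))
  # clamping outside the range
  expect_equal(ispline_basis(-5, knots), ispline_basis(0, knots))
  expect_equal(ispline_basis(9, knots), ispline_basis(1, knots))

  set.seed(13)
  for (r in 1:20) {
    x <- sort(runif(2))
    b <- ispline_basis(x, knots)
    expect_true(all(b[2, ] - b[1, ] >= -1e-12))
    expect_true(all(b >= 0 & b <= 1))
  }
  # also for 4 and 5 quantile knots
  for (k in c(4, 5)) {
    kn <- sort(runif(k))
    xs <- seq(min(kn), max(kn), length.out = 50)
    B <- ispline_basis(xs, kn)
    expect_true(all(diff(B) >= -1e-12))
    expect_equal(as.numeric(B[1, ]), rep(0, k))
    expect_equal(as.numeric(B[50, ]), rep(1, k))
  }
  expect_error(ispline_basis(0.5, c(1, 1)), "distinct knots")
})

test_that("gdm fit honours constraints and explains no deviance without signal", {
  # no covariate signal: dissimilarities vary only by binomial noise
  devs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    n <- 40
    covs <- data.frame(x = runif(n), z = runif(n))
    mu <- 1 - exp(-0.9)
    d <- matrix(0, n, n)
    ut <- which(upper.tri(d))
    d[ut] <- rbinom(length(ut), 100, mu) / 100
    d <- d + t(d)
    fit <- fit_gdm(d, covs)
    expect_true(all(unlist(fit$coefficients) >= 0))
    expect_gte(fit$intercept, 0)
    fit$deviance_explained
  }, numeric(1))
  expect_lte(median(devs), 5)
})

test_that("gdm recovers a known intercept and turnover magnitude", {
  s <- sim_gdm_data(n = 80, a0 = 0.891, mag = 0.95, seed = 14)
  fit <- fit_gdm(s$d, s$covs)
  expect_true(fit$converged)
  expect_lt(abs((1 - exp(-fit$intercept)) - 0.59), 0.05)
  expect_lt(abs(gdm_magnitudes(fit)["x"] - 0.95), 0.2)
  expect_lt(gdm_magnitudes(fit)["z"], 0.15)
  expect_true(fit$deviance_explained >= 0 && fit$deviance_explained <= 100)

  # fitted functions start at 0 and reach their magnitude at the max
  f_min <- gdm_transform(fit, data.frame(x = min(s$covs$x), z = min(s$covs$z)))
  f_max <- gdm_transform(fit, data.frame(x = max(s$covs$x), z = max(s$covs$z)))
  expect_equal(as.numeric(f_min), c(0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(f_max), unname(gdm_magnitudes(fit)),
               tolerance = 1e-10)
})

test_that("adding the active covariate only improves deviance explained", {
  s <- sim_gdm_data(n = 50, seed = 15)
  fit_null <- fit_gdm(s$d, s$covs, predictors = "z")
  fit_full <- fit_gdm(s$d, s$covs, predictors = c("z", "x"))
  expect_gte(fit_full$deviance_explained, fit_null$deviance_explained)
})

test_that("predicted dissimilarity follows the closed-form link", {
  s <- sim_gdm_data(n = 60, seed = 16)
  fit <- fit_gdm(s$d, s$covs)
  same <- data.frame(x = c(0.2, 0.7), z = c(0.5, 0.1))
  p_same <- predict_gdm_dissimilarity(fit, same, same)
  expect_equal(p_same, rep(1 - exp(-fit$intercept), 2), tolerance = 1e-12)

  # widening any covariate gap never decreases the prediction
  set.seed(17)
  for (r in 1:10) {
    x0 <- runif(1, 0.3, 0.5)
    g1 <- runif(1, 0, 0.2); g2 <- g1 + runif(1, 0, 0.3)
    p1 <- predict_gdm_dissimilarity(fit, data.frame(x = x0, z = 0.5),
                                    data.frame(x = x0 + g1, z = 0.5))
    p2 <- predict_gdm_dissimilarity(fit, data.frame(x = x0, z = 0.5),
                                    data.frame(x = x0 + g2, z = 0.5))
    expect_gte(p2, p1 - 1e-12)
  }
})

test_that("composition map separates covariate clusters and stays in [0,1]", {
  s <- sim_gdm_data(n = 60, seed = 18)
  fit <- fit_gdm(s$d, s$covs)

  # grid with two covariate clusters
  n_half <- 60
  cells <- data.frame(cell_id = seq_len(2 * n_half),
                      lon = runif(2 * n_half, 146, 146.5),
                      lat = runif(2 * n_half, -44.5, -44))
  cells$depth <- c(rnorm(n_half, 0.15, 0.02), rnorm(n_half, 0.85, 0.02))
  cells$mud <- runif(2 * n_half, 0.4, 0.6)
  grid <- environmental_grid(cells, 0.01)
  fit$predictors <- c("x", "z")
  # map model predictors onto grid layers by renaming
  names(grid$cells)[match(c("depth", "mud"), names(grid$cells))] <- c("x", "z")
  grid$layers <- c("x", "z")
  grid2 <- grid
  class(grid2) <- "environmental_grid"
  rgbm <- composition_rgb_map(fit, grid2, anchor_count = 40, seed = 19)
  expect_true(all(rgbm$R >= 0 & rgbm$R <= 1))
  expect_true(all(rgbm$G >= 0 & rgbm$G <= 1))
  expect_true(all(rgbm$B >= 0 & rgbm$B <= 1))
  cols <- as.matrix(rgbm[, c("R", "G", "B")])
  within <- mean(dist(cols[1:n_half, ])) + mean(dist(cols[-(1:n_half), ]))
  between <- mean(manhattan_between <- sqrt(rowSums((
    cols[1:n_half, ] - cols[-(1:n_half), ])^2)))
  expect_lt(within / 2, between)

  expect_error(composition_rgb_map(fit, grid2, anchor_count = 3),
               "anchor_count")
})

test_that("uniform covariates give a constant map with a warning", {
  s <- sim_gdm_data(n = 40, seed = 20)
  fit <- fit_gdm(s$d, s$covs)
  cells <- data.frame(cell_id = 1:30, lon = runif(30), lat = runif(30),
                      depth = 0.5, mud = 0.5)
  names(cells)[4:5] <- c("x", "z")
  grid <- structure(list(cells = cells, layers = c("x", "z"),
                         cell_size = 0.01), class = "environmental_grid")
  expect_warning(rgbm <- composition_rgb_map(fit, grid, anchor_count = 10,
                                             seed = 21), "degenerate")
  expect_true(all(rgbm$R == rgbm$R[1]))
})

test_that("anchor projection reproduces anchor coordinates", {
  # classical MDS + Gower out-of-sample: anchors project onto themselves,
  # so anchor rows of the map equal the direct MDS colours
  s <- sim_gdm_data(n = 50, seed = 22)
  fit <- fit_gdm(s$d, s$covs)
  cells <- data.frame(cell_id = 1:40, lon = runif(40), lat = runif(40),
                      x = runif(40), z = runif(40))
  grid <- structure(list(cells = cells, layers = c("x", "z"),
                         cell_size = 0.01), class = "environmental_grid")
  rgb_all <- composition_rgb_map(fit, grid, anchor_count = 40, seed = 23)
  rgb_sub <- composition_rgb_map(fit, grid, anchor_count = 15, seed = 23)
  # both colourings order the same underlying axes up to sign/scale;
  # check rank agreement of the first channel on shared structure
  expect_gt(abs(cor(rgb_all$R, rgb_sub$R, method = "spearman")), 0.7)
})
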