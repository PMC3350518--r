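# Generalized dissimilarity modelling: Sorensen dissimilarity of
# presence/absence, monotone I-spline turnover functions fitted by
# deviance minimisation under non-negativity, and RGB composition maps
# from principal-coordinates axes of predicted dissimilarities.

#' Sorensen dissimilarity of a presence/absence matrix
#'
#' d_ij = 1 - 2a / (2a + b + c), where a is the number of species shared
#' by sites i and j and b, c the numbers unique to each. (Bray-Curtis
#' distance applied to presence/absence data reduces to this.)
#'
#' @param pa Binary matrix, sites in rows.
#' @return Symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
sorensen_dissimilarity <- function(pa) {
  pa <- (as.matrix(pa) > 0) * 1
  if (nrow(pa) < 2) stop("need at least 2 sites")
  rs <- rowSums(pa)
  if (any(rs == 0)) {
    bad <- rownames(pa)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("site with zero presences: ", paste(bad, collapse = ", "))
  }
  shared <- tcrossprod(pa)              # a
  denom <- outer(rs, rs, "+")           # 2a + b + c
  d <- 1 - 2 * shared / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  d
}

#' Monotone I-spline basis (order 2)
#'
#' Each basis function rises from 0 at the minimum knot to 1 at the
#' maximum knot and is non-decreasing everywhere; values outside the
#' knot range are clamped. With k knots there are k basis functions
#' (one per knot, quadratic between its neighbouring knots).
#'
#' @param x Numeric vector of covariate values.
#' @param knots Sorted knot locations (>= 2 distinct values).
#' @return Matrix, length(x) rows by length(knots) columns, values in
#'   `[0, 1]`.
#' @export
ispline_basis <- function(x, knots) {
  knots <- sort(knots)
  if (length(unique(knots)) < 2) stop("need at least 2 distinct knots")
  k <- length(knots)
  x <- pmin(pmax(x, knots[1]), knots[k])
  ext <- c(knots[1], knots, knots[k])   # q0 = q1, q_{k+1} = q_k
  out <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    a <- ext[j]; b <- ext[j + 1]; cc <- ext[j + 2]
    val <- numeric(length(x))
    val[x >= cc] <- 1
    if (b > a) {
      lo <- x > a & x <= b
      val[lo] <- (x[lo] - a)^2 / ((b - a) * (cc - a))
    }
    if (cc > b) {
      hi <- x > b & x < cc
      val[hi] <- 1 - (cc - x[hi])^2 / ((cc - b) * (cc - a))
    }
    out[, j] <- val
  }
  out
}

# pairwise design matrix: |I(x_i) - I(x_j)| per predictor per basis
gdm_pair_design <- function(covariates, knots_list) {
  n <- nrow(covariates)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cols <- list()
  for (p in names(knots_list)) {
    B <- ispline_basis(covariates[[p]], knots_list[[p]])
    cols[[p]] <- abs(B[pairs[, 1], , drop = FALSE] -
                       B[pairs[, 2], , drop = FALSE])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(names(knots_list), function(p)
    paste0(p, "_s", seq_along(knots_list[[p]]))))
  list(X = X, pairs = pairs)
}

gdm_deviance <- function(y, mu) {
  eps <- 1e-10
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# projected gradient descent with backtracking on the GDM deviance;
# theta = (a0, coefs), all constrained >= 0
gdm_optimise <- function(y, X, max_iter = 5000, tol = 1e-8) {
  Xa <- cbind(intercept = 1, X)
  theta <- c(max(-log(1 - pmin(mean(y), 0.99)), 1e-3), rep(0, ncol(X)))
  obj <- function(th) {
    eta <- pmin(as.numeric(Xa %*% th), 50)
    gdm_deviance(y, 1 - exp(-eta))
  }
  grad <- function(th) {
    eta <- pmin(as.numeric(Xa %*% th), 50)
    mu <- 1 - exp(-eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- (1 - y) - y * (1 - mu) / mu
    2 * as.numeric(crossprod(Xa, w))
  }
  f <- obj(theta)
  step <- 1 / max(colSums(Xa^2))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(theta)
    s <- step
    repeat {
      cand <- pmax(theta - s * g, 0)
      fc <- obj(cand)
      if (fc <= f || s < 1e-14) break
      s <- s / 2
    }
    if (s >= step / 2) step <- step * 1.3  # cautiously grow the step
    rel <- (f - fc) / max(abs(f), 1e-12)
    theta <- cand
    moved <- f - fc
    f <- fc
    if (moved >= 0 && rel < tol) { converged <- TRUE; break }
  }
  list(theta = theta, deviance = f, converged = converged, iterations = it)
}

#' Fit a generalized dissimilarity model
#'
#' Minimises the binomial-type deviance between observed dissimilarities
#' d_ij and mu_ij = 1 - exp(-eta_ij), where eta_ij = a0 +
#' sum_p |f_p(x_ip) - f_p(x_jp)| and each turnover function f_p is a
#' non-negative combination of monotone I-splines, so f_p never
#' decreases. Fitting is by projected gradient descent with
#' backtracking under the non-negativity constraints. Percent deviance
#' explained is 100 (1 - D_model / D_null), with D_null from the
#' intercept-only fit.
#'
#' @param dist Symmetric dissimilarity matrix (e.g. from
#'   [sorensen_dissimilarity()]).
#' @param covariates Data frame of site covariates (rows in the order of
#'   `dist`).
#' @param predictors Covariate columns to use (default all).
#' @param n_basis I-spline basis functions per predictor (= number of
#'   knots; default 3, knots at min/median/max).
#' @param max_iter,tol Optimiser controls.
#' @return A `gdm_model`: intercept, per-predictor coefficient vectors,
#'   knots, deviance explained, convergence flag.
#' @export
fit_gdm <- function(dist, covariates, predictors = NULL, n_basis = 3,
                    max_iter = 5000, tol = 1e-8) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) < 3) stop("need at least 3 sites")
  if (nrow(covariates) != nrow(dist))
    stop("covariate rows do not match the dissimilarity matrix")
  if (is.null(predictors)) predictors <- names(covariates)
  knots_list <- lapply(covariates[predictors], function(x) {
    q <- unique(quantile(x, probs = seq(0, 1, length.out = n_basis)))
    if (length(q) < 2) q <- c(q[1], q[1] + 1e-8)
    q
  })
  names(knots_list) <- predictors
  des <- gdm_pair_design(covariates[predictors], knots_list)
  y <- dist[des$pairs]

  null_a0 <- optimise(function(a)
    gdm_deviance(y, 1 - exp(-a)), c(0, 20))$minimum
  d_null <- gdm_deviance(y, 1 - exp(-null_a0))

  opt <- gdm_optimise(y, des$X, max_iter = max_iter, tol = tol)
  if (!opt$converged)
    warning("GDM fit did not converge in ", max_iter,
            " iterations; partial fit returned")
  coefs <- opt$theta[-1]
  per_pred <- split(coefs, rep(predictors, vapply(knots_list, length,
                                                  integer(1))))
  per_pred <- per_pred[predictors]
  structure(list(intercept = opt$theta[1], coefficients = per_pred,
                 knots = knots_list, predictors = predictors,
                 deviance = opt$deviance, null_deviance = d_null,
                 deviance_explained = 100 * (1 - opt$deviance / d_null),
                 converged = opt$converged, iterations = opt$iterations,
                 n_sites = nrow(covariates)),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat("gdm_model:", x$n_sites, "sites,", length(x$predictors), "predictors\n")
  cat(sprintf("  intercept a0 = %.4f (dissimilarity at zero distance = %.3f)\n",
              x$intercept, 1 - exp(-x$intercept)))
  cat(sprintf("  deviance explained: %.1f%%%s\n", x$deviance_explained,
              if (!x$converged) " (not converged)" else ""))
  mag <- sort(gdm_magnitudes(x), decreasing = TRUE)
  cat("  fitted-function magnitudes:\n")
  for (nm in names(mag)) cat(sprintf("    %-16s %.3f\n", nm, mag[nm]))
  invisible(x)
}

#' Magnitudes of the fitted turnover functions
#'
#' The magnitude of f_p (its value at the covariate maximum, equal to
#' the sum of its I-spline coefficients) measures the total
#' compositional turnover associated with predictor p.
#'
#' @param model A `gdm_model`.
#' @return Named numeric vector.
#' @export
gdm_magnitudes <- function(model) {
  vapply(model$coefficients, sum, numeric(1))
}

#' Evaluate the fitted turnover functions
#'
#' @param model A `gdm_model`.
#' @param covariates Data frame with the model predictors.
#' @return Matrix of f_p values, one column per predictor.
#' @export
gdm_transform <- function(model, covariates) {
  out <- vapply(model$predictors, function(p) {
    if (!p %in% names(covariates)) stop("missing covariate: ", p)
    as.numeric(ispline_basis(covariates[[p]], model$knots[[p]]) %*%
                 model$coefficients[[p]])
  }, numeric(nrow(as.data.frame(covariates))))
  matrix(out, nrow = nrow(as.data.frame(covariates)),
         dimnames = list(NULL, model$predictors))
}

#' Predicted dissimilarity between site pairs
#'
#' Returns 1 - exp(-eta) for each pair; at zero environmental distance
#' this equals 1 - exp(-a0), the expected dissimilarity of samples taken
#' in identical environments.
#'
#' @param model A `gdm_model`.
#' @param x1,x2 Data frames of covariates (paired row-wise).
#' @return Vector of predicted dissimilarities in `[0, 1)`.
#' @export
predict_gdm_dissimilarity <- function(model, x1, x2) {
  f1 <- gdm_transform(model, as.data.frame(x1))
  f2 <- gdm_transform(model, as.data.frame(x2))
  eta <- model$intercept + rowSums(abs(f1 - f2))
  1 - exp(-pmin(eta, 50))
}

# predicted dissimilarity matrix among rows of a covariate frame
gdm_dissimilarity_matrix <- function(model, covariates) {
  f <- gdm_transform(model, covariates)
  eta <- model$intercept + as.matrix(dist(f, method = "manhattan"))
  d <- 1 - exp(-pmin(eta, 50))
  diag(d) <- 0
  d
}

#' RGB composition map from a fitted GDM
#'
#' Classical MDS (principal coordinates) is applied to the predicted
#' dissimilarities among a random subset of anchor cells; the remaining
#' cells are projected onto the first three axes from their
#' dissimilarities to the anchors (Gower's out-of-sample formula). Each
#' axis is min-max scaled to `[0, 1]` and assigned to the red, green and
#' blue channels, so cells with similar predicted composition receive
#' similar colours.
#'
#' @param model A `gdm_model`.
#' @param grid An `environmental_grid` supplying the model covariates.
#' @param anchor_count Number of anchor cells (>= 4).
#' @param seed Integer seed for the anchor sample.
#' @return Data frame: `cell_id`, `lon`, `lat`, `R`, `G`, `B`.
#' @export
composition_rgb_map <- function(model, grid, anchor_count = 500, seed = 1) {
  stopifnot(inherits(grid, "environmental_grid"))
  if (anchor_count < 4) stop("anchor_count must be at least 4")
  covs <- grid_covariates(grid, model$predictors)
  n <- nrow(covs)
  set.seed(seed)
  anchors <- sort(sample.int(n, min(anchor_count, n)))
  f <- gdm_transform(model, covs)
  fa <- f[anchors, , drop = FALSE]
  eta_a <- model$intercept + as.matrix(dist(fa, method = "manhattan"))
  Da <- 1 - exp(-pmin(eta_a, 50)); diag(Da) <- 0

  off <- Da[upper.tri(Da)]
  if (length(off) == 0 || max(off) - min(off) < 1e-12) {
    warning("degenerate (all-equal) dissimilarities; constant map returned")
    return(data.frame(cell_id = grid$cells$cell_id, lon = grid$cells$lon,
                      lat = grid$cells$lat, R = 0.5, G = 0.5, B = 0.5))
  }
  mds <- cmdscale(Da, k = 3, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < 3)  # fewer than 3 positive eigenvalues
    pts <- cbind(pts, matrix(0, nrow(pts), 3 - ncol(pts)))

  # Gower out-of-sample projection of every cell onto the anchor axes
  q <- rowSums(pts^2)
  XtXinv <- MASS::ginv(crossprod(pts))
  eta_all <- model$intercept +
    manhattan_cross(f, fa)
  D2 <- (1 - exp(-pmin(eta_all, 50)))^2
  D2[cbind(anchors, seq_along(anchors))] <- 0
  coords <- 0.5 * sweep(-D2, 2, q, "+") %*% pts %*% XtXinv

  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  data.frame(cell_id = grid$cells$cell_id,
             lon = grid$cells$lon, lat = grid$cells$lat,
             R = scale01(coords[, 1]), G = scale01(coords[, 2]),
             B = scale01(coords[, 3]))
}

# cross Manhattan distances between rows of A and rows of B
manhattan_cross <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A)))
    out <- out + abs(outer(A[, j], B[, j], "-"))
  out
}
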