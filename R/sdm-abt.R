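# Aggregated boosted regression trees for single-species
# presence/absence: stagewise gradient boosting on the Bernoulli
# deviance with shallow regression trees, pruned per fold by 10-fold
# cross-validation, and predictions averaged over the fold models.

# ---- compact regression trees -------------------------------------------

# convert an rpart fit to a flat node table with Newton leaf values
# computed on the bag rows: value = sum(residual) / sum(p (1 - p))
rpart_to_table <- function(fit, r_bag, hess_bag) {
  frame <- fit$frame
  nodes <- as.integer(row.names(frame))
  is_leaf <- frame$var == "<leaf>"
  tab <- data.frame(node = nodes,
                    var = as.character(frame$var),
                    cut = NA_real_, dir = NA_integer_,
                    value = NA_real_, stringsAsFactors = FALSE)
  if (any(!is_leaf)) {
    sp <- fit$splits  # one row per primary split (maxcompete=maxsurrogate=0)
    tab$cut[!is_leaf] <- sp[, "index"]
    tab$dir[!is_leaf] <- sign(sp[, "ncat"])  # -1: left if x < cut
  }
  # route bag rows to leaves to compute Newton values
  leaf_of <- nodes[fit$where]
  for (ld in which(is_leaf)) {
    in_leaf <- leaf_of == nodes[ld]
    num <- sum(r_bag[in_leaf])
    den <- sum(hess_bag[in_leaf])
    tab$value[ld] <- if (den > 1e-10) num / den else 0
  }
  tab
}

# vectorised prediction from a node table
tree_predict <- function(tab, X) {
  node <- rep(1L, nrow(X))
  repeat {
    rows <- match(node, tab$node)
    leaf <- tab$var[rows] == "<leaf>"
    if (all(leaf)) return(tab$value[rows])
    idx <- which(!leaf)
    xv <- X[cbind(idx, match(tab$var[rows[idx]], colnames(X)))]
    go_left <- ifelse(tab$dir[rows[idx]] < 0,
                      xv < tab$cut[rows[idx]],
                      xv >= tab$cut[rows[idx]])
    node[idx] <- node[idx] * 2L + ifelse(go_left, 0L, 1L)
  }
}

# squared-error improvements of each split, summed per covariate
tree_improvements <- function(tab, X_bag, r_bag, covariates) {
  imp <- setNames(numeric(length(covariates)), covariates)
  internal <- which(tab$var != "<leaf>")
  if (length(internal) == 0) return(imp)
  node <- rep(1L, nrow(X_bag))
  # walk top-down: at each internal node compute SS(parent) - SS(children)
  for (row in internal[order(tab$node[internal])]) {
    members <- which(node == tab$node[row])
    if (length(members) == 0) next
    xv <- X_bag[members, tab$var[row]]
    go_left <- if (tab$dir[row] < 0) xv < tab$cut[row] else xv >= tab$cut[row]
    rl <- r_bag[members[go_left]]; rr <- r_bag[members[!go_left]]
    ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
    gain <- ss(r_bag[members]) - ss(rl) - ss(rr)
    imp[tab$var[row]] <- imp[tab$var[row]] + max(gain, 0)
    node[members[go_left]] <- tab$node[row] * 2L
    node[members[!go_left]] <- tab$node[row] * 2L + 1L
  }
  imp
}

bernoulli_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- boosted model -------------------------------------------------------

#' Fit a boosted regression tree model
#'
#' Stagewise gradient boosting of the Bernoulli deviance: at each stage
#' a shallow regression tree is fitted to the gradient residuals y - p
#' on a random bag of rows, its leaf values are replaced by Newton
#' steps, and the model is updated with shrinkage `learning_rate`.
#' Per-stage squared-error improvements are recorded per covariate for
#' the relative-influence summary.
#'
#' @param X Data frame of numeric covariates.
#' @param y Binary response (needs both classes).
#' @param learning_rate Shrinkage nu in (0, 1].
#' @param tree_depth Maximum tree depth (default 2, allowing pairwise
#'   interactions).
#' @param n_trees Number of boosting stages (>= 1).
#' @param bag_fraction Row-subsampling fraction per stage.
#' @param min_obs Minimum observations in a node eligible for splitting.
#' @param seed Optional integer seed (bag draws).
#' @param validation Optional list(X, y); when given, the held-out
#'   deviance after each stage is recorded in `$valid_deviance`.
#' @return A `brt_model`.
#' @export
fit_brt <- function(X, y, learning_rate = 0.01, tree_depth = 2,
                    n_trees = 1000, bag_fraction = 0.5, min_obs = 8,
                    seed = NULL, validation = NULL) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("constant response: need both classes")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]")
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  Xm <- as.matrix(X)
  covariates <- colnames(Xm)

  F0 <- qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  Fx <- rep(F0, n)
  Fv <- NULL
  Xv <- NULL
  if (!is.null(validation)) {
    Xv <- as.matrix(as.data.frame(validation$X))
    Fv <- rep(F0, nrow(Xv))
  }
  trees <- vector("list", n_trees)
  improvements <- matrix(0, n_trees, length(covariates),
                         dimnames = list(NULL, covariates))
  valid_dev <- numeric(n_trees)
  ctrl <- rpart::rpart.control(maxdepth = tree_depth, cp = 0,
                               minsplit = min_obs, minbucket = max(2, min_obs %/% 2),
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  n_bag <- max(2, floor(bag_fraction * n))
  df_fit <- as.data.frame(Xm)
  for (m in seq_len(n_trees)) {
    bag <- sample.int(n, n_bag)
    p <- plogis(Fx)
    r <- y - p
    hess <- p * (1 - p)
    dat <- df_fit[bag, , drop = FALSE]
    dat$..r <- r[bag]
    fit <- rpart::rpart(..r ~ ., data = dat, method = "anova",
                        control = ctrl)
    tab <- rpart_to_table(fit, r[bag], hess[bag])
    trees[[m]] <- tab
    improvements[m, ] <- tree_improvements(tab, Xm[bag, , drop = FALSE],
                                           r[bag], covariates)
    Fx <- Fx + learning_rate * tree_predict(tab, Xm)
    if (!is.null(Fv)) {
      Fv <- Fv + learning_rate * tree_predict(tab, Xv)
      valid_dev[m] <- bernoulli_deviance(validation$y, plogis(Fv))
    }
  }
  structure(list(trees = trees, intercept = F0,
                 learning_rate = learning_rate,
                 covariates = covariates,
                 improvements = improvements,
                 valid_deviance = if (is.null(Fv)) NULL else valid_dev),
            class = "brt_model")
}

#' Predict presence probability from a boosted model
#'
#' @param object A `brt_model`.
#' @param newdata Data frame with the model covariates.
#' @param n_trees Use only the first `n_trees` stages (default all).
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.brt_model <- function(object, newdata, n_trees = NULL, ...) {
  Xm <- as.matrix(as.data.frame(newdata)[, object$covariates, drop = FALSE])
  m <- if (is.null(n_trees)) length(object$trees) else n_trees
  Fx <- rep(object$intercept, nrow(Xm))
  for (k in seq_len(m))
    Fx <- Fx + object$learning_rate * tree_predict(object$trees[[k]], Xm)
  plogis(Fx)
}

# truncate a brt_model to its first m trees
truncate_brt <- function(model, m) {
  model$trees <- model$trees[seq_len(m)]
  model$improvements <- model$improvements[seq_len(m), , drop = FALSE]
  model$valid_deviance <- model$valid_deviance[seq_len(m)]
  model
}

# ---- aggregated boosted trees -------------------------------------------

stratified_folds <- function(y, n_folds) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  if (length(idx1) < n_folds || length(idx0) < n_folds) {
    # every fold must retain both classes in the TRAINING split; with
    # few presences assign them round-robin so no fold holds them all
    if (length(idx1) < 2 || length(idx0) < 2)
      stop("too few presences for stratified folds")
  }
  fold <- integer(length(y))
  fold[sample(idx1)] <- rep_len(seq_len(n_folds), length(idx1))
  fold[sample(idx0)] <- rep_len(seq_len(n_folds), length(idx0))
  fold
}

#' Fit an aggregated boosted tree (ABT) model
#'
#' Fits one boosted model per cross-validation fold, each trained on the
#' other folds and pruned to the tree count that minimises the held-out
#' Bernoulli deviance on its own fold; the aggregated prediction is the
#' arithmetic mean of the fold-model probabilities. Fold assignment is
#' stratified by the response.
#'
#' @param X Data frame of covariates.
#' @param y Binary response.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed (fold draw and bag draws).
#' @param ... Passed to [fit_brt()] (`learning_rate`, `n_trees`, ...).
#' @return An `abt_model`: fold models, fold assignment, selected tree
#'   counts, training data (kept for partial dependence).
#' @export
fit_abt <- function(X, y, n_folds = 10, seed = 1, ...) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (nrow(X) < n_folds) stop("fewer rows than folds")
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  models <- vector("list", n_folds)
  best_trees <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    m <- fit_brt(X[tr, , drop = FALSE], y[tr], ...,
                 validation = list(X = X[!tr, , drop = FALSE], y = y[!tr]))
    best_trees[f] <- which.min(m$valid_deviance)
    models[[f]] <- truncate_brt(m, best_trees[f])
  }
  structure(list(fold_models = models, fold = fold,
                 best_trees = best_trees, covariates = colnames(X),
                 X = X, y = y),
            class = "abt_model")
}

#' @export
print.abt_model <- function(x, ...) {
  cat("abt_model:", length(x$fold_models), "fold models over",
      length(x$covariates), "covariates\n")
  cat("  selected tree counts:", paste(x$best_trees, collapse = ", "), "\n")
  infl <- relative_influence(x)
  top <- head(sort(infl$percent, decreasing = TRUE), 3)
  cat("  top influences:", paste(sprintf("%s %.1f%%", names(top), top),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Aggregated probability predictions
#'
#' @param object An `abt_model`.
#' @param newdata Data frame or `environmental_grid` supplying every
#'   covariate the model used.
#' @param ... Unused.
#' @return Vector of probabilities in `[0, 1]` (mean over fold models).
#' @export
predict.abt_model <- function(object, newdata, ...) {
  nd <- if (inherits(newdata, "environmental_grid"))
    grid_covariates(newdata, object$covariates) else as.data.frame(newdata)
  missing_covs <- setdiff(object$covariates, names(nd))
  if (length(missing_covs) > 0)
    stop("missing covariate layer: ", paste(missing_covs, collapse = ", "))
  probs <- vapply(object$fold_models, function(m) predict(m, nd),
                  numeric(nrow(nd)))
  rowMeans(matrix(probs, nrow = nrow(nd)))
}

#' Gridded probability-of-presence map
#'
#' @param model An `abt_model`.
#' @param grid An `environmental_grid`.
#' @return Data frame: `cell_id`, `lon`, `lat`, `probability`.
#' @export
predict_abt_map <- function(model, grid) {
  stopifnot(inherits(grid, "environmental_grid"))
  data.frame(cell_id = grid$cells$cell_id,
             lon = grid$cells$lon, lat = grid$cells$lat,
             probability = predict(model, grid))
}

#' Relative influence of the covariates
#'
#' Squared-error split improvements are summed per covariate across all
#' retained trees and folds and normalised to percentages (summing to
#' 100). A covariate never split on scores 0.
#'
#' @param model An `abt_model` or `brt_model`.
#' @return List with `percent` (named vector) and `raw` sums.
#' @export
relative_influence <- function(model) {
  raw <- if (inherits(model, "abt_model")) {
    Reduce(`+`, lapply(model$fold_models, function(m) colSums(m$improvements)))
  } else colSums(model$improvements)
  total <- sum(raw)
  pct <- if (total > 0) 100 * raw / total else raw * 0
  list(percent = pct, raw = raw)
}

#' Partial dependence of the aggregated prediction on one covariate
#'
#' The covariate is clamped at each grid point and the aggregated
#' probability is averaged over the training rows.
#'
#' @param model An `abt_model`.
#' @param covariate Covariate name.
#' @param grid_points Number of evaluation points (quantile-spread over
#'   the training range), or a numeric vector of points.
#' @return Data frame `x`, `p`.
#' @export
partial_dependence <- function(model, covariate, grid_points = 20) {
  if (!covariate %in% model$covariates) stop("unknown covariate: ", covariate)
  xs <- if (length(grid_points) > 1) grid_points else {
    vals <- unique(model$X[[covariate]])
    if (length(vals) <= grid_points) sort(vals) else
      seq(min(vals), max(vals), length.out = grid_points)
  }
  p <- vapply(xs, function(v) {
    Xc <- model$X
    Xc[[covariate]] <- v
    mean(predict(model, Xc))
  }, numeric(1))
  data.frame(x = xs, p = p)
}

#' Classify the sign of a partial-dependence curve
#'
#' `"+"` when the Spearman correlation of the curve with its grid is at
#' least 0.6, `"-"` when at most -0.6; otherwise `"peak"` when an
#' interior maximum exceeds both endpoints, else `"flat"`.
#'
#' @param curve Data frame from [partial_dependence()] (columns `x`,
#'   `p`).
#' @return One of `"+"`, `"-"`, `"peak"`, `"flat"`.
#' @export
classify_sign <- function(curve) {
  p <- curve$p
  if (max(p) - min(p) < 1e-10) return("flat")
  rho <- suppressWarnings(cor(curve$x, p, method = "spearman"))
  if (!is.na(rho)) {
    if (rho >= 0.6) return("+")
    if (rho <= -0.6) return("-")
  }
  k <- which.max(p)
  if (k > 1 && k < length(p) && p[k] > p[1] && p[k] > p[length(p)])
    return("peak")
  "flat"
}

#' Area under the ROC curve
#'
#' Mann-Whitney probability that a random presence outranks a random
#' absence; ties count one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes required).
#' @return Value in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of an ABT model
#'
#' Each site is scored by the fold model that held it out, so the AUC
#' measures out-of-sample ranking accuracy rather than resubstitution
#' fit.
#'
#' @param model An `abt_model`.
#' @return AUC in `[0, 1]`.
#' @export
abt_cv_auc <- function(model) {
  p <- numeric(length(model$y))
  for (f in seq_along(model$fold_models)) {
    idx <- model$fold == f
    p[idx] <- predict(model$fold_models[[f]],
                      model$X[idx, , drop = FALSE])
  }
  auc(p, model$y)
}

#' Influence / sign / AUC summary of an ABT model
#'
#' One row per covariate with its percent influence and, for covariates
#' above `sign_threshold` percent, the partial-dependence sign label;
#' the cross-validated AUC ([abt_cv_auc()]) is attached as an
#' attribute.
#'
#' @param model An `abt_model`.
#' @param sign_threshold Percent influence above which the sign is
#'   reported (default 10, matching common reporting practice).
#' @return Data frame `covariate`, `percent_influence`, `sign`; with
#'   attribute `auc`.
#' @export
abt_summary <- function(model, sign_threshold = 10) {
  infl <- relative_influence(model)$percent
  signs <- rep("", length(infl))
  for (i in seq_along(infl)) {
    if (infl[i] > sign_threshold)
      signs[i] <- classify_sign(partial_dependence(model, names(infl)[i]))
  }
  out <- data.frame(covariate = names(infl),
                    percent_influence = unname(infl),
                    sign = signs, stringsAsFactors = FALSE)
  attr(out, "auc") <- abt_cv_auc(model)
  out
}
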