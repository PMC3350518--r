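# Rank-abundance-distribution analysis: a site's RAD is factorized into
# total abundance N, species richness S | N, and relative abundances
# n | N, S, each modelled separately; the site log-likelihood is the sum
# of the three component log-likelihoods.

#' Decompose a site's counts into RAD components
#'
#' Total abundance N is the sum of counts over countable species (taxa
#' flagged non-countable, e.g. colonial corals, are excluded throughout);
#' richness S is the number of countable species with positive count;
#' the relative-abundance vector n holds the sorted (descending)
#' proportions; evenness is computed by [compute_evenness()].
#'
#' @param counts Non-negative integer vector of species counts at one
#'   site.
#' @param countable Logical vector marking countable taxa (default all).
#' @param area Swept area of the sample, m^2 (> 0).
#' @return A `rad_components` list with `N`, `S`, `n`, `area`,
#'   `evenness`.
#' @export
decompose_rad <- function(counts, countable = NULL, area = 1) {
  if (any(counts < 0)) stop("negative count")
  if (area <= 0) stop("area must be positive")
  if (is.null(countable)) countable <- rep(TRUE, length(counts))
  cc <- counts[countable]
  N <- sum(cc)
  pos <- cc[cc > 0]
  S <- length(pos)
  n <- if (S > 0) sort(pos, decreasing = TRUE) / N else numeric(0)
  structure(list(N = as.integer(N), S = as.integer(S), n = n,
                 area = area, evenness = compute_evenness(n)),
            class = "rad_components")
}

#' Evenness of a relative-abundance vector
#'
#' The RAD curve is log proportion against scaled rank
#' z = (r - 1)/(S - 1); a quadratic g(z) is fitted by least squares and
#' evenness is |g'(0)|, the steepness of the curve at the most abundant
#' species. A perfectly flat RAD gives 0. For S = 2 the definition
#' reduces to |log n1 - log n2|; for S <= 1 evenness is 0 by convention.
#'
#' @param n Descending relative-abundance vector (sums to 1).
#' @return Non-negative scalar; larger values mean steeper (less even)
#'   rank-abundance curves.
#' @export
compute_evenness <- function(n) {
  S <- length(n)
  if (S <= 1) return(0)
  if (any(n <= 0)) stop("zero proportion in relative-abundance vector")
  if (S == 2) return(abs(log(n[1]) - log(n[2])))
  z <- (seq_len(S) - 1) / (S - 1)
  fit <- lm(log(n) ~ z + I(z^2))
  abs(unname(coef(fit)[2]))
}

#' RAD components for every site of a survey
#'
#' @param dataset A `survey_dataset`.
#' @return List of `rad_components`, one per site, named by site_id.
#' @export
survey_rad_components <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  countable <- dataset$species$countable
  out <- lapply(seq_len(nrow(dataset$samples)), function(i)
    decompose_rad(dataset$abundance[i, ], countable,
                  dataset$samples$area_swept_m2[i]))
  names(out) <- dataset$samples$site_id
  out
}

# ---- component model container ------------------------------------------

#' Construct a component model
#'
#' Usually produced by the fitting functions; the constructor is exposed
#' so that a known generative model can be written down directly (e.g.
#' to simulate from it with [simulate_rad_components()]).
#'
#' @param family One of `"nb_abundance"`, `"truncated_nb_richness"`,
#'   `"multinomial_rank_curve"`, `"gamma_evenness"`.
#' @param coefficients Named coefficient vector (first element the
#'   intercept for regression families).
#' @param vcov Coefficient covariance matrix (zeros for a known model).
#' @param theta NB dispersion, where applicable.
#' @param terms Covariate names (excluding the intercept).
#' @param aic,loglik Fit statistics (NA for a known model).
#' @param ... Further fields (e.g. `cap`, `dispersion`, `moments`).
#' @return A `component_model`.
#' @export
component_model <- function(family, coefficients, vcov = NULL, theta = NULL,
                            terms = NULL, aic = NA_real_, loglik = NA_real_,
                            ...) {
  if (is.null(vcov))
    vcov <- matrix(0, length(coefficients), length(coefficients),
                   dimnames = list(names(coefficients), names(coefficients)))
  if (is.null(terms))
    terms <- setdiff(names(coefficients), "(Intercept)")
  new_component_model(family, coefficients, vcov, aic, loglik,
                      theta = theta, extra = list(terms = terms, ...))
}

new_component_model <- function(family, coefficients, vcov, aic, loglik,
                                theta = NULL, theta_se = NULL, extra = list()) {
  structure(c(list(family = family, coefficients = coefficients,
                   vcov = vcov, aic = aic, loglik = loglik,
                   theta = theta, theta_se = theta_se), extra),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat("component_model [", x$family, "]\n", sep = "")
  tab <- data.frame(coefficient = x$coefficients,
                    se = sqrt(pmax(diag(x$vcov), 0)))
  print(round(tab, 4))
  if (!is.null(x$theta))
    cat("theta:", round(x$theta, 3),
        if (!is.null(x$theta_se)) paste0("(SE ", round(x$theta_se, 3), ")"), "\n")
  cat("AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' Wald 95% confidence intervals of a component model
#'
#' @param model A `component_model`.
#' @return Matrix with columns `lower`, `upper`.
#' @export
component_confint <- function(model) {
  se <- sqrt(pmax(diag(model$vcov), 0))
  cbind(lower = model$coefficients - 1.96 * se,
        upper = model$coefficients + 1.96 * se)
}

# ---- abundance model ----------------------------------------------------

#' Negative-binomial model of total site abundance
#'
#' Fits N ~ NB(mu, theta) with log link; log(swept area) enters as a
#' free-coefficient covariate (not a fixed offset), so the effort
#' elasticity is estimated from the data. theta is estimated by maximum
#' likelihood.
#'
#' @param N Integer vector of site totals.
#' @param covariates Data frame of environmental covariates (or NULL for
#'   an intercept-only fit).
#' @param areas Swept areas; when supplied, `log(area)` is added as a
#'   covariate.
#' @return A `component_model` (family `nb_abundance`).
#' @export
fit_abundance_model <- function(N, covariates = NULL, areas = NULL) {
  if (all(N == 0)) stop("all-zero abundance")
  df <- data.frame(N = N)
  terms <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    terms <- names(covariates)
  }
  if (!is.null(areas)) {
    df$log_area <- log(areas)
    terms <- c(terms, "log_area")
  }
  fml <- if (length(terms) == 0) N ~ 1 else
    as.formula(paste("N ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- suppressWarnings(MASS::glm.nb(fml, data = df))
  th <- fit$theta
  new_component_model(
    "nb_abundance", coef(fit), vcov(fit),
    aic = fit$aic, loglik = as.numeric(logLik(fit)),
    theta = th, theta_se = fit$SE.theta,
    extra = list(terms = terms, fitted = unname(fitted(fit))))
}

#' Predict mean total abundance
#'
#' @param model `component_model` from [fit_abundance_model()].
#' @param covariates Data frame of covariates (may be missing columns
#'   not in the model).
#' @param areas Swept areas (reference effort for maps).
#' @param coefficients Optional replacement coefficient vector (used by
#'   the parametric bootstrap).
#' @return Vector of means exp(X beta).
#' @export
predict_abundance <- function(model, covariates, areas = NULL,
                              coefficients = NULL) {
  b <- if (is.null(coefficients)) model$coefficients else coefficients
  X <- component_design(model$terms, covariates, areas)
  as.numeric(exp(X %*% b))
}

component_design <- function(terms, covariates, areas = NULL) {
  n <- if (!is.null(areas)) length(areas) else nrow(as.data.frame(covariates))
  get_col <- function(nm) {
    if (!nm %in% names(covariates)) stop("missing covariate: ", nm)
    covariates[[nm]]
  }
  X <- matrix(1, n, 1)
  for (nm in terms) {
    col <- if (nm == "log_area") log(areas)
    else if (grepl(":", nm, fixed = TRUE)) {
      # interaction term: product of the two mains
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      get_col(parts[1]) * get_col(parts[2])
    } else get_col(nm)
    X <- cbind(X, col)
  }
  colnames(X) <- c("(Intercept)", terms)
  X
}

# ---- truncated NB richness ----------------------------------------------

#' Probability mass of a right-truncated negative binomial
#'
#' NB(mu, theta) renormalised over {0, ..., upper}.
#'
#' @param x Quantiles.
#' @param mu,theta NB mean and dispersion.
#' @param upper Truncation point (vector or scalar).
#' @param log Return log probabilities.
#' @return Probabilities; zero above `upper`.
#' @export
dtruncnb <- function(x, mu, theta, upper, log = FALSE) {
  lz <- pnbinom(upper, mu = mu, size = theta, log.p = TRUE)
  lp <- dnbinom(x, mu = mu, size = theta, log = TRUE) - lz
  lp[x > upper] <- -Inf
  if (log) lp else exp(lp)
}

truncnb_mean <- function(mu, theta, upper) {
  vapply(seq_along(mu), function(i) {
    up <- if (length(upper) > 1) upper[i] else upper
    s <- 0:up
    p <- dtruncnb(s, mu[i], theta, up)
    sum(s * p)
  }, numeric(1))
}

#' Right-truncated negative-binomial model of species richness
#'
#' Richness S cannot exceed the number of individuals N, so S is
#' modelled as NB(mu, theta) with log link, right-truncated at N (per
#' site, probabilities renormalised over 0..min(N, cap)). The candidate
#' covariates conventionally include log(N/area) and N/area, giving a
#' power-law richness-abundance relationship; build them with
#' [rad_scaled_covariates()].
#'
#' @param S Integer richness per site.
#' @param N Integer total abundance per site (S <= N).
#' @param covariates Data frame of covariates (already including any
#'   abundance-derived terms), or NULL.
#' @param cap Tractability cap on the truncation point; default
#'   10 * mean(S).
#' @return A `component_model` (family `truncated_nb_richness`).
#' @export
fit_richness_model <- function(S, N, covariates = NULL, cap = NULL) {
  if (any(S > N)) stop("richness exceeds total abundance at some site")
  if (is.null(cap)) cap <- ceiling(10 * mean(S))
  upper <- pmin(N, cap)
  if (any(S > upper)) upper <- pmax(upper, S)
  terms <- if (is.null(covariates)) character(0) else names(as.data.frame(covariates))
  X <- component_design(terms, covariates)
  npar <- ncol(X) + 1

  # untruncated NB fit as starting values
  start_fit <- try(suppressWarnings(
    MASS::glm.nb(S ~ X - 1)), silent = TRUE)
  start <- if (inherits(start_fit, "try-error"))
    c(log(mean(S) + 0.5), rep(0, ncol(X) - 1), 0)
  else c(coef(start_fit), log(start_fit$theta))
  if (any(!is.finite(start)))
    start <- c(log(mean(S) + 0.5), rep(0, ncol(X) - 1), 0)

  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    theta <- exp(pmin(par[npar], 20))
    mu <- exp(pmin(X %*% beta, 25))
    # extreme exploratory values can underflow pnbinom; treat as infeasible
    val <- suppressWarnings(-sum(dtruncnb(S, mu, theta, upper, log = TRUE)))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  if (opt$convergence != 0)
    warning("richness model did not fully converge (code ",
            opt$convergence, "); partial fit returned")
  beta <- opt$par[seq_len(ncol(X))]
  names(beta) <- colnames(X)
  vc_full <- try(solve(opt$hessian), silent = TRUE)
  if (inherits(vc_full, "try-error"))
    vc_full <- matrix(NA_real_, npar, npar)
  vc <- vc_full[seq_len(ncol(X)), seq_len(ncol(X)), drop = FALSE]
  dimnames(vc) <- list(names(beta), names(beta))
  theta <- exp(opt$par[npar])
  theta_se <- theta * sqrt(abs(vc_full[npar, npar]))  # delta method
  new_component_model(
    "truncated_nb_richness", beta, vc,
    aic = 2 * opt$value + 2 * npar, loglik = -opt$value,
    theta = theta, theta_se = theta_se,
    extra = list(terms = terms, cap = cap, converged = opt$convergence == 0))
}

#' Predict mean richness under the truncated NB model
#'
#' @param model `component_model` from [fit_richness_model()].
#' @param covariates Covariate data frame matching the model terms.
#' @param N Conditioning total abundance per prediction point.
#' @param coefficients Optional replacement coefficients.
#' @return Truncated-NB means; never exceed `pmin(N, cap)`.
#' @export
predict_richness <- function(model, covariates, N, coefficients = NULL) {
  b <- if (is.null(coefficients)) model$coefficients else coefficients
  X <- component_design(model$terms, covariates)
  mu <- as.numeric(exp(pmin(X %*% b, 30)))
  truncnb_mean(mu, model$theta, pmin(round(N), model$cap))
}

#' Area-scaled abundance and richness covariates
#'
#' Builds the derived covariates used by the richness and evenness
#' models: `N_scale` (z-standardised N/area), `log_N_scale`
#' (standardised log(N/area)), `S_scale`, and polynomial powers. The
#' standardisation moments are returned as attributes so that grid
#' predictions reuse the fitting-time scaling.
#'
#' @param N,S,areas Site vectors.
#' @param moments Optional list of stored moments (from a previous call)
#'   to apply instead of recomputing.
#' @return Data frame with columns `log_N_scale`, `N_scale`, `N_scale2`,
#'   `N_scale3`, `S_scale`, `S_scale2`, carrying a `moments` attribute.
#' @export
rad_scaled_covariates <- function(N, S = NULL, areas, moments = NULL) {
  nsc_raw <- N / areas
  lnsc_raw <- log(pmax(nsc_raw, 1e-12))
  ssc_raw <- if (!is.null(S)) S / areas else NULL
  if (is.null(moments)) {
    moments <- list(N_scale = c(mean(nsc_raw), sd(nsc_raw)),
                    log_N_scale = c(mean(lnsc_raw), sd(lnsc_raw)),
                    S_scale = if (!is.null(ssc_raw))
                      c(mean(ssc_raw), sd(ssc_raw)) else c(0, 1))
  }
  z <- function(x, m) (x - m[1]) / ifelse(is.finite(m[2]) && m[2] > 0, m[2], 1)
  nsc <- z(nsc_raw, moments$N_scale)
  out <- data.frame(log_N_scale = z(lnsc_raw, moments$log_N_scale),
                    N_scale = nsc, N_scale2 = nsc^2, N_scale3 = nsc^3)
  if (!is.null(ssc_raw)) {
    ssc <- z(ssc_raw, moments$S_scale)
    out$S_scale <- ssc
    out$S_scale2 <- ssc^2
  }
  attr(out, "moments") <- moments
  out
}

# ---- multinomial rank curve ---------------------------------------------

rank_curve_probs <- function(S, beta, gamma) {
  z <- if (S == 1) 0 else (seq_len(S) - 1) / (S - 1)
  w <- exp(beta * z + gamma * z^2)
  w / sum(w)
}

#' Multinomial model of the rank-abundance curve
#'
#' Conditional on N and S, the ranked counts follow a multinomial whose
#' cell probabilities are proportional to exp(beta z + gamma z^2) on the
#' scaled rank z = (r-1)/(S-1) (the proportionality constant absorbs the
#' intercept). beta and gamma are shared across sites and estimated by
#' joint maximum likelihood over all sites with S >= 2.
#'
#' @param components List of `rad_components` (sites with S < 2 are
#'   ignored).
#' @return A `component_model` (family `multinomial_rank_curve`) with
#'   coefficients `beta` and `gamma`.
#' @export
fit_rank_curve <- function(components) {
  use <- Filter(function(x) x$S >= 2, components)
  if (length(use) == 0) stop("no sites with at least two species")
  counts <- lapply(use, function(x) round(x$n * x$N))
  nll <- function(par) {
    val <- -sum(vapply(counts, function(cc) {
      p <- rank_curve_probs(length(cc), par[1], par[2])
      lgamma(sum(cc) + 1) - sum(lgamma(cc + 1)) + sum(cc * log(p))
    }, numeric(1)))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- optim(c(-1, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, 2, 2)
  beta <- setNames(opt$par, c("beta", "gamma"))
  dimnames(vc) <- list(names(beta), names(beta))
  new_component_model(
    "multinomial_rank_curve", beta, vc,
    aic = 2 * opt$value + 2 * 2, loglik = -opt$value,
    extra = list(n_sites = length(use)))
}

# ---- gamma evenness model -----------------------------------------------

#' Gamma regression of evenness on community structure
#'
#' Evenness responds to the environment only through abundance and
#' richness, so the linear predictor contains polynomials in the
#' area-scaled (standardised) N and S and no direct environmental terms.
#' The family is gamma with log link (evenness is positive and
#' right-skewed). Sites with S < 2 or zero evenness are excluded.
#'
#' @param eta Evenness values per site.
#' @param scaled Data frame from [rad_scaled_covariates()] (same sites).
#' @param terms Character vector of columns of `scaled` to use.
#' @return A `component_model` (family `gamma_evenness`); stores the
#'   standardisation moments for prediction.
#' @export
fit_evenness_model <- function(eta, scaled,
                               terms = c("N_scale", "N_scale2", "S_scale")) {
  keep <- is.finite(eta) & eta > 0
  if (sum(keep) < length(terms) + 2)
    stop("too few sites with positive evenness")
  df <- data.frame(eta = eta[keep], scaled[keep, , drop = FALSE])
  fml <- if (length(terms) == 0) eta ~ 1 else
    as.formula(paste("eta ~", paste(terms, collapse = " + ")))
  fit <- glm(fml, data = df, family = Gamma(link = "log"))
  new_component_model(
    "gamma_evenness", coef(fit), vcov(fit),
    aic = AIC(fit), loglik = as.numeric(logLik(fit)),
    extra = list(terms = terms, moments = attr(scaled, "moments"),
                 dispersion = summary(fit)$dispersion))
}

#' Predict mean evenness
#'
#' @param model `component_model` from [fit_evenness_model()].
#' @param scaled Data frame of scaled covariates (use the model's stored
#'   `moments` via [rad_scaled_covariates()]).
#' @param coefficients Optional replacement coefficients.
#' @return Predicted means exp(X beta).
#' @export
predict_evenness <- function(model, scaled, coefficients = NULL) {
  b <- if (is.null(coefficients)) model$coefficients else coefficients
  X <- cbind(1, as.matrix(scaled[, model$terms, drop = FALSE]))
  as.numeric(exp(X %*% b))
}

# ---- factorized likelihood ----------------------------------------------

#' Bundle the three fitted component models
#'
#' @param abundance,richness,rank_curve,evenness Fitted
#'   `component_model`s ([fit_abundance_model()],
#'   [fit_richness_model()], [fit_rank_curve()],
#'   [fit_evenness_model()]; `evenness` optional — it is a summary
#'   model, not part of the likelihood factorization).
#' @return A `rad_model_set`.
#' @export
rad_model_set <- function(abundance, richness, rank_curve, evenness = NULL) {
  structure(list(abundance = abundance, richness = richness,
                 rank_curve = rank_curve, evenness = evenness),
            class = "rad_model_set")
}

#' Factorized RAD log-likelihood of one site
#'
#' Returns l_N(N) + l_S|N(S) + l_n|N,S(n): the NB abundance log-mass,
#' the right-truncated NB richness log-mass, and the multinomial
#' rank-curve log-mass of the ranked counts.
#'
#' @param sample A `rad_components`.
#' @param models A `rad_model_set`.
#' @param covariates One-row data frame of covariates for the site.
#' @param richness_upper Optional truncation point override for the
#'   richness component (defaults to min(N, cap of the fitted model)).
#' @return Scalar log-likelihood, with the three parts as the
#'   `"components"` attribute.
#' @export
rad_loglik <- function(sample, models, covariates,
                       richness_upper = NULL) {
  stopifnot(inherits(sample, "rad_components"),
            inherits(models, "rad_model_set"))
  if (sample$S > sample$N) stop("sample violates S <= N")
  mu_N <- predict_abundance(models$abundance, covariates,
                            areas = sample$area)
  l_N <- dnbinom(sample$N, mu = mu_N, size = models$abundance$theta,
                 log = TRUE)
  rm_terms <- models$richness$terms
  rich_covs <- covariates
  if (length(setdiff(rm_terms, names(rich_covs))) > 0) {
    # abundance-derived terms (N_scale etc.) built from the sample itself
    sc <- rad_scaled_covariates(sample$N, sample$S, sample$area,
                                moments = models$evenness$moments)
    rich_covs <- cbind(rich_covs, sc)
  }
  up <- if (is.null(richness_upper))
    min(sample$N, models$richness$cap) else richness_upper
  Xr <- component_design(rm_terms, rich_covs)
  mu_S <- as.numeric(exp(pmin(Xr %*% models$richness$coefficients, 30)))
  l_S <- dtruncnb(sample$S, mu_S, models$richness$theta, up, log = TRUE)
  counts <- round(sample$n * sample$N)
  l_n <- if (sample$S == 0) 0 else {
    p <- rank_curve_probs(sample$S, models$rank_curve$coefficients["beta"],
                          models$rank_curve$coefficients["gamma"])
    lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) + sum(counts * log(p))
  }
  total <- l_N + l_S + l_n
  attr(total, "components") <- c(abundance = l_N, richness = l_S,
                                 rank_curve = l_n)
  total
}

#' Simulate RAD components from known component models
#'
#' Draws each site's total abundance from the NB abundance model, its
#' richness from the right-truncated NB richness model conditional on
#' the drawn N, and its evenness from the gamma evenness model
#' conditional on the (area-scaled, standardised) N and S — the
#' generative counterpart of the factorized likelihood, used for
#' parameter-recovery validation.
#'
#' @param models A `rad_model_set` whose richness `terms` may refer to
#'   environmental covariates and/or the derived columns of
#'   [rad_scaled_covariates()]; the evenness model must carry `moments`
#'   and `dispersion`.
#' @param covariates Data frame of environmental covariates per site.
#' @param areas Swept areas per site.
#' @param seed Integer seed.
#' @return Data frame with columns `N`, `S`, `evenness`.
#' @export
simulate_rad_components <- function(models, covariates, areas, seed = 1) {
  stopifnot(inherits(models, "rad_model_set"))
  set.seed(seed)
  n <- length(areas)
  mu_N <- predict_abundance(models$abundance, covariates, areas)
  N <- rnbinom(n, mu = mu_N, size = models$abundance$theta)

  rm <- models$richness
  sc <- rad_scaled_covariates(N, NULL, areas,
                              moments = models$evenness$moments)
  rich_frame <- cbind(as.data.frame(covariates), sc)
  Xr <- component_design(rm$terms, rich_frame)
  mu_S <- as.numeric(exp(pmin(Xr %*% rm$coefficients, 30)))
  upper <- pmin(N, rm$cap)
  S <- vapply(seq_len(n), function(i) {
    if (upper[i] == 0) return(0L)
    s <- 0:upper[i]
    sample(s, 1, prob = dtruncnb(s, mu_S[i], rm$theta, upper[i]))
  }, integer(1))

  em <- models$evenness
  sc2 <- rad_scaled_covariates(N, S, areas, moments = em$moments)
  mu_e <- predict_evenness(em, sc2)
  shape <- 1 / em$dispersion
  eta <- rgamma(n, shape = shape, rate = shape / mu_e)
  data.frame(N = N, S = S, evenness = eta)
}

# ---- forward AIC selection ----------------------------------------------

#' Forward model selection by AIC
#'
#' Greedily adds, from `candidates`, the term with the largest AIC
#' decrease until no candidate decreases the AIC. Interaction terms
#' (`"a:b"`) are admissible only once both main effects are in the model
#' (hierarchy rule); polynomial terms (`"x2"` conventions are the
#' caller's) carry no such restriction.
#'
#' @param fit_fun Function(terms) -> `component_model` (must report
#'   `$aic`).
#' @param candidates Character vector of candidate terms.
#' @param base_terms Terms always included (default none).
#' @return The selected `component_model`, with a `selection` data frame
#'   (step, term, AIC) attached.
#' @export
forward_select_aic <- function(fit_fun, candidates, base_terms = character(0)) {
  current <- base_terms
  best <- fit_fun(current)
  trace <- data.frame(step = 0L, term = "(base)", aic = best$aic,
                      stringsAsFactors = FALSE)
  remaining <- setdiff(candidates, current)
  step <- 0L
  repeat {
    admissible <- remaining[vapply(remaining, function(tm) {
      if (!grepl(":", tm, fixed = TRUE)) return(TRUE)
      all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% current)
    }, logical(1))]
    if (length(admissible) == 0) break
    fits <- lapply(admissible, function(tm) {
      try(fit_fun(c(current, tm)), silent = TRUE)
    })
    aics <- vapply(fits, function(f)
      if (inherits(f, "try-error")) Inf else f$aic, numeric(1))
    if (min(aics) >= best$aic) break
    k <- which.min(aics)
    step <- step + 1L
    current <- c(current, admissible[k])
    best <- fits[[k]]
    trace <- rbind(trace, data.frame(step = step, term = admissible[k],
                                     aic = best$aic))
    remaining <- setdiff(remaining, admissible[k])
  }
  best$selection <- trace
  best$terms_selected <- current
  best
}

# ---- prediction maps -----------------------------------------------------

#' Gridded RAD predictions with coefficient-of-variation maps
#'
#' Plug-in mean maps of total abundance N, richness S and evenness at a
#' reference swept area, with per-cell coefficients of variation from a
#' parametric bootstrap: coefficient vectors are drawn from each model's
#' asymptotic normal distribution and propagated through the prediction
#' chain (N feeds the richness model; N and S feed the evenness model).
#' CV = sd(draws) / mean(draws); a value of 1 means the standard error
#' equals the mean.
#'
#' @param models A `rad_model_set` (with evenness model).
#' @param grid An `environmental_grid`.
#' @param reference_area Swept area at which to predict, m^2.
#' @param n_draws Bootstrap draws (>= 50).
#' @param seed Integer seed for the draws.
#' @return Data frame: `cell_id`, `lon`, `lat`, `N`, `N_cv`, `S`,
#'   `S_cv`, `evenness`, `evenness_cv`.
#' @export
predict_rad_maps <- function(models, grid, reference_area = 1000,
                             n_draws = 200, seed = 1) {
  stopifnot(inherits(models, "rad_model_set"),
            inherits(grid, "environmental_grid"))
  if (n_draws < 50) stop("n_draws must be at least 50")
  set.seed(seed)
  covs <- grid_covariates(grid)
  n <- nrow(covs)
  areas <- rep(reference_area, n)
  moments <- models$evenness$moments

  chain <- function(coef_N, coef_S, coef_eta) {
    muN <- predict_abundance(models$abundance, covs, areas,
                             coefficients = coef_N)
    muS <- predict_richness(models$richness,
                            chain_rich_covs(muN), muN,
                            coefficients = coef_S)
    sc <- rad_scaled_covariates(muN, muS, areas, moments = moments)
    mue <- predict_evenness(models$evenness, sc, coefficients = coef_eta)
    list(N = muN, S = muS, evenness = mue)
  }
  chain_rich_covs <- function(muN) {
    sc <- rad_scaled_covariates(muN, NULL, areas, moments = moments)
    cbind(covs, sc)  # component_design selects the model terms
  }

  plug <- chain(NULL, NULL, NULL)

  draw_coefs <- function(model) {
    vc <- model$vcov
    if (any(!is.finite(vc))) stop("singular covariance; CV map omitted")
    vc <- (vc + t(vc)) / 2
    e <- eigen(vc, symmetric = TRUE)
    lam <- pmax(e$values, 0)  # clamp tiny negative eigenvalues
    L <- e$vectors %*% diag(sqrt(lam), length(lam))
    z <- matrix(rnorm(n_draws * length(lam)), n_draws)
    sweep(z %*% t(L), 2, model$coefficients, "+")
  }
  dN <- draw_coefs(models$abundance)
  dS <- draw_coefs(models$richness)
  dE <- draw_coefs(models$evenness)

  acc <- list(N = matrix(0, n, n_draws), S = matrix(0, n, n_draws),
              evenness = matrix(0, n, n_draws))
  for (b in seq_len(n_draws)) {
    res <- chain(dN[b, ], dS[b, ], dE[b, ])
    acc$N[, b] <- res$N; acc$S[, b] <- res$S; acc$evenness[, b] <- res$evenness
  }
  cv <- function(m) {
    mu <- rowMeans(m)
    sds <- apply(m, 1, sd)
    ifelse(mu > 0, sds / mu, 0)
  }
  data.frame(cell_id = grid$cells$cell_id,
             lon = grid$cells$lon, lat = grid$cells$lat,
             N = plug$N, N_cv = cv(acc$N),
             S = plug$S, S_cv = cv(acc$S),
             evenness = plug$evenness, evenness_cv = cv(acc$evenness))
}

#' @export
print.rad_model_set <- function(x, ...) {
  cat("rad_model_set\n")
  for (nm in c("abundance", "richness", "rank_curve", "evenness")) {
    if (is.null(x[[nm]])) next
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}
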