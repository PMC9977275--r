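#' Standardize a predictor to zero mean and unit variance
#'
#' @param x numeric vector with at least two distinct values.
#' @return `(x - mean(x)) / sd(x)` (sample sd, n-1 denominator).
#' @export
standardize <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2)
    stop("cannot standardize a constant vector")
  as.numeric((x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE))
}

COUNT_FAMILIES <- list(
  strain_count = c("trunc_poisson", "trunc_nb_linear", "trunc_nb_quadratic"),
  genes_lost = c("nb_linear", "nb_quadratic"),
  genes_gained = c("nb_linear", "nb_quadratic"))

glmmtmb_family <- function(family) {
  switch(family,
         trunc_poisson = glmmTMB::truncated_poisson(),
         trunc_nb_linear = glmmTMB::truncated_nbinom1(),
         trunc_nb_quadratic = glmmTMB::truncated_nbinom2(),
         nb_linear = glmmTMB::nbinom1(),
         nb_quadratic = glmmTMB::nbinom2(),
         stop("unknown count family: ", family))
}

#' Specify a diversity-slope model
#'
#' @param response one of `"polymorphism_rate"`, `"strain_count"`,
#'   `"genes_lost"`, `"genes_gained"`, `"polymorphism_change"`.
#' @param predictor diversity metric column name (e.g. `"shannon"`,
#'   `"richness"`, `"rarefied_richness"`).
#' @param rank taxonomic rank the predictor was computed at (metadata).
#' @param interaction_with_lag include the diversity x time-lag interaction
#'   (temporal models).
#' @param random_effects subset of `c("species", "host", "sample")`;
#'   `character()` fits fixed-effects-only models via a fast direct-ML path.
#' @param family force one family instead of AIC selection among the
#'   admissible set; count responses admit only count families
#'   (zero-truncated for strain counts), `polymorphism_rate` admits
#'   `"beta_logit"` and `polymorphism_change` `"gaussian_log_response"`.
#' @param smooth use spline smooths for the beta-logit model (default TRUE).
#' @param k spline basis dimension for smooth terms.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, predictor = "shannon", rank = "species",
                       interaction_with_lag = FALSE,
                       random_effects = c("species", "host", "sample"),
                       family = NULL, smooth = TRUE, k = 5) {
  response <- match.arg(response, c("polymorphism_rate", "strain_count",
                                    "genes_lost", "genes_gained",
                                    "polymorphism_change"))
  if (!is.null(family)) {
    admissible <- switch(response,
      polymorphism_rate = "beta_logit",
      polymorphism_change = "gaussian_log_response",
      COUNT_FAMILIES[[response]])
    if (!family %in% admissible)
      stop("family '", family, "' not admissible for response '", response, "'")
  }
  structure(list(response = response, predictor = predictor, rank = rank,
                 interaction_with_lag = interaction_with_lag,
                 random_effects = random_effects, family = family,
                 smooth = smooth, k = k),
            class = "model_spec")
}

# ---- direct maximum-likelihood engine (fixed effects only) -----------------

.count_nll <- function(family) {
  switch(family,
    trunc_poisson = function(y, mu, disp)
      -sum(dpois(y, mu, log = TRUE) - log1p(-exp(-mu))),
    trunc_nb_quadratic = function(y, mu, disp)
      -sum(dnbinom(y, mu = mu, size = disp, log = TRUE) -
             log1p(-(disp / (disp + mu))^disp)),
    trunc_nb_linear = function(y, mu, disp)
      -sum(dnbinom(y, mu = mu, size = mu / disp, log = TRUE) -
             log1p(-(1 / (1 + disp))^(mu / disp))),
    nb_quadratic = function(y, mu, disp)
      -sum(dnbinom(y, mu = mu, size = disp, log = TRUE)),
    nb_linear = function(y, mu, disp)
      -sum(dnbinom(y, mu = mu, size = mu / disp, log = TRUE)),
    stop("unknown count family: ", family))
}

fit_count_ml <- function(y, X, family, offset = 0) {
  has_disp <- family != "trunc_poisson"
  nllf <- .count_nll(family)
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    mu <- exp(pmin(as.numeric(X %*% beta) + offset, 30))
    disp <- if (has_disp) exp(par[length(par)]) else NULL
    v <- nllf(y, mu, disp)
    if (!is.finite(v)) 1e10 else v
  }
  grad <- if (family == "trunc_poisson") {
    function(par) {
      mu <- exp(pmin(as.numeric(X %*% par) + offset, 30))
      # truncated-Poisson mean is mu / (1 - e^-mu)
      -as.numeric(crossprod(X, y - mu / (1 - exp(-mu))))
    }
  } else NULL
  # moment start from a Poisson working fit
  b0 <- tryCatch(coef(glm.fit(X, y, family = stats::poisson(),
                              offset = rep_len(offset, length(y)))),
                 error = function(e) c(log(mean(y)), rep(0, ncol(X) - 1)))
  par0 <- c(b0, if (has_disp) 0)
  fit <- optim(par0, nll, grad, method = "BFGS", hessian = TRUE,
               control = list(maxit = 1000, reltol = 1e-12,
                              ndeps = rep(1e-5, length(par0))))
  se <- rep(NA_real_, length(fit$par))
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  terms <- c(colnames(X), if (has_disp) "log_dispersion")
  list(coefficients = data.frame(term = terms, estimate = fit$par,
                                 std_error = se, stringsAsFactors = FALSE),
       logL = -fit$value, n_params = length(fit$par),
       AIC = 2 * length(fit$par) + 2 * fit$value,
       converged = fit$convergence == 0, model = NULL, engine = "ml")
}

# ---- glmmTMB engine --------------------------------------------------------

fit_count_tmb <- function(dat, fixed_rhs, random_effects, family) {
  re <- if (length(random_effects))
    paste(sprintf("(1 | %s)", random_effects), collapse = " + ")
  fml <- as.formula(paste(".y ~", fixed_rhs,
                          if (!is.null(re)) paste("+", re) else ""))
  m <- glmmTMB::glmmTMB(fml, data = dat, family = glmmtmb_family(family))
  sm <- summary(m)$coefficients$cond
  ll <- logLik(m)
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                 std_error = sm[, 2], stringsAsFactors = FALSE),
       logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m),
       converged = isTRUE(m$fit$convergence == 0) || is.na(m$fit$convergence),
       model = m, engine = "glmmTMB")
}

# ---- shared plumbing -------------------------------------------------------

prepare_slope_data <- function(data, spec, temporal = FALSE) {
  if (!spec$predictor %in% names(data))
    stop("data lacks predictor column '", spec$predictor, "'")
  if (!spec$response %in% names(data))
    stop("data lacks response column '", spec$response, "'")
  if (!"read_count" %in% names(data)) stop("data lacks read_count column")
  d <- data.frame(.y = data[[spec$response]],
                  div_z = standardize(data[[spec$predictor]]),
                  rc_z = standardize(data$read_count))
  if (temporal && spec$interaction_with_lag) {
    if (!"delta_days" %in% names(data)) stop("data lacks delta_days column")
    if (length(unique(data$delta_days)) < 2)
      stop("interaction inestimable: delta_days is constant, the diversity x ",
           "lag interaction is collinear with the main effect")
    d$lag_z <- standardize(data$delta_days)
  }
  for (re in spec$random_effects) {
    if (!re %in% names(data)) stop("data lacks random-effect column '", re, "'")
    d[[re]] <- factor(data[[re]])
  }
  d
}

fixed_rhs_of <- function(spec, temporal, drop = NULL) {
  terms <- if (temporal && spec$interaction_with_lag)
    c("div_z", "lag_z", "div_z:lag_z", "rc_z")
  else c("div_z", "rc_z")
  if (!is.null(drop)) {
    if (drop == "div_z")   # dropping a main effect drops its interaction too
      terms <- setdiff(terms, c("div_z", "div_z:lag_z"))
    else terms <- setdiff(terms, drop)
  }
  if (!length(terms)) "1" else paste(terms, collapse = " + ")
}

fit_one_count <- function(dat, spec, family, temporal, drop = NULL) {
  rhs <- fixed_rhs_of(spec, temporal, drop)
  if (length(spec$random_effects)) {
    fit_count_tmb(dat, rhs, spec$random_effects, family)
  } else {
    X <- stats::model.matrix(as.formula(paste("~", rhs)), dat)
    fit_count_ml(dat$.y, X, family)
  }
}

# beta-logit (optionally smoothed) model via mgcv; gaussian via gam as well
fit_one_gam <- function(dat, spec, family, temporal, drop = NULL) {
  rhs <- fixed_rhs_of(spec, temporal, drop)
  terms <- strsplit(rhs, " \\+ ")[[1]]
  if (spec$smooth && family == "beta_logit") {
    terms[terms == "div_z"] <- sprintf("s(div_z, k = %d)", spec$k)
    terms[terms == "rc_z"] <- sprintf("s(rc_z, k = %d)", spec$k)
  }
  re_terms <- sprintf('s(%s, bs = "re")', spec$random_effects)
  fml <- as.formula(paste(".y ~", paste(c(terms, re_terms), collapse = " + ")))
  fam <- if (family == "beta_logit") mgcv::betar(link = "logit") else stats::gaussian()
  y <- dat$.y
  nudged <- FALSE
  if (family == "beta_logit" && (any(y <= 0) || any(y >= 1))) {
    n <- length(y)
    dat$.y <- (y * (n - 1) + 0.5) / n   # open-interval nudge, beta support is (0,1)
    nudged <- TRUE
  }
  # ML, not REML: the log-likelihoods feed LRTs across fixed-effect structures
  m <- mgcv::gam(fml, data = dat, family = fam, method = "ML")
  ll <- logLik(m)
  sm <- summary(m)
  co <- data.frame(term = names(coef(m)), estimate = as.numeric(coef(m)),
                   std_error = sqrt(diag(stats::vcov(m))), stringsAsFactors = FALSE)
  list(coefficients = co, logL = as.numeric(ll), n_params = attr(ll, "df"),
       AIC = AIC(m), converged = m$converged, model = m, engine = "mgcv",
       # negative ML score: the log marginal likelihood, the only quantity
       # comparable across fixed-effect structures for penalized fits
       logL_ml = as.numeric(-m$gcv.ubre),
       nudged = nudged)
}

slope_of <- function(fit, dat, spec) {
  co <- fit$coefficients
  if (fit$engine == "mgcv" && spec$smooth) {
    # finite-difference summary of the (possibly smoothed) diversity effect
    nd <- dat[rep(1, 2), , drop = FALSE]
    nd$div_z <- c(-1, 1); nd$rc_z <- 0
    if ("lag_z" %in% names(nd)) nd$lag_z <- 0
    excl <- sprintf('s(%s)', spec$random_effects)
    pr <- predict(fit$model, newdata = nd, type = "link", exclude = excl,
                  newdata.guaranteed = TRUE)
    c(slope = as.numeric(diff(pr)) / 2, slope_se = NA_real_)
  } else {
    i <- match("div_z", co$term)
    c(slope = co$estimate[i], slope_se = co$std_error[i])
  }
}

overdispersion_of <- function(fit, dat) {
  if (is.null(fit$model) || fit$engine != "glmmTMB") return(NA_real_)
  pr <- residuals(fit$model, type = "pearson")
  sum(pr^2) / stats::df.residual(fit$model)
}

finish_fit <- function(fit, dat, spec, family, temporal) {
  sl <- slope_of(fit, dat, spec)
  structure(list(spec = spec, family = family, engine = fit$engine,
                 temporal = temporal, model = fit$model,
                 logL_ml = fit$logL_ml,
                 coefficients = fit$coefficients,
                 slope = unname(sl["slope"]), slope_se = unname(sl["slope_se"]),
                 logL = fit$logL, n_params = fit$n_params, AIC = fit$AIC,
                 n_obs = nrow(dat), converged = fit$converged,
                 overdispersion = overdispersion_of(fit, dat),
                 nudged = isTRUE(fit$nudged),
                 data = dat),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope_fit [%s, %s%s]: slope=%.4f (se %.4f), logL=%.2f, AIC=%.2f, n=%d\n",
              x$family, x$engine, if (x$temporal) ", temporal" else "",
              x$slope, x$slope_se, x$logL, x$AIC, x$n_obs))
  invisible(x)
}

#' Fit a cross-sectional diversity-slope model
#'
#' For count responses (strain counts: zero-truncated Poisson/NB1/NB2; gene
#' gains and losses: NB1/NB2) fits every admissible family and returns the
#' AIC-best, unless `spec$family` pins one. For polymorphism rates fits a
#' beta-logit (optionally smoothed) model. Predictors are standardized
#' internally; per-sample read count always enters as a covariate; random
#' effects named in `spec$random_effects` enter as exchangeable intercepts. With
#' `random_effects = character()` count models use a direct
#' maximum-likelihood engine, otherwise glmmTMB; the beta family always uses
#' mgcv.
#'
#' @param data data.frame with columns named by `spec$response` and
#'   `spec$predictor`, plus `read_count` and any random-effect grouping
#'   columns.
#' @param spec a [model_spec()].
#' @param seed integer seed (kept for interface symmetry; fitting is
#'   deterministic).
#' @return A `slope_fit`: coefficients with standard errors, the diversity
#'   slope on the standardized scale, logL, AIC, overdispersion diagnostic,
#'   and the prepared data for nested refits. On non-convergence the fit is
#'   returned with `converged = FALSE` and diagnostics, never a silent
#'   fallback.
#' @export
fit_cross_sectional <- function(data, spec, seed = 1L) {
  dat <- prepare_slope_data(data, spec, temporal = FALSE)
  if (spec$response %in% names(COUNT_FAMILIES)) {
    fams <- spec$family %||% COUNT_FAMILIES[[spec$response]]
    fits <- lapply(fams, function(f) fit_one_count(dat, spec, f, FALSE))
    best <- which.min(vapply(fits, `[[`, numeric(1), "AIC"))
    finish_fit(fits[[best]], dat, spec, fams[best], FALSE)
  } else if (spec$response == "polymorphism_rate") {
    finish_fit(fit_one_gam(dat, spec, "beta_logit", FALSE), dat, spec,
               "beta_logit", FALSE)
  } else {
    stop("response '", spec$response, "' is temporal; use fit_temporal()")
  }
}

#' Fit a temporal diversity-slope model
#'
#' Models within-host change (polymorphism change, gene gains/losses between
#' time points) as a function of diversity at the earlier time point, with
#' the diversity x time-lag interaction when
#' `spec$interaction_with_lag = TRUE`. Count responses use NB families
#' (AIC-selected); polymorphism change uses a Gaussian model on
#' log-modulus-transformed change (`sign(x) log1p(|x| / 1e-5)`), which
#' handles the negative changes a signed difference produces.
#'
#' @param data data.frame with the response column, the predictor at the
#'   earlier time point, `delta_days`, `read_count`, and random-effect
#'   columns.
#' @inheritParams fit_cross_sectional
#' @return A `slope_fit`. A constant `delta_days` with an interaction
#'   requested is reported as a fit failure naming the collinearity.
#' @export
fit_temporal <- function(data, spec, seed = 1L) {
  dat <- tryCatch(prepare_slope_data(data, spec, temporal = TRUE),
                  error = function(e) e)
  if (inherits(dat, "error")) {
    return(structure(list(spec = spec, family = spec$family, engine = NA,
                          temporal = TRUE, converged = FALSE,
                          failure = conditionMessage(dat)),
                     class = "slope_fit"))
  }
  if (spec$response %in% c("genes_lost", "genes_gained", "strain_count")) {
    fams <- spec$family %||% c("nb_linear", "nb_quadratic")
    fits <- lapply(fams, function(f) fit_one_count(dat, spec, f, TRUE))
    best <- which.min(vapply(fits, `[[`, numeric(1), "AIC"))
    finish_fit(fits[[best]], dat, spec, fams[best], TRUE)
  } else if (spec$response == "polymorphism_change") {
    dat$.y <- sign(dat$.y) * log1p(abs(dat$.y) / 1e-5)
    fit <- if (length(spec$random_effects))
      fit_one_gam(dat, spec, "gaussian_log_response", TRUE)
    else {
      rhs <- fixed_rhs_of(spec, TRUE)
      m <- lm(as.formula(paste(".y ~", rhs)), data = dat)
      ll <- logLik(m)
      sm <- summary(m)$coefficients
      list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                     std_error = sm[, 2], stringsAsFactors = FALSE),
           logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m),
           converged = TRUE, model = m, engine = "lm")
    }
    finish_fit(fit, dat, spec, "gaussian_log_response", TRUE)
  } else {
    stop("response '", spec$response, "' is cross-sectional; use fit_cross_sectional()")
  }
}

refit_without <- function(fit, drop) {
  spec <- fit$spec; dat <- fit$data
  if (fit$family == "beta_logit" || fit$family == "gaussian_log_response") {
    if (fit$engine == "lm") {
      rhs <- fixed_rhs_of(spec, fit$temporal, drop)
      m <- lm(as.formula(paste(".y ~", rhs)), data = dat)
      ll <- logLik(m)
      list(logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m))
    } else fit_one_gam(dat, spec, fit$family, fit$temporal, drop)
  } else {
    fit_one_count(dat, spec, fit$family, fit$temporal, drop)
  }
}

#' Profile (LRT-inverted) confidence interval for the diversity slope
#'
#' Inverts the likelihood-ratio test: the interval holds every slope value b
#' for which 2 (logL_hat - logL_profile(b)) <= qchisq(level, 1), with the
#' profile maximizing over all other parameters. Matches the package's
#' LRT-first inference; available for the direct-ML count engine, other
#' engines fall back to the Wald interval.
#'
#' @param fit a converged `slope_fit`.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "slope_fit"), isTRUE(fit$converged))
  wald <- fit$slope + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) * fit$slope_se
  if (fit$engine != "ml") return(wald)
  dat <- fit$data
  rhs <- fixed_rhs_of(fit$spec, fit$temporal)
  X <- stats::model.matrix(as.formula(paste("~", rhs)), dat)
  j <- match("div_z", colnames(X))
  if (is.na(j)) return(wald)
  Xr <- X[, -j, drop = FALSE]
  crit <- stats::qchisq(level, 1)
  prof_dev <- function(b) {
    r <- fit_count_ml(dat$.y, Xr, fit$family, offset = b * X[, j])
    2 * (fit$logL - r$logL)
  }
  find_bound <- function(dir) {
    step <- fit$slope_se
    lo <- fit$slope; hi <- fit$slope + dir * step
    while (prof_dev(hi) < crit && abs(hi - fit$slope) < 20 * step) {
      lo <- hi; hi <- hi + dir * step
    }
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (prof_dev(mid) < crit) lo <- mid else hi <- mid
      if (abs(hi - lo) < 1e-5) break
    }
    (lo + hi) / 2
  }
  sort(c(find_bound(-1), find_bound(1)))
}

#' Drop-one likelihood-ratio test
#'
#' Refits the model without `term` (same family and engine) and reports the
#' LRT statistic 2 (logL_full - logL_reduced), its degrees of freedom (the
#' difference in parameter counts) and the chi-square p-value. Dropping the
#' diversity main effect also removes its interaction with the time lag.
#'
#' @param fit a converged `slope_fit`.
#' @param term `"div_z"` (the diversity term), `"rc_z"`, `"div_z:lag_z"`, or
#'   `"lag_z"`.
#' @return List with `term`, `statistic`, `df`, `p_value`, `AIC_reduced`.
#' @export
drop_one_lrt <- function(fit, term = "div_z") {
  stopifnot(inherits(fit, "slope_fit"), isTRUE(fit$converged))
  red <- refit_without(fit, term)
  if (fit$engine == "mgcv") {
    # penalized log-likelihoods are not comparable across fixed-effect
    # structures; compare the ML scores (log marginal likelihoods) instead,
    # with the dropped term's effective degrees of freedom
    stat <- max(0, 2 * (fit$logL_ml - red$logL_ml))
    edf <- sum(fit$model$edf[grepl(term, names(coef(fit$model)), fixed = TRUE)])
    df <- if (edf == 0) 0 else max(1, round(edf))
  } else {
    stat <- max(0, 2 * (fit$logL - red$logL))
    df <- max(0, round(fit$n_params - red$n_params))
  }
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(term = term, statistic = stat, df = df, p_value = p,
       AIC_reduced = red$AIC)
}

#' Compare a fitted model to its intercept + random-effects null
#'
#' @param fit a converged `slope_fit`.
#' @return List with `delta_AIC` (AIC_null - AIC_full, positive when the full
#'   model is preferred), `statistic`, `df`, `p_value`.
#' @export
null_model_comparison <- function(fit) {
  stopifnot(inherits(fit, "slope_fit"), isTRUE(fit$converged))
  spec <- fit$spec; dat <- fit$data
  null_fit <- if (fit$family %in% c("beta_logit", "gaussian_log_response")) {
    if (fit$engine == "lm") {
      m <- lm(.y ~ 1, data = dat)
      ll <- logLik(m)
      list(logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m))
    } else {
      re_terms <- sprintf('s(%s, bs = "re")', spec$random_effects)
      fml <- as.formula(paste(".y ~", paste(c("1", re_terms), collapse = " + ")))
      fam <- if (fit$family == "beta_logit") mgcv::betar(link = "logit")
             else stats::gaussian()
      d2 <- dat
      if (isTRUE(fit$nudged)) {
        n <- nrow(d2); d2$.y <- (d2$.y * (n - 1) + 0.5) / n
      }
      m <- mgcv::gam(fml, data = d2, family = fam, method = "ML")
      ll <- logLik(m)
      list(logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m),
           logL_ml = as.numeric(-m$gcv.ubre))
    }
  } else {
    if (length(spec$random_effects)) {
      re <- paste(sprintf("(1 | %s)", spec$random_effects), collapse = " + ")
      m <- glmmTMB::glmmTMB(as.formula(paste(".y ~ 1 +", re)), data = dat,
                            family = glmmtmb_family(fit$family))
      ll <- logLik(m)
      list(logL = as.numeric(ll), n_params = attr(ll, "df"), AIC = AIC(m))
    } else {
      X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
      fit_count_ml(dat$.y, X, fit$family)
    }
  }
  if (fit$engine == "mgcv" && !is.null(null_fit$logL_ml)) {
    stat <- max(0, 2 * (fit$logL_ml - null_fit$logL_ml))
    keep <- grepl("div_z|rc_z|lag_z", names(coef(fit$model)))
    df <- max(1, round(sum(fit$model$edf[keep])))
  } else {
    stat <- max(0, 2 * (fit$logL - null_fit$logL))
    df <- max(0, round(fit$n_params - null_fit$n_params))
  }
  list(delta_AIC = null_fit$AIC - fit$AIC, statistic = stat, df = df,
       p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Simulate a diversity-slope data set directly from a count model
#'
#' Generates the regression-scale ground truth used to check slope recovery
#' and test calibration without running the full cohort generator: per-host
#' Shannon values, species labels, and responses drawn from the requested
#' count family with log-mean `intercept + slope * standardized(shannon) +
#' species effect`.
#'
#' @param n_hosts,n_species design size (one sample per host, all species
#'   observed in all hosts).
#' @param slope true diversity slope on the standardized scale.
#' @param family generating family (`"trunc_poisson"`,
#'   `"trunc_nb_quadratic"`, `"nb_quadratic"`, ...).
#' @param intercept log-scale intercept.
#' @param dispersion NB size (quadratic) or NB1 dispersion.
#' @param species_sd sd of species-level random intercepts (0 = none).
#' @param response name the response column should get.
#' @param lag_effect,lag_levels optional time-lag structure for temporal
#'   designs: when `lag_levels > 1`, rows get a `delta_days` value and the
#'   log-mean gains `lag_effect * div_z * lag_z`.
#' @param seed integer seed.
#' @return data.frame with columns `shannon`, `read_count`, `species`,
#'   `host`, `sample`, optionally `delta_days`, and the response.
#' @export
simulate_slope_data <- function(n_hosts = 200, n_species = 20, slope = 0.5,
                                family = "trunc_nb_quadratic", intercept = 0.3,
                                dispersion = 2, species_sd = 0,
                                response = "strain_count",
                                lag_effect = 0, lag_levels = 1, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- rnorm(n_hosts, 2.5, 0.5)
  d <- expand.grid(host = seq_len(n_hosts), species = seq_len(n_species))
  d$shannon <- H[d$host]
  # standardized over rows, exactly as the fitting layer standardizes, so
  # `slope` is the true coefficient on the fitted scale
  zz <- standardize(d$shannon)
  d$read_count <- round(2e7 * exp(rnorm(nrow(d), 0, 0.2)))
  sp_eff <- rnorm(n_species, 0, species_sd)
  eta <- intercept + slope * zz + sp_eff[d$species]
  if (lag_levels > 1) {
    lags <- seq(30, 30 * lag_levels, by = 30)
    d$delta_days <- sample(lags, nrow(d), replace = TRUE)
    eta <- eta + lag_effect * zz * standardize(d$delta_days)
  }
  mu <- exp(eta)
  draw <- function(mu) switch(family,
    trunc_poisson = qpois(runif(length(mu), dpois(0, mu), 1), mu),
    trunc_nb_quadratic = {
      p0 <- dnbinom(0, mu = mu, size = dispersion)
      y <- rnbinom(length(mu), mu = mu, size = dispersion)
      while (any(y == 0)) {
        i <- y == 0
        y[i] <- rnbinom(sum(i), mu = mu[i], size = dispersion)
      }
      y
    },
    nb_quadratic = rnbinom(length(mu), mu = mu, size = dispersion),
    nb_linear = rnbinom(length(mu), mu = mu, size = mu / dispersion),
    stop("unsupported generating family: ", family))
  d[[response]] <- draw(mu)
  d$species <- sprintf("sp%02d", d$species)
  d$host <- sprintf("H%03d", d$host)
  d$sample <- paste0(d$host, "_S1")
  d
}
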