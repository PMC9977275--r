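#' Select sites for strain-number inference
#'
#' Passes all multi-allelic sites (1 <= alt <= D-1) with depth at least
#' `min_depth` in the sample. Pairs with fewer than `min_sites` qualifying
#' sites are flagged not analyzable; by default the floor counts multi-allelic
#' sites, optionally all sites at sufficient coverage.
#'
#' @param snv an [snv_matrix()].
#' @param sample_id sample to extract.
#' @param min_depth per-site depth floor (default 20).
#' @param min_sites site-count floor (default 100).
#' @param floor_counts `"multiallelic"` (default) or `"coverage"`: which site
#'   count the floor applies to.
#' @return List with `species_id`, `sample_id`, `site_id`, `depth`, `alt`
#'   (qualifying sites only) and logical `analyzable`.
#' @export
select_sites <- function(snv, sample_id, min_depth = 20, min_sites = 100,
                         floor_counts = c("multiallelic", "coverage")) {
  floor_counts <- match.arg(floor_counts)
  D <- snv$depth[, sample_id]
  a <- snv$alt[, sample_id]
  covered <- D >= min_depth
  multi <- covered & a >= 1 & a <= D - 1
  n_floor <- if (floor_counts == "multiallelic") sum(multi) else sum(covered)
  list(species_id = snv$species_id, sample_id = sample_id,
       site_id = snv$sites$site_id[multi], depth = D[multi], alt = a[multi],
       analyzable = n_floor >= min_sites)
}

# all 2^K binary genotype patterns, ordered by number of alternate alleles so
# that ties in the per-site argmax resolve toward the sparser pattern
genotype_patterns <- function(K) {
  P <- as.matrix(expand.grid(rep(list(0:1), K)))
  P[order(rowSums(P)), , drop = FALSE]
}

# binomial log-likelihood of alt counts given per-site success prob p (with
# sequencing error folded in)
.mix_loglik <- function(alt, depth, p, eps) {
  pt <- (1 - eps) * p + eps * (1 - p)
  pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  alt * log(pt) + (depth - alt) * log1p(-pt)
}

# continuous step: maximize logL over (pi on the simplex, eps in [0, eps_max])
# for fixed genotypes G (S x K), by bounded quasi-Newton with analytic
# gradients on transformed coordinates (additive log-ratio for pi, scaled
# logit for eps)
.optimize_pi_eps <- function(alt, depth, G, pi0, eps0, eps_max,
                             precise = FALSE) {
  K <- ncol(G)
  # start the error coordinate inside (-8, 8): at the exact bound the
  # logistic transform's gradient vanishes and the optimizer cannot leave
  to_par <- function(pi, eps) c(if (K > 1) log(pi[-K] / pi[K]),
                                min(max(qlogis(eps / eps_max), -8), 8))
  from_par <- function(par) {
    if (K > 1) {
      e <- exp(c(par[seq_len(K - 1)], 0))
      pi <- e / sum(e)
    } else pi <- 1
    list(pi = pi, eps = eps_max * plogis(par[K]))
  }
  nll <- function(par) {
    th <- from_par(par)
    -sum(.mix_loglik(alt, depth, as.numeric(G %*% th$pi), th$eps))
  }
  grad <- function(par) {
    th <- from_par(par); pi <- th$pi; eps <- th$eps
    p <- as.numeric(G %*% pi)
    pt <- (1 - eps) * p + eps * (1 - p)
    pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
    w <- alt / pt - (depth - alt) / (1 - pt)   # d logL / d pt, per site
    g <- numeric(K)
    if (K > 1) {
      # d p_s / d t_j = pi_j (G_sj - p_s) under the alr parameterization
      gp <- crossprod(G[, seq_len(K - 1), drop = FALSE] - p, w) * pi[seq_len(K - 1)]
      g[seq_len(K - 1)] <- (1 - 2 * eps) * as.numeric(gp)
    }
    sig <- eps / eps_max
    g[K] <- sum(w * (1 - 2 * p)) * eps_max * sig * (1 - sig)
    -g
  }
  par0 <- to_par(pi0, max(eps0, 1e-6))
  # the error coordinate needs a wide box so eps can reach its bounds
  lo <- c(rep(-12, K - 1), -25); up <- c(rep(12, K - 1), 25)
  ctrl <- if (precise) list(maxit = 300, factr = 10) else list(maxit = 50)
  fit <- tryCatch(
    optim(par0, nll, grad, method = "L-BFGS-B", lower = lo, upper = up,
          control = ctrl),
    error = function(e) list(par = par0, value = nll(par0)))
  if (fit$value > nll(par0) + 1e-10) fit <- list(par = par0, value = nll(par0))
  c(from_par(fit$par), logL = -fit$value)
}

# exact per-site genotype assignment given (pi, eps): argmax over all 2^K
# patterns, ties toward fewer alternate alleles (P is ordered that way)
.genotype_step <- function(alt, depth, P, pi, eps) {
  p_pat <- as.numeric(P %*% pi)
  pt <- pmin(pmax((1 - eps) * p_pat + eps * (1 - p_pat), 1e-12), 1 - 1e-12)
  ll <- outer(alt, log(pt)) + outer(depth - alt, log1p(-pt))
  best <- max.col(ll, ties.method = "first")
  list(G = P[best, , drop = FALSE],
       logL = sum(ll[cbind(seq_along(alt), best)]))
}

# deterministic starts built from the empirical allele-frequency spectrum:
# candidate frequency vectors whose entries sit at observed quantiles, so a
# strain whose frequency matches a cluster of sites is found even when random
# restarts miss it
.informed_pis <- function(f, K, max_starts = 8) {
  if (K == 1) return(list())
  qs <- unique(round(quantile(f, seq(0.05, 0.95, length.out = 6),
                              names = FALSE, type = 1), 3))
  qs <- unique(pmin(pmax(qs, 0.02), 0.98))
  out <- list()
  if (K == 2) {
    out <- lapply(qs, function(q) c(q, 1 - q))
  } else {
    cmb <- utils::combn(qs, min(K - 1, length(qs)))
    for (j in seq_len(ncol(cmb))) {
      v <- cmb[, j]
      if (length(v) < K - 1) next
      rest <- 1 - sum(v)
      if (rest >= 0.02) out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  if (length(out) > max_starts)
    out <- out[round(seq(1, length(out), length.out = max_starts))]
  out
}

#' Fit a K-strain binomial mixture to allele counts at polymorphic sites
#'
#' Model: each strain k has a binary genotype g_ks per site and frequency
#' pi_k; the expected alternate-allele fraction at site s is
#' p_s = sum_k pi_k g_ks, perturbed by a symmetric sequencing-error rate
#' epsilon, and alt_s ~ Binomial(D_s, (1-eps) p_s + eps (1-p_s)). Fitting
#' alternates (i) exact per-site genotype assignment by enumeration over all
#' 2^K patterns (ties broken toward fewer alternate alleles) with (ii)
#' bounded continuous maximization over (pi, eps), so the log-likelihood is
#' non-decreasing across iterations; the best of `n_restarts` random
#' initializations is returned. Strains are reported in descending frequency
#' order.
#'
#' @param sites a site set from [select_sites()] (or any list with `depth`
#'   and `alt` vectors).
#' @param K number of strains, 1..4.
#' @param seed integer seed for restart initializations.
#' @param n_restarts random restarts (default 10).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param eps_max upper bound of the error-rate search (default 0.1).
#' @param max_iter iteration cap per restart.
#' @param init optional list(pi, G) warm start used as an extra restart.
#' @param bic parameter-counting convention for the BIC. `"pattern"` (the
#'   default) counts the continuous parameters plus the site-pattern-class
#'   proportions the genotype assignment implicitly estimates,
#'   `nu = (2^K - 1) + K`, with the total read count over included sites as
#'   the sample size (the binomial trials are the observations).
#'   `"classification"` counts every genotype entry as a parameter,
#'   `nu = (K - 1) + K S + 1`, with the site count as the sample size; that
#'   penalty grows linearly in S and in practice can never select a minor
#'   strain, so it is not the default.
#' @return An object of class `strain_fit`: `K`, `genotypes` (K x S),
#'   `pi`, `eps`, `logL`, `n_params`, `BIC`, `n_sites`, `n_restarts_used`,
#'   `seed`.
#' @export
fit_strain_model <- function(sites, K, seed = 1L, n_restarts = 10,
                             tol = 1e-6, eps_max = 0.1, max_iter = 200,
                             init = NULL, bic = c("pattern", "classification")) {
  bic <- match.arg(bic)
  if (!K %in% 1:4) stop("K must be in 1..4")
  alt <- as.numeric(sites$alt); depth <- as.numeric(sites$depth)
  S <- length(alt)
  if (S < 1) stop("site set is empty: not analyzable")
  f_emp <- alt / depth
  P <- genotype_patterns(K)

  run_once <- function(pi, G, eps) {
    logL <- logL_prev <- -Inf
    for (it in seq_len(max_iter)) {
      th <- .optimize_pi_eps(alt, depth, G, pi, eps, eps_max)
      pi <- th$pi; eps <- th$eps
      gs <- .genotype_step(alt, depth, P, pi, eps)
      G <- gs$G; logL <- gs$logL
      if (logL - logL_prev < tol && it > 1) break
      logL_prev <- logL
    }
    # high-precision polish rounds until a joint fixed point
    for (pp in 1:25) {
      th <- .optimize_pi_eps(alt, depth, G, pi, eps, eps_max, precise = TRUE)
      gs <- .genotype_step(alt, depth, P, th$pi, th$eps)
      if (gs$logL < logL + 1e-9) break
      pi <- th$pi; eps <- th$eps; G <- gs$G; logL <- gs$logL
    }
    list(pi = pi, eps = eps, G = G, logL = logL, iters = it)
  }

  # random restarts, deterministic frequency-informed starts, optional warm
  # start from the caller
  start_list <- list()
  for (r in seq_len(n_restarts)) {
    old <- .Random.seed_save(); set.seed(derive_seed(seed, paste0("restart", r)))
    g <- rgamma(K, 1)
    start_list[[r]] <- list(pi = g / sum(g),
                            G = matrix(rbinom(S * K, 1, rep(f_emp, K)), nrow = S),
                            eps = 0.01)
    .Random.seed_restore(old)
  }
  for (pi_c in .informed_pis(f_emp, K)) {
    start_list[[length(start_list) + 1L]] <-
      list(pi = pi_c, G = .genotype_step(alt, depth, P, pi_c, 0.02)$G,
           eps = 0.02)
  }
  if (!is.null(init)) start_list[[length(start_list) + 1L]] <- init
  if (!length(start_list))
    start_list <- list(list(pi = rep(1 / K, K),
                            G = .genotype_step(alt, depth, P, rep(1 / K, K),
                                               0.02)$G,
                            eps = 0.02))
  best <- NULL
  for (s0 in start_list) {
    res <- run_once(s0$pi, s0$G, s0$eps %||% 0.01)
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  starts <- length(start_list)
  ord <- order(best$pi, decreasing = TRUE)
  if (bic == "pattern") {
    nu <- (2^K - 1) + K
    n_bic <- sum(depth)
  } else {
    nu <- (K - 1) + K * S + 1
    n_bic <- S
  }
  structure(list(K = K, genotypes = t(best$G[, ord, drop = FALSE]),
                 pi = best$pi[ord], eps = best$eps, logL = best$logL,
                 n_params = nu, BIC = -2 * best$logL + nu * log(n_bic),
                 bic_convention = bic,
                 n_sites = S, n_restarts_used = starts, seed = seed),
            class = "strain_fit")
}

#' @export
print.strain_fit <- function(x, ...) {
  cat(sprintf("strain_fit: K=%d, pi=(%s), eps=%.4f, logL=%.2f, BIC=%.2f (%d sites)\n",
              x$K, paste(sprintf("%.3f", x$pi), collapse = ", "),
              x$eps, x$logL, x$BIC, x$n_sites))
  invisible(x)
}

#' Infer the number of strains in a sample by BIC
#'
#' Fits the mixture for K = 1..`k_max` and returns the fit minimizing the
#' BIC (see the `bic` argument of [fit_strain_model()] for the
#' parameter-counting convention); ties break toward smaller K. Each K > 1
#' receives, in addition to its random restarts, a warm start
#' built from the best (K-1)-strain fit (the new strain starts at low
#' frequency with the most frequent genotype), which guarantees the maximized
#' log-likelihood is non-decreasing in K.
#'
#' @param sites a site set from [select_sites()]; must be analyzable.
#' @param k_max maximum strain number (default 4).
#' @inheritParams fit_strain_model
#' @return The BIC-optimal `strain_fit`, with attribute `"all_fits"` holding
#'   one fit per K.
#' @export
infer_strain_number <- function(sites, k_max = 4, seed = 1L, n_restarts = 10,
                                tol = 1e-6, eps_max = 0.1,
                                bic = c("pattern", "classification")) {
  bic <- match.arg(bic)
  if (!isTRUE(sites$analyzable))
    stop("site set is not analyzable (site floor not met)")
  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    init <- NULL
    if (K > 1) {
      prev <- fits[[K - 1]]
      Gp <- t(prev$genotypes)                        # S x (K-1)
      init <- list(pi = c(prev$pi * (1 - 1e-3), 1e-3),
                   G = cbind(Gp, Gp[, 1]), eps = prev$eps)
    }
    fits[[K]] <- fit_strain_model(sites, K, seed = derive_seed(seed, paste0("K", K)),
                                  n_restarts = n_restarts, tol = tol,
                                  eps_max = eps_max, init = init, bic = bic)
  }
  bics <- vapply(fits, `[[`, numeric(1), "BIC")
  best <- fits[[which.min(bics)]]   # which.min takes the first (smallest K) on ties
  attr(best, "all_fits") <- fits
  best
}

#' Strain-number fits for all eligible species and samples of a cohort
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param config a [run_config()].
#' @param seed integer seed.
#' @param species optional subset of species ids.
#' @return data.frame with one row per analyzable (species, sample): `K`,
#'   `pi` (comma-separated), `eps`, `logL`, `BIC`, `n_sites`.
#' @export
strain_table <- function(cohort, config = run_config(), seed = 1L,
                         species = NULL) {
  out <- list()
  sps <- intersect(eligible_species(cohort, config$min_marker_cov,
                                    config$min_marker_samples),
                   names(cohort$snv))
  if (!is.null(species)) sps <- intersect(sps, species)
  for (sp in sps) {
    snv <- cohort$snv[[sp]]
    for (s in filter_samples(snv, config$min_median_depth)) {
      ss <- select_sites(snv, s, config$strain_min_depth, config$strain_min_sites,
                         config$site_floor_counts)
      if (!ss$analyzable) next
      fit <- infer_strain_number(ss, config$strain_k_max,
                                 seed = derive_seed(seed, paste(sp, s)),
                                 n_restarts = config$strain_n_restarts,
                                 tol = config$strain_tol,
                                 eps_max = config$strain_eps_max)
      out[[paste(sp, s)]] <- data.frame(
        species_id = sp, sample_id = s, K = fit$K,
        pi = paste(sprintf("%.6f", fit$pi), collapse = ","),
        eps = fit$eps, logL = fit$logL, BIC = fit$BIC, n_sites = fit$n_sites,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else NULL
}
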