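# brute-force global optimum of the K-strain mixture log-likelihood:
# enumerate all per-site genotype patterns exactly (sites are independent, so
# maximizing per site over patterns equals maximizing over genotype
# matrices), on a grid over strain frequency (step pi_step) and error rate
# (step eps_step). Independent of the package's alternating optimizer.
oracle_strain_logL <- function(depth, alt, K, eps_max = 0.1,
                               pi_step = 0.01, eps_step = 0.005) {
  stopifnot(K %in% 1:2)
  eps_grid <- seq(0, eps_max, by = eps_step)
  site_ll <- function(p, eps) {
    pt <- (1 - eps) * p + eps * (1 - p)
    pt <- min(max(pt, 1e-12), 1 - 1e-12)
    alt * log(pt) + (depth - alt) * log(1 - pt)
  }
  best <- -Inf
  if (K == 1) {
    for (eps in eps_grid) {
      ll <- sum(pmax(site_ll(0, eps), site_ll(1, eps)))
      best <- max(best, ll)
    }
  } else {
    pi_grid <- seq(pi_step, 1 - pi_step, by = pi_step)
    for (p1 in pi_grid) for (eps in eps_grid) {
      # patterns (0,0), (1,0), (0,1), (1,1) -> p in {0, p1, 1-p1, 1}
      lls <- rbind(site_ll(0, eps), site_ll(p1, eps),
                   site_ll(1 - p1, eps), site_ll(1, eps))
      best <- max(best, sum(apply(lls, 2, max)))
    }
  }
  best
}

# analytic expected rarefied richness (hypergeometric), the independent
# oracle for the random-subsampling implementation
expected_rarefied_richness <- function(counts, depth) {
  as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), depth)))
}
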