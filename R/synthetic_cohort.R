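#' Simulation parameters for a synthetic cohort
#'
#' Defaults emulate a longitudinally sampled stool-metagenome cohort: a
#' 100-species pool with uneven Dirichlet communities, ~20 million reads per
#' sample, focal species at boosted abundance (median depth in the tens), up
#' to four strains per focal species with strain count coupled to community
#' Shannon diversity through `beta_dbd`, binomial read sampling with
#' sequencing error, accessory gene content per strain, and per-gene loss
#' hazards coupled to Shannon diversity through `gamma_bq` (the Black-Queen
#' regime when positive).
#'
#' @param n_hosts number of hosts.
#' @param time_points_per_host samples per host.
#' @param days_between_samples days between consecutive samples (~6 months by
#'   default, matching typical longitudinal stool cohorts).
#' @param n_species_pool size of the species pool.
#' @param abundance_concentration symmetric Dirichlet concentration of the
#'   non-focal community (evenness control).
#' @param focal_boost multiplicative Dirichlet-weight boost of focal species,
#'   keeping them deep enough to assay.
#' @param reads_per_sample expected metagenomic reads per sample.
#' @param read_depth_jitter_sd lognormal sd of per-sample read counts.
#' @param coverage_per_read expected per-base genome coverage contributed by
#'   one read of a species (read length / genome size).
#' @param n_focal_species number of focal species with SNV/gene tables.
#' @param sites_per_species assayed nucleotide sites per focal species.
#' @param fourfold_fraction,onefold_fraction fractions of sites labelled
#'   fourfold and onefold degenerate ("other" gets the remainder).
#' @param strain_divergence pairwise fraction of sites at which two strains
#'   differ.
#' @param beta_dbd coupling of strain-count log-odds to standardized Shannon
#'   diversity (0 = neutral, > 0 = diversity begets diversity,
#'   < 0 = ecological controls).
#' @param base_strain_logit baseline log-odds of the shifted-binomial strain
#'   count.
#' @param strain_freq_walk_sd step sd of the logistic-normal random walk of
#'   strain frequencies between time points.
#' @param seq_error sequencing error rate per read base.
#' @param genes_per_species pangenome size per focal species (excluding the
#'   15 marker genes).
#' @param core_gene_fraction fraction of the pangenome carried by every
#'   strain at baseline.
#' @param accessory_carriage probability a strain carries an accessory gene.
#' @param gene_units effective independent coverage units per gene
#'   (controls Poisson noise of per-gene coverage).
#' @param gamma_bq coupling of the per-gene loss hazard to standardized
#'   Shannon diversity.
#' @param base_loss_rate per-gene per-day baseline loss hazard.
#' @param base_gain_rate per-gene per-day baseline gain hazard (uncoupled).
#' @param seed integer seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_hosts = 50,
                       time_points_per_host = 2,
                       days_between_samples = 180,
                       n_species_pool = 100,
                       abundance_concentration = 0.5,
                       focal_boost = 10,
                       reads_per_sample = 2e7,
                       read_depth_jitter_sd = 0.2,
                       coverage_per_read = 5e-5,
                       n_focal_species = 5,
                       sites_per_species = 200,
                       fourfold_fraction = 0.25,
                       onefold_fraction = 0.70,
                       strain_divergence = 0.1,
                       beta_dbd = 0,
                       base_strain_logit = qlogis(0.25),
                       strain_freq_walk_sd = 0.3,
                       seq_error = 0.005,
                       genes_per_species = 150,
                       core_gene_fraction = 0.7,
                       accessory_carriage = 0.6,
                       gene_units = 100,
                       gamma_bq = 0,
                       base_loss_rate = 1e-4,
                       base_gain_rate = 2e-5,
                       seed = 1L) {
  p <- as.list(environment())
  with(p, {
    stopifnot(n_hosts >= 1, time_points_per_host >= 1, n_species_pool >= 1,
              n_focal_species >= 1, n_focal_species <= n_species_pool,
              sites_per_species >= 1, genes_per_species >= 1,
              abundance_concentration > 0, reads_per_sample >= 1)
    if (core_gene_fraction < 0 || core_gene_fraction > 1)
      stop("core_gene_fraction must be in [0,1]")
    if (fourfold_fraction + onefold_fraction > 1)
      stop("fourfold_fraction + onefold_fraction must be <= 1")
    if (strain_divergence < 0 || strain_divergence > 0.5)
      stop("strain_divergence must be in [0, 0.5]")
    if (seq_error < 0 || seq_error >= 1) stop("seq_error must be in [0,1)")
    if (base_loss_rate < 0 || base_gain_rate < 0) stop("rates must be >= 0")
  })
  structure(p, class = "sim_params")
}

# per-strain alternate-allele probability giving pairwise divergence d:
# two iid Bernoulli(theta) genotypes differ with prob 2 theta (1-theta) = d
.theta_of_d <- function(d) (1 - sqrt(1 - 2 * d)) / 2

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

#' Simulate allele counts for one strain mixture
#'
#' Unit-scale generator used to test strain inference and the polymorphism
#' statistic: K binary genotypes whose pairwise divergence is ~Binomial(L, d),
#' per-site depths Poisson(`depth_mean`), and alternate counts
#' Binomial(D, (1-eps) p + eps (1-p)) with p the frequency-weighted genotype
#' mean.
#'
#' @param K number of strains (1..4).
#' @param pi strain frequencies, summing to 1.
#' @param d pairwise strain divergence (fraction of differing sites).
#' @param L number of sites.
#' @param depth_mean mean per-site depth.
#' @param eps_sim sequencing error rate.
#' @param seed integer seed.
#' @return List with `depth`, `alt`, `genotypes` (K x L), `site_id`,
#'   `analyzable = TRUE` (so it can feed [fit_strain_model()] directly).
#' @export
simulate_strain_sample <- function(K, pi, d, L, depth_mean, eps_sim = 0,
                                   seed = 1L) {
  stopifnot(K %in% 1:4, length(pi) == K, all(pi > 0))
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  theta <- .theta_of_d(d)
  G <- matrix(rbinom(K * L, 1, theta), nrow = K)
  p <- as.numeric(pi %*% G)
  D <- rpois(L, depth_mean)
  pt <- (1 - eps_sim) * p + eps_sim * (1 - p)
  a <- rbinom(L, D, pt)
  list(species_id = "sim", sample_id = "sim", site_id = paste0("s", seq_len(L)),
       depth = D, alt = a, genotypes = G, analyzable = TRUE)
}

#' Simulate a cohort with known eco-evolutionary ground truth
#'
#' Generates a full [cohort_tables()] bundle plus a truth ledger. Community
#' compositions are host-level Dirichlet draws (focal species boosted);
#' per-sample reads allocate multinomially; focal-species strain counts are
#' 1 + Binomial(3, plogis(base + beta_dbd * z)) with z the cohort-standardized
#' true Shannon diversity; site depths are Poisson at the species' expected
#' coverage, alternate counts binomial with sequencing error; gene coverages
#' are Poisson around frequency-weighted strain carriage times the marker
#' median; between consecutive time points each (strain, gene) presence flips
#' to absent with probability 1 - exp(-base_loss_rate *
#' exp(gamma_bq * z) * delta_days), and absent genes are regained at
#' `base_gain_rate` (a gene leaves the community's gene content only when no
#' carrying strain remains, so both deletion and strain-replacement flavours
#' of loss arise from one mechanism).
#'
#' @param params a [sim_params()] list.
#' @return List with `tables` (a `cohort_tables`) and `truth`, a list holding
#'   `community` (per-sample true Shannon/richness), `strains` (per
#'   host x species x time: `K_true`, frequencies), `events` (gene
#'   gain/loss events with days), and `gene_content` (per-species true
#'   copy-number matrices).
#' @export
simulate_cohort <- function(params = sim_params()) {
  p <- params
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)

  n_samp <- p$n_hosts * p$time_points_per_host
  hosts <- sprintf("H%03d", seq_len(p$n_hosts))
  gaps <- rep_len(p$days_between_samples, max(p$time_points_per_host - 1L, 1L))
  days <- cumsum(c(0L, if (p$time_points_per_host > 1) gaps))
  samples <- data.frame(
    sample_id = sprintf("%s_T%d", rep(hosts, each = p$time_points_per_host),
                        seq_len(p$time_points_per_host)),
    host_id = rep(hosts, each = p$time_points_per_host),
    time_point = rep(seq_len(p$time_points_per_host) - 1L, p$n_hosts),
    collection_day = rep(days, p$n_hosts),
    read_count = 0L, stringsAsFactors = FALSE)

  species <- sprintf("sp%03d", seq_len(p$n_species_pool))
  focal <- species[seq_len(p$n_focal_species)]
  alpha <- rep(p$abundance_concentration, p$n_species_pool)
  alpha[seq_len(p$n_focal_species)] <- p$abundance_concentration * p$focal_boost

  comm <- t(vapply(seq_len(p$n_hosts), function(i) rdirichlet1(alpha),
                   numeric(p$n_species_pool)))
  H_true <- apply(comm, 1, function(x) -sum(x * log(x)))
  z <- as.numeric(scale(H_true))

  idx_host <- rep(seq_len(p$n_hosts), each = p$time_points_per_host)
  rel_abund <- comm[idx_host, , drop = FALSE]
  dimnames(rel_abund) <- list(samples$sample_id, species)
  samples$read_count <- as.integer(round(
    p$reads_per_sample * exp(rnorm(n_samp, 0, p$read_depth_jitter_sd))))

  # expected per-base depth of each species in each sample
  depth_exp <- rel_abund * samples$read_count * p$coverage_per_read
  marker_coverage <- matrix(
    rpois(length(depth_exp), depth_exp * 15) / 15,
    nrow = n_samp, dimnames = dimnames(rel_abund))

  taxonomy <- data.frame(
    species_id = species,
    genus = paste0("g", (seq_along(species) - 1) %/% 2),
    family = paste0("f", (seq_along(species) - 1) %/% 5),
    order = paste0("o", (seq_along(species) - 1) %/% 10),
    class = paste0("c", (seq_along(species) - 1) %/% 25),
    phylum = paste0("p", (seq_along(species) - 1) %/% 50),
    stringsAsFactors = FALSE)

  L <- p$sites_per_species
  M <- p$genes_per_species
  n_core <- round(M * p$core_gene_fraction)
  theta <- .theta_of_d(p$strain_divergence)
  degen_p <- c(p$fourfold_fraction, p$onefold_fraction,
               1 - p$fourfold_fraction - p$onefold_fraction)

  snv <- list(); genes <- list()
  truth_strains <- list(); truth_events <- list(); truth_content <- list()

  for (sp in focal) {
    gene_ids <- sprintf("%s_g%04d", sp, seq_len(M))
    core_ids <- gene_ids[seq_len(n_core)]
    sites <- data.frame(
      site_id = sprintf("%s_s%05d", sp, seq_len(L)),
      gene_id = sample(core_ids, L, replace = TRUE),
      degeneracy = sample(c("fourfold", "onefold", "other"), L, TRUE, degen_p),
      stringsAsFactors = FALSE)
    depth_m <- matrix(0L, L, n_samp, dimnames = list(sites$site_id, samples$sample_id))
    alt_m <- depth_m
    cov_m <- matrix(0, M, n_samp, dimnames = list(gene_ids, samples$sample_id))
    mm <- numeric(n_samp)
    c_true <- matrix(0, M, n_samp, dimnames = dimnames(cov_m))

    for (h in seq_len(p$n_hosts)) {
      K <- 1L + rbinom(1, 3, plogis(p$base_strain_logit + p$beta_dbd * z[h]))
      G <- matrix(rbinom(K * L, 1, theta), nrow = K)
      pi_t <- rdirichlet1(rep(2, K))
      carry <- rbind(matrix(TRUE, n_core, K) [, seq_len(K), drop = FALSE],
                     matrix(rbinom((M - n_core) * K, 1, p$accessory_carriage) == 1,
                            M - n_core, K))
      loss_haz <- p$base_loss_rate * exp(p$gamma_bq * z[h])

      for (tp in seq_len(p$time_points_per_host)) {
        j <- (h - 1L) * p$time_points_per_host + tp
        s_id <- samples$sample_id[j]
        if (tp > 1) {
          dd <- samples$collection_day[j] - samples$collection_day[j - 1]
          # strain frequency random walk on the additive log-ratio scale
          if (K > 1) {
            lr <- log(pi_t) - log(pi_t[K]) + c(rnorm(K - 1, 0, p$strain_freq_walk_sd), 0)
            pi_t <- exp(lr) / sum(exp(lr))
          }
          p_loss <- 1 - exp(-loss_haz * dd)
          p_gain <- 1 - exp(-p$base_gain_rate * dd)
          flip_loss <- carry & matrix(runif(M * K) < p_loss, M, K)
          flip_gain <- !carry & matrix(runif(M * K) < p_gain, M, K)
          if (any(flip_loss) || any(flip_gain)) {
            ev <- which(flip_loss | flip_gain, arr.ind = TRUE)
            truth_events[[length(truth_events) + 1L]] <- data.frame(
              species_id = sp, host_id = hosts[h], gene_id = gene_ids[ev[, 1]],
              strain = ev[, 2],
              type = ifelse(flip_loss[ev], "loss", "gain"),
              day = samples$collection_day[j], stringsAsFactors = FALSE)
          }
          carry <- (carry & !flip_loss) | flip_gain
        }
        lam <- depth_exp[j, sp]
        D <- rpois(L, lam)
        pr <- as.numeric(pi_t %*% G)
        pt <- (1 - p$seq_error) * pr + p$seq_error * (1 - pr)
        alt_m[, j] <- rbinom(L, D, pt)
        depth_m[, j] <- D
        cf <- as.numeric(carry %*% pi_t)   # true copy number per gene
        c_true[, j] <- cf
        mm[j] <- median(rpois(15, lam * p$gene_units) / p$gene_units)
        cov_m[, j] <- rpois(M, cf * lam * p$gene_units) / p$gene_units
        truth_strains[[length(truth_strains) + 1L]] <- data.frame(
          species_id = sp, host_id = hosts[h], sample_id = s_id,
          time_point = tp - 1L, K_true = K,
          pi_true = paste(sprintf("%.6f", pi_t), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    snv[[sp]] <- snv_matrix(sp, sites, depth_m, alt_m)
    genes[[sp]] <- gene_cn_matrix(sp, cov_m, mm)
    truth_content[[sp]] <- c_true
  }

  tables <- cohort_tables(rel_abund, marker_coverage, taxonomy, samples,
                          snv, genes)
  truth <- list(
    community = data.frame(sample_id = samples$sample_id,
                           host_id = samples$host_id,
                           shannon_true = H_true[idx_host],
                           shannon_z = z[idx_host],
                           richness_true = rowSums(rel_abund > 0),
                           stringsAsFactors = FALSE),
    strains = do.call(rbind, c(truth_strains, make.row.names = FALSE)),
    events = if (length(truth_events))
      do.call(rbind, c(truth_events, make.row.names = FALSE)) else NULL,
    gene_content = truth_content)
  list(tables = tables, truth = truth)
}
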