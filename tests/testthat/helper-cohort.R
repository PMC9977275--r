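# small deterministic cohort used across I/O and validation tests
make_test_cohort <- function(n_samples = 4, n_species = 6, n_sites = 30,
                             n_genes = 20, seed = 1) {
  set.seed(seed)
  hosts <- rep(sprintf("h%d", seq_len(n_samples / 2)), each = 2)
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(n_samples)),
    host_id = hosts,
    time_point = rep(0:1, n_samples / 2),
    collection_day = rep(c(0L, 180L), n_samples / 2),
    read_count = as.integer(2e6 + seq_len(n_samples)),
    stringsAsFactors = FALSE)
  species <- sprintf("spA%02d", seq_len(n_species))
  ra <- matrix(rgamma(n_samples * n_species, 1), n_samples,
               dimnames = list(samples$sample_id, species))
  ra <- ra / rowSums(ra)
  mc <- matrix(runif(n_samples * n_species, 5, 40), n_samples,
               dimnames = dimnames(ra))
  taxonomy <- data.frame(species_id = species,
                         genus = rep(c("gA", "gB", "gC"), length.out = n_species),
                         family = rep(c("fA", "fB"), length.out = n_species),
                         order = "oA", class = "cA",
                         phylum = rep(c("pA", "pB"), length.out = n_species),
                         stringsAsFactors = FALSE)
  sp1 <- species[1]
  gene_ids <- sprintf("%s_g%02d", sp1, seq_len(n_genes))
  sites <- data.frame(site_id = sprintf("%s_s%03d", sp1, seq_len(n_sites)),
                      gene_id = sample(gene_ids[1:10], n_sites, replace = TRUE),
                      degeneracy = sample(c("fourfold", "onefold", "other"),
                                          n_sites, TRUE, c(.4, .4, .2)),
                      stringsAsFactors = FALSE)
  depth <- matrix(rpois(n_sites * n_samples, 30), n_sites,
                  dimnames = list(sites$site_id, samples$sample_id))
  alt <- matrix(rbinom(length(depth), depth, 0.05), n_sites,
                dimnames = dimnames(depth))
  storage.mode(depth) <- storage.mode(alt) <- "integer"
  cov <- matrix(runif(n_genes * n_samples, 10, 40), n_genes,
                dimnames = list(gene_ids, samples$sample_id))
  mm <- apply(cov[1:10, ], 2, median)
  cohort_tables(ra, mc, taxonomy, samples,
                snv = setNames(list(snv_matrix(sp1, sites, depth, alt)), sp1),
                genes = setNames(list(gene_cn_matrix(sp1, cov, mm,
                                                     blacklist = gene_ids[n_genes])),
                                 sp1))
}

# an snv_matrix wrapping one sample's worth of site depths/alt counts
snv_from_vectors <- function(depth, alt, degeneracy = "fourfold",
                             gene_id = "g1", sample_id = "s1",
                             species_id = "spX") {
  n <- length(depth)
  sites <- data.frame(site_id = sprintf("x%05d", seq_len(n)),
                      gene_id = rep_len(gene_id, n),
                      degeneracy = rep_len(degeneracy, n),
                      stringsAsFactors = FALSE)
  d <- matrix(as.integer(depth), ncol = 1,
              dimnames = list(sites$site_id, sample_id))
  a <- matrix(as.integer(alt), ncol = 1, dimnames = dimnames(d))
  snv_matrix(species_id, sites, d, a)
}
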