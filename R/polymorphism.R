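DEGEN_OF_CLASS <- c(synonymous = "fourfold", nonsynonymous = "onefold")

#' Species eligible for within-species analyses
#'
#' A species is analyzed only when its marker-gene coverage reaches
#' `min_cov` in at least `min_samples` samples.
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param min_cov marker coverage threshold (default 10).
#' @param min_samples minimum number of samples at that coverage (default 10).
#' @return Character vector of species ids.
#' @export
eligible_species <- function(cohort, min_cov = 10, min_samples = 10) {
  mc <- cohort$marker_coverage
  if (ncol(mc) == 0) return(character())
  colnames(mc)[colSums(mc >= min_cov) >= min_samples]
}

#' Samples retained for SNV analysis of one species
#'
#' Samples with median depth below `min_median` over covered protein-coding
#' sites are excluded.
#'
#' @param snv an [snv_matrix()].
#' @param min_median median-depth floor (default 5; strict `<` exclusion, so a
#'   sample at exactly 5 is retained).
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(snv, min_median = 5) {
  names(snv$median_depth)[snv$median_depth >= min_median]
}

#' Apply per-site coverage and gene filters to an SNV matrix
#'
#' Retains a site in a sample iff its depth D satisfies
#' `lo_frac * Dbar <= D <= hi_frac * Dbar` (Dbar the sample's median depth),
#' its gene is a core gene, and its gene is neither blacklisted nor in the
#' high-copy exclusion set. Retention is per (site, sample): failing cells
#' have depth and alt set to 0, which downstream rate computations treat as
#' unassayed. The per-sample median depth is computed before filtering and is
#' left untouched.
#'
#' @param snv an [snv_matrix()].
#' @param core character vector of core gene ids.
#' @param blacklist,high_copy gene ids excluded from SNV calling.
#' @param lo_frac,hi_frac depth window as multiples of the median depth.
#' @return A filtered `snv_matrix` (sites in non-core/excluded genes dropped,
#'   out-of-window cells zeroed).
#' @export
filter_sites <- function(snv, core, blacklist = character(),
                         high_copy = character(), lo_frac = 0.3, hi_frac = 3) {
  keep_gene <- snv$sites$gene_id %in% setdiff(core, union(blacklist, high_copy))
  sites <- snv$sites[keep_gene, , drop = FALSE]
  depth <- snv$depth[keep_gene, , drop = FALSE]
  alt <- snv$alt[keep_gene, , drop = FALSE]
  md <- snv$median_depth
  lo <- matrix(lo_frac * md, nrow = nrow(depth), ncol = ncol(depth), byrow = TRUE)
  hi <- matrix(hi_frac * md, nrow = nrow(depth), ncol = ncol(depth), byrow = TRUE)
  bad <- depth < lo | depth > hi
  depth[bad] <- 0L
  alt[bad] <- 0L
  out <- snv_matrix(snv$species_id, sites, depth, alt)
  out$median_depth <- md  # Dbar is defined on the unfiltered matrix
  out
}

#' Polymorphism rate of one species in one sample
#'
#' The proportion of assayed sites of a degeneracy class whose within-sample
#' alternate-allele frequency f = alt/D lies in the intermediate window
#' `[f_lo, f_hi]` (bounds inclusive). The denominator is all retained sites of
#' the class with D > 0 (monomorphic sites included); synonymous means
#' fourfold-degenerate sites, nonsynonymous onefold.
#'
#' @param snv a filtered [snv_matrix()] (see [filter_sites()]).
#' @param sample_id sample to score.
#' @param class `"synonymous"` or `"nonsynonymous"`.
#' @param f_lo,f_hi intermediate-frequency window (default 0.2 and 0.8).
#' @return One-row data.frame with `species_id`, `sample_id`, `class`,
#'   `n_sites_passing`, `n_intermediate`, `rate` (`NA` when no site passes).
#' @export
polymorphism_rate <- function(snv, sample_id, class = "synonymous",
                              f_lo = 0.2, f_hi = 0.8) {
  class <- match.arg(class, names(DEGEN_OF_CLASS))
  stopifnot(sample_id %in% colnames(snv$depth))
  sel <- snv$sites$degeneracy == DEGEN_OF_CLASS[[class]]
  D <- snv$depth[sel, sample_id]
  a <- snv$alt[sel, sample_id]
  covered <- D > 0
  f <- a[covered] / D[covered]
  n_pass <- sum(covered)
  n_int <- sum(f >= f_lo & f <= f_hi)
  data.frame(species_id = snv$species_id, sample_id = sample_id, class = class,
             n_sites_passing = n_pass, n_intermediate = n_int,
             rate = if (n_pass > 0) n_int / n_pass else NA_real_,
             stringsAsFactors = FALSE)
}

#' Within-host change in polymorphism rate between two time points
#'
#' @param rec1,rec2 one-row records from [polymorphism_rate()] at the earlier
#'   and later time point of one host, same species and class.
#' @param samples the cohort's samples table (for collection days).
#' @return One-row data.frame with `delta = rate(t2) - rate(t1)` and
#'   `delta_days`, or `NULL` (with a message) when either rate is undefined.
#' @export
polymorphism_change <- function(rec1, rec2, samples) {
  stopifnot(rec1$species_id == rec2$species_id, rec1$class == rec2$class)
  if (is.na(rec1$rate) || is.na(rec2$rate)) {
    message("skipping pair ", rec1$sample_id, " -> ", rec2$sample_id,
            ": undefined polymorphism rate")
    return(NULL)
  }
  day <- function(s) samples$collection_day[match(s, samples$sample_id)]
  host <- function(s) samples$host_id[match(s, samples$sample_id)]
  stopifnot(host(rec1$sample_id) == host(rec2$sample_id))
  dd <- day(rec2$sample_id) - day(rec1$sample_id)
  if (dd <= 0) stop("t2 must be later than t1")
  data.frame(species_id = rec1$species_id, host_id = host(rec1$sample_id),
             t1 = rec1$sample_id, t2 = rec2$sample_id, delta_days = dd,
             class = rec1$class, delta = rec2$rate - rec1$rate,
             stringsAsFactors = FALSE)
}

# time-point pairs within one host: consecutive, anchored at the first
# sample, or all ordered pairs
host_pairs <- function(sample_ids, samples, pairing = "consecutive") {
  ord <- sample_ids[order(samples$time_point[match(sample_ids, samples$sample_id)])]
  n <- length(ord)
  if (n < 2) return(NULL)
  switch(pairing,
    consecutive = data.frame(t1 = ord[-n], t2 = ord[-1], stringsAsFactors = FALSE),
    first_anchor = data.frame(t1 = ord[1], t2 = ord[-1], stringsAsFactors = FALSE),
    all_pairs = {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      data.frame(t1 = ord[idx[, 1]], t2 = ord[idx[, 2]], stringsAsFactors = FALSE)
    },
    stop("unknown pairing: ", pairing))
}

#' Cohort-wide polymorphism rates and temporal changes
#'
#' Orchestrates the full filtering stack per eligible species: core genes and
#' high-copy exclusions from the gene table, sample exclusion on median depth,
#' the per-site depth window, then synonymous and nonsynonymous rates per
#' retained sample and rate changes between within-host time-point pairs.
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param config a [run_config()].
#' @return List with data.frames `rates` and `changes`.
#' @export
polymorphism_table <- function(cohort, config = run_config()) {
  rates <- list(); changes <- list()
  for (sp in intersect(eligible_species(cohort, config$min_marker_cov,
                                        config$min_marker_samples),
                       names(cohort$snv))) {
    gcn <- cohort$genes[[sp]]
    core <- core_genes(gcn, threshold = config$core_prevalence,
                       marker_min = config$prevalence_marker_min,
                       c_lo = config$prevalence_c_lo, c_hi = config$prevalence_c_hi)
    hc <- high_copy_exclusions(gcn, c_max = config$high_copy_c)
    filt <- filter_sites(cohort$snv[[sp]], core, gcn$blacklist, hc,
                         config$site_depth_lo_frac, config$site_depth_hi_frac)
    keep <- filter_samples(filt, config$min_median_depth)
    recs <- list()
    for (s in keep) for (cl in names(DEGEN_OF_CLASS))
      recs[[paste(s, cl)]] <- polymorphism_rate(filt, s, cl, config$f_lo, config$f_hi)
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    rates[[sp]] <- recs
    # temporal pairs within hosts
    sm <- cohort$samples[cohort$samples$sample_id %in% keep, ]
    for (h in unique(sm$host_id)) {
      prs <- host_pairs(sm$sample_id[sm$host_id == h], cohort$samples,
                        config$temporal_pairing)
      if (is.null(prs)) next
      for (i in seq_len(nrow(prs))) for (cl in names(DEGEN_OF_CLASS)) {
        r1 <- recs[recs$sample_id == prs$t1[i] & recs$class == cl, ]
        r2 <- recs[recs$sample_id == prs$t2[i] & recs$class == cl, ]
        if (!nrow(r1) || !nrow(r2)) next
        ch <- suppressMessages(polymorphism_change(r1, r2, cohort$samples))
        if (!is.null(ch)) changes[[paste(sp, h, i, cl)]] <- ch
      }
    }
  }
  list(rates = if (length(rates)) do.call(rbind, c(rates, make.row.names = FALSE))
         else NULL,
       changes = if (length(changes)) do.call(rbind, c(changes, make.row.names = FALSE))
         else NULL)
}
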