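#' Gene copy number
#'
#' A gene's copy number in a sample is its per-base coverage divided by the
#' median coverage of the species' single-copy marker genes in that sample.
#'
#' @param gene_coverage numeric coverage (scalar or vector).
#' @param marker_median median marker-gene coverage (recycled).
#' @return Copy number; `NA` where `marker_median <= 0` (gene not callable).
#' @export
copy_number <- function(gene_coverage, marker_median) {
  ifelse(marker_median > 0, gene_coverage / marker_median, NA_real_)
}

#' Copy-number matrix of a species
#'
#' @param gcn a [gene_cn_matrix()].
#' @return genes x samples matrix of copy numbers (`NA` columns where the
#'   marker median is zero).
#' @export
copy_number_matrix <- function(gcn) {
  cn <- sweep(gcn$coverage, 2, gcn$marker_median, `/`)
  cn[, gcn$marker_median <= 0] <- NA_real_
  cn
}

#' Between-host gene prevalence
#'
#' The fraction of eligible samples (marker coverage >= `marker_min`) in which
#' a gene's copy number lies in `[c_lo, c_hi]`.
#'
#' @param gcn a [gene_cn_matrix()].
#' @param marker_min marker-coverage eligibility floor (default 5).
#' @param c_lo,c_hi copy-number window (defaults 0.3 and 3).
#' @return Named numeric vector of per-gene prevalences; all-`NA` when no
#'   sample is eligible.
#' @export
gene_prevalence <- function(gcn, marker_min = 5, c_lo = 0.3, c_hi = 3) {
  elig <- gcn$marker_median >= marker_min
  genes <- rownames(gcn$coverage)
  if (!any(elig)) return(setNames(rep(NA_real_, length(genes)), genes))
  cn <- copy_number_matrix(gcn)[, elig, drop = FALSE]
  setNames(rowMeans(cn >= c_lo & cn <= c_hi), genes)
}

#' Core genes of a species in a cohort
#'
#' Genes with prevalence at least `threshold` (default 90%) across eligible
#' samples.
#'
#' @inheritParams gene_prevalence
#' @param threshold prevalence cutoff, inclusive (default 0.9).
#' @return Character vector of gene ids.
#' @export
core_genes <- function(gcn, threshold = 0.9, marker_min = 5, c_lo = 0.3, c_hi = 3) {
  prev <- gene_prevalence(gcn, marker_min, c_lo, c_hi)
  as.character(names(prev)[!is.na(prev) & prev >= threshold])
}

#' Genes excluded for reaching high copy number
#'
#' Genes whose copy number reaches `c_max` (default 3) in at least one sample
#' are excluded from polymorphism and gain/loss analyses: such copy numbers
#' usually reflect reads donated by other species carrying a homologous gene.
#'
#' @param gcn a [gene_cn_matrix()].
#' @param c_max copy-number trigger, inclusive (default 3).
#' @return Character vector of gene ids.
#' @export
high_copy_exclusions <- function(gcn, c_max = 3) {
  cn <- copy_number_matrix(gcn)
  hit <- apply(cn, 1, function(x) any(!is.na(x) & x >= c_max))
  rownames(gcn$coverage)[hit]
}

#' Presence/absence calls for genes of one species
#'
#' A gene is called absent when c <= 0.05, present (single copy) when
#' 0.6 <= c <= 1.2 with marker coverage >= 20, and ambiguous otherwise
#' (including the 0.05-0.6 zone, c > 1.2, insufficient marker coverage, or
#' marker coverage below the minimal calling floor of 5).
#'
#' @param gcn a [gene_cn_matrix()].
#' @param genes,samples subsets to call (default all).
#' @param absent_c_max,present_c_lo,present_c_hi copy-number cutoffs.
#' @param present_marker_min marker floor for a present call (default 20).
#' @param call_marker_min marker floor for any call at all (default 5).
#' @return Character matrix (genes x samples) with entries `"present"`,
#'   `"absent"`, `"ambiguous"`.
#' @export
call_presence <- function(gcn, genes = NULL, samples = NULL,
                          absent_c_max = 0.05, present_c_lo = 0.6,
                          present_c_hi = 1.2, present_marker_min = 20,
                          call_marker_min = 5) {
  cn <- copy_number_matrix(gcn)
  if (!is.null(genes)) cn <- cn[genes, , drop = FALSE]
  if (!is.null(samples)) cn <- cn[, samples, drop = FALSE]
  mm <- gcn$marker_median[colnames(cn)]
  state <- matrix("ambiguous", nrow(cn), ncol(cn), dimnames = dimnames(cn))
  callable <- matrix(rep(mm >= call_marker_min, each = nrow(cn)), nrow(cn))
  ok20 <- matrix(rep(mm >= present_marker_min, each = nrow(cn)), nrow(cn))
  state[callable & !is.na(cn) & cn <= absent_c_max] <- "absent"
  state[callable & ok20 & !is.na(cn) &
          cn >= present_c_lo & cn <= present_c_hi] <- "present"
  state
}

#' Count gene gains and losses between two time points
#'
#' Gains are absent-to-present transitions, losses present-to-absent; genes
#' ambiguous at either end are excluded from both the numerators and the
#' assayed-gene denominator.
#'
#' @param calls_t1,calls_t2 named character vectors (or single-sample columns
#'   of [call_presence()]) over the same genes.
#' @return One-row data.frame with `n_gained`, `n_lost`, `n_assayed`.
#' @export
count_gains_losses <- function(calls_t1, calls_t2) {
  stopifnot(length(calls_t1) == length(calls_t2))
  ok <- calls_t1 != "ambiguous" & calls_t2 != "ambiguous"
  data.frame(
    n_gained = sum(ok & calls_t1 == "absent" & calls_t2 == "present"),
    n_lost = sum(ok & calls_t1 == "present" & calls_t2 == "absent"),
    n_assayed = sum(ok))
}

#' Cohort-wide gene gain/loss records
#'
#' For each eligible species and each within-host time-point pair, calls
#' presence states over the assayable gene universe (blacklist and high-copy
#' exclusions removed) and counts gains and losses.
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param config a [run_config()].
#' @return data.frame with one row per (species, host, pair): `t1`, `t2`,
#'   `delta_days`, `n_gained`, `n_lost`, `n_assayed`.
#' @export
gain_loss_table <- function(cohort, config = run_config()) {
  out <- list()
  for (sp in intersect(eligible_species(cohort, config$min_marker_cov,
                                        config$min_marker_samples),
                       names(cohort$genes))) {
    gcn <- cohort$genes[[sp]]
    excl <- union(gcn$blacklist, high_copy_exclusions(gcn, config$high_copy_c))
    genes <- setdiff(rownames(gcn$coverage), excl)
    if (!length(genes)) next
    states <- call_presence(gcn, genes = genes,
                            absent_c_max = config$absent_c_max,
                            present_c_lo = config$present_c_lo,
                            present_c_hi = config$present_c_hi,
                            present_marker_min = config$present_marker_min,
                            call_marker_min = config$call_marker_min)
    sm <- cohort$samples[cohort$samples$sample_id %in% colnames(states), ]
    for (h in unique(sm$host_id)) {
      prs <- host_pairs(sm$sample_id[sm$host_id == h], cohort$samples,
                        config$temporal_pairing)
      if (is.null(prs)) next
      for (i in seq_len(nrow(prs))) {
        cnt <- count_gains_losses(states[, prs$t1[i]], states[, prs$t2[i]])
        day <- function(s) cohort$samples$collection_day[
          match(s, cohort$samples$sample_id)]
        out[[paste(sp, h, i)]] <- cbind(
          data.frame(species_id = sp, host_id = h, t1 = prs$t1[i], t2 = prs$t2[i],
                     delta_days = day(prs$t2[i]) - day(prs$t1[i]),
                     stringsAsFactors = FALSE),
          cnt)
      }
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else NULL
}
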