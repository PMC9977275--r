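#' Assemble cross-sectional model data
#'
#' Joins a per-(species, sample) response table to per-sample diversity and
#' metadata, producing the data.frame [fit_cross_sectional()] consumes.
#'
#' @param response_table data.frame with `species_id`, `sample_id` and the
#'   response column.
#' @param diversity output of [diversity_table()].
#' @param cohort a [cohort_tables()] bundle.
#' @param rank taxonomic rank of the diversity predictor.
#' @return data.frame with the response column plus `shannon`, `richness`,
#'   `rarefied_richness`, `read_count`, `species`, `host`, `sample`.
#' @export
cross_sectional_data <- function(response_table, diversity, cohort,
                                 rank = "species") {
  dv <- diversity[diversity$rank == rank, ]
  i <- match(response_table$sample_id, dv$sample_id)
  j <- match(response_table$sample_id, cohort$samples$sample_id)
  cbind(response_table,
        shannon = dv$shannon[i], richness = dv$richness[i],
        rarefied_richness = dv$rarefied_richness[i],
        read_count = cohort$samples$read_count[j],
        species = response_table$species_id,
        host = cohort$samples$host_id[j],
        sample = response_table$sample_id)
}

#' Assemble temporal model data
#'
#' Joins within-host change records (gene gains/losses or polymorphism
#' changes) to diversity and read count at the earlier time point.
#'
#' @param change_table data.frame with `species_id`, `host_id`, `t1`, `t2`,
#'   `delta_days` and the response column(s).
#' @inheritParams cross_sectional_data
#' @return data.frame ready for [fit_temporal()].
#' @export
temporal_data <- function(change_table, diversity, cohort, rank = "species") {
  dv <- diversity[diversity$rank == rank, ]
  i <- match(change_table$t1, dv$sample_id)
  j <- match(change_table$t1, cohort$samples$sample_id)
  cbind(change_table,
        shannon = dv$shannon[i], richness = dv$richness[i],
        rarefied_richness = dv$rarefied_richness[i],
        read_count = cohort$samples$read_count[j],
        species = change_table$species_id,
        host = change_table$host_id,
        sample = change_table$t1)
}

#' Run the full analysis pipeline on a cohort
#'
#' Computes per-sample diversity at all ranks, polymorphism rates and
#' changes, gene gain/loss records, and (optionally, it is the slow step)
#' strain-number fits.
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param config a [run_config()].
#' @param seed integer seed (rarefaction subsampling, strain restarts).
#' @param strains fit strain numbers as well (default TRUE).
#' @param rarefaction_depth passed to [diversity_table()]; `NULL` skips
#'   rarefied richness.
#' @return List with `diversity`, `polymorphism`, `gain_loss`, `strains`.
#' @export
run_pipeline <- function(cohort, config = run_config(), seed = 1L,
                         strains = TRUE, rarefaction_depth = NULL) {
  list(diversity = diversity_table(cohort, rarefaction_depth = rarefaction_depth,
                                   seed = derive_seed(seed, "diversity")),
       polymorphism = polymorphism_table(cohort, config),
       gain_loss = gain_loss_table(cohort, config),
       strains = if (strains) strain_table(cohort, config,
                                           seed = derive_seed(seed, "strains")))
}
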