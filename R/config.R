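#' Analysis configuration
#'
#' Collects every threshold used by the pipeline in one list. Defaults are the
#' values standard in within-host gut-metagenome analyses: sites are kept when
#' their depth lies within \[0.3, 3\] times the sample's median depth over
#' covered protein-coding sites; samples need median depth >= 5; species need
#' marker-gene coverage >= 10 in >= 10 samples; intermediate-frequency alleles
#' are those with 0.2 <= f <= 0.8; gene prevalence counts samples with
#' 0.3 <= c <= 3 among samples with marker coverage >= 5; core genes have
#' prevalence >= 0.9; genes reaching copy number >= 3 anywhere are excluded;
#' presence calls use c <= 0.05 (absent) and 0.6 <= c <= 1.2 with marker
#' coverage >= 20 (single-copy present); strain inference uses multi-allelic
#' sites at >= 20x with a 100-site floor and K in 1..4 selected by BIC.
#'
#' @param ... named overrides of any default listed above.
#' @return A named list with class `microdiv_config`.
#' @export
#' @examples
#' cfg <- run_config(min_median_depth = 10)
#' cfg$f_lo
run_config <- function(...) {
  cfg <- list(
    # species eligibility
    min_marker_cov     = 10,
    min_marker_samples = 10,
    # SNV sample / site filters
    min_median_depth   = 5,
    site_depth_lo_frac = 0.3,
    site_depth_hi_frac = 3,
    # polymorphism window
    f_lo = 0.2,
    f_hi = 0.8,
    # gene prevalence / core genes / exclusions
    prevalence_c_lo       = 0.3,
    prevalence_c_hi       = 3,
    prevalence_marker_min = 5,
    core_prevalence       = 0.9,
    high_copy_c           = 3,
    # presence/absence calls
    absent_c_max       = 0.05,
    present_c_lo       = 0.6,
    present_c_hi       = 1.2,
    present_marker_min = 20,
    call_marker_min    = 5,
    # strain inference
    strain_min_depth  = 20,
    strain_min_sites  = 100,
    strain_k_max      = 4,
    strain_n_restarts = 10,
    strain_tol        = 1e-6,
    strain_eps_max    = 0.1,
    site_floor_counts = "multiallelic", # or "coverage"
    # community diversity
    rarefaction_depth = 2e7,
    # temporal pairing: "consecutive" or "first_anchor" or "all_pairs"
    temporal_pairing = "consecutive"
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "microdiv_config")
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML with one entry per threshold; absent keys
#' fall back to the defaults of [run_config()].
#'
#' @param path file path.
#' @return `read_run_config` returns a `microdiv_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}

#' @rdname read_run_config
#' @param config a `microdiv_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
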