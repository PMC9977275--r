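#' Construct the per-species SNV matrix
#'
#' Holds site-by-sample read depths and alternate-allele counts for one
#' species, together with site annotations (gene, codon degeneracy class) and
#' the per-sample median depth over covered sites, which anchors the
#' depth-window site filter.
#'
#' @param species_id species identifier.
#' @param sites data.frame with columns `site_id`, `gene_id`, `degeneracy`
#'   (one of `"fourfold"`, `"onefold"`, `"other"`).
#' @param depth,alt integer matrices (sites x samples) of read depth and
#'   alternate-allele counts; column names are sample ids.
#' @return An object of class `snv_matrix` with elements `species_id`,
#'   `sites`, `depth`, `alt` and `median_depth` (named per-sample median depth
#'   over sites with nonzero coverage).
#' @export
snv_matrix <- function(species_id, sites, depth, alt) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "gene_id", "degeneracy") %in% names(sites)),
            is.matrix(depth), is.matrix(alt),
            nrow(depth) == nrow(sites), all(dim(depth) == dim(alt)))
  rownames(depth) <- rownames(alt) <- sites$site_id
  md <- apply(depth, 2, function(d) {
    d <- d[d > 0]
    if (!length(d)) 0 else stats::median(d)
  })
  structure(list(species_id = species_id, sites = sites,
                 depth = depth, alt = alt, median_depth = md),
            class = "snv_matrix")
}

#' Construct the per-species gene coverage matrix
#'
#' @param species_id species identifier.
#' @param coverage numeric matrix (genes x samples) of per-base read depth;
#'   row names are gene ids, column names sample ids.
#' @param marker_median named numeric vector: per-sample median coverage of
#'   the species' single-copy marker genes.
#' @param blacklist character vector of gene ids shared across species and
#'   excluded from SNV and gain/loss calling.
#' @return An object of class `gene_cn_matrix`.
#' @export
gene_cn_matrix <- function(species_id, coverage, marker_median,
                           blacklist = character()) {
  stopifnot(is.matrix(coverage),
            nrow(coverage) == 0 || !is.null(rownames(coverage)),
            length(marker_median) == ncol(coverage))
  if (is.null(rownames(coverage))) rownames(coverage) <- character()
  names(marker_median) <- colnames(coverage)
  structure(list(species_id = species_id, coverage = coverage,
                 marker_median = marker_median,
                 blacklist = as.character(blacklist)),
            class = "gene_cn_matrix")
}

#' Bundle a cohort's tables
#'
#' The universal input bundle: per-sample species relative abundances and
#' marker coverages, sample metadata, a five-rank taxonomy, and per-species
#' SNV and gene-coverage matrices.
#'
#' @param rel_abund,marker_coverage numeric matrices (samples x species).
#' @param taxonomy data.frame with columns `species_id`, `genus`, `family`,
#'   `order`, `class`, `phylum`.
#' @param samples data.frame with columns `sample_id`, `host_id`,
#'   `time_point`, `collection_day`, `read_count`.
#' @param snv named list of [snv_matrix()] objects keyed by species id.
#' @param genes named list of [gene_cn_matrix()] objects keyed by species id.
#' @return An object of class `cohort_tables`.
#' @export
cohort_tables <- function(rel_abund, marker_coverage, taxonomy, samples,
                          snv = list(), genes = list()) {
  stopifnot(is.matrix(rel_abund), is.matrix(marker_coverage),
            all(dim(rel_abund) == dim(marker_coverage)),
            is.data.frame(taxonomy), is.data.frame(samples))
  structure(list(rel_abund = rel_abund, marker_coverage = marker_coverage,
                 taxonomy = taxonomy, samples = samples,
                 snv = snv, genes = genes),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("cohort_tables:", nrow(x$rel_abund), "samples,",
      ncol(x$rel_abund), "species,", length(x$snv),
      "species with SNV/gene tables\n")
  invisible(x)
}

RANKS <- c("genus", "family", "order", "class", "phylum")

#' Validate a cohort bundle
#'
#' Checks every structural invariant of the bundle and reports each violation
#' once, with coordinates; it never raises.
#'
#' @param tables a [cohort_tables()] bundle.
#' @param tol unit-sum tolerance for abundance rows.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_cohort <- function(tables, tol = 1e-6) {
  v <- character()
  ra <- tables$rel_abund
  neg <- which(ra < 0, arr.ind = TRUE)
  for (i in seq_len(nrow(neg)))
    v <- c(v, sprintf("negative relative abundance at sample '%s', species '%s'",
                      rownames(ra)[neg[i, 1]], colnames(ra)[neg[i, 2]]))
  rs <- rowSums(ra)
  off <- which(abs(rs - 1) > tol & rs != 0)
  for (i in off)
    v <- c(v, sprintf("abundance row for sample '%s' sums to %.8f, not 1",
                      rownames(ra)[i], rs[i]))
  if (any(tables$marker_coverage < 0))
    v <- c(v, "negative marker coverage entries")

  # taxonomy resolves all species at all five ranks
  miss <- setdiff(colnames(ra), tables$taxonomy$species_id)
  for (s in miss) v <- c(v, sprintf("species '%s' missing from taxonomy", s))
  tx <- tables$taxonomy
  for (r in RANKS) {
    if (!r %in% names(tx)) { v <- c(v, sprintf("taxonomy lacks rank '%s'", r)); next }
    bad <- which(is.na(tx[[r]]) | !nzchar(tx[[r]]))
    for (i in bad)
      v <- c(v, sprintf("species '%s' has empty %s label", tx$species_id[i], r))
  }

  # sample metadata: collection_day 0 at the first sample, strictly increasing
  sm <- tables$samples
  if (any(sm$read_count < 0)) v <- c(v, "negative read_count in samples")
  for (h in unique(sm$host_id)) {
    d <- sm[sm$host_id == h, ]
    d <- d[order(d$time_point), ]
    if (d$collection_day[1] != 0 || is.unsorted(d$collection_day, strictly = TRUE))
      v <- c(v, sprintf(
        "host '%s': collection_day must start at 0 and strictly increase with time_point", h))
  }
  if (!setequal(sm$sample_id, rownames(ra)))
    v <- c(v, "sample ids differ between samples table and abundance table")

  # per-species matrices
  for (sp in names(tables$snv)) {
    m <- tables$snv[[sp]]
    bad <- which(m$alt > m$depth, arr.ind = TRUE)
    for (i in seq_len(nrow(bad)))
      v <- c(v, sprintf("species '%s': alt_count %d > depth %d at site '%s', sample '%s'",
                        sp, m$alt[bad[i, 1], bad[i, 2]], m$depth[bad[i, 1], bad[i, 2]],
                        rownames(m$depth)[bad[i, 1]], colnames(m$depth)[bad[i, 2]]))
    if (any(m$depth < 0)) v <- c(v, sprintf("species '%s': negative depths", sp))
    if (!all(m$sites$degeneracy %in% c("fourfold", "onefold", "other")))
      v <- c(v, sprintf("species '%s': unknown degeneracy class", sp))
    if (!all(colnames(m$depth) %in% sm$sample_id))
      v <- c(v, sprintf("species '%s': SNV samples not in samples table", sp))
    if (!sp %in% names(tables$genes))
      v <- c(v, sprintf("species '%s' has an SNV matrix but no gene matrix", sp))
  }
  for (sp in names(tables$genes)) {
    g <- tables$genes[[sp]]
    if (any(g$coverage < 0)) v <- c(v, sprintf("species '%s': negative gene coverage", sp))
    if (any(g$marker_median < 0)) v <- c(v, sprintf("species '%s': negative marker median", sp))
    extra <- setdiff(g$blacklist, rownames(g$coverage))
    if (length(extra))
      v <- c(v, sprintf("species '%s': blacklisted gene '%s' not in gene universe",
                        sp, extra))
  }
  v
}

fmt_num <- function(x) {
  # lossless for integers, 1e-9-relative for reals
  ifelse(x == round(x) & abs(x) < 2^53, format(x, scientific = FALSE, trim = TRUE),
         format(x, digits = 15, trim = TRUE))
}

write_keyed_tsv <- function(mat, key_name, path) {
  df <- data.frame(rownames(mat), apply(mat, 2, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(key_name, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_keyed_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a cohort to a directory of TSV files
#'
#' Layout mirrors merged per-species output of standard metagenome profilers:
#' `abundance.tsv` and `marker_coverage.tsv` (species x samples),
#' `taxonomy.tsv`, `samples.tsv`, and per species `<sp>_snv_depth.tsv`,
#' `<sp>_snv_alt.tsv`, `<sp>_site_info.tsv`, `<sp>_gene_coverage.tsv` (with a
#' `marker_median` row) plus `blacklist.txt` when any blacklist is non-empty.
#'
#' @param tables a [cohort_tables()] bundle.
#' @param root_path directory to create/write into.
#' @return Invisibly, the manifest: character vector of files written.
#' @export
write_cohort <- function(tables, root_path) {
  dir.create(root_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(root_path)) stop("cannot create directory: ", root_path)
  manifest <- character()
  put <- function(f) { manifest <<- c(manifest, f); file.path(root_path, f) }

  write_keyed_tsv(t(tables$rel_abund), "species_id", put("abundance.tsv"))
  write_keyed_tsv(t(tables$marker_coverage), "species_id", put("marker_coverage.tsv"))
  write.table(tables$taxonomy, put("taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tables$samples, put("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  bl <- unique(unlist(lapply(tables$genes, `[[`, "blacklist")))
  if (length(bl)) writeLines(bl, put("blacklist.txt"))

  for (sp in names(tables$snv)) {
    m <- tables$snv[[sp]]
    write_keyed_tsv(m$depth, "site_id", put(paste0(sp, "_snv_depth.tsv")))
    write_keyed_tsv(m$alt, "site_id", put(paste0(sp, "_snv_alt.tsv")))
    write.table(m$sites, put(paste0(sp, "_site_info.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  for (sp in names(tables$genes)) {
    g <- tables$genes[[sp]]
    cov <- rbind(g$coverage, marker_median = g$marker_median)
    write_keyed_tsv(cov, "gene_id", put(paste0(sp, "_gene_coverage.tsv")))
  }
  invisible(manifest)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()]. The bundle is validated on load; any invariant
#' violation aborts with coordinates.
#'
#' @param root_path directory written by [write_cohort()] (or adapted from
#'   upstream profiler output).
#' @param config a [run_config()]; currently unused by the reader but accepted
#'   so callers can thread one configuration through the pipeline.
#' @return A validated [cohort_tables()] bundle.
#' @export
read_cohort <- function(root_path, config = run_config()) {
  need <- function(f, what) {
    p <- file.path(root_path, f)
    if (!file.exists(p)) stop("missing required ", what, " file: ", f)
    p
  }
  ra <- t(read_keyed_tsv(need("abundance.tsv", "abundance")))
  mc <- t(read_keyed_tsv(need("marker_coverage.tsv", "marker_coverage")))
  taxonomy <- read.delim(need("taxonomy.tsv", "taxonomy"), stringsAsFactors = FALSE,
                         colClasses = "character")
  samples <- read.delim(need("samples.tsv", "samples"), stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$host_id <- as.character(samples$host_id)

  blp <- file.path(root_path, "blacklist.txt")
  bl <- if (file.exists(blp)) readLines(blp) else character()

  sp_files <- list.files(root_path, pattern = "_snv_depth\\.tsv$")
  species <- sub("_snv_depth\\.tsv$", "", sp_files)
  snv <- list(); genes <- list()
  for (sp in species) {
    depth <- read_keyed_tsv(need(paste0(sp, "_snv_depth.tsv"), "SNV depth"))
    alt <- read_keyed_tsv(need(paste0(sp, "_snv_alt.tsv"), "SNV alt"))
    sites <- read.delim(need(paste0(sp, "_site_info.tsv"), "site info"),
                        stringsAsFactors = FALSE)
    sites$site_id <- as.character(sites$site_id)
    storage.mode(depth) <- storage.mode(alt) <- "integer"
    snv[[sp]] <- snv_matrix(sp, sites, depth, alt)
  }
  gene_files <- list.files(root_path, pattern = "_gene_coverage\\.tsv$")
  for (sp in sub("_gene_coverage\\.tsv$", "", gene_files)) {
    cov <- read_keyed_tsv(file.path(root_path, paste0(sp, "_gene_coverage.tsv")))
    mm <- cov["marker_median", ]
    cov <- cov[rownames(cov) != "marker_median", , drop = FALSE]
    genes[[sp]] <- gene_cn_matrix(sp, cov, mm,
                                  blacklist = intersect(bl, rownames(cov)))
  }
  tables <- cohort_tables(ra, mc, taxonomy, samples, snv, genes)
  v <- validate_cohort(tables)
  if (length(v)) stop("invalid cohort:\n  ", paste(v, collapse = "\n  "))
  tables
}
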