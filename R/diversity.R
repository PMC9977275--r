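#' Shannon diversity of a (relative) abundance vector
#'
#' Natural-log Shannon index over the strictly positive entries after
#' renormalization: H' = -sum p_i ln p_i. Zero entries contribute nothing, so
#' the index is scale-invariant.
#'
#' @param abundances non-negative numeric vector.
#' @return H' in nats.
#' @export
#' @examples
#' shannon(c(0.5, 0.5))       # ln 2
#' shannon(c(0.5, 0.25, 0.25)) # 1.5 ln 2
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (sum(abundances) <= 0) stop("undefined diversity: all abundances are zero")
  as.numeric(vegan::diversity(abundances, index = "shannon"))
}

#' Species richness of an abundance vector
#'
#' @param abundances non-negative numeric vector.
#' @return Count of strictly positive entries.
#' @export
richness <- function(abundances) {
  sum(abundances > 0)
}

#' Rarefied richness by random subsampling of reads
#'
#' Draws exactly `depth` reads without replacement (multivariate
#' hypergeometric) from the sample's species-labelled reads and counts species
#' with at least one retained read. Samples with fewer total reads than
#' `depth` are excluded (returns `NA`) rather than upsampled.
#'
#' @param read_counts_per_species non-negative integer vector.
#' @param depth subsampling depth (reads).
#' @param seed integer seed for the subsample.
#' @return Integer rarefied richness, or `NA_integer_` when total reads <
#'   `depth`.
#' @export
rarefy_richness <- function(read_counts_per_species, depth, seed = 1L) {
  x <- read_counts_per_species
  if (any(x < 0) || any(x != round(x))) stop("read counts must be non-negative integers")
  if (depth < 1 || depth != round(depth)) stop("depth must be a positive integer")
  if (sum(x) < depth) return(NA_integer_)
  if (sum(x) == depth) return(richness(x))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # rrarefy warns about the magnitude of metagenome-scale read counts; the
  # subsampling itself is exact
  sub <- suppressWarnings(vegan::rrarefy(matrix(x, nrow = 1), depth))
  as.integer(sum(sub > 0))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Aggregate species abundances to a higher taxonomic rank
#'
#' A taxon's abundance in a sample is the sum of the abundances of its member
#' species; row sums are preserved exactly. Marker coverages are summed the
#' same way.
#'
#' @param rel_abund samples x species matrix.
#' @param taxonomy data.frame mapping `species_id` to rank labels.
#' @param rank one of `"genus"`, `"family"`, `"order"`, `"class"`, `"phylum"`
#'   (or `"species"`, the identity).
#' @return samples x taxa matrix.
#' @export
aggregate_rank <- function(rel_abund, taxonomy, rank) {
  if (rank == "species") return(rel_abund)
  if (!rank %in% RANKS) stop("unknown rank: ", rank)
  idx <- match(colnames(rel_abund), taxonomy$species_id)
  if (anyNA(idx)) {
    stop("species not resolvable in taxonomy: ",
         paste(colnames(rel_abund)[is.na(idx)], collapse = ", "))
  }
  lab <- taxonomy[[rank]][idx]
  if (any(is.na(lab) | !nzchar(lab))) {
    stop("species with empty ", rank, " label: ",
         paste(colnames(rel_abund)[is.na(lab) | !nzchar(lab)], collapse = ", "))
  }
  t(rowsum(t(rel_abund), group = lab))
}

#' Per-sample diversity at one or more taxonomic ranks
#'
#' Computes Shannon diversity (nats) and richness per sample at each requested
#' rank, and optionally rarefied richness at the species rank. Per-species
#' read counts for rarefaction are `round(relative_abundance * read_count)`.
#'
#' @param cohort a [cohort_tables()] bundle.
#' @param ranks character vector of ranks (default species through phylum).
#' @param rarefaction_depth reads to rarefy to, or `NULL` to skip.
#' @param seed integer seed for rarefaction subsampling.
#' @return data.frame with columns `sample_id`, `rank`, `shannon`, `richness`,
#'   `rarefied_richness`, `rarefaction_depth`.
#' @export
diversity_table <- function(cohort, ranks = c("species", RANKS),
                            rarefaction_depth = NULL, seed = 1L) {
  out <- list()
  for (rk in ranks) {
    m <- aggregate_rank(cohort$rel_abund, cohort$taxonomy, rk)
    H <- apply(m, 1, function(p) if (sum(p) > 0) shannon(p) else NA_real_)
    S <- apply(m, 1, richness)
    rr <- rep(NA_integer_, nrow(m))
    if (rk == "species" && !is.null(rarefaction_depth)) {
      rc <- cohort$samples$read_count[match(rownames(m), cohort$samples$sample_id)]
      for (i in seq_len(nrow(m))) {
        counts <- round(m[i, ] * rc[i])
        rr[i] <- rarefy_richness(counts, rarefaction_depth,
                                 seed = derive_seed(seed, paste0("rarefy_", rownames(m)[i])))
      }
    }
    out[[rk]] <- data.frame(sample_id = rownames(m), rank = rk, shannon = H,
                            richness = S, rarefied_richness = rr,
                            rarefaction_depth = if (rk == "species" && !is.null(rarefaction_depth))
                              rarefaction_depth else NA_integer_,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
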