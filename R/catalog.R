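#' Build a barcoded deletion-library catalog
#'
#' Generates a synthetic barcode catalog for a pool of homozygous deletion
#' strains: each strain carries a unique 20-base uptag barcode, and the
#' catalog keeps a minimum pairwise Hamming distance of `min_dist` so that
#' single-mismatch barcode assignment is unambiguous. Barcodes are drawn by
#' rejection sampling: random 20-mers are generated and a candidate is kept
#' only if it is at least `min_dist` away from every barcode already kept.
#'
#' @param n_strains number of deletion strains in the pool. The default
#'   matches a genome-scale homozygous diploid deletion collection of 4653
#'   clones.
#' @param seed integer seed making the catalog reproducible.
#' @param barcode_len barcode length in bases (uptags are 20-mers).
#' @param min_dist minimum pairwise Hamming distance enforced between any
#'   two barcodes.
#' @param max_attempts cap on the total number of candidate barcodes drawn
#'   before giving up (signals that `n_strains` is too large for the
#'   distance constraint).
#' @return a `barcode_catalog`: a data.frame with columns `strain_id`,
#'   `yeast_gene` and `uptag`.
#' @examples
#' cat50 <- build_library(50, seed = 7)
#' nrow(cat50)
#' @export
build_library <- function(n_strains, seed = 1L, barcode_len = 20L,
                          min_dist = 3L, max_attempts = 1e6) {
  stopifnot(n_strains >= 1, barcode_len >= 1, min_dist >= 1)
  uptags <- character(0)
  attempts <- 0
  with_seed(seed, {
    while (length(uptags) < n_strains) {
      batch <- max(1024L, ceiling((n_strains - length(uptags)) * 1.1))
      if (attempts + batch > max_attempts)
        batch <- max_attempts - attempts
      if (batch <= 0)
        stop("could not build ", n_strains, " barcodes at min Hamming ",
             "distance ", min_dist, " within ", max_attempts,
             " rejection-sampling attempts; n_strains too large for the ",
             "constraint")
      mat <- matrix(sample(DNA_BASES, batch * barcode_len, replace = TRUE),
                    nrow = batch)
      cand <- unique(apply(mat, 1L, paste0, collapse = ""))
      attempts <- attempts + batch
      pool <- c(uptags, cand)
      keep <- .cpp_greedy_min_dist(pool, as.integer(min_dist),
                                   as.integer(n_strains))
      uptags <- pool[keep]
    }
  })
  data.frame(
    strain_id = sprintf("strain_%05d", seq_len(n_strains)),
    yeast_gene = sprintf("YGENE%04d", seq_len(n_strains)),
    uptag = uptags,
    stringsAsFactors = FALSE
  ) |> structure(class = c("barcode_catalog", "data.frame"))
}

validate_catalog <- function(catalog) {
  req <- c("strain_id", "yeast_gene", "uptag")
  if (!all(req %in% names(catalog)))
    stop("catalog must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(catalog$strain_id))
    stop("catalog strain_ids are not unique")
  if (anyDuplicated(catalog$uptag))
    stop("catalog uptag barcodes are not unique")
  if (any(nchar(catalog$uptag) != nchar(catalog$uptag[1])))
    stop("catalog uptags must all have the same length")
  if (any(!grepl("^[ACGT]+$", catalog$uptag)))
    stop("catalog uptags must be DNA over {A,C,G,T}")
  invisible(catalog)
}

#' Write / read a barcode catalog TSV
#'
#' Tab-separated with header `strain_id  yeast_gene  uptag`.
#'
#' @param catalog a barcode catalog data.frame.
#' @param path file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the validated catalog.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  write_tsv(catalog[, c("strain_id", "yeast_gene", "uptag")], path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, c("strain_id", "yeast_gene", "uptag"),
                        "catalog")
  validate_catalog(df)
  structure(df, class = c("barcode_catalog", "data.frame"))
}

#' Fold coverage of a deletion library implied by a plating titer
#'
#' In a pooled transformation, plating a small fraction of the culture and
#' counting colonies estimates the total number of independent
#' transformants; dividing by the library size gives the fold coverage of
#' the deletion collection. Plating 0.1% of a transformation and observing
#' 50 colonies over a 4653-strain library implies roughly 10.7x coverage.
#'
#' @param colonies colony count observed on the plate.
#' @param plating_fraction fraction of the culture plated (e.g. 0.001 for
#'   0.1%).
#' @param library_size number of strains in the deletion library.
#' @return estimated fold coverage (total transformants / library size).
#' @examples
#' fold_coverage(50, 0.001, 4653)
#' @export
fold_coverage <- function(colonies, plating_fraction, library_size) {
  stopifnot(colonies >= 0, plating_fraction > 0, plating_fraction <= 1,
            library_size >= 1)
  (colonies / plating_fraction) / library_size
}
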