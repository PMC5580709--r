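#' Generate a multiplex index-tag design
#'
#' Assigns each (query, condition) sample a distinct combination of a
#' forward and a reverse 6-mer index tag, mirroring a multiplexed Bar-seq
#' amplification in which every query gene gets its own tag combination.
#' Forward tags are drawn at minimum pairwise Hamming distance 3 so that
#' single-mismatch tag assignment stays unambiguous (only the forward read
#' is parsed downstream).
#'
#' @param queries character vector of query gene names.
#' @param conditions conditions per query (default GLU and GAL).
#' @param seed integer seed.
#' @return a `multiplex_design` data.frame with columns `query`,
#'   `condition`, `fwd_tag`, `rev_tag`, `fastq` (empty until FASTQs are
#'   written).
#' @export
make_design <- function(queries, conditions = c("GLU", "GAL"), seed = 1L) {
  stopifnot(length(queries) >= 1, !anyDuplicated(queries))
  n <- length(queries) * length(conditions)
  tags <- with_seed(seed, {
    pool <- unique(apply(matrix(sample(DNA_BASES, 4L * n * TAG_LEN * 20L,
                                       replace = TRUE),
                                ncol = TAG_LEN),
                         1L, paste0, collapse = ""))
    keep <- .cpp_greedy_min_dist(pool, 3L, 2L * n)
    if (length(keep) < 2L * n)
      stop("could not draw ", 2L * n, " index tags at Hamming distance 3")
    pool[keep]
  })
  df <- expand.grid(condition = conditions, query = queries,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("query", "condition")]
  df$fwd_tag <- tags[seq_len(n)]
  df$rev_tag <- tags[n + seq_len(n)]
  df$fastq <- ""
  rownames(df) <- NULL
  validate_design(df)
}

validate_design <- function(df) {
  req <- c("query", "condition", "fwd_tag", "rev_tag")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("design is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"fastq" %in% names(df)) df$fastq <- ""
  if (!all(df$condition %in% c("GLU", "GAL")))
    stop("design condition must be GLU or GAL")
  if (any(nchar(df$fwd_tag) != TAG_LEN) || any(nchar(df$rev_tag) != TAG_LEN))
    stop("index tags must be exactly ", TAG_LEN, " bases")
  if (any(!grepl("^[ACGT]+$", c(df$fwd_tag, df$rev_tag))))
    stop("index tags must be DNA over {A,C,G,T}")
  combo <- paste(df$fwd_tag, df$rev_tag)
  if (anyDuplicated(combo)) {
    clash <- combo[duplicated(combo)][1]
    stop("duplicate (fwd_tag, rev_tag) combination in design: ",
         sub(" ", "/", clash))
  }
  structure(df, class = c("multiplex_design", "data.frame"))
}

#' Read / write a multiplex design TSV
#'
#' Tab-separated with header `query  condition  fwd_tag  rev_tag  fastq`.
#' Duplicate (forward, reverse) tag combinations are a hard error naming
#' the clashing tags.
#'
#' @param path design file path.
#' @param df a design data.frame.
#' @export
parse_design <- function(path) {
  df <- read_tsv_strict(path, c("query", "condition", "fwd_tag", "rev_tag"),
                        "design")
  validate_design(df)
}

#' @rdname parse_design
#' @export
write_design <- function(df, path) {
  validate_design(df)
  write_tsv(df[, c("query", "condition", "fwd_tag", "rev_tag", "fastq")],
            path)
}

#' Assign reads to samples by their inline index tag
#'
#' Vectorised demultiplexing of forward reads against a design: the 6-mer
#' at positions 2-7 must match a design forward tag with a unique best hit
#' at Hamming distance <= `tag_mismatch`, and the 18-mer at positions 8-25
#' must match the common primer at Hamming distance <= `primer_mismatch`.
#' The barcode window (positions 26-45) is fixed; there is no sliding
#' search. Unassignable reads are returned with a reason, never an error.
#'
#' @param reads character vector of read sequences.
#' @param design a multiplex design.
#' @param tag_mismatch maximum Hamming distance for the index tag.
#' @param primer_mismatch maximum Hamming distance for the common primer.
#' @return data.frame with `sample` (`"<query>_<condition>"` or `NA`),
#'   `reason` (`assigned`, `unassigned_tag`, `unassigned_primer`,
#'   `too_short`) and `barcode` (the 20-base window, `NA` if unassigned).
#' @export
demultiplex_reads <- function(reads, design, tag_mismatch = 1L,
                              primer_mismatch = 2L) {
  design <- validate_design(design)
  st <- read_structure()
  n <- length(reads)
  sample_id <- rep(NA_character_, n)
  reason <- rep("too_short", n)
  barcode <- rep(NA_character_, n)
  long <- nchar(reads) >= st$min_read_len
  if (any(long)) {
    tag <- substr(reads[long], st$tag_window[1], st$tag_window[2])
    primer <- substr(reads[long], st$primer_window[1], st$primer_window[2])
    tags_uniq <- unique(design$fwd_tag)
    # exact hits take the fast path; non-exact go through the Hamming scan
    tag_idx <- match(tag, tags_uniq)
    if (tag_mismatch > 0 && anyNA(tag_idx)) {
      miss <- which(is.na(tag_idx))
      res <- .cpp_best_hamming(tag[miss], tags_uniq,
                               as.integer(tag_mismatch))
      tag_idx[miss] <- ifelse(res[, 1L] > 0, res[, 1L], NA_integer_)
    }
    # a forward tag shared by several design rows cannot identify a sample
    tab <- table(design$fwd_tag)
    multi <- names(tab)[tab > 1L]
    tag_idx[tags_uniq[tag_idx] %in% multi] <- NA_integer_
    ok_tag <- !is.na(tag_idx)
    pd <- hamming_distance(primer, st$fwd_common)
    ok_primer <- pd <= primer_mismatch
    r <- ifelse(!ok_tag, "unassigned_tag",
                ifelse(!ok_primer, "unassigned_primer", "assigned"))
    reason[long] <- r
    row_of_tag <- match(tags_uniq, design$fwd_tag)
    assigned <- which(long)[r == "assigned"]
    smp <- paste0(design$query, "_", design$condition)
    sample_id[assigned] <- smp[row_of_tag[tag_idx[r == "assigned"]]]
    barcode[assigned] <- substr(reads[long][r == "assigned"],
                                st$barcode_window[1], st$barcode_window[2])
  }
  data.frame(sample = sample_id, reason = reason, barcode = barcode,
             stringsAsFactors = FALSE)
}

#' Match 20-mer barcodes against the strain catalog
#'
#' Exact matches win; otherwise the unique catalog entry within Hamming
#' distance <= `max_mismatch` wins; two or more equidistant best hits are
#' ambiguous; no hit within the bound (or any non-ACGT character, e.g. N)
#' is unmatched.
#'
#' @param seqs character vector of barcode sequences.
#' @param catalog a barcode catalog.
#' @param max_mismatch maximum Hamming distance for assignment.
#' @return character vector: the matched `strain_id`, `"ambiguous"` or
#'   `"unmatched"`.
#' @export
match_barcode <- function(seqs, catalog, max_mismatch = 2L) {
  validate_catalog(catalog)
  out <- rep("unmatched", length(seqs))
  clean <- grepl("^[ACGT]+$", seqs) &
    nchar(seqs) == nchar(catalog$uptag[1])
  idx <- match(seqs, catalog$uptag)  # exact fast path
  hit <- clean & !is.na(idx)
  out[hit] <- catalog$strain_id[idx[hit]]
  rest <- which(clean & is.na(idx))
  if (length(rest) && max_mismatch > 0) {
    res <- .cpp_best_hamming(seqs[rest], catalog$uptag,
                             as.integer(max_mismatch))
    out[rest][res[, 1L] > 0] <- catalog$strain_id[res[res[, 1L] > 0, 1L]]
    out[rest][res[, 1L] == -1L] <- "ambiguous"
  }
  out
}

read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  seqs <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) stop("malformed FASTQ ", path, ": ",
                             conditionMessage(e)))
  unname(seqs)
}

#' Count barcodes across all samples of a design
#'
#' Streams every FASTQ referenced by the design, demultiplexes reads by
#' index tag, matches barcode windows against the catalog, and returns the
#' strains x samples count matrix together with a per-sample accounting
#' ledger. Ambiguous barcodes are excluded from counts but tallied.
#'
#' @param design a multiplex design with `fastq` paths filled in.
#' @param catalog a barcode catalog.
#' @param tag_mismatch,primer_mismatch,max_mismatch Hamming tolerances for
#'   tag, common primer and barcode assignment.
#' @param verbose emit one structured log line per file processed.
#' @return list with `counts` (integer matrix, rows = strain_id, columns =
#'   `"<query>_<condition>"`, zero-filled for unobserved strains) and
#'   `stats` (data.frame: per sample `total_reads`, `reads_assigned`,
#'   `reads_unassigned_tag`, `reads_unassigned_primer`,
#'   `barcodes_matched`, `barcodes_ambiguous`, `barcodes_unmatched`).
#' @export
count_barcodes <- function(design, catalog, tag_mismatch = 1L,
                           primer_mismatch = 2L, max_mismatch = 2L,
                           verbose = FALSE) {
  design <- validate_design(design)
  validate_catalog(catalog)
  samples <- paste0(design$query, "_", design$condition)
  counts <- matrix(0L, nrow(catalog), length(samples),
                   dimnames = list(catalog$strain_id, samples))
  stats <- data.frame(
    sample = samples, total_reads = 0L, reads_assigned = 0L,
    reads_unassigned_tag = 0L, reads_unassigned_primer = 0L,
    barcodes_matched = 0L, barcodes_ambiguous = 0L,
    barcodes_unmatched = 0L, stringsAsFactors = FALSE)
  for (f in unique(design$fastq)) {
    if (nzchar(f) && !file.exists(f)) stop("FASTQ file not found: ", f)
    reads <- if (nzchar(f) && file.size(f) > 0) read_fastq_seqs(f)
             else character(0)
    in_file <- which(design$fastq == f)
    # each file is demultiplexed against the design rows that reference it
    # (one file per sample, or a fully multiplexed lane shared by several)
    dm <- demultiplex_reads(reads, design[in_file, , drop = FALSE],
                            tag_mismatch, primer_mismatch)
    for (i in in_file) {
      here <- which(!is.na(dm$sample) & dm$sample == samples[i])
      stats$reads_assigned[i] <- length(here)
      if (length(here)) {
        sid <- match_barcode(dm$barcode[here], catalog, max_mismatch)
        stats$barcodes_ambiguous[i] <- sum(sid == "ambiguous")
        stats$barcodes_unmatched[i] <- sum(sid == "unmatched")
        good <- sid[!(sid %in% c("ambiguous", "unmatched"))]
        stats$barcodes_matched[i] <- length(good)
        if (length(good))
          counts[, i] <- counts[, i] +
            tabulate(match(good, catalog$strain_id), nbins = nrow(catalog))
      }
    }
    # file-level totals and unassigned reads are booked on the file's
    # first sample row; with one FASTQ per sample (the usual layout) the
    # per-sample ledger identity total = assigned + unassigned holds row
    # by row
    i0 <- in_file[1]
    stats$total_reads[i0] <- length(reads)
    stats$reads_unassigned_tag[i0] <-
      sum(dm$reason %in% c("unassigned_tag", "too_short"))
    stats$reads_unassigned_primer[i0] <- sum(dm$reason == "unassigned_primer")
    log_line("demux", file = f, reads = length(reads),
             assigned = sum(dm$reason == "assigned"), verbose = verbose)
  }
  list(counts = counts, stats = stats)
}

#' Write / read a count matrix TSV
#'
#' Rows are strains, columns are `"<query>_<condition>"` samples; the
#' first column is `strain_id`.
#'
#' @param counts integer matrix with strain rownames.
#' @param path file path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(strain_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_strict(path, "strain_id", "count matrix")
  m <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$strain_id
  m
}
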