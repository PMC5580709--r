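#' @useDynLib bartox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper p.adjust pnorm qnorm rbinom sd setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed for a named pipeline stage from a
# global seed; keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which two strings differ. Vectorised over `a`.
#'
#' @param a character vector of sequences.
#' @param b a single sequence of the same nchar as the elements of `a`.
#' @return integer vector of distances.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(length(b) == 1L)
  if (any(nchar(a) != nchar(b))) stop("sequences must have equal length")
  res <- .cpp_best_hamming(a, b, nchar(b))
  res[, 2L]
}

# Minimum pairwise Hamming distance within a set of equal-length strings.
min_pairwise_hamming <- function(seqs) {
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences must have equal length")
  .cpp_min_pairwise_hamming(seqs)
}

# key=value structured log line, INFO level by default
log_line <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("stage=", stage)
  if (length(kv))
    msg <- paste(msg, paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}

read_tsv_strict <- function(path, required_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
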