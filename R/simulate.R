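# Read structure constants of the composite amplification primer: one fixed
# base, a 6-mer inline index tag, the 18-base common uptag primer, then the
# 20-mer strain barcode.
FIXED_PREFIX <- "G"
FWD_COMMON <- "GATGTCCACGAGGTCTCT"
REV_COMMON <- "GTCGACCTGCAGCGTACG"
TAG_LEN <- 6L
BARCODE_LEN <- 20L

#' Read structure of the barcode amplicon
#'
#' Describes the fixed layout of a forward Bar-seq read: a fixed leading
#' base, the 6-mer multiplexing index tag, the 18-base common primer
#' flanking the uptag, and the 20-mer uptag barcode. Coordinates are
#' 1-based and inclusive on the read as sequenced: tag = 2-7, primer =
#' 8-25, barcode = 26-45.
#'
#' @return a list with elements `fixed_prefix`, `tag_len`, `fwd_common`,
#'   `rev_common`, `barcode_len`, `min_read_len` and the 1-based windows
#'   `tag_window`, `primer_window`, `barcode_window`.
#' @export
read_structure <- function() {
  list(
    fixed_prefix = FIXED_PREFIX,
    tag_len = TAG_LEN,
    fwd_common = FWD_COMMON,
    rev_common = REV_COMMON,
    barcode_len = BARCODE_LEN,
    min_read_len = 1L + TAG_LEN + nchar(FWD_COMMON) + BARCODE_LEN,
    tag_window = c(2L, 1L + TAG_LEN),
    primer_window = c(2L + TAG_LEN, 1L + TAG_LEN + nchar(FWD_COMMON)),
    barcode_window = c(2L + TAG_LEN + nchar(FWD_COMMON),
                       1L + TAG_LEN + nchar(FWD_COMMON) + BARCODE_LEN)
  )
}

#' Simulation settings for a pooled toxicity-modifier screen
#'
#' Bundles the knobs of the synthetic pooled competition experiment: pool
#' size, numbers of designated toxicity suppressors and enhancers, their
#' fitness effects relative to the pool-wide baseline under query
#' induction, the number of population doublings of pooled growth, the
#' sequencing depth per sample, and the per-base substitution error rate.
#'
#' Under the control condition (GLU, query off) every strain grows at
#' relative fitness 1. Under induction (GAL, query on) the toxic query
#' slows the whole pool to `baseline_gal`; suppressor deletions grow faster
#' by `suppressor_effect` and enhancer deletions slower by
#' `enhancer_effect`.
#'
#' @param n_strains pool size (default 4653, a genome-scale homozygous
#'   deletion collection).
#' @param n_suppressors,n_enhancers numbers of strains with true effects.
#' @param baseline_gal pool-wide relative fitness under query induction.
#' @param suppressor_effect,enhancer_effect fitness increment/decrement of
#'   true modifiers (both positive; the enhancer effect is subtracted).
#' @param generations population doublings elapsed during pooled growth.
#' @param depth sequenced reads per (query, condition) sample.
#' @param seq_error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_strains = 4653L, n_suppressors = 50L,
                       n_enhancers = 50L, baseline_gal = 0.5,
                       suppressor_effect = 0.3, enhancer_effect = 0.3,
                       generations = 10, depth = 1e6,
                       seq_error_rate = 0.001, seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              n_suppressors = as.integer(n_suppressors),
              n_enhancers = as.integer(n_enhancers),
              baseline_gal = baseline_gal,
              suppressor_effect = suppressor_effect,
              enhancer_effect = enhancer_effect,
              generations = generations, depth = depth,
              seq_error_rate = seq_error_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_strains < 1) stop("n_strains must be >= 1")
    if (n_suppressors < 0 || n_enhancers < 0)
      stop("modifier counts must be >= 0")
    if (n_suppressors + n_enhancers > n_strains)
      stop("n_suppressors + n_enhancers must not exceed n_strains")
    if (depth < 0) stop("depth must be >= 0")
    if (seq_error_rate < 0 || seq_error_rate >= 1)
      stop("seq_error_rate must be in [0, 1)")
    if (generations < 0) stop("generations must be >= 0")
    if (baseline_gal <= 0) stop("baseline_gal must be > 0")
    if (suppressor_effect < 0 || enhancer_effect < 0)
      stop("effects are magnitudes and must be >= 0")
    if (enhancer_effect >= baseline_gal)
      stop("enhancer_effect must be smaller than baseline_gal ",
           "(fitness must stay positive)")
  })
  invisible(cfg)
}

#' Assign ground-truth fitness effects to catalog strains
#'
#' Randomly designates `n_suppressors` strains as toxicity suppressors
#' (GAL fitness `baseline_gal + suppressor_effect`) and `n_enhancers` as
#' toxicity enhancers (GAL fitness `baseline_gal - enhancer_effect`);
#' all remaining strains sit at the pool baseline. Control (GLU) fitness
#' is 1 for every strain.
#'
#' @param catalog a barcode catalog.
#' @param config a [sim_config()].
#' @return a data.frame (the truth table) with columns `strain_id`,
#'   `yeast_gene`, `true_class`, `fitness_glu`, `fitness_gal`.
#' @export
assign_effects <- function(catalog, config) {
  validate_catalog(catalog)
  validate_sim_config(config)
  n <- nrow(catalog)
  if (n != config$n_strains)
    stop("catalog has ", n, " strains but config says ", config$n_strains)
  cls <- rep("no_effect", n)
  picked <- with_seed(derive_seed(config$seed, "effects"),
                      sample.int(n, config$n_suppressors + config$n_enhancers))
  if (config$n_suppressors > 0)
    cls[picked[seq_len(config$n_suppressors)]] <- "suppressor"
  if (config$n_enhancers > 0)
    cls[picked[config$n_suppressors + seq_len(config$n_enhancers)]] <-
      "enhancer"
  fit_gal <- config$baseline_gal +
    ifelse(cls == "suppressor", config$suppressor_effect,
           ifelse(cls == "enhancer", -config$enhancer_effect, 0))
  data.frame(strain_id = catalog$strain_id,
             yeast_gene = catalog$yeast_gene,
             true_class = cls,
             fitness_glu = 1,
             fitness_gal = fit_gal,
             stringsAsFactors = FALSE)
}

#' Deterministic exponential competition growth
#'
#' Starting from equal abundance, strain i reaches relative abundance
#' proportional to `2^(fitness_i * generations)` after the given number of
#' population doublings; the returned vector is normalised to sum to 1.
#' Stochastic drift is deliberately omitted: sampling noise enters at the
#' sequencing step.
#'
#' @param effects truth table from [assign_effects()].
#' @param generations population doublings (>= 0).
#' @param condition `"GLU"` (control) or `"GAL"` (query induced).
#' @return named numeric vector of abundance fractions summing to 1.
#' @export
simulate_growth <- function(effects, generations, condition = c("GLU", "GAL")) {
  condition <- match.arg(condition)
  if (nrow(effects) == 0) stop("empty effect table")
  if (generations < 0) stop("generations must be >= 0")
  f <- if (condition == "GLU") effects$fitness_glu else effects$fitness_gal
  # subtract the max exponent for numerical stability at large generations
  e <- f * generations
  w <- 2^(e - max(e))
  setNames(w / sum(w), effects$strain_id)
}

# Inject independent per-base substitution errors into equal-length reads.
# Exactly equivalent to Bernoulli(p) per base: the error count per read is
# Binomial(len, p) and error positions are a uniform subset.
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads[1])
  n_err <- rbinom(length(reads), len, error_rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(reads)
  mat <- matrix(charToRaw(paste0(reads[hit], collapse = "")),
                nrow = len)
  for (k in seq_along(hit)) {
    pos <- sample.int(len, n_err[hit[k]])
    for (p in pos) {
      cur <- rawToChar(mat[p, k])
      mat[p, k] <- charToRaw(sample(setdiff(DNA_BASES, cur), 1L))
    }
  }
  out <- reads
  out[hit] <- substring(rawToChar(mat), seq(1, length(hit) * len, by = len),
                        seq(len, length(hit) * len, by = len))
  out
}

#' Sample sequencing reads from a pooled sample
#'
#' Draws `depth` reads multinomially from the strain abundance vector and
#' synthesises each read as fixed base + forward 6-mer index tag + 18-base
#' common primer + the strain's 20-mer uptag, then applies independent
#' per-base substitution errors. Quality is constant Q40 ('I'); the
#' analysis never uses it.
#'
#' @param abundances named abundance vector from [simulate_growth()].
#' @param catalog barcode catalog (order must match `abundances`).
#' @param design a multiplex design data.frame (see [parse_design()]).
#' @param query query gene name, present in `design`.
#' @param condition `"GLU"` or `"GAL"`.
#' @param depth number of reads to draw (>= 0).
#' @param seq_error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return list with `reads` (character vector of read sequences), `qual`
#'   (constant quality string), `ids` (read names) and `true_counts`
#'   (named integer vector: the multinomial draw per strain).
#' @export
sample_reads <- function(abundances, catalog, design, query,
                         condition = c("GLU", "GAL"), depth,
                         seq_error_rate = 0, seed = 1L) {
  condition <- match.arg(condition)
  validate_catalog(catalog)
  if (depth < 0) stop("depth must be >= 0")
  row <- design[design$query == query & design$condition == condition, ]
  if (nrow(row) != 1L)
    stop("query/condition (", query, ", ", condition,
         ") not found uniquely in design")
  if (!identical(names(abundances), catalog$strain_id))
    stop("abundances must be named by catalog strain_id, in catalog order")
  depth <- as.integer(depth)
  n <- nrow(catalog)
  qual <- strrep("I", 1L + TAG_LEN + nchar(FWD_COMMON) + BARCODE_LEN)
  if (depth == 0L) {
    return(list(reads = character(0), qual = qual, ids = character(0),
                true_counts = setNames(integer(n), catalog$strain_id)))
  }
  with_seed(derive_seed(seed, paste0("reads_", query, "_", condition)), {
    strain <- sample.int(n, depth, replace = TRUE, prob = abundances)
    reads <- paste0(FIXED_PREFIX, row$fwd_tag, FWD_COMMON,
                    catalog$uptag[strain])
    reads <- inject_errors(reads, seq_error_rate)
    list(reads = reads,
         qual = qual,
         ids = sprintf("%s_%s_read%d", query, condition, seq_len(depth)),
         true_counts = setNames(tabulate(strain, nbins = n),
                                catalog$strain_id))
  })
}

#' Write reads as a FASTQ file
#'
#' Plain 4-line FASTQ records with Sanger/Phred+33 qualities. Output is
#' byte-deterministic for identical input.
#'
#' @param sample a list as returned by [sample_reads()].
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sample, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- length(sample$reads)
  if (n > 0) {
    rec <- character(4L * n)
    rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", sample$ids)
    rec[seq(2L, by = 4L, length.out = n)] <- sample$reads
    rec[seq(3L, by = 4L, length.out = n)] <- "+"
    rec[seq(4L, by = 4L, length.out = n)] <- substr(rep(sample$qual, n), 1L,
                                                    nchar(sample$reads))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write / read a ground-truth table TSV
#'
#' Header: `strain_id  yeast_gene  true_class  fitness_glu  fitness_gal`.
#' Round-trips losslessly (numeric columns at full precision).
#'
#' @param effects truth table from [assign_effects()].
#' @param path file path.
#' @export
write_truth <- function(effects, path) {
  if (nrow(effects) == 0) stop("empty truth table")
  stopifnot(all(effects$true_class %in%
                  c("suppressor", "enhancer", "no_effect")))
  df <- effects
  df$fitness_glu <- formatC(df$fitness_glu, digits = 17, format = "g")
  df$fitness_gal <- formatC(df$fitness_gal, digits = 17, format = "g")
  write_tsv(df, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_tsv_strict(path, c("strain_id", "yeast_gene", "true_class",
                                "fitness_glu", "fitness_gal"), "truth")
  df$fitness_glu <- as.numeric(df$fitness_glu)
  df$fitness_gal <- as.numeric(df$fitness_gal)
  df
}

#' Simulate a complete multi-query pooled screen
#'
#' Runs the whole synthetic experiment for one or more toxic query genes:
#' builds (or accepts) a barcode catalog, designs index-tag multiplexing,
#' assigns ground-truth fitness effects per query, grows the pool under
#' GLU and GAL, samples reads, and writes one FASTQ per (query, condition)
#' plus `catalog.tsv`, `design.tsv` and `truth_<query>.tsv` to `outdir`.
#'
#' @param config a [sim_config()].
#' @param queries character vector of query gene names.
#' @param outdir output directory (created if needed).
#' @param catalog optional pre-built catalog; by default one is built from
#'   the config seed.
#' @param gzip compress FASTQ output.
#' @return invisibly, a list with `catalog`, `design`, `truth` (per query),
#'   `true_counts` (strain x sample integer matrix of the multinomial
#'   draws) and the written `paths`.
#' @export
simulate_screen <- function(config, queries = "QUERY1", outdir,
                            catalog = NULL, gzip = FALSE) {
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(catalog))
    catalog <- build_library(config$n_strains,
                             seed = derive_seed(config$seed, "library"))
  validate_catalog(catalog)
  design <- make_design(queries, seed = derive_seed(config$seed, "design"))
  paths <- list(catalog = file.path(outdir, "catalog.tsv"),
                design = file.path(outdir, "design.tsv"))
  write_catalog(catalog, paths$catalog)
  truth <- list()
  true_counts <- matrix(0L, nrow(catalog), 0,
                        dimnames = list(catalog$strain_id, NULL))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    qcfg <- config
    qcfg$seed <- derive_seed(config$seed, paste0("query_", q))
    eff <- assign_effects(catalog, qcfg)
    truth[[q]] <- eff
    tpath <- file.path(outdir, paste0("truth_", q, ".tsv"))
    write_truth(eff, tpath)
    paths[[paste0("truth_", q)]] <- tpath
    for (cond in c("GLU", "GAL")) {
      ab <- simulate_growth(eff, config$generations, cond)
      smp <- sample_reads(ab, catalog, design, q, cond, config$depth,
                          config$seq_error_rate, seed = qcfg$seed)
      fq <- file.path(outdir, paste0(q, "_", cond, ext))
      write_fastq(smp, fq)
      design$fastq[design$query == q & design$condition == cond] <- fq
      true_counts <- cbind(true_counts, smp$true_counts)
      colnames(true_counts)[ncol(true_counts)] <- paste0(q, "_", cond)
    }
  }
  write_design(design, paths$design)
  invisible(list(catalog = catalog, design = design, truth = truth,
                 true_counts = true_counts, paths = paths))
}
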