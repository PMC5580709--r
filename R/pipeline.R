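PIPELINE_KEYS <- c("outdir", "seed", "queries", "simulation", "design",
                   "catalog", "orthologs", "annotation", "universe",
                   "imported_edges", "thresholds", "flags")
SIM_KEYS <- c("n_strains", "n_suppressors", "n_enhancers", "baseline_gal",
              "suppressor_effect", "enhancer_effect", "generations",
              "depth", "seq_error_rate", "seed")
THRESH_KEYS <- c("suppressor_cut", "enhancer_cut", "pseudocount")
FLAG_KEYS <- c("robust", "fdr", "quantile", "gzip")

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, rejects unknown keys, fills defaults
#' (cutoffs 1.96 / -1.96, pseudocount 0.5, all flags off) and checks that
#' exactly one input mode is present: either a `simulation` block (the
#' synthetic experiment is generated) or `design` + `catalog` paths to
#' existing FASTQ data. Referenced files must exist at validation time.
#'
#' @param path YAML config file.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_sim <- !is.null(cfg$simulation)
  has_fastq <- !is.null(cfg$design)
  if (has_sim && has_fastq)
    stop("config must not contain both a simulation block and a design ",
         "(FASTQ) input")
  if (!has_sim && !has_fastq)
    stop("config needs either a simulation block or a design (FASTQ) input")
  if (is.null(cfg$outdir)) stop("config needs an outdir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (has_sim) {
    unknown <- setdiff(names(cfg$simulation), SIM_KEYS)
    if (length(unknown))
      stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
    sim <- cfg$simulation
    sim$seed <- cfg$seed
    cfg$simulation <- do.call(sim_config, sim)
    if (is.null(cfg$queries)) cfg$queries <- "QUERY1"
    cfg$queries <- as.character(unlist(cfg$queries))
  } else {
    for (f in c("design", "catalog"))
      if (!file.exists(cfg[[f]]))
        stop(f, " file not found: ", cfg[[f]])
    des <- parse_design(cfg$design)
    missing_fq <- des$fastq[!file.exists(des$fastq)]
    if (length(missing_fq))
      stop("FASTQ file(s) named in design not found: ",
           paste(missing_fq, collapse = ", "))
  }
  for (f in c("orthologs", "annotation", "universe", "imported_edges"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(f, " file not found: ", cfg[[f]])
  th <- cfg$thresholds
  unknown <- setdiff(names(th), THRESH_KEYS)
  if (length(unknown))
    stop("unknown thresholds key(s): ", paste(unknown, collapse = ", "))
  cfg$thresholds <- do.call(screen_thresholds,
                            if (is.null(th)) list()
                            else th[intersect(names(th), THRESH_KEYS)])
  fl <- cfg$flags
  unknown <- setdiff(names(fl), FLAG_KEYS)
  if (length(unknown))
    stop("unknown flag(s): ", paste(unknown, collapse = ", "))
  cfg$flags <- list(robust = isTRUE(fl$robust), fdr = isTRUE(fl$fdr),
                    quantile = isTRUE(fl$quantile),
                    gzip = isTRUE(fl$gzip))
  structure(cfg, class = "pipeline_config")
}

#' Run the full screen pipeline
#'
#' Orchestrates simulate (optional) -> demultiplex/count -> score ->
#' network as one reproducible run. Every stage writes its artifact into
#' the configured output directory and a JSON run manifest records the
#' config, the seed and an MD5 hash of every output, so identical
#' config + seed reproduce identical ztable bytes. When ground truth is
#' available (simulation mode) a truth-vs-called confusion matrix per
#' query is also written.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a path
#'   to a YAML config).
#' @param verbose emit structured log lines per stage.
#' @return invisibly, a list with `counts`, `stats`, `fit`
#'   (`modifier_screen`), `network` (or `NULL`), `confusion` (or `NULL`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    log_line("simulate", queries = length(config$queries),
             verbose = verbose)
    sim <- run_stage("simulate",
                     simulate_screen(config$simulation, config$queries,
                                     outdir, gzip = config$flags$gzip))
    design <- sim$design
    catalog <- sim$catalog
    truth <- sim$truth
    outputs <- c(outputs, unlist(sim$paths), design$fastq)
  } else {
    design <- run_stage("demux", parse_design(config$design))
    catalog <- run_stage("demux", read_catalog(config$catalog))
  }
  log_line("demux", files = length(unique(design$fastq)),
           verbose = verbose)
  dx <- run_stage("demux", count_barcodes(design, catalog,
                                          verbose = verbose))
  counts_path <- file.path(outdir, "counts.tsv")
  write_count_matrix(dx$counts, counts_path)
  stats_path <- file.path(outdir, "demux_stats.tsv")
  write_tsv(dx$stats, stats_path)
  outputs <- c(outputs, counts_path, stats_path)
  log_line("score", strains = nrow(dx$counts), verbose = verbose)
  fit <- run_stage("score",
                   score_screen(dx$counts, catalog,
                                thresholds = config$thresholds,
                                normalization = if (config$flags$quantile)
                                  "quantile" else "average",
                                robust = config$flags$robust,
                                fdr = config$flags$fdr))
  ztable_path <- file.path(outdir, "ztable.tsv")
  write_ztable(fit, ztable_path)
  outputs <- c(outputs, ztable_path)
  confusion <- NULL
  if (!is.null(truth)) {
    confusion <- lapply(names(truth), function(q) {
      zt <- fit$ztable[fit$ztable$query == q, ]
      tr <- truth[[q]]
      table(truth = tr$true_class[match(zt$strain_id, tr$strain_id)],
            called = factor(zt$label, levels = c("suppressor", "enhancer",
                                                 "no_effect")))
    })
    names(confusion) <- names(truth)
    conf_path <- file.path(outdir, "confusion.tsv")
    conf_df <- do.call(rbind, lapply(names(confusion), function(q) {
      d <- as.data.frame(confusion[[q]], stringsAsFactors = FALSE)
      cbind(query = q, d)
    }))
    write_tsv(conf_df, conf_path)
    outputs <- c(outputs, conf_path)
  }
  net <- NULL
  if (!is.null(config$orthologs)) {
    log_line("network", verbose = verbose)
    omap <- run_stage("network", load_ortholog_map(config$orthologs))
    mapped <- run_stage("network", map_suppressors(fit$ztable, omap))
    imported <- if (!is.null(config$imported_edges))
      read_tsv_strict(config$imported_edges, c("source", "target", "type"),
                      "imported edges")
    net <- run_stage("network", build_network(mapped$interactions,
                                              imported))
    net_path <- file.path(outdir, "network.graphml")
    export_network(net, net_path, "graphml")
    unmapped_path <- file.path(outdir, "unmapped_suppressors.tsv")
    write_tsv(mapped$unmapped, unmapped_path)
    outputs <- c(outputs, net_path, unmapped_path)
    if (!is.null(config$annotation) && !is.null(config$universe)) {
      ann_df <- read_tsv_strict(config$annotation, c("category", "gene"),
                                "annotation")
      universe <- readLines(config$universe)
      genes <- unique(mapped$interactions$partner)
      genes <- intersect(genes, universe)
      if (length(genes)) {
        enr <- run_stage("network",
                         enrich_categories(genes,
                                           split(ann_df$gene,
                                                 ann_df$category),
                                           universe))
        enr_path <- file.path(outdir, "enrichment.tsv")
        write_tsv(enr, enr_path)
        outputs <- c(outputs, enr_path)
      }
    }
  }
  manifest <- list(
    seed = config$seed,
    config = lapply(unclass(config)[setdiff(names(config), "thresholds")],
                    function(x) if (is.list(x)) unclass(x) else x),
    thresholds = unclass(config$thresholds),
    outputs = as.list(tools::md5sum(sort(unique(outputs)))),
    package_version = as.character(utils::packageVersion("bartox")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_line("done", outputs = length(outputs), verbose = verbose)
  invisible(list(counts = dx$counts, stats = dx$stats, fit = fit,
                 network = net, confusion = confusion,
                 manifest = manifest))
}
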