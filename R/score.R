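#' Classification thresholds for modifier calling
#'
#' Defaults follow the two-sided 5% standard-normal critical values:
#' corrected Z above 1.96 calls a toxicity suppressor, below -1.96 a
#' toxicity enhancer, anything else no-effect. The pseudocount stabilises
#' ratios and error propagation at zero counts.
#'
#' @param suppressor_cut positive cutoff for suppressors.
#' @param enhancer_cut negative cutoff for enhancers.
#' @param pseudocount added to raw counts in ratios and error terms.
#' @return a validated `thresholds` list.
#' @export
screen_thresholds <- function(suppressor_cut = 1.96, enhancer_cut = -1.96,
                              pseudocount = 0.5) {
  if (!(suppressor_cut > 0 && enhancer_cut < 0))
    stop("suppressor_cut must be > 0 > enhancer_cut")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(suppressor_cut = suppressor_cut,
                 enhancer_cut = enhancer_cut,
                 pseudocount = pseudocount),
            class = "screen_thresholds")
}

#' Normalize barcode counts by the per-sample average
#'
#' Divides each barcode count by the mean count of its sample so every
#' sample has mean normalized abundance 1, making samples of different
#' sequencing depth comparable. A true quantile-normalization mode (every
#' sample forced onto the identical count distribution) is available for
#' comparison via `method = "quantile"`.
#'
#' @param counts integer count matrix, strains x samples.
#' @param method `"average"` (divide by the sample mean; default) or
#'   `"quantile"` (delegates to `limma::normalizeQuantiles`).
#' @return numeric matrix of normalized abundances, same dimensions.
#' @examples
#' m <- cbind(s1 = c(10L, 20L, 30L))
#' normalize_counts(m)
#' @export
normalize_counts <- function(counts, method = c("average", "quantile")) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (method == "quantile") {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("method = 'quantile' requires the limma package")
    nm <- limma::normalizeQuantiles(counts)
    dimnames(nm) <- dimnames(counts)
    return(nm)
  }
  sweep(counts, 2L, colMeans(counts), "/")
}

#' Per-strain log ratios and Z-scores for one query
#'
#' For each strain the normalized GAL (query on) abundance is compared to
#' the normalized GLU (query off) abundance as a log2 ratio; the ratios
#' are standardised across strains into Z-scores. A pseudocount (applied
#' on the raw-count scale, i.e. divided by the sample's raw mean before
#' entering the normalized ratio) keeps zero counts finite.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param counts the raw count matrix (needed for the pseudocount scale
#'   and for error propagation).
#' @param query query gene; columns `"<query>_GAL"` and `"<query>_GLU"`
#'   must exist.
#' @param pseudocount pseudocount on the raw-count scale.
#' @param robust standardise with median/MAD instead of mean/sd.
#' @return data.frame with `strain_id`, `n_glu`, `n_gal`, `norm_glu`,
#'   `norm_gal`, `log_ratio`, `z`, plus attribute `scale` (the sd or MAD
#'   used).
#' @export
compute_zscores <- function(norm, counts, query, pseudocount = 0.5,
                            robust = FALSE) {
  gal <- paste0(query, "_GAL")
  glu <- paste0(query, "_GLU")
  if (!all(c(gal, glu) %in% colnames(norm)))
    stop("query ", query, " needs both GAL and GLU samples")
  if (nrow(norm) < 3) stop("need at least 3 strains to standardise")
  m_gal <- mean(counts[, gal])
  m_glu <- mean(counts[, glu])
  lr <- log2((norm[, gal] + pseudocount / m_gal) /
               (norm[, glu] + pseudocount / m_glu))
  ctr <- if (robust) median(lr) else mean(lr)
  scl <- if (robust) mad(lr) else sd(lr)
  if (!is.finite(scl) || scl == 0)
    stop("degenerate screen for query ", query,
         ": log-ratio spread is zero")
  z <- (lr - ctr) / scl
  out <- data.frame(strain_id = rownames(norm),
                    n_glu = counts[, glu], n_gal = counts[, gal],
                    norm_glu = norm[, glu], norm_gal = norm[, gal],
                    log_ratio = unname(lr), z = unname(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scale") <- scl
  out
}

#' Relative error of a Z-score by Poisson error propagation
#'
#' Barcode counts are treated as Poisson, so a count n carries relative
#' error 1/sqrt(n + pseudocount). Propagating through the log2 ratio
#' gives an absolute log-ratio error
#' `delta = sqrt(1/(n_gal+pc) + 1/(n_glu+pc)) / ln(2)`; dividing by the
#' across-strain log-ratio spread converts it to an absolute error of z,
#' and dividing by |z| yields the relative error rate used for the
#' corrected Z-score. A strain with z = 0 is fully uncertain
#' (error rate 1 by convention).
#'
#' @param n_glu,n_gal raw counts in the control and induced samples.
#' @param z the strain's Z-score.
#' @param sd_logratio across-strain spread of the log ratios (> 0).
#' @param pseudocount pseudocount shared with [compute_zscores()].
#' @return numeric vector of error rates (dimensionless, >= 0; may
#'   exceed 1).
#' @export
estimate_error_rate <- function(n_glu, n_gal, z, sd_logratio,
                                pseudocount = 0.5) {
  if (any(n_glu < 0) || any(n_gal < 0)) stop("counts must be >= 0")
  if (sd_logratio <= 0) stop("sd_logratio must be > 0")
  delta <- sqrt(1 / (n_gal + pseudocount) + 1 / (n_glu + pseudocount)) /
    log(2)
  z_err <- delta / sd_logratio
  ifelse(z == 0, 1, z_err / abs(z))
}

#' Corrected Z-score bounds
#'
#' Scales a Z-score by one-minus and one-plus its relative error rate:
#' the low bound shrinks the score toward zero (capped so it never
#' crosses zero) and the high bound inflates it. Classification uses the
#' conservative low bound, so hit lists shrink rather than grow under
#' counting uncertainty.
#'
#' @param z Z-scores.
#' @param error_rate relative error rates (>= 0).
#' @return list with numeric vectors `low` and `high`.
#' @examples
#' correct_zscores(2.5, 0.1)  # low 2.25, high 2.75
#' @export
correct_zscores <- function(z, error_rate) {
  if (any(error_rate < 0)) stop("error_rate must be >= 0")
  list(low = (1 - pmin(error_rate, 1)) * z,
       high = (1 + error_rate) * z)
}

#' Label strains as suppressors, enhancers or no-effect
#'
#' A strain is a toxicity suppressor when its conservative corrected
#' Z-score exceeds the suppressor cutoff, a toxicity enhancer when it
#' falls below the enhancer cutoff (strict inequalities), and no-effect
#' otherwise.
#'
#' @param z_corrected_low conservative corrected Z-scores.
#' @param thresholds a [screen_thresholds()].
#' @return character vector of labels.
#' @export
classify_modifiers <- function(z_corrected_low,
                               thresholds = screen_thresholds()) {
  ifelse(z_corrected_low > thresholds$suppressor_cut, "suppressor",
         ifelse(z_corrected_low < thresholds$enhancer_cut, "enhancer",
                "no_effect"))
}

#' Score a pooled toxicity-modifier screen
#'
#' The package's central estimator. Takes the strains x samples barcode
#' count matrix of a pooled screen (columns `"<query>_GLU"` /
#' `"<query>_GAL"`), normalizes counts by the per-sample average, forms
#' per-strain log2 GAL/GLU abundance ratios, standardises them into
#' Z-scores, propagates Poisson counting error into a per-strain error
#' rate, computes corrected Z-score bounds `(1 +/- error rate) * Z`, and
#' classifies every strain per query as toxicity suppressor, enhancer or
#' no-effect on the conservative bound.
#'
#' @param counts integer count matrix with strain rownames and
#'   `"<query>_<condition>"` column names.
#' @param catalog optional barcode catalog supplying `yeast_gene` names.
#' @param queries queries to score (default: all with both conditions).
#' @param thresholds a [screen_thresholds()].
#' @param normalization `"average"` or `"quantile"`.
#' @param robust standardise with median/MAD instead of mean/sd.
#' @param fdr also report Benjamini-Hochberg q-values from two-sided
#'   normal p-values of the corrected Z (diagnostic; labels still come
#'   from the fixed cutoffs).
#' @return an object of class `modifier_screen`: a list with `ztable`
#'   (one row per strain per query), `thresholds`, `queries`, `scales`
#'   (per-query log-ratio spread) and the matched `call`. Methods:
#'   [print.modifier_screen()], [summary.modifier_screen()],
#'   [coef.modifier_screen()], [plot.modifier_screen()].
#' @examples
#' set.seed(1)
#' counts <- matrix(rpois(40, 100), 10,
#'                  dimnames = list(sprintf("s%02d", 1:10),
#'                                  c("Q_GLU", "Q_GAL", "R_GLU", "R_GAL")),
#'                  ncol = 4)
#' fit <- score_screen(counts)
#' summary(fit)
#' @export
score_screen <- function(counts, catalog = NULL, queries = NULL,
                         thresholds = screen_thresholds(),
                         normalization = c("average", "quantile"),
                         robust = FALSE, fdr = FALSE) {
  normalization <- match.arg(normalization)
  if (is.null(rownames(counts)))
    stop("counts must have strain_id rownames")
  cond <- sub(".*_", "", colnames(counts))
  if (!all(cond %in% c("GLU", "GAL")))
    stop("count matrix columns must be named <query>_GLU / <query>_GAL")
  qs <- sub("_(GLU|GAL)$", "", colnames(counts))
  avail <- intersect(qs[cond == "GAL"], qs[cond == "GLU"])
  if (is.null(queries)) queries <- unique(avail)
  if (!all(queries %in% avail))
    stop("missing GLU or GAL sample for query: ",
         paste(setdiff(queries, avail), collapse = ", "))
  norm <- normalize_counts(counts, normalization)
  gene <- if (!is.null(catalog))
    setNames(catalog$yeast_gene, catalog$strain_id)[rownames(counts)]
  else rownames(counts)
  pieces <- vector("list", length(queries))
  scales <- numeric(length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    zt <- compute_zscores(norm, counts, q, thresholds$pseudocount, robust)
    scales[i] <- attr(zt, "scale")
    er <- estimate_error_rate(zt$n_glu, zt$n_gal, zt$z, scales[i],
                              thresholds$pseudocount)
    cz <- correct_zscores(zt$z, er)
    zt$error_rate <- er
    zt$z_corrected_low <- cz$low
    zt$z_corrected_high <- cz$high
    zt$label <- classify_modifiers(cz$low, thresholds)
    if (fdr) {
      p <- 2 * pnorm(-abs(cz$low))
      zt$q_value <- p.adjust(p, method = "BH")
    }
    zt <- cbind(data.frame(query = q, stringsAsFactors = FALSE), zt)
    zt$yeast_gene <- unname(gene)
    pieces[[i]] <- zt
  }
  zt <- do.call(rbind, pieces)
  first <- c("strain_id", "yeast_gene", "query")
  zt <- zt[, c(first, setdiff(names(zt), first))]
  rownames(zt) <- NULL
  structure(list(ztable = zt, thresholds = thresholds, queries = queries,
                 scales = setNames(scales, queries),
                 normalization = normalization, robust = robust,
                 call = match.call()),
            class = "modifier_screen")
}

#' @export
print.modifier_screen <- function(x, ...) {
  cat("Pooled toxicity-modifier screen\n")
  cat(sprintf("  %d strains, %d quer%s (%s normalization%s)\n",
              length(unique(x$ztable$strain_id)), length(x$queries),
              if (length(x$queries) == 1) "y" else "ies",
              x$normalization, if (x$robust) ", robust" else ""))
  cat(sprintf("  cutoffs: suppressor > %.2f, enhancer < %.2f on corrected Z\n",
              x$thresholds$suppressor_cut, x$thresholds$enhancer_cut))
  tab <- table(x$ztable$query, x$ztable$label)
  print(tab)
  invisible(x)
}

#' @export
summary.modifier_screen <- function(object, ...) {
  zt <- object$ztable
  out <- do.call(rbind, lapply(split(zt, zt$query), function(d) {
    data.frame(query = d$query[1],
               n_strains = nrow(d),
               suppressors = sum(d$label == "suppressor"),
               enhancers = sum(d$label == "enhancer"),
               no_effect = sum(d$label == "no_effect"),
               median_error_rate = median(d$error_rate),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("summary.modifier_screen", "data.frame"))
}

#' @export
print.summary.modifier_screen <- function(x, ...) {
  cat("Modifier calls per query (corrected Z classification)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Matrix of corrected Z-scores
#'
#' @param object a `modifier_screen` fit.
#' @param which `"z_corrected_low"` (default), `"z"` or
#'   `"z_corrected_high"`.
#' @param ... unused.
#' @return strains x queries numeric matrix.
#' @export
coef.modifier_screen <- function(object,
                                 which = c("z_corrected_low", "z",
                                           "z_corrected_high"), ...) {
  which <- match.arg(which)
  zt <- object$ztable
  strains <- unique(zt$strain_id)
  m <- matrix(NA_real_, length(strains), length(object$queries),
              dimnames = list(strains, object$queries))
  m[cbind(match(zt$strain_id, strains), match(zt$query, object$queries))] <-
    zt[[which]]
  m
}

#' Plot corrected Z-scores of a screen
#'
#' One panel per query: conservative corrected Z against log10 mean raw
#' count, with the classification cutoffs drawn and calls coloured.
#'
#' @param x a `modifier_screen` fit.
#' @param queries subset of queries to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.modifier_screen <- function(x, queries = x$queries, ...) {
  zt <- x$ztable[x$ztable$query %in% queries, ]
  old <- graphics::par(mfrow = c(1, length(queries)))
  on.exit(graphics::par(old))
  for (q in queries) {
    d <- zt[zt$query == q, ]
    col <- ifelse(d$label == "suppressor", "firebrick",
                  ifelse(d$label == "enhancer", "dodgerblue3", "grey50"))
    graphics::plot(log10((d$n_glu + d$n_gal) / 2 + 1), d$z_corrected_low,
                   col = col, pch = 20, xlab = "log10 mean barcode count",
                   ylab = "corrected Z (low bound)", main = q, ...)
    graphics::abline(h = c(x$thresholds$suppressor_cut,
                           x$thresholds$enhancer_cut), lty = 2)
  }
  invisible(x)
}

#' Write / read a Z-table TSV
#'
#' Long format, one row per strain per query, with the columns of
#' `modifier_screen$ztable`.
#'
#' @param fit a `modifier_screen` fit (or its `ztable`).
#' @param path file path.
#' @export
write_ztable <- function(fit, path) {
  zt <- if (inherits(fit, "modifier_screen")) fit$ztable else fit
  num <- vapply(zt, is.numeric, logical(1)) &
    !vapply(zt, is.integer, logical(1))
  out <- zt
  out[num] <- lapply(zt[num], formatC, digits = 17, format = "g")
  write_tsv(out, path)
}

#' @rdname write_ztable
#' @export
read_ztable <- function(path) {
  df <- read_tsv_strict(path, c("strain_id", "query", "z", "error_rate",
                                "z_corrected_low", "label"), "ztable")
  for (cc in c("n_glu", "n_gal", "norm_glu", "norm_gal", "log_ratio", "z",
               "error_rate", "z_corrected_low", "z_corrected_high",
               "q_value"))
    if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' @importFrom stats median mad
NULL
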