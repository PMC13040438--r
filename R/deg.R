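# Two-condition differential-expression stage, written out in full so the
# classification rule (|log2FC| >= 2 and adjusted p < 0.05) is reproducible
# without any external DE engine: median-of-ratios size factors, a
# negative-binomial Wald test with a moment-based dispersion trend, and
# step-up Benjamini-Hochberg adjustment.

#' Construct a two-condition count matrix
#'
#' @param counts Integer matrix, genes x samples, non-negative.  Row names
#'   (or `gene_ids`) identify genes.
#' @param condition Per-sample labels; exactly the two levels `"reference"`
#'   and `"treatment"`, each with at least two replicates.
#' @param gene_ids Optional gene identifiers (defaults to row names).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, condition, gene_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(condition) != ncol(counts)) {
    stop("one condition label per sample required")
  }
  condition <- factor(condition, levels = c("reference", "treatment"))
  if (any(is.na(condition))) {
    stop("condition labels must be 'reference' or 'treatment'")
  }
  if (any(table(condition) < 2)) {
    stop("at least two replicates per condition required")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  rownames(counts) <- gene_ids
  structure(
    list(counts = counts, condition = condition, gene_ids = gene_ids),
    class = "count_matrix"
  )
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to
#' genes with a positive geometric mean across all samples) of the ratio
#' count / geometric mean; factors are then rescaled to geometric mean 1,
#' which preserves all between-sample ratios.
#'
#' @param m A [count_matrix()].
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has nonzero counts in every sample; cannot form ratios")
  }
  log_f <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    stats::median(log(col) - log_geo[usable])
  })
  exp(log_f - mean(log_f))
}

# Moment dispersion machinery.  Per-gene method-of-moments values
# ((pooled within-condition variance - mean) / mean^2) are noisy at two or
# three replicates, so the default pools them into a mean-dispersion trend
# alpha(mu) = a/mu + b fitted by least squares across genes; per-gene
# values (floored) are available as an alternative.
moment_dispersion <- function(mean_ref, mean_trt, var_ref, var_trt,
                              method = c("trended", "per-gene"),
                              floor = 1e-8) {
  method <- match.arg(method)
  mu <- (mean_ref + mean_trt) / 2
  raw <- ifelse(mu > 0, ((var_ref + var_trt) / 2 - mu) / mu^2, NA_real_)
  if (method == "per-gene") {
    return(pmax(ifelse(is.na(raw), floor, raw), floor))
  }
  ok <- !is.na(raw) & mu > 0
  if (sum(ok) < 10) {
    return(pmax(ifelse(is.na(raw), floor, raw), floor))
  }
  fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), raw[ok])
  b <- max(fit$coefficients[1], 0)
  a <- max(fit$coefficients[2], 0)
  pmax(a / mu + b, floor)
}

#' Negative-binomial Wald test
#'
#' Per gene: the log2 fold change is computed from pseudocounted normalised
#' condition means, its standard error by the delta method under an NB
#' variance (var = mu + alpha * mu^2) with a moment-based dispersion, and a
#' two-sided p-value from the normal approximation of the Wald statistic
#' z = log2FC / SE.  Genes with degenerate variance (all counts zero) get
#' log2FC = 0 and p = 1 with a flag rather than NaN.
#'
#' @param m A [count_matrix()] with >= 2 replicates per condition.
#' @param factors Size factors, default [size_factors()].
#' @param pseudocount Added to both normalised means for the fold change
#'   (default 0.5).
#' @param dispersion `"trended"` (default: per-gene moment values pooled
#'   into an alpha = a/mu + b trend, which is what keeps the test
#'   calibrated at 2-3 replicates) or `"per-gene"` (raw moment estimates
#'   floored at 1e-8).
#' @return Data frame with `gene_id`, `base_mean_ref`, `base_mean_trt`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `degenerate`.
#' @export
nb_wald_test <- function(m, factors = size_factors(m), pseudocount = 0.5,
                         dispersion = c("trended", "per-gene")) {
  stopifnot(inherits(m, "count_matrix"))
  dispersion <- match.arg(dispersion)
  norm <- sweep(m$counts, 2, factors, "/")
  ref <- norm[, m$condition == "reference", drop = FALSE]
  trt <- norm[, m$condition == "treatment", drop = FALSE]
  n_ref <- ncol(ref)
  n_trt <- ncol(trt)
  mean_ref <- rowMeans(ref)
  mean_trt <- rowMeans(trt)
  var_ref <- apply(ref, 1, stats::var)
  var_trt <- apply(trt, 1, stats::var)

  lfc <- log2((mean_trt + pseudocount) / (mean_ref + pseudocount))
  alpha <- moment_dispersion(mean_ref, mean_trt, var_ref, var_trt, dispersion)

  nb_var <- function(mu) mu + alpha * mu^2
  # Delta method on log2 of the pseudocounted mean of each condition.
  se2 <- (nb_var(mean_ref) / (n_ref * (mean_ref + pseudocount)^2) +
            nb_var(mean_trt) / (n_trt * (mean_trt + pseudocount)^2)) / log(2)^2
  degenerate <- !(se2 > 0) | !is.finite(se2)
  se <- sqrt(ifelse(degenerate, NA_real_, se2))
  stat <- ifelse(degenerate, 0, lfc / se)
  pvalue <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(stat)))

  data.frame(
    gene_id = m$gene_ids,
    base_mean_ref = mean_ref,
    base_mean_trt = mean_trt,
    log2fc = ifelse(degenerate & mean_ref == 0 & mean_trt == 0, 0, lfc),
    se = se,
    stat = stat,
    pvalue = pvalue,
    degenerate = degenerate,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are p * m / rank with monotonicity enforced by a
#' cumulative minimum from the largest rank down; tied p-values therefore
#' share the smallest qualifying adjusted value.  Thresholding the
#' adjusted values at alpha reproduces exactly the rejection set of the
#' classic step-up procedure at level alpha.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[ord] * m / seq(m, 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Classify DEGs and summarise
#'
#' Applies the differential-expression rule: a gene is a DEG iff
#' |log2FC| >= `fc_threshold` and BH-adjusted p < `alpha`.  Genes with zero
#' counts in all samples are reported with log2FC = 0 and p = padj = 1 and
#' are excluded from the BH multiplicity `m`, while `n_total_genes` keeps
#' the fraction anchored to the full annotated gene universe.  With the
#' full 2594-gene universe, 489 DEGs give 18.85% and 517 give 19.93%.
#'
#' @param result Per-gene table from [nb_wald_test()].
#' @param annotation Optional data frame (`gene_id`, `category`); a gene
#'   may appear in several categories and is counted in each.
#' @param n_total_genes Size of the gene universe for the percentage
#'   (default: number of rows in `result`).
#' @param fc_threshold Absolute log2 fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A `deg_result`: `table` (per-gene with `padj`, `is_deg`) and
#'   `summary` (`n_deg`, `fraction_deg` in percent rounded to 2 decimals,
#'   `per_category` counts).
#' @export
classify_and_summarize <- function(result, annotation = NULL,
                                   n_total_genes = nrow(result),
                                   fc_threshold = 2, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(result)))
  tested <- if (all(c("base_mean_ref", "base_mean_trt") %in% names(result))) {
    !(result$base_mean_ref == 0 & result$base_mean_trt == 0)
  } else {
    rep(TRUE, nrow(result))
  }
  padj <- rep(1, nrow(result))
  padj[tested] <- bh_adjust(result$pvalue[tested])
  result$padj <- padj
  result$is_deg <- abs(result$log2fc) >= fc_threshold & result$padj < alpha

  n_deg <- sum(result$is_deg)
  summary <- list(
    n_deg = n_deg,
    n_total_genes = n_total_genes,
    fraction_deg = round(100 * n_deg / n_total_genes, 2),
    fc_threshold = fc_threshold,
    alpha = alpha
  )
  if (!is.null(annotation)) {
    stopifnot(all(c("gene_id", "category") %in% names(annotation)))
    deg_ids <- result$gene_id[result$is_deg]
    hits <- annotation[annotation$gene_id %in% deg_ids, , drop = FALSE]
    tab <- table(hits$category)
    summary$per_category <- data.frame(
      category = names(tab), n_deg = as.integer(tab),
      stringsAsFactors = FALSE
    )
  }
  structure(list(table = result, summary = summary), class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "DEG screen: %d of %d genes differentially expressed (%.2f%%)\n",
    s$n_deg, s$n_total_genes, s$fraction_deg
  ))
  cat(sprintf(
    "  rule: |log2FC| >= %g and BH-adjusted p < %g\n", s$fc_threshold, s$alpha
  ))
  if (!is.null(s$per_category)) {
    cat("  DEGs per category:\n")
    for (i in seq_len(nrow(s$per_category))) {
      cat(sprintf(
        "    %-40s %d\n", s$per_category$category[i], s$per_category$n_deg[i]
      ))
    }
  }
  invisible(x)
}

#' Run the full differential-expression stage
#'
#' Convenience pipeline: size factors, NB Wald test, BH adjustment and DEG
#' classification in one call.
#'
#' @param m A [count_matrix()].
#' @param annotation Optional annotation data frame (`gene_id`, `category`).
#' @param fc_threshold,alpha Classification thresholds (defaults 2, 0.05).
#' @param n_total_genes Gene universe size (default `nrow(counts)`).
#' @param dispersion Passed to [nb_wald_test()].
#' @return A `deg_result`.
#' @export
deg_analyze <- function(m, annotation = NULL, fc_threshold = 2, alpha = 0.05,
                        n_total_genes = nrow(m$counts),
                        dispersion = c("trended", "per-gene")) {
  res <- nb_wald_test(m, dispersion = match.arg(dispersion))
  classify_and_summarize(
    res, annotation,
    n_total_genes = n_total_genes,
    fc_threshold = fc_threshold, alpha = alpha
  )
}
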