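# Seeded synthetic-data generators for every input the analysis stages
# read: negative-binomial count matrices with planted fold changes, OD
# growth curves, and photometric assay traces.  Each generator runs on its
# own RNG stream (the caller's random state is untouched) and is
# byte-deterministic under its seed.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic count-matrix generator
#'
#' Defaults emulate the statistical shape of a two-condition prokaryotic
#' transcriptome screen over 2594 protein-coding genes with three
#' replicates per condition and roughly 19% of genes differentially
#' expressed at |log2FC| >= 2.
#'
#' @param seed Integer seed; same seed, same matrix, byte for byte.
#' @param n_genes Number of genes (default 2594).
#' @param replicates Replicates per condition (default 3).
#' @param deg_fraction Fraction of genes with a planted effect
#'   (default 0.19; the planted count is `round(deg_fraction * n_genes)`).
#' @param lfc_min,lfc_max Planted |log2FC| is uniform on this range
#'   (default \[2, 8\]) with random sign; set both equal for a point mass.
#' @param mean_log_mean,mean_log_sd Log-normal parameters of the base mean
#'   expression distribution (defaults log-mean 5, log-sd 1.2, i.e. typical
#'   means of ~150 counts spanning a few orders of magnitude).
#' @param disp_a,disp_b Dispersion trend alpha = disp_a/mean + disp_b
#'   (defaults 1 and 0.05).
#' @param libsize_log_sd Log-normal spread of per-sample library-size
#'   factors around 1 (default 0.1).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed, n_genes = 2594, replicates = 3,
                         deg_fraction = 0.19, lfc_min = 2, lfc_max = 8,
                         mean_log_mean = 5, mean_log_sd = 1.2,
                         disp_a = 1, disp_b = 0.05, libsize_log_sd = 0.1) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_genes >= 1, replicates >= 2,
    deg_fraction >= 0, deg_fraction <= 1,
    lfc_min >= 0, lfc_max >= lfc_min,
    mean_log_sd >= 0, disp_a >= 0, disp_b >= 0, libsize_log_sd >= 0
  )
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      replicates = as.integer(replicates), deg_fraction = deg_fraction,
      lfc_min = lfc_min, lfc_max = lfc_max,
      mean_log_mean = mean_log_mean, mean_log_sd = mean_log_sd,
      disp_a = disp_a, disp_b = disp_b, libsize_log_sd = libsize_log_sd
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic two-condition count matrix with planted DEGs
#'
#' Base means are log-normal; per-gene dispersions follow the trend
#' alpha = a/mean + b; counts are negative-binomial around
#' mean x library-size factor.  Planted genes are stratified across the
#' expression range (one per stratum of the mean-sorted gene list) so that
#' recovery can be summarised by expression level, and their log2 fold
#' change is applied to the treatment condition.
#'
#' @param cfg A [synth_config()].
#' @return List with `matrix` (a [count_matrix()]) and `truth` (data frame
#'   `gene_id`, `base_mean`, `log2fc`, `planted`).
#' @export
generate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_genes
    reps <- cfg$replicates
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    base_mean <- stats::rlnorm(n, cfg$mean_log_mean, cfg$mean_log_sd)
    alpha <- cfg$disp_a / base_mean + cfg$disp_b

    n_planted <- round(cfg$deg_fraction * n)
    lfc <- rep(0, n)
    planted <- rep(FALSE, n)
    if (n_planted > 0) {
      strata <- split(order(base_mean), cut(seq_len(n), n_planted, labels = FALSE))
      chosen <- vapply(strata, function(idx) {
        if (length(idx) == 1) idx else sample(idx, 1)
      }, integer(1))
      planted[chosen] <- TRUE
      magnitude <- stats::runif(n_planted, cfg$lfc_min, cfg$lfc_max)
      lfc[chosen] <- magnitude * sample(c(-1, 1), n_planted, replace = TRUE)
    }

    sf <- stats::rlnorm(2 * reps, 0, cfg$libsize_log_sd)
    mu_ref <- base_mean
    mu_trt <- base_mean * 2^lfc
    counts <- matrix(0L, nrow = n, ncol = 2 * reps)
    for (j in seq_len(2 * reps)) {
      mu_j <- (if (j <= reps) mu_ref else mu_trt) * sf[j]
      counts[, j] <- stats::rnbinom(n, mu = mu_j, size = 1 / alpha)
    }
    storage.mode(counts) <- "integer"
    colnames(counts) <- c(
      sprintf("ref_%d", seq_len(reps)), sprintf("trt_%d", seq_len(reps))
    )
    rownames(counts) <- gene_ids
    condition <- rep(c("reference", "treatment"), each = reps)
    list(
      matrix = count_matrix(counts, condition),
      truth = data.frame(
        gene_id = gene_ids, base_mean = base_mean,
        log2fc = lfc, planted = planted, stringsAsFactors = FALSE
      ),
      seed = cfg$seed
    )
  })
}

#' Generate a synthetic OD growth curve
#'
#' OD(t) = od0 * exp(mu * t) * (1 + e_t) with seeded multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param seed Integer seed.
#' @param mu Specific growth rate per hour (> 0).
#' @param od0 Initial OD (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param t_max Duration in hours.
#' @param dt Sampling interval in hours (> 0).
#' @return A [growth_curve()] with the seed stored as an attribute.
#' @export
generate_growth <- function(seed, mu = 0.075, od0 = 0.02, noise_cv = 0,
                            t_max = 48, dt = 2) {
  if (mu <= 0 || od0 <= 0 || dt <= 0) stop("mu, od0 and dt must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  with_local_seed(seed, {
    times <- seq(0, t_max, by = dt)
    noise <- if (noise_cv > 0) 1 + stats::rnorm(length(times), 0, noise_cv) else 1
    od <- od0 * exp(mu * times) * noise
    curve <- growth_curve(times, od)
    attr(curve, "seed") <- seed
    attr(curve, "true_mu") <- mu
    curve
  })
}

#' Generate a synthetic absorbance trace with known specific activity
#'
#' Inverts the Beer-Lambert chain of [specific_activity()] to obtain the
#' absorbance slope implied by a target activity, then emits a linear ramp
#' plus seeded Gaussian noise.  At zero noise,
#' `specific_activity(generate_trace(seed, a))` recovers `a` exactly.
#'
#' @param seed Integer seed.
#' @param activity_u_per_mg Target specific activity in U/mg (>= 0).
#' @param epsilon,path_length,volume,protein_mass,electrons_per_chromophore
#'   Assay parameters as in [assay_trace()].
#' @param noise_sd Absorbance noise standard deviation.
#' @param t_max Trace duration in minutes.
#' @param dt Sampling interval in minutes.
#' @param a0 Baseline absorbance.
#' @return An [assay_trace()] with the seed stored as an attribute.
#' @export
generate_trace <- function(seed, activity_u_per_mg, epsilon = 6.3,
                           path_length = 1, volume = 1, protein_mass = 0.1,
                           electrons_per_chromophore = 2, noise_sd = 0,
                           t_max = 5, dt = 0.25, a0 = 0.05) {
  if (activity_u_per_mg < 0) stop("activity must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  slope <- activity_u_per_mg * protein_mass * 2 / electrons_per_chromophore /
    volume * epsilon * path_length
  with_local_seed(seed, {
    times <- seq(0, t_max, by = dt)
    noise <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
    trace <- assay_trace(
      times, a0 + slope * times + noise,
      epsilon = epsilon, path_length = path_length, volume = volume,
      protein_mass = protein_mass,
      electrons_per_chromophore = electrons_per_chromophore
    )
    attr(trace, "seed") <- seed
    attr(trace, "true_activity") <- activity_u_per_mg
    trace
  })
}
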