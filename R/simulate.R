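## Synthetic paired two-platform miRNA studies with known ground truth.

#' Simulation configuration
#'
#' Defines a paired array/qPCR study of three biological groups measured in
#' triplicate, sharing one latent log2 expression profile. Defaults emulate
#' the magnitudes seen in comparative one-color miRNA profiling: roughly
#' 300 expressed miRNAs, ~20% of them differentially expressed per contrast
#' with near-symmetric up/down effects of 0.5–3 log2 units, replicate noise
#' around 0.2 (array) and 0.6 (qPCR) SD units, per-sample additive shifts
#' of SD 0.5, a smooth quadratic intensity-dependent distortion on the
#' array, array fold-change compression (slope 0.45) and a Cq detection
#' ceiling of 35 cycles.
#'
#' @param n_mirnas Number of miRNAs (default 300).
#' @param groups Group labels in order (default `MB`, `MT`, `MT_TNF`);
#'   consecutive pairs define the contrasts.
#' @param replicates Replicates per group (default 3).
#' @param de_fraction Fraction of miRNAs differentially expressed per
#'   contrast, in `[0, 1)` (default 0.2).
#' @param effect_range Range of absolute log2 effects, drawn uniformly
#'   (default `c(0.5, 3)`); signs are Bernoulli(0.5).
#' @param array_noise_sd,qpcr_noise_sd Replicate noise SDs (defaults 0.2
#'   and 0.6).
#' @param sample_shift_sd SD of per-sample additive shifts (default 0.5).
#' @param distortion_amplitude Amplitude of the per-array smooth quadratic
#'   intensity distortion (default 0.4); coefficients are drawn uniformly
#'   in `[-amplitude, amplitude]`.
#' @param compression_slope Multiplier applied to true effects on the array
#'   platform, in `(0, 1]` (default 0.45).
#' @param cq_ceiling Detection ceiling for Cq values (default 35); larger
#'   Cq values are censored at the ceiling and flagged.
#' @param cq_constant Constant C relating latent expression to Cq as
#'   `Cq = C - latent` (default 40).
#' @param baseline_range Range of latent baseline log2 expression (default
#'   `c(6, 14)`).
#' @param species `"human"` or `"mouse"`.
#' @param seed Integer seed; the whole study is bit-reproducible.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulation_config <- function(n_mirnas = 300L,
                              groups = c("MB", "MT", "MT_TNF"),
                              replicates = 3L,
                              de_fraction = 0.2,
                              effect_range = c(0.5, 3),
                              array_noise_sd = 0.2,
                              qpcr_noise_sd = 0.6,
                              sample_shift_sd = 0.5,
                              distortion_amplitude = 0.4,
                              compression_slope = 0.45,
                              cq_ceiling = 35,
                              cq_constant = 40,
                              baseline_range = c(6, 14),
                              species = c("human", "mouse"),
                              seed = 1L) {
  species <- match.arg(species)
  if (de_fraction < 0 || de_fraction >= 1)
    stop("de_fraction must lie in [0, 1)", call. = FALSE)
  if (array_noise_sd <= 0 || qpcr_noise_sd <= 0)
    stop("noise SDs must be positive", call. = FALSE)
  if (compression_slope <= 0 || compression_slope > 1)
    stop("compression_slope must lie in (0, 1]", call. = FALSE)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (replicates < 2L) stop("need >= 2 replicates", call. = FALSE)
  structure(
    list(n_mirnas = as.integer(n_mirnas), groups = groups,
         replicates = as.integer(replicates), de_fraction = de_fraction,
         effect_range = effect_range, array_noise_sd = array_noise_sd,
         qpcr_noise_sd = qpcr_noise_sd, sample_shift_sd = sample_shift_sd,
         distortion_amplitude = distortion_amplitude,
         compression_slope = compression_slope, cq_ceiling = cq_ceiling,
         cq_constant = cq_constant, baseline_range = baseline_range,
         species = species, seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Simulate a paired two-platform miRNA study
#'
#' One latent log2 expression profile per miRNA and group drives both
#' platforms. Per contrast (consecutive group pairs) a `de_fraction` subset
#' receives a uniform effect with random sign; effects accumulate along the
#' group sequence. Array signals are
#' `baseline + slope * effect + shift_s + distortion_s(latent) + noise`
#' (fold-change compression, per-sample shift, smooth per-array quadratic
#' distortion, Gaussian noise); qPCR values are
#' `Cq = C - latent + shift_s + noise`, right-censored at the Cq ceiling
#' (censored cells flagged).
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `"SimulatedStudy"` with elements `array` and
#'   `qpcr` (`ExpressionMatrix` objects), `design` (`StudyDesign` covering
#'   both platforms), `truth` (data frame: `id`, `contrast`, `de`, `delta`),
#'   and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_mirnas
  G <- length(cfg$groups)
  reps <- cfg$replicates
  ids <- sprintf("mir-%04d", seq_len(n))
  contrasts <- lapply(seq_len(G - 1L), function(i)
    c(cfg$groups[i], cfg$groups[i + 1L]))

  baseline <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])

  ## per-contrast effects, accumulated along the group sequence
  effects <- matrix(0, n, G, dimnames = list(ids, cfg$groups))
  truth <- NULL
  for (ci in seq_along(contrasts)) {
    n_de <- round(cfg$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    delta <- numeric(n)
    if (n_de > 0) {
      mag <- stats::runif(n_de, cfg$effect_range[1], cfg$effect_range[2])
      sgn <- ifelse(stats::runif(n_de) < 0.5, -1, 1)
      delta[de_idx] <- mag * sgn
    }
    effects[, ci + 1L] <- effects[, ci] + delta
    tag <- paste(contrasts[[ci]], collapse = "_vs_")
    truth <- rbind(truth, data.frame(
      id = ids, contrast = tag, de = delta != 0, delta = delta,
      stringsAsFactors = FALSE))
  }

  latent <- sweep(effects, 1, baseline, "+")  # n x G latent log2 expression

  sample_ids <- function(platform) {
    as.vector(t(outer(cfg$groups, seq_len(reps), function(g, r)
      sprintf("%s_%s_%s_%d", toupper(substr(cfg$species, 1, 1)),
              ifelse(platform == "array", "A", "Q"), g, r))))
  }
  n_samp <- G * reps
  grp_of <- rep(cfg$groups, each = reps)
  rep_of <- rep(seq_len(reps), times = G)

  ## array platform
  a_ids <- sample_ids("array")
  shift_a <- stats::rnorm(n_samp, 0, cfg$sample_shift_sd)
  dist_c <- stats::runif(n_samp, -cfg$distortion_amplitude,
                         cfg$distortion_amplitude)
  mid <- mean(cfg$baseline_range)
  hw <- diff(cfg$baseline_range) / 2
  arr <- matrix(0, n, n_samp, dimnames = list(ids, a_ids))
  for (s in seq_len(n_samp)) {
    g <- grp_of[s]
    lat <- latent[, g]
    eff <- effects[, g]
    arr[, s] <- baseline + cfg$compression_slope * eff + shift_a[s] +
      dist_c[s] * ((lat - mid) / hw)^2 +
      stats::rnorm(n, 0, cfg$array_noise_sd)
  }

  ## qPCR platform
  q_ids <- sample_ids("qpcr")
  shift_q <- stats::rnorm(n_samp, 0, cfg$sample_shift_sd)
  cq <- matrix(0, n, n_samp, dimnames = list(ids, q_ids))
  for (s in seq_len(n_samp)) {
    g <- grp_of[s]
    cq[, s] <- cfg$cq_constant - latent[, g] + shift_q[s] +
      stats::rnorm(n, 0, cfg$qpcr_noise_sd)
  }
  censored <- cq > cfg$cq_ceiling
  cq[censored] <- cfg$cq_ceiling

  design <- study_design(
    sample = c(a_ids, q_ids),
    group = rep(grp_of, 2),
    replicate = rep(rep_of, 2),
    species = cfg$species,
    platform = rep(c("array", "qpcr"), each = n_samp))

  structure(
    list(array = expression_matrix(arr, "log2_intensity", "array",
                                   cfg$species),
         qpcr = expression_matrix(cq, "cq", "qpcr", cfg$species,
                                  flagged = censored),
         design = design, truth = truth, config = cfg),
    class = "SimulatedStudy"
  )
}

#' Ground-truth differential-expression labels of a simulated study
#'
#' @param s A `"SimulatedStudy"`.
#' @param contrast Character pair among the generated groups (consecutive
#'   pair used at generation).
#' @return A list with `ids` (the truly differential miRNAs) and `delta`
#'   (named vector of true effects over all miRNAs).
#' @export
ground_truth <- function(s, contrast) {
  stopifnot(inherits(s, "SimulatedStudy"))
  tag <- paste(contrast, collapse = "_vs_")
  tr <- s$truth[s$truth$contrast == tag, ]
  if (nrow(tr) == 0L)
    stop("unknown contrast '", tag, "'", call. = FALSE)
  list(ids = tr$id[tr$de],
       delta = stats::setNames(tr$delta, tr$id))
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat(sprintf(
    "SimulatedStudy (%s): %d miRNAs, %d groups x %d replicates, seed %d\n",
    x$config$species, x$config$n_mirnas, length(x$config$groups),
    x$config$replicates, x$config$seed))
  cat(sprintf("  truly DE per contrast: %s\n",
              paste(tapply(x$truth$de, x$truth$contrast, sum),
                    collapse = ", ")))
  invisible(x)
}
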