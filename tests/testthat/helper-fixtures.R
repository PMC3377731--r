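# Fixture builders shared across test files; everything is generated in code.

mk_matrix <- function(values, scale = "log2_intensity", platform = "array",
                      species = "human", ids = NULL, samples = NULL, ...) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("mir-%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, samples)
  expression_matrix(values, scale, platform, species, ...)
}

# One-species one-platform design: groups x reps, sample names s01, s02, ...
mk_design <- function(groups = c("MB", "MT", "MT_TNF"), reps = 3,
                      species = "human", platform = "array",
                      samples = NULL) {
  n <- length(groups) * reps
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  study_design(sample = samples,
               group = rep(groups, each = reps),
               replicate = rep(seq_len(reps), length(groups)),
               species = species, platform = platform)
}

# Random log2-like matrix with per-sample shifts (seeded).
rand_matrix <- function(n = 50, groups = c("MB", "MT", "MT_TNF"), reps = 3,
                        noise = 0.2, shift = 0.5, seed = 1, ...) {
  set.seed(seed)
  ns <- length(groups) * reps
  base <- runif(n, 6, 14)
  v <- matrix(rnorm(n * ns, 0, noise), n, ns) + base +
    rep(rnorm(ns, 0, shift), each = n)
  mk_matrix(v, ...)
}
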