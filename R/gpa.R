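## Generalized Procrustes analysis over replicate groups.

## Orthogonal Procrustes rotation aligning X onto Y (minimizing ||XR - Y||).
## Reflections are excluded by flipping the last singular vector when
## det(R) < 0, unless allowed.
procrustes_rotation <- function(X, Y, allow_reflection = FALSE) {
  sv <- svd(crossprod(X, Y))
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  R
}

#' Generalized Procrustes analysis (GPA) normalization
#'
#' Assumption-free between-sample normalization adapted to one-color data:
#' each biological group's replicate columns form one configuration of
#' points (rows = miRNAs, dimensions = replicates), and the configurations
#' are superimposed by translation, isotropic scaling and rotation onto an
#' iteratively updated consensus. Translation aligns each configuration's
#' centroid to the common (mean) centroid and scaling matches each
#' configuration's centroid size to the mean size, so values stay on the
#' input scale; rotations are then alternated with consensus updates until
#' the residual sum of squares stops decreasing. A final single global
#' factor matches the output grand mean to the input's.
#'
#' @param m An `ExpressionMatrix` whose columns are complete replicate sets.
#' @param design A `StudyDesign`; every group among the matrix columns must
#'   have the same replicate count d >= 2.
#' @param allow_reflection Allow improper rotations (default `FALSE`).
#' @param tol Stop when the residual decrease per sweep falls below this.
#' @param max_iter Sweep cap; non-convergence yields a warning.
#' @return A `NormalizedMatrix` (`method = "gpa"`) carrying `$gpa`, a
#'   `"GpaResult"` with per-group translations, scale factors, accumulated
#'   rotation matrices, the consensus configuration, the residual-sum-of-
#'   squares trace and the iteration count.
#' @export
normalize_gpa <- function(m, design, allow_reflection = FALSE,
                          tol = 1e-10, max_iter = 1000L) {
  d <- design_for(m, design)
  groups <- unique(d$group)
  cols_by_group <- lapply(groups, function(g) {
    idx <- which(d$group == g)
    idx[order(d$replicate[idx])]
  })
  names(cols_by_group) <- groups
  dr <- lengths(cols_by_group)
  if (length(unique(dr)) != 1L)
    stop("groups have unequal replicate counts; configurations are not ",
         "superimposable", call. = FALSE)
  dr <- dr[[1]]
  if (dr < 2L) stop("GPA needs >= 2 replicates per group", call. = FALSE)
  G <- length(groups)

  configs <- lapply(cols_by_group, function(cl) m$values[, cl, drop = FALSE])
  trans <- lapply(configs, colMeans)
  centered <- Map(function(X, t) sweep(X, 2, t), configs, trans)
  sizes <- vapply(centered, function(X) sqrt(sum(X^2)), numeric(1))
  if (any(sizes == 0))
    stop("degenerate (constant) configuration; GPA undefined", call. = FALSE)
  sbar <- mean(sizes)
  scales <- sbar / sizes
  X <- Map(function(C, f) C * f, centered, scales)

  rots <- replicate(G, diag(dr), simplify = FALSE)
  consensus <- Reduce(`+`, X) / G
  rss <- function() sum(vapply(X, function(Z) sum((Z - consensus)^2),
                               numeric(1)))
  trace <- rss()
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    for (g in seq_len(G)) {
      R <- procrustes_rotation(X[[g]], consensus, allow_reflection)
      X[[g]] <- X[[g]] %*% R
      rots[[g]] <- rots[[g]] %*% R
    }
    consensus <- Reduce(`+`, X) / G
    trace <- c(trace, rss())
    iters <- it
    if (abs(trace[it] - trace[it + 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("GPA did not converge within ", max_iter, " sweeps")

  ## write transformed configurations back onto the input scale
  tbar <- Reduce(`+`, trans) / G
  vals <- m$values
  for (g in seq_len(G)) {
    Y <- sweep(X[[g]], 2, tbar, "+")
    vals[, cols_by_group[[g]]] <- Y
  }
  gm_in <- mean(m$values)
  gm_out <- mean(vals)
  phi <- 1
  if (abs(gm_out) > 1e-8) {
    phi <- gm_in / gm_out
    vals <- vals * phi
  } else if (abs(gm_in) > 1e-8) {
    warning("output grand mean is ~0; skipping global rescale")
  }

  gpa <- structure(
    list(groups = groups,
         translations = trans,
         scales = stats::setNames(scales, groups),
         rotations = stats::setNames(rots, groups),
         consensus = consensus,
         rss = trace[length(trace)],
         rss_trace = trace,
         iterations = iters,
         converged = converged,
         global_factor = phi),
    class = "GpaResult"
  )
  new_normalized(m, vals, "gpa",
                 parameters = list(allow_reflection = allow_reflection,
                                   tol = tol, max_iter = max_iter),
                 extra = list(gpa = gpa))
}

#' @export
print.GpaResult <- function(x, ...) {
  cat(sprintf(
    "GpaResult: %d configurations, residual SS %.4g after %d sweep(s)%s\n",
    length(x$groups), x$rss, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}
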