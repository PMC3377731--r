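#' Construct an expression matrix with platform metadata
#'
#' The central container of the package: a numeric matrix of miRNA expression
#' values (rows = miRNAs, columns = samples) together with the scale the
#' values live on, the platform that produced them and the species profiled.
#' Hybridization arrays carry log2 intensities ("higher = more expressed");
#' RT-qPCR cards carry quantification cycles (Cq, "lower = more template").
#' Cells that were undetected but imputed at the platform's detection bound
#' are recorded in `flagged` so smoothers can exclude them.
#'
#' @param values Numeric matrix with unique, non-empty row names (miRNA
#'   identifiers) and unique column names (sample identifiers). All values
#'   must be finite; represent missing wells by imputing the detection bound
#'   and flagging the cell.
#' @param scale One of `"log2_intensity"`, `"cq"`, or `"expression"` (the
#'   uniform orientation produced by [to_expression_scale()]).
#' @param platform `"array"` or `"qpcr"`.
#' @param species `"human"` or `"mouse"`.
#' @param flagged Optional logical matrix of the same shape marking imputed /
#'   censored cells. Defaults to all-`FALSE`.
#' @param cq_constant The constant C used when Cq values were re-oriented as
#'   `C - Cq`; `NULL` unless `scale == "expression"` came from Cq data.
#' @return An object of class `"ExpressionMatrix"`.
#' @examples
#' v <- matrix(rnorm(6, 10), 3, 2,
#'             dimnames = list(paste0("mir-", 1:3), c("s1", "s2")))
#' m <- expression_matrix(v, "log2_intensity", "array", "human")
#' dim(m)
#' @export
expression_matrix <- function(values,
                              scale = c("log2_intensity", "cq", "expression"),
                              platform = c("array", "qpcr"),
                              species = c("human", "mouse"),
                              flagged = NULL,
                              cq_constant = NULL) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  species <- match.arg(species)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  rn <- rownames(values)
  cn <- colnames(values)
  if (nrow(values) == 0L && is.null(rn)) {
    rownames(values) <- rn <- character(0)
  }
  if (is.null(rn) || any(!nzchar(rn)))
    stop("row identifiers must be non-empty miRNA names", call. = FALSE)
  if (anyDuplicated(rn))
    stop("duplicate miRNA identifier(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  if (is.null(cn) || anyDuplicated(cn))
    stop("column identifiers must be present and unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values present; impute at the detection bound and flag ",
         "instead of storing NA/Inf", call. = FALSE)
  if (scale == "cq" && platform != "qpcr")
    stop("scale 'cq' implies platform 'qpcr'", call. = FALSE)
  if (is.null(flagged)) {
    flagged <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  } else {
    if (!is.logical(flagged) || !identical(dim(flagged), dim(values)))
      stop("'flagged' must be a logical matrix matching 'values'",
           call. = FALSE)
    dimnames(flagged) <- dimnames(values)
  }
  structure(
    list(values = values, scale = scale, platform = platform,
         species = species, flagged = flagged, cq_constant = cq_constant),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' Subset an ExpressionMatrix by rows and/or columns
#'
#' @param x An `ExpressionMatrix`.
#' @param i,j Row / column indices (any form accepted by matrix subsetting).
#' @param ... Ignored.
#' @return The subsetted `ExpressionMatrix`.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE], x$scale, x$platform,
                    x$species, flagged = x$flagged[i, j, drop = FALSE],
                    cq_constant = x$cq_constant)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d miRNAs x %d samples (%s, %s, scale=%s)\n",
              nrow(x$values), ncol(x$values), x$platform, x$species, x$scale))
  if (any(x$flagged))
    cat(sprintf("  %d flagged (imputed/censored) cells\n", sum(x$flagged)))
  n <- min(4L, nrow(x$values))
  p <- min(6L, ncol(x$values))
  print(round(x$values[seq_len(n), seq_len(p), drop = FALSE], 3))
  invisible(x)
}

#' Construct a study design table
#'
#' Maps each sample to its biological group, replicate index, species and
#' platform. The default experiment compares three muscle-cell states
#' (myoblasts `MB`, myotubes `MT`, and TNF-alpha-treated myotubes `MT_TNF`)
#' in triplicate on two platforms.
#'
#' @param sample Character vector of sample identifiers (matrix column names).
#' @param group Group label per sample.
#' @param replicate Integer replicate index (>= 1) within the group.
#' @param species `"human"` or `"mouse"` per sample.
#' @param platform `"array"` or `"qpcr"` per sample.
#' @return A data frame of class `"StudyDesign"`.
#' @export
study_design <- function(sample, group, replicate, species, platform) {
  d <- data.frame(sample = as.character(sample),
                  group = as.character(group),
                  replicate = as.integer(replicate),
                  species = as.character(species),
                  platform = as.character(platform),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample))
    stop("duplicate sample identifiers in design", call. = FALSE)
  if (any(d$replicate < 1L))
    stop("replicate indices must be >= 1", call. = FALSE)
  if (!all(d$species %in% c("human", "mouse")))
    stop("unknown species in design", call. = FALSE)
  if (!all(d$platform %in% c("array", "qpcr")))
    stop("unknown platform in design", call. = FALSE)
  cell <- interaction(d$group, d$species, d$platform, drop = TRUE)
  if (any(table(cell) < 2L))
    stop("every (group, species, platform) cell needs >= 2 replicates",
         call. = FALSE)
  class(d) <- c("StudyDesign", "data.frame")
  d
}

## Design rows for the columns of m, in column order; validates coverage.
design_for <- function(m, design) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- match(colnames(m$values), design$sample)
  if (anyNA(idx))
    stop("sample(s) missing from design: ",
         paste(colnames(m$values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  d <- as.data.frame(design)[idx, , drop = FALSE]
  rownames(d) <- NULL
  if (any(table(d$group) < 2L))
    stop("each group must have >= 2 replicates among the matrix columns",
         call. = FALSE)
  d
}
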