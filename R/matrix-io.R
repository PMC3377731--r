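## Reading, validating, filtering and cross-matching expression matrices.

## Cq detection cutoffs per species (vendor-recommended quality criteria).
cq_cutoff <- function(species) {
  switch(species,
         human = 35,
         mouse = 32,
         stop("no Cq cutoff defined for species '", species, "'",
              call. = FALSE))
}

## Detection bound used to impute missing cells: zero signal on the array,
## the Cq cutoff on qPCR cards.
detection_bound <- function(platform, species, scale) {
  if (platform == "array") return(0)
  if (scale == "cq") return(cq_cutoff(species))
  stop("cannot impute qPCR values on scale '", scale, "'", call. = FALSE)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8 TSV whose first column holds miRNA identifiers (header
#' cell conventionally `"mirna"`) and whose remaining columns are samples.
#' `NA` cells are allowed: they are imputed at the platform's detection bound
#' (0 for arrays, the species Cq cutoff for qPCR) and flagged.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   scale = c("log2_intensity", "cq"),
                                   platform = c("array", "qpcr"),
                                   species = c("human", "mouse")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  species <- match.arg(species)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("no data rows in '", path, "'", call. = FALSE)
  if (ncol(raw) < 2L)
    stop("malformed header in '", path,
         "': need an ID column plus >= 1 sample column", call. = FALSE)
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate miRNA identifier(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  num <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(num), dim = dim(num),
                                 dimnames = list(ids, colnames(num))))
  bad <- is.na(vals) & !is.na(num) & !(trimws(num) %in% "")
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at miRNA '%s', sample '%s'",
                 ids[w[1]], colnames(num)[w[2]]), call. = FALSE)
  }
  flagged <- is.na(vals)
  if (any(flagged))
    vals[flagged] <- detection_bound(platform, species, scale)
  expression_matrix(vals, scale, platform, species, flagged = flagged)
}

#' Write an expression matrix as TSV
#'
#' Flagged (imputed) cells are written back as `NA`.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  v <- m$values
  v[m$flagged] <- NA
  df <- data.frame(mirna = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design TSV
#'
#' Columns required: `sample`, `group`, `replicate`, `species`, `platform`.
#'
#' @param path Path to the TSV file.
#' @return A [study_design()] object.
#' @export
read_study_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "group", "replicate", "species", "platform")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  study_design(d$sample, d$group, d$replicate, d$species, d$platform)
}

#' Read a two-column synonym table (alias, canonical)
#'
#' @param path Path to a TSV with columns `alias` and `canonical`.
#' @return A named character vector mapping alias to canonical name.
#' @export
read_synonym_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("synonym table needs two columns", call. = FALSE)
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Filter miRNAs by the platform-specific detection rule
#'
#' A miRNA is retained if it is detected in at least two replicates of at
#' least one biological group. Detection means a signal greater than zero on
#' the array platform, or a Cq below the species cutoff (35 human, 32 mouse)
#' on the qPCR platform. Flagged (imputed) cells never count as detected.
#' Requiring only one group preserves condition-specific miRNAs (e.g. a
#' miRNA switched on only in myotubes) for differential testing.
#'
#' @param m An `ExpressionMatrix` (any scale; qPCR matrices already
#'   re-oriented by [to_expression_scale()] are handled).
#' @param design A `StudyDesign` covering the columns of `m`.
#' @return The row-subset `ExpressionMatrix`; the identifiers of dropped
#'   rows are attached as `attr(, "dropped")`.
#' @export
filter_detected <- function(m, design) {
  d <- design_for(m, design)
  det <- detected_cells(m)
  keep <- rep(FALSE, nrow(m$values))
  for (g in unique(d$group)) {
    cols <- which(d$group == g)
    keep <- keep | rowSums(det[, cols, drop = FALSE]) >= 2L
  }
  out <- m[which(keep), ]
  attr(out, "dropped") <- rownames(m$values)[!keep]
  out
}

## Logical matrix of detected cells under the platform rule.
detected_cells <- function(m) {
  if (m$platform == "array") {
    det <- m$values > 0
  } else if (m$scale == "cq") {
    det <- m$values < cq_cutoff(m$species)
  } else if (m$scale == "expression" && !is.null(m$cq_constant)) {
    det <- m$values > m$cq_constant - cq_cutoff(m$species)
  } else {
    stop("cannot evaluate qPCR detection on scale '", m$scale, "'",
         call. = FALSE)
  }
  det & !m$flagged
}

#' Canonicalize miRNA identifiers for cross-platform matching
#'
#' Lower-cases the name and strips the species prefix (`hsa-`, `mmu-`),
#' absorbing miRBase-version name drift between platforms.
#'
#' @param ids Character vector of miRNA identifiers.
#' @return Canonical identifiers.
#' @export
canonical_mirna_id <- function(ids) {
  sub("^(hsa|mmu)-", "", tolower(trimws(ids)))
}

#' Restrict two matrices to their common miRNA subset
#'
#' Identifiers are canonicalized ([canonical_mirna_id()]) and an optional
#' synonym map (alias -> canonical) is applied before intersecting. Both
#' returned matrices carry the shared canonical identifiers as row names, in
#' identical order.
#'
#' @param a,b `ExpressionMatrix` objects of the same species.
#' @param synonym_table Optional named character vector (alias -> canonical).
#' @return A list with elements `a` and `b`, row-aligned.
#' @export
match_common_subset <- function(a, b, synonym_table = NULL) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  if (!identical(a$species, b$species))
    stop("matrices must be from the same species", call. = FALSE)
  canon <- function(ids) {
    x <- canonical_mirna_id(ids)
    if (!is.null(synonym_table)) {
      map <- stats::setNames(canonical_mirna_id(synonym_table),
                             canonical_mirna_id(names(synonym_table)))
      hit <- x %in% names(map)
      x[hit] <- unname(map[x[hit]])
    }
    x
  }
  ca <- canon(rownames(a$values))
  cb <- canon(rownames(b$values))
  if (anyDuplicated(ca) || anyDuplicated(cb))
    stop("canonicalization produced duplicate identifiers; refine the ",
         "synonym table", call. = FALSE)
  common <- intersect(ca, cb)
  if (!length(common)) stop("empty identifier intersection", call. = FALSE)
  sub_a <- a[match(common, ca), ]
  sub_b <- b[match(common, cb), ]
  rownames(sub_a$values) <- rownames(sub_a$flagged) <- common
  rownames(sub_b$values) <- rownames(sub_b$flagged) <- common
  list(a = sub_a, b = sub_b)
}

#' Re-orient Cq values to a common expression scale
#'
#' Normalization and differential-expression internals assume "higher =
#' more expressed". Cq values are re-oriented as `e = C - Cq` with a fixed
#' constant `C` (default 40, the usual cycle ceiling), which is an
#' order-reversing bijection; the constant is recorded so fold-change
#' reporting can invert the transform. log2-intensity matrices pass through
#' unchanged.
#'
#' @param m An `ExpressionMatrix`.
#' @param C Orientation constant (default 40).
#' @return An `ExpressionMatrix` on scale `"expression"` (Cq input) or the
#'   input unchanged (log2 input).
#' @export
to_expression_scale <- function(m, C = 40) {
  if (m$scale == "expression")
    stop("matrix is already on the expression scale", call. = FALSE)
  if (m$scale == "log2_intensity") return(m)
  expression_matrix(C - m$values, "expression", m$platform, m$species,
                    flagged = m$flagged, cq_constant = C)
}
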