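## Serialisation of a BenchmarkReport: tidy TSVs, JSON and figures.

write_tsv <- function(df, path, rownames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rownames,
                     col.names = if (rownames) NA else TRUE)
  path
}

#' Box plots of signal distributions across normalization methods
#'
#' One panel per method, samples on the x axis — the usual visual check
#' that normalization made per-sample distributions comparable.
#'
#' @param norm_list Named list of `NormalizedMatrix` objects (one per
#'   method) sharing columns.
#' @param main Overall title.
#' @export
plot_signal_distributions <- function(norm_list, main = "") {
  k <- length(norm_list)
  nc <- min(4L, k)
  nr <- ceiling(k / nc)
  old <- graphics::par(mfrow = c(nr, nc), mar = c(4, 3, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(norm_list)) {
    graphics::boxplot(norm_list[[nm]]$values, las = 2, cex.axis = 0.6,
                      main = nm, outline = FALSE)
  }
  graphics::mtext(main, outer = TRUE, line = -1.2)
  invisible(NULL)
}

#' Heatmap of a concordance matrix
#'
#' @param cm A `"ConcordanceMatrix"`.
#' @param main Title.
#' @export
plot_concordance_heatmap <- function(cm, main = "Jaccard concordance") {
  J <- cm$jaccard
  old <- graphics::par(mar = c(6, 6, 3, 2))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("firebrick", "white"))(100)
  graphics::image(seq_len(ncol(J)), seq_len(nrow(J)),
                  t(J[rev(seq_len(nrow(J))), , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(ncol(J)), colnames(J), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(J)), rev(rownames(J)), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(nrow(J))) for (j in seq_len(ncol(J)))
    graphics::text(j, nrow(J) - i + 1, sprintf("%.2f", J[i, j]),
                   cex = 0.7)
  invisible(NULL)
}

## Report fields serialised into report.json (matrices/figures excluded).
report_json_payload <- function(r) {
  cm_json <- function(cm) if (is.null(cm)) NULL else
    list(jaccard = as.data.frame(cm$jaccard),
         n_intersection = as.data.frame(cm$n_intersection),
         n_union = as.data.frame(cm$n_union),
         mode = cm$mode, platforms = cm$platforms)
  list(meta = r$meta,
       sd_table = r$sd_table, auc_table = r$auc_table,
       sig_table = r$sig_table,
       compression = r$compression, symmetry = r$symmetry,
       retention = r$retention,
       concordance_intra = lapply(r$concordance_intra, cm_json),
       concordance_inter = cm_json(r$concordance_inter),
       failures = r$failures)
}

#' Write a benchmark report to disk
#'
#' Emits tidy TSV tables (SD, AUC, significant counts, Jaccard matrices,
#' compression, symmetry), a machine-readable `report.json` and PNG figures
#' (signal-distribution box plots per species and platform, concordance
#' heatmaps).
#'
#' @param r A `"BenchmarkReport"`.
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures (default `TRUE`).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(r, out_dir, figures = TRUE) {
  stopifnot(inherits(r, "BenchmarkReport"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)

  files <- c(files, write_tsv(r$sd_table, p("sd_summary.tsv")))
  files <- c(files, write_tsv(r$sd_cells, p("sd_cells.tsv")))
  files <- c(files, write_tsv(r$auc_table, p("auc_summary.tsv")))
  files <- c(files, write_tsv(r$sig_table, p("significant_counts.tsv")))
  if (!is.null(r$compression))
    files <- c(files, write_tsv(r$compression, p("compression.tsv")))
  if (!is.null(r$symmetry))
    files <- c(files, write_tsv(r$symmetry, p("symmetry.tsv")))
  files <- c(files, write_tsv(r$retention, p("retention.tsv")))
  for (pl in names(r$concordance_intra))
    files <- c(files, write_tsv(
      as.data.frame(r$concordance_intra[[pl]]$jaccard),
      p(sprintf("jaccard_intra_%s.tsv", pl)), rownames = TRUE))
  if (!is.null(r$concordance_inter))
    files <- c(files, write_tsv(
      as.data.frame(r$concordance_inter$jaccard),
      p("jaccard_inter.tsv"), rownames = TRUE))

  json_path <- p("report.json")
  jsonlite::write_json(report_json_payload(r), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, json_path)

  if (figures) {
    for (sp in names(r$normalized)) {
      for (pl in names(r$normalized[[sp]])) {
        if (!length(r$normalized[[sp]][[pl]])) next
        f <- p(sprintf("signal_distributions_%s_%s.png", sp, pl))
        grDevices::png(f, width = 1200, height = 800)
        plot_signal_distributions(r$normalized[[sp]][[pl]],
                                  main = paste(sp, pl))
        grDevices::dev.off()
        files <- c(files, f)
      }
    }
    for (pl in names(r$concordance_intra)) {
      f <- p(sprintf("jaccard_heatmap_%s.png", pl))
      grDevices::png(f, width = 800, height = 700)
      plot_concordance_heatmap(r$concordance_intra[[pl]],
                               main = paste("Intra-platform Jaccard,", pl))
      grDevices::dev.off()
      files <- c(files, f)
    }
    if (!is.null(r$concordance_inter)) {
      f <- p("jaccard_heatmap_inter.png")
      grDevices::png(f, width = 800, height = 700)
      plot_concordance_heatmap(r$concordance_inter,
                               main = "Inter-platform Jaccard")
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Validate a written report.json against the shipped schema
#'
#' The schema (`inst/extdata/report-schema.json`) lists the required
#' top-level keys and the required columns of each table.
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "mirnorm"))
  doc <- jsonlite::read_json(path)
  problems <- character(0)
  for (key in unlist(schema$required)) {
    if (!key %in% names(doc))
      problems <- c(problems, paste("missing key:", key))
  }
  for (tab in names(schema$table_columns)) {
    if (!tab %in% names(doc) || !length(doc[[tab]])) next
    have <- names(doc[[tab]][[1]])
    need <- unlist(schema$table_columns[[tab]])
    miss <- setdiff(need, have)
    if (length(miss))
      problems <- c(problems,
                    paste0(tab, " misses column(s): ",
                           paste(miss, collapse = ", ")))
  }
  if (length(problems)) problems else TRUE
}
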