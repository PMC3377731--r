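## Full benchmark: simulate/load -> filter -> normalize x methods ->
## SAM per contrast -> evaluation tables.

#' Benchmark configuration
#'
#' Declarative description of a full comparison run. Either build it in R or
#' load it from a YAML file with the same field names via
#' [run_benchmark()].
#'
#' @param seed Master seed; every random stage derives from it.
#' @param species Species to simulate (default both).
#' @param methods Normalization methods to compare (see
#'   [normalize_matrix()]).
#' @param contrasts List of group pairs (default differentiation
#'   `MB -> MT` and cytokine treatment `MT -> MT_TNF`).
#' @param fdr_target FDR level for significant sets (default 0.05).
#' @param n_perm Permutation cap for SAM (the 3v3 design enumerates all 20).
#' @param fc_method Method whose normalized common-subset data feeds the
#'   fold-change compression and symmetry analyses (default `"loessm"`).
#' @param simulation Named list of overrides for [simulation_config()]
#'   (e.g. `n_mirnas`).
#' @return A list of class `"BenchmarkConfig"`.
#' @export
benchmark_config <- function(seed = 1L,
                             species = c("human", "mouse"),
                             methods = c("none", "rgi", "geomean",
                                         "quantile", "inv", "loess",
                                         "loessm", "gpa"),
                             contrasts = list(c("MB", "MT"),
                                              c("MT", "MT_TNF")),
                             fdr_target = 0.05,
                             n_perm = 1000L,
                             fc_method = "loessm",
                             simulation = list()) {
  species <- match.arg(species, several.ok = TRUE)
  methods <- match.arg(methods, c("none", "rgi", "geomean", "quantile",
                                  "inv", "loess", "loessm", "gpa"),
                       several.ok = TRUE)
  if (!is.list(contrasts) || !all(lengths(contrasts) == 2L))
    stop("contrasts must be a list of group pairs", call. = FALSE)
  if (fdr_target <= 0 || fdr_target > 1)
    stop("fdr_target must lie in (0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), species = species,
                 methods = methods, contrasts = contrasts,
                 fdr_target = fdr_target, n_perm = as.integer(n_perm),
                 fc_method = fc_method, simulation = simulation),
            class = "BenchmarkConfig")
}

## Load a BenchmarkConfig from a YAML file.
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$contrasts)) y$contrasts <- lapply(y$contrasts, unlist)
  do.call(benchmark_config, y)
}

## Hash of the resolved configuration for run provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

## Normalize with per-method argument plumbing; errors bubble to caller.
apply_method <- function(m, method, design) {
  normalize_matrix(m, method, design = design)
}

#' Run the full normalization benchmark
#'
#' Simulates a paired array/qPCR study per species (seeded from the master
#' seed), applies the detection filters, re-orients Cq data, matches the
#' cross-platform common subset, normalizes with every configured method,
#' runs SAM per contrast and assembles the evaluation tables: mean
#' inter-replicate SDs, AUC against the generator's ground truth (platform-
#' specific and common subsets), significant counts, intra- and
#' inter-platform Jaccard concordance, fold-change compression regressions
#' and symmetry statistics. Failures of individual method cells are
#' isolated and recorded in `$failures`.
#'
#' @param config A [benchmark_config()] or the path to a YAML file with the
#'   same fields.
#' @return A list of class `"BenchmarkReport"`; see [write_report()] for
#'   serialisation.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  if (is.character(config)) config <- read_benchmark_config(config)
  stopifnot(inherits(config, "BenchmarkConfig"))
  ctags <- vapply(config$contrasts, paste, "", collapse = "_vs_")

  sd_cells <- auc_cells <- sig_cells <- NULL
  de_specific <- de_common <- list()
  compression <- symmetry <- retention <- NULL
  failures <- list()
  normalized <- list()

  fail <- function(where, e) {
    failures[[length(failures) + 1L]] <<-
      list(cell = where, error = conditionMessage(e))
    NULL
  }

  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    sim_args <- utils::modifyList(
      config$simulation,
      list(species = sp, seed = config$seed + si - 1L))
    cfg_s <- do.call(simulation_config, sim_args)
    study <- simulate_study(cfg_s)

    arr <- filter_detected(study$array, study$design)
    qpf <- filter_detected(study$qpcr, study$design)
    qpe <- to_expression_scale(qpf, C = cfg_s$cq_constant)
    common <- match_common_subset(arr, qpe)
    retention <- rbind(retention, data.frame(
      species = sp,
      array_retained = nrow(arr$values),
      qpcr_retained = nrow(qpe$values),
      common = nrow(common$a$values), stringsAsFactors = FALSE))

    truth_by_ct <- lapply(config$contrasts,
                          function(ct) ground_truth(study, ct))
    names(truth_by_ct) <- ctags

    mats <- list(array = arr, qpcr = qpe)
    normalized[[sp]] <- list(array = list(), qpcr = list())
    fc_tabs <- list()  # [[ctag]][[platform]] fold-change tables

    for (p in names(mats)) {
      for (meth in config$methods) {
        nm <- tryCatch(apply_method(mats[[p]], meth, study$design),
                       error = function(e)
                         fail(paste("specific", sp, p, meth, sep = "/"), e))
        if (is.null(nm)) next
        normalized[[sp]][[p]][[meth]] <- nm
        vs <- inter_replicate_sd(nm, study$design)
        sd_cells <- rbind(sd_cells, vs$cells)
        for (ci in seq_along(config$contrasts)) {
          ct <- config$contrasts[[ci]]
          tag <- ctags[ci]
          sam <- sam_two_class(nm, study$design, ct,
                               n_perm = config$n_perm, seed = config$seed,
                               fdr_target = config$fdr_target)
          lab <- rownames(nm$values) %in% truth_by_ct[[tag]]$ids
          auc <- if (any(lab) && !all(lab))
            roc_auc(abs(sam$d), lab)$auc else NA_real_
          auc_cells <- rbind(auc_cells, data.frame(
            method = meth, platform = p, subset = "platform_specific",
            species = sp, contrast = tag, auc = auc,
            stringsAsFactors = FALSE))
          sig_cells <- rbind(sig_cells, data.frame(
            method = meth, platform = p, species = sp, contrast = tag,
            n_significant = length(sam$significant),
            stringsAsFactors = FALSE))
          de_specific[[length(de_specific) + 1L]] <-
            list(method = meth, platform = p, contrast = tag,
                 species = sp, ids = sam$significant)
        }
      }
    }

    ## common-subset analyses (inter-platform comparability)
    cm <- list(array = common$a, qpcr = common$b)
    for (p in names(cm)) {
      for (meth in config$methods) {
        nm <- tryCatch(apply_method(cm[[p]], meth, study$design),
                       error = function(e)
                         fail(paste("common", sp, p, meth, sep = "/"), e))
        if (is.null(nm)) next
        for (ci in seq_along(config$contrasts)) {
          ct <- config$contrasts[[ci]]
          tag <- ctags[ci]
          sam <- sam_two_class(nm, study$design, ct,
                               n_perm = config$n_perm, seed = config$seed,
                               fdr_target = config$fdr_target)
          lab <- rownames(nm$values) %in% truth_by_ct[[tag]]$ids
          auc <- if (any(lab) && !all(lab))
            roc_auc(abs(sam$d), lab)$auc else NA_real_
          auc_cells <- rbind(auc_cells, data.frame(
            method = meth, platform = p, subset = "common", species = sp,
            contrast = tag, auc = auc, stringsAsFactors = FALSE))
          de_common[[length(de_common) + 1L]] <-
            list(method = meth, platform = p, contrast = tag,
                 species = sp, ids = sam$significant)
          if (meth == config$fc_method) {
            fc <- delta_delta(nm, study$design, ct)
            if (is.null(fc_tabs[[tag]])) fc_tabs[[tag]] <- list()
            fc_tabs[[tag]][[p]] <- fc
            sy <- symmetry_stats(fc)
            symmetry <- rbind(symmetry, data.frame(
              platform = p, species = sp, contrast = tag,
              mean = sy$mean, sd = sy$sd, n = sy$n,
              stringsAsFactors = FALSE))
          }
        }
      }
    }

    for (tag in names(fc_tabs)) {
      pair <- fc_tabs[[tag]]
      if (!is.null(pair$array) && !is.null(pair$qpcr)) {
        reg <- regress_platform_fc(pair$array, pair$qpcr)
        compression <- rbind(compression, data.frame(
          species = sp, contrast = tag, method = config$fc_method,
          slope = reg$slope, intercept = reg$intercept,
          slope_t = reg$slope_t, n = reg$n, stringsAsFactors = FALSE))
      }
    }
  }

  agg <- function(df, value, by) {
    out <- stats::aggregate(df[[value]], df[by], function(v)
      c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE)))
    cbind(out[by], mean = out$x[, "mean"], sd = out$x[, "sd"])
  }
  sd_table <- agg(sd_cells, "mean_sd", c("method", "platform"))
  auc_table <- agg(auc_cells, "auc", c("method", "platform", "subset"))
  sig_table <- agg(sig_cells, "n_significant", c("method", "platform"))

  conc_intra <- list()
  for (p in c("array", "qpcr")) {
    lists_p <- Filter(function(e) e$platform == p, de_specific)
    if (length(lists_p) >= 2L)
      conc_intra[[p]] <- concordance_table(lists_p, mode = "intra")
  }
  conc_inter <- if (length(de_common) >= 2L &&
                    length(unique(vapply(de_common, `[[`, "",
                                         "platform"))) == 2L)
    concordance_table(de_common, mode = "inter") else NULL

  structure(
    list(sd_table = sd_table, sd_cells = sd_cells,
         auc_table = auc_table, auc_cells = auc_cells,
         sig_table = sig_table, sig_cells = sig_cells,
         de_lists = de_specific, de_lists_common = de_common,
         concordance_intra = conc_intra, concordance_inter = conc_inter,
         compression = compression, symmetry = symmetry,
         retention = retention, failures = failures,
         normalized = normalized,
         meta = list(seed = config$seed, methods = config$methods,
                     contrasts = ctags, fdr_target = config$fdr_target,
                     n_perm = config$n_perm, species = config$species,
                     config_hash = config_hash(config),
                     package_version =
                       as.character(utils::packageVersion("mirnorm")))),
    class = "BenchmarkReport"
  )
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("BenchmarkReport\n")
  cat("  seed:", x$meta$seed, " hash:", x$meta$config_hash, "\n")
  cat("  mean inter-replicate SD by method/platform:\n")
  print(x$sd_table, row.names = FALSE)
  if (length(x$failures))
    cat("  ", length(x$failures), "cell(s) failed; see $failures\n")
  invisible(x)
}
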