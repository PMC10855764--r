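#' Read and validate a pipeline configuration
#'
#' The configuration is a JSON document with either a `synthetic` block (a
#' [study_config()] argument list) or an `input` block (paths to peak, ladder
#' and metadata CSVs), plus optional `chemometrics` (`vip_cutoff`, `max_lv`,
#' `threshold`) and `validation` (`outer_k`, `inner_k`, `n_repetitions`,
#' `permutation_iterations`) blocks and a mandatory top-level `seed`.
#'
#' @param path Path to a JSON config file, or a list with the same structure.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  if (!is.list(cfg)) stop("config must be a JSON object", call. = FALSE)
  has_syn <- !is.null(cfg$synthetic)
  has_real <- !is.null(cfg$input)
  if (has_syn == has_real) {
    stop("config error at /: exactly one of 'synthetic' or 'input' required",
         call. = FALSE)
  }
  if (is.null(cfg$seed)) {
    stop("config error at /seed: a seed is mandatory", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$chemometrics <- utils::modifyList(
    list(vip_cutoff = 1.2, max_lv = 10L, threshold = 0.5),
    as.list(cfg$chemometrics))
  cfg$validation <- utils::modifyList(
    list(outer_k = 5L, inner_k = 5L, n_repetitions = 20L,
         permutation_iterations = 1000L),
    as.list(cfg$validation))
  structure(cfg, class = "pipeline_config")
}

provenance_record <- function(config, out_dir) {
  rec <- list(package = "voccheese",
              version = as.character(utils::packageVersion("voccheese")),
              seed = config$seed,
              config = unclass(config))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

stage_banner <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " ")))
}

#' Simulate a synthetic study and write its artifacts
#'
#' Generates the configured VOC feature table and writes `feature_table.csv`,
#' the ground-truth marker list (`markers_truth.json`), the compound class map
#' (`class_map.csv`) and a provenance record (config + seed + version) to
#' `out_dir`. Identical configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or path to one) with a `synthetic`
#'   block.
#' @param out_dir Output directory, created if absent.
#' @return The generated `voc_table`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$synthetic)) {
    stop("config error at /synthetic: block required for simulation",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- config$synthetic
  args$seed <- args$seed %||% config$seed
  sc <- do.call(study_config, args)
  stage_banner("simulate", sc$cheese, "seed", sc$seed)
  tab <- generate_voc_table(sc)
  write_feature_table(tab, file.path(out_dir, "feature_table.csv"))
  jsonlite::write_json(attr(tab, "discriminant"),
                       file.path(out_dir, "markers_truth.json"))
  cm <- attr(tab, "class_map")
  utils::write.csv(data.frame(compound = names(cm), class = unname(cm)),
                   file.path(out_dir, "class_map.csv"), row.names = FALSE)
  provenance_record(config, out_dir)
  invisible(tab)
}

#' Run the discrimination workflow end-to-end
#'
#' Executes autoscaling, PCA with per-dose confidence ellipses, one-vs-rest
#' PLS-DA, VIP marker selection, double cross-validation and the permutation
#' test on a feature table, writing `pca_scores.csv`, `ellipses.json`,
#' `vip.csv`, `markers_selected.csv`, `cv_report.csv`,
#' `permutation.csv` and a provenance record to `out_dir`.
#'
#' @param config A [pipeline_config()] or path to one.
#' @param table Optional `voc_table`; if missing it is read from
#'   `config$input$feature_table` or generated from the `synthetic` block.
#' @param out_dir Output directory.
#' @return List with the fitted objects (`pca`, `ellipses`, `plsda`, `vip`,
#'   `markers`, `cv`, `permutation`), invisibly.
#' @export
run_discriminate <- function(config, out_dir, table = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(table)) {
    table <- if (!is.null(config$input)) {
      read_feature_table(config$input$feature_table)
    } else {
      run_simulate(config, out_dir)
    }
  }
  X <- voc_matrix(table)
  labels <- dose_class_labels(table$dose_kgy)
  if (length(unique(labels)) < 2L) {
    stop("discriminate stage: need at least 2 dose classes", call. = FALSE)
  }
  cm <- config$chemometrics; vl <- config$validation

  stage_banner("autoscale+pca", nrow(X), "x", ncol(X))
  scaled <- autoscale_quiet(X)
  pc <- pca(scaled, n_components = 2L)
  utils::write.csv(data.frame(sample_id = table$sample_id, dose = labels,
                              pc$scores),
                   file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  ell <- lapply(split(seq_len(nrow(X)), labels), function(i) {
    e <- confidence_ellipse(pc$scores[i, , drop = FALSE], level = 0.95)
    list(center = e$center, shape = e$shape, level = e$level)
  })
  jsonlite::write_json(ell, file.path(out_dir, "ellipses.json"),
                       auto_unbox = TRUE, digits = NA)

  stage_banner("plsda+vip")
  binary <- ifelse(table$dose_kgy == 0, "non_irradiated", "irradiated")
  model <- fit_plsda(X, labels, n_lv = min(cm$max_lv, 5L))
  vip <- vip_max(model)
  markers <- select_markers(vip, cutoff = cm$vip_cutoff)
  utils::write.csv(data.frame(compound = names(vip), vip = unname(vip)),
                   file.path(out_dir, "vip.csv"), row.names = FALSE)
  utils::write.csv(data.frame(compound = names(markers), vip = unname(markers)),
                   file.path(out_dir, "markers_selected.csv"), row.names = FALSE)

  stage_banner("double-cv", vl$n_repetitions, "repetitions")
  cv <- double_cross_validate(X, labels, outer_k = vl$outer_k,
                              inner_k = vl$inner_k,
                              n_repetitions = vl$n_repetitions,
                              max_lv = cm$max_lv, seed = config$seed,
                              threshold = cm$threshold)
  utils::write.csv(cv_report_table(cv), file.path(out_dir, "cv_report.csv"),
                   row.names = FALSE)

  stage_banner("permutation", vl$permutation_iterations, "iterations")
  perm <- permutation_test(X, binary,
                           n_iterations = vl$permutation_iterations,
                           outer_k = vl$outer_k, inner_k = vl$inner_k,
                           max_lv = min(cm$max_lv, 3L),
                           seed = config$seed + 1L)
  utils::write.csv(data.frame(iteration = seq_along(perm$misclassified),
                              misclassified = perm$misclassified),
                   file.path(out_dir, "permutation.csv"), row.names = FALSE)
  provenance_record(config, out_dir)
  invisible(list(pca = pc, ellipses = ell, plsda = model, vip = vip,
                 markers = markers, cv = cv, permutation = perm))
}

#' Dose labels as class strings
#'
#' @param dose_kgy Numeric dose vector.
#' @return Character labels (`"0_kGy"`, `"2_kGy"`, ...).
#' @export
dose_class_labels <- function(dose_kgy) {
  sprintf("%g_kGy", dose_kgy)
}

#' Run the extraction-condition optimization workflow
#'
#' Compares fibers on the VOC-count response, fits second-order surfaces to
#' both responses for the selected fiber and maximizes the global
#' desirability, writing `dom_report.json` to `out_dir`.
#'
#' @param responses Named list (one element per fiber) of data frames with
#'   columns `y1_total_area` and `y2_n_vocs`, rows aligned with the design.
#' @param design A `ccd_design` (default: the two-factor 11-run layout with
#'   temperature 30--50 C and time 20--60 min).
#' @param out_dir Output directory.
#' @param resolution Desirability grid resolution per factor.
#' @return List with `fiber` (the [compare_fibers()] result), `surfaces`,
#'   `dom` (a `dom_result`), invisibly.
#' @export
run_optimize_doe <- function(responses, out_dir,
                             design = generate_ccd(
                               list(doe_factor("temp_c", 30, 50),
                                    doe_factor("time_min", 20, 60))),
                             resolution = 201L) {
  stopifnot(is.list(responses), !is.null(names(responses)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_runs <- nrow(design$coded)
  for (nm in names(responses)) {
    if (nrow(responses[[nm]]) != n_runs) {
      stop("fiber ", nm, " covers ", nrow(responses[[nm]]), " of ", n_runs,
           " design runs", call. = FALSE)
    }
  }
  stage_banner("fiber-comparison")
  sel <- compare_fibers(lapply(responses, `[[`, "y2_n_vocs"))
  resp <- responses[[sel$selected]]

  stage_banner("surface-fit+dom", "fiber", sel$selected)
  surfaces <- list(y1 = fit_response_surface(design, resp$y1_total_area),
                   y2 = fit_response_surface(design, resp$y2_n_vocs))
  dom <- optimize_dom(surfaces, design$factors, resolution = resolution)
  report <- list(
    fiber = sel,
    coefficients = lapply(surfaces, function(s) as.list(s$coefficients)),
    r_squared = lapply(surfaces, `[[`, "r_squared"),
    d_at_optimum = as.list(dom$d_at_optimum),
    D_max = dom$D_max,
    optimum = as.list(dom$optimum),
    tie = dom$tie)
  jsonlite::write_json(report, file.path(out_dir, "dom_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fiber = sel, surfaces = surfaces, dom = dom))
}
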