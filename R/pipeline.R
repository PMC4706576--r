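#' Pipeline configuration
#'
#' Aggregates the stage parameters: geometry (100 segments, relaxation
#' tolerance), statistics (alpha, retention threshold, Bonferroni family
#' size), SVM (cost, folds, standardization) and the synthetic generator
#' configuration, plus the run seed.
#'
#' @param n_segments radial segments for extraction (99 slices when 100).
#' @param tol_mm,max_iter centreline relaxation controls.
#' @param alpha significance level for all inferential stages.
#' @param retain_threshold PCA retention threshold (fraction of variance).
#' @param bonferroni_m number of tests corrected for (the 99 centiles).
#' @param svm_C,folds,standardize classifier controls.
#' @param generator a [generator_config()].
#' @param seed run seed (generator, folds).
#' @return A list of class `cc_pipeline_config`.
#' @export
pipeline_config <- function(n_segments = 100L, tol_mm = 0.01, max_iter = 100L,
                            alpha = 0.05, retain_threshold = 0.01,
                            bonferroni_m = 99L, svm_C = 1.0, folds = 10L,
                            standardize = TRUE,
                            generator = generator_config(), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(n_segments = as.integer(n_segments), tol_mm = tol_mm,
                 max_iter = as.integer(max_iter), alpha = alpha,
                 retain_threshold = retain_threshold,
                 bonferroni_m = as.integer(bonferroni_m), svm_C = svm_C,
                 folds = as.integer(folds), standardize = standardize,
                 generator = generator, seed = as.integer(seed)),
            class = "cc_pipeline_config")
}

write_provenance <- function(out_dir, config, seed) {
  echo <- list(package = "ccmorph",
               version = as.character(utils::packageVersion("ccmorph")),
               seed = seed, config = config)
  jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
}

#' Simulate a synthetic cohort and write it to disk
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param seed overrides `config$seed` when given.
#' @param write_masks also render and write one PNG mask per subject
#'   (0.25 mm spacing, default arch).
#' @return The simulated [cc_cohort()], invisibly when writing.
#' @export
run_simulate <- function(config = generator_config(), out_dir = NULL,
                         seed = NULL, write_masks = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_provenance(out_dir, config, config$seed)
    if (write_masks) {
      for (i in seq_len(nrow(cohort$widths))) {
        m <- render_mask(cohort$widths[i, ])
        write_mask_png(m, file.path(out_dir,
                                    paste0(cohort$subject_id[i], ".png")))
      }
    }
    return(invisible(cohort))
  }
  cohort
}

#' Extract width profiles from a set of mask files
#'
#' Runs the geometry chain over PNG or NIfTI masks, one CSV row per subject.
#' Per-subject failures are logged as warnings and the run continues; it is
#' an error for every subject to fail.
#'
#' @param mask_files character vector of file paths (`.png`, `.nii`,
#'   `.nii.gz`).
#' @param spacing pixel spacing in mm for PNG masks (NIfTI masks carry
#'   their own); required if any PNG is present.
#' @param out_csv optional output CSV path.
#' @param n_segments,tol_mm,max_iter see [fit_centile_widths()].
#' @return Data frame: subject_id, w01..w99, area, perimeter,
#'   centreline_length, convergence_iters.
#' @export
run_extract <- function(mask_files, spacing = NULL, out_csv = NULL,
                        n_segments = 100L, tol_mm = 0.01, max_iter = 100L) {
  if (is.null(spacing) && any(grepl("\\.png$", mask_files, ignore.case = TRUE)))
    cc_stop("bad-config", "spacing is required for PNG masks")
  rows <- list()
  for (f in mask_files) {
    res <- tryCatch({
      mask <- if (grepl("\\.png$", f, ignore.case = TRUE))
        read_mask_png(f, spacing)
      else read_mask_nifti(f)
      prof <- extract_widths(mask, n_segments = n_segments, tol_mm = tol_mm,
                             max_iter = max_iter)
      df <- as.data.frame(as.list(stats::setNames(prof$widths,
                                                  sprintf("w%02d", 1:99))))
      cbind(data.frame(subject_id = sub("\\.(png|nii|nii\\.gz)$", "",
                                        basename(f), ignore.case = TRUE)),
            df,
            data.frame(area = prof$area, perimeter = prof$perimeter,
                       centreline_length = prof$centreline_length,
                       convergence_iters = prof$convergence$iterations))
    }, error = function(e) {
      cc_warn("subject-failed", sprintf("%s: %s", basename(f), conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    cc_stop("no-subjects", "width extraction failed for every mask")
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Run the statistical analysis chain on a cohort
#'
#' The inferential chain in order: Shapiro-Wilk screens (ages and global
#' measures, when available), paired t-tests of the global measures,
#' PCA/varimax regionalization, factor-score ANOVA (end-taper factors
#' excluded), and the Bonferroni-corrected per-centile comparison. A
#' human-readable summary names the regions significant at `alpha`.
#'
#' @param cohort a [cc_cohort()]; global measures are read from the
#'   `globals` attribute if present.
#' @param out_dir optional output directory for the report files.
#' @param alpha significance level.
#' @param retain_threshold PCA retention threshold.
#' @return List: `normality`, `globals`, `regional` (the
#'   [regionalize()] result), `anova`, `centiles`, `summary` (character).
#' @export
run_analyze <- function(cohort, out_dir = NULL, alpha = 0.05,
                        retain_threshold = 0.01) {
  stopifnot(inherits(cohort, "cc_cohort"))
  if (min(table(cohort$group)) < 2L)
    cc_stop("too-few", "need at least 2 subjects per group")
  normality <- list()
  if (!is.null(cohort$age))
    normality$age <- tryCatch(cc_shapiro(cohort$age), ccmorph_error = identity)
  glb <- attr(cohort, "globals")
  globals <- NULL
  if (!is.null(glb)) {
    for (m in intersect(c("area", "perimeter", "centreline_length"), names(glb)))
      normality[[m]] <- tryCatch(cc_shapiro(glb[[m]]), ccmorph_error = identity)
    globals <- compare_globals(glb, cohort$group, pairing = cohort$pairing)
  }
  regional <- regionalize(cohort, threshold = retain_threshold)
  keep <- !regional$end_taper
  anova <- anova_factor_scores(regional$scores[, keep, drop = FALSE],
                               cohort$group, alpha = alpha)
  centiles <- compare_centiles(cohort, alpha = alpha)
  sig <- anova$factor[anova$significant]
  lines <- c(
    sprintf("Retained %d factor(s); %s flagged as end-taper.",
            regional$retained_k,
            if (any(regional$end_taper))
              paste(colnames(regional$loadings)[regional$end_taper],
                    collapse = ", ") else "none"),
    if (length(sig))
      sprintf("Significant factor-score ANOVA at alpha = %.2f: %s.", alpha,
              paste(sig, collapse = ", "))
    else sprintf("No factor significant at alpha = %.2f.", alpha),
    sprintf("Largest per-centile mean difference %.2f mm at centile %d; %s.",
            attr(centiles, "summary")$max_abs_diff_mm,
            attr(centiles, "summary")$at_centile,
            if (any(centiles$sig_bonferroni))
              "some centiles survive Bonferroni correction"
            else "no centile survives Bonferroni correction"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(centile = 1:99, regional$loadings),
                     file.path(out_dir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(centile = 1:99,
                                region = regional$region_of_centile),
                     file.path(out_dir, "region_map.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = cohort$subject_id,
                                group = cohort$group, regional$scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(anova, file.path(out_dir, "anova.csv"), row.names = FALSE)
    utils::write.csv(centiles, file.path(out_dir, "centile_comparison.csv"),
                     row.names = FALSE)
    if (!is.null(globals))
      utils::write.csv(globals, file.path(out_dir, "global_comparison.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(normality = normality, anova = anova,
           summary = lines,
           explained_fraction = regional$explained_fraction,
           end_taper = regional$end_taper),
      file.path(out_dir, "stats_report.json"),
      auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
    writeLines(lines, file.path(out_dir, "summary.txt"))
  }
  list(normality = normality, globals = globals, regional = regional,
       anova = anova, centiles = centiles, summary = lines)
}

#' Run cross-validated SVM stratification on a cohort
#'
#' @param cohort a [cc_cohort()].
#' @param out_dir optional output directory (`classification_report.json`,
#'   `roc.csv`).
#' @param C,folds,seed,standardize see [classify_cohort()].
#' @return A `cc_classification_report`.
#' @export
run_classify <- function(cohort, out_dir = NULL, C = 1.0, folds = 10L,
                         seed = 1L, standardize = TRUE) {
  if (nlevels(droplevels(cohort$group)) < 2L)
    cc_stop("one-class", "both groups are required for classification")
  rep <- classify_cohort(cohort, C = C, folds = folds, seed = seed,
                         standardize = standardize)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(seed = rep$seed, folds = rep$folds, C = rep$C,
           standardize = rep$standardize,
           accuracy = rep$accuracy, error_rate = rep$error_rate,
           sensitivity = rep$sensitivity, specificity = rep$specificity,
           per_class = rep$per_class,
           confusion = as.data.frame(rep$confusion)),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
    roc <- rbind(cbind(positive = "case", rep$roc$case$points),
                 cbind(positive = "control", rep$roc$control$points))
    utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
  }
  rep
}

#' Run the full pipeline: simulate, analyze, classify
#'
#' End-to-end orchestration on a synthetic cohort, writing every stage
#' report plus a provenance echo (configuration, seed, package version).
#' With a fixed seed the numeric outputs are reproducible byte for byte up
#' to CSV/JSON serialization rounding.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` for in-memory results only.
#' @return List: `cohort`, `analysis`, `classification`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  gen <- config$generator
  gen$seed <- config$seed
  cohort <- run_simulate(gen, out_dir = out_dir)
  analysis <- run_analyze(cohort, out_dir = out_dir, alpha = config$alpha,
                          retain_threshold = config$retain_threshold)
  classification <- run_classify(cohort, out_dir = out_dir, C = config$svm_C,
                                 folds = config$folds, seed = config$seed,
                                 standardize = config$standardize)
  if (!is.null(out_dir)) write_provenance(out_dir, config, config$seed)
  list(cohort = cohort, analysis = analysis, classification = classification)
}
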