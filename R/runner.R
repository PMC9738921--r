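# Orchestration: the per-subject analysis chain, cohort-level feature
# tables for the four feature sets, and the two-arm (with / without PSF
# deconvolution) experiment grid with its artifact tree.

#' Analyse one rendered subject in one reconstruction arm
#'
#' Chain: (optional) Richardson-Lucy deconvolution of the static image and
#' of every dynamic frame, HYPR-LR denoising of the dynamic study, brain
#' reference, threshold segmentation of tumour and striatum, TBR and TTP
#' parametric maps, region features and the two 105-feature radiomics
#' vectors.
#'
#' @param subject output of [render_subject()].
#' @param psfd logical: apply PSF deconvolution?
#' @param dcfg a [deconv_config()].
#' @param hcfg a [hypr_config()].
#' @return list with maps, masks, features.
#' @export
analyze_subject <- function(subject, psfd = FALSE, dcfg = deconv_config(),
                            hcfg = hypr_config()) {
  static <- subject$static
  study <- subject$study
  if (psfd) {
    static <- deconvolve_study(static, dcfg)
    study <- deconvolve_study(study, dcfg)
  }
  study <- hypr_denoise(study, hcfg)
  masks <- subject$masks
  brain_mean <- brain_reference(static, masks$brain)
  tbr <- tbr_map(static, brain_mean)
  tumor <- segment_tumor(static, brain_mean, masks$tumor_region)
  striatum <- segment_striatum(static, masks$striatum_seed)
  ttpm <- ttp_map(study, masks$brain, masks$tumor_region)
  region <- region_features(tbr, study, list(tumor = tumor,
                                             striatum = striatum,
                                             brain = masks$brain))
  fv_tbr <- extract_all(tbr, tumor, "tbr")
  fv_ttp <- extract_all(ttpm, tumor, "ttp")
  list(tbr = tbr, ttp = ttpm, tumor = tumor, striatum = striatum,
       brain_mean = brain_mean, region = region,
       fv_tbr = fv_tbr, fv_ttp = fv_ttp, psfd = psfd)
}

#' Assemble cohort feature tables for the four feature sets
#'
#' * `static`: 94 TBR radiomics + 11 morphological features (105)
#' * `dynamic`: 94 TTP radiomics + 11 morphological features (105)
#' * `static_dynamic`: 94 TBR + 94 TTP + 11 morphological (199)
#' * `region`: 105 TBR-map features + 7 conventional + 2 region-dynamic
#'   features (114)
#'
#' @param analyses list of [analyze_subject()] results (one per subject).
#' @param labels 0/1 class labels.
#' @param psfd arm tag carried into each table.
#' @return named list of [feature_table()] objects.
#' @export
cohort_feature_tables <- function(analyses, labels, psfd = NA) {
  tbr <- do.call(rbind, lapply(analyses, `[[`, "fv_tbr"))
  ttp <- do.call(rbind, lapply(analyses, `[[`, "fv_ttp"))
  reg <- do.call(rbind, lapply(analyses, `[[`, "region"))
  morph_cols <- grep("^morph_", colnames(tbr))
  ttp_rad <- ttp[, -grep("^morph_", colnames(ttp)), drop = FALSE]
  list(
    static = feature_table(tbr, labels, set = "static", psfd = psfd),
    dynamic = feature_table(cbind(tbr[, morph_cols, drop = FALSE], ttp_rad),
                            labels, set = "dynamic", psfd = psfd),
    static_dynamic = feature_table(cbind(tbr, ttp_rad), labels,
                                   set = "static_dynamic", psfd = psfd),
    region = feature_table(cbind(tbr, reg), labels, set = "region",
                           psfd = psfd))
}

#' Experiment configuration
#'
#' @param n_subjects cohort size (default 40).
#' @param class_balance fraction of class-1 subjects (default 0.5).
#' @param phantom a [phantom_spec()] template.
#' @param deconv a [deconv_config()].
#' @param hypr a [hypr_config()].
#' @param cv a [cv_spec()].
#' @param feature_sets subset of c("static","dynamic","static_dynamic","region").
#' @param n_perm permutations per model (0 disables the permutation test).
#' @param n_boot bootstrap draws.
#' @param write_volumes write per-subject NIfTI volumes under `cohort/`.
#' @param seed global seed.
#' @export
experiment_config <- function(n_subjects = 40L, class_balance = 0.5,
                              phantom = phantom_spec(),
                              deconv = deconv_config(),
                              hypr = hypr_config(),
                              cv = cv_spec(repeats = 5L),
                              feature_sets = c("static", "dynamic",
                                               "static_dynamic", "region"),
                              n_perm = 0L, n_boot = 1000L,
                              write_volumes = FALSE, seed = 1L) {
  structure(list(n_subjects = n_subjects, class_balance = class_balance,
                 phantom = phantom, deconv = deconv, hypr = hypr, cv = cv,
                 feature_sets = feature_sets, n_perm = n_perm,
                 n_boot = n_boot, write_volumes = write_volumes,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# rolling polynomial hash of a deparsed object, for provenance stamps
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (ch in s) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the two-arm experiment grid on a synthetic cohort
#'
#' Generates a cohort, analyses every subject with and without PSF
#' deconvolution, builds the feature tables, runs the CV harness per
#' (arm x feature set), computes paired feature-change statistics between
#' arms and the lesion-size dependence of the TBRmax change, and writes
#' all artifacts (CSV feature tables, JSON reports, a summary table) under
#' `out_dir`. The run is a pure function of its configuration.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with tables, reports, change statistics and
#'   the summary data.frame.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = tempfile()) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  hash <- config_hash(unclass(config))
  for (sub in c("cohort", "features", "reports"))
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config_hash = hash)
  jsonlite::write_json(c(meta, list(config = rapply(unclass(config), unclass,
                                                    how = "replace"))),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  cohort <- stage("phantom", generate_cohort(config$n_subjects,
                                             config$class_balance,
                                             config$phantom, config$seed))
  if (config$write_volumes)
    for (s in seq_along(cohort$subjects))
      write_subject(cohort$subjects[[s]],
                    file.path(out_dir, "cohort", sprintf("subject_%02d", s)))

  arms <- c(nopsfd = FALSE, psfd = TRUE)
  tables <- list(); reports <- list()
  for (arm in names(arms)) {
    analyses <- stage(paste0("analysis_", arm),
                      lapply(cohort$subjects, analyze_subject,
                             psfd = arms[[arm]], dcfg = config$deconv,
                             hcfg = config$hypr))
    tables[[arm]] <- stage("features",
                           cohort_feature_tables(analyses, cohort$labels,
                                                 psfd = arms[[arm]]))
    for (set in config$feature_sets) {
      tb <- tables[[arm]][[set]]
      utils::write.csv(data.frame(subject = tb$ids, label = tb$y, tb$X,
                                  check.names = FALSE),
                       file.path(out_dir, "features",
                                 sprintf("%s_%s.csv", set, arm)),
                       row.names = FALSE)
    }
  }

  for (arm in names(arms)) for (set in config$feature_sets) {
    key <- paste(set, arm, sep = "_")
    rep <- stage(paste0("cv_", key), run_cv(tables[[arm]][[set]], config$cv))
    bs <- bootstrap_summary(rep, config$n_boot, seed = config$seed)
    shp <- shap_importance(rep)
    perm <- if (config$n_perm > 0)
      stage(paste0("perm_", key),
            permutation_test(tables[[arm]][[set]], config$cv, config$n_perm,
                             observed = pooled_metrics(rep$predictions)[["auc"]]))
    else NULL
    reports[[key]] <- list(report = rep, bootstrap = bs, shap = shp,
                           permutation = perm)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash, set = set, arm = arm,
           metrics = bs,
           fold_auc = vapply(rep$folds, `[[`, numeric(1), "auc"),
           permutation_p = if (is.null(perm)) NULL else perm$p,
           shap_importance = as.list(shp$importance),
           shap_minimal_set = shp$minimal_set),
      file.path(out_dir, "reports", paste0(key, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  change <- stage("compare", list(
    tbr = paired_change(tables$nopsfd$static, tables$psfd$static),
    ttp = paired_change(tables$nopsfd$dynamic, tables$psfd$dynamic)))
  sdep <- stage("compare", size_dependence(
    tables$nopsfd$region$X[, "MTV"],
    tables$nopsfd$region$X[, "TBR_max"],
    tables$psfd$region$X[, "TBR_max"]))
  for (nm in names(change))
    utils::write.csv(change[[nm]]$features,
                     file.path(out_dir, "reports",
                               paste0("change_", nm, ".csv")),
                     row.names = FALSE)

  summary_df <- do.call(rbind, lapply(names(reports), function(k) {
    bs <- reports[[k]]$bootstrap
    data.frame(model = k, t(stats::setNames(bs$mean, bs$metric)),
               auc_lower = bs$lower[bs$metric == "auc"],
               auc_upper = bs$upper[bs$metric == "auc"])
  }))
  utils::write.csv(summary_df, file.path(out_dir, "reports", "summary.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, tables = tables, reports = reports,
                 change = change, size_dependence = sdep,
                 summary = summary_df, out_dir = out_dir, hash = hash))
}
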