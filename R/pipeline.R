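# End-to-end pipeline: read inputs, assemble patient records, exclude
# suspects, extract features, calibrate, evaluate rules, train and report.

#' Assemble a cohort from contour files, an OCT table and a label table
#'
#' Joins the two modalities by patient id and laterality, excluding
#' suspects and patients with incomplete data, and logging every exclusion
#' with a reason. Contour files are looked up as
#' `<patient_id>_<OD|OS>_<disc|cup>.txt` under `contour_dir`.
#'
#' @param contour_dir directory of contour annotation files (or `NULL` to
#'   skip the fundus modality).
#' @param oct_csv path to the OCT sector table CSV (or `NULL` to skip OCT).
#' @param labels_csv path to the label CSV with columns patient_id,
#'   diagnosis (healthy/glaucoma/suspect), age, sex.
#' @param n_angles angular sampling of the fundus rim profiles.
#' @param cdr_method passed to [compute_cdr()].
#' @return list with `patients` (patient records carrying `oct` and/or
#'   `fundus` [sector_profile()]s, `cdr`, `rdr`) and `exclusions`
#'   (data.frame: patient_id, reason).
#' @export
assemble_cohort <- function(contour_dir = NULL, oct_csv = NULL, labels_csv,
                            n_angles = 360, cdr_method = "vertical") {
  labels <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "diagnosis")
  if (!all(need %in% names(labels)))
    stop("label table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(labels$patient_id))
    stop("duplicate patient id(s) in label table")
  oct <- if (!is.null(oct_csv)) read_oct_table(oct_csv) else NULL
  excl <- list()
  note <- function(id, reason)
    excl[[length(excl) + 1]] <<- data.frame(patient_id = id, reason = reason)
  if (!is.null(oct) && nrow(oct$rejected) > 0) {
    for (i in seq_len(nrow(oct$rejected)))
      note(oct$rejected$patient_id[i],
           paste("OCT row rejected:", oct$rejected$reason[i]))
  }
  side_code <- c(right = "OD", left = "OS")
  patients <- list()
  for (i in seq_len(nrow(labels))) {
    id <- labels$patient_id[i]
    diag <- labels$diagnosis[i]
    if (diag == "suspect") { note(id, "suspect diagnosis"); next }
    rec <- list(patient_id = id, diagnosis = diag,
                age = labels$age[i], sex = labels$sex[i])
    ok <- TRUE
    if (!is.null(oct)) {
      rows <- oct$table[oct$table$patient_id == id, ]
      if (!all(c("right", "left") %in% rows$laterality)) {
        note(id, "missing OCT eye"); ok <- FALSE
      } else {
        rec$oct <- list(
          right = oct_row_profile(rows[rows$laterality == "right", ][1, ]),
          left = oct_row_profile(rows[rows$laterality == "left", ][1, ]))
      }
    }
    if (ok && !is.null(contour_dir)) {
      rec$fundus <- list()
      for (side in c("right", "left")) {
        paths <- file.path(contour_dir, sprintf("%s_%s_%s.txt", id,
                                                side_code[side],
                                                c("disc", "cup")))
        if (!all(file.exists(paths))) {
          note(id, paste("missing", side, "eye contour file(s)"))
          ok <- FALSE
          break
        }
        feat <- tryCatch(
          fundus_features(read_contour(paths[1]), read_contour(paths[2]),
                          laterality = side, n_angles = n_angles,
                          cdr_method = cdr_method,
                          label = paste(id, side_code[side])),
          error = function(e) e)
        if (inherits(feat, "error")) {
          note(id, paste("fundus extraction failed:",
                         conditionMessage(feat)))
          ok <- FALSE
          break
        }
        rec$fundus[[side]] <- feat$sector_profile
        rec$cdr[[side]] <- feat$cdr
        rec$rdr[[side]] <- feat$rdr
      }
    }
    if (ok) patients[[length(patients) + 1]] <- rec
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), reason = character())
  list(patients = patients, exclusions = exclusions)
}

#' Asymmetry feature matrix of a cohort for one modality
#'
#' Computes cohort stats and per-patient asymmetry vectors from the
#' patient records' stored sector profiles, optionally rescaling fundus
#' widths by a calibration factor `f` (which leaves every asymmetry metric
#' either unchanged or uniformly scaled).
#'
#' @param patients list of patient records (see [assemble_cohort()]).
#' @param modality `"OCT"` or `"RET"`.
#' @param metrics metric subset, see [feature_matrix()].
#' @param scale_f optional factor applied to fundus widths first.
#' @return data.frame from [feature_matrix()].
#' @export
cohort_features <- function(patients, modality = c("OCT", "RET"),
                            metrics = METRICS, scale_f = NULL) {
  modality <- match.arg(modality)
  slot <- if (modality == "OCT") "oct" else "fundus"
  keep <- vapply(patients, function(p)
    !is.null(p[[slot]]$right) && !is.null(p[[slot]]$left), TRUE)
  patients <- patients[keep]
  if (length(patients) == 0) stop("no patient with ", modality, " data")
  pairs <- lapply(patients, function(p) {
    pr <- p[[slot]]
    if (!is.null(scale_f) && modality == "RET") {
      pr <- list(right = sector_profile(pr$right$w * scale_f, "RET", "right"),
                 left = sector_profile(pr$left$w * scale_f, "RET", "left"))
    }
    pr
  })
  stats <- cohort_stats(pairs)
  asym <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    compute_asymmetry(pairs[[i]]$right, pairs[[i]]$left, stats,
                      cdr_r = p$cdr$right, cdr_l = p$cdr$left,
                      rdr_r = p$rdr$right, rdr_l = p$rdr$left)
  })
  names(asym) <- vapply(patients, function(p) p$patient_id, "")
  feature_matrix(asym, vapply(patients, function(p) p$diagnosis, ""),
                 metrics = metrics)
}

#' Run the full analysis pipeline
#'
#' Stages: assemble (or simulate) -> fundus extraction -> scale calibration
#' -> asymmetry features -> ISNT compliance -> cross-validated classifier.
#' All artifacts are written under `out_dir` together with a JSON manifest
#' sufficient to re-run the configuration.
#'
#' @param config list (or path to a JSON file) with entries:
#'   * `simulate`: list of [cohort_params()] arguments (used when no input
#'     paths are given), or
#'   * `contour_dir`, `oct_csv`, `labels_csv`: input paths;
#'   * `modality` (`"OCT"` or `"RET"`, default `"OCT"`), `metrics`
#'     (default `"absrel"`), `family`, `mns`, `cost_fn`, `k_folds`, `seed`,
#'     `msp_k` (optional: select the top-k features by averaged tree
#'     relevance before training, with `msp_reps` trees).
#' @param out_dir output directory.
#' @return list with `compliance`, `features`, `cv`, `calibration_f`,
#'   `manifest` (invisibly also written to disk).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(modality = "OCT", metrics = "absrel",
                                family = "tree", mns = Inf, cost_fn = 1,
                                k_folds = 5, seed = 1L, msp_k = NULL,
                                msp_reps = 1000), config)
  if (identical(cfg$mns, "unlimited")) cfg$mns <- Inf
  # --- assemble -------------------------------------------------------------
  if (!is.null(cfg$labels_csv)) {
    asm <- assemble_cohort(cfg$contour_dir, cfg$oct_csv, cfg$labels_csv)
    patients <- asm$patients
    exclusions <- asm$exclusions
  } else if (!is.null(cfg$simulate)) {
    params <- do.call(cohort_params, cfg$simulate)
    cohort <- generate_cohort(params)
    patients <- cohort$patients
    exclusions <- data.frame(patient_id = character(), reason = character())
  } else stop("config must provide either input paths or a 'simulate' block")
  have_fundus <- all(vapply(patients, function(p)
    !is.null(p$fundus$right) && !is.null(p$fundus$left), TRUE))
  have_oct <- all(vapply(patients, function(p)
    !is.null(p$oct$right) && !is.null(p$oct$left), TRUE))
  # --- calibration ----------------------------------------------------------
  calibration_f <- NULL
  if (have_fundus && have_oct) {
    ret_g <- unlist(lapply(patients, function(p)
      c(p$fundus$right$w["G"], p$fundus$left$w["G"])))
    oct_g <- unlist(lapply(patients, function(p)
      c(p$oct$right$w["G"], p$oct$left$w["G"])))
    calibration_f <- calibrate_scale(ret_g, oct_g)
  }
  # --- ISNT compliance ------------------------------------------------------
  compliance <- NULL
  if (have_fundus) {
    compliance <- cohort_compliance(patients)
    write_compliance(compliance, file.path(out_dir, "compliance.csv"))
  }
  # --- features & model -----------------------------------------------------
  if (cfg$modality == "RET" && !have_fundus)
    stop("stage features: fundus modality requested but not available")
  if (cfg$modality == "OCT" && !have_oct)
    stop("stage features: OCT modality requested but not available")
  features <- cohort_features(patients, modality = cfg$modality,
                              metrics = cfg$metrics,
                              scale_f = if (cfg$modality == "RET")
                                calibration_f else NULL)
  write_features(features, file.path(out_dir,
                                     paste0("features_", cfg$modality,
                                            ".csv")))
  Xall <- features[setdiff(names(features), "label")]
  y <- features$label
  selected <- names(Xall)
  if (!is.null(cfg$msp_k)) {
    rel <- feature_relevance(Xall, y, n_reps = cfg$msp_reps, seed = cfg$seed)
    selected <- select_msp(rel, k = cfg$msp_k)
  }
  spec <- model_spec(family = cfg$family, mns = cfg$mns,
                     cost_fn = cfg$cost_fn, k_folds = cfg$k_folds,
                     seed = cfg$seed)
  cv <- stratified_kfold_cv(spec, Xall[selected], y)
  cv_df <- data.frame(family = cfg$family,
                      mns = format(cfg$mns), cost_fn = cfg$cost_fn,
                      modality = cfg$modality,
                      features = paste(selected, collapse = ";"),
                      t(unclass(cv$counts)),
                      sensitivity = cv$metrics[["sensitivity"]],
                      specificity = cv$metrics[["specificity"]],
                      precision = cv$metrics[["precision"]],
                      accuracy = cv$metrics[["accuracy"]])
  utils::write.csv(cv_df, file.path(out_dir, "cv_report.csv"),
                   row.names = FALSE)
  # --- manifest & summary ---------------------------------------------------
  manifest <- list(config = lapply(cfg, function(v)
    if (identical(v, Inf)) "unlimited" else v),
    selected_features = selected,
    calibration_f = calibration_f,
    n_patients = length(patients),
    exclusions = exclusions,
    package_version = as.character(utils::packageVersion("oculasym")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  if (!is.null(compliance)) {
    sink(con); print(compliance); sink()
  }
  writeLines(c(sprintf("model: %s (MNS=%s, C(FN)=%g, k=%d, seed=%d)",
                       cfg$family, format(cfg$mns), cfg$cost_fn,
                       cfg$k_folds, cfg$seed),
               sprintf("features [%s %s]: %s", cfg$modality,
                       paste(cfg$metrics, collapse = "+"),
                       paste(selected, collapse = ", ")),
               sprintf("pooled confusion: TP=%d FN=%d TN=%d FP=%d",
                       cv$counts["tp"], cv$counts["fn"],
                       cv$counts["tn"], cv$counts["fp"]),
               sprintf(paste0("sensitivity %.1f%%  specificity %.1f%%  ",
                              "precision %.1f%%  accuracy %.1f%%"),
                       cv$metrics[["sensitivity"]],
                       cv$metrics[["specificity"]],
                       cv$metrics[["precision"]],
                       cv$metrics[["accuracy"]])), con)
  close(con)
  invisible(list(compliance = compliance, features = features, cv = cv,
                 calibration_f = calibration_f, manifest = manifest))
}
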