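# Inter-eye asymmetry metrics.
#
# For a sector value w in the right (r) and left (l) eye of patient i,
# six metrics quantify the asymmetry:
#   delta      = w_r - w_l                          (raw difference)
#   abs_delta  = |w_r - w_l|
#   rel        = (w_r - w_l) / (w_r + w_l)          (patient-sector norm)
#   abs_rel    = |w_r - w_l| / (w_r + w_l)
#   cohort_rel = (w_r - w_l) / (wbar_r + wbar_l)    (cohort-sector norm)
#   global_rel = (w_r - w_l) / (wG_r + wG_l)        (patient-global norm)
# where wbar are cohort means of the sector per eye and wG the patient's
# global sector values. The signed metrics are near-Gaussian with zero mean
# in both classes but larger variance under glaucoma; taking the modulus
# moves that variance difference into the mean, which is what makes the
# absolute metrics good classifier features.

METRICS <- c("delta", "absdelta", "rel", "absrel", "cohortrel", "globalrel")

#' Cohort-level per-sector mean profiles
#'
#' Arithmetic means of the right-eye and left-eye sector values over all
#' included patients, used as the denominator of the cohort-normalized
#' metric. Computed over the full included cohort (healthy + glaucoma)
#' before any train/test split; note this is a mild leakage caveat for
#' cross-validated models.
#'
#' @param pairs list of `list(right = , left = )` pairs of
#'   [sector_profile()] objects, one per patient.
#' @return object of class `cohort_stats`: list with named numerics
#'   `right` and `left` (sector means incl. G) and `n`.
#' @export
cohort_stats <- function(pairs) {
  if (length(pairs) == 0) stop("empty cohort")
  r <- vapply(pairs, function(p) p$right$w[SECTORS_G], numeric(7))
  l <- vapply(pairs, function(p) p$left$w[SECTORS_G], numeric(7))
  structure(list(right = rowMeans(r), left = rowMeans(l),
                 n = length(pairs)),
            class = "cohort_stats")
}

#' Compute the asymmetry vector for one patient
#'
#' @param right,left [sector_profile()] objects of the same modality.
#' @param stats [cohort_stats()] for the cohort the patient belongs to.
#' @param cdr_r,cdr_l,rdr_r,rdr_l optional per-eye cup-to-disc and
#'   rim-to-disc ratios; when given, `abs_dcdr = |cdr_r - cdr_l|` and
#'   `abs_drdr = |rdr_r - rdr_l|` are included.
#' @return object of class `asymmetry_vector`: list of named numerics
#'   `delta`, `absdelta`, `rel`, `absrel`, `cohortrel`, `globalrel` (each
#'   over sectors TS, T, TI, NS, N, NI, G) plus optional `abs_dcdr`,
#'   `abs_drdr`, and the modality.
#' @export
compute_asymmetry <- function(right, left, stats,
                              cdr_r = NULL, cdr_l = NULL,
                              rdr_r = NULL, rdr_l = NULL) {
  stopifnot(inherits(right, "sector_profile"),
            inherits(left, "sector_profile"),
            inherits(stats, "cohort_stats"))
  if (right$modality != left$modality)
    stop("right/left profiles have different modalities")
  if (right$laterality != "right" || left$laterality != "left")
    stop("profiles passed in the wrong laterality slots")
  wr <- right$w[SECTORS_G]; wl <- left$w[SECTORS_G]
  d <- wr - wl
  pair_sum <- wr + wl
  if (any(pair_sum == 0)) {
    stop("zero denominator for metric rel in sector(s): ",
         paste(SECTORS_G[pair_sum == 0], collapse = ", "))
  }
  coh_sum <- stats$right[SECTORS_G] + stats$left[SECTORS_G]
  if (any(coh_sum == 0)) {
    stop("zero denominator for metric cohortrel in sector(s): ",
         paste(SECTORS_G[coh_sum == 0], collapse = ", "))
  }
  g_sum <- unname(wr["G"] + wl["G"])
  if (g_sum == 0) stop("zero denominator for metric globalrel (G sum)")
  out <- list(delta = d, absdelta = abs(d),
              rel = d / pair_sum, absrel = abs(d) / pair_sum,
              cohortrel = d / coh_sum, globalrel = d / g_sum,
              modality = right$modality)
  if (!is.null(cdr_r) && !is.null(cdr_l)) out$abs_dcdr <- abs(cdr_r - cdr_l)
  if (!is.null(rdr_r) && !is.null(rdr_l)) out$abs_drdr <- abs(rdr_r - rdr_l)
  structure(out, class = "asymmetry_vector")
}

#' Build a per-patient feature matrix of asymmetry metrics
#'
#' One row per patient, columns `{metric}_{sector}` (e.g. `absrel_TS`),
#' plus `abs_dcdr` / `abs_drdr` when present, plus the diagnosis label.
#'
#' @param asym_list named list of `asymmetry_vector` objects (names =
#'   patient ids).
#' @param labels character vector of diagnoses aligned with `asym_list`.
#' @param metrics subset of metrics to include (default all six).
#' @return data.frame with rownames = patient ids and a `label` column.
#' @export
feature_matrix <- function(asym_list, labels, metrics = METRICS) {
  stopifnot(length(asym_list) == length(labels),
            all(metrics %in% METRICS))
  rows <- lapply(asym_list, function(a) {
    v <- unlist(lapply(metrics, function(m) {
      x <- a[[m]][SECTORS_G]
      names(x) <- paste0(m, "_", SECTORS_G)
      x
    }))
    if (!is.null(a$abs_dcdr)) v <- c(v, abs_dcdr = a$abs_dcdr)
    if (!is.null(a$abs_drdr)) v <- c(v, abs_drdr = a$abs_drdr)
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- labels
  df
}

#' Write a feature matrix to CSV
#'
#' @param features data.frame from [feature_matrix()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- cbind(patient_id = rownames(features), features)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
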