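# ISNT rule evaluation.
#
# In healthy eyes the neuroretinal rim width typically orders
# Inferior >= Superior >= Nasal >= Temporal (the ISNT rule); IST and IS are
# relaxed variants dropping the nasal and then the temporal comparison.
# The six sectors are regrouped to four: I = (TI + NI)/2, S = (TS + NS)/2
# (both constituents span 45 deg, so a simple mean), N and T unchanged.

RULES <- c("ISNT", "IST", "IS")

#' Regroup six sectors into the four ISNT sectors
#'
#' @param profile a [sector_profile()].
#' @return named numeric with I, S, N, T plus a laterality attribute.
#' @export
regroup_sectors <- function(profile) {
  stopifnot(inherits(profile, "sector_profile"))
  w <- profile$w
  out <- c(I = unname((w["TI"] + w["NI"]) / 2),
           S = unname((w["TS"] + w["NS"]) / 2),
           N = unname(w["N"]), T = unname(w["T"]))
  attr(out, "laterality") <- profile$laterality
  out
}

#' Evaluate the ISNT rule and its variants on a four-sector profile
#'
#' Non-strict comparisons (>=) with an optional tolerance `tol`:
#' a comparison `x >= y` passes when `x >= y - tol`. Default `tol = 0`
#' takes the rule literally, so exact ties are compliant.
#'
#' @param four named numeric with elements I, S, N, T (see
#'   [regroup_sectors()]).
#' @param tol non-negative slack (same units as the profile).
#' @return named logical `c(ISNT = , IST = , IS = )`.
#' @export
check_rules <- function(four, tol = 0) {
  stopifnot(all(c("I", "S", "N", "T") %in% names(four)), tol >= 0)
  ge <- function(x, y) four[[x]] >= four[[y]] - tol
  is_ <- ge("I", "S")
  c(ISNT = is_ && ge("S", "N") && ge("N", "T"),
    IST = is_ && ge("S", "T"),
    IS = unname(is_))
}

#' Per-patient rule compliance for both eyes
#'
#' @param right,left [sector_profile()] objects (fundus rim widths).
#' @param tol comparison slack, see [check_rules()].
#' @return data.frame: one row per rule with logical columns `right_eye`,
#'   `left_eye`, `both_eyes`.
#' @export
patient_compliance <- function(right, left, tol = 0) {
  r <- check_rules(regroup_sectors(right), tol)
  l <- check_rules(regroup_sectors(left), tol)
  data.frame(rule = RULES, right_eye = unname(r[RULES]),
             left_eye = unname(l[RULES]),
             both_eyes = unname(r[RULES] & l[RULES]))
}

#' Cohort compliance table
#'
#' Counts and percentages of patients of each class complying with ISNT,
#' IST and IS in the right eye, the left eye, and both eyes simultaneously.
#' Patients missing a fundus profile for either eye are excluded and
#' reported.
#'
#' @param patients list of patient records: each a list with `diagnosis`
#'   and fundus [sector_profile()]s under `fundus$right` / `fundus$left`
#'   (as produced by [assemble_cohort()] or [generate_cohort()]).
#' @param tol comparison slack, see [check_rules()].
#' @return object of class `compliance_table`: list with `counts` (long
#'   data.frame: class, rule, scope, n, total, percent) and `excluded`
#'   (character vector of patient ids).
#' @export
cohort_compliance <- function(patients, tol = 0) {
  has_fundus <- vapply(patients, function(p)
    !is.null(p$fundus$right) && !is.null(p$fundus$left), TRUE)
  excluded <- vapply(patients[!has_fundus], function(p) p$patient_id, "")
  patients <- patients[has_fundus]
  if (length(patients) == 0) stop("no patient with fundus data in both eyes")
  per <- lapply(patients, function(p)
    cbind(patient_compliance(p$fundus$right, p$fundus$left, tol),
          class = p$diagnosis))
  long <- do.call(rbind, per)
  scopes <- c(right = "right_eye", left = "left_eye", both = "both_eyes")
  rows <- list()
  for (cl in unique(long$class)) {
    for (rule in RULES) {
      sub <- long[long$class == cl & long$rule == rule, ]
      for (sc in names(scopes)) {
        n <- sum(sub[[scopes[sc]]])
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, rule = rule, scope = sc, n = n, total = nrow(sub),
          percent = 100 * n / nrow(sub))
      }
    }
  }
  structure(list(counts = do.call(rbind, rows), excluded = excluded),
            class = "compliance_table")
}

#' @export
print.compliance_table <- function(x, ...) {
  wide <- stats::reshape(
    x$counts[c("class", "rule", "scope", "n", "percent")],
    idvar = c("class", "scope"), timevar = "rule", direction = "wide")
  cat("ISNT-family rule compliance by class and scope:\n")
  print(wide, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (missing eye):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write a compliance table to CSV
#'
#' @param compliance a `compliance_table`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_compliance <- function(compliance, path) {
  utils::write.csv(compliance$counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
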