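# Sector conventions shared by the fundus and OCT sides of the pipeline.
#
# Angles are "anatomic": 0 deg points temporally along the horizontal,
# 90 deg is superior, growing counter-clockwise when the eye is viewed in
# this convention. Temporal/nasal mirror between eyes, so the mapping from
# anatomic angles to image coordinates depends on laterality (see
# anatomic_dirs()).

#' Peripapillary sector definitions
#'
#' The peripapillary circle is divided into six sectors: temporal (T),
#' temporal superior (TS), nasal superior (NS), nasal (N), nasal inferior
#' (NI) and temporal inferior (TI). T and N span 90 degrees each, the four
#' oblique sectors 45 degrees each. A seventh pseudo-sector G is the
#' angle-weighted global mean.
#'
#' @format `SECTORS` is the canonical sector ordering (without G);
#'   `SECTORS_G` appends G.
#' @keywords internal
#' @name sectors
NULL

SECTORS <- c("TS", "T", "TI", "NS", "N", "NI")
SECTORS_G <- c(SECTORS, "G")

# half-open anatomic ranges in degrees; T wraps through 0
SECTOR_RANGES <- list(
  T  = c(315, 405),  # [-45, 45) stored shifted; handled by sector_of()
  TS = c(45, 90),
  NS = c(90, 135),
  N  = c(135, 225),
  NI = c(225, 270),
  TI = c(270, 315)
)

SECTOR_SPAN <- c(TS = 45, T = 90, TI = 45, NS = 45, N = 90, NI = 45)

#' Map anatomic angles to sector labels
#'
#' @param angles_deg numeric vector of angles in degrees (any real values;
#'   reduced modulo 360).
#' @return character vector of sector labels among `SECTORS`.
#' @keywords internal
sector_of <- function(angles_deg) {
  a <- angles_deg %% 360
  out <- character(length(a))
  out[a >= 315 | a < 45] <- "T"
  out[a >= 45 & a < 90] <- "TS"
  out[a >= 90 & a < 135] <- "NS"
  out[a >= 135 & a < 225] <- "N"
  out[a >= 225 & a < 270] <- "NI"
  out[a >= 270 & a < 315] <- "TI"
  out
}

#' Angle-weighted global mean of six sector values
#'
#' G = (90 T + 45 TS + 45 NS + 90 N + 45 NI + 45 TI) / 360.
#'
#' @param w named numeric with elements TS, T, TI, NS, N, NI.
#' @return scalar global mean.
#' @export
sector_global_mean <- function(w) {
  stopifnot(all(SECTORS %in% names(w)))
  sum(SECTOR_SPAN[SECTORS] * unlist(w[SECTORS])) / 360
}

#' Unit ray directions in image coordinates for anatomic angles
#'
#' Image coordinates have x rightward and y downward. For a right eye (OD)
#' the temporal direction is image-left; for a left eye (OS) it is
#' image-right. Superior is image-up for both.
#'
#' @param angles_deg anatomic angles in degrees.
#' @param laterality `"right"` or `"left"`.
#' @return two-column matrix of unit direction vectors (dx, dy).
#' @keywords internal
anatomic_dirs <- function(angles_deg, laterality) {
  laterality <- match_laterality(laterality)
  th <- angles_deg * pi / 180
  sx <- if (laterality == "right") -1 else 1
  cbind(dx = sx * cos(th), dy = -sin(th))
}

#' Normalize a laterality token
#'
#' Accepts right/left/OD/OS (case-insensitive), returns "right"/"left".
#' @param x character scalar or vector.
#' @return normalized character vector.
#' @keywords internal
match_laterality <- function(x) {
  key <- c(right = "right", od = "right", left = "left", os = "left",
           r = "right", l = "left")
  out <- key[tolower(as.character(x))]
  if (any(is.na(out))) {
    stop("unrecognized laterality token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Construct a sector profile
#'
#' A `SectorProfile` holds the seven sector values of one eye in one
#' modality (fundus rim width in pixels or micrometres, or OCT RNFL
#' thickness in micrometres).
#'
#' @param values named numeric containing TS, T, TI, NS, N, NI and
#'   optionally G; if G is absent it is computed as the angle-weighted
#'   global mean.
#' @param modality `"RET"` (fundus) or `"OCT"`.
#' @param laterality `"right"`, `"left"`, `"OD"` or `"OS"`.
#' @return object of class `sector_profile`: named numeric `w` plus
#'   modality and laterality attributes.
#' @export
sector_profile <- function(values, modality = c("RET", "OCT"), laterality) {
  modality <- match.arg(modality)
  laterality <- match_laterality(laterality)
  stopifnot(all(SECTORS %in% names(values)))
  w <- unlist(values)[SECTORS]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("sector values must be finite and non-negative")
  }
  g <- if ("G" %in% names(values)) unname(unlist(values)["G"]) else
    sector_global_mean(w)
  structure(list(w = c(w, G = g), modality = modality,
                 laterality = laterality),
            class = "sector_profile")
}

#' @export
print.sector_profile <- function(x, ...) {
  cat(sprintf("<sector_profile %s eye, %s>\n", x$laterality, x$modality))
  print(round(x$w, 2))
  invisible(x)
}
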