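# Synthetic paired-eye cohort generator.
#
# Emulates the statistical structure reported for the clinical cohort:
# inter-eye sector thickness differences are zero-mean Gaussian with a
# larger standard deviation in glaucoma; glaucoma sector thicknesses are
# lower overall; fundus rim widths are approximately linear in the OCT
# thicknesses with a slope near 1/f (f ~ 0.6425 is the factor that brings
# fundus widths to the OCT scale). Fundus contours are written as exact
# ellipses: the disc is a circle and the cup an offset, rotated ellipse
# whose first-order harmonic expansion matches the six per-sector rim-width
# targets in least squares (the pipeline's own ellipse-fit smoothing would
# destroy any sharper per-sector modulation). The realized (ellipse-
# implied) sector widths are stored with each record; downstream
# extraction reproduces them almost exactly.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are configurable choices of this package, not values from any
#' clinical dataset: healthy sector means follow the normative
#' peripapillary double-hump profile; the thinning fraction and the two
#' inter-eye standard deviations give a glaucoma class that is 25% thinner
#' with three times the inter-eye variability.
#'
#' @param n_healthy,n_glaucoma class sizes.
#' @param oct_sector_means_healthy named numeric (TS, T, TI, NS, N, NI), um.
#' @param glaucoma_thinning_fraction in (0, 1): glaucoma class means are
#'   healthy means times (1 - fraction).
#' @param sigma_delta_healthy,sigma_delta_glaucoma SD (um) of the zero-mean
#'   Gaussian inter-eye sector difference per class;
#'   `sigma_delta_glaucoma >= sigma_delta_healthy`.
#' @param patient_jitter_sd SD (um) of between-patient sector-mean jitter.
#' @param ret_oct_slope multiplicative factor from OCT um to fundus rim
#'   width px; default 1/0.6425 so that scale calibration recovers
#'   f ~ 0.6425.
#' @param ret_noise_sd SD (um, applied before scaling) of the fundus
#'   measurement noise around the linear relation.
#' @param disc_radius_px disc radius in pixels.
#' @param thickness_floor lower truncation (um) keeping normalized metrics
#'   defined.
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_healthy = 161, n_glaucoma = 47,
                          oct_sector_means_healthy = c(
                            TS = 132, T = 72, TI = 140,
                            NS = 103, N = 75, NI = 110),
                          glaucoma_thinning_fraction = 0.25,
                          sigma_delta_healthy = 3,
                          sigma_delta_glaucoma = 9,
                          patient_jitter_sd = 7,
                          ret_oct_slope = 1 / 0.6425,
                          ret_noise_sd = 2,
                          disc_radius_px = 300,
                          thickness_floor = 1,
                          seed = 1L) {
  p <- list(n_healthy = as.integer(n_healthy),
            n_glaucoma = as.integer(n_glaucoma),
            oct_sector_means_healthy = oct_sector_means_healthy[SECTORS],
            glaucoma_thinning_fraction = glaucoma_thinning_fraction,
            sigma_delta_healthy = sigma_delta_healthy,
            sigma_delta_glaucoma = sigma_delta_glaucoma,
            patient_jitter_sd = patient_jitter_sd,
            ret_oct_slope = ret_oct_slope,
            ret_noise_sd = ret_noise_sd,
            disc_radius_px = disc_radius_px,
            thickness_floor = thickness_floor,
            seed = as.integer(seed))
  if (p$n_healthy <= 0 || p$n_glaucoma <= 0)
    stop("class sizes must be positive")
  if (any(is.na(p$oct_sector_means_healthy)) ||
      any(p$oct_sector_means_healthy <= 0))
    stop("healthy sector means must be positive and cover ",
         paste(SECTORS, collapse = ", "))
  if (p$glaucoma_thinning_fraction <= 0 || p$glaucoma_thinning_fraction >= 1)
    stop("glaucoma_thinning_fraction must lie in (0, 1)")
  if (p$sigma_delta_healthy < 0 || p$sigma_delta_glaucoma < 0 ||
      p$sigma_delta_glaucoma < p$sigma_delta_healthy)
    stop("need 0 <= sigma_delta_healthy <= sigma_delta_glaucoma")
  if (p$ret_oct_slope <= 0 || p$disc_radius_px <= 0 || p$ret_noise_sd < 0 ||
      p$patient_jitter_sd < 0)
    stop("scales and noise SDs must be non-negative, slopes positive")
  structure(p, class = "cohort_params")
}

# sector-mean design matrix of (1, cos, sin, cos2, sin2) over the six
# anatomic sector ranges; rows in SECTORS order
harmonic_sector_matrix <- function() {
  rng <- list(TS = c(45, 90), T = c(-45, 45), TI = c(270, 315),
              NS = c(90, 135), N = c(135, 225), NI = c(225, 270))
  basis_mean <- function(lim) {
    a <- lim[1] * pi / 180; b <- lim[2] * pi / 180
    c(1,
      (sin(b) - sin(a)) / (b - a),
      (cos(a) - cos(b)) / (b - a),
      (sin(2 * b) - sin(2 * a)) / (2 * (b - a)),
      (cos(2 * a) - cos(2 * b)) / (2 * (b - a)))
  }
  t(vapply(rng[SECTORS], basis_mean, numeric(5)))
}

# Build disc (circle) and cup (offset ellipse) fits whose rim-width sector
# means approximate target_px (named, SECTORS order, pixels). Returns NULL
# when no feasible geometry exists for these targets.
design_eye_ellipses <- function(target_px, disc_radius, disc_center,
                                laterality) {
  M <- harmonic_sector_matrix()
  rho <- disc_radius - target_px[SECTORS]       # cup radius sector means
  coef <- qr.solve(M, rho)                      # least squares, 5 dof
  r0 <- coef[1]
  disc_fit <- structure(list(center = c(x = disc_center[1],
                                        y = disc_center[2]),
                             semi_major = disc_radius,
                             semi_minor = disc_radius,
                             orientation = 0, rms_residual = 0),
                        class = "ellipse_fit")
  e1 <- as.numeric(anatomic_dirs(0, laterality))
  e2 <- as.numeric(anatomic_dirs(90, laterality))
  target_g <- sector_global_mean(target_px)
  for (iter in 1:3) {
    if (r0 <= 2 || r0 >= disc_radius - 2) return(NULL)
    amp <- sqrt(coef[4]^2 + coef[5]^2)
    ecc <- min(amp / r0, 0.95)
    phi_a <- atan2(coef[5], coef[4]) / 2
    ctr <- disc_center + coef[2] * e1 + coef[3] * e2
    vmaj <- cos(phi_a) * e1 + sin(phi_a) * e2
    cup_fit <- structure(list(center = c(x = ctr[1], y = ctr[2]),
                              semi_major = r0 * (1 + ecc),
                              semi_minor = r0 * (1 - ecc),
                              orientation = atan2(vmaj[2], vmaj[1]) %% pi,
                              rms_residual = 0),
                         class = "ellipse_fit")
    if (!point_in_ellipse(ctr, disc_fit)) return(NULL)
    prof <- suppressWarnings(
      rim_width_profile(disc_fit, cup_fit, laterality, 360))
    if (min(prof$width) <= 0 ||
        max(disc_radius - prof$width) >= disc_radius - 1) return(NULL)
    realized <- sector_means(prof)
    if (iter < 3) r0 <- r0 + (realized$w[["G"]] - target_g)  # mean correction
  }
  list(disc_fit = disc_fit, cup_fit = cup_fit, realized = realized,
       profile = prof)
}

ellipse_points <- function(fit, n = 72) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- fit$orientation
  x <- fit$semi_major * cos(t); y <- fit$semi_minor * sin(t)
  cbind(x = fit$center[1] + x * cos(phi) - y * sin(phi),
        y = fit$center[2] + x * sin(phi) + y * cos(phi))
}

#' Generate a synthetic paired-eye cohort
#'
#' Per patient and sector, a patient-level mean thickness is drawn around
#' the class mean, the inter-eye difference is drawn from the class's
#' zero-mean Gaussian, and right/left thicknesses are the mean plus/minus
#' half the difference (truncated at the thickness floor). The per-eye
#' global value G is the angle-weighted sector mean. Fundus rim-width
#' targets are the OCT thicknesses plus measurement noise, scaled by
#' `ret_oct_slope`; disc and cup contour ellipses are constructed so the
#' extracted sector widths match those targets to first order. Infeasible
#' geometries (cup leaving the disc) are regenerated with fresh noise, with
#' a warning, up to `max_retries` times.
#'
#' @param params a [cohort_params()] object.
#' @param modalities subset of `c("oct", "fundus")`; dropping `"fundus"`
#'   skips the (slower) contour synthesis.
#' @param n_contour_points points written per contour.
#' @param max_retries bounded retries per eye for infeasible geometry.
#' @return object of class `cohort`: list with `patients` (list of patient
#'   records), `oct` (data.frame in [read_oct_table()] layout), `labels`
#'   (data.frame: patient_id, diagnosis, age, sex) and `params`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            modalities = c("oct", "fundus"),
                            n_contour_points = 72, max_retries = 5) {
  stopifnot(inherits(params, "cohort_params"))
  modalities <- match.arg(modalities, c("oct", "fundus"),
                          several.ok = TRUE)
  set.seed(params$seed)
  n <- params$n_healthy + params$n_glaucoma
  classes <- rep(c("healthy", "glaucoma"),
                 c(params$n_healthy, params$n_glaucoma))
  ids <- sprintf("P%03d", seq_len(n))
  mu_h <- params$oct_sector_means_healthy
  floor_um <- params$thickness_floor
  patients <- vector("list", n)
  oct_rows <- list()
  for (i in seq_len(n)) {
    cls <- classes[i]
    mu <- if (cls == "healthy") mu_h else
      mu_h * (1 - params$glaucoma_thinning_fraction)
    sig <- if (cls == "healthy") params$sigma_delta_healthy else
      params$sigma_delta_glaucoma
    m <- pmax(mu + stats::rnorm(6, 0, params$patient_jitter_sd), 5)
    delta <- stats::rnorm(6, 0, sig)
    wr <- pmax(m + delta / 2, floor_um)
    wl <- pmax(m - delta / 2, floor_um)
    names(wr) <- names(wl) <- SECTORS
    age <- if (cls == "healthy") stats::rnorm(1, 59.1, 12.7) else
      stats::rnorm(1, 70.15, 9.21)
    age <- round(min(max(age, 25), 95), 1)
    sex <- if (stats::runif(1) < (if (cls == "healthy") 54 / 161 else
                                  19 / 47)) "male" else "female"
    rec <- list(patient_id = ids[i], diagnosis = cls, age = age, sex = sex)
    if ("oct" %in% modalities) {
      rec$oct <- list(
        right = sector_profile(wr, modality = "OCT", laterality = "right"),
        left = sector_profile(wl, modality = "OCT", laterality = "left"))
      oct_rows[[length(oct_rows) + 1]] <- data.frame(
        patient_id = ids[i], laterality = c("right", "left"),
        rbind(c(wr, G = sector_global_mean(wr)),
              c(wl, G = sector_global_mean(wl))), check.names = FALSE)
    }
    if ("fundus" %in% modalities) {
      rec$fundus <- list(); rec$contours <- list()
      rec$fundus_target <- list()
      for (side in c("right", "left")) {
        w_um <- if (side == "right") wr else wl
        ctr <- c(1000, 1000) + stats::rnorm(2, 0, 15)
        des <- NULL
        for (try in 0:max_retries) {
          tgt <- pmax(w_um + stats::rnorm(6, 0, params$ret_noise_sd), 1) *
            params$ret_oct_slope
          names(tgt) <- SECTORS
          des <- design_eye_ellipses(tgt, params$disc_radius_px, ctr, side)
          if (!is.null(des)) break
          warning(sprintf("infeasible cup geometry for %s %s; regenerating",
                          ids[i], side))
        }
        if (is.null(des)) stop("no feasible cup geometry for ", ids[i], " ",
                               side, " after ", max_retries, " retries")
        rec$fundus[[side]] <- des$realized
        rec$fundus_target[[side]] <- tgt
        feat <- list(cdr = compute_cdr(des$disc_fit, des$cup_fit),
                     rdr = compute_rdr(des$profile))
        rec$cdr[[side]] <- feat$cdr
        rec$rdr[[side]] <- feat$rdr$rdr
        rec$contours[[side]] <- list(
          disc = ellipse_points(des$disc_fit, n_contour_points),
          cup = ellipse_points(des$cup_fit, n_contour_points))
      }
    }
    patients[[i]] <- rec
  }
  labels <- data.frame(
    patient_id = ids, diagnosis = classes,
    age = vapply(patients, function(p) p$age, 0),
    sex = vapply(patients, function(p) p$sex, ""))
  oct <- if (length(oct_rows)) do.call(rbind, oct_rows) else NULL
  structure(list(patients = patients, oct = oct, labels = labels,
                 params = params, modalities = modalities),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d healthy + %d glaucoma, seed %d, %s>\n",
              x$params$n_healthy, x$params$n_glaucoma, x$params$seed,
              paste(x$modalities, collapse = "+")))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Contour files `contours/<id>_<OD|OS>_<disc|cup>.txt` (one "x y" pair per
#' line), `oct.csv`, `labels.csv` and a `manifest.json` recording the
#' generator parameters and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$oct)) {
    write_oct_table(cohort$oct, file.path(dir, "oct.csv"))
  }
  if ("fundus" %in% cohort$modalities) {
    cdir <- file.path(dir, "contours")
    dir.create(cdir, showWarnings = FALSE)
    side_code <- c(right = "OD", left = "OS")
    for (p in cohort$patients) {
      for (side in names(p$contours)) {
        for (structure_ in c("disc", "cup")) {
          write_contour(p$contours[[side]][[structure_]],
                        file.path(cdir, sprintf("%s_%s_%s.txt", p$patient_id,
                                                side_code[side], structure_)))
        }
      }
    }
  }
  manifest <- list(generator = "oculasym::generate_cohort",
                   params = unclass(cohort$params),
                   modalities = cohort$modalities,
                   n_patients = nrow(cohort$labels))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
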