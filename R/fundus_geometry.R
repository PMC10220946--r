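# Geometry of the optic nerve head from contour annotations.
#
# Contours are point lists in image pixel coordinates (x rightward,
# y downward). Expert annotations are noisy, so both the disc and the cup
# contour are smoothed by a direct least-squares ellipse fit before any
# width is measured; the neuroretinal rim width at an angle is the distance
# from the disc-ellipse center to the disc boundary minus the distance to
# the cup boundary along the same ray.

#' Read a contour annotation file
#'
#' Plain-text contour files hold one "x y" coordinate pair per line
#' (pixel units), one file per structure per eye.
#'
#' @param path file path.
#' @return two-column numeric matrix with columns x, y.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y")))
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("non-numeric or non-finite coordinates in ", path)
  }
  m
}

#' Write a contour annotation file
#'
#' @param points two-column matrix of (x, y) pixel coordinates.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_contour <- function(points, path) {
  utils::write.table(format(points, trim = TRUE, digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fit an ellipse to contour points by direct least squares
#'
#' Stabilised direct least-squares conic fit constrained to an ellipse
#' (Halir & Flusser's formulation of the Fitzgibbon fit). Used to smooth
#' manual disc/cup annotations before measuring widths.
#'
#' @param points two-column matrix of (x, y) coordinates, at least 5
#'   non-collinear points.
#' @param label optional name used in error messages (e.g. "P001 OD cup").
#' @return object of class `ellipse_fit`: list with `center` (x, y),
#'   `semi_major`, `semi_minor`, `orientation` (radians, angle of the major
#'   axis versus the x axis) and `rms_residual` (radial RMS in the units of
#'   the input).
#' @export
fit_ellipse <- function(points, label = "contour") {
  points <- as.matrix(points)
  if (nrow(points) < 5) {
    stop("ellipse fit for ", label, " needs >= 5 points, got ", nrow(points))
  }
  if (any(!is.finite(points))) stop("non-finite coordinates in ", label)
  # center for numerical conditioning
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx; y <- points[, 2] - my
  if (max(abs(x)) < 1e-12 && max(abs(y)) < 1e-12) {
    stop("degenerate (single-point) contour: ", label)
  }
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration in ", label))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution for ", label,
                            " (collinear or degenerate points?)")
  a1 <- ev[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))  # A B C D E F on centered coords
  geo <- conic_to_ellipse(coef)
  if (is.null(geo)) stop("conic fit for ", label, " is not an ellipse")
  center <- c(x = geo$cx + mx, y = geo$cy + my)
  # radial residual: distance of each point from the boundary along its ray
  r_pt <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  ang <- atan2(points[, 2] - center[2], points[, 1] - center[1])
  r_el <- ellipse_radius_at(geo$a, geo$b, geo$phi, ang)
  structure(list(center = center, semi_major = geo$a, semi_minor = geo$b,
                 orientation = geo$phi,
                 rms_residual = sqrt(mean((r_pt - r_el)^2)),
                 n_points = nrow(points)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit center=(%.2f, %.2f) a=%.2f b=%.2f phi=%.1f deg rms=%.3g>\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor,
    x$orientation * 180 / pi, x$rms_residual))
  invisible(x)
}

# conic A x^2 + B xy + C y^2 + D x + E y + F = 0 -> geometric parameters,
# or NULL if not an ellipse
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values  # decreasing
  ax2 <- -F0 / lam
  if (any(ax2 <= 0)) return(NULL)
  r <- sqrt(ax2)            # r[1] pairs with lam[1] (larger lambda, minor)
  if (r[1] >= r[2]) {       # r[1] is the major axis
    a <- r[1]; b <- r[2]; v <- eq$vectors[, 1]
  } else {
    a <- r[2]; b <- r[1]; v <- eq$vectors[, 2]
  }
  list(cx = cx, cy = cy, a = a, b = b, phi = atan2(v[2], v[1]) %% pi)
}

# radius of an origin-centered ellipse (a, b, phi) along polar angle theta
ellipse_radius_at <- function(a, b, phi, theta) {
  ct <- cos(theta - phi); st <- sin(theta - phi)
  a * b / sqrt((b * ct)^2 + (a * st)^2)
}

# distance(s) from point `origin` along unit direction rows of `dirs` to the
# boundary of `fit`; returns the far positive root (NA when the ray misses).
ray_ellipse_dist <- function(origin, dirs, fit) {
  phi <- fit$orientation
  Rb <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2)  # R(-phi)
  p <- c(origin[1] - fit$center[1], origin[2] - fit$center[2])
  pr <- as.vector(Rb %*% p)  # into ellipse frame
  dr <- dirs %*% t(Rb)
  a2 <- fit$semi_major^2; b2 <- fit$semi_minor^2
  A <- dr[, 1]^2 / a2 + dr[, 2]^2 / b2
  B <- 2 * (pr[1] * dr[, 1] / a2 + pr[2] * dr[, 2] / b2)
  C <- pr[1]^2 / a2 + pr[2]^2 / b2 - 1
  disc <- B^2 - 4 * A * C
  t2 <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
  t2[disc < 0 | t2 <= 0] <- NA_real_
  t2
}

point_in_ellipse <- function(pt, fit) {
  phi <- fit$orientation
  Rb <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2)  # R(-phi)
  pr <- as.vector(Rb %*% (pt - fit$center))
  (pr[1] / fit$semi_major)^2 + (pr[2] / fit$semi_minor)^2 <= 1
}

#' Radial neuroretinal rim width profile
#'
#' Casts rays from the disc-ellipse center at uniformly spaced anatomic
#' angles and returns, per angle, the distance to the disc boundary minus
#' the distance to the cup boundary along the same ray. Negative widths
#' (cup annotation locally outside the disc) are clipped to zero with a
#' warning. Anatomic angles place 0 deg temporal and 90 deg superior, so
#' the image-space ray direction depends on laterality.
#'
#' @param disc,cup `ellipse_fit` objects for the disc and cup contours.
#' @param laterality `"right"`/`"OD"` or `"left"`/`"OS"`.
#' @param n_angles number of uniformly spaced angles (default 360).
#' @return object of class `radial_profile`: list with `angles_deg`,
#'   `width` (same length), `disc_dist` (center-to-disc distances) and
#'   `laterality`.
#' @export
rim_width_profile <- function(disc, cup, laterality, n_angles = 360) {
  stopifnot(inherits(disc, "ellipse_fit"), inherits(cup, "ellipse_fit"),
            n_angles >= 12)
  laterality <- match_laterality(laterality)
  if (!point_in_ellipse(cup$center, disc)) {
    stop("cup center lies outside the disc ellipse")
  }
  angles <- seq(0, 360 - 360 / n_angles, by = 360 / n_angles)
  dirs <- anatomic_dirs(angles, laterality)
  t_disc <- ray_ellipse_dist(disc$center, dirs, disc)
  t_cup <- ray_ellipse_dist(disc$center, dirs, cup)
  t_cup[is.na(t_cup)] <- 0  # ray misses the cup: the whole radius is rim
  width <- t_disc - t_cup
  if (any(width < -1e-9)) {
    warning(sprintf("%d of %d rim widths negative (cup outside disc); %s",
                    sum(width < -1e-9), n_angles, "clipped to 0"))
  }
  structure(list(angles_deg = angles, width = pmax(width, 0),
                 disc_dist = t_disc, laterality = laterality),
            class = "radial_profile")
}

#' Sector means of a radial rim-width profile
#'
#' Averages the rim width over each sector's anatomic angular range
#' (T and N span 90 deg, the oblique sectors 45 deg); the global value G is
#' the mean over all sampled angles, so with uniform angular sampling the
#' angle-weighted mean of the six sectors equals G exactly.
#'
#' @param profile a `radial_profile`.
#' @param modality stored on the result; fundus profiles are `"RET"`.
#' @return a [sector_profile()].
#' @export
sector_means <- function(profile, modality = "RET") {
  stopifnot(inherits(profile, "radial_profile"))
  a <- profile$angles_deg %% 360
  if (length(a) < 12 || (max(diff(sort(unique(a)))) > 361 / length(a) + 1e-9))
    stop("profile does not cover the full 360 degrees uniformly")
  lab <- sector_of(a)
  w <- vapply(SECTORS, function(s) mean(profile$width[lab == s]), 0)
  sector_profile(c(w, G = mean(profile$width)), modality = modality,
                 laterality = profile$laterality)
}

#' Cup-to-disc ratio from fitted ellipses
#'
#' Clinical convention: ratio of the vertical (superior-inferior) cup
#' diameter to the vertical disc diameter. The vertical extent of an
#' ellipse with semi-axes a >= b and orientation phi is
#' 2 sqrt((a sin phi)^2 + (b cos phi)^2). A mean-diameter variant
#' ((a_cup + b_cup) / (a_disc + b_disc)) is available via `method`.
#'
#' @param disc,cup `ellipse_fit` objects.
#' @param method `"vertical"` (default) or `"mean"`.
#' @return unitless ratio.
#' @export
compute_cdr <- function(disc, cup, method = c("vertical", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(disc, "ellipse_fit"), inherits(cup, "ellipse_fit"))
  vext <- function(f)
    2 * sqrt((f$semi_major * sin(f$orientation))^2 +
             (f$semi_minor * cos(f$orientation))^2)
  num_den <- switch(method,
    vertical = c(vext(cup), vext(disc)),
    mean = c(cup$semi_major + cup$semi_minor,
             disc$semi_major + disc$semi_minor))
  if (num_den[2] <= 0) stop("zero disc diameter")
  num_den[1] / num_den[2]
}

#' Rim-to-disc ratio and its angle
#'
#' The minimum rim width over the profile, normalized by the full disc
#' chord through the disc center at the same meridian (the disc diameter at
#' the arg-min angle). Ties are broken by the first sampled angle.
#'
#' @param profile a `radial_profile` produced by [rim_width_profile()].
#' @param disc the disc `ellipse_fit` (used for the chord; if omitted the
#'   profile's stored center-to-disc distances are used).
#' @param method `"meridian"` (default, chord at the arg-min angle) or
#'   `"mean"` (mean disc diameter).
#' @return list with `rdr` (unitless) and `angle_deg` (anatomic degrees).
#' @export
compute_rdr <- function(profile, disc = NULL, method = c("meridian", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "radial_profile"))
  if (length(profile$width) == 0) stop("empty profile")
  # first angle attaining the minimum, with a small tolerance so that
  # floating-point noise does not defeat the first-on-ties rule
  i <- which(profile$width <= min(profile$width) +
               1e-9 * max(1, abs(min(profile$width))))[1]
  # rays start at the disc center, so the chord at angle i is
  # t(theta) + t(theta + 180) = 2 t(theta) only for a centered ellipse;
  # use the stored opposite-ray distance when available.
  opp <- ((i - 1 + length(profile$width) / 2) %% length(profile$width)) + 1
  chord <- switch(method,
    meridian = profile$disc_dist[i] +
      profile$disc_dist[round(opp)],
    mean = mean(2 * profile$disc_dist))
  list(rdr = profile$width[i] / chord, angle_deg = profile$angles_deg[i])
}

#' Fundus-to-OCT scale calibration factor
#'
#' The factor f that, applied to fundus rim widths, matches the cohort mean
#' of the global sector G between modalities: f = mean(OCT G) / mean(RET G).
#'
#' @param ret_g_values per-eye global rim widths from fundus images (px).
#' @param oct_g_values paired per-eye global RNFL thicknesses (um).
#' @return scalar factor f.
#' @export
calibrate_scale <- function(ret_g_values, oct_g_values) {
  if (length(ret_g_values) == 0 || length(oct_g_values) == 0)
    stop("empty calibration input")
  if (length(ret_g_values) != length(oct_g_values))
    stop("calibration inputs must be paired (same length)")
  if (any(ret_g_values <= 0) || any(oct_g_values <= 0))
    stop("calibration values must be positive")
  mean(oct_g_values) / mean(ret_g_values)
}

#' Extract all fundus features for one eye
#'
#' Convenience wrapper: fits both contours, computes the rim-width profile,
#' sector means, CDR and RDR.
#'
#' @param disc_points,cup_points contour point matrices.
#' @param laterality eye side.
#' @param n_angles angular sampling of the profile.
#' @param cdr_method passed to [compute_cdr()].
#' @param label identifier used in error messages.
#' @return list with `sector_profile`, `cdr`, `rdr`, `rdr_angle`,
#'   `disc_fit`, `cup_fit`, `profile`.
#' @export
fundus_features <- function(disc_points, cup_points, laterality,
                            n_angles = 360, cdr_method = "vertical",
                            label = "eye") {
  disc <- fit_ellipse(disc_points, label = paste(label, "disc"))
  cup <- fit_ellipse(cup_points, label = paste(label, "cup"))
  prof <- rim_width_profile(disc, cup, laterality, n_angles)
  rdr <- compute_rdr(prof)
  list(sector_profile = sector_means(prof),
       cdr = compute_cdr(disc, cup, method = cdr_method),
       rdr = rdr$rdr, rdr_angle = rdr$angle_deg,
       disc_fit = disc, cup_fit = cup, profile = prof)
}
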