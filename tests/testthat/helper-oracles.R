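# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's geometry/metric code paths.

SECTORS <- c("TS", "T", "TI", "NS", "N", "NI")
SECTORS_G <- c(SECTORS, "G")

# ellipse_fit-shaped object built directly from parameters
make_ellipse <- function(cx, cy, a, b, phi = 0) {
  structure(list(center = c(x = cx, y = cy), semi_major = a, semi_minor = b,
                 orientation = phi, rms_residual = 0),
            class = "ellipse_fit")
}

# dense polygon approximation of an ellipse boundary
ellipse_polygon <- function(fit, n = 4000) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  x <- fit$semi_major * cos(t); y <- fit$semi_minor * sin(t)
  phi <- fit$orientation
  cbind(fit$center[1] + x * cos(phi) - y * sin(phi),
        fit$center[2] + x * sin(phi) + y * cos(phi))
}

# far intersection distance of ray origin + t*dir with a closed polygon,
# by brute-force ray-segment intersection (the stated geometry oracle)
ray_polygon_dist <- function(origin, dir, poly) {
  p1 <- poly[-nrow(poly), , drop = FALSE]
  p2 <- poly[-1, , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  det <- dir[1] * (-ey) - dir[2] * (-ex)
  rx <- p1[, 1] - origin[1]; ry <- p1[, 2] - origin[2]
  t <- (rx * (-ey) + ry * ex) / det
  s <- (dir[1] * ry - dir[2] * rx) / det
  hit <- is.finite(t) & t > 0 & s >= 0 & s < 1
  if (!any(hit)) return(NA_real_)
  max(t[hit])
}

# rim width oracle: polygonal disc and cup, rays from the disc center at
# the given anatomic angles (laterality mapping re-derived independently)
oracle_rim_widths <- function(disc, cup, laterality, angles_deg, n_poly = 4000) {
  sx <- if (laterality %in% c("right", "OD")) -1 else 1
  dp <- ellipse_polygon(disc, n_poly)
  cp <- ellipse_polygon(cup, n_poly)
  vapply(angles_deg, function(a) {
    th <- a * pi / 180
    d <- c(sx * cos(th), -sin(th))
    td <- ray_polygon_dist(disc$center, d, dp)
    tc <- ray_polygon_dist(disc$center, d, cp)
    if (is.na(tc)) tc <- 0
    max(td - tc, 0)
  }, 0)
}

# hand-arithmetic asymmetry oracle on raw numbers (no package containers)
oracle_asymmetry <- function(wr, wl, coh_r, coh_l) {
  d <- wr - wl
  list(delta = d, absdelta = abs(d),
       rel = d / (wr + wl), absrel = abs(d) / (wr + wl),
       cohortrel = d / (coh_r + coh_l),
       globalrel = d / (wr[["G"]] + wl[["G"]]))
}

# random positive sector profile pair (returns raw named vectors incl. G)
random_sector_values <- function() {
  w <- stats::runif(6, 40, 160)
  names(w) <- c("TS", "T", "TI", "NS", "N", "NI")
  c(w, G = sum(w * c(45, 90, 45, 45, 90, 45)) / 360)
}

make_profile_pair <- function(wr, wl, modality = "OCT") {
  list(right = sector_profile(wr, modality, "right"),
       left = sector_profile(wl, modality, "left"))
}

# minimal OCT CSV on disk; rows = list of c(id, lat, 7 numbers)
write_tmp_oct <- function(rows, path = tempfile(fileext = ".csv")) {
  hdr <- "patient_id,laterality,TS,T,TI,NS,N,NI,G"
  writeLines(c(hdr, vapply(rows, paste, "", collapse = ",")), path)
  path
}

# small valid OCT row string with consistent G
oct_row_string <- function(id, lat, w = c(130, 70, 138, 100, 74, 108)) {
  g <- sum(w * c(45, 90, 45, 45, 90, 45)) / 360
  paste(c(id, lat, w, g), collapse = ",")
}

# random feasible disc/cup ellipse pair for geometry property tests
random_ellipse_pair <- function() {
  ad <- stats::runif(1, 80, 120)
  bd <- ad * stats::runif(1, 0.75, 1)
  disc <- make_ellipse(stats::runif(1, -5, 5), stats::runif(1, -5, 5),
                       ad, bd, stats::runif(1, 0, pi))
  ac <- bd * stats::runif(1, 0.25, 0.55)
  bc <- ac * stats::runif(1, 0.7, 1)
  off <- stats::runif(2, -0.15, 0.15) * bd
  cup <- make_ellipse(disc$center[1] + off[1], disc$center[2] + off[2],
                      ac, bc, stats::runif(1, 0, pi))
  list(disc = disc, cup = cup)
}
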