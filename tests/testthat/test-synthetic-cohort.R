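test_that("cohort_params validates its invariants", {
  expect_error(cohort_params(n_healthy = 0), "positive")
  expect_error(cohort_params(glaucoma_thinning_fraction = 1.2), "0, 1")
  expect_error(cohort_params(sigma_delta_healthy = 5,
                             sigma_delta_glaucoma = 2), "sigma")
  expect_error(cohort_params(ret_oct_slope = -1))
})

test_that("same params and seed give bit-identical cohorts", {
  p <- cohort_params(n_healthy = 6, n_glaucoma = 4, seed = 99)
  # bounded feasibility retries warn by design; they are seeded too
  a <- suppressWarnings(generate_cohort(p))
  b <- suppressWarnings(generate_cohort(p))
  expect_identical(a$oct, b$oct)
  expect_identical(a$labels, b$labels)
  expect_identical(a$patients[[3]]$contours, b$patients[[3]]$contours)
  c2 <- generate_cohort(cohort_params(n_healthy = 6, n_glaucoma = 4,
                                      seed = 100))
  expect_false(identical(a$oct, c2$oct))
})

test_that("degenerate noise gives exactly symmetric eyes in both modalities", {
  p <- cohort_params(n_healthy = 4, n_glaucoma = 3,
                     sigma_delta_healthy = 0, sigma_delta_glaucoma = 0,
                     ret_noise_sd = 0, seed = 12)
  co <- generate_cohort(p)
  stats_oct <- cohort_stats(lapply(co$patients, function(q) q$oct))
  stats_ret <- cohort_stats(lapply(co$patients, function(q) q$fundus))
  for (q in co$patients) {
    expect_equal(unname(q$oct$right$w), unname(q$oct$left$w))
    a <- compute_asymmetry(q$oct$right, q$oct$left, stats_oct)
    expect_equal(unname(a$delta), rep(0, 7))
    ar <- compute_asymmetry(q$fundus$right, q$fundus$left, stats_ret)
    expect_equal(unname(ar$delta), rep(0, 7), tolerance = 1e-9)
  }
})

test_that("law of large numbers: delta_G mean ~ 0, SD recovers sigma", {
  p <- cohort_params(n_healthy = 500, n_glaucoma = 2, seed = 23)
  co <- generate_cohort(p, modalities = "oct")
  healthy <- co$patients[vapply(co$patients, function(q)
    q$diagnosis == "healthy", TRUE)]
  dG <- vapply(healthy, function(q) q$oct$right$w[["G"]] - q$oct$left$w[["G"]],
               0)
  # delta_G is the angle-weighted mean of six iid N(0, sigma) sector deltas
  sd_G <- p$sigma_delta_healthy *
    sqrt(sum((c(45, 90, 45, 45, 90, 45) / 360)^2))
  expect_lt(abs(mean(dG)), 3 * sd_G / sqrt(500))
  expect_lt(abs(sd(dG) - sd_G) / sd_G, 0.10)
})

test_that("glaucoma class is thinner and more asymmetric", {
  p <- cohort_params(n_healthy = 200, n_glaucoma = 200, seed = 31)
  co <- generate_cohort(p, modalities = "oct")
  is_g <- vapply(co$patients, function(q) q$diagnosis == "glaucoma", TRUE)
  mg <- mean(vapply(co$patients[is_g], function(q) q$oct$right$w[["G"]], 0))
  mh <- mean(vapply(co$patients[!is_g], function(q) q$oct$right$w[["G"]], 0))
  expect_lt(mg, mh * 0.85)
  sd_g <- sd(unlist(lapply(co$patients[is_g], function(q)
    q$oct$right$w[SECTORS] - q$oct$left$w[SECTORS])))
  sd_h <- sd(unlist(lapply(co$patients[!is_g], function(q)
    q$oct$right$w[SECTORS] - q$oct$left$w[SECTORS])))
  expect_lt(abs(sd_h - p$sigma_delta_healthy) / p$sigma_delta_healthy, 0.1)
  expect_lt(abs(sd_g - p$sigma_delta_glaucoma) / p$sigma_delta_glaucoma, 0.1)
})

test_that("|Delta| centroid for glaucoma lies farther from the origin", {
  p <- cohort_params(n_healthy = 200, n_glaucoma = 200, seed = 37)
  co <- suppressWarnings(generate_cohort(p))  # both modalities
  fo <- cohort_features(co$patients, "OCT", metrics = "absrel")
  fr <- cohort_features(co$patients, "RET", metrics = "absrel")
  cen <- function(fx, cls) c(mean(fx$absrel_G[fx$label == cls]))
  d_h <- sqrt(cen(fr, "healthy")^2 + cen(fo, "healthy")^2)
  d_g <- sqrt(cen(fr, "glaucoma")^2 + cen(fo, "glaucoma")^2)
  expect_gt(d_g, d_h)
})

test_that("fundus extraction reproduces the generator's realized widths", {
  p <- cohort_params(n_healthy = 4, n_glaucoma = 3, seed = 53)
  co <- generate_cohort(p)
  for (q in co$patients[c(1, 5)]) {
    for (side in c("right", "left")) {
      lat <- side
      ff <- fundus_features(q$contours[[side]]$disc, q$contours[[side]]$cup,
                            laterality = lat)
      expect_equal(unname(ff$sector_profile$w), unname(q$fundus[[side]]$w),
                   tolerance = 0.02)  # design tolerance (2%)
      expect_equal(ff$cdr, q$cdr[[side]], tolerance = 1e-6)
    }
  }
})

test_that("scale calibration recovers ~ 1/slope from a generated cohort", {
  p <- cohort_params(n_healthy = 60, n_glaucoma = 20, seed = 61)
  co <- generate_cohort(p)
  ret_g <- unlist(lapply(co$patients, function(q)
    c(q$fundus$right$w["G"], q$fundus$left$w["G"])))
  oct_g <- unlist(lapply(co$patients, function(q)
    c(q$oct$right$w["G"], q$oct$left$w["G"])))
  f <- calibrate_scale(ret_g, oct_g)
  expect_lt(abs(f - 1 / p$ret_oct_slope) / (1 / p$ret_oct_slope), 0.03)
})

test_that("write_cohort emits the pipeline's input formats", {
  dir <- tempfile("cohort")
  co <- generate_cohort(cohort_params(n_healthy = 3, n_glaucoma = 2,
                                      seed = 71))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "oct.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(file.path(dir, "contours")), 5 * 2 * 2)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$params$seed, 71)
  oct <- read_oct_table(file.path(dir, "oct.csv"))
  expect_equal(nrow(oct$table), 10)
  expect_equal(nrow(oct$rejected), 0)
})
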