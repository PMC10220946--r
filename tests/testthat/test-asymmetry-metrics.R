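test_that("compute_asymmetry reproduces the hand-arithmetic case", {
  # single-patient worked example (sector T): w_T 100 vs 80, G 95 vs 90
  wr <- c(TS = 100, T = 100, TI = 100, NS = 100, N = 100, NI = 100, G = 95)
  wl <- c(TS = 100, T = 80, TI = 100, NS = 100, N = 100, NI = 100, G = 90)
  stats <- cohort_stats(list(make_profile_pair(
    c(TS = 92, T = 92, TI = 92, NS = 92, N = 92, NI = 92, G = 92),
    c(TS = 94, T = 94, TI = 94, NS = 94, N = 94, NI = 94, G = 94))))
  a <- compute_asymmetry(sector_profile(wr, "OCT", "right"),
                         sector_profile(wl, "OCT", "left"), stats)
  expect_equal(a$delta[["T"]], 20)
  expect_equal(a$absdelta[["T"]], 20)
  expect_equal(a$rel[["T"]], 20 / 180)
  expect_equal(a$cohortrel[["T"]], 20 / 186)
  expect_equal(a$globalrel[["T"]], 20 / 185)
})

test_that("identical eyes give all-zero metrics; CDR/RDR differences", {
  w <- random_sector_values()
  pair <- make_profile_pair(w, w)
  stats <- cohort_stats(list(pair))
  a <- compute_asymmetry(pair$right, pair$left, stats,
                         cdr_r = 0.4, cdr_l = 0.3, rdr_r = 0.2, rdr_l = 0.25)
  for (m in c("delta", "absdelta", "rel", "absrel", "cohortrel", "globalrel"))
    expect_equal(unname(a[[m]]), rep(0, 7))
  expect_equal(a$abs_dcdr, 0.1)
  expect_equal(a$abs_drdr, 0.05)
})

test_that("antisymmetry under right/left swap; scale invariance", {
  set.seed(31)
  for (i in 1:25) {
    wr <- random_sector_values(); wl <- random_sector_values()
    stats <- cohort_stats(list(make_profile_pair(wr, wl)))
    a <- compute_asymmetry(sector_profile(wr, "OCT", "right"),
                           sector_profile(wl, "OCT", "left"), stats,
                           cdr_r = 0.4, cdr_l = 0.32,
                           rdr_r = 0.21, rdr_l = 0.18)
    stats_sw <- cohort_stats(list(make_profile_pair(wl, wr)))
    b <- compute_asymmetry(sector_profile(wl, "OCT", "right"),
                           sector_profile(wr, "OCT", "left"), stats_sw,
                           cdr_r = 0.32, cdr_l = 0.4,
                           rdr_r = 0.18, rdr_l = 0.21)
    for (m in c("delta", "rel", "cohortrel", "globalrel"))
      expect_equal(unname(a[[m]]), -unname(b[[m]]))
    for (m in c("absdelta", "absrel"))
      expect_equal(unname(a[[m]]), unname(b[[m]]))
    expect_equal(a$abs_dcdr, b$abs_dcdr)
    expect_equal(a$abs_drdr, b$abs_drdr)

    # scaling both eyes by c > 0: rel/globalrel invariant, delta scales
    cc <- 3.7
    stats_sc <- cohort_stats(list(make_profile_pair(cc * wr, cc * wl)))
    s <- compute_asymmetry(sector_profile(cc * wr, "OCT", "right"),
                           sector_profile(cc * wl, "OCT", "left"), stats_sc)
    expect_equal(unname(s$rel), unname(a$rel), tolerance = 1e-12)
    expect_equal(unname(s$globalrel), unname(a$globalrel), tolerance = 1e-12)
    expect_equal(unname(s$delta), cc * unname(a$delta), tolerance = 1e-12)
  }
})

test_that("cohort_stats: single patient, arithmetic, generator recovery", {
  w <- random_sector_values()
  st1 <- cohort_stats(list(make_profile_pair(w, w)))
  expect_equal(st1$right, w[SECTORS_G])

  p1 <- make_profile_pair(random_sector_values(), random_sector_values())
  p1$right$w["G"] <- 90  # direct arithmetic on G
  p2 <- make_profile_pair(random_sector_values(), random_sector_values())
  p2$right$w["G"] <- 110
  st2 <- cohort_stats(list(p1, p2))
  expect_equal(st2$right[["G"]], 100)

  # 500 synthetic patients: sector means within 3 SE of generator means
  pr <- cohort_params(n_healthy = 500, n_glaucoma = 2, seed = 5)
  co <- generate_cohort(pr, modalities = "oct")
  healthy <- co$patients[vapply(co$patients, function(p)
    p$diagnosis == "healthy", TRUE)]
  pairs <- lapply(healthy, function(p) p$oct)
  st <- cohort_stats(pairs)
  se <- sqrt(pr$patient_jitter_sd^2 + (pr$sigma_delta_healthy / 2)^2) /
    sqrt(500)
  expect_true(all(abs(st$right[1:6] - pr$oct_sector_means_healthy) < 3.5 * se))
})

test_that("mean |delta| matches the half-normal prediction", {
  pr <- cohort_params(n_healthy = 400, n_glaucoma = 100,
                      sigma_delta_healthy = 3, sigma_delta_glaucoma = 9,
                      seed = 17)
  co <- generate_cohort(pr, modalities = "oct")
  fx <- cohort_features(co$patients, "OCT", metrics = c("delta", "absdelta"))
  for (cls in c("healthy", "glaucoma")) {
    sig <- if (cls == "healthy") 3 else 9
    d <- as.matrix(fx[fx$label == cls, paste0("delta_", SECTORS)])
    ad <- as.matrix(fx[fx$label == cls, paste0("absdelta_", SECTORS)])
    n <- length(d)
    expect_lt(abs(mean(d)), 3 * sig / sqrt(n))         # zero-mean Gaussian
    expect_lt(abs(mean(ad) - sig * sqrt(2 / pi)),      # half-normal mean
              4 * sig * sqrt(1 - 2 / pi) / sqrt(n))
  }
})

test_that("zero denominators raise errors naming the metric", {
  wz <- c(TS = 0, T = 0, TI = 0, NS = 0, N = 0, NI = 0, G = 0)
  w <- random_sector_values()
  stats <- cohort_stats(list(make_profile_pair(w, w)))
  expect_error(
    compute_asymmetry(sector_profile(wz, "OCT", "right"),
                      sector_profile(wz, "OCT", "left"), stats),
    "rel")
})

test_that("feature_matrix lays out {metric}_{sector} columns plus label", {
  wr <- random_sector_values(); wl <- random_sector_values()
  stats <- cohort_stats(list(make_profile_pair(wr, wl)))
  a <- compute_asymmetry(sector_profile(wr, "OCT", "right"),
                         sector_profile(wl, "OCT", "left"), stats,
                         cdr_r = .4, cdr_l = .3, rdr_r = .2, rdr_l = .1)
  fx <- feature_matrix(list(P1 = a), labels = "glaucoma")
  expect_true(all(c("absrel_TS", "delta_G", "abs_dcdr", "abs_drdr",
                    "label") %in% names(fx)))
  expect_equal(fx$absrel_T, abs(wr[["T"]] - wl[["T"]]) / (wr[["T"]] + wl[["T"]]))
  expect_equal(fx$label, "glaucoma")
})
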