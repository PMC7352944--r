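test_that("kNN imputation reproduces hand-computed neighbour means", {
  # sample s3 is identical to s1 on observed features; k = 1 copies s1
  m <- rbind(c(1, 2, 3), c(10, 20, 30), c(1, 2, NA))
  tab <- ft(m)
  out <- impute_missing(tab, k = 1)
  expect_equal(unclass(out)["s03", "f03"], 3)
  expect_equal(unclass(out)[1:2, ], unclass(tab)[1:2, ])

  # two equidistant donors with values 2 and 4 average to 3
  m2 <- rbind(c(0, 1, 2), c(0, -1, 4), c(0, 0, NA))
  out2 <- impute_missing(ft(m2), k = 2)
  expect_equal(unclass(out2)["s03", "f03"], 3)
})

test_that("imputation is the identity on complete tables", {
  tab <- ft(matrix(rnorm(20), 4, 5))
  expect_identical(impute_missing(tab, k = 3), tab)
})

test_that("imputation rejects all-missing features and clamps large k", {
  m <- rbind(c(NA, 1), c(NA, 2), c(NA, 3))
  expect_error(impute_missing(ft(m), k = 1), "f01")
  m2 <- rbind(c(1, 1), c(2, 2), c(NA, 1.5))
  expect_warning(out <- impute_missing(ft(m2), k = 10), "clamped")
  expect_false(anyNA(unclass(out)))
})

test_that("referencing shifts the standard peak onto 0.00 ppm", {
  peaks <- data.frame(center = 3, height = 1, hwhm = 0.05)
  mis <- generate_spectra(spectrum_spec(peaks = peaks, noise_sd = 0,
                                        reference_peak_offset = 0.02,
                                        seed = 1), 1)$spectra
  ref <- reference_to_standard(mis)
  win <- abs(ref$ppm) <= 0.2
  peak_at <- ref$ppm[win][which.max(ref$intensities[1, win])]
  expect_lt(abs(peak_at), diff(ref$ppm[1:2]) + 1e-12)

  # already referenced: identity
  ok <- generate_spectra(spectrum_spec(peaks = peaks, noise_sd = 0,
                                       seed = 1), 1)$spectra
  expect_equal(reference_to_standard(ok)$intensities, ok$intensities)
})

test_that("referencing aligns opposite offsets to within one grid step", {
  peaks <- data.frame(center = 3, height = 1, hwhm = 0.05)
  a <- generate_spectra(spectrum_spec(peaks = peaks, noise_sd = 0,
                                      reference_peak_offset = 0.01, seed = 1),
                        1)$spectra
  b <- generate_spectra(spectrum_spec(peaks = peaks, noise_sd = 0,
                                      reference_peak_offset = -0.01, seed = 1),
                        1)$spectra
  both <- spectrum_set(a$ppm, rbind(a$intensities, b$intensities))
  ref <- reference_to_standard(both)
  centers <- apply(ref$intensities, 1, function(y) {
    win <- abs(ref$ppm - 3) < 0.5
    ref$ppm[win][which.max(y[win])]
  })
  expect_lt(abs(centers[1] - centers[2]), diff(ref$ppm[1:2]) + 1e-12)
})

test_that("referencing warns on a flat window and applies no shift", {
  s <- spectrum_set(seq(-1, 1, 0.01), matrix(1, 1, 201))
  expect_warning(out <- reference_to_standard(s), "flat")
  expect_equal(out$intensities, s$intensities)
})

test_that("bucket counts follow the grid arithmetic", {
  s <- spectrum_set(seq(-0.1, 1.1, 0.001), matrix(1, 1, 1201))
  bt <- bucket_spectra(s, bucketing_config(width = 0.01, region = c(0, 1),
                                           exclusions = list()))
  expect_equal(ncol(bt$values), 100)
  # constant unit intensity: every full bucket integrates to its width
  expect_equal(unname(bt$values[1, ]), rep(0.01, 100), tolerance = 1e-12)

  s2 <- spectrum_set(seq(0, 9, 0.001), matrix(rexp(9001), 1))
  bt2 <- bucket_spectra(s2, bucketing_config(width = 0.01,
                                             region = c(0.261, 8.757),
                                             exclusions = list()))
  expect_equal(ncol(bt2$values), 850)
  # final bucket truncated at the high edge
  expect_equal(unname(bt2$intervals[850, ]), c(8.751, 8.757))
})

test_that("bucketing drops any-overlap exclusion buckets but conserves mass", {
  set.seed(7)
  s <- spectrum_set(seq(0, 9, 0.002), matrix(rexp(2 * 4501), 2))
  cfg <- bucketing_config()
  bt <- bucket_spectra(s, cfg)
  whole <- vapply(1:2, function(i)
    bilepanel:::trapz_interval(s$ppm, s$intensities[i, ], 0.261, 8.757),
    numeric(1))
  total <- rowSums(bt$values) + rowSums(bt$dropped$values)
  expect_equal(unname(total), whole, tolerance = 1e-9)
  # every kept bucket is clear of every exclusion region
  for (e in cfg$exclusions)
    expect_true(all(bt$intervals[, "high"] <= e[1] |
                    bt$intervals[, "low"] >= e[2]))
})

test_that("out-of-axis regions and rogue exclusions are handled", {
  s <- spectrum_set(seq(0, 5, 0.01), matrix(1, 1, 501))
  expect_error(bucket_spectra(s, bucketing_config(region = c(0.261, 8.757),
                                                  exclusions = list())),
               "outside")
  expect_warning(bucketing_config(region = c(0, 1),
                                  exclusions = list(c(2, 3))), "ignored")
})

test_that("total-area normalization makes rows sum to one", {
  set.seed(1)
  s <- spectrum_set(seq(0, 2, 0.01), matrix(rexp(3 * 201), 3))
  bt <- normalize_buckets(bucket_spectra(s, bucketing_config(
    width = 0.05, region = c(0, 2), exclusions = list())), "total_area")
  expect_equal(unname(rowSums(bt$values)), rep(1, 3), tolerance = 1e-9)
  expect_equal(bt$normalization, "total_area")
})

test_that("PQN matches the hand-computed quotient example", {
  bt <- structure(list(
    intervals = cbind(low = c(0, 1, 2), high = c(1, 2, 3)),
    values = matrix(c(2, 4, 9), 1, dimnames = list("s1", NULL)),
    normalization = "raw", dilution = c(s1 = 1), pqn_factor = NULL,
    dropped = list(intervals = NULL, values = matrix(0, 1, 0))),
    class = "bucket_table")
  out <- normalize_buckets(bt, "pqn", reference = c(1, 2, 3))
  expect_equal(unname(out$pqn_factor), 2)   # quotients 2, 2, 3
  expect_equal(unname(out$values[1, ]), c(1, 2, 4.5))

  # a row that is exactly twice the reference collapses onto it
  bt$values <- matrix(2 * c(1, 2, 3), 1, dimnames = list("s1", NULL))
  out2 <- normalize_buckets(bt, "pqn", reference = c(1, 2, 3))
  expect_equal(unname(out2$pqn_factor), 2)
  expect_equal(unname(out2$values[1, ]), c(1, 2, 3))
})

test_that("zero-total rows are rejected by name", {
  bt <- structure(list(
    intervals = cbind(low = 0, high = 1),
    values = matrix(c(1, 0), 2, 1, dimnames = list(c("good", "bad"), NULL)),
    normalization = "raw", dilution = c(good = 1, bad = 1), pqn_factor = NULL,
    dropped = list(intervals = NULL, values = matrix(0, 2, 0))),
    class = "bucket_table")
  expect_error(normalize_buckets(bt, "total_area"), "bad")
})

test_that("the total-area + PQN chain recovers relative dilution factors", {
  peaks <- data.frame(center = c(1.2, 2.1, 5.5, 7.3),
                      height = c(3, 1, 2, 4), hwhm = c(0.02, 0.03, 0.02, 0.05))
  d_true <- seq(0.5, 2, length.out = 10)
  sim <- generate_spectra(spectrum_spec(peaks = peaks,
                                        dilution_factors = d_true,
                                        noise_sd = 0, seed = 9), 10)
  bt <- bucket_spectra(sim$spectra, bucketing_config(exclusions = list()))
  bt <- normalize_buckets(normalize_buckets(bt, "total_area"), "pqn")
  est <- unname(bt$dilution)
  # identifiable up to the reference scale: rescale by matching medians
  est <- est * stats::median(d_true) / stats::median(est)
  expect_lt(max(abs(est / d_true - 1)), 1e-9)
})
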