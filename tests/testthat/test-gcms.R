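# noiseless trace with Gaussian peaks at known apexes
synth_trace <- function(apexes, heights, sigma = 0.02, baseline = 0.2,
                        label = "CD", id = "S1") {
  rt <- seq(2, 11, by = 0.005)
  y <- rep(baseline, length(rt))
  for (i in seq_along(apexes)) {
    y <- y + heights[i] * exp(-(rt - apexes[i])^2 / (2 * sigma^2))
  }
  chromatogram(id, label, rt, y)
}

test_that("only peaks above the 1.8 MCps threshold are reported", {
  ch <- synth_trace(c(4.0, 6.0), c(2.5, 1.0))
  pk <- detect_peaks(ch, threshold = 1.8)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$rt_apex - 4.0), 0.01)
  expect_true(all(pk$height > 1.8))

  # flat zero trace: nothing
  flat <- chromatogram("Z", "CD", seq(2, 4, by = 0.01), rep(0, 201))
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("close peaks separated by 5 sigma are both resolved near truth", {
  ch <- synth_trace(c(5.0, 5.0 + 5 * 0.02), c(2.5, 2.2))
  pk <- detect_peaks(ch, threshold = 1.8)
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$rt_apex[1] - 5.0), 0.0051)
  expect_lt(abs(pk$rt_apex[2] - 5.1), 0.0051)
  # bounds bracket apexes
  expect_true(all(pk$left < pk$rt_apex & pk$rt_apex < pk$right))
})

test_that("peak detection rejects malformed traces", {
  expect_error(chromatogram("a", "CD", c(1, 3, 2), c(0, 0, 0)),
               "strictly increasing")
  expect_error(chromatogram("a", "CD", c(-1, 2, 3), c(0, 0, 0)),
               "non-negative")
  expect_error(detect_peaks(chromatogram("a", "CD", c(1, 2), c(0, 0))),
               "at least 3")
})

test_that("retention-time binning groups by tolerance into bounded bins", {
  peaks <- data.frame(rt_apex = c(4.66, 4.68, 7.95),
                      height = c(2, 2, 3),
                      sample_id = c("s1", "s2", "s1"),
                      label = c("CD", "CD", "D-IBS"))
  bins <- bin_retention_times(peaks, tolerance = 0.05)
  expect_identical(nrow(bins), 2L)
  expect_equal(bins$center, c(4.67, 7.95))
  expect_identical(bins$n_cd, c(2L, 0L))
  expect_identical(bins$n_ibs, c(0L, 1L))

  # single peak: one bin centred on its apex
  single <- bin_retention_times(peaks[3, ], tolerance = 0.05)
  expect_identical(nrow(single), 1L)
  expect_equal(single$center, 7.95)

  # no peaks: no bins
  expect_identical(nrow(bin_retention_times(peaks[0, ], 0.05)), 0L)
  expect_error(bin_retention_times(peaks, tolerance = 0), "> 0")
})

test_that("binning is a partition with span at most twice the tolerance", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    peaks <- data.frame(rt_apex = round(runif(n, 2, 11), 3),
                        height = runif(n, 2, 5),
                        sample_id = sample(letters[1:6], n, replace = TRUE),
                        label = sample(c("CD", "D-IBS"), n, replace = TRUE))
    tol <- runif(1, 0.02, 0.2)
    bins <- bin_retention_times(peaks, tolerance = tol)
    members <- unname(unlist(bins$members))
    expect_identical(sort(members), seq_len(n))       # every peak, once
    expect_identical(sum(bins$n_peaks), n)
    for (b in seq_len(nrow(bins))) {
      rts <- peaks$rt_apex[bins$members[[b]]]
      expect_lte(max(rts) - min(rts), 2 * tol + 1e-12)
      expect_true(all(abs(rts - bins$center[b]) <= tol + 1e-12))
    }
  }
})

test_that("class-unique bins require near-universal presence and strict absence", {
  mk_bins <- function(n_cd, n_ibs, center = 4.67) {
    peaks <- data.frame(
      rt_apex = rep(center, n_cd + n_ibs),
      height = 2,
      sample_id = c(sprintf("cd%d", seq_len(n_cd)),
                    sprintf("ib%d", seq_len(n_ibs))),
      label = rep(c("CD", "D-IBS"), c(n_cd, n_ibs)))
    bin_retention_times(peaks[peaks$rt_apex > 0, ], 0.05)
  }
  # present in all 20 CD, absent in controls -> flagged
  u <- find_class_unique_peaks(mk_bins(20, 0), n_cd = 20, n_ibs = 15)
  expect_identical(nrow(u), 1L)
  expect_identical(u$unique_class, "CD")
  expect_equal(u$prev_cd, 1)

  # 100% CD but 5% of controls -> absence is violated, not returned
  u2 <- find_class_unique_peaks(mk_bins(20, 1), n_cd = 20, n_ibs = 20)
  expect_identical(nrow(u2), 0L)

  # identical peak sets in both classes -> nothing unique
  u3 <- find_class_unique_peaks(mk_bins(10, 10), n_cd = 10, n_ibs = 10)
  expect_identical(nrow(u3), 0L)

  # below the prevalence floor -> not returned
  u4 <- find_class_unique_peaks(mk_bins(10, 0), n_cd = 20, n_ibs = 10)
  expect_identical(nrow(u4), 0L)
})

test_that("chromatogram CSV round-trips through the two-column dialect", {
  ch <- synth_trace(5.0, 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, f)
  expect_identical(readLines(f)[1], "rt_min,intensity_mcps")
  back <- read_chromatogram(f, "S1", "CD")
  expect_equal(back$rt, ch$rt)
  expect_equal(back$intensity, ch$intensity, tolerance = 1e-12)
})

test_that("screen finds exactly the planted coeliac marker end to end", {
  chroms <- generate_chromatograms(n_cd = 8, n_ibs = 6, seed = 4)
  res <- screen_chromatograms(c(chroms$CD, chroms$`D-IBS`))
  expect_true(all(res$peaks$height > 1.8))
  expect_identical(nrow(res$unique_bins), 1L)
  expect_identical(res$unique_bins$unique_class, "CD")
  expect_lt(abs(res$unique_bins$center - 4.67), 0.05)
  # the shared volatiles bin across both classes at full prevalence
  shared <- res$bins[res$bins$n_cd == 8 & res$bins$n_ibs == 6, ]
  expect_gte(nrow(shared), 4L)
})
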