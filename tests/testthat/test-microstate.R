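# helper: build a recording that alternates two fixed topographies
alternating_topo_recording <- function(maps, seg_len = 25, n_seg = 100,
                                       amp_sd = 0.3, noise_sd = 0.02,
                                       fs = 250, seed = 1,
                                       flip_segment = NULL) {
  set.seed(seed)
  C <- ncol(maps)
  dat <- matrix(0, C, seg_len * n_seg)
  for (s in seq_len(n_seg)) {
    k <- 1 + (s - 1) %% nrow(maps)
    amp <- abs(1 + rnorm(seg_len, 0, amp_sd))
    seg <- outer(maps[k, ], amp)
    if (!is.null(flip_segment) && s %in% flip_segment) seg <- -seg
    dat[, ((s - 1) * seg_len + 1):(s * seg_len)] <- seg
  }
  dat <- dat + matrix(rnorm(length(dat), 0, noise_sd), C)
  rec <- eeg_recording(dat, fs, paste0("CH", seq_len(C)))
  epoch_recording(rec, seg_len * 2 / fs)
}

orthonormal_centered_maps <- function(C = 8, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(2 * C), 2, C)
  m <- m - rowMeans(m)                  # average-referenced
  m[1, ] <- m[1, ] / sqrt(sum(m[1, ]^2))
  m[2, ] <- m[2, ] - sum(m[2, ] * m[1, ]) * m[1, ]
  m[2, ] <- m[2, ] / sqrt(sum(m[2, ]^2))
  m
}

test_that("GFP is the per-sample channel SD and scales with amplitude", {
  x <- cbind(c(1, -1, 0, 0))
  expect_equal(gfp(x), sd(c(1, -1, 0, 0)))
  set.seed(2)
  y <- matrix(rnorm(40), 8)
  expect_equal(gfp(3 * y), 3 * gfp(y))
  const <- matrix(5, 4, 10)
  const <- sweep(const, 2, colMeans(const))   # average reference
  expect_equal(gfp(const), rep(0, 10))
})

test_that("local GFP maxima are detected", {
  g <- c(1, 3, 2, 5, 4, 4, 6, 1)
  expect_equal(gfp_peaks(g), c(2L, 4L, 7L))
  expect_length(gfp_peaks(c(1, 2)), 0)
})

test_that("two planted topographies are recovered with |r| >= 0.99", {
  maps <- orthonormal_centered_maps()
  ep <- alternating_topo_recording(maps)
  peaks <- pool_gfp_peaks(list(ep), seed = 1)
  fit <- fit_microstates(peaks, k = 2, seed = 3)
  cors <- abs(cor(t(fit$maps), t(maps)))
  # each true map matched by some fitted map
  expect_gte(max(cors[, 1]), 0.99)
  expect_gte(max(cors[, 2]), 0.99)
  expect_gte(fit$gev, 0.9)
})

test_that("fitting is polarity-invariant and seed-deterministic", {
  maps <- orthonormal_centered_maps()
  ep1 <- alternating_topo_recording(maps, noise_sd = 0)
  ep2 <- alternating_topo_recording(maps, noise_sd = 0,
                                    flip_segment = c(3, 10, 41))
  f1 <- fit_microstates(pool_gfp_peaks(list(ep1), seed = 1), 2, seed = 3)
  f2 <- fit_microstates(pool_gfp_peaks(list(ep2), seed = 1), 2, seed = 3)
  expect_equal(abs(f1$maps), abs(f2$maps), tolerance = 1e-8)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-10)
  f1b <- fit_microstates(pool_gfp_peaks(list(ep1), seed = 1), 2, seed = 3)
  expect_identical(f1$maps, f1b$maps)
})

test_that("k = 1 reduces to the dominant eigenvector of the peak maps", {
  maps <- orthonormal_centered_maps()
  ep <- alternating_topo_recording(maps, seed = 9)
  peaks <- pool_gfp_peaks(list(ep), seed = 1)
  fit <- fit_microstates(peaks, k = 1, seed = 2)
  x <- sweep(peaks, 2, colMeans(peaks))
  eig <- eigen(tcrossprod(x), symmetric = TRUE)
  expect_gte(abs(sum(fit$maps[1, ] * eig$vectors[, 1])), 1 - 1e-8)
  expect_equal(fit$gev, eig$values[1] / sum(eig$values), tolerance = 1e-8)
})

test_that("GEV does not decrease with k", {
  maps <- orthonormal_centered_maps()
  ep <- alternating_topo_recording(maps, noise_sd = 0.3)
  peaks <- pool_gfp_peaks(list(ep), seed = 1)
  gev <- vapply(1:4, function(k)
    fit_microstates(peaks, k, n_restarts = 20, seed = 4)$gev, 0)
  expect_true(all(diff(gev) > -0.01))
})

test_that("backfit statistics match a constructed label sequence", {
  maps <- orthonormal_centered_maps()
  # alternating A/B segments of 100 ms (25 samples at 250 Hz) over 10 s
  ep <- alternating_topo_recording(maps, seg_len = 25, n_seg = 100,
                                   noise_sd = 0)
  model <- structure(list(maps = maps, gev = 1, k = 2),
                     class = "microstate_model")
  st <- backfit_microstates(model, ep, min_duration = 30)
  expect_equal(unname(st$coverage), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(st$occurrence_hz), c(5, 5), tolerance = 0.05)
  expect_equal(unname(st$duration_ms), c(100, 100), tolerance = 1)
  expect_equal(st$transitions, rbind(MS1 = c(0, 1), MS2 = c(1, 0)),
               ignore_attr = TRUE)
  expect_equal(sum(st$coverage), 1, tolerance = 1e-9)
})

test_that("backfit statistics are invariant to amplitude scaling", {
  maps <- orthonormal_centered_maps()
  ep <- alternating_topo_recording(maps, noise_sd = 0.1)
  model <- structure(list(maps = maps, gev = 1, k = 2),
                     class = "microstate_model")
  s1 <- backfit_microstates(model, ep)
  ep$data <- ep$data * 7.5
  s2 <- backfit_microstates(model, ep)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s1$coverage, s2$coverage)
  expect_equal(s1$transitions, s2$transitions)
})

test_that("insufficient GFP peaks raise a quality error", {
  maps <- orthonormal_centered_maps()
  expect_error(fit_microstates(t(maps)[, c(1, 2), drop = FALSE], k = 2),
               "quality error")
})
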