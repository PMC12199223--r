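make_stack <- function(m_fun, wl = 550:700, h = 8, w = 8,
                       irf_level = 0.5) {
  n_w <- length(wl)
  cube <- array(0, c(h, w, n_w))
  for (k in seq_len(n_w)) cube[, , k] <- irf_level * m_fun(k, h, w)
  irf <- array(irf_level, c(h, w, n_w))
  pws_stack(wl, cube, irf)
}

test_that("sigma map is zero without fluctuation and a/sqrt(2) for sinusoids", {
  st <- make_stack(function(k, h, w) matrix(1, h, w))
  expect_true(all(compute_pws_image(st)$sigma_map == 0))

  # whole discrete periods: population sd of the sinusoid is exactly
  # a / sqrt(2) on the 151-point grid
  a <- 0.04
  n_w <- 151
  st2 <- make_stack(function(k, h, w)
    matrix(1 + a * sin(2 * pi * 3 * (k - 1) / n_w), h, w))
  sig <- compute_pws_image(st2)$sigma_map
  expect_lt(max(abs(sig - a / sqrt(2))) / (a / sqrt(2)), 1e-3)

  # homogeneity: doubling the fluctuation amplitude doubles sigma
  st3 <- make_stack(function(k, h, w)
    matrix(1 + 2 * a * sin(2 * pi * 3 * (k - 1) / n_w), h, w))
  expect_equal(compute_pws_image(st3)$sigma_map, 2 * sig,
               tolerance = 1e-10)
})

test_that("sigma map is invariant to a common per-wavelength factor", {
  set.seed(5)
  wl <- 550:700
  cube <- array(0.3 + 0.05 * runif(8 * 8 * 151), c(8, 8, 151))
  irf <- array(rep(0.4 + 0.001 * (wl - 550), each = 64), c(8, 8, 151))
  st <- pws_stack(wl, cube, irf)
  fac <- 0.5 + 0.3 * sin(wl / 20)^2
  st2 <- pws_stack(wl, sweep(cube, 3, fac, `*`),
                   sweep(irf, 3, fac, `*`))
  expect_equal(compute_pws_image(st)$sigma_map,
               compute_pws_image(st2)$sigma_map, tolerance = 1e-12)
})

test_that("quantization bins uniformly and collapses constants", {
  expect_true(all(quantize_image(matrix(2.2, 5, 5), 16) == 1L))

  two <- matrix(c(0, 1), 4, 4)
  q2 <- quantize_image(two, 2)
  expect_identical(sort(unique(as.vector(q2))), c(1L, 2L))
  expect_identical(q2 == 2L, two == 1)

  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  q4 <- quantize_image(ramp, 4)
  expect_equal(as.vector(table(q4)), c(16, 16, 16, 16))
})

test_that("GLCM matches closed forms and the exhaustive-pair oracle", {
  one <- matrix(1L, 4, 4)
  p <- compute_glcm(one, c(0, 1), levels = 1)
  expect_equal(p, matrix(1, 1, 1))

  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)
  cb <- (row(cb) + col(cb)) %% 2L + 1L
  pcb <- compute_glcm(cb, c(0, 1), levels = 2)
  expect_equal(pcb, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  set.seed(10)
  for (rep in 1:10) {
    img <- matrix(sample.int(4L, 64, replace = TRUE), 8, 8)
    off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, 2), c(2, -3))[[sample.int(6, 1)]]
    expect_equal(compute_glcm(img, off, levels = 4),
                 glcm_oracle(img, off, 4), tolerance = 1e-14)
  }

  set.seed(11)
  img <- matrix(sample.int(4L, 64, replace = TRUE), 8, 8)
  expect_equal(sum(compute_glcm(img, c(1, 1), levels = 4)), 1,
               tolerance = 1e-12)
  expect_error(compute_glcm(img, c(0, 0)), "nonzero")
  expect_error(compute_glcm(img, c(9, 0)), "bounds")
})

test_that("IDM hits its closed-form values and decreases off-diagonal", {
  expect_equal(idm(diag(c(0.3, 0.3, 0.4))), 1)
  expect_equal(idm(matrix(c(0, 0.5, 0.5, 0), 2, 2)), 0.5)
  # moving mass off the diagonal strictly decreases IDM
  p1 <- diag(2) / 2
  p2 <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  expect_lt(idm(p2), idm(p1))
  expect_error(idm(diag(2)), "normalized")
})

test_that("IDM curves behave on constant, white and smooth images", {
  cimg <- structure(list(sigma_map = matrix(1, 16, 16), fov_id = "c",
                         detrend = "mean"), class = "pws_image")
  cv <- idm_curve(cimg, max_offset = 5)
  expect_true(all(cv$idm == 1))

  # white noise: flat curve at the value implied by the level histogram
  set.seed(12)
  wimg <- matrix(rnorm(96 * 96), 96, 96)
  q <- quantize_image(wimg, 8)
  h <- tabulate(q, 8) / length(q)
  expected <- sum(outer(h, h) / (1 + outer(1:8, 1:8, `-`)^2))
  cvw <- idm_curve(q, max_offset = 6)
  expect_true(all(abs(cvw$idm - expected) / expected < 0.1))
  expect_lt(diff(range(cvw$idm)) / expected, 0.1)

  # smoothed noise: IDM decays with offset beyond the correlation length
  set.seed(13)
  simg <- ramanpws:::smooth_field(matrix(rnorm(64 * 64), 64, 64), 3)
  cvs <- idm_curve(simg, max_offset = 10)
  expect_gt(cvs$idm[1], cvs$idm[6])
  expect_gt(cvs$idm[3], cvs$idm[10])
  expect_error(idm_curve(simg, max_offset = 64), "smaller")
})

test_that("group curve summaries average pointwise and flag mismatches", {
  c1 <- idm_curve(quantize_image(matrix(runif(64), 8, 8), 4),
                  max_offset = 3)
  s1 <- summarize_group_curves(list(c1), "a")
  expect_equal(s1$mean_idm, c1$idm)
  expect_true(all(s1$sd_idm == 0))

  s2 <- summarize_group_curves(list(c1, c1), c("a", "a"))
  expect_true(all(s2$sd_idm == 0))

  c2 <- idm_curve(quantize_image(matrix(runif(64), 8, 8), 4),
                  max_offset = 2)
  expect_error(summarize_group_curves(list(c1, c2), c("a", "b")),
               "offsets")
})

test_that("higher disorder shifts group IDM in a consistent direction", {
  cfg <- small_config(image_shape = c(48, 48),
                      disorder_amplitude = c(control = 0.015,
                                             disease = 0.05))
  idm1 <- function(group, seed) {
    st <- generate_pws_stack(cfg, group, seed)
    idm_curve(compute_pws_image(st), max_offset = 5)$idm[1]
  }
  lo <- vapply(1:6, function(i) idm1("control", i), numeric(1))
  hi <- vapply(1:6, function(i) idm1("disease", 100 + i), numeric(1))
  # stronger disorder dominates the camera-noise floor, so the sigma map
  # is smoother relative to its dynamic range: higher IDM at offset 1
  expect_gt(mean(hi), mean(lo))
})
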