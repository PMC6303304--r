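test_that("background correction removes flat fields and ramps but keeps blobs", {
  flat <- matrix(123.4, 64, 64)
  out <- background_correct(flat, 20)
  expect_lt(max(abs(out)), 1e-6)
  expect_error(background_correct(flat, -1), "positive")

  # ramp + blob on a 128 x 128 frame
  ramp <- matrix(rep(seq(0, 400, length.out = 128), each = 128), 128, 128)
  blob <- blob_image(128, 128, cbind(64, 64), amplitude = 500, sigma = 5)
  corr <- background_correct(ramp + blob, 50)
  ramp_resid <- background_correct(ramp, 50)
  # flat-fielding is judged away from the frame border
  expect_lt(max(abs(ramp_resid[17:112, 17:112])), 400 / 10)
  peak <- max(corr)
  expect_gt(peak, 0.8 * 500)
  expect_lt(abs(peak - 500) / 500, 0.2)
  # peak position unchanged for a blob on zero background
  cb <- background_correct(blob, 50)
  w <- which(cb == max(cb), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(65, 65))
})

test_that("local contrast normalization equalizes amplitudes", {
  expect_lt(max(abs(local_contrast_normalize(matrix(7, 64, 64), 16))), 1e-3)
  expect_error(local_contrast_normalize(matrix(0, 10, 10), 32), "larger")

  set.seed(1)
  noise <- matrix(rnorm(128 * 256, 0, 20), 128, 256)
  img <- noise + blob_image(128, 256, cbind(60, 64), 100, 5) +
    blob_image(128, 256, cbind(190, 64), 1000, 5)
  nrm <- local_contrast_normalize(img, 64)
  p1 <- max(nrm[, 30:90]); p2 <- max(nrm[, 160:220])
  expect_lt(max(p1, p2) / min(p1, p2), 2)

  # checkerboard of period << window: output sd ~ 1 per tile
  cb <- matrix(rep(c(0, 50), length.out = 64), 64, 64)
  cb[, seq(2, 64, 2)] <- 50 - cb[, seq(2, 64, 2)]
  nc <- local_contrast_normalize(cb, 32)
  expect_equal(sd(nc[16:48, 16:48]), 1, tolerance = 0.1)
})

test_that("minimum-error threshold matches the exhaustive-scan oracle", {
  # bimodal: two narrow modes, equal mass
  counts <- integer(256)
  counts[50 + 1 + (-2:2)] <- 200
  counts[200 + 1 + (-2:2)] <- 200
  t1 <- minimum_error_threshold(counts)
  expect_gt(t1, 50); expect_lt(t1, 200)
  expect_identical(t1, brute_min_error(counts))

  # symmetric modes at 100 and 150: threshold at the midpoint
  counts <- integer(256)
  counts[100 + 1 + (-3:3)] <- c(10, 40, 80, 100, 80, 40, 10)
  counts[150 + 1 + (-3:3)] <- c(10, 40, 80, 100, 80, 40, 10)
  tsym <- minimum_error_threshold(counts)
  expect_true(tsym %in% c(124L, 125L))

  # unequal masses (0.9 / 0.1) shift the threshold toward the minority
  # mode relative to the equal-mass case (overlapping modes)
  c_eq <- integer(256); c_sk <- integer(256)
  for (o in -40:40) {
    c_eq[100 + 1 + o] <- c_eq[100 + 1 + o] + round(5000 * dnorm(o, 0, 12))
    c_eq[180 + 1 + o] <- c_eq[180 + 1 + o] + round(5000 * dnorm(o, 0, 12))
    c_sk[100 + 1 + o] <- c_sk[100 + 1 + o] + round(9000 * dnorm(o, 0, 12))
    c_sk[180 + 1 + o] <- c_sk[180 + 1 + o] + round(1000 * dnorm(o, 0, 12))
  }
  expect_gt(minimum_error_threshold(c_sk), minimum_error_threshold(c_eq))
  expect_identical(minimum_error_threshold(c_sk), brute_min_error(c_sk))
  expect_identical(minimum_error_threshold(c_eq), brute_min_error(c_eq))

  expect_error(minimum_error_threshold(rep(0L, 256)), "degenerate")
  one <- integer(256); one[77] <- 10
  expect_error(minimum_error_threshold(one), "degenerate")
})

test_that("minimum-error threshold equals the oracle on random histograms", {
  set.seed(99)
  for (i in 1:200) {
    counts <- integer(256)
    n_modes <- sample(2:4, 1)
    for (m in seq_len(n_modes)) {
      mu <- sample(5:250, 1)
      sdv <- runif(1, 1, 25)
      mass <- sample(50:2000, 1)
      x <- pmin(pmax(round(rnorm(mass, mu, sdv)), 0), 255)
      counts <- counts + tabulate(x + 1L, 256L)
    }
    if (sum(counts > 0) < 2) next
    expect_identical(minimum_error_threshold(counts),
                     brute_min_error(counts))
  }
})

test_that("temporal mean correction removes static structure, keeps movers", {
  static <- matrix(0, 40, 120)
  static[18:22, ] <- 300   # ridge
  N <- 10
  frames <- lapply(seq_len(N), function(k)
    static + blob_image(40, 120, cbind(10 + 10 * k, 10), 500, 3))
  out <- temporal_mean_correct(frames)
  # ridge residual: look away from the blob track (blob at y=10, ridge y=20)
  resid <- max(vapply(out, function(f) max(abs(f[18:22, 1:5])), numeric(1)))
  expect_lt(resid, 300 / 10)
  # blob amplitude retained >= (1 - 1/N)
  peak <- max(out[[5]][5:15, ])
  expect_gt(peak, (1 - 1 / N) * 500 * 0.98)
  expect_error(temporal_mean_correct(list(static)), ">= 2 frames")

  # pure static stack collapses to ~0
  out2 <- temporal_mean_correct(list(static, static, static))
  expect_lt(max(vapply(out2, max, numeric(1))), 1e-9)
})

test_that("LoG detection localizes blobs and separates close pairs", {
  expect_equal(nrow(detect_log(matrix(0, 64, 64), 5, 1)), 0)

  img <- blob_image(100, 100, cbind(60, 40), 800, 5)
  d <- detect_log(img, 5, 100, 8)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 60), 1.01)
  expect_lt(abs(d$y - 40), 1.01)

  two <- blob_image(100, 120, rbind(c(40, 50), c(60, 50)), 800, 5)
  d2 <- detect_log(two, 5, 100, 8)
  expect_equal(nrow(d2), 2)
  expect_equal(sort(round(d2$x)), c(40, 60), tolerance = 1.5)
})

test_that("the detection chain is translation-equivariant", {
  set.seed(2)
  base <- matrix(rnorm(160 * 160, 300, 10), 160, 160)
  img <- base + blob_image(160, 160, cbind(70, 80), 900, 5)
  shift <- function(m, dy, dx) {
    out <- matrix(stats::median(m), nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  img2 <- shift(img, 7, 11)
  p <- preprocess_params(log_threshold = 200)
  d1 <- detect_log(local_contrast_normalize(background_correct(img, 50), 64),
                   5, 3, 8)
  d2 <- detect_log(local_contrast_normalize(background_correct(img2, 50), 64),
                   5, 3, 8)
  i1 <- which.max(d1$response); i2 <- which.max(d2$response)
  expect_equal(d2$x[i2] - d1$x[i1], 11, tolerance = 1.01)
  expect_equal(d2$y[i2] - d1$y[i1], 7, tolerance = 1.01)
})

test_that("fluorescence detection finds onsets, suppresses static signal and noise", {
  set.seed(3)
  nr <- 60; nc <- 80; N <- 12
  mk_noise <- function() matrix(rnorm(nr * nc, 100, 10), nr, nc)
  # blob appearing from frame 5 onward
  frames <- lapply(seq_len(N), function(k) {
    f <- mk_noise()
    if (k >= 5) f <- f + blob_image(nr, nc, cbind(40, 30), 800, 5)
    f
  })
  st <- movie_stack(frames, 0.5, "fluor")
  d <- detect_fluorescence(st, preprocess_params())
  expect_equal(min(d$frame), 5)
  expect_true(all(abs(d$x - 40) < 3 & abs(d$y - 30) < 3))

  # static blob in every frame is removed by the mean correction
  frames2 <- lapply(seq_len(N), function(k)
    mk_noise() + blob_image(nr, nc, cbind(40, 30), 800, 5))
  d2 <- detect_fluorescence(movie_stack(frames2, 0.5, "fluor"),
                            preprocess_params())
  expect_equal(nrow(d2), 0)

  # pure noise at an explicit 3-sigma threshold: < 1 detection per frame
  set.seed(4)
  noise_frames <- lapply(1:6, function(k) matrix(rnorm(512 * 512), 512, 512))
  corr <- temporal_mean_correct(noise_frames)
  resp_sd <- sd(as.vector(log_response(corr[[1]], 5)))
  dn <- detect_fluorescence(movie_stack(noise_frames, 0.5, "fluor"),
                            preprocess_params(log_threshold = 3 * resp_sd))
  expect_lt(nrow(dn) / 6, 1)
})
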