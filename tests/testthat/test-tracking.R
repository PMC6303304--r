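test_that("trench labeling assigns raster-order ids and handles merges", {
  mask <- matrix(0L, 40, 60)
  mask[5:10, 5:20] <- 1L    # top-left rod
  mask[5:10, 30:45] <- 1L   # top-right rod
  mask[25:30, 10:25] <- 1L  # bottom rod
  tmap <- label_trenches(mask)
  expect_equal(tmap$ids, 1:3)
  expect_equal(tmap$labels[6, 6], 1L)
  expect_equal(tmap$labels[6, 35], 2L)
  expect_equal(tmap$labels[26, 15], 3L)

  # touching rods merge into one component
  mask2 <- matrix(0L, 20, 40)
  mask2[5:10, 5:20] <- 1L
  mask2[10:15, 20:35] <- 1L
  expect_equal(length(label_trenches(mask2)$ids), 1L)

  expect_error(label_trenches(matrix(0L, 5, 5)), "empty")

  # simulator mask has exactly n_trenches components
  cfg <- sim_config(n_trenches = 12, duration = 1, seed = 1)
  mv <- render_movie(simulate_lineages(cfg), cfg)
  expect_equal(length(label_trenches(mv$trench_mask)$ids), 12L)
})

test_that("detections are assigned to trenches with a 5 px tolerance", {
  mask <- matrix(0L, 40, 60)
  mask[10:20, 10:30] <- 1L
  tmap <- label_trenches(mask)
  dets <- data.frame(frame = 1L,
                     x = c(15, 6.4, 45),   # inside; 3 px out; far away
                     y = c(15, 15, 35),
                     response = 1)
  out <- assign_detections(dets, tmap)
  expect_equal(nrow(out), 2L)
  expect_equal(out$trench_id, c(1L, 1L))
})

test_that("frame linking handles the trivial cases", {
  p <- link_params(max_link_distance = 15)
  a <- data.frame(x = 10, y = 10)
  b <- data.frame(x = 13, y = 12)
  res <- link_frames(a, b, p)
  expect_equal(res$links, cbind(1L, 1L), ignore_attr = TRUE)
  expect_length(res$births, 0)

  far <- data.frame(x = 50, y = 10)
  res2 <- link_frames(a, far, p)
  expect_equal(nrow(res2$links), 0)
  expect_equal(res2$births, 1L)
  expect_equal(res2$deaths, 1L)

  expect_equal(nrow(link_frames(a, data.frame(x = numeric(0),
                                              y = numeric(0)), p)$links), 0)
})

test_that("frame linking equals the brute-force assignment oracle", {
  p <- link_params(max_link_distance = 20)
  set.seed(123)
  for (i in 1:500) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    a <- data.frame(x = runif(n, 0, 60), y = runif(n, 0, 25))
    b <- data.frame(x = runif(m, 0, 60), y = runif(m, 0, 25))
    res <- link_frames(a, b, p)
    cost <- matrix(Inf, n, m)
    if (n > 0 && m > 0) {
      d2 <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
      cost[d2 <= 400] <- d2[d2 <= 400]
    }
    adm <- cost[is.finite(cost)]
    bb <- if (length(adm) > 0) 1.05 * quantile(adm, 0.9, names = FALSE)
    else 400
    bb <- max(bb, 1e-9)
    oracle <- brute_lap(cost, bb)
    expect_equal(lap_total_cost(res, cost, bb), oracle$total,
                 tolerance = 1e-9)
  }
})

test_that("a crossing 3-vs-3 configuration is solved optimally", {
  p <- link_params(max_link_distance = 15)
  a <- data.frame(x = c(10, 20, 30), y = c(10, 10, 10))
  b <- data.frame(x = c(12, 21, 29), y = c(11, 9, 10))
  res <- link_frames(a, b, p)
  cost <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
  cost[cost > 225] <- Inf
  bb <- 1.05 * quantile(cost[is.finite(cost)], 0.9, names = FALSE)
  oracle <- brute_lap(cost, bb)
  expect_equal(lap_total_cost(res, cost, bb), oracle$total)
  expect_equal(res$links[order(res$links[, 1]), 2], 1:3)
})

test_that("single moving cell yields one track spanning the movie", {
  set.seed(5)
  x <- cumsum(c(30, rnorm(49, 0, 2)))
  y <- cumsum(c(12, rnorm(49, 0, 2)))
  dets <- data.frame(frame = 1:50, x = x, y = y)
  tr <- build_tracks(dets)
  expect_equal(nrow(tr$tracks), 1L)
  expect_equal(tr$tracks$start_frame, 1L)
  expect_equal(tr$tracks$end_frame, 50L)
})

test_that("two parentless cells stay two tracks; gaps are closed", {
  dets <- data.frame(frame = rep(1:30, 2),
                     x = c(rep(20, 30), rep(80, 30)),
                     y = rep(12, 60))
  tr <- build_tracks(dets)
  expect_equal(nrow(tr$tracks), 2L)
  expect_true(all(is.na(tr$tracks$parent_track_id)))

  # one cell with a single missing frame: gap closed into one track
  dets2 <- data.frame(frame = c(1:10, 12:20), x = 20 + 0.5 * c(1:10, 12:20),
                      y = 12)
  tr2 <- build_tracks(dets2)
  expect_equal(nrow(tr2$tracks), 1L)
  expect_equal(tr2$tracks$end_frame, 20L)
})

test_that("a division becomes a two-child split at the right frame", {
  # one cell until frame 20, two cells afterwards
  dets <- rbind(
    data.frame(frame = 1:20, x = 60, y = 15),
    data.frame(frame = 21:40, x = 52, y = 15),
    data.frame(frame = 21:40, x = 68, y = 15))
  tr <- build_tracks(dets)
  expect_equal(nrow(tr$tracks), 3L)
  root <- tr$tracks[is.na(tr$tracks$parent_track_id), ]
  expect_equal(nrow(root), 1L)
  expect_equal(root$n_children, 2L)
  kids <- tr$tracks[!is.na(tr$tracks$parent_track_id), ]
  expect_equal(kids$parent_track_id, rep(root$track_id, 2))
  expect_equal(kids$start_frame, c(21L, 21L))
})

test_that("track construction is invariant to detection input order", {
  set.seed(9)
  dets <- rbind(
    data.frame(frame = 1:15, x = 40 + rnorm(15), y = 15 + rnorm(15)),
    data.frame(frame = 16:30, x = 33 + rnorm(15), y = 15 + rnorm(15)),
    data.frame(frame = 16:30, x = 48 + rnorm(15), y = 15 + rnorm(15)))
  tr1 <- build_tracks(dets)
  perm <- sample(nrow(dets))
  tr2 <- build_tracks(dets[perm, ])
  key <- function(tr) {
    p <- tr$points[order(tr$points$frame, tr$points$x), ]
    s <- split(paste(p$frame, round(p$x, 6), round(p$y, 6)), p$track_id)
    sort(vapply(s, paste, character(1), collapse = ";"))
  }
  expect_equal(unname(key(tr1)), unname(key(tr2)))
})

test_that("accounting identity holds and classifies correctly", {
  # three trenches: divide / persist / lost
  mkdets <- function(tid, df) { df$trench_id <- tid; df }
  d1 <- rbind(data.frame(frame = 1:10, x = 60, y = 15),
              data.frame(frame = 11:30, x = 52, y = 15),
              data.frame(frame = 11:30, x = 68, y = 15))
  d2 <- data.frame(frame = 1:30, x = 20, y = 15)
  d3 <- data.frame(frame = 1:12, x = 20, y = 15)
  dets <- rbind(mkdets(1L, d1), mkdets(2L, d2), mkdets(3L, d3))
  tr <- track_trenches(dets)
  acct <- accounting(tr, 30L)
  expect_equal(acct$N0, 3L)
  expect_equal(acct$N_tracked_divided, 1L)
  expect_equal(acct$N_not_divided, 1L)
  expect_equal(acct$N_losses, 1L)
  expect_equal(acct$N0, acct$N_tracked_divided + acct$N_not_divided +
                 acct$N_losses)

  # empty input
  acct0 <- accounting(track_trenches(
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               trench_id = integer(0))), 10L)
  expect_equal(acct0$N0, 0L)

  # a death-terminated root counts as tracked, not lost
  tr3 <- track_trenches(mkdets(1L, d3))
  acct3 <- accounting(tr3, 30L, died_track_ids = tr3$tracks$track_id)
  expect_equal(acct3$N_not_divided, 1L)
  expect_equal(acct3$N_losses, 0L)
})
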