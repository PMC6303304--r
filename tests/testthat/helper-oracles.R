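# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation available so they share no code
# with the implementation they check.

# Exhaustive-scan minimum-error threshold: for every interior threshold T
# compute the Kittler-Illingworth criterion from the raw histogram slices.
brute_min_error <- function(counts) {
  v <- 0:255
  n <- sum(counts)
  js <- rep(Inf, 255)
  for (T in 0:254) {
    c1 <- counts[1:(T + 1)]; v1 <- v[1:(T + 1)]
    c2 <- counts[(T + 2):256]; v2 <- v[(T + 2):256]
    n1 <- sum(c1); n2 <- sum(c2)
    if (n1 == 0 || n2 == 0) next
    p1 <- n1 / n; p2 <- n2 / n
    mu1 <- sum(c1 * v1) / n1; mu2 <- sum(c2 * v2) / n2
    s1 <- max(sum(c1 * (v1 - mu1)^2) / n1, 0.25)
    s2 <- max(sum(c2 * (v2 - mu2)^2) / n2, 0.25)
    js[T + 1] <- 1 + 2 * (p1 * log(sqrt(s1)) + p2 * log(sqrt(s2))) -
      2 * (p1 * log(p1) + p2 * log(p2))
  }
  # tied minima (e.g. across an empty inter-mode gap): middle of the range
  jm <- min(js)
  tied <- which(js <= jm + 1e-12 * max(abs(jm), 1))
  tied[(length(tied) + 1L) %/% 2L] - 1L
}

# Brute-force minimum-cost assignment with birth/death alternatives:
# enumerate every subset matching between the two sides.
brute_lap <- function(cost, b) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(cost = n * b + m * b, links = matrix(0L, 0, 2))
  if (n == 0 || m == 0) {
    return(list(links = best$links, births = seq_len(m),
                deaths = seq_len(n), total = best$cost))
  }
  ks <- 0:min(n, m)
  for (k in ks) {
    if (k == 0) next
    subs_i <- utils::combn(n, k, simplify = FALSE)
    subs_j <- utils::combn(m, k, simplify = FALSE)
    perms <- all_perms(k)
    for (si in subs_i) for (sj in subs_j) for (p in perms) {
      cs <- cost[cbind(si, sj[p])]
      if (any(!is.finite(cs))) next
      tot <- sum(cs) + (n - k) * b + (m - k) * b
      if (tot < best$cost - 1e-9)
        best <- list(cost = tot, links = cbind(si, sj[p]))
    }
  }
  links <- best$links
  list(links = links,
       births = setdiff(seq_len(m), links[, 2]),
       deaths = setdiff(seq_len(n), links[, 1]),
       total = best$cost)
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

# Total cost of a link_frames result under the stated objective.
lap_total_cost <- function(res, cost, b) {
  s <- 0
  if (nrow(res$links) > 0) s <- sum(cost[res$links])
  s + b * (length(res$births) + length(res$deaths))
}

# Draw a Gaussian blob image for detection tests.
blob_image <- function(nr, nc, centers, amplitude = 900, sigma = 5,
                       background = 0) {
  img <- matrix(background, nr, nc)
  for (i in seq_len(nrow(centers))) {
    x <- centers[i, 1]; y <- centers[i, 2]
    cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
    rows <- matrix(rep(0:(nr - 1), nc), nr, nc)
    img <- img + amplitude * exp(-((cols - x)^2 + (rows - y)^2) /
                                   (2 * sigma^2))
  }
  img
}

# Greedy truth/detection matching within a pixel tolerance; returns counts.
match_detections <- function(dets, truth, tol = 3) {
  hits <- 0
  for (k in unique(dets$frame)) {
    d <- dets[dets$frame == k, , drop = FALSE]
    t <- truth[truth$frame == k, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (nrow(t) == 0) next
      d2 <- (t$x_px - d$x[i])^2 + (t$y_px - d$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) { hits <- hits + 1; t <- t[-j, , drop = FALSE] }
    }
  }
  list(hits = hits, n_det = nrow(dets), n_truth = nrow(truth),
       precision = hits / max(nrow(dets), 1),
       recall = hits / max(nrow(truth), 1))
}
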