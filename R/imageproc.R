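#' Detection / preprocessing parameters
#'
#' Parameters of the phase-contrast and fluorescence detection chains. The
#' defaults are scaled off the simulated cell size (blob sigma 5 px):
#' `background_sigma = 50` px for the pseudo-flat-field, a 64 px local
#' contrast window, LoG scale 5 px and an 8 px minimum peak separation.
#' When `log_threshold` is `NULL` the response threshold is set
#' automatically per stack from the minimum-error threshold of the pooled
#' response histogram, floored at a robust noise level
#' (median + 5 * 1.4826 * MAD of the response).
#'
#' @param background_sigma Gaussian sigma (px) of the background estimate.
#' @param contrast_window local contrast window size (px).
#' @param log_sigma LoG scale (px), about the cell radius.
#' @param log_threshold numeric response threshold, or `NULL` for automatic.
#' @param min_peak_separation minimum distance between detections (px).
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(background_sigma = 50, contrast_window = 64,
                              log_sigma = 5, log_threshold = NULL,
                              min_peak_separation = 8) {
  if (background_sigma <= 0 || contrast_window <= 0 || log_sigma <= 0 ||
      min_peak_separation <= 0)
    stop("preprocessing parameters must be strictly positive")
  structure(list(background_sigma = background_sigma,
                 contrast_window = contrast_window, log_sigma = log_sigma,
                 log_threshold = log_threshold,
                 min_peak_separation = min_peak_separation),
            class = "preprocess_params")
}

# Box filter by summed-area table with replicate padding: exact, O(1) per
# pixel, and much faster than FFT convolution for the large windows used
# here (agrees with EBImage::filter2 to ~1e-11).
box_filter_sat <- function(x, w) {
  if (is.integer(x)) storage.mode(x) <- "double"  # cumsum overflow guard
  w <- as.integer(w); if (w %% 2L == 0L) w <- w + 1L
  r <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  S <- rbind(0, apply(xp, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  (S[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
     S[i1, j1 + 2L * r + 1L, drop = FALSE] -
     S[i1 + 2L * r + 1L, j1, drop = FALSE] +
     S[i1, j1, drop = FALSE]) / w^2
}

# Large-sigma Gaussian smoothing via three iterated box filters (the
# standard O(1) approximation: three boxes of width ~ sqrt(4 sigma^2 / 3)
# have combined sd sigma), with replicate boundary handling.
gblur_large <- function(x, sigma) {
  w <- max(3L, as.integer(round(sqrt(4 * sigma^2 / 3 + 1))))
  if (w %% 2L == 0L) w <- w + 1L
  w <- min(w, 2L * min(dim(x)) - 1L)
  for (i in 1:3) x <- box_filter_sat(x, w)
  x
}

#' Remove smooth background from a frame
#'
#' Subtracts the large-sigma Gaussian-smoothed version of the frame
#' (a pseudo-flat-field), flattening illumination gradients and the smooth
#' component of static structures while retaining cell-sized blobs. The
#' smoothing uses the standard three-iterated-box approximation of the
#' Gaussian, which is exact in its first two moments and O(1) per pixel.
#'
#' @param frame numeric matrix.
#' @param background_sigma Gaussian sigma (px), much larger than a cell.
#' @return matrix of the same size with approximately zero mean.
#' @export
background_correct <- function(frame, background_sigma) {
  if (background_sigma <= 0) stop("background_sigma must be positive")
  frame - gblur_large(frame, background_sigma)
}

box_mean <- function(x, w) box_filter_sat(x, w)

#' Local contrast normalization
#'
#' Per-pixel `(value - local mean) / (local sd + 1e-6)` with the mean and sd
#' taken over a square window, equalizing blob responses across regions of
#' different brightness and noise level.
#'
#' @param frame numeric matrix.
#' @param contrast_window window size in px (>= 3, not larger than the frame).
#' @return normalized matrix.
#' @export
local_contrast_normalize <- function(frame, contrast_window) {
  if (contrast_window < 3) stop("contrast_window must be >= 3 px")
  if (contrast_window > min(dim(frame)))
    stop("contrast_window larger than the frame")
  m <- box_mean(frame, contrast_window)
  m2 <- box_mean(frame * frame, contrast_window)
  s <- sqrt(pmax(m2 - m * m, 0))
  (frame - m) / (s + 1e-6)
}

#' Minimum-error (Kittler-Illingworth) threshold of a 256-bin histogram
#'
#' Models the histogram as a mixture of two Gaussians and returns the
#' threshold `T` (a bin index, 0-based) minimizing the classification-error
#' criterion
#' `J(T) = 1 + 2 * (P1 log s1 + P2 log s2) - 2 * (P1 log P1 + P2 log P2)`
#' over all `T` for which both classes are non-empty. Class variances are
#' floored at 0.25 bin^2 to guard against `log(0)` on spiky histograms.
#' `J` is constant across any empty gap between the two classes, so tied
#' minima resolve to the middle of the tied range (for two symmetric modes
#' this is their midpoint).
#'
#' @param counts integer vector of 256 bin counts (bins 0..255).
#' @return the 0-based threshold bin index: class 1 is bins `0..T`, class 2
#'   bins `T+1..255`.
#' @export
minimum_error_threshold <- function(counts) {
  if (length(counts) != 256L) stop("expected a 256-bin histogram")
  if (any(counts < 0)) stop("negative bin counts")
  nz <- which(counts > 0)
  if (length(nz) < 2L) stop("degenerate histogram: fewer than 2 distinct values")
  v <- 0:255
  n <- sum(counts)
  c1 <- cumsum(counts)
  s1 <- cumsum(counts * v)
  q1 <- cumsum(counts * v^2)
  P1 <- c1 / n
  P2 <- 1 - P1
  mu1 <- s1 / pmax(c1, 1)
  mu2 <- (s1[256] - s1) / pmax(n - c1, 1)
  var1 <- pmax(q1 / pmax(c1, 1) - mu1^2, 0.25)
  var2 <- pmax((q1[256] - q1) / pmax(n - c1, 1) - mu2^2, 0.25)
  J <- 1 + 2 * (P1 * log(sqrt(var1)) + P2 * log(sqrt(var2))) -
    2 * (P1 * log(pmax(P1, 1e-300)) + P2 * log(pmax(P2, 1e-300)))
  valid <- c1 > 0 & c1 < n
  J[!valid] <- Inf
  J[256] <- Inf
  jmin <- min(J)
  tied <- which(J <= jmin + 1e-12 * max(abs(jmin), 1))
  tied[(length(tied) + 1L) %/% 2L] - 1L
}

#' Histogram a frame into 256 bins and threshold it
#'
#' Bins the intensity range `[min, max]` of the frame into 256 equal levels,
#' applies [minimum_error_threshold()] and returns the threshold back on the
#' intensity scale (the upper edge of the threshold bin).
#'
#' @param frame numeric matrix.
#' @return the intensity threshold, or `NA` when the frame is degenerate
#'   (fewer than two distinct values).
#' @export
threshold_frame <- function(frame) {
  lo <- min(frame); hi <- max(frame)
  if (hi - lo < 1e-12) return(NA_real_)
  bins <- pmin(floor((frame - lo) / (hi - lo) * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  t_bin <- tryCatch(minimum_error_threshold(counts), error = function(e) NA)
  if (is.na(t_bin)) return(NA_real_)
  lo + (t_bin + 1) / 256 * (hi - lo)
}

#' Temporal mean correction of a stack
#'
#' Subtracts the pixel-wise temporal mean image from every frame and clamps
#' negative values to zero, suppressing static structures such as trench
#' walls while retaining moving cells (up to a `1/N` bias at visited
#' pixels).
#'
#' @param stack a [movie_stack()] or list of frames (>= 2 frames).
#' @return the corrected stack in the same representation.
#' @export
temporal_mean_correct <- function(stack) {
  frames <- if (inherits(stack, "movie_stack")) stack$frames else stack
  if (length(frames) < 2L) stop("temporal mean correction needs >= 2 frames")
  m <- frames[[1]] * 1.0
  for (k in seq_along(frames)[-1]) m <- m + frames[[k]]
  m <- m / length(frames)
  out <- lapply(frames, function(f) pmax(f - m, 0))
  if (inherits(stack, "movie_stack")) {
    stack$frames <- out
    stack
  } else out
}

log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  v <- -r:r
  d2 <- outer(v^2, v^2, `+`)
  k <- (2 - d2 / sigma^2) * exp(-d2 / (2 * sigma^2))
  k - mean(k)  # zero DC response
}

#' Scale-normalized Laplacian-of-Gaussian response of a frame
#'
#' @param frame numeric matrix.
#' @param log_sigma LoG scale in px.
#' @return the response matrix (positive at bright blobs of radius ~ sigma).
#' @export
log_response <- function(frame, log_sigma) {
  EBImage::filter2(frame, log_kernel(log_sigma), boundary = "replicate")
}

# Logical matrix of strict-or-equal local maxima over the 8-neighbourhood.
local_maxima <- function(r) {
  nr <- nrow(r); nc <- ncol(r)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- r
  ok <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ok <- ok & (r >= pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx])
  }
  ok
}

#' Laplacian-of-Gaussian blob detection on a single frame
#'
#' Computes the scale-normalized LoG response, collects local maxima above
#' `log_threshold` (optionally restricted to a foreground `mask`), and
#' applies greedy non-maximum suppression within `min_peak_separation` px:
#' candidates are visited in order of decreasing response, ties broken by
#' lower `(y, x)`, and a candidate is kept only if no kept detection lies
#' within the separation radius.
#'
#' @param frame numeric matrix (preprocessed).
#' @param log_sigma LoG scale in px.
#' @param log_threshold minimum response.
#' @param min_peak_separation suppression radius in px.
#' @param mask optional logical matrix; maxima outside it are discarded.
#' @return a `data.frame` with `x`, `y` (0-based px) and `response`.
#' @export
detect_log <- function(frame, log_sigma, log_threshold,
                       min_peak_separation = 8, mask = NULL) {
  r <- log_response(frame, log_sigma)
  detect_from_response(r, log_threshold, min_peak_separation, mask)
}

# Detection step operating on a precomputed LoG response matrix. `mask`
# may be a logical matrix or a vector of foreground pixel indices.
detect_from_response <- function(r, log_threshold, min_peak_separation,
                                 mask = NULL) {
  cand <- local_maxima(r) & (r > log_threshold)
  if (!is.null(mask)) {
    if (is.logical(mask)) {
      cand <- cand & mask
    } else {
      ml <- matrix(FALSE, nrow(r), ncol(r))
      ml[mask] <- TRUE
      cand <- cand & ml
    }
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  resp <- r[cand]
  ord <- order(-resp, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; resp <- resp[ord]
  kept <- integer(0)
  sep2 <- min_peak_separation^2
  for (i in seq_along(resp)) {
    if (length(kept) > 0L) {
      d2 <- (idx[kept, 1] - idx[i, 1])^2 + (idx[kept, 2] - idx[i, 2])^2
      if (any(d2 < sep2)) next
    }
    kept <- c(kept, i)
  }
  data.frame(x = idx[kept, 2] - 1, y = idx[kept, 1] - 1,
             response = resp[kept])
}

# Automatic response threshold: minimum-error level of the pooled response
# values, floored at a robust noise level (median + 5 * MAD-sigma). A
# matched-filter response to a real cell stands two orders of magnitude
# above the noise floor, while the maxima of pure noise sit near 5 robust
# sigmas; when no response exceeds 10 robust sigmas the stack is treated
# as signal-free and an infinite threshold is returned.
auto_response_threshold <- function(responses) {
  v <- responses[is.finite(responses)]
  med <- stats::median(v); mads <- stats::mad(v)
  if (max(v) < med + 10 * mads) return(Inf)
  me <- threshold_frame(matrix(v, nrow = 1))
  max(me, med + 5 * mads, na.rm = TRUE)
}

#' Detect cells in a defocused phase-contrast stack
#'
#' The full phase-contrast chain: per-frame background correction and local
#' contrast normalization; a per-frame foreground mask from the
#' minimum-error threshold of the normalized frame; temporal mean
#' correction of the normalized stack; then LoG detection, with maxima
#' accepted only inside the frame's foreground mask.
#'
#' @param stack a phase [movie_stack()].
#' @param params a [preprocess_params()].
#' @return a `data.frame` with `channel`, `frame` (1-based), `t_hours`,
#'   `x`, `y` (0-based px) and `response`.
#' @export
detect_cells <- function(stack, params = preprocess_params()) {
  nf <- length(stack$frames)
  # Normalized frames; the same workspace later holds the LoG responses so
  # only one full-stack copy lives alongside the input.
  work <- vector("list", nf)
  masks <- vector("list", nf)   # sparse: foreground pixel indices
  m <- NULL
  for (k in seq_len(nf)) {
    f <- local_contrast_normalize(
      background_correct(stack$frames[[k]], params$background_sigma),
      params$contrast_window)
    th <- threshold_frame(f)
    masks[[k]] <- if (is.na(th)) integer(0) else which(f > th)
    work[[k]] <- f
    m <- if (is.null(m)) f else m + f
  }
  m <- m / nf
  pool <- vector("list", nf)
  for (k in seq_len(nf)) {
    r <- log_response(pmax(work[[k]] - m, 0), params$log_sigma)
    work[[k]] <- r
    v <- as.vector(r)
    pool[[k]] <- if (length(v) > 20000L)
      v[seq(1L, length(v), length.out = 20000L)] else v
  }
  thr <- params$log_threshold
  if (is.null(thr)) thr <- auto_response_threshold(unlist(pool))
  out <- lapply(seq_len(nf), function(k) {
    d <- detect_from_response(work[[k]], thr, params$min_peak_separation,
                              mask = masks[[k]])
    if (nrow(d) == 0L) return(NULL)
    cbind(frame = k, d)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      response = numeric(0))
  data.frame(channel = rep("phase", nrow(out)), frame = out$frame,
             t_hours = frame_time(stack, out$frame), x = out$x, y = out$y,
             response = out$response)
}

#' Detect death-marker signals in a fluorescence stack
#'
#' Fluorescence frames undergo a brightness/contrast adjustment — a min-max
#' intensity rescaling with a single setting for the whole movie, so that
#' signal-free frames are not noise-amplified — and temporal mean
#' correction (suppressing any static signal), followed by the same LoG
#' detection as the phase channel. Returned detections carry the
#' fluorescence frame times.
#'
#' @param stack a fluorescence [movie_stack()].
#' @param params a [preprocess_params()]; `log_threshold = NULL` uses the
#'   automatic pooled-response threshold.
#' @return a `data.frame` as in [detect_cells()] with `channel = "fluor"`.
#' @export
detect_fluorescence <- function(stack, params = preprocess_params()) {
  rng <- range(vapply(stack$frames, range, numeric(2)))
  frames <- if (diff(rng) < 1e-12) {
    lapply(stack$frames, function(f) f * 0)
  } else {
    lapply(stack$frames, function(f) (f - rng[1]) / diff(rng))
  }
  corr <- temporal_mean_correct(frames)
  rm(frames)
  for (k in seq_along(corr))
    corr[[k]] <- log_response(corr[[k]], params$log_sigma)
  thr <- params$log_threshold
  if (is.null(thr))
    thr <- auto_response_threshold(unlist(lapply(corr, as.vector)))
  out <- lapply(seq_along(corr), function(k) {
    d <- detect_from_response(corr[[k]], thr, params$min_peak_separation)
    if (nrow(d) == 0L) return(NULL)
    cbind(frame = k, d)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      response = numeric(0))
  data.frame(channel = rep("fluor", nrow(out)), frame = out$frame,
             t_hours = frame_time(stack, out$frame), x = out$x, y = out$y,
             response = out$response)
}
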