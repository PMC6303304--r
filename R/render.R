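#' Trench array layout in pixels
#'
#' Places `n_trenches` horizontal rod-shaped trenches on a near-square grid.
#' Interior rectangles exclude the 2 px dark wall drawn around each trench.
#' Coordinates are 0-based pixels, `x` = column, `y` = row.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with one row per trench: `trench_id`, `x0`, `y0`
#'   (top-left interior corner), `w`, `h` (interior extent in px), plus the
#'   full image dimensions as attributes `img_nrow` / `img_ncol`.
#' @keywords internal
trench_layout <- function(config) {
  cfg <- validate_sim_config(config)
  h_px <- round(cfg$trench_size[1] / cfg$pixel_size)  # short axis (rows)
  w_px <- round(cfg$trench_size[2] / cfg$pixel_size)  # long axis (cols)
  gap <- 14L; margin <- 10L
  n <- cfg$n_trenches
  ncol_t <- max(1L, ceiling(sqrt(n * (h_px + gap) / (w_px + gap))))
  nrow_t <- ceiling(n / ncol_t)
  idx <- seq_len(n) - 1L
  row_i <- idx %/% ncol_t
  col_i <- idx %% ncol_t
  out <- data.frame(
    trench_id = seq_len(n),
    x0 = margin + col_i * (w_px + gap),
    y0 = margin + row_i * (h_px + gap),
    w = w_px, h = h_px
  )
  attr(out, "img_ncol") <- margin * 2L + ncol_t * (w_px + gap) - gap
  attr(out, "img_nrow") <- margin * 2L + nrow_t * (h_px + gap) - gap
  out
}

# Push cells apart until every pair is >= sep px apart, keeping them inside
# the inset trench box. P is an n x 2 matrix of (x, y).
enforce_separation <- function(P, sep, xlim, ylim, iters = 4L) {
  n <- nrow(P)
  if (n < 2L) return(P)
  for (it in seq_len(iters)) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      d <- P[j, ] - P[i, ]
      dist <- sqrt(sum(d^2))
      if (dist < sep) {
        dir <- if (dist < 1e-9) c(1, 0) else d / dist
        push <- (sep - dist) / 2
        P[i, ] <- P[i, ] - dir * push
        P[j, ] <- P[j, ] + dir * push
        moved <- TRUE
      }
    }
    P[, 1] <- clip(P[, 1], xlim[1], xlim[2])
    P[, 2] <- clip(P[, 2], ylim[1], ylim[2])
    if (!moved) break
  }
  P
}

add_blob <- function(img, x, y, amplitude, sigma) {
  r <- ceiling(3.5 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1L, round(y) + 1L - r):min(nr, round(y) + 1L + r)
  cols <- max(1L, round(x) + 1L - r):min(nc, round(x) + 1L + r)
  gy <- exp(-((rows - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x)^2) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  img
}

#' Render simulated lineages into synthetic two-channel movies
#'
#' Produces the defocused phase-contrast stack, the death-marker
#' fluorescence stack and the labeled trench mask for a simulated lineage
#' table. Trenches are drawn as static dark rod outlines on a uniform
#' background; each live cell is an isotropic Gaussian blob (sigma =
#' `cell_sigma` px) performing reflected Brownian motion confined to its
#' trench interior, with a minimum centre-to-centre separation of
#' `3 * cell_sigma` px (touching cells, given the ~2:1 trench-width to
#' cell-diameter ratio), so freshly divided daughters are resolvable.
#' Additive Gaussian pixel noise (`noise_sd`) is applied to every frame.
#' Fluorescence frames are emitted only at `fluor_interval` multiples and
#' contain blobs only for cells at or past their `death_time`, frozen at the
#' position where the cell died.
#'
#' @param events lineage table from [simulate_lineages()].
#' @param config the matching [sim_config()].
#' @return a list with elements `phase` and `fluor` ([movie_stack()]s),
#'   `trench_mask` (integer label matrix), `truth_positions` (per phase
#'   frame and live cell: `frame`, `t_hours`, `cell_id`, `trench_id`,
#'   `x_px`, `y_px`; 0-based pixel coordinates) and `layout`.
#' @export
render_movie <- function(events, config) {
  cfg <- validate_sim_config(config)
  if (nrow(events) > 0 && any(events$birth_time > cfg$duration))
    stop("events extend beyond the configured duration")
  set.seed(substream_seed(cfg$seed, "render"))
  lay <- trench_layout(cfg)
  nr <- attr(lay, "img_nrow"); nc <- attr(lay, "img_ncol")
  sigma <- cfg$cell_sigma
  step_sd <- cfg$motion_sd / cfg$pixel_size
  # excluded volume: cell diameter ~ 3 * blob sigma (trench/cell ratio ~ 2)
  sep <- 3 * sigma

  n_pf <- floor(cfg$duration / cfg$phase_interval + 1e-9) + 1L
  t_phase <- (seq_len(n_pf) - 1) * cfg$phase_interval
  ratio <- round(cfg$fluor_interval / cfg$phase_interval)
  fluor_idx <- which((seq_len(n_pf) - 1L) %% ratio == 0L)
  t_fluor <- t_phase[fluor_idx]

  # Static pattern: uniform background with dark rod outlines.
  base <- matrix(300, nr, nc)
  mask <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(lay))) {
    r0 <- lay$y0[i] + 1L; r1 <- lay$y0[i] + lay$h[i]
    c0 <- lay$x0[i] + 1L; c1 <- lay$x0[i] + lay$w[i]
    base[(r0 - 2L):(r1 + 2L), (c0 - 2L):(c1 + 2L)] <- 120
    base[r0:r1, c0:c1] <- 300
    mask[r0:r1, c0:c1] <- lay$trench_id[i]
  }

  # Per-trench cell positions for every phase frame.
  pos <- vector("list", n_pf)  # each: matrix cell_id, x, y
  death_pos <- list()          # cell_id -> frozen (x, y)
  for (ti in seq_len(nrow(lay))) {
    cells <- events[events$trench_id == lay$trench_id[ti], , drop = FALSE]
    if (nrow(cells) == 0L) next
    xlim <- c(lay$x0[ti] + sigma, lay$x0[ti] + lay$w[ti] - 1 - sigma)
    ylim <- c(lay$y0[ti] + sigma, lay$y0[ti] + lay$h[ti] - 1 - sigma)
    end_t <- pmin(ifelse(is.na(cells$division_time), Inf, cells$division_time),
                  ifelse(is.na(cells$death_time), Inf, cells$death_time))
    cur <- matrix(numeric(0), 0, 2)
    cur_ids <- integer(0)
    for (k in seq_len(n_pf)) {
      tk <- t_phase[k]
      keep <- end_t[match(cur_ids, cells$cell_id)] > tk
      gone <- cur_ids[!keep]
      for (g in gone) death_pos[[as.character(g)]] <-
          cur[which(cur_ids == g), ]
      cur <- cur[keep, , drop = FALSE]; cur_ids <- cur_ids[keep]
      if (nrow(cur) > 0L) {
        cur <- cur + matrix(stats::rnorm(2L * nrow(cur), 0, step_sd),
                            ncol = 2)
        cur[, 1] <- clip(cur[, 1], xlim[1], xlim[2])
        cur[, 2] <- clip(cur[, 2], ylim[1], ylim[2])
      }
      newly <- cells[cells$birth_time <= tk & end_t > tk &
                       !(cells$cell_id %in% cur_ids), , drop = FALSE]
      if (nrow(newly) > 0L) {
        newly <- newly[order(newly$cell_id), , drop = FALSE]
        for (ci in seq_len(nrow(newly))) {
          pid <- newly$parent_id[ci]
          pp <- if (!is.na(pid)) death_pos[[as.character(pid)]] else NULL
          if (is.null(pp) || newly$birth_time[ci] <= 0) {
            np <- c(stats::runif(1, xlim[1], xlim[2]),
                    stats::runif(1, ylim[1], ylim[2]))
          } else {
            side <- if (ci %% 2L == 1L) -1 else 1
            np <- c(clip(pp[1] + side * sep / 2, xlim[1], xlim[2]), pp[2])
          }
          cur <- rbind(cur, np); cur_ids <- c(cur_ids, newly$cell_id[ci])
        }
      }
      if (nrow(cur) > 1L)
        cur <- enforce_separation(cur, sep, xlim, ylim)
      if (nrow(cur) > 0L)
        pos[[k]] <- rbind(pos[[k]],
                          cbind(cur_ids, cur[, 1], cur[, 2], k))
      # remember last known position (used as frozen death position)
      for (ci in seq_along(cur_ids))
        death_pos[[as.character(cur_ids[ci])]] <- cur[ci, ]
    }
  }
  truth <- do.call(rbind, pos)
  truth <- if (is.null(truth)) {
    data.frame(frame = integer(0), t_hours = numeric(0),
               cell_id = integer(0), trench_id = integer(0),
               x_px = numeric(0), y_px = numeric(0))
  } else {
    data.frame(frame = as.integer(truth[, 4]),
               t_hours = t_phase[truth[, 4]],
               cell_id = as.integer(truth[, 1]),
               trench_id = events$trench_id[match(truth[, 1],
                                                  events$cell_id)],
               x_px = truth[, 2], y_px = truth[, 3])
  }
  truth <- truth[order(truth$frame, truth$cell_id), ]
  rownames(truth) <- NULL

  phase_frames <- vector("list", n_pf)
  for (k in seq_len(n_pf)) {
    img <- base
    pk <- truth[truth$frame == k, , drop = FALSE]
    for (ci in seq_len(nrow(pk)))
      img <- add_blob(img, pk$x_px[ci], pk$y_px[ci], cfg$cell_amplitude,
                      sigma)
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    img <- round(clip(img, 0, 65535))
    storage.mode(img) <- "integer"   # 16-bit counts; halves memory
    phase_frames[[k]] <- img
  }

  dead <- events[!is.na(events$death_time), , drop = FALSE]
  fluor_frames <- vector("list", length(fluor_idx))
  for (fi in seq_along(fluor_idx)) {
    tk <- t_fluor[fi]
    img <- matrix(100, nr, nc)
    dk <- dead[dead$death_time <= tk, , drop = FALSE]
    for (ci in seq_len(nrow(dk))) {
      dp <- death_pos[[as.character(dk$cell_id[ci])]]
      if (!is.null(dp))
        img <- add_blob(img, dp[1], dp[2], cfg$cell_amplitude, sigma)
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    img <- round(clip(img, 0, 65535))
    storage.mode(img) <- "integer"
    fluor_frames[[fi]] <- img
  }

  list(
    phase = movie_stack(phase_frames, cfg$phase_interval, "phase",
                        cfg$pixel_size),
    fluor = movie_stack(fluor_frames, cfg$fluor_interval, "fluor",
                        cfg$pixel_size),
    trench_mask = mask,
    truth_positions = truth,
    layout = lay
  )
}
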