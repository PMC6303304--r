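#' Cell-cycle phase boundaries
#'
#' Phase is inferred from elapsed time only: a fraction of the reference
#' cycle below `g1_end` is G1, below `s_end` is S, and G2/M otherwise.
#' Defaults place G1 at the first 40% and S at the next 40% of a 19.7 h
#' reference cycle.
#'
#' @param g1_end,s_end cycle fractions in `(0, 1)`, `g1_end < s_end`.
#' @param reference_cycle reference cycle duration in hours.
#' @return a `phase_boundaries` list.
#' @export
phase_boundaries <- function(g1_end = 0.4, s_end = 0.8,
                             reference_cycle = 19.7) {
  if (!(g1_end > 0 && g1_end < s_end && s_end < 1))
    stop("need 0 < g1_end < s_end < 1")
  if (reference_cycle <= 0) stop("reference_cycle must be positive")
  structure(list(g1_end = g1_end, s_end = s_end,
                 reference_cycle = reference_cycle),
            class = "phase_boundaries")
}

#' Extract division times t0, t1, t2 per trench
#'
#' For every trench with a single root track, reports the root's first
#' division time `t0` (the start frame of its children) and, when the
#' daughters divide in turn, their division times `t1 <= t2`, together with
#' the two cycle durations `t1 - t0` and `t2 - t0`. Times are
#' `(frame - 1) * phase_interval` hours.
#'
#' @param tracking a [track_trenches()] result.
#' @param phase_interval phase frame interval in hours.
#' @return a `data.frame` with one row per single-root trench: `trench_id`,
#'   `root_track`, `t0`, `t1`, `t2`, `dur1`, `dur2` (`NA` when unobserved).
#' @export
extract_divisions <- function(tracking, phase_interval) {
  trk <- tracking$tracks
  out <- NULL
  t_of_frame <- function(f) (f - 1) * phase_interval
  for (tid in sort(unique(trk$trench_id))) {
    tt <- trk[trk$trench_id == tid, ]
    roots <- tt[is.na(tt$parent_track_id) & tt$start_frame == 1L, ]
    if (nrow(roots) != 1L) next
    root <- roots$track_id[1]
    row <- data.frame(trench_id = tid, root_track = root, t0 = NA_real_,
                      t1 = NA_real_, t2 = NA_real_, dur1 = NA_real_,
                      dur2 = NA_real_)
    kids <- tt[!is.na(tt$parent_track_id) & tt$parent_track_id == root, ]
    if (nrow(kids) == 2L) {
      row$t0 <- t_of_frame(min(kids$start_frame))
      dts <- sort(vapply(kids$track_id, function(k) {
        gk <- tt[!is.na(tt$parent_track_id) & tt$parent_track_id == k, ]
        if (nrow(gk) == 2L) t_of_frame(min(gk$start_frame)) else NA_real_
      }, numeric(1)), na.last = TRUE)
      row$t1 <- dts[1]; row$t2 <- dts[2]
      row$dur1 <- row$t1 - row$t0
      row$dur2 <- row$t2 - row$t0
    }
    out <- rbind(out, row)
  }
  if (is.null(out))
    out <- data.frame(trench_id = integer(0), root_track = integer(0),
                      t0 = numeric(0), t1 = numeric(0), t2 = numeric(0),
                      dur1 = numeric(0), dur2 = numeric(0))
  out
}

#' Match fluorescence (death) tracks to phase-contrast tracks
#'
#' Fluorescence detections are tracked per trench with the same LAP
#' machinery; each fluorescence track's onset (its first measured time
#' point) defines a candidate death. The death is assigned to the
#' phase-contrast track of the same trench whose position at (or last
#' position within `match_window` phase frames before) the onset frame is
#' nearest, within `split_radius` px; each phase track receives at most one
#' death. Time-to-death is the onset time minus `drug_add_time`; negative
#' values are flagged `pre_drug`.
#'
#' @param tracking phase-channel [track_trenches()] result.
#' @param fluor_dets fluorescence detections with `trench_id`, `frame`,
#'   `x`, `y` (frames on the fluorescence grid).
#' @param drug_add_time drug addition time in hours.
#' @param phase_interval,fluor_interval channel frame intervals in hours.
#' @param params a [link_params()].
#' @param match_window how many phase frames before onset a phase track may
#'   have ended and still be matched (default 6).
#' @return a `data.frame` with one row per fluorescence track:
#'   `trench_id`, `fluor_track`, `onset_time`, `phase_track` (`NA` if
#'   unmatched), `death_time`, `time_to_death`, `pre_drug`.
#' @export
match_death <- function(tracking, fluor_dets, drug_add_time,
                        phase_interval, fluor_interval,
                        params = link_params(), match_window = 6L) {
  ftr <- track_trenches(fluor_dets, params)
  out <- NULL
  taken <- integer(0)
  fl_tracks <- ftr$tracks[order(ftr$tracks$start_frame,
                                ftr$tracks$track_id), , drop = FALSE]
  for (i in seq_len(nrow(fl_tracks))) {
    ft <- fl_tracks[i, ]
    onset_f <- ft$start_frame
    onset_t <- (onset_f - 1) * fluor_interval
    p0 <- ftr$points[ftr$points$track_id == ft$track_id &
                       ftr$points$frame == onset_f, ][1, ]
    phase_f <- round(onset_t / phase_interval) + 1L
    cand <- tracking$tracks[tracking$tracks$trench_id == ft$trench_id &
                              !(tracking$tracks$track_id %in% taken), ,
                            drop = FALSE]
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(cand))) {
      ct <- cand[j, ]
      if (ct$start_frame > phase_f) next
      if (ct$end_frame < phase_f - match_window) next
      if (ct$n_children >= 2L && ct$end_frame < phase_f) next  # divided away
      use_f <- min(phase_f, ct$end_frame)
      cp <- tracking$points[tracking$points$track_id == ct$track_id &
                              tracking$points$frame == use_f, ]
      if (nrow(cp) == 0L) next
      d <- sqrt((cp$x[1] - p0$x)^2 + (cp$y[1] - p0$y)^2)
      if (d <= params$split_radius && d < best_d) {
        best_d <- d; best <- ct$track_id
      }
    }
    if (!is.na(best)) taken <- c(taken, best)
    out <- rbind(out, data.frame(
      trench_id = ft$trench_id, fluor_track = ft$track_id,
      onset_time = onset_t, phase_track = best,
      death_time = onset_t, time_to_death = onset_t - drug_add_time,
      pre_drug = onset_t < drug_add_time))
  }
  if (is.null(out))
    out <- data.frame(trench_id = integer(0), fluor_track = integer(0),
                      onset_time = numeric(0), phase_track = integer(0),
                      death_time = numeric(0), time_to_death = numeric(0),
                      pre_drug = logical(0))
  out
}

#' Cycle progression and phase at drug addition
#'
#' The progression fraction is
#' `clip((drug_add_time - last_division_time) / reference_cycle, 0, 1)`
#' and the phase is G1 below `g1_end`, S below `s_end`, G2/M otherwise.
#'
#' @param last_division_time time (h) of the cell's last division before
#'   drug addition (vectorized).
#' @param drug_add_time drug addition time (h).
#' @param boundaries a [phase_boundaries()].
#' @return a `data.frame` with `progression` and `phase`
#'   (factor G1/S/G2M).
#' @export
progression_at_drug <- function(last_division_time, drug_add_time,
                                boundaries = phase_boundaries()) {
  if (any(last_division_time > drug_add_time, na.rm = TRUE))
    stop("last_division_time must not exceed drug_add_time")
  fr <- clip((drug_add_time - last_division_time) /
               boundaries$reference_cycle, 0, 1)
  ph <- ifelse(fr < boundaries$g1_end, "G1",
               ifelse(fr < boundaries$s_end, "S", "G2M"))
  data.frame(progression = fr,
             phase = factor(ph, levels = c("G1", "S", "G2M")))
}

#' Pair sister-cell values per trench
#'
#' Takes per-daughter measurements (two rows per qualifying trench) and
#' returns one pair per trench in which both daughters carry a value. The
#' within-pair order is randomized under `seed` so that correlation
#' estimates carry no ordering artifact.
#'
#' @param df `data.frame` with columns `trench_id` and `value`.
#' @param seed integer seed for the pair-order randomization.
#' @return a `data.frame` with `trench_id`, `v1`, `v2`.
#' @export
pair_sisters <- function(df, seed = 1L) {
  df <- df[!is.na(df$value), , drop = FALSE]
  tab <- table(df$trench_id)
  keep <- names(tab)[tab == 2L]
  out <- NULL
  set.seed(substream_seed(seed, "pair_sisters"))
  for (tid in keep) {
    v <- df$value[df$trench_id == tid]
    if (stats::runif(1) < 0.5) v <- rev(v)
    out <- rbind(out, data.frame(trench_id = as.integer(tid),
                                 v1 = v[1], v2 = v[2]))
  }
  if (is.null(out))
    out <- data.frame(trench_id = integer(0), v1 = numeric(0),
                      v2 = numeric(0))
  out
}
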