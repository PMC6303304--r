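#' Linking parameters for per-trench LAP tracking
#'
#' @param max_link_distance maximum frame-to-frame displacement in px.
#' @param gap_max maximum frame gap bridged in the gap-closing pass.
#' @param split_radius maximum distance (px) between a new track start and
#'   its candidate parent at the previous frame for division detection.
#' @param alt_cost_factor multiplier on the 90th percentile of admissible
#'   link costs giving the birth/death alternative cost.
#' @return a `link_params` list.
#' @export
link_params <- function(max_link_distance = 20, gap_max = 2,
                        split_radius = 15, alt_cost_factor = 1.05) {
  if (max_link_distance <= 0 || gap_max <= 0 || split_radius <= 0 ||
      alt_cost_factor <= 0)
    stop("link parameters must be strictly positive")
  structure(list(max_link_distance = max_link_distance, gap_max = gap_max,
                 split_radius = split_radius,
                 alt_cost_factor = alt_cost_factor),
            class = "link_params")
}

#' Label trenches in a mask image
#'
#' 8-connected component labeling of the (binary or already labeled) trench
#' mask, with identities reassigned in raster order of the component
#' centroids (top-left to bottom-right). Touching rods merge into a single
#' component by construction.
#'
#' @param mask numeric/integer matrix; non-zero pixels are trench.
#' @return a `trench_map`: list with `labels` (integer matrix), `ids` and
#'   `boxes` (per id: `x0`, `y0`, `x1`, `y1` in 0-based px).
#' @export
label_trenches <- function(mask) {
  bin <- mask != 0
  if (!any(bin)) stop("empty trench mask")
  lab <- EBImage::bwlabel(bin)
  labels <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  ids <- sort(unique(labels[labels > 0]))
  cent <- t(vapply(ids, function(i) {
    w <- which(labels == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])  # raster: top to bottom, left to right
  remap <- integer(max(ids)); remap[ids[ord]] <- seq_along(ids)
  labels[labels > 0] <- remap[labels[labels > 0]]
  boxes <- t(vapply(seq_along(ids), function(i) {
    w <- which(labels == i, arr.ind = TRUE)
    c(x0 = min(w[, 2]) - 1, y0 = min(w[, 1]) - 1,
      x1 = max(w[, 2]) - 1, y1 = max(w[, 1]) - 1)
  }, numeric(4)))
  structure(list(labels = labels, ids = seq_along(ids),
                 boxes = as.data.frame(boxes)),
            class = "trench_map")
}

#' Assign detections to trenches
#'
#' Each detection receives the trench label at its rounded pixel position;
#' detections on background are assigned to the nearest trench pixel within
#' `tol` px, and dropped otherwise.
#'
#' @param detections `data.frame` with `x`, `y` (0-based px).
#' @param trenchmap a [label_trenches()] result.
#' @param tol background tolerance in px (default 5).
#' @return the detections with a `trench_id` column, background-only rows
#'   removed.
#' @export
assign_detections <- function(detections, trenchmap, tol = 5) {
  if (nrow(detections) == 0L) {
    detections$trench_id <- integer(0)
    return(detections)
  }
  lab <- trenchmap$labels
  nr <- nrow(lab); nc <- ncol(lab)
  ri <- clip(round(detections$y) + 1L, 1L, nr)
  ci <- clip(round(detections$x) + 1L, 1L, nc)
  id <- lab[cbind(ri, ci)]
  miss <- which(id == 0L)
  if (length(miss) > 0L) {
    fg <- which(lab > 0L, arr.ind = TRUE)
    for (k in miss) {
      d2 <- (fg[, 1] - ri[k])^2 + (fg[, 2] - ci[k])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) id[k] <- lab[fg[j, 1], fg[j, 2]]
    }
  }
  detections$trench_id <- id
  detections[id > 0L, , drop = FALSE]
}

# Minimum-cost rectangular assignment with birth/death alternatives,
# solved as a maximum-weight perfect matching on the augmented square
# matrix (links | deaths // births | zero-cost complement).
# cost: n x m matrix with Inf for forbidden pairs; b: alternative cost.
# Returns list(links = 2-col matrix (i, j), births = j idx, deaths = i idx).
lap_solve <- function(cost, b) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L && m == 0L)
    return(list(links = matrix(0L, 0, 2), births = integer(0),
                deaths = integer(0)))
  if (n == 0L)
    return(list(links = matrix(0L, 0, 2), births = seq_len(m),
                deaths = integer(0)))
  if (m == 0L)
    return(list(links = matrix(0L, 0, 2), births = integer(0),
                deaths = seq_len(n)))
  N <- n + m
  finite <- is.finite(cost)
  maxc <- max(c(cost[finite], b, 1))
  M <- (N + 1) * (maxc + 1)
  # edge list: rows 1..N (left), cols N+1..2N (right)
  ei <- ej <- ew <- NULL
  if (any(finite)) {
    w <- which(finite, arr.ind = TRUE)
    ei <- w[, 1]; ej <- N + w[, 2]; ew <- M - cost[finite]
  }
  ei <- c(ei, seq_len(n)); ej <- c(ej, N + m + seq_len(n))
  ew <- c(ew, rep(M - b, n))                       # deaths
  ei <- c(ei, n + seq_len(m)); ej <- c(ej, N + seq_len(m))
  ew <- c(ew, rep(M - b, m))                       # births
  comp <- expand.grid(i = seq_len(n), j = seq_len(m))
  ei <- c(ei, n + comp$j); ej <- c(ej, N + m + comp$i)
  ew <- c(ew, rep(M, nrow(comp)))                  # zero-cost complement
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, N), rep(TRUE, N)),
    edges = as.vector(rbind(ei, ej)))
  mt <- igraph::max_bipartite_match(g, weights = ew, eps = 1e-9)$matching
  links <- NULL
  for (i in seq_len(n)) {
    mi <- mt[i]
    if (!is.na(mi) && mi > N && mi <= N + m)
      links <- rbind(links, c(i, mi - N))
  }
  if (is.null(links)) links <- matrix(0L, 0, 2)
  linked_j <- links[, 2]
  list(links = links,
       births = setdiff(seq_len(m), linked_j),
       deaths = setdiff(seq_len(n), links[, 1]))
}

#' Link detections between two consecutive frames
#'
#' Solves the rectangular linear assignment problem with cost equal to the
#' squared Euclidean distance for pairs within `max_link_distance` (other
#' pairs forbidden) and an alternative birth/death cost equal to
#' `alt_cost_factor` times the 90th percentile of the admissible costs (or
#' `max_link_distance^2` when no pair is admissible). The returned
#' assignment is globally cost-minimal.
#'
#' @param dets_t,dets_t1 `data.frame`s with `x`, `y` for the two frames
#'   (one trench).
#' @param params a [link_params()].
#' @return list with `links` (2-column matrix of row indices into
#'   `dets_t`, `dets_t1`), `births` (indices in `dets_t1`) and `deaths`
#'   (indices in `dets_t`).
#' @export
link_frames <- function(dets_t, dets_t1, params = link_params()) {
  n <- nrow(dets_t); m <- nrow(dets_t1)
  maxd2 <- params$max_link_distance^2
  cost <- matrix(Inf, n, m)
  if (n > 0L && m > 0L) {
    dx <- outer(dets_t$x, dets_t1$x, `-`)
    dy <- outer(dets_t$y, dets_t1$y, `-`)
    d2 <- dx * dx + dy * dy
    cost[d2 <= maxd2] <- d2[d2 <= maxd2]
  }
  adm <- cost[is.finite(cost)]
  b <- if (length(adm) > 0L)
    params$alt_cost_factor * stats::quantile(adm, 0.9, names = FALSE)
  else maxd2
  b <- max(b, 1e-9)
  lap_solve(cost, b)
}

#' Build per-trench tracks with gap closing and division detection
#'
#' Three passes over the detections of a single trench:
#' \enumerate{
#'   \item sequential frame-to-frame LAP linking ([link_frames()]) producing
#'     tracklets;
#'   \item global gap closing: a LAP over (track end, track start) pairs
#'     with gap `2 <= g <= gap_max + 1` frames and cost admissible within
#'     `max_link_distance * sqrt(g)`;
#'   \item division detection: a remaining track start at frame `f + 1` is
#'     attached as a child to a track that has points at frames `f` and
#'     `f + 1` within `split_radius`, provided that track has fewer than
#'     two children; the parent is cut at `f` and its continuation becomes
#'     the second child. Candidates are processed chronologically (earliest
#'     start frame first), then by increasing start distance, ties by lower
#'     track id, so a later division cannot consume a parent's child slots
#'     before an earlier one is resolved.
#' }
#'
#' @param dets `data.frame` with `frame` (1-based), `x`, `y` for one trench.
#' @param params a [link_params()].
#' @param id_offset integer added to all track ids (for global uniqueness).
#' @return list with `points` (`track_id`, `frame`, `x`, `y`) and `tracks`
#'   (`track_id`, `parent_track_id`, `start_frame`, `end_frame`,
#'   `n_children`).
#' @export
build_tracks <- function(dets, params = link_params(), id_offset = 0L) {
  empty <- list(
    points = data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0)),
    tracks = data.frame(track_id = integer(0),
                        parent_track_id = integer(0),
                        start_frame = integer(0), end_frame = integer(0),
                        n_children = integer(0)))
  if (nrow(dets) == 0L) return(empty)
  dets <- dets[order(dets$frame, dets$y, dets$x), , drop = FALSE]
  frames <- sort(unique(dets$frame))
  by_frame <- split(seq_len(nrow(dets)), dets$frame)

  track_of <- integer(nrow(dets))
  next_tid <- 1L
  prev_rows <- by_frame[[as.character(frames[1])]]
  track_of[prev_rows] <- seq_along(prev_rows)
  next_tid <- length(prev_rows) + 1L
  if (length(frames) > 1L) {
    for (fi in seq(2L, length(frames))) {
      rows1 <- by_frame[[as.character(frames[fi])]]
      if (frames[fi] - frames[fi - 1L] == 1L) {
        res <- link_frames(dets[prev_rows, , drop = FALSE],
                           dets[rows1, , drop = FALSE], params)
        if (nrow(res$links) > 0L)
          track_of[rows1[res$links[, 2]]] <- track_of[prev_rows[res$links[, 1]]]
        for (j in res$births) {
          track_of[rows1[j]] <- next_tid; next_tid <- next_tid + 1L
        }
      } else {
        for (j in seq_along(rows1)) {
          track_of[rows1[j]] <- next_tid; next_tid <- next_tid + 1L
        }
      }
      prev_rows <- rows1
    }
  }

  pts <- data.frame(track_id = track_of, frame = dets$frame,
                    x = dets$x, y = dets$y)

  # --- gap closing ---------------------------------------------------------
  tinfo <- function(p) {
    agg <- do.call(rbind, lapply(split(seq_len(nrow(p)), p$track_id),
      function(ix) {
        fr <- p$frame[ix]
        c(id = p$track_id[ix[1]], s = min(fr), e = max(fr),
          sx = p$x[ix[which.min(fr)]], sy = p$y[ix[which.min(fr)]],
          ex = p$x[ix[which.max(fr)]], ey = p$y[ix[which.max(fr)]])
      }))
    as.data.frame(agg)
  }
  ti <- tinfo(pts)
  ends <- ti; starts <- ti
  maxd <- params$max_link_distance
  g_of <- outer(starts$s, ends$e, `-`)      # [start, end]
  cost <- matrix(Inf, nrow(ends), nrow(starts))
  for (a in seq_len(nrow(ends))) for (b2 in seq_len(nrow(starts))) {
    g <- starts$s[b2] - ends$e[a]
    if (ends$id[a] == starts$id[b2] || g < 2 || g > params$gap_max + 1) next
    d2 <- (ends$ex[a] - starts$sx[b2])^2 + (ends$ey[a] - starts$sy[b2])^2
    if (d2 <= maxd^2 * g) cost[a, b2] <- d2
  }
  if (any(is.finite(cost))) {
    adm <- cost[is.finite(cost)]
    b <- max(params$alt_cost_factor * stats::quantile(adm, 0.9,
                                                      names = FALSE), 1e-9)
    res <- lap_solve(cost, b)
    if (nrow(res$links) > 0L) {
      # merge start track into end track; follow chains deterministically
      remap <- stats::setNames(ends$id[res$links[, 1]],
                               starts$id[res$links[, 2]])
      resolve <- function(id) {
        while (as.character(id) %in% names(remap))
          id <- remap[[as.character(id)]]
        id
      }
      pts$track_id <- vapply(pts$track_id, resolve, numeric(1))
    }
  }

  # --- division detection --------------------------------------------------
  parent_of <- integer(0)     # names: child id -> parent id
  children_n <- integer(0)    # names: id -> count
  getn <- function(id) {
    v <- children_n[as.character(id)]
    if (is.na(v)) 0L else v
  }
  repeat {
    ti <- tinfo(pts)
    first_f <- min(ti$s)
    cand <- NULL
    for (b2 in seq_len(nrow(ti))) {
      fs <- ti$s[b2]
      if (fs <= first_f) next
      if (as.character(ti$id[b2]) %in% names(parent_of)) next
      for (a in seq_len(nrow(ti))) {
        if (ti$id[a] == ti$id[b2]) next
        if (!(ti$s[a] <= fs - 1L && ti$e[a] >= fs)) next
        if (getn(ti$id[a]) >= 2L) next
        pa <- pts[pts$track_id == ti$id[a] & pts$frame == fs - 1L, ]
        if (nrow(pa) == 0L) next
        d <- sqrt((pa$x[1] - ti$sx[b2])^2 + (pa$y[1] - ti$sy[b2])^2)
        if (d <= params$split_radius)
          cand <- rbind(cand, data.frame(start = ti$id[b2],
                                         parent = ti$id[a],
                                         f = fs, d = d))
      }
    }
    if (is.null(cand) || nrow(cand) == 0L) break
    # chronological first: a later division must not consume the parent's
    # child slots before an earlier one is resolved
    cand <- cand[order(cand$f, cand$d, cand$start, cand$parent), ,
                 drop = FALSE]
    cs <- cand[1, ]
    # cut parent at cs$f - 1: continuation (frames >= f) becomes a new track
    cont_rows <- pts$track_id == cs$parent & pts$frame >= cs$f
    cont_id <- max(pts$track_id) + 1L
    pts$track_id[cont_rows] <- cont_id
    parent_of[as.character(cs$start)] <- cs$parent
    parent_of[as.character(cont_id)] <- cs$parent
    # the continuation inherits the original's child count
    children_n[as.character(cont_id)] <- getn(cs$parent)
    children_n[as.character(cs$parent)] <- 2L
  }

  # --- finalize ids --------------------------------------------------------
  ti <- tinfo(pts)
  ord <- order(ti$s, ti$sy, ti$sx, ti$id)
  old_ids <- ti$id[ord]
  new_ids <- seq_along(old_ids) + id_offset
  id_map <- stats::setNames(new_ids, old_ids)
  pts$track_id <- as.integer(id_map[as.character(pts$track_id)])
  pts <- pts[order(pts$track_id, pts$frame), ]
  rownames(pts) <- NULL
  tracks <- data.frame(
    track_id = new_ids,
    parent_track_id = vapply(old_ids, function(id) {
      p <- parent_of[as.character(id)]
      if (is.na(p)) NA_integer_ else as.integer(id_map[as.character(p)])
    }, integer(1)),
    start_frame = ti$s[ord], end_frame = ti$e[ord],
    n_children = vapply(old_ids, getn, integer(1))
  )
  rownames(tracks) <- NULL
  list(points = pts, tracks = tracks)
}

#' Track all trenches of a detection table
#'
#' Partitions detections by trench ([assign_detections()] must have been
#' applied) and runs [build_tracks()] per trench with globally unique track
#' ids.
#'
#' @param detections `data.frame` with `trench_id`, `frame`, `x`, `y`.
#' @param params a [link_params()].
#' @return list with `points` (plus `trench_id`) and `tracks` (plus
#'   `trench_id`).
#' @export
track_trenches <- function(detections, params = link_params()) {
  pts_all <- NULL; trk_all <- NULL
  offset <- 0L
  for (tid in sort(unique(detections$trench_id))) {
    d <- detections[detections$trench_id == tid, , drop = FALSE]
    res <- build_tracks(d, params, id_offset = offset)
    if (nrow(res$points) > 0L) {
      res$points$trench_id <- tid
      res$tracks$trench_id <- tid
      pts_all <- rbind(pts_all, res$points)
      trk_all <- rbind(trk_all, res$tracks)
      offset <- max(res$tracks$track_id)
    }
  }
  if (is.null(pts_all))
    return(list(points = data.frame(track_id = integer(0), frame = integer(0),
                                    x = numeric(0), y = numeric(0),
                                    trench_id = integer(0)),
                tracks = data.frame(track_id = integer(0),
                                    parent_track_id = integer(0),
                                    start_frame = integer(0),
                                    end_frame = integer(0),
                                    n_children = integer(0),
                                    trench_id = integer(0))))
  list(points = pts_all, tracks = trk_all)
}

#' Accounting of tracked starting cells
#'
#' Restricts to trenches with exactly one root track starting at frame 1 and
#' classifies each starting cell: `N_tracked_divided` roots whose lineage
#' shows at least one division; `N_not_divided` roots tracked to the final
#' frame (or terminated by an assigned death) without division;
#' `N_losses` roots whose track ends early with neither division nor death.
#' The identity `N0 = N_tracked_divided + N_not_divided + N_losses` holds by
#' construction and is asserted.
#'
#' @param tracking a [track_trenches()] result.
#' @param n_frames total number of phase frames.
#' @param died_track_ids ids of tracks with an assigned death event.
#' @return list with `N0`, `N_tracked_divided`, `N_not_divided`, `N_losses`
#'   and `trenches` (the single-start trench ids used).
#' @export
accounting <- function(tracking, n_frames, died_track_ids = integer(0)) {
  trk <- tracking$tracks
  if (nrow(trk) == 0L)
    return(list(N0 = 0L, N_tracked_divided = 0L, N_not_divided = 0L,
                N_losses = 0L, trenches = integer(0)))
  roots <- trk[is.na(trk$parent_track_id) & trk$start_frame == 1L, ]
  tab <- table(roots$trench_id)
  single <- as.integer(names(tab)[tab == 1L])
  roots <- roots[roots$trench_id %in% single, ]
  # does any division occur anywhere in the root's lineage?
  lineage_divides <- function(root_id) {
    frontier <- root_id
    repeat {
      if (any(trk$n_children[trk$track_id %in% frontier] >= 2L))
        return(TRUE)
      kids <- trk$track_id[!is.na(trk$parent_track_id) &
                             trk$parent_track_id %in% frontier]
      if (length(kids) == 0L) return(FALSE)
      frontier <- kids
    }
  }
  # last frame reached by the root's lineage, and whether it ends in death
  lineage_end <- function(root_id) {
    frontier <- root_id; leaves <- integer(0)
    repeat {
      kids <- trk$track_id[!is.na(trk$parent_track_id) &
                             trk$parent_track_id %in% frontier]
      leaves <- c(leaves,
                  frontier[trk$n_children[match(frontier, trk$track_id)] < 2L])
      if (length(kids) == 0L) break
      frontier <- kids
    }
    list(end = max(trk$end_frame[trk$track_id %in% leaves]),
         died = any(leaves %in% died_track_ids))
  }
  n0 <- nrow(roots)
  divided <- vapply(roots$track_id, lineage_divides, logical(1))
  nd <- nl <- 0L
  for (i in which(!divided)) {
    le <- lineage_end(roots$track_id[i])
    if (le$end >= n_frames || le$died) nd <- nd + 1L else nl <- nl + 1L
  }
  nt <- sum(divided)
  stopifnot(n0 == nt + nd + nl)
  list(N0 = n0, N_tracked_divided = as.integer(nt),
       N_not_divided = as.integer(nd), N_losses = as.integer(nl),
       trenches = single)
}
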