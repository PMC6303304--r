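#' Simulate ground-truth cell lineages in micro-trenches
#'
#' Generates one starting cell per trench and grows its lineage over the
#' movie duration. Cycle durations are log-normal with the configured mean
#' and SD; the two daughters of a division draw their durations either from
#' a Gaussian copula on log-durations with correlation `sister_rho`, or
#' (when `sister_diff_mean` is set) as a shared log-normal draw plus an
#' exponential absolute difference split with random sign. Unsynchronized
#' starting cells begin at a uniformly random point of their cycle;
#' synchronized ones at the G1/S boundary advanced by `release_offset`
#' hours. When the configuration includes a drug (or a non-zero background
#' death probability), [apply_drug_model()] is applied before returning.
#'
#' @param config a [sim_config()] object.
#' @param apply_drug logical; apply the death model (default `TRUE`).
#' @return a `data.frame` with one row per cell: `cell_id`, `trench_id`,
#'   `parent_id` (`NA` for the starting cell), `generation`, `birth_time`,
#'   `division_time` (h; the scheduled division, possibly beyond the movie
#'   end; `NA` if death cancels it), `death_time` (h or `NA`) and
#'   `progression_at_drug` (fraction of the reference cycle elapsed at drug
#'   addition; `NA` for cells not alive then). Deterministic for a fixed
#'   config seed.
#' @seealso [apply_drug_model()], [render_movie()]
#' @export
simulate_lineages <- function(config, apply_drug = TRUE) {
  cfg <- validate_sim_config(config)
  set.seed(substream_seed(cfg$seed, "lineages"))
  lp <- lnorm_params(cfg$cycle_mean, cfg$cycle_sd)

  n <- cfg$n_trenches
  t0_dur <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
  age0 <- if (cfg$synchronized) {
    pmin(cfg$g1_end * t0_dur + cfg$release_offset, 0.999 * t0_dur)
  } else {
    stats::runif(n) * t0_dur
  }
  ev <- data.frame(
    cell_id = seq_len(n), trench_id = seq_len(n), parent_id = NA_integer_,
    generation = 0L, birth_time = -age0, division_time = -age0 + t0_dur
  )

  next_id <- n + 1L
  gen <- 0L
  repeat {
    parents <- ev[ev$generation == gen & ev$division_time < cfg$duration, ]
    if (nrow(parents) == 0L) break
    k <- nrow(parents)
    if (is.null(cfg$sister_diff_mean)) {
      durs <- rlnorm_pair(k, lp["meanlog"], lp["sdlog"], cfg$sister_rho)
    } else {
      shared <- stats::rlnorm(k, lp["meanlog"], lp["sdlog"])
      d <- stats::rexp(k, rate = 1 / cfg$sister_diff_mean)
      s <- sample(c(-1, 1), k, replace = TRUE)
      durs <- pmax(cbind(shared + s * d / 2, shared - s * d / 2), 0.1)
    }
    kids <- data.frame(
      cell_id = next_id + seq_len(2L * k) - 1L,
      trench_id = rep(parents$trench_id, each = 2L),
      parent_id = rep(parents$cell_id, each = 2L),
      generation = gen + 1L,
      birth_time = rep(parents$division_time, each = 2L),
      division_time = rep(parents$division_time, each = 2L) +
        as.vector(t(durs))
    )
    ev <- rbind(ev, kids)
    next_id <- next_id + 2L * k
    gen <- gen + 1L
  }

  ev$death_time <- NA_real_
  ev$progression_at_drug <- NA_real_
  rownames(ev) <- NULL
  if (apply_drug) ev <- apply_drug_model(ev, cfg)
  ev
}

#' Apply the chemotherapeutic death model to a simulated lineage table
#'
#' Every cell present at or after `drug_add_time` is selected to die with
#' probability `p(c) = floor + (ceiling - floor) * c^h / (IC50^h + c^h)`.
#' Mechanisms:
#' \describe{
#'   \item{vincristine}{death at the cell's next M-phase entry (its scheduled
#'     division time) plus a log-normal apoptosis delay; in parallel, a
#'     phase-independent exponential hazard with rate
#'     `phase_independent_death_rate * max(0, c/IC50 - 1)` models high-dose
#'     toxicity; the earlier of the two applies.}
#'   \item{daunorubicin}{death at drug addition (or birth, if later) plus a
#'     log-normal delay, independent of cycle phase.}
#'   \item{none}{each cell dies with the background probability
#'     `death_floor`, at a uniform time between drug addition and movie end.}
#' }
#' Sister cells draw their delay (and hazard) quantiles from a Gaussian
#' copula calibrated so that the Pearson correlation of the draws
#' themselves equals `death_sister_rho` (the copula parameter is obtained
#' by inverting the margin attenuation by quadrature). A dying cell does
#' not divide:
#' its scheduled division is cancelled and its descendants are removed.
#' `progression_at_drug` is filled for every cell alive at drug addition as
#' `(drug_add_time - birth) / cycle_mean`, clipped to `[0, 1]`.
#'
#' @param events lineage table from [simulate_lineages()] (drug-free).
#' @param config the matching [sim_config()].
#' @return the events table with `death_time` and `progression_at_drug`
#'   filled and killed subtrees pruned.
#' @export
apply_drug_model <- function(events, config) {
  cfg <- validate_sim_config(config)
  if (cfg$concentration < 0) stop("concentration must be non-negative")
  set.seed(substream_seed(cfg$seed, "drug"))
  ev <- events
  td <- cfg$drug_add_time

  alive_at_drug <- ev$birth_time <= td & ev$division_time > td
  ev$progression_at_drug[alive_at_drug] <-
    clip((td - ev$birth_time[alive_at_drug]) / cfg$cycle_mean, 0, 1)

  cand <- which(alive_at_drug | ev$birth_time > td)
  if (length(cand) == 0L) return(ev)

  p_die <- if (cfg$drug == "none") {
    cfg$death_floor
  } else {
    hill_probability(cfg$concentration, cfg$ic50, cfg$hill,
                     cfg$death_floor, cfg$death_ceiling)
  }

  # Delay/hazard quantiles, correlated within sister pairs via a Gaussian
  # copula. Two independent uniform channels per cell: the apoptosis delay
  # and the phase-independent hazard.
  nc <- length(cand)
  u_delay <- stats::runif(nc)
  u_haz <- stats::runif(nc)
  dl <- lnorm_params(max(cfg$apoptosis_delay_mean, 1e-9),
                     cfg$apoptosis_delay_sd)
  if (cfg$death_sister_rho != 0) {
    # death_sister_rho is the Pearson correlation of the sister delay
    # draws themselves; invert the margin attenuation (exponential and
    # log-normal margins under a Gaussian copula) per channel
    rho_d <- copula_rho_for_pearson(cfg$death_sister_rho, function(u)
      stats::qlnorm(u, dl["meanlog"], dl["sdlog"]))
    rho_h <- copula_rho_for_pearson(cfg$death_sister_rho, function(u)
      stats::qexp(u))
    par_of <- ev$parent_id[cand]
    sib <- split(seq_len(nc), par_of)
    sib <- sib[lengths(sib) == 2L]
    if (length(sib) > 0L) {
      m <- length(sib)
      ud <- runif_pair_copula(m, rho_d)
      uh <- runif_pair_copula(m, rho_h)
      i1 <- vapply(sib, `[`, integer(1), 1L)
      i2 <- vapply(sib, `[`, integer(1), 2L)
      u_delay[i1] <- ud[, 1]; u_delay[i2] <- ud[, 2]
      u_haz[i1] <- uh[, 1]; u_haz[i2] <- uh[, 2]
    }
  }
  delay <- if (cfg$apoptosis_delay_mean <= 0) rep(0, nc) else
    stats::qlnorm(u_delay, dl["meanlog"], dl["sdlog"])
  lambda <- cfg$phase_independent_death_rate *
    max(0, cfg$concentration / cfg$ic50 - 1)
  e_haz <- if (lambda > 0) stats::qexp(u_haz, rate = lambda) else
    rep(Inf, nc)

  sel <- stats::runif(nc) < p_die
  onset <- pmax(ev$birth_time[cand], td)
  death <- rep(NA_real_, nc)
  if (cfg$drug == "vincristine") {
    death <- pmin(ev$division_time[cand] + delay, onset + e_haz)
  } else if (cfg$drug == "daunorubicin") {
    death <- onset + delay
  } else {
    death <- td + stats::runif(nc) * max(cfg$duration - td, 0)
  }
  death[!sel] <- NA_real_
  ev$death_time[cand] <- death

  # A dying cell does not divide; drop its descendants.
  dying <- ev$cell_id[!is.na(ev$death_time)]
  ev$division_time[ev$cell_id %in% dying] <- NA_real_
  drop <- integer(0)
  frontier <- dying
  repeat {
    ch <- ev$cell_id[!is.na(ev$parent_id) & ev$parent_id %in% frontier]
    ch <- setdiff(ch, drop)
    if (length(ch) == 0L) break
    drop <- c(drop, ch)
    frontier <- ch
  }
  if (length(drop) > 0L) ev <- ev[!ev$cell_id %in% drop, ]
  rownames(ev) <- NULL
  ev
}

#' Hill-curve probability of death
#'
#' `p(c) = floor + (ceiling - floor) * c^h / (ic50^h + c^h)`.
#'
#' @param conc concentration (same units as `ic50`); vectorized.
#' @param ic50 midpoint concentration.
#' @param hill Hill slope.
#' @param floor,ceiling asymptotes in `[0, 1]`.
#' @return probability vector.
#' @export
hill_probability <- function(conc, ic50, hill, floor = 0, ceiling = 1) {
  stopifnot(all(conc >= 0), ic50 > 0)
  floor + (ceiling - floor) * conc^hill / (ic50^hill + conc^hill)
}
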