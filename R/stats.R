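#' Maximum-likelihood distribution fit
#'
#' Fits one of three positive-support families to a sample:
#' \describe{
#'   \item{lognormal}{closed-form MLE from the moments of the log-samples.}
#'   \item{gamma}{numerical likelihood maximization
#'     (via \pkg{fitdistrplus}) from a moment-based start.}
#'   \item{exponential}{rate `1 / mean`.}
#' }
#'
#' @param samples positive numeric vector; `n >= 2` (exponential allows
#'   `n >= 1`).
#' @param family `"lognormal"`, `"gamma"` or `"exponential"`.
#' @return a `distribution_fit` list with `family`, `parameters` (named),
#'   `mean` (fitted distribution mean, hours), `log_likelihood` and `n`.
#' @examples
#' fit_distribution(rlnorm(100, 3, 0.2), "lognormal")
#' @export
fit_distribution <- function(samples,
                             family = c("lognormal", "gamma",
                                        "exponential")) {
  family <- match.arg(family)
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("samples must be positive and finite")
  n <- length(samples)
  min_n <- if (family == "exponential") 1L else 2L
  if (n < min_n) stop("too few samples for a ", family, " fit")
  if (family == "lognormal") {
    lx <- log(samples)
    mu <- mean(lx)
    sig <- sqrt(mean((lx - mu)^2))
    pars <- c(meanlog = mu, sdlog = sig)
    ll <- sum(stats::dlnorm(samples, mu, max(sig, 1e-12), log = TRUE))
    mn <- exp(mu + sig^2 / 2)
  } else if (family == "gamma") {
    m <- mean(samples); v <- stats::var(samples)
    start <- list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-6))
    ft <- fitdistrplus::fitdist(samples, "gamma", start = start)
    pars <- stats::coef(ft)
    ll <- ft$loglik
    mn <- pars[["shape"]] / pars[["rate"]]
  } else {
    rate <- 1 / mean(samples)
    pars <- c(rate = rate)
    ll <- sum(stats::dexp(samples, rate, log = TRUE))
    mn <- 1 / rate
  }
  structure(list(family = family, parameters = pars, mean = mn,
                 log_likelihood = ll, n = n),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s; mean %.4g; logLik %.4g\n", x$family,
              x$n, paste(names(x$parameters),
                         signif(x$parameters, 5), sep = " = ",
                         collapse = ", "),
              x$mean, x$log_likelihood))
  invisible(x)
}

#' Pearson correlation with p-value and bootstrap standard error
#'
#' Sample Pearson `r`, the two-sided p-value from the t statistic with
#' `n - 2` degrees of freedom, and a standard error from `B` seeded
#' pair-resampling bootstrap replicates.
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @param n_boot bootstrap replicates (default 1000; 0 disables).
#' @param seed bootstrap seed.
#' @return a `correlation_result` list: `r`, `p_value`, `n_pairs`, `r_se`.
#' @export
pearson_with_p <- function(x, y, n_boot = 1000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  r_se <- NA_real_
  if (n_boot > 0L) {
    set.seed(substream_seed(seed, "pearson_boot"))
    rb <- vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[ix]) == 0 || stats::sd(y[ix]) == 0) return(NA_real_)
      stats::cor(x[ix], y[ix])
    }, numeric(1))
    r_se <- stats::sd(rb, na.rm = TRUE)
  }
  structure(list(r = r, p_value = p, n_pairs = n, r_se = r_se),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f +/- %.3f (n = %d, p = %.3g)\n", x$r,
              if (is.na(x$r_se)) NA else x$r_se, x$n_pairs, x$p_value))
  invisible(x)
}

#' Random-pairing correlation baseline
#'
#' Repeatedly pairs values drawn from different trenches uniformly at
#' random and reports the mean and SD of the Pearson coefficient across
#' rounds — the null reference against which the sister-cell correlation is
#' judged. For exchangeable values the mean coefficient is ~0. A positive
#' baseline can only emerge from unpaired structure (e.g. a drift in
#' conditions across the trench array) when the pairing is local: with a
#' finite `neighborhood`, partners are drawn only among trenches within
#' that many rank positions of each other, mimicking pairing of
#' contemporaneous / nearby cells.
#'
#' @param values numeric vector of per-cell values.
#' @param trench_ids trench of each value (>= 2 distinct trenches).
#' @param n_rounds number of random pairings.
#' @param seed integer seed.
#' @param neighborhood maximum trench-rank distance between pair members
#'   (`Inf` = unrestricted, the default exchangeable null).
#' @return list with `r_mean`, `r_sd` (`NA` when `n_rounds == 1`),
#'   `n_rounds`, `n_pairs` (per round, on average).
#' @export
random_pairing_baseline <- function(values, trench_ids, n_rounds = 100L,
                                    seed = 1L, neighborhood = Inf) {
  ok <- is.finite(values)
  values <- values[ok]; trench_ids <- trench_ids[ok]
  if (length(values) < 4L || length(unique(trench_ids)) < 2L)
    stop("need >= 4 values from >= 2 distinct trenches")
  set.seed(substream_seed(seed, "random_pairing"))
  tr_rank <- match(trench_ids, sort(unique(trench_ids)))
  rs <- numeric(n_rounds); np <- numeric(n_rounds)
  for (b in seq_len(n_rounds)) {
    if (is.finite(neighborhood)) {
      unpaired <- sample.int(length(values))
      i1 <- integer(0); i2 <- integer(0)
      while (length(unpaired) >= 2L) {
        i <- unpaired[1]; unpaired <- unpaired[-1]
        cand <- unpaired[trench_ids[unpaired] != trench_ids[i] &
                           abs(tr_rank[unpaired] - tr_rank[i]) <=
                             neighborhood]
        if (length(cand) == 0L) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        unpaired <- unpaired[unpaired != j]
        i1 <- c(i1, i); i2 <- c(i2, j)
      }
    } else {
      perm <- sample.int(length(values))
      k <- length(perm) %/% 2L
      a <- perm[seq_len(k)]; b2 <- perm[k + seq_len(k)]
      diff_tr <- trench_ids[a] != trench_ids[b2]
      i1 <- a[diff_tr]; i2 <- b2[diff_tr]
    }
    if (length(i1) < 3L) { rs[b] <- NA; np[b] <- length(i1); next }
    rs[b] <- stats::cor(values[i1], values[i2])
    np[b] <- length(i1)
  }
  list(r_mean = mean(rs, na.rm = TRUE),
       r_sd = if (n_rounds > 1L) stats::sd(rs, na.rm = TRUE) else NA_real_,
       n_rounds = n_rounds, n_pairs = mean(np))
}

#' Kernel density estimate of the time-to-death distribution
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth by default,
#' evaluated on a regular grid spanning the data plus three bandwidths.
#'
#' @param times_to_death numeric vector, `n >= 2`.
#' @param bandwidth bandwidth rule or value passed to [stats::density()]
#'   (`"nrd0"` = Silverman).
#' @param n_grid grid size.
#' @return list with `x`, `y` (the density curve), `bandwidth` and the
#'   grid integral `integral` (close to 1).
#' @export
ttd_density <- function(times_to_death, bandwidth = "nrd0",
                        n_grid = 512L) {
  x <- times_to_death[is.finite(times_to_death)]
  if (length(x) < 2L) stop("need at least 2 observations")
  d <- stats::density(x, bw = bandwidth, n = n_grid, cut = 3)
  integral <- sum(d$y) * diff(d$x[1:2])
  list(x = d$x, y = d$y, bandwidth = d$bw, integral = integral)
}

#' Correlation between cycle progression at drug addition and time-to-death
#'
#' Per concentration group: Pearson `r` with p-value ([pearson_with_p()])
#' and the least-squares line of time-to-death on progression. Groups with
#' fewer than 3 records are skipped with a warning.
#'
#' @param records `data.frame` with `concentration`, `progression`,
#'   `time_to_death`.
#' @param n_boot,seed passed to [pearson_with_p()].
#' @return a `data.frame` with one row per concentration: `concentration`,
#'   `n`, `r`, `p_value`, `slope`, `intercept`.
#' @export
phase_ttd_correlation <- function(records, n_boot = 0L, seed = 1L) {
  out <- NULL
  for (conc in sort(unique(records$concentration))) {
    g <- records[records$concentration == conc &
                   is.finite(records$progression) &
                   is.finite(records$time_to_death), , drop = FALSE]
    if (nrow(g) < 3L) {
      warning(sprintf("concentration %g skipped: %d record(s)", conc,
                      nrow(g)))
      next
    }
    cr <- pearson_with_p(g$progression, g$time_to_death, n_boot = n_boot,
                         seed = seed)
    fit <- stats::lm(time_to_death ~ progression, data = g)
    out <- rbind(out, data.frame(
      concentration = conc, n = nrow(g), r = cr$r, p_value = cr$p_value,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1])))
  }
  if (is.null(out))
    out <- data.frame(concentration = numeric(0), n = integer(0),
                      r = numeric(0), p_value = numeric(0),
                      slope = numeric(0), intercept = numeric(0))
  out
}

#' Four-parameter logistic dose-response fit with IC50
#'
#' Computes per-dose dead fractions with Clopper-Pearson 95% intervals and
#' fits `f(c) = floor + (ceiling - floor) * c^h / (IC50^h + c^h)` by
#' weighted least squares on the fractions (weights `n_total`; the zero
#' dose anchors the floor). The IC50 confidence interval comes from a
#' seeded parametric bootstrap: dead counts are redrawn from the fitted
#' binomial model and the curve refitted `n_boot` times.
#'
#' The logistic surface is shallow when no dose reaches saturation, so the
#' main fit is a multi-start Levenberg-Marquardt search over a grid of
#' hill/log-IC50 starting points; bootstrap refits start from the point
#' estimate.
#'
#' @param doses concentrations (nM), including a zero/control level;
#'   `>= 4` levels.
#' @param n_dead,n_total dead and total cell counts per dose. `n_dead` may
#'   be non-integer (expected counts); it is rounded only for the
#'   Clopper-Pearson interval.
#' @param n_boot bootstrap replicates (default 500; 0 disables).
#' @param seed bootstrap seed.
#' @return a `dose_response_fit` list: `ic50`, `hill`, `floor`, `ceiling`,
#'   `ic50_ci` (2.5/97.5 percentiles), `per_dose` (dose, fraction,
#'   `ci_low`, `ci_high`), `degenerate` flag.
#' @export
fit_dose_response <- function(doses, n_dead, n_total, n_boot = 500L,
                              seed = 1L) {
  if (length(unique(doses)) < 4L) stop("need >= 4 dose levels")
  if (!any(doses == 0)) stop("need a zero/control dose level")
  if (any(n_dead < 0 | n_dead > n_total)) stop("invalid counts")
  frac <- n_dead / n_total
  ci <- t(vapply(seq_along(doses), function(i)
    stats::binom.test(round(n_dead[i]), n_total[i])$conf.int, numeric(2)))
  per_dose <- data.frame(dose = doses, n_dead = n_dead, n_total = n_total,
                         fraction = frac, ci_low = ci[, 1],
                         ci_high = ci[, 2])
  degenerate <- (max(frac) - min(frac)) < 0.02 || all(frac == 0) ||
    all(frac == 1)
  pos <- doses > 0
  llo <- log10(max(min(doses[pos]), 1e-6)) - 3
  lhi <- log10(max(doses)) + 3
  fit1 <- function(fr, starts) {
    df <- data.frame(dose = doses, fr = fr, w = n_total)
    best <- NULL; best_rss <- Inf
    for (s in starts) {
      ft <- try(minpack.lm::nlsLM(
        fr ~ fl + (ce - fl) *
          ifelse(dose > 0, 1 / (1 + 10^(h * (lic50 - log10(dose)))), 0),
        data = df, start = s, weights = df$w,
        lower = c(0, 0, llo, 0.1), upper = c(1, 1, lhi, 10),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)), silent = TRUE)
      if (inherits(ft, "try-error")) next
      rss <- sum(df$w * stats::residuals(ft)^2)
      if (rss < best_rss) { best_rss <- rss; best <- stats::coef(ft) }
    }
    if (is.null(best)) return(NULL)
    c(ic50 = unname(10^best["lic50"]), hill = unname(best["h"]),
      floor = unname(best["fl"]), ceiling = unname(best["ce"]))
  }
  grid_starts <- function(fr) {
    out <- list()
    for (h0 in c(0.5, 1, 1.5, 2.5)) {
      for (l0 in stats::quantile(log10(doses[pos]), c(0.25, 0.5, 0.75),
                                 names = FALSE)) {
        out[[length(out) + 1L]] <- list(fl = max(min(fr), 1e-4),
                                        ce = min(max(fr), 1 - 1e-4),
                                        lic50 = l0, h = h0)
      }
    }
    out
  }
  est <- if (degenerate) NULL else fit1(frac, grid_starts(frac))
  if (is.null(est)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_,
                          floor = NA_real_, ceiling = NA_real_,
                          ic50_ci = c(NA_real_, NA_real_),
                          per_dose = per_dose, degenerate = TRUE),
                     class = "dose_response_fit"))
  }
  ci50 <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(substream_seed(seed, "dose_boot"))
    p_fit <- hill_probability(doses, est["ic50"], est["hill"],
                              est["floor"], est["ceiling"])
    est_start <- list(list(fl = est[["floor"]], ce = est[["ceiling"]],
                           lic50 = clip(log10(est[["ic50"]]), llo, lhi),
                           h = est[["hill"]]))
    bs <- vapply(seq_len(n_boot), function(b) {
      fr_b <- stats::rbinom(length(doses), n_total, p_fit) / n_total
      e <- fit1(fr_b, est_start)
      if (is.null(e)) NA_real_ else e["ic50"]
    }, numeric(1))
    ci50 <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE)
  }
  structure(list(ic50 = unname(est["ic50"]), hill = unname(est["hill"]),
                 floor = unname(est["floor"]),
                 ceiling = unname(est["ceiling"]), ic50_ci = ci50,
                 per_dose = per_dose, degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("dose-response fit: degenerate (flat or all-or-none response)\n")
  } else {
    cat(sprintf(
      "4PL fit: IC50 = %.4g [%.4g, %.4g] nM, hill = %.3g, floor = %.3g, ceiling = %.3g\n",
      x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$hill, x$floor, x$ceiling))
  }
  invisible(x)
}
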