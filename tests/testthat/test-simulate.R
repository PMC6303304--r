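test_that("lineage simulation is deterministic and validates input", {
  cfg <- sim_config(n_trenches = 5, duration = 30, seed = 42)
  ev1 <- simulate_lineages(cfg)
  ev2 <- simulate_lineages(cfg)
  expect_identical(ev1, ev2)
  expect_equal(sum(is.na(ev1$parent_id)), 5L)
  expect_true(all(ev1$division_time > ev1$birth_time, na.rm = TRUE))
  expect_error(sim_config(n_trenches = 0), "n_trenches")
  expect_error(sim_config(duration = -1), "duration")
  expect_error(sim_config(sister_rho = 1.5), "sister_rho")
  expect_error(sim_config(phase_interval = 1 / 6, fluor_interval = 0.25),
               "multiple")
})

test_that("sister correlation limits: rho = 1 gives identical durations, rho = 0 none", {
  cfg1 <- sim_config(n_trenches = 200, duration = 70, sister_rho = 1,
                     drug = "none", death_floor = 0, seed = 3)
  ev <- simulate_lineages(cfg1)
  d <- ev[ev$generation == 1L & !is.na(ev$division_time), ]
  durs <- split(d$division_time - d$birth_time, d$trench_id)
  durs <- durs[lengths(durs) == 2L]
  v1 <- vapply(durs, `[`, numeric(1), 1L)
  v2 <- vapply(durs, `[`, numeric(1), 2L)
  expect_gt(length(v1), 100)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(cor(v1, v2), 1, tolerance = 1e-9)

  cfg0 <- sim_config(n_trenches = 10000, duration = 50, sister_rho = 0,
                     drug = "none", death_floor = 0, seed = 4)
  ev0 <- simulate_lineages(cfg0)
  d0 <- ev0[ev0$generation == 1L, ]
  du <- split(d0$division_time - d0$birth_time, d0$trench_id)
  du <- du[lengths(du) == 2L]
  r <- cor(vapply(du, `[`, numeric(1), 1L), vapply(du, `[`, numeric(1), 2L))
  expect_lt(abs(r), 0.05)
})

test_that("cycle durations follow the configured log-normal", {
  cfg <- sim_config(n_trenches = 320, duration = 70, drug = "none",
                    death_floor = 0, seed = 5)
  ev <- simulate_lineages(cfg)
  d <- ev[ev$generation == 1L & !is.na(ev$division_time), ]
  durs <- d$division_time - d$birth_time
  expect_gt(length(durs), 320)
  sem <- 2.6 / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 19.7), 3 * sem)
  # goodness of fit at large n
  big <- sim_config(n_trenches = 5000, duration = 50, drug = "none",
                    death_floor = 0, seed = 6)
  evb <- simulate_lineages(big)
  db <- evb[evb$generation == 1L & !is.na(evb$division_time), ]
  dursb <- db$division_time - db$birth_time
  s2 <- log(1 + (2.6 / 19.7)^2)
  ks <- suppressWarnings(
    ks.test(dursb, "plnorm", log(19.7) - s2 / 2, sqrt(s2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("sister-pair correlation converges to the configured rho", {
  cfg <- sim_config(n_trenches = 5000, duration = 60, sister_rho = 0.85,
                    drug = "none", death_floor = 0, seed = 7)
  ev <- simulate_lineages(cfg)
  d <- ev[ev$generation == 1L & !is.na(ev$division_time), ]
  du <- split(d$division_time - d$birth_time, d$trench_id)
  du <- du[lengths(du) == 2L]
  r <- cor(vapply(du, `[`, numeric(1), 1L), vapply(du, `[`, numeric(1), 2L))
  # Pearson on log-normal margins is slightly attenuated vs the copula rho
  expect_lt(abs(r - 0.85), 0.03)
})

test_that("shared-plus-exponential-difference sister model hits the target mean", {
  cfg <- sim_config(n_trenches = 3000, duration = 60,
                    sister_diff_mean = 2.3, drug = "none", death_floor = 0,
                    seed = 8)
  ev <- simulate_lineages(cfg)
  d <- ev[ev$generation == 1L & !is.na(ev$division_time), ]
  du <- split(d$division_time - d$birth_time, d$trench_id)
  du <- du[lengths(du) == 2L]
  ad <- abs(vapply(du, `[`, numeric(1), 1L) - vapply(du, `[`, numeric(1), 2L))
  expect_lt(abs(mean(ad) - 2.3), 3 * 2.3 / sqrt(length(ad)))
})

test_that("null dose with zero background assigns no deaths", {
  cfg <- sim_config(n_trenches = 50, duration = 40, drug = "vincristine",
                    concentration = 0, death_floor = 0, seed = 9)
  ev <- simulate_lineages(cfg)
  expect_true(all(is.na(ev$death_time)))
})

test_that("background death fraction matches the configured probability", {
  cfg <- sim_config(n_trenches = 1000, duration = 40, drug = "none",
                    death_floor = 0.1, seed = 10)
  ev <- simulate_lineages(cfg)
  # starting cells are never pruned, so they give an unbiased candidate
  # set: a root was at risk iff it had not divided by drug time, i.e. it
  # now carries either a death or a post-drug division
  roots <- ev[is.na(ev$parent_id), ]
  at_risk <- !is.na(roots$death_time) |
    (!is.na(roots$division_time) & roots$division_time > 20)
  n <- sum(at_risk)
  frac <- sum(!is.na(roots$death_time[at_risk])) / n
  expect_lt(abs(frac - 0.1), 2 * sqrt(0.1 * 0.9 / n))
})

test_that("vincristine with zero delay produces r = -1 between progression and TTD", {
  cfg <- sim_config(n_trenches = 400, duration = 60, drug = "vincristine",
                    concentration = 1e6, ic50 = 652, hill = 1.5,
                    cycle_sd = 0, apoptosis_delay_mean = 0,
                    apoptosis_delay_sd = 0,
                    phase_independent_death_rate = 0, death_floor = 0,
                    death_ceiling = 1, seed = 11)
  ev <- simulate_lineages(cfg)
  d <- ev[!is.na(ev$death_time) & !is.na(ev$progression_at_drug), ]
  d$ttd <- d$death_time - 20
  expect_gt(nrow(d), 100)
  expect_equal(cor(d$progression_at_drug, d$ttd), -1, tolerance = 1e-9)
})

test_that("daunorubicin deaths are uncorrelated with cycle progression", {
  cfg <- sim_config(n_trenches = 600, duration = 60, drug = "daunorubicin",
                    concentration = 100, ic50 = 10, hill = 1.5,
                    apoptosis_delay_mean = 10, apoptosis_delay_sd = 4,
                    death_floor = 0, death_ceiling = 1, seed = 12)
  ev <- simulate_lineages(cfg)
  d <- ev[!is.na(ev$death_time) & !is.na(ev$progression_at_drug), ]
  d$ttd <- d$death_time - 20
  expect_gt(nrow(d), 500)
  expect_lt(abs(cor(d$progression_at_drug, d$ttd)), 0.1)
})

test_that("sister death-delay correlation matches the configured Pearson value", {
  cfg <- sim_config(n_trenches = 4000, duration = 60, drug = "daunorubicin",
                    concentration = 100, ic50 = 10, death_sister_rho = 0.5,
                    apoptosis_delay_mean = 6, apoptosis_delay_sd = 4,
                    seed = 3)
  ev <- simulate_lineages(cfg)
  d <- ev[ev$generation == 1L & !is.na(ev$death_time), ]
  d$value <- d$death_time - 20
  sp <- pair_sisters(data.frame(trench_id = d$trench_id, value = d$value),
                     seed = 1)
  expect_gt(nrow(sp), 2000)
  expect_lt(abs(cor(sp$v1, sp$v2) - 0.5), 0.05)
})
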