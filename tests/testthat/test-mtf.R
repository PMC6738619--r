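test_that("capacity allocation meets sum and minimum constraints", {
  set.seed(11)
  for (i in 1:50) {
    caps <- allocate_capacities(800, 15, 5)
    expect_length(caps, 15)
    expect_equal(sum(caps), 800)
    expect_true(all(caps >= 5))
  }
  expect_equal(allocate_capacities(75, 15, 5), rep(5L, 15))
  expect_error(allocate_capacities(70, 15, 5), "infeasible")
})

test_that("capacity allocation is exchangeable: equal marginal means", {
  set.seed(12)
  draws <- t(replicate(10000, allocate_capacities(800, 15, 5)))
  # exchangeability forces every marginal mean to 800/15; the marginal sd
  # of a uniform composition is ~ 45, so the Monte-Carlo SE is ~ 0.45
  expect_true(all(abs(colMeans(draws) - 800 / 15) < 1.5))
})

test_that("arrival sampling conserves per-source totals and routing means", {
  cfg <- load_mtf_tables()
  expect_equal(sample_arrivals(0, cfg), matrix(0L, 15, 5))
  set.seed(21)
  for (i in 1:20) {
    a <- sample_arrivals(57, cfg)
    expect_equal(colSums(a), rep(57, 5))
    expect_true(all(a >= 0))
  }
  # mean dispatched to facility 14 from source 5 at rate 100 is 100 * 0.1372
  draws <- replicate(3000, sample_arrivals(100, cfg)[14, 5])
  expect_lt(abs(mean(draws) - 13.72), 0.5)
})

test_that("transit attrition follows the per-km Bernoulli closed form", {
  cfg <- load_mtf_tables()
  zero <- transit_attrition(matrix(0L, 15, 5), cfg)
  expect_equal(zero$transit_dow, 0)
  expect_true(all(zero$survivors == 0))

  # survival over 25 km = 0.985^25
  expect_equal((1 - cfg$p_dow_transit_per_km)^25, 0.68533, tolerance = 1e-4)
  set.seed(31)
  big <- matrix(0L, 15, 5); big[1, 1] <- 200000L  # facility 1 is 25 km from source 1
  att <- transit_attrition(big, cfg)
  expect_lt(abs(att$survivors[1, 1] / 200000 - 0.985^25), 0.005)
  expect_equal(att$transit_dow, 200000 - att$survivors[1, 1])

  # zero distance means certain survival
  cfg0 <- cfg; cfg0$distances[, ] <- 0
  expect_equal(transit_attrition(big, cfg0)$transit_dow, 0)
})

test_that("a day's step conserves patients and caps occupancy", {
  cfg <- load_mtf_tables()

  # no casualties, empty system: nothing happens
  cfg0 <- cfg; cfg0$casualty_rate <- 0L
  st <- new_mtf_state(rep(50L, 15))
  set.seed(41)
  res <- step_day(st, cfg0)
  expect_equal(res$state$occupancy, integer(15))
  expect_equal(res$fullness, rep(0, 15))
  expect_equal(res$daily_dow, 0)

  # occupancy k above capacity with exits and arrivals disabled:
  # exactly k overflow deaths
  cfg_ov <- cfg0
  cfg_ov$p_dow <- rep(0, 15); cfg_ov$p_rtd <- rep(0, 15)
  cfg_ov$r_out <- rep(0L, 15)
  st <- new_mtf_state(rep(50L, 15))
  st$occupancy <- rep(57L, 15)  # k = 7 per facility
  st$cum_generated <- sum(st$occupancy)
  res <- step_day(st, cfg_ov)
  expect_equal(res$daily_dow, 7 * 15)
  expect_equal(res$state$occupancy, rep(50L, 15))
  expect_equal(res$fullness, rep(1, 15))
})

test_that("per-facility exit split matches its multinomial expectation", {
  # one facility, occupancy 100, p_dow .25, p_rtd .05, r_out 10:
  # expected post-exit occupancy is 100 * 0.70 - 10 = 60
  cfg1 <- mtf_config(distances = matrix(30, 1, 1),
                     routing_probs = matrix(1, 1, 1),
                     p_dow = 0.25, p_rtd = 0.05, r_out = 10L,
                     casualty_rate = 0L, total_capacity = 1000L,
                     min_capacity = 5L)
  set.seed(51)
  occs <- replicate(3000, {
    st <- new_mtf_state(1000L)
    st$occupancy <- 100L
    st$cum_generated <- 100L
    step_day(st, cfg1)$state$occupancy
  })
  expect_lt(abs(mean(occs) - 60), 0.5)
})

test_that("count-based day matches a per-agent oracle in distribution", {
  cfg1 <- mtf_config(distances = matrix(30, 1, 1),
                     routing_probs = matrix(1, 1, 1),
                     p_dow = 0.2, p_rtd = 0.1, r_out = 4L,
                     casualty_rate = 0L, total_capacity = 20L,
                     min_capacity = 5L)
  set.seed(61)
  n_rep <- 4000
  pkg <- replicate(n_rep, {
    st <- new_mtf_state(20L)
    st$occupancy <- 15L
    st$cum_generated <- 15L
    r <- step_day(st, cfg1)
    c(r$state$occupancy, r$daily_dow)
  })
  agent <- replicate(n_rep, {
    r <- oracle_agent_day(15, 0, 0.2, 0.1, 4, 20)
    c(r$occupancy, r$dow)
  })
  # means agree within Monte-Carlo error (sd ~ 1.5 / sqrt(4000))
  expect_lt(abs(mean(pkg[1, ]) - mean(agent[1, ])), 0.15)
  expect_lt(abs(mean(pkg[2, ]) - mean(agent[2, ])), 0.15)
})

test_that("full runs have the documented shape, determinism and zero-rate limit", {
  cfg <- load_mtf_tables()
  run <- run_mtf(cfg, seed = 71)
  expect_equal(dim(run$fullness), c(365L, 15L))
  expect_equal(sum(run$capacities), 800)
  expect_identical(run_mtf(cfg, seed = 71), run)

  cfg0 <- cfg; cfg0$casualty_rate <- 0L
  expect_equal(run_mtf(cfg0, seed = 72)$total_dow, 0L)
})

test_that("patient conservation and fullness bounds hold across random days", {
  cfg <- load_mtf_tables()
  set.seed(81)
  for (trial in 1:8) {
    cfg$casualty_rate <- sample(c(10L, 90L, 250L), 1)
    cfg$n_days <- 30L
    run <- run_mtf(cfg)
    expect_true(all(run$fullness >= 0 & run$fullness <= 1))
    st <- run$state
    expect_equal(st$cum_generated,
                 st$cum_dow_transit + st$cum_dow_facility + st$cum_rtd +
                   st$cum_transferred + sum(st$occupancy))
    expect_equal(run$total_dow, st$cum_dow_transit + st$cum_dow_facility)
  }
})

test_that("cumulative deaths do not decrease with casualty load (common random numbers)", {
  cfg <- load_mtf_tables()
  cfg$n_days <- 120L
  dows <- sapply(1:20, function(rep_i) {
    sapply(c(30L, 330L), function(rate) {
      cfg$casualty_rate <- rate
      run_mtf(cfg, seed = derive_seed(5, 1, rep_i))$total_dow
    })
  })
  expect_gt(mean(dows[2, ]), mean(dows[1, ]))
})

test_that("death-toll summaries normalize by casualty rate", {
  fake <- function(dow) structure(list(total_dow = dow), class = "mtf_run")
  s <- dow_summary(list(fake(5000)), 100)
  expect_equal(s$mean_dow, 5000)
  expect_equal(s$sd_dow, 0)
  expect_equal(s$normalized_mean, 50)
  s2 <- dow_summary(list(fake(4000), fake(6000)), 100)
  expect_equal(s2$mean_dow, 5000)
  expect_equal(s2$normalized_sd, stats::sd(c(4000, 6000)) / 100)
  expect_error(dow_summary(list(), 100), "empty")
  expect_error(dow_summary(list(fake(0)), 0), "casualty_rate")
})
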