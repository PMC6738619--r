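test_that("hex lattice adjacency matches the cube-coordinate oracle", {
  for (dims in list(c(6L, 6L), c(5L, 4L), c(3L, 7L))) {
    net <- build_hex_grid(dims[1], dims[2])
    n <- dims[1] * dims[2]
    for (a in seq_len(n)) for (b in seq_len(n)) {
      expect_equal(b %in% net$neighbors[[a]],
                   oracle_hex_adjacent(a, b, dims[1], dims[2]),
                   info = sprintf("grid %dx%d sites %d-%d",
                                  dims[1], dims[2], a, b))
    }
  }
})

test_that("the 6x6 grid has the documented degree structure and depot links", {
  net <- build_hex_grid(6, 6)
  expect_length(net$neighbors, 36)
  expect_equal(net$depot_links, c(1L, 31L))
  degrees <- lengths(net$neighbors)
  expect_true(all(degrees >= 2 & degrees <= 6))
  # interior sites of a hex lattice have 6 neighbors
  interior <- c(8, 9, 10, 14, 15, 16, 20, 21, 22, 26, 27, 28)
  expect_true(all(degrees[interior] == 6))
  # single-cell grid is a degenerate lattice with no site neighbors
  expect_equal(build_hex_grid(1, 1)$neighbors[[1]], integer(0))
})

test_that("legal action sets enumerate stay, transfers and moves", {
  cfg <- sf_config(site_capacity = 100)
  net <- build_hex_grid(6, 6)
  fuel <- rep(100L, 36)

  # towed empty: stay + moves only
  a <- list(location = 8L, internal = 100L, towed = 0L, alive = TRUE)
  fuel[8] <- 30L
  acts <- legal_actions(a, fuel, net, cfg)
  expect_equal(acts$n_transfer, 0L)
  expect_equal(acts$n, 1L + length(net$neighbors[[8]]))

  # site at capacity: no transfer actions
  a$towed <- 400L
  fuel[8] <- 100L
  expect_equal(legal_actions(a, fuel, net, cfg)$n_transfer, 0L)

  # interior site, towed 400, deficit 70: 1 + 70 + 6 actions
  fuel[8] <- 30L
  acts <- legal_actions(a, fuel, net, cfg)
  expect_equal(acts$n, 1L + 70L + 6L)

  # depot-linked site offers the depot as a move destination
  a$location <- 1L
  fuel[1] <- 100L
  expect_true(0L %in% legal_actions(a, fuel, net, cfg)$moves)

  # depot, internal below max: refuel is the only action
  a$location <- 0L; a$internal <- 100L
  acts <- legal_actions(a, fuel, net, cfg)
  expect_true(acts$refuel)
  expect_equal(acts$n, 1L)

  # depot, internal full: must move to a depot-linked site
  a$internal <- 150L
  acts <- legal_actions(a, fuel, net, cfg)
  expect_equal(sort(acts$moves), c(1L, 31L))

  a$alive <- FALSE
  expect_error(legal_actions(a, fuel, net, cfg), "dead")
})

test_that("stepping burns fuel, kills stranded assets and ends missions", {
  # no assets: pure linear burn, mission life exactly the site capacity
  cfg <- sf_config(site_capacity = 25, n_assets = 0L)
  run <- run_sf(cfg, seed = 1)
  expect_equal(run$mission_life, 25L)
  expect_false(run$censored)
  expect_equal(unname(run$site_fuel[25, ]), rep(0L, 36))
  expect_true(all(run$site_fuel[1:24, ] > 0))

  # a full asset at the depot must move out to site 1 or 31
  cfg6 <- sf_config(site_capacity = 100)
  net <- build_hex_grid(6, 6)
  st <- kooplog:::new_sf_state(cfg6)
  set.seed(2)
  st2 <- sf_step(st, net, cfg6)
  expect_true(all(vapply(st2$assets, function(a)
    a$location %in% c(1L, 31L), logical(1))))

  # an asset outside the depot with 2 internal fuel dies after the burn
  st$assets[[1]]$location <- 15L
  st$assets[[1]]$internal <- 2L
  st$assets[[1]]$towed <- 0L
  st3 <- sf_step(st, net, cfg6)
  expect_false(st3$assets[[1]]$alive)
  expect_equal(st3$assets[[1]]$internal, 0L)
})

test_that("fuel bookkeeping respects capacities and conservation", {
  cfg <- sf_config(site_capacity = 60)
  net <- build_hex_grid(6, 6)
  set.seed(3)
  st <- kooplog:::new_sf_state(cfg)
  for (step_i in 1:80) {
    prev <- st
    st <- sf_step(st, net, cfg)
    expect_true(all(st$site_fuel <= cfg$site_capacity))
    for (a in st$assets) {
      expect_true(a$internal >= 0 && a$internal <= cfg$internal_max)
      expect_true(a$towed >= 0 && a$towed <= cfg$towed_max)
    }
    # site fuel change = transfers-in - burn; transfers come from towed stock
    transferred <- sum(st$site_fuel) - sum(prev$site_fuel) + 36 * cfg$site_burn
    towed_spent <- sum(vapply(prev$assets, `[[`, integer(1), "towed")) -
      sum(vapply(st$assets, function(a)
        if (a$location == 0L) 0L else a$towed, integer(1)))
    expect_gte(transferred, 0)
    if (all(vapply(st$assets, function(a) a$location != 0L, logical(1))) &&
        all(vapply(prev$assets, function(a) a$location != 0L, logical(1))))
      expect_equal(transferred, towed_spent)
    if (any(st$site_fuel <= 0L)) break
  }
})

test_that("runs are deterministic and mission life is bounded below by capacity", {
  cfg <- sf_config(site_capacity = 25)
  r1 <- run_sf(cfg, seed = 9)
  expect_identical(run_sf(cfg, seed = 9), r1)
  for (s in 1:10) {
    run <- run_sf(cfg, seed = s)
    expect_gte(run$mission_life, 25L)
    # every recorded step before the last has all sites alive
    if (run$mission_life > 1)
      expect_true(all(run$site_fuel[seq_len(run$mission_life - 1L), ] > 0))
    expect_true(any(run$site_fuel[run$mission_life, ] <= 0))
  }
})

test_that("higher site capacity lengthens missions and spreads refueling", {
  never_refueled <- function(run)
    mean(apply(run$site_fuel, 2, function(x) all(diff(x) < 0)))
  runs25 <- lapply(1:10, function(i)
    run_sf(sf_config(site_capacity = 25), seed = derive_seed(3, 2, i)))
  runs200 <- lapply(1:10, function(i)
    run_sf(sf_config(site_capacity = 200), seed = derive_seed(3, 2, i)))
  ml25 <- mission_life_summary(runs25)
  ml200 <- mission_life_summary(runs200)
  expect_gt(ml200$mean, ml25$mean)
  expect_gte(ml25$mean_minus_capacity, 0)
  expect_gte(ml200$mean_minus_capacity, 0)
  expect_lt(mean(sapply(runs200, never_refueled)),
            mean(sapply(runs25, never_refueled)))
})

test_that("mission-life summaries behave on degenerate inputs", {
  fake <- function(life, cap) structure(
    list(mission_life = life, site_capacity = cap), class = "sf_run")
  s <- mission_life_summary(list(fake(25L, 25L), fake(25L, 25L)))
  expect_equal(s$sd, 0)
  expect_equal(s$mean_minus_capacity, 0)
  expect_error(mission_life_summary(list()), "empty")
  expect_error(mission_life_summary(list(fake(30L, 25L), fake(60L, 50L))),
               "capacities")
})
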