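test_that("occupancy credits inter-sample intervals to the leading zone", {
  map <- default_zone_map()
  # animal parked in side_A for a 900 s session at 20 frames/s
  t <- seq(0, 900 - 0.05, by = 0.05)
  parked <- trajectory(t, rep(5, length(t)), rep(12, length(t)),
                       span_s = 900)
  occ <- occupancy(parked, map)
  expect_equal(occ[["side_A"]], 900)
  expect_equal(occ[["side_B"]], 0)
  expect_equal(occ[["center"]], 0)

  # exactly half the session per side
  x <- c(rep(5, length(t) / 2), rep(27, length(t) / 2))
  half <- trajectory(t, x, rep(12, length(t)), span_s = 900)
  occ2 <- occupancy(half, map)
  expect_equal(occ2[["side_A"]], occ2[["side_B"]])
  expect_lte(sum(occ2), 900 + 1e-9)

  # a sample outside every zone goes to the off bucket, with a warning
  stray <- trajectory(c(0, 1, 2), c(5, 100, 5), c(12, 100, 12),
                      span_s = 3)
  expect_warning(occ3 <- occupancy(stray, map), "outside")
  expect_equal(occ3[["off"]], 1)
})

test_that("occupancy is invariant under rigid translation of arena and path", {
  base <- default_zone_map()
  set.seed(5)
  t <- seq(0, 100 - 0.05, by = 0.05)
  x <- runif(length(t), 0, 33); y <- runif(length(t), 0, 25)
  traj <- trajectory(t, x, y, span_s = 100)
  shift <- c(13.7, -4.2)
  zones2 <- lapply(base$zones, function(z)
    c(z[1:2] + shift[1], z[3:4] + shift[2]))
  map2 <- zone_map(zones2)
  traj2 <- trajectory(t, x + shift[1], y + shift[2], span_s = 100)
  o1 <- suppressWarnings(occupancy(traj, base))
  o2 <- suppressWarnings(occupancy(traj2, map2))
  expect_equal(o1, o2)
})

test_that("preference score subtracts pretest from test on the paired side", {
  mk <- function(phase, a, b, cen)
    cpp_session("m1", phase, c(side_A = a, side_B = b, center = cen),
                "side_A", span_s = 900)
  expect_equal(preference_score(mk("test", 500, 300, 100),
                                mk("pretest", 300, 500, 100)), 200)
  expect_equal(preference_score(mk("test", 300, 500, 100),
                                mk("pretest", 300, 500, 100)), 0)
  expect_equal(preference_score(mk("test", 250, 550, 100),
                                mk("pretest", 400, 400, 100)), -150)
  # center time never enters the score
  expect_equal(preference_score(mk("test", 400, 100, 400),
                                mk("pretest", 400, 400, 100)), 0)
  # antisymmetry under swapping the sessions' occupancies
  a <- mk("test", 520, 280, 100); b <- mk("pretest", 310, 490, 100)
  swapped_a <- mk("test", 310, 490, 100)
  swapped_b <- mk("pretest", 520, 280, 100)
  expect_equal(preference_score(a, b),
               -preference_score(swapped_a, swapped_b))

  other <- cpp_session("m2", "pretest",
                       c(side_A = 300, side_B = 500, center = 100),
                       "side_A", 900)
  expect_error(preference_score(mk("test", 1, 2, 3), other), "animal")
  flipped <- cpp_session("m1", "pretest",
                         c(side_A = 300, side_B = 500, center = 100),
                         "side_B", 900)
  expect_error(preference_score(mk("test", 1, 2, 3), flipped), "pairing")
})

test_that("difference-mode scoring uses the side contrast", {
  mk <- function(phase, a, b)
    cpp_session("m1", phase, c(side_A = a, side_B = b, center = 100),
                "side_A", span_s = 900)
  expect_equal(preference_score(mk("test", 500, 300),
                                mk("pretest", 300, 500),
                                mode = "difference"), 400)
})

test_that("group balancing minimizes the worst group-mean bias", {
  res <- balance_groups(c(100, -100, 50, -50), 2)
  expect_equal(res$objective, 0)
  expect_equal(res$group_means, c(0, 0))

  res0 <- balance_groups(rep(0, 6), 3)
  expect_equal(res0$objective, 0)

  res2 <- balance_groups(c(90, 10), 2)
  expect_equal(res2$objective, 90)

  expect_error(balance_groups(c(1, 2), 3), "groups")

  # never worse than a random partition of the same sizes
  set.seed(17)
  for (rep_i in 1:10) {
    ps <- rnorm(10, 0, 80)
    res <- balance_groups(ps, 2)
    rand <- sample(rep(1:2, 5))
    rand_obj <- max(abs(tapply(ps, rand, mean)))
    expect_lte(res$objective, rand_obj + 1e-9)
  }
})

test_that("swap heuristic handles cohorts beyond exhaustive size", {
  set.seed(23)
  ps <- rnorm(20, 0, 60)
  res <- balance_groups(ps, 2, seed = 9)
  expect_equal(sort(table(res$assignment)), sort(table(rep(1:2, 10))),
               ignore_attr = TRUE)
  expect_lt(res$objective, sd(ps)) # far better than a typical split
})

test_that("cpp_summary reports mean, SEM and a one-sample test", {
  tab <- cpp_summary(c(rep(150, 6), rnorm(6, 0, 30)),
                     rep(c("nicotine", "saline"), each = 6))
  expect_equal(tab$n, c(6, 6))
  expect_equal(tab$sem_ps[tab$group == "nicotine"], 0)
  expect_equal(tab$mean_ps[tab$group == "nicotine"], 150)
})

test_that("trajectory files round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,x,y", "0,5,12", "0.05,5.5,12", "0.1,6,12"), path)
  traj <- load_trajectory(path, span_s = 0.15)
  expect_equal(nrow(traj), 3L)
  occ <- occupancy(traj, default_zone_map())
  expect_equal(occ[["side_A"]], 0.15)
})

test_that("zone maps reject overlaps and load from JSON", {
  expect_error(zone_map(list(side_A = c(0, 12, 0, 25),
                             side_B = c(11, 22, 0, 25))), "overlap")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(zones = list(side_A = c(0, 11, 0, 25),
                                         center = c(11, 22, 0, 11),
                                         side_B = c(22, 33, 0, 25)),
                            paired_side = "side_B"),
                       path, auto_unbox = TRUE)
  map <- load_zone_map(path)
  expect_equal(map$paired_side, "side_B")
})
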