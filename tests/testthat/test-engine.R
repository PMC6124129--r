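test_that("waiting times and event selection follow the exact sampling law", {
  set.seed(2024)
  es1 <- eventSet("move", 1L, 2L, rate = 4)
  taus <- replicate(1e5, sampleNextEvent(es1)$tau)
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 1 / 4), 3 * se)

  es2 <- eventSet(c("move", "move"), c(1L, 1L), c(2L, 3L), rate = c(1, 3))
  picks <- replicate(1e5, sampleNextEvent(es2)$index)
  phat <- mean(picks == 2L)
  seb <- sqrt(0.75 * 0.25 / length(picks))
  expect_lt(abs(phat - 0.75), 3 * seb)

  empty <- eventSet()
  samp <- sampleNextEvent(empty)
  expect_identical(samp$tau, Inf)
  expect_true(is.na(samp$index))
})

test_that("local processes integrate the internal state without touching mechanics", {
  g <- buildStructuredGrid("cartesian2d", c(4, 4))
  s <- initializeState(g, occupancy = c(6L, 7L), fillCount = 1L,
                       internalInit = c(x = 2))
  decay <- function(t, y, setup, params) -y
  s1 <- advanceLocalProcesses(s, 0, rhs = decay)
  expect_equal(internalState(s1), internalState(s))
  s2 <- advanceLocalProcesses(s, 1.5, rhs = decay)
  expect_equal(unname(internalState(s2)[, 1]), rep(2 * exp(-1.5), 2),
               tolerance = 1e-4)
  expect_equal(occupancy(s2), occupancy(s))
  expect_equal(simTime(s2), 1.5)
  s3 <- advanceLocalProcesses(s, 2, rhs = NULL)
  expect_equal(internalState(s3), internalState(s))
  expect_equal(simTime(s3), 2)
  expect_error(advanceLocalProcesses(s, -1), "nonnegative")
})

test_that("a population with no sources is an absorbing equilibrium", {
  g <- buildStructuredGrid("cartesian2d", c(6, 6))
  s <- initializeState(g, occupancy = c(14L, 15L, 21L), fillCount = 1L)
  traj <- runSimulation(g, s, rateConstants(1, 1, 1), horizon = 50,
                        snapshotTimes = c(10, 30), seed = 3)
  expect_equal(nrow(eventLog(traj)), 0L)
  expect_equal(runInfo(traj)$termination, "absorbed")
  expect_equal(occupancy(finalState(traj)), occupancy(s))
  for (sn in snapshots(traj)) expect_equal(occupancy(sn), occupancy(s))
})

test_that("a doubly occupied block relaxes to all-single occupancy", {
  g <- buildStructuredGrid("cartesian2d", c(8, 8))
  id <- function(ix, iy) (iy - 1) * 8 + ix
  vox <- c(id(4, 4), id(5, 4), id(4, 5), id(5, 5))
  s <- initializeState(g, occupancy = vox, fillCount = 2L)
  traj <- runSimulation(g, s, rateConstants(1, 1, 1), seed = 8, debug = TRUE)
  fs <- finalState(traj)
  expect_equal(nLivingCells(fs), 8L) # conservation
  expect_equal(max(occupancy(fs)), 1L) # absorption
  expect_equal(runInfo(traj)$termination, "absorbed")
  # event times strictly increase
  tt <- eventLog(traj)$time
  expect_true(all(diff(tt) > 0))
})

test_that("every seeded relaxation run reaches the absorbing state", {
  g <- buildStructuredGrid("cartesian2d", c(10, 10))
  co <- voxelCenters(g)
  vox <- which(abs(co[, 1] - 4.5) <= 1.5 & abs(co[, 2] - 4.5) <= 1.5)
  for (seed in 1:20) {
    s <- initializeState(g, occupancy = vox, fillCount = 2L)
    traj <- runSimulation(g, s, rateConstants(1, 1, 1), seed = seed)
    expect_equal(sum(occupancy(finalState(traj)) == 2L), 0L)
    expect_equal(nLivingCells(finalState(traj)), 2L * length(vox))
    expect_lte(runInfo(traj)$maxOccupancy, 2L)
  }
})

test_that("identical seeds and configurations give identical trajectories", {
  g <- buildStructuredGrid("cartesian2d", c(9, 9))
  strip <- which(abs(voxelCenters(g)[, 1] - 4) <= 1 & voxelCenters(g)[, 2] == 4)
  run <- function() {
    s <- initializeState(g, occupancy = strip, fillCount = 2L)
    runSimulation(g, s, rateConstants(1, 1, 1), seed = 77)
  }
  t1 <- run(); t2 <- run()
  expect_identical(eventLog(t1), eventLog(t2))
  expect_identical(occupancy(finalState(t1)), occupancy(t2@finalState))
})

test_that("snapshots are synchronous with the local-process clock", {
  g <- buildStructuredGrid("cartesian2d", c(4, 4))
  s <- initializeState(g, occupancy = 6L, fillCount = 1L,
                       internalInit = c(x = 1))
  decay <- function(t, y, setup, params) -y
  traj <- runSimulation(g, s, rateConstants(), horizon = 2,
                        snapshotTimes = c(0.5, 1, 2), rhs = decay)
  expect_equal(length(snapshots(traj)), 3L)
  for (k in seq_along(snapshots(traj))) {
    sn <- snapshots(traj)[[k]]
    expect_equal(simTime(sn), traj@snapshotTimes[k])
    expect_equal(unname(internalState(sn)[1, 1]), exp(-simTime(sn)),
                 tolerance = 1e-4)
  }
})
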