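test_that("oxygen solves match hand calculations and the no-cell limit", {
  g <- buildStructuredGrid("cartesian2d", c(3, 3))
  s0 <- initializeState(g, occupancy = integer(9))
  c0 <- tumourOxygen(s0, g, lambda = 0.0015)
  expect_equal(as.numeric(c0), rep(1, 9)) # no consumption anywhere

  # single cell in the one interior voxel: 4 c_centre = 4 - lambda
  s1 <- initializeState(g, occupancy = 5L, fillCount = 1L)
  c1 <- tumourOxygen(s1, g, lambda = 0.0015)
  expect_equal(c1[5], 1 - 0.0015 / 4, tolerance = 1e-12)
  expect_equal(as.numeric(c1)[-5], rep(1, 8))

  # a doubly occupied voxel consumes twice as much
  s2 <- initializeState(g, occupancy = {u <- integer(9); u[5] <- 2L; u})
  c2 <- tumourOxygen(s2, g, lambda = 0.0015)
  expect_equal(c2[5], 1 - 2 * 0.0015 / 4, tolerance = 1e-12)

  # dead cells consume nothing
  sDead <- applyEvent(s1, "die", from = 5L)$state
  cD <- tumourOxygen(sDead, g, lambda = 0.0015)
  expect_equal(as.numeric(cD), rep(1, 9))
})

test_that("adding a cell never increases oxygen anywhere (comparison principle)", {
  set.seed(13)
  g <- buildStructuredGrid("cartesian2d", c(8, 8))
  cache <- tumourOxygenCache(g)
  for (rep in 1:6) {
    u <- randomOccupancy(g, 0.3, 0.3)
    s <- initializeState(g, occupancy = u)
    cBase <- as.numeric(tumourOxygen(s, g, lambda = 0.05, cache = cache))
    free <- which(u == 0L & !externalBoundary(g))
    v <- free[sample.int(length(free), 1)]
    u2 <- u; u2[v] <- 1L
    s2 <- initializeState(g, occupancy = u2)
    cMore <- as.numeric(tumourOxygen(s2, g, lambda = 0.05, cache = cache))
    expect_true(all(cMore <= cBase + 1e-12))
  }
})

test_that("kinetic events follow the strict oxygen thresholds", {
  p <- tumourParams() # kappaProl = 0.65, kappaDeath = 0.55
  g <- buildStructuredGrid("cartesian2d", c(5, 5))
  u <- integer(25); u[c(7, 8, 13)] <- 1L
  s <- initializeState(g, occupancy = u)

  # plentiful oxygen: every singly occupied voxel proliferates, none dies
  ev <- tumourEvents(s, scalarField(rep(1, 25)), p)
  et <- eventTable(ev)
  expect_equal(sort(et$from[et$type == "proliferate"]), c(7L, 8L, 13L))
  expect_equal(sum(et$type == "die"), 0L)
  expect_true(all(et$rate[et$type == "proliferate"] == 0.125))

  # a concentration exactly at a threshold generates no event
  cThresh <- rep(1, 25); cThresh[7] <- 0.65; cThresh[8] <- 0.55
  et2 <- eventTable(tumourEvents(s, scalarField(cThresh), p))
  expect_false(7L %in% et2$from) # at kappaProl: no proliferation
  expect_true(8L %in% et2$from[et2$type == "proliferate"] == FALSE)
  expect_equal(sum(et2$type == "die"), 0L) # 0.55 is not < kappaDeath

  # hypoxia: death but no proliferation; a dead voxel degrades regardless
  cLow <- rep(0.5, 25)
  et3 <- eventTable(tumourEvents(s, scalarField(cLow), p))
  expect_equal(sort(et3$from[et3$type == "die"]), c(7L, 8L, 13L))
  expect_equal(sum(et3$type == "proliferate"), 0L)
  sDead <- applyEvent(s, "die", from = 7L)$state
  et4 <- eventTable(tumourEvents(sDead, scalarField(rep(1, 25)), p))
  deg <- et4[et4$type == "degrade", ]
  expect_equal(nrow(deg), 1L)
  expect_equal(deg$from, 7L)
  expect_equal(deg$rate, 0.01)
})

test_that("without oxygen consumption no cell ever dies", {
  p <- tumourParams(lambda = 0)
  res <- tumourExperiment(params = p, gridExtent = c(41, 41), horizon = 40,
                          seed = 2)
  ev <- eventLog(res$trajectory)
  expect_equal(sum(ev$type == "die"), 0L)
  expect_gt(sum(ev$type == "proliferate"), 0L)
  expect_true(is.na(res$firstDeathTime))
})

test_that("the growing tumour respects carrying capacity and registry invariants", {
  res <- tumourExperiment(horizon = 60, seed = 4)
  fs <- finalState(res$trajectory)
  checkState(fs)
  expect_lte(runInfo(res$trajectory)$maxOccupancy, 2L)
  expect_gt(nLivingCells(fs), 25L) # early growth from the 5 x 5 block
})
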