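test_that("the Hill response functions take their closed-form values", {
  p <- deltaNotchParams() # (a, b, v, k, h) = (0.01, 100, 1, 2, 2)
  expect_equal(notchActivation(0, p), 0)
  expect_equal(deltaInhibition(0, p), 1)
  expect_equal(notchActivation(1, p), 1 / 1.01, tolerance = 1e-12)
  expect_equal(deltaInhibition(1, p), 1 / 101, tolerance = 1e-12)
  expect_error(deltaNotchParams(a = -1), "positive")
})

test_that("the homogeneous fixed point annihilates the coupled right-hand side", {
  p <- deltaNotchParams()
  fp <- deltaNotchFixedPoint(p)
  expect_equal(unname(fp["n"]), notchActivation(fp["d"], p), tolerance = 1e-9,
               ignore_attr = TRUE)
  g <- buildStructuredGrid("hexagonal", c(6, 6))
  s <- initializeState(g, occupancy = rep(1L, nVoxels(g)),
                       internalInit = c(n = unname(fp["n"]), d = unname(fp["d"])))
  setup <- cellAdjacency(s, g)
  dy <- deltaNotchRhs(0, internalState(s), setup, p)
  expect_lt(max(abs(dy)), 1e-9)
})

test_that("contact structure couples voxel neighbours and co-occupants", {
  g <- buildStructuredGrid("cartesian2d", c(3, 1))
  s <- initializeState(g, occupancy = c(2L, 1L, 0L),
                       internalInit = c(n = 0, d = 0))
  setup <- cellAdjacency(s, g)
  # cells 1, 2 share voxel 1 and each contacts cell 3 in voxel 2
  expect_equal(unname(setup$deg), c(2, 2, 2))
  expect_equal(as.numeric(setup$adj[1, ]), c(0, 1, 1))
  # mean-Delta: cell 3 averages its two contacts
  y <- cbind(n = c(0, 0, 0), d = c(0.2, 0.6, 1))
  dy <- deltaNotchRhs(0, y, setup, deltaNotchParams())
  expect_equal(dy[3, 1], notchActivation(0.4, deltaNotchParams()), ignore_attr = TRUE)
  expect_error(deltaNotchRhs(0, -y, setup, deltaNotchParams()), "negative")
})

test_that("long-time lateral inhibition yields no adjacent low-Notch pair", {
  g <- buildStructuredGrid("hexagonal", c(8, 8))
  set.seed(7)
  s <- initializeState(g, occupancy = rep(1L, nVoxels(g)),
                       internalInit = function(nc) cbind(n = runif(nc), d = runif(nc)))
  setup <- cellAdjacency(s, g)
  s2 <- advanceLocalProcesses(s, 500, rhs = deltaNotchRhs, setup = setup,
                              params = deltaNotchParams())
  n <- internalState(s2)[, 1]
  expect_gt(diff(range(n)), 0.8) # a genuine pattern, not the uniform state
  low <- n < 0.5 # the high-Delta primary fate
  ij <- Matrix::which(setup$adj == 1, arr.ind = TRUE)
  expect_equal(sum(low[ij[, 1]] & low[ij[, 2]]), 0)
  expect_gt(sum(low), 0)
})

test_that("a growing tissue halts at the configured population and stays consistent", {
  res <- deltaNotchExperiment(radius = 4, gridExtent = c(31, 31),
                              cellTarget = 150, seed = 5)
  expect_equal(nLivingCells(res$finalState), 150L)
  expect_equal(runInfo(res$trajectory)$termination, "cellTarget")
  checkState(res$finalState)
  expect_lte(max(occupancy(res$finalState)), 2L)
  # proliferation only occurred inside the fixed initial region
  ev <- eventLog(res$trajectory)
  prol <- ev[ev$type == "proliferate", ]
  expect_gt(nrow(prol), 0)
  co <- voxelCenters(res$grid)
  expect_true(all(rowSums(co[prol$from, , drop = FALSE]^2) <= 16 + 1e-9))
})

test_that("fast signalling stays in quasi-steady state while the tissue grows", {
  slow <- deltaNotchExperiment(radius = 4, gridExtent = c(31, 31),
                               cellTarget = 150, seed = 9,
                               params = deltaNotchParams(speedFactor = 1),
                               monitorRhs = TRUE)
  fast <- deltaNotchExperiment(radius = 4, gridExtent = c(31, 31),
                               cellTarget = 150, seed = 9,
                               params = deltaNotchParams(speedFactor = 50),
                               monitorRhs = TRUE)
  mSlow <- stats::median(slow$rhsNormAtEvents[, "medianRhsNorm"])
  mFast <- stats::median(fast$rhsNormAtEvents[, "medianRhsNorm"])
  # note: rhs norms include the speed factor, so compare the *state* distance
  # from equilibrium: norm / speedFactor
  expect_lt(mFast / 50, mSlow / 1)
})
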