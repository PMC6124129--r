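test_that("the 1x3 strip reproduces the hand-solved pressure and currents", {
  strip <- makeStrip()
  g <- strip$grid; s <- strip$state
  p <- computePressure(s, g)
  expect_equal(p[c(strip$A, strip$B, strip$C)], c(1 / 14, 2 / 7, 1 / 14),
               tolerance = 1e-12)
  expect_true(all(p >= 0))
  # edge currents from the hand-solved field
  expect_equal(edgeCurrent(p, g, strip$B, strip$A), 3 / 14, tolerance = 1e-12)
  expect_equal(edgeCurrent(p, g, strip$A, strip$B),
               -edgeCurrent(p, g, strip$B, strip$A))
  lateral <- voxelNeighbours(g, strip$A)
  lateral <- setdiff(lateral, strip$B)
  expect_equal(edgeCurrent(p, g, strip$A, lateral[1]), 1 / 14, tolerance = 1e-12)
  expect_error(edgeCurrent(p, g, strip$A, strip$C), "not neighbours")

  ev <- enumerateMoveEvents(s, g, p, rateConstants(1, 1, 1))
  et <- eventTable(ev)
  expect_equal(totalRate(ev), 10 / 7, tolerance = 1e-12)
  # B -> A and B -> C crowding moves at 3/14 each
  crowd <- et[et$to %in% c(strip$A, strip$C), ]
  expect_equal(sort(crowd$rate), rep(3 / 14, 2), tolerance = 1e-12)
  # total rate into empty voxels equals the single enclosed source
  u <- occupancy(s)
  intoEmpty <- sum(et$rate[u[et$to] == 0])
  expect_equal(intoEmpty, 1, tolerance = 1e-10)
  # source voxel's total outgoing rate is also 1 (divergence identity, D2 = D3)
  outOfB <- sum(et$rate[et$from == strip$B])
  expect_equal(outOfB, 1, tolerance = 1e-10)
})

test_that("populations without overcrowding are in mechanical equilibrium", {
  g <- buildStructuredGrid("cartesian2d", c(9, 9))
  s <- initializeState(g, occupancy = randomOccupancy(g, 0.5, 0))
  p <- computePressure(s, g)
  expect_true(all(as.numeric(p) == 0))
  ev <- enumerateMoveEvents(s, g, p, rateConstants(1, 1, 1))
  expect_equal(nEvents(ev), 0L)
  expect_equal(totalRate(ev), 0)
})

test_that("a fully populated grid with no free boundary is rejected", {
  g <- buildStructuredGrid("cartesian2d", c(3, 3))
  u <- rep(1L, 9); u[5] <- 2L
  s <- initializeState(g, occupancy = u)
  expect_error(computePressure(s, g), "free boundary")
})

test_that("pressure respects lattice symmetry around a central source", {
  g <- buildStructuredGrid("cartesian2d", c(11, 11), center = TRUE)
  co <- voxelCenters(g)
  u <- integer(nVoxels(g))
  u[rowSums(co^2) <= 9] <- 1L
  u[rowSums(co^2) < 1e-9] <- 2L
  s <- initializeState(g, occupancy = u)
  p <- as.numeric(computePressure(s, g))
  # rotate coordinates by 90 degrees: the field must be invariant
  rot <- match(
    paste(round(-co[, 2], 9), round(co[, 1], 9)),
    paste(round(co[, 1], 9), round(co[, 2], 9)))
  expect_equal(p, p[rot], tolerance = 1e-12)
  # maximum principle: min = 0, max at the source voxel
  expect_equal(min(p), 0)
  expect_equal(which.max(p), which(u == 2L))
})

test_that("divergence identity holds on random occupancy configurations", {
  set.seed(61)
  g <- buildStructuredGrid("cartesian2d", c(12, 12))
  for (rep in 1:10) {
    u <- randomOccupancy(g, 0.45, 0.4)
    if (!any(u == 2L)) next
    s <- initializeState(g, occupancy = u)
    p <- computePressure(s, g)
    et <- edgeTable(g)
    # sum of currents from occupied to empty voxels over the free boundary
    Ifwd <- et$w * (as.numeric(p)[et$from] - as.numeric(p)[et$to])
    bnd <- (u[et$from] != 0 & u[et$to] == 0) | (u[et$from] == 0 & u[et$to] != 0)
    outward <- ifelse(u[et$from] != 0, Ifwd, -Ifwd)
    expect_equal(sum(outward[bnd]), sum(u == 2L), tolerance = 1e-10)
    expect_gte(min(as.numeric(p)), -1e-14)
  }
})

test_that("sparse restricted solves match dense brute-force solves", {
  set.seed(71)
  for (rep in 1:8) {
    g <- buildStructuredGrid("cartesian2d", c(10, 10)) # 100 voxels
    u <- randomOccupancy(g, 0.5, 0.4)
    if (!any(u == 2L)) next
    s <- initializeState(g, occupancy = u)
    p <- as.numeric(computePressure(s, g))
    pd <- densePressure(g, u)
    expect_lt(max(abs(p - pd)) / max(pd), 1e-12)
  }
})

test_that("adhesion acts as a pure resistance with the documented geometry", {
  g <- buildStructuredGrid("cartesian2d", c(5, 5))
  id <- function(ix, iy) (iy - 1) * 5 + ix
  ctr <- id(3, 3)
  # populated neighbour diametrically opposite the move direction
  u <- integer(25); u[ctr] <- 2L; u[id(2, 3)] <- 1L
  s <- initializeState(g, occupancy = u)
  expect_equal(adhesionCorrection(s, g, ctr, id(4, 3), 0), 0)
  a <- 0.7
  expect_equal(adhesionCorrection(s, g, ctr, id(4, 3), a), -a * 1 * 1) # e_ik = d_ij = 1
  # orthogonal populated neighbour contributes nothing (min(0, 0) = 0)
  expect_equal(adhesionCorrection(s, g, ctr, id(3, 4), a), 0)
  # strong adhesion floors rates at zero rather than reversing moves
  evFree <- enumerateMoveEvents(s, g, computePressure(s, g), rateConstants(1, 1, 1))
  evStuck <- enumerateMoveEvents(s, g, computePressure(s, g),
                                 rateConstants(1, 1, 1, alphaAdh = 100))
  expect_lt(totalRate(evStuck), totalRate(evFree))
  expect_true(all(eventTable(evStuck)$rate >= 0))
})

test_that("drift pressure reduces to the plain solve and matches a dense assembly", {
  strip <- makeStrip()
  g <- strip$grid; s <- strip$state
  p0 <- as.numeric(computePressure(s, g))
  Sconst <- scalarField(rep(3, nVoxels(g)))
  expect_equal(as.numeric(computePressureWithDrift(s, g, Sconst, chi1 = 5)), p0,
               tolerance = 1e-12)
  Slin <- scalarField(voxelCenters(g)[, 1] * 0.2)
  expect_equal(as.numeric(computePressureWithDrift(s, g, Slin, chi1 = 0)), p0,
               tolerance = 1e-15)

  # manufactured check: dense assembly of the same discrete equations
  chi1 <- 0.8
  pD <- as.numeric(computePressureWithDrift(s, g, Slin, chi1))
  act <- which(occupancy(s) != 0)
  n <- nVoxels(g)
  A <- matrix(0, length(act), length(act))
  rhs <- as.numeric(occupancy(s)[act] == 2)
  Sv <- as.numeric(Slin)
  pos <- match(seq_len(n), act)
  for (ai in seq_along(act)) {
    i <- act[ai]
    for (j in voxelNeighbours(g, i)) {
      w <- edgeTable(g)$w[1] # uniform grid: all weights equal
      dS <- Sv[i] - Sv[j]
      A[ai, ai] <- A[ai, ai] + w * (1 + chi1 * dS / 2)
      if (!is.na(pos[j])) A[ai, pos[j]] <- A[ai, pos[j]] + w * (-1 + chi1 * dS / 2)
    }
  }
  pDense <- base::solve(A, rhs)
  expect_equal(pD[act], pDense, tolerance = 1e-12)
})

test_that("the Slit field has the analytic profile and repels near the source", {
  g <- buildStructuredGrid("cartesian2d", c(101, 3))
  S <- slitField(g, DS = 50, k = 0.1, Q = 2, Xs = 50)
  x1 <- voxelCenters(g)[, 1]
  # peak value Q / (2 sqrt(k DS)) = 1/sqrt(5) on the source line
  expect_equal(max(S), 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(x1[which.max(as.numeric(S)[1:101])], 50)
  # symmetric about the source line
  at <- function(x) as.numeric(S)[match(paste(x, 0), paste(x1, voxelCenters(g)[, 2]))]
  expect_equal(at(40), at(60), tolerance = 1e-12)
  expect_equal(at(45), 1 / sqrt(5) * exp(-sqrt(0.1 / 50) * 5), tolerance = 1e-12)
  # active current between x1 = 49 and x1 = 50 points away from the source
  i49 <- which(x1 == 49 & voxelCenters(g)[, 2] == 1)
  i50 <- which(x1 == 50 & voxelCenters(g)[, 2] == 1)
  expect_gt(activeDriftCurrent(S, g, i50, i49, chi2 = 5), 0)
  expect_lt(activeDriftCurrent(S, g, i49, i50, chi2 = 5), 0)
  expect_equal(activeDriftCurrent(S, g, i49, i50, chi2 = 0), 0)
  Sunif <- scalarField(rep(1, nVoxels(g)))
  expect_equal(activeDriftCurrent(Sunif, g, i49, i50, chi2 = 5), 0)
})

test_that("event sets reject negative rates and drop zero rates", {
  expect_error(eventSet("move", 1L, 2L, rate = -1), "negative")
  es <- eventSet(c("move", "move"), c(1L, 2L), c(2L, 3L), rate = c(0, 2))
  expect_equal(nEvents(es), 1L)
  expect_equal(totalRate(es), 2)
  merged <- mergeEventSets(es, eventSet("die", 4L, rate = 0.5))
  expect_equal(nEvents(merged), 2L)
  expect_equal(totalRate(merged), 2.5)
})
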