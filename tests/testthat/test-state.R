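test_that("initialization counts cells and flags visited voxels", {
  g <- buildStructuredGrid("cartesian2d", c(9, 9))
  co <- voxelCenters(g)
  block <- which(abs(co[, 1] - 4) <= 2 & abs(co[, 2] - 4) <= 2) # 5 x 5

  s1 <- initializeState(g, occupancy = block, fillCount = 1L)
  expect_equal(nLivingCells(s1), 25L)
  expect_equal(sum(visitedVoxels(s1)), 25L)
  expect_equal(simTime(s1), 0)
  checkState(s1)

  s2 <- initializeState(g, occupancy = block, fillCount = 2L)
  expect_equal(nLivingCells(s2), 50L) # doubly occupied block
  expect_false(anyDuplicated(cellTable(s2)$id) > 0)

  s0 <- initializeState(g, occupancy = integer(nVoxels(g)))
  expect_equal(nLivingCells(s0), 0L)
  p <- computePressure(s0, g)
  expect_true(all(as.numeric(p) == 0))

  expect_error(initializeState(g, occupancy = rep(3L, nVoxels(g))),
               "configuration error")
})

test_that("active domain and free boundary are computed correctly", {
  g <- buildStructuredGrid("cartesian2d", c(7, 5))
  id <- function(ix, iy) (iy - 1) * 7 + ix

  s <- initializeState(g, occupancy = id(4, 3), fillCount = 1L)
  ad <- activeDomain(s, g)
  expect_equal(ad$domain, id(4, 3))
  expect_length(ad$boundary, 4L)

  strip <- makeStrip()
  ad <- activeDomain(strip$state, strip$grid)
  expect_length(ad$boundary, 8L) # perimeter of a 1 x 3 strip
  expect_length(intersect(ad$domain, ad$boundary), 0L)

  g2 <- buildStructuredGrid("cartesian2d", c(3, 3))
  sFull <- initializeState(g2, occupancy = rep(1L, 9))
  expect_length(activeDomain(sFull, g2)$boundary, 0L)
})

test_that("events update occupancy, registry and visited flags atomically", {
  g <- buildStructuredGrid("cartesian2d", c(5, 1))
  s <- initializeState(g, occupancy = c(0L, 2L, 1L, 0L, 0L))
  # move from the crowded voxel into the singly occupied one
  r <- applyEvent(s, "move", from = 2L, to = 3L)
  expect_equal(occupancy(r$state)[2:3], c(1L, 2L))
  checkState(r$state)
  # move into a never-visited voxel flips its flag
  expect_false(visitedVoxels(s)[1])
  r2 <- applyEvent(s, "move", from = 2L, to = 1L)
  expect_true(visitedVoxels(r2$state)[1])
  # equal occupancy is not a legal move
  expect_error(applyEvent(s, "move", from = 3L, to = 2L), "illegal event")
  expect_error(applyEvent(s, "move", from = 3L), "illegal event")

  # proliferation inherits internal state and adds one cell
  sInt <- initializeState(g, occupancy = c(0L, 1L, 0L, 0L, 0L),
                          internalInit = c(n = 0.3, d = 0.7))
  rp <- applyEvent(sInt, "proliferate", from = 2L)
  expect_equal(nLivingCells(rp$state), 2L)
  expect_equal(unname(internalState(rp$state)[2, ]), c(0.3, 0.7))
  expect_error(applyEvent(rp$state, "proliferate", from = 2L), "illegal event")

  # death then degradation frees the voxel but keeps it visited
  rd <- applyEvent(sInt, "die", from = 2L)
  expect_equal(occupancy(rd$state)[2], -1L)
  expect_equal(nLivingCells(rd$state), 0L)
  checkState(rd$state)
  expect_error(applyEvent(rd$state, "die", from = 2L), "illegal event")
  expect_error(applyEvent(rd$state, "move", from = 3L, to = 2L), "illegal event")
  rg <- applyEvent(rd$state, "degrade", from = 2L)
  expect_equal(occupancy(rg$state)[2], 0L)
  expect_true(visitedVoxels(rg$state)[2])
  expect_equal(nrow(cellTable(rg$state)), 0L)
})

test_that("random legal event sequences conserve the registry invariants", {
  g <- buildStructuredGrid("cartesian2d", c(8, 8))
  set.seed(99)
  for (rep in 1:5) {
    s <- initializeState(g, occupancy = randomOccupancy(g, 0.5, 0.5))
    visitedBefore <- visitedVoxels(s)
    for (step in 1:30) {
      u <- occupancy(s)
      et <- edgeTable(g)
      legal <- which(u[et$from] >= 1 & u[et$to] >= 0 & u[et$to] < u[et$from] & u[et$to] <= 1)
      legalRev <- which(u[et$to] >= 1 & u[et$from] >= 0 & u[et$from] < u[et$to] & u[et$from] <= 1)
      if (!length(legal) && !length(legalRev)) break
      if (length(legal) && (!length(legalRev) || runif(1) < 0.5)) {
        r <- legal[sample.int(length(legal), 1)]
        s <- applyEvent(s, "move", et$from[r], et$to[r])$state
      } else {
        r <- legalRev[sample.int(length(legalRev), 1)]
        s <- applyEvent(s, "move", et$to[r], et$from[r])$state
      }
      checkState(s)
    }
    # moves conserve cells, visited never reverts
    expect_equal(sum(pmax(occupancy(s), 0)), nLivingCells(s))
    expect_true(all(visitedVoxels(s)[visitedBefore]))
  }
})

test_that("corrupted states are detected", {
  g <- buildStructuredGrid("cartesian2d", c(3, 3))
  s <- initializeState(g, occupancy = 5L, fillCount = 1L)
  sBad <- s
  attr(sBad, "u")[5] <- 2L # bypass the validity-checked setter
  expect_error(checkState(sBad), "invariant violated")
})
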