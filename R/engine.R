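# Continuous-time event loop (Gillespie direct method) with interleaved
# deterministic integration of per-cell processes.

#' Sample the next event (Gillespie direct method)
#'
#' With total rate `R = totalRate(events)`, the waiting time is exponential
#' with rate `R` and the event is chosen with probability proportional to
#' its rate.  With an empty event set the waiting time is infinite.
#'
#' @param events an [EventSet-class]
#' @return list with `tau` (waiting time) and `index` (event row, `NA` when
#'   none).
#' @export
sampleNextEvent <- function(events) {
  R <- totalRate(events)
  if (R < 0 || any(events@rate < 0)) stop("internal error: negative rate")
  if (R == 0) return(list(tau = Inf, index = NA_integer_))
  tau <- stats::rexp(1, rate = R)
  uu <- stats::runif(1) * R
  idx <- which(cumsum(events@rate) >= uu)[1]
  if (is.na(idx)) idx <- length(events@rate) # guard against rounding at uu ~ R
  list(tau = tau, index = idx)
}

#' Advance per-cell local processes deterministically
#'
#' Integrates the internal (signalling) state of all living cells over a
#' time interval with `deSolve`, leaving the mechanical state (occupancy,
#' visited flags) untouched; the simulation clock advances by `dt`.  With no
#' right-hand side this only advances the clock.
#'
#' @param state a [CellState-class]
#' @param dt interval length, `>= 0`.
#' @param rhs `NULL`, or a function `rhs(t, y, setup, params)` taking the
#'   internal-state matrix `y` of living cells (rows aligned with the living
#'   subset of the registry) and returning the derivative matrix.
#' @param setup structural data for `rhs` (e.g. a cell adjacency matrix),
#'   typically rebuilt by the engine after each discrete event.
#' @param params parameter object passed through to `rhs`.
#' @param method `deSolve` integration method.
#' @return the advanced [CellState-class]
#' @export
advanceLocalProcesses <- function(state, dt, rhs = NULL, setup = NULL,
                                  params = NULL, method = "lsoda") {
  if (dt < 0) stop("dt must be nonnegative")
  if (is.null(rhs) || dt == 0 || ncol(state@internal) == 0) {
    state@time <- state@time + dt
    return(state)
  }
  live <- which(state@cellAlive)
  if (!length(live)) {
    state@time <- state@time + dt
    return(state)
  }
  y0 <- state@internal[live, , drop = FALSE]
  nr <- nrow(y0); ncv <- ncol(y0)
  fn <- function(t, y, parms) {
    m <- matrix(y, nrow = nr, ncol = ncv)
    list(as.numeric(rhs(t, m, setup, params)))
  }
  sol <- deSolve::ode(y = as.numeric(y0), times = c(0, dt), func = fn,
                      parms = NULL, method = method)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integrator failure advancing local processes at t = %g (cells: %s)",
                 state@time, paste(utils::head(state@cellId[live]), collapse = ",")))
  yT <- matrix(sol[nrow(sol), -1], nrow = nr, ncol = ncv)
  state@internal[live, ] <- yT
  state@time <- state@time + dt
  state
}

#' Run an event-driven simulation
#'
#' The outer loop over successive events: solve the auxiliary fields and the
#' quasi-steady pressure for the current population, enumerate all discrete
#' events (pressure-driven moves plus any model-specific events), sample the
#' waiting time and the event with the Gillespie direct method, integrate
#' per-cell local processes up to the event time (or the next scheduled
#' snapshot), and apply the event.  Rates are recomputed from a fresh
#' pressure solve after every applied event; no stale rates are reused.
#' Identical `(seed, arguments)` produce an identical trajectory.
#'
#' Termination: at the time horizon, when the living-cell count reaches
#' `cellTarget`, when `stopWhen` returns `TRUE`, or when no events remain
#' (the population is then an absorbing equilibrium and remaining snapshots
#' are emitted unchanged unless local dynamics are still running).
#'
#' @param grid a [VoxelGrid-class]
#' @param state initial [CellState-class]
#' @param constants a [RateConstants-class]
#' @param horizon time horizon (may be `Inf` when no local ODEs are active).
#' @param snapshotTimes times at which to record state copies; local
#'   processes are integrated to the snapshot time before recording so that
#'   signalling states are synchronous with the snapshot clock.
#' @param cellTarget stop as soon as the number of living cells reaches this
#'   value (`NA` to disable).
#' @param auxFields `NULL`, or `function(state, grid)` returning a named
#'   list of [ScalarField-class]s; the entry `S` (if present) feeds the
#'   chemotactic terms (`chi1`, `chi2`).
#' @param extraEvents `NULL`, or `function(state, grid, fields)` returning
#'   an [EventSet-class] of model-specific events merged with the movement
#'   events.
#' @param rhs,rhsSetup,rhsParams local ODE right-hand side (see
#'   [advanceLocalProcesses()]); `rhsSetup(state, grid)` rebuilds the
#'   structural data after every event.
#' @param monitor `NULL`, or `function(state, fields)` returning a named
#'   numeric vector collected after every applied event (with the event
#'   time) into `runInfo(trajectory)$monitor`.
#' @param stopWhen `NULL`, or `function(state, fields)` returning `TRUE` to
#'   terminate after the current event.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param maxEvents safety cap on the number of applied events.
#' @param debug if `TRUE`, run [checkState()] after every event.
#' @return a [SimulationTrajectory-class]
#' @export
runSimulation <- function(grid, state, constants = rateConstants(),
                          horizon = Inf, snapshotTimes = numeric(0),
                          cellTarget = NA, auxFields = NULL,
                          extraEvents = NULL, rhs = NULL, rhsSetup = NULL,
                          rhsParams = NULL, monitor = NULL, stopWhen = NULL,
                          seed = NULL, maxEvents = Inf, debug = FALSE) {
  stopifnot(is(grid, "VoxelGrid"), is(state, "CellState"),
            is(constants, "RateConstants"))
  if (!is.null(seed)) set.seed(seed)
  L <- assembleLaplacian(grid)
  snapshotTimes <- sort(snapshotTimes)
  snaps <- vector("list", length(snapshotTimes))
  snapIdx <- 1L
  hasODE <- !is.null(rhs) && ncol(state@internal) > 0
  if (hasODE && !is.finite(horizon) && !is.finite(maxEvents) && is.na(cellTarget) &&
      is.null(stopWhen))
    stop("a finite horizon (or another stop condition) is required with local ODEs")

  evCap <- 1024L
  evTime <- numeric(evCap); evType <- character(evCap)
  evFrom <- integer(evCap); evTo <- integer(evCap); evCell <- integer(evCap)
  nEv <- 0L
  monRows <- list(); monTimes <- numeric(0)
  maxOcc <- max(state@u, 0L)
  termination <- "horizon"

  advanceTo <- function(state, tTarget, setup) {
    advanceLocalProcesses(state, tTarget - state@time,
                          rhs = if (hasODE) rhs else NULL,
                          setup = setup, params = rhsParams)
  }

  repeat {
    fields <- if (!is.null(auxFields)) auxFields(state, grid) else list()
    S <- fields$S
    p <- if (constants@chi1 != 0 && !is.null(S)) {
      computePressureWithDrift(state, grid, S, constants@chi1, L)
    } else {
      computePressure(state, grid, L)
    }
    fields$pressure <- p
    ev <- enumerateMoveEvents(state, grid, p, constants, S)
    if (!is.null(extraEvents)) ev <- mergeEventSets(ev, extraEvents(state, grid, fields))
    setup <- if (hasODE && !is.null(rhsSetup)) rhsSetup(state, grid) else NULL
    samp <- sampleNextEvent(ev)
    tEvent <- state@time + samp$tau

    # snapshots scheduled before the event (or before the horizon)
    while (snapIdx <= length(snapshotTimes) &&
           snapshotTimes[snapIdx] <= min(tEvent, horizon)) {
      state <- advanceTo(state, snapshotTimes[snapIdx], setup)
      snaps[[snapIdx]] <- state
      snapIdx <- snapIdx + 1L
    }

    if (is.infinite(samp$tau) && (!hasODE || !is.finite(horizon))) {
      # no discrete events remain; scheduled snapshots up to the horizon have
      # already been emitted above (the state is constant from here on, up to
      # any local dynamics, which require a finite horizon to keep running)
      if (is.finite(horizon)) state@time <- horizon
      termination <- "absorbed"
      break
    }
    if (tEvent > horizon) {
      state <- advanceTo(state, horizon, setup)
      termination <- "horizon"
      break
    }

    state <- advanceTo(state, tEvent, setup)
    row <- list(type = ev@type[samp$index], from = ev@from[samp$index],
                to = ev@to[samp$index])
    res <- applyEvent(state, row$type, row$from, row$to)
    state <- res$state
    if (debug) checkState(state)
    nEv <- nEv + 1L
    if (nEv > evCap) {
      evCap <- evCap * 2L
      length(evTime) <- evCap; length(evType) <- evCap
      length(evFrom) <- evCap; length(evTo) <- evCap; length(evCell) <- evCap
    }
    evTime[nEv] <- state@time; evType[nEv] <- row$type
    evFrom[nEv] <- row$from; evTo[nEv] <- if (is.na(row$to)) NA_integer_ else row$to
    evCell[nEv] <- res$cell
    maxOcc <- max(maxOcc, state@u[row$from], if (!is.na(row$to)) state@u[row$to] else -1L)
    if (!is.null(monitor)) {
      monRows[[length(monRows) + 1L]] <- monitor(state, fields)
      monTimes <- c(monTimes, state@time)
    }
    if (!is.na(cellTarget) && sum(state@cellAlive) >= cellTarget) {
      termination <- "cellTarget"
      break
    }
    if (!is.null(stopWhen) && isTRUE(stopWhen(state, fields))) {
      termination <- "stopWhen"
      break
    }
    if (nEv >= maxEvents) {
      termination <- "maxEvents"
      break
    }
  }

  events <- data.frame(time = evTime[seq_len(nEv)], type = evType[seq_len(nEv)],
                       from = evFrom[seq_len(nEv)], to = evTo[seq_len(nEv)],
                       cell = evCell[seq_len(nEv)])
  info <- list(termination = termination, seed = seed, nEvents = nEv,
               maxOccupancy = maxOcc)
  if (!is.null(monitor) && length(monRows)) {
    info$monitor <- cbind(time = monTimes, do.call(rbind, monRows))
  }
  keep <- !vapply(snaps, is.null, logical(1))
  new("SimulationTrajectory", snapshots = snaps[keep],
      snapshotTimes = snapshotTimes[keep], events = events,
      finalState = state, info = info)
}
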