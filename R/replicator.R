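#' Replicator right-hand side
#'
#' Velocity of the three strategy frequencies:
#' `dx/dt = x(1-x) Dg`, `dy/dt = y(1-y) Db`, `dz/dt = z(1-z) Dh`, where each
#' `D` is the actor's fitness difference ([fitness_difference()]) under the
#' current state. `Db` is oriented so that a positive value favours
#' opportunism, matching the `y` coordinate. All eight cube vertices are
#' exact fixed points for every parameter set.
#'
#' @inheritParams fitness_difference
#' @param s Strategy state `c(x, y, z)`.
#' @return Named numeric triple `(dx, dy, dz)`.
#' @examples
#' p <- builtin_scenario("I")$params
#' replicator_rhs(p, c(1, 0.5, 0)) # dy/dt = 0.25 * 17.9
#' @export
replicator_rhs <- function(p, s, mode = c("derived", "as_printed")) {
  mode <- match.arg(mode)
  p <- as_game_params(p)
  s <- .as_state(s)
  .replicator_rhs(unclass(p), s, mode)
}

# evaluated unclamped: outside the cube the logistic factors change sign and
# push roundoff excursions back toward the faces
#' @keywords internal
.replicator_rhs <- function(v, s, mode) {
  c(x = s[[1L]] * (1 - s[[1L]]) * .fitness_difference(v, s, "government", mode),
    y = s[[2L]] * (1 - s[[2L]]) * .fitness_difference(v, s, "platform", mode),
    z = s[[3L]] * (1 - s[[3L]]) * .fitness_difference(v, s, "enterprise", mode))
}

#' Integrate the replicator dynamics
#'
#' Adaptive-step integration (via [deSolve::lsodar()]) of the three coupled
#' replicator equations over `[0, horizon]`, stopping early once the
#' right-hand side's sup-norm falls below `stop_tol` (the state has settled).
#'
#' Internally the free coordinates are integrated on the logit scale,
#' `u = logit(s)`, where the replicator system becomes `du/dt = D(sigma(u))`
#' with a bounded right-hand side. This keeps the unit cube forward-invariant
#' *exactly* (no clamping is ever needed) and tracks the log-distance to a
#' face, so a trajectory that passes within less than machine epsilon of a
#' face and later leaves it again is followed faithfully — in plain cube
#' coordinates such a state would be absorbed by rounding. Components of `s0`
#' that sit exactly on a face (0 or 1) are held fixed, since faces are
#' invariant under the dynamics.
#'
#' @inheritParams replicator_rhs
#' @param s0 Initial state, default `c(0.5, 0.5, 0.5)`.
#' @param horizon Integration horizon in model time units (default 200).
#' @param rtol,atol Relative/absolute integrator tolerances on the logit
#'   coordinates (defaults `1e-8`, `1e-10`).
#' @param stop_tol Early-stop threshold on the cube-coordinate RHS sup-norm
#'   (default `1e-9`).
#' @param dt Output grid spacing (default 0.2).
#' @param scenario Optional scenario tag stored on the trajectory.
#' @return A `game_trajectory` object: list with `times`, `states` (matrix
#'   with columns `x`, `y`, `z`; `y` is the opportunism probability), `mode`,
#'   `scenario`, `params`, `stop_tol`, `settled` (did the early-stop fire)
#'   and `rhs_end` (cube-coordinate RHS at the terminal state).
#' @examples
#' tr <- simulate_game(builtin_scenario("I")$params, scenario = "I")
#' classify_outcome(tr)$corner # "E5"
#' @export
simulate_game <- function(p, s0 = c(0.5, 0.5, 0.5), horizon = 200,
                          mode = c("derived", "as_printed"),
                          rtol = 1e-8, atol = 1e-10, stop_tol = 1e-9,
                          dt = 0.2, scenario = NULL) {
  mode <- match.arg(mode)
  p <- as_game_params(p)
  s0 <- .as_state(s0)
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  v <- unclass(p)
  actors <- c("government", "platform", "enterprise")
  free <- s0 > 0 & s0 < 1  # face components are invariant: hold them fixed

  full_state <- function(u) {
    s <- s0
    s[free] <- stats::plogis(u)
    s
  }
  cube_rhs_norm <- function(s) max(abs(.replicator_rhs(v, s, mode)))

  settled_at_start <- !any(free) || cube_rhs_norm(s0) <= stop_tol
  if (settled_at_start) {
    times <- 0
    states <- matrix(s0, nrow = 1L)
  } else {
    func <- function(t, u, parms) {
      s <- full_state(u)
      list(vapply(actors[free], function(a) .fitness_difference(v, s, a, mode),
                  numeric(1)))
    }
    rootfunc <- function(t, u, parms) cube_rhs_norm(full_state(u)) - stop_tol
    grid <- seq(0, horizon, by = dt)
    if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
    sol <- unclass(deSolve::lsodar(y = stats::qlogis(s0[free]), times = grid,
                                   func = func, rootfunc = rootfunc,
                                   rtol = rtol, atol = atol))
    if (any(!is.finite(sol[, -1L]))) {
      stop("integration produced a non-finite state; parameters: ",
           paste(names(v), unclass(v), sep = "=", collapse = ", "),
           call. = FALSE)
    }
    times <- as.numeric(sol[, 1L])
    states <- t(apply(sol[, -1L, drop = FALSE], 1L, full_state))
  }
  colnames(states) <- c("x", "y", "z")
  terminal <- states[nrow(states), ]
  structure(list(
    times = times,
    states = states,
    mode = mode,
    scenario = scenario,
    params = p,
    stop_tol = stop_tol,
    settled = settled_at_start ||
      cube_rhs_norm(terminal) <= stop_tol * (1 + 1e-6),
    rhs_end = .replicator_rhs(v, terminal, mode)
  ), class = "game_trajectory")
}

#' @export
print.game_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  lab <- classify_outcome(x)
  cat("Replicator trajectory (", x$mode, " mode",
      if (!is.null(x$scenario)) paste0(", scenario ", x$scenario), ")\n", sep = "")
  cat(sprintf("  %d states over t in [0, %g]; settled: %s\n",
              n, x$times[n], x$settled))
  cat(sprintf("  terminal (x, y_opportunism, z) = (%.6g, %.6g, %.6g)\n",
              x$states[n, 1], x$states[n, 2], x$states[n, 3]))
  cat("  outcome:", format(lab), "\n")
  invisible(x)
}

#' Classify the outcome of a trajectory
#'
#' Labels the terminal behaviour: `corner` when the final state lies within
#' `tol` (Chebyshev distance) of a cube vertex and the dynamics have settled
#' (terminal RHS sup-norm below the trajectory's stop tolerance);
#' `oscillating` when, failing the corner test, any velocity component changes
#' sign at least four times over the final half of the trajectory;
#' `interior` when the dynamics settled away from every vertex; otherwise
#' `undetermined` (truncated at the horizon with the state still moving).
#'
#' @param traj A `game_trajectory`.
#' @param tol Corner tolerance on the terminal state (default `1e-3`).
#' @return An `outcome_label` object: list with `class`, `corner` (E1-E8 or
#'   `NA`), `strategies` (the corner's strategy words), `terminal` state and
#'   `rhs_norm`.
#' @export
classify_outcome <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "game_trajectory"))
  n <- nrow(traj$states)
  terminal <- traj$states[n, ]
  rhs_norm <- max(abs(traj$rhs_end))
  near <- .nearest_corner(terminal)
  cls <- "undetermined"
  corner <- NA_character_
  if (near$distance <= tol && traj$settled) {
    cls <- "corner"
    corner <- near$corner
  } else if (.oscillation_flag(traj)) {
    cls <- "oscillating"
  } else if (traj$settled) {
    cls <- "interior"
  }
  structure(list(
    class = cls,
    corner = corner,
    strategies = if (!is.na(corner)) .corner_words(corner) else NA_character_,
    terminal = terminal,
    rhs_norm = rhs_norm
  ), class = "outcome_label")
}

#' @export
format.outcome_label <- function(x, ...) {
  if (x$class == "corner") {
    sprintf("corner %s (%s)", x$corner, x$strategies)
  } else {
    sprintf("%s at (%.4g, %.4g, %.4g)", x$class,
            x$terminal[1], x$terminal[2], x$terminal[3])
  }
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# >= 4 sign changes of any velocity component over the final half
#' @keywords internal
.oscillation_flag <- function(traj, min_changes = 4L, zero_tol = 1e-12) {
  n <- nrow(traj$states)
  if (n < 8L) return(FALSE)
  idx <- seq.int(ceiling(n / 2), n)
  v <- unclass(traj$params)
  vel <- t(apply(traj$states[idx, , drop = FALSE], 1L,
                 function(s) .replicator_rhs(v, s, traj$mode)))
  any(apply(vel, 2L, function(w) {
    sgn <- sign(w)
    sgn <- sgn[abs(w) > zero_tol]
    if (length(sgn) < 2L) return(0L)
    sum(diff(sgn) != 0)
  }) >= min_changes)
}
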