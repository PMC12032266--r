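#' Sweep one parameter and record trajectory outcomes
#'
#' Re-simulates the replicator dynamics from `s0` for each value of the swept
#' parameter and records the terminal state and outcome label. The default
#' government algebra is `"as_printed"`: the cooperative corner E8 that the
#' reward/punishment sweeps flip into is only stable under that algebra for
#' the published scenario bases (their `Cg1` slightly exceeds `rho1*Rg1`, so
#' the derived-algebra government abandons regulation at E8 and the system
#' cycles). Pass `mode = "derived"` for sweeps based on scenario V.
#'
#' @param base Base parameter set (`game_params`) or a `game_scenario`.
#' @param name Parameter to sweep (one of the 18 field names).
#' @param values Strictly increasing numeric grid.
#' @param s0 Initial state (default centre of the cube).
#' @param mode Government algebra for the simulations.
#' @param horizon,tol Passed to [simulate_game()] / [classify_outcome()].
#' @return A `sweep_result`: list with `param`, `mode`, `results` (data frame
#'   with `value`, `class`, `corner`, `x_end`, `y_end`, `z_end`) and
#'   `threshold` (`NA` until filled by a threshold estimator).
#' @examples
#' sw <- sweep_param(builtin_scenario("I"), "mu1", c(0.2, 0.4, 0.5, 0.6))
#' sw$results[, c("value", "corner")]
#' @export
sweep_param <- function(base, name, values, s0 = c(0.5, 0.5, 0.5),
                        mode = c("as_printed", "derived"),
                        horizon = 200, tol = 1e-3) {
  mode <- match.arg(mode)
  p <- if (inherits(base, "game_scenario")) base$params else as_game_params(base)
  if (!name %in% .param_fields) {
    stop("'", name, "' is not a model parameter", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) == 0L || is.unsorted(values, strictly = TRUE)) {
    stop("values must be a strictly increasing grid", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    pv <- p
    pv[name] <- v
    bad <- validate_params(pv)
    if (nrow(bad)) {
      stop("substituting ", name, " = ", v, " violates: ",
           paste0(bad$field, " (", bad$constraint, ")", collapse = "; "),
           call. = FALSE)
    }
    tr <- simulate_game(pv, s0 = s0, horizon = horizon, mode = mode)
    lab <- classify_outcome(tr, tol = tol)
    data.frame(value = v, class = lab$class,
               corner = ifelse(is.na(lab$corner), "", lab$corner),
               x_end = lab$terminal[["x"]], y_end = lab$terminal[["y"]],
               z_end = lab$terminal[["z"]], stringsAsFactors = FALSE)
  })
  structure(list(
    param = name, mode = mode, s0 = .as_state(s0),
    results = do.call(rbind, rows),
    threshold = NA_real_, threshold_method = NA_character_
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep of", x$param, paste0("(", x$mode, " mode)\n"))
  print(x$results, row.names = FALSE)
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold (%s): %.6g\n", x$threshold_method, x$threshold))
  }
  invisible(x)
}

#' Terminal strategy flips along a sweep
#'
#' Counts how often the watched actor's rounded terminal strategy changes
#' between consecutive grid values of a [sweep_param()] result.
#'
#' @param sweep A `sweep_result`.
#' @param watch Actor whose terminal strategy is watched: `"government"`,
#'   `"platform"` or `"enterprise"` (equivalently `"x"`, `"y"`, `"z"`).
#' @return List with `n_flips`, `strategies` (the rounded terminal component
#'   per grid value) and `flip_between` (grid values bracketing each flip).
#' @export
count_flips <- function(sweep, watch) {
  stopifnot(inherits(sweep, "sweep_result"))
  comp <- .watch_component(watch)
  strat <- round(sweep$results[[paste0(comp, "_end")]])
  ch <- which(diff(strat) != 0)
  list(n_flips = length(ch),
       strategies = strat,
       flip_between = if (length(ch)) {
         cbind(lower = sweep$results$value[ch], upper = sweep$results$value[ch + 1])
       } else NULL)
}

#' @keywords internal
.watch_component <- function(watch) {
  switch(watch,
    government = "x", platform = "y", enterprise = "z",
    x = "x", y = "y", z = "z",
    stop("unknown watch actor '", watch, "'", call. = FALSE))
}

#' Closed-form critical parameter value from a corner eigenvalue
#'
#' Every corner eigenvalue is affine in each model parameter, so the
#' parameter value at which the watched actor's eigenvalue at the given
#' corner changes sign is an exact root. This is the analytic counterpart of
#' the trajectory-flip threshold estimated by [empirical_threshold()].
#'
#' @param base Base parameter set or `game_scenario`.
#' @param name Parameter to solve for.
#' @param actor `"government"`, `"platform"` or `"enterprise"`.
#' @param corner Corner label E1-E8 at which the eigenvalue is evaluated.
#' @param mode Government algebra (matters for the government eigenvalue of
#'   E4/E8-type corners only).
#' @return List with `root` (full precision), `rounded` (2 decimals, for
#'   comparison with published values), `status` (`"ok"`,
#'   `"none in range"`, `"not identifiable"`), and `domain`.
#' @examples
#' base <- builtin_scenario("I")
#' analytic_threshold(base, "mu1", "enterprise", "E5")$rounded # 0.48
#' analytic_threshold(base, "mu1", "platform", "E5")$rounded   # 0.54
#' @export
analytic_threshold <- function(base, name,
                               actor = c("government", "platform", "enterprise"),
                               corner, mode = c("derived", "as_printed")) {
  actor <- match.arg(actor)
  mode <- match.arg(mode)
  p <- if (inherits(base, "game_scenario")) base$params else as_game_params(base)
  if (!name %in% .param_fields) {
    stop("'", name, "' is not a model parameter", call. = FALSE)
  }
  lam_at <- function(v) {
    pv <- p
    pv[name] <- v
    corner_eigenvalues(pv, corner, mode, check = FALSE)[[actor]]
  }
  l0 <- lam_at(0)
  l1 <- lam_at(1)
  slope <- l1 - l0
  domain <- if (name %in% .fraction_fields) c(0, 1) else c(0, Inf)
  out <- list(root = NA_real_, rounded = NA_real_, status = "ok",
              domain = domain, actor = actor, corner = corner, mode = mode)
  if (abs(slope) < 1e-12) {
    out$status <- "not identifiable"
    return(out)
  }
  root <- -l0 / slope
  out$root <- root
  out$rounded <- round(root, 2)
  if (root < domain[1] || root > domain[2]) out$status <- "none in range"
  out
}

#' Bisection estimate of a critical parameter value
#'
#' Bisects the swept parameter on `interval` until the watched actor's
#' rounded terminal strategy (from a fresh simulation at each probe) stops
#' changing across an interval narrower than `tol`. The endpoints must
#' produce different watched outcomes.
#'
#' @inheritParams sweep_param
#' @param interval `c(lo, hi)` bisection bracket.
#' @param watch Actor watched for the strategy flip (see [count_flips()]).
#' @param tol Bisection tolerance on the parameter (default `1e-3`).
#' @return List with `threshold` (interval midpoint; `NA` when the endpoints
#'   agree), `status` (`"ok"` or `"no flip in interval"`), and `probes`:
#'   a data frame logging every probed value and its watched outcome.
#' @examples
#' \donttest{
#' empirical_threshold(builtin_scenario("I"), "mu1", c(0.2, 0.6),
#'                     watch = "enterprise")$threshold # ~0.479
#' }
#' @export
empirical_threshold <- function(base, name, interval, watch,
                                s0 = c(0.5, 0.5, 0.5),
                                mode = c("as_printed", "derived"),
                                tol = 1e-3, horizon = 200) {
  mode <- match.arg(mode)
  p <- if (inherits(base, "game_scenario")) base$params else as_game_params(base)
  comp <- .watch_component(watch)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  probes <- data.frame(value = numeric(0), strategy = integer(0))
  outcome_at <- function(v) {
    pv <- p
    pv[name] <- v
    bad <- validate_params(pv)
    if (nrow(bad)) {
      stop("probe ", name, " = ", v, " violates: ",
           paste(bad$field, collapse = ", "), call. = FALSE)
    }
    tr <- simulate_game(pv, s0 = s0, horizon = horizon, mode = mode)
    strat <- round(tr$states[nrow(tr$states), comp])
    probes <<- rbind(probes, data.frame(value = v, strategy = strat))
    strat
  }
  lo <- interval[1]; hi <- interval[2]
  s_lo <- outcome_at(lo)
  s_hi <- outcome_at(hi)
  if (s_lo == s_hi) {
    return(list(threshold = NA_real_, status = "no flip in interval",
                probes = probes))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (outcome_at(mid) == s_lo) lo <- mid else hi <- mid
  }
  list(threshold = (lo + hi) / 2, status = "ok", probes = probes)
}

#' Published critical values versus closed-form eigenvalue roots
#'
#' The Discussion-style sweeps each come with a published critical parameter
#' value. Only the two regulation-level (`mu1`) thresholds agree with the
#' sign-change roots of the corresponding corner eigenvalues; the other
#' published values contradict the published eigenvalue algebra itself. This
#' table reports both side by side rather than forcing agreement: the roots
#' are computed at call time with [analytic_threshold()], the published
#' values are carried as data.
#'
#' @return A data frame with one row per sweep (the cost sweep appears once
#'   per government algebra) and columns `param`, `base` (scenario),
#'   `actor`, `corner`, `mode`, `analytic_root`, `analytic_root_rounded`
#'   (2 decimals) and `printed_value`.
#' @examples
#' discussion_thresholds()
#' @export
discussion_thresholds <- function() {
  spec <- list(
    list("mu1",  "I",   "enterprise", "E5", "derived",    0.48),
    list("mu1",  "I",   "platform",   "E5", "derived",    0.54),
    list("rho2", "II",  "platform",   "E6", "derived",    0.45),
    list("Pb1",  "II",  "platform",   "E6", "derived",    29),
    list("Ph1",  "III", "enterprise", "E7", "derived",    23),
    list("Rh3",  "III", "enterprise", "E7", "derived",    25),
    list("Cg1",  "V",   "government", "E8", "derived",    20),
    list("Cg1",  "V",   "government", "E8", "as_printed", 20)
  )
  rows <- lapply(spec, function(r) {
    at <- analytic_threshold(builtin_scenario(r[[2L]]), r[[1L]],
                             actor = r[[3L]], corner = r[[4L]], mode = r[[5L]])
    data.frame(param = r[[1L]], base = r[[2L]], actor = r[[3L]],
               corner = r[[4L]], mode = r[[5L]],
               analytic_root = at$root, analytic_root_rounded = at$rounded,
               printed_value = r[[6L]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
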