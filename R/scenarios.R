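#' @keywords internal
.base_params_I <- function() {
  game_params(
    rho1 = 0.6, Rg1 = 40, Pg1 = 40, Pg2 = 20, Cg1 = 25, mu1 = 0.2,
    rho2 = 0.3, Rb1 = 18, Rb2 = 48, Rb3 = 5, Rb4 = 0, Pb1 = 5,
    rho3 = 0.3, Rh1 = 18, Rh2 = 42, Rh3 = 5, Rh4 = 0, Ph1 = 5
  )
}

# published overlays; II-IV overlay condition I, V overlays condition IV
#' @keywords internal
.scenario_overlays <- list(
  I   = list(),
  II  = list(Rb1 = 20, Rb2 = 45, Rb3 = 10, mu1 = 0.3, Pb1 = 20,
             rho3 = 0.6, Rh3 = 10, Ph1 = 20),
  III = list(Rb1 = 30, rho2 = 0.6, Rb2 = 45, Rb3 = 20, mu1 = 0.3, Pb1 = 20,
             Rh1 = 15, rho3 = 0.2, Rh3 = 20, Rh2 = 40, Ph1 = 20),
  IV  = list(rho2 = 0.6, Rb2 = 45, Rb4 = 10, mu1 = 0.5,
             rho3 = 0.6, Rh4 = 10, Rh2 = 42),
  V   = list(Cg1 = 30, Rg1 = 40, Rb1 = 50, Rb3 = 10, Rb4 = 10, mu1 = 0.3,
             Pb1 = 10, Rh1 = 50, Rh3 = 10, Rh4 = 10, Rh2 = 45, Ph1 = 10)
)

#' @keywords internal
.scenario_meta <- list(
  I   = list(expected = "E5", modes = c("derived", "as_printed")),
  II  = list(expected = "E6", modes = c("derived", "as_printed")),
  III = list(expected = "E7", modes = c("derived", "as_printed")),
  IV  = list(expected = "E8", modes = "as_printed"),
  V   = list(expected = "E4", modes = "derived")
)

#' Built-in validation scenarios (conditions I-V)
#'
#' The five published parameter sets used to validate the model, one per
#' stability condition. Scenario I is the base assignment; scenarios II-IV
#' overlay adjustments on it, and scenario V overlays scenario IV. Each
#' scenario records the corner it is expected to converge to from the centre
#' of the cube and the government-algebra mode(s) under which that convergence
#' holds (I-III: both; IV: `as_printed` only; V: `derived` only — the two
#' algebras genuinely disagree on the government eigenvalue at E8/E4).
#'
#' @param condition One of `"I"` to `"V"`.
#' @return A `game_scenario` object: list with `id`, `params`
#'   (`game_params`), `modes` (recommended government algebra(s)) and
#'   `expected_corner`.
#' @examples
#' sc <- builtin_scenario("I")
#' sc$expected_corner # "E5"
#' @export
builtin_scenario <- function(condition) {
  if (!condition %in% .condition_ids) {
    stop("unknown condition '", condition, "' (expected I..V)", call. = FALSE)
  }
  base <- as.list(unclass(.base_params_I()))
  if (condition == "V") {
    base <- utils::modifyList(base, .scenario_overlays$IV)
  }
  base <- utils::modifyList(base, .scenario_overlays[[condition]])
  meta <- .scenario_meta[[condition]]
  structure(list(
    id = condition,
    params = do.call(game_params, base),
    modes = meta$modes,
    expected_corner = meta$expected
  ), class = "game_scenario")
}

#' @export
print.game_scenario <- function(x, ...) {
  cat("Game scenario", x$id, "\n")
  if (!is.null(x$expected_corner) && !is.na(x$expected_corner)) {
    cat("  expected outcome:", x$expected_corner,
        paste0("(", .corner_words(x$expected_corner), ")"), "\n")
  }
  cat("  recommended mode(s):", paste(x$modes, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Default sampling ranges for random scenarios
#'
#' Fractions are drawn uniformly on `[0.05, 0.95]` (avoiding degenerate
#' extremes) and payoff parameters uniformly on `[1, 100]`, which brackets all
#' published values.
#'
#' @return Named list of `c(lo, hi)` ranges, one per parameter.
#' @export
default_sample_ranges <- function() {
  r <- stats::setNames(rep(list(c(1, 100)), length(.param_fields)), .param_fields)
  for (f in .fraction_fields) r[[f]] <- c(0.05, 0.95)
  r
}

#' Sample a random scenario satisfying a stability condition
#'
#' Rejection-samples parameter sets uniformly over `ranges` until one passes
#' [validate_params()] (in particular `Pg1 > Cg1`, enforced by redrawing) and
#' satisfies [check_condition()] for the requested condition. For conditions
#' IV and V, whose government inequality is mode-dependent, satisfaction in at
#' least one mode suffices and the witnessing mode(s) are recorded.
#' Deterministic given `seed`.
#'
#' @param condition One of `"I"` to `"V"`.
#' @param seed Integer seed (required).
#' @param ranges Named list of `c(lo, hi)` sampling ranges; defaults to
#'   [default_sample_ranges()]. Ranges must stay inside each parameter's valid
#'   domain.
#' @param max_draws Rejection budget (default `1e5`).
#' @return A `game_scenario` with `id = condition`, the sampled `params`,
#'   the witnessing `modes`, `expected_corner` (the condition's ESS corner),
#'   and `draws` (number of rejection draws used).
#' @examples
#' sc <- sample_scenario("I", seed = 1)
#' check_condition(sc$params, "I")$satisfied # TRUE by construction
#' @export
sample_scenario <- function(condition, seed, ranges = default_sample_ranges(),
                            max_draws = 1e5) {
  if (!condition %in% .condition_ids) {
    stop("unknown condition '", condition, "' (expected I..V)", call. = FALSE)
  }
  if (missing(seed) || !is.finite(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  missing_r <- setdiff(.param_fields, names(ranges))
  if (length(missing_r)) {
    stop("ranges must bound every parameter; missing: ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  for (f in .param_fields) {
    r <- ranges[[f]]
    lo_ok <- r[1] >= 0
    hi_ok <- if (f %in% .fraction_fields) r[2] <= 1 else is.finite(r[2])
    if (length(r) != 2L || r[1] > r[2] || !lo_ok || !hi_ok) {
      stop("invalid sampling range for ", f, call. = FALSE)
    }
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  last_check <- NULL
  for (draw in seq_len(max_draws)) {
    vals <- vapply(.param_fields, function(f) {
      stats::runif(1, ranges[[f]][1], ranges[[f]][2])
    }, numeric(1))
    p <- do.call(game_params, c(as.list(vals), list(check = FALSE)))
    if (nrow(validate_params(p))) next  # e.g. Pg1 <= Cg1: redraw
    checks <- lapply(c("as_printed", "derived"), function(m) {
      check_condition(p, condition, mode = m)
    })
    ok <- vapply(checks, `[[`, logical(1), "satisfied")
    last_check <- checks
    if (any(ok)) {
      meta <- .scenario_meta[[condition]]
      return(structure(list(
        id = condition,
        params = p,
        modes = c("as_printed", "derived")[ok],
        expected_corner = meta$expected,
        seed = as.integer(seed),
        draws = draw
      ), class = "game_scenario"))
    }
  }
  binding <- unique(unlist(lapply(last_check, function(ck) {
    ck$inequalities$label[!ck$inequalities$holds]
  })))
  stop("rejection budget (", max_draws, " draws) exhausted for condition ",
       condition, "; last unmet inequalities: ",
       paste(binding, collapse = "; "), call. = FALSE)
}

#' Read / write a scenario config
#'
#' Scenarios serialize to the same flat JSON/YAML dialect as parameter sets,
#' with the additional keys `id`, `mode` (comma-free character vector) and
#' `expected_corner`.
#'
#' @param path Config path (`.json`, `.yaml` or `.yml`).
#' @return `read_scenario()`: a `game_scenario`; `write_scenario()`: `path`,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- .read_config(path)
  p <- do.call(game_params, cfg[.param_fields])
  structure(list(
    id = if (!is.null(cfg$id)) cfg$id else "custom",
    params = p,
    modes = if (!is.null(cfg$mode)) unlist(cfg$mode) else c("derived", "as_printed"),
    expected_corner = if (!is.null(cfg$expected_corner)) cfg$expected_corner
                      else NA_character_
  ), class = "game_scenario")
}

#' @param scenario A `game_scenario`.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "game_scenario"))
  cfg <- c(
    list(id = scenario$id, mode = scenario$modes,
         expected_corner = scenario$expected_corner),
    as.list(unclass(scenario$params))
  )
  .write_config(cfg, path)
  invisible(path)
}
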