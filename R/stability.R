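#' Jacobian of the replicator system
#'
#' Exact partial derivatives of the three replicator right-hand sides with
#' respect to `(x, y, z)`, obtained symbolically. At any cube vertex the
#' off-diagonal entries vanish (the logistic factors `x(1-x)` etc. are zero),
#' so the eigenvalues there are the diagonal entries
#' `(1-2x*) Dg`, `(1-2y*) Db`, `(1-2z*) Dh`.
#'
#' @inheritParams replicator_rhs
#' @return A 3x3 numeric matrix, rows/columns ordered `(x, y, z)`.
#' @export
jacobian_matrix <- function(p, s, mode = c("derived", "as_printed")) {
  mode <- match.arg(mode)
  p <- as_game_params(p)
  s <- .as_state(s)
  v <- unclass(p)
  x <- s[[1L]]; y <- s[[2L]]; z <- s[[3L]]
  dg <- .fitness_difference(v, s, "government", mode)
  db <- .fitness_difference(v, s, "platform", mode)
  dh <- .fitness_difference(v, s, "enterprise", mode)
  sgn <- if (mode == "derived") 1 else -1
  dg_dy <- sgn * v[["mu1"]] * v[["Pb1"]] + (v[["Pg1"]] + v[["Pg2"]]) * z
  dg_dz <- -sgn * v[["mu1"]] * v[["Ph1"]] - (v[["Pg1"]] + v[["Pg2"]]) * (1 - y)
  db_dx <- -v[["mu1"]] * (v[["Rb2"]] + v[["Pb1"]]) - v[["rho2"]] * v[["Rb3"]]
  db_dz <- -v[["rho2"]] * v[["Rb4"]]
  dh_dx <- v[["rho3"]] * v[["Rh3"]] + v[["mu1"]] * (v[["Rh2"]] + v[["Ph1"]])
  dh_dy <- -v[["rho3"]] * v[["Rh4"]]
  matrix(c(
    (1 - 2 * x) * dg,     x * (1 - x) * dg_dy, x * (1 - x) * dg_dz,
    y * (1 - y) * db_dx,  (1 - 2 * y) * db,    y * (1 - y) * db_dz,
    z * (1 - z) * dh_dx,  z * (1 - z) * dh_dy, (1 - 2 * z) * dh
  ), nrow = 3L, byrow = TRUE,
  dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

#' Closed-form eigenvalues at a corner equilibrium
#'
#' At a vertex the Jacobian is diagonal, so the three eigenvalues are
#' available in closed form. With `mode = "as_printed"` the government entry
#' reproduces the published eigenvalue table verbatim; the platform and
#' enterprise entries are mode-independent.
#'
#' @inheritParams replicator_rhs
#' @param corner Corner label, `"E1"` to `"E8"` (published labelling; see
#'   [corner_table()]).
#' @param check Validate the parameter invariants (default `TRUE`). Threshold
#'   root-finding evaluates the closed forms outside the admissible region and
#'   switches this off.
#' @return Named numeric triple `(government, platform, enterprise)`.
#' @examples
#' corner_eigenvalues(builtin_scenario("I")$params, "E5") # all negative: ESS
#' @export
corner_eigenvalues <- function(p, corner, mode = c("derived", "as_printed"),
                               check = TRUE) {
  mode <- match.arg(mode)
  p <- as_game_params(p, check = check)
  s <- .corner_state(corner)
  v <- unclass(p)
  c(government = (1 - 2 * s[["x"]]) * .fitness_difference(v, s, "government", mode),
    platform   = (1 - 2 * s[["y"]]) * .fitness_difference(v, s, "platform", mode),
    enterprise = (1 - 2 * s[["z"]]) * .fitness_difference(v, s, "enterprise", mode))
}

#' Classify a corner equilibrium
#'
#' Lyapunov indirect method: the corner is an evolutionarily stable strategy
#' (ESS) when all three eigenvalues are below `-lambda_tol`, unstable when any
#' eigenvalue exceeds `+lambda_tol`, and marginal otherwise (some eigenvalue
#' numerically zero and none positive).
#'
#' @inheritParams corner_eigenvalues
#' @param lambda_tol Numerical tolerance separating signed classifications
#'   from `"marginal"` (default `1e-10`).
#' @return An `equilibrium_report`: list with `corner`, `vertex` (published
#'   coordinates), `state` (internal coordinates), `strategies`,
#'   `eigenvalues`, `class` and `mode`.
#' @examples
#' classify_equilibrium(builtin_scenario("I")$params, "E5")$class # "ESS"
#' @export
classify_equilibrium <- function(p, corner, mode = c("derived", "as_printed"),
                                 lambda_tol = 1e-10) {
  mode <- match.arg(mode)
  lam <- corner_eigenvalues(p, corner, mode)
  cls <- if (all(lam < -lambda_tol)) "ESS"
         else if (any(lam > lambda_tol)) "unstable"
         else "marginal"
  row <- .corner_row(corner)
  structure(list(
    corner = corner,
    vertex = c(x = row$x, y_published = row$y_published, z = row$z),
    state = .corner_state(corner),
    strategies = .corner_words(corner),
    eigenvalues = lam,
    class = cls,
    mode = mode
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("%s (%s) [%s mode]\n", x$corner, x$strategies, x$mode))
  cat(sprintf("  eigenvalues (gov, platform, enterprise): %.6g, %.6g, %.6g\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  cat("  class:", x$class, "\n")
  invisible(x)
}

#' @keywords internal
.condition_ids <- c("I", "II", "III", "IV", "V")

#' Check a stability condition (I-V)
#'
#' Evaluates the strict parameter inequalities under which each corner is an
#' ESS: condition I for E5, II for E6, III for E7, IV for E8, V for E4.
#' The platform/enterprise inequalities are mode-independent; the government
#' inequality appearing in conditions IV and V depends on the government
#' algebra: the published (`as_printed`) form compares `Cg1` with
#' `rho1*Rg1 + 2*mu1*(Pb1 + Ph1)`, the `derived` form with `rho1*Rg1` (the
#' sign-change of the corresponding government eigenvalue). Equality never
#' satisfies a condition (strictness convention).
#'
#' @inheritParams replicator_rhs
#' @param condition One of `"I"` to `"V"`.
#' @return List with `condition`, `mode`, `satisfied` (logical), and
#'   `inequalities`: a data frame with columns `label`, `lhs`, `rhs`, `holds`.
#' @examples
#' check_condition(builtin_scenario("I")$params, "I")$satisfied # TRUE
#' @export
check_condition <- function(p, condition, mode = c("as_printed", "derived")) {
  mode <- match.arg(mode)
  p <- as_game_params(p)
  v <- as.list(unclass(p))
  if (!condition %in% .condition_ids) {
    stop("unknown condition '", condition, "' (expected I..V)", call. = FALSE)
  }
  lt <- function(label, lhs, rhs) data.frame(
    label = label, lhs = lhs, rhs = rhs, holds = lhs < rhs,
    stringsAsFactors = FALSE)
  gt <- function(label, lhs, rhs) data.frame(
    label = label, lhs = lhs, rhs = rhs, holds = lhs > rhs,
    stringsAsFactors = FALSE)
  plat_opp_net <- with(v, Rb2 - mu1 * (Rb2 + Pb1))   # opportunism net of penalty
  ent_pass_net <- with(v, Rh2 - mu1 * (Rh2 + Ph1))   # passive coop net of penalty
  gov_reg_gain <- if (mode == "as_printed") {
    with(v, rho1 * Rg1 + 2 * mu1 * (Pb1 + Ph1))
  } else {
    with(v, rho1 * Rg1)
  }
  ineq <- switch(condition,
    I = rbind(
      lt("Rb1 + rho2*Rb3 < Rb2 - mu1*(Rb2+Pb1)",
         with(v, Rb1 + rho2 * Rb3), plat_opp_net),
      lt("Rh1 + rho3*Rh3 < Rh2 - mu1*(Rh2+Ph1)",
         with(v, Rh1 + rho3 * Rh3), ent_pass_net)),
    II = rbind(
      lt("Rb1 + rho2*(Rb3+Rb4) < Rb2 - mu1*(Rb2+Pb1)",
         with(v, Rb1 + rho2 * (Rb3 + Rb4)), plat_opp_net),
      gt("Rh1 + rho3*Rh3 > Rh2 - mu1*(Rh2+Ph1)",
         with(v, Rh1 + rho3 * Rh3), ent_pass_net)),
    III = rbind(
      gt("Rb1 + rho2*Rb3 > Rb2 - mu1*(Rb2+Pb1)",
         with(v, Rb1 + rho2 * Rb3), plat_opp_net),
      lt("Rh1 + rho3*(Rh3+Rh4) < Rh2 - mu1*(Rh2+Ph1)",
         with(v, Rh1 + rho3 * (Rh3 + Rh4)), ent_pass_net)),
    IV = rbind(
      lt(paste0("Cg1 < ", if (mode == "as_printed")
        "rho1*Rg1 + 2*mu1*(Pb1+Ph1)" else "rho1*Rg1"),
        v$Cg1, gov_reg_gain),
      gt("Rb1 + rho2*(Rb3+Rb4) > Rb2 - mu1*(Rb2+Pb1)",
         with(v, Rb1 + rho2 * (Rb3 + Rb4)), plat_opp_net),
      gt("Rh1 + rho3*(Rh3+Rh4) > Rh2 - mu1*(Rh2+Ph1)",
         with(v, Rh1 + rho3 * (Rh3 + Rh4)), ent_pass_net)),
    V = rbind(
      gt(paste0("Cg1 > ", if (mode == "as_printed")
        "rho1*Rg1 + 2*mu1*(Pb1+Ph1)" else "rho1*Rg1"),
        v$Cg1, gov_reg_gain),
      gt("Rb1 + rho2*Rb4 > Rb2", with(v, Rb1 + rho2 * Rb4), v$Rb2),
      gt("Rh1 + rho3*Rh4 > Rh2", with(v, Rh1 + rho3 * Rh4), v$Rh2))
  )
  list(condition = condition, mode = mode,
       satisfied = all(ineq$holds), inequalities = ineq)
}

#' Census of evolutionarily stable corners across scenarios
#'
#' Classifies all eight corners for each scenario under each requested
#' government-algebra mode and counts the distinct corners that are ESS under
#' at least one (scenario, mode) pair, recording a witness for each.
#'
#' @param scenarios A list of scenarios ([builtin_scenario()] /
#'   [sample_scenario()] objects, `game_params` objects, or condition labels
#'   `"I"`-`"V"`).
#' @param modes Character vector of government-algebra modes to try
#'   (default both).
#' @param lambda_tol Passed to [classify_equilibrium()].
#' @return List with `count`, `corners` (sorted ESS corner labels) and
#'   `witnesses`: data frame with columns `corner`, `scenario`, `mode`.
#' @examples
#' ess_census(as.list(c("I", "II", "III", "IV", "V")))$count # 5
#' @export
ess_census <- function(scenarios, modes = c("derived", "as_printed"),
                       lambda_tol = 1e-10) {
  if (length(scenarios) == 0L) stop("scenario list must be non-empty", call. = FALSE)
  modes <- match.arg(modes, c("derived", "as_printed"), several.ok = TRUE)
  wit <- data.frame(corner = character(0), scenario = character(0),
                    mode = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (is.character(sc) && length(sc) == 1L && sc %in% .condition_ids) {
      sc <- builtin_scenario(sc)
    }
    if (inherits(sc, "game_scenario")) {
      p <- sc$params
      tag <- sc$id
    } else {
      p <- as_game_params(sc)
      tag <- if (!is.null(names(scenarios)) && nzchar(names(scenarios)[i])) {
        names(scenarios)[i]
      } else paste0("scenario", i)
    }
    for (mode in modes) {
      for (corner in corner_table()$corner) {
        rep <- classify_equilibrium(p, corner, mode, lambda_tol)
        if (rep$class == "ESS" && !corner %in% wit$corner) {
          wit <- rbind(wit, data.frame(corner = corner, scenario = tag,
                                       mode = mode, stringsAsFactors = FALSE))
        }
      }
    }
  }
  wit <- wit[order(wit$corner), , drop = FALSE]
  rownames(wit) <- NULL
  list(count = nrow(wit), corners = wit$corner, witnesses = wit)
}

#' Government indifference frequency
#'
#' For a given enterprise frequency `z`, solves the government's fitness
#' difference `Dg(y, z) = 0` for the platform frequency at which the
#' government is indifferent between positive and passive regulation. `Dg` is
#' affine in `y`, so the root is closed-form; it is reported as undefined when
#' the `y`-coefficient vanishes (no dependence) or the root leaves `[0, 1]`
#' (the raw root is still returned).
#'
#' @inheritParams replicator_rhs
#' @param z Enterprise positive-cooperation frequency in `[0, 1]`.
#' @return List with `defined` (logical), `y_opportunism`, `y_reciprocity`
#'   (`1 - y_opportunism`), `raw_root` (internal coordinates, possibly outside
#'   `[0, 1]`), `reason` (`NA`, `"zero denominator"` or `"root outside [0,1]"`)
#'   and `mode`.
#' @export
government_indifference <- function(p, z, mode = c("derived", "as_printed")) {
  mode <- match.arg(mode)
  p <- as_game_params(p)
  if (!is.finite(z) || z < 0 || z > 1) stop("z must lie in [0, 1]", call. = FALSE)
  v <- unclass(p)
  d0 <- .fitness_difference(v, c(0, 0, z), "government", mode)
  d1 <- .fitness_difference(v, c(0, 1, z), "government", mode)
  slope <- d1 - d0  # Dg is affine in y
  out <- list(defined = FALSE, y_opportunism = NA_real_, y_reciprocity = NA_real_,
              raw_root = NA_real_, reason = NA_character_, mode = mode)
  if (abs(slope) < 1e-12) {
    out$reason <- "zero denominator"
    return(out)
  }
  root <- -d0 / slope
  out$raw_root <- root
  if (root < 0 || root > 1) {
    out$reason <- "root outside [0,1]"
    return(out)
  }
  out$defined <- TRUE
  out$y_opportunism <- root
  out$y_reciprocity <- 1 - root
  out
}
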