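#' @keywords internal
.fmt_num <- function(x) {
  # 12 significant digits, plain decimal notation, diff-stable across platforms
  vapply(x, function(v) formatC(v, digits = 12, format = "g"), character(1))
}

#' Export a trajectory to CSV with a JSON sidecar
#'
#' Writes the time series as CSV with header `t,x,y_opportunism,z` (LF line
#' endings, `.` decimal separator, 12 significant digits) and a `.json`
#' sidecar holding the scenario tag, mode, parameters, outcome label and
#' terminal state.
#'
#' @param traj A `game_trajectory`.
#' @param path CSV destination; the sidecar is written at `<path>.json`.
#' @param tol Corner tolerance for the recorded outcome label.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, tol = 1e-3) {
  stopifnot(inherits(traj, "game_trajectory"))
  df <- data.frame(
    t = .fmt_num(traj$times),
    x = .fmt_num(traj$states[, "x"]),
    y_opportunism = .fmt_num(traj$states[, "y"]),
    z = .fmt_num(traj$states[, "z"])
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("t,x,y_opportunism,z",
               do.call(paste, c(df, sep = ","))), con, sep = "\n")
  lab <- classify_outcome(traj, tol = tol)
  sidecar <- list(
    scenario = traj$scenario,
    mode = traj$mode,
    params = as.list(unclass(traj$params)),
    outcome = list(class = lab$class, corner = lab$corner,
                   strategies = lab$strategies,
                   terminal = as.list(lab$terminal),
                   rhs_norm = lab$rhs_norm),
    settled = traj$settled,
    coordinate_note ="y is the platform opportunism probability; published corner labels use y = reciprocity"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a sweep to CSV with a JSON summary
#'
#' CSV columns: `param_value,outcome_corner,x_end,y_end,z_end`. The JSON
#' summary records the swept parameter, mode, and any threshold estimates
#' attached to the sweep.
#'
#' @param sweep A `sweep_result`.
#' @param path CSV destination; the summary is written at `<path>.json`.
#' @param thresholds Optional named list of threshold estimates (for example
#'   `list(analytic = ..., bisection = ...)`) stored in the summary.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, thresholds = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  r <- sweep$results
  lines <- paste(.fmt_num(r$value), r$corner, .fmt_num(r$x_end),
                 .fmt_num(r$y_end), .fmt_num(r$z_end), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("param_value,outcome_corner,x_end,y_end,z_end", lines),
             con, sep = "\n")
  summary <- list(
    param = sweep$param,
    mode = sweep$mode,
    s0 = as.list(sweep$s0),
    outcomes = r,
    thresholds = thresholds
  )
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stability report across all corners
#'
#' Classifies every corner under the requested mode(s) and assembles a
#' report: vertex (published coordinates), strategy words, per-mode
#' eigenvalues and class, and which condition (if any) the parameter set
#' satisfies.
#'
#' @inheritParams replicator_rhs
#' @param modes Government algebras to include (default both).
#' @return A list, one element per corner, plus `conditions`: the per-mode
#'   satisfaction of conditions I-V.
#' @export
stability_report <- function(p, modes = c("derived", "as_printed")) {
  p <- as_game_params(p)
  modes <- match.arg(modes, c("derived", "as_printed"), several.ok = TRUE)
  corners <- lapply(corner_table()$corner, function(cr) {
    row <- .corner_row(cr)
    per_mode <- lapply(modes, function(m) {
      rep <- classify_equilibrium(p, cr, m)
      list(mode = m, eigenvalues = as.list(rep$eigenvalues), class = rep$class)
    })
    list(corner = cr,
         vertex = list(x = row$x, y_published = row$y_published, z = row$z),
         y_opportunism = row$y_opportunism,
         strategies = .corner_words(cr),
         analysis = per_mode)
  })
  names(corners) <- corner_table()$corner
  conds <- lapply(.condition_ids, function(cid) {
    lapply(modes, function(m) {
      ck <- check_condition(p, cid, mode = m)
      list(mode = m, satisfied = ck$satisfied)
    })
  })
  names(conds) <- .condition_ids
  c(corners, list(conditions = conds))
}

#' Write a stability report as JSON
#'
#' @inheritParams stability_report
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(p, path, modes = c("derived", "as_printed")) {
  rep <- stability_report(p, modes = modes)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
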