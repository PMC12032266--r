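#' @keywords internal
.param_fields <- c(
  "rho1", "Rg1", "Pg1", "Pg2", "Cg1", "mu1",
  "rho2", "Rb1", "Rb2", "Rb3", "Rb4", "Pb1",
  "rho3", "Rh1", "Rh2", "Rh3", "Rh4", "Ph1"
)

#' @keywords internal
.fraction_fields <- c("rho1", "mu1", "rho2", "rho3")

#' Construct a model parameter set
#'
#' Bundles the named real parameters of the tripartite regulation game into a
#' validated `game_params` object. Fractions (`rho1`, `mu1`, `rho2`, `rho3`)
#' live on `[0, 1]`; every other parameter is a nonnegative payoff in common
#' units. The accountability penalty for passive regulation must exceed the
#' cost of positive regulation (`Pg1 > Cg1`), otherwise passive regulation
#' would dominate trivially.
#'
#' @param ... Either a single named list/vector holding all parameters, or the
#'   parameters themselves as named arguments. The names must be exactly:
#'   `rho1, Rg1, Pg1, Pg2, Cg1, mu1, rho2, Rb1, Rb2, Rb3, Rb4, Pb1, rho3,
#'   Rh1, Rh2, Rh3, Rh4, Ph1`.
#' @param check If `TRUE` (default) stop on any invariant violation; the error
#'   message lists every violated constraint.
#'
#' @return An object of class `game_params`: a named numeric vector with the
#'   18 parameters in canonical order.
#'
#' @details Parameter meaning, in the field's usual reading:
#' \describe{
#'   \item{rho1}{seniors' willingness to use smart senior-care services}
#'   \item{Rg1}{ideal reward to a positively regulating government}
#'   \item{Pg1}{direct accountability penalty for passive regulation}
#'   \item{Pg2}{indirect governance loss under passive regulation}
#'   \item{Cg1}{cost of positive regulation}
#'   \item{mu1}{level (effectiveness) of positive regulation}
#'   \item{rho2}{platform smart-aging service conversion rate}
#'   \item{Rb1, Rb2}{platform base benefit under reciprocity / opportunism}
#'   \item{Rb3}{maximum government reward for platform reciprocity}
#'   \item{Rb4}{platform synergy benefit when both sides cooperate}
#'   \item{Pb1}{maximum penalty for platform opportunism}
#'   \item{rho3}{enterprise service age-coverage rate}
#'   \item{Rh1, Rh2}{enterprise base benefit under positive / passive cooperation}
#'   \item{Rh3}{maximum government reward for enterprise positive cooperation}
#'   \item{Rh4}{enterprise synergy benefit when both sides cooperate}
#'   \item{Ph1}{maximum penalty for enterprise passive cooperation}
#' }
#'
#' @examples
#' p <- builtin_scenario("I")$params
#' p["Cg1"]
#' validate_params(p)
#' @export
game_params <- function(..., check = TRUE) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && identical(names(args), "")) ) {
    args <- as.list(args[[1L]])
  } else if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args)[1L])) {
    args <- as.list(args[[1L]])
  }
  missing_f <- setdiff(.param_fields, names(args))
  if (length(missing_f)) {
    stop("missing parameter(s): ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(args), .param_fields)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  p <- vapply(args[.param_fields], function(v) as.numeric(v)[1L], numeric(1))
  names(p) <- .param_fields
  class(p) <- "game_params"
  if (check) assert_valid_params(p)
  p
}

#' Coerce to a `game_params` object
#'
#' @param x A named list or numeric vector with the 18 parameter fields.
#' @param check Validate invariants (default `TRUE`).
#' @return A `game_params` object.
#' @export
as_game_params <- function(x, check = TRUE) {
  if (inherits(x, "game_params")) {
    if (check) assert_valid_params(x)
    return(x)
  }
  do.call(game_params, c(as.list(x), list(check = check)))
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter space: fractions in `[0, 1]`,
#' payoffs finite and nonnegative, and the accountability ordering
#' `Pg1 > Cg1`. Violations are returned, not raised, so callers can report
#' them all at once.
#'
#' @param p A `game_params` object (or coercible named list/vector).
#' @return A data frame with one row per violation and columns `field` and
#'   `constraint`; zero rows when the parameter set is valid.
#' @examples
#' p <- builtin_scenario("I")$params
#' nrow(validate_params(p)) # 0
#' p["mu1"] <- 1.3
#' validate_params(unclass(p))
#' @export
validate_params <- function(p) {
  p <- if (inherits(p, "game_params")) unclass(p) else {
    v <- vapply(as.list(p)[.param_fields], function(x) as.numeric(x)[1L], numeric(1))
    names(v) <- .param_fields
    v
  }
  bad <- data.frame(field = character(0), constraint = character(0),
                    stringsAsFactors = FALSE)
  add <- function(field, constraint) {
    rbind(bad, data.frame(field = field, constraint = constraint,
                          stringsAsFactors = FALSE))
  }
  for (f in .param_fields) {
    v <- p[[f]]
    if (!is.finite(v)) {
      bad <- add(f, "must be a finite number")
      next
    }
    if (f %in% .fraction_fields) {
      if (v < 0 || v > 1) bad <- add(f, "fraction must lie in [0, 1]")
    } else {
      if (v < 0) bad <- add(f, "payoff must be >= 0")
    }
  }
  if (is.finite(p[["Pg1"]]) && is.finite(p[["Cg1"]]) && p[["Pg1"]] <= p[["Cg1"]]) {
    bad <- add("Pg1", "accountability penalty must exceed regulation cost (Pg1 > Cg1)")
  }
  bad
}

#' @keywords internal
assert_valid_params <- function(p) {
  bad <- validate_params(p)
  if (nrow(bad)) {
    stop("invalid parameter set:\n",
         paste0("  - ", bad$field, ": ", bad$constraint, collapse = "\n"),
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Tripartite game parameters\n")
  v <- unclass(x)
  cat("  fractions:", paste0(.fraction_fields, " = ",
                             format(v[.fraction_fields]), collapse = ", "), "\n")
  pay <- setdiff(.param_fields, .fraction_fields)
  cat("  payoffs:  ", paste0(pay, " = ", format(v[pay]), collapse = ", "), "\n")
  invisible(x)
}

#' Read a parameter set from a JSON or YAML config file
#'
#' The config is a flat key-value mapping whose keys are exactly the parameter
#' symbols (`rho1`, `Rg1`, ...). The format is chosen from the file extension:
#' `.json` or `.yaml`/`.yml`.
#'
#' @param path Path to the config file.
#' @param check Validate the invariants (default `TRUE`).
#' @return A `game_params` object.
#' @seealso [write_params()], [read_scenario()]
#' @export
read_params <- function(path, check = TRUE) {
  cfg <- .read_config(path)
  do.call(game_params, c(cfg[.param_fields], list(check = check)))
}

#' Write a parameter set to a JSON or YAML config file
#'
#' @param p A `game_params` object.
#' @param path Destination; format chosen from the extension
#'   (`.json`, `.yaml`, `.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- as_game_params(p, check = FALSE)
  .write_config(as.list(unclass(p)), path)
  invisible(path)
}

#' @keywords internal
.read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE)
  }
}

#' @keywords internal
.write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    stop("unsupported config extension '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE)
  }
  invisible(path)
}

#' @keywords internal
.as_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 3L || anyNA(s)) {
    stop("a strategy state must be a numeric triple (x, y, z)", call. = FALSE)
  }
  if (any(s < -1e-9) || any(s > 1 + 1e-9)) {
    stop("strategy state components must lie in [0, 1]", call. = FALSE)
  }
  s <- pmin(pmax(s, 0), 1)
  names(s) <- c("x", "y", "z")
  s
}
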