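#' Corner equilibria of the unit cube
#'
#' The eight pure-strategy profiles are the vertices of `[0, 1]^3` and are
#' always fixed points of the replicator dynamics. Published equilibrium
#' labels E1-E8 write the platform coordinate as a *reciprocity* indicator
#' (`y_published = 1` means reciprocity), whereas the internal state tracks the
#' *opportunism* probability; this table carries both coordinates plus the
#' strategy words so no report ever prints a bare, ambiguous coordinate.
#'
#' @return A data frame with columns `corner` (E1-E8), `x`, `y_published`, `z`
#'   (published coordinates), `y_opportunism` (internal platform coordinate,
#'   `1 - y_published`), and the strategy words `government`, `platform`,
#'   `enterprise`.
#' @examples
#' corner_table()
#' @export
corner_table <- function() {
  grid <- expand.grid(z = 0:1, y_published = 0:1, x = 0:1)[, c("x", "y_published", "z")]
  # published census order: E1(0,0,0), E2(0,0,1), E3(0,1,0), ... E8(1,1,1)
  out <- data.frame(
    corner = paste0("E", 1:8),
    x = grid$x,
    y_published = grid$y_published,
    z = grid$z,
    y_opportunism = 1 - grid$y_published,
    stringsAsFactors = FALSE
  )
  out$government <- ifelse(out$x == 1, "positive regulation", "passive regulation")
  out$platform <- ifelse(out$y_published == 1, "reciprocity", "opportunism")
  out$enterprise <- ifelse(out$z == 1, "positive cooperation", "passive cooperation")
  out
}

#' @keywords internal
.corner_row <- function(corner) {
  tab <- corner_table()
  i <- match(corner, tab$corner)
  if (is.na(i)) {
    stop("unknown corner '", corner, "' (expected E1..E8)", call. = FALSE)
  }
  tab[i, , drop = FALSE]
}

# internal state (x, y_opportunism, z) of a corner
#' @keywords internal
.corner_state <- function(corner) {
  row <- .corner_row(corner)
  c(x = row$x, y = row$y_opportunism, z = row$z)
}

#' @keywords internal
.corner_words <- function(corner) {
  row <- .corner_row(corner)
  paste(row$government, row$platform, row$enterprise, sep = ", ")
}

# nearest vertex (internal coordinates) and its Chebyshev distance
#' @keywords internal
.nearest_corner <- function(s) {
  tab <- corner_table()
  verts <- cbind(tab$x, tab$y_opportunism, tab$z)
  d <- apply(abs(sweep(verts, 2, as.numeric(s))), 1L, max)
  i <- which.min(d)
  list(corner = tab$corner[i], distance = d[i],
       state = c(x = verts[i, 1], y = verts[i, 2], z = verts[i, 3]))
}
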