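#' Payoff tensor over the eight pure-strategy profiles
#'
#' Evaluates each actor's payoff at every combination of pure strategies:
#' government positive/passive regulation, platform opportunism/reciprocity,
#' enterprise positive/passive cooperation. The published payoff table is
#' typographically garbled, so the cells are reconstructed from the model's
#' behavioural assumptions, with each penalty attached to the misbehaving
#' actor and the synergy benefits `rho2*Rb4` / `rho3*Rh4` paid only when the
#' platform reciprocates *and* the enterprise cooperates positively:
#' \itemize{
#'   \item government, positive: `rho1*Rg1 - Cg1 + mu1*Pb1*[opportunism] +
#'     mu1*Ph1*[enterprise passive]`
#'   \item government, passive: `0` when the platform reciprocates and the
#'     enterprise cooperates positively, else `-(Pg1 + Pg2)`
#'   \item platform, reciprocity: `Rb1 + rho2*Rb3*[gov positive] +
#'     rho2*Rb4*[enterprise positive]`
#'   \item platform, opportunism: `(1-mu1)*Rb2 - mu1*Pb1` under positive
#'     regulation, else `Rb2`
#'   \item enterprise, positive: `Rh1 + rho3*Rh3*[gov positive] +
#'     rho3*Rh4*[platform reciprocity]`
#'   \item enterprise, passive: `(1-mu1)*Rh2 - mu1*Ph1` under positive
#'     regulation, else `Rh2`
#' }
#'
#' @param p A valid `game_params` object.
#' @return A numeric array of dimension `3 x 2 x 2 x 2` with dimnames
#'   `actor` (government, platform, enterprise), `government`
#'   (positive, passive), `platform` (opportunism, reciprocity) and
#'   `enterprise` (positive, passive).
#' @examples
#' tens <- payoff_tensor(builtin_scenario("I")$params)
#' tens["government", "positive", "reciprocity", "positive"] # 0.6*40 - 25 = -1
#' @export
payoff_tensor <- function(p) {
  p <- as_game_params(p)
  v <- as.list(unclass(p))
  out <- array(
    NA_real_, dim = c(3L, 2L, 2L, 2L),
    dimnames = list(
      actor      = c("government", "platform", "enterprise"),
      government = c("positive", "passive"),
      platform   = c("opportunism", "reciprocity"),
      enterprise = c("positive", "passive")
    )
  )
  for (g in 1:2) for (b in 1:2) for (h in 1:2) {
    gov_pos <- g == 1L
    opp     <- b == 1L
    ent_pos <- h == 1L
    out["government", g, b, h] <- if (gov_pos) {
      v$rho1 * v$Rg1 - v$Cg1 + v$mu1 * v$Pb1 * opp + v$mu1 * v$Ph1 * !ent_pos
    } else {
      if (!opp && ent_pos) 0 else -(v$Pg1 + v$Pg2)
    }
    out["platform", g, b, h] <- if (opp) {
      if (gov_pos) (1 - v$mu1) * v$Rb2 - v$mu1 * v$Pb1 else v$Rb2
    } else {
      v$Rb1 + v$rho2 * v$Rb3 * gov_pos + v$rho2 * v$Rb4 * ent_pos
    }
    out["enterprise", g, b, h] <- if (ent_pos) {
      v$Rh1 + v$rho3 * v$Rh3 * gov_pos + v$rho3 * v$Rh4 * !opp
    } else {
      if (gov_pos) (1 - v$mu1) * v$Rh2 - v$mu1 * v$Ph1 else v$Rh2
    }
  }
  out
}

#' Fitness difference between an actor's two strategies
#'
#' Expected payoff of the actor's first strategy minus its second, under the
#' opponents' current mixed frequencies. Orientation follows the state
#' convention: for the government the difference is positive minus passive
#' regulation, for the platform opportunism minus reciprocity (so a positive
#' value pushes `y` up), for the enterprise positive minus passive
#' cooperation.
#'
#' Two algebras are provided for the government, which disagree in the
#' literature source by the sign of the platform/enterprise penalty factors:
#' `"derived"` is the exact expectation over the payoff tensor (the default),
#' `"as_printed"` reproduces the published replicator display with its
#' `(1+y)`-type factors. The platform and enterprise differences are
#' mode-independent.
#'
#' @param p A valid `game_params` object.
#' @param s Strategy state `c(x, y, z)`; `y` is the opportunism probability.
#' @param actor One of `"government"`, `"platform"`, `"enterprise"`.
#' @param mode `"derived"` or `"as_printed"` (government only).
#' @return A single numeric fitness difference.
#' @examples
#' p <- builtin_scenario("I")$params
#' fitness_difference(p, c(1, 0.5, 0), "platform") # 17.9: opportunism favoured
#' @export
fitness_difference <- function(p, s,
                               actor = c("government", "platform", "enterprise"),
                               mode = c("derived", "as_printed")) {
  actor <- match.arg(actor)
  mode <- match.arg(mode)
  p <- as_game_params(p)
  s <- .as_state(s)
  .fitness_difference(unclass(p), s, actor, mode)
}

# core, no validation: called from the ODE right-hand side
#' @keywords internal
.fitness_difference <- function(v, s, actor, mode) {
  x <- s[[1L]]; y <- s[[2L]]; z <- s[[3L]]
  switch(actor,
    government = {
      common <- v[["rho1"]] * v[["Rg1"]] - v[["Cg1"]] +
        (v[["Pg1"]] + v[["Pg2"]]) * (1 - (1 - y) * z)
      if (mode == "derived") {
        common + v[["mu1"]] * (v[["Pb1"]] * y + v[["Ph1"]] * (1 - z))
      } else {
        common + v[["mu1"]] * (v[["Pb1"]] * (2 - y) + v[["Ph1"]] * (1 + z))
      }
    },
    platform =
      (v[["Rb2"]] - x * v[["mu1"]] * (v[["Rb2"]] + v[["Pb1"]])) -
      (v[["Rb1"]] + x * v[["rho2"]] * v[["Rb3"]] + z * v[["rho2"]] * v[["Rb4"]]),
    enterprise =
      (v[["Rh1"]] + x * v[["rho3"]] * v[["Rh3"]] + (1 - y) * v[["rho3"]] * v[["Rh4"]]) -
      (v[["Rh2"]] - x * v[["mu1"]] * (v[["Rh2"]] + v[["Ph1"]]))
  )
}
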