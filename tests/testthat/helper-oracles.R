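# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the fitness oracle enumerates the payoff tensor, the
# Jacobian oracle uses central differences, the integration oracle is a plain
# fixed-step RK4 loop.

# expected payoff difference by brute-force expectation over the 4 opponent
# pure-profiles, weighted by the opponents' mixed frequencies
brute_force_difference <- function(p, s, actor) {
  tens <- payoff_tensor(p)
  x <- s[1]; y <- s[2]; z <- s[3]
  wg <- c(positive = x, passive = 1 - x)
  wb <- c(opportunism = y, reciprocity = 1 - y)
  wh <- c(positive = z, passive = 1 - z)
  expect_payoff <- function(g, b, h) {
    tot <- 0
    for (gn in names(g)) for (bn in names(b)) for (hn in names(h)) {
      tot <- tot + g[[gn]] * b[[bn]] * h[[hn]] * tens[actor, gn, bn, hn]
    }
    tot
  }
  switch(actor,
    government = expect_payoff(c(positive = 1), wb, wh) -
                 expect_payoff(c(passive = 1), wb, wh),
    platform   = expect_payoff(wg, c(opportunism = 1), wh) -
                 expect_payoff(wg, c(reciprocity = 1), wh),
    enterprise = expect_payoff(wg, wb, c(positive = 1)) -
                 expect_payoff(wg, wb, c(passive = 1)))
}

# central-difference Jacobian, h = 1e-6
fd_jacobian <- function(p, s, mode, h = 1e-6) {
  v <- unclass(as_game_params(p))
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- s; up[j] <- up[j] + h
    dn <- s; dn[j] <- dn[j] - h
    J[, j] <- (tripgame:::.replicator_rhs(v, up, mode) -
               tripgame:::.replicator_rhs(v, dn, mode)) / (2 * h)
  }
  J
}

# classic fixed-step RK4 on the cube coordinates
rk4_integrate <- function(p, s0, horizon, h, mode) {
  v <- unclass(as_game_params(p))
  f <- function(s) tripgame:::.replicator_rhs(v, s, mode)
  s <- as.numeric(s0)
  for (i in seq_len(round(horizon / h))) {
    k1 <- f(s)
    k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    s <- pmin(pmax(s, 0), 1)
  }
  s
}

# published eigenvalue table, transcribed verbatim (government rows in the
# published algebra; platform rows with the reward/synergy conversion-rate
# grouping confirmed by the condition footnotes)
table3_eigenvalues <- function(p, corner) {
  with(as.list(unclass(as_game_params(p))), switch(corner,
    E1 = c(-Cg1 + rho1 * Rg1 + Pg1 + Pg2 + Pb1 * mu1 + Ph1 * mu1,
           Rb1 - Rb2,
           Rh1 - Rh2),
    E2 = c(-Cg1 + rho1 * Rg1 + Pg1 + Pg2 + Pb1 * mu1 + 2 * Ph1 * mu1,
           Rb1 + rho2 * Rb4 - Rb2,
           Rh2 - Rh1),
    E3 = c(-Cg1 + rho1 * Rg1 + Pg1 + Pg2 + 2 * Pb1 * mu1 + Ph1 * mu1,
           -Rb1 + Rb2,
           Rh1 + rho3 * Rh4 - Rh2),
    E4 = c(-Cg1 + rho1 * Rg1 + 2 * Pb1 * mu1 + 2 * Ph1 * mu1,
           -Rb1 - rho2 * Rb4 + Rb2,
           -Rh1 - rho3 * Rh4 + Rh2),
    E5 = c(Cg1 - rho1 * Rg1 - Pg1 - Pg2 - Pb1 * mu1 - Ph1 * mu1,
           Rb1 + rho2 * Rb3 - Rb2 + mu1 * (Rb2 + Pb1),
           Rh1 + rho3 * Rh3 - Rh2 + mu1 * Ph1 + mu1 * Rh2),
    E6 = c(Cg1 - rho1 * Rg1 - Pg1 - Pg2 - Pb1 * mu1 - 2 * Ph1 * mu1,
           Rb1 + rho2 * (Rb3 + Rb4) - Rb2 + mu1 * (Rb2 + Pb1),
           -Rh1 - rho3 * Rh3 + Rh2 - mu1 * Ph1 - mu1 * Rh2),
    E7 = c(Cg1 - rho1 * Rg1 - Pg1 - Pg2 - 2 * Pb1 * mu1 - Ph1 * mu1,
           -Rb1 - rho2 * Rb3 + Rb2 - mu1 * (Rb2 + Pb1),
           Rh1 + rho3 * Rh3 + rho3 * Rh4 - Rh2 + mu1 * Ph1 + mu1 * Rh2),
    E8 = c(Cg1 - rho1 * Rg1 - 2 * Pb1 * mu1 - 2 * Ph1 * mu1,
           -Rb1 - rho2 * (Rb3 + Rb4) + Rb2 - mu1 * (Rb2 + Pb1),
           -Rh1 - rho3 * Rh3 - rho3 * Rh4 + Rh2 - mu1 * Ph1 - mu1 * Rh2),
    stop("unknown corner")
  ))
}

# random valid parameter sets over the default sampling ranges
random_valid_params <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    vals <- vapply(tripgame:::.param_fields, function(f) {
      r <- default_sample_ranges()[[f]]
      runif(1, r[1], r[2])
    }, numeric(1))
    p <- do.call(game_params, c(as.list(vals), list(check = FALSE)))
    if (nrow(validate_params(p)) == 0L) {
      i <- i + 1L
      out[[i]] <- p
    }
  }
  out
}

scenario_mode_grid <- function() {
  data.frame(
    condition = c("I", "I", "II", "II", "III", "III", "IV", "V"),
    mode = c("derived", "as_printed", "derived", "as_printed",
             "derived", "as_printed", "as_printed", "derived"),
    expected = c("E5", "E5", "E6", "E6", "E7", "E7", "E8", "E4"),
    stringsAsFactors = FALSE
  )
}
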