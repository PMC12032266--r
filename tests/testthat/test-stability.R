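test_that("analytic Jacobian matches a central-difference oracle at interior points", {
  set.seed(99)
  params <- c(list(builtin_scenario("I")$params, builtin_scenario("V")$params),
              random_valid_params(3, seed = 13))
  for (p in params) {
    for (rep in 1:20) {
      s <- runif(3, 0.05, 0.95)
      for (mode in c("derived", "as_printed")) {
        expect_lt(max(abs(jacobian_matrix(p, s, mode) - fd_jacobian(p, s, mode))),
                  1e-5)
      }
    }
  }
})

test_that("the Jacobian is diagonal at corners with the closed-form eigenvalues", {
  p <- builtin_scenario("I")$params
  J <- jacobian_matrix(p, c(1, 1, 0))  # E5 in internal coordinates
  expect_identical(J[upper.tri(J) | lower.tri(J)], rep(0, 6))
  expect_equal(unname(diag(J)), c(-61, -17.9, -13.1))
  # closed forms vs numeric eigenvalues at all corners, random parameter sets
  for (p in random_valid_params(20, seed = 3)) {
    for (corner in corner_table()$corner) {
      s <- tripgame:::.corner_state(corner)
      for (mode in c("derived", "as_printed")) {
        lam_closed <- sort(corner_eigenvalues(p, corner, mode))
        lam_numeric <- sort(eigen(jacobian_matrix(p, s, mode),
                                  only.values = TRUE)$values)
        expect_lt(max(abs(lam_closed - lam_numeric)), 1e-10)
      }
    }
  }
})

test_that("corner eigenvalues reproduce the published eigenvalue table", {
  # platform/enterprise rows in either mode, government rows in the published
  # algebra, across all five validation scenarios and all corners
  for (cid in c("I", "II", "III", "IV", "V")) {
    p <- builtin_scenario(cid)$params
    for (corner in corner_table()$corner) {
      frozen <- table3_eigenvalues(p, corner)
      lam_ap <- corner_eigenvalues(p, corner, mode = "as_printed")
      expect_equal(unname(lam_ap), frozen, tolerance = 1e-12)
      lam_dv <- corner_eigenvalues(p, corner, mode = "derived")
      expect_equal(unname(lam_dv[2:3]), frozen[2:3], tolerance = 1e-12)
    }
  }
  # spot values quoted in the source analysis
  pI <- builtin_scenario("I")$params
  expect_equal(corner_eigenvalues(pI, "E1", "as_printed")[["government"]],
               -25 + 24 + 40 + 20 + 1 + 1)
  pIV <- builtin_scenario("IV")$params
  expect_equal(corner_eigenvalues(pIV, "E8", "as_printed")[["government"]], -9)
  expect_equal(corner_eigenvalues(pIV, "E8", "derived")[["government"]], 1)
})

test_that("equilibrium classification follows the eigenvalue signs", {
  pI <- builtin_scenario("I")$params
  for (mode in c("derived", "as_printed")) {
    expect_identical(classify_equilibrium(pI, "E5", mode)$class, "ESS")
    expect_identical(classify_equilibrium(pI, "E1", mode)$class, "unstable")
  }
  # an eigenvalue at its exact sign-change root classifies as marginal
  p0 <- unclass(pI)
  p0["mu1"] <- (p0["Rh2"] - p0["Rh1"] - p0["rho3"] * p0["Rh3"]) /
    (p0["Rh2"] + p0["Ph1"])
  rep <- classify_equilibrium(as_game_params(p0), "E5")
  expect_lt(abs(rep$eigenvalues[["enterprise"]]), 1e-10)
  expect_identical(rep$class, "marginal")
})

test_that("passive-regulation corners facing misconduct are always unstable", {
  # E1-E3 keep a positive government eigenvalue for every valid parameter set:
  # the accountability ordering Pg1 > Cg1 makes the government's gain from
  # regulating positive whenever someone misbehaves
  for (p in random_valid_params(1000, seed = 5)) {
    for (corner in c("E1", "E2", "E3")) {
      for (mode in c("derived", "as_printed")) {
        expect_gt(corner_eigenvalues(p, corner, mode)[["government"]], 0)
      }
    }
  }
})

test_that("stability conditions I-V evaluate the printed strict inequalities", {
  for (cid in c("I", "II", "III")) {
    ck <- check_condition(builtin_scenario(cid)$params, cid)
    expect_true(ck$satisfied)
  }
  # condition IV holds in published algebra only; V in derived algebra only
  pIV <- builtin_scenario("IV")$params
  expect_true(check_condition(pIV, "IV", "as_printed")$satisfied)
  expect_false(check_condition(pIV, "IV", "derived")$satisfied)
  pV <- builtin_scenario("V")$params
  expect_false(check_condition(pV, "V", "as_printed")$satisfied)
  expect_true(check_condition(pV, "V", "derived")$satisfied)
  ckV <- check_condition(pV, "V", "as_printed")
  expect_identical(which(!ckV$inequalities$holds), 1L)  # only the Cg1 inequality
  # strictness: equality never satisfies
  peq <- unclass(builtin_scenario("I")$params)
  peq["mu1"] <- 0
  peq["rho2"] <- 0
  peq["Rb1"] <- peq["Rb2"]
  ck <- check_condition(as_game_params(peq), "I")
  expect_false(ck$inequalities$holds[1])
  expect_error(check_condition(pV, "VI"), "unknown condition")
})

test_that("classification agrees with simulated convergence on the scenarios", {
  grid <- scenario_mode_grid()
  for (i in seq_len(nrow(grid))) {
    sc <- builtin_scenario(grid$condition[i])
    rep <- classify_equilibrium(sc$params, grid$expected[i], grid$mode[i])
    expect_identical(rep$class, "ESS")
    lab <- classify_outcome(simulate_game(sc$params, mode = grid$mode[i]))
    expect_identical(lab$corner, grid$expected[i])
  }
})

test_that("the ESS census counts distinct stable corners with witnesses", {
  cen <- ess_census(as.list(c("I", "II", "III", "IV", "V")))
  expect_identical(cen$count, 5L)
  expect_identical(cen$corners, c("E4", "E5", "E6", "E7", "E8"))
  expect_identical(cen$witnesses$scenario[cen$witnesses$corner == "E4"], "V")
  expect_identical(cen$witnesses$mode[cen$witnesses$corner == "E4"], "derived")
  # one scenario alone stabilizes only its own corner
  cenI <- ess_census(list("I"))
  expect_identical(cenI$corners, "E5")
  # idempotence under a repeated scenario
  cen2 <- ess_census(list("I", "I"))
  expect_identical(cen2$corners, cenI$corners)
  expect_error(ess_census(list()), "non-empty")
})

test_that("the government indifference frequency solves Dg = 0 when defined", {
  pV <- builtin_scenario("V")$params
  gi <- government_indifference(pV, z = 1, mode = "derived")
  expect_true(gi$defined)
  expect_lt(abs(fitness_difference(pV, c(0.5, gi$y_opportunism, 1),
                                   "government", "derived")), 1e-10)
  expect_equal(gi$y_reciprocity, 1 - gi$y_opportunism)
  # under the published algebra scenario V has no interior indifference at
  # z = 1; use a costly-regulation parameter set that does
  pc <- unclass(pV)
  pc[c("Cg1", "Pg1", "Pg2", "mu1", "Pb1", "Ph1", "rho1")] <-
    c(90, 95, 0, 0.1, 5, 5, 0.5)
  pc <- as_game_params(pc)
  gi_ap <- government_indifference(pc, z = 1, mode = "as_printed")
  expect_true(gi_ap$defined)
  expect_lt(abs(fitness_difference(pc, c(0.2, gi_ap$y_opportunism, 1),
                                   "government", "as_printed")), 1e-10)
  # zero denominator: Dg cannot depend on y
  p0 <- unclass(builtin_scenario("I")$params)
  p0["mu1"] <- 0
  gi <- government_indifference(as_game_params(p0), z = 0)
  expect_false(gi$defined)
  expect_identical(gi$reason, "zero denominator")
  # root outside the unit interval is reported raw
  gi2 <- government_indifference(builtin_scenario("I")$params, z = 0)
  expect_false(gi2$defined)
  expect_identical(gi2$reason, "root outside [0,1]")
  expect_true(is.finite(gi2$raw_root))
})
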