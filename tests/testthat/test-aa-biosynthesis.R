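test_that("synthesis rate follows the inhibited saturating form", {
  tc <- tiny_chain()
  enz <- c(a1 = 2, a2 = 1)

  # zero enzyme shuts the reaction off
  v <- synthesis_rate(tc$net, tc$kin, c(a1 = 10, a2 = 10), c(a1 = 0, a2 = 0))
  expect_equal(unname(v), c(0, 0))

  # root at its K_I, no upstream set: half inhibition only
  v <- synthesis_rate(tc$net, tc$kin, c(a1 = 100, a2 = 0), enz)
  expect_equal(v[["a1"]], 2 * 2 / 2)

  # kcat_f = 1, E = 2, AA = K_I, one upstream amino acid at its K_M:
  # v = 1 * 2 * (1/2) * (1/2) = 0.5
  kin2 <- tc$kin
  kin2$kcat_f[["a2"]] <- 1
  v <- synthesis_rate(tc$net, kin2, c(a1 = 100, a2 = 50), c(a1 = 1, a2 = 2))
  expect_equal(v[["a2"]], 0.5)

  # upstream amino acid at zero concentration kills the product term
  v <- synthesis_rate(tc$net, tc$kin, c(a1 = 0, a2 = 50), enz)
  expect_equal(v[["a2"]], 0)

  expect_error(synthesis_rate(tc$net, tc$kin, c(a1 = -1, a2 = 0), enz),
               "must be finite")
  expect_error(synthesis_rate(tc$net, tc$kin, c(bogus = 1, a2 = 0), enz),
               "unknown identifier")
})

test_that("synthesis rate is monotone in own and upstream concentrations", {
  tc <- tiny_chain()
  enz <- c(a1 = 2, a2 = 1)
  set.seed(42)
  for (i in 1:20) {
    aa <- c(a1 = runif(1, 1, 500), a2 = runif(1, 1, 500))
    v0 <- synthesis_rate(tc$net, tc$kin, aa, enz)
    up <- aa
    up[["a2"]] <- up[["a2"]] + 10
    v_own <- synthesis_rate(tc$net, tc$kin, up, enz)
    expect_lt(v_own[["a2"]], v0[["a2"]])  # own conc up -> inhibition up
    up2 <- aa
    up2[["a1"]] <- up2[["a1"]] + 10
    v_up <- synthesis_rate(tc$net, tc$kin, up2, enz)
    expect_gt(v_up[["a2"]], v0[["a2"]])   # precursor up -> saturation up
  }
})

test_that("removing allosteric inhibition raises synthesis", {
  tc <- tiny_chain()
  enz <- c(a1 = 2, a2 = 1)
  aa <- c(a1 = 150, a2 = 80)
  kin_inf <- tc$kin
  kin_inf$inhibition_scale[] <- Inf
  v1 <- synthesis_rate(tc$net, tc$kin, aa, enz)
  v2 <- synthesis_rate(tc$net, kin_inf, aa, enz)
  expect_true(all(v2 > v1))
  # equality only at zero concentration of the product
  aa0 <- c(a1 = 0, a2 = 80)
  expect_equal(synthesis_rate(tc$net, tc$kin, aa0, enz)[["a1"]],
               synthesis_rate(tc$net, kin_inf, aa0, enz)[["a1"]])
})

test_that("loss and downstream rates follow the single-step abstraction", {
  tc <- tiny_chain()
  enz <- c(a1 = 2, a2 = 1)
  aa <- c(a1 = 200, a2 = 500)  # a2 at its loss K_M
  v_synth <- synthesis_rate(tc$net, tc$kin, aa, enz)
  lr <- loss_rates(tc$net, tc$kin, aa, enz, v_synth)
  expect_equal(lr$v_down[["a2"]], 0)                  # leaf
  expect_equal(lr$v_down[["a1"]], v_synth[["a2"]])    # literal sum
  expect_equal(lr$v_loss[["a2"]], 0.5 * 1 / 2)        # half saturation
  expect_equal(lr$v_loss[["a1"]], 0)                  # no loss reaction

  # 3-AA chain: v_down is immediate-downstream only, not transitive
  net3 <- aa_network(c("r", "a", "b"),
                     data.frame(from = c("r", "a"), to = c("a", "b")))
  kin3 <- aa_kinetics(net3, kcat_f = c(r = 1, a = 1, b = 1),
                      kcat_loss = c(r = 0, a = 0, b = 0),
                      K_I = c(r = 1, a = 1, b = 1) * 100,
                      K_M_up = list(r = NULL, a = c(r = 50), b = c(a = 50)),
                      K_M_loss = c(r = 1, a = 1, b = 1) * 1000)
  aa3 <- c(r = 100, a = 100, b = 100)
  e3 <- c(r = 1, a = 1, b = 1)
  vs <- synthesis_rate(net3, kin3, aa3, e3)
  lr3 <- loss_rates(net3, kin3, aa3, e3, vs)
  expect_equal(lr3$v_down[["a"]], vs[["b"]])
  expect_equal(lr3$v_down[["r"]], vs[["a"]])   # b not included
})

test_that("supply rate is the signed sum of its components", {
  tc <- tiny_chain()
  # all rates zero
  v <- supply_rate(tc$net, tc$kin, c(a1 = 0, a2 = 0), c(a1 = 0, a2 = 0),
                   c(a1 = 0, a2 = 0))
  expect_equal(unname(v), c(0, 0))
  # spot check against manual composition
  aa <- c(a1 = 150, a2 = 90)
  enz <- c(a1 = 2, a2 = 1)
  vex <- c(a1 = 0.1, a2 = -0.3)
  vs <- synthesis_rate(tc$net, tc$kin, aa, enz)
  lr <- loss_rates(tc$net, tc$kin, aa, enz, vs)
  expect_equal(supply_rate(tc$net, tc$kin, aa, enz, vex),
               vs - lr$v_down - lr$v_loss + vex)
})

test_that("default constants follow the minimal-media assumptions", {
  net <- aa_network(c("x", "y"), data.frame(from = "x", to = "y"),
                    loss_kind = c(x = "none", y = "degradation"))
  cons <- assign_default_constants(net, c(x = 100, y = 100))
  expect_equal(cons$K_M_up$y[["x"]], 100)
  expect_equal(cons$K_M_loss[["y"]], 1000)
  expect_equal(cons$K_I[["y"]], 100)
  # K_I clamped into curated bounds
  cons2 <- assign_default_constants(net, c(x = 100, y = 100),
    curated = list(K_I_bounds = list(x = c(50, 80), y = c(120, 200))))
  expect_equal(cons2$K_I[["x"]], 80)
  expect_equal(cons2$K_I[["y"]], 120)
  expect_error(assign_default_constants(net, c(x = 100, y = 100),
    curated = list(K_I_bounds = list(x = c(90, 50)))), "empty K_I bounds")
})

test_that("kcat fitting round-trips planted parameters", {
  for (shape in c("chain", "branch")) {
    toy <- generate_toy_aa_network(4, shape, seed = 7)
    fit <- fit_kcats_and_exchange(toy$net, toy$constants, toy$cond_minimal,
                                  toy$cond_rich)
    expect_lt(max(abs(fit$kinetics$kcat_f - toy$kinetics$kcat_f) /
                    toy$kinetics$kcat_f), 1e-6)
    kl <- toy$kinetics$kcat_loss
    expect_lt(max(abs(fit$kinetics$kcat_loss - kl) / pmax(kl, 1)), 1e-6)
    expect_lt(max(abs(fit$v_exchange - toy$v_exchange) /
                    pmax(abs(toy$v_exchange), 1)), 1e-6)
    # mass balances hold at both anchors
    expect_lt(max(abs(fit$residuals$minimal)), 1e-6)
    expect_lt(max(abs(fit$residuals$rich)), 1e-6)
    expect_true(all(fit$kinetics$kcat_f >= 0))
    expect_true(all(fit$kinetics$kcat_loss >= 0))
  }
})

test_that("null demand yields the zero solution; exchange shifts restore feasibility", {
  net <- aa_network(c("u", "v"), data.frame(from = "u", to = "v"))
  cons <- assign_default_constants(net, c(u = 100, v = 100))
  zero <- c(u = 0, v = 0)
  cmin <- condition_table("minimal", c("u", "v"), c(100, 100), c(1, 1), zero,
                          0, 1)
  crich <- condition_table("rich", c("u", "v"), c(300, 300), c(1, 1), zero,
                           0, 1)
  fit <- fit_kcats_and_exchange(net, cons, cmin, crich)
  expect_equal(unname(fit$kinetics$kcat_f), c(0, 0))
  expect_equal(unname(fit$v_exchange), c(0, 0))

  # rich demand exceeding synthesis capacity is absorbed by exchange, echoing
  # the rationale that varying uptake restores a nonnegative solution
  cmin2 <- condition_table("minimal", c("u", "v"), c(100, 100), c(1, 1),
                           c(0.5, 0.5), 0, 1)
  crich2 <- condition_table("rich", c("u", "v"), c(300, 300), c(1, 1),
                            c(1e4, 1e4), 0, 1)
  fit2 <- fit_kcats_and_exchange(net, cons, cmin2, crich2)
  expect_true(all(fit2$v_exchange > 0))
  expect_true(all(fit2$kinetics$kcat_f >= 0))
  expect_lt(max(abs(fit2$residuals$rich)), 1e-6)

  # infeasible: demand with zero synthesis capacity
  cmin3 <- condition_table("minimal", c("u", "v"), c(100, 100), c(0, 0),
                           c(1, 1), 0, 1)
  expect_error(fit_kcats_and_exchange(net, cons, cmin3, crich2), "infeasible")
})
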