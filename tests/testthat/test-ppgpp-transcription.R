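test_that("RNAP bound fraction follows the squared Hill form", {
  b <- rnap_binding(50)
  expect_equal(fraction_bound(b, 50), 0.5)
  expect_equal(fraction_bound(b, 0), 0)
  expect_equal(fraction_bound(b, 150), 0.9)   # 9K^2/(K^2+9K^2)
  x <- fraction_bound(b, seq(0, 500, by = 10))
  expect_true(all(x >= 0 & x <= 1))
  expect_true(all(diff(x) > 0))
  expect_error(rnap_binding(50, hill = 3), "fixed at 2")
})

test_that("the binding constant is recovered from a growth-law table", {
  tab <- generate_growth_law_table(n_rows = 6, K_M = 70, exp_free = 0.012,
                                   exp_ppgpp = 0.004, noise_sd = 0)
  fit <- fit_km_rnap(tab)
  expect_equal(fit$binding$K_M_ppgpp, 70, tolerance = 1e-6)
  expect_equal(fit$exp_free, 0.012, tolerance = 1e-6)
  expect_equal(fit$exp_ppgpp, 0.004, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-12)

  # constant ppGpp across rows is degenerate
  tab2 <- tab; tab2$ppgpp_conc_uM <- 50
  expect_error(fit_km_rnap(tab2), "degenerate")

  # equal free and bound expression makes K_M unidentifiable
  tab3 <- generate_growth_law_table(n_rows = 6, K_M = 70, exp_free = 0.01,
                                    exp_ppgpp = 0.01)
  expect_error(fit_km_rnap(tab3), "unidentifiable")

  # noisy recovery: at 1% multiplicative noise and 10 rows the binding
  # constant comes back within 20% (K_M is only weakly identified from
  # tables of this shape; see the methods vignette)
  tab4 <- generate_growth_law_table(n_rows = 10, K_M = 70, noise_sd = 0.01,
                                    seed = 42)
  fit4 <- fit_km_rnap(tab4)
  expect_lt(abs(fit4$binding$K_M_ppgpp - 70) / 70, 0.2)
})

test_that("gene expression pairs solve, round-trip, and truncate", {
  f_rich <- 0.8; f_basal <- 0.3
  # no regulation: both levels equal the basal expression
  sol <- solve_gene_expression(FC = 0, exp_basal = 5, f_rich, f_basal)
  expect_equal(sol$exp_free, 5)
  expect_equal(sol$exp_ppgpp, 5)

  # forward-generate then re-solve exactly
  set.seed(9)
  for (i in 1:20) {
    ef <- runif(1, 0.1, 10); ep <- runif(1, 0.1, 10)
    FC <- log2(ep / ((1 - f_rich) * ef + f_rich * ep))
    basal <- (1 - f_basal) * ef + f_basal * ep
    sol <- solve_gene_expression(FC, basal, f_rich, f_basal)
    expect_equal(sol$exp_free, ef, tolerance = 1e-10)
    expect_equal(sol$exp_ppgpp, ep, tolerance = 1e-10)
    expect_false(sol$truncated)
  }

  # a large positive fold change forces truncation at exp_free = 0
  sol <- solve_gene_expression(FC = 8, exp_basal = 3, f_rich, f_basal)
  expect_true(sol$truncated)
  expect_equal(sol$exp_free, 0)
  expect_equal(sol$exp_ppgpp, 3 / f_basal)
  # the basal relation still holds exactly after truncation
  expect_equal((1 - f_basal) * sol$exp_free + f_basal * sol$exp_ppgpp, 3)

  # fallbacks by regulation sign
  sol2 <- solve_gene_expression(FC = c(1, NA, NA), exp_basal = c(2, 2, 2),
                                f_rich = 0.9, f_basal = 0.3,
                                reg_sign = c(1, 1, -1), FC_minus = -2)
  expect_equal(sol2$exp_free[2], sol2$exp_free[1])  # FC_plus = mean measured = 1
  expect_false(anyNA(sol2))
  expect_error(solve_gene_expression(FC = c(NA), exp_basal = 1, 0.5, 0.3,
                                     reg_sign = -1), "FC_minus")
})

test_that("condition matching is exact on planted pairs and errors when rank-deficient", {
  f <- c(0.7, 0.3, 0.5)
  ef <- c(g1 = 2, g2 = 0.5); ep <- c(g1 = 0.4, g2 = 3)
  E <- outer(ef, 1 - f) + outer(ep, f)
  fit <- condition_match(E, f = f)
  expect_equal(fit$exp_free, unname(ef), tolerance = 1e-10)
  expect_equal(fit$exp_ppgpp, unname(ep), tolerance = 1e-10)

  # TF contributions are subtracted before the fit
  tf <- matrix(0.2, 2, 3)
  fit2 <- condition_match(E + tf, tf_targets = tf, f = f)
  expect_equal(fit2$exp_free, unname(ef), tolerance = 1e-10)

  expect_error(condition_match(E[, c(1, 1)], f = c(0.4, 0.4)),
               "rank-deficient")

  # zero-mean noise: the least-squares estimate is unbiased
  set.seed(21)
  f5 <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  est <- replicate(300, {
    e <- (1 - f5) * 2 + f5 * 0.5 + rnorm(5, 0, 0.1)
    unlist(condition_match(matrix(e, 1), f = f5))
  })
  expect_equal(rowMeans(est), c(exp_free = 2, exp_ppgpp = 0.5),
               tolerance = 0.02)
})

test_that("tf_contribution converts probability changes to expression scale", {
  expect_equal(tf_contribution(10, 0.02, 0.05), 4)
  expect_error(tf_contribution(10, 0.02, 0), "p_cond")
})

test_that("synthesis probabilities keep TF effects proportional under ppGpp", {
  alpha_o <- c(0.5, 0.2, 0.1)
  P_T <- c(0.6, 0.4)
  dr <- rbind(c(-0.1, 0, 0.05), c(0.2, 0, -0.02))
  v_fixed <- synth_probability(alpha_o, P_T, dr, mode = "fixed")
  # no TFs: v = alpha in both modes
  expect_equal(as.numeric(synth_probability(alpha_o, mode = "fixed")), alpha_o)
  # alpha(ppGpp) = alpha_o collapses the ppGpp form onto the fixed form
  v_pp <- synth_probability(alpha_o, P_T, dr, mode = "ppgpp", alpha_o = alpha_o)
  expect_equal(as.numeric(v_pp), as.numeric(v_fixed))

  # after the scale correction the two modes agree at the basal condition
  # for every TF-regulated gene (gene 2 carries no TF effect and keeps its
  # own ppGpp-dependent basal)
  alpha_basal <- c(0.8, 0.15, 0.02)   # a different ppGpp-dependent basal
  scale <- calibrate_tf_scale(alpha_basal, alpha_o, P_T, dr)
  v_scaled <- synth_probability(alpha_basal * scale, P_T, dr, mode = "ppgpp",
                                alpha_o = alpha_o)
  tf_reg <- as.numeric(crossprod(dr, P_T)) != 0
  expect_equal(as.numeric(v_scaled)[tf_reg], as.numeric(v_fixed)[tf_reg],
               tolerance = 1e-12)
  expect_equal(scale[2], 1)

  # negative probabilities are clipped with a warning and counted
  expect_warning(v_neg <- synth_probability(c(0.01), c(1), matrix(-1, 1, 1),
                                            mode = "fixed"), "clipped")
  expect_equal(as.numeric(v_neg), 0)
  expect_equal(attr(v_neg, "n_clipped"), 1)
  expect_error(synth_probability(c(0.1), c(1), matrix(1, 1, 1),
                                 mode = "ppgpp", alpha_o = c(0)), "alpha_o")
})

test_that("ppGpp-dependent basal recruitment composes loss and gene dosage", {
  b <- rnap_binding(50)
  tab <- generate_growth_law_table(6)
  tau <- tau_interpolant(tab)
  # interpolant reproduces the table nodes and refuses to extrapolate
  expect_equal(tau(tab$ppgpp_conc_uM[2]), tab$doubling_time_min[2])
  expect_error(tau(1e6), "outside interpolation range")

  # terminus gene with D = 0 has unit dosage: alpha = exp * loss
  a1 <- alpha_of_ppgpp(exp_free = 2, exp_ppgpp = 1, b, 50, tau,
                       rna_halflife_s = Inf, gene_position = 1,
                       C_period_min = 40, D_period_min = 0)
  f <- fraction_bound(b, 50)
  expj <- (1 - f) * 2 + f * 1
  loss <- log(2) / (tau(50) * 60)
  expect_equal(a1, expj * loss)

  # doubling the expression pair doubles alpha (linearity)
  a2 <- alpha_of_ppgpp(4, 2, b, 50, tau, Inf, 1, 40, 0)
  expect_equal(a2, 2 * a1)

  # origin-proximal genes carry more copies, lowering alpha per copy
  a_ori <- alpha_of_ppgpp(2, 1, b, 50, tau, Inf, 0, 40, 20)
  a_ter <- alpha_of_ppgpp(2, 1, b, 50, tau, Inf, 1, 40, 20)
  expect_lt(a_ori, a_ter)
  # finite RNA half-life adds degradation to the loss term
  a_deg <- alpha_of_ppgpp(2, 1, b, 50, tau, 300, 1, 40, 0)
  expect_equal(a_deg, expj * (loss + log(2) / 300))
})
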