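hp_cache <- NULL
get_hp <- function() {
  if (is.null(hp_cache)) hp_cache <<- host_params()
  hp_cache
}

test_that("growth and degradation metrics evaluate their formulas", {
  expect_equal(growth_rate(100, 100, 1), 0)
  expect_equal(growth_rate(100, 200, 2), 0.5)  # doubling over dt
  # exponential trajectory: finite-difference rate approaches mu
  mu <- 3e-4
  g <- growth_rate(100, 100 * exp(mu * 0.01), 0.01)
  expect_equal(g, mu, tolerance = 1e-5)
  expect_error(growth_rate(0, 1, 1), "mass_t")

  expect_equal(rna_degradation_rate(0, 50, 1), 0)
  expect_equal(rna_degradation_rate(50, 50, 2), 0.5)
  # only mRNA degrading in a mixed pool
  expect_equal(rna_degradation_rate(3, 3 + 57, 1), 0.05)
})

test_that("capacities scale linearly in the pools", {
  hp <- get_hp()
  st <- cell_state(hp, "minimal")
  cap1 <- capacities(st, hp)
  st2 <- st
  st2$protein_by_class <- st$protein_by_class * 2
  st2$mrna_by_class <- st$mrna_by_class * 2
  st2$rrna_mass <- st$rrna_mass * 2
  st2$trna_mass <- st$trna_mass * 2
  st2$aa_amount <- st$aa_amount * 2
  cap2 <- capacities(st2, hp)
  # volume doubles with mass, so concentrations are unchanged but counts double
  expect_equal(cap2$ribosome, 2 * cap1$ribosome, tolerance = 1e-12)
  expect_equal(cap2$enzyme, 2 * cap1$enzyme, tolerance = 1e-12)
  # hand evaluation of the enzyme sum
  V <- cell_volume(st, hp)
  counts <- vapply(paste0("enzyme_", hp$aa), function(cl)
    1e6 * st$protein_by_class[[cl]] / (hp$mw$enzyme * V), 0) * V * 602.214
  expect_equal(cap1$enzyme, sum(hp$kinetics$kcat_f * counts))
})

test_that("inhibition metrics sit on their half-points", {
  hp <- get_hp()
  st <- cell_state(hp, "minimal")
  st$ppgpp <- 0
  expect_equal(inhibition_metrics(st, hp)$gtpase, 0)
  st$ppgpp <- hp$charging$K_I_GTPase
  expect_equal(inhibition_metrics(st, hp)$gtpase, 0.5)
  # every amino acid at its effective K_I: each pathway half inhibited
  V <- cell_volume(st, hp)
  st$aa_amount <- hp$kinetics$K_I * hp$kinetics$inhibition_scale * V
  m <- inhibition_metrics(st, hp)
  expect_equal(unname(m$allosteric_by_aa), rep(0.5, 4))
  expect_equal(m$allosteric, 0.5)
})

test_that("the fast supply closure agrees with the public rate laws", {
  hp <- get_hp()
  opt <- sim_options()
  st <- cell_state(hp, "rich")
  V <- cell_volume(st, hp)
  enz <- stats::setNames(vapply(paste0("enzyme_", hp$aa), function(cl)
    1e6 * st$protein_by_class[[cl]] / (hp$mw$enzyme * V), 0), hp$aa)
  tc <- 1e6 * st$protein_by_class[["transporter"]] /
    (hp$mw$transporter * V) / length(hp$aa)
  pools <- transporter_pools(hp$aa, rep(tc, 4), rep(tc, 4))
  fast <- growthctrl:::make_supply_fun(hp, opt, st$media, st$condition, enz,
                                       pools)
  set.seed(2)
  for (i in 1:10) {
    aa <- stats::setNames(runif(4, 1, 5000), hp$aa)
    vex <- exchange_rate(hp$transport, pools, aa, st$media)
    ref <- supply_rate(hp$net, hp$kinetics, aa, enz, vex)
    expect_equal(fast(unname(aa[hp$aa])), unname(ref), tolerance = 1e-12)
  }
  # phenomenological route
  opt2 <- sim_options(mechanistic_translation_supply = FALSE)
  fast2 <- growthctrl:::make_supply_fun(hp, opt2, st$media, "rich", enz, pools)
  aa <- stats::setNames(runif(4, 1, 5000), hp$aa)
  ref2 <- pheno_supply_rate(hp$pheno, hp$v_supply_media, "rich", aa, st$media)
  expect_equal(fast2(unname(aa[hp$aa])), unname(ref2), tolerance = 1e-12)
})

test_that("stepping is deterministic for a fixed seed", {
  hp <- get_hp()
  opt <- sim_options(seed = 99)
  r1 <- run_simulation(cell_state(hp, "minimal"), opt, hp, t_end = 5)
  r2 <- run_simulation(cell_state(hp, "minimal"), opt, hp, t_end = 5)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$state, r2$state)
})

test_that("a ppGpp clamp ramps at the configured rate", {
  hp <- get_hp()
  # charging/regulation off isolates the clamp arithmetic
  opt <- sim_options(trna_charging = FALSE, ppgpp_regulation = FALSE,
                     aa_supply_in_charging = FALSE, attenuation = FALSE,
                     ppgpp_clamp = 51, ppgpp_ramp = 0.01)
  st <- cell_state(hp, "minimal")   # starts at 50 uM
  res <- run_simulation(st, opt, hp, t_end = 120)
  # 1 uM of ramp at 0.01 uM/s: target reached after 100 s, then held
  expect_equal(res$series$ppgpp[50], 50 + 0.5, tolerance = 1e-9)
  expect_equal(res$series$ppgpp[100], 51, tolerance = 1e-9)
  expect_equal(res$series$ppgpp[120], 51, tolerance = 1e-9)
})

test_that("with all regulation off the cell grows exponentially and balanced", {
  hp <- get_hp()
  opt <- sim_options(mechanistic_translation_supply = FALSE,
                     mechanistic_aa_transport = FALSE,
                     trna_charging = FALSE, aa_supply_in_charging = FALSE,
                     ppgpp_regulation = FALSE,
                     ppgpp_elongation_inhibition = FALSE,
                     attenuation = FALSE)
  res <- run_simulation(cell_state(hp, "minimal"), opt, hp, t_end = 3000)
  s <- res$series
  late <- s[s$time > 1500, ]
  # growth rate settles at the condition's expected rate
  mu_exp <- log(2) / hp$tau[["minimal"]]
  expect_equal(mean(late$growth), mu_exp, tolerance = 0.15)
  # RNA/protein ratio stabilizes (windowed coefficient of variation < 5%)
  expect_lt(sd(late$rna_protein) / mean(late$rna_protein), 0.05)
  # growth rate itself is near constant late on
  expect_lt(sd(late$growth) / mean(late$growth), 0.05)
})

test_that("schedules validate their inputs", {
  hp <- get_hp()
  opt <- sim_options(trna_charging = FALSE)
  st <- cell_state(hp, "minimal")
  expect_error(run_simulation(st, opt, hp, 10,
    schedule = data.frame(time = c(5, 2), media = c("rich", "minimal"))),
    "strictly increasing")
  expect_error(run_simulation(st, opt, hp, 10,
    schedule = data.frame(time = 1, media = "broth")), "unknown media")
})
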