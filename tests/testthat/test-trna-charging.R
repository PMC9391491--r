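test_that("charging rate follows the bi-substrate saturation form", {
  cp <- charging_params("s", k_S = 100, K_M_tRNAu = 1, K_M_aa = 100)
  st <- charging_state("s", c(s = 5), c(s = 1), c(s = 2), 10, c(s = 100),
                       c(s = 1))
  # both substrates at their K_M: saturation (1*1)/(1+1+1+1) = 1/4
  expect_equal(charging_rate(cp, st)[["s"]], 100 * 2 / 4)
  # full saturation limit
  st2 <- st; st2$tRNA_uncharged[] <- 1e9; st2$aa_conc[] <- 1e9
  expect_equal(charging_rate(cp, st2)[["s"]], 200, tolerance = 1e-6)
  # no synthetase, no charging
  st3 <- st; st3$synthetase_conc[] <- 0
  expect_equal(charging_rate(cp, st3)[["s"]], 0)
})

test_that("ppGpp caps the ribosome elongation rate through the Hill form", {
  cp <- charging_params("s", k_rib_max = 22, K_I_GTPase = 90, H = 2)
  expect_equal(ribosome_rate_cap(cp, 90), 11)
  expect_equal(ribosome_rate_cap(cp, 0), 22)
  expect_equal(ribosome_rate_cap(cp, 500, gtpase_inhibition_enabled = FALSE), 22)
})

test_that("elongation distributes the capped rate with A-site competition", {
  os <- one_species_state()
  # k_rib = 20, rib = 10, tc = 5, tu = 1, K_Dc = 1, K_Du = 2, f = 1:
  # v = 200 / (1 + 1/5 + (1/5)(1/2)) = 2000/13
  v <- elongation_rate(os$params, os$state, 20)
  expect_equal(v[["s1"]], 2000 / 13)

  # saturated limit: huge charged pool, no uncharged
  st <- os$state; st$tRNA_charged[] <- 1e9; st$tRNA_uncharged[] <- 0
  expect_equal(elongation_rate(os$params, st, 20)[["s1"]], 200,
               tolerance = 1e-6)

  # two identical species split the flux symmetrically
  cp2 <- charging_params(c("a", "b"), K_D_tRNAc = 1, K_D_tRNAu = 2,
                         k_rib_max = 20)
  st2 <- charging_state(c("a", "b"), c(a = 5, b = 5), c(a = 1, b = 1),
                        c(a = 1, b = 1), 10, c(a = 50, b = 50),
                        c(a = 0.5, b = 0.5))
  v2 <- elongation_rate(cp2, st2, 20)
  expect_equal(v2[["a"]], v2[["b"]])

  # starvation: zero charged pool with demand flags the species, all rates 0
  st3 <- st2; st3$tRNA_charged[["a"]] <- 0
  v3 <- elongation_rate(cp2, st3, 20)
  expect_equal(as.numeric(v3), c(0, 0))
  expect_equal(attr(v3, "starved"), "a")
})

test_that("relaxation conserves tRNA totals and bounds elongation", {
  cp <- charging_params(c("a", "b"), k_S = 100)
  st <- charging_state(c("a", "b"), c(a = 80, b = 40), c(a = 20, b = 10),
                       c(a = 3, b = 3), 25, c(a = 200, b = 50),
                       c(a = 0.6, b = 0.4))
  for (coupled in c(FALSE, TRUE)) {
    r <- relax_charging(cp, st, supply = c(a = 30, b = 20), dt = 1,
                        couple_supply = coupled)
    tot0 <- st$tRNA_charged + st$tRNA_uncharged
    tot1 <- r$state$tRNA_charged + r$state$tRNA_uncharged
    expect_equal(unname(tot1), unname(tot0), tolerance = 1e-8)
    expect_lte(sum(r$v_elongation), cp$k_rib_max * 25 + 1e-9)
    expect_true(all(r$state$aa_conc >= 0))
  }
})

test_that("a fixed point of the charging system stays fixed", {
  cp <- charging_params("s", k_S = 50, K_D_tRNAc = 1, K_D_tRNAu = 10,
                        k_rib_max = 20)
  total <- 10; syn <- 1; rib <- 8; aa <- 120
  # find tc where charging equals elongation
  bal <- function(tc) {
    st <- charging_state("s", c(s = tc), c(s = total - tc), c(s = syn), rib,
                         c(s = aa), c(s = 1))
    charging_rate(cp, st)[["s"]] - elongation_rate(cp, st, 20)[["s"]]
  }
  tc_star <- uniroot(bal, c(1e-6, total - 1e-6), tol = 1e-14)$root
  st <- charging_state("s", c(s = tc_star), c(s = total - tc_star),
                       c(s = syn), rib, c(s = aa), c(s = 1))
  v_eq <- charging_rate(cp, st)[["s"]]
  r <- relax_charging(cp, st, supply = c(s = v_eq), dt = 1,
                      couple_supply = TRUE)
  expect_equal(r$state$tRNA_charged[["s"]], tc_star, tolerance = 1e-6)
  expect_equal(r$state$aa_conc[["s"]], aa, tolerance = 1e-6)
})

test_that("stiff relaxation matches a dense explicit reference integration", {
  os <- one_species_state(tc = 5, tu = 3, syn = 0.5, rib = 10, aa = 150)
  a <- relax_charging(os$params, os$state, supply = c(s1 = 20), dt = 0.5,
                      couple_supply = TRUE, rtol = 1e-8, atol = 1e-10)
  b <- relax_charging(os$params, os$state, supply = c(s1 = 20), dt = 0.5,
                      couple_supply = TRUE, rtol = 1e-10, atol = 1e-12,
                      method = "rk45")
  expect_equal(a$state$tRNA_charged[["s1"]], b$state$tRNA_charged[["s1"]],
               tolerance = 1e-8)
  expect_equal(a$v_elongation[["s1"]], b$v_elongation[["s1"]],
               tolerance = 1e-6)
})

test_that("raising the limiting supply raises the charged fraction", {
  cp <- charging_params("s", k_S = 100)
  st <- charging_state("s", c(s = 20), c(s = 80), c(s = 2), 30, c(s = 5),
                       c(s = 1))
  chi <- vapply(c(5, 20, 60), function(sup) {
    r <- relax_charging(cp, st, supply = c(s = sup), dt = 5,
                        couple_supply = TRUE)
    r$state$tRNA_charged[["s"]] /
      (r$state$tRNA_charged[["s"]] + r$state$tRNA_uncharged[["s"]])
  }, 0)
  expect_true(all(diff(chi) >= -1e-9))
  expect_gt(chi[3], chi[1])
})
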