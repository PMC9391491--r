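# tRNA aminoacylation and ribosome elongation kinetics.  Charging follows a
# random-order bi-substrate saturation law in uncharged tRNA and free amino
# acid; elongation distributes a ppGpp-capped maximum ribosome rate over tRNA
# species according to codon demand, with competition through a shared A-site
# occupancy denominator.  Within each simulation timestep the charged:
# uncharged ratio is relaxed toward the steady state of the coupled ODEs.

#' Charging and elongation kinetic parameters
#'
#' @param species tRNA species identifiers (one per amino acid here).
#' @param k_S Synthetase turnover (1/s), default 100.
#' @param K_M_tRNAu Named per-species Michaelis constants for uncharged tRNA
#'   binding synthetases (uM); default 1 for uncurated species.
#' @param K_M_aa Named per-species Michaelis constants for amino acids binding
#'   synthetases (uM); default 100 for uncurated species.
#' @param K_D_tRNAc,K_D_tRNAu Ribosome A-site dissociation constants for
#'   charged and uncharged tRNA (uM).
#' @param k_rib_max Maximum ribosome elongation rate (aa/s per ribosome).
#' @param K_I_GTPase Competitive-inhibition constant of ppGpp on translational
#'   GTPases (uM).
#' @param H Hill coefficient of the GTPase inhibition.
#' @return Object of class `charging_params`.
#' @export
charging_params <- function(species, k_S = 100, K_M_tRNAu = 1, K_M_aa = 100,
                            K_D_tRNAc = 1, K_D_tRNAu = 500,
                            k_rib_max = 22, K_I_GTPase = 90, H = 2) {
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x)))
      x <- stats::setNames(rep(x, length(species)), species)
    align_ids(x, species, what)
  }
  p <- list(species = species, k_S = k_S,
            K_M_tRNAu = expand(K_M_tRNAu, "K_M_tRNAu"),
            K_M_aa = expand(K_M_aa, "K_M_aa"),
            K_D_tRNAc = K_D_tRNAc, K_D_tRNAu = K_D_tRNAu,
            k_rib_max = k_rib_max, K_I_GTPase = K_I_GTPase, H = H)
  check_pos(c(p$k_S, p$K_M_tRNAu, p$K_M_aa, p$K_D_tRNAc, p$K_D_tRNAu,
              p$k_rib_max, p$K_I_GTPase, p$H), "charging parameters")
  structure(p, class = "charging_params")
}

#' Charging state (pools entering the charging/elongation laws)
#'
#' @param species tRNA species identifiers.
#' @param tRNA_charged,tRNA_uncharged Named per-species pools (uM).
#' @param synthetase_conc Named per-species synthetase concentrations (uM).
#' @param ribosome_conc Active ribosome concentration (uM), scalar.
#' @param aa_conc Named per-species free amino-acid concentrations (uM).
#' @param codon_fraction Named per-species codon demand fractions, summing
#'   to 1.
#' @return Object of class `charging_state`.
#' @export
charging_state <- function(species, tRNA_charged, tRNA_uncharged,
                           synthetase_conc, ribosome_conc, aa_conc,
                           codon_fraction) {
  s <- list(species = species,
            tRNA_charged = align_ids(tRNA_charged, species, "tRNA_charged"),
            tRNA_uncharged = align_ids(tRNA_uncharged, species, "tRNA_uncharged"),
            synthetase_conc = align_ids(synthetase_conc, species, "synthetase_conc"),
            ribosome_conc = ribosome_conc,
            aa_conc = align_ids(aa_conc, species, "aa_conc"),
            codon_fraction = align_ids(codon_fraction, species, "codon_fraction"))
  check_nonneg(c(s$tRNA_charged, s$tRNA_uncharged, s$synthetase_conc,
                 s$ribosome_conc, s$aa_conc), "charging pools")
  if (abs(sum(s$codon_fraction) - 1) > 1e-9)
    stop_domain("codon_fraction must sum to 1")
  structure(s, class = "charging_state")
}

#' tRNA charging rate
#'
#' Random-order bi-substrate saturation:
#' `v = k_S * [synthetase] * x*y / (1 + x + y + x*y)` with
#' `x = [tRNAu]/K_M_tRNAu`, `y = [AA]/K_M_aa`.
#'
#' @param params A [charging_params()].
#' @param state A [charging_state()] (or any list carrying the same pools).
#' @return Named per-species charging rates (uM/s).
#' @export
charging_rate <- function(params, state) {
  x <- state$tRNA_uncharged / params$K_M_tRNAu
  y <- state$aa_conc / params$K_M_aa
  params$k_S * state$synthetase_conc * (x * y) / (1 + x + y + x * y)
}

#' ppGpp-capped maximum ribosome elongation rate
#'
#' Competitive inhibition of translational GTPases by ppGpp:
#' `k_rib = k_rib_max / (1 + (ppGpp/K_I)^H)` when enabled, else the constant
#' maximum.
#'
#' @param params A [charging_params()].
#' @param ppgpp_conc ppGpp concentration (uM), `>= 0`.
#' @param gtpase_inhibition_enabled Logical flag.
#' @return Elongation rate cap (aa/s per ribosome).
#' @export
ribosome_rate_cap <- function(params, ppgpp_conc, gtpase_inhibition_enabled = TRUE) {
  check_nonneg(ppgpp_conc, "ppgpp_conc")
  if (!gtpase_inhibition_enabled) return(params$k_rib_max)
  params$k_rib_max / (1 + (ppgpp_conc / params$K_I_GTPase)^params$H)
}

#' Per-species ribosome elongation rates
#'
#' `v_i = f_i * k_rib * [ribosome] / (1 + sum_j f_j * (K_Dc/tc_j +
#' (tu_j/tc_j) * K_Dc/K_Du))`.  A species with codon demand but zero charged
#' tRNA drives the shared denominator to infinity (all rates 0, the algebraic
#' limit); the result then carries a `starved` attribute naming the species.
#'
#' @inheritParams charging_rate
#' @param k_rib Elongation rate cap (aa/s), e.g. from [ribosome_rate_cap()].
#' @return Named per-species elongation rates (uM/s of amino acids), with
#'   attribute `starved`.
#' @export
elongation_rate <- function(params, state, k_rib = params$k_rib_max) {
  f <- state$codon_fraction
  tc <- state$tRNA_charged
  tu <- state$tRNA_uncharged
  active <- f > 0
  starved <- state$species[active & tc <= 0]
  terms <- numeric(length(f))
  terms[active] <- f[active] * (params$K_D_tRNAc / tc[active] +
    (tu[active] / tc[active]) * params$K_D_tRNAc / params$K_D_tRNAu)
  denom <- 1 + sum(terms)
  v <- if (is.finite(denom)) f * k_rib * state$ribosome_conc / denom
       else stats::setNames(numeric(length(f)), state$species)
  v[!active] <- 0
  names(v) <- state$species
  attr(v, "starved") <- starved
  v
}

#' Relax charging toward within-timestep steady state
#'
#' Integrates `d[tc_i]/dt = v_charging,i - v_elongation,i` (with
#' `d[tu_i]/dt` its negative, enforced exactly by integrating only the
#' charged pool against the conserved per-species total) over one timestep.
#' With `couple_supply = TRUE` the free amino-acid pools are integrated in the
#' same system via `d[AA_i]/dt = v_supply,i - v_charging,i`; otherwise amino
#' acids are held constant during the step and updated once afterwards from
#' the time-averaged rates.
#'
#' @inheritParams elongation_rate
#' @param supply Per-species supply (uM/s): a named vector, a function of the
#'   current amino-acid concentration vector, or `NULL` for zero.
#' @param dt Timestep (s), `> 0`.
#' @param couple_supply Logical; integrate amino acids inside the system.
#' @param rtol,atol Integrator tolerances.
#' @param method `"stiff"` (adaptive implicit, the default — the charging
#'   system relaxes on sub-millisecond scales) or `"rk45"` (explicit, for
#'   cross-validation on small problems).
#' @return List with `state` (updated [charging_state()]), `v_charging` and
#'   `v_elongation` (named per-species time averages over `dt`, uM/s).
#' @export
relax_charging <- function(params, state, supply = NULL, dt,
                           couple_supply = FALSE, k_rib = params$k_rib_max,
                           rtol = 1e-8, atol = 1e-10,
                           method = c("stiff", "rk45")) {
  if (dt <= 0) stop_domain("dt must be > 0")
  method <- match.arg(method)
  n <- length(state$species)
  total <- state$tRNA_charged + state$tRNA_uncharged
  supply_fun <- if (is.function(supply)) supply
    else if (is.null(supply)) function(aa) numeric(n)
    else {
      sv <- align_ids(supply, state$species, "supply")
      function(aa) sv
    }

  idx_tc <- seq_len(n)
  idx_aa <- if (couple_supply) n + seq_len(n) else integer(0)
  idx_cc <- (if (couple_supply) 2L * n else n) + seq_len(n)
  idx_ce <- idx_cc + n

  # flat precomputed constants; the derivative avoids all allocation-heavy
  # constructors since it sits inside Newton iterations
  kSsyn <- params$k_S * as.numeric(state$synthetase_conc)
  KMt <- as.numeric(params$K_M_tRNAu)
  KMa <- as.numeric(params$K_M_aa)
  KDc <- params$K_D_tRNAc
  KDu <- params$K_D_tRNAu
  fcod <- as.numeric(state$codon_fraction)
  krr <- k_rib * state$ribosome_conc
  aa_fixed <- as.numeric(state$aa_conc)
  active <- fcod > 0

  deriv <- function(t, y) {
    tc <- pmin(pmax(y[idx_tc], 0), total)
    tu <- total - tc
    aa <- if (couple_supply) pmax(y[idx_aa], 0) else aa_fixed
    x <- tu / KMt
    z <- aa / KMa
    vc <- kSsyn * (x * z) / (1 + x + z + x * z)
    denom <- 1 + sum(fcod[active] * (KDc / tc[active] +
                       (tu[active] / tc[active]) * KDc / KDu))
    ve <- if (is.finite(denom)) fcod * krr / denom else numeric(n)
    dy <- numeric(length(y))
    dy[idx_tc] <- vc - ve
    if (couple_supply) {
      ds <- supply_fun(aa) - vc
      # hold depleted pools at zero instead of integrating below it
      ds[aa <= 0 & ds < 0] <- 0
      dy[idx_aa] <- ds
    }
    dy[idx_cc] <- vc
    dy[idx_ce] <- ve
    dy
  }

  y0 <- c(state$tRNA_charged,
          if (couple_supply) state$aa_conc else NULL,
          numeric(n), numeric(n))
  integrate <- if (method == "stiff") {
    function() ode_bdf1(deriv, y0, 0, dt, rtol = rtol, atol = atol,
                        nonneg = TRUE, n_quad = 2L * n)
  } else {
    function() ode_rk45(deriv, y0, 0, dt, rtol = rtol, atol = atol,
                        nonneg = TRUE)
  }
  y1 <- tryCatch(integrate(),
    error = function(e) stop_domain("relax_charging: integrator failure: ",
                                    conditionMessage(e)))
  tc1 <- pmin(pmax(y1[idx_tc], 0), total)
  names(tc1) <- state$species
  avg_vc <- stats::setNames(y1[idx_cc] / dt, state$species)
  avg_ve <- stats::setNames(y1[idx_ce] / dt, state$species)
  aa1 <- if (couple_supply) {
    stats::setNames(pmax(y1[idx_aa], 0), state$species)
  } else {
    pmax(state$aa_conc + dt * (supply_fun(state$aa_conc) - avg_vc), 0)
  }
  # invariants hold by construction; skip re-validation on the hot path
  out_state <- structure(list(species = state$species, tRNA_charged = tc1,
                              tRNA_uncharged = total - tc1,
                              synthetase_conc = state$synthetase_conc,
                              ribosome_conc = state$ribosome_conc,
                              aa_conc = aa1,
                              codon_fraction = state$codon_fraction),
                         class = "charging_state")
  list(state = out_state, v_charging = avg_vc, v_elongation = avg_ve)
}
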