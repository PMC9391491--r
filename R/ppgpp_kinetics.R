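# RelA/SpoT ppGpp kinetics.  RelA synthesis is driven by ribosomes carrying
# uncharged tRNA at the A-site (with competition between tRNA species), SpoT
# provides constitutive synthesis and first-order hydrolysis inhibited by
# uncharged tRNA.  SpoT rate constants are derived analytically from a
# measured decay half-life and steady-state concentration.

#' ppGpp kinetic parameters
#'
#' @param species tRNA species identifiers.
#' @param k_RelA RelA turnover (1/s).
#' @param K_D_RelA Named per-species dissociation constants of RelA for
#'   ribosome:uncharged-tRNA complexes (uM), usually prevalence-adjusted via
#'   [species_adjustments()].
#' @param k_SpoT_syn SpoT synthesis rate constant (1/s).
#' @param k_SpoT_deg SpoT hydrolysis rate constant (1/(uM*s)).
#' @param K_I_SpoT Named per-species inhibition constants of uncharged tRNA on
#'   SpoT hydrolysis (uM).
#' @param C_SpoT_ref,ppgpp_ss_ref,halflife_ref Calibration assumptions behind
#'   the derived constants: SpoT at 0.1 uM, steady-state ppGpp 11.4 uM (taken
#'   as a given input; the OD-to-volume conversion is not reimplemented) and a
#'   30 s decay half-life.
#' @return Object of class `ppgpp_params`.
#' @export
ppgpp_params <- function(species, k_RelA = 75, K_D_RelA = 0.26,
                         k_SpoT_syn = NULL, k_SpoT_deg = NULL,
                         K_I_SpoT = 4000, C_SpoT_ref = 0.1,
                         ppgpp_ss_ref = 11.4, halflife_ref = 30) {
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x)))
      x <- stats::setNames(rep(x, length(species)), species)
    align_ids(x, species, what)
  }
  if (is.null(k_SpoT_syn) || is.null(k_SpoT_deg)) {
    d <- derive_spot_constants(halflife_ref, C_SpoT_ref, ppgpp_ss_ref)
    if (is.null(k_SpoT_deg)) k_SpoT_deg <- d$k_SpoT_deg
    if (is.null(k_SpoT_syn)) k_SpoT_syn <- d$k_SpoT_syn
  }
  p <- list(species = species, k_RelA = k_RelA,
            K_D_RelA = expand(K_D_RelA, "K_D_RelA"),
            k_SpoT_syn = k_SpoT_syn, k_SpoT_deg = k_SpoT_deg,
            K_I_SpoT = expand(K_I_SpoT, "K_I_SpoT"),
            C_SpoT_ref = C_SpoT_ref, ppgpp_ss_ref = ppgpp_ss_ref,
            halflife_ref = halflife_ref)
  check_pos(c(p$k_RelA, p$K_D_RelA, p$k_SpoT_syn, p$k_SpoT_deg, p$K_I_SpoT,
              p$C_SpoT_ref, p$ppgpp_ss_ref, p$halflife_ref), "ppgpp parameters")
  structure(p, class = "ppgpp_params")
}

#' Ribosome A-site occupancy by tRNA
#'
#' Computes, per species: the A-site charged saturation
#' `sigma_i = (tc/K_Dc) / (1 + tu/K_Du + tc/K_Dc)`, the concentration of
#' ribosomes with species `i` at the A-site `C_rib,i = v_elong,i /
#' (sigma_i * k_rib)` (0/0 treated as 0), and the concentration of ribosomes
#' bound to uncharged tRNA.
#'
#' @param charging_params A [charging_params()].
#' @param charging_state A [charging_state()].
#' @param v_elongation Named per-species elongation rates (uM/s).
#' @param k_rib Elongation rate cap (aa/s), `> 0`.
#' @return Object of class `ribosome_occupancy` with per-species `sigma`,
#'   `C_rib` and `C_rib_tRNAu`.
#' @export
ribosome_occupancy <- function(charging_params, charging_state, v_elongation,
                               k_rib) {
  check_pos(k_rib, "k_rib")
  tc <- charging_state$tRNA_charged
  tu <- charging_state$tRNA_uncharged
  xc <- tc / charging_params$K_D_tRNAc
  xu <- tu / charging_params$K_D_tRNAu
  sigma <- xc / (1 + xu + xc)
  v <- align_ids(stats::setNames(as.numeric(v_elongation),
                                 names(v_elongation)),
                 charging_state$species, "v_elongation")
  C_rib <- ifelse(sigma > 0, v / (sigma * k_rib), 0)
  C_rib_tRNAu <- C_rib * xu / (1 + xu + xc)
  structure(list(species = charging_state$species, sigma = sigma,
                 C_rib = C_rib, C_rib_tRNAu = C_rib_tRNAu),
            class = "ribosome_occupancy")
}

#' Prevalence adjustment of per-species constants
#'
#' Scales literature dissociation/inhibition constants by each species'
#' relative abundance so every tRNA species has approximately the same control
#' over ppGpp production and degradation:
#' `adjustment_i = ratio_i / (mean ratio)`, `K_i = adjustment_i * K_lit`.
#'
#' @param total_tRNA_conc Named per-species total tRNA concentrations (uM),
#'   `> 0`.
#' @param K_D_RelA_lit,K_I_SpoT_lit Literature base constants (uM).
#' @return List with named per-species `K_D_RelA` and `K_I_SpoT` (and the
#'   `adjustment` factors, which sum to the number of species).
#' @export
species_adjustments <- function(total_tRNA_conc, K_D_RelA_lit, K_I_SpoT_lit) {
  check_pos(total_tRNA_conc, "total_tRNA_conc")
  ratio <- total_tRNA_conc / sum(total_tRNA_conc)
  adjustment <- ratio / mean(ratio)
  list(K_D_RelA = adjustment * K_D_RelA_lit,
       K_I_SpoT = adjustment * K_I_SpoT_lit,
       adjustment = adjustment)
}

#' RelA ppGpp synthesis rate
#'
#' Sum over species of fractional occupancy terms, each with the product over
#' competing species in its denominator:
#' `v = k_RelA * C_RelA * sum_i x_i / (x_i + prod_{j != i} (1 + x_j))` with
#' `x_i = C_rib:tRNAu,i / K_D_RelA,i`.  Bounded above by `k_RelA * C_RelA`.
#'
#' @param params A [ppgpp_params()].
#' @param occupancy A [ribosome_occupancy()].
#' @param C_RelA RelA concentration (uM).
#' @return ppGpp synthesis rate (uM/s).
#' @export
rela_rate <- function(params, occupancy, C_RelA) {
  x <- occupancy$C_rib_tRNAu / params$K_D_RelA
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) {
    if (x[i] <= 0) next
    competition <- prod(1 + x[-i])
    total <- total + x[i] / (x[i] + competition)
  }
  unname(params$k_RelA * C_RelA * total)
}

#' SpoT synthesis and degradation rates
#'
#' `syn = k_SpoT_syn * C_SpoT`;
#' `deg = k_SpoT_deg * C_SpoT * ppGpp / (1 + sum_i tu_i/K_I_SpoT,i)`.
#'
#' @param params A [ppgpp_params()].
#' @param C_SpoT SpoT concentration (uM).
#' @param ppgpp_conc ppGpp concentration (uM).
#' @param tRNA_uncharged Named per-species uncharged tRNA pools (uM).
#' @return List with `syn` and `deg` (uM/s).
#' @export
spot_rates <- function(params, C_SpoT, ppgpp_conc, tRNA_uncharged) {
  check_nonneg(c(C_SpoT, ppgpp_conc), "SpoT inputs")
  tu <- align_ids(tRNA_uncharged, params$species, "tRNA_uncharged")
  check_nonneg(tu, "tRNA_uncharged")
  list(syn = params$k_SpoT_syn * C_SpoT,
       deg = params$k_SpoT_deg * C_SpoT * ppgpp_conc /
         (1 + sum(tu / params$K_I_SpoT)))
}

#' Net ppGpp derivative
#'
#' `d[ppGpp]/dt = v_RelA + v_SpoT,syn - v_SpoT,deg`.
#'
#' @param params A [ppgpp_params()] (unused; kept for interface symmetry).
#' @param rela RelA synthesis rate (uM/s).
#' @param spot List with `syn` and `deg` from [spot_rates()].
#' @return Net derivative (uM/s).
#' @export
ppgpp_derivative <- function(params, rela, spot) {
  rela + spot$syn - spot$deg
}

#' Derive SpoT rate constants from decay calibration
#'
#' With synthesis off and hydrolysis uninhibited, ppGpp decays exponentially
#' (`d[ppGpp]/dt = -k_deg * C_SpoT * ppGpp`), so a measured half-life gives
#' `k_deg = ln(2) / t_half / C_SpoT`; the steady state of a RelA knockout then
#' gives `k_syn = k_deg * ppGpp_ss`.
#'
#' @param halflife_ref Decay half-life (s), default 30.
#' @param C_SpoT_ref SpoT concentration assumption (uM), default 0.1.
#' @param ppgpp_ss_ref Steady-state ppGpp in the RelA knockout (uM),
#'   default 11.4.
#' @return List with `k_SpoT_deg` (1/(uM*s)) and `k_SpoT_syn` (1/s).
#' @export
derive_spot_constants <- function(halflife_ref = 30, C_SpoT_ref = 0.1,
                                  ppgpp_ss_ref = 11.4) {
  check_pos(c(halflife_ref, C_SpoT_ref, ppgpp_ss_ref), "calibration inputs")
  k_deg <- log(2) / halflife_ref / C_SpoT_ref
  list(k_SpoT_deg = k_deg, k_SpoT_syn = k_deg * ppgpp_ss_ref)
}

#' Integrate the SpoT-only ppGpp ODE
#'
#' Convenience integrator for the ppGpp balance with RelA off: optionally
#' disable synthesis (pure decay) and supply fixed uncharged tRNA pools.
#' Used by the calibration round-trip checks.
#'
#' @param params A [ppgpp_params()].
#' @param ppgpp0 Initial concentration (uM).
#' @param C_SpoT SpoT concentration (uM).
#' @param t_end End time (s).
#' @param tRNA_uncharged Named per-species pools (uM); default all zero.
#' @param synthesis Logical; include the SpoT synthesis term.
#' @param n_out Number of saved time points.
#' @return data.frame with columns `time` and `ppgpp`.
#' @export
integrate_spot_ode <- function(params, ppgpp0, C_SpoT = params$C_SpoT_ref,
                               t_end, tRNA_uncharged = NULL, synthesis = TRUE,
                               n_out = 200) {
  tu <- if (is.null(tRNA_uncharged))
    stats::setNames(numeric(length(params$species)), params$species)
  else align_ids(tRNA_uncharged, params$species, "tRNA_uncharged")
  f <- function(t, y) {
    s <- spot_rates(params, C_SpoT, max(y[1], 0), tu)
    (if (synthesis) s$syn else 0) - s$deg
  }
  times <- seq(0, t_end, length.out = n_out + 1)
  out <- numeric(length(times))
  out[1] <- ppgpp0
  y <- ppgpp0
  for (i in seq_len(n_out)) {
    y <- ode_rk45(f, y, times[i], times[i + 1], rtol = 1e-10, atol = 1e-12,
                  nonneg = TRUE)
    out[i + 1] <- y
  }
  data.frame(time = times, ppgpp = out)
}
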