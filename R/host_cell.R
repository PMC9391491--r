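# Reduced coarse-grained host cell.  Couples transcription (ppGpp-dependent
# partitioning of RNA polymerase output, with attenuation sampling), RNA
# degradation, amino-acid supply (mechanistic network + transport, or
# phenomenological), tRNA charging / ribosome elongation, and RelA/SpoT ppGpp
# kinetics, one timestep at a time.  The host stands in for the full
# whole-cell model: it is deterministic except for attenuation sampling and
# aims at mechanisms and qualitative responses, not fluctuation statistics.
#
# Units: masses fg, volume fL, concentrations uM, time s.  With molecular
# weights in Da, conc_uM = 1e6 * mass_fg / (MW * volume_fL), and the
# counts<->concentration factor is N_Avogadro-scaled: counts = conc_uM *
# volume_fL * 602.214.

COUNTS_PER_UM_FL <- 602.214

#' Simulation options
#'
#' Feature flags mirroring the simulator's regulation switches, the optional
#' ppGpp clamp, timestep and seed.
#'
#' @param mechanistic_translation_supply Use the kinetic biosynthesis network
#'   (otherwise the phenomenological supply).
#' @param mechanistic_aa_transport Use mechanistic import/export (only
#'   meaningful with mechanistic supply).
#' @param trna_charging Enable tRNA charging (otherwise translation follows
#'   the condition's expected rate).
#' @param aa_supply_in_charging Integrate amino-acid supply inside the
#'   charging ODEs (sub-timestep coupling).
#' @param ppgpp_regulation Enable ppGpp kinetics and its transcriptional
#'   effects.
#' @param ppgpp_elongation_inhibition Enable GTPase inhibition of the
#'   ribosome elongation rate by ppGpp.
#' @param attenuation Enable charged-tRNA transcriptional attenuation
#'   (the only stochastic element).
#' @param ppgpp_clamp Optional clamp target (uM); approached by a slow ramp.
#' @param ppgpp_ramp Ramp rate toward the clamp target (uM/s), default 0.01.
#' @param dt Timestep (s), default 1.
#' @param seed Integer RNG seed.
#' @return Object of class `sim_options`.
#' @export
sim_options <- function(mechanistic_translation_supply = TRUE,
                        mechanistic_aa_transport = TRUE,
                        trna_charging = TRUE,
                        aa_supply_in_charging = TRUE,
                        ppgpp_regulation = TRUE,
                        ppgpp_elongation_inhibition = TRUE,
                        attenuation = TRUE,
                        ppgpp_clamp = NULL, ppgpp_ramp = 0.01,
                        dt = 1, seed = 1L) {
  if (!is.null(ppgpp_clamp)) check_pos(ppgpp_ramp, "ppgpp_ramp")
  if (dt <= 0) stop_domain("dt must be > 0")
  structure(list(mechanistic_translation_supply = mechanistic_translation_supply,
                 mechanistic_aa_transport = mechanistic_aa_transport,
                 trna_charging = trna_charging,
                 aa_supply_in_charging = aa_supply_in_charging,
                 ppgpp_regulation = ppgpp_regulation,
                 ppgpp_elongation_inhibition = ppgpp_elongation_inhibition,
                 attenuation = attenuation,
                 ppgpp_clamp = ppgpp_clamp, ppgpp_ramp = ppgpp_ramp,
                 dt = dt, seed = as.integer(seed)),
            class = "sim_options")
}

# steady-state proteome / mRNA-allocation shares implied by a bound fraction
host_mrna_shares <- function(params, f) {
  w <- (1 - f) * params$gene$exp_free + f * params$gene$exp_ppgpp
  names(w) <- params$gene$class
  w_m <- w[params$mrna_classes]
  w_m / sum(w_m)
}

host_alloc_weights <- function(params, f) {
  w <- (1 - f) * params$gene$exp_free + f * params$gene$exp_ppgpp
  stats::setNames(w, params$gene$class)
}

#' Default host-cell parameter bundle
#'
#' Builds a self-consistent E. coli-like stated world: a four-amino-acid
#' glutamate-rooted network (glu -> ala, glu -> pro, pro -> arg), planted
#' minimal/rich concentrations, doubling-time-derived translation demands,
#' fitted biosynthesis and transport constants, charging and ppGpp kinetics,
#' a small gene-class table whose free/ppGpp-bound expression levels drive
#' RNAP output partitioning, and attenuation constants for the enzyme genes.
#' All defaults are documented in the methods vignette and are not meant to
#' be tuned per experiment.
#'
#' @param tau_rich_min,tau_minimal_min Target doubling times (min).
#' @param ppgpp_rich,ppgpp_minimal Expected ppGpp concentrations (uM).
#' @param inhibition_scale Optional named per-AA multiplier on the allosteric
#'   K_I (Inf removes inhibition; mutant experiments).
#' @return Object of class `host_params`.
#' @export
host_params <- function(tau_rich_min = 25, tau_minimal_min = 45,
                        ppgpp_rich = 15, ppgpp_minimal = 50,
                        inhibition_scale = NULL) {
  aa <- c("glu", "ala", "pro", "arg")
  net <- aa_network(aa,
                    edges = data.frame(from = c("glu", "glu", "pro"),
                                       to = c("ala", "pro", "arg")),
                    root = "glu",
                    loss_kind = c(glu = "none", ala = "reverse",
                                  pro = "none", arg = "degradation"))
  codon_fraction <- c(glu = 0.3, ala = 0.3, pro = 0.2, arg = 0.2)
  conc_minimal <- c(glu = 20000, ala = 500, pro = 1500, arg = 500)
  conc_rich <- c(glu = 25000, ala = 2000, pro = 3000, arg = 1800)

  # geometry: fg, fL; dry mass is 75% protein+RNA at density 330 fg/fL
  protein0 <- 165; rna0 <- 60
  rna_split <- c(rrna = 0.80, trna = 0.15, mrna = 0.05)
  volume0 <- (protein0 + rna0) / 0.75 / 330
  mw <- list(aa = 110, nt = 325, rrna = 1.55e6, trna = 2.5e4,
             enzyme = 1e5, transporter = 1e5, synthetase = 1e5,
             rnap = 4.5e5, rprot = 8e5, rela = 8.4e4, spot = 7.9e4,
             housekeeping = 5e4)

  # gene classes: free / ppGpp-bound expression levels (relative units);
  # stable RNA down with ppGpp, biosynthesis enzymes up (stringent response)
  enzyme_classes <- paste0("enzyme_", aa)
  gene <- data.frame(
    class = c("rrna", "trna", "rprot", "rnap", enzyme_classes,
              "transporter", "synthetase", "rela", "spot", "housekeeping"),
    exp_free = c(60, 12, 10, 0.32, rep(0.6, 4), 0.8, 1.5,
                 0.0015, 0.003, 12),
    exp_ppgpp = c(4, 2, 2.5, 0.18, rep(2.2, 4), 1.2, 0.8,
                  0.003, 0.003, 9),
    stringsAsFactors = FALSE)
  mrna_classes <- setdiff(gene$class, c("rrna", "trna"))
  # K_M of ppGpp-RNAP binding: 45 uM places the basal condition on the steep
  # part of the Hill curve, which is what makes stable-RNA allocation fall
  # faster than elongation slows between rich and minimal (growth-law
  # direction); see the methods vignette
  binding <- rnap_binding(45)
  f_min <- fraction_bound(binding, ppgpp_minimal)
  f_rich <- fraction_bound(binding, ppgpp_rich)

  params <- list(aa = aa, net = net, codon_fraction = codon_fraction,
                 conc_minimal = conc_minimal, conc_rich = conc_rich,
                 protein0 = protein0, rna0 = rna0, rna_split = rna_split,
                 volume0 = volume0, mw = mw, density_dry = 330,
                 dry_fraction = 0.75,
                 gene = gene, mrna_classes = mrna_classes, binding = binding,
                 tau = c(rich = tau_rich_min * 60, minimal = tau_minimal_min * 60),
                 ppgpp_expected = c(rich = ppgpp_rich, minimal = ppgpp_minimal),
                 mrna_halflife = 300, stable_halflife = Inf,
                 rnap_elong_nt = 65,
                 media = list(rich = stats::setNames(rep(TRUE, 4), aa),
                              minimal = stats::setNames(rep(FALSE, 4), aa)))
  # total RNAP engagement follows the summed recruitment weights (bound
  # polymerase still transcribes, with its own per-gene program); the scale
  # pins half the polymerase pool active at the basal (minimal) condition
  params$rnap_activity_scale <-
    0.5 / sum(host_alloc_weights(params, f_min))

  # expected per-condition pool concentrations from allocation shares
  pool_conc <- function(f, class, mw_key) {
    shares <- host_mrna_shares(params, f)
    1e6 * shares[[class]] * protein0 / (mw[[mw_key]] * volume0)
  }
  enzyme_conc_at <- function(f) {
    stats::setNames(vapply(enzyme_classes, pool_conc, 0, f = f,
                           mw_key = "enzyme"), aa)
  }
  enz_min <- enzyme_conc_at(f_min)
  enz_rich <- enzyme_conc_at(f_rich)

  protein_aa_conc <- 1e6 * protein0 / (mw$aa * volume0)
  S_min <- codon_fraction * log(2) / params$tau[["minimal"]] * protein_aa_conc
  S_rich <- codon_fraction * log(2) / params$tau[["rich"]] * protein_aa_conc

  cond_min <- condition_table("minimal", aa, conc_minimal, enz_min, S_min,
                              exchange_lit_uM_per_s = 0, kcat_lit_per_s = 10)
  cond_rich <- condition_table("rich", aa, conc_rich, enz_rich, S_rich,
                               exchange_lit_uM_per_s = 0.5 * S_rich,
                               kcat_lit_per_s = 10)
  constants <- assign_default_constants(net, conc_minimal)
  fit <- fit_kcats_and_exchange(net, constants, cond_min, cond_rich)
  kin <- fit$kinetics
  if (!is.null(inhibition_scale))
    kin$inhibition_scale[names(inhibition_scale)] <- inhibition_scale

  # transport: export K_M from the imputation rule with one curated anchor,
  # kcats calibrated to the fitted rich-media exchange
  K_M_ex <- estimate_missing_export_km(c(glu = 10 * conc_minimal[["glu"]]),
                                       conc_minimal)
  t_share <- host_mrna_shares(params, f_rich)[["transporter"]]
  T_pool <- 1e6 * t_share * protein0 / (mw$transporter * volume0) / length(aa)
  pools <- transporter_pools(aa, rep(T_pool, 4), rep(T_pool, 4))
  tp0 <- transport_params(aa, kcat_im = rep(1, 4), kcat_ex = rep(1, 4),
                          K_I_im = conc_rich, K_M_ex = K_M_ex)
  transport <- fit_transport_kcats(tp0, pools, conc_rich, fit$v_exchange)

  # phenomenological alternative: base rates are the per-condition demands
  pheno <- solve_pheno_params(0.25, 0.25, conc_minimal, conc_rich)
  v_supply_media <- list(minimal = S_min, rich = S_rich)

  # charging + ppGpp kinetics.  The GTPase inhibition constant is calibrated
  # (as in the source model, where it is fit to elongation-vs-ppGpp data) so
  # that at the expected minimal-media state the ppGpp-capped ribosome
  # capacity matches the stated translation demand at ~97% saturation.
  rib_conc0 <- 1e6 * rna0 * rna_split[["rrna"]] / (mw$rrna * volume0)
  cap_ratio <- 22 * rib_conc0 * 0.97 / sum(S_min)
  if (cap_ratio <= 1)
    stop_domain("host_params: ribosome capacity below minimal-media demand")
  K_I_gtpase <- ppgpp_minimal / sqrt(cap_ratio - 1)
  charging <- charging_params(aa, K_I_GTPase = K_I_gtpase)
  trna_conc0 <- 1e6 * rna0 * rna_split[["trna"]] * codon_fraction /
    (mw$trna * volume0)
  adj <- species_adjustments(trna_conc0, K_D_RelA_lit = 0.26,
                             K_I_SpoT_lit = 4000)
  ppgpp <- ppgpp_params(aa, k_RelA = 75, K_D_RelA = adj$K_D_RelA,
                        K_I_SpoT = adj$K_I_SpoT)

  # attenuation of enzyme genes: fold change 0.5 at rich charged tRNA
  chi_rich <- 0.9
  trna_rich <- chi_rich * trna_conc0
  att_fc <- stats::setNames(rep(0.5, 4), enzyme_classes)
  gene_aa <- stats::setNames(aa, enzyme_classes)
  attenuation <- fit_attenuation_k(att_fc, gene_aa, trna_rich)
  p_stop_expected <- p_stop(attenuation, trna_rich)

  params$kinetics <- kin
  params$constants <- constants
  params$v_exchange_fit <- fit$v_exchange
  params$fit_residuals <- fit$residuals
  params$transport <- transport
  params$transporter_pool_per_aa <- T_pool
  params$pheno <- pheno
  params$v_supply_media <- v_supply_media
  params$charging <- charging
  params$ppgpp <- ppgpp
  params$attenuation <- attenuation
  params$p_stop_expected <- p_stop_expected
  params$att_nominal_transcripts <- 20L
  params$demand <- list(minimal = S_min, rich = S_rich)

  # rRNA surveillance: rRNA in excess of what ribosomal proteins can
  # assemble is degraded.  The tolerated rRNA:rProtein mass ratio is the
  # larger of the two balanced-growth ratios plus 8% slack, so the cap is
  # inactive in either steady state and engages only during imbalance
  # transients (e.g. a downshift with allocation frozen).
  ratios <- vapply(c("rich", "minimal"), function(cond) {
    host_balanced_growth(params, cond)$rrna_over_rprot
  }, 0)
  params$rrna_per_rprot_max <- 1.08 * max(ratios)
  params$rrna_excess_halflife <- 120
  structure(params, class = "host_params")
}

# closed-form balanced-growth composition for a condition's expected ppGpp:
# mu^2 = k_rib * sat * (MW_aa/MW_rrna) * s_rrna * c_o with
# c_o = phi_rnap * elong_nt * (MW_nt/MW_rnap) * activity and activity the
# weight-summed RNAP engagement
host_balanced_growth <- function(params, condition, sat = 0.97) {
  f <- fraction_bound(params$binding, params$ppgpp_expected[[condition]])
  w <- host_alloc_weights(params, f)
  s_rrna <- w[["rrna"]] / sum(w)
  shares_m <- host_mrna_shares(params, f)
  phi_rnap <- shares_m[["rnap"]]
  psi_rprot <- shares_m[["rprot"]]
  activity <- params$rnap_activity_scale * sum(w)
  k_rib <- ribosome_rate_cap(params$charging,
                             params$ppgpp_expected[[condition]], TRUE)
  c_o <- phi_rnap * params$rnap_elong_nt * (params$mw$nt / params$mw$rnap) *
    activity
  mu <- sqrt(k_rib * sat * (params$mw$aa / params$mw$rrna) * s_rrna * c_o)
  list(mu = mu, c_o = c_o, s_rrna = s_rrna,
       rrna_over_rprot = s_rrna * c_o / mu / psi_rprot)
}

#' Initial host-cell state
#'
#' Builds a cell at the steady-state composition expected for a condition:
#' pool shares at the condition's allocation, amino acids at planted
#' concentrations, ppGpp at its expected level, tRNA 90% charged.
#'
#' @param params A [host_params()].
#' @param condition `"rich"` or `"minimal"`.
#' @return Object of class `cell_state`.
#' @export
cell_state <- function(params, condition = c("minimal", "rich")) {
  condition <- match.arg(condition)
  f <- fraction_bound(params$binding, params$ppgpp_expected[[condition]])
  shares <- host_mrna_shares(params, f)
  protein_by_class <- shares * params$protein0
  w <- host_alloc_weights(params, f)
  w_m <- w[params$mrna_classes]
  mrna_by_class <- params$rna0 * params$rna_split[["mrna"]] * w_m / sum(w_m)
  conc <- if (condition == "rich") params$conc_rich else params$conc_minimal
  structure(list(
    time = 0,
    protein_by_class = protein_by_class,
    mrna_by_class = mrna_by_class,
    rrna_mass = params$rna0 * params$rna_split[["rrna"]],
    trna_mass = params$rna0 * params$rna_split[["trna"]],
    aa_amount = conc * cell_volume_masses(params,
      sum(protein_by_class), sum(mrna_by_class) +
        params$rna0 * (params$rna_split[["rrna"]] + params$rna_split[["trna"]])),
    chi = stats::setNames(rep(0.9, length(params$aa)), params$aa),
    ppgpp = params$ppgpp_expected[[condition]],
    media = params$media[[condition]],
    condition = condition,
    deg_mass_last = 0), class = "cell_state")
}

cell_volume_masses <- function(params, protein_mass, rna_mass) {
  (protein_mass + rna_mass) / params$dry_fraction / params$density_dry
}

#' Cell volume (fL)
#' @param state A [cell_state()].
#' @param params A [host_params()].
#' @return Volume in fL (fixed dry density).
#' @export
cell_volume <- function(state, params) {
  cell_volume_masses(params, sum(state$protein_by_class),
                     sum(state$mrna_by_class) + state$rrna_mass + state$trna_mass)
}

# concentration (uM) of a protein pool
pool_conc_of <- function(state, params, class, mw_key) {
  V <- cell_volume(state, params)
  1e6 * state$protein_by_class[[class]] / (params$mw[[mw_key]] * V)
}

#' Advance the host cell by one timestep
#'
#' Timestep order: (1) transcription — RNAP output partitioned over gene
#' classes by ppGpp-dependent expression weights, with attenuation sampling
#' on the enzyme classes; (2) RNA degradation by per-class half-lives;
#' (3) amino-acid supply (mechanistic or phenomenological) and charging
#' relaxation, producing protein; (4) ppGpp ODE update or clamp ramp;
#' (5) pool update — translation output allocated by mRNA class shares;
#' (6) volume from total mass at fixed density.
#'
#' @param state A [cell_state()].
#' @param options A [sim_options()].
#' @param params A [host_params()].
#' @return List with `state` (advanced) and `diag` (one-row data.frame of
#'   diagnostics).
#' @export
cell_step <- function(state, options, params) {
  dt <- options$dt
  V <- cell_volume(state, params)
  protein_mass <- sum(state$protein_by_class)
  mrna_mass <- sum(state$mrna_by_class)
  rna_mass <- mrna_mass + state$rrna_mass + state$trna_mass

  # --- (1) transcription ----------------------------------------------------
  # without ppGpp regulation, expression follows per-condition step
  # functions (the expected allocation for the active media), with no
  # dynamic ppGpp response
  f <- if (options$ppgpp_regulation) fraction_bound(params$binding, state$ppgpp)
       else fraction_bound(params$binding, params$ppgpp_expected[[state$condition]])
  w <- host_alloc_weights(params, f)
  att_completed <- stats::setNames(rep(1, length(params$aa)),
                                   paste0("enzyme_", params$aa))
  if (options$attenuation) {
    trna_conc <- trna_species_conc(state, params, V)
    ps <- p_stop(params$attenuation, state$chi * trna_conc)
    adjust <- 1 / (1 - params$p_stop_expected)
    m <- params$att_nominal_transcripts
    done <- stats::rbinom(length(ps), m, 1 - ps) / m
    names(done) <- names(ps)
    att_completed[names(ps)] <- done
    w[names(ps)] <- w[names(ps)] * adjust[names(ps)] * done
  }
  shares <- w / sum(w)
  rnap_conc <- pool_conc_of(state, params, "rnap", "rnap")
  activity <- params$rnap_activity_scale * sum(w)
  rna_out_fg <- params$rnap_elong_nt * rnap_conc * activity *
    params$mw$nt * V / 1e6 * dt
  d_rrna <- rna_out_fg * shares[["rrna"]]
  d_trna <- rna_out_fg * shares[["trna"]]
  d_mrna <- rna_out_fg * shares[params$mrna_classes]
  names(d_mrna) <- params$mrna_classes

  # --- (2) RNA degradation ---------------------------------------------------
  keep_mrna <- 2^(-dt / params$mrna_halflife)
  deg_mass <- sum(state$mrna_by_class) * (1 - keep_mrna)
  mrna_by_class <- state$mrna_by_class * keep_mrna + d_mrna
  rrna_mass <- state$rrna_mass + d_rrna
  trna_mass_new <- state$trna_mass + d_trna
  # surveillance of rRNA beyond ribosomal-protein assembly capacity
  rrna_cap <- params$rrna_per_rprot_max * state$protein_by_class[["rprot"]]
  excess <- rrna_mass - rrna_cap
  if (excess > 0) {
    trimmed <- excess * (1 - 2^(-dt / params$rrna_excess_halflife))
    rrna_mass <- rrna_mass - trimmed
    deg_mass <- deg_mass + trimmed
  }

  # --- (3) supply + charging -> protein --------------------------------------
  aa_conc <- state$aa_amount / V
  enz_conc <- stats::setNames(vapply(paste0("enzyme_", params$aa),
    function(cl) pool_conc_of(state, params, cl, "enzyme"), 0), params$aa)
  t_conc <- pool_conc_of(state, params, "transporter", "transporter") /
    length(params$aa)
  pools <- transporter_pools(params$aa, rep(t_conc, length(params$aa)),
                             rep(t_conc, length(params$aa)))
  supply_fun <- make_supply_fun(params, options, state$media, state$condition,
                                enz_conc, pools)

  if (options$trna_charging) {
    trna_conc <- trna_species_conc(state, params, V)
    rib_conc <- 1e6 * state$rrna_mass / (params$mw$rrna * V)
    syn_conc <- pool_conc_of(state, params, "synthetase", "synthetase") /
      length(params$aa)
    k_rib <- if (options$ppgpp_regulation) {
      ribosome_rate_cap(params$charging, state$ppgpp,
                        options$ppgpp_elongation_inhibition)
    } else {
      # step function at the condition's expected ppGpp (legacy behavior)
      ribosome_rate_cap(params$charging,
                        params$ppgpp_expected[[state$condition]], TRUE)
    }
    chs <- structure(list(species = params$aa,
                          tRNA_charged = state$chi * trna_conc,
                          tRNA_uncharged = (1 - state$chi) * trna_conc,
                          synthetase_conc = stats::setNames(
                            rep(syn_conc, length(params$aa)), params$aa),
                          ribosome_conc = rib_conc,
                          aa_conc = aa_conc,
                          codon_fraction = params$codon_fraction),
                     class = "charging_state")
    relax <- relax_charging(params$charging, chs, supply_fun, dt,
                            couple_supply = options$aa_supply_in_charging,
                            k_rib = k_rib, rtol = 1e-4, atol = 1e-6)
    v_elong <- relax$v_elongation
    aa_amount <- relax$state$aa_conc * V
    chi_new <- ifelse(trna_conc > 0,
                      relax$state$tRNA_charged / trna_conc, state$chi)
    d_protein <- sum(v_elong) * dt * params$mw$aa * V / 1e6
    charging_out <- relax
  } else {
    mu <- log(2) / params$tau[[state$condition]]
    d_protein <- mu * protein_mass * dt
    v_elong <- params$demand[[state$condition]]
    sup <- supply_fun(aa_conc)
    aa_amount <- pmax(state$aa_amount + dt * (sup - v_elong) * V, 0)
    chi_new <- state$chi
    k_rib <- params$charging$k_rib_max
    charging_out <- NULL
  }

  # new tRNA arrives uncharged: charged amount conserved through mass growth
  chi_new <- chi_new * state$trna_mass / trna_mass_new

  # --- (4) ppGpp -------------------------------------------------------------
  ppgpp <- state$ppgpp
  if (!is.null(options$ppgpp_clamp)) {
    delta <- options$ppgpp_clamp - ppgpp
    ppgpp <- ppgpp + sign(delta) * min(abs(delta), options$ppgpp_ramp * dt)
  } else if (options$ppgpp_regulation && options$trna_charging) {
    occ <- ribosome_occupancy(params$charging, charging_out$state,
                              v_elong, k_rib)
    rela <- rela_rate(params$ppgpp, occ,
                      pool_conc_of(state, params, "rela", "rela"))
    spot <- spot_rates(params$ppgpp,
                       pool_conc_of(state, params, "spot", "spot"),
                       ppgpp, charging_out$state$tRNA_uncharged)
    ppgpp <- max(0, ppgpp + dt * ppgpp_derivative(params$ppgpp, rela, spot))
  }

  # --- (5) pools: allocate translation output by mRNA shares -----------------
  psi <- mrna_by_class / sum(mrna_by_class)
  protein_by_class <- state$protein_by_class + d_protein * psi

  new_state <- state
  new_state$time <- state$time + dt
  new_state$protein_by_class <- protein_by_class
  new_state$mrna_by_class <- mrna_by_class
  new_state$rrna_mass <- rrna_mass
  new_state$trna_mass <- trna_mass_new
  new_state$aa_amount <- aa_amount
  new_state$chi <- pmin(pmax(chi_new, 0), 1)
  new_state$ppgpp <- ppgpp
  new_state$deg_mass_last <- deg_mass

  bad <- c(new_state$protein_by_class, new_state$mrna_by_class,
           new_state$rrna_mass, new_state$trna_mass, new_state$aa_amount,
           new_state$ppgpp)
  if (any(!is.finite(bad)) || any(bad < 0))
    stop_domain("cell_step: negative or non-finite state at t = ",
                new_state$time)

  mass_old <- protein_mass + rna_mass
  new_rna <- sum(mrna_by_class) + rrna_mass + trna_mass_new
  mass_new <- sum(protein_by_class) + new_rna
  V_new <- cell_volume(new_state, params)
  diag <- c(
    time = new_state$time,
    growth = (mass_new - mass_old) / (mass_old * dt),
    protein_mass = sum(protein_by_class),
    rna_mass = new_rna,
    rna_protein = new_rna / sum(protein_by_class),
    mrna_rrna = sum(mrna_by_class) / rrna_mass,
    ppgpp = ppgpp,
    rna_deg_rate = deg_mass / (rna_mass * dt),
    elong_total = sum(v_elong),
    chi_mean = mean(new_state$chi),
    stats::setNames(as.numeric(aa_amount) / V_new, paste0("aa_", params$aa)),
    stats::setNames(as.numeric(new_state$chi), paste0("chi_", params$aa)))
  list(state = new_state, diag = diag)
}

trna_species_conc <- function(state, params, V) {
  1e6 * state$trna_mass * params$codon_fraction / (params$mw$trna * V)
}

# Precomputed flat-closure version of supply_rate + exchange_rate; the
# returned function is called inside the charging Newton iterations, so it
# avoids names, constructors and validation.  Equivalence with the public
# rate laws is covered by a test.
make_supply_fun <- function(params, options, media, condition, enz_conc,
                            pools) {
  n <- length(params$aa)
  if (!options$mechanistic_translation_supply) {
    ph <- params$pheno
    base <- as.numeric(params$v_supply_media[[condition]])
    c1 <- as.numeric(ph$c1); c2 <- as.numeric(ph$c2)
    KI <- as.numeric(ph$K_I); KM <- as.numeric(ph$K_M)
    present <- as.numeric(media[params$aa])
    return(function(aa_conc) {
      aa <- pmax(aa_conc, 0)
      (c1 + 1 / (1 + aa / KI) + present * c2 - aa / (KM + aa)) * base
    })
  }
  kin <- params$kinetics
  net <- params$net
  kfE <- as.numeric(kin$kcat_f) * as.numeric(enz_conc)
  KIeff <- as.numeric(kin$K_I) * as.numeric(kin$inhibition_scale)
  klE <- as.numeric(kin$kcat_loss) * as.numeric(enz_conc)
  KMloss <- as.numeric(kin$K_M_loss)
  has_loss <- net$loss_kind != "none"
  idx <- stats::setNames(seq_len(n), params$aa)
  ups <- lapply(params$aa, function(a) unname(idx[net$upstream[[a]]]))
  kmu <- lapply(params$aa, function(a) as.numeric(kin$K_M_up[[a]][net$upstream[[a]]]))
  children <- lapply(params$aa, function(a) unname(idx[net$downstream[[a]]]))
  use_transport <- options$mechanistic_aa_transport
  tp <- params$transport
  can_import <- as.logical(media[params$aa]) & as.logical(tp$importable)
  kimT <- as.numeric(tp$kcat_im) * as.numeric(pools$T_im)
  KIim <- as.numeric(tp$K_I_im)
  kexT <- as.numeric(tp$kcat_ex) * as.numeric(pools$T_ex)
  KMex <- as.numeric(tp$K_M_ex)
  loss_mask <- as.numeric(has_loss)
  import_mask <- as.numeric(can_import)
  function(aa_conc) {
    aa <- pmax(aa_conc, 0)
    synth <- numeric(n)
    down <- numeric(n)
    for (i in seq_len(n)) {
      up <- 1
      u <- ups[[i]]
      if (length(u) > 0) up <- prod(aa[u] / (aa[u] + kmu[[i]]))
      synth[i] <- kfE[i] / (1 + aa[i] / KIeff[i]) * up
    }
    for (i in seq_len(n)) {
      ch <- children[[i]]
      if (length(ch) > 0) down[i] <- sum(synth[ch])
    }
    out <- synth - down - loss_mask * klE * aa / (aa + KMloss)
    if (use_transport)
      out <- out + import_mask * kimT / (1 + aa / KIim) -
        kexT * aa / (aa + KMex)
    out
  }
}

#' Mass-based growth rate
#'
#' `growth = (mass_t1 - mass_t) / (mass_t * dt)`.
#'
#' @param mass_t,mass_t1 Masses at the start and end of the step.
#' @param dt Timestep (s).
#' @return Growth rate (1/s).
#' @export
growth_rate <- function(mass_t, mass_t1, dt) {
  check_pos(mass_t, "mass_t")
  (mass_t1 - mass_t) / (mass_t * dt)
}

#' RNA degradation rate
#'
#' `rate = mass_deg / (mass_rna * dt)`.
#'
#' @param mass_deg RNA mass degraded during the step (fg).
#' @param mass_rna Total RNA mass (fg), `> 0`.
#' @param dt Timestep (s).
#' @return Degradation rate (1/s).
#' @export
rna_degradation_rate <- function(mass_deg, mass_rna, dt) {
  check_pos(mass_rna, "mass_rna")
  mass_deg / (mass_rna * dt)
}

#' Ribosome and enzyme capacities
#'
#' Ribosome capacity `k_rib_max * (N_active + N_inactive)` (all ribosomes
#' counted) and enzyme capacity `sum_AA kcat_f,AA * N_enz,AA`, in counts/s.
#' Normalization to a reference condition is the caller's business.
#'
#' @param state A [cell_state()].
#' @param params A [host_params()].
#' @return List with `ribosome` and `enzyme` capacities (1/s, count basis).
#' @export
capacities <- function(state, params) {
  V <- cell_volume(state, params)
  n_rib <- 1e6 * state$rrna_mass / (params$mw$rrna * V) * V * COUNTS_PER_UM_FL
  enz_counts <- vapply(paste0("enzyme_", params$aa), function(cl)
    pool_conc_of(state, params, cl, "enzyme"), 0) * V * COUNTS_PER_UM_FL
  list(ribosome = params$charging$k_rib_max * n_rib,
       enzyme = sum(params$kinetics$kcat_f * enz_counts))
}

#' GTPase and allosteric inhibition metrics
#'
#' GTPase inhibition `1 - 1/(1 + (ppGpp/K_I)^H)` and per-pathway allosteric
#' inhibition `1 - 1/(1 + AA/K_I)` (using the effective, possibly scaled,
#' inhibition constant), averaged over amino acids.
#'
#' @param state A [cell_state()].
#' @param params A [host_params()].
#' @return List with `gtpase` (scalar) and `allosteric` (mean over pathways)
#'   plus `allosteric_by_aa`.
#' @export
inhibition_metrics <- function(state, params) {
  V <- cell_volume(state, params)
  aa_conc <- state$aa_amount / V
  gtpase <- 1 - 1 / (1 + (state$ppgpp / params$charging$K_I_GTPase)^
                       params$charging$H)
  K_eff <- params$kinetics$K_I * params$kinetics$inhibition_scale
  allo <- 1 - inhib(aa_conc, K_eff)
  list(gtpase = gtpase, allosteric = mean(allo), allosteric_by_aa = allo)
}

#' Run a simulation with optional media shifts
#'
#' Steps the cell from its current state, switching media at scheduled times,
#' and collects the per-step diagnostics.
#'
#' @param state A [cell_state()].
#' @param options A [sim_options()].
#' @param params A [host_params()].
#' @param t_end End time (s).
#' @param schedule Optional data.frame with columns `time`, `media`
#'   (condition labels, strictly increasing times).
#' @return List with `series` (data.frame of diagnostics) and `state`
#'   (final).
#' @export
run_simulation <- function(state, options, params, t_end, schedule = NULL) {
  if (!is.null(schedule)) {
    if (is.unsorted(schedule$time, strictly = TRUE))
      stop_domain("schedule times must be strictly increasing")
    unknown <- setdiff(schedule$media, names(params$media))
    if (length(unknown) > 0)
      stop_domain("unknown media label(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(options$seed)
  n_steps <- ceiling((t_end - state$time) / options$dt)
  rows <- NULL
  next_shift <- 1L
  for (i in seq_len(n_steps)) {
    if (!is.null(schedule) && next_shift <= nrow(schedule) &&
        state$time >= schedule$time[next_shift]) {
      lab <- schedule$media[next_shift]
      state$media <- params$media[[lab]]
      state$condition <- lab
      next_shift <- next_shift + 1L
    }
    res <- cell_step(state, options, params)
    state <- res$state
    if (is.null(rows))
      rows <- matrix(NA_real_, n_steps, length(res$diag),
                     dimnames = list(NULL, names(res$diag)))
    rows[i, ] <- res$diag
  }
  list(series = as.data.frame(rows), state = state)
}

#' Media-shift experiment
#'
#' Initializes the cell in the first scheduled medium and runs through the
#' full schedule.
#'
#' @param params A [host_params()].
#' @param options A [sim_options()].
#' @param schedule data.frame with columns `time`, `media`; the first row
#'   must start at time 0 and defines the initial condition.
#' @param t_end End time (s).
#' @return List with `series` and final `state` as in [run_simulation()].
#' @export
run_shift_experiment <- function(params, options, schedule, t_end) {
  state <- cell_state(params, schedule$media[1])
  run_simulation(state, options, params, t_end, schedule = schedule)
}
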