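# Single-step amino-acid biosynthesis network: every amino acid is reached in
# one lumped reaction from its precursor amino acid(s), with glutamate treated
# as the root upstream of all pathways.  Rates follow saturating
# Michaelis-Menten forms with allosteric end-product inhibition, and the
# forward/loss rate constants are fitted against mass balances at two anchor
# growth conditions (minimal and rich media).

#' Amino-acid network topology
#'
#' Defines the single-step reaction network over amino acids: a set of directed
#' edges (precursor -> product) forming a DAG rooted at one amino acid
#' (biologically, glutamate), plus an optional loss reaction per amino acid.
#'
#' @param amino_acids Character vector of amino-acid identifiers (ordered).
#' @param edges Two-column matrix or data.frame of directed edges
#'   (from = precursor, to = product).
#' @param root Identifier of the root amino acid, upstream of all pathways.
#' @param loss_kind Named character vector over amino acids, each one of
#'   `"none"`, `"reverse"` or `"degradation"`.  At most one loss reaction per
#'   amino acid is representable.  Defaults to `"none"` for all.
#' @return An object of class `aa_network` with `upstream` and `downstream`
#'   adjacency lists (exact inverses of each other).
#' @export
aa_network <- function(amino_acids, edges = NULL, root = amino_acids[[1]],
                       loss_kind = NULL) {
  stopifnot(is.character(amino_acids), length(amino_acids) >= 1,
            !anyDuplicated(amino_acids))
  if (!root %in% amino_acids)
    stop_domain("root '", root, "' is not among the amino acids")
  if (is.null(loss_kind)) {
    loss_kind <- stats::setNames(rep("none", length(amino_acids)), amino_acids)
  } else {
    loss_kind <- align_ids(loss_kind, amino_acids, "loss_kind")
    bad <- setdiff(unique(loss_kind), c("none", "reverse", "degradation"))
    if (length(bad) > 0)
      stop_domain("loss_kind must be one of none/reverse/degradation, got: ",
                  paste(bad, collapse = ", "))
  }
  upstream <- stats::setNames(vector("list", length(amino_acids)), amino_acids)
  downstream <- upstream
  for (aa in amino_acids) {
    upstream[[aa]] <- character()
    downstream[[aa]] <- character()
  }
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
    unknown <- setdiff(unique(c(edges$from, edges$to)), amino_acids)
    if (length(unknown) > 0)
      stop_domain("edges reference unknown amino acid(s): ",
                  paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(edges))) {
      upstream[[edges$to[i]]] <- union(upstream[[edges$to[i]]], edges$from[i])
      downstream[[edges$from[i]]] <- union(downstream[[edges$from[i]]], edges$to[i])
    }
  }
  net <- structure(list(amino_acids = amino_acids, root = root,
                        upstream = upstream, downstream = downstream,
                        loss_kind = loss_kind),
                   class = "aa_network")
  ord <- topo_order(net)  # errors on cycles
  # reachability from root (root itself trivially reachable)
  reach <- root
  repeat {
    nxt <- unique(unlist(downstream[reach], use.names = FALSE))
    new <- setdiff(nxt, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  if (!setequal(reach, amino_acids))
    stop_domain("network not reachable from root: ",
                paste(setdiff(amino_acids, reach), collapse = ", "))
  net$topo_order <- ord
  net
}

# Kahn topological order (root-first); errors on cycles.
topo_order <- function(net) {
  ids <- net$amino_acids
  indeg <- vapply(net$upstream[ids], length, integer(1))
  queue <- ids[indeg == 0]
  out <- character()
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, v)
    for (w in net$downstream[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids))
    stop_domain("forward edges contain a cycle")
  out
}

#' Kinetic constants of the biosynthesis network
#'
#' @param net An [aa_network()].
#' @param kcat_f,kcat_loss Named per-AA forward and loss rate constants (1/s),
#'   `>= 0`.
#' @param K_I Named per-AA allosteric end-product inhibition constants (uM).
#' @param K_M_up Named list: for each amino acid, a named vector of Michaelis
#'   constants (uM) over its upstream amino acids.
#' @param K_M_loss Named per-AA Michaelis constants of the loss reaction (uM);
#'   ignored where `loss_kind == "none"`.
#' @param inhibition_scale Named per-AA multiplier on `K_I` (`1` = wildtype,
#'   `Inf` = inhibition removed); must be `>= 1`.
#' @return An object of class `aa_kinetics`.
#' @export
aa_kinetics <- function(net, kcat_f, kcat_loss, K_I, K_M_up, K_M_loss,
                        inhibition_scale = NULL) {
  ids <- net$amino_acids
  kcat_f <- align_ids(kcat_f, ids, "kcat_f")
  kcat_loss <- align_ids(kcat_loss, ids, "kcat_loss")
  K_I <- align_ids(K_I, ids, "K_I")
  K_M_loss <- align_ids(K_M_loss, ids, "K_M_loss")
  check_nonneg(kcat_f, "kcat_f"); check_nonneg(kcat_loss, "kcat_loss")
  check_pos(K_I, "K_I")
  for (aa in ids) {
    ups <- net$upstream[[aa]]
    if (length(ups) > 0) {
      if (is.null(K_M_up[[aa]]))
        stop_domain("K_M_up missing for ", aa)
      K_M_up[[aa]] <- align_ids(K_M_up[[aa]], ups, paste0("K_M_up[", aa, "]"))
      check_pos(K_M_up[[aa]], paste0("K_M_up[", aa, "]"))
    } else K_M_up[[aa]] <- stats::setNames(numeric(0), character(0))
    if (net$loss_kind[[aa]] != "none") check_pos(K_M_loss[[aa]], "K_M_loss")
  }
  if (is.null(inhibition_scale))
    inhibition_scale <- stats::setNames(rep(1, length(ids)), ids)
  inhibition_scale <- align_ids(inhibition_scale, ids, "inhibition_scale")
  if (any(inhibition_scale < 1))
    stop_domain("inhibition_scale must be >= 1")
  structure(list(kcat_f = kcat_f, kcat_loss = kcat_loss, K_I = K_I,
                 K_M_up = K_M_up[ids], K_M_loss = K_M_loss,
                 inhibition_scale = inhibition_scale),
            class = "aa_kinetics")
}

#' Anchor-condition table
#'
#' Per-condition concentrations, pooled enzyme levels, translation demand and
#' literature priors used to parameterize the biosynthesis network.
#'
#' @param name Condition label (e.g. `"minimal"`, `"rich"`).
#' @param aa Amino-acid identifiers.
#' @param conc_uM Amino-acid concentrations (uM).
#' @param enzyme_uM Pooled biosynthesis enzyme concentrations (uM).
#' @param demand_uM_per_s Translation supply demand S (uM/s).
#' @param exchange_lit_uM_per_s Literature uptake rates (uM/s); default 0.
#' @param kcat_lit_per_s Literature forward rate constants (1/s); default 1.
#' @return A data.frame of class `condition_table` with a `name` attribute.
#' @export
condition_table <- function(name, aa, conc_uM, enzyme_uM, demand_uM_per_s,
                            exchange_lit_uM_per_s = 0, kcat_lit_per_s = 1) {
  df <- data.frame(aa = aa, conc_uM = conc_uM, enzyme_uM = enzyme_uM,
                   demand_uM_per_s = demand_uM_per_s,
                   exchange_lit_uM_per_s = rep_len(exchange_lit_uM_per_s, length(aa)),
                   kcat_lit_per_s = rep_len(kcat_lit_per_s, length(aa)),
                   stringsAsFactors = FALSE)
  check_nonneg(df$conc_uM, "conc_uM"); check_nonneg(df$enzyme_uM, "enzyme_uM")
  check_nonneg(df$demand_uM_per_s, "demand_uM_per_s")
  rownames(df) <- NULL
  attr(df, "name") <- name
  class(df) <- c("condition_table", class(df))
  df
}

cond_vec <- function(cond, col, ids) {
  align_ids(stats::setNames(cond[[col]], cond$aa), ids, col)
}

#' Amino-acid synthesis rates
#'
#' Saturating forward rate with allosteric end-product inhibition and a
#' multiplicative saturation term for each upstream (precursor) amino acid:
#' `v_synth = kcat_f * E / (1 + AA/(scale*K_I)) * prod_j AA_j/(AA_j + K_M_j)`.
#' An upstream amino acid at zero concentration drives its factor to zero.
#'
#' @param net An [aa_network()].
#' @param kin An [aa_kinetics()].
#' @param aa_conc Named per-AA concentrations (uM).
#' @param enzyme_conc Named per-AA pooled enzyme concentrations (uM).
#' @return Named per-AA synthesis rates (uM/s).
#' @export
synthesis_rate <- function(net, kin, aa_conc, enzyme_conc) {
  ids <- net$amino_acids
  aa_conc <- align_ids(aa_conc, ids, "aa_conc")
  enzyme_conc <- align_ids(enzyme_conc, ids, "enzyme_conc")
  check_nonneg(aa_conc, "aa_conc"); check_nonneg(enzyme_conc, "enzyme_conc")
  v <- stats::setNames(numeric(length(ids)), ids)
  for (aa in ids) {
    up <- 1
    ups <- net$upstream[[aa]]
    if (length(ups) > 0)
      up <- prod(sat(aa_conc[ups], kin$K_M_up[[aa]][ups]))
    v[[aa]] <- kin$kcat_f[[aa]] * enzyme_conc[[aa]] *
      inhib(aa_conc[[aa]], kin$inhibition_scale[[aa]] * kin$K_I[[aa]]) * up
  }
  v
}

#' Downstream and loss rates
#'
#' `v_down,i` sums the synthesis rates of the immediate downstream amino acids
#' (single-step abstraction, applied literally); `v_loss,i` is the reverse or
#' degradation Michaelis-Menten loss where one exists.
#'
#' @inheritParams synthesis_rate
#' @param v_synth Named per-AA synthesis rates, as from [synthesis_rate()].
#' @return List with named per-AA vectors `v_down` and `v_loss` (uM/s).
#' @export
loss_rates <- function(net, kin, aa_conc, enzyme_conc, v_synth) {
  ids <- net$amino_acids
  aa_conc <- align_ids(aa_conc, ids, "aa_conc")
  enzyme_conc <- align_ids(enzyme_conc, ids, "enzyme_conc")
  v_synth <- align_ids(v_synth, ids, "v_synth")
  v_down <- stats::setNames(numeric(length(ids)), ids)
  v_loss <- v_down
  for (aa in ids) {
    dn <- net$downstream[[aa]]
    if (length(dn) > 0) v_down[[aa]] <- sum(v_synth[dn])
    if (net$loss_kind[[aa]] != "none")
      v_loss[[aa]] <- kin$kcat_loss[[aa]] * enzyme_conc[[aa]] *
        sat(aa_conc[[aa]], kin$K_M_loss[[aa]])
  }
  list(v_down = v_down, v_loss = v_loss)
}

#' Net supply rate to translation
#'
#' `v_supply = v_synth - v_down - v_loss + v_exchange`; may be negative (net
#' drain).
#'
#' @inheritParams synthesis_rate
#' @param v_exchange Named per-AA net exchange rates (uM/s), import positive.
#' @return Named per-AA supply rates (uM/s).
#' @export
supply_rate <- function(net, kin, aa_conc, enzyme_conc, v_exchange) {
  ids <- net$amino_acids
  v_exchange <- align_ids(v_exchange, ids, "v_exchange")
  v_synth <- synthesis_rate(net, kin, aa_conc, enzyme_conc)
  l <- loss_rates(net, kin, aa_conc, enzyme_conc, v_synth)
  v_synth - l$v_down - l$v_loss + v_exchange
}

#' Default Michaelis and inhibition constants
#'
#' Where no curated value exists, upstream `K_M` equal the minimal-media
#' concentration of the precursor (high dynamic range), loss `K_M` equal 10x
#' the minimal-media concentration (limited loss at physiological levels), and
#' `K_I` equals the minimal-media concentration clamped into curated bounds
#' when bounds are reported.
#'
#' @param net An [aa_network()].
#' @param minimal_conc Named per-AA minimal-media concentrations (uM), `> 0`.
#' @param curated Optional list with entries `K_M_up` (named list like
#'   [aa_kinetics()]), `K_M_loss` (named vector) and `K_I_bounds` (named list
#'   of `c(lo, hi)` per AA).
#' @return List with `K_I`, `K_M_up`, `K_M_loss` filled for every amino acid.
#' @export
assign_default_constants <- function(net, minimal_conc, curated = list()) {
  ids <- net$amino_acids
  minimal_conc <- align_ids(minimal_conc, ids, "minimal_conc")
  check_pos(minimal_conc, "minimal_conc")
  K_M_up <- stats::setNames(vector("list", length(ids)), ids)
  for (aa in ids) {
    ups <- net$upstream[[aa]]
    km <- stats::setNames(minimal_conc[ups], ups)
    cur <- curated$K_M_up[[aa]]
    if (!is.null(cur)) km[names(cur)] <- cur
    K_M_up[[aa]] <- km
  }
  K_M_loss <- 10 * minimal_conc
  if (!is.null(curated$K_M_loss))
    K_M_loss[names(curated$K_M_loss)] <- curated$K_M_loss
  K_I <- minimal_conc
  for (aa in names(curated$K_I_bounds %||% list())) {
    b <- curated$K_I_bounds[[aa]]
    if (length(b) != 2 || b[1] > b[2])
      stop_domain("empty K_I bounds interval for ", aa)
    K_I[[aa]] <- min(max(minimal_conc[[aa]], b[1]), b[2])
  }
  list(K_I = K_I, K_M_up = K_M_up, K_M_loss = K_M_loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit forward/loss rate constants and exchange rates
#'
#' Solves, per amino acid, the two steady-state mass balances linking
#' synthesis, loss and translation demand at the minimal and rich anchor
#' conditions (exchange appears only on the rich side), choosing among the
#' feasible nonnegative solutions the one minimizing
#' `1000*||v_ex - v_ex_lit||^2 + ||kcat_f - kcat_lit||^2 + ||kcat_loss||^2`.
#' Amino acids are processed in reverse topological order so each balance only
#' involves already-fitted downstream forward constants; each subproblem is a
#' box-constrained quadratic solved in closed form, so the balance residuals
#' are zero up to round-off.
#'
#' @param net An [aa_network()].
#' @param constants List with `K_I`, `K_M_up`, `K_M_loss` (see
#'   [assign_default_constants()]).
#' @param cond_minimal,cond_rich [condition_table()]s covering every AA.
#' @param weight Weight on the exchange deviation term (default 1000).
#' @return List with `kinetics` (an [aa_kinetics()]), `v_exchange` (named
#'   per-AA uM/s, the rich-media exchange) and `residuals` (data.frame of
#'   per-AA balance violations at both conditions).
#' @export
fit_kcats_and_exchange <- function(net, constants, cond_minimal, cond_rich,
                                   weight = 1000) {
  ids <- net$amino_acids
  conc_min <- cond_vec(cond_minimal, "conc_uM", ids)
  conc_rich <- cond_vec(cond_rich, "conc_uM", ids)
  enz_min <- cond_vec(cond_minimal, "enzyme_uM", ids)
  enz_rich <- cond_vec(cond_rich, "enzyme_uM", ids)
  S_min <- cond_vec(cond_minimal, "demand_uM_per_s", ids)
  S_rich <- cond_vec(cond_rich, "demand_uM_per_s", ids)
  vex_lit <- cond_vec(cond_rich, "exchange_lit_uM_per_s", ids)
  kcat_lit <- cond_vec(cond_rich, "kcat_lit_per_s", ids)

  zero <- stats::setNames(numeric(length(ids)), ids)
  kcat_f <- zero; kcat_loss <- zero; v_ex <- zero

  # saturation-weighted capacities C = v/kcat at each condition
  cap_synth <- function(aa, conc, enz) {
    up <- 1
    ups <- net$upstream[[aa]]
    if (length(ups) > 0) up <- prod(sat(conc[ups], constants$K_M_up[[aa]][ups]))
    enz[[aa]] * inhib(conc[[aa]], constants$K_I[[aa]]) * up
  }
  cap_loss <- function(aa, conc, enz) {
    if (net$loss_kind[[aa]] == "none") return(0)
    enz[[aa]] * sat(conc[[aa]], constants$K_M_loss[[aa]])
  }

  ord <- rev(net$topo_order)
  for (aa in ord) {
    dn <- net$downstream[[aa]]
    vdown_min <- if (length(dn)) sum(kcat_f[dn] * vapply(dn, cap_synth, 0,
                                     conc = conc_min, enz = enz_min)) else 0
    vdown_rich <- if (length(dn)) sum(kcat_f[dn] * vapply(dn, cap_synth, 0,
                                      conc = conc_rich, enz = enz_rich)) else 0
    Cs_min <- cap_synth(aa, conc_min, enz_min)
    Cs_rich <- cap_synth(aa, conc_rich, enz_rich)
    Cl_min <- cap_loss(aa, conc_min, enz_min)
    Cl_rich <- cap_loss(aa, conc_rich, enz_rich)
    rhs_min <- S_min[[aa]] + vdown_min
    if (Cs_min <= 0) {
      if (abs(rhs_min) > 1e-12)
        stop_domain("fit_kcats_and_exchange: infeasible for '", aa,
                    "': zero minimal-media synthesis capacity but demand ",
                    signif(rhs_min, 4), " uM/s")
      alpha <- 0; beta <- 0
    } else {
      alpha <- rhs_min / Cs_min           # kcat_f = alpha + beta * kcat_loss
      beta <- Cl_min / Cs_min
    }
    gam <- S_rich[[aa]] + vdown_rich - alpha * Cs_rich  # v_ex = gam + del * kl
    del <- Cl_rich - beta * Cs_rich
    if (net$loss_kind[[aa]] == "none") {
      kl <- 0
    } else {
      # minimize w*(gam + del*kl - vl)^2 + (alpha + beta*kl - kc)^2 + kl^2
      a2 <- weight * del^2 + beta^2 + 1
      a1 <- weight * del * (gam - vex_lit[[aa]]) + beta * (alpha - kcat_lit[[aa]])
      kl <- max(0, -a1 / a2)
    }
    kf <- alpha + beta * kl
    if (kf < 0)
      stop_domain("fit_kcats_and_exchange: infeasible for '", aa,
                  "': forward kcat forced negative (", signif(kf, 4), ")")
    kcat_f[[aa]] <- kf
    kcat_loss[[aa]] <- kl
    v_ex[[aa]] <- gam + del * kl
  }

  kin <- aa_kinetics(net, kcat_f, kcat_loss, constants$K_I,
                     constants$K_M_up, constants$K_M_loss)
  res_min <- supply_rate(net, kin, conc_min, enz_min, zero) - S_min
  res_rich <- supply_rate(net, kin, conc_rich, enz_rich, v_ex) - S_rich
  list(kinetics = kin, v_exchange = v_ex,
       residuals = data.frame(aa = ids, minimal = as.numeric(res_min),
                              rich = as.numeric(res_rich)))
}
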