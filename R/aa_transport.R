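# Mechanistic amino-acid transport: saturating import inhibited by the
# internal pool (K_I set to the rich-media concentration, so uptake falls as
# the pool fills) and Michaelis-Menten export calibrated so that net exchange
# vanishes when the internal concentration equals the export K_M.

#' Transport kinetic parameters
#'
#' @param aa Amino-acid identifiers.
#' @param kcat_im,kcat_ex Named per-AA import/export rate constants (1/s).
#' @param K_I_im Named per-AA import inhibition constants (uM); by calibration
#'   convention equal to the rich-media concentration.
#' @param K_M_ex Named per-AA export Michaelis constants (uM).
#' @param importable Named per-AA logical; `FALSE` for amino acids without a
#'   dedicated importer (cysteine), which forces `kcat_im = 0`.
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(aa, kcat_im, kcat_ex, K_I_im, K_M_ex,
                             importable = NULL) {
  if (is.null(importable)) importable <- stats::setNames(rep(TRUE, length(aa)), aa)
  p <- list(aa = aa,
            kcat_im = align_ids(kcat_im, aa, "kcat_im"),
            kcat_ex = align_ids(kcat_ex, aa, "kcat_ex"),
            K_I_im = align_ids(K_I_im, aa, "K_I_im"),
            K_M_ex = align_ids(K_M_ex, aa, "K_M_ex"),
            importable = align_ids(importable, aa, "importable"))
  check_nonneg(p$kcat_im, "kcat_im"); check_nonneg(p$kcat_ex, "kcat_ex")
  check_pos(p$K_I_im, "K_I_im"); check_pos(p$K_M_ex, "K_M_ex")
  p$kcat_im[!p$importable] <- 0
  structure(p, class = "transport_params")
}

#' Pooled transporter concentrations
#'
#' Multiple transporters acting on the same amino acid are summed into one
#' pool sharing a single parameter set.
#'
#' @param aa Amino-acid identifiers.
#' @param T_im,T_ex Named per-AA pooled importer/exporter concentrations (uM).
#' @return Object of class `transporter_pools`.
#' @export
transporter_pools <- function(aa, T_im, T_ex) {
  p <- list(aa = aa, T_im = align_ids(T_im, aa, "T_im"),
            T_ex = align_ids(T_ex, aa, "T_ex"))
  check_nonneg(p$T_im, "T_im"); check_nonneg(p$T_ex, "T_ex")
  structure(p, class = "transporter_pools")
}

#' Net exchange rate (import minus export)
#'
#' Import is active only when the amino acid is present in the media and the
#' amino acid has an importer; when absent from the media, import is zero and
#' export remains mechanistic.
#'
#' @param params A [transport_params()].
#' @param pools A [transporter_pools()].
#' @param aa_conc Named per-AA internal concentrations (uM).
#' @param media Named per-AA logical presence flags.
#' @return Named per-AA net exchange rates (uM/s), import positive.
#' @export
exchange_rate <- function(params, pools, aa_conc, media) {
  ids <- params$aa
  aa_conc <- align_ids(aa_conc, ids, "aa_conc")
  media <- align_ids(media, ids, "media")
  check_nonneg(aa_conc, "aa_conc")
  v_import <- ifelse(media & params$importable,
                     params$kcat_im * pools$T_im * inhib(aa_conc, params$K_I_im),
                     0)
  v_export <- params$kcat_ex * pools$T_ex * sat(aa_conc, params$K_M_ex)
  stats::setNames(as.numeric(v_import - v_export), ids)
}

#' Impute missing export Michaelis constants
#'
#' Missing export `K_M` are estimated from the mean ratio of curated `K_M` to
#' the minimal-media concentration: `factor = mean(K_M_i / AA_i)` over curated
#' amino acids, then `K_M_j = factor * AA_j` for the rest.
#'
#' @param known Named vector of curated export `K_M` (uM); a subset of the
#'   amino acids in `minimal_conc`.
#' @param minimal_conc Named per-AA minimal-media concentrations (uM).
#' @return Named per-AA export `K_M` covering every amino acid.
#' @export
estimate_missing_export_km <- function(known, minimal_conc) {
  if (length(known) == 0)
    stop_domain("estimate_missing_export_km: no curated K_M values")
  unknown_ids <- setdiff(names(known), names(minimal_conc))
  if (length(unknown_ids) > 0)
    stop_domain("curated K_M for unknown amino acid(s): ",
                paste(unknown_ids, collapse = ", "))
  check_pos(minimal_conc, "minimal_conc")
  factor <- mean(known / minimal_conc[names(known)])
  out <- factor * minimal_conc
  out[names(known)] <- known
  out
}

#' Calibrate import/export rate constants
#'
#' Per amino acid, solves the 2x2 linear system pinning the exchange law at
#' two points: at rich-media concentrations the net exchange equals the rate
#' fitted by [fit_kcats_and_exchange()], and at an internal concentration
#' equal to the export `K_M` the net exchange is zero (the curation convention
#' defining `K_M`).  Negative algebraic solutions are clipped to zero with a
#' warning.
#'
#' @param params A [transport_params()] whose kcats are ignored.
#' @param pools A [transporter_pools()]; must be positive where the target
#'   exchange is nonzero.
#' @param rich_conc Named per-AA rich-media internal concentrations (uM).
#' @param v_exchange_fit Named per-AA target exchange rates at rich
#'   concentrations (uM/s).
#' @return A [transport_params()] with fitted `kcat_im`, `kcat_ex`.
#' @export
fit_transport_kcats <- function(params, pools, rich_conc, v_exchange_fit) {
  ids <- params$aa
  rich_conc <- align_ids(rich_conc, ids, "rich_conc")
  v_exchange_fit <- align_ids(v_exchange_fit, ids, "v_exchange_fit")
  kcat_im <- stats::setNames(numeric(length(ids)), ids)
  kcat_ex <- kcat_im
  clipped <- character()
  for (aa in ids) {
    ge_rich <- sat(rich_conc[[aa]], params$K_M_ex[[aa]])
    if (!params$importable[[aa]]) {
      # export-only species (cysteine): the zero-crossing condition cannot
      # hold with nonzero export, so the rich condition alone fixes kcat_ex
      denom <- pools$T_ex[[aa]] * ge_rich
      if (denom <= 0) {
        if (abs(v_exchange_fit[[aa]]) < 1e-12) next
        stop_domain("fit_transport_kcats: singular system for '", aa,
                    "' (zero transporter pools with nonzero target exchange)")
      }
      k_ex <- -v_exchange_fit[[aa]] / denom
      if (k_ex < 0) { clipped <- c(clipped, aa); k_ex <- 0 }
      kcat_ex[[aa]] <- k_ex
      next
    }
    gi_rich <- inhib(rich_conc[[aa]], params$K_I_im[[aa]])
    gi_km <- inhib(params$K_M_ex[[aa]], params$K_I_im[[aa]])
    ge_km <- 0.5
    M <- rbind(c(pools$T_im[[aa]] * gi_rich, -pools$T_ex[[aa]] * ge_rich),
               c(pools$T_im[[aa]] * gi_km,  -pools$T_ex[[aa]] * ge_km))
    b <- c(v_exchange_fit[[aa]], 0)
    if (abs(det(M)) < 1e-14) {
      if (abs(b[1]) < 1e-12) next  # zero solution admissible
      stop_domain("fit_transport_kcats: singular system for '", aa,
                  "' (zero transporter pools with nonzero target exchange)")
    }
    k <- solve(M, b)
    if (any(k < 0)) {
      clipped <- c(clipped, aa)
      k[k < 0] <- 0
    }
    kcat_im[[aa]] <- k[1]
    kcat_ex[[aa]] <- k[2]
  }
  if (length(clipped) > 0)
    warning("fit_transport_kcats: negative kcat clipped to 0 for: ",
            paste(clipped, collapse = ", "))
  transport_params(ids, kcat_im, kcat_ex, params$K_I_im, params$K_M_ex,
                   params$importable)
}
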