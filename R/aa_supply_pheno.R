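# Phenomenological amino-acid supply: an alternative to the mechanistic
# biosynthesis/transport kinetics that scales a per-condition base rate by a
# concentration-responsive factor.  Two anchor fractions (f_I, f_M) pin the
# inhibited-synthesis contribution at the basal concentration and the export
# contribution at the rich concentration, and the remaining constants follow
# in closed form so that the scaling equals exactly 1 at both anchors.

#' Solve phenomenological supply constants
#'
#' Closed forms: `K_I = f_I*basal/(1-f_I)`, `K_M = (1/f_M - 1)*rich`,
#' `c1 = 1 - (f_I - basal/(K_M+basal))`, and
#' `c2 = 1 - (c1 + 1/(1+rich/K_I) - f_M)`.
#'
#' @param f_I Anchor fraction of the inhibited-synthesis term at the basal
#'   concentration, in (0,1).
#' @param f_M Anchor fraction of the export term at the rich concentration,
#'   in (0,1).
#' @param basal_conc,rich_conc Named per-AA expected concentrations (uM) in
#'   minimal (no amino acids in the environment) and rich media.
#' @return Object of class `pheno_params` with per-AA `c1`, `c2`, `K_I`,
#'   `K_M` and the anchors.
#' @export
solve_pheno_params <- function(f_I, f_M, basal_conc, rich_conc) {
  if (length(f_I) != 1 || length(f_M) != 1 ||
      !is.finite(f_I) || !is.finite(f_M) ||
      f_I <= 0 || f_I >= 1 || f_M <= 0 || f_M >= 1)
    stop_domain("f_I and f_M must be scalars in (0, 1)")
  check_pos(basal_conc, "basal_conc")
  rich_conc <- align_ids(rich_conc, names(basal_conc), "rich_conc")
  check_pos(rich_conc, "rich_conc")
  K_I <- f_I * basal_conc / (1 - f_I)
  K_M <- (1 / f_M - 1) * rich_conc
  c1 <- 1 - (f_I - basal_conc / (K_M + basal_conc))
  c2 <- 1 - (c1 + 1 / (1 + rich_conc / K_I) - f_M)
  structure(list(aa = names(basal_conc), c1 = c1, c2 = c2, K_I = K_I,
                 K_M = K_M, f_I = f_I, f_M = f_M),
            class = "pheno_params")
}

#' Dimensionless supply scaling
#'
#' `f_supply = c1 + 1/(1+AA/K_I) + (c2 if present in media else 0)
#'  - AA/(K_M+AA)`; equals 1 at the basal concentration without amino acids
#' in the media and at the rich concentration with them.
#'
#' @param params A `pheno_params` from [solve_pheno_params()].
#' @param aa_conc Named per-AA concentrations (uM).
#' @param media Named per-AA logical presence flags.
#' @return Named per-AA dimensionless scaling factors.
#' @export
supply_scaling <- function(params, aa_conc, media) {
  ids <- params$aa
  aa_conc <- align_ids(aa_conc, ids, "aa_conc")
  media <- align_ids(media, ids, "media")
  check_nonneg(aa_conc, "aa_conc")
  params$c1 + inhib(aa_conc, params$K_I) + ifelse(media, params$c2, 0) -
    sat(aa_conc, params$K_M)
}

#' Phenomenological supply rate
#'
#' `v_supply = f_supply * v_supply_media` for the active condition.
#'
#' @inheritParams supply_scaling
#' @param v_supply_media Named list of per-AA base supply rates (uM/s), one
#'   entry per condition.
#' @param condition Name of the active condition.
#' @return Named per-AA supply rates (uM/s).
#' @export
pheno_supply_rate <- function(params, v_supply_media, condition, aa_conc, media) {
  if (!condition %in% names(v_supply_media))
    stop_domain("unknown condition '", condition, "'")
  base <- align_ids(v_supply_media[[condition]], params$aa, "v_supply_media")
  supply_scaling(params, aa_conc, media) * base
}
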