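# ppGpp regulation of transcription.  ppGpp binds RNA polymerase with a Hill
# coefficient of 2; free and ppGpp-bound polymerases express each gene at
# different levels, so the bound fraction partitions expression.  The binding
# constant is fitted to a growth-law table (RNA mass fraction, RNAP and ppGpp
# concentrations across doubling times); per-gene free/bound expression levels
# are solved from induced-condition fold changes plus basal expression, and
# basal RNAP recruitment becomes ppGpp-dependent through transcript loss rates
# and gene dosage.

#' ppGpp-RNAP binding model
#'
#' @param K_M_ppgpp Michaelis constant of ppGpp binding RNA polymerase (uM).
#' @param hill Hill exponent; fixed at 2 (multiple interaction sites).
#' @return Object of class `rnap_binding`.
#' @export
rnap_binding <- function(K_M_ppgpp, hill = 2) {
  check_pos(K_M_ppgpp, "K_M_ppgpp")
  if (hill != 2) stop_domain("hill coefficient is fixed at 2")
  structure(list(K_M_ppgpp = K_M_ppgpp, hill = 2), class = "rnap_binding")
}

#' Fraction of RNA polymerase bound to ppGpp
#'
#' `f = C^2 / (K_M^2 + C^2)`.
#'
#' @param binding An [rnap_binding()].
#' @param ppgpp_conc ppGpp concentration(s) (uM), `>= 0`.
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
fraction_bound <- function(binding, ppgpp_conc) {
  check_nonneg(ppgpp_conc, "ppgpp_conc")
  ppgpp_conc^2 / (binding$K_M_ppgpp^2 + ppgpp_conc^2)
}

#' Growth-law calibration table
#'
#' Population-level rows of doubling time, RNA mass fraction, RNAP
#' concentration and ppGpp concentration (the shape of the classic
#' steady-state growth physiology tables).
#'
#' @param doubling_time_min Doubling times (min), `> 0`.
#' @param rna_mass_fraction RNA mass fractions of dry mass.
#' @param rnap_conc_uM RNA polymerase concentrations (uM).
#' @param ppgpp_conc_uM ppGpp concentrations (uM).
#' @return data.frame of class `growth_law_table`.
#' @export
growth_law_table <- function(doubling_time_min, rna_mass_fraction,
                             rnap_conc_uM, ppgpp_conc_uM) {
  check_pos(doubling_time_min, "doubling_time_min")
  df <- data.frame(doubling_time_min = doubling_time_min,
                   rna_mass_fraction = rna_mass_fraction,
                   rnap_conc_uM = rnap_conc_uM,
                   ppgpp_conc_uM = ppgpp_conc_uM)
  class(df) <- c("growth_law_table", class(df))
  df
}

#' Fit the RNAP binding constant to a growth-law table
#'
#' Nonlinear least squares of
#' `RNA_fraction = C_RNAP * ((1-f)*exp_free + f*exp_ppgpp)` with
#' `f = C^2/(K_M^2 + C^2)`, profiled: for each candidate `K_M` the expression
#' levels are the exact linear least-squares solution, and `K_M` minimizes the
#' profiled residual by 1-D optimization in log space.  Deterministic; exact
#' on noiseless planted tables.
#'
#' @param table A [growth_law_table()] with at least 3 rows.
#' @return List with `binding` (an [rnap_binding()]), `exp_free`, `exp_ppgpp`
#'   (aggregate expression per RNAP, table units) and `residual` (RSS).
#' @export
fit_km_rnap <- function(table) {
  if (nrow(table) < 3) stop_domain("fit_km_rnap: need >= 3 rows")
  C <- table$ppgpp_conc_uM
  if (stats::sd(C) == 0)
    stop_domain("fit_km_rnap: degenerate table (constant ppGpp)")
  y <- table$rna_mass_fraction
  R <- table$rnap_conc_uM
  rss_at <- function(logK) {
    f <- C^2 / (exp(2 * logK) + C^2)
    X <- cbind(R * (1 - f), R * f)
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) return(list(rss = Inf, beta = c(NA, NA)))
    list(rss = sum((y - X %*% beta)^2), beta = beta)
  }
  lo <- log(min(C[C > 0]) / 100)
  hi <- log(max(C) * 100)
  grid <- seq(lo, hi, length.out = 41)
  grss <- vapply(grid, function(k) rss_at(k)$rss, 0)
  if (max(grss) - min(grss) <= 1e-12 * max(max(grss), 1))
    stop_domain("fit_km_rnap: K_M unidentifiable (RNA fraction proportional ",
                "to RNAP concentration; exp_free = exp_ppgpp)")
  opt <- stats::optimize(function(k) rss_at(k)$rss,
                         interval = range(grid[order(grss)][1:3]) + c(-1, 1),
                         tol = 1e-12)
  sol <- rss_at(opt$minimum)
  list(binding = rnap_binding(exp(opt$minimum)),
       exp_free = sol$beta[1], exp_ppgpp = sol$beta[2], residual = sol$rss)
}

#' Solve per-gene free/bound expression levels
#'
#' Per gene, solves the 2x2 system given a high-ppGpp induction fold change
#' `FC = log2(exp_ppgpp / ((1-f_rich)*exp_free + f_rich*exp_ppgpp))` and basal
#' expression `exp_basal = (1-f_basal)*exp_free + f_basal*exp_ppgpp`.  Genes
#' whose large positive fold change would force negative free expression are
#' truncated at `exp_free = 0` with `exp_ppgpp` re-solved from the basal
#' relation.  Genes lacking a fold change fall back to `FC_plus` or
#' `FC_minus` by annotated regulation sign.
#'
#' @param FC Per-gene log2 fold changes; `NA` where unmeasured.
#' @param exp_basal Per-gene basal expression, `>= 0`.
#' @param f_rich,f_basal RNAP bound fractions in the induced-reference (rich)
#'   and basal conditions, in `[0, 1]`.
#' @param reg_sign Per-gene regulation sign (+1/-1), used for fallbacks.
#' @param FC_plus Fallback fold change for positively regulated genes;
#'   defaults to the mean measured FC over genes with `reg_sign > 0`.
#' @param FC_minus Fallback fold change for negatively regulated genes
#'   (typically from the aggregate stable-RNA fit); required if needed.
#' @return data.frame with `exp_free`, `exp_ppgpp`, `truncated`.
#' @export
solve_gene_expression <- function(FC, exp_basal, f_rich, f_basal,
                                  reg_sign = NULL, FC_plus = NULL,
                                  FC_minus = NULL) {
  if (f_rich < 0 || f_rich > 1 || f_basal < 0 || f_basal > 1)
    stop_domain("f_rich and f_basal must lie in [0, 1]")
  check_nonneg(exp_basal, "exp_basal")
  n <- length(FC)
  if (any(is.na(FC))) {
    if (is.null(reg_sign))
      stop_domain("reg_sign required when FC has missing values")
    if (is.null(FC_plus) && any(is.na(FC) & reg_sign > 0)) {
      measured_pos <- !is.na(FC) & reg_sign > 0
      if (!any(measured_pos))
        stop_domain("no measured positively regulated genes to define FC_plus")
      FC_plus <- mean(FC[measured_pos])
    }
    if (!is.null(FC_plus)) FC[is.na(FC) & reg_sign > 0] <- FC_plus
    if (any(is.na(FC))) {
      if (is.null(FC_minus))
        stop_domain("FC_minus required for unmeasured negatively regulated genes")
      FC[is.na(FC)] <- FC_minus
    }
  }
  b <- 2^FC
  if (f_rich == 1 && any(is.finite(FC)))
    stop_domain("f_rich = 1 leaves the induced condition uninformative")
  den <- 1 - b * f_rich
  truncated <- den <= 0
  ratio <- ifelse(truncated, Inf, b * (1 - f_rich) / den)  # exp_ppgpp/exp_free
  exp_free <- ifelse(truncated, 0,
                     exp_basal / ((1 - f_basal) + f_basal * ratio))
  if (any(truncated) && f_basal == 0)
    stop_domain("truncation requires f_basal > 0 to recover exp_ppgpp")
  exp_ppgpp <- ifelse(truncated, exp_basal / f_basal, ratio * exp_free)
  data.frame(exp_free = exp_free, exp_ppgpp = exp_ppgpp, truncated = truncated)
}

#' Transcription-factor contribution to expression
#'
#' `tf = exp * delta_r / p`: converts the expected synthesis-probability
#' change from transcription factors into an expected expression change,
#' assuming a constant per-gene ratio between expression and synthesis
#' probability.
#'
#' @param exp_cond Expression level(s) in the condition.
#' @param delta_r Expected probability change from average TF binding.
#' @param p_cond Expected synthesis probability in the condition, `> 0`.
#' @return TF-controlled expression contribution(s).
#' @export
tf_contribution <- function(exp_cond, delta_r, p_cond) {
  check_pos(p_cond, "p_cond")
  exp_cond * delta_r / p_cond
}

#' Re-fit expression pairs against per-condition targets
#'
#' For genes whose expression is adjusted outside the ppGpp framework
#' (ribosome and RNAP related genes), ordinary least squares across
#' conditions: rows of the design are `(1-f_cond, f_cond)` and the response
#' is the target expression minus the TF contribution ([tf_contribution()]).
#'
#' @param exp_targets Genes x conditions matrix of target expression.
#' @param tf_targets Matrix of the same shape with TF contributions (0 if
#'   none).
#' @param f Per-condition RNAP bound fractions (>= 2 distinct values).
#' @return data.frame with per-gene `exp_free`, `exp_ppgpp`.
#' @export
condition_match <- function(exp_targets, tf_targets = NULL, f) {
  exp_targets <- as.matrix(exp_targets)
  if (is.null(tf_targets)) tf_targets <- matrix(0, nrow(exp_targets), ncol(exp_targets))
  if (length(f) != ncol(exp_targets))
    stop_domain("length(f) must equal the number of conditions")
  Fm <- cbind(1 - f, f)
  if (qr(Fm)$rank < 2)
    stop_domain("condition_match: rank-deficient design (conditions share ",
                "the same bound fraction)")
  e <- exp_targets - tf_targets
  # r_hat = (F'F)^-1 F' e, gene by gene (columns of t(e))
  r_hat <- solve(crossprod(Fm), crossprod(Fm, t(e)))
  data.frame(exp_free = r_hat[1, ], exp_ppgpp = r_hat[2, ],
             row.names = rownames(exp_targets))
}

#' Transcript synthesis probabilities
#'
#' Fixed mode: `v_j = alpha_j + sum_i P_T,i * delta_r[i,j]`.  ppGpp mode:
#' `v_j = alpha_j + (alpha_j / alpha_o,j) * sum_i P_T,i * delta_r[i,j]`, so a
#' transcription factor always changes expression by the same fraction
#' regardless of the ppGpp-dependent basal recruitment.  Negative results are
#' clipped at 0; the number of clipped genes is attached as attribute
#' `n_clipped`.
#'
#' @param alpha Per-gene basal recruitment (fixed mode: the reference value;
#'   ppGpp mode: from [alpha_of_ppgpp()]).
#' @param P_T Per-TF DNA-bound probabilities in `[0, 1]`.
#' @param delta_r TF x gene matrix of recruitment effects.
#' @param mode `"fixed"` or `"ppgpp"`.
#' @param alpha_o Per-gene reference basal recruitment (ppGpp mode only).
#' @return Per-gene synthesis probabilities (clipped at 0).
#' @export
synth_probability <- function(alpha, P_T = numeric(0), delta_r = NULL,
                              mode = c("fixed", "ppgpp"), alpha_o = NULL) {
  mode <- match.arg(mode)
  if (length(P_T) > 0 && (any(P_T < 0) || any(P_T > 1)))
    stop_domain("P_T must lie in [0, 1]")
  tf_term <- if (is.null(delta_r) || length(P_T) == 0) {
    numeric(length(alpha))
  } else {
    as.numeric(crossprod(delta_r, P_T))
  }
  v <- if (mode == "fixed") {
    alpha + tf_term
  } else {
    if (is.null(alpha_o)) stop_domain("alpha_o required in ppgpp mode")
    if (any(alpha_o == 0 & tf_term != 0))
      stop_domain("alpha_o = 0 with nonzero TF effects")
    alpha + ifelse(tf_term == 0, 0, alpha / alpha_o * tf_term)
  }
  n_clipped <- sum(v < 0)
  if (n_clipped > 0)
    warning("synth_probability: ", n_clipped, " negative probabilities clipped at 0")
  v <- pmax(v, 0)
  attr(v, "n_clipped") <- n_clipped
  v
}

#' TF-scale correction for ppGpp-mode expression pairs
#'
#' Computes `scale_j = v_synth,o,j / v_synth,ppGpp,j` at the basal ppGpp
#' concentration; multiplying both `exp_free` and `exp_ppgpp` of every
#' TF-regulated gene by its scale makes the ppGpp-mode probability match the
#' fixed-mode probability exactly at the basal condition.
#'
#' @param alpha_basal Per-gene ppGpp-mode basal recruitment evaluated at the
#'   basal ppGpp concentration (from [alpha_of_ppgpp()]).
#' @param alpha_o Per-gene reference basal recruitment.
#' @param P_T,delta_r As in [synth_probability()].
#' @return Per-gene scale factors (1 for genes without TF regulation).
#' @export
calibrate_tf_scale <- function(alpha_basal, alpha_o, P_T, delta_r) {
  v_o <- synth_probability(alpha_o, P_T, delta_r, mode = "fixed")
  v_p <- synth_probability(alpha_basal, P_T, delta_r, mode = "ppgpp",
                           alpha_o = alpha_o)
  tf_term <- as.numeric(crossprod(delta_r, P_T))
  scale <- ifelse(tf_term != 0 & v_p > 0, as.numeric(v_o) / as.numeric(v_p), 1)
  scale
}

#' Doubling-time interpolant over a growth-law table
#'
#' Monotone piecewise-cubic interpolation of doubling time against ppGpp
#' concentration; queries outside the table's ppGpp range are an
#' extrapolation error.
#'
#' @param table A [growth_law_table()].
#' @return Function mapping ppGpp (uM) to doubling time (min).
#' @export
tau_interpolant <- function(table) {
  ord <- order(table$ppgpp_conc_uM)
  x <- table$ppgpp_conc_uM[ord]
  y <- table$doubling_time_min[ord]
  fn <- stats::splinefun(x, y, method = "monoH.FC")
  rng <- range(x)
  function(ppgpp) {
    if (any(ppgpp < rng[1]) || any(ppgpp > rng[2]))
      stop_domain("tau_interpolant: ppGpp ", paste(signif(ppgpp, 4), collapse = ", "),
                  " outside interpolation range [", rng[1], ", ", rng[2], "]")
    fn(ppgpp)
  }
}

#' ppGpp-dependent basal recruitment
#'
#' `alpha_j = exp_j(ppGpp) * loss / n_genes` where
#' `exp_j = (1-f)*exp_free + f*exp_ppgpp`, `loss = ln2/tau + ln2/t_half`
#' (transcript dilution plus degradation, 1/s), and the gene copy number
#' follows the replication-overlap dosage form
#' `n_genes = 2^((C*(1-x) + D)/tau)` with `x` the fractional origin-to-gene
#' distance.
#'
#' @param exp_free,exp_ppgpp Per-gene expression levels.
#' @param binding An [rnap_binding()].
#' @param ppgpp_conc ppGpp concentration (uM).
#' @param tau_fun Interpolant from [tau_interpolant()] (ppGpp -> min).
#' @param rna_halflife_s Per-gene transcript half-lives (s); `Inf` for stable
#'   species.
#' @param gene_position Per-gene fractional genome coordinate in `[0, 1]`
#'   (0 = origin, 1 = terminus).
#' @param C_period_min,D_period_min Replication C and D periods (min).
#' @return Per-gene basal recruitment values.
#' @export
alpha_of_ppgpp <- function(exp_free, exp_ppgpp, binding, ppgpp_conc, tau_fun,
                           rna_halflife_s, gene_position,
                           C_period_min = 40, D_period_min = 20) {
  f <- fraction_bound(binding, ppgpp_conc)
  expj <- (1 - f) * exp_free + f * exp_ppgpp
  tau_s <- tau_fun(ppgpp_conc) * 60
  loss <- log(2) / tau_s + log(2) / rna_halflife_s
  tau_min <- tau_s / 60
  n_genes <- 2^((C_period_min * (1 - gene_position) + D_period_min) / tau_min)
  expj * loss / n_genes
}
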