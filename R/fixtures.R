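# Synthetic fixtures and serialization.  Every generator is a pure function
# of its arguments (seed included), so tests document their own provenance
# and nothing binary ships with the package.  Planted-parameter fixtures are
# built self-consistently through the model's own forward equations so the
# corresponding fits round-trip.

#' Toy amino-acid network with self-consistent demands
#'
#' Builds a glutamate-rooted chain or branched network with planted loss
#' kcats and forward kcats chosen so every amino acid carries a positive
#' translation demand; demands and rich-media exchange are computed through
#' the forward mass balances, so [fit_kcats_and_exchange()] can recover the
#' planted constants.  Enzyme pools are in the hundreds of uM so the
#' exchange-deviation weight dominates the loss-kcat regularizer and the
#' planted optimum is identifiable to fine tolerance.
#'
#' @param n_aa Number of amino acids (>= 2).
#' @param shape `"chain"` (a1 -> a2 -> ...) or `"branch"` (root feeds two
#'   arms).
#' @param seed Integer seed.
#' @param demand_minimal,demand_rich Planted per-AA demands (uM/s), recycled.
#' @return List with `net`, `kinetics` (planted), `constants`,
#'   `cond_minimal`, `cond_rich` and `v_exchange` (planted rich exchange).
#' @export
generate_toy_aa_network <- function(n_aa = 3, shape = c("chain", "branch"),
                                    seed = 1, demand_minimal = 60,
                                    demand_rich = 100) {
  shape <- match.arg(shape)
  stopifnot(n_aa >= 2)
  set.seed(seed)
  ids <- paste0("aa", seq_len(n_aa))
  edges <- if (shape == "chain") {
    data.frame(from = ids[-n_aa], to = ids[-1])
  } else {
    parent <- c(NA, vapply(2:n_aa, function(i) ids[max(1, i %/% 2)], ""))
    data.frame(from = parent[-1], to = ids[-1])
  }
  loss_kind <- stats::setNames(rep(c("none", "reverse", "degradation"),
                                   length.out = n_aa), ids)
  loss_kind[[1]] <- "none"
  net <- aa_network(ids, edges, root = ids[[1]], loss_kind = loss_kind)

  conc_min <- stats::setNames(stats::runif(n_aa, 800, 4000), ids)
  conc_rich <- conc_min * stats::runif(n_aa, 2, 4)
  enz <- stats::setNames(stats::runif(n_aa, 300, 700), ids)
  constants <- assign_default_constants(net, conc_min)
  kcat_loss <- stats::setNames(stats::runif(n_aa, 0.2, 0.8), ids)
  kcat_loss[loss_kind == "none"] <- 0

  S_min <- stats::setNames(rep_len(demand_minimal, n_aa), ids)
  S_rich <- stats::setNames(rep_len(demand_rich, n_aa), ids)

  cap_synth <- function(aa, conc) {
    up <- net$upstream[[aa]]
    upf <- if (length(up)) prod(sat(conc[up], constants$K_M_up[[aa]][up])) else 1
    enz[[aa]] * inhib(conc[[aa]], constants$K_I[[aa]]) * upf
  }
  cap_loss <- function(aa, conc) {
    if (net$loss_kind[[aa]] == "none") return(0)
    enz[[aa]] * sat(conc[[aa]], constants$K_M_loss[[aa]])
  }
  # choose kcat_f so the minimal-media balance holds with the planted demand
  kcat_f <- stats::setNames(numeric(n_aa), ids)
  for (aa in rev(net$topo_order)) {
    dn <- net$downstream[[aa]]
    vdown <- if (length(dn)) sum(kcat_f[dn] * vapply(dn, cap_synth, 0,
                                                     conc = conc_min)) else 0
    kcat_f[[aa]] <- (S_min[[aa]] + vdown + kcat_loss[[aa]] * cap_loss(aa, conc_min)) /
      cap_synth(aa, conc_min)
  }
  kin <- aa_kinetics(net, kcat_f, kcat_loss, constants$K_I, constants$K_M_up,
                     constants$K_M_loss)
  # rich-media exchange closes the rich balance exactly
  v_synth_rich <- synthesis_rate(net, kin, conc_rich, enz)
  lr <- loss_rates(net, kin, conc_rich, enz, v_synth_rich)
  v_ex <- S_rich + lr$v_down + lr$v_loss - v_synth_rich

  cond_min <- condition_table("minimal", ids, conc_min, enz, S_min,
                              exchange_lit_uM_per_s = 0,
                              kcat_lit_per_s = kcat_f)
  cond_rich <- condition_table("rich", ids, conc_rich, enz, S_rich,
                               exchange_lit_uM_per_s = v_ex,
                               kcat_lit_per_s = kcat_f)
  list(net = net, kinetics = kin, constants = constants,
       cond_minimal = cond_min, cond_rich = cond_rich, v_exchange = v_ex)
}

#' Synthetic growth-law table from planted RNAP-binding parameters
#'
#' Rows span slow to fast growth (decreasing doubling time, decreasing
#' ppGpp, increasing RNAP), with RNA mass fractions generated through the
#' bound-fraction partition model, optionally with multiplicative noise.
#'
#' @param n_rows Number of rows (>= 3).
#' @param K_M Planted binding constant (uM).
#' @param exp_free,exp_ppgpp Planted aggregate expression levels.
#' @param noise_sd Multiplicative lognormal-ish noise sd (0 = exact).
#' @param seed Integer seed.
#' @return A [growth_law_table()].
#' @export
generate_growth_law_table <- function(n_rows = 5, K_M = 70, exp_free = 0.012,
                                      exp_ppgpp = 0.004, noise_sd = 0,
                                      seed = 1) {
  stopifnot(n_rows >= 3)
  set.seed(seed)
  tau <- seq(100, 24, length.out = n_rows)
  ppgpp <- seq(95, 18, length.out = n_rows)
  rnap <- seq(2, 10, length.out = n_rows)
  f <- ppgpp^2 / (K_M^2 + ppgpp^2)
  rna_frac <- rnap * ((1 - f) * exp_free + f * exp_ppgpp)
  if (noise_sd > 0)
    rna_frac <- rna_frac * (1 + stats::rnorm(n_rows, 0, noise_sd))
  growth_law_table(tau, rna_frac, rnap, ppgpp)
}

#' Synthetic expression compendium with a planted factorization
#'
#' Draws a sparse signed regulator -> gene topology (every regulator touching
#' at least two genes, every gene at least one regulator), planted strengths
#' `A` respecting the mask signs and activities `P`, and returns
#' `E = A %*% P + noise`.
#'
#' @param n_genes,n_regulators,n_conditions Dimensions (`n_conditions >= 10`
#'   for extreme-set extraction).
#' @param edges_per_regulator Average support size per regulator.
#' @param noise_sd Additive Gaussian noise sd (0 = exact).
#' @param seed Integer seed.
#' @return List with `E`, `edges` (regulator/gene/sign data.frame), `mask`,
#'   `A`, `P`.
#' @export
generate_expression_compendium <- function(n_genes = 30, n_regulators = 4,
                                           n_conditions = 40,
                                           edges_per_regulator = 8,
                                           noise_sd = 0, seed = 1) {
  stopifnot(n_conditions >= 10)
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  regs <- paste0("tf", seq_len(n_regulators))
  A <- matrix(0, n_genes, n_regulators, dimnames = list(genes, regs))
  for (j in seq_len(n_regulators)) {
    k <- min(n_genes, max(2, stats::rpois(1, edges_per_regulator)))
    idx <- sample.int(n_genes, k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    A[idx, j] <- sgn * stats::runif(k, 0.5, 2)
  }
  uncovered <- which(rowSums(A != 0) == 0)
  for (g in uncovered) {
    j <- sample.int(n_regulators, 1)
    A[g, j] <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2)
  }
  P <- matrix(stats::rnorm(n_regulators * n_conditions), n_regulators,
              n_conditions,
              dimnames = list(regs, paste0("c", seq_len(n_conditions))))
  E <- A %*% P
  if (noise_sd > 0) E <- E + matrix(stats::rnorm(length(E), 0, noise_sd),
                                    nrow(E), ncol(E))
  idx <- which(A != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = regs[idx[, 2]], gene = genes[idx[, 1]],
                      sign = sign(A[idx]), stringsAsFactors = FALSE)
  mask <- matrix(0, n_regulators, n_genes, dimnames = list(regs, genes))
  mask[cbind(idx[, 2], idx[, 1])] <- sign(A[idx])
  list(E = E, edges = edges, mask = structure(mask,
       class = c("topology_mask", "matrix", "array")), A = A, P = P)
}

# --- serialization -----------------------------------------------------------

#' Write a parameter document as versioned JSON
#'
#' Serializes any parameter bundle (fitted kinetics, transport constants,
#' calibration values, residual blocks) losslessly, stamped with a format
#' version.
#'
#' @param params Named list of parameter objects (numeric vectors, nested
#'   lists, data.frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  # named atomic vectors become JSON objects (names are data here)
  listify <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, listify)
    else x
  }
  doc <- list(format = "growthctrl-params", version = 1L,
              params = listify(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a parameter document written by [write_params_json()]
#'
#' @param path Input path.
#' @return The `params` list.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "growthctrl-params")
    stop_domain("not a growthctrl parameter document: ", path)
  doc$params
}

#' Write / read a condition table as CSV
#'
#' Columns: `aa, conc_uM, enzyme_uM, demand_uM_per_s, exchange_lit_uM_per_s,
#' kcat_lit_per_s` (UTF-8, header row, '.' decimal separator).
#'
#' @param cond A [condition_table()].
#' @param path File path.
#' @return `path` invisibly (write); a [condition_table()] (read).
#' @export
write_condition_csv <- function(cond, path) {
  utils::write.csv(as.data.frame(cond), path, row.names = FALSE)
  invisible(path)
}

#' @param name Condition label to attach on read.
#' @rdname write_condition_csv
#' @export
read_condition_csv <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("aa", "conc_uM", "enzyme_uM", "demand_uM_per_s",
                "exchange_lit_uM_per_s", "kcat_lit_per_s")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_domain("condition CSV missing column(s): ",
                paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra) > 0)
    stop_domain("condition CSV has unknown column(s): ",
                paste(extra, collapse = ", "))
  condition_table(name, df$aa, df$conc_uM, df$enzyme_uM, df$demand_uM_per_s,
                  df$exchange_lit_uM_per_s, df$kcat_lit_per_s)
}

#' Read a run configuration (JSON dialect)
#'
#' Documented schema: top-level keys `options` (any [sim_options()] argument)
#' and `experiment` (`t_end`, optional `schedule` with `time`/`media`
#' columns).  Unknown keys are a validation error.
#'
#' @param path Path to a JSON run config.
#' @return List with `options` (a [sim_options()]) and `experiment`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed_top <- c("options", "experiment")
  bad <- setdiff(names(cfg), allowed_top)
  if (length(bad) > 0)
    stop_domain("run config: unknown field(s): ", paste(bad, collapse = ", "))
  opt_args <- cfg$options %||% list()
  bad_opt <- setdiff(names(opt_args), names(formals(sim_options)))
  if (length(bad_opt) > 0)
    stop_domain("run config options: unknown field(s): ",
                paste(bad_opt, collapse = ", "))
  list(options = do.call(sim_options, opt_args),
       experiment = cfg$experiment %||% list())
}
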