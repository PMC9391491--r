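# Charged-tRNA-dependent transcriptional attenuation.  Termination at the
# attenuation site is a Poissonian stop with probability
# P_stop = 1 - exp(-sum_j tRNA_j / K_ij); K is back-calculated from NCA fold
# changes at rich-media charged tRNA levels, and basal synthesis
# probabilities are compensated upward so expected completed transcription is
# unchanged at the expected stop probability.

#' Attenuation parameters
#'
#' @param K Gene x amino-acid matrix of attenuation constants (uM); entries
#'   `Inf` (or `NA`) where a tRNA pool does not act on a gene.  tRNA species
#'   for an amino acid are summed into one pool sharing a single `K`.
#' @return Object of class `attenuation_params`.
#' @export
attenuation_params <- function(K) {
  K <- as.matrix(K)
  K[is.na(K)] <- Inf
  if (any(K <= 0)) stop_domain("attenuation K must be > 0")
  structure(list(K = K, genes = rownames(K), aa = colnames(K)),
            class = "attenuation_params")
}

#' Stop probability at the attenuation site
#'
#' `P_stop,i = 1 - exp(-sum_j tRNA_j / K_ij)`, in `[0, 1)`; 0 at zero
#' charged tRNA.
#'
#' @param params An [attenuation_params()].
#' @param charged_trna_by_aa Named per-amino-acid charged tRNA pools (uM),
#'   already summed over isoacceptors.
#' @return Named per-gene stop probabilities.
#' @export
p_stop <- function(params, charged_trna_by_aa) {
  trna <- align_ids(charged_trna_by_aa, params$aa, "charged_trna_by_aa")
  check_nonneg(trna, "charged_trna_by_aa")
  ratio <- sweep(1 / params$K, 2, trna, `*`)  # tRNA_j / K_ij
  stats::setNames(1 - exp(-rowSums(ratio)), params$genes)
}

#' Back-calculate attenuation constants from fold changes
#'
#' The fold change of an attenuated gene is read as the ratio of read-through
#' at rich-media charged tRNA to read-through at zero charged tRNA, so
#' `FC = exp(-tRNA_rich / K)` and `K = -tRNA_rich / ln(FC)` (the sign is
#' corrected relative to the raw rearrangement so `K > 0` for repression,
#' `0 < FC < 1`).
#'
#' @param FC Named per-gene fold changes (linear scale), each in `(0, 1)`.
#' @param gene_aa Named per-gene amino-acid identifier whose charged tRNA pool
#'   controls the gene.
#' @param trna_rich_by_aa Named per-amino-acid charged tRNA pools in rich
#'   media (uM).
#' @return An [attenuation_params()] over the union of amino acids involved.
#' @export
fit_attenuation_k <- function(FC, gene_aa, trna_rich_by_aa) {
  genes <- names(FC)
  bad <- genes[FC <= 0 | FC >= 1]
  if (length(bad) > 0)
    stop_domain("fold change outside (0, 1) for gene(s): ",
                paste(bad, collapse = ", "))
  aas <- unique(unname(gene_aa[genes]))
  K <- matrix(Inf, length(genes), length(aas), dimnames = list(genes, aas))
  for (g in genes) {
    aa <- gene_aa[[g]]
    K[g, aa] <- -trna_rich_by_aa[[aa]] / log(FC[[g]])
  }
  attenuation_params(K)
}

#' Compensate basal recruitment for attenuation
#'
#' `alpha_adjusted = alpha / (1 - P_stop)`, so expected completed
#' transcription with attenuation equals the unattenuated rate:
#' `(1 - P_stop) * alpha_adjusted = alpha` exactly.
#'
#' @param alpha Per-gene basal recruitment.
#' @param p_stop_expected Per-gene expected stop probabilities in `[0, 1)`.
#' @return Adjusted per-gene recruitment.
#' @export
adjust_basal <- function(alpha, p_stop_expected) {
  if (any(p_stop_expected < 0) || any(p_stop_expected >= 1))
    stop_domain("p_stop_expected must lie in [0, 1)")
  alpha / (1 - p_stop_expected)
}

#' Sample stochastic termination events
#'
#' One uniform draw per active transcript; a transcript terminates when its
#' draw falls below the stop probability.  Reproducible under the session RNG
#' seed.
#'
#' @param p_stop Per-transcript stop probabilities.
#' @return Logical vector of stop flags.
#' @export
sample_termination <- function(p_stop) {
  if (any(p_stop < 0) || any(p_stop > 1))
    stop_domain("p_stop must lie in [0, 1]")
  stats::runif(length(p_stop)) < p_stop
}
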