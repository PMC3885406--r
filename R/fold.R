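#' Equilibrium base-pair probabilities for an RNA sequence
#'
#' Computes the matrix of pair probabilities P(i,j) over the Boltzmann
#' ensemble of pseudoknot-free secondary structures (the McCaskill
#' inside-outside algorithm) under the loop-decomposed nearest-neighbor
#' model in `model`. This is the quantity compared between wild-type and
#' mutant alleles by the structure-disruption stage.
#'
#' @param seq RNA sequence (character scalar over A/C/G/U, case-insensitive;
#'   T is accepted and read as U).
#' @param model an [energy_model()].
#' @return a `bp_matrix`: list with `n` (sequence length), `p` (n x n
#'   symmetric probability matrix) and `too_short` flag. Sequences shorter
#'   than `min_hairpin + 2` yield an all-zero matrix flagged `too_short`.
#' @examples
#' bpm <- compute_pair_probabilities("GGGAAAACCC", default_energy_model())
#' range(rowSums(bpm$p))
#' @export
compute_pair_probabilities <- function(seq, model = default_energy_model()) {
  v <- encode_rna(seq)
  n <- length(v)
  if (n < model$min_hairpin + 2L) {
    return(structure(list(n = n, p = matrix(0, n, n), too_short = TRUE),
                     class = "bp_matrix"))
  }
  p <- .mccaskill_bppm_cpp(v, unclass(model))
  structure(list(n = n, p = p, too_short = FALSE), class = "bp_matrix")
}

#' Position-wise pairing probability profile
#'
#' Collapses a pair-probability matrix to the per-position probability of
#' being paired with anything, `p_k = sum_l P(k,l)`. These profiles are the
#' inputs to the Pearson-correlation disruption measure.
#'
#' @param bpm a `bp_matrix` from [compute_pair_probabilities()], or a bare
#'   symmetric numeric matrix.
#' @return numeric vector of per-position pairing probabilities in [0, 1].
#' @export
positional_profile <- function(bpm) {
  p <- if (inherits(bpm, "bp_matrix")) bpm$p else bpm
  rowSums(p)
}

# A/C/G/U -> 0..3 integer encoding; errors on any other character.
encode_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(chartr("acgutT", "ACGUUU", seq), "", fixed = TRUE)[[1]]
  v <- match(ch, BASES) - 1L
  if (anyNA(v))
    stop("invalid characters in sequence: ",
         paste(unique(ch[is.na(v)]), collapse = ", "))
  v
}
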