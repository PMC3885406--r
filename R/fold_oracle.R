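#' Exact pair probabilities by exhaustive structure enumeration
#'
#' Enumerates every pseudoknot-free secondary structure of a short sequence
#' (respecting the model's allowed pairs and minimum hairpin size), computes
#' each structure's loop-decomposition energy, Boltzmann-weights it, and
#' returns the exact pair-probability matrix. This is an independent oracle
#' for [compute_pair_probabilities()]: it shares no code with the dynamic
#' program and is exponential in sequence length.
#'
#' @param seq RNA sequence, at most `max_len` nt.
#' @param model an [energy_model()].
#' @param max_len refuse sequences longer than this (default 20).
#' @return a `bp_matrix` (same shape as [compute_pair_probabilities()]),
#'   with an extra `n_structures` element.
#' @export
enumerate_structures <- function(seq, model = default_energy_model(),
                                 max_len = 20L) {
  v <- encode_rna(seq)
  n <- length(v)
  if (n > max_len)
    stop("enumeration refused for length ", n, " > ", max_len)
  structs <- enumerate_pairsets(v, model)
  p <- matrix(0, n, n)
  z <- 0
  rt <- rt_of(model)
  for (s in structs) {
    e <- structure_energy(s, n, v, model)
    if (!is.finite(e)) next
    w <- exp(-e / rt)
    z <- z + w
    if (nrow(s) > 0)
      for (r in seq_len(nrow(s))) {
        p[s[r, 1], s[r, 2]] <- p[s[r, 1], s[r, 2]] + w
      }
  }
  p <- p / z
  p <- p + t(p)
  structure(list(n = n, p = p, too_short = n < model$min_hairpin + 2L,
                 n_structures = length(structs)), class = "bp_matrix")
}

# All pseudoknot-free pair sets on v, as a list of 2-column matrices.
# Decomposition: base i is unpaired, or paired to some k (splits the interval).
enumerate_pairsets <- function(v, model) {
  mh <- model$min_hairpin
  pt <- model$pair_table
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(rec(i + 1L, j), identity)
    ks <- if (j - i > mh) (i + mh + 1L):j else integer(0)
    for (k in ks) {
      if (pt[v[i] + 1L, v[k] + 1L] == 0L) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), 1, 2), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, length(v))
}

# Loop-decomposition energy of one structure; +Inf if it contains an
# interior/bulge loop larger than the model cap (such structures are
# excluded from the ensemble, matching the dynamic program).
structure_energy <- function(pairs, n, v, model) {
  if (nrow(pairs) == 0) return(0)
  pv <- integer(n)
  pv[pairs[, 1]] <- pairs[, 2]
  pv[pairs[, 2]] <- pairs[, 1]
  pt <- model$pair_table
  type_of <- function(i, j) pt[v[i] + 1L, v[j] + 1L]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # direct children of (i, j)
    ch <- matrix(integer(0), 0, 2)
    unp <- 0L
    k <- i + 1L
    while (k < j) {
      if (pv[k] > k) {
        ch <- rbind(ch, c(k, pv[k]))
        k <- pv[k] + 1L
      } else {
        unp <- unp + 1L
        k <- k + 1L
      }
    }
    if (nrow(ch) == 0L) {
      e <- e + model$hairpin[1] + model$hairpin[2] * (j - i - 1L)
    } else if (nrow(ch) == 1L) {
      k <- ch[1, 1]; l <- ch[1, 2]
      if (k == i + 1L && l == j - 1L) {
        e <- e + model$stack[type_of(i, j), type_of(k, l)]
      } else {
        size <- (k - i - 1L) + (j - l - 1L)
        if (size > model$max_loop) return(Inf)
        e <- e + model$interior[1] + model$interior[2] * size
      }
    } else {
      e <- e + model$multiloop[1] + model$multiloop[2] * (1L + nrow(ch)) +
        model$multiloop[3] * unp
    }
  }
  e
}

#' Count pseudoknot-free structures (Nussinov-style recursion)
#'
#' Independent count of all structures the enumeration should produce; used
#' to validate uniform-ensemble (zero-energy) probabilities.
#'
#' @inheritParams enumerate_structures
#' @return number of structures (including the open structure).
#' @export
count_structures <- function(seq, model = default_energy_model()) {
  v <- encode_rna(seq)
  n <- length(v)
  mh <- model$min_hairpin
  pt <- model$pair_table
  memo <- matrix(NA_real_, n + 2L, n + 2L)
  rec <- function(i, j) {
    if (i >= j) return(1)
    if (!is.na(memo[i, j])) return(memo[i, j])
    tot <- rec(i + 1L, j)
    if (j - i > mh)
      for (k in seq(i + mh + 1L, j)) {
        if (pt[v[i] + 1L, v[k] + 1L] == 0L) next
        tot <- tot + rec(i + 1L, k - 1L) * rec(k + 1L, j)
      }
    memo[i, j] <<- tot
    tot
  }
  rec(1L, n)
}
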