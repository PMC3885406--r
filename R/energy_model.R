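#' Nearest-neighbor energy model for RNA folding and duplex scoring
#'
#' Builds the thermodynamic parameter set used by both the intramolecular
#' folding stage ([compute_pair_probabilities()]) and the miRNA duplex stage
#' ([scan_duplex()]). The model is a simplified nearest-neighbor scheme:
#' Watson-Crick and G:U wobble pairs, stacking energies per adjacent pair of
#' pairs, affine hairpin / interior-bulge / multiloop penalties, no dangles
#' and no special tetraloops. Energies are standard free energies in
#' kcal/mol; `temperature` only sets RT in the Boltzmann weights.
#'
#' @param allowed_pairs character vector of allowed pair types, a subset of
#'   `c("AU","UA","CG","GC","GU","UG")`.
#' @param stack 6x6 numeric matrix of stacking energies (kcal/mol), rows =
#'   outer (closing) pair type, columns = inner pair type, in the order
#'   AU, UA, CG, GC, GU, UG.
#' @param hairpin length-2 numeric, affine hairpin-loop penalty `a + b*len`.
#' @param interior length-2 numeric, affine interior/bulge penalty `a + b*len`.
#' @param multiloop length-3 numeric `c(a, b, c)`: multiloop penalty
#'   `a + b*(branches incl. closing pair) + c*unpaired`.
#' @param duplex_init duplex initiation penalty (kcal/mol), used by the
#'   miRNA duplex energy only.
#' @param temperature folding temperature in Kelvin.
#' @param min_hairpin minimum number of unpaired bases in a hairpin loop.
#' @param max_loop maximum interior/bulge loop size (nt); larger loops are
#'   disallowed (standard convention).
#' @return an object of class `energy_model`.
#' @seealso [default_energy_model()], [zero_energy_model()],
#'   [read_energy_model()]
#' @export
energy_model <- function(allowed_pairs = PAIR_TYPES,
                         stack = default_stack_table(),
                         hairpin = c(5.0, 0.05),
                         interior = c(3.5, 0.25),
                         multiloop = c(3.4, 0.4, 0.0),
                         duplex_init = 4.1,
                         temperature = 310.15,
                         min_hairpin = 3L,
                         max_loop = 30L) {
  allowed_pairs <- match.arg(allowed_pairs, PAIR_TYPES, several.ok = TRUE)
  stopifnot(is.matrix(stack), all(dim(stack) == c(6L, 6L)),
            all(is.finite(stack)), length(hairpin) == 2L,
            length(interior) == 2L, length(multiloop) == 3L,
            min_hairpin >= 3L, temperature > 0, max_loop >= 1L)
  dimnames(stack) <- list(PAIR_TYPES, PAIR_TYPES)
  m <- structure(list(
    allowed_pairs = allowed_pairs,
    stack = stack,
    hairpin = as.numeric(hairpin),
    interior = as.numeric(interior),
    multiloop = as.numeric(multiloop),
    duplex_init = as.numeric(duplex_init),
    temperature = as.numeric(temperature),
    min_hairpin = as.integer(min_hairpin),
    max_loop = as.integer(max_loop)
  ), class = "energy_model")
  m$pair_table <- pair_type_table(allowed_pairs)
  m
}

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
BASES <- c("A", "C", "G", "U")

#' @rdname energy_model
#' @export
default_energy_model <- function() energy_model()

#' @rdname energy_model
#' @export
zero_energy_model <- function() {
  energy_model(stack = matrix(0, 6, 6), hairpin = c(0, 0), interior = c(0, 0),
               multiloop = c(0, 0, 0), duplex_init = 0)
}

# Turner-style Watson-Crick stacks; wobble-containing stacks collapsed to two
# representative values (one wobble: -1.4; two wobbles: -0.3). Row = outer
# (closing) pair, column = inner pair.
default_stack_table <- function() {
  wc <- matrix(c(
    # inner:  AU     UA     CG     GC
    -0.93, -1.10, -2.24, -2.08,   # outer AU
    -1.33, -0.93, -2.35, -2.11,   # outer UA
    -2.11, -2.08, -3.26, -2.36,   # outer CG
    -2.35, -2.24, -3.42, -3.26    # outer GC
  ), nrow = 4, byrow = TRUE)
  st <- matrix(-1.4, 6, 6)
  st[1:4, 1:4] <- wc
  st[5:6, 5:6] <- -0.3
  dimnames(st) <- list(PAIR_TYPES, PAIR_TYPES)
  st
}

# 4x4 integer lookup (A,C,G,U x A,C,G,U): 0 = cannot pair, otherwise the
# pair-type index 1..6 in the order AU, UA, CG, GC, GU, UG.
pair_type_table <- function(allowed_pairs) {
  pt <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  for (k in seq_along(PAIR_TYPES)) {
    p <- PAIR_TYPES[k]
    if (p %in% allowed_pairs)
      pt[substr(p, 1, 1), substr(p, 2, 2)] <- k
  }
  pt
}

pair_type_of <- function(model, a, b) model$pair_table[a, b]

#' Read or write an energy model as a plain TSV
#'
#' The on-disk format is a two-column `param`/`value` table; stacking entries
#' are keyed `stack.<outer>.<inner>`. This lets tests and pipelines inject
#' alternative parameter sets (e.g. the zero-energy model) without code.
#'
#' @param path file path.
#' @param model an `energy_model`.
#' @return `read_energy_model` returns an `energy_model`;
#'   `write_energy_model` returns `path` invisibly.
#' @export
read_energy_model <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("param", "value") %in% names(tab)))
  val <- function(key) as.numeric(tab$value[match(key, tab$param)])
  st <- matrix(0, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  for (o in PAIR_TYPES) for (i in PAIR_TYPES)
    st[o, i] <- val(paste("stack", o, i, sep = "."))
  ap_row <- tab$value[match("allowed_pairs", tab$param)]
  ap <- if (is.na(ap_row)) PAIR_TYPES else strsplit(ap_row, ",", fixed = TRUE)[[1]]
  energy_model(
    allowed_pairs = ap, stack = st,
    hairpin = c(val("hairpin.a"), val("hairpin.b")),
    interior = c(val("interior.a"), val("interior.b")),
    multiloop = c(val("multiloop.a"), val("multiloop.b"), val("multiloop.c")),
    duplex_init = val("duplex_init"), temperature = val("temperature"),
    min_hairpin = as.integer(val("min_hairpin")),
    max_loop = as.integer(val("max_loop")))
}

#' @rdname read_energy_model
#' @export
write_energy_model <- function(model, path) {
  stopifnot(inherits(model, "energy_model"))
  keys <- character(0); vals <- character(0)
  for (o in PAIR_TYPES) for (i in PAIR_TYPES) {
    keys <- c(keys, paste("stack", o, i, sep = "."))
    vals <- c(vals, format(model$stack[o, i]))
  }
  keys <- c(keys, "hairpin.a", "hairpin.b", "interior.a", "interior.b",
            "multiloop.a", "multiloop.b", "multiloop.c", "duplex_init",
            "temperature", "min_hairpin", "max_loop", "allowed_pairs")
  vals <- c(vals, format(c(model$hairpin, model$interior, model$multiloop,
                           model$duplex_init, model$temperature,
                           model$min_hairpin, model$max_loop)),
            paste(model$allowed_pairs, collapse = ","))
  utils::write.table(data.frame(param = keys, value = vals),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

rt_of <- function(model) 0.0019872 * model$temperature
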