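#' Read transcript sequences with UTR annotations
#'
#' Loads RefSeq-style mRNA sequences from a FASTA file and joins them with a
#' sidecar table of 1-based, inclusive UTR spans. Sequences are uppercased
#' and DNA T is transcribed to U. Records without a UTR row are dropped with
#' a warning. All coordinates in the package are transcript-space, 1-based
#' and inclusive.
#'
#' @param fasta_path transcript FASTA (DNA or RNA alphabet; `N` tolerated).
#' @param utr_table_path TSV with header columns `transcript_id`, `gene`,
#'   `utr5_start`, `utr5_end`, `utr3_start`, `utr3_end` (NA / empty for a
#'   missing UTR).
#' @return a `transcript_set`: data frame with columns `transcript_id`,
#'   `gene`, `sequence`, `utr5_start`, `utr5_end`, `utr3_start`, `utr3_end`.
#' @export
read_transcripts <- function(fasta_path, utr_table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- normalize_rna(as.character(seqs))
  utr <- utils::read.table(utr_table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "utr5_start", "utr5_end",
            "utr3_start", "utr3_end")
  if (!all(need %in% names(utr)))
    stop("UTR table must have columns: ", paste(need, collapse = ", "))
  keep <- ids %in% utr$transcript_id
  if (any(!keep))
    warning(sum(!keep), " FASTA record(s) without a UTR row were dropped")
  idx <- match(ids[keep], utr$transcript_id)
  out <- data.frame(
    transcript_id = ids[keep],
    gene = utr$gene[idx],
    sequence = unname(seq_chr[keep]),
    utr5_start = as.integer(utr$utr5_start[idx]),
    utr5_end = as.integer(utr$utr5_end[idx]),
    utr3_start = as.integer(utr$utr3_start[idx]),
    utr3_end = as.integer(utr$utr3_end[idx]),
    stringsAsFactors = FALSE)
  validate_transcripts(out)
  class(out) <- c("transcript_set", "data.frame")
  out
}

normalize_rna <- function(x) {
  x <- chartr("acgut", "ACGUU", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad))
    stop("sequence(s) contain characters outside A/C/G/U/N")
  x
}

validate_transcripts <- function(tx) {
  for (r in seq_len(nrow(tx))) {
    len <- nchar(tx$sequence[r])
    id <- tx$transcript_id[r]
    chk <- function(s, e, lab) {
      if (is.na(s) != is.na(e))
        stop(id, ": ", lab, " has one missing endpoint")
      if (!is.na(s)) {
        if (s > e) stop(id, ": inverted ", lab, " interval (", s, ", ", e, ")")
        if (s < 1L || e > len)
          stop(id, ": ", lab, " span (", s, ", ", e,
               ") outside sequence [1, ", len, "]")
      }
    }
    chk(tx$utr5_start[r], tx$utr5_end[r], "utr5")
    chk(tx$utr3_start[r], tx$utr3_end[r], "utr3")
    if (!is.na(tx$utr5_end[r]) && !is.na(tx$utr3_start[r]) &&
        tx$utr5_end[r] >= tx$utr3_start[r])
      stop(id, ": utr5 must end before utr3 starts")
  }
  invisible(tx)
}

#' Write transcripts back to FASTA + UTR table (lossless round trip)
#' @param tx a `transcript_set`.
#' @param fasta_path,utr_table_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(tx, fasta_path, utr_table_path) {
  writeLines(paste0(">", tx$transcript_id, "\n", tx$sequence), fasta_path)
  utils::write.table(
    tx[, c("transcript_id", "gene", "utr5_start", "utr5_end",
           "utr3_start", "utr3_end")],
    utr_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, utr_table_path))
}

#' Read SNVs in transcript coordinates
#'
#' Accepts either explicit `position`/`ref`/`alt` columns or a compact
#' `snv` token column (e.g. `U1552G` = ref U, position 1552, alt G). The ref
#' allele is cross-checked against the transcript sequence; mismatching rows
#' are excluded with a warning, rows for unknown transcripts are skipped
#' with a warning, and each retained SNV gets a UTR label from
#' [classify_utr()].
#'
#' @param tsv_path TSV with header; columns `transcript_id` plus either
#'   `snv` or (`position`, `ref`, `alt`); optional `dbsnp_id`.
#' @param transcripts a `transcript_set`.
#' @return an `snv_set` data frame: `transcript_id`, `gene`, `position`,
#'   `ref`, `alt`, `utr_label`, `dbsnp_id`; attributes `n_ref_mismatch` and
#'   `n_unknown_transcript` count the exclusions.
#' @export
read_snvs <- function(tsv_path, transcripts) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"transcript_id" %in% names(tab))
    stop("SNV table must have a transcript_id column")
  if ("snv" %in% names(tab)) {
    parsed <- parse_snv_token(tab$snv)
    tab$position <- parsed$position; tab$ref <- parsed$ref; tab$alt <- parsed$alt
  } else if (!all(c("position", "ref", "alt") %in% names(tab))) {
    stop("SNV table needs either an 'snv' token column or position/ref/alt")
  }
  tab$ref <- normalize_rna(tab$ref); tab$alt <- normalize_rna(tab$alt)
  if (any(tab$ref == tab$alt))
    stop("degenerate SNV rows (ref == alt): rows ",
         paste(which(tab$ref == tab$alt), collapse = ", "))
  if (!"dbsnp_id" %in% names(tab)) tab$dbsnp_id <- NA_character_

  known <- tab$transcript_id %in% transcripts$transcript_id
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    warning(n_unknown, " SNV row(s) on unknown transcripts skipped")
  tab <- tab[known, , drop = FALSE]

  idx <- match(tab$transcript_id, transcripts$transcript_id)
  len <- nchar(transcripts$sequence[idx])
  if (any(tab$position < 1L | tab$position > len))
    stop("SNV position outside transcript: rows ",
         paste(which(tab$position < 1L | tab$position > len), collapse = ", "))
  at <- substr(transcripts$sequence[idx], tab$position, tab$position)
  ok <- at == tab$ref
  n_mismatch <- sum(!ok)
  if (n_mismatch > 0)
    warning(n_mismatch, " SNV row(s) excluded: ref allele does not match ",
            "the transcript sequence")
  tab <- tab[ok, , drop = FALSE]
  idx <- idx[ok]

  lab <- vapply(seq_len(nrow(tab)), function(r)
    classify_utr(tab$position[r], transcripts[idx[r], , drop = FALSE]),
    character(1))
  out <- data.frame(
    transcript_id = tab$transcript_id, gene = transcripts$gene[idx],
    position = as.integer(tab$position), ref = tab$ref, alt = tab$alt,
    utr_label = lab, dbsnp_id = tab$dbsnp_id, stringsAsFactors = FALSE)
  attr(out, "n_ref_mismatch") <- n_mismatch
  attr(out, "n_unknown_transcript") <- n_unknown
  class(out) <- c("snv_set", "data.frame")
  out
}

parse_snv_token <- function(token) {
  m <- regmatches(token, regexec("^([ACGUTacgut])([0-9]+)([ACGUTacgut])$", token))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("unparsable SNV token(s): ", paste(token[bad], collapse = ", "))
  list(ref = normalize_rna(vapply(m, `[`, "", 2L)),
       position = as.integer(vapply(m, `[`, "", 3L)),
       alt = normalize_rna(vapply(m, `[`, "", 4L)))
}

#' @export
format_snv_token <- function(snvs) paste0(snvs$ref, snvs$position, snvs$alt)

#' Write SNVs to TSV (lossless round trip)
#' @param snvs an `snv_set`.
#' @param tsv_path output path.
#' @export
write_snvs <- function(snvs, tsv_path) {
  utils::write.table(
    snvs[, c("transcript_id", "position", "ref", "alt", "dbsnp_id")],
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

#' UTR membership of a transcript position
#'
#' Classifies a position against the UTR spans of the transcripts it maps
#' to: `"5"` if inside the 5' UTR of every mapped transcript (that places it
#' in a UTR), `"3"` likewise for the 3' UTR, `"both"` when overlapping
#' transcripts disagree (5' UTR in one, 3' UTR in another), `"none"` when it
#' falls in no UTR. The result does not depend on transcript order.
#'
#' @param position 1-based transcript coordinate.
#' @param transcripts the mapped transcripts (rows of a `transcript_set`).
#' @return one of `"5"`, `"3"`, `"both"`, `"none"`.
#' @export
classify_utr <- function(position, transcripts) {
  in5 <- !is.na(transcripts$utr5_start) &
    position >= transcripts$utr5_start & position <= transcripts$utr5_end
  in3 <- !is.na(transcripts$utr3_start) &
    position >= transcripts$utr3_start & position <= transcripts$utr3_end
  if (any(in5) && any(in3)) "both"
  else if (any(in5)) "5"
  else if (any(in3)) "3"
  else "none"
}

#' Extract the wild-type/mutant window around an SNV
#'
#' Cuts the `+/- flank` nt window around the SNV position (clipped at the
#' transcript ends) and substitutes the alternate base to form the mutant
#' window. The folding stage uses `flank = 200`, the miRNA stage
#' `flank = 30` (61-mers).
#'
#' @param snv one row of an `snv_set` (or any list with `transcript_id`,
#'   `position`, `ref`, `alt`).
#' @param transcript the matching row of a `transcript_set`.
#' @param flank flank size in nt (>= 1).
#' @return a `window_pair`: list with `wt_seq`, `mt_seq`, `window_start`
#'   (transcript coordinate of the first window base) and `snv_offset`
#'   (1-based position of the SNV within the window).
#' @export
extract_window <- function(snv, transcript, flank) {
  stopifnot(flank >= 1L)
  len <- nchar(transcript$sequence)
  pos <- snv$position
  stopifnot(pos >= 1L, pos <= len)
  a <- max(1L, pos - as.integer(flank))
  b <- min(len, pos + as.integer(flank))
  wt <- substr(transcript$sequence, a, b)
  off <- pos - a + 1L
  if (substr(wt, off, off) != snv$ref)
    stop("ref allele mismatch at ", transcript$transcript_id, ":", pos)
  mt <- wt
  substr(mt, off, off) <- snv$alt
  structure(list(wt_seq = wt, mt_seq = mt, window_start = a,
                 snv_offset = off), class = "window_pair")
}

#' Size of the miRNA x SNV screening space
#'
#' @param n_mirnas,n_snvs nonnegative integers.
#' @return list with `per_allele` (`n_mirnas * n_snvs`) and `total`
#'   (twice that: wild-type and mutant alleles are both screened).
#' @export
count_screen_space <- function(n_mirnas, n_snvs) {
  stopifnot(n_mirnas >= 0, n_snvs >= 0)
  per <- as.numeric(n_mirnas) * as.numeric(n_snvs)
  list(per_allele = per, total = 2 * per)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param fasta_path miRBase-style FASTA of mature miRNAs.
#' @return data frame `mirna_id`, `sequence` (RNA, 5'->3'); sequences
#'   shorter than 15 nt are rejected.
#' @export
read_mirnas <- function(fasta_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  out <- data.frame(mirna_id = sub("\\s.*$", "", names(seqs)),
                    sequence = normalize_rna(as.character(seqs)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(nchar(out$sequence) < 15L))
    stop("miRNA sequence(s) shorter than 15 nt")
  out
}

#' GC fraction of a sequence
#' @param seq character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(seq) {
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / nchar(seq)
}
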