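#' Read BED-like intervals in transcript space
#'
#' On disk the intervals are BED dialect (0-based, half-open, `chrom` holds
#' the transcript accession); they are converted to the package's 1-based
#' inclusive convention on read.
#'
#' @param path BED-like file: `transcript_id`, `start`, `end` and optional
#'   `name`, `score`, `bc` columns, tab-separated, no header.
#' @param n_extra how many optional columns to read (0-3).
#' @return data frame `transcript_id`, `start`, `end` (1-based inclusive)
#'   plus any optional columns.
#' @export
read_bed_intervals <- function(path, n_extra = 1L) {
  cols <- c("transcript_id", "start", "end", "name", "score", "bc")
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = cols[seq_len(3L + n_extra)],
                           fill = TRUE)
  tab$start <- as.integer(tab$start) + 1L  # 0-based half-open -> 1-based incl.
  tab$end <- as.integer(tab$end)
  stopifnot(all(tab$start <= tab$end))
  tab
}

write_bed_intervals <- function(tab, path, extra = character(0)) {
  out <- data.frame(transcript_id = tab$transcript_id,
                    start = tab$start - 1L, end = tab$end,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- tab[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Assemble the annotation bundle used by the downstream filters
#'
#' Collects the side inputs of the pipeline: the cancer-gene list, conserved
#' secondary-structure intervals (with a `cmfinder`/`rnaz` source tag in the
#' BED name column), Ago CLIP clusters with their biological-complexity (BC)
#' support counts, expressed / lung-cancer / NSCLC miRNA ID lists, and
#' linkage-disequilibrium partner variants. All file arguments are optional;
#' missing ones yield empty components.
#'
#' @param cancer_genes_path one gene symbol per line.
#' @param conserved_path BED-like with source tag in column 4.
#' @param clip_path BED-like with `name`, `score`, `bc` columns (BC = number
#'   of supporting CLIP experiments).
#' @param expressed_mirnas_path,lung_cancer_mirnas_path,nsclc_mirnas_path
#'   one miRNA ID per line.
#' @param ld_pairs_path TSV with header: `transcript_id`, `snv` (token),
#'   `partner_position`, `partner_ref`, `partner_alt`.
#' @return an `annotation_bundle` list.
#' @export
read_annotation_bundle <- function(cancer_genes_path = NULL,
                                   conserved_path = NULL,
                                   clip_path = NULL,
                                   expressed_mirnas_path = NULL,
                                   lung_cancer_mirnas_path = NULL,
                                   nsclc_mirnas_path = NULL,
                                   ld_pairs_path = NULL) {
  conserved <- if (is.null(conserved_path)) {
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), name = character(0))
  } else read_bed_intervals(conserved_path, n_extra = 1L)
  clip <- if (is.null(clip_path)) {
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), name = character(0), score = numeric(0),
               bc = integer(0))
  } else read_bed_intervals(clip_path, n_extra = 3L)
  if (nrow(clip) > 0) {
    clip$bc <- as.integer(clip$bc)
    stopifnot(all(clip$bc >= 0L))
  }
  ld <- if (is.null(ld_pairs_path)) {
    data.frame(transcript_id = character(0), snv = character(0),
               partner_position = integer(0), partner_ref = character(0),
               partner_alt = character(0))
  } else utils::read.table(ld_pairs_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(list(
    cancer_genes = if (is.null(cancer_genes_path)) character(0)
                   else read_id_list(cancer_genes_path),
    conserved = conserved,
    clip = clip,
    expressed_mirnas = if (is.null(expressed_mirnas_path)) character(0)
                       else read_id_list(expressed_mirnas_path),
    lung_cancer_mirnas = if (is.null(lung_cancer_mirnas_path)) character(0)
                         else read_id_list(lung_cancer_mirnas_path),
    nsclc_mirnas = if (is.null(nsclc_mirnas_path)) character(0)
                   else read_id_list(nsclc_mirnas_path),
    ld_pairs = ld
  ), class = "annotation_bundle")
}

empty_annotation_bundle <- function() read_annotation_bundle()
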