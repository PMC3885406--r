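#' One-sided Fisher's exact test for a 2x2 table
#'
#' Upper-tail (enrichment direction) hypergeometric probability of an
#' association at least as strong as observed, computed with log-factorials.
#' Rows of the table are carries / does-not-carry a disruptive variant;
#' columns are cancer-associated / other.
#'
#' @param a,b,c,d cell counts: `a` = disruptive & cancer, `b` = disruptive &
#'   other, `c` = non-disruptive & cancer, `d` = non-disruptive & other.
#' @return p-value in (0, 1]; a zero margin gives p = 1 with a warning.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("degenerate margin in contingency table; p = 1")
    return(1)
  }
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  amax <- min(r1, c1)
  ks <- a:amax
  logp <- lchoose2(c1, ks) + lchoose2(n - c1, r1 - ks) - lchoose2(n, r1)
  sum(exp(logp))
}

#' Gene-level enrichment of disruptive variants in cancer genes
#'
#' A gene is disruptive when it carries at least one structure candidate or
#' one retained target-site change. Builds the 2x2 table over the supplied
#' gene universe and applies [fisher_one_sided()].
#'
#' @param disruptive_genes character vector of genes carrying disruptive
#'   SNVs (must be a subset of `all_genes`).
#' @param cancer_genes cancer-associated gene symbols.
#' @param all_genes the gene universe.
#' @return list with the `table` (a, b, c, d), `p_one_sided`,
#'   `ratio_disruptive` (% cancer genes among disruptive) and
#'   `ratio_background` (% cancer genes in the universe).
#' @export
gene_level_enrichment <- function(disruptive_genes, cancer_genes, all_genes) {
  disruptive_genes <- unique(disruptive_genes)
  all_genes <- unique(all_genes)
  cancer_genes <- unique(cancer_genes)
  if (!all(disruptive_genes %in% all_genes))
    stop("disruptive genes must be a subset of the gene universe")
  cancer_genes <- intersect(cancer_genes, all_genes)
  a <- length(intersect(disruptive_genes, cancer_genes))
  b <- length(disruptive_genes) - a
  c <- length(cancer_genes) - a
  d <- length(all_genes) - a - b - c
  p <- if (length(disruptive_genes) == 0) 1 else fisher_one_sided(a, b, c, d)
  list(table = c(a = a, b = b, c = c, d = d), p_one_sided = p,
       ratio_disruptive = if (a + b > 0) 100 * a / (a + b) else NA_real_,
       ratio_background = 100 * (a + c) / (a + b + c + d))
}

#' SNV-level enrichment of disruptive variants in cancer genes
#'
#' As [gene_level_enrichment()] but with SNVs as the units: the population
#' of SNVs is split into disruptive / non-disruptive and located-in-cancer-
#' gene / other.
#'
#' @param all_snvs an `snv_set` (or any data frame with a `gene` column and
#'   one row per SNV).
#' @param disruptive_idx logical or integer index of the disruptive rows.
#' @param cancer_genes cancer-associated gene symbols.
#' @return as [gene_level_enrichment()].
#' @export
snv_level_enrichment <- function(all_snvs, disruptive_idx, cancer_genes) {
  in_cancer <- all_snvs$gene %in% cancer_genes
  disr <- logical(nrow(all_snvs))
  disr[disruptive_idx] <- TRUE
  a <- sum(disr & in_cancer); b <- sum(disr & !in_cancer)
  c <- sum(!disr & in_cancer); d <- sum(!disr & !in_cancer)
  if (length(cancer_genes) == 0) {
    warning("no cancer genes supplied; p = 1")
    return(list(table = c(a = a, b = b, c = c, d = d), p_one_sided = 1,
                ratio_disruptive = NA_real_, ratio_background = 0))
  }
  p <- if (!any(disr)) 1 else fisher_one_sided(a, b, c, d)
  list(table = c(a = a, b = b, c = c, d = d), p_one_sided = p,
       ratio_disruptive = if (a + b > 0) 100 * a / (a + b) else NA_real_,
       ratio_background = 100 * (a + c) / (a + b + c + d))
}

#' Candidates supported by both pipeline arms
#'
#' A (SNV, miRNA) site change is a combined candidate when its retained
#' target-site span intersects the local region where that SNV's
#' significant structural change was predicted (either measure's region).
#'
#' @param structure_results a `structure_results` table.
#' @param site_changes a `site_changes` table (retained rows are used when
#'   a `retained` column is present).
#' @return the subset of `site_changes` rows that overlap, with the
#'   matching structure p-values attached.
#' @export
structure_mirts_overlap <- function(structure_results, site_changes) {
  if (!is.null(site_changes$retained))
    site_changes <- site_changes[site_changes$retained, , drop = FALSE]
  if (nrow(site_changes) == 0 || nrow(structure_results) == 0)
    return(cbind(site_changes[0, , drop = FALSE],
                 p_d = numeric(0), p_r = numeric(0)))
  key_site <- paste(site_changes$transcript_id, site_changes$position,
                    site_changes$alt)
  key_str <- paste(structure_results$transcript_id,
                   structure_results$position, structure_results$alt)
  idx <- match(key_site, key_str)
  ok <- logical(nrow(site_changes))
  for (i in seq_len(nrow(site_changes))) {
    j <- idx[i]
    if (is.na(j)) next
    sr <- structure_results[j, ]
    inter <- function(s1, e1, s2, e2)
      !is.na(s2) && s1 <= e2 && s2 <= e1
    ok[i] <- inter(site_changes$span_start[i], site_changes$span_end[i],
                   sr$d_region_start, sr$d_region_end) ||
      inter(site_changes$span_start[i], site_changes$span_end[i],
            sr$r_region_start, sr$r_region_end)
  }
  out <- site_changes[ok, , drop = FALSE]
  out$p_d <- structure_results$p_d[idx[ok]]
  out$p_r <- structure_results$p_r[idx[ok]]
  out
}

#' Recurrently hit genes and miRNAs
#'
#' @param candidates data frame with `gene`, and SNV identity columns
#'   (`transcript_id`, `position`, `alt`); `mirna_id` optional.
#' @return list with `genes` (genes carrying >= 2 disruptive SNVs, with
#'   counts) and `mirnas` (miRNAs with > 2 changed targets, with counts).
#' @export
multi_hit_summary <- function(candidates) {
  snv_key <- unique(candidates[, intersect(
    c("gene", "transcript_id", "position", "alt"), names(candidates))])
  gcount <- table(snv_key$gene)
  genes <- data.frame(gene = names(gcount), n_snvs = as.integer(gcount),
                      stringsAsFactors = FALSE)
  genes <- genes[genes$n_snvs >= 2L, , drop = FALSE]
  genes <- genes[order(-genes$n_snvs, genes$gene), , drop = FALSE]
  mirnas <- data.frame(mirna_id = character(0), n_targets = integer(0))
  if ("mirna_id" %in% names(candidates)) {
    mcount <- table(candidates$mirna_id)
    mirnas <- data.frame(mirna_id = names(mcount),
                         n_targets = as.integer(mcount),
                         stringsAsFactors = FALSE)
    mirnas <- mirnas[mirnas$n_targets > 2L, , drop = FALSE]
    mirnas <- mirnas[order(-mirnas$n_targets, mirnas$mirna_id), ,
                     drop = FALSE]
  }
  list(genes = genes, mirnas = mirnas)
}
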