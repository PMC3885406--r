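#' Run configuration for the end-to-end pipeline
#'
#' Collects all input paths and tunable thresholds. The defaults are the
#' analysis defaults: folding flank 200 nt, miRNA flank 30 nt (61-mers),
#' raw-p cutoff 0.1, high-confidence cutoff 0.05, FDR 10%, duplex score 45
#' and relaxed energy -5 kcal/mol with seed scale 2, working-site threshold
#' -11 kcal/mol, CLIP BC >= 2.
#'
#' @param transcripts_fa,utr_spans,snvs,mirnas_fa input paths (see
#'   [read_transcripts()], [read_snvs()], [read_mirnas()]).
#' @param cancer_genes,conserved,clip,expressed_mirnas,lung_cancer_mirnas,nsclc_mirnas,ld_pairs
#'   optional annotation paths (see [read_annotation_bundle()]).
#' @param out_dir output directory.
#' @param flank_structure,flank_mirna window flanks (nt).
#' @param p_cutoff,high_conf_cutoff,fdr structure-stage thresholds.
#' @param k_null null substitutions per SNV.
#' @param energy_threshold,score_min,energy_relaxed,scale duplex thresholds.
#' @param bc_min CLIP biological-complexity minimum.
#' @param rng_seed integer seed (all randomness derives from it).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(transcripts_fa, utr_spans, snvs, mirnas_fa = NULL,
                            cancer_genes = NULL, conserved = NULL,
                            clip = NULL, expressed_mirnas = NULL,
                            lung_cancer_mirnas = NULL, nsclc_mirnas = NULL,
                            ld_pairs = NULL, out_dir = "utrsnv_out",
                            flank_structure = 200L, flank_mirna = 30L,
                            p_cutoff = 0.1, high_conf_cutoff = 0.05,
                            fdr = 0.10, k_null = 1000L,
                            energy_threshold = -11, score_min = 45,
                            energy_relaxed = -5, scale = 2, bc_min = 2L,
                            rng_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline end to end (or stage by stage)
#'
#' Stages: `structure` (riboSNitch-style folding-disruption scan), `mirna`
#' (target-site change cascade), `integrate` (overlap of the two arms,
#' recurrence summaries, cancer-gene enrichment). Writes TSV reports and a
#' JSON metadata file (thresholds, seed, per-stage counts) into
#' `config$out_dir`; identical config + seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of `c("structure", "mirna", "integrate")`.
#' @param model an [energy_model()].
#' @return invisibly, a list with `structure`, `mirna`, `integration` and
#'   `metadata`.
#' @export
run_pipeline <- function(config, stages = c("structure", "mirna", "integrate"),
                         model = default_energy_model()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("structure", "mirna", "integrate"),
                      several.ok = TRUE)
  for (p in c("transcripts_fa", "utr_spans", "snvs")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("missing input: --", gsub("_", "-", p), " (", config[[p]], ")")
  }
  if ("mirna" %in% stages &&
      (is.null(config$mirnas_fa) || !file.exists(config$mirnas_fa)))
    stop("missing input: --mirnas-fa (required for the mirna stage)")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  transcripts <- read_transcripts(config$transcripts_fa, config$utr_spans)
  snvs <- read_snvs(config$snvs, transcripts)
  ann <- read_annotation_bundle(
    cancer_genes_path = config$cancer_genes,
    conserved_path = config$conserved, clip_path = config$clip,
    expressed_mirnas_path = config$expressed_mirnas,
    lung_cancer_mirnas_path = config$lung_cancer_mirnas,
    nsclc_mirnas_path = config$nsclc_mirnas,
    ld_pairs_path = config$ld_pairs)

  out <- list()
  meta <- list(
    thresholds = config[c("flank_structure", "flank_mirna", "p_cutoff",
                          "high_conf_cutoff", "fdr", "k_null",
                          "energy_threshold", "score_min", "energy_relaxed",
                          "scale", "bc_min")],
    rng_seed = config$rng_seed,
    n_transcripts = nrow(transcripts), n_snvs = nrow(snvs),
    gene_level_units = "unique (gene, SNV) pairs",
    pvalue_null = "random single substitutions in the same window")

  sfile <- file.path(config$out_dir, "structure_results.tsv")
  if ("structure" %in% stages) {
    out$structure <- run_structure_stage(
      transcripts, snvs, ann, model, flank = config$flank_structure,
      k = config$k_null, fdr = config$fdr, p_cutoff = config$p_cutoff,
      rng_seed = config$rng_seed)
    utils::write.table(out$structure, sfile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta$structure_skipped_ambiguous <-
      attr(out$structure, "n_skipped_ambiguous")
  } else if (file.exists(sfile)) {
    out$structure <- utils::read.table(sfile, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  }

  mfile <- file.path(config$out_dir, "site_changes.tsv")
  if ("mirna" %in% stages) {
    mirnas <- read_mirnas(config$mirnas_fa)
    out$mirna <- run_mirna_stage(
      transcripts, snvs, mirnas, ann, model, flank = config$flank_mirna,
      scale = config$scale, score_min = config$score_min,
      energy_relaxed = config$energy_relaxed,
      energy_threshold = config$energy_threshold, bc_min = config$bc_min)
    utils::write.table(out$mirna, mfile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta$mirna_stage_counts <- as.list(attr(out$mirna, "stage_counts"))
    meta$alter_lr_mu <- attr(out$mirna, "mu")
  } else if (file.exists(mfile)) {
    out$mirna <- utils::read.table(mfile, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }

  if ("integrate" %in% stages && !is.null(out$structure) &&
      !is.null(out$mirna)) {
    str_cand <- out$structure[out$structure$pass_raw_d |
                                out$structure$pass_raw_r, , drop = FALSE]
    site_cand <- out$mirna[isTRUE_vec(out$mirna$retained), , drop = FALSE]
    combined <- structure_mirts_overlap(out$structure, out$mirna)
    disruptive_genes <- union(str_cand$gene, site_cand$gene)
    enr <- gene_level_enrichment(disruptive_genes, ann$cancer_genes,
                                 unique(transcripts$gene))
    snv_keys <- paste(snvs$gene, snvs$position, snvs$alt)
    dis_keys <- union(paste(str_cand$gene, str_cand$position, str_cand$alt),
                      paste(site_cand$gene, site_cand$position,
                            site_cand$alt))
    enr_snv <- snv_level_enrichment(snvs, snv_keys %in% dis_keys,
                                    ann$cancer_genes)
    recur <- multi_hit_summary(rbind(
      str_cand[, c("gene", "transcript_id", "position", "alt")],
      site_cand[, c("gene", "transcript_id", "position", "alt")]))
    out$integration <- list(combined = combined,
                            gene_enrichment = enr,
                            snv_enrichment = enr_snv,
                            recurrence = recur)
    utils::write.table(combined,
                       file.path(config$out_dir, "combined_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sort(disruptive_genes),
               file.path(config$out_dir, "disruptive_genes.txt"))
    meta$gene_enrichment <- enr[c("table", "p_one_sided",
                                  "ratio_disruptive", "ratio_background")]
    meta$snv_enrichment <- enr_snv[c("table", "p_one_sided")]
    meta$n_combined_candidates <- nrow(combined)
  }

  out$metadata <- meta
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x
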