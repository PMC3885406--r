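#' Reverse complement of an RNA sequence
#' @param seq character vector of RNA sequences.
#' @return reverse complements (RNA alphabet).
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Canonical seed matches of a miRNA in a target subsequence
#'
#' Scans every 8-nt register of the subsequence for TargetScan-style seed
#' matches against the miRNA seed. Types, in increasing strength:
#' `7mer-1a` (Watson-Crick match to miRNA positions 2-7 plus an A opposite
#' position 1), `7mer-m8` (Watson-Crick match to positions 2-8), `8mer-1a`
#' (both). G:U pairs do not count as seed matches. One register reports only
#' its strongest type. `site_end` is the 1-based subsequence position
#' opposite miRNA position 1.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param subseq target subsequence (>= 8 nt).
#' @return data frame `site_end`, `type`.
#' @export
find_seed_matches <- function(mirna, subseq) {
  n <- nchar(subseq)
  stopifnot(n >= 8L)
  rc28 <- reverse_complement(substr(mirna, 2L, 8L))  # 7 nt
  rc27 <- reverse_complement(substr(mirna, 2L, 7L))  # 6 nt
  ends <- 8:n
  s <- ends - 7L
  first7 <- substr(rep(subseq, length(s)), s, s + 6L)
  mid6 <- substr(rep(subseq, length(s)), s + 1L, s + 6L)
  a1 <- substr(rep(subseq, length(s)), s + 7L, s + 7L) == "A"
  m28 <- first7 == rc28
  m27 <- mid6 == rc27
  type <- ifelse(m28 & a1, "8mer-1a",
                 ifelse(m28, "7mer-m8",
                        ifelse(m27 & a1, "7mer-1a", NA_character_)))
  keep <- !is.na(type)
  data.frame(site_end = ends[keep], type = type[keep],
             stringsAsFactors = FALSE)
}

SEED_TYPE_ORDER <- c("7mer-1a" = 1L, "7mer-m8" = 2L, "8mer-1a" = 3L)

#' Does the seed-match pattern differ between the two alleles?
#'
#' @param wt_matches,mt_matches outputs of [find_seed_matches()] on the
#'   aligned wild-type and mutant subsequences.
#' @return TRUE when the set of (register, type) pairs differs.
#' @export
seed_change_filter <- function(wt_matches, mt_matches) {
  key <- function(m) sort(paste(m$site_end, m$type))
  !identical(key(wt_matches), key(mt_matches))
}

default_duplex_params <- function(scale = 2, score_min = 45,
                                  energy_relaxed = -5) {
  list(match = 5, gu = 1, mismatch = -3, gap_open = -9, gap_extend = -4,
       scale = scale, seed_lo = 2L, seed_hi = 8L,
       score_min = score_min, energy_relaxed = energy_relaxed)
}

#' Scan a subsequence for miRNA duplex binding sites
#'
#' miRanda-style anchored local complementarity alignment: for every
#' register (subsequence position opposite miRNA position 1), an
#' antiparallel gapped alignment is scored (Watson-Crick +5, G:U +1,
#' mismatch -3, gap open -9 / extend -4; columns opposite miRNA positions
#' 2-8 weighted by `scale`, default 2 so the seed is not over-weighted).
#' Sites with score >= `score_min` get a duplex free energy (stacks over
#' consecutive paired columns, affine interior/bulge penalties, plus the
#' model's duplex initiation); sites above `energy_relaxed` are dropped.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param subseq target subsequence.
#' @param model an [energy_model()].
#' @param params scoring parameters, see `default_duplex_params()`;
#'   defaults are the relaxed cutoffs (score 45, energy -5 kcal/mol).
#' @return data frame `register`, `score`, `energy`, `span_start`,
#'   `span_end`, `n_pairs` (site span in subsequence coordinates).
#' @export
scan_duplex <- function(mirna, subseq, model = default_energy_model(),
                        params = default_duplex_params()) {
  .duplex_scan_cpp(encode_rna(mirna), encode_rna(subseq), unclass(model),
                   params)
}

#' Retain the strongest binding site that differs between alleles
#'
#' Sites are paired by register (the subsequence position opposite miRNA
#' position 1; substitution-only SNVs keep the frames aligned). Among
#' registers whose presence or energy differs between wild type and mutant,
#' the one minimizing `min(dG_wt, dG_snv)` is retained.
#'
#' @param wt_sites,mt_sites outputs of [scan_duplex()] for the two alleles.
#' @return NULL when no register differs; otherwise a list with `register`,
#'   `dG_wt`, `dG_snv` (NA for an absent side), and the spans of whichever
#'   side(s) exist.
#' @export
strongest_differing_site <- function(wt_sites, mt_sites) {
  regs <- union(wt_sites$register, mt_sites$register)
  if (length(regs) == 0) return(NULL)
  wt_idx <- match(regs, wt_sites$register)
  mt_idx <- match(regs, mt_sites$register)
  dg_wt <- wt_sites$energy[wt_idx]
  dg_mt <- mt_sites$energy[mt_idx]
  differs <- is.na(dg_wt) != is.na(dg_mt) |
    (!is.na(dg_wt) & !is.na(dg_mt) & abs(dg_wt - dg_mt) > 1e-9)
  if (!any(differs)) return(NULL)
  best <- pmin(dg_wt, dg_mt, na.rm = TRUE)
  best[!differs] <- Inf
  pick <- which.min(best)
  span <- if (!is.na(wt_idx[pick]))
    c(wt_sites$span_start[wt_idx[pick]], wt_sites$span_end[wt_idx[pick]])
  else
    c(mt_sites$span_start[mt_idx[pick]], mt_sites$span_end[mt_idx[pick]])
  list(register = regs[pick], dG_wt = dg_wt[pick], dG_snv = dg_mt[pick],
       span_start = span[1], span_end = span[2])
}

#' Classify a target-site change as create / destroy / alter
#'
#' Uses the conservative working threshold (default -11 kcal/mol):
#' `create` when only the mutant has a site and its energy reaches the
#' threshold; `destroy` when only the wild type does; `alter` when both
#' alleles have a site and at least one reaches the threshold.
#'
#' @param dG_wt,dG_snv duplex energies (kcal/mol), NA for an absent site.
#' @param threshold working-interaction energy threshold.
#' @return `"create"`, `"destroy"`, `"alter"`, or NA when neither side
#'   reaches the threshold.
#' @export
classify_site_change <- function(dG_wt, dG_snv, threshold = -11) {
  stopifnot(!(is.na(dG_wt) && is.na(dG_snv)))
  if (is.na(dG_wt) && dG_snv <= threshold) return("create")
  if (is.na(dG_snv) && dG_wt <= threshold) return("destroy")
  if (!is.na(dG_wt) && !is.na(dG_snv) &&
      min(dG_wt, dG_snv) <= threshold) return("alter")
  NA_character_
}

#' Base-2 log-ratio of mutant to wild-type duplex energy
#'
#' `lr = log2(dG_snv / dG_wt)` for two negative energies: 0 when the energy
#' is unchanged, negative when the wild type binds more strongly (lower
#' energy), positive otherwise.
#'
#' @param dG_wt,dG_snv duplex energies, both < 0.
#' @return the log-ratio, or NA when either energy is >= 0 or missing.
#' @export
log_ratio <- function(dG_wt, dG_snv) {
  if (is.na(dG_wt) || is.na(dG_snv) || dG_wt >= 0 || dG_snv >= 0)
    return(NA_real_)
  log2(dG_snv / dG_wt)
}

#' Keep alter-set candidates with above-mean |lr|
#'
#' The threshold is the mean of |lr| over the whole alter set of the run;
#' retention is strict (`|lr| > mu`), so a degenerate set with all equal
#' |lr| retains nothing (logged).
#'
#' @param alter_set data frame with an `lr` column.
#' @return list with the `retained` subset and the threshold `mu`.
#' @export
alter_mean_filter <- function(alter_set) {
  stopifnot(nrow(alter_set) > 0)
  mu <- mean(abs(alter_set$lr), na.rm = TRUE)
  retained <- alter_set[!is.na(alter_set$lr) & abs(alter_set$lr) > mu, ,
                        drop = FALSE]
  if (nrow(retained) == 0)
    message("alter-set |lr| filter retained nothing (all values <= mean)")
  list(retained = retained, mu = mu)
}

#' Ago CLIP-cluster support filter
#'
#' For destroy/alter candidates the SNV must lie inside a CLIP cluster with
#' biological complexity >= `bc_min`. Create candidates pass through (the
#' CLIP evidence covers the wild type only), flagged `NA`.
#'
#' @param class site-change class.
#' @param transcript_id,position SNV location (transcript coordinates).
#' @param clip CLIP clusters (`transcript_id`, `start`, `end`, `bc`).
#' @param bc_min minimum biological complexity (default 2).
#' @return TRUE / FALSE, or NA for create (not applicable).
#' @export
clip_filter <- function(class, transcript_id, position, clip, bc_min = 2L) {
  if (class == "create") return(NA)
  hits <- clip[clip$transcript_id == transcript_id &
                 clip$start <= position & clip$end >= position &
                 clip$bc >= bc_min, , drop = FALSE]
  nrow(hits) > 0
}

#' Respiratory-expression filter for miRNAs
#'
#' @param mirna_id miRNA identifier(s).
#' @param expressed_set IDs of miRNAs expressed in the tissue of interest;
#'   an empty set fails everything with a warning.
#' @return logical vector.
#' @export
expression_filter <- function(mirna_id, expressed_set) {
  if (length(expressed_set) == 0) {
    warning("expressed-miRNA set is empty: all candidates fail the filter")
    return(rep(FALSE, length(mirna_id)))
  }
  mirna_id %in% expressed_set
}

#' Run the miRNA target-site stage
#'
#' The full cascade: extract the 61-mer around each SNV, keep (SNV, miRNA)
#' pairs whose seed-match pattern differs between alleles, score duplexes
#' for both alleles with relaxed cutoffs, retain the strongest differing
#' site per pair, classify create/destroy/alter at the working energy
#' threshold, compute the log-ratio for alter candidates, then apply the
#' CLIP support filter, the above-mean |lr| filter, and the
#' expressed-miRNA filter. Per-stage counts are recorded.
#'
#' @param transcripts a `transcript_set`.
#' @param snvs an `snv_set`.
#' @param mirnas data frame `mirna_id`, `sequence`.
#' @param annotations an `annotation_bundle` (CLIP clusters and miRNA sets).
#' @param model an [energy_model()].
#' @param flank subsequence flank (default 30, i.e. 61-mers).
#' @param scale,score_min,energy_relaxed alignment parameters (defaults 2,
#'   45, -5).
#' @param energy_threshold working-site threshold (default -11 kcal/mol).
#' @param bc_min CLIP biological-complexity minimum (default 2).
#' @param mu_after_clip compute the alter-set |lr| mean after the CLIP
#'   filter (default TRUE) or before it.
#' @return a `site_changes` data frame (one row per retained (SNV, miRNA)
#'   candidate) with energies, class, lr, spans and filter flags; attributes
#'   `stage_counts` (the cascade's in/out counts) and `mu` (the |lr|
#'   threshold).
#' @export
run_mirna_stage <- function(transcripts, snvs, mirnas,
                            annotations = empty_annotation_bundle(),
                            model = default_energy_model(), flank = 30L,
                            scale = 2, score_min = 45, energy_relaxed = -5,
                            energy_threshold = -11, bc_min = 2L,
                            mu_after_clip = TRUE) {
  params <- default_duplex_params(scale, score_min, energy_relaxed)
  counts <- c(pairs_screened = 0, seed_change = 0, with_differing_site = 0,
              classified = 0, clip_pass = 0, lr_pass = 0, expressed = 0)
  rows <- list()
  for (r in seq_len(nrow(snvs))) {
    snv <- snvs[r, , drop = FALSE]
    tx <- transcripts[transcripts$transcript_id == snv$transcript_id, ,
                      drop = FALSE]
    if (nrow(tx) == 0L) next
    win <- extract_window(snv, tx, flank)
    if (grepl("N", win$wt_seq, fixed = TRUE)) next
    for (m in seq_len(nrow(mirnas))) {
      counts["pairs_screened"] <- counts["pairs_screened"] + 1
      wt_seed <- find_seed_matches(mirnas$sequence[m], win$wt_seq)
      mt_seed <- find_seed_matches(mirnas$sequence[m], win$mt_seq)
      if (!seed_change_filter(wt_seed, mt_seed)) next
      counts["seed_change"] <- counts["seed_change"] + 1
      wt_sites <- scan_duplex(mirnas$sequence[m], win$wt_seq, model, params)
      mt_sites <- scan_duplex(mirnas$sequence[m], win$mt_seq, model, params)
      site <- strongest_differing_site(wt_sites, mt_sites)
      if (is.null(site)) next
      counts["with_differing_site"] <- counts["with_differing_site"] + 1
      cls <- classify_site_change(site$dG_wt, site$dG_snv, energy_threshold)
      if (is.na(cls)) next
      counts["classified"] <- counts["classified"] + 1
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = snv$transcript_id, gene = snv$gene,
        position = snv$position, ref = snv$ref, alt = snv$alt,
        utr_label = snv$utr_label, dbsnp_id = snv$dbsnp_id,
        mirna_id = mirnas$mirna_id[m], class = cls,
        dG_wt = site$dG_wt, dG_snv = site$dG_snv,
        lr = log_ratio(site$dG_wt, site$dG_snv),
        span_start = site$span_start + win$window_start - 1L,
        span_end = site$span_end + win$window_start - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), gene = character(0),
               position = integer(0), ref = character(0), alt = character(0),
               utr_label = character(0), dbsnp_id = character(0),
               mirna_id = character(0), class = character(0),
               dG_wt = numeric(0), dG_snv = numeric(0), lr = numeric(0),
               span_start = integer(0), span_end = integer(0))
  attr(out, "pre_filter") <- out   # classified candidates before filters

  # CLIP filter (destroy/alter only; create passes through)
  if (nrow(out) > 0) {
    out$clip_pass <- vapply(seq_len(nrow(out)), function(i)
      clip_filter(out$class[i], out$transcript_id[i], out$position[i],
                  annotations$clip, bc_min), NA)
    keep <- is.na(out$clip_pass) | out$clip_pass
    counts["clip_pass"] <- sum(keep)
    mu <- NA_real_
    if (mu_after_clip) {
      alter_pool <- out[keep & out$class == "alter", , drop = FALSE]
    } else {
      alter_pool <- out[out$class == "alter", , drop = FALSE]
    }
    if (nrow(alter_pool) > 0) mu <- mean(abs(alter_pool$lr), na.rm = TRUE)
    lr_keep <- out$class != "alter" |
      (!is.na(out$lr) & !is.na(mu) & abs(out$lr) > mu)
    keep <- keep & lr_keep
    counts["lr_pass"] <- sum(keep)
    out$mirna_expressed <- expression_filter_quiet(out$mirna_id,
                                                  annotations$expressed_mirnas)
    out$lung_cancer_mirna <- out$mirna_id %in% annotations$lung_cancer_mirnas
    out$nsclc_mirna <- out$mirna_id %in% annotations$nsclc_mirnas
    if (length(annotations$expressed_mirnas) > 0)
      keep <- keep & out$mirna_expressed
    counts["expressed"] <- sum(keep)
    out$retained <- keep
    attr(out, "mu") <- mu
  }
  attr(out, "stage_counts") <- counts
  class(out) <- c("site_changes", "data.frame")
  out
}

# expression_filter without the empty-set warning, for annotation columns
expression_filter_quiet <- function(mirna_id, expressed_set) {
  if (length(expressed_set) == 0) return(rep(NA, length(mirna_id)))
  mirna_id %in% expressed_set
}
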