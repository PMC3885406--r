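#' Euclidean distance between two pair-probability matrices over a region
#'
#' `d = sqrt( sum_{start <= k < l <= end} (P_wt[k,l] - P_mt[k,l])^2 ) / len`,
#' where `len` is the region length. Normalizing by length keeps the measure
#' comparable across regions of different size.
#'
#' @param p_wt,p_mt same-shape symmetric pair-probability matrices.
#' @param region integer c(start, end), 1-based inclusive, in window
#'   coordinates.
#' @return nonnegative numeric scalar.
#' @export
region_distance_euclidean <- function(p_wt, p_mt, region) {
  a <- region[1]; b <- region[2]
  stopifnot(all(dim(p_wt) == dim(p_mt)), a >= 1, b <= nrow(p_wt), a <= b)
  d2 <- 0
  if (b > a) {
    sub <- (p_wt[a:b, a:b] - p_mt[a:b, a:b])^2
    d2 <- sum(sub[upper.tri(sub)])
  }
  sqrt(d2) / (b - a + 1)
}

#' Pearson correlation of positional pairing profiles over a region
#'
#' @param profile_wt,profile_mt positional profiles
#'   (see [positional_profile()]).
#' @param region integer c(start, end) in window coordinates; length >= 2.
#' @return correlation in [-1, 1], or NA when either slice has zero
#'   variance (the region is then non-evaluable and excluded from the
#'   minimum in [scan_local_regions()]).
#' @export
region_corr_pearson <- function(profile_wt, profile_mt, region) {
  a <- region[1]; b <- region[2]
  stopifnot(length(profile_wt) == length(profile_mt), a >= 1,
            b <= length(profile_wt), b - a + 1 >= 2)
  x <- profile_wt[a:b]; y <- profile_mt[a:b]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Exhaustive scan of local regions for the strongest ensemble change
#'
#' Scans every region of length `l_min` up to the full window and reports
#' the region of maximum Euclidean distance (`d_max`) and the region of
#' minimum profile correlation (`r_min`). Ties are broken toward the longer
#' region, then the smaller start, so the scan is deterministic. Implemented
#' with 2-D prefix sums, O(n^2) overall.
#'
#' @param p_wt,p_mt pair-probability matrices (or `bp_matrix` objects).
#' @param l_min minimum region length (default 10).
#' @return list with `d_max`, `d_region`, `r_min`, `r_region`, and
#'   `no_change` (TRUE when the matrices are identical).
#' @export
scan_local_regions <- function(p_wt, p_mt, l_min = 10L) {
  if (inherits(p_wt, "bp_matrix")) p_wt <- p_wt$p
  if (inherits(p_mt, "bp_matrix")) p_mt <- p_mt$p
  n <- nrow(p_wt)
  stopifnot(n >= l_min, all(dim(p_mt) == c(n, n)))

  ends <- matrix(seq_len(n), n, n, byrow = TRUE)    # column index = region end
  starts <- matrix(seq_len(n), n, n)                # row index = region start
  len <- ends - starts + 1L
  valid <- len >= l_min

  # --- d over all regions: 2-D prefix sums of squared differences ---
  D <- (p_wt - p_mt)^2
  Cp <- matrix(0, n + 1L, n + 1L)
  Cp[-1L, -1L] <- apply(apply(D, 2L, cumsum), 1L, cumsum)  # Cp[i+1,j+1]=sum D[1:i,1:j]
  diagC <- diag(Cp)
  # block[a,b] = sum of D over rows a..b, cols a..b; Cp is symmetric, so the
  # two cross terms coincide
  block <- outer(rep(1, n), diagC[-1L]) - 2 * Cp[seq_len(n), -1L] +
    outer(diagC[seq_len(n)], rep(1, n))
  dmat <- sqrt(pmax(block, 0) / 2) / len
  dmat[!valid] <- NA_real_

  # --- r over all regions: prefix sums of the two profiles ---
  x <- rowSums(p_wt); y <- rowSums(p_mt)
  csum <- function(v) c(0, cumsum(v))
  sx <- csum(x); sxx <- csum(x^2); sy <- csum(y); syy <- csum(y^2)
  sxy <- csum(x * y)
  seg <- function(s) outer(rep(1, n), s[-1L]) - outer(s[seq_len(n)], rep(1, n))
  Sx <- seg(sx); Sy <- seg(sy)
  Vx <- seg(sxx) - Sx^2 / len
  Vy <- seg(syy) - Sy^2 / len
  Cxy <- seg(sxy) - Sx * Sy / len
  eps <- 1e-12
  rmat <- Cxy / sqrt(pmax(Vx, 0) * pmax(Vy, 0))
  rmat[Vx <= eps | Vy <= eps] <- NA_real_
  rmat[rmat > 1] <- 1; rmat[rmat < -1] <- -1
  rmat[!valid] <- NA_real_

  pick <- function(mat, what) {
    if (all(is.na(mat))) return(NULL)
    target <- if (what == "max") max(mat, na.rm = TRUE) else min(mat, na.rm = TRUE)
    idx <- which(!is.na(mat) & mat == target, arr.ind = TRUE)
    l <- idx[, 2L] - idx[, 1L] + 1L
    ord <- order(-l, idx[, 1L])
    best <- idx[ord[1L], ]
    list(value = target, region = c(unname(best[1L]), unname(best[2L])))
  }
  d <- pick(dmat, "max")
  r <- pick(rmat, "min")
  list(d_max = d$value, d_region = d$region,
       r_min = if (is.null(r)) NA_real_ else r$value,
       r_region = if (is.null(r)) NULL else r$region,
       no_change = isTRUE(d$value == 0))
}

#' Empirical p-values for an SNV's structural effect
#'
#' The null distribution is built from `k` random single substitutions in
#' the same window (uniform over positions and the three alternate bases,
#' excluding the observed substitution). With the plus-one convention,
#' `p_d = (1 + #{null d_max >= observed}) / (k + 1)`; the correlation
#' measure is mirrored (`<=`).
#'
#' @param window a `window_pair` from [extract_window()].
#' @param model an [energy_model()].
#' @param k number of null substitutions (>= 19).
#' @param l_min minimum region length for the scan.
#' @param rng_seed integer seed; the draw is reproducible given the seed.
#' @return list with the observed `d_max`, `d_region`, `r_min`, `r_region`
#'   and the p-values `p_d`, `p_r`.
#' @export
empirical_pvalue <- function(window, model = default_energy_model(),
                             k = 1000L, l_min = 10L, rng_seed = NULL) {
  stopifnot(k >= 19L)
  wt <- compute_pair_probabilities(window$wt_seq, model)
  mt <- compute_pair_probabilities(window$mt_seq, model)
  obs <- scan_local_regions(wt$p, mt$p, l_min)
  null_d <- numeric(k); null_r <- numeric(k)
  n <- nchar(window$wt_seq)
  wt_chars <- strsplit(window$wt_seq, "", fixed = TRUE)[[1]]
  obs_alt <- substr(window$mt_seq, window$snv_offset, window$snv_offset)
  draw <- function() {
    repeat {
      pos <- sample.int(n, 1L)
      alt <- sample(setdiff(BASES, wt_chars[pos]), 1L)
      if (!(pos == window$snv_offset && alt == obs_alt))
        return(c(pos, alt))
    }
  }
  run <- function() {
    for (i in seq_len(k)) {
      sub <- draw()
      mseq <- window$wt_seq
      substr(mseq, as.integer(sub[1L]), as.integer(sub[1L])) <- sub[2L]
      mbp <- compute_pair_probabilities(mseq, model)
      sc <- scan_local_regions(wt$p, mbp$p, l_min)
      null_d[i] <<- sc$d_max
      null_r[i] <<- if (is.na(sc$r_min)) 1 else sc$r_min
    }
  }
  if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
  obs_r <- if (is.na(obs$r_min)) 1 else obs$r_min
  list(d_max = obs$d_max, d_region = obs$d_region,
       r_min = obs$r_min, r_region = obs$r_region,
       p_d = (1 + sum(null_d >= obs$d_max)) / (k + 1),
       p_r = (1 + sum(null_r <= obs_r)) / (k + 1))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param fdr false discovery rate threshold (default 0.10).
#' @return list with `q` (monotone step-up q-values) and `pass`
#'   (`q <= fdr`); empty input gives empty output.
#' @export
bh_adjust <- function(pvalues, fdr = 0.10) {
  if (length(pvalues) == 0)
    return(list(q = numeric(0), pass = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, pass = !is.na(q) & q <= fdr)
}

#' Confidence tier from the two structure p-values
#'
#' `high` when both p-values are below 0.05; `medium` when not high but
#' either is below 0.10; `none` otherwise.
#'
#' @param p_d,p_r p-values of the distance and correlation measures.
#' @return `"high"`, `"medium"` or `"none"` (vectorized).
#' @export
classify_confidence <- function(p_d, p_r) {
  high <- p_d < 0.05 & p_r < 0.05
  medium <- !high & (p_d < 0.1 | p_r < 0.1)
  ifelse(high, "high", ifelse(medium, "medium", "none"))
}

#' Overlap of a disrupted region with conserved-structure intervals
#'
#' `100 * |region intersect interval| / |region|`, rounded to integer; only
#' the best-overlapping interval per source is reported.
#'
#' @param region c(start, end) in transcript coordinates.
#' @param conserved data frame `transcript_id`, `start`, `end`, `name`
#'   (source tag), already restricted or restrictable by `transcript_id`.
#' @param transcript_id optional filter applied to `conserved`.
#' @return data frame `source`, `pct` (one row per source with a positive
#'   overlap; zero rows when nothing overlaps).
#' @export
conserved_overlap_pct <- function(region, conserved, transcript_id = NULL) {
  if (!is.null(transcript_id))
    conserved <- conserved[conserved$transcript_id == transcript_id, ,
                           drop = FALSE]
  if (nrow(conserved) == 0)
    return(data.frame(source = character(0), pct = integer(0)))
  len <- region[2] - region[1] + 1
  ov <- pmax(0L, pmin(region[2], conserved$end) -
               pmax(region[1], conserved$start) + 1L)
  pct <- as.integer(round(100 * ov / len))
  keep <- pct > 0
  if (!any(keep))
    return(data.frame(source = character(0), pct = integer(0)))
  agg <- tapply(pct[keep], conserved$name[keep], max)
  data.frame(source = names(agg), pct = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

format_overlap <- function(ov) {
  if (nrow(ov) == 0) return("-")
  paste(sprintf("%d^%s", ov$pct, ov$source), collapse = ";")
}

#' Summaries of region lengths and SNV-to-region distances
#'
#' @param results a structure-stage result table
#'   (see [run_structure_stage()]) with columns `d_region_start`,
#'   `d_region_end` (transcript coordinates) and `position`.
#' @return list with the raw `lengths` and `distances` vectors and binned
#'   tables (`length_hist` bins include 50-100 and >300; distance 0 means
#'   the SNV lies inside its region).
#' @export
region_stats <- function(results) {
  stopifnot(nrow(results) > 0)
  lengths <- results$d_region_end - results$d_region_start + 1L
  distances <- snv_region_distance(results$position,
                                   results$d_region_start,
                                   results$d_region_end)
  length_hist <- table(cut(lengths, c(0, 50, 100, 150, 200, 250, 300, Inf),
                           right = TRUE))
  dist_hist <- table(cut(distances, c(-1, 0, 10, 25, 50, 100, Inf),
                         right = TRUE))
  list(lengths = lengths, distances = distances,
       length_hist = length_hist, distance_hist = dist_hist)
}

snv_region_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0L,
         ifelse(pos < start, start - pos, pos - end))
}

#' Compare GC content of disruptive vs. all windows
#'
#' Two-sided two-sample Kolmogorov-Smirnov comparison of the GC-fraction
#' distributions of the flanking windows of disruptive SNVs against all
#' SNVs.
#'
#' @param disruptive_gc,all_gc numeric vectors of window GC fractions.
#' @return list with `statistic` (KS D), `p_value`, and both input vectors.
#' @export
gc_compare <- function(disruptive_gc, all_gc) {
  stopifnot(length(disruptive_gc) > 0, length(all_gc) > 0)
  kt <- suppressWarnings(stats::ks.test(disruptive_gc, all_gc,
                                        alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       disruptive_gc = disruptive_gc, all_gc = all_gc)
}

#' Re-test a disruptive SNV jointly with a linked partner variant
#'
#' Applies both the SNV and its linkage-disequilibrium partner to the
#' mutant window and recomputes the empirical p-values against the
#' unmodified wild type. The pair is a structure-stabilizing haplotype when
#' neither measure remains significant at `p_cutoff`. The null is the same
#' as the main stage's (random single substitutions in the window), so the
#' joint change is judged on the same significance scale as the original
#' call. Partners farther than `flank` nt from the SNV are skipped.
#'
#' @param snv one row of an `snv_set`.
#' @param partner list/row with `position`, `ref`, `alt` (transcript
#'   coordinates).
#' @param transcript matching row of a `transcript_set`.
#' @param model an [energy_model()].
#' @param flank window flank (default 200, also the proximity bound).
#' @param k,l_min,rng_seed as in [empirical_pvalue()].
#' @param p_cutoff significance cutoff (default 0.1).
#' @return list with `status` (`"stabilizing"`, `"still_disruptive"` or
#'   `"skipped"`), `reason` for skips, and the joint `p_d`, `p_r`.
#' @export
ld_haplotype_test <- function(snv, partner, transcript,
                              model = default_energy_model(), flank = 200L,
                              k = 1000L, l_min = 10L, rng_seed = NULL,
                              p_cutoff = 0.1) {
  if (abs(partner$position - snv$position) > flank)
    return(list(status = "skipped",
                reason = "partner outside the folding window",
                p_d = NA_real_, p_r = NA_real_))
  win <- extract_window(snv, transcript, flank)
  p_off <- partner$position - win$window_start + 1L
  if (p_off < 1L || p_off > nchar(win$wt_seq))
    return(list(status = "skipped", reason = "partner clipped from window",
                p_d = NA_real_, p_r = NA_real_))
  if (substr(win$wt_seq, p_off, p_off) != partner$ref)
    stop("LD partner ref mismatch at ", transcript$transcript_id, ":",
         partner$position)
  mt2 <- win$mt_seq
  substr(mt2, p_off, p_off) <- partner$alt

  wt <- compute_pair_probabilities(win$wt_seq, model)
  mt <- compute_pair_probabilities(mt2, model)
  obs <- scan_local_regions(wt$p, mt$p, l_min)
  obs_r <- if (is.na(obs$r_min)) 1 else obs$r_min
  n <- nchar(win$wt_seq)
  wt_chars <- strsplit(win$wt_seq, "", fixed = TRUE)[[1]]
  null_d <- numeric(k); null_r <- numeric(k)
  run <- function() {
    for (i in seq_len(k)) {
      p <- sample.int(n, 1L)
      alt <- sample(setdiff(BASES, wt_chars[p]), 1L)
      mseq <- win$wt_seq
      substr(mseq, p, p) <- alt
      sc <- scan_local_regions(wt$p,
                               compute_pair_probabilities(mseq, model)$p,
                               l_min)
      null_d[i] <<- sc$d_max
      null_r[i] <<- if (is.na(sc$r_min)) 1 else sc$r_min
    }
  }
  if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
  p_d <- (1 + sum(null_d >= obs$d_max)) / (k + 1)
  p_r <- (1 + sum(null_r <= obs_r)) / (k + 1)
  status <- if (p_d >= p_cutoff && p_r >= p_cutoff) "stabilizing"
            else "still_disruptive"
  list(status = status, reason = NA_character_, p_d = p_d, p_r = p_r)
}

#' Run the structure-disruption stage over an SNV set
#'
#' For each SNV: extract the folding window, compute wild-type and mutant
#' pair-probability ensembles, scan all local regions for `d_max`/`r_min`,
#' and attach empirical p-values. The d- and r-based candidate lists are
#' each Benjamini-Hochberg corrected separately; confidence tiers,
#' conserved-structure overlap and window GC content are annotated per SNV.
#' Windows containing non-ACGU characters are skipped with a logged count.
#'
#' @param transcripts a `transcript_set`.
#' @param snvs an `snv_set`.
#' @param annotations an `annotation_bundle` (conserved intervals used).
#' @param model an [energy_model()].
#' @param flank folding window flank (default 200).
#' @param k null substitutions per SNV (default 1000).
#' @param l_min minimum region length.
#' @param fdr FDR threshold for the BH pass flags.
#' @param p_cutoff raw-p candidate cutoff (default 0.1).
#' @param rng_seed integer seed.
#' @return a `structure_results` data frame, one row per analyzed SNV, with
#'   d/r scores, regions (window and transcript coordinates), p- and
#'   q-values, pass flags (raw and BH), confidence tier, conserved overlap
#'   strings, window GC; attribute `n_skipped_ambiguous` counts skipped
#'   windows.
#' @export
run_structure_stage <- function(transcripts, snvs,
                                annotations = empty_annotation_bundle(),
                                model = default_energy_model(),
                                flank = 200L, k = 1000L, l_min = 10L,
                                fdr = 0.10, p_cutoff = 0.1,
                                rng_seed = NULL) {
  rows <- list()
  skipped <- 0L
  seeds <- if (is.null(rng_seed)) rep(list(NULL), nrow(snvs))
           else as.list(rng_seed + seq_len(nrow(snvs)))
  for (r in seq_len(nrow(snvs))) {
    snv <- snvs[r, , drop = FALSE]
    tx <- transcripts[transcripts$transcript_id == snv$transcript_id, ,
                      drop = FALSE]
    if (nrow(tx) == 0L) next
    win <- extract_window(snv, tx, flank)
    if (grepl("N", win$wt_seq, fixed = TRUE)) {
      skipped <- skipped + 1L
      next
    }
    res <- empirical_pvalue(win, model, k = k, l_min = l_min,
                            rng_seed = seeds[[r]])
    d_tr <- res$d_region + win$window_start - 1L
    r_tr <- if (is.null(res$r_region)) c(NA_integer_, NA_integer_)
            else res$r_region + win$window_start - 1L
    ov_d <- conserved_overlap_pct(d_tr, annotations$conserved,
                                  snv$transcript_id)
    ov_r <- if (is.na(r_tr[1])) data.frame(source = character(0),
                                           pct = integer(0))
            else conserved_overlap_pct(r_tr, annotations$conserved,
                                       snv$transcript_id)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = snv$transcript_id, gene = snv$gene,
      position = snv$position, ref = snv$ref, alt = snv$alt,
      utr_label = snv$utr_label, dbsnp_id = snv$dbsnp_id,
      d_max = res$d_max,
      d_region_start = d_tr[1], d_region_end = d_tr[2],
      p_d = res$p_d,
      r_min = res$r_min,
      r_region_start = r_tr[1], r_region_end = r_tr[2],
      p_r = res$p_r,
      conserved_d = format_overlap(ov_d),
      conserved_r = format_overlap(ov_r),
      window_gc = gc_content(win$wt_seq),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (nrow(out) > 0) {
    bh_d <- bh_adjust(out$p_d, fdr)
    bh_r <- bh_adjust(out$p_r, fdr)
    out$q_d <- bh_d$q; out$q_r <- bh_r$q
    out$pass_raw_d <- out$p_d < p_cutoff
    out$pass_raw_r <- out$p_r < p_cutoff
    out$pass_bh_d <- bh_d$pass
    out$pass_bh_r <- bh_r$pass
    out$confidence <- classify_confidence(out$p_d, out$p_r)
  }
  attr(out, "n_skipped_ambiguous") <- skipped
  class(out) <- c("structure_results", "data.frame")
  out
}
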