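#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' transcripts with 5'/3' UTRs at 40-60% GC, perfect stem-loops planted in
#' 3' UTRs, SNVs that break stem pairs or sit in neutral background, planted
#' miRNA seed sites that SNVs create/destroy/weaken, CLIP clusters covering
#' planted wild-type sites, and a cancer-gene labelling with configurable
#' enrichment odds.
#'
#' @param n_genes number of genes (one transcript per gene by default).
#' @param transcripts_per_gene isoforms per gene.
#' @param utr5_len,utr3_len integer c(min, max) UTR length ranges (nt).
#' @param cds_len length of the coding filler between the UTRs.
#' @param gc_range GC-content range for background sequence.
#' @param stem_len,loop_len c(min, max) ranges of planted hairpin stems (bp)
#'   and loops (nt). Stems carry a fixed ~60% GC composition and are
#'   verified by folding (mean stem pair probability > 0.5 in a local
#'   window), redrawing up to ten times, so a single mid-stem break is
#'   energetically cooperative.
#' @param n_snvs total SNVs to plant.
#' @param fraction_structural_positives fraction of SNVs breaking a planted
#'   stem pair.
#' @param fraction_site_create,fraction_site_destroy,fraction_site_alter
#'   fractions of SNVs planted as miRNA target-site events; the remainder
#'   are neutral background substitutions >= 50 nt from any plant.
#' @param n_mirnas total miRNAs; site events get one planted miRNA each,
#'   the rest are dinucleotide-preserving shuffles (decoys).
#' @param cancer_gene_fraction baseline probability that a non-disruptive
#'   gene is labelled cancer-associated.
#' @param planted_enrichment_odds odds ratio of a disruptive-SNV gene being
#'   labelled cancer-associated, relative to baseline.
#' @param clip_coverage_prob probability that a planted wild-type site is
#'   covered by a CLIP cluster.
#' @param bc_rate Poisson rate; cluster BC values are `1 + Poisson(bc_rate)`.
#' @param rng_seed integer seed (mandatory).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 60L, transcripts_per_gene = 1L,
                              utr5_len = c(60L, 100L),
                              utr3_len = c(280L, 360L), cds_len = 90L,
                              gc_range = c(0.40, 0.60),
                              stem_len = c(5L, 6L), loop_len = c(4L, 7L),
                              n_snvs = 80L,
                              fraction_structural_positives = 0.30,
                              fraction_site_create = 0.10,
                              fraction_site_destroy = 0.10,
                              fraction_site_alter = 0.10,
                              n_mirnas = 32L,
                              cancer_gene_fraction = 0.208,
                              planted_enrichment_odds = 1.2,
                              clip_coverage_prob = 1.0,
                              bc_rate = 2,
                              rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed))
    stop("rng_seed is mandatory")
  fr <- c(fraction_structural_positives, fraction_site_create,
          fraction_site_destroy, fraction_site_alter)
  stopifnot(all(fr >= 0), sum(fr) <= 1, n_genes >= 1, n_snvs >= 1,
            gc_range[1] <= gc_range[2], planted_enrichment_odds > 0)
  structure(list(
    n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    cds_len = as.integer(cds_len), gc_range = gc_range,
    stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
    n_snvs = as.integer(n_snvs),
    fraction_structural_positives = fraction_structural_positives,
    fraction_site_create = fraction_site_create,
    fraction_site_destroy = fraction_site_destroy,
    fraction_site_alter = fraction_site_alter,
    n_mirnas = as.integer(n_mirnas),
    cancer_gene_fraction = cancer_gene_fraction,
    planted_enrichment_odds = planted_enrichment_odds,
    clip_coverage_prob = clip_coverage_prob,
    bc_rate = bc_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

random_rna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Stem with a fixed GC count (~60%), shuffled order.
random_stem <- function(stem) {
  ngc <- ceiling(0.6 * stem)
  comp <- c(sample(c("G", "C"), ngc, replace = TRUE),
            sample(c("A", "U"), stem - ngc, replace = TRUE))
  paste(sample(comp), collapse = "")
}

# Fold a local window around a planted hairpin and return the mean pair
# probability over its stem pairs.
stem_pair_prob <- function(seq, hp_local, stem, loop, flank = 60L,
                           model = default_energy_model()) {
  hp_len <- 2L * stem + loop
  a <- max(1L, hp_local - flank)
  b <- min(nchar(seq), hp_local + hp_len - 1L + flank)
  win <- substr(seq, a, b)
  p <- compute_pair_probabilities(win, model)$p
  k <- seq_len(stem) - 1L
  iw <- hp_local + k - a + 1L
  jw <- hp_local + hp_len - 1L - k - a + 1L
  mean(p[cbind(iw, jw)])
}

# Plant a hairpin that demonstrably folds (mean stem pair probability
# > 0.5 in its local window), redrawing the stem/loop up to ten times.
plant_verified_hairpin <- function(utr3_bg, hp_local, stem, loop,
                                   model = default_energy_model()) {
  best <- NULL; best_p <- -1
  for (try in 1:10) {
    left <- random_stem(stem)
    loop_seq <- paste(sample(c("A", "C", "U"), loop, replace = TRUE),
                      collapse = "")
    hairpin <- paste0(left, loop_seq, reverse_complement(left))
    cand <- utr3_bg
    substr(cand, hp_local, hp_local + nchar(hairpin) - 1L) <- hairpin
    pp <- stem_pair_prob(cand, hp_local, stem, loop, model = model)
    if (pp > best_p) { best <- cand; best_p <- pp }
    if (pp > 0.8) break
  }
  best
}

#' Simulate transcripts with planted hairpins and target-site boxes
#'
#' Each gene gets background-sequence transcripts (GC drawn from the
#' configured range) with a 5' UTR, coding filler, and a 3' UTR into which
#' one perfect stem-loop hairpin and one 22-nt target-site box are planted
#' at recorded, non-overlapping positions. The conserved-structure
#' annotation intervals are emitted over the planted hairpins.
#'
#' @param config a [simulation_config()].
#' @return list with `transcripts` (a `transcript_set`), `plants` (one row
#'   per transcript: hairpin span, stem pairs, loop span, box span) and
#'   `conserved` (BED-style intervals in memory, `cmfinder`-tagged).
#' @export
simulate_transcripts <- function(config) {
  with_seed(config$rng_seed, {
    rows <- list(); plants <- list()
    for (g in seq_len(config$n_genes)) {
      gene <- sprintf("SYNG%03d", g)
      for (t in seq_len(config$transcripts_per_gene)) {
        id <- sprintf("SYNT%03d_%d", g, t)
        gc <- stats::runif(1, config$gc_range[1], config$gc_range[2])
        u5 <- sample(config$utr5_len[1]:config$utr5_len[2], 1L)
        u3 <- sample(config$utr3_len[1]:config$utr3_len[2], 1L)
        stem <- sample(config$stem_len[1]:config$stem_len[2], 1L)
        loop <- sample(config$loop_len[1]:config$loop_len[2], 1L)
        hp_len <- 2L * stem + loop
        box_len <- 22L
        # 3' UTR layout:
        #   margin | quiet+hairpin+quiet | gap | quiet+box+quiet | margin.
        # The gap keeps the GC-rich hairpin out of the 61-mer window around
        # the site SNV; the AU-rich quiet zones isolate both planted
        # elements, so the hairpin is the dominant local structure and
        # accidental flanking helices stay too weak to mimic a binding
        # site.
        margin <- 15L; gap <- 28L; quiet <- 10L; hquiet <- 50L
        need <- 2L * margin + hp_len + 2L * hquiet + gap + box_len +
          2L * quiet
        if (u3 < need)
          stop("3' UTR too short for requested plants (need ", need, " nt)")
        seq5 <- random_rna(u5, gc)
        cds <- random_rna(config$cds_len, gc)
        utr3_bg <- random_rna(u3, gc)
        u3_start <- u5 + config$cds_len + 1L
        slack <- u3 - need
        off1 <- sample(0:slack, 1L)
        hp_local <- margin + off1 + hquiet + 1L   # within 3' UTR
        substr(utr3_bg, hp_local - hquiet, hp_local - 1L) <-
          random_rna(hquiet, 0.15)
        substr(utr3_bg, hp_local + hp_len,
               hp_local + hp_len + hquiet - 1L) <- random_rna(hquiet, 0.15)
        # perfect hairpin, fixed ~60% GC stem, verified by folding
        utr3_bg <- plant_verified_hairpin(utr3_bg, hp_local, stem, loop)
        box_local <- hp_local + hp_len + hquiet + gap + quiet
        # target-site box: AU-leaning body and guard, a GC-rich but
        # non-repetitive seed complement (positions 15..21, facing miRNA
        # 8..2) and an A at the 1a position (22)
        box <- paste0(random_rna(box_len - 11L, 0.35), "AUA", "GCGGCGC", "A")
        cassette <- paste0(random_rna(quiet, 0.25), box,
                           random_rna(quiet, 0.25))
        substr(utr3_bg, box_local - quiet,
               box_local + box_len + quiet - 1L) <- cassette
        seqs <- paste0(seq5, cds, utr3_bg)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, gene = gene, sequence = seqs,
          utr5_start = 1L, utr5_end = u5,
          utr3_start = u3_start, utr3_end = u5 + config$cds_len + u3,
          stringsAsFactors = FALSE)
        hp_start <- u3_start + hp_local - 1L
        plants[[length(plants) + 1L]] <- data.frame(
          transcript_id = id, gene = gene,
          hp_start = hp_start, hp_end = hp_start + hp_len - 1L,
          stem = stem, loop = loop,
          box_start = u3_start + box_local - 1L,
          box_end = u3_start + box_local + box_len - 2L,
          stringsAsFactors = FALSE)
      }
    }
    tx <- do.call(rbind, rows)
    validate_transcripts(tx)
    class(tx) <- c("transcript_set", "data.frame")
    plants <- do.call(rbind, plants)
    conserved <- data.frame(transcript_id = plants$transcript_id,
                            start = plants$hp_start, end = plants$hp_end,
                            name = "cmfinder", stringsAsFactors = FALSE)
    list(transcripts = tx, plants = plants, conserved = conserved)
  })
}

# stem pair coordinates of a planted hairpin: (hp_start+k, hp_end-k)
stem_pairs_of <- function(plant) {
  k <- seq_len(plant$stem) - 1L
  data.frame(i = plant$hp_start + k, j = plant$hp_end - k)
}

# Choose the stem-break substitution: for every 5'-side stem position, try
# the alternate bases that can pair with the partner by neither
# Watson-Crick nor wobble rules, fold the mutant in the local window, and
# among candidates that genuinely collapse the helix (mean residual stem
# pair probability < 0.2) keep the one the disruption measure sees most
# strongly (largest d_max). If no candidate collapses the stem, fall back
# to the lowest residual.
select_stem_break <- function(tr, pl, model = default_energy_model(),
                              flank = 80L) {
  sp <- stem_pairs_of(pl)
  pt <- pair_type_table(PAIR_TYPES)
  a <- max(1L, pl$hp_start - flank)
  b <- min(nchar(tr$sequence), pl$hp_end + flank)
  wt_win <- substr(tr$sequence, a, b)
  p_wt <- compute_pair_probabilities(wt_win, model)$p
  iw <- sp$i - a + 1L; jw <- sp$j - a + 1L
  best <- NULL; best_d <- -Inf
  fallback <- NULL; fallback_res <- Inf
  for (r in seq_len(nrow(sp))) {
    pos <- sp$i[r]; partner <- sp$j[r]
    ref <- substr(tr$sequence, pos, pos)
    pb <- substr(tr$sequence, partner, partner)
    alts <- setdiff(BASES, ref)
    alts <- alts[vapply(alts, function(x) pt[x, pb] == 0L, logical(1))]
    for (alt in alts) {
      mwin <- wt_win
      substr(mwin, pos - a + 1L, pos - a + 1L) <- alt
      p_mt <- compute_pair_probabilities(mwin, model)$p
      resid <- mean(p_mt[cbind(iw, jw)])
      d <- scan_local_regions(p_wt, p_mt)$d_max
      cand <- list(pos = pos, ref = ref, alt = alt)
      if (resid < 0.2 && d > best_d) { best <- cand; best_d <- d }
      if (resid < fallback_res) { fallback <- cand; fallback_res <- resid }
    }
  }
  if (is.null(best)) fallback else best
}

#' Simulate SNVs with ground-truth labels
#'
#' Structural positives break a planted stem pair: candidate substitutions
#' (stem positions, alternate bases that pair with the partner by neither
#' Watson-Crick nor wobble rules) are folded in the local window and the
#' one the disruption measure sees most strongly (largest `d_max`) is
#' planted. Neutral SNVs land in background at least 50 nt from any plant;
#' site events are substitutions inside the planted target-site boxes
#' (destroy: mid-seed break; create: seed completion; alter: the m8
#' position).
#'
#' @param config a [simulation_config()].
#' @param sim output of [simulate_transcripts()].
#' @return list with `snvs` (an `snv_set`) and `truth` (one row per SNV:
#'   `truth` label and plant geometry).
#' @export
simulate_snvs <- function(config, sim) {
  tx <- sim$transcripts; plants <- sim$plants
  n <- config$n_snvs
  n_pos <- round(n * config$fraction_structural_positives)
  n_cre <- round(n * config$fraction_site_create)
  n_des <- round(n * config$fraction_site_destroy)
  n_alt <- round(n * config$fraction_site_alter)
  n_neu <- n - n_pos - n_cre - n_des - n_alt
  stopifnot(n_neu >= 0)
  labels <- c(rep("stem_break", n_pos), rep("site_create", n_cre),
              rep("site_destroy", n_des), rep("site_alter", n_alt),
              rep("neutral", n_neu))
  if (nrow(plants) < n_pos + n_cre + n_des + n_alt)
    stop("not enough transcripts to place the requested planted events")
  with_seed(config$rng_seed + 1L, {
    # assign each planted event its own transcript (no interference)
    tx_order <- sample(nrow(plants))
    ev_idx <- 0L
    rows <- list(); truths <- list()
    base_at <- function(seqs, p) substr(seqs, p, p)
    for (s in seq_along(labels)) {
      lab <- labels[s]
      if (lab != "neutral") {
        ev_idx <- ev_idx + 1L
        pl <- plants[tx_order[ev_idx], , drop = FALSE]
      } else {
        pl <- plants[sample(nrow(plants), 1L), , drop = FALSE]
      }
      tr <- tx[tx$transcript_id == pl$transcript_id, , drop = FALSE]
      if (lab == "stem_break") {
        brk <- select_stem_break(tr, pl)
        pos <- brk$pos; ref <- brk$ref; alt <- brk$alt
      } else if (lab %in% c("site_destroy", "site_create")) {
        pos <- pl$box_end - 4L        # mid-seed (opposite miRNA position 5)
        ref <- base_at(tr$sequence, pos)
        pt <- pair_type_table(PAIR_TYPES)
        comp1 <- function(b) chartr("ACGU", "UGCA", b)
        cand <- setdiff(BASES, ref)
        if (lab == "site_destroy") {
          # the miRNA will complement the wild type: the alternate base
          # must pair the opposing miRNA base by neither WC nor wobble
          cand <- cand[pt[cand, comp1(ref)] == 0L]
        } else {
          # the miRNA will complement the mutant: the wild-type base must
          # not pair the miRNA base complementary to the alternate
          cand <- cand[vapply(cand, function(a) pt[ref, comp1(a)] == 0L,
                              logical(1))]
        }
        alt <- cand[sample.int(length(cand), 1L)]
      } else if (lab == "site_alter") {
        pos <- pl$box_end - 7L        # the m8 position (opposite miRNA 8)
        ref <- base_at(tr$sequence, pos)
        alt <- sample(setdiff(BASES, ref), 1L)
      } else {
        # neutral: inside a UTR, >= 50 nt from any plant on this transcript
        len <- nchar(tr$sequence)
        utr_pos <- c(seq(tr$utr5_start, tr$utr5_end),
                     seq(tr$utr3_start, tr$utr3_end))
        away <- utr_pos[utr_pos < pl$hp_start - 50L |
                          utr_pos > pl$box_end + 50L]
        if (length(away) == 0) stop("no room for a neutral SNV")
        pos <- away[sample.int(length(away), 1L)]
        ref <- base_at(tr$sequence, pos)
        alt <- sample(setdiff(BASES, ref), 1L)
      }
      rows[[s]] <- data.frame(
        transcript_id = pl$transcript_id, position = pos, ref = ref,
        alt = alt, dbsnp_id = NA_character_, stringsAsFactors = FALSE)
      truths[[s]] <- data.frame(
        transcript_id = pl$transcript_id, gene = pl$gene, position = pos,
        ref = ref, alt = alt, truth = lab,
        hp_start = pl$hp_start, hp_end = pl$hp_end, stem = pl$stem,
        box_start = pl$box_start, box_end = pl$box_end,
        stringsAsFactors = FALSE)
    }
    snvs <- do.call(rbind, rows)
    truth <- do.call(rbind, truths)
    # finish as a validated snv_set via the standard reader path
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    utils::write.table(snvs, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    snv_set <- read_snvs(tmp, tx)
    stopifnot(nrow(snv_set) == nrow(truth))
    list(snvs = snv_set, truth = truth)
  })
}

#' Simulate miRNAs and the annotation bundle
#'
#' Planted miRNAs are built as exact complements of the planted target-site
#' boxes on the allele each event dictates (destroy: wild type; create:
#' mutant; alter: mutant seed plus a 3' supplementary patch complementary
#' to both alleles). Decoys are shuffles of planted miRNAs. CLIP clusters
#' cover planted wild-type sites with probability `clip_coverage_prob`;
#' cancer labels are drawn so that genes carrying disruptive SNVs have the
#' configured enrichment odds.
#'
#' @param config a [simulation_config()].
#' @param sim output of [simulate_transcripts()].
#' @param snv_sim output of [simulate_snvs()].
#' @param fold_model the [energy_model()] used to verify planted events.
#' @return list with `mirnas`, `annotations` (an `annotation_bundle`) and
#'   `mirna_truth` (event-to-miRNA map).
#' @export
simulate_mirnas_and_annotations <- function(config, sim, snv_sim,
                                            fold_model = default_energy_model()) {
  tx <- sim$transcripts; truth <- snv_sim$truth
  with_seed(config$rng_seed + 2L, {
    mir_rows <- list(); mt_rows <- list()
    events <- truth[truth$truth %in%
                      c("site_create", "site_destroy", "site_alter"), ,
                    drop = FALSE]
    for (i in seq_len(nrow(events))) {
      ev <- events[i, , drop = FALSE]
      tr <- tx[tx$transcript_id == ev$transcript_id, , drop = FALSE]
      e <- ev$box_end                       # position opposite miRNA pos 1
      site_seq <- substr(tr$sequence, ev$box_start, ev$box_end)
      if (ev$truth == "site_create") {      # complement the mutant box
        off <- ev$position - ev$box_start + 1L
        substr(site_seq, off, off) <- ev$alt
      }
      if (ev$truth == "site_alter") {
        off <- ev$position - ev$box_start + 1L
        substr(site_seq, off, off) <- ev$alt  # m8 pairs in the mutant
      }
      # miRNA position k sits opposite box position (e - k + 1). The body
      # is random; only the seed (2-8) -- plus, for alter events, a 3'
      # supplementary patch (13-18) -- is made complementary to the site,
      # so the duplex is genuinely seed-driven with no off-register
      # complementarity inherited from the box.
      pt_full <- pair_type_table(PAIR_TYPES)
      L <- 22L
      opp <- function(p) substr(site_seq, nchar(site_seq) - p + 1L,
                                nchar(site_seq) - p + 1L)
      set_complement <- function(mir, at) {
        for (p in at)
          substr(mir, p, p) <- reverse_complement(opp(p))
        mir
      }
      avoid_pairing <- function(mir, at) {
        for (p in at) {
          s <- opp(p)
          ops <- setdiff(BASES[pt_full[, s] == 0L], substr(mir, p, p))
          if (length(ops) > 0)
            substr(mir, p, p) <- ops[sample.int(length(ops), 1L)]
        }
        mir
      }
      draw_mir <- function() {
        mir <- random_rna(L, 0.5)
        mir <- set_complement(mir, 2:8)
        mir <- avoid_pairing(mir, 1L)  # keep the 1a adenosine unpaired
        if (ev$truth == "site_alter") mir <- set_complement(mir, 13:18)
        mir
      }
      # verify the planted event classifies as intended with the actual
      # cascade; accidental complementarity of the random miRNA body can
      # spoil an event, so redraw the body until the event is clean
      len_tr <- nchar(tr$sequence)
      a61 <- max(1L, ev$position - 30L)
      b61 <- min(len_tr, ev$position + 30L)
      wt61 <- substr(tr$sequence, a61, b61)
      mt61 <- wt61
      substr(mt61, ev$position - a61 + 1L, ev$position - a61 + 1L) <- ev$alt
      intended <- sub("site_", "", ev$truth)
      mir <- draw_mir()
      for (try in 1:25) {
        wts <- scan_duplex(mir, wt61, fold_model)
        mts <- scan_duplex(mir, mt61, fold_model)
        sd <- strongest_differing_site(wts, mts)
        cls <- if (is.null(sd)) NA_character_
               else classify_site_change(sd$dG_wt, sd$dG_snv)
        if (identical(cls, intended)) break
        mir <- draw_mir()
      }
      id <- sprintf("syn-miR-%03d", i)
      mir_rows[[i]] <- data.frame(mirna_id = id, sequence = mir,
                                  stringsAsFactors = FALSE)
      mt_rows[[i]] <- data.frame(
        transcript_id = ev$transcript_id, position = ev$position,
        alt = ev$alt, truth = ev$truth, mirna_id = id,
        stringsAsFactors = FALSE)
    }
    mirnas <- if (length(mir_rows)) do.call(rbind, mir_rows) else
      data.frame(mirna_id = character(0), sequence = character(0))
    n_decoy <- max(0L, config$n_mirnas - nrow(mirnas))
    if (nrow(events) > 0) {
      for (k in seq_len(n_decoy)) {
        src <- mirnas$sequence[1L + (k - 1L) %% nrow(events)]
        shuf <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
        mirnas <- rbind(mirnas, data.frame(
          mirna_id = sprintf("syn-decoy-%03d", k), sequence = shuf,
          stringsAsFactors = FALSE))
      }
    }
    # CLIP clusters over planted wild-type sites (destroy / alter)
    wt_sites <- truth[truth$truth %in% c("site_destroy", "site_alter"), ,
                      drop = FALSE]
    covered <- stats::runif(nrow(wt_sites)) <= config$clip_coverage_prob
    clip <- data.frame(
      transcript_id = wt_sites$transcript_id[covered],
      start = wt_sites$box_start[covered] - 10L,
      end = wt_sites$box_end[covered] + 10L,
      name = "ago_clip", score = 0,
      bc = 1L + stats::rpois(sum(covered), config$bc_rate),
      stringsAsFactors = FALSE)
    # cancer labels with planted enrichment odds
    disruptive_genes <- unique(truth$gene[truth$truth != "neutral"])
    cancer_genes <- assign_cancer_labels(
      unique(tx$gene), disruptive_genes, config$cancer_gene_fraction,
      config$planted_enrichment_odds)
    expressed <- c(utils::head(mirnas$mirna_id, nrow(events)),
                   utils::head(grep("decoy", mirnas$mirna_id, value = TRUE),
                               n_decoy %/% 2))
    lung <- if (nrow(mirnas) > 0)
      sample(mirnas$mirna_id, max(1L, nrow(mirnas) %/% 3)) else character(0)
    annotations <- structure(list(
      cancer_genes = cancer_genes,
      conserved = sim$conserved,
      clip = clip,
      expressed_mirnas = expressed,
      lung_cancer_mirnas = lung,
      nsclc_mirnas = utils::head(lung, max(1L, length(lung) %/% 4)),
      ld_pairs = data.frame(transcript_id = character(0),
                            snv = character(0),
                            partner_position = integer(0),
                            partner_ref = character(0),
                            partner_alt = character(0))
    ), class = "annotation_bundle")
    list(mirnas = mirnas, annotations = annotations,
         mirna_truth = do.call(rbind, mt_rows))
  })
}

#' Draw cancer-gene labels with a planted enrichment odds ratio
#'
#' Non-disruptive genes are labelled with probability `fraction`; genes in
#' `disruptive_genes` with the probability implied by multiplying the
#' baseline odds by `odds`.
#'
#' @param genes gene universe.
#' @param disruptive_genes genes carrying disruptive SNVs.
#' @param fraction baseline cancer-gene fraction.
#' @param odds planted odds ratio (1 = no enrichment).
#' @return character vector of cancer-labelled genes.
#' @export
assign_cancer_labels <- function(genes, disruptive_genes, fraction, odds) {
  base_odds <- fraction / (1 - fraction)
  p_dis <- (base_odds * odds) / (1 + base_odds * odds)
  p <- ifelse(genes %in% disruptive_genes, p_dis, fraction)
  genes[stats::runif(length(genes)) <= p]
}

#' Generate a complete synthetic data set
#'
#' Runs the three simulation stages and optionally writes every input file
#' in the exact on-disk formats the readers consume, plus a `truth.tsv`
#' ground-truth ledger.
#'
#' @param config a [simulation_config()].
#' @param dir if non-NULL, write all files into this directory.
#' @return list with `transcripts`, `plants`, `snvs`, `truth`, `mirnas`,
#'   `annotations`, `mirna_truth`, and (when written) `paths`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  sim <- simulate_transcripts(config)
  snv_sim <- simulate_snvs(config, sim)
  ann_sim <- simulate_mirnas_and_annotations(config, sim, snv_sim)
  out <- list(transcripts = sim$transcripts, plants = sim$plants,
              conserved = sim$conserved,
              snvs = snv_sim$snvs, truth = snv_sim$truth,
              mirnas = ann_sim$mirnas, annotations = ann_sim$annotations,
              mirna_truth = ann_sim$mirna_truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_transcripts(out$transcripts, p("transcripts.fa"), p("utr_spans.tsv"))
    write_snvs(out$snvs, p("snvs.tsv"))
    writeLines(paste0(">", out$mirnas$mirna_id, "\n", out$mirnas$sequence),
               p("mirnas.fa"))
    write_bed_intervals(out$conserved, p("conserved.bed"), extra = "name")
    write_bed_intervals(out$annotations$clip, p("clip_clusters.bed"),
                        extra = c("name", "score", "bc"))
    writeLines(out$annotations$cancer_genes, p("cancer_genes.txt"))
    writeLines(out$annotations$expressed_mirnas, p("expressed_mirnas.txt"))
    writeLines(out$annotations$lung_cancer_mirnas, p("lung_cancer_mirnas.txt"))
    writeLines(out$annotations$nsclc_mirnas, p("nsclc_mirnas.txt"))
    utils::write.table(out$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- list(
      transcripts_fa = p("transcripts.fa"), utr_spans = p("utr_spans.tsv"),
      snvs = p("snvs.tsv"), mirnas_fa = p("mirnas.fa"),
      conserved = p("conserved.bed"), clip = p("clip_clusters.bed"),
      cancer_genes = p("cancer_genes.txt"),
      expressed_mirnas = p("expressed_mirnas.txt"),
      lung_cancer_mirnas = p("lung_cancer_mirnas.txt"),
      nsclc_mirnas = p("nsclc_mirnas.txt"), truth = p("truth.tsv"))
  }
  out
}
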