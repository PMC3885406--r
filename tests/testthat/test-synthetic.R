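test_that("the generator is fully deterministic given its seed", {
  cfg <- simulation_config(n_genes = 10L, n_snvs = 12L, n_mirnas = 8L,
                           rng_seed = 41L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$transcripts$sequence, d2$transcripts$sequence)
  expect_identical(d1$snvs, d2$snvs)
  expect_identical(d1$mirnas, d2$mirnas)
  expect_identical(d1$annotations$cancer_genes, d2$annotations$cancer_genes)
})

test_that("the truth ledger covers every SNV with valid plant geometry", {
  cfg <- simulation_config(rng_seed = 42L)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$truth), cfg$n_snvs)
  expect_equal(nrow(ds$snvs), cfg$n_snvs)
  expect_true(all(ds$truth$truth %in%
                    c("stem_break", "neutral", "site_create",
                      "site_destroy", "site_alter")))
  # conserved intervals are emitted exactly over planted hairpins
  expect_equal(nrow(ds$conserved), nrow(ds$plants))
  expect_equal(ds$conserved$start, ds$plants$hp_start)
})

test_that("planted hairpins fold and stem-break SNVs collapse them", {
  cfg <- simulation_config(rng_seed = 43L)
  sim <- simulate_transcripts(cfg)
  snv_sim <- simulate_snvs(cfg, sim)
  truth <- snv_sim$truth
  idx <- which(truth$truth == "stem_break")
  wt_p <- mt_p <- numeric(length(idx))
  for (k in seq_along(idx)) {
    tv <- truth[idx[k], ]
    tr <- sim$transcripts[sim$transcripts$transcript_id == tv$transcript_id, ]
    pl <- sim$plants[sim$plants$transcript_id == tv$transcript_id, ]
    mseq <- tr$sequence
    substr(mseq, tv$position, tv$position) <- tv$alt
    wt_p[k] <- utrsnv:::stem_pair_prob(tr$sequence, pl$hp_start, pl$stem,
                                       pl$loop)
    mt_p[k] <- utrsnv:::stem_pair_prob(mseq, pl$hp_start, pl$stem, pl$loop)
  }
  expect_true(all(wt_p > 0.5))
  expect_gte(mean(mt_p < 0.2), 0.85)
  expect_true(all(mt_p < wt_p))
})

test_that("destroy SNVs eliminate the planted seed match", {
  cfg <- simulation_config(rng_seed = 44L)
  ds <- simulate_dataset(cfg)
  ev <- ds$mirna_truth[ds$mirna_truth$truth == "site_destroy", ]
  for (i in seq_len(nrow(ev))) {
    tr <- ds$transcripts[ds$transcripts$transcript_id ==
                           ev$transcript_id[i], ]
    mir <- ds$mirnas$sequence[ds$mirnas$mirna_id == ev$mirna_id[i]]
    a <- ev$position[i] - 30L; b <- ev$position[i] + 30L
    wt <- substr(tr$sequence, a, b)
    mt <- wt
    substr(mt, 31L, 31L) <- ev$alt[i]
    expect_gt(nrow(find_seed_matches(mir, wt)), 0)
    wt_hits <- find_seed_matches(mir, wt)
    mt_hits <- find_seed_matches(mir, mt)
    # the planted register loses its match
    expect_false(any(mt_hits$site_end %in% wt_hits$site_end &
                       mt_hits$type[match(wt_hits$site_end,
                                          mt_hits$site_end)] ==
                       wt_hits$type))
  }
})

test_that("generated files are valid inputs for the readers with no warnings", {
  cfg <- simulation_config(n_genes = 12L, n_snvs = 14L, n_mirnas = 10L,
                           rng_seed = 45L)
  dir <- tempfile()
  ds <- simulate_dataset(cfg, dir = dir)
  expect_no_warning({
    tx <- read_transcripts(ds$paths$transcripts_fa, ds$paths$utr_spans)
    snvs <- read_snvs(ds$paths$snvs, tx)
    mirnas <- read_mirnas(ds$paths$mirnas_fa)
    ann <- read_annotation_bundle(
      cancer_genes_path = ds$paths$cancer_genes,
      conserved_path = ds$paths$conserved,
      clip_path = ds$paths$clip,
      expressed_mirnas_path = ds$paths$expressed_mirnas,
      lung_cancer_mirnas_path = ds$paths$lung_cancer_mirnas,
      nsclc_mirnas_path = ds$paths$nsclc_mirnas)
  })
  expect_equal(nrow(snvs), nrow(ds$snvs))
  expect_equal(mirnas$sequence, ds$mirnas$sequence)
  expect_equal(ann$conserved$start, ds$conserved$start)
  expect_equal(ann$clip$bc, ds$annotations$clip$bc)
})

test_that("full CLIP coverage with high BC passes all wild-type truth sites", {
  cfg <- simulation_config(clip_coverage_prob = 1, rng_seed = 46L)
  ds <- simulate_dataset(cfg)
  ev <- ds$truth[ds$truth$truth %in% c("site_destroy", "site_alter"), ]
  clip <- ds$annotations$clip
  clip$bc <- 3L
  for (i in seq_len(nrow(ev)))
    expect_true(clip_filter("destroy", ev$transcript_id[i], ev$position[i],
                            clip, bc_min = 2L))
})

test_that("cancer labelling tracks the planted odds ratio", {
  set.seed(47)
  genes <- sprintf("G%04d", 1:4000)
  dis <- sample(genes, 1200)
  base <- assign_cancer_labels(genes, character(0), 0.208, 1)
  expect_equal(mean(genes %in% base), 0.208, tolerance = 0.03)
  lab <- assign_cancer_labels(genes, dis, 0.208, 3)
  p_dis <- mean(dis %in% lab)
  p_non <- mean(setdiff(genes, dis) %in% lab)
  odds <- (p_dis / (1 - p_dis)) / (p_non / (1 - p_non))
  expect_equal(odds, 3, tolerance = 0.35)
})
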