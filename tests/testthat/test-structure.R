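test_that("region distance matches its definition and the naive oracle", {
  n <- 30
  expect_equal(region_distance_euclidean(matrix(0.3, n, n), matrix(0.3, n, n),
                                         c(3, 20)), 0)
  # one cell differing by 1.0 inside a length-10 region
  a <- matrix(0, n, n); b <- a
  b[5, 9] <- 1; b[9, 5] <- 1
  expect_equal(region_distance_euclidean(a, b, c(3, 12)), 0.1)
  set.seed(8)
  for (i in 1:5) {
    x <- matrix(runif(n * n), n); x <- (x + t(x)) / 2
    y <- matrix(runif(n * n), n); y <- (y + t(y)) / 2
    reg <- sort(sample(n, 2))
    expect_equal(region_distance_euclidean(x, y, reg),
                 naive_region_d(x, y, reg[1], reg[2]))
  }
})

test_that("region correlation matches the textbook formula", {
  x <- c(0.1, 0.5, 0.9, 0.2, 0.7)
  expect_equal(region_corr_pearson(x, x, c(1, 5)), 1)
  y <- 2 * mean(x) - x  # reflection around the mean
  expect_equal(region_corr_pearson(x, y, c(1, 5)), -1)
  set.seed(9)
  for (i in 1:5) {
    a <- runif(40); b <- runif(40)
    reg <- c(3, 31)
    expect_equal(region_corr_pearson(a, b, reg),
                 naive_region_r(a, b, reg[1], reg[2]))
  }
  expect_true(is.na(region_corr_pearson(rep(0.5, 10), runif(10), c(1, 10))))
})

test_that("the region scan equals the naive O(n^4) scan on small windows", {
  set.seed(10)
  m <- default_energy_model()
  for (i in 1:3) {
    n <- sample(40:55, 1)
    wt <- random_seq(n)
    pos <- sample(10:(n - 10), 1)
    mt <- wt
    substr(mt, pos, pos) <- sample(setdiff(rna_bases,
                                           substr(wt, pos, pos)), 1)
    p1 <- compute_pair_probabilities(wt, m)$p
    p2 <- compute_pair_probabilities(mt, m)$p
    fast <- scan_local_regions(p1, p2)
    slow <- naive_scan(p1, p2)
    expect_equal(fast$d_max, slow$d_max, tolerance = 1e-12)
    expect_equal(fast$r_min, slow$r_min, tolerance = 1e-9)
    expect_equal(fast$d_region, slow$d_region)
  }
})

test_that("identical ensembles are flagged as no change", {
  p <- compute_pair_probabilities(random_seq(30), default_energy_model())$p
  sc <- scan_local_regions(p, p)
  expect_equal(sc$d_max, 0)
  expect_true(sc$no_change)
  expect_equal(sc$r_min, 1)
})

test_that("a localized perturbation is found near its location", {
  set.seed(11)
  p1 <- matrix(runif(60 * 60, 0, 0.02), 60); p1 <- (p1 + t(p1)) / 2
  p2 <- p1
  p2[40:55, 40:55] <- p1[40:55, 40:55] + 0.4
  p2 <- (p2 + t(p2)) / 2
  sc <- scan_local_regions(p1, p2)
  expect_true(sc$d_region[1] <= 55 && sc$d_region[2] >= 40)
})

test_that("empirical p-values follow the plus-one convention", {
  # a substitution in an unpairable poly-A window has no ensemble effect:
  # every null draw ties the observation, so p = (1 + k)/(k + 1) = 1
  wt <- strrep("A", 40)
  mt <- wt; substr(mt, 20, 20) <- "C"
  win <- structure(list(wt_seq = wt, mt_seq = mt, window_start = 1L,
                        snv_offset = 20L), class = "window_pair")
  res <- empirical_pvalue(win, default_energy_model(), k = 19L,
                          rng_seed = 12L)
  expect_equal(res$p_d, 1)
  expect_equal(res$d_max, 0)

  # the single most disruptive substitution in the window strictly exceeds
  # every possible null draw, so with k = 19 the plus-one convention gives
  # exactly p = 1/20
  set.seed(13)
  left <- "GCGGCUG"
  hp <- paste0(left, "AUCA", reverse_complement(left))
  wt2 <- paste0(random_seq(22, gc = 0.2), hp, random_seq(21, gc = 0.2))
  m <- default_energy_model()
  p_wt <- compute_pair_probabilities(wt2, m)$p
  best <- list(d = -1)
  for (pos in seq_len(nchar(wt2))) {
    for (alt in setdiff(rna_bases, substr(wt2, pos, pos))) {
      cand <- wt2; substr(cand, pos, pos) <- alt
      d <- scan_local_regions(p_wt,
                              compute_pair_probabilities(cand, m)$p)$d_max
      if (d > best$d) best <- list(d = d, pos = pos, alt = alt, seq = cand)
    }
  }
  win2 <- structure(list(wt_seq = wt2, mt_seq = best$seq, window_start = 1L,
                         snv_offset = best$pos), class = "window_pair")
  res2 <- empirical_pvalue(win2, m, k = 19L, rng_seed = 14L)
  expect_equal(res2$p_d, 1 / 20)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  out <- bh_adjust(c(0.005, 0.05, 0.5), fdr = 0.10)
  expect_equal(out$q, c(0.015, 0.075, 0.5))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2))$q, rep(0.2, 3))
  expect_equal(bh_adjust(0.03)$q, 0.03)
  expect_length(bh_adjust(numeric(0))$q, 0)
  # monotone in rank, never below p
  set.seed(15)
  p <- runif(50)
  q <- bh_adjust(p)$q
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("confidence tiers follow the two-threshold rule", {
  expect_equal(classify_confidence(0.0030, 0.0213), "high")
  expect_equal(classify_confidence(0.0815, 0.15), "medium")
  expect_equal(classify_confidence(0.2, 0.15), "none")
  expect_equal(classify_confidence(c(0.01, 0.04), c(0.2, 0.049)),
               c("medium", "high"))
})

test_that("conserved-structure overlap percentages are rounded and best-per-source", {
  cons <- data.frame(transcript_id = "T", start = c(100L, 120L),
                     end = c(400L, 160L), name = c("cmfinder", "cmfinder"))
  ov <- conserved_overlap_pct(c(150, 249), cons, "T")
  expect_equal(ov$pct, 100)                     # fully inside 100-400
  ov2 <- conserved_overlap_pct(c(100, 199),
                               data.frame(transcript_id = "T", start = 150L,
                                          end = 249L, name = "rnaz"), "T")
  expect_equal(ov2$pct, 50)
  ov3 <- conserved_overlap_pct(c(1, 50), cons, "T")
  expect_equal(nrow(ov3), 0L)
  expect_equal(utrsnv:::format_overlap(ov3), "-")
})

test_that("region statistics bin lengths and SNV-to-region distances", {
  res <- data.frame(position = c(15, 25, 100),
                    d_region_start = c(10, 10, 150),
                    d_region_end = c(20, 20, 260))
  st <- region_stats(res)
  expect_equal(st$distances, c(0, 5, 50))
  expect_equal(unname(st$length_hist[1]), 2L)  # two regions of length 11
})

test_that("GC comparison recovers trivial KS cases and the CDF oracle", {
  same <- runif(40)
  g <- gc_compare(same, same)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  g2 <- gc_compare(runif(30, 0, 0.4), runif(30, 0.6, 1))
  expect_equal(g2$statistic, 1)
  # naive empirical-CDF sweep
  set.seed(16)
  x <- runif(50); y <- runif(70)
  grid <- sort(c(x, y))
  d_naive <- max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t),
                            numeric(1))))
  expect_equal(gc_compare(x, y)$statistic, d_naive)
})

test_that("LD partner re-testing distinguishes compensatory from neutral pairs", {
  set.seed(17)
  left <- "GGCAGCC"
  hp <- paste0(left, "AAUC", reverse_complement(left))
  bg1 <- random_seq(30, gc = 0.25); bg2 <- random_seq(30, gc = 0.25)
  seqs <- paste0(bg1, hp, bg2)
  tx <- data.frame(transcript_id = "T", gene = "G", sequence = seqs,
                   utr5_start = NA, utr5_end = NA,
                   utr3_start = 1L, utr3_end = nchar(seqs))
  pos <- 30 + 4                       # stem position (A base of GGCAGCC)
  ref <- substr(seqs, pos, pos)
  partner_pos <- 30 + nchar(hp) - 3   # its paired partner
  partner_ref <- substr(seqs, partner_pos, partner_pos)
  snv <- data.frame(transcript_id = "T", gene = "G", position = pos,
                    ref = ref, alt = "C")
  # compensatory: partner flips to restore complementarity (C-G pair)
  comp <- list(position = partner_pos, ref = partner_ref, alt = "G")
  out <- ld_haplotype_test(snv, comp, tx, flank = 40L, k = 99L,
                           rng_seed = 18L)
  expect_equal(out$status, "stabilizing")
  # neutral distant partner: the stem stays broken
  far_pos <- 5L
  neut <- list(position = far_pos, ref = substr(seqs, far_pos, far_pos),
               alt = setdiff(rna_bases, substr(seqs, far_pos, far_pos))[1])
  out2 <- ld_haplotype_test(snv, neut, tx, flank = 40L, k = 99L,
                            rng_seed = 19L)
  expect_equal(out2$status, "still_disruptive")
  # partner outside the window is skipped
  out3 <- ld_haplotype_test(snv, list(position = pos + 300L, ref = "A",
                                      alt = "C"), tx, flank = 200L)
  expect_equal(out3$status, "skipped")
})
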