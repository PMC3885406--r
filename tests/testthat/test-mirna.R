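test_that("seed-match typing follows the canonical definitions", {
  mir <- "UACGUACGAAAAAAAAAAA"   # seed 2-7 ACGUAC, 2-8 ACGUACG
  pad <- function(core) paste0("UUUUU", core, "UUUUU")
  m1 <- find_seed_matches(mir, pad("CGUACGUA"))
  expect_equal(m1$type, "8mer-1a")
  m2 <- find_seed_matches(mir, pad("CGUACGUC"))
  expect_equal(m2$type, "7mer-m8")
  m3 <- find_seed_matches(mir, pad("UGUACGUA"))
  expect_equal(m3$type, "7mer-1a")
  # G:U does not count as a seed match
  m4 <- find_seed_matches(mir, pad("CGUGCGUA"))   # A->G wobble in the middle
  expect_equal(nrow(m4), 0L)
})

test_that("every reported seed match is verified by the reverse-complement oracle", {
  set.seed(20)
  n_planted_found <- 0
  for (i in 1:2000) {
    mir <- random_seq(20)
    sub <- random_seq(61)
    rc28 <- reverse_complement(substr(mir, 2, 8))
    rc27 <- reverse_complement(substr(mir, 2, 7))
    hits <- find_seed_matches(mir, sub)
    for (h in seq_len(nrow(hits))) {
      e <- hits$site_end[h]
      if (hits$type[h] %in% c("8mer-1a", "7mer-m8"))
        expect_identical(substr(sub, e - 7, e - 1), rc28)
      if (hits$type[h] == "7mer-1a")
        expect_identical(substr(sub, e - 6, e - 1), rc27)
      if (hits$type[h] %in% c("8mer-1a", "7mer-1a"))
        expect_identical(substr(sub, e, e), "A")
    }
    # plant an 8mer and require it found (no false negatives)
    if (i <= 300) {
      planted <- paste0(substr(sub, 1, 20), rc28, "A", substr(sub, 29, 61))
      ph <- find_seed_matches(mir, planted)
      expect_true(any(ph$site_end == 28 & ph$type == "8mer-1a"))
      n_planted_found <- n_planted_found + 1
    }
  }
  expect_equal(n_planted_found, 300)
})

test_that("the seed-change filter compares (register, type) multisets", {
  a <- data.frame(site_end = 30L, type = "7mer-m8")
  none <- a[0, ]
  expect_true(seed_change_filter(a, none))
  expect_false(seed_change_filter(a, a))
  b <- data.frame(site_end = 30L, type = "8mer-1a")
  expect_true(seed_change_filter(a, b))
})

test_that("duplex scan recovers a perfect-complement site with the expected energy", {
  m <- default_energy_model()
  mir <- "ACGUACGUACGUACGUACGU"
  target <- paste0("AAAAAAAAAA", reverse_complement(mir), "AAAAAAAAAA")
  hits <- scan_duplex(mir, target, m)
  expect_gt(nrow(hits), 0)
  best <- hits[which.min(hits$energy), ]
  expect_equal(best$energy, helix_energy(mir, m), tolerance = 1e-9)
  expect_lt(best$energy, -11)
  expect_equal(best$n_pairs, nchar(mir))
  # zero complementarity: no sites
  expect_equal(nrow(scan_duplex(strrep("A", 20), strrep("A", 61), m)), 0L)
  # 8-bp duplex: energy is its 7 stacks plus initiation
  mir8 <- "GCGCGCGCAAAAAAAAAAAA"  # pairs via its first 8 bases only
  t8 <- paste0("CCCCCCCCCC", reverse_complement(substr(mir8, 1, 8)),
               "CCCCCCCCCC")      # C flanks cannot pair the poly-A tail
  h8 <- scan_duplex(mir8, t8, m, utrsnv:::default_duplex_params(
    score_min = 40, energy_relaxed = -1))
  b8 <- h8[which.min(h8$energy), ]
  expect_equal(b8$energy, helix_energy(substr(mir8, 1, 8), m),
               tolerance = 1e-9)
})

test_that("the strongest differing site is retained by register", {
  wt <- data.frame(register = c(10L, 20L), score = c(50, 60),
                   energy = c(-15, -18), span_start = c(3L, 13L),
                   span_end = c(10L, 20L), n_pairs = c(8L, 8L))
  mt <- data.frame(register = c(10L, 20L), score = c(50, 55),
                   energy = c(-15, -12), span_start = c(3L, 13L),
                   span_end = c(10L, 20L), n_pairs = c(8L, 7L))
  s <- strongest_differing_site(wt, mt)
  expect_equal(s$register, 20L)
  expect_equal(s$dG_wt, -18)
  expect_equal(s$dG_snv, -12)

  s2 <- strongest_differing_site(wt[1, ], mt[0, ])
  expect_equal(s2$dG_wt, -15)
  expect_true(is.na(s2$dG_snv))

  expect_null(strongest_differing_site(wt, wt))
})

test_that("site changes classify as create / destroy / alter at -11 kcal/mol", {
  expect_equal(classify_site_change(NA, -16.70), "create")
  expect_equal(classify_site_change(-11.01, NA), "destroy")
  expect_equal(classify_site_change(-16.10, -10.65), "alter")
  expect_true(is.na(classify_site_change(-9.0, -10.0)))
  expect_true(is.na(classify_site_change(NA, -10.9)))
  expect_equal(classify_site_change(-10.0, -11.0), "alter")
})

test_that("log-ratios are base-2 with the documented sign convention", {
  expect_equal(log_ratio(-20, -10), -1)
  expect_equal(log_ratio(-10, -10), 0)
  expect_equal(log_ratio(-16.10, -10.65), log2(10.65 / 16.10))
  expect_equal(round(log_ratio(-16.10, -10.65), 3), -0.596)
  expect_true(is.na(log_ratio(-10, 0.5)))
  expect_true(is.na(log_ratio(NA, -10)))
})

test_that("the above-mean |lr| filter is strict and matches a naive filter", {
  alt <- data.frame(lr = c(0.2, -0.6, 1.0))
  out <- alter_mean_filter(alt)
  expect_equal(out$mu, 0.6)
  expect_equal(out$retained$lr, 1.0)
  expect_message(out2 <- alter_mean_filter(data.frame(lr = rep(0.4, 3))),
                 "retained nothing")
  expect_equal(nrow(out2$retained), 0L)
  set.seed(21)
  lr <- rnorm(40)
  out3 <- alter_mean_filter(data.frame(lr = lr))
  expect_equal(sort(out3$retained$lr), sort(lr[abs(lr) > mean(abs(lr))]))
})

test_that("CLIP and expression filters behave per class and set", {
  clip <- data.frame(transcript_id = "T", start = 100L, end = 200L, bc = 3L)
  expect_true(clip_filter("destroy", "T", 150L, clip))
  expect_false(clip_filter("alter", "T", 150L,
                           transform(clip, bc = 1L)))
  expect_true(is.na(clip_filter("create", "T", 150L, clip[0, ])))
  expect_false(clip_filter("destroy", "T", 250L, clip))

  expect_true(expression_filter("miR-1", c("miR-1", "miR-2")))
  expect_false(expression_filter("miR-9", c("miR-1", "miR-2")))
  expect_warning(f <- expression_filter("miR-1", character(0)), "empty")
  expect_false(f)
})

test_that("every emitted site change satisfies exactly one class invariant", {
  cfg <- simulation_config(rng_seed = 31L)
  ds <- simulate_dataset(cfg)
  sc <- run_mirna_stage(ds$transcripts, ds$snvs, ds$mirnas, ds$annotations)
  expect_gt(nrow(sc), 0)
  for (i in seq_len(nrow(sc))) {
    cls <- sc$class[i]; wt <- sc$dG_wt[i]; mt <- sc$dG_snv[i]
    is_create <- is.na(wt) && !is.na(mt) && mt <= -11
    is_destroy <- is.na(mt) && !is.na(wt) && wt <= -11
    is_alter <- !is.na(wt) && !is.na(mt) && min(wt, mt) <= -11
    expect_equal(sum(is_create, is_destroy, is_alter), 1L)
    expect_equal(cls, c("create", "destroy", "alter")[
      which(c(is_create, is_destroy, is_alter))])
  }
  # lr defined exactly when both energies are negative
  both <- !is.na(sc$dG_wt) & !is.na(sc$dG_snv) & sc$dG_wt < 0 & sc$dG_snv < 0
  expect_true(all(!is.na(sc$lr[both])))
  expect_true(all(is.na(sc$lr[!both])))
})

test_that("cascade counts are monotonically non-increasing through the filters", {
  cfg <- simulation_config(rng_seed = 32L)
  ds <- simulate_dataset(cfg)
  sc <- run_mirna_stage(ds$transcripts, ds$snvs, ds$mirnas, ds$annotations)
  cn <- attr(sc, "stage_counts")
  expect_true(all(diff(unname(cn)) <= 0))
  expect_equal(unname(cn["expressed"]), sum(sc$retained))
})
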