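test_that("transcript reading normalizes DNA to RNA and validates UTR spans", {
  p <- write_tiny_transcripts(c(NM_X = "acgt"), utr3 = cbind(1L, 4L))
  tx <- read_transcripts(p$fasta, p$utr)
  expect_equal(tx$sequence, "ACGU")
  expect_equal(tx$utr3_start, 1L)

  p2 <- write_tiny_transcripts(c(NM_Y = "ACGUACGUAC"), utr3 = cbind(10L, 5L))
  expect_error(read_transcripts(p2$fasta, p2$utr), "inverted")

  p3 <- write_tiny_transcripts(c(A1 = "ACGUA", B1 = "GGGCC", C1 = "UUUAA"),
                               genes = c("GA", "GB", "GC"))
  tx3 <- read_transcripts(p3$fasta, p3$utr)
  expect_equal(nrow(tx3), 3L)
  expect_equal(tx3$gene, c("GA", "GB", "GC"))
})

test_that("FASTA records without UTR rows are dropped with a warning", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "tx.fa")
  writeLines(c(">K1", "ACGUACGU", ">K2", "ACGUACGU"), fa)
  utr <- file.path(dir, "utr.tsv")
  write.table(data.frame(transcript_id = "K1", gene = "G1",
                         utr5_start = NA, utr5_end = NA,
                         utr3_start = 1, utr3_end = 8),
              utr, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tx <- read_transcripts(fa, utr), "dropped")
  expect_equal(tx$transcript_id, "K1")
})

test_that("SNV tokens parse, validate against the sequence, and get labels", {
  seqs <- c(T1 = paste(rep("ACGU", 500), collapse = ""))
  p <- write_tiny_transcripts(seqs, utr3 = cbind(1001L, 2000L))
  tx <- read_transcripts(p$fasta, p$utr)
  # base at 1552: position 1552 %% 4 == 0 -> "U"
  snv_file <- file.path(p$dir, "snvs.tsv")
  write.table(data.frame(transcript_id = "T1", snv = "U1552G"),
              snv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  snvs <- read_snvs(snv_file, tx)
  expect_equal(snvs$position, 1552L)
  expect_equal(snvs$ref, "U")
  expect_equal(snvs$alt, "G")
  expect_equal(snvs$utr_label, "3")

  # ref mismatch is excluded and counted
  write.table(data.frame(transcript_id = "T1", snv = c("U1552G", "A10C")),
              snv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(s2 <- read_snvs(snv_file, tx), "ref allele")
  expect_equal(nrow(s2), 1L)
  expect_equal(attr(s2, "n_ref_mismatch"), 1L)

  # degenerate token is a row error
  write.table(data.frame(transcript_id = "T1", snv = "U10U"),
              snv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_snvs(snv_file, tx), "ref == alt")

  # unknown transcript skipped with a warning
  write.table(data.frame(transcript_id = c("T1", "NOPE"),
                         snv = c("U1552G", "A10C")),
              snv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(s3 <- read_snvs(snv_file, tx), "unknown")
  expect_equal(nrow(s3), 1L)
})

test_that("UTR classification covers 5', 3', both, and none", {
  tx <- data.frame(transcript_id = c("A", "B"), gene = c("G", "G"),
                   sequence = c(strrep("A", 100), strrep("A", 100)),
                   utr5_start = c(1L, 1L), utr5_end = c(30L, 10L),
                   utr3_start = c(60L, 20L), utr3_end = c(100L, 100L))
  expect_equal(classify_utr(70, tx[1, ]), "3")
  expect_equal(classify_utr(5, tx[1, ]), "5")
  expect_equal(classify_utr(40, tx[1, ]), "none")
  # inside utr5 of A but utr3 of B -> both; invariant to ordering
  expect_equal(classify_utr(25, tx), "both")
  expect_equal(classify_utr(25, tx[2:1, ]), "both")
})

test_that("window extraction clips at transcript ends", {
  tx <- data.frame(transcript_id = "T", gene = "G",
                   sequence = random_seq(1000))
  snv <- list(transcript_id = "T", position = 250L,
              ref = substr(tx$sequence, 250, 250), alt = "X")
  snv$alt <- setdiff(rna_bases, snv$ref)[1]
  w <- extract_window(snv, tx, 200L)
  expect_equal(w$window_start, 50L)
  expect_equal(nchar(w$wt_seq), 401L)
  expect_equal(w$snv_offset, 201L)

  snv$position <- 100L
  snv$ref <- substr(tx$sequence, 100, 100)
  snv$alt <- setdiff(rna_bases, snv$ref)[1]
  w2 <- extract_window(snv, tx, 200L)
  expect_equal(w2$window_start, 1L)
  expect_equal(nchar(w2$wt_seq), 300L)
  expect_equal(w2$snv_offset, 100L)

  tx3 <- data.frame(transcript_id = "T", gene = "G",
                    sequence = random_seq(1692))
  snv3 <- list(transcript_id = "T", position = 1552L,
               ref = substr(tx3$sequence, 1552, 1552))
  snv3$alt <- setdiff(rna_bases, snv3$ref)[1]
  w3 <- extract_window(snv3, tx3, 200L)
  expect_equal(w3$window_start, 1352L)
  expect_equal(nchar(w3$wt_seq), 341L)

  # unclipped interior windows: exact length and a single difference
  set.seed(1)
  for (i in 1:20) {
    len <- sample(300:500, 1); pos <- sample(150:(len - 150), 1)
    tx4 <- data.frame(transcript_id = "T", gene = "G",
                      sequence = random_seq(len))
    ref <- substr(tx4$sequence, pos, pos)
    s <- list(transcript_id = "T", position = pos, ref = ref,
              alt = sample(setdiff(rna_bases, ref), 1))
    w4 <- extract_window(s, tx4, 100L)
    expect_equal(nchar(w4$wt_seq), 201L)
    diffs <- which(strsplit(w4$wt_seq, "")[[1]] != strsplit(w4$mt_seq, "")[[1]])
    expect_equal(diffs, w4$snv_offset)
  }
})

test_that("transcript and SNV tables round-trip losslessly", {
  set.seed(2)
  cfg <- simulation_config(n_genes = 6L, n_snvs = 8L, rng_seed = 3L)
  ds <- simulate_dataset(cfg)
  dir <- tempfile(); dir.create(dir)
  write_transcripts(ds$transcripts, file.path(dir, "t.fa"),
                    file.path(dir, "u.tsv"))
  tx2 <- read_transcripts(file.path(dir, "t.fa"), file.path(dir, "u.tsv"))
  expect_equal(tx2$sequence, ds$transcripts$sequence)
  expect_equal(tx2$utr3_start, ds$transcripts$utr3_start)
  write_snvs(ds$snvs, file.path(dir, "s.tsv"))
  s2 <- read_snvs(file.path(dir, "s.tsv"), tx2)
  expect_equal(s2$position, ds$snvs$position)
  expect_equal(s2$alt, ds$snvs$alt)
  expect_equal(s2$utr_label, ds$snvs$utr_label)
})

test_that("screening-space arithmetic multiplies and doubles", {
  expect_equal(count_screen_space(0, 99)$per_allele, 0)
  expect_equal(count_screen_space(3, 7)$per_allele, 21)
  expect_equal(count_screen_space(3, 7)$total, 42)
})

test_that("BED-like intervals convert to 1-based inclusive on read", {
  f <- tempfile()
  writeLines("TX1\t99\t199\tcmfinder", f)
  bed <- read_bed_intervals(f, n_extra = 1L)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 199L)
  expect_equal(bed$name, "cmfinder")
})
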