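# Shared helpers: tiny in-code fixtures and independent oracles.

rna_bases <- c("A", "C", "G", "U")

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(rna_bases, n, replace = TRUE, prob = p), collapse = "")
}

extdata <- function(f) system.file("extdata", f, package = "utrsnv")

# Write a small transcript FASTA + UTR table and return the paths.
write_tiny_transcripts <- function(seqs, genes = NULL, utr5 = NULL,
                                   utr3 = NULL, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  ids <- names(seqs)
  if (is.null(genes)) genes <- paste0("GENE_", ids)
  fa <- file.path(dir, "tx.fa")
  writeLines(paste0(">", ids, "\n", unname(seqs)), fa)
  n <- length(seqs)
  if (is.null(utr5)) utr5 <- matrix(NA_integer_, n, 2)
  if (is.null(utr3)) utr3 <- cbind(rep(1L, n), nchar(seqs))
  tab <- data.frame(transcript_id = ids, gene = genes,
                    utr5_start = utr5[, 1], utr5_end = utr5[, 2],
                    utr3_start = utr3[, 1], utr3_end = utr3[, 2])
  utr <- file.path(dir, "utr.tsv")
  write.table(tab, utr, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, utr = utr, dir = dir)
}

# Independent naive oracles -------------------------------------------------

naive_region_d <- function(p_wt, p_mt, a, b) {
  s <- 0
  for (k in a:(b - 1)) for (l in (k + 1):b) s <- s + (p_wt[k, l] - p_mt[k, l])^2
  sqrt(s) / (b - a + 1)
}

naive_region_r <- function(x, y, a, b) {
  xs <- x[a:b]; ys <- y[a:b]
  if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  sxy / sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
}

# Exhaustive O(n^4) region scan, independent of the prefix-sum path.
naive_scan <- function(p_wt, p_mt, l_min = 10L) {
  n <- nrow(p_wt)
  x <- rowSums(p_wt); y <- rowSums(p_mt)
  best_d <- -Inf; best_d_reg <- NULL
  best_r <- Inf; best_r_reg <- NULL
  for (a in 1:(n - l_min + 1)) for (b in (a + l_min - 1):n) {
    d <- naive_region_d(p_wt, p_mt, a, b)
    len <- b - a + 1
    if (d > best_d ||
        (d == best_d && (len > diff(best_d_reg) + 1 ||
                         (len == diff(best_d_reg) + 1 && a < best_d_reg[1])))) {
      best_d <- d; best_d_reg <- c(a, b)
    }
    r <- naive_region_r(x, y, a, b)
    if (!is.na(r) &&
        (r < best_r ||
         (r == best_r && (len > diff(best_r_reg) + 1 ||
                          (len == diff(best_r_reg) + 1 && a < best_r_reg[1]))))) {
      best_r <- r; best_r_reg <- c(a, b)
    }
  }
  list(d_max = best_d, d_region = best_d_reg,
       r_min = if (is.finite(best_r)) best_r else NA_real_,
       r_region = best_r_reg)
}

# Brute-force one-sided Fisher p via explicit hypergeometric summation with
# choose() (independent of the log-factorial implementation).
brute_fisher <- function(a, b, c, d) {
  n <- a + b + c + d; r1 <- a + b; c1 <- a + c
  ks <- a:min(r1, c1)
  sum(choose(c1, ks) * choose(n - c1, r1 - ks)) / choose(n, r1)
}

# Duplex energy of a perfect helix, walked independently over the stack
# table (for the fully complementary duplex examples).
helix_energy <- function(mirna, model) {
  comp <- chartr("ACGU", "UGCA", mirna)
  types <- vapply(seq_len(nchar(mirna)), function(k) {
    m <- substr(mirna, k, k); t <- substr(comp, k, k)
    paste0(m, t)
  }, character(1))
  e <- model$duplex_init
  for (k in seq_len(length(types) - 1))
    e <- e + model$stack[types[k], types[k + 1]]
  e
}
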