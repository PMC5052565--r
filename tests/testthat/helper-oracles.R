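# Independent brute-force oracles used across the suite. These stay naive
# on purpose: they re-derive each quantity by enumeration, never by calling
# the implementation under test.

# maximum over all nonempty contiguous subarrays, O(n^2)
brute_max_subarray <- function(x) {
  n <- length(x)
  best <- -Inf
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + x[j]
      if (s > best) best <- s
    }
  }
  best
}

# exhaustive ORF scan: every ATG in every frame, first in-frame stop
# (inclusive) or last complete codon; longest wins, ties -> smaller start,
# then smaller frame
brute_orf <- function(seq) {
  n <- nchar(seq)
  best <- list(frame = 0L, start = 0L, length = 0L)
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < 1L) next
    codons <- vapply(seq_len(n_codons), function(k) {
      substr(seq, f + 3L * (k - 1L) + 1L, f + 3L * k)
    }, character(1))
    for (a in which(codons == "ATG")) {
      len <- NA_integer_
      for (k in a:n_codons) {
        if (codons[k] %in% c("TAA", "TAG", "TGA")) {
          len <- (k - a + 1L) * 3L
          break
        }
      }
      if (is.na(len)) len <- (n_codons - a + 1L) * 3L
      start <- f + (a - 1L) * 3L
      if (len > best$length ||
          (len == best$length && best$length > 0L &&
             (start < best$start ||
                (start == best$start && f < best$frame)))) {
        best <- list(frame = f, start = start, length = len)
      }
    }
  }
  best
}

# AUC by exhaustive pair counting with 0.5 tie credit
brute_auc <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# best accuracy over an exhaustive threshold enumeration (every observed
# score and +/- extremes, rule: positive iff score >= threshold)
brute_best_accuracy <- function(scores, y) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  max(vapply(cand, function(ct) mean((scores >= ct) == (y == 1L)), numeric(1)))
}

# mean in-frame hexamer score by a direct position loop
brute_frame_score <- function(table, seq, frame) {
  n <- nchar(seq)
  total <- 0
  count <- 0
  p <- frame + 1L
  while (p + 5L <= n) {
    h <- substr(seq, p, p + 5L)
    if (!grepl("[^ACGT]", h)) {
      total <- total + table$score[match(h, table$hexamers)]
      count <- count + 1L
    }
    p <- p + 3L
  }
  if (count == 0L) 0 else total / count
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# small shared hexamer table built from fixed synthetic training data
shared_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      ds <- generate_dataset(generator_config(seed = 99L, n_coding = 40L,
                                              n_noncoding = 40L,
                                              partial_fraction = 0))
      hx <- hexamer_training_sequences(ds)
      tab <<- build_hexamer_table(hx$cds_seqs, hx$noncoding_seqs)
    }
    tab
  }
})
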