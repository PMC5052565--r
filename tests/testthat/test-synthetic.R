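test_that("full-length coding transcripts carry ATG..stop at the recorded span", {
  ds <- generate_dataset(generator_config(seed = 71, n_coding = 25,
                                          n_noncoding = 5,
                                          partial_fraction = 0))
  tr <- ds$truth
  for (i in which(tr$label == "coding")) {
    seq <- ds$records[[i]]$sequence
    s <- tr$cds_start[i]; e <- tr$cds_end[i]
    expect_equal(substr(seq, s + 1, s + 3), "ATG")
    expect_true(substr(seq, e - 2, e) %in% c("TAA", "TAG", "TGA"))
    expect_equal((e - s) %% 3, 0)
    # body is stop-free in the CDS frame
    body <- substr(seq, s + 4, e - 3)
    codons <- substring(body, seq(1, nchar(body), 3), seq(3, nchar(body), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("5' truncation removes the start codon; 3' truncation the stop", {
  ds5 <- generate_dataset(generator_config(seed = 72, n_coding = 20,
                                           n_noncoding = 1,
                                           partial_fraction = 1,
                                           truncation_mode = "cut5"))
  t5 <- ds5$truth[ds5$truth$label == "coding", ]
  expect_true(all(t5$truncated))
  for (i in seq_len(nrow(t5))) {
    seq <- ds5$records[[i]]$sequence
    expect_equal(t5$cds_start[i], 0)  # CDS now begins at the 5' end
    # the original start codon is gone but the stop survives at cds_end
    expect_true(substr(seq, t5$cds_end[i] - 2, t5$cds_end[i]) %in%
                  c("TAA", "TAG", "TGA"))
    expect_lt(t5$cds_end[i], t5$length[i])  # cut never reaches the 3' UTR
  }
  ds3 <- generate_dataset(generator_config(seed = 73, n_coding = 20,
                                           n_noncoding = 1,
                                           partial_fraction = 1,
                                           truncation_mode = "cut3"))
  t3 <- ds3$truth[ds3$truth$label == "coding", ]
  for (i in seq_len(nrow(t3))) {
    seq <- ds3$records[[i]]$sequence
    expect_equal(t3$cds_end[i], nchar(seq))  # transcript ends inside the CDS
    last_codon_start <- t3$cds_start[i] + 1 +
      3 * ((nchar(seq) - t3$cds_start[i]) %/% 3 - 1)
    expect_false(substr(seq, last_codon_start, last_codon_start + 2) %in%
                   c("TAA", "TAG", "TGA"))
  }
})

test_that("every emitted transcript respects the length floor", {
  ds <- generate_dataset(generator_config(seed = 74, n_coding = 60,
                                          n_noncoding = 60,
                                          partial_fraction = 1,
                                          truncation_mode = "mix"))
  lens <- vapply(ds$records, function(r) nchar(r$sequence), numeric(1))
  expect_true(all(lens > 200))
  expect_equal(ds$truth$length, unname(lens))
  expect_equal(nrow(ds$truth), 120L)
})

test_that("identical configs reproduce byte-identical outputs", {
  cfg <- generator_config(seed = 75, n_coding = 15, n_noncoding = 15)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1$records, unclass), lapply(d2$records, unclass))
  expect_identical(d1$truth, d2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_dataset(d1, f1, g1)
  write_dataset(d2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  # generation must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_dataset(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("written datasets round-trip through the readers", {
  ds <- generate_dataset(generator_config(seed = 76, n_coding = 10,
                                          n_noncoding = 10))
  fa <- withr::local_tempfile(fileext = ".fa")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  tru <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, fa, gtf, tru)
  recs <- read_fasta(fa)
  expect_equal(vapply(recs, `[[`, character(1), "sequence"),
               vapply(ds$records, `[[`, character(1), "sequence"))
  ann <- read_exon_annotations(gtf)
  n_exons_gtf <- vapply(ds$records, function(r) nrow(ann[[r$id]]$exons),
                        integer(1))
  expect_equal(n_exons_gtf,
               vapply(ds$records, function(r) length(r$exon_spans), integer(1)))
  for (r in recs) {
    expect_equal(paste(exon_segments(r, ann[[r$id]]), collapse = ""),
                 r$sequence)
  }
  truth <- utils::read.table(tru, sep = "\t", header = TRUE)
  expect_equal(nrow(truth), 20L)
})

test_that("noncoding models produce the requested composition process", {
  u <- generate_dataset(generator_config(seed = 77, n_coding = 0,
                                         n_noncoding = 30,
                                         noncoding_model = "uniform"))
  m <- generate_dataset(generator_config(seed = 77, n_coding = 0,
                                         n_noncoding = 30,
                                         noncoding_model = "markov1"))
  freq <- function(ds) {
    s <- paste(vapply(ds$records, `[[`, character(1), "sequence"),
               collapse = "")
    table(strsplit(s, "")[[1]]) / nchar(s)
  }
  fu <- freq(u)
  expect_equal(as.numeric(fu[c("A", "C", "G", "T")]),
               c(0.3, 0.2, 0.2, 0.3), tolerance = 0.02)
  expect_false(identical(u$records[[1]]$sequence, m$records[[1]]$sequence))
})
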