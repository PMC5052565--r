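#' Configuration for the synthetic transcript generator
#'
#' The generator emulates the three transcript classes the classifier
#' must separate: full-length coding transcripts (5'UTR + ATG +
#' codon-biased stop-free body + stop codon + 3'UTR, with exon
#' boundaries), partial-length coding transcripts (5' and/or 3'
#' truncation removing the start and/or stop codon, as in incomplete
#' RNA-seq assemblies), and noncoding transcripts (near-uniform i.i.d.
#' or first-order-Markov base composition). All emitted transcripts
#' exceed `min_length` nucleotides.
#'
#' Codon usage for coding bodies is a fixed, nonuniform,
#' seed-independent distribution: exponentially decaying weights over the
#' 61 sense codons in lexicographic order, with a ratio of about 3.3
#' between the most and the least used codon — comparable to the codon
#' usage bias of mammalian genomes, strong enough for hexamer contrast
#' without making the classes trivially separable. The point is known
#' ground truth, not the codon table of a particular genome.
#'
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   config.
#' @param n_coding,n_noncoding Transcript counts per class.
#' @param cds_len_range CDS length range in nt (bounds multiples of 3),
#'   start and stop codon included.
#' @param utr_len_range Per-UTR length range in nt.
#' @param noncoding_len_range Noncoding transcript length range in nt.
#' @param codon_weights Optional length-61 nonnegative weights over the
#'   sense codons (lexicographic order); default the exponential table
#'   above.
#' @param noncoding_model `"uniform"` (i.i.d. with `base_freq`) or
#'   `"markov1"` (first-order chain with `transition`).
#' @param base_freq Length-4 A/C/G/T probabilities for UTRs and uniform
#'   noncoding sequence (default slightly AT-rich, genome-like).
#' @param transition 4x4 A/C/G/T transition matrix for `"markov1"`
#'   (default a mildly GC-persistent chain).
#' @param partial_fraction Share of coding transcripts truncated to
#'   partial length.
#' @param truncation_mode `"cut5"`, `"cut3"`, `"cut_both"`, or `"mix"`
#'   (per-transcript random choice among the three).
#' @param exon_count_range Range of exon counts per transcript.
#' @param min_length Minimum emitted transcript length (nt); truncations
#'   violating it are redrawn (bounded retries, then error).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 42L, n_coding = 500L, n_noncoding = 500L,
                             cds_len_range = c(300L, 1500L),
                             utr_len_range = c(30L, 300L),
                             noncoding_len_range = c(260L, 2100L),
                             codon_weights = NULL,
                             noncoding_model = c("uniform", "markov1"),
                             base_freq = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                             transition = NULL,
                             partial_fraction = 0.5,
                             truncation_mode = c("mix", "cut5", "cut3", "cut_both"),
                             exon_count_range = c(1L, 8L),
                             min_length = 200L) {
  noncoding_model <- match.arg(noncoding_model)
  truncation_mode <- match.arg(truncation_mode)
  stopifnot(n_coding >= 0L, n_noncoding >= 0L,
            cds_len_range[1L] %% 3L == 0L, cds_len_range[2L] %% 3L == 0L,
            cds_len_range[1L] >= 210L, cds_len_range[1L] <= cds_len_range[2L],
            utr_len_range[1L] >= 0L, partial_fraction >= 0, partial_fraction <= 1,
            exon_count_range[1L] >= 1L, min_length >= 1L)
  if (is.null(codon_weights)) {
    codon_weights <- exp(-seq(0, 1.2, length.out = 61L))
  }
  stopifnot(length(codon_weights) == 61L, all(codon_weights >= 0),
            sum(codon_weights) > 0)
  base_freq <- base_freq / sum(base_freq)
  if (is.null(transition)) {
    transition <- matrix(c(0.35, 0.20, 0.20, 0.25,
                           0.20, 0.30, 0.25, 0.25,
                           0.20, 0.30, 0.30, 0.20,
                           0.30, 0.20, 0.20, 0.30),
                         nrow = 4L, byrow = TRUE,
                         dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  }
  transition <- transition / rowSums(transition)
  structure(list(seed = as.integer(seed), n_coding = as.integer(n_coding),
                 n_noncoding = as.integer(n_noncoding),
                 cds_len_range = as.integer(cds_len_range),
                 utr_len_range = as.integer(utr_len_range),
                 noncoding_len_range = as.integer(noncoding_len_range),
                 codon_weights = codon_weights / sum(codon_weights),
                 noncoding_model = noncoding_model, base_freq = base_freq,
                 transition = transition,
                 partial_fraction = partial_fraction,
                 truncation_mode = truncation_mode,
                 exon_count_range = as.integer(exon_count_range),
                 min_length = as.integer(min_length)),
            class = "generator_config")
}

sense_codons <- function() {
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  all64 <- sort(all64)
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

random_bases <- function(n, config) {
  b <- c("A", "C", "G", "T")
  if (config$noncoding_model == "uniform") {
    return(paste(sample(b, n, replace = TRUE, prob = config$base_freq),
                 collapse = ""))
  }
  out <- integer(n)
  out[1L] <- sample.int(4L, 1L, prob = config$base_freq)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- sample.int(4L, 1L, prob = config$transition[out[i], ])
  }
  paste(b[out], collapse = "")
}

# UTRs share the background base composition regardless of noncoding model.
random_utr <- function(n, config) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = config$base_freq), collapse = "")
}

draw_exon_spans <- function(len, config) {
  kmax <- min(config$exon_count_range[2L], len)
  k <- sample(seq.int(config$exon_count_range[1L], kmax), 1L)
  cuts <- if (k > 1L) sort(sample.int(len - 1L, k - 1L)) else integer(0)
  starts <- c(0L, cuts)
  ends <- c(cuts, len)
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' Generate a labeled synthetic transcript dataset
#'
#' Fully reproducible from the config seed: the same config yields
#' byte-identical records and truth table. Coding transcripts carry their
#' true CDS span in the truth table; truncated (partial-length) variants
#' record the surviving in-frame CDS portion and the truncation mode.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_dataset`: `records` (list of
#'   [transcript_record()] with labels, exon spans and a per-transcript
#'   strand attribute used when writing GTF), `truth` (data.frame: id,
#'   label, truncated, truncation_mode, cds_start, cds_end, cds_frame,
#'   length), and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(config$seed)

  codons <- sense_codons()
  records <- vector("list", config$n_coding + config$n_noncoding)
  truth <- vector("list", length(records))
  n_trunc <- round(config$partial_fraction * config$n_coding)
  trunc_set <- if (config$n_coding > 0L && n_trunc > 0L) {
    sort(sample.int(config$n_coding, n_trunc))
  } else integer(0)

  for (i in seq_len(config$n_coding)) {
    id <- sprintf("coding_%04d", i)
    do_trunc <- i %in% trunc_set
    mode <- if (!do_trunc) NA_character_
            else if (config$truncation_mode == "mix") {
              sample(c("cut5", "cut3", "cut_both"), 1L)
            } else config$truncation_mode
    for (try in 1:25) {
      g <- make_coding_transcript(config, codons, mode)
      if (!is.null(g)) break
      if (try == 25L) stop("could not satisfy length constraints for ", id)
    }
    strand <- sample(c("+", "-"), 1L)
    records[[i]] <- transcript_record(id, g$seq,
                                      exon_spans = draw_exon_spans(nchar(g$seq), config),
                                      label = "coding")
    attr(records[[i]], "strand") <- strand
    truth[[i]] <- data.frame(id = id, label = "coding", truncated = do_trunc,
                             truncation_mode = mode %||% NA_character_,
                             cds_start = g$cds_start, cds_end = g$cds_end,
                             cds_frame = g$cds_frame, length = nchar(g$seq),
                             stringsAsFactors = FALSE)
  }

  for (j in seq_len(config$n_noncoding)) {
    i <- config$n_coding + j
    id <- sprintf("noncoding_%04d", j)
    len <- sample(seq.int(max(config$noncoding_len_range[1L],
                              config$min_length + 1L),
                          config$noncoding_len_range[2L]), 1L)
    seq <- random_bases(len, config)
    strand <- sample(c("+", "-"), 1L)
    records[[i]] <- transcript_record(id, seq,
                                      exon_spans = draw_exon_spans(len, config),
                                      label = "noncoding")
    attr(records[[i]], "strand") <- strand
    truth[[i]] <- data.frame(id = id, label = "noncoding", truncated = FALSE,
                             truncation_mode = NA_character_,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             cds_frame = NA_integer_, length = len,
                             stringsAsFactors = FALSE)
  }

  structure(list(records = records, truth = do.call(rbind, truth),
                 config = config),
            class = "synthetic_dataset")
}

# One coding transcript; applies truncation mode (NA = full length).
# Returns NULL when the draw cannot satisfy the minimum-length floor.
make_coding_transcript <- function(config, codons, mode) {
  n_codons <- sample(seq.int(config$cds_len_range[1L] %/% 3L,
                             config$cds_len_range[2L] %/% 3L), 1L)
  body <- paste(sample(codons, n_codons - 2L, replace = TRUE,
                       prob = config$codon_weights), collapse = "")
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  utr5 <- random_utr(sample(seq.int(config$utr_len_range[1L],
                                    config$utr_len_range[2L]), 1L), config)
  utr3 <- random_utr(sample(seq.int(config$utr_len_range[1L],
                                    config$utr_len_range[2L]), 1L), config)
  seq <- paste0(utr5, "ATG", body, stop_codon, utr3)
  cds_start <- nchar(utr5)
  cds_len <- 3L * n_codons
  cds_end <- cds_start + cds_len
  total <- nchar(seq)
  min_keep <- config$min_length + 1L

  if (is.na(mode)) {
    if (total <= config$min_length) return(NULL)
    return(list(seq = seq, cds_start = cds_start, cds_end = cds_end,
                cds_frame = 0L))
  }
  if (mode == "cut5") {
    lower <- cds_start + 3L
    upper <- min(cds_start + cds_len %/% 2L, total - min_keep)
    if (upper < lower) return(NULL)
    a <- sample(seq.int(lower, upper), 1L)
    new_seq <- substr(seq, a + 1L, total)
    return(list(seq = new_seq, cds_start = 0L, cds_end = cds_end - a,
                cds_frame = (3L - (a - cds_start) %% 3L) %% 3L))
  }
  if (mode == "cut3") {
    lower <- max(cds_end - cds_len %/% 2L, min_keep)
    upper <- cds_end - 3L
    if (upper < lower) return(NULL)
    b <- sample(seq.int(lower, upper), 1L)
    new_seq <- substr(seq, 1L, b)
    return(list(seq = new_seq, cds_start = cds_start, cds_end = b,
                cds_frame = 0L))
  }
  # cut_both: keep an internal CDS window (a, b], no UTR survives
  lower_a <- cds_start + 3L
  upper_a <- cds_end - 3L - min_keep
  if (upper_a < lower_a) return(NULL)
  a <- sample(seq.int(lower_a, upper_a), 1L)
  lower_b <- a + min_keep
  upper_b <- cds_end - 3L
  if (upper_b < lower_b) return(NULL)
  b <- sample(seq.int(lower_b, upper_b), 1L)
  list(seq = substr(seq, a + 1L, b), cds_start = 0L, cds_end = b - a,
       cds_frame = (3L - (a - cds_start) %% 3L) %% 3L)
}

#' Write a synthetic dataset to FASTA + GTF + truth TSV
#'
#' The GTF carries one `exon` line per exon with a `transcript_id`
#' attribute; each transcript is placed on its own contig (named after
#' the transcript) so genomic coordinates are transcript coordinates,
#' with minus-strand transcripts written in reversed genomic order to
#' exercise strand handling downstream. The triplet round-trips through
#' [read_fasta()] / [read_exon_annotations()] / [exon_segments()].
#'
#' @param dataset A [generate_dataset()] result.
#' @param fasta_path,gtf_path,truth_path Output paths (any may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, fasta_path, gtf_path = NULL,
                          truth_path = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!is.null(fasta_path)) write_fasta(dataset$records, fasta_path)
  if (!is.null(gtf_path)) {
    lines <- unlist(lapply(dataset$records, function(r) {
      strand <- attr(r, "strand") %||% "+"
      len <- nchar(r$sequence)
      spans <- r$exon_spans %||% list(c(0L, len))
      gstart <- vapply(spans, `[`, numeric(1), 1L) + 1L
      gend <- vapply(spans, `[`, numeric(1), 2L)
      if (strand == "-") {
        tmp <- len - gend + 1L
        gend <- len - gstart + 1L
        gstart <- tmp
      }
      ord <- order(gstart)
      sprintf(paste0("%s\tlncsieve_sim\texon\t%d\t%d\t.\t%s\t.\t",
                     "transcript_id \"%s\"; gene_id \"%s\";"),
              r$id, gstart[ord], gend[ord], strand, r$id, r$id)
    }))
    writeLines(lines, gtf_path)
  }
  if (!is.null(truth_path)) {
    utils::write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta = fasta_path, gtf = gtf_path, truth = truth_path))
}
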