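#' Locate the putative ORF of a transcript
#'
#' Scans the three forward reading frames. An ORF starts at `ATG` and
#' extends to the first in-frame stop codon (`TAA`/`TAG`/`TGA`)
#' inclusive, or, if no stop occurs, to the last complete codon at the
#' sequence end (`complete = FALSE`, supporting 3'-truncated
#' partial-length transcripts). The longest ORF wins; ties break toward
#' the smaller start position, then the smaller frame. With no `ATG`
#' anywhere, length and coverage are 0.
#'
#' @param seq Uppercase DNA sequence.
#' @return List of class `orf_result`: `frame` (0..2), `start`, `end`
#'   (0-based half-open, nucleotides), `length` (nt, multiple of 3),
#'   `coverage` (length / transcript length), `complete` (stop found).
#' @export
find_orf <- function(seq) {
  n <- nchar(seq)
  best <- list(frame = 0L, start = 0L, end = 0L, length = 0L,
               coverage = 0, complete = FALSE)
  class(best) <- "orf_result"
  if (n < 3L) return(best)
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < 1L) next
    starts <- seq.int(f + 1L, by = 3L, length.out = n_codons)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    # index of the first stop at or after each ATG (ATG itself is never a stop)
    nxt <- findInterval(atg - 1L, stops) + 1L
    has_stop <- nxt <= length(stops)
    end_codon <- ifelse(has_stop, stops[pmin(nxt, length(stops))], n_codons)
    len <- (end_codon - atg + 1L) * 3L
    for (j in seq_along(atg)) {
      cand_start <- f + (atg[j] - 1L) * 3L
      better <- len[j] > best$length ||
        (len[j] == best$length && best$length > 0L &&
           (cand_start < best$start ||
              (cand_start == best$start && f < best$frame)))
      if (better) {
        best <- list(frame = f, start = cand_start,
                     end = cand_start + len[j], length = as.integer(len[j]),
                     coverage = len[j] / n, complete = has_stop[j])
        class(best) <- "orf_result"
      }
    }
  }
  best
}

# Maximum-sum nonempty contiguous run of x, via the prefix-sum form of
# Kadane's recursion (vectorized). Returns sum, first index, last index;
# ties resolve to the earliest maximal end, then the earliest start
# achieving it.
max_subarray <- function(x) {
  n <- length(x)
  if (n == 0L) return(list(sum = 0, from = 0L, to = 0L))
  cs <- cumsum(x)
  prefix <- c(0, cs[-n])
  lo <- cummin(prefix)
  gains <- cs - lo
  to <- which.max(gains)
  from <- which(prefix[seq_len(to)] == lo[to])[1L]
  list(sum = gains[to], from = from, to = to)
}

#' Locate the maximum coding subsequence (MCSS)
#'
#' For each of the three forward frames, the codon-phased hexamer
#' log-ratio scores form an array whose maximum-sum nonempty contiguous
#' run (a Kadane-style maximum-subarray scan) is that frame's candidate
#' MCSS; the frame with the largest run sum wins (ties -> lowest frame).
#' Because it needs neither a start nor a stop codon, the MCSS stays
#' informative on partial-length transcripts where ORF detection fails.
#' Hexamers containing `N` contribute score 0 (they are skipped in all
#' sums but preserve positional contiguity).
#'
#' A run of `k` consecutive in-frame hexamers spans `k + 1` codons, so the
#' reported length is `3k + 3` nucleotides. The coding score percentage is
#' `S_m / (S_1 + S_2 + S_3)` when the denominator is positive, else 1.0
#' (degenerate all-nonpositive case). Sequences shorter than 6 nt return
#' an all-zero result.
#'
#' @param table A [build_hexamer_table()] result.
#' @param seq Uppercase DNA sequence.
#' @return List of class `mcss_result`: `frame`, `start`, `end` (0-based
#'   half-open nucleotide span of the run's codons; `start == frame`
#'   (mod 3)), `score` (`S_m`, run sum), `length` (nt), `frame_scores`
#'   (`S_1..S_3`), `score_percentage`.
#' @export
find_mcss <- function(table, seq) {
  zero <- structure(list(frame = 0L, start = 0L, end = 0L, score = 0,
                         length = 0L, frame_scores = c(0, 0, 0),
                         score_percentage = 0),
                    class = "mcss_result")
  if (nchar(seq) < 6L) return(zero)
  runs <- vector("list", 3L)
  s <- numeric(3L)
  any_hex <- FALSE
  for (f in 0:2) {
    idx <- hexamer_indices(seq, f)
    if (length(idx) == 0L) {
      runs[[f + 1L]] <- list(sum = 0, from = 0L, to = 0L)
      next
    }
    any_hex <- TRUE
    vals <- table$score[idx]
    vals[is.na(idx)] <- 0
    runs[[f + 1L]] <- max_subarray(vals)
    s[f + 1L] <- runs[[f + 1L]]$sum
  }
  if (!any_hex) return(zero)
  best_f <- which.max(s) - 1L
  run <- runs[[best_f + 1L]]
  k <- run$to - run$from + 1L
  start <- best_f + (run$from - 1L) * 3L
  structure(list(frame = best_f, start = as.integer(start),
                 end = as.integer(start + 3L * k + 3L),
                 score = run$sum, length = as.integer(3L * k + 3L),
                 frame_scores = s,
                 score_percentage = coding_score_percentage(s[1L], s[2L], s[3L])),
            class = "mcss_result")
}

#' Coding score percentage of the best frame
#'
#' The share of the summed per-frame MCSS coding scores captured by the
#' best frame: `S_m / (S_1 + S_2 + S_3)` when the sum is positive. When
#' the sum is non-positive the ratio is undefined or unbounded, and the
#' feature takes the value 1.0 (the best frame carries all of whatever
#' coding signal there is).
#'
#' @param s1,s2,s3 Per-frame MCSS coding scores.
#' @return A real.
#' @export
coding_score_percentage <- function(s1, s2, s3) {
  tot <- s1 + s2 + s3
  if (tot > 0) max(s1, s2, s3) / tot else 1.0
}

#' GC fraction of a sequence
#'
#' G+C over counted A/C/G/T characters (ambiguity characters excluded);
#' 0 when no unambiguous base is present.
#'
#' @param seq Uppercase DNA sequence.
#' @return A real in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0L) return(0)
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Exon-level hexamer and GC features
#'
#' Per exon, the hexamer score `S_m`, the hexamer score distance `D`, and
#' the GC fraction are computed; the per-feature maxima over exons (taken
#' independently for each feature) are the exon hexamer score, exon
#' hexamer distance and exon GC-content of the transcript.
#'
#' @param table A [build_hexamer_table()] result.
#' @param exon_seqs Non-empty character vector of exon subsequences.
#' @return Named numeric vector: `exon_hexamer_score`,
#'   `exon_hexamer_distance`, `exon_gc`.
#' @export
exon_features <- function(table, exon_seqs) {
  stopifnot(length(exon_seqs) > 0L)
  hs <- vapply(exon_seqs, function(e) {
    sd <- hexamer_score_and_distance(table, e)
    c(sd$max_score, sd$distance)
  }, numeric(2))
  gc <- vapply(exon_seqs, gc_content, numeric(1))
  c(exon_hexamer_score = max(hs[1L, ]), exon_hexamer_distance = max(hs[2L, ]),
    exon_gc = max(gc))
}

#' Names and order of the 11 transcript features
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("exon_hexamer_score", "exon_hexamer_distance", "exon_gc",
    "mcss_length", "mcss_score", "mcss_score_percentage",
    "orf_length", "orf_coverage", "orf_fickett",
    "orf_hexamer_score", "orf_hexamer_distance")
}

#' Compute the 11-feature vector of one transcript
#'
#' Assembles the exon group (hexamer score, hexamer distance, GC-content;
#' maxima over exons), the MCSS group (length, score, score percentage)
#' and the ORF group (length, coverage, Fickett TESTCODE, hexamer score
#' and distance on the ORF subsequence, whose frame 0 is the codon frame
#' by construction). When no ORF is found, the ORF hexamer features and
#' the Fickett score fall back to whole-transcript values while
#' `orf_length` and `orf_coverage` stay 0.
#'
#' @param table A [build_hexamer_table()] result.
#' @param record A [transcript_record()]; `exon_spans`, if absent, default
#'   to one exon spanning the whole sequence.
#' @return Named numeric vector of length 11, in [feature_names()] order.
#' @export
feature_vector <- function(table, record) {
  seq <- record$sequence
  exons <- exon_segments(record)
  ef <- exon_features(table, exons)
  mcss <- find_mcss(table, seq)
  orf <- find_orf(seq)
  orf_seq <- if (orf$length > 0L) substr(seq, orf$start + 1L, orf$end) else seq
  osd <- hexamer_score_and_distance(table, orf_seq)
  out <- c(ef,
           mcss_length = as.numeric(mcss$length),
           mcss_score = mcss$score,
           mcss_score_percentage = mcss$score_percentage,
           orf_length = as.numeric(orf$length),
           orf_coverage = orf$coverage,
           orf_fickett = fickett_score(orf_seq),
           orf_hexamer_score = osd$max_score,
           orf_hexamer_distance = osd$distance)
  out[feature_names()]
}

#' Feature matrix for a set of transcripts
#'
#' Applies [feature_vector()] to each record, optionally in parallel with
#' length-balanced scheduling (see [partition_by_length()]); row order
#' always follows input order regardless of `threads`.
#'
#' @param table A [build_hexamer_table()] result.
#' @param records List of [transcript_record()] objects.
#' @param threads Worker count (forked processes where available).
#' @return Numeric matrix, one row per record (rownames = ids), 11
#'   columns in [feature_names()] order.
#' @export
feature_matrix <- function(table, records, threads = 1L) {
  if (length(records) == 0L) {
    m <- matrix(numeric(0), ncol = 11L, dimnames = list(NULL, feature_names()))
    return(m)
  }
  compute <- function(idx) {
    t(vapply(records[idx], function(r) feature_vector(table, r), numeric(11L)))
  }
  threads <- max(1L, as.integer(threads))
  if (threads == 1L || length(records) == 1L ||
      .Platform$OS.type != "unix") {
    rows <- compute(seq_along(records))
  } else {
    part <- partition_by_length(records, threads)
    chunks <- parallel::mclapply(part$assignments, compute,
                                 mc.cores = threads)
    rows <- matrix(0, nrow = length(records), ncol = 11L)
    for (i in seq_along(chunks)) {
      if (length(part$assignments[[i]]) > 0L) {
        rows[part$assignments[[i]], ] <- chunks[[i]]
      }
    }
  }
  dimnames(rows) <- list(vapply(records, `[[`, character(1), "id"),
                         feature_names())
  rows
}
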