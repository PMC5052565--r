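#' Build an in-frame hexamer log-ratio table
#'
#' Counts codon-phased (step-3) hexamers starting at position 0 of every
#' training sequence, separately for the coding class (CDS sequences,
#' which must be in frame 0: first base = first codon base) and the
#' noncoding class, normalizes per class, and precomputes a clamped
#' log-ratio score for each of the 4096 hexamers:
#' `score(h) = ln(F(h) / F'(h))`, clamped to `[-floor, +floor]`.
#' A hexamer absent from the coding class but present in noncoding
#' sequences (typically hexamers beginning with a stop codon) scores
#' `-floor`; the converse scores `+floor`; a hexamer absent from both
#' scores 0. Hexamers containing `N` are never counted.
#'
#' @param cds_seqs Character vector of CDS sequences (frame 0).
#' @param noncoding_seqs Character vector of noncoding sequences.
#' @param floor Positive clamp magnitude for the log-ratio (natural log
#'   units). Default 10: a large finite penalty so the maximum-subarray
#'   recursion terminates runs at stop codons without infinities.
#' @return An object of class `hexamer_table`: list with `hexamers`
#'   (4096 names, lexicographic ACGT order), `coding_freq`,
#'   `noncoding_freq`, `score`, `floor`, `log_base`, `n_coding`,
#'   `n_noncoding`.
#' @export
build_hexamer_table <- function(cds_seqs, noncoding_seqs, floor = 10) {
  stopifnot(length(cds_seqs) > 0L, length(noncoding_seqs) > 0L, floor > 0)
  count_class <- function(seqs, what) {
    seqs <- toupper(seqs)
    counts <- colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = 6L, step = 3L))
    if (sum(counts) == 0) {
      stop("no hexamers observed in the ", what,
           " training sequences (all shorter than 6 nt?)")
    }
    counts
  }
  cc <- count_class(cds_seqs, "coding (CDS)")
  nc <- count_class(noncoding_seqs, "noncoding")
  f_c <- cc / sum(cc)
  f_n <- nc / sum(nc)
  score <- numeric(4096L)
  both <- f_c > 0 & f_n > 0
  score[both] <- pmin(pmax(log(f_c[both] / f_n[both]), -floor), floor)
  score[f_c == 0 & f_n > 0] <- -floor
  score[f_c > 0 & f_n == 0] <- floor
  names(score) <- names(f_c)
  structure(list(hexamers = names(f_c), coding_freq = unname(f_c),
                 noncoding_freq = unname(f_n), score = unname(score),
                 floor = floor, log_base = "natural",
                 n_coding = length(cds_seqs),
                 n_noncoding = length(noncoding_seqs)),
            class = "hexamer_table")
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat(sprintf(paste0("<hexamer_table> 4096 hexamers; trained on %d CDS / %d ",
                     "noncoding sequences; clamp +/-%g (%s log)\n"),
              x$n_coding, x$n_noncoding, x$floor, x$log_base))
  invisible(x)
}

# Integer hexamer indices (1..4096, base-4 over A<C<G<T) at step-3 positions
# frame, frame+3, ... of a 0-based sequence; NA where the window contains a
# non-ACGT character. Returns integer(0) when no complete window fits.
hexamer_indices <- function(seq, frame = 0L) {
  n <- nchar(seq)
  if (n < frame + 6L) return(integer(0))
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T")) - 1L
  starts <- seq.int(frame + 1L, n - 5L, by = 3L)
  idx <- integer(length(starts))
  ok <- rep(TRUE, length(starts))
  for (o in 0:5) {
    co <- codes[starts + o]
    ok <- ok & !is.na(co)
    co[is.na(co)] <- 0L
    idx <- idx * 4L + co
  }
  idx <- idx + 1L
  idx[!ok] <- NA_integer_
  idx
}

#' Mean in-frame hexamer score of one reading frame
#'
#' Averages `score(h)` over the codon-phased hexamers beginning at
#' positions `frame, frame + 3, ...` (0-based). Hexamers containing `N`
#' are skipped. Returns 0 when no complete valid hexamer exists.
#'
#' @param table A [build_hexamer_table()] result.
#' @param seq DNA sequence (uppercase).
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return The mean log-ratio score (a real).
#' @export
frame_hexamer_score <- function(table, seq, frame = 0L) {
  idx <- hexamer_indices(seq, as.integer(frame))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(0)
  mean(table$score[idx])
}

#' Hexamer score and hexamer score distance of a sequence
#'
#' Scores the three forward reading frames with [frame_hexamer_score()],
#' takes the maximum `S_m = max(S_1, S_2, S_3)` as the hexamer score, and
#' summarizes frame contrast with the hexamer score distance
#' `D = sum_i (S_m - S_i) / 2`, the mean excess of the best frame over the
#' other two. `D >= 0` always, with equality iff all three frame scores
#' coincide. Sequences shorter than 6 nt return `(0, 0)`.
#'
#' @inheritParams frame_hexamer_score
#' @return List with `frame_scores` (length 3, frames 0..2), `max_score`
#'   (`S_m`), and `distance` (`D`).
#' @export
hexamer_score_and_distance <- function(table, seq) {
  if (nchar(seq) < 6L) {
    return(list(frame_scores = c(0, 0, 0), max_score = 0, distance = 0))
  }
  s <- vapply(0:2, function(f) frame_hexamer_score(table, seq, f), numeric(1))
  sm <- max(s)
  list(frame_scores = s, max_score = sm, distance = sum(sm - s) / 2)
}

#' Save / load a hexamer table
#'
#' The table is written as a tab-separated file with columns
#' `hexamer`, `coding_freq`, `noncoding_freq`, `score`, plus a JSON
#' metadata sidecar (`<path>.json`) recording the clamp floor, log base
#' and training-set sizes.
#'
#' @param table A `hexamer_table`.
#' @param path Output TSV path.
#' @return `path` (save) or the reloaded `hexamer_table` (load).
#' @export
save_hexamer_table <- function(table, path) {
  df <- data.frame(hexamer = table$hexamers, coding_freq = table$coding_freq,
                   noncoding_freq = table$noncoding_freq, score = table$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(floor = table$floor, log_base = table$log_base,
               n_coding = table$n_coding, n_noncoding = table$n_noncoding,
               digest = hexamer_table_digest(table))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_hexamer_table
#' @export
load_hexamer_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", rep("numeric", 3L)))
  if (nrow(df) != 4096L) stop("hexamer table '", path, "' has ", nrow(df),
                              " rows; expected 4096")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(hexamers = df$hexamer, coding_freq = df$coding_freq,
                 noncoding_freq = df$noncoding_freq, score = df$score,
                 floor = meta$floor %||% 10, log_base = meta$log_base %||% "natural",
                 n_coding = meta$n_coding %||% NA_integer_,
                 n_noncoding = meta$n_noncoding %||% NA_integer_),
            class = "hexamer_table")
}

#' Content fingerprint of a hexamer table
#'
#' 32-bit FNV-1a hash over the formatted score and frequency vectors; used
#' to detect a model being applied with a table other than the one it was
#' trained with.
#'
#' @param table A `hexamer_table`.
#' @return An 8-character hexadecimal string.
#' @export
hexamer_table_digest <- function(table) {
  payload <- paste(sprintf("%.10g", c(table$score, table$coding_freq,
                                      table$noncoding_freq)), collapse = ",")
  fnv1a32(payload)
}

fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime, kept exact in doubles
    h <- ((h %% 65536) * 16777619 + ((h %/% 65536) * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
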