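#' Construct a transcript record
#'
#' A transcript record holds one transcript: its id, its sense-strand
#' nucleotide sequence, an optional exon segmentation (transcript-relative,
#' 0-based half-open intervals that tile `[0, nchar(sequence))`), and an
#' optional class label.
#'
#' @param id Transcript identifier, unique within a dataset.
#' @param sequence DNA sequence; lowercase and `U` are normalized on input,
#'   non-ACGT IUPAC ambiguity codes are mapped to `N`.
#' @param exon_spans Optional list of length-2 integer vectors
#'   `c(start, end)` (0-based half-open), sorted, disjoint and contiguous,
#'   whose union is `[0, nchar(sequence))`.
#' @param label Optional, `"coding"` or `"noncoding"`.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, sequence, exon_spans = NULL, label = NULL) {
  sequence <- normalize_sequence(sequence, id = id)
  if (nchar(sequence) < 1L) stop("transcript '", id, "': empty sequence")
  if (!is.null(exon_spans)) validate_exon_spans(exon_spans, nchar(sequence), id)
  if (!is.null(label)) label <- match.arg(label, c("coding", "noncoding"))
  structure(list(id = as.character(id), sequence = sequence,
                 exon_spans = exon_spans, label = label),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s  %d nt  %d exon(s)%s\n", x$id,
              nchar(x$sequence),
              if (is.null(x$exon_spans)) 1L else length(x$exon_spans),
              if (is.null(x$label)) "" else paste0("  [", x$label, "]")))
  invisible(x)
}

# Uppercase, U->T; non-ACGTN IUPAC codes collapse to N; anything else errors
# with its position.
normalize_sequence <- function(sequence, id = "?") {
  s <- toupper(as.character(sequence))
  s <- chartr("U", "T", s)
  iupac_extra <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N", iupac_extra))
  if (length(bad) > 0L) {
    stop("transcript '", id, "': non-IUPAC character '", chars[bad[1L]],
         "' at position ", bad[1L])
  }
  amb <- chars %in% iupac_extra
  if (any(amb)) {
    chars[amb] <- "N"
    s <- paste(chars, collapse = "")
  }
  s
}

validate_exon_spans <- function(spans, len, id) {
  m <- do.call(rbind, lapply(spans, as.integer))
  if (ncol(m) != 2L) stop("exon_spans must be (start, end) pairs")
  if (m[1L, 1L] != 0L || m[nrow(m), 2L] != len ||
      (nrow(m) > 1L && any(m[-1L, 1L] != m[-nrow(m), 2L]))) {
    stop("transcript '", id, "': exon spans must tile [0, ", len, ") contiguously")
  }
  if (any(m[, 2L] <= m[, 1L])) stop("transcript '", id, "': empty exon span")
  invisible(TRUE)
}

#' Read transcript sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`; records are returned
#' in file order. The id is the first whitespace-delimited token of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return A list of [transcript_record()] objects.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    if (file.exists(path) && file.size(path) == 0L) NULL
                    else stop("cannot read FASTA '", path, "': ",
                              conditionMessage(e), call. = FALSE)
                  })
  if (is.null(set) || length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(list())
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(set)
  mapply(function(id, s) transcript_record(id, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write transcript records to a FASTA file
#'
#' @param records List of [transcript_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read exon annotations from a GTF/GFF file
#'
#' Only lines with feature type `exon` are consumed; every exon line must
#' carry a `transcript_id` attribute (GTF `transcript_id "x"` or GFF
#' `transcript_id=x` style). Exons are grouped per transcript; all exons of
#' one transcript must share chromosome and strand.
#'
#' @param path Path to a GTF/GFF file.
#' @return A named list: per transcript id, a list with `transcript_id` and
#'   `exons` (a data.frame with columns chrom, start, end, strand; GTF
#'   1-based inclusive coordinates, sorted by genomic start).
#' @export
read_exon_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- list()
  if (!any(keep)) return(out)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("GTF line ", idx[which(nf < 9L)[1L]], ": fewer than 9 tab-separated fields")
  }
  feat <- vapply(fields, `[`, character(1), 3L)
  ex <- which(feat == "exon")
  if (length(ex) == 0L) return(out)
  attr9 <- vapply(fields[ex], `[`, character(1), 9L)
  hit <- regexpr('transcript_id[ =]+"?[^";]+', attr9)
  ok <- hit > 0L
  if (!all(ok)) {
    stop("GTF line ", idx[ex[which(!ok)[1L]]], ": exon line lacks transcript_id")
  }
  tid <- sub('transcript_id[ =]+"?', "", regmatches(attr9, hit))
  start <- as.integer(vapply(fields[ex], `[`, character(1), 4L))
  end <- as.integer(vapply(fields[ex], `[`, character(1), 5L))
  chrom <- vapply(fields[ex], `[`, character(1), 1L)
  strand <- vapply(fields[ex], `[`, character(1), 7L)
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0L) {
    stop("GTF line ", idx[ex[bad[1L]]], ": invalid exon coordinates (end < start?)")
  }
  for (grp in split(seq_along(ex), tid)) {
    t_id <- tid[grp[1L]]
    if (length(unique(strand[grp])) > 1L) {
      stop("transcript '", t_id, "': exons on mixed strands")
    }
    if (length(unique(chrom[grp])) > 1L) {
      stop("transcript '", t_id, "': exons on multiple chromosomes")
    }
    ord <- grp[order(start[grp])]
    out[[t_id]] <- list(
      transcript_id = t_id,
      exons = data.frame(chrom = chrom[ord], start = start[ord],
                         end = end[ord], strand = strand[ord],
                         stringsAsFactors = FALSE))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a transcript sequence into its exon subsequences
#'
#' Exons are returned 5'->3' in transcript orientation: genomic order for
#' `+` transcripts, reversed genomic order for `-` transcripts. The FASTA
#' sequence is assumed to already be the sense (transcript) sequence; the
#' annotation contributes only exon lengths and order, never a reverse
#' complement. Concatenating the returned segments reproduces the sequence.
#'
#' @param record A [transcript_record()].
#' @param annotation One element of [read_exon_annotations()] output for
#'   this transcript, or `NULL`. With no annotation the whole sequence is a
#'   single segment, so exon-level features degrade to transcript-level
#'   values.
#' @return Character vector of exon subsequences, 5'->3'.
#' @export
exon_segments <- function(record, annotation = NULL) {
  if (is.null(annotation)) {
    if (!is.null(record$exon_spans)) {
      return(vapply(record$exon_spans, function(sp) {
        substr(record$sequence, sp[1L] + 1L, sp[2L])
      }, character(1)))
    }
    return(record$sequence)
  }
  ex <- annotation$exons
  lens <- ex$end - ex$start + 1L
  if (any(ex$strand == "-")) lens <- rev(lens)
  total <- sum(lens)
  if (total != nchar(record$sequence)) {
    stop("transcript '", record$id, "': annotated exon length ", total,
         " != sequence length ", nchar(record$sequence))
  }
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  substring(record$sequence, starts + 1L, ends)
}

#' Attach annotation-derived exon spans to transcript records
#'
#' Converts genomic exon annotations into transcript-relative spans stored
#' on each record. Records without an annotation are left single-exon.
#'
#' @param records List of [transcript_record()].
#' @param annotations Output of [read_exon_annotations()], or `NULL`.
#' @return The records with `exon_spans` populated where annotated.
#' @export
attach_exons <- function(records, annotations = NULL) {
  if (is.null(annotations)) return(records)
  lapply(records, function(r) {
    ann <- annotations[[r$id]]
    if (is.null(ann)) return(r)
    segs <- exon_segments(r, ann)
    ends <- cumsum(nchar(segs))
    starts <- c(0L, ends[-length(ends)])
    r$exon_spans <- mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
    r
  })
}
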