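# Fickett TESTCODE lookup tables: for each base, the probability that a
# sequence with a given position-asymmetry or composition value is coding,
# and the weight (classification power) of each of the 8 parameters.
# Position parameter = max count over the three codon positions divided by
# (min count + 1); composition parameter = base fraction.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)

.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.15, 0.0)

# first (largest) break <= value wins; breaks are descending and end at 0
.fickett_lookup <- function(value, breaks, probs) {
  probs[which(value >= breaks)[1L]]
}

#' Fickett TESTCODE statistic
#'
#' The classic coding-region statistic: for each base, a position
#' parameter (asymmetry of the base's counts over the three codon
#' positions, `max / (min + 1)`) and a composition parameter (base
#' fraction) are each converted to a coding probability via the published
#' lookup tables and combined with the published weights. Higher values
#' indicate coding-like periodicity and composition. Deterministic;
#' non-ACGT characters are ignored; sequences shorter than 2 nt score 0.
#'
#' @param seq DNA sequence (uppercase).
#' @return The TESTCODE score (a real, roughly in `[0.2, 1.9]` for
#'   non-degenerate input).
#' @export
fickett_score <- function(seq) {
  if (nchar(seq) < 2L) return(0)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  base <- match(chars, c("A", "C", "G", "T"))
  pos <- (seq_along(chars) - 1L) %% 3L
  keep <- !is.na(base)
  if (sum(keep) < 2L) return(0)
  base <- base[keep]
  pos <- pos[keep]
  counts <- matrix(0, nrow = 4L, ncol = 3L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  tab <- table(factor(base, levels = 1:4), factor(pos, levels = 0:2))
  counts[] <- as.numeric(tab)
  total <- sum(counts)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    row <- counts[b, ]
    position_par <- max(row) / (min(row) + 1)
    content_par <- sum(row) / total
    score <- score +
      .fickett_lookup(position_par, .fickett_position_breaks,
                      .fickett_position_prob[[b]]) * .fickett_position_weight[[b]] +
      .fickett_lookup(content_par, .fickett_content_breaks,
                      .fickett_content_prob[[b]]) * .fickett_content_weight[[b]]
  }
  score
}
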