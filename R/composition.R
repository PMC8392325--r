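#' Nucleotide composition and strand skews
#'
#' Base counts and the strand-asymmetry statistics
#' `AT-skew = (A - T)/(A + T)` and `GC-skew = (G - C)/(G + C)`, computed on
#' the sequence as given (by convention the majority strand as deposited).
#' Case-insensitive; U is folded into T; IUPAC ambiguity codes are excluded
#' from the counts and reported separately. A skew whose denominator is zero
#' is undefined (`NA`).
#'
#' @param seq A character string, or a [Biostrings::DNAString].
#' @return An object of class `seq_composition`: counts `a`, `t`, `g`, `c`,
#'   `ambiguous`, `length`, and statistics `at_content`, `gc_content`,
#'   `ambiguity_fraction`, `at_skew`, `gc_skew`.
#' @export
composition <- function(seq) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  if (length(seq) != 1L) stop("composition() expects a single sequence")
  seq <- chartr("u", "t", tolower(seq))
  if (!nzchar(seq)) stop("empty sequence")
  dna <- tryCatch(Biostrings::DNAString(seq),
                  error = function(e) stop("invalid nucleotide sequence: ",
                                           conditionMessage(e)))
  freq <- Biostrings::alphabetFrequency(dna)
  if (sum(freq[c("-", "+", ".")]) > 0) {
    stop("invalid nucleotide sequence: gap characters present")
  }
  a <- freq[["A"]]; t <- freq[["T"]]; g <- freq[["G"]]; c <- freq[["C"]]
  amb <- sum(freq) - a - t - g - c
  n <- sum(freq)
  structure(
    list(a = a, t = t, g = g, c = c, ambiguous = amb, length = n,
         at_content = (a + t) / n,
         gc_content = (g + c) / n,
         ambiguity_fraction = amb / n,
         at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
         gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_),
    class = "seq_composition"
  )
}

#' @export
print.seq_composition <- function(x, ...) {
  cat(sprintf(
    "<seq_composition> %d bp  A+T %.1f%%  AT-skew %s  GC-skew %s\n",
    x$length, 100 * x$at_content,
    if (is.na(x$at_skew)) "NA" else sprintf("%.2f", x$at_skew),
    if (is.na(x$gc_skew)) "NA" else sprintf("%.2f", x$gc_skew)))
  invisible(x)
}

#' Per-region composition table of an annotated genome
#'
#' One row for the whole genome plus one per requested annotated region.
#'
#' @param genome An `annotated_genome` from [order_from_genbank()], or a
#'   list with `sequence` (string) and `features` (data.frame with columns
#'   `symbol`, `start`, `end`).
#' @param regions Character vector of feature symbols to report, or `NULL`
#'   for all features.
#' @return A `data.frame`: `region`, `start`, `end`, `length`, `at_content`,
#'   `at_skew`, `gc_skew`.
#' @export
composition_report <- function(genome, regions = NULL) {
  seq <- genome$sequence
  feats <- genome$features
  if (is.null(regions)) regions <- feats$symbol
  rows <- list()
  whole <- composition(seq)
  rows[[1]] <- data.frame(region = "genome", start = 1L,
                          end = nchar(seq), length = whole$length,
                          at_content = whole$at_content,
                          at_skew = whole$at_skew, gc_skew = whole$gc_skew,
                          stringsAsFactors = FALSE)
  for (r in regions) {
    hit <- feats[feats$symbol == r, , drop = FALSE]
    if (!nrow(hit)) stop("unknown region '", r, "'")
    for (k in seq_len(nrow(hit))) {
      s <- hit$start[k]; e <- hit$end[k]
      if (s < 1L || e > nchar(seq) || s > e) {
        stop("region '", r, "' outside sequence bounds")
      }
      cc <- composition(substr(seq, s, e))
      rows[[length(rows) + 1L]] <-
        data.frame(region = r, start = s, end = e, length = cc$length,
                   at_content = cc$at_content, at_skew = cc$at_skew,
                   gc_skew = cc$gc_skew, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
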