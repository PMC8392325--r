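#' Extract the signature of a rearrangement unit from an observed order
#'
#' The unit signature is the identity key under which distinct rearrangements
#' are counted: the minimal circular window of the observed order containing
#' every occurrence of the unit's member genes (intruding genes included),
#' together with the member genes recorded absent and the member genes that
#' fall in unsequenced regions. A unit whose members are all unobservable, or
#' whose window is interrupted by a gap, yields an `unknown` signature that
#' compares equal to nothing.
#'
#' @param order Observed [gene_order].
#' @param unit One element of [unit_definitions()], or any list with `name`
#'   and `members` (a contiguous gene set on the ancestral order).
#' @param ancestral Ground-pattern [gene_order].
#' @return An object of class `unit_signature` with fields `unit`, `tokens`
#'   (formatted token run), `absent`, `uncertain`, `unobserved`, `unknown`.
#' @export
unit_signature <- function(order, unit, ancestral = ancestral_gene_order()) {
  stopifnot(inherits(order, "gene_order"))
  members <- unit$members
  bad <- setdiff(members, gene_vocabulary())
  if (length(bad)) stop("unknown unit member(s): ", paste(bad, collapse = ", "))
  order <- canonicalize(order)
  pos <- which(order$symbol %in% members)
  absent <- intersect(order$absent, members)
  uncertain <- intersect(order$uncertain, members)
  observed_sym <- unique(order$symbol[pos])
  unobserved <- setdiff(members, c(observed_sym, absent))
  sig <- structure(
    list(unit = unit$name, members = members, tokens = character(0),
         absent = sort(absent), uncertain = sort(uncertain),
         unobserved = sort(unobserved), unknown = FALSE),
    class = "unit_signature"
  )
  if (!length(pos)) {
    # nothing positional to anchor on: unknown unless the whole unit is
    # positively recorded absent
    sig$unknown <- length(unobserved) > 0L || length(absent) == 0L
    return(sig)
  }
  if (length(unobserved) && !any(order$symbol == "GAP")) {
    stop("unit ", unit$name, " member(s) ",
         paste(unobserved, collapse = ", "),
         " missing from a gapless order without an absence record")
  }
  n <- length(order$symbol)
  win <- minimal_circular_window(pos, n)
  idx <- ((win$start - 1L + seq_len(win$len) - 1L) %% n) + 1L
  if (any(order$symbol[idx] == "GAP")) {
    sig$unknown <- TRUE
    return(sig)
  }
  sig$tokens <- format_token(order$symbol[idx], order$strand[idx])
  sig
}

# Smallest arc of a circle of size n covering all positions in pos:
# the complement of the largest gap between consecutive occurrences.
minimal_circular_window <- function(pos, n) {
  pos <- sort(unique(pos))
  k <- length(pos)
  if (k == 1L) return(list(start = pos, len = 1L))
  nxt <- c(pos[-1L], pos[1L] + n)
  gaps <- nxt - pos - 1L
  g <- which.max(gaps)
  start <- if (g == k) pos[1L] else pos[g + 1L]
  len <- n - gaps[g]
  list(start = start, len = len)
}

#' @export
print.unit_signature <- function(x, ...) {
  cat("<unit_signature> unit ", x$unit, ": ",
      if (x$unknown) "unknown" else paste(x$tokens, collapse = "-"), sep = "")
  if (length(x$absent)) cat("  absent:", paste(x$absent, collapse = ","))
  if (length(x$unobserved)) {
    cat("  unobserved:", paste(x$unobserved, collapse = ","))
  }
  cat("\n")
  invisible(x)
}

#' Identity key of a unit signature
#'
#' Signatures are equal (one arrangement, counted once in union sets) iff
#' their keys are equal: exact token sequence including strand and
#' multiplicity, plus the absence and unobserved sets. Unknown signatures
#' have key `NA` and never match anything.
#'
#' @param sig A `unit_signature`.
#' @return A string, or `NA_character_` for unknown signatures.
#' @export
signature_key <- function(sig) {
  if (sig$unknown) return(NA_character_)
  abs_tok <- ifelse(sig$absent %in% sig$uncertain,
                    paste0(sig$absent, "?"), sig$absent)
  paste0(paste(sig$tokens, collapse = "-"),
         "|absent:", paste(abs_tok, collapse = ","),
         "|unobs:", paste(sig$unobserved, collapse = ","))
}

#' Is a unit rearranged relative to the ancestral arrangement?
#'
#' `TRUE` iff the signature differs from the ancestral signature of the same
#' unit in token sequence, strand, multiplicity or absences. Members falling
#' in unsequenced regions are dropped from the ancestral reference before
#' comparison, so partial evidence still scores (a positively displaced gene
#' counts even when a fellow member is unsequenced). Unknown signatures
#' return `FALSE`: no observable evidence, conservatively unrearranged.
#'
#' @param sig A `unit_signature` from [unit_signature()].
#' @param ancestral Ground-pattern [gene_order].
#' @return Logical.
#' @export
is_unit_rearranged <- function(sig, ancestral = ancestral_gene_order()) {
  if (sig$unknown) return(FALSE)
  if (length(sig$absent)) return(TRUE)
  anc_sig <- unit_signature(ancestral,
                            list(name = sig$unit,
                                 members = setdiff(sig$members,
                                                   sig$unobserved)),
                            ancestral)
  !identical(sig$tokens, anc_sig$tokens)
}

#' Classify rearrangement events of an order against the ancestral order
#'
#' Detects the four event classes: gene loss (genes in the absence set),
#' gene duplication (multiplicity above one), gene inversion (strand switch
#' of a shared single-copy gene) and gene translocation (the minimal set of
#' shared, same-strand genes whose removal restores circular order
#' agreement; dispersed duplicate copies are always part of it). Absences
#' flagged uncertain (possibly sitting in an unsequenced region) are
#' reported as `unresolved_genes`, not as losses. Rotation of the input
#' never changes the call.
#'
#' @param order Observed [gene_order].
#' @param ancestral Ground-pattern [gene_order].
#' @param units Unit definitions used to fill `affected_units`.
#' @return An object of class `rearrangement_call` with fields `taxon`,
#'   `event_types`, `moved_genes`, `duplicated_genes`, `lost_genes`,
#'   `inverted_genes`, `unresolved_genes`, `affected_units`, `rearranged`.
#' @export
classify_events <- function(order, ancestral = ancestral_gene_order(),
                            units = unit_definitions()) {
  order <- canonicalize(order)
  obs_genes <- unique(order$symbol[order$symbol != "GAP"])
  anc_genes <- unique(ancestral$symbol)
  if (!length(intersect(obs_genes, anc_genes))) {
    stop("no comparison basis: the orders share no genes")
  }
  lost <- sort(intersect(setdiff(order$absent, order$uncertain), anc_genes))
  unresolved <- sort(intersect(order$uncertain, anc_genes))
  counts <- symbol_counts(order)
  duplicated_genes <- sort(names(counts)[counts > 1L])

  # strand comparison on shared single-copy genes
  anc_strand <- stats::setNames(ancestral$strand, ancestral$symbol)
  single <- names(counts)[counts == 1L]
  shared_single <- intersect(intersect(single, anc_genes),
                             names(anc_strand))
  obs_strand <- stats::setNames(order$strand, order$symbol)[shared_single]
  inverted <- sort(shared_single[obs_strand != anc_strand[shared_single] &
                                   !is_unstranded_symbol(shared_single)])

  moved <- translocated_genes(order, ancestral, inverted)

  affected <- character(0)
  for (u in units) {
    sig <- unit_signature(order, u, ancestral)
    if (is_unit_rearranged(sig, ancestral)) affected <- c(affected, u$name)
  }

  types <- c(if (length(moved)) "translocation",
             if (length(duplicated_genes)) "duplication",
             if (length(lost)) "loss",
             if (length(inverted)) "inversion")
  structure(
    list(taxon = order$taxon,
         event_types = sort(types %||% character(0)),
         moved_genes = moved, duplicated_genes = duplicated_genes,
         lost_genes = lost, inverted_genes = inverted,
         unresolved_genes = unresolved, affected_units = affected,
         rearranged = length(c(moved, duplicated_genes, lost,
                               inverted)) > 0L),
    class = "rearrangement_call"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rearrangement_call <- function(x, ...) {
  cat("<rearrangement_call>",
      if (nzchar(x$taxon)) paste0(" ", x$taxon) else "", "\n", sep = "")
  cat("  rearranged: ", x$rearranged, "\n", sep = "")
  if (length(x$event_types)) {
    cat("  types: ", paste(x$event_types, collapse = ", "), "\n", sep = "")
  }
  for (f in c("moved_genes", "duplicated_genes", "lost_genes",
              "inverted_genes", "unresolved_genes", "affected_units")) {
    if (length(x[[f]])) {
      cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

# Minimal translocation set: breakpoint analysis on circular adjacency of
# shared same-strand genes. Tandem duplicate runs collapse to one copy;
# genes still multi-copy after collapsing (dispersed copies) are moved by
# definition. The remaining minimum is the complement of a maximum-weight
# common circular subsequence; weights prefer keeping PCGs/rRNAs/CR (so
# equal-sized explanations move tRNAs) and, after that, keeping
# lexicographically later genes (so the moved set is lexicographically
# first).
translocated_genes <- function(order, ancestral, inverted = character(0)) {
  sym <- order$symbol[order$symbol != "GAP"]
  str <- order$strand[order$symbol != "GAP"]
  # collapse circular tandem runs of identical (symbol, strand)
  keep <- rep(TRUE, length(sym))
  if (length(sym) > 1L) {
    prev <- c(length(sym), seq_len(length(sym) - 1L))
    keep <- !(sym == sym[prev] & str == str[prev])
    if (!any(keep)) keep[1L] <- TRUE
  }
  sym <- sym[keep]; str <- str[keep]
  tab <- table(sym)
  dispersed <- names(tab)[tab > 1L]
  anc_genes <- unique(ancestral$symbol)
  dispersed <- intersect(dispersed, anc_genes)

  in_univ <- !(sym %in% dispersed) & (sym %in% anc_genes) &
    !(sym %in% inverted)
  b_sym <- sym[in_univ]; b_str <- str[in_univ]
  anc_keep <- ancestral$symbol %in% b_sym
  a_sym <- ancestral$symbol[anc_keep]; a_str <- ancestral$strand[anc_keep]
  # drop strand-mismatched genes from the universe (handled as inversions)
  strand_of <- stats::setNames(a_str, a_sym)
  same <- b_str == strand_of[b_sym]
  if (!all(same)) {
    b_sym <- b_sym[same]
    a_keep2 <- a_sym %in% b_sym
    a_sym <- a_sym[a_keep2]
  }
  if (length(a_sym) < 2L) return(sort(dispersed))
  kept <- max_common_circular_subsequence(a_sym, b_sym)
  sort(unique(c(dispersed, setdiff(a_sym, kept))))
}

# Maximum-weight common circular subsequence of two circular permutations of
# the same gene set. Returns the kept gene set.
max_common_circular_subsequence <- function(a, b) {
  n <- length(a)
  rank <- stats::setNames(seq_along(sort(a)), sort(a))
  heavy <- !startsWith(a, "trn")
  w <- stats::setNames(1e6 + 1e3 * as.numeric(heavy) + rank[a], a)
  best <- -Inf; best_set <- character(0)
  for (r in seq_len(n) - 1L) {
    br <- b[((seq_len(n) - 1L + r) %% n) + 1L]
    res <- weighted_lcs(a, br, w)
    if (res$weight > best) {
      best <- res$weight
      best_set <- res$kept
    }
  }
  best_set
}

weighted_lcs <- function(a, b, w) {
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    ai <- a[i]; wi <- w[[ai]]
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <-
        if (ai == b[j]) D[i, j] + wi
        else max(D[i, j + 1L], D[i + 1L, j])
    }
  }
  kept <- character(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && D[i + 1L, j + 1L] == D[i, j] + w[[a[i]]]) {
      kept <- c(a[i], kept); i <- i - 1L; j <- j - 1L
    } else if (D[i, j + 1L] >= D[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(weight = D[n + 1L, m + 1L], kept = kept)
}
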