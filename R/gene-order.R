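#' Construct a circular gene order
#'
#' A gene order is a circular, stranded, possibly incomplete sequence of gene
#' tokens for one taxon. Genes known to be missing from the genome live in a
#' separate absence set, never in the positional sequence; an unsequenced
#' stretch is a `GAP` token. An order containing a `GAP` is incomplete.
#'
#' @param symbols Character vector of gene symbols (see [gene_vocabulary()]).
#' @param strands Character vector, same length: `"+"` (majority), `"-"`
#'   (minority) or `""` for unstranded tokens (CR, NCR, GAP). Defaults to all
#'   majority.
#' @param absent Character vector of gene symbols confirmed absent from the
#'   genome.
#' @param uncertain Character vector, subset of `absent`: genes whose absence
#'   is unresolved (they may instead sit in an unsequenced region).
#' @param taxon Label for the taxon carrying this order.
#' @return An object of class `gene_order` with fields `taxon`, `symbol`,
#'   `strand`, `absent`, `uncertain` and `complete`.
#' @export
gene_order <- function(symbols, strands = NULL, absent = character(),
                       uncertain = character(), taxon = "") {
  if (length(symbols) < 1L) stop("a gene order needs at least one token")
  vocab <- gene_vocabulary()
  bad <- setdiff(unique(c(symbols, absent)), vocab)
  if (length(bad)) {
    stop("unknown gene token(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(strands)) strands <- rep("+", length(symbols))
  if (length(strands) != length(symbols)) {
    stop("strands must match symbols in length")
  }
  strands[is_unstranded_symbol(symbols)] <- ""
  if (any(strands[!is_unstranded_symbol(symbols)] == "")) {
    stop("coding tokens must carry a strand")
  }
  clash <- intersect(absent, symbols)
  if (length(clash)) {
    stop("gene(s) recorded absent but present in the sequence: ",
         paste(clash, collapse = ", "))
  }
  if (length(setdiff(uncertain, absent))) {
    stop("uncertain genes must be a subset of the absence set")
  }
  structure(
    list(taxon = taxon, symbol = as.character(symbols),
         strand = as.character(strands),
         absent = sort(unique(as.character(absent))),
         uncertain = sort(unique(as.character(uncertain))),
         complete = !any(symbols == "GAP")),
    class = "gene_order"
  )
}

#' Parse a gene-order string
#'
#' Grammar: tokens separated by `-`; a leading `~` marks the minority strand;
#' `[X]` records gene X as absent from the genome and `[X?]` as an unresolved
#' absence (missing or translocated into an unsequenced region); `//` records
#' an unsequenced gap. The order is read on the majority strand and may start
#' anywhere on the circle.
#'
#' @param text Gene-order string.
#' @param taxon Taxon label attached to the result.
#' @param aliases Optional named character vector mapping legacy tokens
#'   (e.g. `c(trnS = "trnS1")`) onto vocabulary symbols; bare `trnS`/`trnL`
#'   are otherwise rejected as ambiguous.
#' @return A [gene_order].
#' @export
#' @examples
#' parse_gene_order("trnI-~trnQ-trnM-ND2")
#' parse_gene_order("ND2-trnW-~trnC-COI-//-~rrnL-~rrnS-CR-~trnV-[trnY?]")
parse_gene_order <- function(text, taxon = "", aliases = NULL) {
  raw <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("empty gene-order string")
  vocab <- gene_vocabulary()
  symbols <- character(0); strands <- character(0)
  absent <- character(0); uncertain <- character(0)
  map_symbol <- function(sym, pos) {
    if (!is.null(aliases) && sym %in% names(aliases)) sym <- aliases[[sym]]
    if (sym %in% c("trnS", "trnL")) {
      stop("ambiguous token '", sym, "' at position ", pos,
           ": use trnS1/trnS2 or trnL1/trnL2 (or supply an alias table)")
    }
    if (!sym %in% vocab) {
      stop("unknown gene token '", sym, "' at position ", pos)
    }
    sym
  }
  for (i in seq_along(raw)) {
    tok <- raw[i]
    if (tok == "//") {
      symbols <- c(symbols, "GAP"); strands <- c(strands, "")
    } else if (grepl("^\\[.+\\]$", tok)) {
      inner <- sub("^\\[(.+)\\]$", "\\1", tok)
      unres <- grepl("\\?$", inner)
      sym <- map_symbol(sub("\\?$", "", inner), i)
      absent <- c(absent, sym)
      if (unres) uncertain <- c(uncertain, sym)
    } else {
      minority <- startsWith(tok, "~")
      sym <- map_symbol(sub("^~", "", tok), i)
      symbols <- c(symbols, sym)
      strands <- c(strands, if (is_unstranded_symbol(sym)) "" else
        if (minority) "-" else "+")
    }
  }
  if (!length(symbols)) stop("gene-order string contains no positional tokens")
  gene_order(symbols, strands, absent = absent, uncertain = uncertain,
             taxon = taxon)
}

format_token <- function(symbol, strand) {
  ifelse(symbol == "GAP", "//",
         ifelse(strand == "-", paste0("~", symbol), symbol))
}

#' Format a gene order as its canonical string
#'
#' The inverse of [parse_gene_order()] on canonical orders: the order is
#' canonicalized (see [canonicalize()]) and written in the gene-order
#' grammar, absence records (`[X]`, `[X?]`) appended last in lexicographic
#' order.
#'
#' @param order A [gene_order].
#' @return A single string.
#' @export
format_gene_order <- function(order) {
  order <- canonicalize(order)
  toks <- format_token(order$symbol, order$strand)
  abs_tok <- ifelse(order$absent %in% order$uncertain,
                    paste0("[", order$absent, "?]"),
                    paste0("[", order$absent, "]"))
  paste(c(toks, abs_tok), collapse = "-")
}

rotate_order <- function(order, k) {
  n <- length(order$symbol)
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  order$symbol <- order$symbol[idx]
  order$strand <- order$strand[idx]
  order
}

#' Canonical rotation of a circular gene order
#'
#' Rotates the circular token list to a deterministic anchor: the control
#' region when present exactly once, otherwise the rotation whose formatted
#' token sequence is lexicographically smallest. Strands are untouched;
#' idempotent.
#'
#' @param order A [gene_order].
#' @return The canonical [gene_order].
#' @export
canonicalize <- function(order) {
  stopifnot(inherits(order, "gene_order"))
  n <- length(order$symbol)
  cr <- which(order$symbol == "CR")
  if (length(cr) == 1L) return(rotate_order(order, cr - 1L))
  toks <- format_token(order$symbol, order$strand)
  keys <- vapply(seq_len(n) - 1L, function(k) {
    paste(toks[((seq_len(n) - 1L + k) %% n) + 1L], collapse = "\x01")
  }, "")
  rotate_order(order, which(keys == min(keys))[1L] - 1L)
}

#' Canonical identity key of a gene order
#'
#' Two orders are the same circular arrangement iff their keys are equal:
#' rotation-invariant, strand- and absence-sensitive. Incomplete orders
#' (containing gaps) compare by their known arcs as laid out, so orders
#' differing anywhere observable are distinct.
#'
#' @param order A [gene_order].
#' @return A single string.
#' @export
gene_order_key <- function(order) format_gene_order(order)

#' Test two gene orders for circular equality
#'
#' @param a,b [gene_order] objects.
#' @return `TRUE` iff the two circles are identical up to rotation, including
#'   strands and absence records.
#' @export
gene_order_equal <- function(a, b) {
  identical(gene_order_key(a), gene_order_key(b))
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order>",
      if (nzchar(x$taxon)) paste0(" ", x$taxon) else "",
      if (!x$complete) " (incomplete)" else "", "\n", sep = "")
  cat("  ", format_gene_order(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$symbol)

# Multiplicity of each coding symbol among positional tokens.
symbol_counts <- function(order) {
  tab <- table(order$symbol[order$symbol != "GAP"])
  stats::setNames(as.integer(tab), names(tab))
}
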