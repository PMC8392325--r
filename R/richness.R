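#' Index of distinct rearranged arrangements per unit and family
#'
#' For every rearrangement unit (and for the whole mitogenome) collects the
#' distinct rearranged signatures per family and their catalog-wide union.
#' A signature shared verbatim across families is one element of the union
#' (counted once in denominators) but appears in each carrying family's set
#' (counted once per family in numerators). Whole-mitogenome identity is the
#' canonical circular order including strands, absences and gap layout, so
#' differently-gapped partial orders stay distinct.
#'
#' @param cat A [catalog].
#' @param units Unit definitions, default [unit_definitions()].
#' @return An object of class `arrangement_index`: per column, `by_family`
#'   (named list of key sets) and `union` (character vector of keys).
#' @export
build_index <- function(cat, units = unit_definitions()) {
  stopifnot(inherits(cat, "catalog"))
  cols <- c(names(units), "whole")
  by_family <- stats::setNames(
    replicate(length(cols), list(), simplify = FALSE), cols)
  for (rec in cat$records) {
    call <- classify_events(rec$order, cat$ancestral, units)
    for (u in units) {
      sig <- unit_signature(rec$order, u, cat$ancestral)
      if (!is_unit_rearranged(sig, cat$ancestral)) next
      key <- signature_key(sig)
      for (fam in rec$families) {
        by_family[[u$name]][[fam]] <-
          union(by_family[[u$name]][[fam]], key)
      }
    }
    if (call$rearranged) {
      key <- gene_order_key(rec$order)
      for (fam in rec$families) {
        by_family[["whole"]][[fam]] <- union(by_family[["whole"]][[fam]], key)
      }
    }
  }
  unions <- lapply(by_family, function(fams) {
    sort(unique(unlist(fams, use.names = FALSE)))
  })
  structure(list(by_family = by_family, union = unions, columns = cols),
            class = "arrangement_index")
}

#' @export
print.arrangement_index <- function(x, ...) {
  cat("<arrangement_index>\n")
  for (cl in x$columns) {
    cat("  ", cl, ": union ", length(x$union[[cl]]), " over ",
        length(x$by_family[[cl]]), " families\n", sep = "")
  }
  invisible(x)
}

#' Family-level rearrangement richness
#'
#' For each family and each rearrangement unit (and the whole mitogenome):
#' the number of distinct rearranged arrangements of that unit found in the
#' family divided by the total number of distinct rearranged arrangements of
#' that unit across the catalog. A family with none scores 0; a column whose
#' union is empty is undefined (`NA`).
#'
#' @param index An `arrangement_index` from [build_index()].
#' @return A `data.frame` (class `richness_table`) with a `family` column
#'   and one ratio column per unit plus `whole`, ratios in `[0, 1]`.
#' @export
richness <- function(index) {
  stopifnot(inherits(index, "arrangement_index"))
  families <- sort(unique(unlist(lapply(index$by_family, names),
                                 use.names = FALSE)))
  out <- data.frame(family = families, stringsAsFactors = FALSE)
  for (cl in index$columns) {
    denom <- length(index$union[[cl]])
    out[[cl]] <- vapply(families, function(fam) {
      if (denom == 0L) return(NA_real_)
      length(index$by_family[[cl]][[fam]]) / denom
    }, 0)
  }
  class(out) <- c("richness_table", "data.frame")
  out
}

#' Percentage with one decimal, half away from zero
#'
#' The rendering used for richness ratios: `3/7` prints as `42.9`.
#'
#' @param x Numeric ratios in `[0, 1]`.
#' @return Numeric percentages rounded to one decimal.
#' @export
percent1 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 10

#' Render a richness table as percentages
#'
#' @param tab A `richness_table`.
#' @return A character `data.frame`: `"40.0%"` cells, `"-"` for undefined
#'   columns.
#' @export
format_richness <- function(tab) {
  out <- tab["family"]
  for (cl in setdiff(names(tab), "family")) {
    out[[cl]] <- ifelse(is.na(tab[[cl]]), "-",
                        sprintf("%.1f%%", percent1(tab[[cl]])))
  }
  out
}

#' Survey counts of a gene-order catalog
#'
#' Headline counts of a heteropteran-style survey: the number of distinct
#' gene orders (the ancestral ground pattern plus distinct rearranged
#' orders), the number of distinct rearranged orders, the number of species
#' carrying a rearranged order, and the number of families those span.
#'
#' @param cat A [catalog].
#' @return A list with `n_distinct_orders`, `n_rearranged_orders`,
#'   `n_rearranged_species`, `n_families_with_rearrangement`.
#' @export
survey_counts <- function(cat) {
  stopifnot(inherits(cat, "catalog"))
  keys <- character(0); species <- 0L; fams <- character(0)
  for (rec in cat$records) {
    call <- classify_events(rec$order, cat$ancestral)
    if (!call$rearranged) next
    keys <- union(keys, gene_order_key(rec$order))
    species <- species + sum(rec$species_counts)
    fams <- union(fams, rec$families)
  }
  list(n_distinct_orders = length(keys) + 1L,
       n_rearranged_orders = length(keys),
       n_rearranged_species = as.integer(species),
       n_families_with_rearrangement = length(fams))
}

#' Distinct rearranged arrangements per gene block
#'
#' Counts, for each gene block, the number of distinct rearranged
#' block-level arrangements observed in the catalog (the A1...A10 /
#' B1...B5 style variant count). A block signature is extracted exactly like
#' a unit signature, with the block's full member list.
#'
#' @param cat A [catalog].
#' @param blocks Block definitions, default [block_definitions()].
#' @return Named integer vector, one entry per block.
#' @export
block_diversity <- function(cat, blocks = block_definitions()) {
  stopifnot(inherits(cat, "catalog"))
  out <- stats::setNames(integer(length(blocks)), names(blocks))
  for (b in blocks) {
    keys <- character(0)
    for (rec in cat$records) {
      sig <- unit_signature(rec$order, b, cat$ancestral)
      if (is_unit_rearranged(sig, cat$ancestral)) {
        keys <- union(keys, signature_key(sig))
      }
    }
    out[[b$name]] <- length(keys)
  }
  out
}
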