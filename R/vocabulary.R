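#' Controlled vocabulary of mitochondrial gene symbols
#'
#' The 37 coding genes of a typical insect mitogenome (13 protein-coding
#' genes, 2 rRNAs, 22 tRNAs with the serine and leucine isoacceptors
#' disambiguated as trnS1/trnS2 and trnL1/trnL2), plus the three non-coding
#' markers used by the gene-order grammar: `CR` (control region), `NCR`
#' (unassigned non-coding region) and `GAP` (an unsequenced region, written
#' `//` in gene-order strings).
#'
#' @return Character vector of valid gene symbols.
#' @export
gene_vocabulary <- function() {
  c(mito_pcgs(), mito_rrnas(), mito_trnas(), "CR", "NCR", "GAP")
}

mito_pcgs <- function() {
  c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
    "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB")
}

mito_rrnas <- function() c("rrnL", "rrnS")

mito_trnas <- function() {
  paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"))
}

#' @keywords internal
is_coding_symbol <- function(x) {
  x %in% c(mito_pcgs(), mito_rrnas(), mito_trnas())
}

# Symbols that never carry a strand.
is_unstranded_symbol <- function(x) x %in% c("CR", "NCR", "GAP")

#' Insect ancestral mitochondrial gene order
#'
#' The putative ancestral pancrustacean arrangement, the ground pattern
#' against which heteropteran rearrangements are scored. 37 coding genes plus
#' the control region; 14 genes sit on the minority strand. The canonical
#' form is anchored at CR and reads trnI, trnQ, trnM, ND2, ... on the
#' majority strand.
#'
#' @return A [gene_order] object.
#' @export
ancestral_gene_order <- function() {
  parse_gene_order(
    paste0(
      "CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
      "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
      "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"
    ),
    taxon = "insect ancestral"
  )
}

#' Rearrangement unit definitions
#'
#' The six rearrangement units: contiguous gene runs on the ancestral order
#' inside which heteropteran rearrangements concentrate. Units 1-2 lie in
#' block A (CR to COI), unit 3 is block B (ND3 to ND5), units 4-6 lie in
#' block C (ND5 to CR).
#'
#' @return A named list; each element has `name`, `members` (gene symbols in
#'   ancestral order) and `parent_block`.
#' @export
unit_definitions <- function() {
  defs <- list(
    list(name = "1", members = c("trnI", "trnQ", "trnM"), parent_block = "A"),
    list(name = "2", members = c("trnW", "trnC", "trnY"), parent_block = "A"),
    list(name = "3",
         members = c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"),
         parent_block = "B"),
    list(name = "4", members = c("trnT", "trnP"), parent_block = "C"),
    list(name = "5", members = c("ND6", "CYTB", "trnS2", "ND1"),
         parent_block = "C"),
    list(name = "6", members = c("rrnL", "trnV", "rrnS"), parent_block = "C")
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Gene block definitions
#'
#' The three gene blocks concentrating heteropteran rearrangements:
#' block A between CR and COI, block B (the tRNA cluster) between ND3 and
#' ND5, block C between ND5 and CR.
#'
#' @return A named list; each element has `name`, `members` and `bounds`
#'   (the flanking conserved genes).
#' @export
block_definitions <- function() {
  defs <- list(
    list(name = "A",
         members = c("trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY"),
         bounds = c("CR", "COI")),
    list(name = "B",
         members = c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"),
         bounds = c("ND3", "ND5")),
    list(name = "C",
         members = c("trnH", "ND4", "ND4L", "trnT", "trnP", "ND6", "CYTB",
                     "trnS2", "ND1", "trnL1", "rrnL", "trnV", "rrnS"),
         bounds = c("ND5", "CR"))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}
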