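#' Construct a catalog record
#'
#' One row of a gene-order catalog: a taxon (a species or a group of species
#' sharing one arrangement), its infraorder and family (or families, when one
#' arrangement is shared verbatim across families), the number of species
#' carrying the arrangement, the gene order itself and the taxonomic level at
#' which the arrangement is a potential synapomorphy.
#'
#' @param taxon Unique taxon label.
#' @param infraorder Infraorder label.
#' @param family Family label; several families sharing the arrangement are
#'   separated by `/`.
#' @param species_count Positive integer, or a `/`-separated string of
#'   per-family counts matching `family`.
#' @param order A [gene_order].
#' @param synapomorphy One of `"none"`, `"genus"`, `"family"`,
#'   `"superfamily"`, `"infraorder"`.
#' @return An object of class `catalog_record`.
#' @export
catalog_record <- function(taxon, infraorder, family, species_count, order,
                           synapomorphy = "none") {
  stopifnot(inherits(order, "gene_order"))
  families <- strsplit(family, "/", fixed = TRUE)[[1]]
  counts <- as.integer(strsplit(as.character(species_count), "/",
                                fixed = TRUE)[[1]])
  if (length(counts) == 1L && length(families) > 1L) {
    counts <- rep(counts, length(families))
  }
  if (length(counts) != length(families)) {
    stop("species_count entries must match families for taxon '", taxon, "'")
  }
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("species_count must be >= 1 for taxon '", taxon, "'")
  }
  synapomorphy <- if (synapomorphy %in% c("", "/")) "none" else synapomorphy
  levels_ok <- c("none", "genus", "family", "superfamily", "infraorder")
  if (!synapomorphy %in% levels_ok) {
    stop("unknown synapomorphy level '", synapomorphy, "'")
  }
  structure(
    list(taxon = taxon, infraorder = infraorder, families = families,
         species_counts = counts, order = order, synapomorphy = synapomorphy),
    class = "catalog_record"
  )
}

#' Construct a catalog
#'
#' @param records List of [catalog_record] objects.
#' @param ancestral The ground-pattern [gene_order] rearrangements are scored
#'   against; must be complete, duplication-free and absence-free.
#' @return An object of class `catalog`.
#' @export
catalog <- function(records, ancestral = ancestral_gene_order()) {
  stopifnot(inherits(ancestral, "gene_order"))
  if (!ancestral$complete || length(ancestral$absent) ||
      any(symbol_counts(ancestral) > 1L)) {
    stop("ancestral order must be complete, duplication-free, absence-free")
  }
  taxa <- vapply(records, `[[`, "", "taxon")
  dup <- taxa[duplicated(taxa)]
  if (length(dup)) {
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  }
  structure(list(records = records, ancestral = ancestral),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat("<catalog> ", length(x$records), " records, ",
      sum(vapply(x$records, function(r) sum(r$species_counts), 0L)),
      " species\n", sep = "")
  invisible(x)
}

catalog_columns <- c("taxon", "infraorder", "family", "species_count",
                     "gene_order", "synapomorphy")

#' Read a gene-order catalog from TSV
#'
#' Expects UTF-8 tab-separated columns `taxon`, `infraorder`, `family`,
#' `species_count`, `gene_order`, `synapomorphy`; `#` lines are comments.
#' Gene orders use the grammar of [parse_gene_order()].
#'
#' @param path Path to the TSV file.
#' @param ancestral Ground-pattern order to attach; defaults to
#'   [ancestral_gene_order()].
#' @return A [catalog].
#' @export
read_catalog <- function(path, ancestral = ancestral_gene_order()) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("catalog file has no header: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, catalog_columns)) {
    stop("catalog header must be: ", paste(catalog_columns, collapse = ", "))
  }
  records <- vector("list", length(lines) - 1L)
  for (i in seq_along(records)) {
    ln <- lineno[i + 1L]
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(catalog_columns)) {
      stop("malformed catalog row at line ", ln, ": expected ",
           length(catalog_columns), " fields, got ", length(fields))
    }
    rec <- tryCatch(
      catalog_record(fields[1], fields[2], fields[3], fields[4],
                     parse_gene_order(fields[5], taxon = fields[1]),
                     fields[6]),
      error = function(e) {
        stop("malformed catalog row at line ", ln, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    records[[i]] <- rec
  }
  catalog(records, ancestral = ancestral)
}

#' Write a catalog to TSV
#'
#' Inverse of [read_catalog()] on canonical catalogs: gene orders are written
#' in canonical form, so read-write-read round-trips are the identity.
#'
#' @param cat A [catalog].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  rows <- vapply(cat$records, function(r) {
    paste(c(r$taxon, r$infraorder, paste(r$families, collapse = "/"),
            paste(r$species_counts, collapse = "/"),
            format_gene_order(r$order), r$synapomorphy),
          collapse = "\t")
  }, "")
  writeLines(c(paste(catalog_columns, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' The packaged heteropteran gene-order catalog
#'
#' Transcription of the published heteropteran gene-rearrangement survey:
#' every distinct rearranged arrangement with the families and species counts
#' carrying it, plus one aggregated record for the taxa retaining the
#' ancestral ground pattern. Printed excerpts are embedded in the ancestral
#' background so every record is a full circular order; unsequenced stretches
#' are kept as gaps. See the fixture header comments for the transcription
#' conventions.
#'
#' @return A [catalog].
#' @export
heteroptera_catalog <- function() {
  read_catalog(system.file("extdata", "heteroptera_catalog.tsv",
                           package = "mitorearr", mustWork = TRUE))
}
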