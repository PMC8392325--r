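#' Read a GenBank flat file
#'
#' Minimal reader for annotated mitogenome records: LOCUS name and length,
#' the feature table (feature type, location, strand, qualifiers) and the
#' ORIGIN sequence. Locations may be `x..y`, `complement(x..y)` or
#' `join(...)` (the span of a join is used; coordinates are 1-based
#' inclusive). This is a reader only: no annotation is performed and
#' nothing is written back.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `locus`, `length`, `features` (data.frame: `type`,
#'   `start`, `end`, `strand`, `gene`, `product`, `note`) and `sequence`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- ""; seq_len_decl <- NA_integer_
  li <- grep("^LOCUS", lines)
  if (length(li)) {
    parts <- strsplit(trimws(sub("^LOCUS", "", lines[li[1]])), "\\s+")[[1]]
    locus <- parts[1]
    bp <- suppressWarnings(as.integer(parts[2]))
    if (!is.na(bp)) seq_len_decl <- bp
  }
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- list()
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    block <- lines[(fstart[1] + 1L):fend]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        type <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        cur <- list(type = type, loc = loc, quals = character(0))
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else if (length(cur$quals)) {
          last <- length(cur$quals)
          cur$quals[last] <- paste(cur$quals[last], txt)
        } else {
          cur$loc <- paste0(cur$loc, txt)
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  qual_value <- function(quals, key) {
    hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^"|"$', "", sub(paste0("^/", key, "="), "", hit[1]))
  }
  rows <- lapply(feats, function(f) {
    loc <- f$loc
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (!length(nums)) return(NULL)
    data.frame(type = f$type, start = nums[1], end = max(nums),
               strand = strand,
               gene = qual_value(f$quals, "gene"),
               product = qual_value(f$quals, "product"),
               note = qual_value(f$quals, "note"),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  seq <- ""
  if (length(ostart)) {
    body <- lines[(ostart[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  list(locus = locus, length = seq_len_decl, features = rows,
       sequence = seq)
}

aa3_to_letter <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

# Map a feature's labels onto the gene vocabulary; NA when unmappable.
map_feature_symbol <- function(type, gene, product, note) {
  labels <- tolower(paste(stats::na.omit(c(gene, product, note)),
                          collapse = " "))
  g <- if (is.na(gene)) "" else gene
  # explicit vocabulary names in /gene win
  direct <- gene_vocabulary()
  hit <- direct[tolower(direct) == tolower(g)]
  if (length(hit)) return(hit[1])
  if (type %in% c("misc_feature", "D-loop", "rep_origin")) {
    if (type == "D-loop" || grepl("control region|d-loop|a\\+t[- ]rich",
                                  labels)) {
      return("CR")
    }
    return(NA_character_)
  }
  if (type == "rRNA" || grepl("ribosomal rna|rrna", labels)) {
    if (grepl("16s|large|l-rrna|rrnl", labels)) return("rrnL")
    if (grepl("12s|small|s-rrna|rrns", labels)) return("rrnS")
    return(NA_character_)
  }
  if (type == "tRNA" || grepl("^trn|trna", labels)) {
    m <- regmatches(labels, regexpr("trna-[a-z]{3}", labels))
    aa <- NA_character_
    if (length(m)) {
      aa3 <- paste0(toupper(substr(sub("trna-", "", m), 1, 1)),
                    substr(sub("trna-", "", m), 2, 3))
      aa <- unname(aa3_to_letter[aa3])
    } else if (grepl("^trn[a-z][0-9]?", labels)) {
      aa <- toupper(substr(sub("^trn", "", labels), 1, 1))
    }
    if (is.na(aa)) return(NA_character_)
    if (aa == "S") {
      if (grepl("ucn|uga|s2|tga", labels)) return("trnS2")
      if (grepl("agn|gcu|s1|agc|gct", labels)) return("trnS1")
      return(NA_character_)
    }
    if (aa == "L") {
      if (grepl("cun|uag|l1|tag", labels)) return("trnL1")
      if (grepl("uur|uaa|l2|taa", labels)) return("trnL2")
      return(NA_character_)
    }
    sym <- paste0("trn", aa)
    if (sym %in% gene_vocabulary()) return(sym)
    return(NA_character_)
  }
  # protein-coding genes
  if (grepl("nadh", labels) || grepl("^nd", tolower(g))) {
    if (grepl("4l", labels)) return("ND4L")
    m <- regmatches(labels, regexpr("subunit [1-6]", labels))
    if (length(m)) return(paste0("ND", sub("subunit ", "", m)))
    m <- regmatches(tolower(g), regexpr("^nd[1-6]", tolower(g)))
    if (length(m)) return(toupper(m))
    return(NA_character_)
  }
  if (grepl("cytochrome c oxidase|^cox|^coi", labels)) {
    if (grepl("iii|subunit 3|cox3", labels)) return("COIII")
    if (grepl("ii|subunit 2|cox2", labels)) return("COII")
    return("COI")
  }
  if (grepl("cytochrome b|cytb|cob", labels)) return("CYTB")
  if (grepl("atp", labels)) {
    if (grepl("8", labels)) return("ATP8")
    if (grepl("6", labels)) return("ATP6")
    return(NA_character_)
  }
  NA_character_
}

#' Extract a gene order from a GenBank record
#'
#' Features sorted by 5' coordinate on the majority strand become tokens;
#' complement-strand features become minority tokens. Paired annotations of
#' one locus (a `gene` feature overlapping a `CDS`/`tRNA`/`rRNA` with the
#' same mapped symbol) collapse to one token. Features whose labels cannot
#' be mapped onto the vocabulary become `NCR` tokens with a warning, and
#' are listed in the result's `report`.
#'
#' @param record A path to a GenBank flat file, or the result of
#'   [read_genbank()].
#' @return An object of class `annotated_genome`: `order` (a canonical
#'   [gene_order]), `sequence`, `features` (data.frame with `symbol`,
#'   `start`, `end`, `strand`), and `report` (unmappable features).
#' @export
order_from_genbank <- function(record) {
  if (is.character(record)) record <- read_genbank(record)
  feats <- record$features
  keep_types <- c("CDS", "tRNA", "rRNA", "gene", "misc_feature", "D-loop",
                  "rep_origin")
  feats <- feats[feats$type %in% keep_types, , drop = FALSE]
  if (is.null(feats) || !nrow(feats)) {
    stop("no recognizable features in record '", record$locus, "'")
  }
  feats$symbol <- vapply(seq_len(nrow(feats)), function(i) {
    map_feature_symbol(feats$type[i], feats$gene[i], feats$product[i],
                       feats$note[i])
  }, "")
  # drop bare 'gene' features that duplicate a typed feature of one locus
  typed <- feats$type != "gene"
  drop <- logical(nrow(feats))
  for (i in which(feats$type == "gene")) {
    overlap <- typed & feats$start <= feats$end[i] & feats$end >= feats$start[i] &
      (is.na(feats$symbol[i]) | is.na(feats$symbol) |
         feats$symbol == feats$symbol[i])
    if (any(overlap)) drop[i] <- TRUE
  }
  feats <- feats[!drop, , drop = FALSE]
  # unannotated misc_features that map to nothing: NCR with warning
  unmapped <- which(is.na(feats$symbol))
  report <- feats[unmapped, c("type", "start", "end", "gene", "product"),
                  drop = FALSE]
  if (length(unmapped)) {
    warning("unmappable feature(s) kept as NCR: ",
            paste(stats::na.omit(c(feats$gene[unmapped],
                                   feats$product[unmapped])),
                  collapse = ", "))
    feats$symbol[unmapped] <- "NCR"
  }
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  strands <- ifelse(is_unstranded_symbol(feats$symbol), "", feats$strand)
  ord <- canonicalize(gene_order(feats$symbol, strands,
                                 taxon = record$locus))
  structure(
    list(order = ord, sequence = record$sequence,
         features = feats[, c("symbol", "start", "end", "strand")],
         report = report),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$order$taxon, ": ",
      length(x$order$symbol), " features, ",
      nchar(x$sequence), " bp\n", sep = "")
  print(x$order)
  invisible(x)
}
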