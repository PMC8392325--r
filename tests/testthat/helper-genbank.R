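# Synthetic GenBank fixtures, built programmatically at test time.

gb_feature_line <- function(type, loc) {
  paste0("     ", formatC(type, width = 16, flag = "-"), loc)
}

gb_qualifier <- function(key, value) {
  paste0(strrep(" ", 21), "/", key, "=\"", value, "\"")
}

gb_origin <- function(seq) {
  starts <- seq(1L, nchar(seq), by = 60L)
  lines <- vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(blocks), collapse = " "))
  }, "")
  c("ORIGIN", lines, "//")
}

write_gb <- function(path, locus, seq, features) {
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular INV", locus,
            nchar(seq)),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    features,
    gb_origin(seq))
  writeLines(lines, path)
  path
}

# 5-feature toy: 2 CDS, 2 tRNA, 1 rRNA on a 600-bp sequence
write_toy_genbank <- function(path, rotate = 0L, seed = 11L) {
  seq <- random_sequence(600, 0.7, 0.1, -0.2, seed = seed)
  feats <- list(
    list(type = "tRNA", start = 1, end = 70, strand = "+",
         product = "tRNA-Ile"),
    list(type = "CDS", start = 81, end = 200, strand = "+",
         product = "NADH dehydrogenase subunit 2"),
    list(type = "tRNA", start = 211, end = 280, strand = "-",
         product = "tRNA-Gln"),
    list(type = "CDS", start = 291, end = 450, strand = "+",
         product = "cytochrome c oxidase subunit I"),
    list(type = "rRNA", start = 461, end = 590, strand = "-",
         product = "16S ribosomal RNA"))
  n <- nchar(seq)
  lines <- character(0)
  for (f in feats) {
    s <- ((f$start - 1L + rotate) %% n) + 1L
    e <- ((f$end - 1L + rotate) %% n) + 1L
    loc <- sprintf("%d..%d", s, e)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, gb_feature_line(f$type, loc),
               gb_qualifier("product", f$product))
  }
  if (rotate != 0L) {
    seq <- paste0(substr(seq, n - rotate + 1L, n), substr(seq, 1L, n - rotate))
  }
  write_gb(path, "TOY5", seq, lines)
}

# Full synthetic emulation of an assassin-bug mitogenome: the P. lemur gene
# order (trnW translocated between trnI and trnQ), 15,311 bp drawn at the
# published composition parameters (A+T 0.756, AT-skew 0.15, GC-skew -0.25).
# This is a synthetic stand-in, not the real accession.
synthetic_plemur_order <- function() {
  c("CR", "trnI", "trnW", "trnQ", "trnM", "ND2", "trnC", "trnY", "COI",
    "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6", "COIII", "trnG",
    "ND3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "ND5", "trnH",
    "ND4", "ND4L", "trnT", "trnP", "ND6", "CYTB", "trnS2", "ND1", "trnL1",
    "rrnL", "trnV", "rrnS")
}

write_synthetic_plemur_genbank <- function(path, seed = 99L) {
  total <- 15311L
  syms <- synthetic_plemur_order()
  minority <- c("trnQ", "trnC", "trnY", "trnF", "ND5", "trnH", "ND4",
                "ND4L", "trnP", "ND1", "trnL1", "rrnL", "trnV", "rrnS")
  base_len <- function(s) {
    if (s == "CR") return(1388L)
    if (s == "rrnL") return(1250L)
    if (s == "rrnS") return(780L)
    if (startsWith(s, "trn")) return(66L)
    c(ND1 = 930L, ND2 = 990L, ND3 = 354L, ND4 = 1330L, ND4L = 290L,
      ND5 = 1710L, ND6 = 480L, COI = 1530L, COII = 680L, COIII = 786L,
      ATP6 = 670L, ATP8 = 158L, CYTB = 1135L)[[s]]
  }
  lens <- vapply(syms, base_len, 0L)
  lens[1] <- lens[1] + (total - sum(lens))  # pad CR to the exact size
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seq <- random_sequence(total, 0.756, 0.15, -0.25, seed = seed)
  product_of <- function(s) {
    aa <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
            Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
            K = "Lys", M = "Met", F = "Phe", P = "Pro", T = "Thr",
            W = "Trp", Y = "Tyr", V = "Val")
    if (s == "CR") return(NULL)
    if (s == "rrnL") return("16S ribosomal RNA")
    if (s == "rrnS") return("12S ribosomal RNA")
    if (s == "trnS1") return("tRNA-Ser(AGN)")
    if (s == "trnS2") return("tRNA-Ser(UCN)")
    if (s == "trnL1") return("tRNA-Leu(CUN)")
    if (s == "trnL2") return("tRNA-Leu(UUR)")
    if (startsWith(s, "trn")) {
      return(paste0("tRNA-", aa[[substr(s, 4, 4)]]))
    }
    c(ND1 = "NADH dehydrogenase subunit 1",
      ND2 = "NADH dehydrogenase subunit 2",
      ND3 = "NADH dehydrogenase subunit 3",
      ND4 = "NADH dehydrogenase subunit 4",
      ND4L = "NADH dehydrogenase subunit 4L",
      ND5 = "NADH dehydrogenase subunit 5",
      ND6 = "NADH dehydrogenase subunit 6",
      COI = "cytochrome c oxidase subunit I",
      COII = "cytochrome c oxidase subunit II",
      COIII = "cytochrome c oxidase subunit III",
      ATP6 = "ATP synthase F0 subunit 6",
      ATP8 = "ATP synthase F0 subunit 8",
      CYTB = "cytochrome b")[[s]]
  }
  type_of <- function(s) {
    if (s == "CR") return("misc_feature")
    if (s %in% c("rrnL", "rrnS")) return("rRNA")
    if (startsWith(s, "trn")) return("tRNA")
    "CDS"
  }
  lines <- character(0)
  for (i in seq_along(syms)) {
    s <- syms[i]
    loc <- sprintf("%d..%d", starts[i], ends[i])
    if (s %in% minority) loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, gb_feature_line(type_of(s), loc))
    pr <- product_of(s)
    if (is.null(pr)) {
      lines <- c(lines, gb_qualifier("note", "control region"))
    } else {
      lines <- c(lines, gb_qualifier("product", pr))
    }
  }
  write_gb(path, "SYNPLEMUR", seq, lines)
}
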