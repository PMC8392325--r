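# Independent brute-force oracle for single-step TDRL products.
# Works on plain symbol vectors (all majority strand), with its own
# normalization, deliberately sharing no code with the package's engine.

norm_circle <- function(v) {
  n <- length(v)
  rots <- vapply(seq_len(n) - 1L, function(k) {
    paste(v[((seq_len(n) - 1L + k) %% n) + 1L], collapse = "|")
  }, "")
  min(rots)
}

brute_single_tdrl <- function(genes, maxseg) {
  n <- length(genes)
  out <- character(0)
  for (s in seq_len(n) - 1L) {
    rot <- genes[((seq_len(n) - 1L + s) %% n) + 1L]
    for (L in seq_len(min(maxseg, n - 1L))) {
      seg <- rot[seq_len(L)]
      rest <- rot[-seq_len(L)]
      for (mask in 0:(2^L - 1L)) {
        del_first <- bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0
        res <- c(seg[!del_first], seg[del_first], rest)
        out <- c(out, norm_circle(res))
      }
    }
  }
  sort(unique(out))
}

# all circular permutations of a gene set (first element fixed)
all_circular_orders <- function(genes) {
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  lapply(perm(genes[-1L]), function(p) c(genes[1L], p))
}

random_toy_order <- function(seed, n_min = 5L, n_max = 12L,
                             with_cr = TRUE) {
  set.seed(seed)
  pool <- setdiff(gene_vocabulary(), c("CR", "NCR", "GAP"))
  n <- sample(n_min:n_max, 1L)
  sym <- sample(pool, n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  if (with_cr && runif(1) < 0.7) {
    sym <- c("CR", sym)
    strands <- c("", strands)
  }
  gene_order(sym, strands, taxon = paste0("toy", seed))
}
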