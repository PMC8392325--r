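#' Construct a tandem duplication/random loss step
#'
#' One TDRL event: a contiguous segment of the circular order (it may wrap
#' past the origin) is duplicated in tandem, then for every duplicated
#' position one of the two copies is deleted or pseudogenized. With the
#' loss extension, a position may lose both copies, modelling gene loss in
#' the same framework.
#'
#' @param start 1-based index of the first segment position (on the
#'   canonical rotation of the order the step is applied to).
#' @param len Segment length, at least 1 and less than the token count.
#' @param losses Character vector of length `len`: which copy of each
#'   duplicated position is deleted, `"first"` or `"second"` (or `"both"`
#'   under the loss extension).
#' @return An object of class `tdrl_step`.
#' @export
tdrl_step <- function(start, len, losses) {
  if (len < 1L) stop("segment length must be >= 1")
  if (length(losses) != len) stop("losses must have one entry per position")
  if (!all(losses %in% c("first", "second", "both"))) {
    stop("losses must be 'first', 'second' or 'both'")
  }
  structure(list(start = as.integer(start), len = as.integer(len),
                 losses = losses),
            class = "tdrl_step")
}

#' Apply a TDRL step to a gene order
#'
#' The input is canonicalized first, so step indices always refer to the
#' canonical rotation; the result is canonical too. Strands are never
#' touched (the model has no inversion). A `"both"` loss is only legal with
#' `allow_loss = TRUE`; genes eliminated entirely are moved to the result's
#' absence set.
#'
#' @param order A [gene_order] without gap tokens.
#' @param step A [tdrl_step].
#' @param allow_loss Permit full loss of a gene (both copies deleted).
#' @return The resulting canonical [gene_order].
#' @export
apply_tdrl <- function(order, step, allow_loss = FALSE) {
  order <- canonicalize(order)
  n <- length(order$symbol)
  if (any(order$symbol == "GAP")) {
    stop("TDRL steps require a gapless order")
  }
  if (step$len >= n) stop("segment must be shorter than the order")
  if (!allow_loss && any(step$losses == "both")) {
    stop("gene extinction not permitted without the loss extension")
  }
  res <- tdrl_apply_core(order$symbol, order$strand, step$start, step$len,
                         step$losses)
  if (!length(res$sym)) stop("TDRL step would delete the entire order")
  canonicalize(gene_order(res$sym, res$str,
                          absent = union(order$absent, res$lost),
                          uncertain = order$uncertain,
                          taxon = order$taxon))
}

# Core permutation engine shared by apply/enumerate/search; works on raw
# symbol/strand vectors, returns survivors plus fully-eliminated symbols.
tdrl_apply_core <- function(sym, str, start, len, losses) {
  n <- length(sym)
  rot <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
  seg <- rot[seq_len(len)]
  rest <- if (len < n) rot[(len + 1L):n] else integer(0)
  first_keep <- seg[!losses %in% c("first", "both")]
  second_keep <- seg[!losses %in% c("second", "both")]
  keep <- c(first_keep, second_keep, rest)
  out_sym <- sym[keep]; out_str <- str[keep]
  lost <- setdiff(sym[seg[losses == "both"]], out_sym)
  list(sym = out_sym, str = out_str, lost = lost)
}

loss_patterns <- function(len, allow_loss = FALSE) {
  vals <- if (allow_loss) c("first", "second", "both") else
    c("first", "second")
  as.matrix(expand.grid(rep(list(vals), len), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Enumerate all products of one TDRL step
#'
#' Brute-force oracle: every segment of length 1 to `max_segment` at every
#' start position, crossed with every loss pattern, deduplicated by
#' canonical circular equality. The source itself is always reachable (lose
#' the whole second copy).
#'
#' @param order A gapless [gene_order].
#' @param max_segment Maximum segment length (0 gives an empty set).
#' @param allow_loss Permit full gene loss.
#' @return Named list of canonical [gene_order]s, names are their keys.
#' @export
enumerate_single_tdrl <- function(order, max_segment, allow_loss = FALSE) {
  order <- canonicalize(order)
  n <- length(order$symbol)
  if (max_segment > n - 1L) stop("max_segment must be <= token count - 1")
  out <- list()
  if (max_segment < 1L) return(out)
  for (len in seq_len(max_segment)) {
    pats <- loss_patterns(len, allow_loss)
    for (start in seq_len(n)) {
      for (p in seq_len(nrow(pats))) {
        losses <- pats[p, ]
        if (!allow_loss && all(losses == "first")) next  # same as all-second
        res <- tdrl_apply_core(order$symbol, order$strand, start, len, losses)
        if (!length(res$sym)) next
        key <- order_key_raw(res$sym, res$str,
                             union(order$absent, res$lost), order$uncertain)
        if (is.null(out[[key]])) {
          out[[key]] <- canonicalize(
            gene_order(res$sym, res$str,
                       absent = union(order$absent, res$lost),
                       uncertain = order$uncertain, taxon = order$taxon))
        }
      }
    }
  }
  out
}

# key on raw vectors without building a gene_order (hot path)
order_key_raw <- function(sym, str, absent = character(0),
                          uncertain = character(0)) {
  n <- length(sym)
  cr <- which(sym == "CR")
  if (length(cr) == 1L) {
    idx <- ((cr - 1L + seq_len(n) - 1L) %% n) + 1L
  } else {
    toks0 <- format_token(sym, str)
    keys <- vapply(seq_len(n) - 1L, function(k) {
      paste(toks0[((seq_len(n) - 1L + k) %% n) + 1L], collapse = "\x01")
    }, "")
    k <- which(keys == min(keys))[1L]
    idx <- ((k - 1L + seq_len(n) - 1L) %% n) + 1L
  }
  absent <- sort(unique(absent))
  abs_tok <- ifelse(absent %in% uncertain, paste0("[", absent, "?]"),
                    paste0("[", absent, "]"))
  paste(c(format_token(sym[idx], str[idx]), abs_tok), collapse = "-")
}

#' Search minimal TDRL scenarios between two gene orders
#'
#' Breadth-first search over canonical orders: returns every scenario of
#' minimal step count transforming `source` into `target`, deduplicated by
#' the sequence of intermediate orders (the tandem-duplicated order of each
#' step followed by its post-loss result), and ordered by total duplicated
#' length, then by segment start positions. Identical source and target
#' give one empty scenario; an empty list means the target is unreachable
#' within the bounds.
#'
#' @param source,target Gapless [gene_order]s over compatible vocabularies.
#' @param max_steps Maximum number of TDRL steps (default 2).
#' @param max_segment Maximum duplicated segment length (default 8).
#' @param allow_loss Permit full gene loss (required when `target` lacks
#'   genes of `source`).
#' @param max_scenarios Stop after this many minimal scenarios (default
#'   `Inf`: return the complete minimal set).
#' @return List of `tdrl_scenario` objects.
#' @export
search_scenarios <- function(source, target, max_steps = 2L,
                             max_segment = 8L, allow_loss = FALSE,
                             max_scenarios = Inf) {
  if (max_steps < 1L) stop("max_steps must be >= 1")
  if (max_segment < 1L) stop("max_segment must be >= 1")
  source <- canonicalize(source); target <- canonicalize(target)
  target_key <- gene_order_key(target)
  if (identical(gene_order_key(source), target_key)) {
    return(list(new_scenario(source, list(), list())))
  }
  frontier <- list(list(order = source, steps = list(), inter = list(),
                        ikey = ""))
  visited <- gene_order_key(source)
  for (depth in seq_len(max_steps)) {
    hits <- list()
    nxt <- list()
    nxt_keys <- character(0)
    for (node in frontier) {
      exp <- expand_tdrl(node, target_key, max_segment, allow_loss,
                         build_children = depth < max_steps &&
                           !length(hits),
                         max_hits = max_scenarios - length(hits))
      hits <- c(hits, exp$hits)
      if (length(hits) >= max_scenarios) break
      for (cand in exp$children) {
        key <- cand$key
        if (key %in% visited) next
        if (!key %in% nxt_keys) {
          nxt_keys <- c(nxt_keys, key)
          nxt <- c(nxt, list(cand$node))
        }
      }
    }
    if (length(hits)) {
      return(finalize_scenarios(source, hits))
    }
    visited <- c(visited, nxt_keys)
    frontier <- nxt
    if (!length(frontier)) break
  }
  list()
}

expand_tdrl <- function(node, target_key, max_segment, allow_loss,
                        build_children = TRUE, max_hits = Inf) {
  ord <- node$order
  n <- length(ord$symbol)
  hits <- list(); children <- list()
  maxlen <- min(max_segment, n - 1L)
  for (len in seq_len(maxlen)) {
    pats <- loss_patterns(len, allow_loss)
    for (start in seq_len(n)) {
      dup_key <- NULL
      for (p in seq_len(nrow(pats))) {
        losses <- pats[p, ]
        if (!allow_loss && all(losses == "first")) next
        res <- tdrl_apply_core(ord$symbol, ord$strand, start, len, losses)
        if (!length(res$sym)) next
        absent <- union(ord$absent, res$lost)
        key <- order_key_raw(res$sym, res$str, absent, ord$uncertain)
        is_hit <- identical(key, target_key)
        if (!is_hit && !build_children) next
        if (is.null(dup_key)) {
          dup_key <- duplicated_intermediate_key(ord, start, len)
        }
        child_order <- canonicalize(
          new_gene_order_fast(res$sym, res$str, absent,
                              ord$uncertain, ord$taxon))
        step <- tdrl_step(start, len, losses)
        step$segment_genes <- segment_genes(ord, start, len)
        new_node <- list(
          order = child_order,
          steps = c(node$steps, list(step)),
          inter = c(node$inter,
                    list(list(duplicated = dup_key, after = key))),
          ikey = paste(node$ikey, dup_key, key, sep = "\x02")
        )
        if (is_hit) {
          hits <- c(hits, list(new_node))
          if (length(hits) >= max_hits) {
            return(list(hits = hits, children = children))
          }
        } else {
          children <- c(children, list(list(key = key, node = new_node)))
        }
      }
    }
  }
  list(hits = hits, children = children)
}

# validation-free constructor for hot paths; inputs are trusted
new_gene_order_fast <- function(sym, str, absent = character(0),
                                uncertain = character(0), taxon = "") {
  structure(
    list(taxon = taxon, symbol = sym, strand = str,
         absent = sort(unique(absent)), uncertain = sort(unique(uncertain)),
         complete = !any(sym == "GAP")),
    class = "gene_order"
  )
}

segment_genes <- function(order, start, len) {
  n <- length(order$symbol)
  idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
  format_token(order$symbol[idx], order$strand[idx])
}

duplicated_intermediate_key <- function(order, start, len) {
  n <- length(order$symbol)
  rot <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
  seg <- rot[seq_len(len)]
  idx <- c(seg, seg, if (len < n) rot[(len + 1L):n])
  order_key_raw(order$symbol[idx], order$strand[idx], order$absent,
                order$uncertain)
}

new_scenario <- function(source, steps, inter) {
  structure(list(source = source, steps = steps, intermediates = inter),
            class = "tdrl_scenario")
}

finalize_scenarios <- function(source, hits) {
  ikeys <- vapply(hits, `[[`, "", "ikey")
  hits <- hits[!duplicated(ikeys)]
  dup_len <- vapply(hits, function(h) {
    sum(vapply(h$steps, `[[`, 0L, "len"))
  }, 0L)
  seg_pos <- vapply(hits, function(h) {
    paste(sprintf("%04d", vapply(h$steps, `[[`, 0L, "start")),
          collapse = ",")
  }, "")
  hits <- hits[order(dup_len, seg_pos)]
  lapply(hits, function(h) new_scenario(source, h$steps, h$inter))
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  cat("<tdrl_scenario> ", length(x$steps), " step(s)\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat("  step ", i, ": duplicate [",
        paste(s$segment_genes %||% "", collapse = "-"),
        "], losses ", paste(s$losses, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Replay a scenario and return the resulting order
#'
#' @param scenario A `tdrl_scenario`.
#' @param allow_loss Permit full gene loss during replay.
#' @return The final canonical [gene_order].
#' @export
replay_scenario <- function(scenario, allow_loss = TRUE) {
  ord <- scenario$source
  for (s in scenario$steps) ord <- apply_tdrl(ord, s, allow_loss = allow_loss)
  ord
}

#' Predict remnant sites of a TDRL scenario
#'
#' Every deleted or pseudogenized copy leaves residue sequence behind; this
#' replays the scenario keeping a marker at each deletion and reports the
#' adjacencies of the final order where remnant non-coding sequence is
#' expected (runs of adjacent deletions merge into one site).
#'
#' @param scenario A `tdrl_scenario` whose replay must reproduce a target
#'   (scenarios from [search_scenarios()] qualify).
#' @param target Optional [gene_order]; when supplied the replay is verified
#'   against it and a mismatch is an error.
#' @return Object of class `remnant_prediction`: a `data.frame` `sites` with
#'   columns `left` and `right` (formatted gene tokens flanking the site).
#' @export
predict_remnants <- function(scenario, target = NULL) {
  stopifnot(inherits(scenario, "tdrl_scenario"))
  if (!is.null(target)) {
    got <- replay_scenario(scenario)
    if (!gene_order_equal(got, target)) {
      stop("unverified scenario: replay does not reproduce the target")
    }
  }
  ord <- canonicalize(scenario$source)
  sym <- ord$symbol; str <- ord$strand
  marker <- rep(FALSE, length(sym))  # remnant immediately before token i
  for (s in scenario$steps) {
    n <- length(sym)
    rot <- ((s$start - 1L + seq_len(n) - 1L) %% n) + 1L
    sym <- sym[rot]; str <- str[rot]; marker <- marker[rot]
    seg <- seq_len(s$len)
    rest <- if (s$len < n) (s$len + 1L):n else integer(0)
    first_del <- s$losses %in% c("first", "both")
    second_del <- s$losses %in% c("second", "both")
    build <- function(del, segsym, segstr, segmark) {
      keep <- !del
      mk <- segmark
      # a deleted run pushes a marker onto the next surviving position
      carry <- FALSE
      out_m <- logical(0); out_s <- character(0); out_t <- character(0)
      for (i in seq_along(del)) {
        if (del[i]) {
          carry <- TRUE
        } else {
          out_s <- c(out_s, segsym[i]); out_t <- c(out_t, segstr[i])
          out_m <- c(out_m, mk[i] || carry)
          carry <- FALSE
        }
      }
      list(sym = out_s, str = out_t, marker = out_m, carry = carry)
    }
    c1 <- build(first_del, sym[seg], str[seg], marker[seg])
    c2 <- build(second_del, sym[seg], str[seg], marker[seg])
    # a deletion run at the end of copy 1 marks the first survivor of copy 2
    # (or of the rest); same cascading for copy 2 into the rest
    new_sym <- c(c1$sym, c2$sym, sym[rest])
    new_str <- c(c1$str, c2$str, str[rest])
    new_mark <- c(c1$marker, c2$marker, marker[rest])
    carry <- c1$carry
    if (length(c2$sym)) {
      new_mark[length(c1$sym) + 1L] <- new_mark[length(c1$sym) + 1L] || carry
      carry <- c2$carry
    }
    pos_after <- length(c1$sym) + length(c2$sym) + 1L
    if (carry) {
      if (pos_after <= length(new_sym)) {
        new_mark[pos_after] <- new_mark[pos_after] || carry
      } else if (length(new_sym)) {
        new_mark[1L] <- TRUE
      }
    }
    sym <- new_sym; str <- new_str; marker <- new_mark
  }
  n <- length(sym)
  toks <- format_token(sym, str)
  sites <- data.frame(left = character(0), right = character(0),
                      stringsAsFactors = FALSE)
  if (n && any(marker)) {
    at <- which(marker)
    left <- toks[((at - 2L) %% n) + 1L]
    sites <- unique(data.frame(left = left, right = toks[at],
                               stringsAsFactors = FALSE))
  }
  structure(list(sites = sites), class = "remnant_prediction")
}

#' @export
print.remnant_prediction <- function(x, ...) {
  cat("<remnant_prediction> ", nrow(x$sites), " site(s)\n", sep = "")
  if (nrow(x$sites)) {
    for (i in seq_len(nrow(x$sites))) {
      cat("  between ", x$sites$left[i], " and ", x$sites$right[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}
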