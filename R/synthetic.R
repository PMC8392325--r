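#' Plan for simulated TDRL evolution
#'
#' @param k_events Number of TDRL steps to apply.
#' @param min_segment,max_segment Bounds for the duplicated segment length
#'   (tokens); the defaults cover the segment sizes seen in real
#'   heteropteran scenarios.
#' @param allow_full_loss Permit steps that delete both copies of a gene.
#' @param seed Integer seed; identical plans give identical outputs.
#' @return An object of class `evolution_plan`.
#' @export
evolution_plan <- function(k_events, min_segment = 1L, max_segment = 6L,
                           allow_full_loss = FALSE, seed = 1L) {
  if (k_events < 0L) stop("k_events must be >= 0")
  if (min_segment < 1L || max_segment < min_segment) {
    stop("need 1 <= min_segment <= max_segment")
  }
  structure(list(k_events = as.integer(k_events),
                 min_segment = as.integer(min_segment),
                 max_segment = as.integer(max_segment),
                 allow_full_loss = isTRUE(allow_full_loss),
                 seed = as.integer(seed)),
            class = "evolution_plan")
}

#' Simulate TDRL evolution of a gene order
#'
#' Applies `k_events` random valid TDRL steps: segment start uniform on the
#' circle, segment length uniform in the plan's bounds, loss pattern uniform
#' over the per-position first/second choices. Steps that would leave the
#' order unchanged (degenerate "events") are rejected and resampled, so
#' every recorded step is a real rearrangement event.
#'
#' @param ancestral Source [gene_order] (gapless).
#' @param plan An [evolution_plan()].
#' @return List with `order` (the evolved canonical order) and `scenario`
#'   (the true `tdrl_scenario`).
#' @export
simulate_tdrl_evolution <- function(ancestral, plan) {
  stopifnot(inherits(plan, "evolution_plan"))
  set.seed(plan$seed)
  ord <- canonicalize(ancestral)
  steps <- list(); inter <- list()
  vals <- if (plan$allow_full_loss) c("first", "second", "both") else
    c("first", "second")
  for (ev in seq_len(plan$k_events)) {
    n <- length(ord$symbol)
    done <- FALSE
    len_choices <- seq(plan$min_segment, min(plan$max_segment, n - 1L))
    for (try in seq_len(1000L)) {
      len <- len_choices[sample.int(length(len_choices), 1L)]
      start <- sample(n, 1L)
      losses <- sample(vals, len, replace = TRUE)
      nxt <- tryCatch(
        apply_tdrl(ord, tdrl_step(start, len, losses),
                   allow_loss = plan$allow_full_loss),
        error = function(e) NULL)
      if (is.null(nxt) || gene_order_equal(nxt, ord)) next
      step <- tdrl_step(start, len, losses)
      step$segment_genes <- segment_genes(ord, start, len)
      steps <- c(steps, list(step))
      inter <- c(inter, list(list(
        duplicated = duplicated_intermediate_key(ord, start, len),
        after = gene_order_key(nxt))))
      ord <- nxt
      done <- TRUE
      break
    }
    if (!done) stop("no valid TDRL step available under the plan constraints")
  }
  list(order = ord,
       scenario = new_scenario(canonicalize(ancestral), steps, inter))
}

#' Plan for a synthetic gene-order catalog with planted richness
#'
#' Each planted arrangement permutes the members of one rearrangement unit
#' in place (strands kept, so no inversions); families are assigned
#' arrangements through a sharing matrix, and an arrangement assigned to
#' several families appears as byte-identical orders in each. The richness
#' table implied by the plan is computed arithmetically from the sharing
#' matrix at construction and validated: every arrangement must be carried
#' by at least one family, every family must carry at least one
#' arrangement, and arrangements of one unit must be pairwise distinct
#' non-ancestral permutations.
#'
#' @param families Character vector of family labels.
#' @param arrangements List; each element a list with `unit` (a name from
#'   [unit_definitions()]) and `perm` (a permutation of that unit's member
#'   genes, different from the ancestral one).
#' @param assignment Logical matrix, `length(families)` rows by
#'   `length(arrangements)` columns: which family carries which arrangement.
#' @param ancestral Ground pattern, default [ancestral_gene_order()].
#' @return An object of class `catalog_plan` with a `planted` richness table
#'   shaped like the output of [richness()].
#' @export
catalog_plan <- function(families, arrangements, assignment,
                         ancestral = ancestral_gene_order()) {
  units <- unit_definitions()
  if (!length(arrangements)) stop("plan needs at least one arrangement")
  if (!is.matrix(assignment) ||
      nrow(assignment) != length(families) ||
      ncol(assignment) != length(arrangements)) {
    stop("assignment must be a families x arrangements logical matrix")
  }
  if (any(colSums(assignment) < 1L)) {
    stop("inconsistent plan: an arrangement is carried by no family")
  }
  if (any(rowSums(assignment) < 1L)) {
    stop("inconsistent plan: a family carries no arrangement")
  }
  for (a in arrangements) {
    u <- units[[a$unit]]
    if (is.null(u)) stop("unknown unit '", a$unit, "'")
    if (!identical(sort(a$perm), sort(u$members))) {
      stop("arrangement permutation must use exactly the members of unit ",
           a$unit)
    }
    if (identical(a$perm, u$members)) {
      stop("arrangement permutation must differ from the ancestral order")
    }
  }
  arr_units <- vapply(arrangements, `[[`, "", "unit")
  for (u in unique(arr_units)) {
    perms <- lapply(arrangements[arr_units == u], `[[`, "perm")
    keys <- vapply(perms, paste, "", collapse = "-")
    if (anyDuplicated(keys)) {
      stop("arrangements of unit ", u, " must be pairwise distinct")
    }
  }
  cols <- c(names(units), "whole")
  planted <- data.frame(family = sort(families), stringsAsFactors = FALSE)
  fam_idx <- match(planted$family, families)
  for (cl in cols) {
    sel <- if (cl == "whole") rep(TRUE, length(arrangements)) else
      arr_units == cl
    denom <- sum(sel)
    planted[[cl]] <- if (denom == 0L) NA_real_ else
      rowSums(assignment[fam_idx, sel, drop = FALSE]) / denom
  }
  class(planted) <- c("richness_table", "data.frame")
  structure(list(families = families, arrangements = arrangements,
                 assignment = assignment, ancestral = ancestral,
                 planted = planted),
            class = "catalog_plan")
}

#' Generate a synthetic catalog from a plan
#'
#' @param plan A [catalog_plan()].
#' @return List with `catalog` (a [catalog]) and `planted` (the plan's
#'   richness table); computing [richness()] on the catalog reproduces
#'   `planted` exactly.
#' @export
generate_catalog <- function(plan) {
  stopifnot(inherits(plan, "catalog_plan"))
  units <- unit_definitions()
  anc <- canonicalize(plan$ancestral)
  strand_of <- stats::setNames(anc$strand, anc$symbol)
  records <- list()
  for (j in seq_along(plan$arrangements)) {
    a <- plan$arrangements[[j]]
    pos <- which(anc$symbol %in% units[[a$unit]]$members)
    sym <- anc$symbol; str <- anc$strand
    sym[pos] <- a$perm
    str[pos] <- strand_of[a$perm]
    ord_string_base <- new_gene_order_fast(sym, str)
    for (fam in plan$families[plan$assignment[, j]]) {
      ord <- ord_string_base
      ord$taxon <- paste0(fam, " synthetic ", j)
      records <- c(records, list(catalog_record(
        taxon = ord$taxon, infraorder = "synthetic", family = fam,
        species_count = 1L, order = ord)))
    }
  }
  list(catalog = catalog(records, ancestral = plan$ancestral),
       planted = plan$planted)
}

#' Draw a random consistent catalog plan
#'
#' Convenience generator for recovery experiments: random families, random
#' distinct unit permutations, random sharing, always consistent by
#' construction.
#'
#' @param seed Integer seed.
#' @param n_families Number of families (default drawn from 2:4).
#' @return A [catalog_plan()].
#' @export
random_catalog_plan <- function(seed, n_families = NULL) {
  set.seed(seed)
  units <- unit_definitions()
  if (is.null(n_families)) n_families <- sample(2:4, 1L)
  families <- paste0("Fam", seq_len(n_families))
  arrangements <- list()
  for (u in names(units)) {
    members <- units[[u]]$members
    k <- sample(0:2, 1L)
    if (!k) next
    seen <- character(0)
    for (i in seq_len(k)) {
      for (try in 1:50) {
        perm <- sample(members)
        key <- paste(perm, collapse = "-")
        if (!identical(perm, members) && !key %in% seen) {
          seen <- c(seen, key)
          arrangements <- c(arrangements,
                            list(list(unit = u, perm = perm)))
          break
        }
      }
    }
  }
  if (!length(arrangements)) {
    arrangements <- list(list(unit = "4", perm = rev(units[["4"]]$members)))
  }
  m <- matrix(FALSE, n_families, length(arrangements))
  for (j in seq_len(ncol(m))) {
    carriers <- sample(n_families, sample(n_families, 1L))
    m[carriers, j] <- TRUE
  }
  for (i in seq_len(n_families)) {
    if (!any(m[i, ])) m[i, sample(ncol(m), 1L)] <- TRUE
  }
  catalog_plan(families, arrangements, m)
}

#' Random nucleotide sequence with target composition
#'
#' Per-base sampling whose probabilities solve the target A+T content and
#' strand skews exactly in expectation:
#' `P(A) = at(1 + at_skew)/2`, `P(T) = at(1 - at_skew)/2`, and the G/C
#' analogues.
#'
#' @param length Sequence length (> 0).
#' @param at_content Target A+T fraction in `[0, 1]`.
#' @param at_skew,gc_skew Target skews in `[-1, 1]`.
#' @param seed Integer seed.
#' @return A single character string over ACGT.
#' @export
random_sequence <- function(length, at_content, at_skew = 0, gc_skew = 0,
                            seed = 1L) {
  if (length < 1L) stop("length must be > 0")
  if (at_content < 0 || at_content > 1) stop("at_content must be in [0,1]")
  if (abs(at_skew) > 1 || abs(gc_skew) > 1) {
    stop("infeasible skew: |skew| must be <= 1")
  }
  p <- c(A = at_content * (1 + at_skew) / 2,
         T = at_content * (1 - at_skew) / 2,
         G = (1 - at_content) * (1 + gc_skew) / 2,
         C = (1 - at_content) * (1 - gc_skew) / 2)
  set.seed(seed)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}
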