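# Qualitative producibility (forward closure / network expansion) and
# enumeration of all minimal precursor sets of a target metabolite.
#
# Semantics are strictly Boolean: stoichiometry and cofactor regeneration are
# ignored, and a compound inside a directed cycle is producible only if the
# cycle can be entered from available compounds (no bootstrapping).  This is
# the least fixpoint of "fire any oriented reaction whose substrates are all
# available, adding its products".

# internal: closure over pre-oriented reactions, integer seed indices.
closure_idx <- function(orient, seed_idx) {
  n <- length(orient$compound_ids)
  avail <- logical(n)
  avail[seed_idx] <- TRUE
  nr <- length(orient$subs)
  fired <- logical(nr)
  if (nr > 0L) repeat {
    progress <- FALSE
    for (k in seq_len(nr)) {
      if (!fired[k] && all(avail[orient$subs[[k]]])) {
        fired[k] <- TRUE
        prods <- orient$prods[[k]]
        if (!all(avail[prods])) avail[prods] <- TRUE
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  list(avail = avail, fired = fired)
}

check_compound_ids <- function(ids, known, what) {
  bad <- setdiff(ids, known)
  if (length(bad))
    stop("unknown ", what, " compound id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Forward closure of a seed set
#'
#' Computes the least fixpoint of reaction firing starting from \code{seeds}:
#' a reaction (after reversible expansion) fires once all its substrates are
#' producible, adding its products.
#'
#' @param network A \code{\link{metabolic_network}}.
#' @param seeds Character vector of compound ids (may be empty).
#' @return List with \code{producible} (compound ids, includes the seeds) and
#'   \code{fired_reactions} (originating reaction ids of fired oriented
#'   reactions).
#' @export
producible_closure <- function(network, seeds) {
  orient <- orient_reactions(network)
  check_compound_ids(seeds, orient$compound_ids, "seed")
  res <- closure_idx(orient, match(seeds, orient$compound_ids))
  list(producible = orient$compound_ids[res$avail],
       fired_reactions = unique(orient$source_rid[res$fired]))
}

#' Is a target metabolite producible from a seed set?
#'
#' @param network A \code{\link{metabolic_network}}.
#' @param seeds Character vector of compound ids.
#' @param target A compound id.
#' @return Logical scalar.
#' @export
is_producible <- function(network, seeds, target) {
  orient <- orient_reactions(network)
  check_compound_ids(target, orient$compound_ids, "target")
  check_compound_ids(seeds, orient$compound_ids, "seed")
  res <- closure_idx(orient, match(seeds, orient$compound_ids))
  res$avail[match(target, orient$compound_ids)]
}

canonical_set_order <- function(sets) {
  if (!length(sets)) return(sets)
  sets <- lapply(sets, function(s) sort(s))
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets[order(lengths(sets), keys)]
}

#' Enumerate all minimal precursor sets of a target metabolite
#'
#' A precursor set is a subset S of the declared input compounds with the
#' target in the forward closure of S; it is minimal when no proper subset
#' suffices.  The search proceeds by increasing set size over the inputs that
#' are graph-ancestors of the target (no other input can belong to a minimal
#' set), skipping supersets of sets already found; every returned set is then
#' re-verified producible and minimal by single-member removal.
#'
#' @param network A \code{\link{metabolic_network}}.
#' @param inputs Character vector: the declared input compound set (e.g. from
#'   \code{\link{find_input_compounds}}).
#' @param target A compound id.
#' @param limits List with \code{max_inputs} (default 20) and \code{max_sets}
#'   (default 10000); exceeding either is a hard error, never silent
#'   truncation.
#' @return List of character vectors, sorted canonically (by size, then
#'   lexicographically).  Empty when the target is not producible from the
#'   full input set; \code{list(character(0))} when producible from nothing.
#' @export
enumerate_minimal_precursor_sets <- function(network, inputs, target,
                                             limits = list(max_inputs = 20,
                                                           max_sets = 10000)) {
  max_inputs <- limits$max_inputs %||% 20
  max_sets <- limits$max_sets %||% 10000
  if (length(inputs) > max_inputs)
    stop("resource limit exceeded: ", length(inputs),
         " inputs > max_inputs = ", max_inputs, call. = FALSE)
  orient <- orient_reactions(network)
  check_compound_ids(target, orient$compound_ids, "target")
  check_compound_ids(inputs, orient$compound_ids, "input")
  inputs <- unique(inputs)
  tgt <- match(target, orient$compound_ids)

  prod_from <- function(seed_ids)
    closure_idx(orient, match(seed_ids, orient$compound_ids))$avail[tgt]

  if (prod_from(character(0))) return(list(character(0)))
  if (!prod_from(inputs)) return(list())

  # restrict to inputs in the backward cone of the target: if removing an
  # input breaks production it must lie on some substrate->product path to
  # the target, i.e. be an ancestor in the compound graph.
  relevant <- intersect(inputs, ancestor_compounds(orient, tgt))
  found <- list()
  covers <- function(s) any(vapply(found, function(f) all(f %in% s), TRUE))
  for (k in seq_along(relevant)) {
    cand <- combn(relevant, k, simplify = FALSE)
    open <- !vapply(cand, covers, TRUE)
    # if every size-k subset already contains a found minimal set, so does
    # every larger subset: the search is complete.
    if (!any(open)) break
    for (s in cand[open]) {
      if (covers(s)) next
      if (prod_from(s)) {
        found[[length(found) + 1L]] <- s
        if (length(found) > max_sets)
          stop("resource limit exceeded: more than max_sets = ", max_sets,
               " minimal precursor sets", call. = FALSE)
      }
    }
  }
  # verification pass: each set producible, each single-removal not
  for (s in found) {
    stopifnot(prod_from(s))
    for (m in s) stopifnot(!prod_from(setdiff(s, m)))
  }
  canonical_set_order(found)
}

# internal: compound indices from which `tgt` is reachable along
# substrate -> product edges (including tgt itself).
ancestor_compounds <- function(orient, tgt) {
  n <- length(orient$compound_ids)
  preds <- vector("list", n)
  for (k in seq_along(orient$subs))
    for (p in orient$prods[[k]])
      preds[[p]] <- c(preds[[p]], orient$subs[[k]])
  seen <- logical(n)
  seen[tgt] <- TRUE
  stack <- tgt
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (u in preds[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
  }
  orient$compound_ids[seen]
}

#' Brute-force oracle for minimal precursor sets
#'
#' Tests all 2^n subsets of the input set for producibility of the target and
#' returns the subset-minimal producible ones.  Exponential by construction;
#' intended as an independent correctness oracle for
#' \code{\link{enumerate_minimal_precursor_sets}} on small instances.
#'
#' @param network A \code{\link{metabolic_network}}.
#' @param inputs Character vector of input compound ids (at most 15).
#' @param target A compound id.
#' @return As \code{\link{enumerate_minimal_precursor_sets}}.
#' @export
brute_force_precursor_sets <- function(network, inputs, target) {
  inputs <- unique(inputs)
  if (length(inputs) > 15)
    stop("resource limit exceeded: brute force supports at most 15 inputs",
         call. = FALSE)
  orient <- orient_reactions(network)
  check_compound_ids(target, orient$compound_ids, "target")
  check_compound_ids(inputs, orient$compound_ids, "input")
  tgt <- match(target, orient$compound_ids)
  n <- length(inputs)
  ok <- logical(2^n)
  subsets <- vector("list", 2^n)
  for (mask in 0:(2^n - 1)) {
    s <- inputs[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    subsets[[mask + 1L]] <- s
    ok[mask + 1L] <- closure_idx(orient,
                                 match(s, orient$compound_ids))$avail[tgt]
  }
  prod_sets <- subsets[ok]
  minimal <- prod_sets[vapply(prod_sets, function(s)
    !any(vapply(prod_sets, function(o)
      length(o) < length(s) && all(o %in% s), TRUE)), TRUE)]
  canonical_set_order(minimal)
}
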