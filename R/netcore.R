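#' @importFrom stats fft sd var lm coef pt setNames rnorm runif
#' @importFrom utils read.delim write.table combn modifyList
NULL

COMPOUND_CLASSES <- c(
  "amino_acid", "organic_acid", "nucleotide_or_derivative",
  "sugar_or_derivative", "vitamin_or_cofactor", "ion", "small_solute",
  "lipid", "peptide_or_protein", "misc"
)

#' Default side (currency) compound list
#'
#' Ubiquitous hub metabolites (ATP, water, redox carriers, ...) that are
#' filtered from the network before topology analysis to prevent spurious
#' connectivity.  The set is a package default, overridable in every operation
#' that uses it; qualitative network analyses are sensitive to this choice and
#' the list used is always echoed in reports.
#'
#' @return Character vector of compound ids.
#' @export
default_side_compounds <- function() {
  c("H2O", "H+", "ATP", "ADP", "AMP", "Pi", "PPi",
    "NAD+", "NADH", "NADP+", "NADPH", "FAD", "FADH2",
    "CoA", "CO2", "NH3", "O2")
}

#' Construct a compound
#'
#' @param id Unique compound id (non-empty token; case-sensitive, opaque).
#' @param name Free-text name; defaults to the id.
#' @param compound_class One of the closed class vocabulary
#'   (see \code{COMPOUND_CLASSES} in the package source).
#' @param is_side Logical; is this a currency/hub metabolite?
#' @return A one-row data frame with columns id, name, class, is_side.
#' @export
compound <- function(id, name = id, compound_class = "misc", is_side = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  compound_class <- match.arg(compound_class, COMPOUND_CLASSES)
  data.frame(id = id, name = name, class = compound_class,
             is_side = isTRUE(is_side), stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are stored but ignored by every topology
#' operation in this package: the analysis is qualitative.
#'
#' @param id Unique reaction id.
#' @param substrates,products Named numeric vectors (names are compound ids,
#'   values positive coefficients) or plain character vectors (coefficient 1).
#' @param reversible Logical.
#' @param annotation Optional free text (gene, EC number).
#' @return A reaction object (list with class "reaction").
#' @export
reaction <- function(id, substrates, products, reversible = FALSE,
                     annotation = NA_character_) {
  as_side <- function(x, what) {
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    if (length(x) == 0L)
      stop("reaction '", id, "': empty ", what, " list", call. = FALSE)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reaction '", id, "': unnamed ", what, " coefficients", call. = FALSE)
    if (any(x <= 0))
      stop("reaction '", id, "': non-positive coefficient for ",
           paste(names(x)[x <= 0], collapse = ", "), call. = FALSE)
    data.frame(id = names(x), coef = as.numeric(x), stringsAsFactors = FALSE)
  }
  structure(list(id = id, substrates = as_side(substrates, "substrate"),
                 products = as_side(products, "product"),
                 reversible = isTRUE(reversible), annotation = annotation),
            class = "reaction")
}

#' Construct a metabolic network
#'
#' @param reactions List of \code{\link{reaction}} objects.
#' @param compounds Optional data frame of compounds as returned by
#'   \code{\link{compound}} (row-bound).  Compounds referenced by reactions but
#'   absent from this table are added with default attributes; if
#'   \code{strict = TRUE} they are an error instead.
#' @param strict Enforce that all reaction endpoints are declared compounds.
#' @return An object of class \code{metabolic_network} with elements
#'   \code{compounds} (data frame) and \code{reactions} (named list).
#' @export
metabolic_network <- function(reactions, compounds = NULL, strict = FALSE) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(all(vapply(reactions, inherits, TRUE, "reaction")))
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  names(reactions) <- rids
  used <- unique(unlist(lapply(reactions, function(r)
    c(r$substrates$id, r$products$id))))
  if (is.null(compounds))
    compounds <- data.frame(id = character(), name = character(),
                            class = character(), is_side = logical(),
                            stringsAsFactors = FALSE)
  if (anyDuplicated(compounds$id))
    stop("duplicate compound id(s) in compound table", call. = FALSE)
  missing <- setdiff(used, compounds$id)
  if (length(missing) && strict)
    stop("reaction references undeclared compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing))
    compounds <- rbind(compounds,
                       data.frame(id = missing, name = missing, class = "misc",
                                  is_side = FALSE, stringsAsFactors = FALSE))
  rownames(compounds) <- NULL
  structure(list(compounds = compounds, reactions = reactions),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Qualitative metabolic network:",
      nrow(x$compounds), "compounds,",
      length(x$reactions), "reactions",
      sprintf("(%d reversible)\n",
              sum(vapply(x$reactions, `[[`, TRUE, "reversible"))))
  invisible(x)
}

#' Expand reversible reactions into oriented reactions
#'
#' The single point where direction semantics live: every downstream topology
#' operation works on the oriented expansion.  A reversible reaction R
#' contributes R (forward) and R__rev (backward).
#'
#' @param network A \code{metabolic_network}.
#' @return List with \code{rid} (oriented reaction ids), \code{source_rid}
#'   (originating reaction id), \code{subs}, \code{prods} (lists of integer
#'   indices into \code{compound_ids}), and \code{compound_ids}.
#' @export
orient_reactions <- function(network) {
  cid <- network$compounds$id
  idx <- setNames(seq_along(cid), cid)
  rid <- character(0); src <- character(0)
  subs <- list(); prods <- list()
  for (r in network$reactions) {
    s <- unname(idx[r$substrates$id]); p <- unname(idx[r$products$id])
    rid <- c(rid, r$id); src <- c(src, r$id)
    subs[[length(subs) + 1L]] <- s; prods[[length(prods) + 1L]] <- p
    if (r$reversible) {
      rid <- c(rid, paste0(r$id, "__rev")); src <- c(src, r$id)
      subs[[length(subs) + 1L]] <- p; prods[[length(prods) + 1L]] <- s
    }
  }
  list(rid = rid, source_rid = src, subs = subs, prods = prods,
       compound_ids = cid)
}

# ---- I/O ------------------------------------------------------------------

parse_term_side <- function(field, path, line) {
  terms <- trimws(strsplit(field, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (!length(terms))
    stop(sprintf("%s: record %d: empty substrate/product field", path, line),
         call. = FALSE)
  coefs <- rep(1, length(terms)); ids <- terms
  has_coef <- grepl("*", terms, fixed = TRUE)
  if (any(has_coef)) {
    parts <- strsplit(terms[has_coef], "*", fixed = TRUE)
    coefs[has_coef] <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    ids[has_coef] <- trimws(vapply(parts, `[[`, "", 2L))
    if (anyNA(coefs))
      stop(sprintf("%s: record %d: malformed coefficient", path, line),
           call. = FALSE)
  }
  setNames(coefs, ids)
}

load_network_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("reaction_id", "substrates", "products", "reversible")
  if (!all(need %in% names(tab)))
    stop(path, ": TSV reaction dialect needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    reaction(tab$reaction_id[i],
             parse_term_side(tab$substrates[i], path, i),
             parse_term_side(tab$products[i], path, i),
             reversible = tab$reversible[i] %in% c(1, "1", TRUE))
  })
  metabolic_network(rxns)
}

load_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cmp <- do.call(rbind, lapply(obj$compounds, function(co)
    compound(co$id, co$name %||% co$id, co$class %||% "misc",
             isTRUE(co$is_side))))
  rxns <- lapply(obj$reactions, function(rx) {
    side <- function(x) setNames(vapply(x, function(t) as.numeric(t$coef %||% 1),
                                        1),
                                 vapply(x, `[[`, "", "id"))
    reaction(rx$id, side(rx$substrates), side(rx$products),
             reversible = isTRUE(rx$reversible),
             annotation = rx$annotation %||% NA_character_)
  })
  metabolic_network(rxns, compounds = cmp, strict = TRUE)
}

load_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  cmp <- do.call(rbind, lapply(species, function(sp)
    compound(xml2::xml_attr(sp, "id"),
             xml2::xml_attr(sp, "name") %||% xml2::xml_attr(sp, "id"))))
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  side_of <- function(rn, which) {
    refs <- xml2::xml_find_all(
      rn, sprintf("./s:listOf%s/s:speciesReference", which), ns)
    if (!length(refs)) return(numeric(0))
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    setNames(coef, xml2::xml_attr(refs, "species"))
  }
  rxns <- lapply(rnodes, function(rn) {
    rev <- tolower(xml2::xml_attr(rn, "reversible") %||% "false") == "true"
    reaction(xml2::xml_attr(rn, "id"), side_of(rn, "Reactants"),
             side_of(rn, "Products"), reversible = rev)
  })
  ignored <- setdiff(
    unique(xml2::xml_name(xml2::xml_children(xml2::xml_child(doc)))),
    c("listOfSpecies", "listOfReactions", "listOfCompartments"))
  if (length(ignored))
    warning("SBML constructs ignored: ", paste(ignored, collapse = ", "),
            call. = FALSE)
  metabolic_network(rxns, compounds = cmp, strict = TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Load a metabolic network from file
#'
#' @param path File path.
#' @param format One of \code{"tsv"}, \code{"json"}, \code{"sbml"}; guessed
#'   from the extension when missing.
#' @return A validated \code{\link{metabolic_network}}.  Duplicate reaction
#'   ids and (for json/sbml) references to undeclared compounds are errors.
#' @export
load_network <- function(path, format = c("guess", "tsv", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "guess")
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", json = "json",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess network format from extension of ",
                          path, call. = FALSE))
  switch(format,
         tsv = load_network_tsv(path),
         json = load_network_json(path),
         sbml = load_network_sbml(path))
}

#' Write a metabolic network to file
#'
#' Round-trip companion of \code{\link{load_network}} for the tsv and json
#' dialects.
#'
#' @param network A \code{metabolic_network}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fmt_side <- function(df) paste(
      ifelse(df$coef == 1, df$id, paste0(df$coef, "*", df$id)),
      collapse = " + ")
    tab <- data.frame(
      reaction_id = vapply(network$reactions, `[[`, "", "id"),
      substrates = vapply(network$reactions, function(r) fmt_side(r$substrates), ""),
      products = vapply(network$reactions, function(r) fmt_side(r$products), ""),
      reversible = as.integer(vapply(network$reactions, `[[`, TRUE, "reversible")),
      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- list(
      compounds = lapply(seq_len(nrow(network$compounds)), function(i)
        list(id = network$compounds$id[i], name = network$compounds$name[i],
             class = network$compounds$class[i],
             is_side = network$compounds$is_side[i])),
      reactions = lapply(unname(network$reactions), function(r) {
        side <- function(df) lapply(seq_len(nrow(df)), function(i)
          list(id = df$id[i], coef = df$coef[i]))
        list(id = r$id, substrates = side(r$substrates),
             products = side(r$products), reversible = r$reversible)
      }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- filtering and graph construction -------------------------------------

#' Remove side (currency) compounds from a network
#'
#' Every side-list compound is removed from all substrate and product lists
#' and from the compound table; reactions left with an empty substrate or
#' product side are dropped (their ids are recorded).  Missing ids are
#' ignored, so filtering is idempotent and order-independent:
#' filtering with S then T equals filtering once with S union T.
#'
#' @param network A \code{metabolic_network}.
#' @param side_list Character vector of compound ids;
#'   default \code{\link{default_side_compounds}()}.
#' @return List with \code{network} (filtered copy), \code{removed}
#'   (side_list intersected with the network's compounds) and
#'   \code{dropped_reactions} (ids of reactions dropped).
#' @export
filter_side_compounds <- function(network, side_list = default_side_compounds()) {
  removed <- intersect(side_list, network$compounds$id)
  dropped <- character(0)
  kept <- list()
  for (r in network$reactions) {
    s <- r$substrates[!(r$substrates$id %in% side_list), , drop = FALSE]
    p <- r$products[!(r$products$id %in% side_list), , drop = FALSE]
    if (nrow(s) == 0L || nrow(p) == 0L) {
      dropped <- c(dropped, r$id)
    } else {
      r$substrates <- s; r$products <- p
      kept[[length(kept) + 1L]] <- r
    }
  }
  cmp <- network$compounds[!(network$compounds$id %in% side_list), , drop = FALSE]
  out <- if (length(kept)) metabolic_network(kept, compounds = cmp)
         else structure(list(compounds = cmp, reactions = list()),
                        class = "metabolic_network")
  list(network = out, removed = removed, dropped_reactions = dropped)
}

#' Build the directed compound graph of a network
#'
#' Nodes are compounds; a directed edge (u, v) exists iff some oriented
#' reaction consumes u and produces v.  Reversible reactions contribute edges
#' in both directions.  Edges are deduplicated and carry the set of reaction
#' ids that induced them (provenance).
#'
#' @param network A \code{metabolic_network}.
#' @return An object of class \code{compound_graph}: list with \code{nodes}
#'   (all compound ids) and \code{edges} (data frame \code{from}, \code{to},
#'   list-column \code{reactions}).
#' @export
build_compound_graph <- function(network) {
  orient <- orient_reactions(network)
  cid <- orient$compound_ids
  from <- integer(0); to <- integer(0); rid <- character(0)
  for (k in seq_along(orient$subs)) {
    pairs <- expand.grid(f = orient$subs[[k]], t = orient$prods[[k]])
    from <- c(from, pairs$f); to <- c(to, pairs$t)
    rid <- c(rid, rep(orient$source_rid[k], nrow(pairs)))
  }
  key <- paste(from, to, sep = "|")
  prov <- split(rid, key)
  first <- !duplicated(key)
  ord <- order(from[first], to[first])
  f <- from[first][ord]; t <- to[first][ord]
  edges <- data.frame(from = cid[f], to = cid[t], stringsAsFactors = FALSE)
  edges$reactions <- lapply(paste(f, t, sep = "|"),
                            function(k) sort(unique(prov[[k]])))
  structure(list(nodes = cid, edges = edges), class = "compound_graph")
}

#' @export
print.compound_graph <- function(x, ...) {
  cat("Compound graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  invisible(x)
}

#' In- and out-degrees of a compound graph
#'
#' @param graph A \code{compound_graph}.
#' @return Data frame with columns \code{id}, \code{in_degree},
#'   \code{out_degree} (one row per node).
#' @export
graph_degrees <- function(graph) {
  ind <- table(factor(graph$edges$to, levels = graph$nodes))
  outd <- table(factor(graph$edges$from, levels = graph$nodes))
  data.frame(id = graph$nodes, in_degree = as.integer(ind),
             out_degree = as.integer(outd), stringsAsFactors = FALSE)
}
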