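# Assignment of candidate transporters to boundary compounds and
# membrane-coverage gap (orphan) reporting.
#
# A compound is an orphan at a membrane when no repertoire system of the
# strain matches its class/name, required direction and that membrane; the
# headline deficiency metric is the fraction of import compounds with no
# non-speculative inner-membrane candidate.  Passive-diffusion compounds
# (CO2, O2, H2O, NH3, ...) carry a diffusion flag and are never orphans.

#' Membrane model of a strain
#'
#' The canonical organisation is a three-membraned system: bacterial inner
#' and outer membranes surrounded by the host-derived symbiosomal membrane.
#' BBp appears organised as a double-membrane system only, so its bacterial
#' model carries the inner membrane alone.  The symbiosomal membrane is
#' represented but carries no bacterial transporter.
#'
#' @param strain Strain id.
#' @param bacterial_membranes Character vector, subset of
#'   \code{c("inner", "outer")}; the inner membrane is always required.
#' @param symbiosomal_present Logical.
#' @return Object of class \code{membrane_model}.
#' @export
membrane_model <- function(strain,
                           bacterial_membranes = c("inner", "outer"),
                           symbiosomal_present = TRUE) {
  stopifnot(all(bacterial_membranes %in% c("inner", "outer")),
            "inner" %in% bacterial_membranes)
  structure(list(strain = strain,
                 bacterial_membranes = unique(bacterial_membranes),
                 symbiosomal_present = isTRUE(symbiosomal_present)),
            class = "membrane_model")
}

#' Default membrane models for the four Buchnera strains
#'
#' @param strain One of BAp, BSg, BBp, BCc.
#' @return A \code{\link{membrane_model}}: inner+outer for BAp, BSg and BCc;
#'   inner only for BBp.
#' @export
default_membrane_model <- function(strain) {
  strain <- match.arg(strain, c("BAp", "BSg", "BBp", "BCc"))
  if (strain == "BBp") membrane_model(strain, "inner")
  else membrane_model(strain, c("inner", "outer"))
}

#' Load a substrate-matching rule set
#'
#' @param path JSON rule set; defaults to the packaged rules transcribing
#'   the compound-to-transporter assignments of the source repertoire.
#' @return Data frame with one row per rule: \code{system_id},
#'   list-columns \code{classes} and \code{compounds}, \code{level},
#'   list-column \code{directions}, \code{membrane}.
#' @export
load_transport_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transport_rules.json",
                        package = "symbiotrans")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- obj$rules
  data.frame(
    system_id = vapply(rules, `[[`, "", "system_id"),
    classes = I(lapply(rules, function(r) unlist(r$classes) %||% character(0))),
    compounds = I(lapply(rules, function(r)
      unlist(r$compounds) %||% character(0))),
    level = vapply(rules, `[[`, "", "level"),
    directions = I(lapply(rules, function(r) unlist(r$directions))),
    membrane = vapply(rules, `[[`, "", "membrane"),
    stringsAsFactors = FALSE)
}

#' Load a boundary-compound table
#'
#' @param path TSV with columns \code{compound}, \code{class},
#'   \code{direction} (import/export) and optional \code{diffusion} (0/1);
#'   defaults to the packaged BAp boundary-compound transcription.
#' @return Data frame.
#' @export
load_boundary_compounds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bap_boundary_compounds.tsv",
                        package = "symbiotrans")
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("compound", "class", "direction") %in% names(tab)))
  if (is.null(tab$diffusion)) tab$diffusion <- 0L
  tab$diffusion <- tab$diffusion %in% c(1, "1", TRUE)
  tab
}

#' Assign candidate transporters to boundary compounds
#'
#' For each compound, candidate systems are the strain's intact repertoire
#' systems whose rule matches the compound class (or names the compound),
#' is compatible with the required direction (\code{both} matches either;
#' \code{nd} systems match neither unless explicitly ruled) and sits in the
#' queried membrane.  Orphan flags are computed per bacterial membrane of
#' the strain's membrane model; \code{route_complete} is true when no
#' bacterial membrane is orphan.  Diffusion-flagged compounds are never
#' orphans.
#'
#' @param compounds Data frame with columns \code{compound}, \code{class},
#'   \code{direction}, optional \code{diffusion} (see
#'   \code{\link{load_boundary_compounds}}).
#' @param table A \code{\link{load_repertoire}} table.
#' @param strain Strain id.
#' @param model A \code{\link{membrane_model}};
#'   default \code{\link{default_membrane_model}(strain)}.
#' @param rules A rule set from \code{\link{load_transport_rules}}.
#' @param include_speculative Keep candidates whose system is flagged
#'   speculative (default TRUE).
#' @return Object of class \code{transport_assignment}: data frame with one
#'   row per compound (columns compound, class, direction, diffusion,
#'   route_complete), list-column \code{candidates} (per membrane, data
#'   frames system_id/speculative/level) and logical columns
#'   \code{orphan_<membrane>}.
#' @export
assign_transporters <- function(compounds, table, strain,
                                model = default_membrane_model(strain),
                                rules = load_transport_rules(),
                                include_speculative = TRUE) {
  check_strain(table, strain)
  bad <- setdiff(compounds$class, COMPOUND_CLASSES)
  if (length(bad))
    stop("unknown compound class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(all(compounds$direction %in% c("import", "export")))
  if (is.null(compounds$diffusion)) compounds$diffusion <- FALSE
  intact <- table$entries$system_id[table$entries$strain == strain &
                                      table$entries$intact_count > 0L]
  spec_flag <- setNames(table$systems$speculative, table$systems$system_id)
  rules <- rules[rules$system_id %in% intact, , drop = FALSE]
  if (!include_speculative)
    rules <- rules[!spec_flag[rules$system_id], , drop = FALSE]
  membranes <- model$bacterial_membranes

  cand_for <- function(cls, cmp, dir, mem) {
    hit <- vapply(seq_len(nrow(rules)), function(k) {
      rules$membrane[k] == mem &&
        dir %in% rules$directions[[k]] &&
        (cls %in% rules$classes[[k]] || cmp %in% rules$compounds[[k]])
    }, TRUE)
    if (!any(hit))
      return(data.frame(system_id = character(), speculative = logical(),
                        level = character(), stringsAsFactors = FALSE))
    data.frame(system_id = rules$system_id[hit],
               speculative = unname(spec_flag[rules$system_id[hit]]),
               level = rules$level[hit], stringsAsFactors = FALSE)
  }

  out <- compounds[, c("compound", "class", "direction", "diffusion")]
  out$candidates <- lapply(seq_len(nrow(compounds)), function(i)
    setNames(lapply(membranes, function(mem)
      cand_for(compounds$class[i], compounds$compound[i],
               compounds$direction[i], mem)), membranes))
  for (mem in membranes)
    out[[paste0("orphan_", mem)]] <- vapply(seq_len(nrow(out)), function(i)
      !out$diffusion[i] && nrow(out$candidates[[i]][[mem]]) == 0L, TRUE)
  out$route_complete <- !Reduce(`|`, lapply(membranes, function(mem)
    out[[paste0("orphan_", mem)]]), rep(FALSE, nrow(out)))
  attr(out, "strain") <- strain
  attr(out, "membranes") <- membranes
  class(out) <- c("transport_assignment", "data.frame")
  out
}

#' Membrane-coverage orphan report
#'
#' Summarises, per bacterial membrane and direction, the compounds with no
#' candidate transporter.  The headline metric is the fraction of
#' (non-diffusion) import compounds with no inner-membrane candidate under
#' the assignment's speculative-inclusion setting.
#'
#' @param assignments A \code{\link{assign_transporters}} result.
#' @return List with \code{by_membrane_direction} (data frame membrane,
#'   direction, n_compounds, n_orphans, orphan compounds comma-joined) and
#'   \code{inner_import_orphan_fraction}.
#' @export
orphan_report <- function(assignments) {
  membranes <- attr(assignments, "membranes")
  if (is.null(membranes) || nrow(assignments) == 0L)
    return(list(by_membrane_direction = data.frame(),
                inner_import_orphan_fraction = NA_real_))
  rows <- list()
  for (mem in membranes) {
    for (dir in c("import", "export")) {
      sel <- assignments$direction == dir & !assignments$diffusion
      orph <- assignments[[paste0("orphan_", mem)]] & sel
      rows[[length(rows) + 1L]] <- data.frame(
        membrane = mem, direction = dir, n_compounds = sum(sel),
        n_orphans = sum(orph),
        orphans = paste(assignments$compound[orph], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  by_md <- do.call(rbind, rows)
  imp <- assignments$direction == "import" & !assignments$diffusion
  frac <- if ("orphan_inner" %in% names(assignments) && any(imp))
    sum(assignments$orphan_inner[imp]) / sum(imp) else NA_real_
  list(by_membrane_direction = by_md, inner_import_orphan_fraction = frac)
}

#' Strain transport-capability diagram
#'
#' Machine-readable summary of a strain's intact transport systems grouped
#' by TC class, with substrate annotations, membrane, conserved-in-all-
#' strains and speculative markers.  Protein-processing systems form their
#' own group; metabolite and ion transporters are grouped by TC class.
#'
#' @param table A \code{\link{load_repertoire}} table.
#' @param strain Strain id.
#' @param model A \code{\link{membrane_model}}.
#' @return List with \code{strain}, \code{membranes}, \code{groups}
#'   (named list: per TC class a data frame of systems) and
#'   \code{protein_processing} (data frame).
#' @export
strain_capability_diagram <- function(table, strain,
                                      model = default_membrane_model(strain)) {
  check_strain(table, strain)
  intact <- unique(table$entries$system_id[
    table$entries$strain == strain & table$entries$intact_count > 0L])
  all_strains <- unique(table$entries$strain)
  core <- conserved_core(table, all_strains)
  sys <- table$systems[table$systems$system_id %in% intact, , drop = FALSE]
  sys$conserved_in_all <- sys$system_id %in% core
  transport <- sys[sys$functional_category %in%
                     c("metabolite_transport", "ion_transport"), , drop = FALSE]
  groups <- split(
    transport[, c("system_id", "family", "substrates", "membrane",
                  "speculative", "conserved_in_all")],
    factor(transport$tc_class, levels = setdiff(TC_CLASSES, character(0))))
  groups <- groups[vapply(groups, nrow, 1L) > 0L]
  list(strain = strain, membranes = model$bacterial_membranes,
       symbiosomal_present = model$symbiosomal_present,
       groups = lapply(groups, function(g) { rownames(g) <- NULL; g }),
       protein_processing = {
         pp <- sys[sys$functional_category == "protein_processing",
                   c("system_id", "family", "membrane", "conserved_in_all")]
         rownames(pp) <- NULL
         pp
       })
}

#' Write a transport assignment table as TSV
#'
#' @param assignments A \code{\link{assign_transporters}} result.
#' @param path Output path.
#' @param preamble Optional `#`-prefixed provenance lines.
#' @return \code{path}, invisibly.
#' @export
write_assignment_report <- function(assignments, path, preamble = NULL) {
  membranes <- attr(assignments, "membranes")
  fmt <- function(i, mem) {
    cand <- assignments$candidates[[i]][[mem]]
    if (nrow(cand) == 0L) return("")
    paste(ifelse(cand$speculative, paste0(cand$system_id, "?"),
                 cand$system_id), collapse = ",")
  }
  out <- assignments[, c("compound", "class", "direction", "diffusion")]
  for (mem in membranes) {
    out[[paste0("candidates_", mem)]] <-
      vapply(seq_len(nrow(assignments)), fmt, "", mem = mem)
    out[[paste0("orphan_", mem)]] <- assignments[[paste0("orphan_", mem)]]
  }
  out$route_complete <- assignments$route_complete
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(preamble)) writeLines(preamble, con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
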