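# Boundary (input/output) compound identification and curation emulation.
#
# An input compound is a source of the compound graph: consumed by at least
# one reaction but produced by none.  An output compound is a sink: produced
# by at least one reaction but consumed by none.  Isolated compounds (no
# edges at all) belong to neither list -- both definitions presuppose
# participation in the network -- and are reported separately.

#' Find the input (source) compounds of a compound graph
#'
#' Inputs are nodes with in-degree 0 and out-degree >= 1 (provenance
#' \code{auto}).  Because side-compound filtering removes currency metabolites
#' before the graph is built, the ids removed there can be restored into the
#' input list (provenance \code{restored_side}): a filtered currency compound
#' is by construction not produced within the pruned network yet is consumed
#' by it.
#'
#' @param graph A \code{\link{build_compound_graph}} result.
#' @param restored_side Character vector of compound ids removed earlier by
#'   side filtering, to be restored into the input list.
#' @return Data frame with columns \code{id} and \code{provenance}
#'   (\code{auto} or \code{restored_side}), deduplicated.
#' @export
find_input_compounds <- function(graph, restored_side = character(0)) {
  deg <- graph_degrees(graph)
  auto <- deg$id[deg$in_degree == 0L & deg$out_degree >= 1L]
  out <- data.frame(id = auto,
                    provenance = rep("auto", length(auto)),
                    stringsAsFactors = FALSE)
  restored <- setdiff(restored_side, auto)
  if (length(restored))
    out <- rbind(out, data.frame(id = restored, provenance = "restored_side",
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Find the output (sink) compounds of a compound graph
#'
#' Outputs are nodes with in-degree >= 1 and out-degree 0.
#'
#' @param graph A \code{\link{build_compound_graph}} result.
#' @return Data frame with columns \code{id} and \code{provenance}
#'   (\code{auto}).
#' @export
find_output_compounds <- function(graph) {
  deg <- graph_degrees(graph)
  auto <- deg$id[deg$in_degree >= 1L & deg$out_degree == 0L]
  data.frame(id = auto, provenance = rep("auto", length(auto)),
             stringsAsFactors = FALSE)
}

#' Isolated compounds of a compound graph
#'
#' Nodes with no incident edge; excluded from both boundary lists.
#'
#' @param graph A \code{\link{build_compound_graph}} result.
#' @return Character vector of compound ids.
#' @export
isolated_compounds <- function(graph) {
  deg <- graph_degrees(graph)
  deg$id[deg$in_degree == 0L & deg$out_degree == 0L]
}

#' Curation configuration
#'
#' Emulates the expert manual refinement applied to automatically derived
#' boundary lists: appending known imports/exports (e.g. vitamins produced
#' for the host) and removing false positives caused by enzyme-assignment
#' artefacts.
#'
#' @param manual_input_adds,manual_output_adds Character vectors of compound
#'   ids to append.
#' @param false_positive_removals Data frame with columns \code{id},
#'   \code{list} (\code{"inputs"} or \code{"outputs"}) and \code{reason}.
#' @return An object of class \code{curation_config}.
#' @export
curation_config <- function(manual_input_adds = character(0),
                            manual_output_adds = character(0),
                            false_positive_removals = NULL) {
  if (is.null(false_positive_removals))
    false_positive_removals <- data.frame(id = character(), list = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "list", "reason") %in% names(false_positive_removals)),
            all(false_positive_removals$list %in% c("inputs", "outputs")))
  structure(list(manual_input_adds = manual_input_adds,
                 manual_output_adds = manual_output_adds,
                 false_positive_removals = false_positive_removals),
            class = "curation_config")
}

#' Read a curation configuration from JSON
#'
#' @param path JSON file with optional fields \code{manual_input_adds},
#'   \code{manual_output_adds}, \code{false_positive_removals} (objects with
#'   \code{id}, \code{list}, \code{reason}).
#' @return A \code{\link{curation_config}}.
#' @export
read_curation_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- obj$false_positive_removals
  if (!is.null(fp) && !is.data.frame(fp)) fp <- as.data.frame(fp)
  curation_config(as.character(obj$manual_input_adds %||% character(0)),
                  as.character(obj$manual_output_adds %||% character(0)),
                  fp)
}

#' Apply manual curation to automatic boundary lists
#'
#' Manual additions are appended with provenance \code{manual_add}; false
#' positives are removed with their reasons logged.  Disjointness of the two
#' lists is enforced in favour of the manual action: a compound manually
#' added to one list is dropped from the other with a warning.
#'
#' @param inputs,outputs Data frames from \code{\link{find_input_compounds}}
#'   and \code{\link{find_output_compounds}}.
#' @param config A \code{\link{curation_config}}.
#' @param known_compounds Optional character vector of network compound ids;
#'   config entries referencing unknown compounds then raise a warning (never
#'   a failure).
#' @return An object of class \code{boundary_report}: list with \code{inputs},
#'   \code{outputs} (data frames id/provenance) and
#'   \code{removed_false_positives} (data frame id/list/reason).
#' @export
apply_curation <- function(inputs, outputs, config = curation_config(),
                           known_compounds = NULL) {
  stopifnot(inherits(config, "curation_config"))
  if (!is.null(known_compounds)) {
    referenced <- c(config$manual_input_adds, config$manual_output_adds,
                    config$false_positive_removals$id)
    unknown <- setdiff(referenced, known_compounds)
    if (length(unknown))
      warning("curation references compounds absent from the network: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  add_to <- function(df, ids) {
    ids <- setdiff(ids, df$id)
    if (length(ids))
      df <- rbind(df, data.frame(id = ids, provenance = "manual_add",
                                 stringsAsFactors = FALSE))
    df
  }
  inputs <- add_to(inputs, config$manual_input_adds)
  outputs <- add_to(outputs, config$manual_output_adds)

  fp <- config$false_positive_removals
  removed <- fp  # full log; `applied` marks entries that actually hit a list
  removed$applied <- (removed$list == "inputs" & removed$id %in% inputs$id) |
    (removed$list == "outputs" & removed$id %in% outputs$id)
  inputs <- inputs[!(inputs$id %in% fp$id[fp$list == "inputs"]), , drop = FALSE]
  outputs <- outputs[!(outputs$id %in% fp$id[fp$list == "outputs"]), , drop = FALSE]

  # disjointness: manual action wins over the automatic entry
  clash <- intersect(inputs$id, outputs$id)
  for (id in clash) {
    in_manual <- inputs$provenance[inputs$id == id] == "manual_add"
    out_manual <- outputs$provenance[outputs$id == id] == "manual_add"
    if (in_manual && !out_manual) {
      outputs <- outputs[outputs$id != id, , drop = FALSE]
      warning("'", id, "' manually added to inputs; dropped from outputs",
              call. = FALSE)
    } else {
      inputs <- inputs[inputs$id != id, , drop = FALSE]
      warning("'", id, "' present in both lists; kept in outputs",
              call. = FALSE)
    }
  }
  rownames(inputs) <- rownames(outputs) <- rownames(removed) <- NULL
  structure(list(inputs = inputs, outputs = outputs,
                 removed_false_positives = removed),
            class = "boundary_report")
}

#' @export
print.boundary_report <- function(x, ...) {
  cat("Boundary report:", nrow(x$inputs), "inputs,", nrow(x$outputs),
      "outputs,", sum(x$removed_false_positives$applied),
      "false positives removed\n")
  invisible(x)
}

#' Write a boundary report as TSV or JSON
#'
#' @param report A \code{boundary_report}.
#' @param path Output path.
#' @param format \code{"tsv"} (columns compound, list, provenance, reason) or
#'   \code{"json"}.
#' @param preamble Optional character vector of `#`-prefixed provenance lines
#'   written before the TSV header.
#' @return \code{path}, invisibly.
#' @export
write_boundary_report <- function(report, path, format = c("tsv", "json"),
                                  preamble = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  fp <- report$removed_false_positives
  rows <- rbind(
    data.frame(compound = report$inputs$id, list = "inputs",
               provenance = report$inputs$provenance, reason = "",
               stringsAsFactors = FALSE),
    data.frame(compound = report$outputs$id, list = "outputs",
               provenance = report$outputs$provenance, reason = "",
               stringsAsFactors = FALSE),
    data.frame(compound = fp$id,
               list = if (nrow(fp)) paste0("removed_from_", fp$list)
                      else character(0),
               provenance = rep("manual_removal", nrow(fp)),
               reason = fp$reason, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(preamble)) writeLines(preamble, con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
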