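# End-to-end pipelines tying the stages together, with provenance headers
# and deterministic report output.  Exit-code conventions for the CLI
# wrapper: 0 ok, 1 usage, 2 data, 3 resource.

#' Run configuration for the analysis pipelines
#'
#' @param network_path Path to a reaction-network file.
#' @param side_compounds Character vector of currency-compound ids
#'   (default \code{\link{default_side_compounds}()}).
#' @param curation_path Optional JSON curation config.
#' @param repertoire_path Optional repertoire TSV (NULL = packaged fixture).
#' @param compounds_path Optional boundary-compound TSV (NULL = packaged).
#' @param rules_path Optional rule-set JSON (NULL = packaged).
#' @param strain Strain id for gap analysis (default "BAp").
#' @param include_speculative Include speculative candidates (default FALSE).
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(network_path = NULL,
                       side_compounds = default_side_compounds(),
                       curation_path = NULL, repertoire_path = NULL,
                       compounds_path = NULL, rules_path = NULL,
                       strain = "BAp", include_speculative = FALSE,
                       seed = 1, out_dir = ".") {
  structure(list(network_path = network_path, side_compounds = side_compounds,
                 curation_path = curation_path,
                 repertoire_path = repertoire_path,
                 compounds_path = compounds_path, rules_path = rules_path,
                 strain = strain, include_speculative = include_speculative,
                 seed = seed, out_dir = out_dir), class = "run_config")
}

config_hash <- function(config) {
  # order-stable digest of the analytical fields (timestamp-free; the
  # output directory is not analytical and is excluded)
  fields <- unclass(config)
  fields$out_dir <- NULL
  txt <- paste(names(fields), vapply(fields, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  # small rolling hash; stable across sessions, no external dependency
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Provenance header lines for report files
#'
#' Every pipeline output starts with these `#`-prefixed lines: tool version,
#' configuration hash, seed and timestamp.  Two runs with the same config
#' and seed differ only in the timestamp line.
#'
#' @param config A \code{\link{run_config}}.
#' @return Character vector of header lines.
#' @export
version_and_provenance <- function(config) {
  c(sprintf("# tool: symbiotrans %s",
            as.character(utils::packageVersion("symbiotrans"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", format(config$seed)),
    sprintf("# timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Parse a provenance header back into its fields
#'
#' @param path A report file written by the pipelines.
#' @return Named list (tool, config_hash, seed, timestamp).
#' @export
read_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), ": ", fixed = TRUE)
  setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

#' Run the boundary-analysis pipeline
#'
#' load network -> filter side compounds -> build compound graph -> input
#' and output detection -> curation -> TSV/JSON reports.  Dropped reactions
#' and curation actions are reported in the returned log.
#'
#' @param config A \code{\link{run_config}} with \code{network_path} set.
#' @return List with \code{report} (a \code{boundary_report}), \code{files}
#'   (paths written) and \code{log} (character vector), invisibly returned
#'   components also written under \code{config$out_dir}.
#' @export
run_boundary_pipeline <- function(config) {
  if (is.null(config$network_path) || !file.exists(config$network_path))
    stop("data error: network file not found: ",
         config$network_path %||% "<missing>", call. = FALSE)
  log <- character(0)
  net <- load_network(config$network_path)
  filt <- filter_side_compounds(net, config$side_compounds)
  if (length(filt$dropped_reactions))
    log <- c(log, paste("dropped reaction:", filt$dropped_reactions))
  graph <- build_compound_graph(filt$network)
  inputs <- find_input_compounds(graph, restored_side = filt$removed)
  outputs <- find_output_compounds(graph)
  curation <- if (!is.null(config$curation_path))
    read_curation_config(config$curation_path) else curation_config()
  report <- apply_curation(inputs, outputs, curation,
                           known_compounds = net$compounds$id)
  applied <- report$removed_false_positives
  applied <- applied[applied$applied, , drop = FALSE]
  if (nrow(applied))
    log <- c(log, sprintf("curation removal: %s from %s (%s)", applied$id,
                          applied$list, applied$reason))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "boundary_report.tsv")
  jsn <- file.path(config$out_dir, "boundary_report.json")
  write_boundary_report(report, tsv, "tsv",
                        preamble = version_and_provenance(config))
  write_boundary_report(report, jsn, "json")
  invisible(list(report = report, files = c(tsv, jsn), log = log))
}

#' Run the transporter gap-analysis pipeline
#'
#' Assigns candidate transporters to boundary compounds for a strain and
#' writes the assignment table, the orphan report and the strain capability
#' diagram.
#'
#' @param config A \code{\link{run_config}}.
#' @return List with \code{assignments}, \code{orphans}, \code{diagram} and
#'   \code{files}, invisibly.
#' @export
run_gap_analysis <- function(config) {
  table <- load_repertoire(config$repertoire_path)
  compounds <- load_boundary_compounds(config$compounds_path)
  rules <- if (is.null(config$rules_path)) load_transport_rules()
           else load_transport_rules(config$rules_path)
  model <- default_membrane_model(config$strain)
  assignments <- assign_transporters(
    compounds, table, config$strain, model = model, rules = rules,
    include_speculative = config$include_speculative)
  orphans <- orphan_report(assignments)
  diagram <- strain_capability_diagram(table, config$strain, model)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir,
                   sprintf("assignments_%s.tsv", config$strain))
  write_assignment_report(assignments, tsv,
                          preamble = version_and_provenance(config))
  orph <- file.path(config$out_dir,
                    sprintf("orphan_report_%s.json", config$strain))
  jsonlite::write_json(orphans, orph, auto_unbox = TRUE, digits = NA)
  diag <- file.path(config$out_dir,
                    sprintf("capabilities_%s.json", config$strain))
  jsonlite::write_json(diagram, diag, auto_unbox = TRUE, digits = NA)
  invisible(list(assignments = assignments, orphans = orphans,
                 diagram = diagram, files = c(tsv, orph, diag)))
}
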