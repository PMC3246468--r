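# Four-strain transporter repertoire model: loading, gene/system counting,
# confidence tiers, conserved core, TC-class distributions.
#
# Counting conventions (binding throughout the package):
#   * gene counts sum intact (non-pseudogene) gene multiplicities only, with
#     complex multiplicities as printed (e.g. 8 for the F-ATPase chain);
#   * system totals count grouping-column groups with at least one intact
#     gene; rows with an empty group_id (the GroESL chaperonin) are listed in
#     the repertoire but not counted as transporter systems.

TC_CLASSES <- c("1", "2", "3", "4", "8", "9", "none")
DIRECTIONS <- c("import", "export", "both", "nd")
MEMBRANES <- c("inner", "outer", "cytosolic", "both", "nd")
FUNCTIONAL_CATEGORIES <- c("metabolite_transport", "ion_transport",
                           "protein_processing", "unknown")

parse_exponent <- function(x) {
  x <- trimws(as.character(x))
  ifelse(is.na(x) | x == "" | x == "ns",
         NA_real_,
         ifelse(x %in% c("-inf", "-Inf"), -Inf, suppressWarnings(as.numeric(x))))
}

#' Load a transporter repertoire table
#'
#' Reads the tab-separated repertoire dialect (one row per system-by-strain
#' entry; see the packaged fixture for the column set) and validates it
#' against the closed vocabularies for TC class, direction, membrane and
#' functional category.  \code{best_hit_exponent} accepts an integer
#' exponent, \code{-inf} (perfect hit) or empty (no significant hit).
#'
#' @param path Path to a repertoire TSV.  Defaults to the packaged
#'   transcription of the four-strain Buchnera repertoire.
#' @param strains_path Optional TSV of strain metadata (columns
#'   \code{strain}, \code{genome_kb}, \code{cds_count}, ...); defaults to the
#'   packaged strain table when reading the packaged repertoire.
#' @return An object of class \code{repertoire_table}: list with
#'   \code{systems} (one row per system), \code{entries} (one row per
#'   system-by-strain entry, with \code{intact_count} derived), and
#'   \code{strains}.
#' @export
load_repertoire <- function(path = NULL, strains_path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "buchnera_repertoire.tsv",
                        package = "symbiotrans")
    strains_path <- strains_path %||%
      system.file("extdata", "buchnera_strains.tsv", package = "symbiotrans")
  }
  raw <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    na.strings = NULL, colClasses = "character")
  need <- c("system_id", "group_id", "tc_class", "family", "best_hit_tc",
            "best_hit_exponent", "substrates", "direction", "membrane",
            "tm_domains", "functional_category", "speculative", "strain",
            "genes", "pseudogene_flags", "gene_count")
  if (nrow(raw) == 0L)
    stop(path, ": empty repertoire table", call. = FALSE)
  if (!all(need %in% names(raw)))
    stop(path, ": repertoire dialect needs columns ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  bad_row <- function(i, msg)
    stop(sprintf("%s: row %d (%s/%s): %s", path, i, raw$system_id[i],
                 raw$strain[i], msg), call. = FALSE)
  for (i in seq_len(nrow(raw))) {
    if (!raw$tc_class[i] %in% TC_CLASSES) bad_row(i, "bad tc_class")
    if (!raw$direction[i] %in% DIRECTIONS) bad_row(i, "bad direction")
    if (!raw$membrane[i] %in% MEMBRANES) bad_row(i, "bad membrane")
    if (!raw$functional_category[i] %in% FUNCTIONAL_CATEGORIES)
      bad_row(i, "bad functional_category")
  }
  gene_count <- as.integer(raw$gene_count)
  if (anyNA(gene_count)) stop(path, ": non-integer gene_count", call. = FALSE)
  n_pseudo <- vapply(strsplit(raw$pseudogene_flags, ","), function(x)
    length(x[nzchar(trimws(x))]), 1L)
  if (any(n_pseudo > gene_count))
    stop(path, ": more pseudogene flags than genes", call. = FALSE)
  entries <- data.frame(
    strain = raw$strain, system_id = raw$system_id, genes = raw$genes,
    pseudogene_flags = raw$pseudogene_flags, gene_count = gene_count,
    intact_count = gene_count - n_pseudo, stringsAsFactors = FALSE)
  if (anyDuplicated(paste(entries$strain, entries$system_id)))
    stop(path, ": duplicate (strain, system) entry", call. = FALSE)
  sysdf <- raw[!duplicated(raw$system_id),
               c("system_id", "group_id", "tc_class", "family", "best_hit_tc",
                 "best_hit_exponent", "substrates", "direction", "membrane",
                 "tm_domains", "functional_category", "speculative")]
  sysdf$best_hit_exponent <- parse_exponent(sysdf$best_hit_exponent)
  if (any(sysdf$best_hit_exponent > 0, na.rm = TRUE))
    stop(path, ": positive best_hit_exponent", call. = FALSE)
  sysdf$speculative <- toupper(sysdf$speculative) %in% c("TRUE", "1", "YES")
  rownames(sysdf) <- NULL
  strains <- if (!is.null(strains_path) && nzchar(strains_path)) {
    read.delim(strains_path, stringsAsFactors = FALSE, comment.char = "#")
  } else {
    data.frame(strain = unique(entries$strain), stringsAsFactors = FALSE)
  }
  structure(list(systems = sysdf, entries = entries, strains = strains),
            class = "repertoire_table")
}

#' Write a repertoire table in the loadable TSV dialect
#'
#' @param table A \code{repertoire_table}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_repertoire <- function(table, path) {
  sysdf <- table$systems
  m <- match(table$entries$system_id, sysdf$system_id)
  exp_chr <- ifelse(is.na(sysdf$best_hit_exponent[m]), "",
                    ifelse(is.infinite(sysdf$best_hit_exponent[m]), "-inf",
                           format(sysdf$best_hit_exponent[m],
                                  scientific = FALSE, trim = TRUE)))
  out <- data.frame(
    system_id = table$entries$system_id, group_id = sysdf$group_id[m],
    tc_class = sysdf$tc_class[m], family = sysdf$family[m],
    best_hit_tc = sysdf$best_hit_tc[m], best_hit_exponent = exp_chr,
    substrates = sysdf$substrates[m], direction = sysdf$direction[m],
    membrane = sysdf$membrane[m], tm_domains = sysdf$tm_domains[m],
    functional_category = sysdf$functional_category[m],
    speculative = sysdf$speculative[m], strain = table$entries$strain,
    genes = table$entries$genes,
    pseudogene_flags = table$entries$pseudogene_flags,
    gene_count = table$entries$gene_count, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat("Transporter repertoire:", nrow(x$systems), "systems,",
      length(unique(x$entries$strain)), "strains,",
      nrow(x$entries), "entries\n")
  invisible(x)
}

check_strain <- function(table, strain) {
  known <- unique(c(table$entries$strain, table$strains$strain))
  if (!strain %in% known)
    stop("unknown strain '", strain, "' (declared: ",
         paste(sort(known), collapse = ", "), ")", call. = FALSE)
}

#' Count intact transporter genes of a strain
#'
#' Sums intact (non-pseudogene) gene multiplicities over all repertoire
#' entries of the strain; pseudogenes never count.
#'
#' @param table A \code{repertoire_table}.
#' @param strain Strain id.
#' @return Integer.
#' @export
count_genes <- function(table, strain) {
  if (nrow(table$entries) == 0L) return(0L)
  check_strain(table, strain)
  sum(table$entries$intact_count[table$entries$strain == strain])
}

#' Count identified transporter systems of a strain
#'
#' Counts grouping-column groups with at least one intact gene in the strain.
#' Entries whose system has an empty group id (listed facilitators that are
#' not counted as transporter systems, e.g. the GroESL chaperonin in the
#' packaged fixture) are excluded.
#'
#' @param table A \code{repertoire_table}.
#' @param strain Strain id.
#' @param grouping Optional named character vector mapping system_id to group
#'   id; defaults to the table's \code{group_id} column.
#' @return Integer.
#' @export
count_systems <- function(table, strain, grouping = NULL) {
  if (nrow(table$entries) == 0L) return(0L)
  check_strain(table, strain)
  if (is.null(grouping))
    grouping <- setNames(table$systems$group_id, table$systems$system_id)
  e <- table$entries[table$entries$strain == strain &
                       table$entries$intact_count > 0L, , drop = FALSE]
  groups <- grouping[e$system_id]
  length(unique(groups[!is.na(groups) & nzchar(groups)]))
}

#' Confidence tier of a substrate prediction
#'
#' Predictions whose best TC-Blast expectation value lies above 1e-40 are
#' treated cautiously: \code{confident} iff the exponent is at most -40
#' (including a perfect \code{-Inf} hit); \code{speculative} for larger
#' exponents or when there is no significant hit.
#'
#' @param exponent Numeric exponent(s): the power of ten of the expectation
#'   value; \code{-Inf} for a perfect hit, \code{NA} for no significant hit.
#'   A \code{repertoire_table} systems row (or one-row data frame) is also
#'   accepted.
#' @param threshold_exponent Confidence cutoff (default -40).
#' @return Character vector of \code{"confident"} / \code{"speculative"}.
#' @export
classify_confidence <- function(exponent, threshold_exponent = -40) {
  if (is.data.frame(exponent)) exponent <- exponent$best_hit_exponent
  ifelse(!is.na(exponent) & exponent <= threshold_exponent,
         "confident", "speculative")
}

#' Transporter systems conserved across strains
#'
#' Systems with at least one intact gene in every listed strain, minus the
#' excluded functional categories, in deterministic (fixture) order.
#'
#' @param table A \code{repertoire_table}.
#' @param strains Character vector of strain ids (default: all declared).
#' @param exclude_categories Character vector of functional categories to
#'   drop (e.g. \code{"protein_processing"}).
#' @return Character vector of system ids.
#' @export
conserved_core <- function(table, strains = unique(table$entries$strain),
                           exclude_categories = character(0)) {
  for (s in strains) check_strain(table, s)
  intact <- table$entries[table$entries$intact_count > 0L, , drop = FALSE]
  per_system <- split(intact$strain, intact$system_id)
  core <- names(per_system)[vapply(per_system, function(x)
    all(strains %in% x), TRUE)]
  keep <- table$systems$system_id[
    !(table$systems$functional_category %in% exclude_categories)]
  ordered <- table$systems$system_id[table$systems$system_id %in%
                                       intersect(core, keep)]
  ordered
}

#' TC-class distribution of intact systems in a strain
#'
#' @param table A \code{repertoire_table}.
#' @param strain Strain id.
#' @return Named integer vector over all TC classes (zero counts included):
#'   number of systems with at least one intact gene per class.
#' @export
class_distribution <- function(table, strain) {
  counts <- setNames(integer(length(TC_CLASSES)), TC_CLASSES)
  if (nrow(table$entries) == 0L) return(counts)
  check_strain(table, strain)
  e <- table$entries[table$entries$strain == strain &
                       table$entries$intact_count > 0L, , drop = FALSE]
  cls <- table$systems$tc_class[match(unique(e$system_id),
                                      table$systems$system_id)]
  tab <- table(factor(cls, levels = TC_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Systems of a strain with intact genes, per TC class
#'
#' @param table A \code{repertoire_table}.
#' @param strain Strain id.
#' @param tc_class TC class token.
#' @return Character vector of system ids.
#' @export
systems_in_class <- function(table, strain, tc_class) {
  check_strain(table, strain)
  e <- table$entries[table$entries$strain == strain &
                       table$entries$intact_count > 0L, , drop = FALSE]
  sys <- unique(e$system_id)
  sys[table$systems$tc_class[match(sys, table$systems$system_id)] == tc_class]
}

#' Percentage of CDS that encode transporters
#'
#' @param transporter_gene_count Non-negative count.
#' @param total_cds_count Positive total CDS count.
#' @return 100 * transporter_gene_count / total_cds_count.
#' @export
percent_transporter_genes <- function(transporter_gene_count, total_cds_count) {
  if (any(total_cds_count <= 0))
    stop("total_cds_count must be positive", call. = FALSE)
  100 * transporter_gene_count / total_cds_count
}

#' Per-strain repertoire summary
#'
#' @param table A \code{repertoire_table}.
#' @return Data frame with one row per strain: intact gene count, system
#'   count, and (when CDS counts are available) the transporter-gene
#'   percentage.
#' @export
repertoire_summary <- function(table) {
  strains <- unique(table$entries$strain)
  out <- data.frame(
    strain = strains,
    genes = vapply(strains, function(s) count_genes(table, s), 1L),
    systems = vapply(strains, function(s) count_systems(table, s), 1L),
    stringsAsFactors = FALSE)
  if ("cds_count" %in% names(table$strains)) {
    cds <- table$strains$cds_count[match(strains, table$strains$strain)]
    out$pct_of_cds <- NA_real_
    ok <- !is.na(cds)
    out$pct_of_cds[ok] <- percent_transporter_genes(out$genes[ok], cds[ok])
  }
  rownames(out) <- NULL
  out
}
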