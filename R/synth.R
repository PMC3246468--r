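# Seeded generators for every input the pipeline consumes, each returning a
# ground-truth manifest sufficient to score the corresponding analysis
# operation.  Every generator is a pure function of (spec, seed).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Generate a layered synthetic metabolic network with known structure
#'
#' Builds a layered reaction network whose declared input set is exactly the
#' zero-in-degree compounds, with alternative routes, entered cycles and
#' reversible reactions inserted with the given probabilities.  The manifest
#' records the inputs, the outputs, a target compound and its minimal
#' precursor sets, computed and verified with the brute-force subset oracle
#' at generation time.
#'
#' @param n_compounds Total number of compounds (>= 4).
#' @param n_inputs Number of input (layer-0) compounds (>= 1,
#'   < n_compounds).
#' @param layers Number of reaction layers (default 3).
#' @param p_alternative_route Probability of adding a second producing
#'   reaction for a non-input compound (default 0.3).
#' @param p_cycle Probability of adding a backward (cycle-forming) reaction
#'   per layer (default 0.2).
#' @param p_reversible Probability that an added alternative/cycle reaction
#'   is reversible (default 0.2).
#' @param seed Integer seed; same (spec, seed) gives identical output.
#' @return List with \code{network} (a \code{\link{metabolic_network}}) and
#'   \code{manifest} (list: inputs, outputs, target, minimal_precursor_sets,
#'   n_compounds, n_reactions, seed).
#' @export
generate_network <- function(n_compounds = 18, n_inputs = 5, layers = 3,
                             p_alternative_route = 0.3, p_cycle = 0.2,
                             p_reversible = 0.2, seed = 1) {
  if (n_inputs >= n_compounds)
    stop("infeasible spec: n_inputs must be < n_compounds", call. = FALSE)
  if (n_compounds < 4 || n_inputs < 1 || layers < 1)
    stop("infeasible spec: need n_compounds >= 4, n_inputs >= 1, layers >= 1",
         call. = FALSE)
  stopifnot(p_alternative_route >= 0, p_alternative_route <= 1,
            p_cycle >= 0, p_cycle <= 1, p_reversible >= 0, p_reversible <= 1)
  with_seed(seed, {
    ids <- sprintf("C%02d", seq_len(n_compounds))
    inputs <- ids[seq_len(n_inputs)]
    internal <- ids[(n_inputs + 1):n_compounds]
    layer_of <- sort(sample(seq_len(layers), length(internal), replace = TRUE))
    rxns <- list()
    rid <- 0L
    add_rxn <- function(subs, prods, reversible = FALSE) {
      rid <<- rid + 1L
      rxns[[rid]] <<- reaction(sprintf("R%03d", rid), subs, prods,
                               reversible = reversible)
    }
    avail_below <- function(l) c(inputs, internal[layer_of < l])
    # one producing reaction per internal compound, substrates from lower
    # layers (1 or 2 substrates -> conjunctions arise naturally)
    for (i in seq_along(internal)) {
      pool <- avail_below(layer_of[i])
      k <- min(length(pool), sample(1:2, 1))
      add_rxn(sample(pool, k), internal[i])
    }
    # alternative producing routes
    for (i in seq_along(internal)) {
      if (runif(1) < p_alternative_route) {
        pool <- setdiff(avail_below(layer_of[i]), internal[i])
        if (length(pool))
          add_rxn(sample(pool, min(length(pool), sample(1:2, 1))),
                  internal[i], reversible = runif(1) < p_reversible)
      }
    }
    # cycle-forming reactions: from a higher-layer compound back to a lower
    for (l in seq_len(layers)) {
      if (runif(1) < p_cycle) {
        hi <- internal[layer_of >= l]
        lo <- internal[layer_of <= l]
        if (length(hi) && length(lo)) {
          from <- sample(hi, 1)
          pool <- setdiff(lo, from)
          if (length(pool))
            add_rxn(from, sample(pool, 1),
                    reversible = runif(1) < p_reversible)
        }
      }
    }
    net <- metabolic_network(rxns)
    graph <- build_compound_graph(net)
    deg <- graph_degrees(graph)
    true_inputs <- deg$id[deg$in_degree == 0L & deg$out_degree >= 1L]
    true_outputs <- deg$id[deg$in_degree >= 1L & deg$out_degree == 0L]
    # pick the deepest internal compound reachable from the full input set
    closure_all <- producible_closure(net, true_inputs)$producible
    candidates <- rev(internal[internal %in% closure_all])
    target <- if (length(candidates)) candidates[1] else internal[length(internal)]
    mps <- if (length(true_inputs) <= 15)
      brute_force_precursor_sets(net, true_inputs, target)
    else NULL
    list(network = net,
         manifest = list(inputs = true_inputs, outputs = true_outputs,
                         target = target, minimal_precursor_sets = mps,
                         n_compounds = nrow(net$compounds),
                         n_reactions = length(net$reactions), seed = seed))
  })
}

#' Generate a synthetic lifestyle dataset
#'
#' Transporter-gene fractions are drawn uniformly within each lifestyle
#' group's printed range; genome sizes uniformly within the group's genome
#' range.  The defaults are the study conditions: symbiotic 1-4 % (n = 12),
#' parasitic 2.5-7.1 % (n = 26), free-living 2.8-10.7 % (n = 146).
#'
#' @param groups Data frame with columns \code{lifestyle}, \code{n},
#'   \code{min_pct}, \code{max_pct}, \code{min_mb}, \code{max_mb}.
#' @param seed Integer seed.
#' @return A \code{\link{lifestyle_dataset}}.
#' @export
generate_lifestyle_dataset <- function(groups = default_lifestyle_groups(),
                                       seed = 1) {
  stopifnot(all(c("lifestyle", "n", "min_pct", "max_pct", "min_mb",
                  "max_mb") %in% names(groups)))
  if (any(groups$min_pct >= groups$max_pct) ||
        any(groups$min_mb >= groups$max_mb))
    stop("invalid range: need min < max per group", call. = FALSE)
  empty <- groups$n == 0
  if (any(empty)) {
    warning("omitting group(s) with n = 0: ",
            paste(groups$lifestyle[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty, , drop = FALSE]
  }
  with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      data.frame(
        species = sprintf("%s_sp%03d", substr(g$lifestyle, 1, 4), seq_len(g$n)),
        lifestyle = g$lifestyle,
        genome_mb = runif(g$n, g$min_mb, g$max_mb),
        pct_transporter_genes = runif(g$n, g$min_pct, g$max_pct),
        stringsAsFactors = FALSE)
    }))
    rownames(recs) <- NULL
    lifestyle_dataset(recs)
  })
}

#' Study-condition lifestyle group parameters
#'
#' @return Data frame of the three lifestyle groups with the printed
#'   transporter-gene fraction ranges and sample sizes, and genome-size
#'   ranges typical of each group.
#' @export
default_lifestyle_groups <- function() {
  data.frame(
    lifestyle = c("intracellular_obligate", "parasitic", "free_living"),
    n = c(12L, 26L, 146L),
    min_pct = c(1, 2.5, 2.8), max_pct = c(4, 7.1, 10.7),
    min_mb = c(0.4, 0.8, 1.5), max_mb = c(1.5, 4.5, 10),
    stringsAsFactors = FALSE)
}

#' Generate a TEM-like membrane image with planted line geometry
#'
#' Draws 2 or 3 parallel dark lines with Gaussian cross-sections on a bright
#' background, applies Gaussian blur, then additive Gaussian noise.  Lines
#' run parallel to image rows.  The manifest records the exact line centres
#' (rows), the planted spacing and the signal-to-noise ratio
#' (line_depth / noise_sd).
#'
#' @param shape c(rows, cols) in px (default c(120, 80)).
#' @param n_lines 2 or 3.
#' @param line_spacing Centre-to-centre spacing in px (default 25).
#' @param line_width Gaussian sigma of the line cross-section in px
#'   (default 2).
#' @param line_depth Contrast depth of the lines (default 100 on a
#'   200-intensity background).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param blur_sigma Gaussian blur sigma in px (default 0 = none).
#' @param pixel_size nm per px (default NULL = uncalibrated).
#' @param background Background intensity (default 200).
#' @param seed Integer seed.
#' @return List with \code{image} (a \code{\link{gray_image}}) and
#'   \code{manifest} (line centres, spacing px/nm, snr, seed).
#' @export
generate_membrane_image <- function(shape = c(120, 80), n_lines = 3,
                                    line_spacing = 25, line_width = 2,
                                    line_depth = 100, noise_sd = 0,
                                    blur_sigma = 0, pixel_size = NULL,
                                    background = 200, seed = 1) {
  stopifnot(n_lines %in% c(2, 3), line_spacing > 0, line_width > 0,
            line_depth > 0, noise_sd >= 0)
  nr <- shape[1]; nc <- shape[2]
  extent <- (n_lines - 1) * line_spacing
  if (extent + 6 * line_width >= nr)
    stop("infeasible geometry: lines do not fit in the image", call. = FALSE)
  centre0 <- (nr - extent) / 2
  centres <- centre0 + (seq_len(n_lines) - 1) * line_spacing
  rowsig <- rep(0, nr)
  for (c0 in centres)
    rowsig <- rowsig + line_depth * exp(-((seq_len(nr) - c0)^2) /
                                          (2 * line_width^2))
  m <- matrix(background - rowsig, nr, nc)
  with_seed(seed, {
    if (blur_sigma > 0)
      m <- EBImage::gblur(m, sigma = blur_sigma)
    if (noise_sd > 0)
      m <- m + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    m <- pmax(m, 0)
    list(image = gray_image(matrix(m, nr, nc), pixel_size),
         manifest = list(
           n_lines = n_lines, line_centres_px = centres,
           line_spacing_px = line_spacing,
           line_spacing_nm = if (is.null(pixel_size)) NA_real_
           else line_spacing * pixel_size,
           snr = if (noise_sd > 0) line_depth / noise_sd else Inf,
           seed = seed))
  })
}

#' Generate a paired 585/640 nm ratiometric image set
#'
#' Emulates a two-channel confocal acquisition of a dye-loaded cell: both
#' channels share a smooth illumination field plus noise; an optional
#' planted contrast region multiplies the 585 channel locally (a local pH
#' shift would change the emission ratio there).
#'
#' @param shape c(rows, cols) (default c(96, 96)).
#' @param base Mean channel intensity (default 100).
#' @param noise_sd Per-channel Gaussian noise SD (default 2).
#' @param contrast_region NULL for a uniform pair, otherwise a list with
#'   \code{rows}, \code{cols} (index ranges) and \code{ratio_shift}
#'   (multiplier, e.g. 1.5).
#' @param seed Integer seed.
#' @return List with \code{img_a} (585), \code{img_b} (640) and
#'   \code{manifest} (planted mask or NULL).
#' @export
generate_ratiometric_pair <- function(shape = c(96, 96), base = 100,
                                      noise_sd = 2, contrast_region = NULL,
                                      seed = 1) {
  nr <- shape[1]; nc <- shape[2]
  with_seed(seed, {
    field <- outer(seq_len(nr), seq_len(nc), function(i, j)
      base * (1 + 0.1 * sin(i / nr * pi) * cos(j / nc * pi)))
    a <- field + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    b <- field + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    mask <- NULL
    if (!is.null(contrast_region)) {
      mask <- matrix(FALSE, nr, nc)
      mask[contrast_region$rows, contrast_region$cols] <- TRUE
      a[mask] <- a[mask] * contrast_region$ratio_shift
    }
    list(img_a = gray_image(pmax(a, 0)), img_b = gray_image(pmax(b, 0)),
         manifest = list(planted_mask = mask,
                         ratio_shift = contrast_region$ratio_shift %||% 1,
                         seed = seed))
  })
}

#' Generate a synthetic transporter repertoire with a planted conserved core
#'
#' @param strains Character vector of strain ids.
#' @param n_systems Total number of systems (>= core size).
#' @param core_systems Number of systems planted intact in every strain.
#' @param pseudogene_rate Probability that a non-core entry is a pseudogene;
#'   may be a named vector per strain (rate 1 gives a strain zero intact
#'   genes outside the core; with \code{core_in_all = FALSE} zero overall).
#' @param p_present Probability a non-core system is present in a strain
#'   (default 0.7).
#' @param core_in_all Keep planted core entries intact regardless of
#'   pseudogene_rate (default TRUE).
#' @param seed Integer seed.
#' @return List with \code{table} (a \code{repertoire_table}) and
#'   \code{manifest} (planted core ids, group ids, seed).
#' @export
generate_repertoire <- function(strains = c("S1", "S2", "S3"),
                                n_systems = 12, core_systems = 3,
                                pseudogene_rate = 0.15, p_present = 0.7,
                                core_in_all = TRUE, seed = 1) {
  if (core_systems > n_systems)
    stop("inconsistent params: core_systems > n_systems", call. = FALSE)
  if (length(pseudogene_rate) == 1L)
    pseudogene_rate <- setNames(rep(pseudogene_rate, length(strains)), strains)
  stopifnot(all(strains %in% names(pseudogene_rate)))
  with_seed(seed, {
    sys_ids <- sprintf("SYS%02d", seq_len(n_systems))
    core <- sys_ids[seq_len(core_systems)]
    sysdf <- data.frame(
      system_id = sys_ids, group_id = sys_ids,
      tc_class = sample(c("1", "2", "3", "4", "9"), n_systems, replace = TRUE),
      family = "synthetic", best_hit_tc = "",
      best_hit_exponent = -sample(5:150, n_systems, replace = TRUE),
      substrates = "unknown",
      direction = sample(c("import", "export", "both"), n_systems,
                         replace = TRUE),
      membrane = sample(c("inner", "outer"), n_systems, replace = TRUE,
                        prob = c(0.8, 0.2)),
      tm_domains = as.character(sample(1:12, n_systems, replace = TRUE)),
      functional_category = sample(
        c("metabolite_transport", "ion_transport", "unknown"), n_systems,
        replace = TRUE),
      stringsAsFactors = FALSE)
    sysdf$speculative <- sysdf$best_hit_exponent > -40
    entries <- do.call(rbind, lapply(strains, function(st) {
      present <- sys_ids %in% core | runif(n_systems) < p_present
      ids <- sys_ids[present]
      pseudo <- runif(length(ids)) < pseudogene_rate[[st]]
      if (core_in_all) pseudo[ids %in% core] <- FALSE
      data.frame(strain = st, system_id = ids,
                 genes = paste0(tolower(ids), "_", st),
                 pseudogene_flags = ifelse(pseudo,
                                           paste0(tolower(ids), "_", st), ""),
                 gene_count = 1L, intact_count = as.integer(!pseudo),
                 stringsAsFactors = FALSE)
    }))
    rownames(entries) <- NULL
    # the planted core must be *exactly* the conserved set: knock any
    # accidentally pan-strain non-core system out of one strain
    intact <- entries[entries$intact_count > 0L, ]
    pan <- names(which(vapply(split(intact$strain, intact$system_id),
                              function(x) all(strains %in% x), TRUE)))
    for (sid in setdiff(pan, core)) {
      st <- sample(strains, 1)
      entries <- entries[!(entries$system_id == sid & entries$strain == st), ,
                         drop = FALSE]
    }
    rownames(entries) <- NULL
    table <- structure(
      list(systems = sysdf, entries = entries,
           strains = data.frame(strain = strains, stringsAsFactors = FALSE)),
      class = "repertoire_table")
    list(table = table,
         manifest = list(core = core, groups = setNames(sys_ids, sys_ids),
                         seed = seed))
  })
}
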