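# Independent oracles used across the suite.  These deliberately avoid the
# package's internal representations: they work straight off reaction lists,
# edge lists and raw samples.

# naive forward-closure: repeatedly scan every reaction (both directions for
# reversible ones) until nothing new is produced
naive_closure <- function(network, seeds) {
  have <- unique(seeds)
  repeat {
    added <- FALSE
    for (r in network$reactions) {
      if (all(r$substrates$id %in% have) &&
            !all(r$products$id %in% have)) {
        have <- union(have, r$products$id)
        added <- TRUE
      }
      if (r$reversible && all(r$products$id %in% have) &&
            !all(r$substrates$id %in% have)) {
        have <- union(have, r$substrates$id)
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(have)
}

# brute-force compound-graph edge enumeration straight from the reactions
naive_edges <- function(network) {
  out <- character(0)
  for (r in network$reactions) {
    for (s in r$substrates$id) for (p in r$products$id) {
      out <- c(out, paste(s, p, sep = "->"))
      if (r$reversible) out <- c(out, paste(p, s, sep = "->"))
    }
  }
  sort(unique(out))
}

# degree scan straight off an edge data frame
naive_degrees <- function(nodes, edges) {
  data.frame(id = nodes,
             in_degree = vapply(nodes, function(n) sum(edges$to == n), 1L),
             out_degree = vapply(nodes, function(n) sum(edges$from == n), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# exhaustive two-sample KS permutation oracle: P(D >= d_obs) over all
# reassignments of the pooled sample to groups of sizes n and m
ks_perm_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  dstat <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 1)))
  }
  d_obs <- dstat(x, y)
  idx <- combn(n + m, n, simplify = FALSE)
  hits <- vapply(idx, function(i)
    dstat(pooled[i], pooled[-i]) >= d_obs - 1e-12, TRUE)
  mean(hits)
}

# closed-form OLS via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
}

# random small reaction network (independent of the synth module) for
# property tests that should not trust the generator
random_raw_network <- function(n_compounds = 10, n_reactions = 12,
                               p_rev = 0.2) {
  ids <- sprintf("M%02d", seq_len(n_compounds))
  rxns <- lapply(seq_len(n_reactions), function(k) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- sample(ids, ns)
    prods <- sample(setdiff(ids, subs), np)
    reaction(sprintf("R%02d", k), subs, prods,
             reversible = runif(1) < p_rev)
  })
  metabolic_network(rxns)
}

# byte-level serialisation of a network for determinism checks
write_net_string <- function(network) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_network(network, path, "tsv")
  paste(readLines(path), collapse = "\n")
}

sets_equal <- function(a, b) {
  norm <- function(s) sort(vapply(lapply(s, sort), paste, "", collapse = ","))
  identical(norm(a), norm(b))
}
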