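# Comparative statistics for transporter-gene fractions across bacterial
# lifestyles: two-sample Kolmogorov-Smirnov comparison and ordinary
# least-squares fits of fraction versus genome size.

LIFESTYLES <- c("intracellular_obligate", "parasitic", "free_living")

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the statistic D = sup |ECDF_x - ECDF_y| directly from the two
#' empirical distribution functions.  The p-value uses the asymptotic
#' Kolmogorov distribution with the standard small-sample effective-n
#' correction; for samples with at most \code{exact_max} observations each
#' the exact permutation distribution is used instead
#' (\code{stats::psmirnov}).
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Use the exact distribution when both sample sizes are at
#'   most this value (default 10); set to 0 to force the asymptotic formula.
#' @return List with \code{statistic} (D), \code{p_value}, \code{method}
#'   (\code{"exact"} or \code{"asymptotic"}) and the sample sizes.
#' @export
ks_two_sample <- function(x, y, exact_max = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain NA", call. = FALSE)
  n <- length(x); m <- length(y)
  pooled <- sort(unique(c(x, y)))
  D <- max(abs(vapply(pooled, function(t) mean(x <= t) - mean(y <= t), 1)))
  if (n <= exact_max && m <= exact_max) {
    p <- stats::psmirnov(D, sizes = c(n, m), z = c(x, y),
                         two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
    method <- "exact"
  } else {
    p <- kolmogorov_p(D, n, m)
    method <- "asymptotic"
  }
  list(statistic = D, p_value = min(1, max(0, p)), method = method,
       n = n, m = m)
}

# asymptotic two-sided Kolmogorov tail with effective-n correction
kolmogorov_p <- function(D, n, m) {
  if (D <= 0) return(1)
  n_eff <- n * m / (n + m)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y Numeric vectors of equal length (at least 3 points); \code{x}
#'   must not be constant.  A constant \code{y} yields R-squared 0 by
#'   convention (p-value 1).
#' @return List with \code{slope}, \code{intercept}, \code{r_squared} and
#'   \code{p_value} (slope t-test, n - 2 df).
#' @export
linear_fit_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (var(x) == 0) stop("x is constant", call. = FALSE)
  if (var(y) == 0) {
    fit0 <- lm(y ~ x)
    return(list(slope = 0, intercept = unname(coef(fit0)[1]),
                r_squared = 0, p_value = 1))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' Validate a lifestyle dataset
#'
#' @param records Data frame with columns \code{species}, \code{lifestyle}
#'   (one of intracellular_obligate, parasitic, free_living),
#'   \code{genome_mb}, \code{pct_transporter_genes} (in [0, 100]).
#' @return The validated data frame, classed \code{lifestyle_dataset}.
#' @export
lifestyle_dataset <- function(records) {
  need <- c("species", "lifestyle", "genome_mb", "pct_transporter_genes")
  stopifnot(all(need %in% names(records)))
  if (!all(records$lifestyle %in% LIFESTYLES))
    stop("lifestyle outside the closed vocabulary: ",
         paste(setdiff(unique(records$lifestyle), LIFESTYLES), collapse = ", "),
         call. = FALSE)
  if (any(records$pct_transporter_genes < 0 |
            records$pct_transporter_genes > 100))
    stop("pct_transporter_genes outside [0, 100]", call. = FALSE)
  structure(records, class = c("lifestyle_dataset", "data.frame"))
}

#' Compare transporter-gene fractions between lifestyle groups
#'
#' For each lifestyle group: sample size and observed range; for each pair of
#' groups: the two-sample KS statistic and p-value; for each group and
#' pooled: the OLS fit of fraction versus genome size.  Groups with fewer
#' than two records are excluded with a warning.
#'
#' @param dataset A \code{\link{lifestyle_dataset}}.
#' @param exact_max Passed to \code{\link{ks_two_sample}}.
#' @return List with \code{groups} (data frame), \code{pairwise} (data
#'   frame, empty when fewer than two usable groups), \code{fits} (per-group
#'   and pooled OLS summaries).
#' @export
compare_lifestyle_groups <- function(dataset, exact_max = 10) {
  stopifnot(is.data.frame(dataset))
  counts <- table(dataset$lifestyle)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    dataset <- dataset[!(dataset$lifestyle %in% small), , drop = FALSE]
  }
  groups <- sort(unique(dataset$lifestyle))
  gdf <- do.call(rbind, lapply(groups, function(g) {
    v <- dataset$pct_transporter_genes[dataset$lifestyle == g]
    data.frame(lifestyle = g, n = length(v), min_pct = min(v),
               max_pct = max(v), stringsAsFactors = FALSE)
  }))
  pairwise <- data.frame(group_a = character(), group_b = character(),
                         ks_d = numeric(), p_value = numeric(),
                         stringsAsFactors = FALSE)
  if (length(groups) < 2) {
    warning("fewer than two usable groups; no pairwise comparisons",
            call. = FALSE)
  } else {
    for (pair in combn(groups, 2, simplify = FALSE)) {
      a <- dataset$pct_transporter_genes[dataset$lifestyle == pair[1]]
      b <- dataset$pct_transporter_genes[dataset$lifestyle == pair[2]]
      ks <- ks_two_sample(a, b, exact_max = exact_max)
      pairwise <- rbind(pairwise, data.frame(
        group_a = pair[1], group_b = pair[2], ks_d = ks$statistic,
        p_value = ks$p_value, stringsAsFactors = FALSE))
    }
  }
  fit_of <- function(d) {
    if (nrow(d) < 3 || var(d$genome_mb) == 0) return(NULL)
    linear_fit_r2(d$genome_mb, d$pct_transporter_genes)
  }
  fits <- c(setNames(lapply(groups, function(g)
    fit_of(dataset[dataset$lifestyle == g, , drop = FALSE])), groups),
    list(pooled = fit_of(dataset)))
  list(groups = gdf, pairwise = pairwise, fits = fits)
}
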