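#' Shannon diversity index
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \log_b p_i}, with abundances normalised to
#' proportions. Base 2 by default (bits), configurable; base e gives nats
#' and matches `vegan::diversity`.
#'
#' @param abundances Non-negative numeric vector with at least one positive
#'   entry (counts or proportions; normalised internally).
#' @param base Logarithm base, > 1.
#' @return Non-negative scalar.
#' @examples
#' shannon(rep(1, 4)) # 2 bits
#' @export
shannon <- function(abundances, base = 2) {
  if (!is.numeric(abundances) || anyNA(abundances) || any(abundances < 0)) {
    fmt_stop("abundances must be non-negative and non-missing")
  }
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    fmt_stop("base must be a single number > 1")
  }
  total <- sum(abundances)
  if (total <= 0) fmt_stop("shannon is undefined for an all-zero vector")
  p <- abundances[abundances > 0] / total
  -sum(p * log(p, base = base))
}

#' Observed features (richness)
#'
#' @param counts Non-negative numeric vector.
#' @return Number of strictly positive entries.
#' @export
observed_features <- function(counts) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    fmt_stop("counts must be non-negative and non-missing")
  }
  sum(counts > 0)
}

#' Rarefy a count vector (subsample without replacement)
#'
#' Draws `depth` reads uniformly without replacement from the pooled reads,
#' i.e. one multivariate-hypergeometric sample. Implemented by sequential
#' conditional hypergeometric draws (exact, O(features) rather than
#' O(reads)). The result sums to `depth`, never exceeds the input
#' elementwise, and is reproducible given `seed`.
#'
#' @param counts Non-negative integer vector (names preserved).
#' @param depth Positive integer, at most `sum(counts)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector, same length and names as `counts`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    fmt_stop("counts must be non-negative integers")
  }
  if (!is_count(depth) || depth < 1) fmt_stop("depth must be a positive integer")
  total <- sum(counts)
  if (depth > total) {
    fmt_stop("depth (%d) exceeds sample total (%d)", as.integer(depth), as.integer(total))
  }
  out <- with_seed(seed, {
    res <- integer(length(counts))
    remaining <- total
    need <- depth
    for (i in seq_along(counts)) {
      if (need == 0) break
      ni <- counts[[i]]
      remaining <- remaining - ni
      k <- stats::rhyper(1L, m = ni, n = remaining, k = need)
      res[i] <- k
      need <- need - k
    }
    res
  })
  names(out) <- names(counts)
  out
}

#' Rarefaction curve over a depth grid
#'
#' Evaluates an alpha-diversity metric on repeated rarefactions of each
#' sample at depths `0, step, 2*step, ... <= max_depth`, averaging over
#' `iterations` independent draws. Depth 0 is reported as 0 by convention
#' (the metric's limit) so curves start at the origin; depths exceeding a
#' sample's total are absent for that sample rather than extrapolated.
#'
#' Randomness is driven by per-(sample, depth, iteration) substreams derived
#' from the single master `seed`, so the curve is reproducible regardless of
#' evaluation order.
#'
#' @param table A [feature_table()].
#' @param metric `"shannon"` or `"observed_features"`.
#' @param max_depth Largest depth on the grid (default 10000).
#' @param step Grid spacing (default 500).
#' @param iterations Rarefaction draws per point (default 10).
#' @param seed Master integer seed.
#' @param base Logarithm base for the Shannon metric.
#' @return A `rarefaction_curve`: long data frame with columns `sample_id`,
#'   `depth`, `value` (iteration mean), `metric`, `iterations`, `seed`.
#' @export
rarefaction_curve <- function(table, metric = c("shannon", "observed_features"),
                              max_depth = 10000L, step = 500L, iterations = 10L,
                              seed = 1L, base = 2) {
  stopifnot(is_feature_table(table))
  metric <- match.arg(metric)
  if (!is_count(step) || step < 1) fmt_stop("step must be >= 1")
  if (!is_count(iterations) || iterations < 1) fmt_stop("iterations must be >= 1")
  if (!is_count(max_depth)) fmt_stop("max_depth must be a non-negative integer")
  metric_fun <- switch(metric,
    shannon = function(x) shannon(x, base = base),
    observed_features = observed_features
  )
  depths <- seq(0L, as.integer(max_depth), by = as.integer(step))
  rows <- vector("list", ncol(table))
  for (j in seq_len(ncol(table))) {
    sample_id <- colnames(table)[[j]]
    counts <- unclass_matrix(table)[, j]
    total <- sum(counts)
    usable <- depths[depths <= total]
    vals <- vapply(usable, function(d) {
      if (d == 0L) {
        return(0)
      }
      mean(vapply(seq_len(iterations), function(it) {
        metric_fun(rarefy(counts, d, seed = derive_seed(seed, j, d, it)))
      }, numeric(1L)))
    }, numeric(1L))
    rows[[j]] <- data.frame(
      sample_id = sample_id, depth = usable, value = vals,
      metric = metric, iterations = as.integer(iterations),
      seed = as.integer(seed), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Per-sample alpha diversity table
#'
#' Observed features and Shannon index for every sample at full depth.
#'
#' @param table A [feature_table()].
#' @param base Logarithm base for the Shannon index.
#' @return Data frame with columns `sample_id`, `observed_features`,
#'   `shannon`.
#' @export
alpha_diversity <- function(table, base = 2) {
  stopifnot(is_feature_table(table))
  mat <- unclass_matrix(table)
  data.frame(
    sample_id = colnames(mat),
    observed_features = apply(mat, 2L, observed_features),
    shannon = apply(mat, 2L, shannon, base = base),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
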