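#' Relief-F feature weights
#'
#' Two-class relief-F: every sampled instance contributes, for each feature,
#' the mean normalized difference to its `neighbors` nearest misses (other
#' class) minus the mean normalized difference to its nearest hits (same
#' class). Differences are `|x_f - y_f| / range_f` with the range taken over
#' the whole matrix; a zero-range (constant) feature has its difference
#' defined as 0, so its weight is exactly 0. Neighbours are found under
#' Euclidean distance on the range-scaled features, ties broken by row
#' order, the instance itself excluded. Weights are accumulated as
#' `w_f += sum(diff to misses)/(m*k) - sum(diff to hits)/(m*k)` over the `m`
#' sampled instances.
#'
#' @param x Numeric feature matrix (instances x features, named columns).
#' @param labels Class labels (`positive`/`negative`), one per row.
#' @param neighbors Number of nearest hits and misses per instance
#'   (default 10; clipped to the available class counts).
#' @param sample_size Number of instances scored; `NULL` (default) scores
#'   all of them, in order. Smaller values sample uniformly at random.
#' @param seed Optional seed controlling the instance sample.
#' @return A tibble with columns `feature`, `weight`, `rank` (1 = highest
#'   weight; ties broken by column order).
#' @export
relieff_weights <- function(x, labels, neighbors = 10L, sample_size = NULL,
                            seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (any(!is.finite(x))) {
    abort("Feature matrix must be finite", class = "phossite_data_error")
  }
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("relief-F needs at least 2 instances in each class",
      class = "phossite_data_error"
    )
  }
  n <- nrow(x)
  p <- ncol(x)

  rng <- apply(x, 2L, max) - apply(x, 2L, min)
  zero_rng <- rng <= 0
  if (any(zero_rng)) {
    inform(paste0(
      sum(zero_rng), " feature(s) have zero range; their weights are 0"
    ))
  }
  scale_rng <- ifelse(zero_rng, 1, rng)
  xs <- sweep(x, 2L, apply(x, 2L, min), "-")
  xs <- sweep(xs, 2L, scale_rng, "/")
  xs[, zero_rng] <- 0

  if (is.null(sample_size) || sample_size >= n) {
    sampled <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sampled <- sample(n, sample_size)
  }
  m <- length(sampled)

  dmat <- as.matrix(stats::dist(xs))
  is_pos <- labels == "positive"
  w <- numeric(p)
  for (i in sampled) {
    same <- which(is_pos == is_pos[i])
    same <- same[same != i]
    other <- which(is_pos != is_pos[i])
    hits <- nearest_of(dmat[i, ], same, neighbors)
    misses <- nearest_of(dmat[i, ], other, neighbors)
    diff_hit <- colSums(abs(xs[hits, , drop = FALSE] -
      matrix(xs[i, ], length(hits), p, byrow = TRUE)))
    diff_miss <- colSums(abs(xs[misses, , drop = FALSE] -
      matrix(xs[i, ], length(misses), p, byrow = TRUE)))
    w <- w + diff_miss / (m * length(misses)) - diff_hit / (m * length(hits))
  }
  feat <- colnames(x) %||% paste0("f", seq_len(p))
  ord <- order(-w, seq_len(p))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  tibble(feature = feat, weight = unname(w), rank = rank)
}

nearest_of <- function(drow, candidates, k) {
  ord <- candidates[order(drow[candidates], candidates)]
  ord[seq_len(min(k, length(ord)))]
}

#' Retain the highest-weighted features
#'
#' Keeps the `target_dim` features with the largest relief-F weights (ties
#' broken by original layout order) and returns them in their original
#' layout order, so combined-encoding blocks stay contiguous and saved
#' models can align prediction-time features by identifier.
#'
#' @param x Feature matrix with named columns.
#' @param weights Tibble from [relieff_weights()] covering the columns of
#'   `x`.
#' @param target_dim Number of features to retain.
#' @return A list with `x` (the reduced matrix) and `retained` (the kept
#'   feature identifiers, in layout order).
#' @export
select_top <- function(x, weights, target_dim) {
  stopifnot(target_dim >= 1L)
  if (target_dim > ncol(x)) {
    abort(
      paste0(
        "target_dim (", target_dim, ") exceeds the ", ncol(x),
        " available features"
      ),
      class = "phossite_data_error"
    )
  }
  w <- weights$weight[match(colnames(x), weights$feature)]
  if (anyNA(w)) {
    abort("Weights are missing for some features of the matrix",
      class = "phossite_data_error"
    )
  }
  ord <- order(-w, seq_along(w))
  keep <- sort(ord[seq_len(target_dim)])
  list(x = x[, keep, drop = FALSE], retained = colnames(x)[keep])
}

# Default retained dimension for a scheme: relief-F reduction only applies
# to the combined encodings; sole schemes keep their full layout.
default_target_dim <- function(scheme, available) {
  if (scheme %in% names(DEFAULT_TARGET_DIMS)) {
    min(unname(DEFAULT_TARGET_DIMS[scheme]), available)
  } else {
    available
  }
}
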