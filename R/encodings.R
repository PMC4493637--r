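#' Amino-acid occurrence frequency (AF) encoding
#'
#' Encodes each fragment as the 20-vector of amino-acid frequencies
#' `v_i = c_i / L`, where `c_i` counts occurrences of amino acid `i` in the
#' fragment and `L` is the effective fragment length: the number of
#' positions that are neither the pad symbol nor the wildcard X. For a full,
#' pad-free window this is the plain residue frequency over the 25 positions
#' and the vector sums to 1.
#'
#' @param sequences Character vector of fragment sequences (any length).
#' @param pad Pad character to exclude from counts.
#' @return Numeric matrix, one row per fragment, 20 columns named
#'   `AF:<aa>` in fixed alphabetical amino-acid order.
#' @examples
#' encode_af(c("AAASA", "STYST"))
#' @export
encode_af <- function(sequences, pad = PAD_SYMBOL) {
  idx <- sequences_to_codes(sequences, pad = pad)
  eff_len <- rowSums(!is.na(idx))
  if (any(eff_len == 0L)) {
    abort("Fragment(s) consist only of pad/X characters; cannot encode",
      class = "phossite_data_error"
    )
  }
  n <- nrow(idx)
  flat <- (rep(seq_len(n), ncol(idx)) - 1L) * 20L + as.vector(idx)
  counts <- matrix(
    tabulate(flat[!is.na(flat)], nbins = n * 20L),
    nrow = n, ncol = 20L, byrow = TRUE
  )
  out <- counts / eff_len
  colnames(out) <- paste0("AF:", AMINO_ACIDS)
  rownames(out) <- names(sequences)
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP) encoding
#'
#' For every spacing `k = 0..k_max` and every ordered pair `(a, b)` of the
#' 20 standard amino acids, computes `N_ab,k / N_total,k`: the number of
#' position pairs `(i, i + k + 1)` in the fragment holding `a` then `b`,
#' normalized by the total number of such position pairs. Position pairs in
#' which either member is the pad symbol or X are excluded from both the
#' numerator and the denominator, so truncated windows are compared on the
#' pairs they actually contain. With `k_max = 5` the vector has
#' `400 x 6 = 2400` features.
#'
#' @param sequences Character vector of fragment sequences.
#' @param k_max Largest spacing considered (default 5).
#' @param pad Pad character.
#' @return Numeric matrix with `400 * (k_max + 1)` columns named
#'   `CK:<a><b>:k<k>`, blocks ordered by spacing then pair.
#' @examples
#' encode_cksaap("ASA", k_max = 1)[, c("CK:AS:k0", "CK:SA:k0", "CK:AA:k1")]
#' @export
encode_cksaap <- function(sequences, k_max = 5L, pad = PAD_SYMBOL) {
  stopifnot(k_max >= 0L)
  idx <- sequences_to_codes(sequences, pad = pad)
  n <- nrow(idx)
  width <- ncol(idx)
  blocks <- vector("list", k_max + 1L)
  zero_blocks <- 0L
  for (k in 0L:k_max) {
    npairs <- width - k - 1L
    block <- matrix(0, n, 400L)
    if (npairs >= 1L) {
      left <- idx[, seq_len(npairs), drop = FALSE]
      right <- idx[, seq_len(npairs) + k + 1L, drop = FALSE]
      pair_id <- (left - 1L) * 20L + right # NA propagates for pad/X members
      flat <- (rep(seq_len(n), npairs) - 1L) * 400L + as.vector(pair_id)
      counts <- matrix(
        tabulate(flat[!is.na(flat)], nbins = n * 400L),
        nrow = n, ncol = 400L, byrow = TRUE
      )
      totals <- rowSums(!is.na(pair_id))
      zero <- totals == 0L
      zero_blocks <- zero_blocks + sum(zero)
      totals[zero] <- 1 # leaves the all-zero rows at zero
      block <- counts / totals
    } else {
      zero_blocks <- zero_blocks + n
    }
    blocks[[k + 1L]] <- block
  }
  if (zero_blocks > 0L) {
    warn(paste0(
      zero_blocks, " fragment/spacing block(s) had no valid residue pairs; ",
      "those blocks are all zero"
    ))
  }
  out <- do.call(cbind, blocks)
  pair_names <- as.vector(t(outer(AMINO_ACIDS, AMINO_ACIDS, paste0)))
  colnames(out) <- paste0(
    "CK:", rep(pair_names, k_max + 1L), ":k", rep(0L:k_max, each = 400L)
  )
  rownames(out) <- names(sequences)
  out
}

#' Min-max normalized BLOSUM62 similarity matrix
#'
#' Returns the 20x20 BLOSUM62 substitution matrix affinely rescaled to
#' `[0, 1]`: `sim(a, b) = (B(a, b) - min B) / (max B - min B)` over the
#' standard amino-acid block. The minimum-scoring pair maps to exactly 0 and
#' the maximum-scoring pair to exactly 1; symmetry and score ordering are
#' preserved.
#'
#' @return Symmetric numeric 20x20 matrix with dimnames in the package's
#'   fixed amino-acid order.
#' @export
normalized_blosum62 <- function() {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings", envir = environment()))
  b <- b62[AMINO_ACIDS, AMINO_ACIDS]
  (b - min(b)) / (max(b) - min(b))
}

#' Distance between two aligned fragments under a similarity matrix
#'
#' The distance is one minus the mean pairwise similarity over the aligned
#' positions: `d(s1, s2) = 1 - (1/n) * sum_i sim(s1[i], s2[i])`, where the
#' sum and `n` skip positions at which either fragment holds a pad symbol or
#' X. The distance is symmetric and lies in `[0, 1]` when `sim` does.
#'
#' @param fragment1,fragment2 Fragment sequences of equal length (single
#'   strings).
#' @param sim Similarity matrix from [normalized_blosum62()] (the default).
#' @param pad Pad character.
#' @return A single distance in `[0, 1]`.
#' @export
knn_distance <- function(fragment1, fragment2, sim = normalized_blosum62(),
                         pad = PAD_SYMBOL) {
  if (nchar(fragment1) != nchar(fragment2)) {
    abort("Fragments must have equal length", class = "phossite_data_error")
  }
  d <- fragment_distances(fragment1, fragment2, sim = sim, pad = pad)
  if (is.na(d[1, 1])) {
    abort("No aligned position of the two fragments is comparable",
      class = "phossite_data_error"
    )
  }
  d[1, 1]
}

# All pairwise query x reference distances, vectorized across the alignment.
# Returns an nq x nr matrix; entries with no comparable positions are NA.
fragment_distances <- function(queries, refs, sim = normalized_blosum62(),
                               pad = PAD_SYMBOL) {
  qi <- sequences_to_codes(queries, pad = pad)
  ri <- sequences_to_codes(refs, pad = pad)
  stopifnot(ncol(qi) == ncol(ri))
  nq <- nrow(qi)
  nr <- nrow(ri)
  total <- matrix(0, nq, nr)
  nvalid <- matrix(0L, nq, nr)
  for (p in seq_len(ncol(qi))) {
    s <- sim[qi[, p], ri[, p], drop = FALSE]
    ok <- !is.na(s)
    s[!ok] <- 0
    total <- total + s
    nvalid <- nvalid + ok
  }
  out <- 1 - total / nvalid
  out[nvalid == 0L] <- NA_real_
  out
}

#' Nearest-neighbour distance-ratio (KNN) encoding
#'
#' For each query fragment and each fraction `f`, computes the ratio of the
#' mean distance to its `k_neg` nearest negative reference fragments over
#' the mean distance to its `k_pos` nearest positive reference fragments,
#' with `k = max(1, round(f * n_refs))` (round half away from zero).
#' Distances come from [knn_distance()] under the normalized BLOSUM62
#' similarity. Larger values therefore indicate a fragment that sits closer
#' to the positive class than to the negative class.
#'
#' During cross-validation the query itself is part of the reference pool;
#' set `exclude_self = TRUE` to remove it (matched by protein id and
#' position) from its own class before the neighbour search, preventing a
#' zero self-distance from leaking into the features.
#'
#' @param fragments Query fragment tibble (needs `protein_id`, `position`,
#'   `sequence`).
#' @param pos_refs,neg_refs Reference fragment tibbles for the two classes.
#' @param fractions Neighbour fractions (default 0.1%..10% in 7 steps).
#' @param sim Similarity matrix.
#' @param exclude_self Remove the query from its own reference class.
#' @param cap Value used when the mean positive distance is exactly zero
#'   (duplicated queries across the whole reference set).
#' @param pad Pad character.
#' @return Numeric matrix with `length(fractions)` columns named
#'   `KNN:f<fraction>`.
#' @export
encode_knn <- function(fragments, pos_refs, neg_refs,
                       fractions = DEFAULT_KNN_FRACTIONS,
                       sim = normalized_blosum62(), exclude_self = FALSE,
                       cap = 1e3, pad = PAD_SYMBOL) {
  check_fragments(fragments)
  if (nrow(pos_refs) == 0L || nrow(neg_refs) == 0L) {
    abort("Both reference sets must be non-empty", class = "phossite_data_error")
  }
  d_pos <- fragment_distances(fragments$sequence, pos_refs$sequence, sim, pad)
  d_neg <- fragment_distances(fragments$sequence, neg_refs$sequence, sim, pad)
  if (exclude_self) {
    qk <- fragment_keys(fragments)
    d_pos[outer(qk, fragment_keys(pos_refs), "==")] <- NA_real_
    d_neg[outer(qk, fragment_keys(neg_refs), "==")] <- NA_real_
  }
  k_pos <- pmax(1L, round_half_up(fractions * nrow(pos_refs)))
  k_neg <- pmax(1L, round_half_up(fractions * nrow(neg_refs)))

  mean_pos <- k_nearest_means(d_pos, k_pos)
  mean_neg <- k_nearest_means(d_neg, k_neg)
  capped <- mean_pos == 0
  if (any(capped)) {
    warn(paste0(
      sum(capped), " query/fraction ratio(s) had zero mean positive ",
      "distance; capped at ", cap
    ))
  }
  out <- mean_neg / pmax(mean_pos, .Machine$double.xmin)
  out[capped] <- cap
  colnames(out) <- paste0(
    "KNN:f",
    vapply(fractions, function(f) format(f, scientific = FALSE), character(1))
  )
  rownames(out) <- NULL
  out
}

# Mean of the k nearest distances per row, for each k in `ks`; NA distances
# (self-matches removed from the pool) are ignored. Ties broken by stable
# sort on (distance, reference index).
k_nearest_means <- function(d, ks) {
  n <- nrow(d)
  out <- matrix(NA_real_, n, length(ks))
  for (i in seq_len(n)) {
    row <- d[i, ]
    ord <- order(row, seq_along(row), na.last = TRUE)
    avail <- sum(!is.na(row))
    if (avail == 0L) {
      abort("A query has an empty reference pool after self-exclusion",
        class = "phossite_data_error"
      )
    }
    sorted <- row[ord]
    csum <- cumsum(sorted[seq_len(avail)])
    kk <- pmin(ks, avail)
    out[i, ] <- csum[kk] / kk
  }
  out
}

round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Encode fragments under any of the six encoding schemes
#'
#' Dispatches to [encode_af()], [encode_cksaap()] and [encode_knn()] and
#' concatenates blocks in the fixed order AF, CKSAAP, KNN for the combined
#' schemes. Pre-selection dimensions: AF = 20, KNN = 7, CKSAAP = 2400,
#' AF-KNN = 27, AF-CKSAAP = 2420, CKSAAP-KNN = 2407.
#'
#' @param fragments Fragment tibble.
#' @param scheme One of `"AF"`, `"KNN"`, `"CKSAAP"`, `"AF-KNN"`,
#'   `"AF-CKSAAP"`, `"CKSAAP-KNN"`.
#' @param refs Labeled fragment tibble providing the positive and negative
#'   reference sets for KNN-containing schemes (typically the training set).
#' @param k_max CKSAAP maximum spacing.
#' @param knn_fractions KNN neighbour fractions.
#' @param sim Similarity matrix for KNN.
#' @param exclude_self Passed to [encode_knn()].
#' @param pad Pad character.
#' @return Numeric feature matrix, columns named by feature identifier.
#' @export
encode_fragments <- function(fragments, scheme = "AF-CKSAAP", refs = NULL,
                             k_max = 5L, knn_fractions = DEFAULT_KNN_FRACTIONS,
                             sim = NULL, exclude_self = FALSE,
                             pad = PAD_SYMBOL) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  check_fragments(fragments)
  parts <- strsplit(scheme, "-", fixed = TRUE)[[1]]
  blocks <- list()
  if ("AF" %in% parts) {
    blocks$af <- encode_af(fragments$sequence, pad = pad)
  }
  if ("CKSAAP" %in% parts) {
    blocks$ck <- encode_cksaap(fragments$sequence, k_max = k_max, pad = pad)
  }
  if ("KNN" %in% parts) {
    if (is.null(refs)) {
      abort("KNN-containing schemes require labeled reference fragments",
        class = "phossite_data_error"
      )
    }
    check_fragments(refs, require_label = TRUE)
    if (is.null(sim)) sim <- normalized_blosum62()
    blocks$knn <- encode_knn(
      fragments,
      pos_refs = refs[refs$label == "positive", ],
      neg_refs = refs[refs$label == "negative", ],
      fractions = knn_fractions, sim = sim,
      exclude_self = exclude_self, pad = pad
    )
  }
  out <- do.call(cbind, unname(blocks))
  rownames(out) <- fragment_keys(fragments)
  out
}

# Map fragment strings to a matrix of integer amino-acid codes (1..20 in the
# fixed alphabetical order); pad and X become NA. All fragments must share
# one length.
sequences_to_codes <- function(sequences, pad = PAD_SYMBOL) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort("All fragment sequences must have the same length",
      class = "phossite_data_error"
    )
  }
  chars <- matrix(
    unlist(strsplit(sequences, ""), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE
  )
  bad <- !(chars %in% c(AMINO_ACIDS, "X", pad))
  if (any(bad)) {
    abort(
      paste0(
        "Fragment(s) contain invalid characters: ",
        paste(unique(chars[bad]), collapse = ", ")
      ),
      class = "phossite_data_error"
    )
  }
  m <- matrix(match(chars, AMINO_ACIDS), nrow = nrow(chars))
  m
}
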