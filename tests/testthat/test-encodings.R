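AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

test_that("AF encoding is the per-fragment residue frequency", {
  v <- encode_af("AAAAA")
  expect_equal(unname(v[1, "AF:A"]), 1)
  expect_equal(sum(v), 1)

  v2 <- encode_af(paste0(strrep("A", 13), strrep("S", 12)))
  expect_equal(unname(v2[1, "AF:A"]), 13 / 25)
  expect_equal(unname(v2[1, "AF:S"]), 12 / 25)

  # pad-free fragments always sum to 1; pads/X are excluded from the length
  for (w in random_windows(5, seed = 9)) {
    expect_equal(sum(encode_af(w)), 1)
  }
  padded <- paste0(strrep("-", 12), "S", strrep("X", 4), strrep("A", 8))
  vp <- encode_af(padded)
  expect_equal(unname(vp[1, "AF:S"]), 1 / 9)
  expect_equal(unname(vp[1, "AF:A"]), 8 / 9)
  expect_error(encode_af("----"), class = "phossite_data_error")
})

# Exhaustive pair-enumeration oracle for CKSAAP.
naive_cksaap <- function(fragment, k_max, pad = "-") {
  chars <- strsplit(fragment, "")[[1]]
  out <- numeric(0)
  for (k in 0:k_max) {
    counts <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    total <- 0
    i <- 1
    while (i + k + 1 <= length(chars)) {
      a <- chars[i]
      b <- chars[i + k + 1]
      if (a %in% AA20 && b %in% AA20) {
        counts[a, b] <- counts[a, b] + 1
        total <- total + 1
      }
      i <- i + 1
    }
    vals <- as.vector(t(counts))
    if (total > 0) vals <- vals / total
    names(vals) <- paste0(
      "CK:", as.vector(t(outer(AA20, AA20, paste0))), ":k", k
    )
    out <- c(out, vals)
  }
  out
}

test_that("CKSAAP values match exhaustive pair enumeration", {
  v <- encode_cksaap("ASA", k_max = 1)
  expect_equal(unname(v[1, "CK:AS:k0"]), 1 / 2)
  expect_equal(unname(v[1, "CK:SA:k0"]), 1 / 2)
  expect_equal(unname(v[1, "CK:AA:k1"]), 1)

  v0 <- encode_cksaap("AAAAA", k_max = 0)
  expect_equal(unname(v0[1, "CK:AA:k0"]), 1)
  expect_equal(sum(v0), 1)

  # random fragments (including pads and X) against the oracle
  frags <- c(
    random_windows(4, seed = 21),
    paste0(strrep("-", 6), "KLMSXPA", strrep("A", 12))
  )
  for (f in frags) {
    got <- encode_cksaap(f, k_max = 3)[1, ]
    expect_equal(got, naive_cksaap(f, 3))
  }
})

test_that("CKSAAP layout arithmetic and per-spacing normalization hold", {
  v <- encode_cksaap(random_windows(1), k_max = 5)
  expect_equal(ncol(v), 2400L)
  # each spacing contributes exactly 400 pair features
  for (k in 0:5) {
    block <- grepl(paste0(":k", k, "$"), colnames(v))
    expect_equal(sum(block), 400L)
    expect_equal(sum(v[1, block]), 1) # counts partition the total
  }
  # extreme padding empties a block with a warning, leaving zeros
  expect_warning(
    short <- encode_cksaap(paste0(strrep("-", 24), "S"), k_max = 2),
    regexp = "no valid residue pairs"
  )
  expect_true(all(short == 0))
})

test_that("normalized BLOSUM62 is a tight min-max map preserving order", {
  sim <- normalized_blosum62()
  expect_true(isSymmetric(sim))
  expect_equal(min(sim), 0)
  expect_equal(max(sim), 1)
  expect_true(all(sim >= 0 & sim <= 1))
  # affine map preserves strict score ordering (spot-checked on raw scores)
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
    envir = environment()
  ))[AA20, AA20]
  pairs <- cbind(sample(20, 50, TRUE), sample(20, 50, TRUE))
  for (i in 1:49) {
    a <- pairs[i, ]; b <- pairs[i + 1, ]
    if (b62[a[1], a[2]] > b62[b[1], b[2]]) {
      expect_gt(sim[a[1], a[2]], sim[b[1], b[2]])
    }
  }
})

test_that("fragment distance is one minus mean aligned similarity", {
  sim <- normalized_blosum62()
  # hand computation on 3-position toys
  d <- knn_distance("AKS", "ARS", sim)
  expected <- 1 - (sim["A", "A"] + sim["K", "R"] + sim["S", "S"]) / 3
  expect_equal(d, expected)

  # symmetry on random windows
  w <- random_windows(6, seed = 4)
  for (i in 1:3) {
    expect_equal(
      knn_distance(w[i], w[i + 3], sim), knn_distance(w[i + 3], w[i], sim)
    )
  }
  # maximum-similarity alignment gives distance 0 (W/W is the max pair)
  expect_equal(knn_distance("WWW", "WWW", sim), 0)
  # pads/X excluded from both the sum and the count
  d2 <- knn_distance("-KS", "XRS", sim)
  expect_equal(d2, 1 - (sim["K", "R"] + sim["S", "S"]) / 2)
  expect_error(knn_distance("--A", "AX-", sim), class = "phossite_data_error")
  expect_error(knn_distance("AA", "AAA", sim), class = "phossite_data_error")
})

test_that("KNN encoding matches brute-force neighbour search", {
  sim <- normalized_blosum62()
  pos <- make_fragments(random_windows(5, seed = 31), "positive",
    ids = sprintf("pp%d", 1:5)
  )
  neg <- make_fragments(random_windows(5, seed = 32), "negative",
    ids = sprintf("nn%d", 1:5)
  )
  q <- make_fragments(random_windows(3, seed = 33), "positive",
    ids = sprintf("qq%d", 1:3)
  )
  # f = 0.2 of 5 refs -> k = 1: ratio of the two single nearest distances
  got <- encode_knn(q, pos, neg, fractions = 0.2, sim = sim)
  for (i in 1:3) {
    dp <- vapply(pos$sequence, function(r) knn_distance(q$sequence[i], r, sim),
      numeric(1)
    )
    dn <- vapply(neg$sequence, function(r) knn_distance(q$sequence[i], r, sim),
      numeric(1)
    )
    expect_equal(unname(got[i, 1]), min(dn) / min(dp))
  }
  # f = 0.5 -> k = round(2.5) = 3 (half away from zero): mean of 3 nearest
  got3 <- encode_knn(q, pos, neg, fractions = 0.5, sim = sim)
  for (i in 1:3) {
    dp <- sort(vapply(pos$sequence, function(r) {
      knn_distance(q$sequence[i], r, sim)
    }, numeric(1)))
    dn <- sort(vapply(neg$sequence, function(r) {
      knn_distance(q$sequence[i], r, sim)
    }, numeric(1)))
    expect_equal(unname(got3[i, 1]), mean(dn[1:3]) / mean(dp[1:3]))
  }
})

test_that("KNN encoding degenerate and default behaviours", {
  sim <- normalized_blosum62()
  refs <- make_fragments(random_windows(8, seed = 41), "positive",
    ids = sprintf("r%d", 1:8)
  )
  q <- make_fragments(random_windows(2, seed = 42), ids = c("q1", "q2"))
  # identical positive and negative reference sets: every ratio is 1
  same_neg <- refs
  same_neg$label <- "negative"
  allsame <- encode_knn(q, refs, same_neg, sim = sim)
  expect_true(all(abs(allsame - 1) < 1e-12))
  # default fractions give a 7-feature vector
  expect_equal(ncol(allsame), 7L)
  expect_equal(
    colnames(allsame),
    paste0("KNN:f", c("0.001", "0.002", "0.005", "0.01", "0.02", "0.05", "0.1"))
  )
})

test_that("self-exclusion removes the query from its own reference class", {
  sim <- normalized_blosum62()
  refs <- make_fragments(random_windows(6, seed = 51),
    label = rep(c("positive", "negative"), each = 3),
    ids = sprintf("s%d", 1:6)
  )
  q <- refs[1, ] # a positive reference queried against its own pool
  with_self <- encode_knn(q, refs[refs$label == "positive", ],
    refs[refs$label == "negative", ],
    fractions = 0.7, sim = sim, exclude_self = FALSE
  )
  # distance 0 requires every aligned pair at maximum similarity (W/W under
  # normalized BLOSUM62); a zero mean positive distance is replaced by the cap
  all_w <- strrep("W", 25)
  wq <- make_fragments(all_w, ids = "wq")
  w_pool <- make_fragments(rep(all_w, 2), "positive", ids = c("d1", "d2"))
  expect_warning(
    capped <- encode_knn(wq, w_pool, refs[refs$label == "negative", ],
      fractions = 0.9, sim = sim, exclude_self = FALSE, cap = 123
    ),
    regexp = "capped"
  )
  expect_equal(unname(capped[1, 1]), 123)
  without_self <- encode_knn(q, refs[refs$label == "positive", ],
    refs[refs$label == "negative", ],
    fractions = 0.7, sim = sim, exclude_self = TRUE
  )
  expect_true(without_self[1, 1] < with_self[1, 1])
})

test_that("combined schemes concatenate blocks in AF, CKSAAP, KNN order", {
  frags <- make_fragments(random_windows(6, seed = 61),
    label = rep(c("positive", "negative"), each = 3)
  )
  af_knn <- encode_fragments(frags, "AF-KNN", refs = frags)
  expect_equal(ncol(af_knn), 27L)
  expect_true(all(startsWith(colnames(af_knn)[1:20], "AF:")))
  expect_true(all(startsWith(colnames(af_knn)[21:27], "KNN:")))

  af_ck <- encode_fragments(frags, "AF-CKSAAP")
  expect_equal(ncol(af_ck), 2420L)
  ck_knn <- encode_fragments(frags, "CKSAAP-KNN", refs = frags)
  expect_equal(ncol(ck_knn), 2407L)

  # the AF block of a combined vector equals the sole AF encoding
  af_alone <- encode_af(frags$sequence)
  rownames(af_alone) <- rownames(af_ck)
  expect_equal(af_ck[, 1:20], af_alone)
  # encoding is pure: repeated calls are bit-identical
  expect_identical(af_ck, encode_fragments(frags, "AF-CKSAAP"))
  expect_error(encode_fragments(frags, "CKSAAP-KNN"),
    class = "phossite_data_error"
  )
})
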