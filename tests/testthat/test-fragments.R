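# Brute-force window slicer used as the independent oracle for extraction.
naive_window <- function(sequence, position, pad = "-", hw = 12L) {
  chars <- strsplit(sequence, "")[[1]]
  out <- character(2L * hw + 1L)
  for (j in seq_along(out)) {
    idx <- position - hw + j - 1L
    out[j] <- if (idx >= 1L && idx <= length(chars)) chars[idx] else pad
  }
  paste0(out, collapse = "")
}

test_that("window extraction matches a character-by-character slicer", {
  # centred site in a 25-mer returns the whole protein with no pads
  prot <- paste0(strrep("A", 12), "S", strrep("K", 12))
  expect_equal(extract_fragment(prot, 13), prot)

  # terminal site gets 12 leading pads
  expect_equal(
    extract_fragment("STKLM", 1),
    paste0(strrep("-", 12), "STKLM", strrep("-", 8))
  )

  # position 5 of a 30-mer: 8 leading pads then residues 1..17
  prot30 <- paste0(strrep("A", 4), "S", strrep("L", 25))
  frag <- extract_fragment(prot30, 5)
  expect_equal(frag, paste0(strrep("-", 8), substr(prot30, 1, 17)))

  # every valid S/T/Y of random proteins agrees exactly with the oracle
  set.seed(42)
  for (r in 1:5) {
    prot <- paste0(sample(c("A", "S", "T", "Y", "K", "L", "P"), 40,
      replace = TRUE
    ), collapse = "")
    pos <- which(strsplit(prot, "")[[1]] %in% c("S", "T", "Y"))
    for (p in pos) {
      expect_equal(extract_fragment(prot, p), naive_window(prot, p))
    }
  }
  expect_error(extract_fragment("MKS", 7), class = "phossite_data_error")
})

test_that("fragment windows are 25-mers with the candidate at the centre", {
  frag <- extract_fragment("MSKY", 2)
  expect_equal(nchar(frag), 25L)
  expect_equal(substr(frag, 13, 13), "S")
  # pads only as contiguous prefix/suffix
  expect_match(frag, "^-*[A-Z]+-*$")
})

test_that("dataset compilation labels, auto-negates and deduplicates", {
  # protein with 2 annotated S positives and 1 unannotated T
  seqs <- tibble::tibble(
    protein_id = "p1",
    sequence = paste0("SAK", strrep("A", 5), "TAS", strrep("G", 4))
  )
  sites <- tibble::tibble(
    protein_id = "p1", position = c(1L, 11L), residue = "S",
    label = "positive"
  )
  frags <- build_fragments(seqs, sites)
  expect_equal(sum(frags$label == "positive"), 2L)
  expect_equal(sum(frags$label == "negative"), 1L)
  expect_equal(frags$residue[frags$label == "negative"], "T")

  # identical positive windows across proteins collapse to one
  seqs2 <- tibble::tibble(
    protein_id = c("a", "b"),
    sequence = rep(paste0(strrep("A", 12), "S", strrep("A", 12)), 2)
  )
  sites2 <- tibble::tibble(
    protein_id = c("a", "b"), position = 13L, residue = "S",
    label = "positive"
  )
  frags2 <- build_fragments(seqs2, sites2, auto_negatives = FALSE)
  expect_equal(nrow(frags2), 1L)
  expect_equal(frags2$protein_id, "a") # first occurrence kept

  # no S/T/Y at all: empty result, no error
  seqs3 <- tibble::tibble(protein_id = "p", sequence = "AAAKKKLLL")
  empty_sites <- sites2[0, ]
  expect_equal(nrow(build_fragments(seqs3, empty_sites)), 0L)
})

test_that("annotation errors are caught with offenders named", {
  seqs <- tibble::tibble(protein_id = "p1", sequence = "MKSTY")
  missing <- tibble::tibble(
    protein_id = "ghost", position = 3L, residue = "S", label = "positive"
  )
  expect_error(build_fragments(seqs, missing),
    regexp = "ghost", class = "phossite_data_error"
  )
  mismatch <- tibble::tibble(
    protein_id = "p1", position = 2L, residue = "S", label = "positive"
  )
  expect_error(build_fragments(seqs, mismatch),
    regexp = "p1:2", class = "phossite_data_error"
  )
})

test_that("solvent-accessibility filter keeps only flagged-buried negatives", {
  frags <- make_fragments(random_windows(12),
    label = rep(c("positive", "negative"), c(2, 10))
  )
  # 4 of the 10 negatives flagged inaccessible, 4 accessible, 2 unflagged
  neg <- frags[frags$label == "negative", ]
  acc <- tibble::tibble(
    protein_id = neg$protein_id[1:8], position = neg$position[1:8],
    accessible = rep(c(FALSE, TRUE), each = 4)
  )
  expect_warning(out <- filter_inaccessible(frags, acc), regexp = "2 negative")
  expect_equal(sum(out$label == "negative"), 4L)
  expect_equal(sum(out$label == "positive"), 2L)

  # all accessible: no negatives survive
  acc_all <- tibble::tibble(
    protein_id = neg$protein_id, position = neg$position, accessible = TRUE
  )
  out2 <- filter_inaccessible(frags, acc_all)
  expect_equal(sum(out2$label == "negative"), 0L)
})

test_that("train/test split is disjoint, exhaustive, and reproducible", {
  frags <- make_fragments(random_windows(90, seed = 5),
    label = rep(c("positive", "negative"), c(30, 60))
  )
  s1 <- split_fragments(frags, test_fraction = 1 / 3, seed = 11)
  s2 <- split_fragments(frags, test_fraction = 1 / 3, seed = 11)
  expect_identical(s1$test, s2$test)
  expect_identical(s1$train, s2$train)

  k_train <- paste(s1$train$protein_id, s1$train$position)
  k_test <- paste(s1$test$protein_id, s1$test$position)
  expect_length(intersect(k_train, k_test), 0L)
  expect_setequal(c(k_train, k_test), paste(frags$protein_id, frags$position))
  expect_equal(sum(s1$test$label == "positive"), 10L)
  expect_equal(sum(s1$test$label == "negative"), 20L)
})

test_that("ratio subsampling downsamples the majority class only", {
  frags <- make_fragments(random_windows(900, seed = 2),
    label = rep(c("positive", "negative"), c(300, 600))
  )
  s <- split_fragments(frags, test_fraction = 1 / 3, ratio = c(1, 1), seed = 7)
  expect_equal(
    sum(s$train$label == "positive"), sum(s$train$label == "negative")
  )
  expect_equal(sum(s$train$label == "positive"), 200L) # positives untouched

  # an unbalanced request keeps the ratio within floor rounding
  s2 <- split_fragments(frags, test_fraction = 1 / 3, ratio = c(1, 1.5), seed = 7)
  np <- sum(s2$train$label == "positive")
  nn <- sum(s2$train$label == "negative")
  expect_equal(nn, floor(np * 1.5))
})

test_that("class counts matching a published configuration are reachable", {
  # 112 positives vs 127 negatives (a 0.88:1 ratio) from larger pools
  frags <- make_fragments(random_windows(600, seed = 3),
    label = rep(c("positive", "negative"), c(112, 488))
  )
  set.seed(1)
  out <- sample_to_ratio(frags, c(112, 127))
  expect_equal(sum(out$label == "positive"), 112L)
  expect_equal(sum(out$label == "negative"), 127L)
})

test_that("unsatisfiable ratios report the maximum achievable counts", {
  frags <- make_fragments(random_windows(12),
    label = rep(c("positive", "negative"), c(2, 10))
  )
  expect_error(sample_to_ratio(frags, c(30, 1)),
    regexp = "maximum achievable", class = "phossite_data_error"
  )
})
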