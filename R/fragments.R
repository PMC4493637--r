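#' Extract a fixed-width sequence window around a position
#'
#' Returns the 25-residue window spanning offsets -12..+12 around `position`
#' (1-based) of `sequence`. Window positions that fall outside the protein
#' are filled with the pad symbol, which therefore only ever appears as a
#' contiguous prefix and/or suffix.
#'
#' @param sequence A protein sequence (single string, standard letters + X).
#' @param position 1-based position of the candidate residue. Vectorized:
#'   may be a vector of positions into the same sequence.
#' @param pad Single pad character (default `"-"`).
#' @param half_width Window half-width (default 12, giving 25-mers).
#' @return Character vector of windows, one per position.
#' @examples
#' extract_fragment("MKKSAPTTSLLRS", 4)
#' @export
extract_fragment <- function(sequence, position,
                             pad = PAD_SYMBOL, half_width = WINDOW_HALF_WIDTH) {
  stopifnot(length(sequence) == 1L, nchar(pad) == 1L)
  n <- nchar(sequence)
  if (any(position < 1L | position > n)) {
    abort(
      paste0("position out of range 1..", n),
      class = "phossite_data_error"
    )
  }
  start <- position - half_width
  end <- position + half_width
  left_pad <- pmax(0L, 1L - start)
  right_pad <- pmax(0L, end - n)
  core <- substring(sequence, pmax(1L, start), pmin(n, end))
  paste0(
    strrep(pad, left_pad), core, strrep(pad, right_pad)
  )
}

#' Build labeled fragment datasets from sequences and site annotations
#'
#' Resolves each annotation against the sequences, checks that the annotated
#' residue matches the sequence, extracts the 25-mer window around each site
#' and deduplicates exact window sequences within each class (keeping the
#' first occurrence in `(protein_id, position)` order). Windows identical
#' across the two classes are kept and reported as conflicts.
#'
#' When `auto_negatives` is `TRUE` (the default when the annotation table
#' contains no negative rows), every S, T or Y residue not annotated as
#' positive becomes a negative candidate.
#'
#' @param sequences Tibble from [read_fasta()].
#' @param sites Tibble of site annotations (see [read_sites()]); negative
#'   rows are optional.
#' @param auto_negatives Generate negatives from unannotated S/T/Y residues.
#'   `NULL` (default) auto-detects: negatives are generated only when the
#'   annotation table has no negative rows.
#' @param pad Pad symbol for windows that overrun the termini.
#' @return A tibble of fragments with columns `protein_id`, `position`,
#'   `residue`, `label`, `sequence` (the 25-mer window).
#' @export
build_fragments <- function(sequences, sites, auto_negatives = NULL,
                            pad = PAD_SYMBOL) {
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))
  stopifnot(all(c("protein_id", "position", "residue", "label") %in% names(sites)))

  missing_prot <- setdiff(unique(sites$protein_id), sequences$protein_id)
  if (length(missing_prot)) {
    abort(
      paste0(
        "Annotations reference protein(s) absent from the sequences: ",
        paste(head(missing_prot, 10), collapse = ", ")
      ),
      class = "phossite_data_error"
    )
  }

  seq_lookup <- setNames(sequences$sequence, sequences$protein_id)
  actual <- substring(
    seq_lookup[sites$protein_id], sites$position, sites$position
  )
  mism <- which(actual != sites$residue)
  if (length(mism)) {
    offenders <- paste0(
      sites$protein_id[mism], ":", sites$position[mism],
      " (annotated ", sites$residue[mism], ", sequence has ", actual[mism], ")"
    )
    abort(
      paste0(
        "Annotated residue does not match the sequence at: ",
        paste(head(offenders, 10), collapse = "; ")
      ),
      class = "phossite_data_error"
    )
  }

  if (is.null(auto_negatives)) {
    auto_negatives <- !any(sites$label == "negative")
  }

  pos_sites <- sites[sites$label == "positive", ]
  if (auto_negatives) {
    neg_sites <- sty_candidates(sequences)
    neg_sites <- anti_join(
      neg_sites, pos_sites[c("protein_id", "position")],
      by = c("protein_id", "position")
    )
    neg_sites$label <- "negative"
  } else {
    neg_sites <- sites[sites$label == "negative", ]
  }

  all_sites <- bind_rows(pos_sites, neg_sites)
  all_sites <- arrange(all_sites, .data$protein_id, .data$position)
  all_sites$sequence <- vapply(
    seq_len(nrow(all_sites)),
    function(i) {
      extract_fragment(seq_lookup[[all_sites$protein_id[i]]],
        all_sites$position[i],
        pad = pad
      )
    },
    character(1)
  )
  frag <- all_sites
  # deduplicate exact windows within each class, first occurrence wins
  frag <- frag |>
    group_by(.data$label) |>
    filter(!duplicated(.data$sequence)) |>
    ungroup()

  conflicts <- intersect(
    frag$sequence[frag$label == "positive"],
    frag$sequence[frag$label == "negative"]
  )
  if (length(conflicts)) {
    inform(paste0(
      length(conflicts),
      " window sequence(s) occur in both classes (kept in both)"
    ))
  }
  as_tibble(frag[c("protein_id", "position", "residue", "label", "sequence")])
}

# All S/T/Y positions of every protein, as an annotation-shaped tibble.
sty_candidates <- function(sequences) {
  res <- lapply(seq_len(nrow(sequences)), function(i) {
    chars <- strsplit(sequences$sequence[i], "")[[1]]
    pos <- which(chars %in% c("S", "T", "Y"))
    tibble(
      protein_id = sequences$protein_id[i],
      position = pos,
      residue = chars[pos]
    )
  })
  bind_rows(res)
}

#' Restrict negatives to solvent-inaccessible sites
#'
#' Keeps every positive fragment, and only those negative fragments whose
#' site is flagged as buried (`accessible = FALSE`) in the accessibility
#' table. Negatives with no accessibility record are dropped with a warning
#' giving the count, mirroring the common practice of discarding
#' unannotatable candidate negatives rather than guessing.
#'
#' @param fragments Fragment tibble from [build_fragments()].
#' @param accessibility Tibble from [read_accessibility()].
#' @return Filtered fragment tibble.
#' @export
filter_inaccessible <- function(fragments, accessibility) {
  stopifnot(all(c("protein_id", "position", "accessible") %in% names(accessibility)))
  neg <- fragments[fragments$label == "negative", ]
  pos <- fragments[fragments$label == "positive", ]
  neg <- left_join(neg, accessibility, by = c("protein_id", "position"))
  n_unflagged <- sum(is.na(neg$accessible))
  if (n_unflagged > 0L) {
    warn(paste0(
      n_unflagged, " negative site(s) had no accessibility flag and were dropped"
    ))
  }
  neg <- neg[!is.na(neg$accessible) & !neg$accessible, ]
  neg$accessible <- NULL
  bind_rows(pos, neg)
}

#' Split fragments into training and independent test sets
#'
#' Holds out `test_fraction` of each class (uniformly at random) as an
#' independent test set, then optionally subsamples the remaining training
#' pool, without replacement, to a requested (+):(-) class ratio. Only the
#' majority pool under the requested ratio is downsampled; neither class is
#' ever upsampled. With `by_protein = TRUE` the split unit is the protein
#' rather than the site, for users worried about homologous-window leakage.
#'
#' @param fragments Fragment tibble.
#' @param test_fraction Proportion of each class held out (default 1/3).
#' @param ratio Optional numeric pair `c(pos, neg)` giving the target
#'   (+):(-) ratio of the training set, e.g. `c(1, 1)`. `NULL` keeps all
#'   training fragments.
#' @param seed Integer seed making the split reproducible.
#' @param by_protein Split whole proteins instead of individual sites.
#' @return A list with tibbles `train` and `test`.
#' @export
split_fragments <- function(fragments, test_fraction = 1 / 3, ratio = NULL,
                            seed = NULL, by_protein = FALSE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labs <- fragments$label
  if (!all(CLASS_LEVELS %in% labs)) {
    abort("Both classes must be present before splitting",
      class = "phossite_data_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)

  if (by_protein) {
    prots <- unique(fragments$protein_id)
    test_prots <- sample(prots, floor(length(prots) * test_fraction))
    test_idx <- which(fragments$protein_id %in% test_prots)
  } else {
    test_idx <- unlist(lapply(CLASS_LEVELS, function(cl) {
      idx <- which(labs == cl)
      sample(idx, floor(length(idx) * test_fraction))
    }))
  }
  test <- fragments[sort(test_idx), ]
  train <- fragments[setdiff(seq_len(nrow(fragments)), test_idx), ]

  if (!is.null(ratio)) {
    train <- sample_to_ratio(train, ratio)
  }
  list(train = train, test = test)
}

#' Subsample fragments to a target class ratio
#'
#' Downsamples the class that is over-represented relative to the requested
#' `(+):(-)` ratio; the other class is kept whole. Sampling is uniform
#' without replacement (seed the RNG beforehand for reproducibility).
#'
#' @param fragments Fragment tibble.
#' @param ratio Numeric pair `c(pos, neg)` with both components >= 1.
#' @return Subsampled fragment tibble (original row order preserved).
#' @export
sample_to_ratio <- function(fragments, ratio) {
  stopifnot(length(ratio) == 2L, all(ratio >= 1))
  pos_idx <- which(fragments$label == "positive")
  neg_idx <- which(fragments$label == "negative")
  np <- length(pos_idx)
  nn <- length(neg_idx)
  target_nn <- floor(np * ratio[2] / ratio[1])
  if (target_nn <= nn) {
    keep_pos <- pos_idx
    keep_neg <- sample(neg_idx, target_nn)
  } else {
    target_np <- floor(nn * ratio[1] / ratio[2])
    keep_pos <- sample(pos_idx, target_np)
    keep_neg <- neg_idx
  }
  if (length(keep_pos) < 1L || length(keep_neg) < 1L) {
    max_r <- if (np >= 1 && nn >= 1) paste0(np, ":", nn) else "none"
    abort(
      paste0(
        "Requested ratio ", ratio[1], ":", ratio[2],
        " is unsatisfiable from ", np, " positive / ", nn,
        " negative fragments; maximum achievable counts are ", max_r
      ),
      class = "phossite_data_error"
    )
  }
  fragments[sort(c(keep_pos, keep_neg)), ]
}

# Validate a fragment tibble; used at the entrance of encoding and training.
check_fragments <- function(fragments, require_label = FALSE) {
  needed <- c("protein_id", "position", "residue", "sequence")
  if (require_label) needed <- c(needed, "label")
  missing_cols <- setdiff(needed, names(fragments))
  if (length(missing_cols)) {
    abort(paste0(
      "Fragment table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "phossite_data_error")
  }
  invisible(fragments)
}

fragment_keys <- function(fragments) {
  paste(fragments$protein_id, fragments$position, sep = ":")
}
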