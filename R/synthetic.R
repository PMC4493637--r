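#' Specification for the synthetic fragment generator
#'
#' Describes a two-class population of 25-mer fragments. Negatives are drawn
#' i.i.d. from `background` with the centre residue drawn from
#' `center_distribution`. Positives start from the same background and are
#' then (a) overwritten at each positional-motif offset with the stated
#' residue and probability, and (b) tilted toward the paired motifs by
#' rejection sampling: a candidate lacking a planted `(a, b, k)` pair is
#' accepted with probability `1/enrichment`, so fragments containing the
#' pair are enriched by roughly that factor.
#'
#' The default centre distribution (0.85, 0.12, 0.03 over S, T, Y)
#' approximates the relative abundance of experimentally observed
#' phospho-serine, -threonine and -tyrosine sites in rice.
#'
#' @param n_pos,n_neg Fragments per class.
#' @param background Named amino-acid probability vector (default uniform
#'   over the 20 standard residues).
#' @param positional_motifs Tibble/data frame with columns `offset`
#'   (-12..+12, excluding 0), `residue`, `prob`.
#' @param pair_motifs Tibble/data frame with columns `a`, `b`, `k`
#'   (spacing) and `enrichment` (>= 1).
#' @param center_distribution Named probabilities over S, T, Y.
#' @param seed Integer seed.
#' @return A `phossite_generator_spec` list.
#' @export
generator_spec <- function(n_pos = 500L, n_neg = 500L, background = NULL,
                           positional_motifs = NULL, pair_motifs = NULL,
                           center_distribution = c(S = 0.85, T = 0.12, Y = 0.03),
                           seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AMINO_ACIDS)
  }
  if (!setequal(names(background), AMINO_ACIDS) ||
    abs(sum(background) - 1) > 1e-8 || any(background < 0)) {
    abort("background must be a probability vector over the 20 amino acids",
      class = "phossite_config_error"
    )
  }
  if (!setequal(names(center_distribution), c("S", "T", "Y")) ||
    abs(sum(center_distribution) - 1) > 1e-8) {
    abort("center_distribution must be probabilities over S, T, Y",
      class = "phossite_config_error"
    )
  }
  if (!is.null(positional_motifs)) {
    positional_motifs <- as_tibble(positional_motifs)
    stopifnot(all(c("offset", "residue", "prob") %in% names(positional_motifs)))
    if (any(positional_motifs$offset == 0L) ||
      any(abs(positional_motifs$offset) > WINDOW_HALF_WIDTH)) {
      abort("Motif offsets must lie in -12..+12 and exclude 0 (the centre)",
        class = "phossite_config_error"
      )
    }
    stopifnot(all(positional_motifs$prob >= 0 & positional_motifs$prob <= 1))
  }
  if (!is.null(pair_motifs)) {
    pair_motifs <- as_tibble(pair_motifs)
    stopifnot(all(c("a", "b", "k", "enrichment") %in% names(pair_motifs)))
    if (any(pair_motifs$enrichment < 1)) {
      abort(
        "Pair enrichment multipliers must be >= 1 (rejection sampling cannot deplete)",
        class = "phossite_config_error"
      )
    }
  }
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      background = background[AMINO_ACIDS],
      positional_motifs = positional_motifs,
      pair_motifs = pair_motifs,
      center_distribution = center_distribution[c("S", "T", "Y")],
      seed = as.integer(seed)
    ),
    class = "phossite_generator_spec"
  )
}

#' Preset generator configurations
#'
#' `"null"` plants no motifs, so the two classes are exchangeable and any
#' classifier's cross-validated MCC should hover around 0. `"strong"`
#' plants a pronounced proline-directed signature in the positives —
#' positional motifs P at +1 (prob 0.95), R at -3 (0.8), D at +2 (0.6) —
#' plus paired-motif enrichment of S-P at spacing 0 (x4) and L..K at
#' spacing 2 (x3), a caricature of the motif structure around real
#' phosphosites that a working pipeline must separate easily.
#'
#' @param signal `"null"` or `"strong"`.
#' @param n_pos,n_neg Fragments per class.
#' @param seed Integer seed.
#' @return A `phossite_generator_spec`.
#' @export
preset_generator <- function(signal = c("strong", "null"), n_pos = 500L,
                             n_neg = 500L, seed = 1L) {
  signal <- match.arg(signal)
  if (signal == "null") {
    return(generator_spec(n_pos = n_pos, n_neg = n_neg, seed = seed))
  }
  generator_spec(
    n_pos = n_pos, n_neg = n_neg,
    positional_motifs = tibble(
      offset = c(1L, -3L, 2L),
      residue = c("P", "R", "D"),
      prob = c(0.95, 0.8, 0.6)
    ),
    pair_motifs = tibble(
      a = c("S", "L"), b = c("P", "K"), k = c(0L, 2L),
      enrichment = c(4, 3)
    ),
    seed = seed
  )
}

#' Generate labeled synthetic fragments
#'
#' @param spec A `phossite_generator_spec`.
#' @return A fragment tibble (25-mer `sequence`, centre `residue`, `label`,
#'   synthetic `protein_id`/`position` provenance with the centre at
#'   position 13).
#' @export
generate_fragments <- function(spec) {
  stopifnot(inherits(spec, "phossite_generator_spec"))
  set.seed(spec$seed)
  neg <- draw_fragments(spec$n_neg, spec)
  pos <- draw_positive_fragments(spec$n_pos, spec)
  tibble(
    protein_id = c(
      sprintf("SYN%d.POS%05d", spec$seed, seq_len(spec$n_pos)),
      sprintf("SYN%d.NEG%05d", spec$seed, seq_len(spec$n_neg))
    ),
    position = CENTER_INDEX,
    residue = substr(c(pos, neg), CENTER_INDEX, CENTER_INDEX),
    label = rep(CLASS_LEVELS[c(2L, 1L)], c(spec$n_pos, spec$n_neg)),
    sequence = c(pos, neg)
  )
}

# n background fragments with sampled centre residues.
draw_fragments <- function(n, spec) {
  chars <- matrix(
    sample(AMINO_ACIDS, n * FRAGMENT_LENGTH, replace = TRUE,
      prob = spec$background
    ),
    nrow = n
  )
  chars[, CENTER_INDEX] <- sample(
    c("S", "T", "Y"), n,
    replace = TRUE, prob = spec$center_distribution
  )
  apply(chars, 1L, paste0, collapse = "")
}

draw_positive_fragments <- function(n, spec) {
  out <- character(0)
  tries <- 0L
  max_tries <- 1000L * n
  batch <- max(n, 100L)
  while (length(out) < n) {
    if (tries >= max_tries) {
      abort(
        paste0(
          "Pair-motif rejection sampling did not reach ", n,
          " accepted fragments within ", max_tries, " draws; lower the ",
          "enrichment multipliers"
        ),
        class = "phossite_config_error"
      )
    }
    cand <- draw_fragments(batch, spec)
    if (!is.null(spec$positional_motifs)) {
      m <- spec$positional_motifs
      for (j in seq_len(nrow(m))) {
        hit <- runif(batch) < m$prob[j]
        idx <- CENTER_INDEX + m$offset[j]
        substr(cand[hit], idx, idx) <- m$residue[j]
      }
    }
    keep <- rep(TRUE, batch)
    if (!is.null(spec$pair_motifs)) {
      pm <- spec$pair_motifs
      for (j in seq_len(nrow(pm))) {
        pat <- paste0(pm$a[j], strrep(".", pm$k[j]), pm$b[j])
        has <- grepl(pat, cand)
        keep <- keep & (has | runif(batch) < 1 / pm$enrichment[j])
      }
    }
    out <- c(out, cand[keep])
    tries <- tries + batch
  }
  out[seq_len(n)]
}

#' Embed synthetic fragments into full-length proteins
#'
#' Generates fragments from `spec` and plants each one inside a random
#' background protein, recording the centre position, so the FASTA +
#' site-table pair exercises the whole extraction pipeline end to end.
#' Protein lengths shorter than 25 truncate the planted fragment (the
#' recorded site stays inside the protein), which is how terminal padding
#' gets tested.
#'
#' @param spec A `phossite_generator_spec`.
#' @param length_range Integer pair: protein lengths are drawn uniformly
#'   from this range (default 60..120).
#' @return A list with `sequences` (tibble: `protein_id`, `sequence`) and
#'   `sites` (tibble: `protein_id`, `position`, `residue`, `label`), one
#'   protein per fragment.
#' @export
generate_proteins <- function(spec, length_range = c(60L, 120L)) {
  stopifnot(inherits(spec, "phossite_generator_spec"))
  frags <- generate_fragments(spec)
  set.seed(spec$seed + 1L)
  n <- nrow(frags)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- character(n)
  positions <- integer(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    frag <- frags$sequence[i]
    if (L >= FRAGMENT_LENGTH) {
      start <- sample(seq_len(L - FRAGMENT_LENGTH + 1L), 1L)
      flank_n <- L - FRAGMENT_LENGTH
      flanks <- paste0(
        sample(AMINO_ACIDS, flank_n, replace = TRUE, prob = spec$background),
        collapse = ""
      )
      left <- substr(flanks, 1L, start - 1L)
      right <- substr(flanks, start, flank_n)
      seqs[i] <- paste0(left, frag, right)
      positions[i] <- start + CENTER_INDEX - 1L
    } else {
      # short protein: keep a window of the fragment containing its centre
      choices <- seq(
        max(0L, L - (FRAGMENT_LENGTH - CENTER_INDEX) - 1L),
        min(CENTER_INDEX - 1L, L - 1L)
      )
      left_keep <- if (length(choices) == 1L) choices else sample(choices, 1L)
      start <- CENTER_INDEX - left_keep
      seqs[i] <- substr(frag, start, start + L - 1L)
      positions[i] <- left_keep + 1L
    }
  }
  prot_ids <- sprintf("SPROT%d.%05d", spec$seed, seq_len(n))
  list(
    sequences = tibble(protein_id = prot_ids, sequence = seqs),
    sites = tibble(
      protein_id = prot_ids, position = positions,
      residue = frags$residue, label = frags$label
    )
  )
}
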