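# Shared fixture builders. Fragments are built in code; nothing binary on disk.

# A fragment tibble from raw window strings (default length 25, centre S).
make_fragments <- function(sequences, label = "positive",
                           ids = sprintf("P%03d", seq_along(sequences)),
                           position = 13L) {
  tibble::tibble(
    protein_id = ids,
    position = position,
    residue = substr(sequences, pmin(13L, nchar(sequences)), pmin(13L, nchar(sequences))),
    label = rep_len(label, length(sequences)),
    sequence = sequences
  )
}

# Random valid 25-mers with an S/T/Y centre, as plain strings.
random_windows <- function(n, seed = 1) {
  set.seed(seed)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  vapply(seq_len(n), function(i) {
    chars <- sample(aa, 25, replace = TRUE)
    chars[13] <- sample(c("S", "T", "Y"), 1)
    paste0(chars, collapse = "")
  }, character(1))
}

# Write a FASTA file into a temp path and return it.
temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(
    as.vector(rbind(paste0(">", names(records)), unname(records))),
    path
  )
  path
}

# Write a site TSV and return the path.
temp_sites <- function(sites) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(sites, path, progress = FALSE)
  path
}
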