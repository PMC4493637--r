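#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a tibble. Record
#' identifiers are the first whitespace-delimited token of each header line.
#' Sequences are upper-cased and the non-standard letters B, J, O, U, Z and
#' the stop symbol `*` are mapped to the wildcard `X` (as is any literal X),
#' so downstream code only ever sees the 20 standard amino acids plus X.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "MKSSPT", ">p2", "arndcu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "phossite_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(
        paste0("Failed to parse FASTA file '", path, "': ", conditionMessage(e)),
        class = "phossite_fasta_error"
      )
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"),
      class = "phossite_fasta_error"
    )
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(
      paste0(
        "Duplicate protein id(s) in '", path, "': ",
        paste(dups, collapse = ", ")
      ),
      class = "phossite_fasta_error"
    )
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[BJOUZ*]", "X", seqs)
  bad <- grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    abort(
      paste0(
        "Non-amino-acid characters in record(s): ",
        paste(head(ids[bad], 5), collapse = ", ")
      ),
      class = "phossite_fasta_error"
    )
  }
  tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Tibble with columns `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(sequences)))
  lines <- as.vector(rbind(paste0(">", sequences$protein_id), sequences$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a site annotation table
#'
#' Reads a tab-delimited table of candidate phosphorylation sites with
#' columns `protein_id`, `position` (1-based), `residue` (S, T or Y) and
#' `label` (`positive` or `negative`). Lines starting with `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the four annotation columns.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Site table not found: ", path), class = "phossite_io_error")
  }
  sites <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      residue = readr::col_character(),
      label = readr::col_character()
    )
  )
  required <- c("protein_id", "position", "residue", "label")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    abort(
      paste0(
        "Site table '", path, "' is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "phossite_io_error"
    )
  }
  if (any(sites$position < 1L)) {
    abort("Site positions must be >= 1 (positions are 1-based)",
      class = "phossite_data_error"
    )
  }
  bad_res <- setdiff(unique(sites$residue), c("S", "T", "Y"))
  if (length(bad_res)) {
    abort(paste0(
      "Site residues must be S, T or Y; found: ",
      paste(bad_res, collapse = ", ")
    ), class = "phossite_data_error")
  }
  bad_lab <- setdiff(unique(sites$label), CLASS_LEVELS)
  if (length(bad_lab)) {
    abort(paste0(
      "Site labels must be 'positive' or 'negative'; found: ",
      paste(bad_lab, collapse = ", ")
    ), class = "phossite_data_error")
  }
  sites[required]
}

#' Read a solvent-accessibility annotation table
#'
#' Reads a tab-delimited table with columns `protein_id`, `position` and
#' `accessible` (0 = buried, 1 = solvent accessible), typically produced by
#' an external surface-accessibility predictor. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_id`, `position`, `accessible`
#'   (logical).
#' @export
read_accessibility <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Accessibility table not found: ", path),
      class = "phossite_io_error"
    )
  }
  acc <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      accessible = readr::col_integer()
    )
  )
  required <- c("protein_id", "position", "accessible")
  missing_cols <- setdiff(required, names(acc))
  if (length(missing_cols)) {
    abort(
      paste0(
        "Accessibility table '", path, "' is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "phossite_io_error"
    )
  }
  if (!all(acc$accessible %in% c(0L, 1L))) {
    abort("'accessible' must be 0 or 1", class = "phossite_data_error")
  }
  acc$accessible <- acc$accessible == 1L
  acc[required]
}

#' Write a site annotation table
#'
#' @param sites Tibble with columns `protein_id`, `position`, `residue`,
#'   `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites[c("protein_id", "position", "residue", "label")], path,
    progress = FALSE
  )
  invisible(path)
}
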