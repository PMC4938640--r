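# Reading and writing degron libraries (peptide FASTA or TSV).

#' Read a degron library
#'
#' Reads peptide records from FASTA (via Biostrings) or a TSV with `id` and
#' `peptide` columns, and returns a feature-annotated tibble
#' (see [degron_features()]). Features are always recomputed on read so a
#' stale `gravy` column in a TSV cannot drift from the sequence.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return A tibble with columns `id`, `peptide`, `length`, `gravy`,
#'   `max_hydrophobic_run`.
#' @export
read_degron_library <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    recs <- tibble::tibble(
      id = sub("\\s.*$", "", names(seqs)),
      peptide = unname(as.character(seqs))
    )
  } else {
    recs <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    missing <- setdiff(c("id", "peptide"), names(recs))
    if (length(missing) > 0) {
      stop("degron TSV is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    recs <- dplyr::select(recs, "id", "peptide")
  }
  if (anyDuplicated(recs$id)) {
    stop("duplicate degron ids in ", path, call. = FALSE)
  }
  degron_features(recs)
}

#' Write a degron library
#'
#' @param degrons Data frame with `id` and `peptide` columns (extra feature
#'   columns are written for TSV, ignored for FASTA).
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_degron_library <- function(degrons, path, format = c("auto", "fasta", "tsv")) {
  stopifnot(all(c("id", "peptide") %in% names(degrons)))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::AAStringSet(degrons$peptide)
    names(seqs) <- degrons$id
    Biostrings::writeXStringSet(seqs, path)
  } else {
    readr::write_tsv(degrons, path, progress = FALSE)
  }
  invisible(path)
}

#' The degron tester-set peptides
#'
#' Loads the 14 bundled tester-set peptides (13 screen isolates plus the
#' CL1 control degron) with recomputed sequence features.
#'
#' @return A tibble of 14 annotated degron records.
#' @export
#' @examples
#' tester_set()
tester_set <- function() {
  path <- system.file("extdata", "tester_set.tsv", package = "degronscreen",
                      mustWork = TRUE)
  read_degron_library(path, format = "tsv")
}
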