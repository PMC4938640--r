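# Peptide-level sequence features for degron annotation.

#' Kyte-Doolittle hydropathy scale
#'
#' The classic residue hydropathy values used to compute GRAVY (grand
#' average of hydropathy). Values are dimensionless and bounded in
#' \[-4.5, 4.5\]; positive means hydrophobic.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
#' @examples
#' kd_hydropathy()[c("V", "R")]
kd_hydropathy <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Default hydrophobic residue set
#'
#' Residues treated as hydrophobic when scanning for contiguous hydrophobic
#' stretches: the residues with positive Kyte-Doolittle hydropathy, i.e.
#' A, C, F, I, L, M, V, W. The set is an argument everywhere it is used,
#' since different quality-control receptors may warrant different sets.
#'
#' @return Character vector of single-letter residue codes.
#' @export
default_hydrophobic_set <- function() {
  c("A", "C", "F", "I", "L", "M", "V", "W")
}

# Split a peptide into residues and fail loudly on anything outside `alphabet`,
# naming the offending character and its 1-based position.
check_residues <- function(peptide, alphabet, what = "peptide") {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  chars
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values over a peptide.
#'
#' @param peptide Character vector of peptides (uppercase single-letter
#'   amino-acid codes, standard alphabet only).
#' @param scale Named numeric hydropathy scale; defaults to
#'   [kd_hydropathy()].
#' @return Numeric vector of mean hydropathy scores, one per peptide.
#' @export
#' @examples
#' gravy("VVLVVVF")                     # 3.943 after rounding
#' gravy(c("ACKNWFSSLSHFVIHL", "V"))
gravy <- function(peptide, scale = kd_hydropathy()) {
  stopifnot(is.character(peptide), is.numeric(scale), !is.null(names(scale)))
  vapply(peptide, function(p) {
    if (is.na(p) || nchar(p) == 0) {
      stop("gravy() is undefined for an empty peptide", call. = FALSE)
    }
    chars <- check_residues(p, names(scale))
    mean(scale[chars])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest contiguous hydrophobic stretch
#'
#' Length of the longest run of residues belonging to `hydrophobic`.
#' Stretches of at least five contiguous hydrophobic residues are the
#' recognition rule reported for the nuclear quality-control ligase San1,
#' which motivates carrying this feature alongside GRAVY.
#'
#' @param peptide Character vector of peptides; the empty string gives 0.
#' @param hydrophobic Character vector of residues counted as hydrophobic;
#'   defaults to [default_hydrophobic_set()].
#' @return Integer vector of maximal run lengths (0 if no residue matches).
#' @export
#' @examples
#' max_hydrophobic_run("VVLVVVF")   # 7: every residue is hydrophobic
max_hydrophobic_run <- function(peptide, hydrophobic = default_hydrophobic_set()) {
  stopifnot(all(hydrophobic %in% names(kd_hydropathy())))
  vapply(peptide, function(p) {
    if (is.na(p) || nchar(p) == 0) return(0L)
    chars <- check_residues(p, names(kd_hydropathy()))
    runs <- rle(chars %in% hydrophobic)
    hits <- runs$lengths[runs$values]
    if (length(hits) == 0) 0L else as.integer(max(hits))
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute sequence features for a degron table
#'
#' Takes a data frame with at least `id` and `peptide` columns and returns a
#' tibble with `length`, `gravy` and `max_hydrophobic_run` columns appended
#' (recomputed even if present). This is the tabular surface over [gravy()]
#' and [max_hydrophobic_run()].
#'
#' @param degrons Data frame with columns `id`, `peptide`.
#' @param scale Hydropathy scale passed to [gravy()].
#' @param hydrophobic Residue set passed to [max_hydrophobic_run()].
#' @return A tibble, one row per input degron.
#' @export
#' @examples
#' degron_features(tibble::tibble(id = "CL1", peptide = "ACKNWFSSLSHFVIHL"))
degron_features <- function(degrons, scale = kd_hydropathy(),
                            hydrophobic = default_hydrophobic_set()) {
  stopifnot(is.data.frame(degrons), all(c("id", "peptide") %in% names(degrons)))
  if (anyDuplicated(degrons$id)) {
    stop("duplicate degron ids: ",
         paste(unique(degrons$id[duplicated(degrons$id)]), collapse = ", "),
         call. = FALSE)
  }
  degrons |>
    tibble::as_tibble() |>
    dplyr::mutate(
      length = nchar(.data$peptide),
      gravy = gravy(.data$peptide, scale = scale),
      max_hydrophobic_run = max_hydrophobic_run(.data$peptide,
                                                hydrophobic = hydrophobic)
    )
}
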