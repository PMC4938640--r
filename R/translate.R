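# Fusion-frame translation of cloned library inserts.
#
# Library fragments are cloned directly downstream of the reporter ORF, so
# the insert is read from its first base in the reporter's frame and
# translation runs on into the vector until it meets a stop. The vector
# carries stop codons in all three frames, so termination is guaranteed
# whatever the insert length modulo 3.

#' Default vector tail downstream of the cloning site
#'
#' A short sequence containing a stop codon in each of the three reading
#' frames (`TAAGTAAGTAA`): frame 0 stops immediately, frames 1 and 2 read
#' through at most three junction codons before stopping. This mimics a
#' cloning vector designed to terminate every fusion.
#'
#' @return A nucleotide string.
#' @export
fusion_vector_tail <- function() "TAAGTAAGTAA"

#' Translate a cloned insert in the fusion reading frame
#'
#' Translates `insert_dna` from position 0 with the standard genetic code,
#' continuing into `vector_tail_dna`, and returns the peptide appended to
#' the reporter, up to (not including) the first stop codon. An insert with
#' an internal stop yields a peptide shorter than its length/3; an insert
#' whose length is not a multiple of 3 reads a junction codon spanning the
#' insert/vector boundary, as in the real fusion.
#'
#' @param insert_dna Nucleotide string over A/C/G/T (the cloned fragment,
#'   already oriented as inserted).
#' @param vector_tail_dna Vector sequence downstream of the insertion point;
#'   must contain a stop codon in each of the three frames. Defaults to
#'   [fusion_vector_tail()].
#' @return The appended peptide as a single string (possibly empty).
#' @export
#' @examples
#' translate_fusion("TTTAAATAG")           # "FK" (internal TAG stop)
#' translate_fusion("GTTGTACTGGTAGTCGTATTC") # "VVLVVVF"
translate_fusion <- function(insert_dna, vector_tail_dna = fusion_vector_tail()) {
  stopifnot(is.character(insert_dna), length(insert_dna) == 1,
            is.character(vector_tail_dna), length(vector_tail_dna) == 1)
  for (s in c(insert = insert_dna, vector_tail = vector_tail_dna)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad) > 0) {
      stop(sprintf("non-ACGT character '%s' at position %d", chars[bad[1]], bad[1]),
           call. = FALSE)
    }
  }
  if (!has_stop_all_frames(vector_tail_dna)) {
    stop("vector_tail_dna must contain a stop codon in all three frames",
         call. = FALSE)
  }
  full <- paste0(insert_dna, vector_tail_dna)
  n_codon <- nchar(full) %/% 3
  if (n_codon == 0) return("")
  codons <- substring(full, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) {
    # unreachable when the tail precondition holds; guard for odd tails
    stop("no stop codon encountered in fusion frame", call. = FALSE)
  }
  paste(aa[seq_len(stop_at[1] - 1)], collapse = "")
}

has_stop_all_frames <- function(dna) {
  stops <- c("TAA", "TAG", "TGA")
  all(vapply(0:2, function(off) {
    n <- (nchar(dna) - off) %/% 3
    if (n < 1) return(FALSE)
    codons <- substring(dna, off + 3 * seq_len(n) - 2, off + 3 * seq_len(n))
    any(codons %in% stops)
  }, logical(1)))
}
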