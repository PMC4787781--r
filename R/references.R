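#' Read and validate a reference set
#'
#' References are single-stranded, template-sense RNA or DNA sequences
#' (tRNA/rRNA-scale). `U` is normalized to `T` so that downstream base
#' accounting is in mapping (DNA) space; the admitted alphabet is
#' `A, C, G, T, N`.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] with unique ids.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "GAUUACA"), fa)
#' refs <- read_reference_fasta(fa)
#' as.character(refs)
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_reference_set(setNames(as.character(x), names(x)))
}

#' Coerce sequences to a validated reference set
#'
#' @param refs a named character vector or `DNAStringSet`.
#' @return a named [Biostrings::DNAStringSet].
#' @export
as_reference_set <- function(refs) {
  if (inherits(refs, "DNAStringSet")) {
    seqs <- as.character(refs)
  } else if (is.character(refs)) {
    seqs <- refs
  } else {
    stop("references must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("every reference sequence needs an id")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate reference ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(chartr("Uu", "Tt", seqs))
  if (any(nchar(seqs) == 0L)) stop("empty reference sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("reference ", names(seqs)[bad][1L],
         " contains characters outside {A,C,G,T,N,U}")
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write a reference set to FASTA
#'
#' @param refs reference set (see [as_reference_set()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  refs <- as_reference_set(refs)
  Biostrings::writeXStringSet(refs, path)
  invisible(path)
}

# single reference base lookup, 1-based; "-" outside the sequence
.ref_base_at <- function(refs, ref_id, pos) {
  s <- as.character(refs[[ref_id]])
  ifelse(pos >= 1L & pos <= nchar(s), substring(s, pos, pos), "-")
}
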