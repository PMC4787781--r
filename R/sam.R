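#' Read end-to-end alignments from a SAM file
#'
#' The file is converted to BAM with [Rsamtools::asBam()] and scanned; the
#' fields needed for profile construction (name, flag, reference, 1-based
#' leftmost position, CIGAR, sequence) are returned as a data frame. Only
#' global (end-to-end) alignments are admitted downstream: clipped CIGARs are
#' rejected by [build_profile()].
#'
#' @param path path to a SAM file with an `@SQ` header.
#' @return a data.frame with columns `qname, flag, ref_id, pos, cigar, seq`.
#' @seealso [write_sam()], [build_profile()]
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    ref_id = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
}

#' Write alignments to a SAM file
#'
#' Emits a minimal, valid SAM: `@HD`/`@SQ` header derived from the reference
#' set, one line per alignment, constant placeholder base qualities.
#'
#' @param alignments data.frame as returned by [read_sam()] or
#'   [simulate_reads()].
#' @param refs reference set the alignments refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path) {
  refs <- as_reference_set(refs)
  stopifnot(all(c("qname", "flag", "ref_id", "pos", "cigar", "seq") %in%
                  names(alignments)))
  unknown <- setdiff(unique(alignments$ref_id), names(refs))
  if (length(unknown)) {
    stop("alignments reference unknown sequence id(s): ",
         paste(unknown, collapse = ", "))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), Biostrings::width(refs)),
    "@PG\tID:rtsig\tPN:rtsig"
  )
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                  alignments$qname, alignments$flag, alignments$ref_id,
                  alignments$pos, alignments$cigar, alignments$seq,
                  strrep("I", nchar(alignments$seq)))
  writeLines(c(header, body), path)
  invisible(path)
}

# Expand an aligned read into reference space: one character per reference
# position covered, "-" for deletions; insertions consume query only and are
# dropped (no reference coordinate). Soft/hard clips and splice gaps violate
# the end-to-end alignment contract and raise an error.
.expand_to_refspace <- function(seq, cigar, qname = "") {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || sum(nchar(ops)) != nchar(cigar)) {
    stop("malformed CIGAR '", cigar, "' for read ", qname)
  }
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  if (any(op %in% c("S", "H"))) {
    stop("clipped alignment (CIGAR ", cigar, ") for read ", qname,
         ": only end-to-end alignments are admitted")
  }
  if (any(op %in% c("N", "P"))) {
    stop("unsupported CIGAR operation in '", cigar, "' for read ", qname)
  }
  out <- character(0)
  qpos <- 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      out <- c(out, substring(seq, qpos, qpos + n[i] - 1L))
      qpos <- qpos + n[i]
    } else if (op[i] == "I") {
      qpos <- qpos + n[i]
    } else if (op[i] == "D") {
      out <- c(out, strrep("-", n[i]))
    }
  }
  paste(out, collapse = "")
}
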