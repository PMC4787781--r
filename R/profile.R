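#' Build per-position RT profiles from alignments
#'
#' Accumulates, for every reference position, the coverage, the number of
#' reads starting there (= RT stops, since cDNA synthesis proceeds from high
#' to low template coordinates), base-call counts, the arrest rate and the
#' mismatch rate. The arrest rate at position p is the fraction of reads
#' covering p+1 whose leftmost aligned position is p+1, i.e. reads that end
#' one position 3' of p without covering p. The mismatch rate at p is the
#' share of non-reference A/C/G/T calls among all A/C/G/T calls at p; `N`
#' calls and deletions are excluded from both numerator and denominator.
#'
#' Reverse-strand alignments are skipped with a warning (libraries are
#' strand-preserving, template-sense); unmapped records are skipped silently;
#' an alignment to an unknown reference id is an error. Soft-clipped
#' alignments are rejected: the protocol maps end-to-end and clipping would
#' corrupt the read-start counts.
#'
#' @param refs reference set (see [as_reference_set()]).
#' @param alignments data.frame of alignments (see [read_sam()]) or a path to
#'   a SAM file.
#' @return a data.frame ("profile") with one row per reference position and
#'   columns `ref_id, pos, ref_base, coverage, start_count, A, C, G, T, N,
#'   DEL, arrest_rate, mismatch_rate, flags`. Undefined ratios (zero
#'   denominator) are reported as 0 and flagged (`arrest_undefined`,
#'   `mismatch_undefined`) so downstream filters can exclude them
#'   deterministically. Skip counts are attached as the `"skipped"` attribute.
#' @examples
#' refs <- c(r = "ACGTACGTAA")
#' aln <- data.frame(qname = "x", flag = 0L, ref_id = "r", pos = 3L,
#'                   cigar = "5M", seq = "GTACG")
#' build_profile(refs, aln)[3:7, c("pos", "coverage", "start_count")]
#' @export
build_profile <- function(refs, alignments) {
  refs <- as_reference_set(refs)
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam(alignments)
  }
  stopifnot(is.data.frame(alignments))
  need <- c("qname", "flag", "ref_id", "pos", "cigar", "seq")
  if (!all(need %in% names(alignments))) {
    stop("alignments must have columns: ", paste(need, collapse = ", "))
  }

  skipped <- c(unmapped = 0L, reverse_strand = 0L)
  if (nrow(alignments)) {
    unmapped <- bitwAnd(alignments$flag, 4L) != 0L
    skipped["unmapped"] <- sum(unmapped)
    alignments <- alignments[!unmapped, , drop = FALSE]
    rev <- bitwAnd(alignments$flag, 16L) != 0L
    if (any(rev)) {
      warning(sum(rev), " reverse-strand alignment(s) skipped")
      skipped["reverse_strand"] <- sum(rev)
      alignments <- alignments[!rev, , drop = FALSE]
    }
    unknown <- setdiff(unique(alignments$ref_id), names(refs))
    if (length(unknown)) {
      stop("alignment(s) to unknown reference id(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  rows <- lapply(names(refs), function(rid) {
    .profile_one_reference(refs, rid,
                           alignments[alignments$ref_id == rid, , drop = FALSE])
  })
  prof <- do.call(rbind, rows)
  rownames(prof) <- NULL
  attr(prof, "skipped") <- skipped
  prof
}

.profile_one_reference <- function(refs, rid, aln) {
  L <- nchar(as.character(refs[[rid]]))
  ref_bases <- strsplit(as.character(refs[[rid]]), "")[[1L]]

  counts <- matrix(0, nrow = 6L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "N", "DEL"), NULL))
  start_count <- integer(L)
  if (nrow(aln)) {
    simple <- grepl("^\\d+M$", aln$cigar)
    refspace <- aln$seq
    if (!all(simple)) {
      idx <- which(!simple)
      refspace[idx] <- mapply(.expand_to_refspace, aln$seq[idx],
                              aln$cigar[idx], aln$qname[idx])
    }
    span <- nchar(refspace)
    if (any(aln$pos < 1L) || any(aln$pos + span - 1L > L)) {
      bad <- which(aln$pos < 1L | aln$pos + span - 1L > L)[1L]
      stop("alignment ", aln$qname[bad], " extends outside reference ", rid)
    }
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(refspace),
                                      shift = aln$pos - 1L, width = L)
    for (b in c("A", "C", "G", "T", "N")) {
      if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
    }
    if ("-" %in% rownames(cm)) counts["DEL", ] <- cm["-", ]
    start_count <- tabulate(aln$pos, nbins = L)
  }

  coverage <- colSums(counts)
  acgt_total <- colSums(counts[c("A", "C", "G", "T"), , drop = FALSE])
  ref_idx <- match(ref_bases, c("A", "C", "G", "T"))
  match_count <- ifelse(is.na(ref_idx), NA_real_,
                        counts[cbind(ref_idx, seq_len(L))])

  mism_def <- acgt_total > 0 & !is.na(ref_idx)
  mismatch_rate <- ifelse(mism_def, (acgt_total - match_count) / acgt_total, 0)

  # a(p) = start_count(p+1) / coverage(p+1); undefined at p = L and where
  # coverage(p+1) = 0
  arrest_def <- c(coverage[-1L] > 0, FALSE)
  arrest_rate <- ifelse(arrest_def,
                        c(start_count[-1L], 0) / pmax(c(coverage[-1L], 0), 1),
                        0)

  flags <- character(L)
  flags[!arrest_def] <- "arrest_undefined"
  flags[!mism_def] <- paste0(ifelse(nzchar(flags[!mism_def]),
                                    paste0(flags[!mism_def], ","), ""),
                             "mismatch_undefined")

  data.frame(
    ref_id = rid, pos = seq_len(L), ref_base = ref_bases,
    coverage = as.integer(coverage),
    start_count = as.integer(start_count),
    A = as.integer(counts["A", ]), C = as.integer(counts["C", ]),
    G = as.integer(counts["G", ]), T = as.integer(counts["T", ]),
    N = as.integer(counts["N", ]), DEL = as.integer(counts["DEL", ]),
    arrest_rate = as.numeric(arrest_rate),
    mismatch_rate = as.numeric(mismatch_rate),
    flags = flags,
    stringsAsFactors = FALSE
  )
}

.profile_rows <- function(profile, ref_id, pos) {
  i <- which(profile$ref_id == ref_id & profile$pos %in% pos)
  if (length(i) != length(pos)) {
    stop("position(s) ", paste(setdiff(pos, profile$pos[i]), collapse = ", "),
         " not present in the profile for reference ", ref_id)
  }
  profile[i[order(profile$pos[i])][match(pos, sort(profile$pos[i]))], ,
          drop = FALSE]
}

#' Arrest rate at a position
#'
#' Recomputes a(p) = start_count(p+1) / coverage(p+1) from the profile: the
#' fraction of reads covering p+1 that end at p+1 (do not cover p). Reads are
#' template-sense; the RT stop is the read's leftmost reference coordinate.
#'
#' @param profile a profile from [build_profile()].
#' @param ref_id reference id.
#' @param p 1-based position, `1 <= p <= reference length - 1`.
#' @return list with `value` (0 when undefined) and `defined` (FALSE when no
#'   read covers p+1).
#' @export
arrest_rate <- function(profile, ref_id, p) {
  stopifnot(length(p) == 1L, p >= 1L)
  L <- max(profile$pos[profile$ref_id == ref_id])
  if (p > L - 1L) stop("p must be at most reference length - 1")
  r <- .profile_rows(profile, ref_id, p + 1L)
  if (r$coverage == 0L) {
    list(value = 0, defined = FALSE)
  } else {
    list(value = r$start_count / r$coverage, defined = TRUE)
  }
}

#' Mismatch rate and composition at a position
#'
#' m(p) is the share of non-reference base calls among A/C/G/T calls at p;
#' the composition gives each non-reference base's share of the mismatched
#' calls (all zero when there are none). `N` calls and deletions are excluded
#' throughout. For a reference adenosine the composition is reported over
#' (G, T, C), the template-sense order used by the classifier features.
#'
#' @inheritParams arrest_rate
#' @return list with `m`, `composition` (named over the three non-reference
#'   bases) and `defined` (FALSE when there are no A/C/G/T calls at p).
#' @export
mismatch_stats <- function(profile, ref_id, p) {
  r <- .profile_rows(profile, ref_id, p)
  ref <- r$ref_base
  if (!ref %in% .base_alphabet) {
    stop("reference base at ", ref_id, ":", p, " is ", ref,
         "; mismatch statistics require A, C, G or T")
  }
  others <- c(setdiff(c("G", "T", "C"), ref), setdiff("A", ref))
  others <- others[others != ref]
  cnt <- unlist(r[, .base_alphabet])
  total <- sum(cnt)
  if (total == 0L) {
    return(list(m = 0, composition = setNames(numeric(length(others)), others),
                defined = FALSE))
  }
  mm <- total - cnt[[ref]]
  comp <- if (mm > 0) cnt[others] / mm else setNames(numeric(length(others)), others)
  list(m = mm / total, composition = setNames(as.numeric(comp), others),
       defined = TRUE)
}
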