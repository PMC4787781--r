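.profile_columns <- c("ref_id", "pos", "ref_base", "coverage", "start_count",
                      "A", "C", "G", "T", "N", "DEL",
                      "arrest_rate", "mismatch_rate", "flags")

# fractions are serialized with 17 significant digits so that the TSV round
# trip is lossless (doubles re-parse to identical bit patterns)
.fmt_frac <- function(x) sprintf("%.17g", x)

#' Write a profile table to TSV
#'
#' Tab-separated with a header line; fractions are written at full precision
#' so `read_profile(write_profile(x))` is lossless and re-serialization is
#' byte-identical. Flags are comma-separated tokens, empty when none.
#'
#' @param profile profile data.frame from [build_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  out <- profile[, .profile_columns]
  out$arrest_rate <- .fmt_frac(profile$arrest_rate)
  out$mismatch_rate <- .fmt_frac(profile$mismatch_rate)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile table from TSV
#'
#' @param path path written by [write_profile()].
#' @return the profile data.frame; malformed rows raise an error naming the
#'   offending line.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(ref_id = "character", ref_base = "character",
                                 flags = "character"))
  if (!identical(names(x), .profile_columns)) {
    stop("unexpected profile header: ", paste(names(x), collapse = ", "))
  }
  x$flags[is.na(x$flags)] <- ""
  validate_profile(x, lines = seq_len(nrow(x)) + 1L)
  x
}

#' Validate profile invariants
#'
#' Checks that base counts sum to coverage, counts are non-negative and rates
#' lie in \[0, 1\].
#'
#' @param profile profile data.frame.
#' @param lines optional file line numbers used in error messages.
#' @return `profile`, invisibly.
#' @export
validate_profile <- function(profile, lines = NULL) {
  if (!all(.profile_columns %in% names(profile))) {
    stop("profile lacks column(s): ",
         paste(setdiff(.profile_columns, names(profile)), collapse = ", "))
  }
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  counts <- as.matrix(profile[, c("A", "C", "G", "T", "N", "DEL")])
  bad <- which(profile$coverage < 0 | profile$start_count < 0 |
                 apply(counts < 0, 1L, any))
  if (length(bad)) stop("negative count at ", where(bad[1L]))
  bad <- which(rowSums(counts) != profile$coverage)
  if (length(bad)) {
    stop("base counts do not sum to coverage at ", where(bad[1L]))
  }
  bad <- which(profile$arrest_rate < 0 | profile$arrest_rate > 1 |
                 profile$mismatch_rate < 0 | profile$mismatch_rate > 1)
  if (length(bad)) stop("rate outside [0, 1] at ", where(bad[1L]))
  invisible(profile)
}
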