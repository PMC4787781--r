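#' Context-sensitive arrest rate (CSA)
#'
#' Fold change of a site's arrest rate relative to the mean arrest rate in
#' its -5..+5 neighborhood (center excluded, window truncated at reference
#' boundaries). Excluding the center prevents a strong site from damping its
#' own fold change. Neighbors with an undefined arrest rate are ignored; if
#' the neighborhood mean is 0 the ratio is guarded with epsilon = 1e-3 and
#' flagged; if no neighbor is defined the CSA is 0 and flagged.
#'
#' @inheritParams arrest_rate
#' @param window half-width of the neighborhood (default 5).
#' @return list with `value`, `defined` and `flag` ("" or one of
#'   `csa_eps_guard`, `csa_no_neighborhood`).
#' @export
csa <- function(profile, ref_id, p, window = 5L) {
  prof <- profile[profile$ref_id == ref_id, , drop = FALSE]
  if (!nrow(prof)) stop("reference ", ref_id, " not present in profile")
  L <- max(prof$pos)
  stopifnot(p >= 1L, p <= L)
  a_def <- !grepl("arrest_undefined", prof$flags)
  a <- prof$arrest_rate[order(prof$pos)]
  a_def <- a_def[order(prof$pos)]

  nb <- setdiff(max(1L, p - window):min(L, p + window), p)
  nb <- nb[a_def[nb]]
  a_p <- if (p <= L && a_def[p]) a[p] else 0
  if (!length(nb)) {
    return(list(value = 0, defined = FALSE, flag = "csa_no_neighborhood"))
  }
  mu <- mean(a[nb])
  if (mu == 0) {
    list(value = a_p / .rtsig_eps, defined = TRUE, flag = "csa_eps_guard")
  } else {
    list(value = a_p / mu, defined = TRUE, flag = "")
  }
}

#' Extract per-adenosine signature records
#'
#' One record per reference adenosine passing the coverage filters
#' (`coverage >= min_cov` at the site and `coverage >= min_cov_3prime` at the
#' 3'-adjacent position p+1, where arrest manifests). Each record carries the
#' classifier feature set: arrest rate `a`, mismatch rate `m`, mismatch
#' composition (`comp_G`, `comp_T`, `comp_C`), `m_over_a` (epsilon-guarded
#' when a = 0), the context-sensitive arrest rate `csa`, plus the reference
#' context bases at -1/+1/+2 ("-" beyond the boundary) and the two coverages.
#'
#' @param profile profile from [build_profile()].
#' @param refs the reference set the profile was built over.
#' @param min_cov minimum coverage at the site (default 10).
#' @param min_cov_3prime minimum coverage at p+1 (default 15).
#' @param csa_window neighborhood half-width for [csa()].
#' @return data.frame of signature records with `label = "unknown"`; possibly
#'   zero rows.
#' @export
extract_signatures <- function(profile, refs, min_cov = 10L,
                               min_cov_3prime = 15L, csa_window = 5L) {
  refs <- as_reference_set(refs)
  recs <- lapply(names(refs), function(rid) {
    prof <- profile[profile$ref_id == rid, , drop = FALSE]
    if (!nrow(prof)) return(NULL)
    prof <- prof[order(prof$pos), , drop = FALSE]
    L <- nrow(prof)
    cov3 <- c(prof$coverage[-1L], 0L)
    keep <- which(prof$ref_base == "A" & prof$coverage >= min_cov &
                    cov3 >= min_cov_3prime & prof$pos < L)
    if (!length(keep)) return(NULL)
    do.call(rbind, lapply(keep, function(i) {
      p <- prof$pos[i]
      a <- prof$arrest_rate[i]
      ms <- mismatch_stats(prof, rid, p)
      cs <- csa(prof, rid, p, window = csa_window)
      data.frame(
        ref_id = rid, pos = p,
        a = a, m = ms$m,
        comp_G = ms$composition[["G"]],
        comp_T = ms$composition[["T"]],
        comp_C = ms$composition[["C"]],
        m_over_a = if (a > 0) ms$m / a else ms$m / .rtsig_eps,
        csa = cs$value,
        minus1 = .ref_base_at(refs, rid, p - 1L),
        plus1 = .ref_base_at(refs, rid, p + 1L),
        plus2 = .ref_base_at(refs, rid, p + 2L),
        coverage = prof$coverage[i], coverage_3p = cov3[i],
        label = "unknown",
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), pos = integer(), a = numeric(),
                      m = numeric(), comp_G = numeric(), comp_T = numeric(),
                      comp_C = numeric(), m_over_a = numeric(),
                      csa = numeric(), minus1 = character(),
                      plus1 = character(), plus2 = character(),
                      coverage = integer(), coverage_3p = integer(),
                      label = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Label signature records from a site annotation table
#'
#' @param signatures data.frame from [extract_signatures()].
#' @param sites annotation data.frame with `ref_id`, `pos` and `label`
#'   (`"m1A"` / `"non_m1A"`); any further columns (e.g. `rna_class`,
#'   `isotype`, `replicate`) are merged in as grouping keys.
#' @param default_label label for unannotated records (default `"non_m1A"`:
#'   unannotated adenosines are presumed unmodified).
#' @return the signature data.frame with labels (and extra columns) attached.
#' @export
label_signatures <- function(signatures, sites, default_label = "non_m1A") {
  stopifnot(all(c("ref_id", "pos", "label") %in% names(sites)))
  signatures$label <- NULL
  out <- merge(signatures, sites, by = c("ref_id", "pos"), all.x = TRUE,
               sort = FALSE)
  out$label[is.na(out$label)] <- default_label
  out
}

#' Confusable-negative rule
#'
#' A non-m1A record resembles an m1A signature (and so qualifies as a
#' "confusable" negative for the stringent validation setting) iff its arrest
#' rate is at least 0.2, or its mismatch rate is at least 0.2, or its
#' mismatch rate is at least 0.1 with at least two mismatch types holding a
#' share of at least 0.1.
#'
#' @param rec data.frame of signature records (vectorized over rows).
#' @param a_min,m_min,m_min_two,share_min the four thresholds (defaults 0.2,
#'   0.2, 0.1, 0.1).
#' @return logical vector.
#' @export
is_confusable_negative <- function(rec, a_min = 0.2, m_min = 0.2,
                                   m_min_two = 0.1, share_min = 0.1) {
  two_types <- (rec$comp_G >= share_min) + (rec$comp_T >= share_min) +
    (rec$comp_C >= share_min) >= 2L
  rec$a >= a_min | rec$m >= m_min | (rec$m >= m_min_two & two_types)
}

.signature_features <- c("a", "m", "m_over_a", "comp_G", "comp_T", "comp_C",
                         "csa")

#' Average signature records within groups
#'
#' Arithmetic mean of every numeric feature within each group defined by the
#' `by` columns (`by = character(0)` averages everything into one record).
#' Used hierarchically: replicates first, then isotypes, then the final mean,
#' so that over-represented groups do not dominate — the final mean is the
#' mean of group means, not the pooled mean.
#'
#' @param records signature data.frame.
#' @param by character vector of grouping column names.
#' @param features numeric columns to average (defaults to the classifier
#'   feature set plus coverages when present).
#' @return data.frame with one row per group: grouping keys, feature means,
#'   per-feature standard deviations (`sd_*`) and the group size `n_averaged`.
#'   Context-base columns are retained when constant within a group, else NA
#'   with a warning.
#' @export
average_signatures <- function(records, by,
                               features = intersect(
                                 c(.signature_features, "coverage",
                                   "coverage_3p"), names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (length(by) && !all(by %in% names(records))) {
    stop("grouping column(s) missing: ",
         paste(setdiff(by, names(records)), collapse = ", "))
  }
  key <- if (length(by)) {
    interaction(records[by], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(records)))
  }
  ctx <- intersect(c("minus1", "plus1", "plus2", "label"), names(records))
  groups <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(groups, function(i) {
    g <- records[i, , drop = FALSE]
    row <- if (length(by)) g[1L, by, drop = FALSE] else
      data.frame(row.names = 1L)
    for (f in features) row[[f]] <- mean(g[[f]])
    for (f in features) row[[paste0("sd_", f)]] <- if (length(i) > 1L)
      sd(g[[f]]) else 0
    for (cc in ctx) {
      u <- unique(g[[cc]])
      if (length(u) > 1L) {
        warning("column ", cc, " not constant within a group; set to NA")
        row[[cc]] <- NA_character_
      } else {
        row[[cc]] <- u
      }
    }
    row$n_averaged <- length(i)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a signature table
#'
#' Plain TSV with a header; fractions at full precision (lossless round
#' trip).
#'
#' @param signatures signature data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_signatures <- function(signatures, path) {
  out <- signatures
  for (f in intersect(c(.signature_features), names(out))) {
    out[[f]] <- .fmt_frac(out[[f]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(ref_id = "character"))
  for (cc in intersect(c("minus1", "plus1", "plus2", "label"), names(x))) {
    x[[cc]] <- as.character(x[[cc]])
  }
  x
}
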