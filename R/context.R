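#' Ternary-plot coordinates of a mismatch composition
#'
#' Maps (G, T, C) shares onto the unit triangle with corners G = (0, 0),
#' T = (1, 0), C = (0.5, sqrt(3)/2): x = T + C/2, y = C * sqrt(3)/2. The
#' corner assignment is a plotting convention, recorded in the attributes.
#'
#' @param composition numeric vector `c(G, T, C)` or a matrix/data.frame with
#'   columns `comp_G`, `comp_T`, `comp_C` (rows summing to 1).
#' @return a matrix with columns `x`, `y`.
#' @export
ternary_coords <- function(composition) {
  m <- .comp_matrix(composition)
  if (any(abs(rowSums(m) - 1) > 1e-6) || any(m < -1e-12)) {
    stop("compositions must be non-negative and sum to 1")
  }
  out <- cbind(x = m[, 2L] + m[, 3L] / 2, y = m[, 3L] * sqrt(3) / 2)
  attr(out, "corners") <- c(G = "(0,0)", T = "(1,0)", C = "(0.5,sqrt(3)/2)")
  out
}

#' Invert ternary coordinates back to a composition
#'
#' @param xy matrix with columns `x`, `y` as produced by [ternary_coords()].
#' @return matrix with columns `G`, `T`, `C`.
#' @export
ternary_invert <- function(xy) {
  xy <- rbind(xy)
  C <- 2 * xy[, 2L] / sqrt(3)
  T_ <- xy[, 1L] - C / 2
  cbind(G = 1 - T_ - C, T = T_, C = C)
}

.comp_matrix <- function(composition) {
  if (is.null(dim(composition))) {
    matrix(composition, nrow = 1L, dimnames = list(NULL, c("G", "T", "C")))
  } else {
    cols <- if (all(c("comp_G", "comp_T", "comp_C") %in% colnames(composition)))
      c("comp_G", "comp_T", "comp_C") else c("G", "T", "C")
    as.matrix(as.data.frame(composition)[, cols])
  }
}

#' Reduce signature records to non-redundant context instances
#'
#' Three sequential averaging steps mirror how over-represented sequence
#' contexts are collapsed before context analysis: (1) experimental
#' replicates of the same site (`ref_id`, `pos`) are averaged; (2) records
#' from references of over 95% global-alignment sequence identity are merged
#' (single-linkage components of the identity graph), so e.g. near-identical
#' tRNA sequence variants count once; (3) records with identical
#' (-1, +1, +2) context triples are averaged into one instance per context.
#' Records whose reference sequence is unavailable pass through step 2
#' unmerged with a warning. Applying the reduction to an already reduced set
#' changes nothing.
#'
#' @param records signature data.frame (needs `comp_G/T/C`, `minus1`,
#'   `plus1`, `plus2`; `ref_id`/`pos` used for steps 1-2).
#' @param ref_seqs optional reference set supplying sequences for step 2.
#' @param identity_threshold merge threshold on pairwise identity (default
#'   0.95).
#' @return data.frame of context instances: context triple, averaged
#'   compositions and features, ternary coordinates, `n_sources` and
#'   `provenance` (merged site ids).
#' @export
reduce_instances <- function(records, ref_seqs = NULL,
                             identity_threshold = 0.95) {
  stopifnot(nrow(records) > 0L)
  if ("provenance" %in% names(records)) {
    # already reduced once: only the context-collapsing step can apply
    return(.reduce_by_context(records))
  }
  feats <- intersect(c(.signature_features), names(records))

  # (1) replicate averaging per site
  key <- paste(records$ref_id, records$pos, sep = ":")
  step1 <- do.call(rbind, lapply(split(seq_len(nrow(records)), key),
                                 function(i) {
    g <- records[i, , drop = FALSE]
    row <- g[1L, c("ref_id", "pos", "minus1", "plus1", "plus2"),
             drop = FALSE]
    for (f in feats) row[[f]] <- mean(g[[f]])
    row$provenance <- paste(unique(paste(g$ref_id, g$pos, sep = ":")),
                            collapse = "|")
    row$n_sources <- nrow(g)
    row
  }))

  # (2) merge across near-identical references
  if (!is.null(ref_seqs)) {
    ref_seqs <- as_reference_set(ref_seqs)
    ids <- unique(step1$ref_id)
    known <- ids[ids %in% names(ref_seqs)]
    if (length(known) < length(ids)) {
      warning(length(ids) - length(known),
              " reference(s) without sequence pass step 2 unmerged")
    }
    comp <- .identity_components(ref_seqs[known], identity_threshold)
    grp <- setNames(paste0("component_", comp), known)
    gkey <- ifelse(step1$ref_id %in% known, grp[step1$ref_id], step1$ref_id)
    step1 <- do.call(rbind, lapply(split(seq_len(nrow(step1)), gkey),
                                   function(i) {
      g <- step1[i, , drop = FALSE]
      row <- g[1L, , drop = FALSE]
      for (f in feats) row[[f]] <- mean(g[[f]])
      for (cc in c("minus1", "plus1", "plus2")) {
        u <- unique(g[[cc]])
        if (length(u) > 1L) {
          warning("context base ", cc, " disagrees within an identity group; ",
                  "majority taken")
          row[[cc]] <- names(sort(table(g[[cc]]), decreasing = TRUE))[1L]
        }
      }
      row$ref_id <- paste(unique(g$ref_id), collapse = "|")
      row$provenance <- paste(g$provenance, collapse = "|")
      row$n_sources <- sum(g$n_sources)
      row
    }))
  }

  .reduce_by_context(step1)
}

.reduce_by_context <- function(x) {
  feats <- intersect(.signature_features, names(x))
  key <- paste(x$minus1, x$plus1, x$plus2, sep = "")
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), key), function(i) {
    g <- x[i, , drop = FALSE]
    row <- g[1L, c("minus1", "plus1", "plus2"), drop = FALSE]
    for (f in feats) row[[f]] <- mean(g[[f]])
    row$provenance <- if ("provenance" %in% names(g)) {
      paste(g$provenance, collapse = "|")
    } else {
      paste(paste(g$ref_id, g$pos, sep = ":"), collapse = "|")
    }
    row$n_sources <- if ("n_sources" %in% names(g)) sum(g$n_sources) else
      nrow(g)
    row
  }))
  rownames(out) <- NULL
  csum <- out$comp_G + out$comp_T + out$comp_C
  ok <- csum > 0
  out$tern_x <- NA_real_
  out$tern_y <- NA_real_
  if (any(ok)) {
    norm <- cbind(out$comp_G, out$comp_T, out$comp_C)[ok, , drop = FALSE] /
      csum[ok]
    xy <- ternary_coords(`colnames<-`(norm, c("G", "T", "C")))
    out$tern_x[ok] <- xy[, "x"]
    out$tern_y[ok] <- xy[, "y"]
  }
  out
}

# single-linkage components of the >threshold identity graph (union-find)
.identity_components <- function(refs, threshold) {
  n <- length(refs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (seq_identity(refs[[i]], refs[[j]]) > threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (end gaps penalized); identity is the
#' number of matching columns divided by the alignment length.
#'
#' @param s1,s2 sequences (character or `DNAString`).
#' @return identity in \[0, 1\].
#' @export
seq_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(s1)),
    Biostrings::DNAString(as.character(s2)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  gapped <- as.character(Biostrings::alignedPattern(aln))
  Biostrings::nmatch(aln) / nchar(gapped)
}

#' Hierarchical clustering of context instances
#'
#' Agglomerative clustering (average linkage, euclidean metric) over the
#' mismatch-composition vectors.
#'
#' @param instances data.frame from [reduce_instances()] (or any table with
#'   `comp_G/T/C`).
#' @param k number of flat clusters to cut (default 4, one per +1 base).
#' @return list with `hclust`, `clusters` (integer assignment) and the
#'   distance matrix.
#' @export
cluster_by_context <- function(instances, k = 4L) {
  stopifnot(nrow(instances) >= 2L)
  m <- as.matrix(instances[, c("comp_G", "comp_T", "comp_C")])
  d <- dist(m)
  hc <- hclust(d, method = "average")
  list(hclust = hc, clusters = cutree(hc, k = min(k, nrow(instances))),
       dist = d)
}

#' Permutation test for context-group separation
#'
#' Statistic S = (mean between-group pairwise distance) - (mean within-group
#' pairwise distance) over the composition vectors; groups with fewer than
#' two members contribute no within-group pairs and are noted. The p-value is
#' the add-one-smoothed fraction of label permutations with a statistic at
#' least as large as observed. This test stands in for the original
#' verification procedure of the clustering, whose exact statistic is not
#' public; reports label it accordingly.
#'
#' @param instances table with `comp_G/T/C`.
#' @param grouping group labels (default: the `plus1` column).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `statistic`, `p_value`, `n_perm`, `groups`,
#'   `small_groups` (excluded from the within term) and `note`.
#' @export
separation_test <- function(instances, grouping = instances$plus1,
                            n_perm = 999L, seed = 1L) {
  m <- as.matrix(instances[, c("comp_G", "comp_T", "comp_C")])
  g <- as.character(grouping)
  stopifnot(nrow(m) == length(g), nrow(m) >= 3L)
  if (length(unique(g)) < 2L) stop("need at least two groups")
  D <- as.matrix(dist(m))
  stat <- function(g) {
    same <- outer(g, g, "==")
    ut <- upper.tri(D)
    w <- D[ut & same]
    b <- D[ut & !same]
    if (!length(w) || !length(b)) return(NA_real_)
    mean(b) - mean(w)
  }
  s_obs <- stat(g)
  if (is.na(s_obs)) stop("no within-group or no between-group pairs")
  set.seed(seed)
  s_perm <- vapply(seq_len(n_perm), function(i) stat(sample(g)), 0)
  small <- names(which(table(g) < 2L))
  list(statistic = s_obs,
       p_value = (1 + sum(s_perm >= s_obs, na.rm = TRUE)) / (n_perm + 1),
       n_perm = n_perm,
       groups = table(g),
       small_groups = small,
       note = paste("in-house permutation test for cluster separation;",
                    "not the original published verification procedure"))
}

#' Pairwise Levenshtein distance matrix
#'
#' Unit-cost edit distance between all reference pairs; low distances flag
#' reference pairs (typically tRNA isoacceptors) between which reads are at
#' risk of mismapping.
#'
#' @param refs reference set (at least 2 sequences).
#' @return symmetric integer matrix with zero diagonal, ids as dimnames.
#' @export
levenshtein_matrix <- function(refs) {
  refs <- as_reference_set(refs)
  if (length(refs) < 2L) stop("need at least two references")
  s <- as.character(refs)
  m <- adist(s)
  dimnames(m) <- list(names(refs), names(refs))
  storage.mode(m) <- "integer"
  m
}
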