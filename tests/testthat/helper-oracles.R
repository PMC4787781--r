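# Independent oracles, deliberately written with naive per-read loops and
# plain recursion so they share no code path with the package.

# Brute-force profile oracle: walks every read position by position.
oracle_profile <- function(refs, aln) {
  refs <- as.character(rtsig::as_reference_set(refs))
  out <- list()
  for (rid in names(refs)) {
    L <- nchar(refs[[rid]])
    counts <- matrix(0L, nrow = L, ncol = 6,
                     dimnames = list(NULL, c("A", "C", "G", "T", "N", "DEL")))
    starts <- integer(L)
    rows <- which(aln$ref_id == rid & bitwAnd(aln$flag, 4L) == 0L &
                    bitwAnd(aln$flag, 16L) == 0L)
    for (i in rows) {
      # parse cigar with a dumb character scan
      cig <- aln$cigar[i]
      num <- ""
      refpos <- aln$pos[i]
      qpos <- 1L
      starts[aln$pos[i]] <- starts[aln$pos[i]] + 1L
      for (ch in strsplit(cig, "")[[1]]) {
        if (ch %in% as.character(0:9)) {
          num <- paste0(num, ch)
        } else {
          n <- as.integer(num)
          num <- ""
          if (ch %in% c("M", "=", "X")) {
            for (k in seq_len(n)) {
              b <- substr(aln$seq[i], qpos, qpos)
              counts[refpos, b] <- counts[refpos, b] + 1L
              refpos <- refpos + 1L
              qpos <- qpos + 1L
            }
          } else if (ch == "I") {
            qpos <- qpos + n
          } else if (ch == "D") {
            for (k in seq_len(n)) {
              counts[refpos, "DEL"] <- counts[refpos, "DEL"] + 1L
              refpos <- refpos + 1L
            }
          }
        }
      }
    }
    coverage <- rowSums(counts)
    out[[rid]] <- data.frame(ref_id = rid, pos = seq_len(L),
                             coverage = as.integer(coverage),
                             start_count = starts,
                             A = counts[, "A"], C = counts[, "C"],
                             G = counts[, "G"], T = counts[, "T"],
                             N = counts[, "N"], DEL = counts[, "DEL"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exponential-time recursive Levenshtein (no DP table).
oracle_levenshtein <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(oracle_levenshtein(substr(a, 2, nchar(a)), b) + 1L,
      oracle_levenshtein(a, substr(b, 2, nchar(b))) + 1L,
      oracle_levenshtein(substr(a, 2, nchar(a)),
                         substr(b, 2, nchar(b))) + cost)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random small alignment instance; some reads carry D/I cigars.
random_alignment_instance <- function(max_reads = 50L, max_len = 100L) {
  L <- sample(20:max_len, 1)
  refs <- c(ref = random_dna(L))
  n <- sample(1:max_reads, 1)
  aln <- do.call(rbind, lapply(seq_len(n), function(i) {
    span <- sample(3:min(15L, L), 1)
    pos <- sample(seq_len(L - span + 1L), 1)
    kind <- sample(c("M", "D", "I"), 1, prob = c(0.7, 0.15, 0.15))
    if (kind == "M" || span < 5L) {
      cigar <- paste0(span, "M")
      seq <- random_dna(span)
    } else if (kind == "D") {
      d <- sample(1:2, 1)
      left <- sample(seq_len(span - d - 1L), 1)
      right <- span - d - left
      cigar <- sprintf("%dM%dD%dM", left, d, right)
      seq <- random_dna(left + right)
    } else {
      ins <- sample(1:2, 1)
      left <- sample(seq_len(span - 1L), 1)
      right <- span - left
      cigar <- sprintf("%dM%dI%dM", left, ins, right)
      seq <- random_dna(span + ins)
    }
    data.frame(qname = paste0("r", i), flag = 0L, ref_id = "ref",
               pos = pos, cigar = cigar, seq = seq,
               stringsAsFactors = FALSE)
  }))
  list(refs = refs, aln = aln)
}

# Minimal labeled dataset with well-separated or overlapping classes.
toy_dataset <- function(n_pos = 20L, n_neg = 20L, sep = 0.9, noise = 0.0,
                        seed = 1L) {
  set.seed(seed)
  mk <- function(n, a, m) {
    data.frame(
      a = pmin(1, pmax(0, a + rnorm(n, 0, noise))),
      m = pmin(1, pmax(0, m + rnorm(n, 0, noise))),
      m_over_a = pmin(1, pmax(0, m + rnorm(n, 0, noise))) /
        pmax(1e-3, a + rnorm(n, 0, noise)),
      comp_G = rep(1 / 3, n), comp_T = rep(1 / 3, n),
      comp_C = rep(1 / 3, n),
      csa = pmax(0, a * 10 + rnorm(n, 0, noise * 10))
    )
  }
  pos <- mk(n_pos, sep, sep)
  pos$label <- "m1A"
  neg <- mk(n_neg, 0.02, 0.02)
  neg$label <- "non_m1A"
  out <- rbind(pos, neg)
  class(out) <- c("rt_dataset", "data.frame")
  out
}
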