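#' Default misincorporation presets keyed by the +1 base
#'
#' Template-sense base distribution emitted at a modified site upon
#' read-through. The presets follow the qualitative clustering of natural
#' m1A sites by their 3'-neighbor: a +1 uridine (T in mapping space) drives a
#' strongly T-dominated signal (efficient dATP misincorporation); +1 G and
#' +1 A give mixed G/T signals with a low C share; +1 C gives a high C and
#' low T share. An A component is retained throughout because the RT
#' occasionally incorporates the correct dTTP even opposite m1A. Exact values
#' are free parameters of the simulator, not measured constants.
#'
#' @param plus1 the +1 base, one of `"A", "C", "G", "T"`.
#' @return named probability vector over A, C, G, T (sums to 1).
#' @export
misinc_preset <- function(plus1) {
  presets <- list(
    T = c(A = 0.10, C = 0.05, G = 0.15, T = 0.70),
    G = c(A = 0.15, C = 0.05, G = 0.45, T = 0.35),
    A = c(A = 0.15, C = 0.05, G = 0.35, T = 0.45),
    C = c(A = 0.15, C = 0.45, G = 0.25, T = 0.15)
  )
  if (!plus1 %in% names(presets)) stop("no misincorporation preset for +1 = ", plus1)
  presets[[plus1]]
}

#' Describe a simulated m1A site
#'
#' @param ref_id reference id.
#' @param position 1-based site position on the reference.
#' @param occupancy fraction of molecules modified at the site, in \[0, 1\].
#' @param p_arrest probability that the RT terminates when it meets a
#'   modified residue (read ends at position + 1).
#' @param misinc read-through emission distribution over A, C, G, T
#'   (template-sense). `NULL` selects the [misinc_preset()] for the
#'   reference's +1 base at simulation time.
#' @return a `sim_site` list.
#' @export
sim_site <- function(ref_id, position, occupancy = 1, p_arrest = 0.85,
                     misinc = NULL) {
  stopifnot(occupancy >= 0, occupancy <= 1, p_arrest >= 0, p_arrest <= 1,
            position >= 1)
  if (!is.null(misinc)) {
    stopifnot(identical(sort(names(misinc)), c("A", "C", "G", "T")))
    if (abs(sum(misinc) - 1) > 1e-9) stop("misinc must sum to 1")
  }
  structure(list(ref_id = ref_id, position = as.integer(position),
                 occupancy = occupancy, p_arrest = p_arrest, misinc = misinc),
            class = "sim_site")
}

#' Simulator configuration
#'
#' @param seed integer seed (mandatory; the whole simulation is reproducible
#'   from it).
#' @param depth target number of reads per reference.
#' @param sites list of [sim_site()] descriptions.
#' @param frag_len_range fragment size-selection window in nt (default
#'   c(50, 150), the excised band of the library protocol).
#' @param error_rate per-base background substitution probability, uniform
#'   over the three alternatives (default 0.001).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, depth = 5000L, sites = list(),
                       frag_len_range = c(50L, 150L), error_rate = 0.001) {
  stopifnot(is.numeric(seed), length(seed) == 1L, depth > 0,
            length(frag_len_range) == 2L,
            frag_len_range[1] >= 1, frag_len_range[1] <= frag_len_range[2],
            error_rate >= 0, error_rate < 1)
  if (inherits(sites, "sim_site")) sites <- list(sites)
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 sites = sites,
                 frag_len_range = as.integer(frag_len_range),
                 error_rate = error_rate),
            class = "sim_config")
}

#' Read a simulator configuration from YAML
#'
#' Schema: top-level keys `seed` (mandatory), `depth`, `frag_len_range`
#' (2-element list), `error_rate`, and `sites`, a list of mappings with
#' `ref_id`, `position`, `occupancy`, `p_arrest` and optional `misinc`
#' (mapping with keys A/C/G/T).
#'
#' @param path YAML file path.
#' @return a [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("simulator config must set a seed")
  sites <- lapply(y$sites, function(s) {
    sim_site(s$ref_id, s$position,
             occupancy = if (is.null(s$occupancy)) 1 else s$occupancy,
             p_arrest = if (is.null(s$p_arrest)) 0.85 else s$p_arrest,
             misinc = if (is.null(s$misinc)) NULL else unlist(s$misinc))
  })
  sim_config(seed = y$seed,
             depth = if (is.null(y$depth)) 5000L else y$depth,
             sites = sites,
             frag_len_range = if (is.null(y$frag_len_range)) c(50L, 150L)
               else unlist(y$frag_len_range),
             error_rate = if (is.null(y$error_rate)) 0.001 else y$error_rate)
}

#' Simulate template-sense reads with m1A signatures
#'
#' Generative model, per molecule: a fragment is drawn with its 3' end
#' uniform over the reference and its length uniform over the size-selection
#' window, clipped at the 5' boundary; fragments shorter than the window
#' minimum are discarded (size selection). The molecule is modified at each
#' covered site independently with probability `occupancy`. cDNA synthesis
#' walks the fragment from its 3' end (highest reference coordinate) toward
#' the 5' end; at a modified site the RT terminates with probability
#' `p_arrest`, leaving a read whose leftmost reference position is site + 1;
#' on read-through the base emitted at the site is drawn from the site's
#' misincorporation distribution. Every other emitted base is the reference
#' base, flipped uniformly to one of the other three with probability
#' `error_rate`. Reads are reported as forward-strand end-to-end alignments,
#' so no mapper is involved and the truth is exact.
#'
#' @param refs reference set.
#' @param config a [sim_config()].
#' @return list of class `rt_sim` with `alignments` (data.frame as in
#'   [read_sam()]), `truth` (one row per site: ref_id, pos, occupancy,
#'   p_arrest, misinc_A..misinc_T), `refs` and `config`. Outputs are
#'   byte-reproducible from the seed.
#' @export
simulate_reads <- function(refs, config) {
  refs <- as_reference_set(refs)
  stopifnot(inherits(config, "sim_config"))
  site_ref <- vapply(config$sites, `[[`, "", "ref_id")
  unknown <- setdiff(site_ref, names(refs))
  if (length(unknown)) {
    stop("site on unknown reference: ", paste(unknown, collapse = ", "))
  }
  for (s in config$sites) {
    if (s$position > nchar(as.character(refs[[s$ref_id]]))) {
      stop("site at ", s$ref_id, ":", s$position, " lies outside the reference")
    }
  }
  lmin <- config$frag_len_range[1]
  if (any(Biostrings::width(refs) < lmin)) {
    stop("all references must be at least as long as the minimum fragment (",
         lmin, " nt)")
  }

  set.seed(config$seed)
  aln <- vector("list", length(refs))
  for (k in seq_along(refs)) {
    rid <- names(refs)[k]
    sites <- config$sites[site_ref == rid]
    aln[[k]] <- .simulate_one_reference(refs, rid, sites, config)
  }
  truth <- do.call(rbind, lapply(config$sites, function(s) {
    mis <- s$misinc
    if (is.null(mis)) {
      mis <- misinc_preset(.ref_base_at(refs, s$ref_id, s$position + 1L))
    }
    data.frame(ref_id = s$ref_id, pos = s$position, occupancy = s$occupancy,
               p_arrest = s$p_arrest,
               misinc_A = mis[["A"]], misinc_C = mis[["C"]],
               misinc_G = mis[["G"]], misinc_T = mis[["T"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(ref_id = character(), pos = integer(),
                        occupancy = numeric(), p_arrest = numeric(),
                        misinc_A = numeric(), misinc_C = numeric(),
                        misinc_G = numeric(), misinc_T = numeric())
  }
  structure(list(alignments = do.call(rbind, aln), truth = truth,
                 refs = refs, config = config),
            class = "rt_sim")
}

.simulate_one_reference <- function(refs, rid, sites, config) {
  L <- nchar(as.character(refs[[rid]]))
  lmin <- config$frag_len_range[1]
  lmax <- config$frag_len_range[2]
  n <- config$depth

  draw_frags <- function(m) {
    end3 <- sample.int(L, m, replace = TRUE)
    len <- sample(seq.int(lmin, lmax), m, replace = TRUE)
    start5 <- pmax(1L, end3 - len + 1L)
    keep <- (end3 - start5 + 1L) >= lmin
    cbind(start5 = start5[keep], end3 = end3[keep])
  }
  fr <- draw_frags(n)
  tries <- 0L
  while (nrow(fr) < n && tries < 50L) {
    fr <- rbind(fr, draw_frags(max(16L, 2L * (n - nrow(fr)))))
    tries <- tries + 1L
  }
  if (nrow(fr) < n) {
    stop("could not draw ", n, " size-selected fragments for reference ", rid)
  }
  fr <- fr[seq_len(n), , drop = FALSE]
  cur_start <- fr[, "start5"]
  end3 <- fr[, "end3"]

  # walk sites from high to low coordinate, mirroring the RT direction
  emit <- list()
  if (length(sites)) {
    ord <- order(vapply(sites, `[[`, 1L, "position"), decreasing = TRUE)
    for (s in sites[ord]) {
      pos <- s$position
      mis <- s$misinc
      if (is.null(mis)) mis <- misinc_preset(.ref_base_at(refs, rid, pos + 1L))
      active <- pos >= cur_start & pos <= end3
      modified <- active & (runif(n) < s$occupancy)
      arrested <- modified & (runif(n) < s$p_arrest)
      cur_start[arrested] <- pos + 1L
      rt <- which(modified & !arrested)
      if (length(rt)) {
        emit[[length(emit) + 1L]] <- data.frame(
          read = rt, pos = pos,
          base = sample(.base_alphabet, length(rt), replace = TRUE, prob = mis))
      }
    }
  }

  # a fragment whose 3'-terminal base is an arrested site yields no cDNA
  alive <- cur_start <= end3
  keep_idx <- which(alive)
  cur_start <- cur_start[alive]
  end3 <- end3[alive]
  lens <- end3 - cur_start + 1L
  m <- length(cur_start)

  ref_chars <- strsplit(as.character(refs[[rid]]), "")[[1L]]
  flat_pos <- sequence(lens, from = cur_start)
  bases <- ref_chars[flat_pos]
  if (config$error_rate > 0) {
    err <- which(runif(length(bases)) < config$error_rate)
    if (length(err)) {
      alt <- matrix(c("C", "G", "T",   # alternatives to A
                      "A", "G", "T",   # to C
                      "A", "C", "T",   # to G
                      "A", "C", "G"),  # to T
                    nrow = 4L, byrow = TRUE,
                    dimnames = list(.base_alphabet, NULL))
      pick <- sample.int(3L, length(err), replace = TRUE)
      bases[err] <- alt[cbind(match(bases[err], .base_alphabet), pick)]
    }
  }
  # overwrite read-through site positions with the drawn misincorporation base
  if (length(emit)) {
    offsets <- c(0L, cumsum(lens))[seq_len(m)]
    surv <- match(seq_len(n), keep_idx)  # original index -> surviving index
    for (e in emit) {
      i <- surv[e$read]
      ok <- !is.na(i) & e$pos >= cur_start[ifelse(is.na(i), 1L, i)]
      i <- i[ok]
      if (!length(i)) next
      bases[offsets[i] + (e$pos[ok] - cur_start[i] + 1L)] <- e$base[ok]
    }
  }
  big <- paste(bases, collapse = "")
  ends_flat <- cumsum(lens)
  seqs <- substring(big, ends_flat - lens + 1L, ends_flat)

  data.frame(
    qname = sprintf("%s:%06d", rid, keep_idx),
    flag = 0L, ref_id = rid, pos = cur_start,
    cigar = paste0(lens, "M"), seq = seqs,
    stringsAsFactors = FALSE
  )
}

#' Write simulation outputs to files
#'
#' @param sim result of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the written paths (fasta, sam, truth).
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "rt_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, "_refs.fasta")),
    sam = file.path(dir, paste0(prefix, "_reads.sam")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_reference_fasta(sim$refs, paths[["fasta"]])
  write_sam(sim$alignments, sim$refs, paths[["sam"]])
  truth <- sim$truth
  for (cc in c("occupancy", "p_arrest", "misinc_A", "misinc_C", "misinc_G",
               "misinc_T")) {
    truth[[cc]] <- .fmt_frac(truth[[cc]])
  }
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Occupancy titration series
#'
#' Runs one simulation per occupancy fraction, with all sites set to that
#' fraction and per-fraction seeds derived from the base seed by fixed
#' offsets.
#'
#' @param refs reference set.
#' @param base_config a [sim_config()]; its sites define positions, arrest
#'   probabilities and misincorporation distributions.
#' @param fractions numeric vector of occupancies in \[0, 1\].
#' @return named list of `rt_sim` objects (names = fractions).
#' @export
titration_series <- function(refs, base_config, fractions) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  out <- lapply(seq_along(fractions), function(i) {
    cfg <- base_config
    cfg$sites <- lapply(cfg$sites, function(s) {
      s$occupancy <- fractions[i]
      s
    })
    cfg$seed <- base_config$seed + i
    simulate_reads(refs, cfg)
  })
  names(out) <- as.character(fractions)
  out
}

#' Summarize a titration series at one site
#'
#' For each fraction, builds the profile and reports the site's arrest rate
#' a(p), the per-call mismatch rate m(p), and the per-molecule
#' misincorporation rate: mismatched calls at p divided by the coverage at
#' p+1 (molecules whose RT reached the site). Arrest depletes read-through
#' coverage, so m(p) grows superlinearly with occupancy at high arrest
#' probability, while both a(p) and the per-molecule misincorporation rate
#' are affine in the modified fraction; the occupancy lower bound is their
#' sum.
#'
#' @param series list from [titration_series()].
#' @param ref_id,p site location.
#' @return data.frame with columns `fraction, arrest_rate, mismatch_rate,
#'   misinc_rate, coverage, coverage_3p`.
#' @export
titration_summary <- function(series, ref_id, p) {
  do.call(rbind, lapply(names(series), function(f) {
    sim <- series[[f]]
    prof <- build_profile(sim$refs, sim$alignments)
    row <- .profile_rows(prof, ref_id, p)
    row3 <- .profile_rows(prof, ref_id, p + 1L)
    acgt <- sum(row[, .base_alphabet])
    mm_calls <- acgt - row[[row$ref_base]]
    data.frame(
      fraction = as.numeric(f),
      arrest_rate = row$arrest_rate,
      mismatch_rate = row$mismatch_rate,
      misinc_rate = if (row3$coverage > 0) mm_calls / row3$coverage else 0,
      coverage = row$coverage, coverage_3p = row3$coverage
    )
  }))
}
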