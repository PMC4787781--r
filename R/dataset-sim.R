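#' Simulate a labeled signature dataset end to end
#'
#' Convenience harness for validation studies: generates tRNA-like random
#' references (76 nt, one candidate site at position 58, the canonical m1A58
#' location), plants one modified site per reference with the +1 base cycled
#' through T/G/C/A and the matching [misinc_preset()], simulates reads,
#' builds profiles and extracts labeled signatures. All other adenosines
#' passing the coverage filters become non-m1A instances. Placing the site
#' within one minimum fragment length of the 3' end means no size-selected
#' fragment starts naturally at p+1, so the site's arrest rate estimates
#' occupancy x arrest probability without background.
#'
#' @param n_sites number of modified references (default 48).
#' @param depth reads per reference (default 5000).
#' @param p_arrest_range range the per-site arrest probability is drawn from
#'   uniformly (default c(0.7, 0.9)).
#' @param occupancy_range range for per-site occupancy (default c(1, 1),
#'   i.e. fully modified).
#' @param error_rate background substitution rate (default 0.001).
#' @param ref_length,site_pos reference geometry (defaults 76 and 58).
#' @param rna_class class tag attached to all records (default "tRNA").
#' @param seed mandatory seed.
#' @return list with `signatures` (labeled, with `rna_class`), `profile`,
#'   `truth`, `refs` and `sim`.
#' @export
simulate_signature_dataset <- function(n_sites = 48L, depth = 5000L,
                                       p_arrest_range = c(0.7, 0.9),
                                       occupancy_range = c(1, 1),
                                       error_rate = 0.001,
                                       ref_length = 76L, site_pos = 58L,
                                       rna_class = "tRNA", seed) {
  stopifnot(!missing(seed), site_pos < ref_length)
  set.seed(seed)
  plus1_cycle <- rep_len(c("T", "G", "C", "A"), n_sites)
  refs <- vapply(seq_len(n_sites), function(i) {
    s <- sample(.base_alphabet, ref_length, replace = TRUE)
    s[site_pos] <- "A"
    s[site_pos + 1L] <- plus1_cycle[i]
    paste(s, collapse = "")
  }, "")
  names(refs) <- sprintf("tRNA_sim_%03d", seq_len(n_sites))

  p_arrest <- runif(n_sites, p_arrest_range[1], p_arrest_range[2])
  occupancy <- runif(n_sites, occupancy_range[1], occupancy_range[2])
  sites <- lapply(seq_len(n_sites), function(i) {
    sim_site(names(refs)[i], site_pos, occupancy = occupancy[i],
             p_arrest = p_arrest[i])
  })
  cfg <- sim_config(seed = seed + 1L, depth = depth, sites = sites,
                    error_rate = error_rate)
  sim <- simulate_reads(refs, cfg)
  profile <- build_profile(refs, sim$alignments)
  sigs <- extract_signatures(profile, refs)
  ann <- data.frame(ref_id = sim$truth$ref_id, pos = sim$truth$pos,
                    label = "m1A", stringsAsFactors = FALSE)
  sigs <- label_signatures(sigs, ann, default_label = "non_m1A")
  sigs$rna_class <- rna_class
  list(signatures = sigs, profile = profile, truth = sim$truth,
       refs = sim$refs, sim = sim)
}
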