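# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (enumeration / single expressions) and share no code
# with the implementation paths they check.

# enumeration oracle for the half-overlap start-position count
enum_effective_positions <- function(a, b, L, rl) {
  if (rl > L) return(0L)
  hits <- 0L
  for (s in 0:(L - rl)) {
    ov <- min(b, s + rl) - max(a, s)
    if (ov > 0 && 2 * ov >= rl) hits <- hits + 1L
  }
  hits
}

# Brute-force all-offsets ungapped matcher oracle.  Scores every
# (reference, offset) pair exhaustively, applies the per-class identity and
# span thresholds, picks the best accepted hit by (identity, span,
# lexicographically smallest ref_id) using exact integer comparisons, then
# applies any confirmation identity.  Returns the winning ref_id or NA.
oracle_best_ref <- function(read, refs, thresholds) {
  rl <- nchar(read)
  rv <- utf8ToInt(read)
  best <- NULL  # list(m, span, ref_id, class)
  for (i in seq_len(nrow(refs))) {
    th <- thresholds[[refs$reference_class[i]]]
    fv <- utf8ToInt(refs$seq[i])
    L <- length(fv)
    for (off in seq(-(rl - 1L), L - 1L)) {
      j0 <- max(0L, -off); j1 <- min(rl, L - off)
      span <- j1 - j0
      if (span <= 0 || span < th$min_aln_read_fraction * rl) next
      m <- sum(rv[(j0 + 1L):j1] == fv[(j0 + off + 1L):(j1 + off)])
      if (m * 100 < th$min_pct_identity * span) next
      if (is.null(best) ||
          m * best$span > best$m * span ||
          (m * best$span == best$m * span &&
             (span > best$span ||
                (span == best$span && refs$ref_id[i] < best$ref_id))))
        best <- list(m = m, span = span, ref_id = refs$ref_id[i],
                     class = refs$reference_class[i])
    }
  }
  if (is.null(best)) return(NA_character_)
  conf <- thresholds[[best$class]]$confirm_pct_identity
  if (!is.na(conf) && best$m * 100 < conf * best$span) return(NA_character_)
  best$ref_id
}

seq_divergence_helper <- function(a, b) mean(utf8ToInt(a) != utf8ToInt(b))

# small transect used across tests: modest genomes and read counts so that
# sequence-level stages stay fast
tiny_config <- function(n_samples = 1L, seed = 1L, n_reads = 2000L, ...) {
  default_transect_config(n_samples = n_samples, seed = seed,
                          n_reads = n_reads, ...)
}

# truth-joined abundance ratios for a finished end-to-end run
recovery_ratios <- function(res) {
  ab <- res$abundance
  tru <- res$transect$truth
  key <- paste(ab$sample_id, ab$taxon_id)
  tk <- paste(tru$sample_id, tru$taxon_id)
  ab$truth <- tru$haploid_equiv_per_liter[match(key, tk)]
  ab
}
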