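#' Simulate merged shotgun reads for one spiked sample
#'
#' Reads are drawn by a two-step model implied by the recovery calculus:
#' the source genome (taxon or standard) is chosen with probability
#' proportional to copies x genome length (DNA mass), and the read start is
#' uniform over positions where the read fits.  A read is a *latent* marker
#' or standard-gene hit iff its overlap with the locus is at least half the
#' read length; a latent hit is retained as an *annotated* hit with the
#' sample's per-marker sensitivity.  Substitution errors are applied at the
#' sample's error rate.  The draw is reproducible given `sample$seed`, and
#' the per-source read counts sum to `n_reads` exactly.
#'
#' @param transect A `spike_transect` from [build_transect()] (carries the
#'   community truth, genome sequences and standards).
#' @param sample A `sample_spec`, or the id of a sample in the transect.
#' @param emit_sequences If `FALSE`, skip building read sequences and
#'   return counts only (much faster; used for count-level simulations).
#' @param reverse_complement If `TRUE`, each read is emitted as its
#'   reverse complement with probability 1/2 (off by default; the matcher
#'   must then run with `both_strands = TRUE`).  Latent/annotated counts
#'   are strand-independent.
#' @return List with `reads` (named character vector; header encodes
#'   sample id, read index and a latent source tag used only by tests),
#'   `true_counts` (data.frame: `sample_id`, `reference_class`,
#'   `reference_id`, `taxon_id`, `latent_count`, `annotated_count`) and
#'   `sample`.
#' @export
simulate_reads <- function(transect, sample, emit_sequences = TRUE,
                           reverse_complement = FALSE) {
  if (is.character(sample)) sample <- transect$samples[[sample]]
  stopifnot(inherits(sample, "sample_spec"))
  rl <- sample$read_length
  t_ov <- as.integer(ceiling(rl / 2))  # latent-hit overlap threshold

  truth <- transect$truth[transect$truth$sample_id == sample$sample_id, ]
  stds <- transect$standards_table[
    transect$standards_table$sample_id == sample$sample_id, ]
  if (nrow(truth) == 0L)
    stop(sprintf("sample '%s' not found in transect truth", sample$sample_id))

  src_ids <- c(truth$taxon_id, stds$standard_id)
  src_len <- c(truth$genome_length, stds$genome_length)
  copies <- c(truth$copies_in_sample, stds$S_a)
  if (any(rl > src_len)) stop("read_length exceeds a source genome length")
  w <- copies * src_len
  if (sum(w) <= 0) stop("total DNA mass must be > 0")

  sens_of <- function(marker) {
    s <- sample$per_marker_sensitivity
    if (!is.null(s) && marker %in% names(s)) unname(s[[marker]]) else 1
  }

  local_seed(sample$seed, {
    n_src <- drop(rmultinom(1L, sample$n_reads, w))
    starts <- lapply(seq_along(src_ids), function(i)
      if (n_src[i] > 0L) sample.int(src_len[i] - rl + 1L, n_src[i],
                                    replace = TRUE) - 1L
      else integer())

    # latent / annotated counting against each source's loci
    rows <- list()
    count_latent <- function(s, a, b) {
      if (b - a < t_ov) return(0L)
      sum(s >= a - rl + t_ov & s <= b - t_ov)
    }
    for (i in seq_len(nrow(truth))) {
      tx <- transect$taxa[[truth$taxon_id[i]]]
      s <- starts[[i]]
      for (m in tx$markers) {
        latent <- count_latent(s, m$start, m$end)
        annotated <- rbinom(1L, latent, sens_of(m$marker_name))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample$sample_id, reference_class = m$marker_name,
          reference_id = paste0(m$marker_name, "|", tx$taxon_id),
          taxon_id = tx$taxon_id, latent_count = latent,
          annotated_count = annotated, stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(nrow(stds))) {
      st <- transect$standards[[stds$standard_id[j]]]
      s <- starts[[nrow(truth) + j]]
      latent <- 0L
      for (gi in seq_len(nrow(st$gene_loci)))
        latent <- latent + count_latent(s, st$gene_loci$start[gi],
                                        st$gene_loci$end[gi])
      annotated <- rbinom(1L, latent, sens_of("standard_gene"))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample$sample_id, reference_class = "standard_gene",
        reference_id = st$standard_id, taxon_id = st$standard_id,
        latent_count = latent, annotated_count = annotated,
        stringsAsFactors = FALSE)
    }
    true_counts <- do.call(rbind, rows)

    reads <- NULL
    if (emit_sequences && sample$n_reads > 0L) {
      seq_list <- vector("list", length(src_ids))
      for (i in seq_along(src_ids)) {
        if (n_src[i] == 0L) { seq_list[[i]] <- character(); next }
        g <- if (i <= nrow(truth)) transect$genomes[[src_ids[i]]]
             else transect$standards[[src_ids[i]]]$genome
        seq_list[[i]] <- substring(g, starts[[i]] + 1L, starts[[i]] + rl)
      }
      reads <- unlist(seq_list, use.names = FALSE)
      reads <- inject_errors(reads, sample$error_rate)
      strand <- rep("+", length(reads))
      if (reverse_complement) {
        flip <- runif(length(reads)) < 0.5
        if (any(flip))
          reads[flip] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(reads[flip])))
        strand[flip] <- "-"
      }
      names(reads) <- sprintf("%s|r%07d|src=%s|start=%d|strand=%s",
                              sample$sample_id, seq_along(reads),
                              rep(src_ids, n_src),
                              unlist(starts, use.names = FALSE), strand)
    } else if (emit_sequences) {
      reads <- character()
    }
    list(reads = reads, true_counts = true_counts, sample = sample)
  })
}

# per-base substitution errors; each erroneous base becomes one of the
# other three uniformly
inject_errors <- function(seqs, rate) {
  if (rate < 0) stop("negative error rate")
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(.BASES[.BASES != old], 1L)
    }
  }
  seqs
}

#' Convert simulator truth counts into a read-count table
#'
#' The annotated hits of `true_counts` become the `count` column of a
#' table with the same schema the matcher produces, so the quantification
#' stage can consume either source interchangeably.
#'
#' @param true_counts The `true_counts` data.frame from [simulate_reads()].
#' @return A read-count data.frame (`sample_id`, `reference_class`,
#'   `reference_id`, `taxon_id`, `count`).
#' @export
counts_from_truth <- function(true_counts) {
  data.frame(sample_id = true_counts$sample_id,
             reference_class = true_counts$reference_class,
             reference_id = true_counts$reference_id,
             taxon_id = true_counts$taxon_id,
             count = true_counts$annotated_count,
             stringsAsFactors = FALSE)
}

#' Closed-form expected latent and annotated hit counts
#'
#' For each marker locus and standard, the expected number of reads whose
#' overlap satisfies the half-read rule:
#' `n_reads x (copies x effective_positions / sum(copies x positions))`,
#' times the annotation sensitivity for the annotated expectation.
#'
#' @param transect A `spike_transect`.
#' @param sample A `sample_spec` or sample id.
#' @return data.frame mirroring `true_counts` with numeric columns
#'   `expected_latent` and `expected_annotated`.
#' @export
expected_counts <- function(transect, sample) {
  if (is.character(sample)) sample <- transect$samples[[sample]]
  rl <- sample$read_length
  truth <- transect$truth[transect$truth$sample_id == sample$sample_id, ]
  stds <- transect$standards_table[
    transect$standards_table$sample_id == sample$sample_id, ]
  src_len <- c(truth$genome_length, stds$genome_length)
  copies <- c(truth$copies_in_sample, stds$S_a)
  # source drawn proportional to DNA mass (copies x length), then the start
  # is uniform over the (L - rl + 1) positions where the read fits
  mass_tot <- sum(copies * src_len)
  sens_of <- function(marker) {
    s <- sample$per_marker_sensitivity
    if (!is.null(s) && marker %in% names(s)) unname(s[[marker]]) else 1
  }
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tx <- transect$taxa[[truth$taxon_id[i]]]
    for (m in tx$markers) {
      eff <- effective_positions(m$start, m$end, tx$genome_length, rl)
      lam <- sample$n_reads *
        (truth$copies_in_sample[i] * tx$genome_length / mass_tot) *
        (eff / (tx$genome_length - rl + 1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample$sample_id, reference_class = m$marker_name,
        reference_id = paste0(m$marker_name, "|", tx$taxon_id),
        taxon_id = tx$taxon_id, expected_latent = lam,
        expected_annotated = lam * sens_of(m$marker_name),
        stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(nrow(stds))) {
    st <- transect$standards[[stds$standard_id[j]]]
    eff <- sum(vapply(seq_len(nrow(st$gene_loci)), function(gi)
      effective_positions(st$gene_loci$start[gi], st$gene_loci$end[gi],
                          st$genome_length, rl), 0L))
    lam <- sample$n_reads * (stds$S_a[j] * st$genome_length / mass_tot) *
      (eff / (st$genome_length - rl + 1))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample$sample_id, reference_class = "standard_gene",
      reference_id = st$standard_id, taxon_id = st$standard_id,
      expected_latent = lam,
      expected_annotated = lam * sens_of("standard_gene"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
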