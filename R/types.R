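#' Single-copy marker gene locus
#'
#' Describes one marker-gene locus (recA, radA or psbO) on a haploid genome.
#' Coordinates are 0-based, half-open, as in BED.
#'
#' @param marker_name One of `"recA"`, `"radA"`, `"psbO"`.
#' @param start 0-based inclusive start on the genome.
#' @param end 0-based exclusive end; `end > start`.
#' @param sequence Nucleotide string of length `end - start`.
#' @return An object of class `marker_locus`.
#' @export
marker_locus <- function(marker_name, start, end, sequence) {
  marker_name <- match.arg(marker_name, c("recA", "radA", "psbO"))
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("marker locus must have end > start")
  if (nchar(sequence) != end - start)
    stop("marker sequence length must equal end - start")
  structure(list(marker_name = marker_name, start = start, end = end,
                 sequence = toupper(sequence)),
            class = "marker_locus")
}

# markers each domain must carry, exactly once per haploid genome
.domain_markers <- list(
  bacteria                = "recA",
  archaea                 = "radA",
  cyanobacteria           = c("recA", "psbO"),
  eukaryote_phytoplankton = "psbO"
)

#' Taxon description for the synthetic community
#'
#' A taxon carries a haploid genome length, a ploidy level, and the
#' single-copy marker loci its domain implies: bacteria carry `recA`,
#' archaea `radA`, cyanobacteria both `recA` and `psbO`, and eukaryotic
#' phytoplankton `psbO` only.  Each marker appears at most once per haploid
#' genome (the single-copy assumption on which the whole calculus rests).
#'
#' @param taxon_id Character id.
#' @param domain_label One of `"bacteria"`, `"archaea"`, `"cyanobacteria"`,
#'   `"eukaryote_phytoplankton"`.
#' @param genome_length Haploid genome length in bases.
#' @param ploidy Integer genome copies per cell, `>= 1`.
#' @param markers List of [marker_locus()] objects.
#' @param true_cells_per_liter Optional ground-truth cell density
#'   (cells per liter, `>= 0`); per-sample truth normally lives in the
#'   transect truth table instead.
#' @return An object of class `taxon_spec`.
#' @export
taxon_spec <- function(taxon_id, domain_label, genome_length, ploidy = 1L,
                       markers = list(), true_cells_per_liter = NA_real_) {
  domain_label <- match.arg(domain_label, names(.domain_markers))
  genome_length <- as.integer(genome_length)
  ploidy <- as.integer(ploidy)
  if (genome_length <= 0L) stop("genome_length must be positive")
  if (ploidy < 1L) stop("ploidy must be an integer >= 1")
  if (!is.na(true_cells_per_liter) && true_cells_per_liter < 0)
    stop("true_cells_per_liter must be >= 0")
  nm <- vapply(markers, function(m) m$marker_name, "")
  if (anyDuplicated(nm))
    stop("each marker may appear at most once per haploid genome")
  expected <- .domain_markers[[domain_label]]
  if (length(markers) && !setequal(nm, expected))
    stop(sprintf("taxon '%s' (%s) must carry exactly: %s", taxon_id,
                 domain_label, paste(expected, collapse = ", ")))
  for (m in markers) {
    if (m$start < 0L || m$end > genome_length)
      stop("marker locus outside [0, genome_length)")
  }
  if (length(markers) > 1L) {
    o <- order(vapply(markers, `[[`, 0L, "start"))
    s <- markers[o]
    for (i in seq_len(length(s) - 1L))
      if (s[[i + 1L]]$start < s[[i]]$end) stop("marker loci overlap")
  }
  structure(list(taxon_id = taxon_id, domain_label = domain_label,
                 genome_length = genome_length, ploidy = ploidy,
                 markers = markers,
                 true_cells_per_liter = true_cells_per_liter),
            class = "taxon_spec")
}

#' Genomic internal standard (spike-in)
#'
#' One spiked standard genome: `S_p` protein-coding genes laid out as
#' non-overlapping loci, and `S_a` copies of the genome added to the sample.
#'
#' @param standard_id Character id.
#' @param genome_length Genome length in bases.
#' @param gene_loci data.frame with 0-based half-open columns `start`, `end`
#'   and a `gene_id` column; loci must be non-overlapping and inside the
#'   genome.
#' @param S_a Copies of the standard genome added to the sample (`> 0`).
#' @param genome Optional genome sequence (required by the read simulator).
#' @return An object of class `standard_spec` with `S_p = nrow(gene_loci)`.
#' @export
standard_spec <- function(standard_id, genome_length, gene_loci, S_a = NA_real_,
                          genome = NULL) {
  genome_length <- as.integer(genome_length)
  if (genome_length <= 0L) stop("genome_length must be positive")
  stopifnot(is.data.frame(gene_loci),
            all(c("gene_id", "start", "end") %in% names(gene_loci)))
  if (nrow(gene_loci) < 1L) stop("a standard needs S_p >= 1 gene loci")
  if (any(gene_loci$end <= gene_loci$start) || any(gene_loci$start < 0L) ||
      any(gene_loci$end > genome_length))
    stop("gene loci must lie within [0, genome_length)")
  o <- order(gene_loci$start)
  g <- gene_loci[o, ]
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
    stop("gene loci overlap")
  if (!is.na(S_a) && S_a <= 0) stop("S_a must be > 0")
  if (!is.null(genome) && nchar(genome) != genome_length)
    stop("genome sequence length disagrees with genome_length")
  structure(list(standard_id = standard_id, genome_length = genome_length,
                 S_p = nrow(gene_loci), gene_loci = gene_loci, S_a = S_a,
                 genome = genome),
            class = "standard_spec")
}

#' Sample description for read simulation
#'
#' @param sample_id Character id.
#' @param volume_liters Liters of water filtered (`> 0`); the denominator of
#'   every volumetric abundance.
#' @param n_reads Total merged reads to simulate (`>= 0`).
#' @param read_length Length of each merged read, bases.
#' @param per_marker_sensitivity Named numeric in (0, 1]: probability that a
#'   read truly overlapping a marker is annotated as such.  Emulates
#'   database-driven annotation undercounts (e.g. sparse psbO references);
#'   markers not named default to 1.
#' @param seed Integer RNG seed for this sample.
#' @param error_rate Per-base substitution error rate (`>= 0`).
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, volume_liters = 1, n_reads = 1e5L,
                        read_length = 250L,
                        per_marker_sensitivity = numeric(), seed = 1L,
                        error_rate = 0.002) {
  if (volume_liters <= 0) stop("volume_liters must be > 0")
  n_reads <- as.integer(n_reads)
  if (n_reads < 0L) stop("n_reads must be >= 0")
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  if (error_rate < 0) stop("negative error rate")
  s <- per_marker_sensitivity
  if (length(s) && (is.null(names(s)) || any(s <= 0) || any(s > 1)))
    stop("per_marker_sensitivity must be named probabilities in (0, 1]")
  structure(list(sample_id = sample_id, volume_liters = volume_liters,
                 n_reads = n_reads, read_length = read_length,
                 per_marker_sensitivity = s, seed = as.integer(seed),
                 error_rate = error_rate),
            class = "sample_spec")
}

#' Read-filter thresholds for one reference class
#'
#' The matcher accepts a hit iff percent identity `>= min_pct_identity` and
#' the aligned span is `>= min_aln_read_fraction` of the read length.  For
#' internal-standard genes a second confirmation identity can be demanded
#' over the accepted span (the two-stage standard identification collapsed
#' to nucleotide space).
#'
#' @param min_pct_identity Percent identity cutoff in (0, 100].
#' @param min_aln_read_fraction Minimum aligned fraction of the read, (0, 1].
#' @param best_hit_only Keep only the single best hit per read (the `-k 1`
#'   convention).
#' @param confirm_pct_identity Optional second-stage identity cutoff applied
#'   to an already accepted hit; `NA` disables it.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_pct_identity, min_aln_read_fraction = 0.5,
                              best_hit_only = TRUE,
                              confirm_pct_identity = NA_real_) {
  if (min_pct_identity <= 0 || min_pct_identity > 100)
    stop("min_pct_identity must be in (0, 100]")
  if (min_aln_read_fraction <= 0 || min_aln_read_fraction > 1)
    stop("min_aln_read_fraction must be in (0, 1]")
  structure(list(min_pct_identity = min_pct_identity,
                 min_aln_read_fraction = min_aln_read_fraction,
                 best_hit_only = isTRUE(best_hit_only),
                 confirm_pct_identity = confirm_pct_identity),
            class = "filter_thresholds")
}

#' Default per-class filter thresholds
#'
#' Standards: 95% nucleotide identity with a 98% confirmation pass; recA,
#' radA and psbO markers: 80% identity; all classes require the alignment to
#' cover at least half the read and keep only the best hit.
#'
#' @return Named list of [filter_thresholds()] keyed by reference class.
#' @export
default_thresholds <- function() {
  list(standard_gene = filter_thresholds(95, 0.5, TRUE, 98),
       recA = filter_thresholds(80, 0.5, TRUE),
       radA = filter_thresholds(80, 0.5, TRUE),
       psbO = filter_thresholds(80, 0.5, TRUE))
}

#' Number of read start positions satisfying the half-overlap rule
#'
#' A read of length `rl` starting at `s` (0-based, fully contained in a
#' genome of length `L`) counts as overlapping the locus `[a, b)` iff the
#' overlap is at least half the read length (`2 * overlap >= rl`).  This
#' closed form counts the start positions `s` for which that holds; it is
#' the effective target length entering expected-count calculations.
#'
#' @param start,end Locus coordinates, 0-based half-open.
#' @param genome_length Genome length `L`.
#' @param read_length Read length `rl <= L`.
#' @return Integer count of qualifying start positions.
#' @export
effective_positions <- function(start, end, genome_length, read_length) {
  rl <- as.integer(read_length)
  t <- as.integer(ceiling(rl / 2))  # integer overlap >= rl/2
  if (end - start < t) return(0L)
  lo <- max(0L, as.integer(start) - rl + t)
  hi <- min(genome_length - rl, as.integer(end) - t)
  max(0L, hi - lo + 1L)
}

#' @export
print.taxon_spec <- function(x, ...) {
  cat(sprintf("<taxon_spec> %s [%s] genome %d bp, ploidy %d, markers: %s\n",
              x$taxon_id, x$domain_label, x$genome_length, x$ploidy,
              paste(vapply(x$markers, `[[`, "", "marker_name"),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.standard_spec <- function(x, ...) {
  cat(sprintf("<standard_spec> %s: %d bp, S_p = %d genes, S_a = %s copies\n",
              x$standard_id, x$genome_length, x$S_p, format(x$S_a)))
  invisible(x)
}

# run code with a private RNG state, restoring the caller's stream
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
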