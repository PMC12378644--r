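#' @importFrom Rcpp sourceCpp
#' @useDynLib spikequant, .registration = TRUE
NULL

# normalize a reference set to the data.frame form
# (ref_id, reference_class, source_id, seq)
as_reference_df <- function(references, reference_class = NA_character_) {
  if (is.data.frame(references)) {
    stopifnot(all(c("ref_id", "reference_class", "source_id", "seq") %in%
                    names(references)))
    return(references)
  }
  if (is.null(names(references)) || any(names(references) == ""))
    stop("references must be named sequences or a reference data.frame")
  data.frame(ref_id = names(references), reference_class = reference_class,
             source_id = names(references), seq = unname(references),
             stringsAsFactors = FALSE)
}

# per-reference threshold vectors from a per-class thresholds list
ref_thresholds <- function(refs, thresholds) {
  if (inherits(thresholds, "filter_thresholds"))
    thresholds <- setNames(rep(list(thresholds),
                               length(unique(refs$reference_class))),
                           unique(refs$reference_class))
  missing <- setdiff(unique(refs$reference_class), names(thresholds))
  if (length(missing))
    stop("no thresholds supplied for class: ", paste(missing, collapse = ", "))
  for (th in thresholds) {
    if (inherits(th, "filter_thresholds") && !th$best_hit_only)
      stop("only best-hit (-k 1) counting is implemented")
  }
  list(min_ident = vapply(refs$reference_class, function(cl)
         thresholds[[cl]]$min_pct_identity, 0),
       min_frac = vapply(refs$reference_class, function(cl)
         thresholds[[cl]]$min_aln_read_fraction, 0),
       confirm = vapply(refs$reference_class, function(cl)
         thresholds[[cl]]$confirm_pct_identity, 0))
}

# raw best hits for a vector of reads; one row per read (ref NA if none)
best_hits <- function(reads, refs, thresholds, k = 15L,
                      both_strands = FALSE) {
  if (nrow(refs) == 0L) stop("empty reference set")
  if (anyDuplicated(refs$ref_id))
    stop("duplicate reference_id across reference classes")
  th <- ref_thresholds(refs, thresholds)
  seqs <- setNames(refs$seq, refs$ref_id)
  hit <- cpp_match_reads(as.character(reads), seqs, th$min_ident, th$min_frac,
                         as.integer(k), isTRUE(both_strands))
  hit$identity <- ifelse(hit$span > 0, 100 * hit$matches / hit$span, NA_real_)
  # second-stage confirmation over the accepted span (standards): an
  # accepted winner failing confirmation is dropped, not replaced
  conf <- rep(NA_real_, nrow(hit))
  got <- hit$ref > 0L
  conf[got] <- th$confirm[hit$ref[got]]
  drop <- got & !is.na(conf) & (hit$matches * 100 < conf * hit$span)
  hit$ref[drop] <- 0L
  hit
}

#' Match one read against a reference set
#'
#' k-mer-seeded (default `k = 15`) ungapped matching: candidate references
#' share at least one exact k-mer with the read; each candidate offset is
#' scored as a single ungapped alignment over the read/reference overlap.
#' A hit is accepted iff percent identity and aligned-span thresholds for
#' its reference class hold; the best accepted hit (highest identity, ties
#' to longer span, then lexicographically smallest `ref_id`) is returned.
#'
#' @param read A single nucleotide string.
#' @param references Named character vector of reference sequences, or a
#'   reference data.frame (`ref_id`, `reference_class`, `source_id`, `seq`)
#'   as produced by [marker_references()].
#' @param thresholds A [filter_thresholds()] (applied to every class) or a
#'   named per-class list as from [default_thresholds()].
#' @param k Seed k-mer length; must not exceed the read length.
#' @param both_strands Also try the reverse complement of the read.
#' @return A one-row data.frame (`ref_id`, `reference_class`, `source_id`,
#'   `identity`, `matches`, `span`, `strand`) or `NULL` when no hit passes.
#' @export
match_read <- function(read, references, thresholds = filter_thresholds(80),
                       k = 15L, both_strands = FALSE) {
  refs <- as_reference_df(references)
  if (nchar(read) < k) stop("k larger than read length")
  hit <- best_hits(read, refs, thresholds, k, both_strands)
  if (hit$ref[1L] == 0L) return(NULL)
  r <- hit$ref[1L]
  data.frame(ref_id = refs$ref_id[r],
             reference_class = refs$reference_class[r],
             source_id = refs$source_id[r], identity = hit$identity[1L],
             matches = hit$matches[1L], span = hit$span[1L],
             strand = c("+", "-")[hit$strand[1L] + 1L],
             stringsAsFactors = FALSE)
}

#' Count standard-gene and marker hits for a sample
#'
#' Applies [match_read()] semantics to every read against the union of the
#' standard-gene and marker reference sets (global best hit across
#' classes, so each read contributes to at most one row), then aggregates
#' counts per reference.  References with zero hits are retained so that
#' downstream detection limits always have a row to attach to.  Per-class
#' acceptance rates are reported to stderr.
#'
#' @param reads Named or unnamed character vector of read sequences.
#' @param standard_refs Reference data.frame for internal-standard genes
#'   ([standard_gene_references()]); may be `NULL`.
#' @param marker_refs Reference data.frame for marker genes
#'   ([marker_references()]); may be `NULL`.
#' @param thresholds Per-class thresholds list, default
#'   [default_thresholds()].
#' @param sample_id Sample id recorded in the output table.
#' @param k,both_strands Passed to the matcher.
#' @return Read-count data.frame: `sample_id`, `reference_class`,
#'   `reference_id`, `taxon_id` (taxon or standard id), `count`, ordered
#'   by class then reference id.
#' @export
count_hits <- function(reads, standard_refs = NULL, marker_refs = NULL,
                       thresholds = default_thresholds(),
                       sample_id = "sample", k = 15L, both_strands = FALSE) {
  refs <- rbind(
    if (!is.null(standard_refs)) as_reference_df(standard_refs),
    if (!is.null(marker_refs)) as_reference_df(marker_refs))
  if (is.null(refs) || nrow(refs) == 0L) stop("empty reference set")
  if (anyDuplicated(refs$ref_id))
    stop("duplicate reference_id across reference classes")

  n <- if (length(reads)) tabulate(
    best_hits(reads, refs, thresholds, k, both_strands)$ref,
    nbins = nrow(refs)) else integer(nrow(refs))

  out <- data.frame(sample_id = sample_id,
                    reference_class = refs$reference_class,
                    reference_id = refs$ref_id, taxon_id = refs$source_id,
                    count = n, stringsAsFactors = FALSE)
  out <- out[order(out$reference_class, out$reference_id), ]
  rownames(out) <- NULL
  for (cl in unique(out$reference_class)) {
    message(sprintf("[count_hits] %s: %s: %d/%d reads accepted", sample_id,
                    cl, sum(out$count[out$reference_class == cl]),
                    length(reads)))
  }
  out
}

#' Aggregate a read-count table to quantification inputs
#'
#' @param counts Read-count data.frame from [count_hits()] or
#'   [counts_from_truth()].
#' @return List with `standards` (`sample_id`, `standard_id`, `S_s`: reads
#'   summed over each standard's genes) and `markers` (`sample_id`,
#'   `marker`, `taxon_id`, `G_s`).
#' @export
aggregate_counts <- function(counts) {
  std <- counts[counts$reference_class == "standard_gene", ]
  mk <- counts[counts$reference_class != "standard_gene", ]
  standards <- if (nrow(std)) {
    a <- aggregate(count ~ sample_id + taxon_id, std, sum)
    data.frame(sample_id = a$sample_id, standard_id = a$taxon_id,
               S_s = a$count, stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(), standard_id = character(),
                    S_s = numeric())
  markers <- if (nrow(mk)) {
    a <- aggregate(count ~ sample_id + reference_class + taxon_id, mk, sum)
    data.frame(sample_id = a$sample_id, marker = a$reference_class,
               taxon_id = a$taxon_id, G_s = a$count, stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(), marker = character(),
                    taxon_id = character(), G_s = numeric())
  standards <- standards[order(standards$sample_id, standards$standard_id), ]
  markers <- markers[order(markers$sample_id, markers$marker,
                           markers$taxon_id), ]
  rownames(standards) <- rownames(markers) <- NULL
  list(standards = standards, markers = markers)
}
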