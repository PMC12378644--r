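#' Copies of standard genome recovered from sequencing
#'
#' `S_r = S_s / S_p`: reads matching any protein-coding gene of the
#' standard, divided by the number of protein-coding genes in its
#' reference genome.
#'
#' @param S_s Reads matching the standard's protein-coding genes (`>= 0`).
#' @param S_p Protein-coding genes in the standard genome (`>= 1`).
#' @return Genome copies recovered (vectorized).
#' @export
standard_recovery <- function(S_s, S_p) {
  if (any(S_p == 0)) stop("S_p must be >= 1")
  if (any(S_s < 0)) stop("S_s must be >= 0")
  S_s / S_p
}

#' Recovery ratio of an internal standard
#'
#' `R = S_r / S_a`: the proportion of added standard genome copies that
#' were recovered through sequencing.  `R > 1` (more recovered than added)
#' signals miscounting and raises a warning.
#'
#' @param S_r Genome copies recovered ([standard_recovery()]).
#' @param S_a Genome copies added to the sample (`> 0`).
#' @return Dimensionless recovery ratio (vectorized).
#' @export
recovery_ratio <- function(S_r, S_a) {
  if (any(S_a <= 0)) stop("S_a must be > 0")
  R <- S_r / S_a
  if (any(R > 1))
    warning("recovery ratio > 1: more standard recovered than added")
  R
}

#' Combine per-standard recovery ratios
#'
#' Multiple spiked standards each yield a recovery ratio; the default
#' combination is the geometric mean (multiplicative noise model).  The
#' pooled method computes `sum(S_s) / sum(S_p * S_a)` from the raw
#' components instead.  A max/min dispersion above 2 (a likely failed
#' spike) raises a warning.
#'
#' @param R Numeric vector of per-standard recovery ratios.
#' @param method `"geometric"` (default), `"arithmetic"` or `"pooled"`.
#' @param S_s,S_p,S_a Raw components, required for `method = "pooled"`.
#' @return Single combined recovery ratio.
#' @export
combine_recoveries <- function(R, method = c("geometric", "arithmetic",
                                             "pooled"),
                               S_s = NULL, S_p = NULL, S_a = NULL) {
  method <- match.arg(method)
  R <- R[is.finite(R)]
  if (!length(R) || all(R == 0)) stop("no finite positive recovery ratios")
  if (max(R) / min(R[R > 0]) > 2)
    warning("per-standard recovery dispersion max/min > 2")
  switch(method,
         geometric = exp(mean(log(R))),
         arithmetic = mean(R),
         pooled = {
           if (is.null(S_s) || is.null(S_p) || is.null(S_a))
             stop("pooled combination needs S_s, S_p and S_a")
           sum(S_s) / sum(S_p * S_a)
         })
}

#' Absolute gene abundance from read counts
#'
#' `G_a = G_s / R`: molecules of a gene in the sample, from its read count
#' and the sample's recovery ratio.
#'
#' @param G_s Reads of the gene in the sample (`>= 0`).
#' @param R Recovery ratio (`> 0`).
#' @return Gene molecules in the sample (vectorized).
#' @export
gene_abundance <- function(G_s, R) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("abundance undefined: recovery ratio must be > 0")
  G_s / R
}

#' Volumetric abundance
#'
#' Divides gene molecules by the volume of water filtered, giving haploid
#' genome equivalents per liter for a single-copy gene.
#'
#' @param G_a Gene molecules in the sample.
#' @param volume_liters Liters filtered (`> 0`).
#' @return Molecules (haploid genome equivalents) per liter.
#' @export
volumetric_abundance <- function(G_a, volume_liters) {
  if (any(volume_liters <= 0)) stop("volume_liters must be > 0")
  G_a / volume_liters
}

#' Detection limit of a sample
#'
#' The volumetric abundance corresponding to a single annotated read
#' (`G_s = 1`): `1 / (R * volume)`.  Deeper sequencing scales `R` up and
#' the limit down proportionally.
#'
#' @param R Recovery ratio (`> 0`).
#' @param volume_liters Liters filtered (`> 0`).
#' @return Haploid genome equivalents per liter at one read.
#' @export
detection_limit <- function(R, volume_liters) {
  if (any(R <= 0)) stop("R must be > 0")
  if (any(volume_liters <= 0)) stop("volume_liters must be > 0")
  1 / (R * volume_liters)
}

#' Cells from haploid genome equivalents
#'
#' For ploidy `p`, cells are `equivalents / p` (for diploids, half the
#' haploid genome equivalents).
#'
#' @param genome_equivalents Haploid genome equivalents (any unit).
#' @param ploidy Genome copies per cell (`>= 1`).
#' @return Cell count in the same unit (vectorized).
#' @export
cells_from_haploid <- function(genome_equivalents, ploidy = 1) {
  if (any(ploidy < 1)) stop("ploidy must be >= 1")
  genome_equivalents / ploidy
}

#' Per-sample recovery estimates from a count table
#'
#' Joins standard-gene counts with the spike metadata and applies the
#' recovery calculus per sample.  A combined recovery ratio of 2 or more
#' means the sample's counting is untrustworthy; such samples are flagged
#' (and excluded from abundance estimation) rather than silently used.
#'
#' @param counts Read-count data.frame ([count_hits()] /
#'   [counts_from_truth()]).
#' @param standards_table data.frame `sample_id`, `standard_id`, `S_p`,
#'   `S_a` (as in a `spike_transect`).
#' @param method Combination method, see [combine_recoveries()].
#' @return List with `per_standard` (`sample_id`, `standard_id`, `S_s`,
#'   `S_r`, `R`) and `combined` (`sample_id`, `R_combined`, `dispersion`,
#'   `n_standards`, `method`, `flagged`).
#' @export
recovery_table <- function(counts, standards_table,
                           method = c("geometric", "arithmetic", "pooled")) {
  method <- match.arg(method)
  agg <- aggregate_counts(counts)$standards
  per <- merge(standards_table, agg, by = c("sample_id", "standard_id"),
               all.x = TRUE)
  per$S_s[is.na(per$S_s)] <- 0
  per$S_r <- standard_recovery(per$S_s, per$S_p)
  per$R <- suppressWarnings(recovery_ratio(per$S_r, per$S_a))
  if (any(per$R > 1))
    warning("recovery ratio > 1 for: ",
            paste(per$sample_id[per$R > 1], per$standard_id[per$R > 1],
                  collapse = ", "))
  combined <- do.call(rbind, lapply(split(per, per$sample_id), function(d) {
    Rc <- tryCatch(combine_recoveries(d$R, method, d$S_s, d$S_p, d$S_a),
                   error = function(e) NA_real_)
    pos <- d$R[d$R > 0]
    disp <- if (length(pos)) max(d$R) / min(pos) else NA_real_
    data.frame(sample_id = d$sample_id[1L], R_combined = Rc,
               dispersion = disp, n_standards = nrow(d), method = method,
               flagged = is.na(Rc) || Rc >= 2, stringsAsFactors = FALSE)
  }))
  rownames(combined) <- NULL
  if (any(combined$flagged))
    warning("sample(s) flagged (R_combined missing or >= 2): ",
            paste(combined$sample_id[combined$flagged], collapse = ", "))
  per <- per[order(per$sample_id, per$standard_id),
             c("sample_id", "standard_id", "S_p", "S_a", "S_s", "S_r", "R")]
  rownames(per) <- NULL
  list(per_standard = per, combined = combined)
}

#' Per-taxon absolute abundance table
#'
#' Applies `G_a = G_s / R_combined` and the volumetric normalization to
#' every marker count, attaching the sample detection limit (abundance at
#' one read) to every record — zero counts therefore report abundance 0
#' together with an explicit upper bound, so absence is never confused
#' with non-detection.  Ploidy defaults to 1 (abundances are haploid
#' genome equivalents) unless a ploidy table is supplied.
#'
#' @param counts Read-count data.frame.
#' @param recovery Result of [recovery_table()].
#' @param samples_table data.frame `sample_id`, `volume_liters`.
#' @param ploidy_table Optional data.frame `taxon_id`, `ploidy`.
#' @return data.frame with one row per sample x marker x taxon: `G_s`,
#'   `G_a`, `haploid_equiv_per_liter`, `cells_per_liter`,
#'   `detection_limit`, `flagged`.
#' @export
abundance_table <- function(counts, recovery, samples_table,
                            ploidy_table = NULL) {
  mk <- aggregate_counts(counts)$markers
  d <- merge(mk, recovery$combined[, c("sample_id", "R_combined", "flagged")],
             by = "sample_id")
  d <- merge(d, samples_table[, c("sample_id", "volume_liters")],
             by = "sample_id")
  d$ploidy <- 1
  if (!is.null(ploidy_table)) {
    i <- match(d$taxon_id, ploidy_table$taxon_id)
    d$ploidy <- ifelse(is.na(i), 1, ploidy_table$ploidy[i])
  }
  ok <- !d$flagged
  d$G_a <- NA_real_
  d$G_a[ok] <- gene_abundance(d$G_s[ok], d$R_combined[ok])
  d$haploid_equiv_per_liter <- volumetric_abundance(d$G_a, d$volume_liters)
  d$cells_per_liter <- cells_from_haploid(d$haploid_equiv_per_liter, d$ploidy)
  d$detection_limit <- NA_real_
  d$detection_limit[ok] <- detection_limit(d$R_combined[ok],
                                           d$volume_liters[ok])
  d <- d[order(d$sample_id, d$marker, d$taxon_id),
         c("sample_id", "marker", "taxon_id", "G_s", "R_combined",
           "volume_liters", "ploidy", "G_a", "haploid_equiv_per_liter",
           "cells_per_liter", "detection_limit", "flagged")]
  rownames(d) <- NULL
  d
}
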