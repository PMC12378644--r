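#' Cross-domain input for the cyanobacteria-anchored estimator
#'
#' Bundles, for one sample, the recovered cyanobacterial recA abundance
#' (any unit: molecules per sample or per liter; the unit is carried
#' through), the total cyanobacterial psbO read count, and the per-taxon
#' eukaryotic psbO read counts.
#'
#' @param sample_id Sample id.
#' @param G_recA_cyano Recovered cyanobacterial recA abundance (`>= 0`).
#' @param psbO_cyano Total cyanobacterial psbO reads (`>= 0`; must be
#'   `> 0` for the anchored estimator to be defined).
#' @param psbO_euk_by_taxon Named numeric vector of eukaryote psbO reads.
#' @param unit Free-text unit tag propagated to outputs.
#' @return An object of class `cross_domain_input`.
#' @export
cross_domain_input <- function(sample_id, G_recA_cyano, psbO_cyano,
                               psbO_euk_by_taxon,
                               unit = "haploid_equiv_per_liter") {
  if (G_recA_cyano < 0 || psbO_cyano < 0 || any(psbO_euk_by_taxon < 0))
    stop("counts must be >= 0")
  if (is.null(names(psbO_euk_by_taxon)))
    stop("psbO_euk_by_taxon must be named by taxon")
  structure(list(sample_id = sample_id, G_recA_cyano = G_recA_cyano,
                 psbO_cyano = psbO_cyano,
                 psbO_euk_by_taxon = psbO_euk_by_taxon, unit = unit),
            class = "cross_domain_input")
}

#' Direct psbO quantification of eukaryotic phytoplankton
#'
#' Applies the sample recovery ratio directly to psbO read counts, exactly
#' as for recA: `G_a = G_s / R`, then the volumetric normalization.  When
#' psbO annotation misses a fraction of true psbO reads, this estimator is
#' biased low by that same fraction.
#'
#' @param psbO_euk_reads psbO reads of a eukaryote taxon (vectorized).
#' @param R_combined Sample recovery ratio (`> 0`).
#' @param volume_liters Liters filtered (`> 0`).
#' @return Haploid genome equivalents per liter.
#' @export
euk_abundance_direct <- function(psbO_euk_reads, R_combined, volume_liters) {
  volumetric_abundance(gene_abundance(psbO_euk_reads, R_combined),
                       volume_liters)
}

#' Cyanobacteria-anchored eukaryote quantification
#'
#' `G_euk = G_recA_cyano x psbO_euk / psbO_cyano`.  Anchoring on the
#' (accurate) cyanobacterial recA abundance cancels any psbO undercount
#' common to cyanobacteria and eukaryotes: a shared annotation sensitivity
#' multiplies numerator and denominator alike.  Undefined when no
#' cyanobacterial psbO reads were observed; the record is then flagged and
#' the direct estimator should be reported instead.
#'
#' @param input A [cross_domain_input()].
#' @return List with `per_taxon` (data.frame `taxon_id`, `G_euk`,
#'   `flagged`), `total` (sum over taxa, `NA` when flagged) and `unit`.
#' @export
euk_abundance_eq4 <- function(input) {
  stopifnot(inherits(input, "cross_domain_input"))
  if (input$psbO_cyano == 0) {
    warning(sprintf(
      "sample '%s': no cyanobacterial psbO reads; anchored estimator %s",
      input$sample_id, "undefined, use the direct estimate"))
    per <- data.frame(taxon_id = names(input$psbO_euk_by_taxon),
                      G_euk = NA_real_, flagged = TRUE,
                      stringsAsFactors = FALSE)
    return(list(per_taxon = per, total = NA_real_, unit = input$unit))
  }
  g <- input$G_recA_cyano * input$psbO_euk_by_taxon / input$psbO_cyano
  per <- data.frame(taxon_id = names(input$psbO_euk_by_taxon),
                    G_euk = unname(g), flagged = FALSE,
                    stringsAsFactors = FALSE)
  list(per_taxon = per, total = sum(g), unit = input$unit)
}

#' Eukaryotic phytoplankton abundance from a count table
#'
#' High-level driver applying the direct and/or anchored estimators to
#' every sample of a read-count table.  The anchor `G_recA_cyano` is the
#' recovered volumetric recA abundance summed over cyanobacterial taxa;
#' `psbO_cyano` is the psbO read total over the same taxa.
#'
#' @param counts Read-count data.frame.
#' @param recovery Result of [recovery_table()].
#' @param samples_table data.frame `sample_id`, `volume_liters`.
#' @param domains data.frame `taxon_id`, `domain_label` assigning each
#'   taxon in the count table to a domain.
#' @param estimator `"both"` (default), `"direct"` or `"eq4"` (anchored).
#' @return data.frame `sample_id`, `taxon_id`, `estimator`,
#'   `haploid_equiv_per_liter`, `flagged`.
#' @export
euk_quantify <- function(counts, recovery, samples_table, domains,
                         estimator = c("both", "direct", "eq4")) {
  estimator <- match.arg(estimator)
  agg <- aggregate_counts(counts)
  mk <- merge(agg$markers, domains, by = "taxon_id")
  out <- list()
  for (sid in unique(mk$sample_id)) {
    d <- mk[mk$sample_id == sid, ]
    comb <- recovery$combined[recovery$combined$sample_id == sid, ]
    vol <- samples_table$volume_liters[samples_table$sample_id == sid][1L]
    if (!nrow(comb) || comb$flagged[1L]) next
    R <- comb$R_combined[1L]
    cyano <- d$domain_label == "cyanobacteria"
    euk <- d$domain_label == "eukaryote_phytoplankton" & d$marker == "psbO"
    psbO_euk <- setNames(d$G_s[euk], d$taxon_id[euk])
    if (estimator %in% c("both", "direct")) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, taxon_id = names(psbO_euk), estimator = "direct",
        haploid_equiv_per_liter = euk_abundance_direct(psbO_euk, R, vol),
        flagged = FALSE, stringsAsFactors = FALSE)
    }
    if (estimator %in% c("both", "eq4")) {
      anchor <- volumetric_abundance(
        gene_abundance(sum(d$G_s[cyano & d$marker == "recA"]), R), vol)
      inp <- cross_domain_input(sid, anchor,
                                sum(d$G_s[cyano & d$marker == "psbO"]),
                                psbO_euk)
      e4 <- suppressWarnings(euk_abundance_eq4(inp))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, taxon_id = e4$per_taxon$taxon_id, estimator = "eq4",
        haploid_equiv_per_liter = e4$per_taxon$G_euk,
        flagged = e4$per_taxon$flagged, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
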