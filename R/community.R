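#' @importFrom stats rbinom rmultinom rnorm runif setNames
NULL

.BASES <- c("A", "C", "G", "T")

# uniform random nucleotide string
random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate`
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(.BASES[.BASES != s[i]], 1L)
  paste(s, collapse = "")
}

# fraction of differing positions between two equal-length strings
seq_divergence <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  mean(av != bv)
}

# One marker family: a random ancestor mutated independently per taxon so
# that pairwise divergence stays above `min_divergence` (identity thresholds
# then cleanly separate taxa).
make_marker_family <- function(taxon_ids, len, mut_rate, min_divergence) {
  ancestor <- random_dna(len)
  seqs <- setNames(vapply(taxon_ids, function(t) mutate_seq(ancestor, mut_rate),
                          ""), taxon_ids)
  if (length(seqs) > 1L) {
    for (attempt in 1:20) {
      ok <- TRUE
      for (i in seq_along(seqs)[-1L]) {
        for (j in seq_len(i - 1L)) {
          if (seq_divergence(seqs[[i]], seqs[[j]]) < min_divergence) {
            seqs[[i]] <- mutate_seq(ancestor, mut_rate)
            ok <- FALSE
          }
        }
      }
      if (ok) break
    }
  }
  seqs
}

#' Default synthetic transect configuration
#'
#' Builds the configuration list consumed by [build_transect()].  Defaults
#' encode the stated experimental world: three genomic standards dosed at
#' ~1% of total DNA mass, taxa spanning a 100-fold abundance range
#' (1e7-1e9 cells per liter), haploid single-copy markers, 250-base merged
#' reads, and 1 L filtered per sample.  Genome lengths are desk-scale
#' (0.1-0.2 Mb) stand-ins for real genomes; the recovery calculus depends
#' only on copies x length products, so the scaling is neutral (see the
#' methods vignette).
#'
#' @param n_samples Number of transect samples.
#' @param seed Master RNG seed; per-sample seeds are derived from it.
#' @param n_reads Merged reads per sample.
#' @param read_length Merged read length, bases.
#' @param volume_liters Liters filtered per sample.
#' @param error_rate Per-base substitution error rate.
#' @param dosing_fraction Target standard share of total DNA mass, in (0, 0.5).
#' @param abundance_min,abundance_max Cells per liter spanned by the roster.
#' @param force_endpoints If `TRUE`, per-taxon jitter is disabled so the
#'   max/min truth ratio equals `abundance_max / abundance_min` exactly.
#' @param sample_scale_sd log10 SD of the common per-sample abundance scale
#'   (emulates the productivity gradient along a transect).
#' @param abundance_jitter_sd log10 SD of independent per-taxon, per-sample
#'   abundance jitter (ignored when `force_endpoints = TRUE`).
#' @param per_marker_sensitivity Named annotation sensitivities in (0, 1].
#' @param taxa Optional data.frame (`taxon_id`, `domain_label`,
#'   `genome_length`, `ploidy`) replacing the default 10-taxon roster.
#' @param standards Optional data.frame (`standard_id`, `genome_length`,
#'   `n_genes`) replacing the default three standards.
#' @return A named list, directly serializable to YAML.
#' @export
default_transect_config <- function(n_samples = 3L, seed = 1L, n_reads = 1e5L,
                                    read_length = 250L, volume_liters = 1,
                                    error_rate = 0.002,
                                    dosing_fraction = 0.01,
                                    abundance_min = 1e7, abundance_max = 1e9,
                                    force_endpoints = FALSE,
                                    sample_scale_sd = 0.3,
                                    abundance_jitter_sd = 0.15,
                                    per_marker_sensitivity =
                                      c(recA = 1, radA = 1, psbO = 1),
                                    taxa = NULL, standards = NULL) {
  if (is.null(taxa)) {
    # roster ordered from most to least abundant; mixed domains as in
    # surface ocean communities (abundant heterotrophs and cyanobacteria,
    # rarer archaea and picoeukaryote phytoplankton)
    taxa <- data.frame(
      taxon_id = c("bac_pelagi", "cya_prochloro", "bac_rhodo", "cya_synecho",
                   "bac_flavo", "arc_mgii", "bac_sar116", "euk_chloro",
                   "euk_hapto", "euk_diatom"),
      domain_label = c("bacteria", "cyanobacteria", "bacteria",
                       "cyanobacteria", "bacteria", "archaea", "bacteria",
                       "eukaryote_phytoplankton", "eukaryote_phytoplankton",
                       "eukaryote_phytoplankton"),
      genome_length = c(1e5, 1e5, 1e5, 1e5, 1e5, 1e5, 1e5, 2e5, 2e5, 2e5),
      ploidy = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
      stringsAsFactors = FALSE)
  }
  if (is.null(standards)) {
    standards <- data.frame(standard_id = c("std_A", "std_B", "std_C"),
                            genome_length = c(1e5, 1e5, 1e5),
                            n_genes = c(90L, 90L, 90L),
                            stringsAsFactors = FALSE)
  }
  list(n_samples = as.integer(n_samples), seed = as.integer(seed),
       n_reads = as.integer(n_reads), read_length = as.integer(read_length),
       volume_liters = volume_liters, error_rate = error_rate,
       dosing_fraction = dosing_fraction,
       abundance_min = abundance_min, abundance_max = abundance_max,
       force_endpoints = isTRUE(force_endpoints),
       sample_scale_sd = sample_scale_sd,
       abundance_jitter_sd = abundance_jitter_sd,
       # marker and standard gene lengths are equal by design: the recovery
       # calculus assumes equal per-copy read yield per gene, so length
       # heterogeneity would add a deterministic bias the method does not
       # correct (see methods vignette)
       per_marker_sensitivity = as.list(per_marker_sensitivity),
       marker_lengths = list(recA = 1000L, radA = 1000L, psbO = 1000L),
       marker_mut_rate = 0.15, marker_min_divergence = 0.20,
       gene_length = 1000L, gene_gap = 100L,
       taxa = taxa, standards = standards)
}

#' Build a synthetic spiked transect
#'
#' Generates the full stated world for a multi-sample transect: taxon
#' genomes with embedded single-copy marker loci, marker reference
#' databases with controlled pairwise divergence, three (by default)
#' genomic internal standards, per-sample ground-truth abundances, and
#' per-sample standard doses `S_a` chosen so the standards make up
#' approximately `dosing_fraction` of total DNA mass (mass taken
#' proportional to copies x genome length).  Everything is deterministic
#' given `config$seed`.
#'
#' @param config Configuration list from [default_transect_config()], or a
#'   path to a YAML file with the same structure.
#' @return An object of class `spike_transect`: taxa specs, genome and
#'   marker/standard reference sequences, sample specs, a `truth`
#'   data.frame (per sample x taxon cells and haploid genome equivalents)
#'   and a `standards_table` (per sample x standard `S_p`, `S_a`).
#' @export
build_transect <- function(config = default_transect_config()) {
  if (is.character(config)) config <- read_config(config)
  config <- normalize_config(config)
  taxa_df <- as.data.frame(config$taxa)
  std_df <- as.data.frame(config$standards)
  if (nrow(taxa_df) == 0L) stop("empty taxon roster")
  if (config$dosing_fraction <= 0 || config$dosing_fraction >= 0.5)
    stop("dosing fraction must lie in (0, 0.5)")

  local_seed(config$seed, {
    ml <- config$marker_lengths
    # marker families: psbO is shared by cyanobacteria and eukaryotes
    carriers <- function(marker) taxa_df$taxon_id[vapply(
      taxa_df$domain_label, function(d) marker %in% .domain_markers[[d]],
      NA)]
    fams <- lapply(setNames(nm = c("recA", "radA", "psbO")), function(m) {
      ids <- carriers(m)
      if (!length(ids)) return(setNames(character(), character()))
      make_marker_family(ids, ml[[m]], config$marker_mut_rate,
                         config$marker_min_divergence)
    })

    # taxon genomes with markers embedded at fixed relative positions
    taxa <- vector("list", nrow(taxa_df))
    genomes <- character(nrow(taxa_df))
    for (i in seq_len(nrow(taxa_df))) {
      tid <- taxa_df$taxon_id[i]
      L <- as.integer(taxa_df$genome_length[i])
      need <- .domain_markers[[taxa_df$domain_label[i]]]
      if (L < 4L * (max(unlist(ml)) + config$read_length))
        stop(sprintf("genome of '%s' too short to host marker loci", tid))
      g <- random_dna(L)
      anchors <- c(0.3, 0.6)[seq_along(need)]
      markers <- list()
      for (j in seq_along(need)) {
        m <- need[j]
        seq_m <- fams[[m]][[tid]]
        a <- as.integer(floor(anchors[j] * L))
        b <- a + nchar(seq_m)
        substr(g, a + 1L, b) <- seq_m
        markers[[j]] <- marker_locus(m, a, b, seq_m)
      }
      taxa[[i]] <- taxon_spec(tid, taxa_df$domain_label[i], L,
                              as.integer(taxa_df$ploidy[i]), markers)
      genomes[i] <- g
    }
    names(genomes) <- taxa_df$taxon_id

    # standards: regular gene grid covering ~90% of the genome
    standards <- vector("list", nrow(std_df))
    for (i in seq_len(nrow(std_df))) {
      L <- as.integer(std_df$genome_length[i])
      ng <- as.integer(std_df$n_genes[i])
      pitch <- config$gene_length + config$gene_gap
      if (ng * pitch > L) stop("standard genome too short for its gene grid")
      offset <- as.integer((L - ng * pitch) / 2)
      starts <- offset + (seq_len(ng) - 1L) * pitch
      loci <- data.frame(gene_id = sprintf("%s|g%03d", std_df$standard_id[i],
                                           seq_len(ng)),
                         start = starts, end = starts + config$gene_length,
                         stringsAsFactors = FALSE)
      standards[[i]] <- standard_spec(std_df$standard_id[i], L, loci,
                                      S_a = NA_real_, genome = random_dna(L))
    }
    names(standards) <- std_df$standard_id

    # per-sample ground truth: log-spaced base profile, common per-sample
    # scale, optional independent per-taxon jitter
    nt <- nrow(taxa_df)
    base <- 10^seq(log10(config$abundance_max), log10(config$abundance_min),
                   length.out = nt)
    n_samples <- config$n_samples
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
    scale <- 10^rnorm(n_samples, 0, config$sample_scale_sd)
    truth <- list(); std_rows <- list(); samples <- list()
    for (s in seq_len(n_samples)) {
      jit <- if (config$force_endpoints) rep(1, nt)
             else 10^rnorm(nt, 0, config$abundance_jitter_sd)
      cells <- base * scale[s] * jit
      haploid <- cells * taxa_df$ploidy
      copies <- haploid * config$volume_liters
      mass <- sum(copies * taxa_df$genome_length)
      # dose so standard mass / (community + standard mass) hits the target
      std_mass_total <- config$dosing_fraction / (1 - config$dosing_fraction) *
        mass
      S_a <- pmax(1, round(std_mass_total / nrow(std_df) /
                             std_df$genome_length))
      truth[[s]] <- data.frame(sample_id = sample_ids[s],
                               taxon_id = taxa_df$taxon_id,
                               domain_label = taxa_df$domain_label,
                               genome_length = taxa_df$genome_length,
                               ploidy = taxa_df$ploidy,
                               true_cells_per_liter = cells,
                               haploid_equiv_per_liter = haploid /
                                 config$volume_liters,
                               copies_in_sample = copies,
                               stringsAsFactors = FALSE)
      std_rows[[s]] <- data.frame(sample_id = sample_ids[s],
                                  standard_id = std_df$standard_id,
                                  genome_length = std_df$genome_length,
                                  S_p = vapply(standards, `[[`, 0L, "S_p"),
                                  S_a = S_a, stringsAsFactors = FALSE)
      samples[[s]] <- sample_spec(
        sample_ids[s], config$volume_liters, config$n_reads,
        config$read_length,
        unlist(config$per_marker_sensitivity), sample_seeds[s],
        config$error_rate)
    }
    names(samples) <- sample_ids

    structure(list(taxa = setNames(taxa, taxa_df$taxon_id),
                   genomes = genomes, standards = standards,
                   samples = samples,
                   truth = do.call(rbind, truth),
                   standards_table = do.call(rbind, std_rows),
                   rng = list(kind = RNGkind()[1L], seed = config$seed),
                   config = config),
              class = "spike_transect")
  })
}

#' @export
print.spike_transect <- function(x, ...) {
  cat(sprintf(paste0("<spike_transect> %d taxa, %d standards, %d samples ",
                     "(seed %d, RNG %s)\n"),
              length(x$taxa), length(x$standards), length(x$samples),
              x$rng$seed, x$rng$kind))
  invisible(x)
}

#' Marker reference database of a transect
#'
#' @param transect A `spike_transect`.
#' @return data.frame with columns `ref_id` (`"<marker>|<taxon>"`),
#'   `reference_class`, `source_id` and `seq` — one row per marker locus.
#' @export
marker_references <- function(transect) {
  rows <- list()
  for (tx in transect$taxa) {
    for (m in tx$markers) {
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = paste0(m$marker_name, "|", tx$taxon_id),
        reference_class = m$marker_name, source_id = tx$taxon_id,
        seq = m$sequence, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Standard protein-coding-gene reference database of a transect
#'
#' @param transect A `spike_transect`.
#' @return data.frame as in [marker_references()], `reference_class` fixed
#'   to `"standard_gene"`, one row per standard gene.
#' @export
standard_gene_references <- function(transect) {
  rows <- list()
  for (st in transect$standards) {
    seqs <- substring(st$genome, st$gene_loci$start + 1L, st$gene_loci$end)
    rows[[length(rows) + 1L]] <- data.frame(
      ref_id = st$gene_loci$gene_id, reference_class = "standard_gene",
      source_id = st$standard_id, seq = seqs, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# fill optional config fields and coerce tabular fields from YAML lists
# (either a named list of columns, as yaml::write_yaml() emits for a
# data.frame, or an unnamed sequence of per-row mappings)
normalize_config <- function(config) {
  def <- default_transect_config()
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.null(names(x)))
      do.call(rbind, lapply(x, function(row)
        as.data.frame(row, stringsAsFactors = FALSE)))
    else as.data.frame(x, stringsAsFactors = FALSE)
  }
  config$taxa <- to_df(config$taxa)
  config$standards <- to_df(config$standards)
  config
}
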