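# synthetic_data module: transect construction and read simulation

test_that("build_transect is deterministic and validates its inputs", {
  cfg <- tiny_config(n_samples = 2L, seed = 42L)
  tr1 <- build_transect(cfg)
  tr2 <- build_transect(cfg)
  expect_identical(tr1$genomes, tr2$genomes)
  expect_identical(tr1$truth, tr2$truth)
  expect_identical(tr1$standards_table, tr2$standards_table)

  bad <- cfg; bad$taxa <- cfg$taxa[0, ]
  expect_error(build_transect(bad), "empty taxon roster")
  bad <- cfg; bad$dosing_fraction <- 0.6
  expect_error(build_transect(bad), "dosing fraction")
  bad <- cfg; bad$dosing_fraction <- 0
  expect_error(build_transect(bad), "dosing fraction")
})

test_that("standard dosing hits the configured DNA-mass fraction", {
  for (f in c(0.01, 0.05)) {
    cfg <- tiny_config(n_samples = 3L, seed = 7L, dosing_fraction = f)
    tr <- build_transect(cfg)
    for (sid in unique(tr$truth$sample_id)) {
      tru <- tr$truth[tr$truth$sample_id == sid, ]
      std <- tr$standards_table[tr$standards_table$sample_id == sid, ]
      m_std <- sum(std$S_a * std$genome_length)
      m_all <- m_std + sum(tru$copies_in_sample * tru$genome_length)
      expect_lt(abs(m_std / m_all - f) / f, 0.10)
    }
  }
})

test_that("forced endpoints give an exact 100-fold abundance span", {
  cfg <- tiny_config(n_samples = 3L, seed = 3L, force_endpoints = TRUE,
                     abundance_min = 1e7, abundance_max = 1e9)
  tr <- build_transect(cfg)
  for (sid in unique(tr$truth$sample_id)) {
    v <- tr$truth$true_cells_per_liter[tr$truth$sample_id == sid]
    expect_equal(max(v) / min(v), 100, tolerance = 1e-12)
  }
})

test_that("marker references are mutually divergent and single-copy", {
  tr <- build_transect(tiny_config(seed = 5L))
  mk <- marker_references(tr)
  # single copy per haploid genome
  expect_false(any(duplicated(paste(mk$reference_class, mk$source_id))))
  # controlled divergence within each family keeps identity tiers apart
  for (cl in unique(mk$reference_class)) {
    s <- mk$seq[mk$reference_class == cl]
    if (length(s) < 2) next
    for (i in 2:length(s)) for (j in 1:(i - 1))
      expect_gte(seq_divergence_helper(s[i], s[j]), 0.20)
  }
  # domain rules: cyanobacteria carry recA+psbO, eukaryotes psbO only
  for (tx in tr$taxa) {
    got <- sort(vapply(tx$markers, `[[`, "", "marker_name"))
    want <- sort(switch(tx$domain_label,
                        bacteria = "recA", archaea = "radA",
                        cyanobacteria = c("recA", "psbO"),
                        eukaryote_phytoplankton = "psbO"))
    expect_identical(got, want)
  }
})

test_that("simulation conserves reads and is byte-deterministic", {
  tr <- build_transect(tiny_config(seed = 11L, n_reads = 1500L))
  s1 <- simulate_reads(tr, "S01")
  s2 <- simulate_reads(tr, "S01")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$true_counts, s2$true_counts)
  expect_length(s1$reads, 1500L)
  # per-source counts from the latent source tags also sum to n_reads
  src <- sub(".*\\|src=([^|]+)\\|.*", "\\1", names(s1$reads))
  expect_identical(sum(table(src)), 1500L)
})

test_that("a taxon with zero copies contributes zero reads", {
  tr <- build_transect(tiny_config(seed = 13L, n_reads = 3000L))
  tr$truth$copies_in_sample[tr$truth$taxon_id == "bac_pelagi"] <- 0
  sim <- simulate_reads(tr, "S01")
  src <- sub(".*\\|src=([^|]+)\\|.*", "\\1", names(sim$reads))
  expect_false("bac_pelagi" %in% src)
  tc <- sim$true_counts
  expect_identical(tc$latent_count[tc$taxon_id == "bac_pelagi"], 0L)
})

test_that("annotated equals latent at sensitivity 1, and scales below it", {
  tr <- build_transect(tiny_config(seed = 17L, n_reads = 5000L))
  sim <- simulate_reads(tr, "S01", emit_sequences = FALSE)
  expect_identical(sim$true_counts$annotated_count,
                   sim$true_counts$latent_count)

  # sensitivity 0.72 on psbO: across 100 seeds, annotated/latent within 3
  # sigma of the binomial expectation
  cfg <- tiny_config(seed = 19L, n_reads = 5000L,
                     per_marker_sensitivity = c(recA = 1, radA = 1,
                                                psbO = 0.72))
  tr <- build_transect(cfg)
  lat <- ann <- 0
  for (k in 1:100) {
    s <- tr$samples[["S01"]]
    s$seed <- 20000L + k
    sim <- simulate_reads(tr, s, emit_sequences = FALSE)
    p <- sim$true_counts[sim$true_counts$reference_class == "psbO", ]
    lat <- lat + sum(p$latent_count)
    ann <- ann + sum(p$annotated_count)
  }
  expect_gt(lat, 0)
  sigma <- sqrt(lat * 0.72 * 0.28)
  expect_lt(abs(ann - 0.72 * lat), 3 * sigma)
})

test_that("observed counts match the closed-form expectation within 3 sigma", {
  cfg <- tiny_config(seed = 23L, n_reads = 2000L)
  tr <- build_transect(cfg)
  exp0 <- expected_counts(tr, "S01")
  tot <- setNames(numeric(nrow(exp0)), exp0$reference_id)
  n_seeds <- 100L
  for (k in seq_len(n_seeds)) {
    s <- tr$samples[["S01"]]
    s$seed <- 50000L + k
    sim <- simulate_reads(tr, s, emit_sequences = FALSE)
    stopifnot(identical(sim$true_counts$reference_id, exp0$reference_id))
    tot <- tot + sim$true_counts$annotated_count
  }
  for (i in seq_len(nrow(exp0))) {
    mu <- n_seeds * exp0$expected_annotated[i]
    sigma <- sqrt(max(mu, 1))  # Poisson-scale bound on the binomial sd
    expect_lt(abs(tot[i] - mu), 3 * sigma + 1e-9,
              label = sprintf("count deviation for %s", exp0$reference_id[i]))
  }
})

test_that("effective_positions agrees with the enumeration oracle", {
  set.seed(1)
  for (rep in 1:200) {
    L <- sample(30:300, 1)
    rl <- sample(2:min(60, L), 1)
    a <- sample(0:(L - 1), 1)
    b <- sample((a + 1):L, 1)
    expect_identical(effective_positions(a, b, L, rl),
                     enum_effective_positions(a, b, L, rl),
                     label = sprintf("L=%d rl=%d a=%d b=%d", L, rl, a, b))
  }
})

test_that("doubling abundances and doses leaves expected ratios unchanged", {
  tr <- build_transect(tiny_config(seed = 29L))
  e1 <- expected_counts(tr, "S01")
  tr2 <- tr
  tr2$truth$copies_in_sample <- tr$truth$copies_in_sample * 2
  tr2$standards_table$S_a <- tr$standards_table$S_a * 2
  e2 <- expected_counts(tr2, "S01")
  expect_equal(e2$expected_annotated / sum(e2$expected_annotated),
               e1$expected_annotated / sum(e1$expected_annotated),
               tolerance = 1e-12)
})

test_that("simulation input validation", {
  tr <- build_transect(tiny_config(seed = 31L))
  s <- tr$samples[["S01"]]
  s$read_length <- 2000000L
  expect_error(simulate_reads(tr, s), "read_length exceeds")
  expect_error(sample_spec("x", n_reads = 10, error_rate = -1),
               "negative error rate")
  expect_error(sample_spec("x", volume_liters = 0), "volume_liters")
  tr0 <- tr
  tr0$truth$copies_in_sample[] <- 0
  tr0$standards_table$S_a[] <- 0
  expect_error(simulate_reads(tr0, "S01"), "total DNA mass")
})
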