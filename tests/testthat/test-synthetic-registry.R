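test_that("concentration sampler reproduces the configured triple", {
  uk <- conc_model_defaults()$UK
  cc <- sample_concentrations(50000, uk, seed = 11)
  expect_lt(abs(median(cc$conc_swab1) - uk$median) / uk$median, 0.05)

  # degenerate point-mass model
  pt <- list(median = 7, lo = 7, hi = 7)
  cc0 <- sample_concentrations(100, pt, seed = 12)
  expect_true(all(abs(cc0$conc_swab1 - 7) < 1e-12))
  expect_true(all(abs(cc0$conc_swab2 - 7) < 1e-12))

  # second-swab correlation on the log scale
  cc2 <- sample_concentrations(100000, uk, r = 0.79, seed = 13)
  r_hat <- cor(log(cc2$conc_swab1), log(cc2$conc_swab2))
  expect_gte(r_hat, 0.77)
  expect_lte(r_hat, 0.81)

  expect_error(sample_concentrations(10, list(median = 5, lo = -1, hi = 9)),
               "positive")
})

test_that("allele panels satisfy their contracts", {
  # two alleles, flat law -> 0.5/0.5
  p2 <- build_allele_panel("HLA-A", 2, 0, freq_spec = list(exponent = 0),
                           seed = 21)
  expect_equal(p2$alleles$frequency, c(0.5, 0.5))

  # power-law spectrum: rank-frequency monotone non-increasing, sums to 1
  p <- build_allele_panel("HLA-B", 10, 5,
                          freq_spec = list(exponent = 1.5, novel_mass = 0.01),
                          seed = 22)
  expect_equal(nrow(p$alleles), 15)
  expect_equal(length(unique(p$alleles$sequence)), 15)
  expect_equal(sum(p$alleles$frequency), 1, tolerance = 1e-9)
  known_f <- p$alleles$frequency[p$alleles$known]
  expect_true(all(diff(known_f) <= 1e-12))

  # brute-force all-pairs Hamming distance >= 1 within every amplicon span
  for (amp in p$amplicons$amplicon) {
    spans <- amplicon_sequences(p, amp)
    for (i in seq_along(spans)) {
      for (j in seq_len(i - 1)) {
        d <- sum(strsplit(spans[i], "")[[1]] != strsplit(spans[j], "")[[1]])
        expect_gte(d, 1)
      }
    }
  }

  expect_error(
    build_allele_panel("HLA-A", 30, 0, seq_length = 60,
                       amplicons = data.frame(amplicon = "e2",
                                              start = 0L, end = 20L)),
    "short")
})

test_that("noise-free reads match allele spans exactly and MM yield holds", {
  panel <- make_test_panel(seed = 31)
  cfg <- noise_free_config(rmax = 4000)
  smp <- one_locus_sample(panel, panel$alleles$allele[1:2])
  sim <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 32)
  expect_true(all(sim$truth$class == "on_target"))
  for (amp in panel$amplicons$amplicon) {
    spans <- unname(amplicon_sequences(panel, amp))
    rows <- sim$truth$amplicon == paste("HLA-C", amp, sep = "|")
    expect_true(all(sim$reads$r1[rows] %in% spans))
    r2rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sim$reads$r2[rows])))
    expect_true(all(r2rc %in% spans))
  }

  # half-saturation: C = K_m gives mean on-target R_max/2, within 3 SE
  cfg2 <- noise_free_config(rmax = 2000)
  smp2 <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = 10)
  counts <- vapply(1:100, function(i) {
    nrow(simulate_reads(smp2, list("HLA-C" = panel), cfg2, seed = 100 + i)$reads)
  }, numeric(1))
  mu <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mu - 1000), 3 * se + 1e-9)
})

test_that("configured PD fraction is realised and truth classes partition", {
  panel <- make_test_panel(seed = 41)
  cfg <- noise_free_config(
    rmax = 40000,
    extra = list(pd_model = list(
      knee = 30,
      fluidigm = list(baseline = 0.20, slope = 0),
      plate384 = list(baseline = 0.20, slope = 0))))
  smp <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = 100)
  sim <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 42)
  expect_gt(nrow(sim$reads), 40000)
  pd_hat <- mean(sim$truth$class == "primer_dimer")
  expect_gte(pd_hat, 0.19)
  expect_lte(pd_hat, 0.21)

  # partition and reconciliation with counts
  expect_setequal(sim$truth$read_id, sim$reads$read_id)
  expect_false(any(duplicated(sim$truth$read_id)))
  agg <- aggregate(Freq ~ class, data = sim$counts, sum)
  expect_equal(sum(agg$Freq), nrow(sim$reads))
  expect_equal(agg$Freq[agg$class == "primer_dimer"],
               sum(sim$truth$class == "primer_dimer"))
})

test_that("yield and PD fraction are monotone in concentration; %Q30 falls with PD", {
  panel <- make_test_panel(seed = 51)
  cfg <- registry_config(mm_truth = list(km = 10, rmax = 3000),
                         off_target_rate = 0, error_rate = 0)
  grid <- c(3, 6, 10, 16, 25, 60)
  stats <- t(vapply(grid, function(conc) {
    wf <- route_workflow(conc)
    smp <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = conc,
                            workflow = wf)
    reps <- lapply(1:20, function(i) {
      simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 500 + 37 * i)$truth
    })
    on <- mean(vapply(reps, function(tr) sum(tr$class != "primer_dimer"),
                      numeric(1)))
    pd <- mean(vapply(reps, function(tr) mean(tr$class == "primer_dimer"),
                      numeric(1)))
    c(on = on, pd = pd)
  }, numeric(2)))
  expect_true(all(diff(stats[, "on"]) > -3))  # non-decreasing up to MC noise
  # PD fraction non-increasing below the knee within one workflow (fluidigm
  # rows are conc >= 18)
  flu <- stats[grid >= 18, "pd"]
  pl <- stats[grid >= 2 & grid < 18, "pd"]
  expect_true(all(diff(pl) <= 1e-3))
  expect_true(all(diff(flu) <= 1e-3))

  # emitted %Q30 strictly decreases as configured PD fraction rises
  q30 <- vapply(c(0, 0.15, 0.35), function(pd) {
    cfgq <- noise_free_config(rmax = 3000, extra = list(
      pd_model = list(knee = 30, fluidigm = list(baseline = pd, slope = 0),
                      plate384 = list(baseline = pd, slope = 0))))
    smp <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = 100)
    sim <- simulate_reads(smp, list("HLA-C" = panel), cfgq, seed = 61)
    hlaflow:::fraction_q30(c(sim$reads$q1, sim$reads$q2))
  }, numeric(1))
  expect_true(all(diff(q30) < 0))
})

test_that("same seed gives byte-identical FASTQ; round trips preserve data", {
  panel <- make_test_panel(seed = 71)
  cfg <- registry_config(mm_truth = list(km = 10, rmax = 1500))
  smp <- one_locus_sample(panel, panel$alleles$allele[c(1, 3)], conc = 12,
                          workflow = "plate384")
  sim1 <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 72)
  sim2 <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 72)
  expect_identical(sim1$reads, sim2$reads)
  d <- withr::local_tempdir()
  f1 <- write_fastq(sim1, file.path(d, "a"))
  f2 <- write_fastq(sim2, file.path(d, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))

  back <- read_fastq(f1[1], f1[2])
  expect_equal(back$r1, sim1$reads$r1)
  expect_equal(back$q2, sim1$reads$q2)

  # panel FASTA/TSV round trip
  fp <- file.path(d, "panel.fasta"); sp <- file.path(d, "spans.tsv")
  write_panel(panel, fp, sp)
  p2 <- read_panel(fp, sp)
  expect_equal(p2$alleles$sequence, panel$alleles$sequence)
  expect_equal(p2$alleles$frequency, panel$alleles$frequency)
  expect_equal(p2$alleles$known, panel$alleles$known)
  expect_equal(p2$amplicons$start, panel$amplicons$start)
})

test_that("registry simulation routes workflows consistently with swab1", {
  cfg <- registry_config(n_donors = 300, seed = 81)
  reg <- simulate_registry(cfg)
  s <- reg$samples
  expect_equal(nrow(s), 300)
  expect_true(all(s$workflow == vapply(s$conc_swab1, route_workflow,
                                       character(1))))
  # genotype alleles exist in panels
  for (i in c(1, 150, 300)) {
    for (locus in names(reg$genotypes[[i]])) {
      expect_true(all(reg$genotypes[[i]][[locus]] %in%
                        reg$panels[[locus]]$alleles$allele))
    }
  }
  # novel carriers are exactly the samples whose genotype holds a novel allele
  novel_by_locus <- lapply(reg$panels, function(p)
    p$alleles$allele[!p$alleles$known])
  expected <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    rows <- lapply(names(reg$genotypes[[i]]), function(locus) {
      hit <- unique(intersect(reg$genotypes[[i]][[locus]],
                              novel_by_locus[[locus]]))
      if (length(hit) == 0) return(NULL)
      data.frame(sample_index = i, locus = locus, allele = hit)
    })
    do.call(rbind, rows)
  }))
  if (is.null(expected)) expected <- data.frame(sample_index = integer(0))
  expect_equal(nrow(reg$novel_carriers), nrow(expected))
})
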