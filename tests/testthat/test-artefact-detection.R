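test_that("primer-dimer scan finds adapters where and only where present", {
  ad <- illumina_adapters()
  set.seed(101)
  clean <- hlaflow:::random_dna(50, 250)
  # random 250-mers can contain a 12-mer adapter prefix match by chance only
  # with prob ~ 250 * 37 / 4^12; none expected in 50 reads
  expect_true(all(is.na(detect_primer_dimer(clean, clean))))

  # constructed positive: 20 nt primer + full adapter + tail
  primer <- hlaflow:::random_dna(1, 20)
  tail_ <- hlaflow:::random_dna(1, 250 - 20 - nchar(ad[["r1"]]))
  read <- paste0(primer, ad[["r1"]], tail_)
  expect_equal(detect_primer_dimer(read, NULL), 20L)

  # detection works through the mate and tolerates mismatches
  mism <- read
  substr(mism, 25, 25) <- ifelse(substr(mism, 25, 25) == "A", "C", "A")
  expect_equal(detect_primer_dimer(clean[1], mism, max_mismatches = 1), 20L)
  expect_error(detect_primer_dimer(read, NULL, min_match = 6), ">= 8")
  expect_true(is.na(detect_primer_dimer("", NULL)))
})

test_that("dimer scan agrees with the sliding-window oracle on mixed reads", {
  ad <- illumina_adapters()
  set.seed(102)
  n <- 800
  is_dimer <- runif(n) < 0.4
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    if (is_dimer[i]) {
      plen <- sample(16:24, 1)
      r1[i] <- paste0(hlaflow:::random_dna(1, plen), ad[["r1"]],
                      hlaflow:::random_dna(1, 250 - plen - nchar(ad[["r1"]])))
      r2[i] <- paste0(hlaflow:::random_dna(1, plen), ad[["r2"]],
                      hlaflow:::random_dna(1, 250 - plen - nchar(ad[["r2"]])))
    } else {
      r1[i] <- hlaflow:::random_dna(1, 250)
      r2[i] <- hlaflow:::random_dna(1, 250)
    }
  }
  # sequencing errors at 0.1%
  r1 <- hlaflow:::mutate_bases(r1, 0.001)
  r2 <- hlaflow:::mutate_bases(r2, 0.001)
  got <- detect_primer_dimer(r1, r2)
  want <- oracle_pd_scan(r1, r2, ad)
  expect_identical(got, want)
})

test_that("chimera detector contract holds on constructed cases", {
  # pure parent: never a chimera
  set.seed(111)
  pa <- hlaflow:::random_dna(1, 60)
  pb <- hlaflow:::mutate_bases(pa, 0.25)
  expect_null(detect_chimera(pa, pa, pb))
  expect_null(detect_chimera(pb, pa, pb))

  # forced by construction
  det <- detect_chimera("AAAACCCC", "AAAAAAAA", "CCCCCCCC",
                        min_flank = 2, margin = 1)
  expect_equal(det$breakpoint, 4)
  expect_equal(det$parents, c("A", "B"))

  # symmetry under swapping parents: same split point, order label flips
  det_sw <- detect_chimera("AAAACCCC", "CCCCCCCC", "AAAAAAAA",
                           min_flank = 2, margin = 1)
  expect_equal(det_sw$breakpoint, det$breakpoint)
  expect_equal(det_sw$parents, c("B", "A"))

  expect_error(detect_chimera("AAA", "AAAA", "CCCC"), "equal length")
})

test_that("chimera detector equals exhaustive brute-force search", {
  set.seed(112)
  for (i in 1:200) {
    L <- sample(30:80, 1)
    pa <- hlaflow:::random_dna(1, L)
    pb <- hlaflow:::mutate_bases(pa, runif(1, 0.05, 0.4))
    k <- sample(seq_len(L - 1), 1)
    base <- paste0(substr(pa, 1, k), substr(pb, k + 1, L))
    read <- hlaflow:::mutate_bases(base, runif(1, 0, 0.05))
    got <- detect_chimera(read, pa, pb)
    want <- oracle_chimera(read, pa, pb)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$breakpoint, want$breakpoint)
      expect_equal(got$parents, want$parents)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("noise-free homozygous run classifies 100% on-target", {
  panel <- make_test_panel(seed = 121)
  cfg <- noise_free_config(rmax = 2000)
  smp <- one_locus_sample(panel, rep(panel$alleles$allele[1], 2))
  sim <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 122)
  res <- classify_run(sim, list("HLA-C" = panel))
  expect_true(all(res$classes$class == "on_target"))
  expect_equal(res$metrics$on_target_rate, 1)
  expect_true(all(res$metrics$chimera_rate_by_amplicon == 0, na.rm = TRUE))
  # rates partition
  with(res$metrics, expect_equal(
    pd_rate + on_target_rate + off_target_rate +
      chimera_rate * 0, 1, tolerance = 1e-9))
})

test_that("classification is deterministic and read-order invariant", {
  panel <- make_test_panel(seed = 131)
  cfg <- registry_config(mm_truth = list(km = 10, rmax = 2500))
  smp <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = 25)
  sim <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 132)
  res1 <- classify_run(sim, list("HLA-C" = panel))
  perm <- sample(nrow(sim$reads))
  res2 <- classify_run(sim$reads[perm, ], list("HLA-C" = panel))
  m <- match(res1$classes$read_id, res2$classes$read_id)
  expect_identical(res1$classes$class, res2$classes$class[m])
  expect_identical(res1$classes$breakpoint, res2$classes$breakpoint[m])
  expect_equal(res1$metrics$pd_rate, res2$metrics$pd_rate)
})

test_that("classifier round-trips simulated truth rates", {
  panel <- make_test_panel(seed = 141)
  # PD truth 0.12, chimera at the HLA-C e3 default, mild errors
  cfg <- registry_config(
    mm_truth = list(km = 10, rmax = 18000),
    pd_model = list(knee = 30, fluidigm = list(baseline = 0.12, slope = 0),
                    plate384 = list(baseline = 0.12, slope = 0)),
    off_target_rate = 0.01, error_rate = 0.001,
    dropout_model = list(fluidigm = list(p_max = 0, c50 = 5, scale = 2),
                         plate384 = list(p_max = 0, c50 = 5, scale = 2)))
  smp <- one_locus_sample(panel, panel$alleles$allele[1:2], conc = 100)
  sim <- simulate_reads(smp, list("HLA-C" = panel), cfg, seed = 142)
  res <- classify_run(sim, list("HLA-C" = panel))
  truth_pd <- mean(sim$truth$class == "primer_dimer")
  expect_lt(abs(res$metrics$pd_rate - truth_pd), 0.02)
  # per-read confusion: dimers and off-target essentially perfectly recovered
  m <- match(sim$truth$read_id, res$classes$read_id)
  called <- res$classes$class[m]
  expect_gt(mean(called[sim$truth$class == "primer_dimer"] == "primer_dimer"),
            0.99)
  expect_gt(mean(called[sim$truth$class == "on_target"] == "on_target"), 0.98)
})

test_that("chimera calls are suppressed when parents are outnumbered", {
  panel <- make_test_panel(seed = 151)
  spans <- amplicon_sequences(panel, "e2")
  pa <- unname(spans[1]); pb <- unname(spans[2])
  k <- 125
  chim <- paste0(substr(pa, 1, k), substr(pb, k + 1, nchar(pb)))
  mk_reads <- function(n_pa, n_pb, n_chi) {
    seqs <- c(rep(pa, n_pa), rep(pb, n_pb), rep(chim, n_chi))
    n <- length(seqs)
    data.frame(read_id = sprintf("r%04d", seq_len(n)), r1 = seqs,
               q1 = strrep("I", 250),
               r2 = hlaflow:::revcomp(seqs), q2 = strrep("I", 250),
               stringsAsFactors = FALSE)
  }
  panels <- list("HLA-C" = panel)
  # parents comfortably above the recombinant count -> chimeras called
  res_ok <- classify_run(mk_reads(100, 100, 30), panels)
  expect_equal(sum(res_ok$classes$class == "chimera"), 30)
  # chimeras outnumber a parent -> detection declines, reads stay on-target
  res_bad <- classify_run(mk_reads(100, 10, 40), panels)
  expect_equal(sum(res_bad$classes$class == "chimera"), 0)
  expect_equal(sum(res_bad$classes$class == "on_target"), 150)
})
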