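# Independent brute-force oracles. These deliberately share no code with the
# implementation paths they check: plain loops over every offset/breakpoint.

# Sliding-window adapter scan: leftmost 0-based offset in either mate where a
# `min_match`-long adapter prefix matches with <= max_mismatches.
oracle_pd_scan <- function(r1, r2, adapters, min_match = 12L,
                           max_mismatches = 1L) {
  scan_one <- function(read) {
    best <- NA_integer_
    for (ad in adapters) {
      prefix <- strsplit(substr(ad, 1, min_match), "")[[1]]
      rv <- strsplit(read, "")[[1]]
      if (length(rv) < min_match) next
      for (o in 0:(length(rv) - min_match)) {
        mm <- sum(rv[(o + 1):(o + min_match)] != prefix)
        if (mm <= max_mismatches) { best <- min(best, o, na.rm = TRUE); break }
      }
    }
    best
  }
  p1 <- vapply(r1, scan_one, integer(1), USE.NAMES = FALSE)
  p2 <- vapply(r2, scan_one, integer(1), USE.NAMES = FALSE)
  pmin(p1, p2, na.rm = TRUE)
}

# Exhaustive breakpoint/order search for a single-crossover chimera.
oracle_chimera <- function(read, pa, pb, min_flank = 3L, margin = 2L) {
  rv <- strsplit(read, "")[[1]]
  av <- strsplit(pa, "")[[1]]
  bv <- strsplit(pb, "")[[1]]
  L <- length(rv)
  info <- which(av != bv)
  tot_a <- sum(rv != av); tot_b <- sum(rv != bv)
  best <- NULL
  # AB order scanned first and k ascending, replacing only on strict
  # improvement: first-found minimum realises the AB-then-smallest-k tie-break
  for (ord in c("AB", "BA")) {
    p1 <- if (ord == "AB") av else bv
    p2 <- if (ord == "AB") bv else av
    for (k in 1:(L - 1)) {
      if (sum(info <= k) < min_flank || sum(info > k) < min_flank) next
      sc <- sum(rv[1:k] != p1[1:k]) + sum(rv[(k + 1):L] != p2[(k + 1):L])
      if (is.null(best) || sc < best$score) {
        best <- list(breakpoint = k,
                     parents = if (ord == "AB") c("A", "B") else c("B", "A"),
                     score = sc)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (!(best$score + margin < min(tot_a, tot_b))) return(NULL)
  best
}

# Exhaustive enumeration of E[distinct] for m*n iid draws over J+1 outcomes
# (the last outcome is "known allele", generating no discovery).
oracle_distinct_enumeration <- function(p, m, n) {
  stopifnot(m * n <= 10)
  probs <- c(p, 1 - sum(p))
  J <- length(p)
  draws <- m * n
  grid <- expand.grid(rep(list(seq_len(J + 1)), draws))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    outcome <- as.integer(grid[r, ])
    pr <- prod(probs[outcome])
    total <- total + pr * length(unique(outcome[outcome <= J]))
  }
  total
}

# Brute-force QC filter over a per-sample results table: recompute repeat
# decisions from flag strings alone, independently of the policy engine.
oracle_qc_filter <- function(results, conc, max_failing = 4, min_conc = 2) {
  sample_ids <- unique(results$sample)
  out <- lapply(sample_ids, function(s) {
    rows <- results[results$sample == s, ]
    failing <- rows$locus[nzchar(rows$flags)]
    full <- conc[[s]] < min_conc || length(failing) > max_failing
    list(sample = s, full_repeat = full,
         locus_repeats = if (full) character(0) else failing)
  })
  names(out) <- sample_ids
  out
}

# Shared small fixtures --------------------------------------------------

make_test_panel <- function(locus = "HLA-C", n_known = 8, n_novel = 2,
                            seed = 42) {
  build_allele_panel(locus, n_known = n_known, n_novel = n_novel, seed = seed)
}

noise_free_config <- function(rmax = 6000, extra = list()) {
  args <- list(
    pd_model = list(knee = 30,
                    fluidigm = list(baseline = 0, slope = 0),
                    plate384 = list(baseline = 0, slope = 0)),
    chimera_model = c(default = 0),
    error_rate = 0,
    dropout_model = list(fluidigm = list(p_max = 0, c50 = 5, scale = 2),
                         plate384 = list(p_max = 0, c50 = 5, scale = 2)),
    off_target_rate = 0,
    mm_truth = list(km = 10, rmax = rmax))
  do.call(registry_config, utils::modifyList(args, extra))
}

one_locus_sample <- function(panel, alleles, conc = 40,
                             workflow = "fluidigm") {
  list(id = "T1", conc = conc, workflow = workflow,
       genotype = stats::setNames(list(alleles), panel$locus))
}
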