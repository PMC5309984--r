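# Synthetic registry generator: donor samples, allele panels, genotypes and
# paired-end amplicon reads with the artefact structure observed in
# registry-scale amplicon HLA typing (primer dimers, PCR chimeras, point
# errors, allelic dropout, saturation-shaped read yield).

HLA_LOCI <- c("HLA-A", "HLA-B", "HLA-C", "HLA-DRB1", "HLA-DQB1", "HLA-DPB1")
CLASS1_LOCI <- c("HLA-A", "HLA-B", "HLA-C")
CLASS2_LOCI <- c("HLA-DRB1", "HLA-DQB1", "HLA-DPB1")

#' Per-provenance DNA concentration models
#'
#' Median and 90% central range (5%/95% quantiles) of buccal-swab DNA
#' concentrations in ng/ul for donors recruited in Germany (DE), Poland (PL)
#' and the UK, as observed in large-scale registry operations.
#'
#' @return Named list of lists with elements `median`, `lo`, `hi` (ng/ul).
#' @export
conc_model_defaults <- function() {
  list(
    DE = list(median = 26.5, lo = 4.8, hi = 83.7),
    PL = list(median = 33.5, lo = 5.5, hi = 101.0),
    UK = list(median = 18.7, lo = 3.9, hi = 62.7)
  )
}

#' Illumina read-through adapter sequences
#'
#' Adapter sequences that appear inside a read when the insert (e.g. a primer
#' dimer) is shorter than the read length. Used both by the simulator and by
#' the primer-dimer detector.
#'
#' @return Named character vector with elements `r1` and `r2`.
#' @export
illumina_adapters <- function() {
  c(r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' Registry simulation configuration
#'
#' Bundles every tunable of the synthetic registry: provenance mix,
#' per-provenance log-normal concentration models, second-swab correlation,
#' workflow routing thresholds, the primer-dimer (PD) rate model, per-amplicon
#' chimera rates, the per-base substitution error rate, the allelic-dropout
#' model, and the Michaelis-Menten truth used for read-yield simulation.
#'
#' The PD fraction for a sample at concentration C is
#' `baseline + slope * max(0, knee - C)`, clipped to `[0, 1]`, with
#' workflow-specific baseline and slope (the rise below the knee mirrors the
#' steep increase in PD rates observed at low template concentrations on
#' nanofluidic chips). Dropout probability per allele is logistic in C:
#' `p_max / (1 + exp((C - c50) / scale))`, workflow-specific.
#'
#' @param n_donors Number of donors to simulate.
#' @param provenance_mix Named proportions over DE/PL/UK; must sum to 1.
#' @param conc_model Per-provenance concentration models
#'   (see [conc_model_defaults()]).
#' @param swab2_correlation Target Pearson correlation of the two swab
#'   concentrations on the log scale.
#' @param reject_below,plate384_below Routing thresholds in ng/ul: below
#'   `reject_below` the sample is rejected; in `[reject_below, plate384_below)`
#'   it is processed on 384-well plates; at or above, on the nanofluidic
#'   (fluidigm) workflow.
#' @param pd_model List with per-workflow `baseline` and `slope` (fraction per
#'   ng/ul below the knee) and a shared `knee` (ng/ul).
#' @param chimera_model Named per-amplicon chimera rates (fraction of
#'   heterozygous on-target reads); names `"<locus>|e2"` / `"<locus>|e3"`.
#'   Unnamed default applies to amplicons not listed.
#' @param error_rate Per-base substitution probability applied to every
#'   emitted on-target/chimeric base.
#' @param dropout_model List with per-workflow `p_max`, `c50`, `scale`.
#' @param mm_truth List with `km` (ng/ul) and `rmax` (reads): Michaelis-Menten
#'   truth for total on-target reads per sample.
#' @param off_target_rate Fraction of reads from unrelated templates.
#' @param read_length Read length in nt (paired-end).
#' @param seed Master seed; per-sample child seeds are derived
#'   deterministically from it.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_donors = 100,
                            provenance_mix = c(DE = 0.60, PL = 0.25, UK = 0.15),
                            conc_model = conc_model_defaults(),
                            swab2_correlation = 0.79,
                            reject_below = 2,
                            plate384_below = 18,
                            pd_model = list(
                              knee = 30,
                              fluidigm = list(baseline = 0.0325, slope = 0.034),
                              plate384 = list(baseline = 0.009, slope = 0.027)
                            ),
                            chimera_model = c(
                              "HLA-C|e3" = 0.152,
                              "HLA-DPB1|e3" = 0.001,
                              "HLA-DRB1|e3" = 0.001,
                              default = 0.05
                            ),
                            error_rate = 0.001,
                            dropout_model = list(
                              fluidigm = list(p_max = 0.10, c50 = 5, scale = 2),
                              plate384 = list(p_max = 0.01, c50 = 5, scale = 2)
                            ),
                            mm_truth = list(km = 10, rmax = 60000),
                            off_target_rate = 0.01,
                            read_length = 250,
                            seed = 1L) {
  stopifnot(n_donors >= 1, read_length > 0)
  if (abs(sum(provenance_mix) - 1) > 1e-9 || any(provenance_mix < 0) ||
      any(provenance_mix > 1)) {
    stop("`provenance_mix` must be proportions in [0,1] summing to 1")
  }
  if (!(reject_below < plate384_below)) {
    stop("thresholds must satisfy reject_below < plate384_below")
  }
  rates <- c(error_rate, off_target_rate, chimera_model,
             pd_model$fluidigm$baseline, pd_model$plate384$baseline,
             dropout_model$fluidigm$p_max, dropout_model$plate384$p_max)
  if (any(rates < 0) || any(rates > 1)) stop("all rates must lie in [0,1]")
  if (mm_truth$km <= 0 || mm_truth$rmax <= 0) stop("mm_truth must be positive")
  structure(list(
    n_donors = n_donors, provenance_mix = provenance_mix,
    conc_model = conc_model, swab2_correlation = swab2_correlation,
    reject_below = reject_below, plate384_below = plate384_below,
    pd_model = pd_model, chimera_model = chimera_model,
    error_rate = error_rate, dropout_model = dropout_model,
    mm_truth = mm_truth, off_target_rate = off_target_rate,
    read_length = read_length, seed = as.integer(seed)
  ), class = "registry_config")
}

# Log-normal parameters for a (median, lo, hi) concentration model. sigma is
# the least-squares fit to the two printed 5%/95% quantiles, which for two
# symmetric normal quantiles reduces to the closed form below. The printed
# ranges are not exactly log-symmetric, so the fitted quantiles carry a
# residual misfit; the median is reproduced exactly.
#' @noRd
lognorm_params <- function(model) {
  if (any(c(model$median, model$lo, model$hi) <= 0)) {
    stop("concentration model quantiles must be positive")
  }
  if (!(model$lo <= model$median && model$median <= model$hi)) {
    stop("concentration model must satisfy lo <= median <= hi")
  }
  z <- stats::qnorm(0.95)
  list(mu = log(model$median), sigma = (log(model$hi) - log(model$lo)) / (2 * z))
}

#' Draw correlated swab-pair DNA concentrations
#'
#' Samples (swab1, swab2) concentration pairs from a log-normal calibrated to
#' a (median, 5% quantile, 95% quantile) triple; the second swab is drawn
#' correlated to the first on the log scale.
#'
#' @param n Number of donors.
#' @param model List with `median`, `lo`, `hi` in ng/ul (see
#'   [conc_model_defaults()]). `lo == median == hi` yields a point mass.
#' @param r Target Pearson correlation on the log scale.
#' @param seed Optional seed.
#' @return Data frame with columns `conc_swab1`, `conc_swab2`.
#' @export
sample_concentrations <- function(n, model, r = 0.79, seed = NULL) {
  stopifnot(n >= 1, r >= -1, r <= 1)
  p <- lognorm_params(model)
  with_seed_if(seed, {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    data.frame(
      conc_swab1 = exp(p$mu + p$sigma * z1),
      conc_swab2 = exp(p$mu + p$sigma * z2)
    )
  })
}

#' Power-law allele frequency spectrum
#'
#' Rank-frequency law `p_j` proportional to `j^-exponent`, scaled to a total
#' mass. Used for known-allele panels and for hidden-novel spectra.
#'
#' @param n Number of alleles.
#' @param exponent Power-law exponent (>= 0).
#' @param total_mass Total probability mass to distribute.
#' @return Numeric vector of length `n`, non-increasing, summing to
#'   `total_mass`.
#' @export
power_law_spectrum <- function(n, exponent = 1.5, total_mass = 1) {
  stopifnot(n >= 1, exponent >= 0, total_mass >= 0)
  w <- seq_len(n)^(-exponent)
  total_mass * w / sum(w)
}

#' Build a synthetic allele reference panel
#'
#' Generates a panel of mutually distinct allele sequences for one locus, a
#' configurable number flagged as hidden novel (present in donors, absent from
#' the reference), and per-exon amplicon spans. Every pair of alleles differs
#' by at least one substitution inside every amplicon span, so each amplicon
#' is informative on its own.
#'
#' @param locus Locus identifier (e.g. `"HLA-A"`).
#' @param n_known Number of reference (known) alleles, >= 2.
#' @param n_novel Number of hidden-novel alleles.
#' @param freq_spec List: `exponent` for the known-allele power law,
#'   `novel_mass` total frequency assigned to hidden-novel alleles (split by
#'   the same law).
#' @param seq_length Allelic sequence length in nt (default 730, the average
#'   combined length of the two core exons).
#' @param amplicons Data frame with columns `amplicon`, `start`, `end`
#'   (0-based, half-open spans within the allele sequence). Default: two
#'   250-nt spans named `e2` and `e3`.
#' @param seed Optional seed.
#' @return An object of class `allele_panel`: list with `locus`, `alleles`
#'   (data frame: `allele`, `sequence`, `frequency`, `known`) and `amplicons`.
#' @export
build_allele_panel <- function(locus, n_known, n_novel = 0,
                               freq_spec = list(exponent = 1.5, novel_mass = 0.002),
                               seq_length = 730,
                               amplicons = NULL,
                               seed = NULL) {
  stopifnot(n_known >= 2, n_novel >= 0)
  if (is.null(amplicons)) {
    amplicons <- data.frame(
      amplicon = c("e2", "e3"),
      start = c(40L, 440L),
      end = c(290L, 690L)
    )
  }
  if (any(amplicons$start < 0) || any(amplicons$end > seq_length) ||
      any(amplicons$end <= amplicons$start)) {
    stop("amplicon spans must be non-empty and lie within [0, seq_length)")
  }
  n_total <- n_known + n_novel
  if (min(amplicons$end - amplicons$start) < n_total) {
    stop("seq_length/amplicon spans too short to host the requested diversity")
  }
  with_seed_if(seed, {
    ancestor <- strsplit(random_dna(1, seq_length), "", fixed = TRUE)[[1]]
    make_allele <- function(i) {
      s <- ancestor
      for (a in seq_len(nrow(amplicons))) {
        span <- seq.int(amplicons$start[a] + 1L, amplicons$end[a])
        # one deterministic marker substitution per span guarantees pairwise
        # distinctness within every span; extra random substitutions add
        # realistic diversity
        marker <- span[1L + ((i - 1L) %% length(span))]
        s[marker] <- DNA_BASES[1L + (match(ancestor[marker], DNA_BASES) + (i - 1L) %/% length(span)) %% 4L]
        # hyperpolymorphic spans: alleles differ at ~15-20 positions per
        # exon (~7% divergence), so random pairs carry ~30+ informative sites
        n_extra <- 3L + stats::rpois(1, 15)
        if (n_extra > 0) {
          pos <- sample(setdiff(span, marker), min(n_extra, length(span) - 1L))
          for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
        }
      }
      paste(s, collapse = "")
    }
    seqs <- vapply(seq_len(n_total), make_allele, character(1))
    # repair any residual collision within a span (extras can, rarely, mask a
    # marker): re-roll the offending allele
    repeat {
      clash <- FALSE
      for (a in seq_len(nrow(amplicons))) {
        sub <- substr(seqs, amplicons$start[a] + 1L, amplicons$end[a])
        dup <- which(duplicated(sub))
        if (length(dup) > 0) {
          clash <- TRUE
          for (i in dup) seqs[i] <- make_allele(i)
        }
      }
      if (!clash) break
    }
    short <- sub("^HLA-", "", locus)
    names(seqs) <- c(
      sprintf("%s*k%03d", short, seq_len(n_known)),
      if (n_novel > 0) sprintf("%s*n%03d", short, seq_len(n_novel))
    )
    novel_mass <- if (n_novel > 0) freq_spec$novel_mass %||% 0.002 else 0
    freq <- c(
      power_law_spectrum(n_known, freq_spec$exponent %||% 1.5, 1 - novel_mass),
      if (n_novel > 0) power_law_spectrum(n_novel, freq_spec$exponent %||% 1.5, novel_mass)
    )
    structure(list(
      locus = locus,
      alleles = data.frame(
        allele = names(seqs), sequence = unname(seqs),
        frequency = freq, known = rep(c(TRUE, FALSE), c(n_known, n_novel)),
        stringsAsFactors = FALSE
      ),
      amplicons = amplicons
    ), class = "allele_panel")
  })
}

#' Amplicon-span sequences of a panel
#'
#' @param panel An `allele_panel`.
#' @param amplicon Amplicon id (e.g. `"e2"`).
#' @return Named character vector: per-allele span sequence.
#' @export
amplicon_sequences <- function(panel, amplicon) {
  a <- panel$amplicons[panel$amplicons$amplicon == amplicon, , drop = FALSE]
  if (nrow(a) != 1) stop("unknown amplicon: ", amplicon)
  out <- substr(panel$alleles$sequence, a$start + 1L, a$end)
  names(out) <- panel$alleles$allele
  out
}

#' Write / read an allele panel (FASTA + span TSV)
#'
#' FASTA headers are structured as `locus|allele|frequency|known`; spans go to
#' a tab-separated table with 0-based half-open coordinates.
#'
#' @param panel An `allele_panel`.
#' @param fasta,spans File paths.
#' @return `write_panel` returns the paths invisibly; `read_panel` returns an
#'   `allele_panel`.
#' @export
write_panel <- function(panel, fasta, spans) {
  x <- Biostrings::DNAStringSet(panel$alleles$sequence)
  names(x) <- sprintf("%s|%s|%.10g|%d", panel$locus, panel$alleles$allele,
                      panel$alleles$frequency, as.integer(panel$alleles$known))
  Biostrings::writeXStringSet(x, fasta)
  utils::write.table(cbind(locus = panel$locus, panel$amplicons), spans,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, spans = spans))
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta, spans) {
  x <- Biostrings::readDNAStringSet(fasta)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  sp <- utils::read.table(spans, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(
    locus = parts[[1]][1],
    alleles = data.frame(
      allele = vapply(parts, `[`, character(1), 2),
      sequence = unname(as.character(x)),
      frequency = as.numeric(vapply(parts, `[`, character(1), 3)),
      known = vapply(parts, `[`, character(1), 4) == "1",
      stringsAsFactors = FALSE
    ),
    amplicons = sp[, c("amplicon", "start", "end")]
  ), class = "allele_panel")
}

#' Default six-locus panel set
#'
#' Convenience constructor of one panel per classical HLA locus, with
#' class-specific diversity (more distinct novelty among class I, mirroring
#' the observed class imbalance in discovery rates).
#'
#' @param n_known,n_novel Per-locus allele counts (recycled over loci).
#' @param seed Master seed.
#' @return Named list of `allele_panel` objects.
#' @export
default_panel_set <- function(n_known = 12, n_novel = 4, seed = 1L) {
  panels <- lapply(seq_along(HLA_LOCI), function(i) {
    build_allele_panel(HLA_LOCI[i], n_known = n_known, n_novel = n_novel,
                       seed = child_seed(seed, 7000 + i))
  })
  names(panels) <- HLA_LOCI
  panels
}

# Per-allele dropout probability at concentration C under a workflow.
#' @noRd
dropout_prob <- function(conc, workflow, dropout_model) {
  m <- dropout_model[[workflow]]
  if (is.null(m)) return(0)
  m$p_max / (1 + exp((conc - m$c50) / m$scale))
}

# Configured primer-dimer fraction at concentration C under a workflow.
#' @noRd
pd_fraction <- function(conc, workflow, pd_model) {
  m <- pd_model[[workflow]]
  if (is.null(m)) return(0)
  clamp(m$baseline + m$slope * max(0, pd_model$knee - conc), 0, 1)
}

#' @noRd
chimera_rate_for <- function(chimera_model, amplicon_id) {
  r <- chimera_model[amplicon_id]
  if (is.na(r)) r <- chimera_model["default"]
  if (is.na(r)) r <- 0
  unname(r)
}

# Mildly uneven per-amplicon depth weights (deterministic), normalised to 1.
#' @noRd
amplicon_weights <- function(panels) {
  ids <- unlist(lapply(panels, function(p) {
    paste(p$locus, p$amplicons$amplicon, sep = "|")
  }), use.names = FALSE)
  w <- 0.6 + 0.8 * ((seq_along(ids) * 7L) %% 11L) / 10
  stats::setNames(w / sum(w), ids)
}

# Apply per-base substitution errors to a character vector of sequences.
#' @noRd
mutate_bases <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  n_err <- stats::rbinom(length(seqs), L, error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L, n_err[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# Quality strings: high-quality plateau with runoff tail from `runoff_from`
# (1-based; NA = no runoff).
#' @noRd
make_quals <- function(n, len, runoff_from = NA) {
  vapply(seq_len(n), function(i) {
    q <- sample(33:40, len, replace = TRUE)  # on-target: ~Q37
    rf <- if (length(runoff_from) > 1) runoff_from[i] else runoff_from
    if (!is.na(rf) && rf <= len) {
      q[rf:len] <- sample(2:15, len - rf + 1L, replace = TRUE)
    }
    phred33(q)
  }, character(1))
}

#' Simulate paired-end amplicon reads for one donor sample
#'
#' Emits reads for every amplicon of every locus in the sample's genotype.
#' Total on-target reads follow a Michaelis-Menten yield
#' `R = C/(C + K_m) * R_max` (Poisson about the mean), a concentration- and
#' workflow-dependent fraction are primer dimers (adapter read-through with a
#' low-quality runoff tail), heterozygous amplicons produce single-crossover
#' chimeras at the configured per-amplicon rate, every emitted base is
#' mutated independently at the configured error rate, and alleles drop out
#' with logistic probability at low concentration.
#'
#' @param sample List or one-row data frame with `id`, `conc` (ng/ul),
#'   `workflow` (`"fluidigm"` or `"plate384"`) and `genotype` (named list:
#'   locus -> character(2) allele names).
#' @param panels Named list of `allele_panel` objects covering the genotype.
#' @param config A `registry_config`.
#' @param seed Optional seed (byte-identical output for identical inputs).
#' @return List of class `sim_reads`: `reads` (data frame `read_id`, `r1`,
#'   `q1`, `r2`, `q2`), `truth` (per-read class, amplicon, allele, chimera
#'   parents and 0-based breakpoint), `dropouts`, and `counts` (per-amplicon
#'   per-class tallies).
#' @export
simulate_reads <- function(sample, panels, config, seed = NULL) {
  if (identical(sample$workflow, "rejected")) {
    stop("cannot simulate reads for a rejected sample")
  }
  conc <- sample$conc
  L <- config$read_length
  weights <- amplicon_weights(panels)
  mean_total <- if (conc <= 0) 0 else conc / (conc + config$mm_truth$km) * config$mm_truth$rmax
  pd <- pd_fraction(conc, sample$workflow, config$pd_model)
  off <- config$off_target_rate
  adapters <- illumina_adapters()

  with_seed_if(seed, {
    # per-locus allele dropout, consistent across that locus' amplicons
    dropouts <- list()
    surviving <- list()
    for (locus in names(sample$genotype)) {
      gt <- sample$genotype[[locus]]
      p_drop <- dropout_prob(conc, sample$workflow, config$dropout_model)
      keep <- stats::runif(2) >= p_drop
      if (!any(keep)) keep[sample.int(2, 1)] <- TRUE  # total failure not modelled
      if (!all(keep)) {
        dropouts[[length(dropouts) + 1L]] <- data.frame(
          locus = locus, allele = gt[!keep], stringsAsFactors = FALSE)
      }
      surviving[[locus]] <- gt[keep]
    }

    all_reads <- list()
    all_truth <- list()
    for (locus in names(sample$genotype)) {
      panel <- panels[[locus]]
      if (is.null(panel)) stop("no panel for locus ", locus)
      alleles <- surviving[[locus]]
      for (ai in seq_len(nrow(panel$amplicons))) {
        amp <- panel$amplicons$amplicon[ai]
        amp_id <- paste(locus, amp, sep = "|")
        spans <- amplicon_sequences(panel, amp)
        mean_on <- mean_total * weights[[amp_id]]
        denom <- max(1 - min(pd, 0.99) - off, 0.01)
        n_tot <- stats::rpois(1, mean_on / denom)
        if (n_tot == 0) next
        cls <- sample(c("primer_dimer", "off_target", "on_target"), n_tot,
                      replace = TRUE, prob = c(pd, off, max(0, 1 - pd - off)))
        n <- length(cls)
        r1 <- character(n); r2 <- character(n)
        q1 <- character(n); q2 <- character(n)
        allele_of <- rep(NA_character_, n)
        parent_a <- rep(NA_character_, n)
        parent_b <- rep(NA_character_, n)
        breakpoint <- rep(NA_integer_, n)

        i_on <- which(cls == "on_target")
        if (length(i_on) > 0) {
          src <- sample(alleles, length(i_on), replace = TRUE)
          seqs <- unname(spans[src])
          allele_of[i_on] <- src
          # chimeras: only where the sample is heterozygous within this span
          het <- length(unique(alleles)) == 2 &&
            spans[alleles[1]] != spans[alleles[2]]
          if (het) {
            rate <- chimera_rate_for(config$chimera_model, amp_id)
            is_chi <- stats::runif(length(i_on)) < rate
            if (any(is_chi)) {
              A <- spans[alleles[1]]; B <- spans[alleles[2]]
              av <- strsplit(A, "", fixed = TRUE)[[1]]
              bv <- strsplit(B, "", fixed = TRUE)[[1]]
              inf <- which(av != bv)
              Ls <- nchar(A)
              # breakpoints with >= 1 informative site on each side
              valid_k <- seq_len(Ls - 1)
              valid_k <- valid_k[valid_k > min(inf) - 1 & valid_k < max(inf) + 1]
              valid_k <- valid_k[vapply(valid_k, function(k) {
                any(inf <= k) && any(inf > k)
              }, logical(1))]
              for (j in which(is_chi)) {
                k <- if (length(valid_k) > 1) sample(valid_k, 1) else valid_k
                ord <- sample(c(TRUE, FALSE), 1)
                p1 <- if (ord) alleles[1] else alleles[2]
                p2 <- if (ord) alleles[2] else alleles[1]
                s1 <- if (ord) av else bv
                s2 <- if (ord) bv else av
                seqs[j] <- paste(c(s1[seq_len(k)], s2[(k + 1):Ls]), collapse = "")
                idx <- i_on[j]
                cls[idx] <- "chimera"
                allele_of[idx] <- NA_character_
                parent_a[idx] <- p1; parent_b[idx] <- p2
                breakpoint[idx] <- k  # 0-based: read[0:k) from parent_a
              }
            }
          }
          seqs1 <- mutate_bases(seqs, config$error_rate)
          seqs2 <- mutate_bases(seqs, config$error_rate)
          r1[i_on] <- seqs1
          r2[i_on] <- revcomp(seqs2)
          q1[i_on] <- make_quals(length(i_on), L)
          q2[i_on] <- make_quals(length(i_on), L)
        }

        i_pd <- which(cls == "primer_dimer")
        if (length(i_pd) > 0) {
          plen <- sample(16:24, length(i_pd), replace = TRUE)
          mk <- function(adapter) {
            ins_len <- plen + nchar(adapter)
            vapply(seq_along(i_pd), function(j) {
              tail_len <- L - ins_len[j]
              paste0(random_dna(1, plen[j]), adapter,
                     if (tail_len > 0) random_dna(1, tail_len) else "")
            }, character(1))
          }
          r1[i_pd] <- mk(adapters[["r1"]])
          r2[i_pd] <- mk(adapters[["r2"]])
          runoff <- plen + nchar(adapters[["r1"]]) + 1L
          q1[i_pd] <- make_quals(length(i_pd), L, runoff_from = runoff)
          q2[i_pd] <- make_quals(length(i_pd), L, runoff_from = runoff)
        }

        i_off <- which(cls == "off_target")
        if (length(i_off) > 0) {
          s <- random_dna(length(i_off), L)
          r1[i_off] <- s
          r2[i_off] <- revcomp(random_dna(length(i_off), L))
          q1[i_off] <- make_quals(length(i_off), L)
          q2[i_off] <- make_quals(length(i_off), L)
        }

        ids <- sprintf("%s:%s:%s:%05d", sample$id, locus, amp, seq_len(n))
        all_reads[[length(all_reads) + 1L]] <- data.frame(
          read_id = ids, r1 = r1, q1 = q1, r2 = r2, q2 = q2,
          stringsAsFactors = FALSE)
        all_truth[[length(all_truth) + 1L]] <- data.frame(
          read_id = ids, class = cls, locus = locus, amplicon = amp_id,
          allele = allele_of, parent_a = parent_a, parent_b = parent_b,
          breakpoint = breakpoint, stringsAsFactors = FALSE)
      }
    }
    reads <- if (length(all_reads) > 0) do.call(rbind, all_reads) else
      data.frame(read_id = character(0), r1 = character(0), q1 = character(0),
                 r2 = character(0), q2 = character(0))
    truth <- if (length(all_truth) > 0) do.call(rbind, all_truth) else
      data.frame(read_id = character(0), class = character(0),
                 locus = character(0), amplicon = character(0),
                 allele = character(0), parent_a = character(0),
                 parent_b = character(0), breakpoint = integer(0))
    counts <- as.data.frame(table(amplicon = truth$amplicon, class = truth$class),
                            stringsAsFactors = FALSE)
    structure(list(
      reads = reads, truth = truth,
      dropouts = if (length(dropouts) > 0) do.call(rbind, dropouts) else
        data.frame(locus = character(0), allele = character(0)),
      counts = counts[counts$Freq > 0, , drop = FALSE]
    ), class = "sim_reads")
  })
}

#' Simulate a donor registry
#'
#' Draws donors with provenance, correlated swab concentrations, genotypes
#' (random mating within the panel frequency spectrum) and workflow routing;
#' records which samples carry hidden-novel alleles.
#'
#' @param config A `registry_config`.
#' @param panels Named list of `allele_panel` objects (default:
#'   [default_panel_set()] seeded from the config).
#' @return List of class `sim_registry`: `samples` (sheet with id, provenance,
#'   concentrations, workflow), `genotypes` (per-sample named list),
#'   `novel_carriers` (sample index, locus, allele), and `panels`.
#' @export
simulate_registry <- function(config, panels = NULL) {
  if (is.null(panels)) panels <- default_panel_set(seed = config$seed)
  n <- config$n_donors
  with_seed_if(child_seed(config$seed, 1L), {
    prov <- sample(names(config$provenance_mix), n, replace = TRUE,
                   prob = config$provenance_mix)
    conc <- do.call(rbind, lapply(seq_len(n), function(i) {
      sample_concentrations(1, config$conc_model[[prov[i]]],
                            r = config$swab2_correlation)
    }))
    workflow <- vapply(conc$conc_swab1, route_workflow, character(1),
                       reject_below = config$reject_below,
                       plate384_below = config$plate384_below)
    genotypes <- vector("list", n)
    carriers <- list()
    for (i in seq_len(n)) {
      gt <- lapply(panels, function(p) {
        sample(p$alleles$allele, 2, replace = TRUE, prob = p$alleles$frequency)
      })
      genotypes[[i]] <- gt
      for (locus in names(gt)) {
        p <- panels[[locus]]
        novel <- gt[[locus]][gt[[locus]] %in% p$alleles$allele[!p$alleles$known]]
        for (a in unique(novel)) {
          carriers[[length(carriers) + 1L]] <- data.frame(
            sample_index = i, locus = locus, allele = a,
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(
      samples = data.frame(
        id = sprintf("S%06d", seq_len(n)), provenance = prov,
        conc_swab1 = conc$conc_swab1, conc_swab2 = conc$conc_swab2,
        workflow = workflow, stringsAsFactors = FALSE),
      genotypes = genotypes,
      novel_carriers = if (length(carriers) > 0) do.call(rbind, carriers) else
        data.frame(sample_index = integer(0), locus = character(0),
                   allele = character(0)),
      panels = panels
    ), class = "sim_registry")
  })
}

#' Simulate a per-locus novel-allele discovery ledger
#'
#' Desk-scale generator used to validate the discovery-forecast machinery:
#' each of `n_samples` donors draws `m` alleles; with per-draw probabilities
#' `p` (summing to at most 1) a draw hits a hidden-novel allele and an event
#' is recorded. The closed-form expectation of distinct alleles after n
#' samples is `sum(1 - (1 - p_j)^(m n))` (see [oracle_expected_distinct()]).
#'
#' @param n_samples Number of donors.
#' @param p Per-draw hidden-novel allele probabilities (sum <= 1; the
#'   remainder is known-allele mass and generates no events).
#' @param m Alleles drawn per sample (2 for one locus).
#' @param locus Locus label for the ledger.
#' @param seed Optional seed.
#' @return A `discovery_ledger`.
#' @export
simulate_novel_ledger <- function(n_samples, p, m = 2, locus = "HLA-X",
                                  seed = NULL) {
  stopifnot(n_samples >= 1, m >= 1, all(p >= 0), sum(p) <= 1 + 1e-12)
  with_seed_if(seed, {
    draws <- sample.int(length(p) + 1L, n_samples * m, replace = TRUE,
                        prob = c(p, max(0, 1 - sum(p))))
    sample_of <- rep(seq_len(n_samples), each = m)
    hit <- draws <= length(p)
    discovery_ledger(sample_index = sample_of[hit],
                     allele_id = sprintf("n%05d", draws[hit]),
                     total_samples = n_samples, locus = locus)
  })
}

#' Write / read paired FASTQ files
#'
#' Sanger Phred+33 paired-end FASTQ, `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#'
#' @param reads A `sim_reads` object or its `reads` data frame.
#' @param prefix Output path prefix.
#' @return `write_fastq` returns the two paths invisibly; `read_fastq`
#'   returns a reads data frame (`read_id`, `r1`, `q1`, `r2`, `q2`).
#' @export
write_fastq <- function(reads, prefix) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (mate in 1:2) {
    x <- Biostrings::DNAStringSet(reads[[c("r1", "r2")[mate]]])
    names(x) <- reads$read_id
    Biostrings::writeXStringSet(
      x, paths[mate], format = "fastq",
      qualities = Biostrings::BStringSet(reads[[c("q1", "q2")[mate]]]))
  }
  invisible(paths)
}

#' @rdname write_fastq
#' @param r1,r2 FASTQ paths for the two mates.
#' @export
read_fastq <- function(r1, r2) {
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2)) stop("mate files differ in read count")
  data.frame(
    read_id = sub(" .*", "", names(x1)),
    r1 = unname(as.character(x1)),
    q1 = unname(as.character(S4Vectors::mcols(x1)$qualities)),
    r2 = unname(as.character(x2)),
    q2 = unname(as.character(S4Vectors::mcols(x2)$qualities)),
    stringsAsFactors = FALSE
  )
}
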