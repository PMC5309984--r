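# Read-artefact classification: primer dimers (adapter read-through),
# PCR chimeras (single-crossover recombinants between the two alleles of a
# heterozygote), on-target and off-target reads, plus per-run quality metrics.

#' Detect adapter read-through (primer dimers)
#'
#' Scans forward and reverse reads for an adapter prefix. A primer dimer is an
#' insert formed by primer-primer interaction that is shorter than the read
#' length, so the sequencer runs off the insert into the adapter: the adapter
#' sequence appears inside the read.
#'
#' @param r1,r2 Character vectors of read sequences (`r2` may be `NULL`).
#' @param adapters Character vector of adapter sequences (default
#'   [illumina_adapters()]).
#' @param min_match Minimum length of the adapter prefix that must match
#'   (>= 8).
#' @param max_mismatches Maximum mismatches tolerated within the matched
#'   prefix.
#' @return Integer vector: leftmost 0-based offset of the adapter start in
#'   either mate (`NA` where no adapter is found).
#' @export
detect_primer_dimer <- function(r1, r2 = NULL, adapters = illumina_adapters(),
                                min_match = 12L, max_mismatches = 1L) {
  if (length(adapters) == 0) stop("adapter set must be non-empty")
  if (min_match < 8L) stop("min_match must be >= 8")
  scan_mate <- function(reads) {
    pos <- rep(NA_integer_, length(reads))
    ok <- which(nchar(reads) >= min_match)
    if (length(ok) == 0L) return(pos)
    subj <- Biostrings::DNAStringSet(reads[ok])
    for (ad in adapters) {
      prefix <- substr(ad, 1L, min_match)
      m <- Biostrings::vmatchPattern(prefix, subj,
                                     max.mismatch = max_mismatches)
      starts <- Biostrings::startIndex(m)
      lens <- nchar(reads[ok])
      # drop out-of-limits matches (prefix must lie fully inside the read)
      hit <- vapply(seq_along(starts), function(i) {
        s <- starts[[i]]
        s <- s[s >= 1L & s <= lens[i] - min_match + 1L]
        if (length(s) == 0L) NA_integer_ else min(s) - 1L
      }, integer(1))
      pos[ok] <- pmin(pos[ok], hit, na.rm = TRUE)
    }
    pos
  }
  p <- scan_mate(r1)
  if (!is.null(r2)) p <- pmin(p, scan_mate(r2), na.rm = TRUE)
  p
}

#' Detect a single-crossover chimera between two parent sequences
#'
#' Evaluates every breakpoint `k`: the split score is the mismatch count of
#' `read[0:k)` against the first parent plus that of `read[k:L)` against the
#' second, in both parent orders. The best split is reported only if it beats
#' the better single-parent explanation by more than `margin` mismatches and
#' each side of the breakpoint carries at least `min_flank` informative
#' (parent-discriminating) positions. Ties are broken towards the smallest
#' breakpoint.
#'
#' @param read,parent_a,parent_b Equal-length sequences on a common amplicon
#'   frame.
#' @param min_flank Minimum informative positions on each side.
#' @param margin Required improvement (mismatches) over the best pure parent.
#' @return `NULL` if no chimera is supported, else a list with `breakpoint`
#'   (0-based: positions `[0, breakpoint)` derive from the first listed
#'   parent), `parents` (character(2) `c("A","B")` or `c("B","A")`), and
#'   `score`.
#' @export
detect_chimera <- function(read, parent_a, parent_b, min_flank = 3L,
                           margin = 2L) {
  L <- nchar(read)
  if (nchar(parent_a) != L || nchar(parent_b) != L) {
    stop("read and parents must have equal length")
  }
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  av <- strsplit(parent_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(parent_b, "", fixed = TRUE)[[1]]
  mma <- cumsum(rv != av)            # mismatches vs A in read[1..i]
  mmb <- cumsum(rv != bv)
  tot_a <- mma[L]; tot_b <- mmb[L]
  info <- cumsum(av != bv)           # informative positions up to i
  tot_info <- info[L]
  if (tot_info == 0) return(NULL)
  ks <- seq_len(L - 1)               # breakpoint after position k (0-based k)
  left_info <- info[ks]
  right_info <- tot_info - left_info
  valid <- left_info >= min_flank & right_info >= min_flank
  if (!any(valid)) return(NULL)
  score_ab <- mma[ks] + (tot_b - mmb[ks])  # A then B
  score_ba <- mmb[ks] + (tot_a - mma[ks])  # B then A
  score_ab[!valid] <- Inf
  score_ba[!valid] <- Inf
  best_ab <- min(score_ab); best_ba <- min(score_ba)
  best <- min(best_ab, best_ba)
  if (!(best + margin < min(tot_a, tot_b))) return(NULL)
  # ties: AB order preferred, then smallest k
  if (best_ab <= best_ba) {
    k <- which(score_ab == best)[1]
    list(breakpoint = k, parents = c("A", "B"), score = best)
  } else {
    k <- which(score_ba == best)[1]
    list(breakpoint = k, parents = c("B", "A"), score = best)
  }
}

# Build a k-mer -> amplicon lookup over all allele span sequences.
#' @noRd
kmer_index <- function(panels, k = 15L) {
  keys <- character(0); amps <- character(0)
  for (panel in panels) {
    for (amp in panel$amplicons$amplicon) {
      amp_id <- paste(panel$locus, amp, sep = "|")
      for (s in unique(unname(amplicon_sequences(panel, amp)))) {
        L <- nchar(s)
        starts <- seq.int(1L, L - k + 1L)
        keys <- c(keys, substring(s, starts, starts + k - 1L))
        amps <- c(amps, rep(amp_id, length(starts)))
      }
    }
  }
  keep <- !duplicated(paste(keys, amps))
  data.frame(kmer = keys[keep], amplicon = amps[keep], stringsAsFactors = FALSE)
}

#' Classify every read of a run
#'
#' Pipeline: (1) adapter scan flags primer dimers; (2) remaining reads are
#' assigned to amplicons by shared k-mer vote (k = 15) with identity
#' confirmation by Hamming distance on the aligned span (off-target if best
#' identity falls below `min_identity`); (3) within each amplicon the two most
#' abundant exact sequences act as candidate parents and every other read is
#' tested for a single-crossover chimera. Chimera calls are only retained
#' while each parent's read count is at least `parent_ratio` times the chimera
#' count; otherwise the putative chimeras are left on-target, mimicking the
#' detection failure that occurs when parents are outnumbered by recombinants.
#'
#' @param reads A `sim_reads` object, a reads data frame (`read_id`, `r1`,
#'   `q1`, `r2`, `q2`), or a length-2 character vector of FASTQ paths.
#' @param panels Named list of `allele_panel` objects covering all expected
#'   amplicons.
#' @param adapters Adapter set for the dimer scan.
#' @param min_match,max_mismatches Dimer-scan parameters
#'   (see [detect_primer_dimer()]).
#' @param min_identity Minimum fraction of matching bases against the best
#'   panel sequence for an on-target assignment.
#' @param min_flank,margin Chimera-detection parameters
#'   (see [detect_chimera()]).
#' @param parent_ratio Retention threshold for chimera calls.
#' @return List of class `run_classification`: `classes` (per-read data frame
#'   with `read_id`, `class`, `amplicon`, `parent_a`, `parent_b`,
#'   `breakpoint`, `mismatches`) and `metrics` (see [run_metrics()]).
#' @export
classify_run <- function(reads, panels, adapters = illumina_adapters(),
                         min_match = 12L, max_mismatches = 1L,
                         min_identity = 0.8, min_flank = 3L, margin = 2L,
                         parent_ratio = 1) {
  if (is.character(reads) && length(reads) == 2L) {
    reads <- read_fastq(reads[1], reads[2])
  } else if (inherits(reads, "sim_reads")) {
    reads <- reads$reads
  }
  need <- c("read_id", "r1", "q1", "r2", "q2")
  if (!all(need %in% names(reads))) {
    bad <- which(!stats::complete.cases(reads))[1]
    stop("unreadable read table (record ", bad %||% 1L, ")")
  }
  n <- nrow(reads)
  cls <- rep("off_target", n)
  amplicon <- rep(NA_character_, n)
  parent_a <- rep(NA_character_, n)
  parent_b <- rep(NA_character_, n)
  breakpoint <- rep(NA_integer_, n)
  mism <- rep(NA_real_, n)

  # 1) primer-dimer scan
  pd_pos <- detect_primer_dimer(reads$r1, reads$r2, adapters,
                                min_match = min_match,
                                max_mismatches = max_mismatches)
  is_pd <- !is.na(pd_pos)
  cls[is_pd] <- "primer_dimer"

  # 2) amplicon assignment by k-mer vote on R1
  k <- 15L
  idx <- kmer_index(panels, k)
  amp_ids <- sort(unique(idx$amplicon))
  todo <- which(!is_pd)
  if (length(todo) > 0 && length(amp_ids) > 0) {
    votes <- matrix(0L, nrow = length(todo), ncol = length(amp_ids),
                    dimnames = list(NULL, amp_ids))
    L <- min(nchar(reads$r1[todo]))
    offsets <- unique(pmax(1L, seq.int(1L, L - k + 1L, by = 25L)))
    for (o in offsets) {
      kmers <- substr(reads$r1[todo], o, o + k - 1L)
      hit <- match(kmers, idx$kmer)
      ok <- !is.na(hit)
      if (any(ok)) {
        cols <- match(idx$amplicon[hit[ok]], amp_ids)
        ij <- cbind(which(ok), cols)
        votes[ij] <- votes[ij] + 1L
      }
    }
    has_vote <- rowSums(votes) > 0
    # ties broken by lexicographic amplicon id (columns are sorted)
    best_amp <- amp_ids[apply(votes, 1, which.max)]
    best_amp[!has_vote] <- NA_character_

    # identity confirmation per amplicon group
    for (amp_id in amp_ids) {
      rows <- todo[which(best_amp == amp_id & has_vote)]
      if (length(rows) == 0) next
      parts <- strsplit(amp_id, "|", fixed = TRUE)[[1]]
      panel <- panels[[parts[1]]]
      spans <- amplicon_sequences(panel, parts[2])
      span_len <- nchar(spans[[1]])
      seqs <- substr(reads$r1[rows], 1L, span_len)
      usable <- nchar(seqs) == span_len
      mat <- seq_matrix(seqs[usable])
      if (nrow(mat) > 0) {
        dmin <- rep(Inf, nrow(mat))
        for (ref in unique(unname(spans))) {
          dmin <- pmin(dmin, hamming_to_ref(mat, ref))
        }
        good <- dmin <= (1 - min_identity) * span_len
        r_ok <- rows[usable][good]
        cls[r_ok] <- "on_target"
        amplicon[r_ok] <- amp_id
        mism[r_ok] <- dmin[good]
      }
    }

    # 3) chimera calls per amplicon against the top-2 abundant sequences
    for (amp_id in amp_ids) {
      rows <- which(cls == "on_target" & amplicon == amp_id)
      if (length(rows) < 3) next
      parts <- strsplit(amp_id, "|", fixed = TRUE)[[1]]
      span_len <- nchar(amplicon_sequences(panels[[parts[1]]], parts[2])[[1]])
      seqs <- substr(reads$r1[rows], 1L, span_len)
      tab <- sort(table(seqs), decreasing = TRUE)
      if (length(tab) < 2) next
      pa <- names(tab)[1]; pb <- names(tab)[2]
      if (pa > pb) { tmp <- pa; pa <- pb; pb <- tmp }  # deterministic order
      cand <- rows[seqs != pa & seqs != pb]
      calls <- list()
      for (r in cand) {
        det <- detect_chimera(substr(reads$r1[r], 1L, span_len), pa, pb,
                              min_flank = min_flank, margin = margin)
        if (!is.null(det)) calls[[length(calls) + 1L]] <- list(row = r, det = det)
      }
      n_chi <- length(calls)
      if (n_chi == 0) next
      n_pa <- sum(seqs == pa); n_pb <- sum(seqs == pb)
      if (n_pa >= parent_ratio * n_chi && n_pb >= parent_ratio * n_chi) {
        for (cl in calls) {
          r <- cl$row
          cls[r] <- "chimera"
          first_a <- identical(cl$det$parents[1], "A")
          parent_a[r] <- if (first_a) pa else pb
          parent_b[r] <- if (first_a) pb else pa
          breakpoint[r] <- cl$det$breakpoint
          mism[r] <- cl$det$score
        }
      }
    }
  }

  classes <- data.frame(
    read_id = reads$read_id, class = cls, amplicon = amplicon,
    parent_a = parent_a, parent_b = parent_b, breakpoint = breakpoint,
    mismatches = mism, stringsAsFactors = FALSE)
  list(classes = classes,
       metrics = run_metrics(classes, c(reads$q1, reads$q2))) |>
    structure(class = "run_classification")
}

#' Per-run quality metrics
#'
#' @param classes Per-read class table as produced by [classify_run()].
#' @param quals Character vector of Phred+33 quality strings (both mates).
#' @return List of class `run_metrics`: `pd_rate`, `on_target_rate`,
#'   `off_target_rate`, `chimera_rate` (overall and per amplicon, as the
#'   proportion of on-target + chimeric reads), `pct_q30`, `n_reads`.
#' @export
run_metrics <- function(classes, quals = character(0)) {
  n <- nrow(classes)
  if (n == 0) stop("empty class table")
  tab <- table(factor(classes$class,
                      levels = c("on_target", "primer_dimer", "chimera",
                                 "off_target")))
  per_amp <- vapply(split(classes$class, classes$amplicon), function(cl) {
    denom <- sum(cl %in% c("on_target", "chimera"))
    if (denom == 0) NA_real_ else sum(cl == "chimera") / denom
  }, numeric(1))
  denom_all <- sum(tab[["on_target"]], tab[["chimera"]])
  structure(list(
    n_reads = n,
    pd_rate = tab[["primer_dimer"]] / n,
    on_target_rate = tab[["on_target"]] / n,
    off_target_rate = tab[["off_target"]] / n,
    chimera_rate = if (denom_all == 0) NA_real_ else tab[["chimera"]] / denom_all,
    chimera_rate_by_amplicon = per_amp,
    pct_q30 = fraction_q30(quals)
  ), class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat(sprintf("run metrics over %d read pairs\n", x$n_reads))
  cat(sprintf("  on-target %.3f | primer dimer %.3f | off-target %.3f\n",
              x$on_target_rate, x$pd_rate, x$off_target_rate))
  cat(sprintf("  chimera rate (of on-target+chimera): %.3f\n", x$chimera_rate))
  cat(sprintf("  %%Q30: %.1f%%\n", 100 * x$pct_q30))
  invisible(x)
}
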