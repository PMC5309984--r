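# Simplified per-locus consensus genotype calling from classified on-target
# reads, with novel-allele signature detection. Exact-sequence clustering is
# deliberate: simulator error rates are low, so sequencing errors form minor
# clusters that the cluster-fraction filter removes, and "novel signature"
# stays crisp (a surviving consensus that matches no reference).

LOCUS_FLAGS <- c("low_total_reads", "low_on_target", "imbalance",
                 "excess_alleles", "no_genotype", "novel_signature")

#' Cluster reads of one amplicon by exact sequence
#'
#' Reads carrying any base below `min_base_quality` are discarded, the rest
#' are grouped by exact sequence, and clusters below `min_cluster_frac` of the
#' amplicon's retained reads are dropped. The consensus of an exact-sequence
#' cluster is the sequence itself.
#'
#' @param seqs Character vector of read sequences (amplicon frame).
#' @param quals Optional Phred+33 quality strings (same length as `seqs`).
#' @param min_cluster_frac Minimum cluster size as a fraction of retained
#'   reads.
#' @param min_base_quality Reads with any base below this Phred score are
#'   discarded before clustering.
#' @return Data frame with columns `consensus` and `count`, ordered by
#'   decreasing count (ties: lexicographic consensus); zero rows for zero
#'   usable reads.
#' @export
cluster_reads <- function(seqs, quals = NULL, min_cluster_frac = 0.1,
                          min_base_quality = 10L) {
  if (length(seqs) == 0L) {
    return(data.frame(consensus = character(0), count = integer(0)))
  }
  if (!is.null(quals)) {
    ok <- vapply(quals, function(q) min(phred_scores(q)) >= min_base_quality,
                 logical(1))
    seqs <- seqs[ok]
  }
  if (length(seqs) == 0L) {
    return(data.frame(consensus = character(0), count = integer(0)))
  }
  tab <- table(seqs)
  keep <- tab >= min_cluster_frac * length(seqs)
  tab <- tab[keep]
  o <- order(-as.integer(tab), names(tab))
  data.frame(consensus = names(tab)[o], count = as.integer(tab)[o],
             stringsAsFactors = FALSE)
}

# Candidate allele names whose span sequence equals `consensus`; empty if the
# consensus matches no panel sequence.
#' @noRd
matching_alleles <- function(consensus, spans) {
  names(spans)[spans == consensus]
}

#' Call a per-locus genotype from per-amplicon clusters
#'
#' The top (at most two) clusters of each amplicon are matched exactly
#' against the panel's span sequences; a consistent allele pairing across the
#' exon amplicons yields the genotype. A single surviving cluster produces a
#' homozygous call. A consensus matching no reference is a novel signature
#' and enters pairing as a wildcard placeholder (its other-exon sequence is
#' unknown). Pairing ties prefer pairs that explain every amplicon, then
#' higher summed panel frequency, then lexicographic order.
#'
#' @param clusters Named list: amplicon id -> cluster data frame from
#'   [cluster_reads()].
#' @param panel An `allele_panel`.
#' @param min_depth Minimum per-amplicon read depth; below it the
#'   `low_total_reads` flag is set (100x is the operational sufficiency
#'   threshold for amplicon genotyping).
#' @param min_balance Minimum minor/major read ratio for heterozygous calls.
#' @param on_target_rate Optional on-target proportion of the sample's run;
#'   below `min_on_target` the `low_on_target` flag is set.
#' @param min_on_target Threshold for `on_target_rate`.
#' @return Object of class `locus_result`: list with `locus`, `genotype`
#'   (character(2) or `NA`), `depth` (per amplicon), `balance`, `flags`,
#'   `novel_consensus` (named character of unmatched consensuses, if any).
#' @export
call_genotype <- function(clusters, panel, min_depth = 100,
                          min_balance = 0.25, on_target_rate = NULL,
                          min_on_target = 0.5) {
  if (nrow(panel$alleles) == 0) stop("panel must be non-empty")
  flags <- character(0)
  amps <- names(clusters)
  depth <- vapply(clusters, function(cl) sum(cl$count), numeric(1))
  if (length(depth) == 0 || any(depth < min_depth)) {
    flags <- c(flags, "low_total_reads")
  }
  if (!is.null(on_target_rate) && on_target_rate < min_on_target) {
    flags <- c(flags, "low_on_target")
  }
  if (any(vapply(clusters, nrow, integer(1)) > 2)) {
    flags <- c(flags, "excess_alleles")
  }

  top2 <- lapply(clusters, function(cl) utils::head(cl, 2))
  novel_consensus <- character(0)
  # per-amplicon, per-cluster candidate allele sets (placeholder for novel)
  cand <- list()
  for (amp in amps) {
    spans <- amplicon_sequences(panel, amp)
    cl <- top2[[amp]]
    sets <- lapply(seq_len(nrow(cl)), function(i) {
      m <- matching_alleles(cl$consensus[i], spans)
      if (length(m) > 0) return(m)
      ph <- sprintf("novel:%s:%s:%d", panel$locus, amp, i)
      novel_consensus[[ph]] <<- cl$consensus[i]
      ph
    })
    cand[[amp]] <- list(sets = sets, counts = cl$count)
  }
  if (length(novel_consensus) > 0) flags <- c(flags, "novel_signature")

  is_placeholder <- function(x) startsWith(x, "novel:")
  # a candidate allele "covers" cluster i of amplicon `amp` if its span
  # matches; placeholders cover their own cluster and act as wildcards on
  # other amplicons
  covers <- function(allele, amp, i) {
    sets <- cand[[amp]]$sets
    if (is_placeholder(allele)) {
      if (allele %in% sets[[i]]) return(TRUE)
      return(!any(vapply(sets, function(s) allele %in% s, logical(1))))
    }
    allele %in% sets[[i]]
  }
  pair_consistent <- function(x, y) {
    n_explained <- 0L
    for (amp in amps) {
      k <- length(cand[[amp]]$sets)
      if (k == 0L) next
      ok <- if (k == 1L) {
        covers(x, amp, 1L) && covers(y, amp, 1L)
      } else {
        (covers(x, amp, 1L) && covers(y, amp, 2L)) ||
          (covers(x, amp, 2L) && covers(y, amp, 1L))
      }
      if (!ok) return(NA)
      n_explained <- n_explained + 1L
    }
    n_explained
  }
  universe <- unique(unlist(lapply(cand, function(a) unlist(a$sets))))
  genotype <- NA_character_
  if (length(universe) > 0) {
    freq_of <- function(a) {
      if (is_placeholder(a)) return(0)
      panel$alleles$frequency[match(a, panel$alleles$allele)]
    }
    best <- NULL
    pairs <- expand.grid(i = seq_along(universe), j = seq_along(universe))
    pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      x <- universe[pairs$i[r]]; y <- universe[pairs$j[r]]
      ne <- pair_consistent(x, y)
      if (is.na(ne)) next
      key <- sort(c(x, y))
      score <- c(ne, freq_of(x) + freq_of(y))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2] + 1e-12) ||
          (score[1] == best$score[1] && abs(score[2] - best$score[2]) <= 1e-12 &&
           paste(key, collapse = "/") < paste(best$key, collapse = "/"))) {
        best <- list(key = key, score = score)
      }
    }
    if (!is.null(best)) genotype <- best$key
  }
  if (all(is.na(genotype))) flags <- c(flags, "no_genotype")

  # allele balance: minor/major over the two called clusters, worst amplicon
  balance <- NA_real_
  if (!all(is.na(genotype))) {
    per_amp <- vapply(amps, function(amp) {
      cts <- cand[[amp]]$counts
      if (length(cts) >= 2) min(cts[1:2]) / max(cts[1:2]) else 1
    }, numeric(1))
    balance <- if (length(per_amp) > 0) min(per_amp) else NA_real_
    het <- genotype[1] != genotype[2]
    if (het && !is.na(balance) && balance < min_balance) {
      flags <- c(flags, "imbalance")
    }
  }

  structure(list(
    locus = panel$locus, genotype = genotype, depth = depth,
    balance = balance, flags = intersect(LOCUS_FLAGS, flags),
    novel_consensus = novel_consensus
  ), class = "locus_result")
}

#' Genotype every locus of a classified run
#'
#' Convenience wrapper: groups a run's on-target reads by locus and amplicon,
#' clusters them, and calls each locus.
#'
#' @param classification A `run_classification` from [classify_run()].
#' @param reads The reads used for classification (`sim_reads` or data
#'   frame), needed for sequences and qualities.
#' @param panels Named list of `allele_panel` objects.
#' @param ... Passed to [call_genotype()].
#' @return Named list of `locus_result`, one per locus with on-target reads.
#' @export
genotype_sample <- function(classification, reads, panels, ...) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  cl <- classification$classes
  on_rate <- classification$metrics$on_target_rate
  out <- list()
  for (locus in names(panels)) {
    panel <- panels[[locus]]
    clusters <- list()
    for (amp in panel$amplicons$amplicon) {
      amp_id <- paste(locus, amp, sep = "|")
      rows <- which(cl$class == "on_target" & cl$amplicon == amp_id)
      idx <- match(cl$read_id[rows], reads$read_id)
      span_len <- nchar(amplicon_sequences(panel, amp)[[1]])
      clusters[[amp]] <- cluster_reads(
        substr(reads$r1[idx], 1L, span_len),
        quals = substr(reads$q1[idx], 1L, span_len))
    }
    if (sum(vapply(clusters, nrow, integer(1))) == 0) next
    out[[locus]] <- call_genotype(clusters, panel,
                                  on_target_rate = on_rate, ...)
  }
  out
}

#' @export
print.locus_result <- function(x, ...) {
  gt <- if (all(is.na(x$genotype))) "-" else paste(x$genotype, collapse = " / ")
  cat(sprintf("%s: %s\n", x$locus, gt))
  cat(sprintf("  depth: %s | balance: %s | flags: %s\n",
              paste(x$depth, collapse = ","),
              ifelse(is.na(x$balance), "-", sprintf("%.2f", x$balance)),
              if (length(x$flags) == 0) "none" else
                paste(x$flags, collapse = ",")))
  invisible(x)
}
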