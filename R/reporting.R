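# Summary statistics over results and ledgers: novel-allele accounting,
# maximum PCR error rate, masking probability, and the PD-vs-concentration
# slope. Ships a machine-readable fixture of the published per-locus
# novel-allele counts (registry operations, January 2015 - May 2016).

#' Registry accounting constants (January 2015 - May 2016)
#'
#' Operational totals accompanying the novel-allele fixture: HLA alleles
#' typed, donors typed, allele typings flagged as potential novel, and
#' flagged typings confirmed as bona fide novel.
#'
#' @return Named list: `alleles_typed`, `donors`, `flagged`, `confirmed`.
#' @export
registry_constants <- function() {
  list(alleles_typed = 17184548L, donors = 1432944L,
       flagged = 13835L, confirmed = 3674L)
}

#' Per-locus novel-allele counts fixture
#'
#' Published operational summary (January 2015 - May 2016): per HLA locus,
#' the number of samples typed, the total confirmed novel alleles, and the
#' distinct novel sequences among them.
#'
#' @return Data frame: `locus`, `hla_class` (1 or 2), `samples_typed`,
#'   `total_novel`, `distinct_novel`.
#' @export
table2_novel_alleles <- function() {
  path <- system.file("extdata", "novel_alleles_by_locus.tsv",
                      package = "hlaflow", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$hla_class <- ifelse(df$locus %in% CLASS1_LOCI, 1L, 2L)
  df[, c("locus", "hla_class", "samples_typed", "total_novel",
         "distinct_novel")]
}

#' Maximum PCR error rate
#'
#' Flagged potential-novel typings that failed verification are PCR or
#' sequencing artefacts; their share of all typed alleles bounds the PCR
#' error rate from above: `100 * (flagged - confirmed) / typed` percent.
#'
#' @param n_flagged Allele typings flagged as potential novel.
#' @param n_confirmed Flagged typings confirmed as bona fide novel.
#' @param n_alleles_typed Total allele typings.
#' @return Percentage (not rounded).
#' @export
pcr_error_rate <- function(n_flagged, n_confirmed, n_alleles_typed) {
  if (!(n_confirmed <= n_flagged && n_flagged <= n_alleles_typed)) {
    stop("need n_confirmed <= n_flagged <= n_alleles_typed")
  }
  100 * (n_flagged - n_confirmed) / n_alleles_typed
}

#' Probability that a PCR error masks a true novel allele
#'
#' An artefactual substitution can hide a novel allele only if it lands on
#' the single divergent position and restores the reference base:
#' `error_rate * 1/allele_length * 1/(alphabet - 1)`.
#'
#' @param error_rate Per-typing artefact probability (proportion).
#' @param allele_length Allelic sequence length in bases (default 730, the
#'   combined core exons).
#' @param substitution_alphabet Nucleotide alphabet size.
#' @return List: `probability`, plus the echoed inputs.
#' @export
masking_probability <- function(error_rate, allele_length = 730,
                                substitution_alphabet = 4) {
  stopifnot(error_rate >= 0, allele_length > 0, substitution_alphabet >= 2)
  list(probability = error_rate / (allele_length * (substitution_alphabet - 1)),
       error_rate = error_rate, allele_length = allele_length,
       substitution_alphabet = substitution_alphabet)
}

#' Novel-allele summary with class aggregates
#'
#' Recomputes every derived column from raw per-locus counts: totals,
#' class I (A, B, C) vs class II (DRB1, DQB1, DPB1) aggregates,
#' flagged-allele rate, confirmed fraction, per-class distinct/total
#' fractions, class II : class I ratio, and the maximum PCR error rate.
#' Printed-precision rates use round-half-away-from-zero (three decimals for
#' the flagged rate, one for class fractions, two for the error rate).
#'
#' @param counts Per-locus counts (default [table2_novel_alleles()]); must
#'   cover all six loci with columns `locus`, `total_novel`,
#'   `distinct_novel`.
#' @param n_alleles_typed,n_flagged Accounting totals (defaults from
#'   [registry_constants()]).
#' @return Object of class `novel_allele_summary`.
#' @export
novel_allele_summary <- function(counts = table2_novel_alleles(),
                                 n_alleles_typed = registry_constants()$alleles_typed,
                                 n_flagged = registry_constants()$flagged) {
  missing <- setdiff(HLA_LOCI, counts$locus)
  if (length(missing) > 0) {
    stop("missing loci: ", paste(missing, collapse = ", "))
  }
  if (any(counts$distinct_novel > counts$total_novel)) {
    stop("distinct counts cannot exceed totals")
  }
  cls <- ifelse(counts$locus %in% CLASS1_LOCI, 1L, 2L)
  agg <- function(v, k) sum(v[cls == k])
  total_novel <- sum(counts$total_novel)
  distinct_novel <- sum(counts$distinct_novel)
  class_totals <- c(class1 = agg(counts$total_novel, 1),
                    class2 = agg(counts$total_novel, 2))
  class_distinct <- c(class1 = agg(counts$distinct_novel, 1),
                      class2 = agg(counts$distinct_novel, 2))
  distinct_frac <- ifelse(class_totals > 0,
                          100 * class_distinct / class_totals, 0)
  structure(list(
    per_locus = counts,
    n_alleles_typed = n_alleles_typed,
    n_flagged = n_flagged,
    total_novel = total_novel,
    distinct_novel = distinct_novel,
    class_totals = class_totals,
    class_distinct = class_distinct,
    flagged_rate_pct = if (n_alleles_typed > 0)
      round_half_away(100 * n_flagged / n_alleles_typed, 3) else 0,
    confirmed_fraction_pct = if (n_flagged > 0)
      round_half_away(100 * total_novel / n_flagged, 1) else 0,
    distinct_fraction_pct = round_half_away(distinct_frac, 1),
    class_ratio = if (class_totals[["class1"]] > 0)
      class_totals[["class2"]] / class_totals[["class1"]] else NA_real_,
    max_pcr_error_pct = if (n_alleles_typed > 0)
      round_half_away(pcr_error_rate(n_flagged, total_novel, n_alleles_typed), 2)
      else 0
  ), class = "novel_allele_summary")
}

#' @export
print.novel_allele_summary <- function(x, ...) {
  cat("novel-allele summary\n")
  print(x$per_locus, row.names = FALSE)
  cat(sprintf("  confirmed novel: %d total, %d distinct\n",
              x$total_novel, x$distinct_novel))
  cat(sprintf("  class I vs class II confirmed: %d vs %d (ratio %.2f)\n",
              x$class_totals[["class1"]], x$class_totals[["class2"]],
              x$class_ratio))
  cat(sprintf("  distinct/total: class I %.1f%%, class II %.1f%%\n",
              x$distinct_fraction_pct[["class1"]],
              x$distinct_fraction_pct[["class2"]]))
  cat(sprintf("  flagged rate %.3f%% of %d typed alleles; confirmed fraction %.1f%%\n",
              x$flagged_rate_pct, x$n_alleles_typed, x$confirmed_fraction_pct))
  cat(sprintf("  max PCR error rate %.2f%%\n", x$max_pcr_error_pct))
  cat("  note: the confirmed fraction is recomputed from the raw counts;\n")
  cat("  contemporaneous reports quoted 26.4% where the raw counts give 26.6%.\n")
  invisible(x)
}

#' Primer-dimer vs concentration slope
#'
#' Ordinary least-squares slope of the primer-dimer rate on DNA
#' concentration, restricted to the low-concentration stratum
#' (`conc < conc_ceiling`), reported sign-flipped as percentage points of PD
#' per ng/ul *less* DNA, with a 95% confidence interval from the standard
#' error.
#'
#' @param conc Per-sample DNA concentrations (ng/ul).
#' @param pd_rate Per-sample primer-dimer rates (proportions in [0, 1]).
#' @param conc_ceiling Stratum ceiling in ng/ul.
#' @param min_n Minimum records required in the stratum.
#' @return List: `slope` (% PD per ng/ul less), `ci` (length-2), `n`.
#' @export
pd_concentration_slope <- function(conc, pd_rate, conc_ceiling = 18,
                                   min_n = 100) {
  keep <- conc < conc_ceiling
  conc <- conc[keep]; pd <- 100 * pd_rate[keep]
  if (length(conc) < min_n) stop("need at least ", min_n, " records below the ceiling")
  if (stats::sd(conc) == 0) stop("degenerate concentration variance")
  fit <- stats::lm(pd ~ conc)
  est <- -stats::coef(fit)[["conc"]]
  se <- summary(fit)$coefficients["conc", "Std. Error"]
  tq <- stats::qt(0.975, df = fit$df.residual)
  list(slope = est, ci = c(est - tq * se, est + tq * se), n = length(conc))
}
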