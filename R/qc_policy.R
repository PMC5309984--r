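# Routing, repeat-typing and novel-allele verification rules as a pure,
# auditable decision engine.

REPEAT_FLAGS <- LOCUS_FLAGS  # any of these triggers a locus repeat

#' Route a sample to a processing workflow by DNA concentration
#'
#' Concentrations below 2 ng/ul compromise genotyping severely and the sample
#' is rejected (second-swab extraction path). Low concentrations (below
#' 18 ng/ul) are processed with the 2-PCR 2-primer plate workflow; at or
#' above the threshold the nanofluidic 1-PCR 4-primer workflow is used. Both
#' thresholds are strict "lower than" comparisons.
#'
#' @param conc DNA concentration in ng/ul (>= 0).
#' @param reject_below,plate384_below Thresholds in ng/ul.
#' @return `"rejected"`, `"plate384"` or `"fluidigm"`.
#' @export
route_workflow <- function(conc, reject_below = 2, plate384_below = 18) {
  if (is.na(conc) || conc < 0) stop("concentration must be >= 0")
  if (conc < reject_below) return("rejected")
  if (conc < plate384_below) return("plate384")
  "fluidigm"
}

#' Per-locus repeat-typing decision
#'
#' A locus repeat is requested iff any repeat-triggering quality flag is set
#' (low read numbers, too few reads on target, heavy allele imbalance, more
#' alleles than expected, genotype construction failure, or a potential novel
#' allele, which routinely undergoes verification typing). The reasons echo
#' the flags.
#'
#' @param result A `locus_result`.
#' @param extra_reasons Optional analyst-discretion override codes to append
#'   (hook for external plausibility checks).
#' @return `NULL` if no repeat is needed, else a `repeat_decision` with
#'   `scope = "locus"`, `reasons`, and `triggered_by` (the locus).
#' @export
locus_repeat_decision <- function(result, extra_reasons = character(0)) {
  reasons <- c(intersect(result$flags, REPEAT_FLAGS), extra_reasons)
  if (length(reasons) == 0) return(NULL)
  structure(list(scope = "locus", reasons = unique(reasons),
                 triggered_by = result$locus),
            class = "repeat_decision")
}

#' Sample-level repeat decision
#'
#' A full sample repeat (including a second DNA extraction) is triggered if
#' the initial DNA concentration is below `min_conc` or more than
#' `max_failing` HLA loci fail to produce credible results ("credible" is
#' operationalised as "no repeat-triggering flag"). Otherwise the per-locus
#' decisions pass through unchanged.
#'
#' @param locus_decisions Named list over all HLA loci: `repeat_decision` or
#'   `NULL` per locus.
#' @param conc Initial DNA concentration (ng/ul).
#' @param n_hla_loci Expected number of HLA loci covered.
#' @param min_conc Sample-repeat concentration threshold (strict "less
#'   than").
#' @param max_failing Maximum tolerated failing loci (repeat when strictly
#'   more fail).
#' @return A `repeat_decision` with `scope = "sample"`, or the pass-through
#'   list of per-locus decisions (possibly all `NULL`).
#' @export
sample_repeat_decision <- function(locus_decisions, conc, n_hla_loci = 6,
                                   min_conc = 2, max_failing = 4) {
  if (length(locus_decisions) != n_hla_loci) {
    stop("decisions must cover all ", n_hla_loci, " HLA loci")
  }
  failing <- names(locus_decisions)[!vapply(locus_decisions, is.null,
                                            logical(1))]
  reasons <- character(0)
  if (conc < min_conc) reasons <- c(reasons, "low_concentration")
  if (length(failing) > max_failing) reasons <- c(reasons, "too_many_failed_loci")
  if (length(reasons) > 0) {
    return(structure(list(scope = "sample", reasons = reasons,
                          triggered_by = failing),
                     class = "repeat_decision"))
  }
  locus_decisions
}

#' Verify a potential novel allele against an independent repeat typing
#'
#' A novel-allele signature is confirmed only if the consensus from an
#' independent PCR is byte-identical to the first consensus and still matches
#' no reference allele; any deviation, or a repeat consensus that matches a
#' known allele, marks the first observation as a PCR/sequencing artefact.
#'
#' @param first Consensus sequence carrying the novel signature.
#' @param second Consensus from the independent repeat (`NULL` if not yet
#'   available).
#' @param panel An `allele_panel`.
#' @param amplicon Amplicon id the consensus belongs to.
#' @return List of class `novel_verification`: `first`, `second`, `status`
#'   in `{"pending", "confirmed", "artefact"}`.
#' @export
confirm_novel <- function(first, second = NULL, panel, amplicon) {
  spans <- amplicon_sequences(panel, amplicon)
  if (length(matching_alleles(first, spans)) > 0) {
    stop("`first` does not carry a novel signature against this panel")
  }
  status <- if (is.null(second)) {
    "pending"
  } else if (identical(second, first) &&
             length(matching_alleles(second, spans)) == 0) {
    "confirmed"
  } else {
    "artefact"
  }
  structure(list(first = first, second = second, status = status),
            class = "novel_verification")
}

#' @export
print.repeat_decision <- function(x, ...) {
  cat(sprintf("repeat [%s] reasons: %s (loci: %s)\n", x$scope,
              paste(x$reasons, collapse = ","),
              paste(x$triggered_by, collapse = ",")))
  invisible(x)
}
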