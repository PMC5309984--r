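# Novel-allele discovery forecasting: binned resampling of a discovery
# ledger, a 3-parameter exponential-decay model of the per-bin discovery
# rate, closed-form projection to larger sample counts, and an analytic
# accumulation oracle for validation.

#' Construct a discovery ledger
#'
#' Ordered record of novel-allele observations: each event pairs a sample
#' index with the (possibly re-observed) novel allele id carried by that
#' sample. `total_samples` includes samples with no events.
#'
#' @param sample_index Integer vector of sample indices (1-based).
#' @param allele_id Character vector of allele ids (repeats allowed).
#' @param total_samples Total samples processed (>= max sample index).
#' @param locus Locus label.
#' @return Object of class `discovery_ledger`.
#' @export
discovery_ledger <- function(sample_index, allele_id, total_samples,
                             locus = "HLA-X") {
  stopifnot(length(sample_index) == length(allele_id))
  if (length(sample_index) > 0) {
    stopifnot(all(sample_index >= 1), max(sample_index) <= total_samples)
  }
  o <- order(sample_index)
  structure(list(
    locus = locus,
    events = data.frame(sample_index = as.integer(sample_index[o]),
                        allele_id = as.character(allele_id[o]),
                        stringsAsFactors = FALSE),
    total_samples = as.integer(total_samples)
  ), class = "discovery_ledger")
}

#' Read / write a ledger as TSV
#'
#' Columns `locus`, `sample_index`, `allele_id`; `total_samples` is carried
#' in a `# total_samples=<n>` header line.
#'
#' @param ledger A `discovery_ledger`.
#' @param path File path.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_samples=%d", ledger$total_samples), con)
  utils::write.table(cbind(locus = ledger$locus, ledger$events), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  first <- readLines(path, n = 1)
  total <- as.integer(sub(".*total_samples=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  discovery_ledger(df$sample_index, df$allele_id, total,
                   locus = df$locus[1] %||% "HLA-X")
}

#' Resampled discovery curve
#'
#' For each replicate the samples are randomly permuted (without
#' replacement), partitioned into consecutive bins of `bin_size` samples
#' (`floor(total/bin_size)` bins; a remainder is dropped), and the number of
#' first-ever-seen distinct allele ids per bin recorded. The curve is the
#' per-bin mean over replicates, mimicking successive months of routine
#' typing.
#'
#' @param ledger A `discovery_ledger`.
#' @param bin_size Samples per bin (> 0; total must cover >= 2 bins).
#' @param n_reps Number of random permutations.
#' @param seed Optional seed.
#' @return Object of class `discovery_curve`: `bin_size`, `n_reps`,
#'   `midpoints` (cumulative sample count at bin midpoints), `mean`, `sd`
#'   (over reps), `total_samples`, `observed_distinct`.
#' @export
discovery_curve <- function(ledger, bin_size, n_reps = 30, seed = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (n_reps < 1) stop("n_reps must be >= 1")
  N <- ledger$total_samples
  n_bins <- floor(N / bin_size)
  if (n_bins < 2) stop("total samples must cover at least 2 bins")
  ev <- ledger$events
  alleles <- factor(ev$allele_id)
  with_seed_if(seed, {
    rates <- matrix(0, nrow = n_reps, ncol = n_bins)
    for (rep in seq_len(n_reps)) {
      pos <- sample.int(N)                       # sample -> shuffled position
      ev_pos <- pos[ev$sample_index]
      # first occurrence position per distinct allele
      first_pos <- tapply(ev_pos, alleles, min)
      b <- ceiling(first_pos / bin_size)
      b <- b[b <= n_bins]
      if (length(b) > 0) {
        tb <- tabulate(b, nbins = n_bins)
        rates[rep, ] <- tb
      }
    }
    structure(list(
      bin_size = bin_size, n_reps = n_reps,
      midpoints = (seq_len(n_bins) - 0.5) * bin_size,
      mean = colMeans(rates),
      sd = apply(rates, 2, stats::sd),
      total_samples = N,
      observed_distinct = length(levels(alleles))
    ), class = "discovery_curve")
  })
}

#' Closed-form expected number of distinct alleles
#'
#' Under independent draws of `m` alleles per sample from per-draw
#' probabilities `p`, the expected number of distinct alleles seen after `n`
#' samples is `sum_j (1 - (1 - p_j)^(m * n))`. Serves as the analytic oracle
#' for the resampling estimator and for end-to-end forecast validation.
#'
#' @param p Per-draw allele probabilities (>= 0, sum <= 1).
#' @param m Alleles drawn per sample.
#' @param n Number of samples (vectorised).
#' @return Expected distinct count for each `n`.
#' @export
oracle_expected_distinct <- function(p, m, n) {
  stopifnot(all(p >= 0), sum(p) <= 1 + 1e-12, m >= 1)
  vapply(n, function(nn) sum(1 - (1 - p)^(m * nn)), numeric(1))
}

# Inner constrained linear LS for (a, c) given decay b, on (x, r):
# r ~ c + a * exp(-b x), a >= 0, c >= 0.
#' @noRd
decay_profile <- function(b, x, r) {
  e <- exp(-b * x)
  fit_ac <- function() {
    X <- cbind(1, e)
    cf <- tryCatch(stats::lsfit(X, r, intercept = FALSE)$coefficients,
                   error = function(err) c(mean(r), 0))
    c(cf[[2]], cf[[1]])  # (a, c)
  }
  ac <- fit_ac()
  a <- ac[1]; cc <- ac[2]
  if (a < 0) { a <- 0; cc <- mean(r) }
  if (cc < 0) { cc <- 0; a <- max(0, sum(r * e) / sum(e * e)) }
  list(a = a, c = cc, sse = sum((r - cc - a * e)^2))
}

#' Fit a 3-parameter exponential-decay model to a discovery curve
#'
#' Nonlinear least squares for `r(n) = c + a * exp(-b * n)` on (abscissa,
#' mean per-bin discovery rate). For fixed `b` the amplitude `a` and
#' asymptote `c` solve a non-negative linear problem in closed form; `b` is
#' found by 1-D minimisation on the log scale over a bracket derived from the
#' abscissa range. A non-decaying curve yields the degenerate `a = 0` model
#' with a warning. The nonzero asymptote `c` is what makes long-horizon
#' projections grow approximately linearly.
#'
#' @param curve A `discovery_curve` (>= 4 bins).
#' @param abscissa `"samples"` fits the rate against the cumulative sample
#'   count at bin midpoints; `"bin_index"` against 1..n_bins.
#' @return Object of class `decay_model`: `a`, `b`, `c` (rate units: alleles
#'   per bin; `b` per abscissa unit), `abscissa`, `bin_size`, `sse`.
#' @export
fit_decay <- function(curve, abscissa = c("samples", "bin_index")) {
  abscissa <- match.arg(abscissa)
  x <- if (abscissa == "samples") curve$midpoints else
    seq_along(curve$mean)
  r <- curve$mean
  if (length(r) < 4) stop("need at least 4 bins")
  if (r[length(r)] > r[1]) {
    warning("non-decaying discovery curve: returning degenerate a = 0 model")
    return(structure(list(a = 0, b = 1, c = mean(r), abscissa = abscissa,
                          bin_size = curve$bin_size, sse = sum((r - mean(r))^2)),
                     class = "decay_model"))
  }
  span <- diff(range(x))
  lo <- log(1e-3 / span); hi <- log(50 / max(x[1], span / length(x)))
  opt <- stats::optimize(function(lb) decay_profile(exp(lb), x, r)$sse,
                         interval = c(lo, hi), tol = 1e-12)
  f <- decay_profile(exp(opt$minimum), x, r)
  structure(list(a = f$a, b = exp(opt$minimum), c = f$c, abscissa = abscissa,
                 bin_size = curve$bin_size, sse = f$sse),
            class = "decay_model")
}

#' Project expected distinct novel alleles to larger sample counts
#'
#' Integrates the fitted discovery rate from the observed horizon to each
#' target: `D(N) = D_obs + [c (N - n0) + a/b (exp(-b n0) - exp(-b N))] /
#' bin_size` (closed form for the exponential model; for `abscissa =
#' "bin_index"` the integral runs over bin indices).
#'
#' @param model A `decay_model`.
#' @param observed_distinct Distinct novel alleles observed so far.
#' @param observed_n Samples processed so far.
#' @param targets Sample counts to project to (each > `observed_n`).
#' @return Data frame of class `forecast_table`: `target_n`, `expected`
#'   (exact), `expected_rounded` (nearest integer, half away from zero).
#' @export
project_discoveries <- function(model, observed_distinct, observed_n,
                                targets) {
  if (any(targets <= observed_n)) stop("targets must exceed observed_n")
  rate_integral <- function(n0, n1) {
    if (model$abscissa == "bin_index") {
      n0 <- n0 / model$bin_size
      n1 <- n1 / model$bin_size
      scale <- 1
    } else {
      scale <- 1 / model$bin_size
    }
    decay_part <- if (model$a == 0) 0 else
      model$a / model$b * (exp(-model$b * n0) - exp(-model$b * n1))
    (model$c * (n1 - n0) + decay_part) * scale
  }
  expected <- observed_distinct +
    vapply(targets, function(N) rate_integral(observed_n, N), numeric(1))
  structure(data.frame(
    target_n = targets, expected = expected,
    expected_rounded = round_half_away(expected)
  ), class = c("forecast_table", "data.frame"))
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "exponential decay r(n) = %.4g + %.4g * exp(-%.4g n)  [per %g-sample bin, n in %s]\n",
    x$c, x$a, x$b, x$bin_size, x$abscissa))
  invisible(x)
}
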