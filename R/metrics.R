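#' Construct an ERG trace
#'
#' A flash-electroretinogram trace: voltage samples (uV) at a fixed
#' sampling interval, with the stimulus at time `t0` and the baseline
#' window immediately preceding it.
#'
#' @param voltage_uV numeric vector of samples.
#' @param dt_ms sampling interval, ms (acquisition systems here digitize
#'   at 0.25-0.5 ms).
#' @param luminance_cdsm2 flash luminance, cd s/m^2.
#' @param t0_ms stimulus onset time, ms (samples start at t = 0).
#' @param baseline_ms duration of the pre-stimulus baseline window, ms.
#' @return an object of class `erg_trace`.
#' @export
erg_trace <- function(voltage_uV, dt_ms = 0.5, luminance_cdsm2 = NA,
                      t0_ms = 20, baseline_ms = 20) {
  stopifnot(is.numeric(voltage_uV), dt_ms > 0, baseline_ms > 0)
  if (t0_ms - baseline_ms < 0) {
    stopf("baseline window (%g ms) must fit before stimulus onset (%g ms)",
          baseline_ms, t0_ms)
  }
  structure(list(voltage_uV = as.numeric(voltage_uV), dt_ms = dt_ms,
                 luminance_cdsm2 = luminance_cdsm2, t0_ms = t0_ms,
                 baseline_ms = baseline_ms),
            class = "erg_trace")
}

#' Average repeated ERG traces at one luminance
#'
#' Five traces per flash luminance are averaged pointwise before b-wave
#' measurement.
#'
#' @param traces list of exactly `n_required` [erg_trace()] objects with
#'   identical length, sampling interval and luminance.
#' @param n_required number of repetitions expected (default 5).
#' @return the pointwise-mean `erg_trace`.
#' @export
average_traces <- function(traces, n_required = 5) {
  if (length(traces) != n_required) {
    stopf("expected %d traces to average, got %d", n_required,
          length(traces))
  }
  ref <- traces[[1]]
  for (tr in traces) {
    stopifnot(inherits(tr, "erg_trace"))
    if (length(tr$voltage_uV) != length(ref$voltage_uV) ||
        tr$dt_ms != ref$dt_ms ||
        !isTRUE(all.equal(tr$luminance_cdsm2, ref$luminance_cdsm2))) {
      stopf("traces to average must share length, dt and luminance")
    }
  }
  v <- rowMeans(vapply(traces, `[[`, numeric(length(ref$voltage_uV)),
                       "voltage_uV"))
  erg_trace(v, ref$dt_ms, ref$luminance_cdsm2, ref$t0_ms, ref$baseline_ms)
}

#' b-wave amplitude of an ERG trace
#'
#' Amplitude is the difference between the pre-stimulus baseline (mean
#' over the baseline window) and the post-stimulus peak. The value is
#' signed: it is negative only if the trace never rises above baseline
#' after the flash. Adding a constant offset to the whole trace leaves
#' the amplitude unchanged.
#'
#' @param trace an [erg_trace()].
#' @return amplitude, uV.
#' @export
bwave_amplitude <- function(trace) {
  stopifnot(inherits(trace, "erg_trace"))
  t <- (seq_along(trace$voltage_uV) - 1) * trace$dt_ms
  base_idx <- t >= (trace$t0_ms - trace$baseline_ms) & t < trace$t0_ms
  post_idx <- t >= trace$t0_ms
  if (!any(post_idx)) stopf("trace has no post-stimulus samples")
  if (!any(base_idx)) stopf("trace has no baseline samples")
  max(trace$voltage_uV[post_idx]) - mean(trace$voltage_uV[base_idx])
}

#' Psychometric threshold at a success-rate criterion
#'
#' Implements the visual water-task readout: a stimulus level counts as
#' perceived when the success rate is strictly above the criterion
#' (default 70 percent of trials). For acuity
#' (`direction = "highest_passing"`) the threshold is the highest spatial
#' frequency such that it and every easier (lower) level pass; for
#' contrast sensitivity (`direction = "lowest_passing"`) it is the lowest
#' contrast such that it and every easier (higher-contrast) level pass.
#' Requiring a monotone run of passing levels guards against isolated
#' lapses. No interpolation between tested levels is performed.
#'
#' @param levels strictly monotone stimulus levels (cycles/degree or
#'   percent contrast).
#' @param successes,trials per-level trial outcomes.
#' @param criterion success-rate criterion (strict inequality).
#' @param direction `"highest_passing"` (acuity) or `"lowest_passing"`
#'   (contrast).
#' @return the threshold level, or `NA` if no level passes.
#' @examples
#' perception_threshold(c(0.087, 0.2, 0.3, 0.4, 0.55),
#'                      successes = c(9, 8, 7.5, 6, 5) * 2,
#'                      trials = rep(20, 5))  # 0.3 cycles/degree
#' @export
perception_threshold <- function(levels, successes, trials,
                                 criterion = 0.70,
                                 direction = c("highest_passing",
                                               "lowest_passing")) {
  direction <- match.arg(direction)
  stopifnot(length(levels) >= 1,
            length(successes) == length(levels),
            length(trials) == length(levels))
  d <- diff(levels)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stopf("stimulus levels must be strictly monotone")
  }
  ord <- order(levels)  # easy -> hard for acuity
  if (direction == "lowest_passing") ord <- rev(ord)  # easy = high contrast
  if (any(successes < 0) || any(successes > trials)) {
    stopf("successes must lie in [0, trials]")
  }
  pass <- (successes / trials) > criterion
  pass <- pass[ord]
  run <- which(!pass)
  last <- if (length(run)) run[1] - 1 else length(pass)
  if (last < 1) return(NA_real_)
  levels[ord][last]
}

#' Relative quantification by the delta-delta-Ct method
#'
#' For one sample, `dCt = mean(target Cts) - mean(reference Cts)`
#' (reference gene: GAPDH in the original design), `ddCt = dCt -
#' calibrator_dct` (calibrator: the standard-housing group), and the
#' relative quantity is `2^(-ddCt)`. Triplicate Cts are expected;
#' replicate scatter above `sd_cutoff` flags the result without dropping
#' it.
#'
#' @param target_ct numeric Ct replicates of the target gene (3).
#' @param reference_ct numeric Ct replicates of the reference gene (3).
#' @param calibrator_dct delta-Ct of the calibrator group.
#' @param sd_cutoff replicate standard-deviation QC threshold.
#' @param n_replicates expected replicate count.
#' @return list with `dct`, `ddct`, `rq` and `flagged`.
#' @export
ddct_rq <- function(target_ct, reference_ct, calibrator_dct,
                    sd_cutoff = 0.5, n_replicates = 3) {
  if (length(target_ct) != n_replicates ||
      length(reference_ct) != n_replicates) {
    stopf("expected %d Ct replicates per gene", n_replicates)
  }
  if (any(c(target_ct, reference_ct) <= 0)) stopf("Ct values must be > 0")
  dct <- mean(target_ct) - mean(reference_ct)
  ddct <- dct - calibrator_dct
  list(dct = dct, ddct = ddct, rq = 2^(-ddct),
       flagged = sd(target_ct) > sd_cutoff || sd(reference_ct) > sd_cutoff)
}

#' Delta-delta-Ct table for a Ct CSV
#'
#' Processes a table with columns `sample, group, gene, ct1, ct2, ct3`
#' containing target genes plus the reference gene. Per sample,
#' `dCt = mean(gene Ct) - mean(reference Ct)`; the calibrator is the mean
#' `dCt` of the `calibrator_group` per gene, so that group averages to
#' `Rq = 1` on the log scale and the other group is expressed relative to
#' it.
#'
#' @param ct table (data frame or CSV path).
#' @param reference_gene reference (housekeeping) gene name.
#' @param calibrator_group group used as calibrator (e.g. `"ST"`).
#' @param sd_cutoff replicate QC threshold, Ct units.
#' @return data frame with one row per sample x target gene: `dct`,
#'   `ddct`, `rq`, `flagged`.
#' @export
ddct_table <- function(ct, reference_gene = "GAPDH",
                       calibrator_group = "ST", sd_cutoff = 0.5) {
  if (is.character(ct)) ct <- read.csv(ct, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct1", "ct2", "ct3")
  if (!all(need %in% names(ct))) {
    stopf("Ct table needs columns: %s", paste(need, collapse = ", "))
  }
  cts <- as.matrix(ct[, c("ct1", "ct2", "ct3")])
  ct$ct_mean <- rowMeans(cts)
  ct$ct_sd <- apply(cts, 1, sd)
  refs <- ct[ct$gene == reference_gene, ]
  if (!nrow(refs)) stopf("reference gene '%s' absent from table", reference_gene)
  targets <- ct[ct$gene != reference_gene, ]
  ref_mean <- setNames(refs$ct_mean, refs$sample)
  ref_sd <- setNames(refs$ct_sd, refs$sample)
  if (anyNA(ref_mean[targets$sample])) {
    stopf("some samples lack reference-gene Cts")
  }
  targets$dct <- targets$ct_mean - ref_mean[targets$sample]
  cal <- tapply(targets$dct[targets$group == calibrator_group],
                targets$gene[targets$group == calibrator_group], mean)
  if (anyNA(cal[targets$gene])) {
    stopf("calibrator group '%s' missing for some gene", calibrator_group)
  }
  targets$ddct <- targets$dct - as.numeric(cal[targets$gene])
  targets$rq <- 2^(-targets$ddct)
  targets$flagged <- targets$ct_sd > sd_cutoff |
    ref_sd[targets$sample] > sd_cutoff
  rownames(targets) <- NULL
  targets[, c("sample", "group", "gene", "dct", "ddct", "rq", "flagged")]
}

#' Normalize a densitometry band reading to its loading control
#'
#' @param band band optical density.
#' @param loading_control loading-control (beta-actin / alpha-tubulin)
#'   density from the same lane; must be positive.
#' @return ratio `band / loading_control` (vectorized).
#' @export
densitometry_normalize <- function(band, loading_control) {
  if (any(loading_control <= 0)) stopf("loading control must be positive")
  band / loading_control
}

#' Percent difference between two group means
#'
#' Densitometry group comparisons are reported as the percent difference
#' of group mean normalized readings (e.g. +35 means 35 percent higher in
#' the first group).
#'
#' @param mean_a,mean_b group means; `mean_b` is the reference.
#' @return percent difference, `100 * (mean_a/mean_b - 1)`.
#' @export
group_percent_difference <- function(mean_a, mean_b) {
  if (mean_b <= 0) stopf("reference group mean must be positive")
  100 * (mean_a / mean_b - 1)
}

#' Read an ERG trace CSV
#'
#' Expects columns `time_ms,voltage_uV` with uniform sampling.
#'
#' @param path CSV file.
#' @param luminance_cdsm2 flash luminance for the file.
#' @param t0_ms,baseline_ms stimulus onset and baseline duration, ms.
#' @return an [erg_trace()].
#' @export
read_erg_csv <- function(path, luminance_cdsm2 = NA, t0_ms = 20,
                         baseline_ms = 20) {
  d <- read.csv(path)
  stopifnot(all(c("time_ms", "voltage_uV") %in% names(d)))
  dt <- diff(d$time_ms)
  if (any(abs(dt - dt[1]) > 1e-9)) stopf("ERG samples must be uniform in time")
  erg_trace(d$voltage_uV, dt[1], luminance_cdsm2, t0_ms, baseline_ms)
}
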