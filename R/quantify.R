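#' Loading-control normalized signal
#'
#' Ratio of a target readout to its loading control: band intensity over
#' actin, chemiluminescence over nuclei count, transcript level over a
#' housekeeping gene.
#'
#' @param target_signal non-negative target intensity (AU).
#' @param control_signal positive control intensity (AU).
#' @return `target_signal / control_signal`, vectorised.
#' @export
normalized_signal <- function(target_signal, control_signal) {
  if (any(!is.finite(target_signal)) || any(!is.finite(control_signal)))
    stop("signals must be finite", call. = FALSE)
  if (any(target_signal < 0))
    stop("target signal must be non-negative", call. = FALSE)
  if (any(control_signal <= 0))
    stop("control signal must be > 0", call. = FALSE)
  target_signal / control_signal
}

#' Fold change relative to a reference condition
#'
#' Ratio of means (not mean of ratios) of normalized signals, matching the
#' convention of reporting condition values relative to a control
#' condition.
#'
#' @param samples normalized signals of the condition of interest.
#' @param reference normalized signals of the reference condition.
#' @return `mean(samples) / mean(reference)`.
#' @export
relative_fold_change <- function(samples, reference) {
  if (length(samples) < 1L || length(reference) < 1L)
    stop("need at least one value per group", call. = FALSE)
  mr <- mean(reference)
  if (!is.finite(mr) || mr <= 0)
    stop("undefined fold change: reference mean must be > 0", call. = FALSE)
  mean(samples) / mr
}

#' Replicate mean and standard error
#'
#' @param values replicate measurements.
#' @return list with `mean` and `sem` (`SD/sqrt(n)`; `NA` when n < 2).
#' @export
replicate_summary <- function(values) {
  if (length(values) < 1L) stop("empty value vector", call. = FALSE)
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Summarise an intensity table with fold changes vs a reference condition
#'
#' Normalizes each measurement to its loading control, summarises each
#' condition (mean, SEM over replicates), and reports each condition's
#' fold change relative to the named reference.
#'
#' @param intensities data.frame `sample_id`, `condition`, `replicate`,
#'   `target_signal`, `control_signal`.
#' @param reference_condition condition label used as fold-change
#'   denominator.
#' @return data.frame per condition: `n`, `mean`, `sem`, `fold_change`.
#' @export
quantify_intensities <- function(intensities, reference_condition) {
  need <- c("condition", "replicate", "target_signal", "control_signal")
  stopifnot(all(need %in% names(intensities)))
  if (!reference_condition %in% intensities$condition)
    stop("reference condition not present: ", reference_condition, call. = FALSE)
  intensities$norm <- normalized_signal(intensities$target_signal,
                                        intensities$control_signal)
  sp <- split(intensities$norm, intensities$condition)
  ref <- sp[[reference_condition]]
  out <- do.call(rbind, lapply(names(sp), function(cond) {
    s <- replicate_summary(sp[[cond]])
    data.frame(condition = cond, n = length(sp[[cond]]),
               mean = s$mean, sem = s$sem,
               fold_change = relative_fold_change(sp[[cond]], ref),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition), , drop = FALSE]
}
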