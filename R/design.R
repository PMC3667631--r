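#' Screen design
#'
#' Describes the physical layout of a plate screen: how many genes are
#' tested, the plate geometry, how many replicate plate sets are run, and
#' how many control wells of each type sit on every plate. Controls occupy
#' fixed positions (the last column(s), filled top to bottom, mock +PMA
#' first), and sample wells fill the remaining grid in column-major order,
#' plate by plate. The layout is a pure function of the design: it does not
#' depend on the seed, so reseeding changes signals but never well
#' positions.
#'
#' @param n_genes number of genes (one siRNA pool per gene), each assigned
#'   to exactly one well position, identical across replicates.
#' @param wells_per_plate plate size; must equal `n_rows * n_cols`.
#' @param n_rows,n_cols plate geometry (default 8 x 12, a 96-well plate).
#' @param n_replicates number of replicate plate sets (default 3).
#' @param controls_per_plate named integer vector giving the number of
#'   mock-control wells per plate for each control type
#'   (`mock_plusPMA`, `mock_minusPMA`).
#' @param sample_wells_per_plate number of gene wells per plate; defaults
#'   to all wells not used by controls.
#' @param seed integer seed for all randomness in the generator.
#'
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(n_genes,
                          wells_per_plate = 96L,
                          n_rows = 8L,
                          n_cols = 12L,
                          n_replicates = 3L,
                          controls_per_plate = c(mock_plusPMA = 4L,
                                                 mock_minusPMA = 4L),
                          sample_wells_per_plate = NULL,
                          seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  wells_per_plate <- as.integer(wells_per_plate)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_genes >= 0L, n_replicates >= 1L, n_rows >= 1L, n_cols >= 1L)
  if (wells_per_plate != n_rows * n_cols)
    stop("`wells_per_plate` must equal n_rows * n_cols", call. = FALSE)
  ctrl_names <- c("mock_plusPMA", "mock_minusPMA")
  if (is.null(names(controls_per_plate)) ||
      !all(names(controls_per_plate) %in% ctrl_names))
    stop("`controls_per_plate` must be named with: ",
         paste(ctrl_names, collapse = ", "), call. = FALSE)
  controls_per_plate <- vapply(ctrl_names, function(nm) {
    v <- controls_per_plate[nm]
    as.integer(ifelse(is.na(v), 0L, v))
  }, integer(1))
  n_ctrl <- sum(controls_per_plate)
  if (is.null(sample_wells_per_plate))
    sample_wells_per_plate <- wells_per_plate - n_ctrl
  sample_wells_per_plate <- as.integer(sample_wells_per_plate)
  if (sample_wells_per_plate + n_ctrl > wells_per_plate)
    stop("design error: sample wells plus control wells exceed plate size",
         call. = FALSE)
  if (sample_wells_per_plate < 1L && n_genes > 0L)
    stop("design error: no sample wells available for genes", call. = FALSE)
  structure(
    list(n_genes = n_genes,
         wells_per_plate = wells_per_plate,
         n_rows = n_rows, n_cols = n_cols,
         n_replicates = n_replicates,
         controls_per_plate = controls_per_plate,
         sample_wells_per_plate = sample_wells_per_plate,
         seed = as.integer(seed)),
    class = "screen_design")
}

#' Generative effect model for synthetic screens
#'
#' Parameters of the signal model used by [simulate_screen()]. A well's
#' chemiluminescence signal (arbitrary units, AU) is
#' `baseline * plate_effect * exp(row_effect + col_effect) * gene_multiplier
#' * noise`, with a multiplicative lognormal plate effect, additive
#' log-scale row/column gradients, and per-well lognormal noise of mean 1
#' and coefficient of variation `noise_cv`. Mock +PMA wells have gene
#' multiplier 1 (the stimulated control band); mock -PMA wells sit at
#' `minus_pma_fraction` of baseline (the unstimulated band). Spiked hits
#' multiply the baseline by `hypo_effect` (< 1) or `hyper_effect` (> 1).
#'
#' @param baseline_signal +PMA mock signal level, AU.
#' @param minus_pma_fraction -PMA level as a fraction of baseline, in (0,1).
#' @param plate_effect_sd log-scale SD of the multiplicative plate effect.
#' @param row_effect_sd,col_effect_sd log-scale SDs of additive row/column
#'   gradients (drawn independently per plate and replicate).
#' @param noise_cv coefficient of variation of per-well lognormal noise.
#' @param hypo_fraction,hyper_fraction fractions of genes spiked as
#'   hypo-/hypersecretory hits.
#' @param hypo_effect,hyper_effect signal multipliers for the spiked hits;
#'   `hypo_effect < 1 < hyper_effect`.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(baseline_signal = 1000,
                         minus_pma_fraction = 0.25,
                         plate_effect_sd = 0.1,
                         row_effect_sd = 0.05,
                         col_effect_sd = 0.05,
                         noise_cv = 0.1,
                         hypo_fraction = 0.05,
                         hyper_fraction = 0.02,
                         hypo_effect = 0.25,
                         hyper_effect = 2.5) {
  stopifnot(baseline_signal > 0,
            minus_pma_fraction > 0, minus_pma_fraction < 1,
            plate_effect_sd >= 0, row_effect_sd >= 0, col_effect_sd >= 0,
            noise_cv >= 0,
            hypo_fraction >= 0, hypo_fraction < 1,
            hyper_fraction >= 0, hyper_fraction < 1,
            hypo_effect > 0, hypo_effect < 1, hyper_effect > 1)
  if (hypo_fraction + hyper_fraction >= 1)
    stop("hypo_fraction + hyper_fraction must be < 1", call. = FALSE)
  structure(
    list(baseline_signal = baseline_signal,
         minus_pma_fraction = minus_pma_fraction,
         plate_effect_sd = plate_effect_sd,
         row_effect_sd = row_effect_sd,
         col_effect_sd = col_effect_sd,
         noise_cv = noise_cv,
         hypo_fraction = hypo_fraction,
         hyper_fraction = hyper_fraction,
         hypo_effect = hypo_effect,
         hyper_effect = hyper_effect),
    class = "effect_model")
}

# zero-padded gene identifiers: gene_0001, ...
gene_ids <- function(n) {
  if (n == 0L) return(character(0))
  sprintf("gene_%0*d", max(4L, nchar(n)), seq_len(n))
}

# row index (1-based) -> plate letter and back
row_letter <- function(i) LETTERS[i]
row_index <- function(ch) match(ch, LETTERS)
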