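#' Simulate a full primary screen with ground truth
#'
#' Generates one well record per (replicate, plate, well) under the
#' generative model of [effect_model()], together with a truth table
#' labelling every gene `hypo`, `hyper` or `null` and recording its true
#' effect multiplier. Gene-to-well assignment is identical across
#' replicates; plate, row and column artifacts and the per-well noise are
#' drawn independently for every (replicate, plate) from deterministic
#' substreams of the design seed, so the same design and effects always
#' reproduce the same tables bit for bit.
#'
#' @param design a [screen_design()].
#' @param effects an [effect_model()].
#' @return A list with `wells` (data.frame: `replicate`, `plate`, `row`
#'   (letter), `col`, `well_type`, `gene_id`, `signal`) and `truth`
#'   (data.frame: `gene_id`, `true_class`, `effect`).
#' @export
simulate_screen <- function(design, effects) {
  stopifnot(inherits(design, "screen_design"), inherits(effects, "effect_model"))
  layout <- screen_layout(design)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(design$seed)
  truth <- draw_truth(design$n_genes, effects)
  n_plates <- max(1L, n_plates_for(design, design$n_genes))
  subseeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                design$n_replicates * n_plates),
                     nrow = design$n_replicates)
  wells <- fill_signals(layout, design, effects, truth, subseeds)
  list(wells = wells, truth = truth)
}

#' Simulate a validation (secondary) screen for a gene subset
#'
#' Re-screens a subset of genes under the same generative model: a fresh
#' plate layout is built for the given gene list (same design conventions)
#' and fresh artifact and noise draws are taken, keeping each gene's true
#' effect from the supplied truth table. Mock control wells are emitted on
#' every plate even when `genes` is empty. The layout depends only on the
#' gene list and design; reseeding changes signals only.
#'
#' @param genes character vector of gene ids to re-screen; must all appear
#'   in `truth$gene_id`.
#' @param truth truth table from [simulate_screen()].
#' @param effects an [effect_model()].
#' @param design a [screen_design()]; `n_genes` is ignored (replaced by
#'   `length(genes)`), its `seed` seeds the fresh draws.
#' @return Well-record data.frame in the same format as
#'   [simulate_screen()]'s `wells`.
#' @export
simulate_validation_screen <- function(genes, truth, effects, design) {
  stopifnot(inherits(design, "screen_design"), inherits(effects, "effect_model"))
  genes <- as.character(genes)
  miss <- setdiff(genes, truth$gene_id)
  if (length(miss) > 0L)
    stop("lookup error: gene ids not in truth table: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  vdesign <- design
  vdesign$n_genes <- length(genes)
  layout <- screen_layout(vdesign, gene_labels = genes)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(vdesign$seed)
  vtruth <- truth[match(genes, truth$gene_id), , drop = FALSE]
  n_plates <- max(1L, n_plates_for(vdesign, length(genes)))
  subseeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                vdesign$n_replicates * n_plates),
                     nrow = vdesign$n_replicates)
  fill_signals(layout, vdesign, effects, vtruth, subseeds)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

n_plates_for <- function(design, n_genes) {
  as.integer(ceiling(n_genes / design$sample_wells_per_plate))
}

draw_truth <- function(n_genes, effects) {
  ids <- gene_ids(n_genes)
  cls <- rep("null", n_genes)
  eff <- rep(1, n_genes)
  n_hypo <- round(effects$hypo_fraction * n_genes)
  n_hyper <- round(effects$hyper_fraction * n_genes)
  if (n_hypo + n_hyper > 0L && n_genes > 0L) {
    pick <- sample.int(n_genes, n_hypo + n_hyper)
    hypo <- pick[seq_len(n_hypo)]
    hyper <- pick[n_hypo + seq_len(n_hyper)]
    cls[hypo] <- "hypo"; eff[hypo] <- effects$hypo_effect
    cls[hyper] <- "hyper"; eff[hyper] <- effects$hyper_effect
  }
  data.frame(gene_id = ids, true_class = cls, effect = eff,
             stringsAsFactors = FALSE)
}

# One replicate's worth of (plate, row, col, well_type, gene_id); the same
# layout is reused for every replicate. Control wells fill the last column
# downwards (then the next-to-last, if needed), +PMA mocks first. Sample
# wells fill the remaining grid column-major so that a partial last plate
# leaves whole columns unused rather than sparsely populated rows.
screen_layout <- function(design, gene_labels = NULL) {
  n_genes <- design$n_genes
  if (is.null(gene_labels)) gene_labels <- gene_ids(n_genes)
  stopifnot(length(gene_labels) == n_genes)
  nr <- design$n_rows; nc <- design$n_cols
  n_ctrl <- sum(design$controls_per_plate)
  # control positions: column-major from the last column
  ctrl_lin <- integer(0)
  if (n_ctrl > 0L) {
    cols_rev <- rev(seq_len(nc))
    pos <- as.vector(vapply(cols_rev, function(j) (j - 1L) * nr + seq_len(nr),
                            integer(nr)))
    ctrl_lin <- pos[seq_len(n_ctrl)]
  }
  ctrl_type <- rep(names(design$controls_per_plate), design$controls_per_plate)
  sample_lin <- setdiff(seq_len(nr * nc), ctrl_lin)[seq_len(design$sample_wells_per_plate)]
  n_plates <- max(1L, n_plates_for(design, n_genes))
  per_plate <- function(p) {
    lo <- (p - 1L) * design$sample_wells_per_plate + 1L
    hi <- min(p * design$sample_wells_per_plate, n_genes)
    idx <- if (lo <= hi) seq(lo, hi) else integer(0)
    k <- length(idx)
    lin <- c(sample_lin[seq_len(k)], ctrl_lin,
             setdiff(seq_len(nr * nc), c(sample_lin[seq_len(k)], ctrl_lin)))
    type <- c(rep("sample", k), ctrl_type,
              rep("empty", nr * nc - k - n_ctrl))
    gid <- c(gene_labels[idx], rep(NA_character_, nr * nc - k))
    data.frame(plate = p,
               row = row_letter(((lin - 1L) %% nr) + 1L),
               col = ((lin - 1L) %/% nr) + 1L,
               well_type = type, gene_id = gid,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_plates), per_plate))
  out[order(out$plate, match(out$row, LETTERS), out$col), , drop = FALSE]
}

# lognormal noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

fill_signals <- function(layout, design, effects, truth, subseeds) {
  mult <- c(stats::setNames(truth$effect, truth$gene_id))
  reps <- lapply(seq_len(design$n_replicates), function(r) {
    plates <- lapply(sort(unique(layout$plate)), function(p) {
      pl <- layout[layout$plate == p, , drop = FALSE]
      set.seed(subseeds[r, p])
      plate_eff <- exp(stats::rnorm(1L, 0, effects$plate_effect_sd))
      row_eff <- stats::rnorm(design$n_rows, 0, effects$row_effect_sd)
      col_eff <- stats::rnorm(design$n_cols, 0, effects$col_effect_sd)
      ri <- row_index(pl$row)
      gmult <- ifelse(pl$well_type == "sample", mult[pl$gene_id],
               ifelse(pl$well_type == "mock_plusPMA", 1,
               ifelse(pl$well_type == "mock_minusPMA",
                      effects$minus_pma_fraction, NA_real_)))
      noise <- rlnorm_cv(nrow(pl), effects$noise_cv)
      sig <- effects$baseline_signal * plate_eff *
        exp(row_eff[ri] + col_eff[pl$col]) * gmult * noise
      sig[pl$well_type == "empty"] <- NA_real_
      cbind(data.frame(replicate = r), pl, data.frame(signal = sig))
    })
    do.call(rbind, plates)
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}
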