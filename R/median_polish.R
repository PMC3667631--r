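#' Two-way median polish
#'
#' Decomposes a plate matrix into `overall + row_effects + col_effects +
#' residuals` by alternately sweeping row and column medians out of the
#' residual matrix (Tukey's median polish). After each sweep the median of
#' the accumulated row (column) effects is folded into the overall term, so
#' at convergence both effect vectors have median ~0 and the reconstruction
#' identity holds exactly. Missing cells are ignored by the medians.
#'
#' Iteration stops when the largest absolute change to any effect in a full
#' sweep falls below `tol`, or after `max_iter` sweeps (with a warning:
#' median polish can cycle, and bounded iteration is standard practice).
#'
#' The median-polish fixed point is not unique: distinct additive surfaces
#' can leave all row and column residual medians at zero, and which one
#' the raw iteration reaches depends on the starting matrix, so b-scores
#' would not be exactly invariant to row/column/plate offsets. The
#' iteration is therefore initialised with a single least-squares sweep
#' (column means, then row means), which is exactly equivariant under
#' additive row/column/plate offsets and positive scaling and pins a
#' canonical fixed point; all refinement after that initial sweep is pure
#' alternating median polish. Set `init = "none"` for the textbook
#' iteration from the raw matrix.
#'
#' @param x numeric matrix, possibly with `NA` cells. Every row and column
#'   must contain at least 2 non-missing values.
#' @param tol convergence tolerance on effect changes (same units as `x`).
#' @param max_iter maximum number of full row+column sweeps.
#' @param init `"means"` (canonical, default) or `"none"`.
#' @return A list of class `polish_decomposition`: `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `iterations`, `converged`.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 100L,
                          init = c("means", "none")) {
  init <- match.arg(init)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (any(is.infinite(x) | is.nan(x)))
    stop("non-finite values in input matrix", call. = FALSE)
  obs <- !is.na(x)
  if (any(rowSums(obs) < 2L) || any(colSums(obs) < 2L))
    stop_degenerate("every row and column needs >= 2 non-missing wells")
  nr <- nrow(x); nc <- ncol(x)
  res <- x
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  if (init == "means") {
    cm <- colMeans(res, na.rm = TRUE)
    res <- sweep(res, 2L, cm)
    col_eff <- col_eff + cm
    rm_ <- rowMeans(res, na.rm = TRUE)
    res <- res - rm_
    row_eff <- row_eff + rm_
    cmed <- stats::median(col_eff)
    col_eff <- col_eff - cmed; overall <- overall + cmed
    rmed <- stats::median(row_eff)
    row_eff <- row_eff - rmed; overall <- overall + rmed
  }
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    rdelta <- apply(res, 1L, stats::median, na.rm = TRUE)
    res <- res - rdelta
    row_eff <- row_eff + rdelta
    cmed <- stats::median(col_eff)
    col_eff <- col_eff - cmed
    overall <- overall + cmed
    cdelta <- apply(res, 2L, stats::median, na.rm = TRUE)
    res <- sweep(res, 2L, cdelta)
    col_eff <- col_eff + cdelta
    rmed <- stats::median(row_eff)
    row_eff <- row_eff - rmed
    overall <- overall + rmed
    if (max(abs(c(rdelta, cdelta, cmed, rmed))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("median polish did not converge in ", max_iter, " iterations")
  structure(list(overall = overall,
                 row_effects = row_eff,
                 col_effects = col_eff,
                 residuals = res,
                 iterations = it,
                 converged = converged),
            class = "polish_decomposition")
}

stop_degenerate <- function(msg, plate = NULL) {
  full <- if (is.null(plate)) paste0("degenerate plate: ", msg)
          else sprintf("degenerate plate %s: %s", plate, msg)
  stop(structure(class = c("degenerate_plate_error", "error", "condition"),
                 list(message = full, call = sys.call(-1))))
}
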