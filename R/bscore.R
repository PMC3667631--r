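#' Assemble a plate grid from well records
#'
#' Builds the signal matrix and aligned annotation matrices for one
#' (replicate, plate) from a long-format well table.
#'
#' @param wells well-record data.frame (`replicate`, `plate`, `row`
#'   (letters), `col`, `well_type`, `gene_id`, `signal`) restricted to, or
#'   filtered for, one plate of one replicate.
#' @param replicate,plate identify the plate when `wells` holds a whole
#'   screen.
#' @param n_rows,n_cols plate geometry.
#' @return An object of class `plate_grid`: `signal`, `well_type`,
#'   `gene_id` matrices plus `plate_id` and `replicate_id`.
#' @export
plate_grid <- function(wells, replicate = NULL, plate = NULL,
                       n_rows = 8L, n_cols = 12L) {
  if (!is.null(replicate)) wells <- wells[wells$replicate == replicate, ]
  if (!is.null(plate)) wells <- wells[wells$plate == plate, ]
  if (nrow(wells) == 0L) stop("no wells for the requested plate", call. = FALSE)
  ri <- row_index(wells$row)
  if (any(is.na(ri)) || any(ri > n_rows) || any(wells$col < 1L | wells$col > n_cols))
    stop("well coordinates outside the ", n_rows, "x", n_cols, " geometry",
         call. = FALSE)
  sig <- matrix(NA_real_, n_rows, n_cols,
                dimnames = list(LETTERS[seq_len(n_rows)], seq_len(n_cols)))
  wt <- matrix("empty", n_rows, n_cols, dimnames = dimnames(sig))
  gid <- matrix(NA_character_, n_rows, n_cols, dimnames = dimnames(sig))
  idx <- cbind(ri, wells$col)
  if (anyDuplicated(idx))
    stop("duplicated well coordinates on plate", call. = FALSE)
  sig[idx] <- wells$signal
  wt[idx] <- wells$well_type
  gid[idx] <- wells$gene_id
  structure(list(signal = sig, well_type = wt, gene_id = gid,
                 plate_id = wells$plate[1], replicate_id = wells$replicate[1]),
            class = "plate_grid")
}

#' Per-well B-scores for one plate
#'
#' Fits a two-way median polish to all measured wells of the plate (sample
#' and control wells together, so that spatial effects are estimated from
#' the full grid) and scales the residuals by the MAD of the sample-well
#' residuals only: `b = residual / (1.4826 * median(|sample residuals|))`.
#' Controls are excluded from the MAD because they sit at extreme levels by
#' design and would inflate it. Control wells still receive b-scores,
#' flagged as non-gene wells.
#'
#' Rows or columns with fewer than 2 measured wells (e.g. on a partly
#' filled final plate) cannot support the polish; they are trimmed before
#' fitting and their wells get `NA` b-scores with a warning. The plate is
#' degenerate if fewer than a 2x2 grid remains or the sample-well MAD is 0.
#'
#' @param plate a [plate_grid()].
#' @param tol,max_iter passed to [median_polish()].
#' @return data.frame with one row per non-empty well: `replicate`,
#'   `plate`, `row`, `col`, `well_type`, `gene_id`, `signal`, `residual`,
#'   `b_score`, `is_gene`.
#' @export
b_score_plate <- function(plate, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(plate, "plate_grid"))
  measured <- plate$well_type != "empty" & !is.na(plate$signal)
  x <- plate$signal
  x[!measured] <- NA_real_
  keep_r <- rowSums(!is.na(x)) >= 2L
  keep_c <- colSums(!is.na(x)) >= 2L
  trimmed <- any(!keep_r & rowSums(!is.na(x)) > 0L) ||
             any(!keep_c & colSums(!is.na(x)) > 0L)
  if (sum(keep_r) < 2L || sum(keep_c) < 2L)
    stop_degenerate("fewer than 2 usable rows or columns", plate$plate_id)
  if (trimmed)
    warning("plate ", plate$plate_id, " replicate ", plate$replicate_id,
            ": wells in rows/columns with <2 measurements got NA b-scores")
  sub <- x[keep_r, keep_c, drop = FALSE]
  # after trimming, a row/col may still have <2: strict polish will say so
  mp <- median_polish(sub, tol = tol, max_iter = max_iter)
  res <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  res[keep_r, keep_c] <- mp$residuals
  samp_res <- res[plate$well_type == "sample" & !is.na(res)]
  mad_s <- 1.4826 * stats::median(abs(samp_res))
  if (!is.finite(mad_s) || mad_s <= 0)
    stop_degenerate("sample-well residual MAD is zero", plate$plate_id)
  b <- res / mad_s
  sel <- which(plate$well_type != "empty", arr.ind = TRUE)
  out <- data.frame(
    replicate = plate$replicate_id,
    plate = plate$plate_id,
    row = LETTERS[sel[, 1L]],
    col = sel[, 2L],
    well_type = plate$well_type[sel],
    gene_id = plate$gene_id[sel],
    signal = plate$signal[sel],
    residual = res[sel],
    b_score = b[sel],
    stringsAsFactors = FALSE)
  out$is_gene <- out$well_type == "sample"
  out[order(match(out$row, LETTERS), out$col), , drop = FALSE]
}

#' B-scores for a whole screen
#'
#' Applies [b_score_plate()] to every (replicate, plate) of a well-record
#' table and assembles the per-gene, per-replicate B-score table that the
#' rank-product and hit-selection stages consume. Degenerate plates are
#' collected and reported together as an error. Genes present in some
#' replicates but not others are kept but trigger a completeness warning.
#'
#' @param wells long-format well-record table (see [simulate_screen()]).
#' @param tol,max_iter passed to [median_polish()].
#' @param n_rows,n_cols plate geometry.
#' @return data.frame `gene_id`, `replicate`, `plate`, `b_score`, with a
#'   `plate_log` attribute (per-plate polish iterations, convergence, MAD).
#' @export
b_score_screen <- function(wells, tol = 1e-6, max_iter = 100L,
                           n_rows = 8L, n_cols = 12L) {
  stopifnot(is.data.frame(wells), nrow(wells) > 0L)
  keys <- unique(wells[, c("replicate", "plate")])
  keys <- keys[order(keys$replicate, keys$plate), , drop = FALSE]
  res <- vector("list", nrow(keys))
  logs <- vector("list", nrow(keys))
  degenerate <- character(0)
  for (i in seq_len(nrow(keys))) {
    grid <- plate_grid(wells, keys$replicate[i], keys$plate[i],
                       n_rows = n_rows, n_cols = n_cols)
    bs <- tryCatch(b_score_plate(grid, tol = tol, max_iter = max_iter),
                   degenerate_plate_error = function(e) e)
    if (inherits(bs, "degenerate_plate_error")) {
      degenerate <- c(degenerate,
                      sprintf("replicate %s plate %s: %s",
                              keys$replicate[i], keys$plate[i],
                              conditionMessage(bs)))
      next
    }
    res[[i]] <- bs[bs$is_gene, c("gene_id", "replicate", "plate", "b_score")]
    samp <- bs$residual[bs$is_gene & !is.na(bs$residual)]
    logs[[i]] <- data.frame(replicate = keys$replicate[i],
                            plate = keys$plate[i],
                            mad = 1.4826 * stats::median(abs(samp)))
  }
  if (length(degenerate) > 0L)
    stop("degenerate plates:\n  ", paste(degenerate, collapse = "\n  "),
         call. = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_rep <- length(unique(out$replicate))
  cnt <- table(out$gene_id)
  incomplete <- names(cnt)[cnt < n_rep]
  if (length(incomplete) > 0L)
    warning(length(incomplete), " gene(s) missing from some replicates: ",
            paste(utils::head(incomplete, 5L), collapse = ", "))
  attr(out, "plate_log") <- do.call(rbind, logs)
  attr(out, "incomplete_genes") <- incomplete
  out
}
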