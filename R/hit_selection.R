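#' Primary-screen hit classification on the median B-score
#'
#' Takes the median of each gene's replicate b-scores and classifies the
#' gene `hyposecretory` if the median lies strictly below `-threshold`,
#' `hypersecretory` strictly above `+threshold`, otherwise `none`. The
#' comparison is strict, so a median of exactly -1.5 is not a hit. Genes
#' with fewer replicates than the screen maximum (or with missing
#' b-scores) are classified on the available values and flagged.
#' Rank-product results, when supplied, are merged as annotations only:
#' they never gate the classification.
#'
#' @param b_table B-score table from [b_score_screen()].
#' @param threshold positive B-score cutoff (default 1.5).
#' @param rp optional rank-product table from [rank_product_table()].
#' @return data.frame `gene_id`, `n_replicates`, `median_b`, `class`,
#'   `complete`, plus rank-product columns when `rp` is given.
#' @export
classify_primary <- function(b_table, threshold = 1.5, rp = NULL) {
  stopifnot(threshold > 0)
  if (!is.data.frame(b_table) || nrow(b_table) == 0L)
    stop("empty b-score table", call. = FALSE)
  sp <- split(b_table$b_score, b_table$gene_id)
  n_rep_max <- max(lengths(sp))
  med <- vapply(sp, function(v) stats::median(v[is.finite(v)]), numeric(1))
  n_ok <- vapply(sp, function(v) sum(is.finite(v)), integer(1))
  if (any(n_ok < 1L))
    stop("gene(s) with no finite b-score in any replicate", call. = FALSE)
  cls <- ifelse(med < -threshold, "hyposecretory",
         ifelse(med > threshold, "hypersecretory", "none"))
  out <- data.frame(gene_id = names(sp),
                    n_replicates = n_ok,
                    median_b = unname(med),
                    class = unname(cls),
                    complete = unname(n_ok == n_rep_max),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(rp))
    out <- merge(out, rp, by = "gene_id", all.x = TRUE, sort = TRUE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Platewise z-score
#'
#' `z = (xi - mean(xn)) / SD(xn)` with the sample standard deviation
#' (n-1 denominator); `xn` is the plate's population of measured wells and
#' `xi` the well of interest.
#'
#' @param signals numeric vector, the plate population `xn` (n >= 2).
#' @param xi signal(s) to score against that population.
#' @return dimensionless z-score(s), same length as `xi`.
#' @export
z_score_platewise <- function(signals, xi) {
  signals <- signals[!is.na(signals)]
  if (length(signals) < 2L) stop("need >= 2 plate signals", call. = FALSE)
  s <- stats::sd(signals)
  if (!is.finite(s) || s == 0)
    stop_degenerate("zero standard deviation in plate population")
  (xi - mean(signals)) / s
}

#' Platewise z-scores for a validation screen
#'
#' Scores every measured well of every (replicate, plate) against that
#' plate's full measured population (sample and mock wells together, the
#' "total population" convention).
#'
#' @param wells long-format well-record table.
#' @return `wells` with an added `z` column (empty wells dropped).
#' @export
z_score_screen <- function(wells) {
  w <- wells[wells$well_type != "empty" & !is.na(wells$signal), , drop = FALSE]
  key <- interaction(w$replicate, w$plate, drop = TRUE)
  w$z <- NA_real_
  for (ix in split(seq_len(nrow(w)), key))
    w$z[ix] <- z_score_platewise(w$signal[ix], w$signal[ix])
  rownames(w) <- NULL
  w
}

#' Validation-screen classification against the mock 2-SD band
#'
#' A gene is validated `hyposecretory` if its mean z-score across
#' replicates lies below `mean(mock_z) - n_sd * SD(mock_z)`,
#' `hypersecretory` above the mirror bound, otherwise `none`. The band is
#' computed on the z scale from the stimulated (+PMA) mock wells.
#'
#' @param z_table data.frame `gene_id`, `replicate`, `z` (one row per
#'   replicate well of each gene).
#' @param mock_z z-scores of the mock wells (>= 2 values).
#' @param n_sd width of the mock band in mock SDs (default 2).
#' @return data.frame `gene_id`, `n_replicates`, `mean_z`,
#'   `validated_class`, with `mean_mock_z`, `sd_mock_z` as attributes and
#'   repeated per row for convenience.
#' @export
classify_validation <- function(z_table, mock_z, n_sd = 2) {
  stopifnot(n_sd > 0)
  mock_z <- mock_z[is.finite(mock_z)]
  if (length(mock_z) < 2L)
    stop("need >= 2 mock measurements", call. = FALSE)
  s <- stats::sd(mock_z)
  if (s == 0) stop_degenerate("mock z-scores have zero SD")
  m <- mean(mock_z)
  sp <- split(z_table$z, z_table$gene_id)
  mz <- vapply(sp, function(v) mean(v[is.finite(v)]), numeric(1))
  cls <- ifelse(mz < m - n_sd * s, "hyposecretory",
         ifelse(mz > m + n_sd * s, "hypersecretory", "none"))
  out <- data.frame(gene_id = names(sp),
                    n_replicates = vapply(sp, function(v) sum(is.finite(v)), integer(1)),
                    mean_z = unname(mz),
                    validated_class = unname(cls),
                    mean_mock_z = m,
                    sd_mock_z = s,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Run the full validation stage on a validation well table
#'
#' Convenience wrapper: platewise z-scores, per-gene means, mock band from
#' the +PMA mock wells, classification with [classify_validation()].
#'
#' @param wells validation well-record table.
#' @param n_sd mock-band width in SDs.
#' @param mock_type which control wells define the null band.
#' @return see [classify_validation()].
#' @export
validate_screen <- function(wells, n_sd = 2, mock_type = "mock_plusPMA") {
  zw <- z_score_screen(wells)
  gene_rows <- zw[zw$well_type == "sample" & !is.na(zw$gene_id), , drop = FALSE]
  if (nrow(gene_rows) == 0L) {
    return(data.frame(gene_id = character(0), n_replicates = integer(0),
                      mean_z = numeric(0), validated_class = character(0),
                      mean_mock_z = numeric(0), sd_mock_z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  mock_z <- zw$z[zw$well_type == mock_type]
  classify_validation(gene_rows[, c("gene_id", "replicate", "z")],
                      mock_z, n_sd = n_sd)
}

#' Annotation-based triage filter
#'
#' Removes hits whose annotation categories intersect a blocklist (e.g.
#' secreted, nuclear, protein modification, basic metabolism), the
#' category-based triage applied between the primary and validation
#' stages. Matching is case-insensitive and any-match: one blocked
#' category removes the gene. Unannotated genes are retained and flagged.
#'
#' @param hits hit table with a `gene_id` column (rows already restricted
#'   to hits, or any gene table to be filtered).
#' @param annotations data.frame `gene_id`, `category` (one row per
#'   gene-category pair).
#' @param blocklist character vector of categories to remove.
#' @return `hits` minus blocked genes, with an `annotated` flag column.
#' @export
filter_by_annotation <- function(hits, annotations, blocklist = character(0)) {
  stopifnot(is.data.frame(hits), "gene_id" %in% names(hits))
  if (length(blocklist) == 0L) {
    hits$annotated <- tolower(hits$gene_id) %in% tolower(annotations$gene_id)
    return(hits)
  }
  bl <- tolower(trimws(blocklist))
  ann <- annotations
  ann$category <- tolower(trimws(ann$category))
  blocked <- unique(ann$gene_id[ann$category %in% bl])
  out <- hits[!(hits$gene_id %in% blocked), , drop = FALSE]
  out$annotated <- out$gene_id %in% annotations$gene_id
  rownames(out) <- NULL
  out
}

#' Expression-detection and regulation filter
#'
#' Per gene and condition, expression relative to a housekeeping gene is
#' the mean of per-replicate intensity ratios; a gene is `detected` when
#' its relative expression exceeds the detection floor in either
#' condition. Regulation between conditions (starved vs nonstarved) is
#' called `up`/`down` when a two-sided Welch t-test on the per-replicate
#' ratios gives p < 0.05, else `unchanged`.
#'
#' @param calls data.frame `gene_id`, `condition` (`nonstarved`/`starved`),
#'   `replicate`, `gene_intensity`, `housekeeping_intensity`.
#' @param detection_floor relative-expression floor (default 0.05).
#' @param alpha significance level of the Welch test.
#' @return data.frame per gene: relative expression in each condition,
#'   `detected`, `regulation`, Welch `p_value`.
#' @export
expression_filter <- function(calls, detection_floor = 0.05, alpha = 0.05) {
  need <- c("gene_id", "condition", "replicate",
            "gene_intensity", "housekeeping_intensity")
  stopifnot(all(need %in% names(calls)))
  if (any(!is.finite(calls$housekeeping_intensity)) ||
      any(calls$housekeeping_intensity <= 0))
    stop("housekeeping intensities must be finite and > 0", call. = FALSE)
  calls$ratio <- calls$gene_intensity / calls$housekeeping_intensity
  per_gene <- function(g) {
    d <- calls[calls$gene_id == g, , drop = FALSE]
    rs <- split(d$ratio, factor(d$condition, levels = c("nonstarved", "starved")))
    rel <- vapply(rs, function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
    detected <- any(rel > detection_floor, na.rm = TRUE)
    reg <- "unchanged"; pv <- NA_real_
    a <- rs$nonstarved; b <- rs$starved
    if (length(a) >= 2L && length(b) >= 2L) {
      if (isTRUE(all.equal(stats::var(c(a, b)), 0))) {
        pv <- 1
      } else {
        pv <- stats::t.test(b, a, var.equal = FALSE)$p.value
      }
      if (is.finite(pv) && pv < alpha)
        reg <- if (mean(b) > mean(a)) "up" else "down"
    }
    data.frame(gene_id = g,
               rel_expr_nonstarved = rel[["nonstarved"]],
               rel_expr_starved = rel[["starved"]],
               detected = detected, regulation = reg, p_value = pv,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(calls$gene_id), per_gene))
  rownames(out) <- NULL
  out
}
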