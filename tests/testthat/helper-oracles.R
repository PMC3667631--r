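# Independent oracles, deliberately coded as naive loops so they share no
# code path with the package implementation.

# Brute-force alternating-median polish: explicit loops, same sweep
# schedule and stopping rule as the contract (canonical least-squares
# initial sweep, then row medians, fold column median into overall,
# column medians, fold row median into overall; stop when no effect moved
# more than tol).
oracle_median_polish <- function(x, tol = 1e-6, max_iter = 100L) {
  nr <- nrow(x); nc <- ncol(x)
  res <- x; overall <- 0
  row_eff <- rep(0, nr); col_eff <- rep(0, nc)
  med <- function(v) stats::median(v[!is.na(v)])
  avg <- function(v) mean(v[!is.na(v)])
  for (j in seq_len(nc)) {
    m <- avg(res[, j])
    for (i in seq_len(nr)) res[i, j] <- res[i, j] - m
    col_eff[j] <- col_eff[j] + m
  }
  for (i in seq_len(nr)) {
    m <- avg(res[i, ])
    for (j in seq_len(nc)) res[i, j] <- res[i, j] - m
    row_eff[i] <- row_eff[i] + m
  }
  m <- med(col_eff); col_eff <- col_eff - m; overall <- overall + m
  m <- med(row_eff); row_eff <- row_eff - m; overall <- overall + m
  for (it in seq_len(max_iter)) {
    moved <- 0
    for (i in seq_len(nr)) {
      m <- med(res[i, ])
      for (j in seq_len(nc)) res[i, j] <- res[i, j] - m
      row_eff[i] <- row_eff[i] + m
      moved <- max(moved, abs(m))
    }
    m <- med(col_eff); col_eff <- col_eff - m; overall <- overall + m
    moved <- max(moved, abs(m))
    for (j in seq_len(nc)) {
      m <- med(res[, j])
      for (i in seq_len(nr)) res[i, j] <- res[i, j] - m
      col_eff[j] <- col_eff[j] + m
      moved <- max(moved, abs(m))
    }
    m <- med(row_eff); row_eff <- row_eff - m; overall <- overall + m
    moved <- max(moved, abs(m))
    if (moved < tol) break
  }
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = res)
}

# sort-based ranking oracle with average ties
oracle_rank <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    smaller <- sum(v < v[i])
    ties <- sum(v == v[i])
    out[i] <- smaller + (ties + 1) / 2
  }
  out
}

# one fully measured 96-well plate of well records
make_plate_wells <- function(signal_matrix, replicate = 1L, plate = 1L,
                             well_type = NULL) {
  nr <- nrow(signal_matrix); nc <- ncol(signal_matrix)
  if (is.null(well_type)) well_type <- matrix("sample", nr, nc)
  idx <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  data.frame(replicate = replicate, plate = plate,
             row = LETTERS[idx$r], col = idx$c,
             well_type = well_type[cbind(idx$r, idx$c)],
             gene_id = ifelse(well_type[cbind(idx$r, idx$c)] == "sample",
                              sprintf("g%02d_%02d", idx$r, idx$c),
                              NA_character_),
             signal = signal_matrix[cbind(idx$r, idx$c)],
             stringsAsFactors = FALSE)
}

# default no-hit design/effects for calibration checks
null_effects <- function(...) {
  effect_model(hypo_fraction = 0, hyper_fraction = 0, ...)
}
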