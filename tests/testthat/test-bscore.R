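test_that("b-score formula matches hand computation on a 4x4 instance", {
  # additive surface + small fixed jitter (so the sample MAD is positive)
  # + one strongly perturbed well
  a <- c(10, 12, 9, 11); b <- c(0, 2, 4, 1)
  jit <- matrix(c( 0.10, -0.08,  0.03, -0.05,
                  -0.06,  0.09, -0.02,  0.04,
                   0.02, -0.04,  0.07, -0.09,
                  -0.03,  0.05, -0.08,  0.06), 4, 4, byrow = TRUE)
  x <- outer(a, b, `+`) + jit
  x[1, 1] <- x[1, 1] + 5
  wells <- make_plate_wells(x)
  bs <- b_score_plate(plate_grid(wells, n_rows = 4, n_cols = 4),
                      tol = 1e-10, max_iter = 500)
  or <- oracle_median_polish(x, tol = 1e-10, max_iter = 500)
  mad_c <- 1.4826 * median(abs(or$residuals))
  expected <- or$residuals / mad_c
  got <- matrix(NA_real_, 4, 4)
  got[cbind(match(bs$row, LETTERS), bs$col)] <- bs$b_score
  expect_lt(max(abs(got - expected)), 1e-9)
  # the perturbed well dominates; every other well is comparatively small
  expect_gt(got[1, 1], 10)
  expect_lt(max(abs(got[-1])), 3)
})

test_that("exactly additive surface with one spike is a degenerate plate (MAD 0)", {
  x <- outer(c(10, 12, 9, 11), c(0, 2, 4, 1), `+`)
  x[1, 1] <- x[1, 1] + 5
  wells <- make_plate_wells(x)
  expect_error(b_score_plate(plate_grid(wells, n_rows = 4, n_cols = 4)),
               class = "degenerate_plate_error")
})

test_that("b-scores are invariant to row/col/plate offsets and plate scaling", {
  set.seed(55)
  for (i in 1:10) {
    x <- matrix(rnorm(96, 100, 12), 8, 12)
    wells <- make_plate_wells(x)
    b0 <- suppressWarnings(
      b_score_plate(plate_grid(wells), tol = 1e-10, max_iter = 500))
    r_off <- rnorm(8, 0, 20); c_off <- rnorm(12, 0, 20)
    k <- rnorm(1, 0, 50); scale <- runif(1, 0.5, 5)
    y <- scale * (x + outer(r_off, rep(1, 12)) +
                    outer(rep(1, 8), c_off) + k)
    b1 <- suppressWarnings(
      b_score_plate(plate_grid(make_plate_wells(y)), tol = 1e-10,
                    max_iter = 500))
    expect_lt(max(abs(b1$b_score - b0$b_score)), 1e-9)
  }
})

test_that("control wells get flagged b-scores but stay out of the MAD", {
  set.seed(77)
  x <- matrix(rnorm(96, 100, 10), 8, 12)
  wt <- matrix("sample", 8, 12)
  wt[1:4, 12] <- "mock_plusPMA"; wt[5:8, 12] <- "mock_minusPMA"
  x[5:8, 12] <- x[5:8, 12] * 0.25  # -PMA wells sit far below the band
  wells <- make_plate_wells(x, well_type = wt)
  bs <- suppressWarnings(b_score_plate(plate_grid(wells)))
  expect_equal(nrow(bs), 96)
  expect_false(any(bs$is_gene[bs$well_type != "sample"]))
  # MAD must equal the sample-well-only value
  samp <- bs[bs$is_gene, ]
  mad_c <- 1.4826 * median(abs(samp$residual))
  expect_equal(samp$b_score, samp$residual / mad_c)
})

test_that("a no-noise screen is degenerate on every plate", {
  d <- screen_design(n_genes = 176, seed = 1)
  e0 <- null_effects(noise_cv = 0, plate_effect_sd = 0, row_effect_sd = 0,
                     col_effect_sd = 0)
  sim <- simulate_screen(d, e0)
  expect_error(b_score_screen(sim$wells), "degenerate plates")
})

test_that("screen b-scores: per-plate median ~ 0 and spiked hypo wells hit the plate minimum", {
  d <- screen_design(n_genes = 880, seed = 13, n_replicates = 3)
  e <- null_effects(noise_cv = 0.08)
  sim <- simulate_screen(d, e)
  # spike one gene per plate at 0.2x baseline
  w <- sim$wells
  spiked <- vapply(split(sim$truth$gene_id,
                         rep(1:10, each = 88)), `[`, character(1), 1L)
  w$signal[w$gene_id %in% spiked] <- 0.2 / 1 *
    w$signal[w$gene_id %in% spiked]
  bt <- suppressWarnings(b_score_screen(w))
  meds <- tapply(bt$b_score, interaction(bt$replicate, bt$plate), median)
  expect_gte(mean(abs(meds) < 0.1), 0.95)
  # spiked gene is the plate minimum in >= 95% of (plate, replicate) cases
  is_min <- mapply(function(g) {
    rows <- bt[bt$gene_id == g, ]
    sapply(seq_len(nrow(rows)), function(i) {
      pl <- bt[bt$plate == rows$plate[i] & bt$replicate == rows$replicate[i], ]
      rows$b_score[i] <= min(pl$b_score)
    })
  }, spiked)
  expect_gte(mean(unlist(is_min)), 0.95)
  # b-scores finite and one entry per (gene, replicate)
  expect_true(all(is.finite(bt$b_score)))
  expect_equal(nrow(bt), 880 * 3)
  expect_equal(anyDuplicated(bt[c("gene_id", "replicate")]), 0L)
})

test_that("partial final plates are handled (trimmed columns get NA, flagged)", {
  # 100 genes -> plate 2 holds 12 sample wells: one full column of 8,
  # one partial column of 4, the rest empty
  d <- screen_design(n_genes = 100, seed = 17)
  e <- null_effects(noise_cv = 0.1)
  sim <- simulate_screen(d, e)
  bt <- suppressWarnings(b_score_screen(sim$wells))
  expect_equal(nrow(bt), 100 * 3)
  # every gene keeps a finite b-score in at least one replicate
  ok <- tapply(is.finite(bt$b_score), bt$gene_id, any)
  expect_true(all(ok))
})
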