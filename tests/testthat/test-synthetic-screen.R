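test_that("noise-free generator is an exact function of the truth table", {
  d <- screen_design(n_genes = 100, seed = 42)
  e <- effect_model(noise_cv = 0, plate_effect_sd = 0, row_effect_sd = 0,
                    col_effect_sd = 0, hypo_fraction = 0, hyper_fraction = 0)
  sim <- simulate_screen(d, e)
  w <- sim$wells
  expect_equal(w$signal[w$well_type == "sample"],
               rep(e$baseline_signal, sum(w$well_type == "sample")))
  expect_equal(w$signal[w$well_type == "mock_plusPMA"],
               rep(e$baseline_signal, sum(w$well_type == "mock_plusPMA")))
  expect_equal(w$signal[w$well_type == "mock_minusPMA"],
               rep(e$baseline_signal * e$minus_pma_fraction,
                   sum(w$well_type == "mock_minusPMA")))
  # with hits spiked, sample wells are baseline times the true multiplier
  e2 <- effect_model(noise_cv = 0, plate_effect_sd = 0, row_effect_sd = 0,
                     col_effect_sd = 0)
  sim2 <- simulate_screen(d, e2)
  w2 <- sim2$wells[sim2$wells$well_type == "sample", ]
  eff <- setNames(sim2$truth$effect, sim2$truth$gene_id)
  expect_equal(w2$signal, e2$baseline_signal * unname(eff[w2$gene_id]))
})

test_that("identical seed gives bit-identical tables, new seed changes only signals", {
  d <- screen_design(n_genes = 150, seed = 9)
  e <- effect_model()
  s1 <- simulate_screen(d, e)
  s2 <- simulate_screen(d, e)
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth, s2$truth)
  d2 <- d; d2$seed <- 10L
  s3 <- simulate_screen(d2, e)
  layout_cols <- c("replicate", "plate", "row", "col", "well_type")
  expect_identical(s1$wells[layout_cols], s3$wells[layout_cols])
  expect_false(isTRUE(all.equal(s1$wells$signal, s3$wells$signal)))
})

test_that("truth table matches requested spike fractions and covers every gene", {
  d <- screen_design(n_genes = 1000, seed = 3)
  e <- effect_model(hypo_fraction = 0.05, hyper_fraction = 0.02)
  sim <- simulate_screen(d, e)
  expect_equal(sum(sim$truth$true_class == "hypo"), 50)
  expect_equal(sum(sim$truth$true_class == "hyper"), 20)
  expect_setequal(sim$truth$gene_id,
                  unique(na.omit(sim$wells$gene_id)))
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  # each gene in exactly one well position, identical across replicates
  sw <- sim$wells[sim$wells$well_type == "sample", ]
  pos <- split(paste(sw$plate, sw$row, sw$col), sw$gene_id)
  expect_true(all(vapply(pos, function(p) length(unique(p)) == 1L, logical(1))))
  expect_true(all(lengths(pos) == d$n_replicates))
})

test_that("pooled CV of null-gene signals converges to noise_cv", {
  d <- screen_design(n_genes = 2000, seed = 5)
  e <- null_effects(plate_effect_sd = 0, row_effect_sd = 0, col_effect_sd = 0,
                    noise_cv = 0.1)
  sim <- simulate_screen(d, e)
  s <- sim$wells$signal[sim$wells$well_type == "sample"]
  cv <- sd(s) / mean(s)
  expect_lt(abs(cv - e$noise_cv) / e$noise_cv, 0.10)
})

test_that("row/col marginal medians of log-signal recover injected gradients", {
  d <- screen_design(n_genes = 88, seed = 21)
  e <- null_effects(plate_effect_sd = 0, row_effect_sd = 0.3,
                    col_effect_sd = 0, noise_cv = 0.05)
  sim <- simulate_screen(d, e)
  w <- sim$wells[sim$wells$replicate == 1 & sim$wells$plate == 1 &
                 sim$wells$well_type == "sample", ]
  # recover the realised effects by replaying the plate substream
  set.seed(d$seed)
  subseeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                d$n_replicates * 1L), nrow = d$n_replicates)
  set.seed(subseeds[1, 1])
  invisible(rnorm(1, 0, e$plate_effect_sd))
  row_true <- rnorm(8, 0, e$row_effect_sd)
  # centred row medians of log signal vs centred true effects
  obs <- tapply(log(w$signal), w$row, median)
  obs <- obs - mean(obs)
  row_true_c <- row_true - mean(row_true)
  sig_log <- sqrt(log(1 + e$noise_cv^2))
  se <- 1.2533 * sig_log / sqrt(11)  # asymptotic SE of a median of 11 wells
  expect_true(all(abs(obs - row_true_c) < 3 * se))
})

test_that("validation screen: empty gene list still emits controls", {
  d <- screen_design(n_genes = 50, seed = 2)
  e <- effect_model()
  sim <- simulate_screen(d, e)
  vw <- simulate_validation_screen(character(0), sim$truth, e, d)
  expect_equal(sum(vw$well_type == "sample"), 0)
  expect_equal(sum(vw$well_type == "mock_plusPMA"),
               d$controls_per_plate[["mock_plusPMA"]] * d$n_replicates)
  expect_gt(sum(vw$well_type == "mock_minusPMA"), 0)
})

test_that("validation screen: null genes at zero noise equal the +PMA mocks", {
  d <- screen_design(n_genes = 40, seed = 8)
  e0 <- null_effects(noise_cv = 0, plate_effect_sd = 0, row_effect_sd = 0,
                     col_effect_sd = 0)
  sim <- simulate_screen(d, e0)
  vw <- simulate_validation_screen(sim$truth$gene_id, sim$truth, e0, d)
  mock <- unique(vw$signal[vw$well_type == "mock_plusPMA"])
  expect_equal(unique(vw$signal[vw$well_type == "sample"]), mock)
})

test_that("validation screen reseeding changes signals, not layout", {
  d <- screen_design(n_genes = 60, seed = 4)
  e <- effect_model()
  sim <- simulate_screen(d, e)
  genes <- sim$truth$gene_id[1:30]
  v1 <- simulate_validation_screen(genes, sim$truth, e, d)
  d2 <- d; d2$seed <- 99L
  v2 <- simulate_validation_screen(genes, sim$truth, e, d2)
  lay <- c("replicate", "plate", "row", "col", "well_type", "gene_id")
  expect_identical(v1[lay], v2[lay])
  expect_false(isTRUE(all.equal(v1$signal, v2$signal)))
  expect_error(simulate_validation_screen("nonexistent_gene", sim$truth, e, d),
               "lookup error")
})

test_that("infeasible designs are rejected", {
  expect_error(screen_design(n_genes = 10, wells_per_plate = 96,
                             controls_per_plate = c(mock_plusPMA = 90,
                                                    mock_minusPMA = 10)),
               "design error")
  expect_error(screen_design(n_genes = 10, wells_per_plate = 90),
               "n_rows")
})
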