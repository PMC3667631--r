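test_that("primary classification applies the strict +/-1.5 median rule", {
  b <- data.frame(
    gene_id = rep(c("gA", "gB", "gC", "gD"), each = 3),
    replicate = rep(1:3, 4),
    b_score = c(-1.7, -1.6, -1.5,   # median -1.6 -> hypo
                 1.5,  1.6,  1.7,   # median  1.6 -> hyper
                -0.2,  0.0,  0.3,   # median  0   -> none
                -1.5, -1.5, -1.5))  # median exactly -1.5 -> none (strict)
  out <- classify_primary(b)
  expect_equal(setNames(out$class, out$gene_id),
               c(gA = "hyposecretory", gB = "hypersecretory",
                 gC = "none", gD = "none"))
  expect_equal(out$median_b, c(-1.6, 1.6, 0, -1.5))
  # monotone: lowering |median| never creates a hit
  shrunk <- b; shrunk$b_score <- shrunk$b_score * 0.5
  out2 <- classify_primary(shrunk)
  expect_true(all(out2$class[out$class == "none"] == "none"))
  expect_error(classify_primary(b[0, ]), "empty")
})

test_that("genes with missing replicates are classified on available data and flagged", {
  b <- data.frame(gene_id = c("gA", "gA", "gA", "gB", "gB"),
                  replicate = c(1, 2, 3, 1, 2),
                  b_score = c(-2, -2, -2, 2, 2))
  out <- classify_primary(b)
  expect_equal(out$complete, c(TRUE, FALSE))
  expect_equal(out$class, c("hyposecretory", "hypersecretory"))
})

test_that("platewise z-score matches hand computation and is location-invariant", {
  expect_equal(z_score_platewise(c(2, 4, 6), 4), 0)
  expect_equal(z_score_platewise(c(2, 4, 6), 6), 1)  # sample SD of {2,4,6} = 2
  expect_equal(z_score_platewise(c(2, 4, 6) + 10, c(2, 4, 6) + 10),
               z_score_platewise(c(2, 4, 6), c(2, 4, 6)))
  expect_error(z_score_platewise(c(3, 3, 3), 3),
               class = "degenerate_plate_error")
  expect_error(z_score_platewise(5, 5), ">= 2")
})

test_that("validation classification uses the mock band with strict bounds", {
  z <- data.frame(gene_id = rep(c("gA", "gB"), each = 3),
                  replicate = rep(1:3, 2),
                  z = c(-0.6, -0.5, -0.4,  0.10, 0.15, 0.20))
  mock <- c(-0.1, 0.0, 0.1)  # mean 0, SD 0.1
  out <- classify_validation(z, mock, n_sd = 2)
  expect_equal(setNames(out$validated_class, out$gene_id),
               c(gA = "hyposecretory", gB = "none"))
  expect_equal(out$mean_z, c(-0.5, 0.15))
  expect_equal(out$sd_mock_z[1], 0.1)
  expect_error(classify_validation(z, c(0.3, 0.3)),
               class = "degenerate_plate_error")
  expect_error(classify_validation(z, 0.3), ">= 2")
})

test_that("validate_screen scores a simulated validation run end to end", {
  d <- screen_design(n_genes = 60, seed = 31)
  e <- effect_model(hypo_fraction = 0.2, hyper_fraction = 0.1,
                    noise_cv = 0.05)
  sim <- simulate_screen(d, e)
  vw <- simulate_validation_screen(sim$truth$gene_id, sim$truth, e, d)
  val <- validate_screen(vw, n_sd = 2)
  tr <- setNames(sim$truth$true_class, sim$truth$gene_id)
  hypo_called <- val$gene_id[val$validated_class == "hyposecretory"]
  hyper_called <- val$gene_id[val$validated_class == "hypersecretory"]
  # strong effects (0.25x / 2.5x) at low noise: calls track truth closely
  expect_gt(mean(tr[hypo_called] == "hypo"), 0.9)
  expect_gt(mean(tr[hyper_called] == "hyper"), 0.9)
  expect_gt(sum(tr == "hypo" & names(tr) %in% hypo_called), 0.8 * sum(tr == "hypo"))
})

test_that("annotation filter removes any-match blocked categories, keeps unannotated", {
  hits <- data.frame(gene_id = sprintf("g%d", 1:5))
  ann <- data.frame(gene_id = c("g1", "g2", "g4", "g4"),
                    category = c("Nuclear", "metabolism", "PM", "secreted"))
  expect_equal(nrow(filter_by_annotation(hits, ann, character(0))), 5)
  out <- filter_by_annotation(hits, ann, blocklist = c("nuclear"))
  expect_setequal(out$gene_id, c("g2", "g3", "g4", "g5"))
  # any-match semantics: g4 is {PM, secreted}, blocked via secreted
  out2 <- filter_by_annotation(hits, ann, blocklist = c("secreted"))
  expect_false("g4" %in% out2$gene_id)
  # unannotated genes retained and flagged
  expect_false(out$annotated[out$gene_id == "g3"])
  expect_true(out$annotated[out$gene_id == "g2"])
})

test_that("expression filter calls detection and Welch-test regulation", {
  calls <- data.frame(
    gene_id = rep(c("gUp", "gFlat", "gOff"), each = 6),
    condition = rep(rep(c("starved", "nonstarved"), each = 3), 3),
    replicate = rep(1:3, 6),
    gene_intensity = c(2.1, 1.9, 2.0, 1.0, 1.0, 1.0,    # up
                       1.2, 1.1, 1.3, 1.2, 1.1, 1.3,    # identical
                       0, 0, 0, 0, 0, 0),               # undetected
    housekeeping_intensity = 1)
  out <- expression_filter(calls, detection_floor = 0.05)
  gUp <- out[out$gene_id == "gUp", ]
  expect_true(gUp$detected)
  expect_equal(gUp$regulation, "up")
  expect_equal(gUp$p_value,
               t.test(c(2.1, 1.9, 2.0), c(1, 1, 1))$p.value)
  expect_equal(out$regulation[out$gene_id == "gFlat"], "unchanged")
  gOff <- out[out$gene_id == "gOff", ]
  expect_false(gOff$detected)
  expect_error(expression_filter(transform(calls, housekeeping_intensity = 0)),
               "housekeeping")
})
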