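#' Pipeline run configuration
#'
#' Collects every tunable of the generate -> normalize -> rank -> select ->
#' validate pipeline in one list, with the screen's conventions as
#' defaults. A config can be read from / written to a JSON file; its MD5
#' hash and the seed are embedded in every output header so a run is fully
#' auditable.
#'
#' @param n_genes number of genes to simulate (ignored when `wells_csv`
#'   supplies real data).
#' @param n_replicates replicate plate sets.
#' @param seed master seed; every stage derives its substream from it.
#' @param baseline_signal,minus_pma_fraction,plate_effect_sd,row_effect_sd,col_effect_sd,noise_cv,hypo_fraction,hyper_fraction,hypo_effect,hyper_effect
#'   see [effect_model()].
#' @param bscore_tol,bscore_max_iter see [median_polish()].
#' @param primary_threshold median-B-score cutoff (default 1.5).
#' @param n_perm rank-product permutations.
#' @param validation_n_sd mock-band width in SDs (default 2).
#' @param blocklist annotation categories removed between stages.
#' @param detection_floor relative-expression detection floor.
#' @param wells_csv,annotation_csv optional input files; when `wells_csv`
#'   is `NULL` the screen is simulated.
#' @param run_validation simulate and score the validation stage?
#' @return list of class `run_config`.
#' @export
run_config <- function(n_genes = 2000L,
                       n_replicates = 3L,
                       seed = 1L,
                       baseline_signal = 1000,
                       minus_pma_fraction = 0.25,
                       plate_effect_sd = 0.1,
                       row_effect_sd = 0.05,
                       col_effect_sd = 0.05,
                       noise_cv = 0.1,
                       hypo_fraction = 0.05,
                       hyper_fraction = 0.02,
                       hypo_effect = 0.25,
                       hyper_effect = 2.5,
                       bscore_tol = 1e-6,
                       bscore_max_iter = 100L,
                       primary_threshold = 1.5,
                       n_perm = 100L,
                       validation_n_sd = 2,
                       blocklist = character(0),
                       detection_floor = 0.05,
                       wells_csv = NULL,
                       annotation_csv = NULL,
                       run_validation = TRUE) {
  stopifnot(primary_threshold > 0, validation_n_sd > 0, bscore_tol > 0,
            detection_floor >= 0, n_perm >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with config fields (missing fields take defaults).
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full two-stage screen pipeline
#'
#' Orchestrates simulate (or load) -> B-score -> rank product -> primary
#' selection -> annotation filter -> validation screen -> mock-band
#' classification, writing every stage's CSV into `out_dir` and a JSON run
#' report summarising the hit funnel. When simulation truth is available
#' the report carries a per-stage confusion matrix (sensitivity, FDR).
#' Deterministic: the same config and seed give byte-identical outputs.
#'
#' @param config a [run_config()] (or a path to a JSON config).
#' @param out_dir output directory, created if needed.
#' @return The run report (list), invisibly; also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(seed = config$seed, config = config_hash(config))
  p <- function(f) file.path(out_dir, f)

  truth <- NULL
  if (is.null(config$wells_csv)) {
    design <- screen_design(n_genes = config$n_genes,
                            n_replicates = config$n_replicates,
                            seed = config$seed)
    effects <- effect_model(baseline_signal = config$baseline_signal,
                            minus_pma_fraction = config$minus_pma_fraction,
                            plate_effect_sd = config$plate_effect_sd,
                            row_effect_sd = config$row_effect_sd,
                            col_effect_sd = config$col_effect_sd,
                            noise_cv = config$noise_cv,
                            hypo_fraction = config$hypo_fraction,
                            hyper_fraction = config$hyper_fraction,
                            hypo_effect = config$hypo_effect,
                            hyper_effect = config$hyper_effect)
    sim <- simulate_screen(design, effects)
    wells <- sim$wells
    truth <- sim$truth
    write_well_table(wells, p("wells.csv"), header = hdr)
    write_truth_table(truth, p("truth.csv"), header = hdr)
  } else {
    wells <- read_well_table(config$wells_csv)
  }

  bt <- b_score_screen(wells, tol = config$bscore_tol,
                       max_iter = config$bscore_max_iter)
  write_b_table(bt, p("bscores.csv"), header = hdr)
  plate_log <- attr(bt, "plate_log")

  rp <- rank_product_table(bt, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 1L))
  write_rankprod_table(rp, p("rankprod.csv"), header = hdr)

  primary <- classify_primary(bt, threshold = config$primary_threshold, rp = rp)
  write_screen_table(primary, p("primary_hits.csv"), header = hdr)
  hits <- primary[primary$class != "none", , drop = FALSE]

  if (!is.null(config$annotation_csv)) {
    ann <- read_annotation_table(config$annotation_csv)
    filtered <- filter_by_annotation(hits, ann, config$blocklist)
  } else {
    filtered <- hits
  }
  write_screen_table(filtered, p("filtered_hits.csv"), header = hdr)

  validated <- NULL
  if (isTRUE(config$run_validation) && !is.null(truth)) {
    vdesign <- screen_design(n_genes = nrow(filtered),
                             n_replicates = config$n_replicates,
                             seed = derive_seed(config$seed, 2L))
    veffects <- effect_model(baseline_signal = config$baseline_signal,
                             minus_pma_fraction = config$minus_pma_fraction,
                             plate_effect_sd = config$plate_effect_sd,
                             row_effect_sd = config$row_effect_sd,
                             col_effect_sd = config$col_effect_sd,
                             noise_cv = config$noise_cv,
                             hypo_fraction = config$hypo_fraction,
                             hyper_fraction = config$hyper_fraction,
                             hypo_effect = config$hypo_effect,
                             hyper_effect = config$hyper_effect)
    vwells <- simulate_validation_screen(filtered$gene_id, truth,
                                         veffects, vdesign)
    write_well_table(vwells, p("validation_wells.csv"), header = hdr)
    validated <- validate_screen(vwells, n_sd = config$validation_n_sd)
    write_screen_table(validated, p("validated_hits.csv"), header = hdr)
  }

  report <- build_report(config, truth, primary, filtered, validated, plate_log)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

# stage seeds derived from the master seed, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + k * 7919L) %% (2^31 - 1))
}

confusion <- function(called, classes, truth) {
  # called: gene ids called hits; classes: their direction labels
  tr <- stats::setNames(truth$true_class, truth$gene_id)
  want <- c(hyposecretory = "hypo", hypersecretory = "hyper")
  tp <- sum(tr[called] == want[classes], na.rm = TRUE)
  fp <- length(called) - tp
  n_true <- sum(truth$true_class != "null")
  list(called = length(called), tp = tp, fp = fp,
       fn = n_true - tp,
       sensitivity = if (n_true > 0) tp / n_true else NA,
       fdr = if (length(called) > 0) fp / length(called) else 0)
}

build_report <- function(config, truth, primary, filtered, validated, plate_log) {
  funnel <- list(
    screened = nrow(primary),
    primary_hyposecretory = sum(primary$class == "hyposecretory"),
    primary_hypersecretory = sum(primary$class == "hypersecretory"),
    after_annotation_filter = nrow(filtered))
  if (!is.null(validated)) {
    funnel$validated_hyposecretory <-
      sum(validated$validated_class == "hyposecretory")
    funnel$validated_hypersecretory <-
      sum(validated$validated_class == "hypersecretory")
  }
  rep <- list(seed = config$seed,
              config = config_hash(config),
              funnel = funnel,
              n_plates_polished = if (!is.null(plate_log)) nrow(plate_log) else 0L)
  if (!is.null(truth)) {
    hit_rows <- primary$class != "none"
    rep$confusion <- list(
      n_genes = nrow(truth),
      primary = confusion(primary$gene_id[hit_rows],
                          primary$class[hit_rows], truth))
    if (!is.null(validated)) {
      vr <- validated$validated_class != "none"
      rep$confusion$validated <- confusion(validated$gene_id[vr],
                                           validated$validated_class[vr],
                                           truth)
    }
  }
  rep
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `bscore`, `rankprod`, `select`, `validate`,
#' `quantify`, `run-all`. Most take `--config <json>`; stage commands read
#' and write the CSV dialects of the pipeline. Invoke from a shell via the
#' script in `inst/cli/mucinscreen.R`, or directly as
#' `screen_cli(c("run-all", "--config", "cfg.json", "--out-dir", "out"))`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
screen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: mucinscreen <simulate|bscore|rankprod|select|validate|",
            "quantify|run-all> [--option value ...]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])
  get_cfg <- function() {
    if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
  }
  switch(cmd,
    "run-all" = {
      run_pipeline(get_cfg(), out_dir = opts$`out-dir` %||% "screen_out")
    },
    "simulate" = {
      cfg <- get_cfg()
      design <- screen_design(n_genes = cfg$n_genes,
                              n_replicates = cfg$n_replicates, seed = cfg$seed)
      eff <- do.call(effect_model, cfg[names(formals(effect_model))])
      sim <- simulate_screen(design, eff)
      hdr <- list(seed = cfg$seed, config = config_hash(cfg))
      write_well_table(sim$wells, opts$out %||% "wells.csv", header = hdr)
      write_truth_table(sim$truth, opts$truth %||% "truth.csv", header = hdr)
    },
    "bscore" = {
      wells <- read_well_table(opts$wells)
      bt <- b_score_screen(wells)
      write_b_table(bt, opts$out %||% "bscores.csv")
    },
    "rankprod" = {
      bt <- read_b_table(opts$bscores)
      rp <- rank_product_table(bt,
                               n_perm = as.integer(opts$`n-perm` %||% 100L),
                               seed = as.integer(opts$seed %||% 1L))
      write_rankprod_table(rp, opts$out %||% "rankprod.csv")
    },
    "select" = {
      bt <- read_b_table(opts$bscores)
      rp <- if (!is.null(opts$rankprod)) read_rankprod_table(opts$rankprod)
      hits <- classify_primary(bt,
                               threshold = as.numeric(opts$threshold %||% 1.5),
                               rp = rp)
      write_screen_table(hits, opts$out %||% "primary_hits.csv")
    },
    "validate" = {
      wells <- read_well_table(opts$wells)
      val <- validate_screen(wells, n_sd = as.numeric(opts$`n-sd` %||% 2))
      write_screen_table(val, opts$out %||% "validated_hits.csv")
    },
    "quantify" = {
      x <- read_intensity_table(opts$`in`)
      out <- quantify_intensities(x, reference_condition = opts$reference)
      write_screen_table(out, opts$out %||% "quantified.csv")
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1L > length(args))
      stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
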