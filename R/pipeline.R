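#' End-to-end run configuration
#'
#' Bundles generator, preprocessing and model settings plus paths and the
#' global seed. In `replicate_paper` mode the protocol parameters are locked:
#' Savitzky-Golay order 3 / window 11, truncation 700--1700 cm^-1, five
#' folds, 20% test fraction, class-stratified split.
#'
#' @param mode `"replicate_paper"` (default) or `"exploratory"`.
#' @param seed Global integer seed; stage seeds are derived from it.
#' @param counts Per-class spectrum counts for the generator.
#' @param effect_scale Generator effect size (default 3).
#' @param out_dir Output directory for run artifacts (`NULL`: no files
#'   written).
#' @param input_dir Optional directory with an existing dataset (as written
#'   by [write_dataset()]); when given, the generator is skipped.
#' @param preprocess A [preprocess_config()].
#' @param model A [model_config()] (its seed/test fraction are overridden by
#'   the run seed and mode locks).
#' @param prominence_factor,min_separation,consensus_tolerance,
#'   prevalence_threshold Peak-feature settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("replicate_paper", "exploratory"),
                       seed = 1L,
                       counts = c(normal = 700, FCD_IIa = 396,
                                  FCD_IIb = 374),
                       effect_scale = 3,
                       out_dir = NULL,
                       input_dir = NULL,
                       preprocess = preprocess_config(),
                       model = model_config(),
                       prominence_factor = 3,
                       min_separation = 8,
                       consensus_tolerance = 5,
                       prevalence_threshold = 0.8) {
  mode <- match.arg(mode)
  if (model$test_fraction <= 0 || model$test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  if (mode == "replicate_paper") {
    preprocess$sg_order <- 3L
    preprocess$sg_window <- 11L
    preprocess$trunc_range <- c(700, 1700)
    model$folds <- 5L
    model$test_fraction <- 0.2
    model$stratify_by <- "class"
  }
  structure(list(mode = mode, seed = as.integer(seed), counts = counts,
                 effect_scale = effect_scale, out_dir = out_dir,
                 input_dir = input_dir, preprocess = preprocess,
                 model = model, prominence_factor = prominence_factor,
                 min_separation = min_separation,
                 consensus_tolerance = consensus_tolerance,
                 prevalence_threshold = prevalence_threshold),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete pipeline
#'
#' Executes simulate (or load) -> preprocess -> peak features -> model 1
#' (FCD type II vs normal, positive class `FCDII`) -> model 2 (FCD IIa vs
#' IIb restricted to the FCD spectra, positive class `FCD_IIb`). When
#' `config$out_dir` is set, artifacts (feature matrix, consensus set, both
#' evaluation reports, audit log, text report, provenance with config hash)
#' are written there; a failure leaves a `FAILED` marker naming the stage.
#'
#' @param config A [run_config()].
#' @param instrument Optional `instrument_model` (default
#'   [instrument_model()]).
#' @return List with `dataset`, `features`, `consensus`, `model1`, `model2`,
#'   `audit`, `provenance`.
#' @export
run_all <- function(config = run_config(), instrument = instrument_model()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage <- "simulate"
  fail_marker <- function(e) {
    if (!is.null(out_dir)) {
      writeLines(sprintf("stage: %s\nerror: %s", stage,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    ds <- if (!is.null(config$input_dir)) {
      d <- read_spectra(file.path(config$input_dir, "spectra.csv"),
                        file.path(config$input_dir, "meta.csv"),
                        stage = "averaged")
      d$refs <- read_calibration_refs(file.path(config$input_dir, "refs"))
      d
    } else {
      profiles <- default_profiles(effect_scale = config$effect_scale)
      simulate_dataset(profiles, instrument, counts = config$counts,
                       seed = config$seed)
    }

    stage <- "preprocess"
    pp <- run_preprocessing(ds, ds$refs, config$preprocess)

    stage <- "features"
    fits <- fit_dataset_peaks(pp$dataset, config$prominence_factor,
                              config$min_separation)
    consensus <- build_consensus(fits, config$consensus_tolerance,
                                 config$prevalence_threshold)
    fm <- extract_features(pp$dataset, consensus, fits)

    stage <- "model1"
    lab1 <- ifelse(fm$diagnosis == "normal", "normal", "FCDII")
    cfg1 <- config$model
    cfg1$seed <- (config$seed + 1001L) %% .Machine$integer.max
    m1 <- run_model(fm, lab1, positive = "FCDII", config = cfg1)

    stage <- "model2"
    sub <- fm$diagnosis %in% c("FCD_IIa", "FCD_IIb")
    cfg2 <- config$model
    cfg2$seed <- (config$seed + 2002L) %% .Machine$integer.max
    m2 <- run_model(fm[sub, , drop = FALSE], fm$diagnosis[sub],
                    positive = "FCD_IIb", config = cfg2)

    stage <- "write"
    prov <- list(package = "ramanfcd",
                 version = as.character(utils::packageVersion("ramanfcd")),
                 seed = config$seed, mode = config$mode,
                 config_hash = config_hash(config))
    result <- list(dataset = pp$dataset, features = fm,
                   consensus = consensus, model1 = m1, model2 = m2,
                   audit = pp$audit, provenance = prov)
    if (!is.null(out_dir)) {
      unlink(file.path(out_dir, "FAILED"))
      data.table::fwrite(fm, file.path(out_dir, "features.csv"))
      jsonlite::write_json(
        list(peaks = consensus$peaks, tolerance = consensus$tolerance,
             prevalence_threshold = consensus$prevalence_threshold),
        file.path(out_dir, "consensus.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      write_eval_report(m1, file.path(out_dir, "eval_model1.json"))
      write_eval_report(m2, file.path(out_dir, "eval_model2.json"))
      write_audit_log(pp$audit, file.path(out_dir, "audit.jsonl"))
      jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
      writeLines(make_report(result), file.path(out_dir, "report.txt"))
    }
    result
  }, error = fail_marker)
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates per-class counts, the consensus peaks with their nearest
#' catalogue assignment (within +/-5 cm^-1), the selected features, and both
#' models' test metrics in a compact table.
#'
#' @param result The list returned by [run_all()], or a run directory
#'   written by it.
#' @return Character vector of report lines.
#' @export
make_report <- function(result) {
  if (is.character(result)) {
    dir <- result
    need <- file.path(dir, c("features.csv", "consensus.json",
                             "eval_model1.json", "eval_model2.json"))
    if (!all(file.exists(need))) {
      stop("incomplete run directory: missing ",
           paste(basename(need[!file.exists(need)]), collapse = ", "))
    }
    fm <- as.data.frame(data.table::fread(need[1]))
    cj <- jsonlite::read_json(need[2], simplifyVector = TRUE)
    consensus <- list(peaks = as.data.frame(cj$peaks))
    m1 <- jsonlite::read_json(need[3], simplifyVector = TRUE)
    m2 <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  } else {
    fm <- result$features
    consensus <- result$consensus
    m1 <- result$model1
    m2 <- result$model2
  }
  lines <- c("Raman single-cell classification run", "")
  tab <- table(fm$diagnosis)
  lines <- c(lines, "Spectra per class:",
             sprintf("  %-10s %5d", names(tab), as.integer(tab)), "")
  lines <- c(lines, "Consensus peaks (nearest band assignment within 5 cm^-1):")
  if (is.null(consensus$peaks) || nrow(consensus$peaks) == 0L) {
    lines <- c(lines, "  (no consensus peaks)")
  } else {
    for (i in seq_len(nrow(consensus$peaks))) {
      p <- consensus$peaks$position[i]
      hit <- band_lookup(p, tolerance = 5)
      ann <- if (nrow(hit)) {
        sprintf("%s (%g cm^-1)", hit$molecule[1L], hit$position[1L])
      } else "-"
      lines <- c(lines, sprintf("  %8.1f cm^-1  %s", p, ann))
    }
  }
  fmt_model <- function(m, name, grouping) {
    acc <- as.numeric(m$accuracy); se <- as.numeric(m$sensitivity)
    sp <- as.numeric(m$specificity)
    cnt <- function(side) {
      if (is.null(m$counts)) return("")
      paste(sprintf("%s=%d", names(m$counts[[side]]),
                    unlist(m$counts[[side]])), collapse = " ")
    }
    c("", sprintf("%s (%s; positive: %s)", name, grouping, m$positive),
      sprintf("  train: %s | test: %s", cnt("train"), cnt("test")),
      sprintf("  sensitivity %5.1f%% | specificity %5.1f%% | accuracy %5.1f%% | AUC %.3f",
              100 * se, 100 * sp, 100 * acc, as.numeric(m$auc)),
      if (!is.null(m$chosen)) {
        sprintf("  chosen C = %g, retained features = %d",
                as.numeric(m$chosen$C), as.integer(m$chosen$n_features))
      })
  }
  lines <- c(lines,
             fmt_model(m1, "Model 1", "FCD type II vs normal"),
             fmt_model(m2, "Model 2", "FCD IIa vs IIb"))
  lines
}

#' Parse a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric, comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}

cli_usage <- function() {
  c("usage: ramanfcd <command> [options]",
    "",
    "commands:",
    "  simulate  --out DIR [--seed N] [--effect-scale X] [--counts n1,n2,n3]",
    "  run-all   --out DIR [--seed N] [--effect-scale X] [--counts n1,n2,n3]",
    "            [--in DIR] [--config FILE] [--mode replicate_paper|exploratory]",
    "  report    --in DIR",
    "",
    "exit codes: 0 ok, 1 validation error, 2 runtime error")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("flag without value: ", a)
    flags[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper over [simulate_dataset()], [run_all()] and
#' [make_report()]; used by the `inst/scripts/ramanfcd` launcher. Returns
#' (rather than calls `quit()` with) the exit code so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code: 0 ok, 1 validation error, 2 runtime error.
#' @export
rfcd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help", "help")) {
    writeLines(cli_usage())
    return(0L)
  }
  cmd <- args[1L]
  flags <- tryCatch(parse_cli_flags(args[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    return(1L)
  }
  seed <- as.integer(flags$seed %||% 1L)
  counts <- c(normal = 700, FCD_IIa = 396, FCD_IIb = 374)
  if (!is.null(flags$counts)) {
    counts[] <- as.numeric(strsplit(flags$counts, ",")[[1L]])
  }
  effect_scale <- as.numeric(flags[["effect-scale"]] %||% 3)
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message(conditionMessage(e))
      2L
    })
  }
  switch(cmd,
    simulate = {
      if (is.null(flags$out)) { message("simulate requires --out"); return(1L) }
      run({
        ds <- simulate_dataset(default_profiles(effect_scale),
                               instrument_model(), counts = counts,
                               seed = seed)
        write_dataset(ds, flags$out,
                      params = list(seed = seed, counts = as.list(counts),
                                    effect_scale = effect_scale))
      })
    },
    `run-all` = {
      if (is.null(flags$out)) { message("run-all requires --out"); return(1L) }
      cfg <- tryCatch(
        run_config(mode = flags$mode %||% "replicate_paper", seed = seed,
                   counts = counts, effect_scale = effect_scale,
                   out_dir = flags$out, input_dir = flags[["in"]]),
        error = function(e) e)
      if (inherits(cfg, "error")) { message(conditionMessage(cfg)); return(1L) }
      run(run_all(cfg))
    },
    report = {
      if (is.null(flags[["in"]])) { message("report requires --in"); return(1L) }
      run(writeLines(make_report(flags[["in"]])))
    },
    {
      message("unknown command: ", cmd)
      writeLines(cli_usage())
      1L
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
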