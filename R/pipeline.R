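# End-to-end orchestration: synthesize or load sources, standardize, build
# leave-one-database-out splits, train, evaluate, and write every artifact
# plus a content-hash manifest under one output directory.

.log_msg <- function(level, fmt, ..., logfile = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) {
    entry <- jsonlite::toJSON(list(time = format(Sys.time()), level = level,
                                   msg = sprintf(fmt, ...)),
                              auto_unbox = TRUE)
    cat(entry, "\n", file = logfile, append = TRUE)
  }
  invisible(NULL)
}

#' Assemble a pipeline run configuration
#'
#' @param outdir output directory for all artifacts.
#' @param synth optional [synthetic_config()]; when given, sources are
#'   generated rather than read from files.
#' @param sources optional list of `list(path=, name=, status_map=)` entries
#'   describing real source tables (ignored when `synth` is given).
#' @param negative_source name of the approved-drug source (default:
#'   `"source1"` for synthetic corpora).
#' @param test_dbs character vector of databases to hold out (default: all
#'   except the negative source).
#' @param modes split modes to run (default both `"agree"`, `"no_agree"`).
#' @param backend classifier backend (default `"fingerprint"` -- cheap;
#'   switch to `"transformer"` for the full model).
#' @param model [model_config()] for the transformer backend, or a settings
#'   list for the fingerprint backend.
#' @param tau decision threshold (default 0.5).
#' @param seed top-level seed; stage seeds are derived from it.
#' @param max_len standardization SMILES length cutoff (default 300).
#' @return list of class `withdrawr_run_config`.
#' @export
run_config <- function(outdir, synth = synthetic_config(), sources = NULL,
                       negative_source = "source1", test_dbs = NULL,
                       modes = c("agree", "no_agree"),
                       backend = c("fingerprint", "transformer"),
                       model = NULL, tau = 0.5, seed = 1L, max_len = 300L) {
  backend <- match.arg(backend)
  stopifnot(tau > 0, tau < 1)
  structure(list(outdir = outdir, synth = synth, sources = sources,
                 negative_source = negative_source, test_dbs = test_dbs,
                 modes = match.arg(modes, several.ok = TRUE),
                 backend = backend, model = model, tau = tau,
                 seed = as.integer(seed), max_len = as.integer(max_len)),
            class = "withdrawr_run_config")
}

.config_for_json <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL # implied by the file location; keeps manifests portable
  cfg$synth <- if (!is.null(cfg$synth)) unclass(cfg$synth)
  cfg$model <- if (!is.null(cfg$model)) unclass(cfg$model)
  cfg
}

#' Run the full withdrawal-prediction pipeline
#'
#' Stages: (1) synthesize or parse source tables; (2) standardize each
#' source; (3) for every requested test database and mode, build the
#' leave-one-database-out split; (4) train the configured backend on the
#' split's training set; (5) evaluate on the test set (metric report,
#' disagreement report for no-agreement splits, ranking report). All
#' artifacts land under `config$outdir` and are listed with MD5 content
#' hashes in `manifest.json`. A directory that already contains a manifest
#' is left untouched unless `force = TRUE`.
#'
#' @param config a [run_config()].
#' @param force rerun even if the output directory already has a manifest.
#' @return invisibly, the manifest as a data.frame (file, md5).
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "withdrawr_run_config"))
  outdir <- config$outdir
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    .log_msg("INFO", "manifest exists in '%s'; skipping (use force=TRUE)",
             outdir)
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    return(invisible(as.data.frame(m)))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log.jsonl")
  if (file.exists(logfile)) file.remove(logfile)
  stage <- "config"
  tryCatch({
    jsonlite::write_json(.config_for_json(config),
                         file.path(outdir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")

    stage <- "sources"
    if (!is.null(config$synth)) {
      synth_cfg <- config$synth
      synth_cfg$seed <- (config$seed * 13L) %% 2000000000L
      corpus <- synthetic_corpus(synth_cfg)
      src_dir <- file.path(outdir, "sources")
      write_synthetic_corpus(corpus, src_dir)
      status_maps <- synthetic_status_maps(synth_cfg)
      source_files <- lapply(names(corpus$databases), function(nm) {
        list(path = file.path(src_dir, paste0(nm, ".csv")), name = nm,
             status_map = status_maps[[nm]])
      })
    } else {
      if (is.null(config$sources) || !length(config$sources)) {
        stop("config must provide either synth or sources")
      }
      source_files <- config$sources
    }
    for (sf in source_files) {
      if (!file.exists(sf$path)) {
        stop(sprintf("source file missing: '%s'", sf$path))
      }
    }

    stage <- "standardize"
    db_dir <- file.path(outdir, "databases")
    dir.create(db_dir, showWarnings = FALSE)
    databases <- list()
    for (sf in source_files) {
      rec <- parse_drug_table(sf$path, sf$name, sf$status_map)
      std <- standardize_database(rec, sf$name, max_len = config$max_len)
      databases[[sf$name]] <- std$database
      write_database(std$database, file.path(db_dir, paste0(sf$name, ".csv")))
      write_exclusion_report(std$report,
                             file.path(db_dir,
                                       paste0(sf$name, "_exclusions.json")))
      .log_msg("INFO", "standardized %s: %d retained", sf$name,
               std$report$retained, logfile = logfile)
    }

    test_dbs <- config$test_dbs %||%
      setdiff(names(databases), config$negative_source)

    for (test_db in test_dbs) {
      for (mode in config$modes) {
        stage <- sprintf("split %s/%s", test_db, mode)
        split <- build_cross_db_split(databases, test_db, mode = mode,
                                      negative_source = config$negative_source)
        sdir <- file.path(outdir, "splits", paste0(test_db, "_", mode))
        write_split(split, sdir)
        .log_msg("INFO", "built split %s/%s", test_db, mode,
                 logfile = logfile)

        stage <- sprintf("train %s/%s", test_db, mode)
        model <- if (config$backend == "transformer") {
          cfg <- config$model %||% model_config()
          cfg$seed <- (config$seed * 17L + 1L) %% 2000000000L
          train_classifier(split$train, cfg, backend = "transformer")
        } else {
          settings <- config$model %||% list()
          settings$seed <- (config$seed * 17L + 1L) %% 2000000000L
          train_classifier(split$train, settings, backend = "fingerprint")
        }

        stage <- sprintf("evaluate %s/%s", test_db, mode)
        scores <- forward_classifier(model, split$test$smiles)
        metrics <- confusion_metrics(split$test$label, scores,
                                     tau = config$tau)
        jsonlite::write_json(unclass(metrics),
                             file.path(sdir, "metrics.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        write_metric_report(stats::setNames(list(metrics), config$backend),
                            file.path(sdir, "metrics.csv"))
        rr <- rank_report(split$test$key, split$test$label, scores)
        utils::write.csv(rr$ranking, file.path(sdir, "ranking.csv"),
                         row.names = FALSE)
        if (mode == "no_agree") {
          dis <- disagreement_subset(split)
          dscores <- scores[match(dis$key, split$test$key)]
          drep <- disagreement_accuracy(dscores, tau = config$tau)
          jsonlite::write_json(drep, file.path(sdir, "disagreement.json"),
                               auto_unbox = TRUE, pretty = TRUE)
        }
        .log_msg("INFO", "evaluated %s/%s: AUC %.3f", test_db, mode,
                 metrics$auc, logfile = logfile)
      }
    }

    stage <- "manifest"
    # the timestamped log is excluded so identical runs hash identically
    files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                          c("manifest.json", "run.log.jsonl")))
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, manifest_path, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    .log_msg("ERROR", "pipeline failed at stage '%s': %s", stage,
             conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write a synthetic corpus), `run` (full pipeline
#' from a JSON config), `standardize`, `split`. Invoked by the
#' `inst/cli/withdrawr` script; callable directly as
#' `cli_main(c("synth", "--n", "100", "--out", "dir"))`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: withdrawr <subcommand> [options]",
    "  synth       --n N --sources S --flip-rate D --seed K --out DIR",
    "  run         --config FILE [--force]",
    "  standardize --in FILE --name NAME --out DIR (withdrawn/approved vocab)",
    "  split       --dbdir DIR --test-db NAME --mode agree|no-agree",
    "              --negative-source NAME --out DIR",
    "  train       --train FILE --backend transformer|fingerprint",
    "              --seed K --out CHECKPOINT",
    "  evaluate    --model CHECKPOINT --test FILE --tau T --out FILE",
    "  disagreement --model CHECKPOINT --split-dir DIR --tau T --out FILE",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- .parse_cli_opts(args[-1])
  status <- tryCatch({
    switch(cmd,
      synth = {
        cfg <- synthetic_config(
          n_molecules = as.integer(opts[["n"]] %||% 500L),
          n_sources = as.integer(opts[["sources"]] %||% 4L),
          flip_rate = as.numeric(opts[["flip-rate"]] %||% 0.02),
          seed = as.integer(opts[["seed"]] %||% 1L))
        write_synthetic_corpus(synthetic_corpus(cfg),
                               opts[["out"]] %||% "synthetic_corpus")
        0L
      },
      run = {
        if (is.null(opts[["config"]])) stop("run requires --config FILE")
        cfg <- .run_config_from_json(opts[["config"]])
        run_pipeline(cfg, force = isTRUE(opts[["force"]]))
        0L
      },
      standardize = {
        rec <- parse_drug_table(opts[["in"]], opts[["name"]] %||% "source",
                                c(withdrawn = "withdrawn",
                                  approved = "approved"))
        std <- standardize_database(rec, opts[["name"]] %||% "source")
        out <- opts[["out"]] %||% "."
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_database(std$database, file.path(out, "database.csv"))
        write_exclusion_report(std$report, file.path(out, "exclusions.json"))
        0L
      },
      split = {
        dbdir <- opts[["dbdir"]] %||% stop("split requires --dbdir")
        paths <- list.files(dbdir, pattern = "\\.csv$", full.names = TRUE)
        dbs <- stats::setNames(lapply(paths, read_database),
                               sub("\\.csv$", "", basename(paths)))
        mode <- sub("-", "_", opts[["mode"]] %||% "agree")
        split <- build_cross_db_split(
          dbs, opts[["test-db"]], mode = mode,
          negative_source = opts[["negative-source"]] %||% names(dbs)[1])
        write_split(split, opts[["out"]] %||% "split")
        0L
      },
      train = {
        train_df <- utils::read.csv(opts[["train"]] %||%
                                      stop("train requires --train FILE"),
                                    stringsAsFactors = FALSE)
        backend <- opts[["backend"]] %||% "fingerprint"
        seed <- as.integer(opts[["seed"]] %||% 1L)
        model <- if (backend == "transformer") {
          train_classifier(train_df, model_config(seed = seed),
                           backend = "transformer")
        } else {
          train_classifier(train_df, list(seed = seed),
                           backend = "fingerprint")
        }
        save_model(model, opts[["out"]] %||% "model.rds")
        0L
      },
      evaluate = {
        model <- load_model(opts[["model"]] %||%
                              stop("evaluate requires --model CHECKPOINT"))
        test_df <- utils::read.csv(opts[["test"]] %||%
                                     stop("evaluate requires --test FILE"),
                                   stringsAsFactors = FALSE)
        tau <- as.numeric(opts[["tau"]] %||% model$threshold)
        scores <- forward_classifier(model, test_df$smiles)
        metrics <- confusion_metrics(test_df$label, scores, tau = tau)
        out <- opts[["out"]] %||% "metrics.json"
        jsonlite::write_json(unclass(metrics), out, auto_unbox = TRUE,
                             pretty = TRUE)
        0L
      },
      disagreement = {
        model <- load_model(opts[["model"]] %||%
                              stop("disagreement requires --model"))
        sdir <- opts[["split-dir"]] %||%
          stop("disagreement requires --split-dir DIR")
        stats <- jsonlite::read_json(file.path(sdir, "stats.json"))
        if (!identical(stats$mode, "no_agree")) {
          stop("disagreement requires a split written in no_agree mode")
        }
        test_df <- utils::read.csv(file.path(sdir, "test.csv"),
                                   stringsAsFactors = FALSE)
        keys <- unlist(stats$conflict_train0_test1)
        sub <- test_df[test_df$key %in% keys, , drop = FALSE]
        tau <- as.numeric(opts[["tau"]] %||% model$threshold)
        drep <- disagreement_accuracy(forward_classifier(model, sub$smiles),
                                      tau = tau)
        jsonlite::write_json(drep, opts[["out"]] %||% "disagreement.json",
                             auto_unbox = TRUE, pretty = TRUE)
        0L
      },
      { message(usage); 1L }
    )
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1L])) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

.run_config_from_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- if (!is.null(j$synth)) do.call(synthetic_config, j$synth)
  model <- if (!is.null(j$model) && identical(j$backend, "transformer")) {
    do.call(model_config, j$model)
  } else j$model
  sources <- if (!is.null(j$sources)) {
    lapply(seq_len(nrow(j$sources)), function(i) {
      list(path = j$sources$path[i], name = j$sources$name[i],
           status_map = unlist(j$sources$status_map[i]))
    })
  }
  run_config(outdir = j$outdir, synth = synth, sources = sources,
             negative_source = j$negative_source %||% "source1",
             test_dbs = j$test_dbs, modes = j$modes %||% c("agree", "no_agree"),
             backend = j$backend %||% "fingerprint", model = model,
             tau = j$tau %||% 0.5, seed = j$seed %||% 1L)
}
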