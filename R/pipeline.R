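# Experiment orchestration: one JSON config drives simulate / preprocess /
# train / evaluate stages with fully seeded randomness.

#' Build an experiment configuration
#'
#' All tunables of the pipeline in one validated list, defaulting to the
#' full-scale analysis constants: the front end of [frontend_config()], model
#' truncations K_beta = 40, K_gamma = 100, K_omega = 100 with all
#' concentrations 1, and the fitting policy (500 restarts, tolerance 0.1,
#' 300 max iterations). Desk-scale work passes overrides (e.g. the test
#' suites use K_beta = 8, K_gamma = 10, 5-10 restarts).
#'
#' @param seed master seed; every stage derives child seeds from it.
#' @param stages character vector out of `"simulate"`, `"preprocess"`,
#'   `"train"`, `"evaluate"`.
#' @param frontend list of [frontend_config()] overrides.
#' @param pcfg list of [pcfg_hyperparams()] overrides.
#' @param hmm list of [hmm_hyperparams()] overrides.
#' @param fit list of [fit_config()] overrides (`n_restarts`, `tol`,
#'   `max_iter`).
#' @param simulate list: `kind`, `n`, `D`, `mean_sep`, `max_len` for
#'   [ground_truth_grammar()] / [sample_corpus()].
#' @param audio_files character vector of WAV paths for the preprocess
#'   stage.
#' @param strings_file JSON Lines feature strings (alternative corpus
#'   source).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L,
                              stages = c("simulate", "train", "evaluate"),
                              frontend = list(), pcfg = list(), hmm = list(),
                              fit = list(), simulate = list(),
                              audio_files = character(0),
                              strings_file = NULL) {
  known <- c("simulate", "preprocess", "train", "evaluate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  sim_defaults <- list(kind = "right_branching", n = 200L, D = 13L,
                       mean_sep = 5, max_len = 20L)
  sim_defaults[names(simulate)] <- simulate
  fit_defaults <- list(n_restarts = 500L, tol = 0.1, max_iter = 300L)
  fit_defaults[names(fit)] <- fit
  cfg <- structure(list(seed = as.integer(seed), stages = stages,
                        frontend = do.call(frontend_config, frontend),
                        pcfg = pcfg, hmm = hmm, fit = fit_defaults,
                        simulate = sim_defaults, audio_files = audio_files,
                        strings_file = strings_file),
                   class = "experiment_config")
  cfg
}

#' Read / write an experiment configuration as JSON
#' @param path JSON file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(experiment_config, raw)
}

#' @rdname read_experiment_config
#' @param config an `experiment_config`.
#' @return invisibly, `path`.
#' @export
write_experiment_config <- function(config, path) {
  out <- unclass(config)
  out$frontend <- NULL # re-derivable; keep the overrides instead
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run an experiment end to end
#'
#' Executes the requested stages -- synthetic corpus generation and/or WAV
#' preprocessing, PCFG and HMM training, posterior evaluation -- writing a
#' versioned copy of the configuration, logs, intermediate artifacts and
#' reports into `out_dir`. Reruns with the same configuration and seed give
#' identical reports.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`corpus`,
#'   `pcfg_fit`, `hmm_fit`, `comparison`) and `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_config(config, file.path(out_dir, "config.json"))
  logf <- file.path(out_dir, "run.log")
  say <- function(...) cat(sprintf(...), "\n", sep = "",
                           file = logf, append = TRUE)
  say("experiment started; seed = %d", config$seed)
  corpus <- NULL; latents <- NULL
  if ("simulate" %in% config$stages) {
    sim <- config$simulate
    grammar <- ground_truth_grammar(sim$kind, D = sim$D,
                                    mean_sep = sim$mean_sep)
    synth <- sample_corpus(grammar, sim$n, seed = child_seed(config$seed, 1),
                           max_len = sim$max_len)
    corpus <- synth$strings
    latents <- synth[c("trees", "paths")]
    strs <- lapply(seq_along(corpus), function(i) structure(
      list(string_id = sprintf("synth_%04d", i),
           region = c(start = NA_real_, end = NA_real_),
           peaks_s = numeric(0), vectors = corpus[[i]]),
      class = "feature_string"))
    write_strings_jsonl(strs, file.path(out_dir, "strings.jsonl"))
    if (!is.null(synth$trees))
      writeLines(vapply(synth$trees, tree_to_bracket, ""),
                 file.path(out_dir, "latent_trees.txt"))
    say("simulated %d strings (kind = %s)", length(corpus), sim$kind)
  }
  if ("preprocess" %in% config$stages) {
    strings <- list()
    for (f in config$audio_files) {
      res <- preprocess_audio(read_wav(f), config$frontend)
      strings <- c(strings, res$strings)
      say("preprocessed %s: %d regions, %d peaks, %d strings", f,
          res$summary$n_regions, res$summary$n_peaks, res$summary$n_strings)
    }
    write_strings_jsonl(strings, file.path(out_dir, "strings.jsonl"))
    corpus <- as_feature_matrices(strings)
  }
  if (is.null(corpus) && !is.null(config$strings_file))
    corpus <- as_feature_matrices(read_strings_jsonl(config$strings_file))
  pcfg_fit <- NULL; hmm_fit <- NULL; comparison <- NULL
  if ("train" %in% config$stages) {
    if (is.null(corpus)) stop("train stage: no corpus (simulate, preprocess ",
                              "or strings_file must provide one)")
    fitc <- fit_config(config$fit$n_restarts, config$fit$tol,
                       config$fit$max_iter, seed = child_seed(config$seed, 2))
    pcfg_fit <- fit_pcfg(corpus, do.call(pcfg_hyperparams, config$pcfg), fitc)
    say("PCFG trained: final ELBO %.3f after %d sweeps",
        pcfg_fit$elbo_trace[length(pcfg_fit$elbo_trace)],
        length(pcfg_fit$elbo_trace))
    fitc$seed <- child_seed(config$seed, 3)
    hmm_fit <- fit_hmm(corpus, do.call(hmm_hyperparams, config$hmm), fitc)
    say("HMM trained: final ELBO %.3f after %d sweeps",
        hmm_fit$elbo_trace[length(hmm_fit$elbo_trace)],
        length(hmm_fit$elbo_trace))
    saveRDS(pcfg_fit, file.path(out_dir, "pcfg_state.rds"))
    saveRDS(hmm_fit, file.path(out_dir, "hmm_state.rds"))
  }
  if ("evaluate" %in% config$stages) {
    if (is.null(pcfg_fit)) {
      pcfg_fit <- readRDS(file.path(out_dir, "pcfg_state.rds"))
      hmm_fit <- readRDS(file.path(out_dir, "hmm_state.rds"))
    }
    parse_rep <- expected_parse_counts(pcfg_fit, corpus)
    comparison <- compare_report(
      parse_rep,
      predictive_report(pcfg_fit, corpus),
      predictive_report(hmm_fit, corpus),
      rule_type_counts(expected_rule_frequencies(pcfg_fit)),
      rule_type_counts(expected_rule_frequencies(hmm_fit)),
      out_dir = file.path(out_dir, "report"))
    say("evaluation written to %s", file.path(out_dir, "report"))
  }
  say("experiment finished")
  invisible(list(corpus = corpus, latents = latents, pcfg_fit = pcfg_fit,
                 hmm_fit = hmm_fit, comparison = comparison,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Dispatches `preprocess`, `simulate`, `train-pcfg`, `train-hmm`,
#' `evaluate` and `run` subcommands; see the shipped executable script
#' `system.file("cli", "songgrammar", package = "songgrammar")`.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the script).
#' @return exit status, invisibly.
#' @export
songgrammar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: songgrammar <command> [options]",
    "commands:",
    "  run        --config cfg.json --out DIR",
    "  simulate   --kind KIND --n N --seed S --out strings.jsonl [--D D]",
    "  preprocess --in file.wav [...] --out strings.jsonl [--config cfg.json]",
    "  train-pcfg --strings strings.jsonl --out state.rds [--restarts R]",
    "             [--seed S] [--tol T] [--max-iter M] [--kbeta K] [--kgamma K]",
    "  train-hmm  --strings strings.jsonl --out state.rds [--restarts R]",
    "             [--seed S] [--tol T] [--max-iter M] [--komega K]",
    "  evaluate   --pcfg state.rds --hmm state.rds --strings s.jsonl --out DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    vals <- character(0)
    while (i < length(args) && !startsWith(args[i + 1], "--")) {
      vals <- c(vals, args[i + 1]); i <- i + 1
    }
    opt[[key]] <- c(opt[[key]], vals)
    i <- i + 1
  }
  num <- function(k, d) if (is.null(opt[[k]])) d else as.numeric(opt[[k]][1])
  chr <- function(k, d = NULL) if (is.null(opt[[k]])) d else opt[[k]][1]
  if (cmd == "run") {
    cfg <- read_experiment_config(chr("config"))
    run_experiment(cfg, chr("out", "songgrammar_run"))
  } else if (cmd == "simulate") {
    g <- ground_truth_grammar(chr("kind", "right_branching"),
                              D = as.integer(num("D", 13)))
    synth <- sample_corpus(g, as.integer(num("n", 200)),
                           seed = as.integer(num("seed", 1)))
    strs <- lapply(seq_along(synth$strings), function(j) structure(
      list(string_id = sprintf("synth_%04d", j),
           region = c(start = NA_real_, end = NA_real_),
           peaks_s = numeric(0), vectors = synth$strings[[j]]),
      class = "feature_string"))
    write_strings_jsonl(strs, chr("out", "synth.jsonl"))
    if (!is.null(synth$trees))
      writeLines(vapply(synth$trees, tree_to_bracket, ""),
                 paste0(chr("out", "synth.jsonl"), ".latents"))
  } else if (cmd == "preprocess") {
    fc <- if (is.null(opt$config)) frontend_config()
          else do.call(frontend_config,
                       jsonlite::fromJSON(chr("config"),
                                          simplifyDataFrame = FALSE))
    strings <- list()
    for (f in opt[["in"]])
      strings <- c(strings, preprocess_audio(read_wav(f), fc)$strings)
    write_strings_jsonl(strings, chr("out", "strings.jsonl"))
  } else if (cmd %in% c("train-pcfg", "train-hmm")) {
    corpus <- read_strings_jsonl(chr("strings"))
    cfg <- fit_config(as.integer(num("restarts", 10)), num("tol", 0.1),
                      as.integer(num("max-iter", 300)),
                      as.integer(num("seed", 1)))
    fit <- if (cmd == "train-pcfg")
      fit_pcfg(corpus, pcfg_hyperparams(K_beta = as.integer(num("kbeta", 40)),
                                        K_gamma = as.integer(num("kgamma",
                                                                 100))),
               cfg)
    else
      fit_hmm(corpus, hmm_hyperparams(K_omega = as.integer(num("komega",
                                                               100))), cfg)
    saveRDS(fit, chr("out", paste0(cmd, "_state.rds")))
  } else if (cmd == "evaluate") {
    corpus <- read_strings_jsonl(chr("strings"))
    pcfg_fit <- readRDS(chr("pcfg")); hmm_fit <- readRDS(chr("hmm"))
    compare_report(expected_parse_counts(pcfg_fit, corpus),
                   predictive_report(pcfg_fit, corpus),
                   predictive_report(hmm_fit, corpus),
                   rule_type_counts(expected_rule_frequencies(pcfg_fit)),
                   rule_type_counts(expected_rule_frequencies(hmm_fit)),
                   out_dir = chr("out", "report"))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
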