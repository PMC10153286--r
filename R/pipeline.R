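#' Pipeline run configuration
#'
#' A serializable description of an end-to-end run: which stages to execute
#' (`corpus`, `train`, `invert`, `evaluate`, `durotaxis`), the master seed,
#' the output directory, and per-stage parameter lists. A persisted config
#' re-executes to identical artifacts up to floating-point reduction order.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param stages Character vector of stages, executed in dependency order.
#' @param corpus List: `count`, `n`, `stiffness_spec`, plus overrides for
#'   [build_corpus()].
#' @param train List of [train_config()] overrides plus optional `gspec` /
#'   `dspec`.
#' @param invert List of [train_config()] overrides for the inverse network.
#' @param evaluate List: `tau` mask threshold.
#' @param durotaxis List of [durotaxis_sweep()] overrides.
#' @param verbose Log per-stage progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("corpus", "train", "evaluate"),
                       corpus = list(count = 40, n = 64L),
                       train = list(), invert = list(),
                       evaluate = list(tau = 0.05), durotaxis = list(),
                       verbose = TRUE) {
  known <- c("corpus", "train", "invert", "evaluate", "durotaxis")
  if (!all(stages %in% known)) {
    stop("run_config: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         corpus = corpus, train = train, invert = invert,
         evaluate = evaluate, durotaxis = durotaxis, verbose = verbose),
    class = "run_config"
  )
}

#' Scaled-down smoke configuration
#'
#' A small end-to-end profile (n = 64 grid, 40 samples, 5 epochs) that
#' exercises every artifact type in a few minutes.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
smoke_profile <- function(out_dir, seed = 1L) {
  run_config(
    out_dir = out_dir, seed = seed,
    stages = c("corpus", "train", "invert", "evaluate", "durotaxis"),
    corpus = list(count = 40, n = 64L,
                  stiffness_spec = list(modes = c("uniform", "linear",
                                                  "circular"),
                                        e_range = c(5000, 40000))),
    train = list(epochs = 5L, batch_size = 8L),
    invert = list(epochs = 5L, batch_size = 8L),
    durotaxis = list(n_reps = 3L, n = 64L)
  )
}

stage_log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message("[dtfm] ", ...)

#' Execute a pipeline run
#'
#' Runs the requested stages in dependency order (corpus, then train /
#' invert, then evaluate / durotaxis), writing each artifact under the
#' output directory together with a `run_manifest.csv` of produced files,
#' their md5 checksums and per-stage timings, and the serialized config
#' (`config.json`). Stages that need an upstream artifact not present in
#' the directory and not scheduled fail with an error naming the stage to
#' run first.
#'
#' @param cfg A [run_config()].
#' @return The output directory, invisibly; the run manifest is attached as
#'   attribute `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  timings <- tibble::tibble(stage = character(), seconds = numeric())
  corpus <- NULL
  gan <- NULL
  inv <- NULL

  jsonlite::write_json(
    rapply(unclass(cfg), function(x) x, how = "replace"),
    file.path(cfg$out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE
  )
  artifacts <- c(artifacts, file.path(cfg$out_dir, "config.json"))

  need_corpus <- function() {
    if (!is.null(corpus)) return(corpus)
    cdir <- file.path(cfg$out_dir, "corpus")
    if (!file.exists(file.path(cdir, "samples.rds"))) {
      stop("run_pipeline: no corpus artifact found; run the 'corpus' stage first")
    }
    corpus <<- read_corpus(cdir)
    corpus
  }

  for (stage in intersect(c("corpus", "train", "invert", "evaluate",
                            "durotaxis"), cfg$stages)) {
    t0 <- proc.time()[3]
    stage_log(cfg, "stage: ", stage)
    switch(stage,
      corpus = {
        args <- utils::modifyList(
          list(count = 40, seed = cfg$seed, n = 64L), cfg$corpus)
        corpus <- do.call(build_corpus, args)
        write_corpus(corpus, file.path(cfg$out_dir, "corpus"))
        artifacts <- c(artifacts,
                       file.path(cfg$out_dir, "corpus",
                                 c("samples.rds", "manifest.csv", "meta.json")))
      },
      train = {
        co <- need_corpus()
        tc_args <- cfg$train
        gspec <- tc_args$gspec %||% generator_spec()
        dspec <- tc_args$dspec %||% discriminator_spec()
        tc_args$gspec <- NULL; tc_args$dspec <- NULL
        tc <- do.call(train_config,
                      utils::modifyList(list(epochs = 5L, seed = cfg$seed),
                                        tc_args))
        gan <- train_gan(co, gspec = gspec, dspec = dspec, config = tc,
                         verbose = cfg$verbose)
        save_checkpoint(gan, file.path(cfg$out_dir, "gan.rds"))
        readr::write_csv(gan$history, file.path(cfg$out_dir, "gan_history.csv"))
        artifacts <- c(artifacts, file.path(cfg$out_dir,
                                            c("gan.rds", "gan_history.csv")))
      },
      invert = {
        co <- need_corpus()
        tc <- do.call(train_config,
                      utils::modifyList(list(epochs = 5L, seed = cfg$seed),
                                        cfg$invert))
        inv <- train_inverse(co, config = tc, verbose = cfg$verbose)
        save_checkpoint(inv, file.path(cfg$out_dir, "inverse.rds"))
        readr::write_csv(inv$history,
                         file.path(cfg$out_dir, "inverse_history.csv"))
        artifacts <- c(artifacts,
                       file.path(cfg$out_dir,
                                 c("inverse.rds", "inverse_history.csv")))
      },
      evaluate = {
        co <- need_corpus()
        if (is.null(gan)) {
          gp <- file.path(cfg$out_dir, "gan.rds")
          if (!file.exists(gp)) {
            stop("run_pipeline: no trained model found; run the 'train' stage first")
          }
          gan <- load_checkpoint(gp)
        }
        idx <- gan$split$test
        if (length(idx) == 0) idx <- gan$split$validation
        preds <- predict_corpus(gan, co, idx)
        truths <- lapply(idx, function(i) co$samples[[i]]$traction)
        rep_ <- epsilon_t(preds, truths, tau = cfg$evaluate$tau %||% 0.05)
        readr::write_csv(tidy(rep_), file.path(cfg$out_dir,
                                               "epsilon_per_sample.csv"))
        jsonlite::write_json(
          list(epsilon_t = rep_$epsilon_t, n = rep_$n_samples,
               tau = rep_$mask_policy$tau),
          file.path(cfg$out_dir, "evaluation.json"), auto_unbox = TRUE,
          digits = NA)
        artifacts <- c(artifacts,
                       file.path(cfg$out_dir, c("epsilon_per_sample.csv",
                                                "evaluation.json")))
      },
      durotaxis = {
        args <- utils::modifyList(list(seed = cfg$seed), cfg$durotaxis)
        sw <- do.call(durotaxis_sweep, args)
        readr::write_csv(sw, file.path(cfg$out_dir, "durotaxis_sweep.csv"))
        artifacts <- c(artifacts, file.path(cfg$out_dir,
                                            "durotaxis_sweep.csv"))
      }
    )
    timings <- dplyr::bind_rows(
      timings, tibble::tibble(stage = stage, seconds = proc.time()[3] - t0))
    stage_log(cfg, "stage ", stage, " done in ",
              sprintf("%.1f s", timings$seconds[nrow(timings)]))
  }

  manifest <- tibble::tibble(
    file = artifacts,
    md5 = as.character(tools::md5sum(artifacts))
  )
  readr::write_csv(manifest, file.path(cfg$out_dir, "run_manifest.csv"))
  readr::write_csv(timings, file.path(cfg$out_dir, "timings.csv"))
  out <- cfg$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
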