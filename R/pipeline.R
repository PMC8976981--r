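#' Pipeline run configuration
#'
#' Nested configuration for the end-to-end study: phantom generation, network
#' training, prediction, heat-map explanation, evaluation and randomization
#' sanity checks. All randomness flows from the single global `seed` through
#' named per-stage substreams, so a rerun with the same configuration
#' reproduces every stochastic stage bit for bit. Unknown keys are rejected.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for artifacts (`NULL` = keep in memory).
#' @param n_train,n_test phantom counts for the training and held-out sets.
#' @param phantom list of [phantom_config] overrides (e.g.
#'   `list(grid_shape = c(32, 32, 16))`).
#' @param network list of [unet_spec] overrides.
#' @param train list of [train_config] overrides.
#' @param patch list of [patch_spec] overrides.
#' @param gradcam list of [gradcam_config] overrides.
#' @param deltas localization thresholds.
#' @param stages character vector of enabled stages, a subset of
#'   `c("train", "evaluate", "explain", "sanity")`; phantom generation always
#'   runs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, n_train = 8L, n_test = 4L,
                       phantom = list(), network = list(), train = list(),
                       patch = list(), gradcam = list(),
                       deltas = c(0, 0.25, 0.5),
                       stages = c("train", "evaluate", "explain", "sanity")) {
  check_keys <- function(given, fn, what) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    assert_that(length(bad) == 0, "unknown %s key(s): %s", what,
                paste(bad, collapse = ", "))
    given
  }
  assert_that(all(stages %in% c("train", "evaluate", "explain", "sanity")),
              "unknown stage name")
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    phantom = check_keys(phantom, phantom_config, "phantom"),
    network = check_keys(network, unet_spec, "network"),
    train = check_keys(train, train_config, "train"),
    patch = check_keys(patch, patch_spec, "patch"),
    gradcam = check_keys(gradcam, gradcam_config, "gradcam"),
    deltas = deltas, stages = stages), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config]
#'   arguments.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

make_cases <- function(config, n, offset) {
  lapply(seq_len(n), function(i) {
    args <- config$phantom
    args$seed <- derive_seed(config$seed, sprintf("phantom-%d", offset + i))
    generate_phantom(do.call(phantom_config, args))
  })
}

#' Run the end-to-end phantom study
#'
#' Generates training and held-out phantom sets, trains the U-Net, predicts
#' and evaluates segmentations on the held-out set, computes Grad-CAM heat
#' maps and localization IOUs, and runs the model randomization sanity check
#' — each stage only if enabled in the configuration. Artifacts are written
#' under `out_dir` when given, stamped with the configuration hash and seed.
#'
#' @param config a [run_config].
#' @return A list with (depending on enabled stages) `train_cases`,
#'   `test_cases`, `net`, `report` (per-case evaluation data.frame),
#'   `aggregate`, `sanity` (randomization report), and `provenance`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  res <- list(provenance = list(package_version =
                                  as.character(utils::packageVersion("segxai")),
                                seed = config$seed,
                                config_hash = config_hash(config)))
  stage <- function(s) s %in% config$stages
  fail <- function(s, e) {
    stop_sx("pipeline stage '%s' failed: %s", s, conditionMessage(e))
  }
  res$train_cases <- tryCatch(make_cases(config, config$n_train, 0L),
                              error = function(e) fail("phantom", e))
  res$test_cases <- tryCatch(make_cases(config, config$n_test, config$n_train),
                             error = function(e) fail("phantom", e))
  gcfg <- do.call(gradcam_config, config$gradcam)
  if (stage("train")) {
    spec_args <- config$network
    tcfg_args <- config$train
    tcfg_args$seed <- tcfg_args$seed %||% derive_seed(config$seed, "train-cfg")
    pargs <- config$patch
    res$net <- tryCatch({
      net <- unet_build(do.call(unet_spec, spec_args),
                        seed = derive_seed(config$seed, "init"))
      unet_train(net, res$train_cases, do.call(train_config, tcfg_args),
                 do.call(patch_spec, pargs))
    }, error = function(e) fail("train", e))
  }
  if (stage("evaluate") || stage("explain")) {
    assert_that(!is.null(res$net),
                "evaluate/explain stages need the train stage (no trained network)")
    rows <- list()
    heats <- list()
    for (i in seq_along(res$test_cases)) {
      cs <- res$test_cases[[i]]
      pred <- tryCatch(predict(res$net, cs$image),
                       error = function(e) fail("predict", e))
      hm <- NULL
      if (stage("explain")) {
        hm <- tryCatch({
          g <- tryCatch(compute_gradcam(res$net, cs$image, gcfg,
                                        gt_labels = cs$labels),
                        error = function(e) {
                          cfg2 <- gcfg
                          cfg2$score_mask_mode <- "whole-volume"
                          compute_gradcam(res$net, cs$image, cfg2)
                        })
          list(tumor = g$normalized_heat_map)
        }, error = function(e) fail(sprintf("explain (case %d)", i), e))
        heats[[i]] <- hm$tumor
      }
      rows[[i]] <- cbind(data.frame(case = i),
                         evaluate_case(pred$class_map, cs$labels,
                                       heatmaps = hm, deltas = config$deltas))
    }
    res$report <- do.call(rbind, rows)
    res$aggregate <- aggregate_report(res$report[-1])
    res$heatmaps <- heats
  }
  if (stage("sanity")) {
    assert_that(!is.null(res$net), "sanity stage needs the train stage")
    res$sanity <- tryCatch(
      model_randomization_test(res$net, res$test_cases, gcfg,
                               seed = derive_seed(config$seed, "sanity")),
      error = function(e) fail("sanity", e))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(res$test_cases)) {
      write_phantom_case(res$test_cases[[i]], config$out_dir,
                         prefix = sprintf("test%02d", i))
    }
    if (!is.null(res$report)) {
      utils::write.csv(res$report, file.path(config$out_dir, "report.csv"),
                       row.names = FALSE)
      utils::write.csv(res$aggregate,
                       file.path(config$out_dir, "aggregate.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$sanity)) {
      utils::write.csv(as.data.frame(res$sanity),
                       file.path(config$out_dir, "sanity.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(res$provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  res
}
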