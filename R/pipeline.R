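# End-to-end orchestration: simulate -> prep -> train -> screen ->
# likeness -> validate, with a machine-readable run manifest and funnel
# counts logged at every filtering step.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{run_pipeline}}.
#' Data-shape defaults mirror the emulated study conditions (953
#' training compounds x 881 bits, a 2563-compound screening library and
#' a 20-active / 500-decoy / 1-control validation set). The demo model
#' is a compact two-layer network so a full synthetic run completes in
#' seconds; substitute \code{qsar_config()} for the full tuned
#' architecture.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return named list of pipeline settings.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    train = list(n = 953L, d = 881L, bit_density = 0.2,
                 k_informative = 20L, weight_scale = 1, noise_sd = 0.3),
    library = list(n = 2563L, bit_density = 0.2),
    validation = list(control_density = 0.1, n_active = 20L,
                      n_decoy = 500L, flip_rate = 0.05, nbits = 2048L,
                      fraction = 0.01),
    variance_threshold = 0.16,
    screening_mode = "value-range",
    model = qsar_config(layers = list(layer_spec(64, "relu", "he_normal", 0),
                                      layer_spec(32, "relu", "he_normal", 0)),
                        l1 = 0, l2 = 1e-4, learning_rate = 0.003,
                        max_epochs = 40L, batch_size = 32L, seed = seed)
  )
}

log_step <- function(log, stage, message, count = NA_integer_,
                     verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, message))
  rbind(log, data.frame(stage = stage, message = message, count = count,
                        stringsAsFactors = FALSE))
}

#' Run the virtual-screening pipeline end to end
#'
#' Executes the stages in order on synthetic inputs: \emph{simulate}
#' (training set, screening library, active/decoy/control validation
#' set), \emph{prep} (variance filtering of train and library descriptor
#' matrices, schema merging, projection), \emph{train} (fit the pIC50
#' regressor on an 80:20 split), \emph{screen} (predict the library and
#' select the upper quartile), \emph{likeness} (drug-likeness table of
#' the selected compounds, which carry SMILES from the built-in molecule
#' panel), and \emph{validate} (similarity scoring against the control,
#' ROC/AUC, enrichment factor, rank-sum test). Every filtering step's
#' count is logged, artifacts are written as CSV, and a JSON manifest
#' records the configuration, seeds and counts.
#'
#' @param out_dir output directory (created if missing).
#' @param config configuration list from \code{\link{pipeline_config}}.
#' @param stages character vector of stages to run (prefix of the full
#'   ordering; later stages require the earlier ones).
#' @param verbose print stage progress.
#' @return invisible list with the main in-memory artifacts
#'   (\code{model}, \code{screen}, \code{likeness}, \code{validation},
#'   \code{log}, \code{manifest_path}).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         stages = c("simulate", "prep", "train", "screen",
                                    "likeness", "validate"),
                         verbose = TRUE) {
  all_stages <- c("simulate", "prep", "train", "screen", "likeness",
                  "validate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(0), message = character(0),
                    count = integer(0))
  seed <- config$seed
  res <- list()

  # --- simulate -------------------------------------------------------
  if (!"simulate" %in% stages)
    stop("pipeline stage 'simulate' is required as the data source")
  tr <- config$train
  sim <- sim_fingerprint_activity(n = tr$n, d = tr$d,
                                  bit_density = tr$bit_density,
                                  k_informative = tr$k_informative,
                                  weight_scale = tr$weight_scale,
                                  noise_sd = tr$noise_sd, seed = seed)
  log <- log_step(log, "simulate", "training compounds generated", tr$n,
                  verbose)
  lib_cfg <- config$library
  old <- .Random.seed_save(); set.seed(seed + 1L)
  lib_x <- matrix(stats::rbinom(lib_cfg$n * tr$d, 1L, lib_cfg$bit_density),
                  lib_cfg$n, tr$d,
                  dimnames = list(sprintf("LIB%04d", seq_len(lib_cfg$n)),
                                  colnames(sim$x)))
  .Random.seed_restore(old)
  log <- log_step(log, "simulate", "library compounds generated",
                  lib_cfg$n, verbose)
  vc <- config$validation
  adl <- sim_active_decoy_library(control_density = vc$control_density,
                                  n_active = vc$n_active,
                                  n_decoy = vc$n_decoy,
                                  flip_rate = vc$flip_rate,
                                  nbits = vc$nbits, seed = seed + 2L)
  log <- log_step(log, "simulate", "validation set generated",
                  vc$n_active + vc$n_decoy + 1L, verbose)

  # --- prep -----------------------------------------------------------
  x_train <- NULL; x_lib <- NULL
  if ("prep" %in% stages) {
    s_train <- variance_filter(sim$x, config$variance_threshold,
                               "train-retained")
    s_lib <- variance_filter(lib_x, config$variance_threshold,
                             "library-retained")
    merged <- merge_schemas(s_train, s_lib)
    x_train <- project_descriptors(sim$x, merged)
    x_lib <- project_descriptors(lib_x, merged)
    log <- log_step(log, "prep", sprintf(
      "descriptors retained: train %d, library %d, merged %d",
      length(s_train), length(s_lib), length(merged)), length(merged),
      verbose)
    utils::write.csv(data.frame(descriptor = merged$names),
                     file.path(out_dir, "merged_schema.csv"),
                     row.names = FALSE)
  }

  # --- train ----------------------------------------------------------
  if ("train" %in% stages) {
    if (is.null(x_train)) stop("stage 'train' requires stage 'prep'")
    cfg <- config$model
    cfg$seed <- seed
    sp <- split_train_test(nrow(x_train), cfg$split_fraction, seed)
    model <- qsar_net(x_train[sp$train, , drop = FALSE], sim$y[sp$train],
                      cfg)
    test_metrics <- regression_metrics(
      sim$y[sp$test], predict(model, x_train[sp$test, , drop = FALSE]))
    log <- log_step(log, "train", sprintf(
      "model trained (%d/%d split); held-out MSE %.4f",
      length(sp$train), length(sp$test), test_metrics$mse),
      length(sp$train), verbose)
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    res$model <- model
    res$test_metrics <- test_metrics
  }

  # --- screen ---------------------------------------------------------
  if (!"screen" %in% stages) return(finish(res, log, out_dir, config))
  if (is.null(res$model)) stop("stage 'screen' requires a trained model")
  preds <- predict(res$model, x_lib)
  scr <- select_upper_quartile(preds, ids = rownames(x_lib),
                               mode = config$screening_mode)
  n_sel <- sum(scr$selected)
  log <- log_step(log, "screen", sprintf(
    "library screened: %d of %d in upper quartile (cut %.3f)",
    n_sel, nrow(scr), attr(scr, "cut")), n_sel, verbose)
  utils::write.csv(scr, file.path(out_dir, "screen.csv"),
                   row.names = FALSE)
  res$screen <- scr

  if (!"likeness" %in% stages) return(finish(res, log, out_dir, config))

  # --- likeness -------------------------------------------------------
  panel <- molecule_panel()
  sel_ids <- scr$id[scr$selected]
  sel_smiles <- panel$smiles[(match(sel_ids, rownames(x_lib)) - 1L) %%
                               nrow(panel) + 1L]
  lk <- druglikeness_table(sel_smiles, sel_ids)
  n_pass <- sum(lk$Lipinski == "Yes", na.rm = TRUE)
  log <- log_step(log, "likeness", sprintf(
    "drug-likeness: %d of %d selected compounds pass Lipinski",
    n_pass, nrow(lk)), n_pass, verbose)
  utils::write.csv(lk, file.path(out_dir, "likeness.csv"),
                   row.names = FALSE)
  res$likeness <- lk

  if (!"validate" %in% stages) return(finish(res, log, out_dir, config))

  # --- validate -------------------------------------------------------
  sc <- similarity_to_control(adl$fps, adl$control, adl$labels)
  # the control itself is scored 1 and counted as an active
  sc <- rbind(data.frame(id = "CONTROL", label = "active", score = 1),
              sc)
  roc <- roc_auc(sc$score, sc$label)
  ef <- enrichment_factor(sc$score, sc$label, vc$fraction, sc$id)
  rs <- rank_sum_test(sc$score[sc$label == "active"],
                      sc$score[sc$label == "decoy"])
  log <- log_step(log, "validate", sprintf(
    "AUC %.3f, EF@%g%% %.2f, rank-sum p %.2e", roc$auc,
    100 * vc$fraction, ef$ef, rs$p_value), NA_integer_, verbose)
  utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                   file.path(out_dir, "roc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fraction = ef$fraction,
                              slice_size = ef$slice_size,
                              actives_in_slice = ef$actives_in_slice,
                              total_actives = ef$total_actives,
                              total = ef$total, ef = ef$ef),
                   file.path(out_dir, "enrichment.csv"),
                   row.names = FALSE)
  sim50 <- pairwise_tanimoto(rbind(CONTROL = adl$control,
                                   adl$fps[seq_len(min(49L, nrow(adl$fps))), ,
                                           drop = FALSE]))
  utils::write.csv(sim50, file.path(out_dir, "similarity_matrix.csv"))
  res$validation <- list(roc = roc, ef = ef, rank_sum = rs)

  finish(res, log, out_dir, config)
}

finish <- function(res, log, out_dir, config) {
  utils::write.csv(log, file.path(out_dir, "funnel_log.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "ligscreen",
    package_version = as.character(utils::packageVersion("ligscreen")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "model")],
    model_config = unclass_config(config$model),
    funnel = log)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  res$log <- log
  res$manifest_path <- path
  invisible(res)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$layers <- lapply(out$layers, unclass)
  out
}
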