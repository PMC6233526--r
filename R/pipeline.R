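
# -- Pipeline orchestration ---------------------------------------------------
#
# Thin single-process orchestration of the preparation, precompute, tuning,
# training, validation and prediction stages, with one declarative YAML
# config and an append-only JSON-lines run manifest (stage, parameters,
# seeds, input/output digests, timestamps).

.config_error <- function(msg) {
  structure(class = c("cpligand_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}
.data_error <- function(msg) {
  structure(class = c("cpligand_data_error", "error", "condition"),
            list(message = msg, call = NULL))
}

.default_config <- list(
  seed = 1L,
  heights = c(1L, 2L, 3L),
  min_actives = 100L, min_nonactives = 100L,
  augmentation_threshold = 10000L, nonactive_ratio = 2,
  canonical_smiles = TRUE,
  calibration_fraction = 0.2, n_icp = 10L,
  costs = c(1, 10, 100), k_folds = 10L, n_replicates = 3L,
  aggregation = "mean",
  confidences = c(0.8, 0.9),
  synth = list(n_targets = 3L, n_active = 1000L, n_nonactive = 1000L,
               label_noise = 0.1, duplicate_rate = 0, conflict_rate = 0))

#' Load a pipeline configuration
#'
#' Reads a YAML file of key-value settings; anything not given falls back
#' to the package defaults.  Per-target cost overrides may be given under
#' `target_costs` (a map gene symbol -> cost).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return named list of settings.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config
  if (!is.null(path)) {
    if (!file.exists(path)) stop(.config_error(paste0("config file not found: ", path)))
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop(.config_error("config file must be a YAML mapping"))
    cfg <- modifyList(cfg, user)
  }
  cfg <- modifyList(cfg, overrides)
  if (!is.numeric(cfg$seed)) stop(.config_error("seed must be an integer"))
  cfg
}

.manifest_path <- function(dir) file.path(dir, "manifest.jsonl")

.manifest_append <- function(dir, stage, params, files = character()) {
  files <- files[file.exists(files)]
  entry <- list(stage = stage,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                version = .cpligand_version(),
                params = params,
                outputs = if (length(files)) {
                  data.frame(path = files,
                             md5 = unname(tools::md5sum(files)))
                } else NULL)
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null")
  cat(line, "\n", sep = "", file = .manifest_path(dir), append = TRUE)
  invisible(entry)
}

#' Read a run manifest
#'
#' @param dir run directory containing `manifest.jsonl`.
#' @return list of manifest entries.
#' @export
read_manifest <- function(dir) {
  p <- .manifest_path(dir)
  if (!file.exists(p)) return(list())
  lapply(readLines(p), jsonlite::fromJSON)
}

#' Pipeline stages
#'
#' Each `run_*` function executes one stage into `out_dir`, appends to the
#' run manifest and returns its primary outputs.  `run_synth` writes a
#' synthetic activity table; `run_prep` cleans and augments an activity
#' table into per-target datasets; `run_precompute` writes sparse signature
#' datasets and the dictionary; `run_tune` selects the SVM cost per target;
#' `run_train` trains and archives one ACP per target; `run_validate`
#' cross-validates each trained configuration and writes calibration and
#' label-set-confusion CSVs; `run_predict` writes a profile for a query
#' molecule.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
run_synth <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- synthetic_spec(n_targets = cfg$synth$n_targets,
                       n_active = cfg$synth$n_active,
                       n_nonactive = cfg$synth$n_nonactive,
                       label_noise = cfg$synth$label_noise,
                       duplicate_rate = cfg$synth$duplicate_rate,
                       conflict_rate = cfg$synth$conflict_rate,
                       seed = cfg$seed)
  tab <- generate_activity_table(sp)
  path <- file.path(out_dir, "activity_table.tsv")
  write_synthetic_table(tab, path)
  .manifest_append(out_dir, "synth", cfg$synth,
                   c(path, paste0(path, ".truth.json")))
  path
}

#' @rdname pipeline_stages
#' @param input path to the activity table TSV (defaults to the synth
#'   stage's output in `out_dir`).
#' @export
run_prep <- function(cfg, out_dir, input = file.path(out_dir, "activity_table.tsv")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(input)) stop(.data_error(paste0("input table not found: ", input)))
  pc <- prep_config(min_actives = cfg$min_actives,
                    min_nonactives = cfg$min_nonactives,
                    augmentation_threshold = cfg$augmentation_threshold,
                    nonactive_ratio = cfg$nonactive_ratio,
                    canonical = cfg$canonical_smiles, seed = cfg$seed)
  records <- load_activity_records(input)
  n0 <- nrow(records)
  records <- remove_conflicts(records, canonical = pc$canonical)
  n1 <- nrow(records)
  records <- deduplicate(records, canonical = pc$canonical)
  n2 <- nrow(records)
  sel <- select_targets(records, pc)
  if (!length(sel$datasets)) {
    utils::write.table(sel$excluded, file.path(out_dir, "excluded_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stop(.data_error("no target passes the inclusion minima"))
  }
  ds_dir <- file.path(out_dir, "datasets")
  dir.create(ds_dir, showWarnings = FALSE)
  files <- character()
  for (tg in names(sel$datasets)) {
    ds <- sel$datasets[[tg]]
    n_n <- sum(ds$records$activity == "N")
    if (n_n < pc$augmentation_threshold) {
      ds <- add_assumed_nonactives(ds, records, pc)
      sel$datasets[[tg]] <- ds
    }
    f <- file.path(ds_dir, paste0(tg, ".tsv"))
    utils::write.table(ds$records, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f_excl <- file.path(out_dir, "excluded_targets.tsv")
  utils::write.table(sel$excluded, f_excl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- list(seed = cfg$seed, thresholds = pc[c("min_actives",
               "min_nonactives", "augmentation_threshold", "nonactive_ratio")],
               rows = list(loaded = n0, after_conflict_removal = n1,
                           after_deduplication = n2))
  f_prov <- file.path(out_dir, "prep_provenance.json")
  jsonlite::write_json(prov, f_prov, auto_unbox = TRUE, digits = NA)
  .manifest_append(out_dir, "prep", prov, c(files, f_excl, f_prov))
  invisible(sel$datasets)
}

.read_target_datasets <- function(out_dir) {
  ds_dir <- file.path(out_dir, "datasets")
  files <- list.files(ds_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop(.data_error(paste0("no prepared datasets under ", ds_dir)))
  out <- list()
  for (f in files) {
    tg <- sub("\\.tsv$", "", basename(f))
    # comment.char disabled: SMILES legitimately contain '#'
    r <- utils::read.table(f, sep = "\t", header = TRUE, quote = "",
                           comment.char = "",
                           colClasses = c("character", "character", "logical",
                                          "character"))
    out[[tg]] <- target_dataset(tg, r)
  }
  out
}

#' @rdname pipeline_stages
#' @export
run_precompute <- function(cfg, out_dir) {
  datasets <- .read_target_datasets(out_dir)
  sc <- signature_config(cfg$heights)
  sp_dir <- file.path(out_dir, "sparse")
  dir.create(sp_dir, showWarnings = FALSE)
  files <- character()
  for (tg in names(datasets)) {
    ds <- datasets[[tg]]
    vecs <- featurize_all(ds$records$smiles, sc)
    dict <- build_dictionary(vecs)
    f_data <- file.path(sp_dir, paste0(tg, ".libsvm"))
    f_dict <- file.path(sp_dir, paste0(tg, ".dictionary.tsv"))
    write_sparse_dataset(vecs, ds$records$activity, dict, f_data)
    write_dictionary(dict, f_dict)
    files <- c(files, f_data, f_dict)
  }
  .manifest_append(out_dir, "precompute",
                   list(heights = sc$heights, seed = cfg$seed), files)
  invisible(files)
}

#' @rdname pipeline_stages
#' @export
run_tune <- function(cfg, out_dir) {
  datasets <- .read_target_datasets(out_dir)
  sw <- sweep_config(costs = cfg$costs, k_folds = cfg$k_folds,
                     n_icp = cfg$n_icp, n_replicates = cfg$n_replicates,
                     seed = cfg$seed)
  sc <- signature_config(cfg$heights)
  rows <- list(); full <- list()
  for (tg in names(datasets)) {
    sweep_res <- cost_sweep(datasets[[tg]], sw, heights = sc)
    rows[[tg]] <- data.frame(target = tg, best_cost = sweep_res$best_cost)
    full[[tg]] <- cbind(target = tg, sweep_res$report)
  }
  best <- do.call(rbind, rows)
  f_best <- file.path(out_dir, "best_costs.csv")
  f_full <- file.path(out_dir, "cost_sweep.csv")
  utils::write.csv(best, f_best, row.names = FALSE)
  utils::write.csv(do.call(rbind, full), f_full, row.names = FALSE)
  .manifest_append(out_dir, "tune",
                   list(costs = sw$costs, k_folds = sw$k_folds,
                        n_icp = sw$n_icp, seed = cfg$seed),
                   c(f_best, f_full))
  invisible(best)
}

.target_cost <- function(cfg, out_dir, target) {
  if (!is.null(cfg$target_costs[[target]])) return(cfg$target_costs[[target]])
  f <- file.path(out_dir, "best_costs.csv")
  if (file.exists(f)) {
    best <- utils::read.csv(f)
    hit <- best$best_cost[best$target == target]
    if (length(hit)) return(hit[1])
  }
  cfg$costs[1]
}

#' @rdname pipeline_stages
#' @export
run_train <- function(cfg, out_dir) {
  datasets <- .read_target_datasets(out_dir)
  sc <- signature_config(cfg$heights)
  mdl_dir <- file.path(out_dir, "models")
  dir.create(mdl_dir, showWarnings = FALSE)
  files <- character(); costs <- list()
  for (tg in names(datasets)) {
    cost <- .target_cost(cfg, out_dir, tg)
    costs[[tg]] <- cost
    model <- acp_train(datasets[[tg]],
                       train = train_config(cost = cost, heights = sc,
                                            aggregation = cfg$aggregation),
                       split = split_config(cfg$calibration_fraction,
                                            cfg$n_icp,
                                            derive_seed(cfg$seed, 31L,
                                                        match(tg, names(datasets)))))
    f <- file.path(mdl_dir, paste0(tg, ".acp.json"))
    save_model(model, f)
    files <- c(files, f)
  }
  .manifest_append(out_dir, "train",
                   list(costs = costs, n_icp = cfg$n_icp,
                        calibration_fraction = cfg$calibration_fraction,
                        seed = cfg$seed), files)
  invisible(files)
}

#' @rdname pipeline_stages
#' @export
run_validate <- function(cfg, out_dir) {
  datasets <- .read_target_datasets(out_dir)
  sw <- sweep_config(costs = cfg$costs, k_folds = cfg$k_folds,
                     n_icp = cfg$n_icp, seed = cfg$seed)
  sc <- signature_config(cfg$heights)
  val_dir <- file.path(out_dir, "validation")
  files <- character()
  for (tg in names(datasets)) {
    preds <- evaluate_cv(datasets[[tg]], .target_cost(cfg, out_dir, tg),
                         sw, seed = derive_seed(cfg$seed, 37L,
                                                match(tg, names(datasets))),
                         heights = sc)
    rep <- efficiency_report(preds, significances = 1 - cfg$confidences)
    files <- c(files, write_efficiency_csvs(rep, tg, val_dir))
  }
  .manifest_append(out_dir, "validate",
                   list(confidences = cfg$confidences, k_folds = sw$k_folds,
                        n_icp = sw$n_icp, seed = cfg$seed), files)
  invisible(files)
}

#' @rdname pipeline_stages
#' @param smiles query SMILES string.
#' @param confidence confidence level for the reported prediction sets.
#' @export
run_predict <- function(cfg, out_dir, smiles, confidence = 0.8) {
  mdl_dir <- file.path(out_dir, "models")
  files <- list.files(mdl_dir, pattern = "\\.acp\\.json$", full.names = TRUE)
  if (!length(files)) stop(.data_error(paste0("no model archives under ", mdl_dir)))
  models <- lapply(files, load_model)
  names(models) <- vapply(models, `[[`, character(1), "target")
  prof <- predict_profile(models, smiles, confidence)
  f_json <- file.path(out_dir, "profile.json")
  f_csv <- file.path(out_dir, "profile.csv")
  write_profile(prof, f_json, f_csv)
  .manifest_append(out_dir, "predict",
                   list(smiles = smiles, confidence = confidence),
                   c(f_json, f_csv))
  prof
}
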