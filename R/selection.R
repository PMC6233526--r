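
# -- Cross-validated cost tuning and replicates -------------------------------

#' Sweep settings
#'
#' @param costs candidate SVM cost values (default 1, 10, 100).
#' @param k_folds cross-validation folds (default 10).
#' @param n_icp ICPs per aggregated predictor (default 10).
#' @param n_replicates replicate runs for [replicate_runs()] (default 3).
#' @param seed master seed; folds, splits and replicates use derived streams
#'   so any unit is independently reproducible.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(costs = c(1, 10, 100), k_folds = 10L, n_icp = 10L,
                         n_replicates = 3L, seed = 1L) {
  stopifnot(length(costs) >= 1, all(costs > 0), k_folds >= 2, n_icp >= 1,
            n_replicates >= 1)
  structure(list(costs = sort(costs), k_folds = as.integer(k_folds),
                 n_icp = as.integer(n_icp),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Stratified k-fold indices over the non-assumed records
#'
#' Folds partition the non-assumed records of a target dataset, stratified
#' by class with per-class fold sizes differing by at most one.  Assumed
#' non-actives belong to no fold: in cross-validation they augment every
#' fold's proper training set and are never tested or used for calibration.
#'
#' @param ds a [target_dataset()].
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer vectors of row indices into `ds$records`.
#' @export
kfold_indices <- function(ds, k, seed = 1L) {
  r <- ds$records
  folds <- rep(list(integer()), k)
  for (cls in c("A", "N")) {
    members <- which(r$activity == cls & !r$assumed)
    if (length(members) < k) {
      stop(sprintf("target %s: class %s has %d non-assumed records, fewer than %d folds",
                   ds$target, cls, length(members), k))
    }
    set.seed(derive_seed(seed, 11L, match(cls, c("A", "N"))))
    shuffled <- sample(members)
    assign_to <- rep(seq_len(k), length.out = length(shuffled))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], shuffled[assign_to == f])
    }
  }
  lapply(folds, sort)
}

#' Pooled cross-validated conformal predictions at one cost
#'
#' For each fold, an ACP is trained on the remaining folds (plus all
#' assumed non-actives) and applied to the held-out fold; predictions are
#' pooled over folds.
#'
#' @param ds a [target_dataset()].
#' @param cost SVM cost.
#' @param sweep a [sweep_config()] (`k_folds`, `n_icp` used).
#' @param seed integer seed for folds and splits.
#' @param sig_vectors optional precomputed `sig_vector` list for
#'   `ds$records`.
#' @param heights a [signature_config()].
#' @return data frame with columns `truth`, `p_A`, `p_N` (one row per
#'   non-assumed record).
#' @export
evaluate_cv <- function(ds, cost, sweep = sweep_config(), seed = sweep$seed,
                        sig_vectors = NULL, heights = signature_config()) {
  r <- ds$records
  if (is.null(sig_vectors)) sig_vectors <- featurize_all(r$smiles, heights)
  folds <- kfold_indices(ds, sweep$k_folds, seed)
  assumed_rows <- which(r$assumed)
  out <- vector("list", sweep$k_folds)
  for (f in seq_along(folds)) {
    test_rows <- folds[[f]]
    train_rows <- c(setdiff(unlist(folds), test_rows), assumed_rows)
    sub <- target_dataset(ds$target, r[train_rows, , drop = FALSE])
    model <- acp_train(sub,
                       train = train_config(cost = cost, heights = heights),
                       split = split_config(n_icp = sweep$n_icp,
                                            seed = derive_seed(seed, 13L, f)),
                       sig_vectors = sig_vectors[train_rows])
    pred <- acp_predict(model, sig_vectors[test_rows])
    out[[f]] <- cbind(data.frame(truth = r$activity[test_rows]), pred)
  }
  do.call(rbind, out)
}

#' Cross-validated cost sweep
#'
#' Evaluates each candidate cost by pooled 10-fold cross-validated observed
#' fuzziness and selects the cost with the lowest OF; ties break toward the
#' smaller cost.  CAOF and the M criterion are reported for information
#' only and never used for selection.
#'
#' @param ds a [target_dataset()].
#' @param sweep a [sweep_config()].
#' @param heights a [signature_config()].
#' @return list with `best_cost` and `report`, a data frame with one row
#'   per cost (cost, OF, CAOF, MC at significance 0.2, chosen flag).
#' @export
cost_sweep <- function(ds, sweep = sweep_config(), heights = signature_config()) {
  sig_vectors <- featurize_all(ds$records$smiles, heights)
  rows <- lapply(sweep$costs, function(cost) {
    preds <- evaluate_cv(ds, cost, sweep, seed = sweep$seed,
                         sig_vectors = sig_vectors, heights = heights)
    data.frame(cost = cost,
               OF = observed_fuzziness(preds),
               CAOF = class_averaged_of(preds),
               MC_sig_0.2 = m_criterion(preds, 0.2))
  })
  report <- do.call(rbind, rows)
  best <- report$cost[which.min(report$OF)]   # costs sorted: ties -> smaller
  report$chosen <- report$cost == best
  list(best_cost = best, report = report)
}

#' Replicated cross-validated evaluation
#'
#' Runs the pooled cross-validated evaluation at a fixed cost
#' `n_replicates` times; replicates differ only through derived RNG streams
#' (fold assignment and ICP splits).
#'
#' @param ds a [target_dataset()].
#' @param cost SVM cost.
#' @param sweep a [sweep_config()].
#' @param heights a [signature_config()].
#' @return list with `replicates` (data frame: replicate, OF, CAOF,
#'   MC at significance 0.2) and `medians` (named numeric vector).
#' @export
replicate_runs <- function(ds, cost, sweep = sweep_config(),
                           heights = signature_config()) {
  sig_vectors <- featurize_all(ds$records$smiles, heights)
  rows <- lapply(seq_len(sweep$n_replicates), function(rep_i) {
    preds <- evaluate_cv(ds, cost, sweep,
                         seed = derive_seed(sweep$seed, 17L, rep_i),
                         sig_vectors = sig_vectors, heights = heights)
    data.frame(replicate = rep_i,
               OF = observed_fuzziness(preds),
               CAOF = class_averaged_of(preds),
               MC_sig_0.2 = m_criterion(preds, 0.2))
  })
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       medians = c(OF = median(reps$OF), CAOF = median(reps$CAOF),
                   MC_sig_0.2 = median(reps$MC_sig_0.2)))
}
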