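
# -- Mondrian inductive / aggregated conformal prediction ---------------------
#
# Each ICP splits the non-assumed training records, per class, into a proper
# training set and a calibration set; assumed non-actives always join the
# proper set.  A linear SVM is fitted on the proper set and the signed
# distance to its decision surface is the nonconformity score: alpha = -d
# for class A and +d for class N (positive direction = A, higher = stranger).
# Mondrian p-values rank a test score within the calibration scores of its
# own class, giving class-conditional validity without resampling tricks.

#' ICP split settings
#'
#' @param calibration_fraction fraction of each class's non-assumed records
#'   put in the calibration set (default 0.2).
#' @param n_icp number of aggregated ICPs (default 10).
#' @param seed master seed; each ICP's split uses a stream derived from
#'   `(seed, icp_index)`.
#' @return object of class `split_config`.
#' @export
split_config <- function(calibration_fraction = 0.2, n_icp = 10L, seed = 1L) {
  stopifnot(calibration_fraction > 0, calibration_fraction < 1, n_icp >= 1)
  structure(list(calibration_fraction = calibration_fraction,
                 n_icp = as.integer(n_icp), seed = as.integer(seed)),
            class = "split_config")
}

#' Model training settings
#'
#' @param cost SVM cost (inverse regularization; the swept parameter).
#' @param heights a [signature_config()].
#' @param aggregation how per-ICP p-values are combined: `"mean"` (default)
#'   or `"median"`.
#' @param smoothed_pvalues use tie-randomized (smoothed) p-values; the
#'   default `FALSE` gives deterministic, slightly conservative p-values.
#' @return object of class `train_config`.
#' @export
train_config <- function(cost = 1, heights = signature_config(),
                         aggregation = c("mean", "median"),
                         smoothed_pvalues = FALSE) {
  stopifnot(cost > 0)
  structure(list(cost = cost, heights = heights,
                 aggregation = match.arg(aggregation),
                 smoothed_pvalues = isTRUE(smoothed_pvalues)),
            class = "train_config")
}

#' Proper-training / calibration split for one ICP
#'
#' Assumed non-actives always go to the proper set.  The remaining records
#' are split per class at the configured fraction; splits differ across
#' `icp_index` but are reproducible under `(seed, icp_index)`.
#'
#' @param ds a [target_dataset()].
#' @param config a [split_config()].
#' @param icp_index 1-based ICP index.
#' @return list of integer row indices `proper` and `calibration`.
#' @export
split_proper_calibration <- function(ds, config, icp_index) {
  r <- ds$records
  cal <- integer()
  for (cls in c("A", "N")) {
    members <- which(r$activity == cls & !r$assumed)
    if (length(members) < 2) {
      stop(sprintf("target %s: class %s has %d non-assumed example(s); cannot calibrate",
                   ds$target, cls, length(members)))
    }
    n_cal <- min(length(members) - 1L,
                 max(1L, round(config$calibration_fraction * length(members))))
    set.seed(derive_seed(config$seed, icp_index, match(cls, c("A", "N"))))
    cal <- c(cal, sample(members, n_cal))
  }
  list(proper = setdiff(seq_len(nrow(r)), cal), calibration = sort(cal))
}

#' Nonconformity from a decision value
#'
#' @param decision_value signed distance from the decision surface, positive
#'   direction = class A.
#' @param label `"A"` or `"N"`.
#' @return the nonconformity score (higher = stranger for that class).
#' @export
nonconformity <- function(decision_value, label) {
  ifelse(label == "A", -decision_value, decision_value)
}

#' Mondrian conformal p-value
#'
#' Unsmoothed: `p = (#\{alpha_j >= alpha\} + 1) / (n + 1)`, which lies in
#' `[1/(n+1), 1]`.  Smoothed p-values randomize over ties (and the +1) with
#' the current RNG stream.
#'
#' @param alpha numeric vector of test nonconformity scores.
#' @param calib_scores sorted numeric vector of calibration scores for the
#'   same class.
#' @param smoothed logical.
#' @return numeric vector of p-values.
#' @export
pvalue <- function(alpha, calib_scores, smoothed = FALSE) {
  n <- length(calib_scores)
  if (!n) stop("empty calibration score list")
  n_lt <- findInterval(alpha, calib_scores, left.open = TRUE)  # #{ < alpha }
  if (!smoothed) {
    (n - n_lt + 1) / (n + 1)
  } else {
    n_le <- findInterval(alpha, calib_scores)                  # #{ <= alpha }
    ties <- n_le - n_lt
    (n - n_le + runif(length(alpha)) * (ties + 1)) / (n + 1)
  }
}

# fit one linear SVM and calibrate; x sparse dgCMatrix, y in {"A","N"}
.fit_icp <- function(x_proper, y_proper, x_cal, y_cal, cost) {
  if (length(unique(y_proper)) < 2) {
    stop("degenerate proper training set: only one class present")
  }
  fit <- e1071::svm(x_proper, factor(y_proper, levels = c("A", "N")),
                    kernel = "linear", cost = cost, scale = FALSE)
  sv <- fit$SV
  if (inherits(sv, "matrix.csr")) sv <- SparseM::as.matrix(sv)
  w <- as.numeric(crossprod(as.matrix(sv), fit$coefs))
  b <- -fit$rho
  # libsvm orients the decision function toward its first internal label;
  # read the orientation off a one-row prediction
  dv <- attr(stats::predict(fit, x_proper[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  if (identical(colnames(dv), "N/A")) { w <- -w; b <- -b }
  d_cal <- as.numeric(x_cal %*% w + b)
  alpha <- nonconformity(d_cal, y_cal)
  list(w = w, b = b,
       calib_A = sort(alpha[y_cal == "A"]),
       calib_N = sort(alpha[y_cal == "N"]))
}

#' Train a Mondrian aggregated conformal predictor for one target
#'
#' Builds the signature dictionary from all training molecules (structure
#' only; shared across ICPs so feature columns agree), then trains `n_icp`
#' ICPs on independent proper/calibration splits.
#'
#' @param ds a [target_dataset()].
#' @param train a [train_config()].
#' @param split a [split_config()].
#' @param sig_vectors optional precomputed list of `sig_vector` for
#'   `ds$records` (in row order), to avoid re-featurizing.
#' @return object of class `acp_model`.
#' @export
acp_train <- function(ds, train = train_config(), split = split_config(),
                      sig_vectors = NULL) {
  stopifnot(inherits(ds, "target_dataset"))
  r <- ds$records
  if (is.null(sig_vectors)) sig_vectors <- featurize_all(r$smiles, train$heights)
  dict <- build_dictionary(sig_vectors)
  x <- .sig_matrix(sig_vectors, dict)
  icps <- vector("list", split$n_icp)
  for (k in seq_len(split$n_icp)) {
    sp <- split_proper_calibration(ds, split, k)
    icps[[k]] <- .fit_icp(x[sp$proper, , drop = FALSE], r$activity[sp$proper],
                          x[sp$calibration, , drop = FALSE],
                          r$activity[sp$calibration], train$cost)
  }
  structure(list(target = ds$target, icps = icps, dictionary = dict,
                 train_config = train, split_config = split,
                 version = .cpligand_version()),
            class = "acp_model")
}

#' @export
print.acp_model <- function(x, ...) {
  cat(sprintf("<acp_model> target %s: %d ICPs, %d features, cost %g, %s aggregation\n",
              x$target, length(x$icps), length(x$dictionary$signatures),
              x$train_config$cost, x$train_config$aggregation))
  invisible(x)
}

#' Predict two-class conformal p-values
#'
#' Each ICP produces a (p_A, p_N) pair per molecule; pairs are combined by
#' the configured aggregation rule (arithmetic mean by default).
#'
#' @param model an [acp_train()] model.
#' @param newdata character vector of SMILES, or a list of precomputed
#'   `sig_vector` objects.
#' @return data frame with columns `p_A`, `p_N`.
#' @export
acp_predict <- function(model, newdata) {
  stopifnot(inherits(model, "acp_model"))
  vecs <- if (is.character(newdata)) {
    featurize_all(newdata, model$train_config$heights)
  } else newdata
  x <- .sig_matrix(vecs, model$dictionary)
  n_icp <- length(model$icps)
  W <- vapply(model$icps, `[[`, numeric(length(model$icps[[1]]$w)), "w")
  d <- as.matrix(x %*% W) +
    matrix(vapply(model$icps, `[[`, numeric(1), "b"),
           nrow(x), n_icp, byrow = TRUE)
  sm <- model$train_config$smoothed_pvalues
  pa <- matrix(0, nrow(x), n_icp); pn <- pa
  for (k in seq_len(n_icp)) {
    pa[, k] <- pvalue(-d[, k], model$icps[[k]]$calib_A, smoothed = sm)
    pn[, k] <- pvalue(d[, k], model$icps[[k]]$calib_N, smoothed = sm)
  }
  agg <- if (model$train_config$aggregation == "mean") rowMeans else
    function(m) apply(m, 1, median)
  data.frame(p_A = agg(pa), p_N = agg(pn))
}

#' Prediction sets, confidence
#'
#' The prediction set at significance `epsilon` is the set of classes with
#' p-value strictly greater than `epsilon`; sets are nested in `epsilon`.
#'
#' @param preds data frame with columns `p_A`, `p_N`.
#' @param significance significance level in (0, 1).
#' @return character vector with values `"A"`, `"N"`, `"Both"`, `"Null"`.
#' @export
prediction_sets <- function(preds, significance) {
  stopifnot(significance > 0, significance < 1)
  in_a <- preds$p_A > significance
  in_n <- preds$p_N > significance
  ifelse(in_a & in_n, "Both", ifelse(in_a, "A", ifelse(in_n, "N", "Null")))
}

#' @rdname prediction_sets
#' @export
prediction_confidence <- function(preds) 1 - pmin(preds$p_A, preds$p_N)

# -- model archive ------------------------------------------------------------

#' Save / load an ACP model archive
#'
#' The archive is a single portable JSON file embedding a manifest, the
#' signature dictionary, and per-ICP weights (sparse) and calibration
#' scores, at full floating-point precision so that a save/load round trip
#' reproduces predictions bit-identically.
#'
#' @param model an `acp_model`.
#' @param path file path.
#' @return `path` (save) or the restored `acp_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  icps <- lapply(model$icps, function(ic) {
    nz <- which(ic$w != 0)
    list(w_index = nz, w_value = ic$w[nz], n_features = length(ic$w),
         b = ic$b, calib_A = ic$calib_A, calib_N = ic$calib_N)
  })
  obj <- list(
    manifest = list(format = "cpligand-acp", format_version = 1L,
                    package_version = model$version,
                    target = model$target,
                    n_icp = length(model$icps),
                    aggregation = model$train_config$aggregation,
                    cost = model$train_config$cost,
                    heights = model$train_config$heights$heights,
                    smoothed_pvalues = model$train_config$smoothed_pvalues,
                    calibration_fraction = model$split_config$calibration_fraction,
                    seed = model$split_config$seed),
    dictionary = model$dictionary$signatures,
    icps = icps)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot read model archive '",
                                           path, "': ", conditionMessage(e)))
  man <- obj$manifest
  if (is.null(man$format) || !identical(man$format, "cpligand-acp")) {
    stop("not a cpligand model archive: ", path)
  }
  if (!identical(as.integer(man$format_version), 1L)) {
    stop(sprintf("model archive format version %s is not supported by this package version",
                 man$format_version))
  }
  icps <- lapply(seq_len(man$n_icp), function(k) {
    ic <- if (is.data.frame(obj$icps)) lapply(obj$icps, `[[`, k) else obj$icps[[k]]
    w <- numeric(ic$n_features)
    w[unlist(ic$w_index)] <- unlist(ic$w_value)
    list(w = w, b = ic$b,
         calib_A = as.numeric(unlist(ic$calib_A)),
         calib_N = as.numeric(unlist(ic$calib_N)))
  })
  structure(list(
    target = man$target, icps = icps,
    dictionary = structure(list(signatures = as.character(obj$dictionary),
                                frozen = TRUE), class = "sig_dictionary"),
    train_config = train_config(cost = man$cost,
                                heights = signature_config(unlist(man$heights)),
                                aggregation = man$aggregation,
                                smoothed_pvalues = isTRUE(man$smoothed_pvalues)),
    split_config = split_config(calibration_fraction = man$calibration_fraction,
                                n_icp = man$n_icp, seed = man$seed),
    version = man$package_version),
    class = "acp_model")
}
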