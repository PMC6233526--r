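
# -- Multi-target profiles and atom contributions -----------------------------

#' Predict a target profile for a query molecule
#'
#' Queries every loaded model with the same molecule.  A failure in one
#' model is recorded in the profile, not fatal to the others.
#'
#' @param models named list of [acp_train()] / [load_model()] models; names
#'   are the target labels (defaulting to each model's own target).
#' @param smiles a single SMILES string.
#' @param confidence confidence level used for the reported prediction set.
#' @return object of class `target_profile`: data frame with columns
#'   `target`, `p_A`, `p_N`, `set`, `confidence`, `error`.
#' @export
predict_profile <- function(models, smiles, confidence = 0.8) {
  stopifnot(length(models) >= 1, is.character(smiles), length(smiles) == 1)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, character(1), "target")
  }
  mol <- parse_smiles(smiles)   # fatal if unparseable
  vec_cache <- new.env(parent = emptyenv())
  rows <- lapply(names(models), function(tg) {
    res <- tryCatch({
      hkey <- paste(models[[tg]]$train_config$heights$heights, collapse = ",")
      if (!exists(hkey, envir = vec_cache)) {
        assign(hkey, list(featurize(mol, models[[tg]]$train_config$heights)),
               envir = vec_cache)
      }
      p <- acp_predict(models[[tg]], get(hkey, envir = vec_cache))
      data.frame(target = tg, p_A = p$p_A, p_N = p$p_N,
                 set = prediction_sets(p, 1 - confidence),
                 confidence = prediction_confidence(p),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(target = tg, p_A = NA_real_, p_N = NA_real_,
                 set = NA_character_, confidence = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "query") <- smiles
  attr(out, "set_confidence") <- confidence
  class(out) <- c("target_profile", class(out))
  out
}

#' Atom-level contribution scores
#'
#' Decomposes the ICP-averaged linear decision function onto atoms: every
#' (atom, height) signature present in the model dictionary contributes its
#' averaged weight to its root atom.  The sum of atom scores equals the
#' averaged decision value minus the averaged intercept.  Scores are
#' oriented so that positive values point toward the larger-p class.
#'
#' @param model an `acp_model`.
#' @param mol a [molgraph()] or SMILES string.
#' @return data frame with columns `atom`, `element`, `score`; attributes
#'   `decision_value`, `intercept` and `larger_class`.
#' @export
atom_contributions <- function(model, mol) {
  stopifnot(inherits(model, "acp_model"))
  if (is.character(mol)) mol <- parse_smiles(mol)
  heights <- model$train_config$heights
  w_avg <- rowMeans(vapply(model$icps, `[[`,
                           numeric(length(model$icps[[1]]$w)), "w"))
  b_avg <- mean(vapply(model$icps, `[[`, numeric(1), "b"))
  occ <- .atom_level_signatures(mol, heights)
  col <- match(occ$tag, model$dictionary$signatures)
  contrib <- ifelse(is.na(col), 0, w_avg[ifelse(is.na(col), 1L, col)])
  score <- vapply(seq_len(mol$n), function(a) sum(contrib[occ$atom == a]),
                  numeric(1))
  p <- acp_predict(model, list(featurize(mol, heights)))
  larger <- if (p$p_A >= p$p_N) "A" else "N"
  # decision value is oriented toward A; flip so positive = larger-p class
  if (larger == "N") score <- -score
  out <- data.frame(atom = seq_len(mol$n), element = mol$element,
                    score = score)
  attr(out, "decision_value") <- sum(vapply(seq_len(mol$n), function(a)
    sum(contrib[occ$atom == a]), numeric(1))) + b_avg
  attr(out, "intercept") <- b_avg
  attr(out, "larger_class") <- larger
  out
}

#' Write a target profile as JSON and CSV
#'
#' @param profile a [predict_profile()] result.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_profile <- function(profile, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(profile, "target_profile"))
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(query = attr(profile, "query"),
           set_confidence = attr(profile, "set_confidence"),
           profile = as.data.frame(profile)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(profile), csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> query %s (%d targets, set confidence %.2f)\n",
              attr(x, "query"), nrow(x), attr(x, "set_confidence")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
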