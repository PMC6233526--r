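
# -- Efficiency and validity metrics ------------------------------------------
#
# All metrics take an "evaluated predictions" data frame: columns `truth`
# ("A"/"N") and the two class p-values `p_A`, `p_N`.  Prediction-set
# membership uses the strict inequality p > epsilon throughout.

.check_preds <- function(preds) {
  stopifnot(is.data.frame(preds),
            all(c("truth", "p_A", "p_N") %in% names(preds)))
  if (!nrow(preds)) stop("empty prediction set")
  stopifnot(all(preds$truth %in% c("A", "N")))
  invisible(preds)
}

#' Observed fuzziness
#'
#' The mean of the wrong-class p-values over all predictions:
#' `OF = (sum_\{y=A\} p_N + sum_\{y=N\} p_A) / (m_A + m_N)`.
#' Lower is better (a sharper predictor).
#'
#' @param preds data frame with columns `truth`, `p_A`, `p_N`.
#' @return a single number in `[0, 1]`.
#' @export
observed_fuzziness <- function(preds) {
  .check_preds(preds)
  wrong <- ifelse(preds$truth == "A", preds$p_N, preds$p_A)
  mean(wrong)
}

#' Class-averaged observed fuzziness
#'
#' Averages the wrong-class p-values within each class separately and sums
#' the two class means, so both classes contribute equally regardless of
#' class sizes: `CAOF = sum_\{y=A\} p_N / m_A + sum_\{y=N\} p_A / m_N`.
#' Equals `2 * OF` when the classes are balanced.
#'
#' @inheritParams observed_fuzziness
#' @return a single number in `[0, 2]`.
#' @export
class_averaged_of <- function(preds) {
  .check_preds(preds)
  m_a <- sum(preds$truth == "A"); m_n <- sum(preds$truth == "N")
  if (m_a == 0 || m_n == 0) {
    stop("class-averaged observed fuzziness requires both classes in the evaluation set")
  }
  sum(preds$p_N[preds$truth == "A"]) / m_a +
    sum(preds$p_A[preds$truth == "N"]) / m_n
}

#' M criterion (fraction of multi-label prediction sets)
#'
#' The fraction of predictions whose set at significance `epsilon` contains
#' more than one label.  Smaller is preferable.
#'
#' @inheritParams observed_fuzziness
#' @param significance significance level in (0, 1).
#' @return a single number in `[0, 1]`.
#' @export
m_criterion <- function(preds, significance) {
  .check_preds(preds)
  stopifnot(significance > 0, significance < 1)
  mean(preds$p_A > significance & preds$p_N > significance)
}

#' Calibration curve (accuracy vs confidence)
#'
#' Accuracy at confidence `c` is the fraction of predictions whose set at
#' significance `1 - c` contains the true label.
#'
#' @inheritParams observed_fuzziness
#' @param grid confidence grid (default 0.05 to 0.95 in steps of 0.05).
#' @return data frame with columns `confidence`, `accuracy`, `n`.
#' @export
calibration_curve <- function(preds, grid = seq(0.05, 0.95, by = 0.05)) {
  .check_preds(preds)
  p_true <- ifelse(preds$truth == "A", preds$p_A, preds$p_N)
  acc <- vapply(grid, function(conf) mean(p_true > 1 - conf), numeric(1))
  data.frame(confidence = grid, accuracy = acc, n = nrow(preds))
}

#' Label-set confusion table
#'
#' Counts of observed label (rows: A, N) against predicted label set
#' (columns: A, N, Both, Null) at the given confidence level.
#'
#' @inheritParams observed_fuzziness
#' @param confidence confidence level in (0, 1); sets are taken at
#'   significance `1 - confidence`.
#' @return a 2 x 4 integer matrix with dimnames observed x predicted.
#' @export
label_set_confusion <- function(preds, confidence) {
  .check_preds(preds)
  stopifnot(confidence > 0, confidence < 1)
  sets <- factor(prediction_sets(preds, 1 - confidence),
                 levels = c("A", "N", "Both", "Null"))
  truth <- factor(preds$truth, levels = c("A", "N"))
  tab <- table(observed = truth, predicted = sets)
  matrix(as.integer(tab), nrow = 2, dimnames = dimnames(tab))
}

#' Full efficiency report
#'
#' @inheritParams observed_fuzziness
#' @param significances significance levels at which the M criterion and
#'   confusion tables are reported (default 0.2 and 0.1, i.e., confidence
#'   0.8 and 0.9).
#' @return object of class `efficiency_report`: list with counts, `OF`,
#'   `CAOF`, `MC` (named by significance), `calibration` and `confusion`
#'   (list of tables named by confidence).
#' @export
efficiency_report <- function(preds, significances = c(0.2, 0.1)) {
  .check_preds(preds)
  conf <- 1 - significances
  structure(list(
    m = nrow(preds),
    m_A = sum(preds$truth == "A"),
    m_N = sum(preds$truth == "N"),
    OF = observed_fuzziness(preds),
    CAOF = class_averaged_of(preds),
    MC = stats::setNames(vapply(significances, function(e)
      m_criterion(preds, e), numeric(1)), significances),
    calibration = calibration_curve(preds),
    confusion = stats::setNames(lapply(conf, function(cf)
      label_set_confusion(preds, cf)), conf)),
    class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> m = %d (A: %d, N: %d)\n", x$m, x$m_A, x$m_N))
  cat(sprintf("  OF   = %.4f\n  CAOF = %.4f\n", x$OF, x$CAOF))
  for (e in names(x$MC)) cat(sprintf("  MC@significance %s = %.4f\n", e, x$MC[[e]]))
  invisible(x)
}

#' Write per-target evaluation CSVs
#'
#' Writes the calibration curve, the label-set confusion counts in long
#' form (target, observed, predicted, count, confidence) and a one-row
#' efficiency summary.
#'
#' @param report an [efficiency_report()].
#' @param target target name used in the file contents.
#' @param dir output directory.
#' @return character vector of the files written, invisibly.
#' @export
write_efficiency_csvs <- function(report, target, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_cal <- file.path(dir, paste0(target, "_calibration.csv"))
  utils::write.csv(report$calibration, f_cal, row.names = FALSE)
  long <- do.call(rbind, lapply(names(report$confusion), function(cf) {
    tab <- report$confusion[[cf]]
    data.frame(target = target,
               observed = rep(rownames(tab), times = ncol(tab)),
               predicted = rep(colnames(tab), each = nrow(tab)),
               count = as.integer(tab), confidence = as.numeric(cf),
               stringsAsFactors = FALSE)
  }))
  f_conf <- file.path(dir, paste0(target, "_confusion.csv"))
  utils::write.csv(long, f_conf, row.names = FALSE)
  summ <- data.frame(target = target, m = report$m, m_A = report$m_A,
                     m_N = report$m_N, OF = report$OF, CAOF = report$CAOF)
  for (e in names(report$MC)) summ[[paste0("MC_sig_", e)]] <- report$MC[[e]]
  f_sum <- file.path(dir, paste0(target, "_efficiency.csv"))
  utils::write.csv(summ, f_sum, row.names = FALSE)
  invisible(c(f_cal, f_conf, f_sum))
}
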