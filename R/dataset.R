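
# -- Activity-table preparation ----------------------------------------------
#
# Records are plain data frames with columns target, entry_id, smiles,
# activity ("A"/"N").  Cleaning follows the extraction rules for large
# bioactivity extracts: rows conflicting on (target, SMILES) are removed
# entirely, duplicates on (target, SMILES, activity) collapse to the
# first-seen entry, targets need at least `min_actives` actives and
# `min_nonactives` non-actives, and data-poor targets are topped up with
# "assumed non-active" compounds sampled from the remaining pool.

#' Preparation settings
#'
#' @param min_actives,min_nonactives inclusion minima per target (default
#'   100/100).
#' @param augmentation_threshold targets with fewer known non-actives than
#'   this are eligible for assumed-non-active augmentation (default 10000).
#' @param nonactive_ratio target total non-actives as a multiple of the
#'   active count after augmentation (default 2).
#' @param canonical compare SMILES by backend-canonical form (default) or
#'   as raw strings.
#' @param seed integer seed for the sampling steps.
#' @return an object of class `prep_config`.
#' @export
prep_config <- function(min_actives = 100L, min_nonactives = 100L,
                        augmentation_threshold = 10000L,
                        nonactive_ratio = 2, canonical = TRUE, seed = 1L) {
  stopifnot(min_actives > 0, min_nonactives > 0, augmentation_threshold > 0,
            nonactive_ratio > 0)
  structure(list(min_actives = as.integer(min_actives),
                 min_nonactives = as.integer(min_nonactives),
                 augmentation_threshold = as.integer(augmentation_threshold),
                 nonactive_ratio = nonactive_ratio,
                 canonical = isTRUE(canonical), seed = as.integer(seed)),
            class = "prep_config")
}

.smiles_key <- function(smiles, canonical) {
  if (!canonical) return(smiles)
  key <- canonical_smiles(smiles)
  # unparseable SMILES fall back to their raw string so they stay distinct
  key[is.na(key)] <- smiles[is.na(key)]
  key
}

#' Load activity records from a delimited text file
#'
#' Reads in fixed-size chunks (so arbitrarily large files never need to be
#' memory-resident during filtering), keeping only the mapped columns.
#' `.gz` files are read transparently.  Rows whose activity value is not
#' `A`/`N`, or that have the wrong field count, are skipped and counted in
#' one warning.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named list mapping the canonical names `target`,
#'   `entry_id`, `smiles`, `activity` to the file's column names.
#' @param delim field delimiter (default tab).
#' @param chunk_size rows per chunk.
#' @return data frame with columns target, entry_id, smiles, activity.
#' @export
load_activity_records <- function(path,
                                  column_map = list(target = "target",
                                                    entry_id = "entry_id",
                                                    smiles = "smiles",
                                                    activity = "activity"),
                                  delim = "\t", chunk_size = 50000L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (!length(header)) {
    warning("empty activity file: ", path)
    return(data.frame(target = character(), entry_id = character(),
                      smiles = character(), activity = character(),
                      stringsAsFactors = FALSE))
  }
  cols <- strsplit(header, delim, fixed = TRUE)[[1]]
  want <- unlist(column_map[c("target", "entry_id", "smiles", "activity")])
  miss <- setdiff(want, cols)
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  idx <- match(want, cols)
  n_bad_row <- 0L; n_bad_act <- 0L
  out <- list()
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    fields <- strsplit(lines, delim, fixed = TRUE)
    ok <- lengths(fields) == length(cols)
    n_bad_row <- n_bad_row + sum(!ok)
    fields <- fields[ok]
    if (!length(fields)) next
    m <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE)
    act_ok <- m[, idx[4]] %in% c("A", "N")
    n_bad_act <- n_bad_act + sum(!act_ok)
    m <- m[act_ok, , drop = FALSE]
    if (nrow(m)) {
      out[[length(out) + 1L]] <- data.frame(
        target = m[, idx[1]], entry_id = m[, idx[2]],
        smiles = m[, idx[3]], activity = m[, idx[4]],
        stringsAsFactors = FALSE)
    }
  }
  if (n_bad_row + n_bad_act > 0) {
    warning(sprintf("skipped %d malformed row(s) and %d row(s) with unmapped activity",
                    n_bad_row, n_bad_act))
  }
  if (!length(out)) {
    warning("no usable records in ", path)
    return(data.frame(target = character(), entry_id = character(),
                      smiles = character(), activity = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Remove activity conflicts
#'
#' Drops every row of any (target, SMILES) key that carries both an `A` and
#' an `N` record.  All rows of a conflicting key are removed, none are
#' majority-voted.
#'
#' @param records activity record data frame.
#' @param canonical compare SMILES by canonical form (default `TRUE`).
#' @return the filtered data frame.
#' @export
remove_conflicts <- function(records, canonical = TRUE) {
  if (!nrow(records)) return(records)
  key <- paste(records$target, .smiles_key(records$smiles, canonical),
               sep = "\r")
  acts <- split(records$activity, key)
  bad <- names(acts)[vapply(acts, function(a) length(unique(a)) > 1, logical(1))]
  records[!(key %in% bad), , drop = FALSE]
}

#' Deduplicate activity records
#'
#' Keeps at most one record per (target, SMILES, activity); the retained
#' record keeps the first-seen entry id.  With `by_entry_id = TRUE` the
#' entry id participates in the key instead (literal duplicate removal
#' only).
#'
#' @param records activity record data frame (conflicts already removed).
#' @param canonical compare SMILES by canonical form (default `TRUE`).
#' @param by_entry_id include entry_id in the deduplication key.
#' @return the deduplicated data frame.
#' @export
deduplicate <- function(records, canonical = TRUE, by_entry_id = FALSE) {
  if (!nrow(records)) return(records)
  skey <- .smiles_key(records$smiles, canonical)
  key <- if (by_entry_id) {
    paste(records$target, records$entry_id, skey, records$activity, sep = "\r")
  } else {
    paste(records$target, skey, records$activity, sep = "\r")
  }
  records[!duplicated(key), , drop = FALSE]
}

#' Per-target dataset container
#'
#' @param target gene symbol.
#' @param records data frame with columns smiles, activity, entry_id and
#'   logical assumed (assumed non-active flag).
#' @return object of class `target_dataset`.
#' @export
target_dataset <- function(target, records) {
  if (!"assumed" %in% names(records)) records$assumed <- FALSE
  stopifnot(all(records$activity %in% c("A", "N")),
            all(records$activity[records$assumed] == "N"))
  structure(list(target = target,
                 records = records[, c("smiles", "activity", "assumed",
                                       "entry_id")]),
            class = "target_dataset")
}

#' @export
print.target_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<target_dataset> %s: %d A, %d N (%d assumed non-active)\n",
              x$target, sum(r$activity == "A"),
              sum(r$activity == "N"), sum(r$assumed)))
  invisible(x)
}

#' Select targets meeting the inclusion minima
#'
#' @param records cleaned activity record data frame.
#' @param config a [prep_config()].
#' @return list with `datasets` (named list of [target_dataset()]) and
#'   `excluded` (data frame target, n_active, n_nonactive, reason).
#' @export
select_targets <- function(records, config = prep_config()) {
  datasets <- list()
  excl <- data.frame(target = character(), n_active = integer(),
                     n_nonactive = integer(), reason = character(),
                     stringsAsFactors = FALSE)
  if (!nrow(records)) return(list(datasets = datasets, excluded = excl))
  for (tg in unique(records$target)) {
    rr <- records[records$target == tg, , drop = FALSE]
    n_a <- sum(rr$activity == "A"); n_n <- sum(rr$activity == "N")
    if (n_a >= config$min_actives && n_n >= config$min_nonactives) {
      datasets[[tg]] <- target_dataset(tg, data.frame(
        smiles = rr$smiles, activity = rr$activity,
        assumed = FALSE, entry_id = rr$entry_id, stringsAsFactors = FALSE))
    } else {
      reason <- if (n_a < config$min_actives && n_n < config$min_nonactives) {
        "too few actives and non-actives"
      } else if (n_a < config$min_actives) "too few actives"
      else "too few non-actives"
      excl <- rbind(excl, data.frame(target = tg, n_active = n_a,
                                     n_nonactive = n_n, reason = reason,
                                     stringsAsFactors = FALSE))
    }
  }
  list(datasets = datasets, excluded = excl)
}

#' Augment a target dataset with assumed non-actives
#'
#' Samples `max(0, ceiling(ratio * n_A) - n_N)` distinct compounds, uniformly
#' without replacement, from pool members that are (i) not reported active
#' for this target and (ii) not already in the dataset.  Sampled records are
#' flagged `assumed = TRUE`; downstream they join the proper training set
#' only, never a calibration or test set.
#'
#' @param ds a [target_dataset()].
#' @param pool activity record data frame to sample from (typically the full
#'   cleaned table across all targets).
#' @param config a [prep_config()]; `nonactive_ratio` and `seed` are used.
#' @return the augmented [target_dataset()].
#' @export
add_assumed_nonactives <- function(ds, pool, config = prep_config()) {
  stopifnot(inherits(ds, "target_dataset"))
  n_a <- sum(ds$records$activity == "A")
  n_n <- sum(ds$records$activity == "N")
  n_add <- max(0L, as.integer(ceiling(config$nonactive_ratio * n_a)) - n_n)
  if (n_add == 0L) return(ds)
  pool_key <- .smiles_key(pool$smiles, config$canonical)
  ds_key <- .smiles_key(ds$records$smiles, config$canonical)
  active_key <- pool_key[pool$target == ds$target & pool$activity == "A"]
  elig <- !(pool_key %in% active_key) & !(pool_key %in% ds_key) &
    !duplicated(pool_key)
  cand <- which(elig)
  if (length(cand) < n_add) {
    warning(sprintf("target %s: pool has only %d eligible compounds (%d requested)",
                    ds$target, length(cand), n_add))
    pick <- cand
  } else {
    rng <- local({ set.seed(derive_seed(config$seed, 7L)); sample(cand, n_add) })
    pick <- rng
  }
  extra <- data.frame(smiles = pool$smiles[pick], activity = "N",
                      assumed = TRUE, entry_id = pool$entry_id[pick],
                      stringsAsFactors = FALSE)
  target_dataset(ds$target, rbind(ds$records, extra))
}

#' Split off an external validation set
#'
#' Moves every record whose id matches `compound_ids` into the external
#' partition.  The partition is exact: no record appears in both parts and
#' none is lost.
#'
#' @param records activity record data frame.
#' @param compound_ids character vector of ids to withhold.
#' @param key match on `"entry_id"` (default) or `"smiles"`.
#' @return list with `train` and `external` data frames.
#' @export
withhold_external <- function(records, compound_ids, key = c("entry_id", "smiles")) {
  key <- match.arg(key)
  if (!length(compound_ids)) {
    return(list(train = records, external = records[0, , drop = FALSE]))
  }
  hit <- records[[key]] %in% compound_ids
  n_matched <- length(intersect(compound_ids, records[[key]]))
  if (n_matched < length(unique(compound_ids))) {
    warning(sprintf("%d withheld id(s) match no record",
                    length(unique(compound_ids)) - n_matched))
  }
  list(train = records[!hit, , drop = FALSE],
       external = records[hit, , drop = FALSE])
}
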