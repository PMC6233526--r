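
# -- Synthetic activity tables -----------------------------------------------
#
# Generates multi-target binary activity tables with a known
# structure-activity signal, so the whole pipeline is testable without any
# external download.  Each target is assigned a functional-group motif;
# actives carry the motif on a randomly grown alkyl/aryl scaffold,
# non-actives carry a different decoration (or none).  Observed labels are
# then flipped independently with probability `label_noise`, so molecules
# are i.i.d. draws and exchangeability holds by construction.  Duplicate
# rows and (target, SMILES) label conflicts can be injected at known rates,
# with exact bookkeeping returned for downstream checks.

# attachable decorations; pairwise distinguishable at signature height >= 1
.motifs <- c(
  carboxylic_acid = "C(=O)O",
  nitro           = "[N+](=O)[O-]",
  sulfonamide     = "S(N)(=O)=O",
  nitrile         = "C#N",
  chloro          = "Cl",
  trifluoromethyl = "C(F)(F)F",
  primary_amine   = "N",
  methoxy         = "OC",
  bromo           = "Br",
  thiol           = "S")

#' Synthetic-data settings
#'
#' @param n_targets number of targets (named `T1`, `T2`, ...); each gets a
#'   distinct functional-group motif from a built-in list.
#' @param n_active,n_nonactive molecules per class per target.
#' @param label_noise probability of flipping an observed label, in
#'   `[0, 0.5)`.
#' @param duplicate_rate,conflict_rate fraction of rows duplicated /
#'   (target, SMILES) keys given an injected conflicting label, in `[0, 1)`.
#' @param chain_len integer range of the scaffold's carbon chain length.
#' @param ring_prob probability that the scaffold carries a phenyl ring.
#' @param branch_prob per-position probability of a methyl/ethyl branch.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_targets = 3L, n_active = 1000L,
                           n_nonactive = 1000L, label_noise = 0.1,
                           duplicate_rate = 0, conflict_rate = 0,
                           chain_len = c(2L, 10L), ring_prob = 0.4,
                           branch_prob = 0.3, seed = 42L) {
  stopifnot(n_targets >= 1, n_targets <= length(.motifs),
            n_active > 0, n_nonactive > 0,
            label_noise >= 0, label_noise < 0.5,
            duplicate_rate >= 0, duplicate_rate < 1,
            conflict_rate >= 0, conflict_rate < 1,
            length(chain_len) == 2, chain_len[1] >= 1,
            chain_len[2] >= chain_len[1])
  structure(list(n_targets = as.integer(n_targets),
                 n_active = as.integer(n_active),
                 n_nonactive = as.integer(n_nonactive),
                 label_noise = label_noise,
                 duplicate_rate = duplicate_rate,
                 conflict_rate = conflict_rate,
                 chain_len = as.integer(chain_len),
                 ring_prob = ring_prob, branch_prob = branch_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.target_motif <- function(target) {
  i <- as.integer(sub("^T", "", target))
  unname(.motifs[i])
}

# one random scaffold + decoration; decoration attaches to the last scaffold
# atom (chain carbon or ring carbon), which is always substitutable
.grow_smiles <- function(spec, decoration) {
  len <- sample(seq(spec$chain_len[1], spec$chain_len[2]), 1)
  parts <- rep("C", len)
  if (len > 2) {
    for (i in 2:(len - 1)) {
      if (runif(1) < spec$branch_prob) {
        parts[i] <- paste0("C(", if (runif(1) < 0.5) "C" else "CC", ")")
      }
    }
  }
  ring <- if (runif(1) < spec$ring_prob) "c1ccccc1" else ""
  paste0(paste(parts, collapse = ""), ring, decoration)
}

#' Generate labeled molecules for one target
#'
#' Pre-noise, actives contain the target's motif and non-actives do not;
#' observed labels are then flipped with probability `label_noise`.  All
#' generated SMILES are valid and canonically distinct within the target.
#'
#' @param spec a [synthetic_spec()].
#' @param target target name (`"T1"`, ...).
#' @return data frame with columns `smiles` (canonical), `activity`
#'   (observed label), `true_activity` (pre-noise) and `has_motif`.
#' @export
generate_molecules <- function(spec, target) {
  motif <- .target_motif(target)
  decoys <- setdiff(unname(.motifs), motif)
  set.seed(derive_seed(spec$seed, 23L, as.integer(sub("^T", "", target))))
  want <- c(A = spec$n_active, N = spec$n_nonactive)
  got <- list(A = character(), N = character())
  for (tries in 1:40) {
    need_a <- want["A"] - length(got$A)
    need_n <- want["N"] - length(got$N)
    if (need_a <= 0 && need_n <= 0) break
    batch_lab <- c(rep("A", ceiling(need_a * 1.5)), rep("N", ceiling(need_n * 1.5)))
    batch <- vapply(batch_lab, function(lb) {
      dec <- if (lb == "A") motif else {
        if (runif(1) < 0.75) sample(decoys, 1) else ""
      }
      .grow_smiles(spec, dec)
    }, character(1))
    canon <- canonical_smiles(batch)
    ok <- !is.na(canon)
    for (lb in c("A", "N")) {
      new <- unique(canon[ok & batch_lab == lb])
      new <- setdiff(new, c(got$A, got$N))
      got[[lb]] <- c(got[[lb]], head(new, want[[lb]] - length(got[[lb]])))
    }
  }
  if (length(got$A) < want["A"] || length(got$N) < want["N"]) {
    stop(sprintf("synthetic generator exhausted for %s: got %d A / %d N of %d / %d; widen chain_len",
                 target, length(got$A), length(got$N), want["A"], want["N"]))
  }
  df <- data.frame(smiles = c(got$A, got$N),
                   true_activity = rep(c("A", "N"), times = want),
                   stringsAsFactors = FALSE)
  df$has_motif <- df$true_activity == "A"
  flip <- runif(nrow(df)) < spec$label_noise
  df$activity <- ifelse(flip, ifelse(df$true_activity == "A", "N", "A"),
                        df$true_activity)
  df[, c("smiles", "activity", "true_activity", "has_motif")]
}

#' Generate a multi-target activity table
#'
#' Concatenates per-target molecule sets into the activity-record schema,
#' then injects exact duplicate rows (fresh entry ids) and conflicting
#' (target, SMILES) label pairs at the configured rates.  The returned
#' ledger records exactly what was injected so the preparation steps can be
#' verified row-for-row.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_table`: list with `records` (activity
#'   record data frame), `truth` (per base row: target, smiles,
#'   true_activity, has_motif) and `ledger` (list: `n_duplicates`,
#'   `conflict_keys` data frame, `n_conflict_rows_dropped`).
#' @export
generate_activity_table <- function(spec) {
  targets <- paste0("T", seq_len(spec$n_targets))
  base <- do.call(rbind, lapply(targets, function(tg) {
    mols <- generate_molecules(spec, tg)
    data.frame(target = tg,
               entry_id = sprintf("SYN-%s-%05d", tg, seq_len(nrow(mols))),
               smiles = mols$smiles, activity = mols$activity,
               true_activity = mols$true_activity,
               has_motif = mols$has_motif, stringsAsFactors = FALSE)
  }))
  set.seed(derive_seed(spec$seed, 29L))
  n <- nrow(base)
  n_dup <- floor(spec$duplicate_rate * n)
  n_cnf <- floor(spec$conflict_rate * n)
  pick <- if (n_dup + n_cnf > 0) sample(n, n_dup + n_cnf) else integer()
  dup_rows <- head(pick, n_dup)
  cnf_rows <- utils::tail(pick, n_cnf)

  records <- base[, c("target", "entry_id", "smiles", "activity")]
  if (n_dup > 0) {
    dups <- records[dup_rows, , drop = FALSE]
    dups$entry_id <- sprintf("DUP-%05d", seq_len(n_dup))
    records <- rbind(records, dups)
  }
  if (n_cnf > 0) {
    cnfs <- records[cnf_rows, , drop = FALSE]
    cnfs$entry_id <- sprintf("CNF-%05d", seq_len(n_cnf))
    cnfs$activity <- ifelse(cnfs$activity == "A", "N", "A")
    records <- rbind(records, cnfs)
  }
  rownames(records) <- NULL
  structure(list(
    records = records,
    truth = base[, c("target", "entry_id", "smiles", "true_activity",
                     "has_motif")],
    ledger = list(
      n_duplicates = n_dup,
      conflict_keys = base[cnf_rows, c("target", "smiles")],
      # each conflict key carries its base row plus the injected row
      n_conflict_rows_dropped = 2L * n_cnf)),
    class = "synthetic_table")
}

#' @export
print.synthetic_table <- function(x, ...) {
  cat(sprintf("<synthetic_table> %d records, %d targets, %d injected duplicates, %d injected conflicts\n",
              nrow(x$records), length(unique(x$records$target)),
              x$ledger$n_duplicates, nrow(x$ledger$conflict_keys)))
  invisible(x)
}

#' Write a synthetic table in the pipeline input schema
#'
#' Emits the TSV consumed by [load_activity_records()] plus a truth sidecar
#' JSON (ground-truth labels and the injected-artifact ledger).
#'
#' @param tab a [generate_activity_table()] result.
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_table <- function(tab, path) {
  stopifnot(inherits(tab, "synthetic_table"))
  utils::write.table(tab$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(truth = tab$truth, ledger = tab$ledger),
                       paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
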