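# raw-string comparisons (canonical = FALSE) keep these tests chemistry-free

test_that("conflict removal drops every row of a conflicting key", {
  r <- rec(c("T1", "T1", "T1"), c("e1", "e2", "e3"),
           c("S1", "S1", "S2"), c("A", "N", "A"))
  out <- remove_conflicts(r, canonical = FALSE)
  expect_equal(nrow(out), 1)
  expect_equal(out$smiles, "S2")

  # no conflicts -> identity
  r2 <- rec(c("T1", "T2"), c("e1", "e2"), c("S1", "S1"), c("A", "A"))
  expect_equal(remove_conflicts(r2, canonical = FALSE), r2)

  # the conflict key includes the target
  r3 <- rec(c("T1", "T1", "T2"), c("e1", "e2", "e3"),
            c("S1", "S1", "S1"), c("A", "N", "A"))
  out3 <- remove_conflicts(r3, canonical = FALSE)
  expect_equal(out3$target, "T2")
})

test_that("conflict removal and deduplication are idempotent", {
  set.seed(4)
  r <- rec(sample(c("T1", "T2"), 60, TRUE),
           sprintf("e%02d", 1:60),
           sample(c("S1", "S2", "S3", "S4"), 60, TRUE),
           sample(c("A", "N"), 60, TRUE))
  c1 <- remove_conflicts(r, canonical = FALSE)
  expect_equal(remove_conflicts(c1, canonical = FALSE), c1)
  d1 <- deduplicate(c1, canonical = FALSE)
  expect_equal(deduplicate(d1, canonical = FALSE), d1)
})

test_that("deduplication keys and first-seen entry id behave as documented", {
  r <- rec(rep("T1", 2), c("e1", "e1"), rep("S1", 2), rep("A", 2))
  expect_equal(nrow(deduplicate(r, canonical = FALSE)), 1)

  # SMILES-level rule: same (target, smiles, activity) under two entry ids
  r <- rec(rep("T1", 2), c("e1", "e2"), rep("S1", 2), rep("A", 2))
  out <- deduplicate(r, canonical = FALSE)
  expect_equal(nrow(out), 1)
  expect_equal(out$entry_id, "e1")
  # ... but both rows survive when the entry id joins the key
  expect_equal(nrow(deduplicate(r, canonical = FALSE, by_entry_id = TRUE)), 2)

  # same smiles under two targets is not a duplicate
  r <- rec(c("T1", "T2"), c("e1", "e1"), rep("S1", 2), rep("A", 2))
  expect_equal(nrow(deduplicate(r, canonical = FALSE)), 2)
})

test_that("canonical comparison catches duplicates raw strings miss", {
  r <- rec(rep("T1", 2), c("e1", "e2"), c("CCO", "OCC"), rep("A", 2))
  expect_equal(nrow(deduplicate(r, canonical = FALSE)), 2)
  expect_equal(nrow(deduplicate(r, canonical = TRUE)), 1)
})

test_that("target selection applies the at-least-100/100 rule inclusively", {
  cfg <- prep_config(canonical = FALSE)
  mk <- function(tg, n_a, n_n) {
    rec(rep(tg, n_a + n_n), sprintf("%s-%04d", tg, seq_len(n_a + n_n)),
        sprintf("%s-S%04d", tg, seq_len(n_a + n_n)),
        c(rep("A", n_a), rep("N", n_n)))
  }
  r <- rbind(mk("OK", 100, 100), mk("FEW_A", 99, 5000), mk("FEW_N", 500, 99))
  sel <- select_targets(r, cfg)
  expect_equal(names(sel$datasets), "OK")
  expect_setequal(sel$excluded$target, c("FEW_A", "FEW_N"))
  expect_equal(sel$excluded$reason[sel$excluded$target == "FEW_A"],
               "too few actives")
  expect_equal(sel$excluded$n_active[sel$excluded$target == "FEW_A"], 99)

  empty <- select_targets(r[0, ], cfg)
  expect_length(empty$datasets, 0)
})

test_that("assumed-non-active augmentation follows the 1:2 arithmetic", {
  cfg <- prep_config(canonical = FALSE, seed = 9)
  mk_ds <- function(n_a, n_n) {
    target_dataset("T1", data.frame(
      smiles = sprintf("T1-S%04d", seq_len(n_a + n_n)),
      activity = c(rep("A", n_a), rep("N", n_n)),
      assumed = FALSE, entry_id = sprintf("e%04d", seq_len(n_a + n_n)),
      stringsAsFactors = FALSE))
  }
  pool <- rec(rep("TX", 2000), sprintf("p%04d", 1:2000),
              sprintf("P-S%04d", 1:2000), rep("N", 2000))

  ds <- add_assumed_nonactives(mk_ds(197, 110), pool, cfg)
  expect_equal(sum(ds$records$assumed), 284)           # ceil(2*197) - 110
  expect_equal(sum(ds$records$activity == "N"), 394)
  expect_true(all(ds$records$activity[ds$records$assumed] == "N"))

  # already at ratio -> no additions
  ds0 <- add_assumed_nonactives(mk_ds(100, 200), pool, cfg)
  expect_equal(sum(ds0$records$assumed), 0)

  # same seed -> identical sample
  ds2 <- add_assumed_nonactives(mk_ds(197, 110), pool, cfg)
  expect_identical(ds$records, ds2$records)

  # compounds active for the target are ineligible; short pools warn
  pool2 <- rbind(rec("T1", "a1", "ACT1", "A"),
                 rec("TX", sprintf("p%d", 1:5), sprintf("P-S%d", 1:5), "N"),
                 rec("T1", "a2", "ACT1", "A"))
  expect_warning(ds3 <- add_assumed_nonactives(mk_ds(10, 2), pool2, cfg),
                 "eligible")
  expect_equal(sum(ds3$records$assumed), 5)
  expect_false("ACT1" %in% ds3$records$smiles)
})

test_that("external holdout partitions records exactly", {
  r <- rec(rep("T1", 10), sprintf("e%02d", 1:10), sprintf("S%02d", 1:10),
           rep(c("A", "N"), 5))
  sp <- withhold_external(r, c("e03", "e07"))
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$external), 2)
  expect_equal(nrow(sp$train) + nrow(sp$external), nrow(r))
  expect_length(intersect(sp$train$entry_id, sp$external$entry_id), 0)

  expect_equal(nrow(withhold_external(r, character())$train), 10)
  expect_equal(nrow(withhold_external(r, r$entry_id)$external), 10)
  expect_warning(withhold_external(r, c("e01", "nope")), "match no record")
  # smiles key
  sp2 <- withhold_external(r, c("S01"), key = "smiles")
  expect_equal(sp2$external$smiles, "S01")
})

test_that("row order does not change set-level results", {
  set.seed(8)
  r <- rec(sample(c("T1", "T2"), 80, TRUE), sprintf("e%02d", 1:80),
           sample(sprintf("S%02d", 1:12), 80, TRUE),
           sample(c("A", "N"), 80, TRUE))
  shuf <- r[sample(nrow(r)), ]
  key <- function(d) sort(paste(d$target, d$smiles, d$activity))
  expect_identical(key(remove_conflicts(r, canonical = FALSE)),
                   key(remove_conflicts(shuf, canonical = FALSE)))
  a <- deduplicate(remove_conflicts(r, canonical = FALSE), canonical = FALSE)
  b <- deduplicate(remove_conflicts(shuf, canonical = FALSE), canonical = FALSE)
  expect_identical(key(a), key(b))
})

test_that("activity tables load in chunks with malformed rows skipped", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "acts.tsv")
  writeLines(c("target\tentry_id\tsmiles\tactivity",
               "T1\te1\tCCO\tA",
               "T1\te2\tCCN\tN",
               "T2\te3\tCCC\tA",
               "T2\te4\tCCCC\tN"), f)
  r <- load_activity_records(f)
  expect_equal(nrow(r), 4)
  expect_equal(r$activity, c("A", "N", "A", "N"))

  writeLines(c("target\tentry_id\tsmiles\tactivity",
               "T1\te1\tCCO\tA", "T1\te2\tCCN\tX",
               "T1\te3\tCCC\tA", "badline"), f)
  expect_warning(r <- load_activity_records(f), "skipped")
  expect_equal(nrow(r), 2)

  writeLines(character(), f)
  expect_warning(r <- load_activity_records(f), "empty")
  expect_equal(nrow(r), 0)

  writeLines(c("a\tb", "1\t2"), f)
  expect_error(load_activity_records(f), "missing column")

  # gzip-transparent, custom column names, tiny chunks
  fz <- file.path(tmp, "acts.tsv.gz")
  con <- gzfile(fz, "w")
  writeLines(c("gene\tid\tstructure\tflag", "T1\te1\tCCO\tA",
               "T1\te2\tCCN\tN"), con)
  close(con)
  r <- load_activity_records(fz, column_map = list(
    target = "gene", entry_id = "id", smiles = "structure",
    activity = "flag"), chunk_size = 1L)
  expect_equal(nrow(r), 2)
  expect_equal(r$target, c("T1", "T1"))
})
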