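
mk_split_ds <- function(n_a, n_n, n_assumed = 0) {
  n <- n_a + n_n + n_assumed
  target_dataset("T1", data.frame(
    smiles = sprintf("S%04d", seq_len(n)),
    activity = c(rep("A", n_a), rep("N", n_n + n_assumed)),
    assumed = c(rep(FALSE, n_a + n_n), rep(TRUE, n_assumed)),
    entry_id = sprintf("e%04d", seq_len(n)), stringsAsFactors = FALSE))
}

test_that("proper/calibration splits are stratified and exclude assumed records", {
  ds <- mk_split_ds(100, 100, 50)
  cfg <- split_config(calibration_fraction = 0.2, n_icp = 3, seed = 2)
  sp <- split_proper_calibration(ds, cfg, 1)
  r <- ds$records
  expect_equal(sum(r$activity[sp$calibration] == "A"), 20)
  expect_equal(sum(r$activity[sp$calibration] == "N"), 20)
  expect_equal(sum(r$assumed[sp$calibration]), 0)
  expect_true(all(which(r$assumed) %in% sp$proper))
  expect_setequal(c(sp$proper, sp$calibration), seq_len(nrow(r)))

  # different ICP index: same sizes, different membership, reproducible
  sp2 <- split_proper_calibration(ds, cfg, 2)
  expect_equal(length(sp2$calibration), length(sp$calibration))
  expect_false(identical(sp$calibration, sp2$calibration))
  expect_identical(split_proper_calibration(ds, cfg, 1), sp)

  sp5 <- split_proper_calibration(mk_split_ds(10, 10),
                                  split_config(0.5, 1, 1), 1)
  expect_equal(length(sp5$calibration), 10)

  expect_error(split_proper_calibration(mk_split_ds(1, 10), cfg, 1),
               "cannot calibrate")
})

test_that("nonconformity is the class-oriented signed distance", {
  expect_equal(nonconformity(3, "A"), -3)
  expect_equal(nonconformity(3, "N"), 3)
  expect_equal(nonconformity(0, "A"), 0)
  expect_equal(nonconformity(c(1, -2), c("A", "N")), c(-1, -2))
})

test_that("p-values follow the (#\\{>=\\} + 1)/(n + 1) rank rule", {
  cal <- sort(c(-4, -3, -2, -1, 0, 1, 2, 3, 4))
  expect_equal(pvalue(10, cal), 1 / 10)           # stranger than all
  expect_equal(pvalue(-10, cal), 1)               # more conforming than all
  expect_equal(pvalue(0, cal), 0.6)               # ties counted with >=
  expect_equal(pvalue(c(10, -10), cal), c(0.1, 1))
  # smoothed p-values stay within (0, 1] and average below the ties rule
  set.seed(1)
  ps <- pvalue(rep(0, 2000), cal, smoothed = TRUE)
  expect_true(all(ps > 0 & ps <= 1))
  expect_lt(mean(ps), 0.6)
  expect_error(pvalue(0, numeric()))
})

test_that("the fitted linear decision function matches the solver oracle", {
  set.seed(7)
  x <- Matrix::Matrix(rbind(matrix(rnorm(60, 2), 15), matrix(rnorm(60, -2), 15)),
                      sparse = TRUE)
  y <- rep(c("A", "N"), each = 15)
  ic <- cpligand:::.fit_icp(x, y, x, y, cost = 1)
  # decision values recomputed from stored weights equal predict()'s
  fit <- e1071::svm(x, factor(y, levels = c("A", "N")), kernel = "linear",
                    cost = 1, scale = FALSE)
  d_or <- drop(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
  d_my <- as.numeric(x %*% ic$w + ic$b)
  expect_equal(abs(d_my), abs(unname(d_or)), tolerance = 1e-8)
  # orientation: actives on the positive side of a separable problem
  expect_true(all(d_my[y == "A"] > 0))
  # separable data: true-class calibration nonconformity is negative
  expect_true(all(ic$calib_A < 0) && all(ic$calib_N < 0))
  expect_error(cpligand:::.fit_icp(x, rep("A", 30), x, y, 1), "degenerate")
})

test_that("ACP aggregation combines per-ICP p-values by the mean", {
  # two hand-built ICPs over a one-signature dictionary, query "C"
  dict <- build_dictionary(list(featurize("C", signature_config(1))))
  mk_icp <- function(b) list(w = 0, b = b, calib_A = sort(c(-2, -1, 0, 1)),
                             calib_N = sort(c(-2, -1, 0, 1)))
  base <- list(target = "T", icps = list(mk_icp(0.5)), dictionary = dict,
               train_config = train_config(heights = signature_config(1)),
               split_config = split_config(n_icp = 1), version = "0")
  m1 <- structure(base, class = "acp_model")
  # d = 0.5: alpha_A = -0.5 -> 2 of 4 scores >= -0.5 -> p_A = 3/5
  #          alpha_N = +0.5 -> 1 of 4 scores >= +0.5 -> p_N = 2/5
  p1 <- acp_predict(m1, "C")
  expect_equal(p1$p_A, 0.6)
  expect_equal(p1$p_N, 0.4)

  # second ICP shifts d to 1.5: alpha_A = -1.5 -> 3 scores >= -> p_A = 4/5
  m2 <- m1; m2$icps <- list(mk_icp(0.5), mk_icp(1.5))
  p2 <- acp_predict(m2, "C")
  expect_equal(p2$p_A, mean(c(0.6, 0.8)))
  expect_equal(p2$p_N, mean(c(0.4, 0.2)))
  # aggregate lies within the per-ICP range
  expect_true(p2$p_A >= 0.6 && p2$p_A <= 0.8)

  m3 <- m2; m3$train_config$aggregation <- "median"
  p3 <- acp_predict(m3, "C")
  expect_equal(p3$p_A, median(c(0.6, 0.8)))
})

test_that("trained ACPs are deterministic and their sets nest", {
  ds <- make_toy_dataset(30, 30, noise = 0.05, seed = 21)
  m1 <- acp_train(ds, train_config(cost = 1), split_config(n_icp = 3, seed = 5))
  m2 <- acp_train(ds, train_config(cost = 1), split_config(n_icp = 3, seed = 5))
  q <- c("CCCC(=O)O", "CCCCCN", "CCc1ccccc1")
  expect_identical(acp_predict(m1, q), acp_predict(m2, q))

  p <- acp_predict(m1, q)
  eps <- seq(0.05, 0.95, by = 0.05)
  sets <- vapply(eps, function(e) prediction_sets(p, e), character(length(q)))
  size <- apply(sets, 2, function(s) match(s, c("Null", "A", "N", "Both")) > 2)
  # each molecule's set can only shrink as significance grows
  for (i in seq_along(q)) {
    sz <- vapply(seq_along(eps), function(k)
      switch(sets[i, k], Both = 2L, Null = 0L, 1L), integer(1))
    expect_true(all(diff(sz) <= 0))
  }
  expect_equal(prediction_confidence(p), 1 - pmin(p$p_A, p$p_N))
})

test_that("model archives round-trip bit-identically", {
  ds <- make_toy_dataset(25, 25, seed = 31)
  model <- acp_train(ds, train_config(cost = 10),
                     split_config(n_icp = 2, seed = 4))
  q <- c("CCCC(=O)O", "CCCCc1ccccc1")
  before <- acp_predict(model, q)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "model.acp.json")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(acp_predict(back, q), before)
  expect_equal(length(back$icps),
               jsonlite::read_json(f)$manifest$n_icp)

  # truncated archive and non-archives fail loudly
  txt <- readLines(f)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), f)
  expect_error(load_model(f))
  f2 <- file.path(tmp, "other.json")
  jsonlite::write_json(list(a = 1), f2, auto_unbox = TRUE)
  expect_error(load_model(f2), "not a cpligand model archive")
})
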