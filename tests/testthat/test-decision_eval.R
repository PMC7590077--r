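# Decision hierarchy, majority voting, metrics, threshold sweep.

test_that("the decision hierarchy reproduces the hand-enumerated truth table", {
  cfg <- decision_config(20)
  knn_ok <- function(conc) list(status = "ok", predicted_conc = conc,
                                predicted_identity = "cocaine HCl")
  knn_nm <- list(status = "no_match", predicted_conc = NA_real_,
                 predicted_identity = NA_character_)
  cases <- list(
    # kNN returned a result: submodel B is ignored entirely
    list(knn_ok(35), "base", 55, "positive", "knn"),
    list(knn_ok(35), "unassigned", NA, "positive", "knn"),
    list(knn_ok(20), "base", 55, "negative", "knn"),   # equal to threshold
    list(knn_ok(20), "unassigned", NA, "negative", "knn"),
    list(knn_ok(5), "hcl", 90, "negative", "knn"),
    list(knn_ok(5), "unassigned", NA, "negative", "knn"),
    # kNN abstained: positive only if a form is assigned AND conc > threshold
    list(knn_nm, "hcl", 55, "positive", "ann_treebag"),
    list(knn_nm, "base", 21, "positive", "ann_treebag"),
    list(knn_nm, "hcl", 20, "negative", "ann_treebag"), # equal to threshold
    list(knn_nm, "base", 5, "negative", "ann_treebag"),
    list(knn_nm, "unassigned", NA, "negative", "ann_treebag"),
    list(knn_nm, "unassigned", 99, "negative", "ann_treebag")
  )
  for (cs in cases) {
    v <- decide_spectrum(cs[[1]], b_form = cs[[2]], b_conc = cs[[3]], config = cfg)
    expect_identical(v$result, cs[[4]])
    expect_identical(v$decided_by, cs[[5]])
  }
})

test_that("sample majority voting follows strict majority with negative ties", {
  mk <- function(results) data.frame(result = results, decided_by = "knn",
                                     predicted_identity = "cocaine HCl",
                                     stringsAsFactors = FALSE)
  # the 2-positive / 3-negative split resolves negative
  sv <- decide_sample(mk(c("positive", "positive", "negative", "negative", "negative")))
  expect_identical(sv$result, "negative")
  expect_equal(c(sv$n_positive, sv$n_negative), c(2L, 3L))
  expect_identical(decide_sample(mk(rep("positive", 5)))$result, "positive")
  # even split is a tie -> negative
  expect_identical(decide_sample(mk(c("positive", "positive",
                                      "negative", "negative")))$result, "negative")
  empty <- data.frame(result = character(0), decided_by = character(0),
                      predicted_identity = character(0),
                      stringsAsFactors = FALSE)
  expect_error(decide_sample(empty), "at least one")
  # flipping one verdict changes the outcome only when the margin is <= 1
  expect_identical(decide_sample(mk(c("positive", "positive", "positive",
                                      "negative", "negative")))$result, "positive")
})

test_that("confusion counts match an independent tally", {
  set.seed(42)
  n <- 60
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     identity = "x",
                     cocaine_form = sample(c("hcl", "base", "none"), n, TRUE),
                     cocaine_wt_pct = 0, set_tag = "A",
                     stringsAsFactors = FALSE)
  meta$cocaine_wt_pct[meta$cocaine_form != "none"] <-
    stats::runif(sum(meta$cocaine_form != "none"), 1, 100)
  verdicts <- data.frame(sample_id = meta$sample_id,
                         result = sample(c("positive", "negative"), n, TRUE),
                         stringsAsFactors = FALSE)
  rep <- confusion_report(verdicts, meta, decision_config(20), level = "sample")
  # brute-force tally
  truth_pos <- meta$cocaine_form != "none" & meta$cocaine_wt_pct > 20
  sub <- meta$cocaine_form != "none" & meta$cocaine_wt_pct <= 20
  pred_pos <- verdicts$result == "positive"
  expect_equal(rep$counts[["tp"]], sum(!sub & truth_pos & pred_pos))
  expect_equal(rep$counts[["fn"]], sum(!sub & truth_pos & !pred_pos))
  expect_equal(rep$counts[["tn"]], sum(!sub & !truth_pos & !pred_pos))
  expect_equal(rep$counts[["fp"]], sum(!sub & !truth_pos & pred_pos))
  expect_equal(rep$n_excluded, sum(sub))
  expect_equal(rep$rates[["tp_rate"]],
               100 * rep$counts[["tp"]] / (rep$counts[["tp"]] + rep$counts[["fn"]]))
  # ten correct positives + ten correct negatives give 100/100
  meta2 <- data.frame(sample_id = sprintf("t%02d", 1:20), identity = "x",
                      cocaine_form = rep(c("hcl", "none"), each = 10),
                      cocaine_wt_pct = rep(c(80, 0), each = 10), set_tag = "A",
                      stringsAsFactors = FALSE)
  verdicts2 <- data.frame(sample_id = meta2$sample_id,
                          result = rep(c("positive", "negative"), each = 10),
                          stringsAsFactors = FALSE)
  rep2 <- confusion_report(verdicts2, meta2, decision_config(20))
  expect_equal(rep2$rates[["tp_rate"]], 100)
  expect_equal(rep2$rates[["tn_rate"]], 100)
  # one FP among ten true negatives -> fp_rate 10
  verdicts2$result[11] <- "positive"
  rep3 <- confusion_report(verdicts2, meta2, decision_config(20))
  expect_equal(rep3$rates[["fp_rate"]], 10)
})

test_that("concentration fit metrics match hand-computed values", {
  expect_equal(concentration_fit_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(r_squared = 1, rmse = 0, n_used = 3L, n_dropped = 0L))
  m <- concentration_fit_metrics(c(11, 22, 33) + 3 - 3, c(8, 19, 30) + 3)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0)
  shifted <- concentration_fit_metrics(c(10, 20, 30, 40), c(7, 17, 27, 37))
  expect_equal(shifted$r_squared, 1)
  expect_equal(shifted$rmse, 3)
  # 5-pair example frozen from an independent spreadsheet-style calculation:
  # pred = (52, 38, 71, 15, 90), known = (50, 40, 75, 10, 95)
  # squared errors (4, 4, 16, 25, 25) -> mse 14.8; r^2 = 0.99559898
  m5 <- concentration_fit_metrics(c(52, 38, 71, 15, 90), c(50, 40, 75, 10, 95))
  expect_equal(m5$rmse, sqrt(14.8))
  expect_equal(m5$r_squared, 0.9955990, tolerance = 1e-6)
  # missing predictions are dropped and counted
  md <- concentration_fit_metrics(c(1, NA, 3, 4), c(1, 2, 3, 5))
  expect_equal(md$n_dropped, 1L)
  expect_equal(md$n_used, 3L)
  expect_error(concentration_fit_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(concentration_fit_metrics(1:3, 1:2), "equal length")
})

test_that("threshold sweep rates are monotone and operating points are reported", {
  set.seed(9)
  n <- 200
  meta <- data.frame(sample_id = sprintf("s%03d", 1:n), identity = "x",
                     cocaine_form = rep(c("hcl", "none"), each = n / 2),
                     cocaine_wt_pct = c(stats::runif(n / 2, 25, 95), rep(0, n / 2)),
                     set_tag = "A", stringsAsFactors = FALSE)
  verdicts <- data.frame(
    sample_id = meta$sample_id,
    knn_status = sample(c("ok", "no_match"), n, TRUE),
    knn_conc = pmin(100, pmax(0, meta$cocaine_wt_pct + stats::rnorm(n, 0, 8))),
    b_form = sample(c("hcl", "base", "unassigned"), n, TRUE),
    b_conc = pmin(100, pmax(0, meta$cocaine_wt_pct + stats::rnorm(n, 0, 15))),
    stringsAsFactors = FALSE)
  cur <- threshold_curve(verdicts, meta, thresholds = 0:100)
  expect_true(all(diff(cur$tp_rate) <= 1e-9))
  expect_true(all(diff(cur$fp_rate) <= 1e-9))
  # threshold 100: nothing exceeds 100
  expect_equal(cur$tp_rate[cur$threshold == 100], 0)
  expect_false(is.na(attr(cur, "max_accuracy_threshold")))

  # perfect predictions attain (fp 0, tp 100) at some threshold
  perfect <- verdicts
  perfect$knn_status <- "ok"
  perfect$knn_conc <- meta$cocaine_wt_pct
  curp <- threshold_curve(perfect, meta, thresholds = 0:100)
  hit <- curp$fp_rate == 0 & curp$tp_rate == 100
  expect_true(any(hit))
  expect_false(is.na(attr(curp, "zero_fp_threshold")))
  expect_error(threshold_curve(verdicts, meta, thresholds = numeric(0)), "empty")
  expect_error(threshold_curve(verdicts, meta, thresholds = c(5, 5)), "increasing")
})

test_that("cross-validation handles degenerate toy libraries", {
  two_sample_library <- function(mat_a, mat_b) {
    mat <- rbind(mat_a, mat_b)
    meta <- data.frame(scan_id = sprintf("q%02d", seq_len(nrow(mat))),
                       sample_id = rep(c("s1", "s2"),
                                       c(nrow(mat_a), nrow(mat_b))),
                       scanner_id = "sc1", replicate = 1L,
                       stringsAsFactors = FALSE)
    smeta <- data.frame(sample_id = c("s1", "s2"),
                        identity = c("compoundA", "compoundB"),
                        cocaine_form = "none", cocaine_wt_pct = 0,
                        set_tag = "B", stringsAsFactors = FALSE)
    structure(list(matrix = mat, wavelengths = seq_len(ncol(mat)),
                   scan_meta = meta, sample_meta = smeta,
                   preprocess_tag = "test"),
              class = "nir_library")
  }
  set.seed(2)
  a <- matrix(stats::rnorm(10), 1, 10)[rep(1, 6), ] +
    matrix(stats::rnorm(60, sd = 0.01), 6, 10)
  b <- matrix(stats::rnorm(10), 1, 10)[rep(1, 6), ] +
    matrix(stats::rnorm(60, sd = 0.01), 6, 10)
  # two mutually distant, uncorrelated samples: every kNN query abstains
  res <- nirscreen:::knn_loso(two_sample_library(a, b), knn_config())
  expect_true(all(res$status == "no_match"))

  # a duplicated sample resolves the twin's scans as near-zero-distance
  # neighbours
  res2 <- nirscreen:::knn_loso(two_sample_library(a, a), knn_config())
  expect_true(all(res2$status == "ok"))
})
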