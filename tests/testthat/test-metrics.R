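test_that("confusion counts with experimental as positive class", {
  truth <- rep(c("experimental", "control"), each = 10)
  all_right <- confusion(truth, truth)
  expect_equal(unclass(all_right)[c("tp", "fn", "fp", "tn")],
               list(tp = 10L, fn = 0L, fp = 0L, tn = 10L))
  all_pos <- confusion(rep("experimental", 20), truth)
  expect_equal(all_pos$tp, 10L)
  expect_equal(all_pos$fp, 10L)
  expect_equal(all_pos$tn, 0L)
  expect_equal(all_pos$fn, 0L)
  # swapping prediction and truth transposes fp <-> fn
  pred <- c(rep("experimental", 7), rep("control", 13))
  a <- confusion(pred, truth)
  b <- confusion(truth, pred)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_equal(a$tp, b$tp)
  expect_error(confusion("experimental", c("a", "b")), "length")
  expect_error(confusion(c("old", "control"), c("control", "control")),
               "unknown group label")
})

test_that("metric_set reproduces hand-computed values on a worked matrix", {
  # tp=59 fn=1 fp=2 tn=46: p_o = 105/108, p_e = (61*60 + 47*48)/108^2
  m <- metric_set(confusion_counts(tp = 59, fn = 1, fp = 2, tn = 46))
  expect_equal(m[["accuracy"]], 105 / 108, tolerance = 1e-12)
  expect_equal(round(m[["accuracy"]], 4), 0.9722)
  expect_equal(round(m[["sensitivity"]], 4), 0.9833)
  expect_equal(round(m[["specificity"]], 4), 0.9583)
  expect_equal(round(m[["ppv"]], 4), 0.9672)
  expect_equal(round(m[["npv"]], 4), 0.9787)
  po <- 105 / 108
  pe <- (61 * 60 + 47 * 48) / 108^2
  expect_equal(m[["kappa"]], (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(round(m[["kappa"]], 4), 0.9436)
})

test_that("metric_set handles perfect, chance and degenerate matrices", {
  perfect <- metric_set(confusion_counts(12, 0, 0, 9))
  expect_equal(unname(unclass(perfect)[1:6]), rep(1, 6))
  chance <- metric_set(confusion_counts(25, 25, 25, 25))
  expect_equal(chance[["accuracy"]], 0.5)
  expect_equal(chance[["kappa"]], 0)
  # nothing predicted positive: ppv undefined, flagged not silently zero
  none_pos <- metric_set(confusion_counts(0, 10, 0, 10))
  expect_true(is.nan(none_pos[["ppv"]]))
  expect_true("ppv" %in% attr(none_pos, "undefined"))
  expect_error(confusion_counts(0, 0, 0, 0), "at least one")
  expect_error(confusion_counts(-1, 0, 0, 5), "non-negative")
})

test_that("kappa bounds and the accuracy cross-identity hold on random matrices", {
  set.seed(402)
  counts <- matrix(sample.int(60, 4 * 4000, replace = TRUE) - 1L, ncol = 4)
  counts <- counts[rowSums(counts) > 0, ]
  for (i in seq_len(nrow(counts))) {
    cm <- confusion_counts(counts[i, 1], counts[i, 2], counts[i, 3],
                           counts[i, 4])
    m <- metric_set(cm)
    k <- m[["kappa"]]
    if (!is.nan(k)) expect_true(k >= -1 - 1e-12 && k <= 1 + 1e-12)
    # accuracy = sensitivity * prevalence + specificity * (1 - prevalence)
    n <- sum(counts[i, ])
    prev <- (counts[i, 1] + counts[i, 2]) / n
    sens <- m[["sensitivity"]]
    spec <- m[["specificity"]]
    if (!is.nan(sens) && !is.nan(spec))
      expect_equal(m[["accuracy"]], sens * prev + spec * (1 - prev),
                   tolerance = 1e-12)
  }
})

test_that("kappa is 1 only for error-free matrices and near 0 for random predictions", {
  expect_equal(metric_set(confusion_counts(5, 0, 0, 7))[["kappa"]], 1)
  expect_lt(metric_set(confusion_counts(5, 1, 0, 7))[["kappa"]], 1)
  set.seed(71)
  ks <- replicate(400, {
    truth <- sample(c("control", "experimental"), 200, replace = TRUE)
    pred <- sample(c("control", "experimental"), 200, replace = TRUE)
    metric_set(confusion(pred, truth))[["kappa"]]
  })
  expect_lt(mean(abs(ks), na.rm = TRUE), 0.08)
  expect_lt(abs(mean(ks, na.rm = TRUE)), 0.05)
})

test_that("rank_models sorts ascending by kappa and filters on both thresholds", {
  df <- data.frame(
    model = c("M3", "M1", "M2", "M4"),
    epoch = c(10L, 15L, 20L, 10L),
    backend = "b", learner = "svm",
    accuracy = c(0.97, 0.99, 0.96, 0.94),
    sensitivity = 0.9, specificity = 0.9, ppv = 0.9, npv = 0.9,
    kappa = c(0.95, 0.88, 0.90, 0.99),
    stringsAsFactors = FALSE
  )
  ranked <- rank_models(df, min_accuracy = 0.95, min_kappa = 0.88)
  # M4 excluded on accuracy despite the best kappa; rest ascending by kappa
  expect_equal(ranked$model, c("M1", "M2", "M3"))
  expect_equal(ranked$kappa, c(0.88, 0.90, 0.95))
  # no row loss without filtering, ties broken by accuracy then model id
  all_rows <- rank_models(df, min_accuracy = -Inf, min_kappa = -Inf)
  expect_setequal(all_rows$model, df$model)
  tie <- df
  tie$kappa <- 0.9
  tie$accuracy <- c(0.97, 0.97, 0.96, 0.97)
  ranked_tie <- rank_models(tie, min_accuracy = -Inf, min_kappa = -Inf)
  expect_equal(ranked_tie$model, c("M2", "M1", "M3", "M4"))
  # empty result keeps the header
  empty <- rank_models(df, min_accuracy = 1.1, min_kappa = 0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("model", "epoch", "backend", "learner", "accuracy",
                        "sensitivity", "specificity", "ppv", "npv", "kappa"))
})

test_that("report export writes the tabular layout and radar block", {
  df <- data.frame(
    model = c("M1", "M2"), epoch = c(10L, 20L), backend = "b",
    learner = c("svm", "nb"),
    accuracy = c(0.98, 0.96), sensitivity = c(0.99, 0.95),
    specificity = c(0.95, 0.94), ppv = c(0.98, 0.97), npv = c(0.98, 0.92),
    kappa = c(0.95, 0.90), stringsAsFactors = FALSE
  )
  ranked <- rank_models(df, min_accuracy = -Inf, min_kappa = -Inf)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  radar <- tempfile(fileext = ".csv")
  export_report(ranked, csv, js, radar)
  header <- readLines(csv, n = 1)
  expect_equal(header,
               "Model,Epoch,CNN,Learner,Accuracy,Sensitivity,Specificity,PPV,NPV,Kappa")
  lines <- readLines(csv)
  expect_match(lines[2], "0\\.90$")  # ascending kappa, two decimals
  rd <- read.csv(radar)
  expect_equal(nrow(rd), 2 * 6)
  expect_setequal(unique(rd$metric),
                  c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "kappa"))
  payload <- jsonlite::read_json(js)
  expect_equal(length(payload$models), 2)
})
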