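test_that("stratified splits reproduce the study's test-set bookkeeping", {
  m <- jnp_manifest(
    path = sprintf("img%03d", 1:270),
    subject_id = rep(sprintf("S%02d", 1:45), each = 6),
    group = rep(c("control", "experimental"), c(120, 150)),
    session = rep(1:6, 45)
  )
  s60 <- split_dataset(m, 0.6, seed = 1)
  expect_equal(unname(s60$counts["test", "control"]), 48)
  expect_equal(unname(s60$counts["test", "experimental"]), 60)
  s70 <- split_dataset(m, 0.7, seed = 1)
  expect_equal(unname(s70$counts["test", "control"]), 36)
  expect_equal(unname(s70$counts["test", "experimental"]), 45)
  # disjoint and exhaustive
  expect_length(intersect(s60$train, s60$test), 0)
  expect_setequal(c(s60$train, s60$test), m$path)
  # deterministic given the seed, different across seeds
  expect_identical(split_dataset(m, 0.6, seed = 5)$test,
                   split_dataset(m, 0.6, seed = 5)$test)
  expect_false(identical(split_dataset(m, 0.6, seed = 5)$test,
                         split_dataset(m, 0.6, seed = 6)$test))
  expect_error(split_dataset(m, 1.2, seed = 1), "between 0 and 1")
})

test_that("the smallest stratified split leaves one unit per side and group", {
  m <- jnp_manifest(path = c("a", "b", "c", "d"),
                    subject_id = c("s1", "s2", "s3", "s4"),
                    group = rep(c("control", "experimental"), each = 2),
                    session = rep(1L, 4))
  s <- split_dataset(m, 0.5, seed = 3)
  expect_equal(sum(s$counts["train", ]), 2)
  expect_equal(sum(s$counts["test", ]), 2)
  expect_equal(unname(s$counts["test", ]), c(1, 1))
})

test_that("subject-level splitting keeps all sessions of a subject together", {
  sim <- simulate_dataset(4, 4, 3, seed = 2)
  s <- split_dataset(sim$manifest, 0.5, seed = 7, unit = "subject")
  test_subjects <- unique(sim$manifest$subject_id[sim$manifest$path %in%
                                                    s$test])
  train_subjects <- unique(sim$manifest$subject_id[sim$manifest$path %in%
                                                     s$train])
  expect_length(intersect(test_subjects, train_subjects), 0)
})

test_that("classifier wrappers behave on canonical toy geometries", {
  set.seed(10)
  # separable blobs 10 sd apart: svm reaches training accuracy 1
  x <- rbind(matrix(rnorm(40 * 3), ncol = 3),
             matrix(rnorm(40 * 3, mean = 10), ncol = 3))
  y <- rep(c("control", "experimental"), each = 40)
  sc <- jnposture:::fit_scaler(x)
  xs <- jnposture:::apply_scaler(sc, x)
  svm_fit <- train_classifier(xs, y, "svm")
  expect_equal(mean(predict(svm_fit, xs) == y), 1.0)
  # logistic regression on perfectly symmetric duplicated rows: p = 0.5
  xdup <- rbind(matrix(1:6, 2, 3, byrow = TRUE),
                matrix(1:6, 2, 3, byrow = TRUE))
  ydup <- c("control", "control", "experimental", "experimental")
  lr_fit <- train_classifier(xdup, ydup, "lr")
  expect_equal(predict(lr_fit, xdup[1, , drop = FALSE], type = "prob"),
               0.5, tolerance = 1e-6)
  # naive Bayes survives zero within-class variance columns
  xz <- cbind(rep(c(0, 1), each = 20), rnorm(40))
  yz <- rep(c("control", "experimental"), each = 20)
  nb_fit <- train_classifier(xz, yz, "nb")
  pred <- predict(nb_fit, xz)
  expect_true(all(pred %in% c("control", "experimental")))
  expect_gt(mean(pred == yz), 0.9)
  expect_error(train_classifier(xs, rep("control", 80), "svm"),
               "single class")
  xbad <- xs
  xbad[1, 1] <- NA
  expect_error(train_classifier(xbad, y, "svm"), "non-finite")
})

test_that("grid enumeration matches the published design counts", {
  paper <- enumerate_grid("paper")
  expect_length(paper, 90)
  slice60 <- Filter(function(s) s$train_fraction == 0.6, paper)
  expect_length(slice60, 45)
  expect_length(enumerate_grid("paper", train_fractions = 0.6), 45)
  # published ids: M29 = VGG16 + SVM, epoch 15, 60% block;
  # M90 = VGG19 + SVM, epoch 20, 70% block
  m29 <- paper[[29]]
  expect_equal(m29$backend$backbone_id, "vgg16")
  expect_equal(m29$classifier, "svm")
  expect_equal(m29$backend$epochs, 15)
  expect_equal(m29$train_fraction, 0.6)
  m90 <- paper[[90]]
  expect_equal(m90$backend$backbone_id, "vgg19")
  expect_equal(m90$classifier, "svm")
  expect_equal(m90$backend$epochs, 20)
  expect_equal(m90$train_fraction, 0.7)
  desk <- enumerate_grid("desk")
  expect_length(desk, 24)
  kinds <- vapply(desk, function(s) s$backend$kind, "")
  expect_equal(sum(kinds == "moments"), 6)
  expect_equal(sum(kinds == "scratch_cnn"), 18)
})

test_that("run_grid caches per split, stays reproducible and audits leakage", {
  co <- small_cohort(n_per_group = 5, sessions = 2, seed = 31)
  grid <- enumerate_grid("desk", train_fractions = 0.6, epochs = 10)
  fit1 <- run_grid(co$sim$manifest, co$images, grid, seed = 21)
  fit2 <- run_grid(co$sim$manifest, co$images, grid, seed = 21)
  expect_length(fit1$results, length(grid))
  expect_identical(as.data.frame(fit1), as.data.frame(fit2))
  df <- as.data.frame(fit1)
  expect_true(all(df$tp + df$fn + df$fp + df$tn ==
                    length(fit1$splits[["0.6"]]$test)))
  # the two classifier cells sharing a backend reuse one fitted backend
  moments_cells <- Filter(function(r) r$spec$backend$kind == "moments",
                          fit1$results)
  fps <- unique(vapply(moments_cells, `[[`, "", "backend_fingerprint"))
  expect_length(fps, 1)
  # leakage audit: no test id ever enters training, and the scaler is a
  # pure function of the training rows
  for (cell in fit1$results) {
    expect_length(intersect(cell$train_ids, cell$test_ids), 0)
    fx <- extract_features(cell$backend, co$images[cell$train_ids])
    expect_equal(cell$scaler$mean, jnposture:::fit_scaler(fx)$mean,
                 tolerance = 1e-12)
  }
})

test_that("backend fits are untouched by the content of held-out images", {
  co <- small_cohort(n_per_group = 3, sessions = 2, seed = 55)
  grid <- enumerate_grid("desk", train_fractions = 0.6, epochs = 10,
                         classifiers = "svm")
  fit1 <- run_grid(co$sim$manifest, co$images, grid, seed = 9)
  # corrupt every test image; training artefacts must not change
  images2 <- co$images
  blank <- array(as.raw(255L), dim = dim(images2[[1]]$pixels))
  for (id in fit1$splits[["0.6"]]$test) images2[[id]]$pixels <- blank
  fit2 <- run_grid(co$sim$manifest, images2, grid, seed = 9)
  for (nm in names(fit1$results)) {
    expect_identical(fit1$results[[nm]]$backend_fingerprint,
                     fit2$results[[nm]]$backend_fingerprint)
    expect_equal(fit1$results[[nm]]$scaler, fit2$results[[nm]]$scaler)
  }
})

test_that("cell failures are contained unless strict", {
  co <- small_cohort(n_per_group = 2, sessions = 1, seed = 61)
  grid <- c(enumerate_grid("desk", train_fractions = 0.6, epochs = 10,
                           classifiers = "svm")[1],
            enumerate_grid("paper", train_fractions = 0.6, epochs = 10,
                           classifiers = "svm")[1])
  grid[[2]]$model <- "broken"
  fit <- run_grid(co$sim$manifest, co$images, grid, seed = 2)
  expect_length(fit$results, 1)
  expect_named(fit$errors, "broken")
  expect_match(fit$errors$broken, "weights unavailable")
  expect_error(run_grid(co$sim$manifest, co$images, grid, seed = 2,
                        strict = TRUE), "weights unavailable")
})

test_that("jnp_grid methods expose results and predict labels for new images", {
  co <- small_cohort(n_per_group = 4, sessions = 2, seed = 77)
  grid <- enumerate_grid("desk", train_fractions = 0.6, epochs = 10,
                         classifiers = c("svm", "lr"))
  fit <- run_grid(co$sim$manifest, co$images, grid, seed = 13)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), length(grid))
  expect_true(all(c("accuracy", "kappa", "tp") %in% names(df)))
  s <- summary(fit, min_accuracy = -Inf, min_kappa = -Inf)
  expect_equal(nrow(s$ranked), nrow(df))
  expect_true(!is.unsorted(s$ranked$kappa))
  preds <- predict(fit, co$images[1:4])
  expect_length(preds, 4)
  expect_true(all(preds %in% c("control", "experimental")))
  expect_output(print(fit), "best by kappa")
})
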