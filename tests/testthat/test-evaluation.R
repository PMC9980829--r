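test_that("auroc agrees with O(n^2) pair counting, ties included", {
  set.seed(81)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    # discrete scores force ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    truths <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(truths)) < 2) truths[1:2] <- c(TRUE, FALSE)
    expect_equal(auroc(scores, truths), ref_auroc(scores, truths),
                 tolerance = 1e-9)
  }
})

test_that("auroc matches hand-computed values and boundary behavior", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)),
               0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)),
               1.0)
  set.seed(82)
  s <- runif(4000)
  y <- runif(4000) < 0.5
  expect_lt(abs(auroc(s, y) - 0.5), 0.05)
  expect_error(auroc(1:5, rep(TRUE, 5)), class = "mucran_value_error")
})

test_that("auroc is invariant to strictly monotone score transforms", {
  set.seed(83)
  s <- rnorm(200)
  y <- runif(200) < plogis(s)
  a <- auroc(s, y)
  expect_equal(auroc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auroc(qnorm(rank(s) / 201), y), a, tolerance = 1e-12)
})

fake_preds <- function(schema, averaged, ids = NULL) {
  lab <- apply(averaged[seq_along(schema$label_categories), , drop = FALSE],
               2, which.max)
  structure(list(per_model = list(averaged), averaged = averaged,
                 label_confidence = apply(averaged[1:2, , drop = FALSE], 2,
                                          max),
                 predicted_label = schema$label_categories[lab],
                 sample_ids = ids, schema = schema),
            class = "ensemble_prediction")
}

test_that("confound predictability reads the averaged confound rows", {
  set.seed(84)
  n <- 400
  md <- data.frame(label = sample(c("case", "control"), n, TRUE),
                   site = sample(c("a", "b"), n, TRUE),
                   age = runif(n, 55, 95))
  md$site[1:2] <- c("a", "b")  # pin first-seen category order
  sch <- tiny_schema(md, n_bins = 2)
  W <- sch$row_width
  avg <- matrix(0, 3 * W, n)
  avg[1, ] <- 0.5; avg[2, ] <- 0.5
  # site row: informative scores; age row: pure noise
  p_site <- ifelse(md$site == "a", 0.9, 0.1) + rnorm(n, sd = 0.05)
  p_site <- pmin(pmax(p_site, 0.01), 0.99)
  avg[W + 1, ] <- p_site
  avg[W + 2, ] <- 1 - p_site
  p_age <- runif(n)
  avg[2 * W + 1, ] <- p_age
  avg[2 * W + 2, ] <- 1 - p_age
  rep <- confound_predictability(fake_preds(sch, avg), metadata = md)
  expect_gt(rep$auroc[rep$confound == "site"], 0.9)
  expect_lt(abs(rep$auroc[rep$confound == "age"] - 0.5), 0.1)
  # a confound with a single observed category is skipped with a warning
  md2 <- md
  md2$site <- "a"
  expect_warning(r2 <- confound_predictability(fake_preds(sch, avg),
                                               metadata = md2),
                 "skipped")
  expect_false("site" %in% r2$confound)
})

test_that("age matching pairs to the smaller group above the threshold", {
  set.seed(85)
  md <- data.frame(label = c(rep("case", 30), rep("control", 50)),
                   age = c(runif(30, 70, 95), runif(50, 56, 80)))
  ms <- age_matched_sample(md, age_min = 55, seed = 1,
                           positive_class = "case")
  expect_length(ms$rows, 60)
  expect_equal(unname(ms$group_sizes), c(30, 30))
  expect_true(all(md$age[ms$rows] >= 55))
  lab <- md$label[ms$rows]
  expect_equal(sum(lab == "case"), sum(lab == "control"))
  # matching shrinks the between-group age difference
  pre <- abs(mean(md$age[md$label == "case"]) -
               mean(md$age[md$label == "control"]))
  post <- abs(mean(md$age[ms$pairs$pos_row]) -
                mean(md$age[ms$pairs$neg_row]))
  expect_lt(post, pre)
  # deterministic given the seed
  expect_identical(age_matched_sample(md, seed = 1,
                                      positive_class = "case")$rows,
                   ms$rows)
})

test_that("identical age distributions match with zero gap", {
  ages <- runif(25, 60, 90)
  md <- data.frame(label = rep(c("case", "control"), each = 25),
                   age = c(ages, ages))
  ms <- age_matched_sample(md, seed = 2, positive_class = "case")
  expect_equal(max(ms$pairs$age_gap), 0)
  expect_length(ms$rows, 50)
  md2 <- data.frame(label = rep("case", 10), age = runif(10, 60, 90))
  expect_error(age_matched_sample(md2, positive_class = "case"),
               class = "mucran_value_error")
})

test_that("stratified accuracy reports mirror the accuracy (n) layout", {
  set.seed(86)
  n <- 120
  md <- data.frame(label = sample(c("case", "control"), n, TRUE),
                   age = runif(n, 50, 95))
  sch <- tiny_schema(cbind(md, site = sample(c("a", "b"), n, TRUE)),
                     n_bins = 2)
  conf <- runif(n, 0.5, 1)
  preds <- structure(list(label_confidence = conf,
                          predicted_label = md$label,
                          schema = sch),
                     class = "ensemble_prediction")
  rep <- stratified_accuracy_report(preds, md$label, md)
  all_05 <- rep[rep$subset == "all" & rep$tau == 0.5, ]
  all_09 <- rep[rep$subset == "all" & rep$tau == 0.9, ]
  expect_equal(all_05$n_kept, n)
  expect_lte(all_09$n_kept, all_05$n_kept)
  # predictions equal the truth -> every cell shows perfect accuracy
  expect_true(all(rep$accuracy == 1, na.rm = TRUE))
  am <- rep[rep$subset == "age_matched", ]
  expect_true(all(am$n_subset < n))
  lines <- format_accuracy_table(rep)
  expect_length(lines, nrow(rep))
  expect_match(lines[1], "100.0%")
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(87)
  s <- c(rnorm(60), rnorm(60, 1))
  y <- rep(c(FALSE, TRUE), each = 60)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})
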