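test_that("categorical confounds enumerate observed categories in order", {
  md <- data.frame(label = c("case", "control", "case", "control"),
                   sex = c("M", "F", "M", "F"))
  sch <- build_schema(md, "label", list("sex"), positive_class = "case")
  expect_identical(sch$confounds$sex$categories, c("M", "F"))
  expect_identical(sch$label_categories, c("case", "control"))
  expect_equal(sch$row_width, 2)
})

test_that("positive class is placed at index 1 regardless of table order", {
  md <- data.frame(label = c("control", "case"), site = c("a", "b"))
  sch <- build_schema(md, "label", list("site"), positive_class = "case")
  expect_identical(sch$label_categories[1], "case")
})

test_that("continuous confounds are quantile-binned on the training split", {
  set.seed(11)
  ages <- runif(400, 55, 95)
  md <- data.frame(label = rep(c("case", "control"), 200), age = ages,
                   split = rep(c("train", "test"), each = 200))
  sch <- build_schema(md, "label",
                      list(list(name = "age", kind = "binned_continuous",
                                n_bins = 4)),
                      positive_class = "case")
  expected <- unname(quantile(ages[md$split == "train"], c(.25, .5, .75)))
  expect_equal(sch$confounds$age$bin_edges, expected)
  expect_length(sch$confounds$age$categories, 4)
})

test_that("single-valued confounds are rejected", {
  md <- data.frame(label = c("case", "control"), site = c("a", "a"),
                   age = c(60, 60))
  expect_error(build_schema(md, "label", list("site")),
               class = "mucran_config_error")
  expect_error(build_schema(md, "label",
                            list(list(name = "age",
                                      kind = "binned_continuous"))),
               class = "mucran_config_error")
  expect_error(build_schema(md, "label", list("nope")),
               class = "mucran_config_error")
})

test_that("true targets are one-hot at the observed categories", {
  md <- data.frame(label = c("case", "control"), sex = c("M", "F"),
                   age = c(60, 90))
  sch <- build_schema(md, "label",
                      list("sex", list(name = "age",
                                       kind = "binned_continuous",
                                       n_bins = 2)),
                      positive_class = "case")
  ta <- encode_true_targets(md[1, ], sch)
  expect_equal(ta$values[1, ], c(1, 0))
  expect_equal(ta$values["sex", ], c(1, 0))
  # age 60 falls below the single quantile edge -> first bin
  expect_equal(which(ta$values["age", ] == 1),
               findInterval(60, sch$confounds$age$bin_edges) + 1L)
  # determinism: same record, same array
  expect_identical(ta, encode_true_targets(md[1, ], sch))
  # values outside the schema are encoding errors
  bad <- md[1, ]
  bad$sex <- "X"
  expect_error(encode_true_targets(bad, sch),
               class = "mucran_encoding_error")
})

test_that("adversarial targets keep the label row and erase confounds", {
  md <- data.frame(label = c("case", "control", "case"),
                   sex = c("M", "F", "F"), age = c(60, 90, 85))
  sch <- build_schema(md, "label",
                      list("sex", list(name = "age",
                                       kind = "binned_continuous",
                                       n_bins = 2)),
                      positive_class = "case")
  a1 <- encode_adversarial_targets(md[1, ], sch)
  a3 <- encode_adversarial_targets(md[3, ], sch)
  # every confound row is the constant [1, 0, ..., 0]
  for (r in 2:3) expect_equal(a1$values[r, ], c(1, 0))
  # records differing only in confounds encode identically
  expect_identical(a1$values, a3$values)
  # label row agrees with the true encoding for every record
  for (i in 1:3) {
    expect_identical(encode_true_targets(md[i, ], sch)$values[1, ],
                     encode_adversarial_targets(md[i, ], sch)$values[1, ])
  }
  a2 <- encode_adversarial_targets(md[2, ], sch)
  expect_equal(which(a2$values[1, ] == 1), 2L)
})

test_that("random records always satisfy the target-array invariants", {
  set.seed(21)
  md <- data.frame(label = sample(c("case", "control"), 200, TRUE),
                   site = sample(c("a", "b", "c"), 200, TRUE),
                   age = runif(200, 40, 100))
  sch <- build_schema(md, "label",
                      list("site", list(name = "age",
                                        kind = "binned_continuous",
                                        n_bins = 4)),
                      positive_class = "case")
  for (i in sample(200, 25)) {
    for (enc in list(encode_true_targets, encode_adversarial_targets)) {
      ta <- enc(md[i, ], sch)
      expect_true(all(ta$values[ta$mask == 0] == 0))
      expect_equal(unname(rowSums(ta$values * ta$mask)),
                   rep(1, nrow(ta$values)))
    }
  }
  # binning is a partition: every age maps to exactly one bin
  idx <- findInterval(md$age, sch$confounds$age$bin_edges) + 1L
  expect_true(all(idx >= 1 & idx <= 4))
})

test_that("missing confound values get a dedicated category", {
  md <- data.frame(label = c("case", "control", "case"),
                   site = c("a", "b", NA))
  sch <- build_schema(md, "label", list("site"), positive_class = "case")
  expect_true("(missing)" %in% sch$confounds$site$categories)
  ta <- encode_true_targets(md[3, ], sch)
  expect_equal(which(ta$values["site", ] == 1),
               match("(missing)", sch$confounds$site$categories))
})

test_that("schemas survive a YAML round trip", {
  md <- data.frame(label = c("case", "control"), site = c("a", "b"),
                   age = c(60, 90))
  sch <- build_schema(md, "label",
                      list("site", list(name = "age",
                                        kind = "binned_continuous",
                                        n_bins = 2)),
                      positive_class = "case")
  f <- tempfile(fileext = ".yaml")
  schema_to_yaml(sch, f)
  sch2 <- schema_from_yaml(f)
  expect_equal(sch2$label_categories, sch$label_categories)
  expect_equal(sch2$confounds$age$bin_edges, sch$confounds$age$bin_edges)
  expect_equal(sch2$row_width, sch$row_width)
  md2 <- md[1, ]
  expect_identical(encode_true_targets(md2, sch)$values,
                   encode_true_targets(md2, sch2)$values)
})
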