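make_pred <- function(values, mask, schema) {
  structure(list(values = values, mask = mask, schema = schema),
            class = "prediction_array")
}

test_that("uniform predictions on 2-category rows give -log(1/2)", {
  md <- data.frame(label = c("case", "control"), site = c("a", "b"))
  sch <- build_schema(md, "label", list("site"), positive_class = "case")
  mask <- mucran:::schema_mask(sch)
  pred <- make_pred(matrix(0.5, 2, 2), mask, sch)
  target <- encode_true_targets(md[1, ], sch)
  expect_equal(weighted_row_bce(pred, target, loss_weights(W = 1)),
               -log(0.5), tolerance = 1e-9)
})

test_that("weighted_row_bce matches the brute-force oracle", {
  for (s in 1:200) {
    cs <- random_loss_case(s)
    got <- weighted_row_bce(cs$pred, cs$target, loss_weights(W = cs$W))
    want <- ref_weighted_bce(cs$pred$values, cs$target$values, cs$mask,
                             cs$W)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("with W = 1 and full masks the loss is plain mean BCE", {
  md <- data.frame(label = rep(c("case", "control"), 3),
                   site = rep(c("a", "b"), 3))
  sch <- build_schema(md, "label", list("site"), positive_class = "case")
  mask <- mucran:::schema_mask(sch)
  set.seed(31)
  vals <- matrix(runif(4), 2, 2)
  pred <- make_pred(vals, mask, sch)
  target <- encode_true_targets(md[2, ], sch)
  plain <- mean(-(target$values * log(vals) +
                    (1 - target$values) * log(1 - vals)))
  expect_equal(weighted_row_bce(pred, target, loss_weights(W = 1)), plain,
               tolerance = 1e-6)
})

test_that("the label row carries W times the weight of a confound row", {
  md <- data.frame(label = c("case", "control"), site = c("a", "b"))
  sch <- build_schema(md, "label", list("site"), positive_class = "case")
  mask <- mucran:::schema_mask(sch)
  target <- encode_true_targets(md[1, ], sch)
  w6 <- loss_weights(W = 6)
  base <- matrix(0.5, 2, 2)
  bump_label <- base; bump_label[1, 1] <- 0.4
  bump_conf <- base; bump_conf[2, 1] <- 0.4
  d_label <- weighted_row_bce(make_pred(bump_label, mask, sch), target, w6) -
    weighted_row_bce(make_pred(base, mask, sch), target, w6)
  d_conf <- weighted_row_bce(make_pred(bump_conf, mask, sch), target, w6) -
    weighted_row_bce(make_pred(base, mask, sch), target, w6)
  expect_equal(d_label / d_conf, 6, tolerance = 1e-6)
})

test_that("perfect predictions give (clipped-)zero loss and it is minimal", {
  cs <- random_loss_case(77)
  perfect <- make_pred(cs$target$values, cs$mask, cs$schema)
  l0 <- weighted_row_bce(perfect, cs$target, loss_weights(W = cs$W))
  expect_lt(l0, 1e-5)
  expect_gte(l0, 0)
  # moving any valid entry towards its target never increases the loss
  set.seed(78)
  for (r in 1:15) {
    cs2 <- random_loss_case(200 + r)
    w <- loss_weights(W = cs2$W)
    l1 <- weighted_row_bce(cs2$pred, cs2$target, w)
    valid <- which(cs2$mask == 1)
    j <- sample(valid, 1)
    v2 <- cs2$pred$values
    v2[j] <- v2[j] + 0.5 * (cs2$target$values[j] - v2[j])
    l2 <- weighted_row_bce(make_pred(v2, cs2$mask, cs2$schema), cs2$target,
                           w)
    expect_lte(l2, l1 + 1e-12)
  }
})

test_that("encoder loss ignores the record's confound values", {
  md <- data.frame(label = c("case", "case", "control"),
                   site = c("a", "b", "a"), age = c(58, 92, 60))
  sch <- build_schema(md, "label",
                      list("site", list(name = "age",
                                        kind = "binned_continuous",
                                        n_bins = 2)),
                      positive_class = "case")
  mask <- mucran:::schema_mask(sch)
  set.seed(41)
  pred <- make_pred(matrix(runif(6), 3, 2) * mask, mask, sch)
  expect_identical(encoder_loss(pred, md[1, ], sch),
                   encoder_loss(pred, md[2, ], sch))
  expect_equal(encoder_loss(pred, md[1, ], sch),
               weighted_row_bce(pred, encode_adversarial_targets(md[1, ],
                                                                 sch)))
})

test_that("a confound-erasing predictor beats a truthful one on the encoder
           loss, and the regressor loss prefers the truth", {
  md <- data.frame(label = "case", site = "b", age = 90)
  md_all <- data.frame(label = c("case", "control"), site = c("a", "b"),
                       age = c(58, 90))
  sch <- build_schema(md_all, "label",
                      list("site", list(name = "age",
                                        kind = "binned_continuous",
                                        n_bins = 2)),
                      positive_class = "case")
  mask <- mucran:::schema_mask(sch)
  soft <- function(v) 0.02 + 0.96 * v
  g_pred <- make_pred(soft(encode_adversarial_targets(md, sch)$values) *
                        mask, mask, sch)
  true_pred <- make_pred(soft(encode_true_targets(md, sch)$values) * mask,
                         mask, sch)
  expect_lt(encoder_loss(g_pred, md, sch), encoder_loss(true_pred, md, sch))
  expect_lt(regressor_loss(true_pred, md, sch),
            regressor_loss(g_pred, md, sch))
  # when all confounds sit in category 0 the two losses coincide
  md0 <- data.frame(label = "case", site = "a", age = 58)
  set.seed(43)
  p <- make_pred(matrix(runif(6), 3, 2) * mask, mask, sch)
  expect_identical(encoder_loss(p, md0, sch), regressor_loss(p, md0, sch))
})

test_that("invalid loss inputs are rejected", {
  cs <- random_loss_case(99)
  bad <- cs$pred
  bad$values[1, 1] <- NaN
  expect_error(weighted_row_bce(bad, cs$target), class = "mucran_value_error")
  expect_error(loss_weights(W = 0), class = "mucran_config_error")
  expect_error(loss_weights(epsilon = 0.7), class = "mucran_config_error")
  cs2 <- random_loss_case(2)  # different geometry with high probability
  if (!identical(dim(cs2$mask), dim(cs$mask))) {
    expect_error(weighted_row_bce(cs$pred, cs2$target),
                 class = "mucran_geometry_error")
  }
})
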