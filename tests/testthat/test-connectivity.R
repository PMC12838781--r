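test_that("truncated-normal sampling is exact rejection within the range", {
  set.seed(1)
  x <- sample_truncated_normal(10000, 0.7, 1.0)
  expect_true(all(x >= 0.7 & x <= 1.0))
  expect_equal(mean(x), 0.85, tolerance = 0.01)
  neg <- sample_truncated_normal(500, -0.8, -0.4)
  expect_true(all(neg >= -0.8 & neg <= -0.4))
  expect_length(sample_truncated_normal(0, 0, 1), 0L)
  expect_error(sample_truncated_normal(5, 0, 1, sigma = 0), "sigma")
  expect_error(sample_truncated_normal(5, 1, 0), "lower < upper")
})

test_that("weight matrices honour the cell-class layout and ranges", {
  spec <- network_condition("ql10_inh")
  wm <- build_weight_matrix(spec, seed = 11)
  b <- rep(1:3, c(2, 5, 3))
  within <- outer(b, b, "==")
  expect_equal(sum(wm$classes == "strong"), 10L)          # the diagonal
  expect_true(all(diag(wm$classes) == "strong"))
  expect_equal(sum(wm$classes %in% c("strong", "negligible")), sum(within))
  expect_equal(sum(wm$classes == "inhibitory"), sum(!within))
  for (nm in names(spec$classes)) {
    idx <- wm$classes == nm
    cl <- spec$classes[[nm]]
    expect_true(all(wm$values[idx] >= cl$lower & wm$values[idx] <= cl$upper))
  }
  # determinism: same seed, same spec -> identical matrices
  expect_identical(wm$values, build_weight_matrix(spec, seed = 11)$values)
  expect_false(identical(wm$values, build_weight_matrix(spec, seed = 12)$values))
})

test_that("class ranges hold across random specs (property)", {
  set.seed(33)
  for (i in 1:20) {
    name <- sample(c("ql5_exc", "ql5_inh", "diag5_exc", "diag5_inh",
                     "ql10_inh", "diag10", "broken10"), 1)
    spec <- network_condition(name)
    wm <- build_weight_matrix(spec, seed = sample.int(1e6, 1))
    for (nm in names(spec$classes)) {
      idx <- wm$classes == nm
      if (!any(idx)) next
      cl <- spec$classes[[nm]]
      expect_true(all(wm$values[idx] >= cl$lower & wm$values[idx] <= cl$upper),
                  label = sprintf("%s/%s in range", name, nm))
    }
  }
})

test_that("diagonal conditions put strong weights only on the diagonal", {
  wm <- build_weight_matrix(network_condition("diag5_exc"), seed = 3)
  expect_equal(sum(wm$classes == "strong"), 5L)
  expect_true(all(diag(wm$classes) == "strong"))
  wm10 <- build_weight_matrix(network_condition("diag10"), seed = 3)
  off <- wm10$values[!diag(10)]
  expect_true(all(off == 0))                      # eliminated, not negligible
})

test_that("break_background permutes the background and preserves counts", {
  wm <- build_weight_matrix(network_condition("ql10_inh"), seed = 21)
  set.seed(99)
  br <- break_background(wm)
  strong <- wm$classes == "strong"
  expect_identical(br$values[strong], wm$values[strong])
  expect_identical(br$classes[strong], wm$classes[strong])
  expect_equal(sort(br$values), sort(wm$values))  # multiset conserved
  expect_equal(table(br$classes), table(wm$classes))
  expect_error(break_background(build_weight_matrix(network_condition("diag10"),
                                                    seed = 1)),
               "quantum-logic")
  # the broken preset is the quantum-logic draw plus an internal permutation
  brp <- build_weight_matrix(network_condition("broken10"), seed = 21)
  expect_equal(sort(brp$values[!strong]), sort(wm$values[!strong]))
  expect_identical(brp$values[strong][order(which(strong))],
                   wm$values[strong][order(which(strong))])
})

test_that("scaling multiplies values and leaves classes untouched", {
  wm <- build_weight_matrix(network_condition("ql5_exc"), seed = 2)
  w2 <- scale_weights(wm, 2)
  expect_equal(as.matrix(w2), 2 * wm$values)
  expect_identical(w2$classes, wm$classes)
  expect_equal(as.matrix(scale_weights(wm, 1)), wm$values)
  expect_error(scale_weights(wm, -1), "W must be > 0")
})

test_that("weight matrices round-trip through CSV + JSON exactly", {
  wm <- scale_weights(build_weight_matrix(network_condition("ql5_inh"),
                                          seed = 77), 2)
  tmp <- tempfile(fileext = ".csv")
  write_weight_matrix(wm, tmp)
  back <- read_weight_matrix(tmp)
  expect_identical(back$values, wm$values)
  expect_equal(back$scale, 2)
  expect_identical(back$classes, wm$classes)
  unlink(c(tmp, paste0(tmp, ".json")))
})

test_that("symmetric sampling mirrors the upper triangle", {
  spec <- network_condition("ql10_inh")
  wm <- build_weight_matrix(spec, seed = 5, symmetric = TRUE)
  expect_identical(wm$values, t(wm$values))
})
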