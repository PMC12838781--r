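test_that("entropy matches hand-computed and degenerate cases", {
  expect_equal(entropy_plugin(rep(3L, 100)), 0)
  expect_equal(entropy_plugin(rep(0:31, 10)), 5)
  # counts {0:3, 1:1}: -(3/4 log2 3/4 + 1/4 log2 1/4)
  expect_equal(entropy_plugin(c(0L, 0L, 0L, 1L)), 0.811278124459133,
               tolerance = 1e-12)
  expect_error(entropy_plugin(integer(0)), "empty")
  expect_error(entropy_plugin(c(-1L, 0L)), "non-negative")
})

test_that("mutual information matches closed forms and the summation oracle", {
  x <- rep(0:3, 25)
  expect_equal(mutual_information(x, x), 2)
  set.seed(5)
  y <- sample(0:3, 100, replace = TRUE)
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  # a single flipped symbol in an otherwise identical pair of series
  y2 <- x; y2[1] <- (x[1] + 1L) %% 4L
  expect_equal(mutual_information(x, y2), oracle_mi(x, y2), tolerance = 1e-12)
  expect_error(mutual_information(x, y[1:10]), "lengths differ")
})

test_that("estimators equal direct-summation oracles on random series (property)", {
  set.seed(99)
  for (ka in 2:4) for (kb in 2:4) {
    for (rep in 1:3) {
      n <- sample(30:80, 1)
      a <- sample(0:(ka - 1), n, replace = TRUE)
      b <- sample(0:(kb - 1), n, replace = TRUE)
      expect_equal(entropy_plugin(a), oracle_entropy(a), tolerance = 1e-10)
      expect_equal(mutual_information(a, b), oracle_mi(a, b), tolerance = 1e-10)
      expect_equal(transfer_entropy(a, b), oracle_te(a, b), tolerance = 1e-10)
      expect_gte(mutual_information(a, b), -1e-12)
      expect_lte(mutual_information(a, b),
                 min(entropy_plugin(a), entropy_plugin(b)) + 1e-9)
      expect_gte(transfer_entropy(a, b), -1e-12)
    }
  }
})

test_that("temporal MI resolves deterministic cycles exactly", {
  expect_equal(temporal_mi(c(rep(c(0L, 1L), 50), 0L)), 1)
  expect_equal(temporal_mi(c(rep(0:3, 25), 0L)), 2)
  expect_error(temporal_mi(1L), "two time steps")
  # i.i.d. symbols leave only the plugin bias, consistent with a shuffle
  set.seed(8)
  z <- sample(0:7, 5000, replace = TRUE)
  zs <- sample(z)
  expect_equal(temporal_mi(z), temporal_mi(zs), tolerance = 0.01)
  expect_lt(temporal_mi(z), 0.05)
})

test_that("transfer entropy detects a copied source and ignores a constant one", {
  set.seed(13)
  a <- sample(0:1, 4000, replace = TRUE)
  b <- c(0L, a[-4000])               # target copies the source with lag 1
  expect_equal(transfer_entropy(a, b), 1, tolerance = 0.01)
  expect_equal(transfer_entropy(rep(2L, 100), b[1:100]), 0)
  # shuffled source keeps only the plugin bias, not exactly zero
  ash <- sample(a)
  te_sh <- transfer_entropy(ash, b)
  expect_lt(te_sh, 0.01)
  expect_gt(te_sh, 0)
})

test_that("noise scans are deterministic and well-shaped", {
  spec <- network_condition("ql5_exc")
  sc <- noise_scan(spec, W = 1, grid = c(0, 1, 2), trials = 2, steps = 400,
                   seed = 6)
  expect_s3_class(sc, "scan_result")
  expect_equal(nrow(sc$data), 2 * 3 * 2)  # trials x grid x observables
  expect_true(all(sc$summary$sd >= 0))
  sc2 <- noise_scan(spec, W = 1, grid = c(0, 1, 2), trials = 2, steps = 400,
                    seed = 6)
  expect_identical(sc$data, sc2$data)
  # subsystem and TE observables ride on the same simulation
  sc3 <- noise_scan(network_condition("ql10_inh"), W = 1, grid = c(1),
                    trials = 2, steps = 400,
                    subsystems = list(A = 1:5, B = 6:10), te = c("A", "B"),
                    seed = 6)
  expect_setequal(unique(sc3$data$observable),
                  c("H_global", "MI_global", "H_A", "MI_A", "H_B", "MI_B",
                    "TE_A_B"))
  expect_error(noise_scan(spec, trials = 0), "trials")
})

test_that("peak finding takes the argmax with ties toward smaller noise", {
  sc <- list(summary = data.frame(r = c(0, 1, 2),
                                  observable = "MI_global",
                                  mean = c(0.1, 0.9, 0.4), sd = c(0, 0, 0)))
  class(sc) <- "scan_result"
  pk <- find_peak(sc)
  expect_equal(pk$r, 1)
  expect_equal(pk$value, 0.9)
  flat <- list(summary = data.frame(r = c(0, 1, 2), observable = "MI_global",
                                    mean = c(0.5, 0.5, 0.5), sd = c(0, 0, 0)))
  class(flat) <- "scan_result"
  expect_equal(find_peak(flat)$r, 0)
  expect_error(find_peak(sc, "TE_A_B"), "not present")
})

test_that("scan export writes tidy tables", {
  sc <- noise_scan(network_condition("ql5_exc"), grid = c(0, 1), trials = 2,
                   steps = 300, seed = 1)
  tmp <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  write_scan(sc, tmp, tmp2)
  long <- read.csv(tmp)
  expect_setequal(names(long),
                  c("condition", "W", "r", "trial", "observable", "value"))
  expect_equal(nrow(read.csv(tmp2)), nrow(sc$summary))
  unlink(c(tmp, tmp2))
})
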