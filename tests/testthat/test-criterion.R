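test_that("expected information matches trivial and derived cases", {
  expect_equal(expected_information(class_distribution(c(10, 0))), 0)
  expect_equal(expected_information(class_distribution(c(5, 5))), 1)
  # frozen from the brute-force oracle: oracle_entropy(c(9, 5))
  expect_equal(expected_information(class_distribution(c(9, 5))),
               0.9402859587, tolerance = 1e-9)
  expect_error(expected_information(class_distribution(c(0, 0))), "empty")
})

test_that("class_distribution validates its invariants", {
  d <- class_distribution(c(a = 3, b = 1))
  expect_equal(sum(d$probs), 1)
  expect_equal(d$probs, c(0.75, 0.25))
  expect_error(class_distribution(numeric(0)), "at least one")
  expect_error(class_distribution(c(-1, 2)), "non-negative")
  expect_error(class_distribution(c(1, 1), probs = c(0.9, 0.3)), "sum to 1")
})

test_that("conditional entropy matches trivial and derived cases", {
  pure <- attribute_partition(matrix(c(4, 0, 0, 7), 2), attribute = "a")
  expect_equal(conditional_entropy(pure), 0)
  single <- attribute_partition(matrix(c(9, 5), ncol = 1), attribute = "a")
  expect_equal(conditional_entropy(single),
               expected_information(class_distribution(c(9, 5))))
  part <- attribute_partition(matrix(c(3, 1, 6, 4), 2), attribute = "a")
  # frozen from oracle_conditional_entropy(cbind(c(3,1), c(6,4)))
  expect_equal(conditional_entropy(part), 0.9253298887, tolerance = 1e-9)
  expect_error(attribute_partition(matrix(c(3, 1, 0, 0), 2)), "empty subset")
})

test_that("information gain matches examples and rejects mismatched totals", {
  d <- class_distribution(c(9, 5))
  part <- attribute_partition(matrix(c(3, 1, 6, 4), 2))
  expect_equal(information_gain(d, part), 0.014956069929, tolerance = 1e-9)
  pure <- attribute_partition(matrix(c(9, 0, 0, 5), 2))
  expect_equal(information_gain(d, pure), expected_information(d))
  prop <- attribute_partition(matrix(c(4.5, 2.5, 4.5, 2.5), 2))
  expect_equal(information_gain(d, prop), 0, tolerance = 1e-12)
  expect_error(information_gain(class_distribution(c(9, 6)), part),
               "do not match")
})

test_that("split information and gain ratio behave per contract", {
  one <- attribute_partition(matrix(c(9, 5), ncol = 1))
  expect_equal(split_information(one), 0)
  halves <- attribute_partition(matrix(c(3, 4, 3, 4), 2))
  expect_equal(split_information(halves), 1)
  part <- attribute_partition(matrix(c(3, 1, 6, 4), 2))
  expect_equal(split_information(part), 0.8631205686, tolerance = 1e-9)
  expect_equal(gain_ratio(0.0149560699, 0.8631205686), 0.0173279035,
               tolerance = 1e-8)
  expect_equal(gain_ratio(0, 0.5), 0)
  expect_true(is.na(gain_ratio(0.2, 0)))
  expect_error(gain_ratio(0.2, -1), "non-negative")
})

test_that("cost matrices validate and load from JSON config", {
  expect_error(cost_matrix(matrix(c(1, 1, 1, 0), 2), labels = c("a", "b")),
               "diagonal")
  expect_error(cost_matrix(matrix(c(0, -1, 1, 0), 2), labels = c("a", "b")),
               "non-negative")
  cfg <- list(a = list(b = 9))
  cm <- load_cost_matrix(cfg, labels = c("a", "b", "c"))
  expect_equal(cm$costs["a", "b"], 9)
  expect_equal(cm$costs["b", "a"], 1)   # omitted cells default to 1
  expect_equal(diag(cm$costs), c(a = 0, b = 0, c = 0))
  expect_equal(cost_totals(cm), c(a = 10, b = 2, c = 2))
  expect_error(load_cost_matrix(list(a = list(a = 3))), "diagonal")
  expect_error(load_cost_matrix(list(a = list(b = -2))), "non-negative")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"a": {"b": 4}, "b": {"a": 2}}', path)
  expect_equal(load_cost_matrix(path)$costs["a", "b"], 4)
})

test_that("class weights implement the cost normalization", {
  d <- class_distribution(c(a = 90, b = 10))
  cw <- cost_matrix(matrix(c(0, 1, 9, 0), 2, byrow = TRUE),
                    labels = c("a", "b"))
  w <- class_weights(cw, d)
  expect_equal(unclass(w), c(a = 5 / 9, b = 5), tolerance = 1e-12)
  expect_equal(sum(w * d$counts), d$total)              # Sum w(i) n_i = n
  # uniform off-diagonal costs -> all weights 1
  wu <- class_weights(uniform_cost_matrix(c("a", "b"), 3), d)
  expect_equal(unclass(wu), c(a = 1, b = 1))
  d1 <- class_distribution(c(a = 7))
  expect_error(class_weights(uniform_cost_matrix(c("a"), 1), d1),
               "all-zero")  # single class has C(i) = 0
  expect_error(class_weights(cw, class_distribution(c(a = 1, b = 1, z = 1))),
               "missing")
})

test_that("weighted class distribution follows the weight normalization", {
  d <- class_distribution(c(a = 90, b = 10))
  expect_equal(weighted_class_distribution(d, c(1, 1))$probs, d$probs)
  wd <- weighted_class_distribution(d, c(5 / 9, 5))
  expect_equal(wd$probs, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(expected_information(wd), 1, tolerance = 1e-12)
  expect_error(weighted_class_distribution(d, c(0, 0)), "zero total")
})

test_that("property: entropy bounds and non-negative gain over random cases", {
  for (seed in 1:60) {
    withr::with_seed(seed, {
      m <- sample(2:4, 1)
      v <- sample(2:4, 1)
      cmat <- matrix(rpois(m * v, 3), nrow = m)
      cmat[, colSums(cmat) == 0] <- cmat[, colSums(cmat) == 0] + 1
      counts <- rowSums(cmat)
      d <- class_distribution(counts)
      if (d$total > 0) {
        h <- expected_information(d)
        expect_gte(h, 0)
        expect_lte(h, log2(m) + 1e-12)
        part <- attribute_partition(cmat)
        expect_gte(information_gain(d, part), -1e-9)
      }
    })
  }
})

test_that("property: refining a partition never increases conditional entropy", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      m <- sample(2:3, 1)
      cmat <- matrix(rpois(m * 2, 4) + 1, nrow = m)
      # refine by splitting column 1 into two random parts
      a <- vapply(cmat[, 1], function(r) sample(0:r, 1), numeric(1))
      b <- cmat[, 1] - a
      if (sum(a) > 0 && sum(b) > 0) {
        coarse <- attribute_partition(cmat)
        fine <- attribute_partition(cbind(a, b, cmat[, 2]))
        expect_lte(conditional_entropy(fine),
                   conditional_entropy(coarse) + 1e-9)
      }
    })
  }
})

test_that("property: uniform costs reduce every weighted quantity to unweighted", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      m <- sample(2:4, 1)
      counts <- rpois(m, 5) + 1
      labels <- letters[seq_len(m)]
      d <- class_distribution(counts, labels = labels)
      cmat <- uniform_cost_matrix(labels, cost = runif(1, 0.1, 10))
      w <- class_weights(cmat, d)
      expect_equal(unclass(w), setNames(rep(1, m), labels), tolerance = 1e-12)
      wd <- weighted_class_distribution(d, w)
      expect_equal(wd$probs, d$probs, tolerance = 1e-12)
      part <- attribute_partition(cbind(pmax(counts - 1, 0) + 1, counts))
      expect_equal(conditional_entropy(part, weights = w),
                   conditional_entropy(part), tolerance = 1e-12)
      expect_equal(information_gain(
        class_distribution(rowSums(cbind(pmax(counts - 1, 0) + 1, counts)),
                           labels = labels),
        part, weights = w),
        information_gain(
          class_distribution(rowSums(cbind(pmax(counts - 1, 0) + 1, counts)),
                             labels = labels),
          part),
        tolerance = 1e-12)
    })
  }
})

test_that("oracle equivalence on a sampled sweep of small distributions", {
  # exhaustive sweep lives in the acceptance suite; spot-check here
  for (total in c(3, 7, 11)) {
    for (counts in enumerate_distributions(2, total)) {
      if (sum(counts) == 0) next
      expect_equal(expected_information(class_distribution(counts)),
                   oracle_entropy(counts), tolerance = 1e-12)
    }
  }
  withr::with_seed(7, {
    for (i in 1:25) {
      counts <- rpois(3, 3) + c(1, 0, 0)
      splits <- enumerate_binary_splits(counts)
      if (length(splits) == 0) next
      s <- splits[[sample.int(length(splits), 1)]]
      d <- class_distribution(counts)
      part <- attribute_partition(s)
      expect_equal(information_gain(d, part), oracle_gain(counts, s),
                   tolerance = 1e-12)
      gr <- oracle_gain_ratio(counts, s)
      pkg_gr <- gain_ratio(information_gain(d, part),
                           split_information(part))
      if (is.na(gr)) expect_true(is.na(pkg_gr))
      else expect_equal(pkg_gr, gr, tolerance = 1e-12)
    }
  })
})
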