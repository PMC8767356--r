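four_records <- function() {
  fit_dataset(data.frame(x = c(14, 15, 19, 21), y = c("a", "a", "b", "b")),
              c(x = "continuous"), "y")
}

test_that("candidate thresholds apply the boundary-point reduction", {
  expect_equal(candidate_thresholds(c(1, 1, 1), c("a", "b", "a")), numeric(0))
  expect_equal(candidate_thresholds(c(14, 15, 19, 21), c("a", "a", "b", "b")),
               17)
  # all adjacent pairs differ in class -> all midpoints survive
  expect_equal(candidate_thresholds(c(1, 2, 3, 4), c("a", "b", "a", "b")),
               c(1.5, 2.5, 3.5))
  # midpoint interior to a single-class run is dropped
  expect_equal(candidate_thresholds(c(1, 2, 3, 4), c("a", "a", "b", "b")),
               2.5)
  # mixed-class value group keeps both adjacent midpoints
  expect_equal(candidate_thresholds(c(1, 2, 2, 3), c("a", "a", "b", "a")),
               c(1.5, 2.5))
})

test_that("best_split finds the exhaustive-search optimum", {
  ds <- four_records()
  sp <- best_split(ds)
  expect_equal(sp$attribute, "x")
  expect_equal(sp$threshold, 17)
  expect_equal(sp$gain, 1)
  expect_equal(sp$gain_ratio, 1)
  pure <- fit_dataset(data.frame(x = c(1, 2, 3), y = c("a", "a", "a")),
                      c(x = "continuous"), "y")
  expect_null(best_split(pure))
})

test_that("fit_dataset validates declarations and missing values", {
  df <- data.frame(x = c(1, NA), y = c("a", "b"))
  expect_error(fit_dataset(df, c(x = "continuous"), "y"), "missing values")
  expect_error(fit_dataset(df, c(x = "fuzzy"), "y"), "unknown attribute kind")
  expect_error(fit_dataset(df, c(z = "continuous"), "y"), "not in data")
  expect_error(fit_dataset(df, c(x = "categorical"), "w"), "not in data")
})

test_that("build_tree handles purity, XOR, and training consistency", {
  pure <- fit_dataset(data.frame(x = c(1, 2), y = c("a", "a")),
                      c(x = "continuous"), "y")
  tp <- build_tree(pure)
  expect_equal(tp$root$type, "leaf")
  expect_equal(predict(tp, data.frame(x = 99)), "a")

  # XOR: every first split has zero gain, yet the tree must reach depth 2
  # and fit the 4 records exactly
  xor_df <- data.frame(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1),
                       y = c("a", "b", "b", "a"))
  ds <- fit_dataset(xor_df, c(x1 = "continuous", x2 = "continuous"), "y")
  tr <- build_tree(ds)
  expect_equal(predict(tr, xor_df), xor_df$y)
  depth <- function(node) {
    if (node$type == "leaf") 0L
    else 1L + max(vapply(node$children, depth, integer(1)))
  }
  expect_equal(depth(tr$root), 2L)

  # consistency property on random label-consistent fixtures
  for (seed in c(2, 5, 9)) {
    df <- random_fixture(n = 60, seed = seed)
    df <- df[!duplicated(df[, c("x", "g")]), ]  # enforce label consistency
    ds <- fit_dataset(df, c(x = "continuous", g = "categorical"), "y")
    tr <- build_tree(ds)
    expect_equal(predict(tr, df), df$y)
  }
})

test_that("stopping controls cap growth", {
  df <- random_fixture(n = 50, seed = 3)
  ds <- fit_dataset(df, c(x = "continuous", g = "categorical"), "y")
  stump <- build_tree(ds, induction_config(max_depth = 1))
  expect_equal(stump$root$type, "leaf")
  depth <- function(node) {
    if (node$type == "leaf") 1L
    else 1L + max(vapply(node$children, depth, integer(1)))
  }
  t2 <- build_tree(ds, induction_config(max_depth = 3))
  expect_lte(depth(t2$root), 3L)
  big_leaf <- build_tree(ds, induction_config(min_samples_to_split = 1000))
  expect_equal(big_leaf$root$type, "leaf")
  expect_error(induction_config(min_samples_to_split = 1), ">= 2")
  expect_error(build_tree(fit_dataset(data.frame(x = numeric(0),
                                                 y = character(0)),
                                      c(x = "continuous"), "y")),
               "empty dataset")
})

test_that("prediction conventions: boundary, unseen values, missing attributes", {
  ds <- four_records()
  tr <- build_tree(ds)
  expect_equal(predict(tr, data.frame(x = 17)), "a")     # <= goes left
  expect_equal(predict(tr, data.frame(x = 17.0001)), "b")
  expect_error(predict(tr, data.frame(z = 1)), "missing tested attribute")

  df <- data.frame(g = c("p", "p", "q", "q", "q"),
                   y = c("a", "a", "b", "b", "b"))
  tg <- build_tree(fit_dataset(df, c(g = "categorical"), "y"))
  expect_warning(out <- predict(tg, data.frame(g = "zz")), "unseen value")
  expect_equal(out, "b")  # majority branch has 3 records
})

test_that("serialization round-trips and rejects corrupted documents", {
  df <- random_fixture(n = 40, seed = 11)
  ds <- fit_dataset(df, c(x = "continuous", g = "categorical"), "y")
  tr <- build_tree(ds, induction_config(min_samples_to_split = 5))
  json <- serialize_tree(tr)
  tr2 <- deserialize_tree(json)
  expect_equal(predict(tr2, df), predict(tr, df))
  expect_equal(serialize_tree(tr2), json)      # byte-stable re-serialization
  path <- withr::local_tempfile(fileext = ".json")
  serialize_tree(tr, path)
  expect_equal(predict(deserialize_tree(path), df), predict(tr, df))

  # hand-written one-split document
  doc <- '{
    "version": "fittree-1",
    "attributes": {"x": "continuous"},
    "classes": ["a", "b"],
    "config": {"min_samples_to_split": 2, "max_depth": "unlimited",
               "cost_sensitive": false, "tie_tol": 1e-9},
    "root": {"type": "internal", "attribute": "x", "kind": "continuous",
             "threshold": 5,
             "children": [
               {"type": "leaf", "label": "a", "counts": {"a": 2, "b": 0},
                "probs": {"a": 1, "b": 0}},
               {"type": "leaf", "label": "b", "counts": {"a": 0, "b": 2},
                "probs": {"a": 0, "b": 1}}]}
  }'
  th <- deserialize_tree(doc)
  expect_equal(predict(th, data.frame(x = c(4, 6))), c("a", "b"))

  bad <- sub('"threshold": 5,', "", doc, fixed = TRUE)
  expect_error(deserialize_tree(bad), "threshold.*root", perl = TRUE)
  expect_error(deserialize_tree('{"version": "zzz"}'), "version")
  expect_error(deserialize_tree("{not json"), "invalid JSON")
})

test_that("induction is deterministic", {
  df <- random_fixture(n = 80, seed = 21)
  ds <- fit_dataset(df, c(x = "continuous", g = "categorical"), "y")
  t1 <- build_tree(ds, induction_config(min_samples_to_split = 4))
  t2 <- build_tree(ds, induction_config(min_samples_to_split = 4))
  expect_identical(serialize_tree(t1), serialize_tree(t2))
})

test_that("uniform costs give a tree identical to the standard criterion", {
  for (seed in 1:12) {
    df <- random_fixture(n = 45, seed = seed)
    ds <- fit_dataset(df, c(x = "continuous", g = "categorical"), "y")
    costs <- uniform_cost_matrix(ds$classes, cost = 2.5)
    t_std <- build_tree(ds)
    t_cs <- build_tree(ds, induction_config(cost_sensitive = TRUE),
                       costs = costs)
    t_cs$config$cost_sensitive <- FALSE   # only the flag may differ
    t_cs["weights"] <- list(NULL)
    expect_identical(serialize_tree(t_cs), serialize_tree(t_std),
                     info = paste("seed", seed))
  }
})
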