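#' Confusion matrix
#'
#' Exact cross-tabulation of true against predicted labels; rows are indexed
#' by the true class.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predictions, same length.
#' @param labels Optional full label set; labels outside it are an error.
#' @return An object of class `confusion_matrix` (a counts matrix with a
#'   `labels` attribute).
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ")
  }
  if (length(truth) == 0L) stop("cannot tabulate zero records")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(labels)) {
    labels <- sort(union(truth, predicted))
  } else {
    unknown <- setdiff(union(truth, predicted), labels)
    if (length(unknown) > 0) {
      stop("unknown label(s): ", paste(unknown, collapse = ", "))
    }
  }
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  m <- matrix(as.integer(cm), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix"), labels = labels)
}

#' Cost strata of the classes
#'
#' Partitions classes into `high` / `general` / `low` misclassification-cost
#' strata by the rank of their row-sum cost \eqn{C(i)}: the distinct `C(i)`
#' values are ranked and spread evenly over the three strata, so the
#' cheapest classes land in `low` and the dearest in `high`. When all
#' `C(i)` are equal no stratification is possible and every class falls in
#' `general` (each stratum rate then equals the total rate). An explicit
#' `mapping` (named vector class -> stratum) overrides the default.
#'
#' @param costs A [cost_matrix()].
#' @param mapping Optional named character vector with values in
#'   `c("high", "general", "low")`.
#' @return Named character vector class -> stratum.
#' @export
cost_strata <- function(costs, mapping = NULL) {
  stopifnot(inherits(costs, "cost_matrix"))
  if (!is.null(mapping)) {
    bad <- setdiff(mapping, c("high", "general", "low"))
    if (length(bad) > 0) stop("unknown stratum name(s): ",
                              paste(bad, collapse = ", "))
    missing_lab <- setdiff(costs$labels, names(mapping))
    if (length(missing_lab) > 0) {
      stop("mapping misses class(es): ", paste(missing_lab, collapse = ", "))
    }
    return(mapping[costs$labels])
  }
  C <- cost_totals(costs)
  if (diff(range(C)) < 1e-12) {
    return(stats::setNames(rep("general", length(C)), names(C)))
  }
  # rank the distinct C(i) values and interpolate the ranks onto the three
  # strata: the cheapest distinct cost is "low", the dearest "high"
  vals <- sort(unique(C))
  grp <- round(1 + 2 * (match(C, vals) - 1) / (length(vals) - 1))
  stats::setNames(c("low", "general", "high")[grp], names(C))
}

#' Cost-stratified error rates
#'
#' Computes the total error rate and, for each misclassification-cost stratum
#' of the classes (see [cost_strata()]), the error rate among records whose
#' TRUE class belongs to that stratum: 100 x misclassified-in-stratum /
#' records-in-stratum. Strata with zero records report a rate of 0 and are
#' flagged.
#'
#' @param cm A [confusion_matrix()].
#' @param costs A [cost_matrix()] covering all labels of `cm`.
#' @param role Dataset role, `"modeling data"` or `"test data"`.
#' @param strata Optional explicit class -> stratum mapping.
#' @return An object of class `error_report` with fields `role`, `rates`
#'   (named: total, high, general, low; percent), `records` (per-stratum
#'   record counts), `empty_strata` and `strata`.
#' @export
stratified_error_rates <- function(cm, costs, role = c("modeling data",
                                                       "test data"),
                                   strata = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(cm, "confusion_matrix"), inherits(costs, "cost_matrix"))
  labels <- attr(cm, "labels")
  missing_lab <- setdiff(labels, costs$labels)
  if (length(missing_lab) > 0) {
    stop("label(s) not in cost matrix: ", paste(missing_lab, collapse = ", "))
  }
  strata <- if (is.null(strata)) cost_strata(costs)[labels]
            else cost_strata(costs, strata)[labels]
  m <- unclass(cm)
  total_n <- sum(m)
  wrong_by_class <- rowSums(m) - diag(m)
  rates <- c(total = 100 * sum(wrong_by_class) / total_n)
  records <- c(total = total_n)
  empty <- character(0)
  for (s in c("high", "general", "low")) {
    cls <- labels[strata == s]
    n_s <- sum(m[cls, , drop = FALSE])
    records[s] <- n_s
    if (n_s == 0) {
      rates[s] <- 0
      empty <- c(empty, s)
    } else {
      rates[s] <- 100 * sum(wrong_by_class[cls]) / n_s
    }
  }
  structure(list(role = role, rates = rates, records = records,
                 empty_strata = empty, strata = strata),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("Error report (", x$role, ")\n", sep = "")
  for (nm in names(x$rates)) {
    cat(sprintf("  %-7s cost error rate: %6.2f %%  (%d records)\n",
                nm, x$rates[[nm]], x$records[[nm]]))
  }
  if (length(x$empty_strata) > 0) {
    cat("  [empty strata reported as 0: ",
        paste(x$empty_strata, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Error-value delta between two models
#'
#' Per-rate difference `new - adjusted`, in percentage points, sign
#' preserved. A negative entry means the adjusted model is worse on that
#' stratum.
#'
#' @param new,adjusted `error_report`s with the same role.
#' @return An object of class `error_delta` with field `deltas` (named
#'   vector: total, high, general, low).
#' @export
error_value <- function(new, adjusted) {
  stopifnot(inherits(new, "error_report"), inherits(adjusted, "error_report"))
  if (!identical(new$role, adjusted$role)) {
    stop("error reports have different roles: '", new$role, "' vs '",
         adjusted$role, "'")
  }
  if (!identical(names(new$rates), names(adjusted$rates))) {
    stop("error reports have different strata")
  }
  structure(list(role = new$role, deltas = new$rates - adjusted$rates),
            class = "error_delta")
}

# Seeded stratified 70/30-style split by class label; both parts non-empty.
stratified_split <- function(labels, modeling_fraction, seed) {
  n <- length(labels)
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), labels), function(ii) {
      k <- round(length(ii) * modeling_fraction)
      if (length(ii) > 0) ii[sample.int(length(ii)) <= k] else integer(0)
    }), use.names = FALSE)
  })
  modeling <- sort(idx)
  test <- setdiff(seq_len(n), modeling)
  if (length(modeling) == 0L || length(test) == 0L) {
    stop("degenerate split: one role is empty (n = ", n, ", fraction = ",
         modeling_fraction, ")")
  }
  list(modeling = modeling, test = test)
}

#' Compare standard and cost-sensitive trees
#'
#' The model-comparison experiment: split the labelled dataset into modeling
#' and test parts (seeded stratified random split), train a standard
#' gain-ratio tree (the "newly built model") and a cost-weighted tree (the
#' "adjusted model") on the modeling part, and report the four
#' cost-stratified error rates for both models on both parts together with
#' their error-value deltas.
#'
#' @param dataset A [fit_dataset()].
#' @param costs A [cost_matrix()] covering the classes.
#' @param config Base [induction_config()]; its `cost_sensitive` flag is
#'   overridden per arm.
#' @param modeling_fraction Fraction of records in the modeling split
#'   (default 0.7).
#' @param seed Seed for the split.
#' @param strata Optional explicit class -> stratum mapping for
#'   [stratified_error_rates()].
#' @return An object of class `model_comparison`: `table` (data frame with
#'   role, rate, newly_built, adjusted, error_value; 8 rows), `reports`
#'   (nested list), and the two trees.
#' @export
compare_models <- function(dataset, costs, config = induction_config(),
                           modeling_fraction = 0.7, seed = 1L,
                           strata = NULL) {
  stopifnot(inherits(dataset, "fit_dataset"), inherits(costs, "cost_matrix"))
  if (modeling_fraction <= 0 || modeling_fraction >= 1) {
    stop("modeling_fraction must be in (0, 1)")
  }
  parts <- stratified_split(dataset$labels, modeling_fraction, seed)
  subset_ds <- function(idx) {
    d <- dataset
    d$data <- dataset$data[idx, , drop = FALSE]
    d$labels <- dataset$labels[idx]
    d
  }
  modeling <- subset_ds(parts$modeling)
  test <- subset_ds(parts$test)

  cfg_std <- config; cfg_std$cost_sensitive <- FALSE
  cfg_cs  <- config; cfg_cs$cost_sensitive <- TRUE
  tree_std <- build_tree(modeling, cfg_std)
  tree_cs  <- build_tree(modeling, cfg_cs, costs = costs)

  roles <- list(`modeling data` = modeling, `test data` = test)
  reports <- list()
  rows <- list()
  for (role in names(roles)) {
    ds <- roles[[role]]
    rep_std <- stratified_error_rates(
      confusion_matrix(ds$labels, predict(tree_std, ds$data),
                       labels = dataset$classes),
      costs, role = role, strata = strata)
    rep_cs <- stratified_error_rates(
      confusion_matrix(ds$labels, predict(tree_cs, ds$data),
                       labels = dataset$classes),
      costs, role = role, strata = strata)
    dl <- error_value(rep_std, rep_cs)
    reports[[role]] <- list(newly_built = rep_std, adjusted = rep_cs,
                            delta = dl)
    rows[[role]] <- data.frame(
      role = role,
      rate = c("total error rate", "high cost error rate",
               "general cost error rate", "low cost error rate"),
      newly_built = unname(rep_std$rates[c("total", "high", "general", "low")]),
      adjusted = unname(rep_cs$rates[c("total", "high", "general", "low")]),
      error_value = unname(dl$deltas[c("total", "high", "general", "low")]))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports,
                 trees = list(newly_built = tree_std, adjusted = tree_cs),
                 split = parts, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (newly built = standard criterion, ",
      "adjusted = cost-weighted)\n", sep = "")
  tab <- x$table
  tab$newly_built <- sprintf("%.2f", tab$newly_built)
  tab$adjusted <- sprintf("%.2f", tab$adjusted)
  tab$error_value <- sprintf("%.2f", tab$error_value)
  print(tab, row.names = FALSE)
  invisible(x)
}
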