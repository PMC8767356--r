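#' Class distribution of a labelled sample set
#'
#' Bundles the per-class counts \eqn{r_i} of a sample set \eqn{S} with the
#' class probabilities \eqn{p_i}. In the unweighted case
#' \eqn{p_i = r_i / \sum_k r_k}; [weighted_class_distribution()] substitutes
#' cost-rescaled probabilities while keeping the raw counts.
#'
#' @param counts Non-negative integer vector of per-class counts, optionally
#'   named by class label.
#' @param labels Class labels; defaults to the names of `counts` or
#'   `"C1".."Cm"`.
#' @param probs Optional probability vector overriding the count-based
#'   probabilities (used internally for cost weighting). Must sum to 1.
#' @return An object of class `class_distribution` with fields `labels`,
#'   `counts`, `probs` and `total`.
#' @examples
#' class_distribution(c(yes = 9, no = 5))
#' @export
class_distribution <- function(counts, labels = NULL, probs = NULL) {
  if (length(counts) < 1L) stop("a class distribution needs at least one class")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("class counts must be finite and non-negative")
  }
  if (is.null(labels)) {
    labels <- names(counts)
    if (is.null(labels)) labels <- paste0("C", seq_along(counts))
  }
  if (length(labels) != length(counts)) stop("labels and counts lengths differ")
  counts <- unname(as.numeric(counts))
  total <- sum(counts)
  if (is.null(probs)) {
    probs <- if (total > 0) counts / total else rep(NA_real_, length(counts))
  } else {
    if (length(probs) != length(counts)) stop("probs and counts lengths differ")
    if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  }
  structure(
    list(labels = as.character(labels), counts = counts,
         probs = unname(as.numeric(probs)), total = total),
    class = "class_distribution"
  )
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("Class distribution (", x$total, " records, ", length(x$labels),
      " classes)\n", sep = "")
  print(data.frame(label = x$labels, count = x$counts,
                   prob = round(x$probs, 4)), row.names = FALSE)
  invisible(x)
}

# Shannon entropy in bits of a probability vector, with 0 log2 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' Expected information (entropy) of a class distribution
#'
#' The expected information \eqn{I(r_1,\dots,r_m) = -\sum_i p_i \log_2 p_i}
#' of the class distribution of a sample set, in bits. The convention
#' \eqn{0 \log_2 0 = 0} applies, so pure sets have entropy 0.
#'
#' @param dist A [class_distribution()].
#' @return Entropy in bits, in `[0, log2(m)]`.
#' @examples
#' expected_information(class_distribution(c(9, 5)))
#' @export
expected_information <- function(dist) {
  stopifnot(inherits(dist, "class_distribution"))
  if (dist$total <= 0) stop("expected_information is undefined for an empty set")
  entropy_bits(dist$probs)
}

#' Partition of a sample set by an attribute
#'
#' Represents the split of a set \eqn{S} into \eqn{v} subsets \eqn{S_j} by an
#' attribute \eqn{A} (one branch per categorical value, or the two sides of a
#' continuous threshold), holding the per-cell class counts \eqn{S_{ij}} and
#' the subset weights \eqn{W_j = |S_j| / |S|}.
#'
#' @param counts An `m x v` matrix of class-by-subset counts (rows = classes,
#'   columns = subsets); row names are taken as class labels.
#' @param attribute Attribute identifier (for reporting).
#' @param branch_values Optional per-subset value / threshold-side tags.
#' @return An object of class `attribute_partition`.
#' @export
attribute_partition <- function(counts, attribute = NA_character_,
                                branch_values = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("a partition needs at least one subset")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("partition counts must be finite and non-negative")
  }
  sizes <- colSums(counts)
  if (any(sizes == 0)) stop("a partition must not contain an empty subset")
  labels <- rownames(counts)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(counts)))
  structure(
    list(attribute = attribute, counts = unname(counts), labels = labels,
         branch_values = branch_values, sizes = unname(sizes),
         W = unname(sizes / sum(sizes)), total = sum(sizes)),
    class = "attribute_partition"
  )
}

#' Conditional entropy of a partition
#'
#' The conditional entropy \eqn{E(A) = \sum_j W_j I(S_{1j},\dots,S_{mj})} of a
#' sample set given its partition by attribute \eqn{A}. Subset weights
#' \eqn{W_j} are always size-based; when a cost weight vector `weights` is
#' supplied the inner probabilities become
#' \eqn{p_{ij} = w_i n_{ij} / \sum_k w_k n_{kj}} (the cost-sensitive
#' criterion), otherwise \eqn{p_{ij} = S_{ij} / |S_j|}.
#'
#' @param partition An [attribute_partition()].
#' @param weights Optional per-class weight vector (see [class_weights()]).
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(partition, weights = NULL) {
  stopifnot(inherits(partition, "attribute_partition"))
  cm <- partition$counts
  if (!is.null(weights)) {
    w <- as_weight_vector(weights, nrow(cm))
    cm <- cm * w
  }
  inner <- vapply(seq_len(ncol(cm)), function(j) {
    tot <- sum(cm[, j])
    if (tot <= 0) stop("zero weighted mass in subset ", j)
    entropy_bits(cm[, j] / tot)
  }, numeric(1))
  sum(partition$W * inner)
}

#' Information gain of a partition
#'
#' \eqn{Gain(A) = I(r_1,\dots,r_m) - E(A)}: the entropy reduction achieved by
#' splitting on attribute \eqn{A}. Non-negative (up to floating tolerance) in
#' the unweighted case.
#'
#' @param dist The [class_distribution()] of the unpartitioned set.
#' @param partition The [attribute_partition()] of the same set.
#' @param weights Optional per-class cost weights; when supplied both the
#'   parent entropy and the subset entropies use weighted probabilities.
#' @return Information gain in bits.
#' @export
information_gain <- function(dist, partition, weights = NULL) {
  stopifnot(inherits(dist, "class_distribution"),
            inherits(partition, "attribute_partition"))
  if (abs(dist$total - partition$total) > 1e-9 ||
      any(abs(dist$counts - rowSums(partition$counts)) > 1e-9)) {
    stop("partition class totals do not match the parent distribution")
  }
  if (is.null(weights)) {
    expected_information(dist) - conditional_entropy(partition)
  } else {
    wd <- weighted_class_distribution(dist, weights)
    expected_information(wd) - conditional_entropy(partition, weights)
  }
}

#' Split information of a partition
#'
#' The entropy of the subset-size distribution,
#' \eqn{SplitInfo(S, v) = -\sum_j (|S_j|/|S|) \log_2 (|S_j|/|S|)}, which
#' penalizes many-valued splits in the gain-ratio criterion. Always computed
#' from raw subset sizes, even in the cost-sensitive variant.
#'
#' @param partition An [attribute_partition()].
#' @return Split information in bits; 0 iff the partition has a single subset.
#' @export
split_information <- function(partition) {
  stopifnot(inherits(partition, "attribute_partition"))
  entropy_bits(partition$W)
}

#' Gain ratio
#'
#' \eqn{GainRatio = Gain / SplitInfo}. Candidates with vanishing split
#' information are degenerate (all mass in one subset) and are reported as
#' invalid (`NA`) rather than as infinite ratios; tree induction rejects them.
#'
#' @param gain Information gain in bits.
#' @param split_info Split information in bits.
#' @param tol Threshold below which `split_info` counts as zero.
#' @return The gain ratio, or `NA_real_` for a degenerate split.
#' @export
gain_ratio <- function(gain, split_info, tol = 1e-12) {
  stopifnot(is.numeric(gain), is.numeric(split_info))
  if (split_info < 0) stop("split_info must be non-negative")
  if (split_info < tol) return(NA_real_)
  gain / split_info
}

#' Misclassification cost matrix
#'
#' Pairwise misclassification costs `cost(i, j)`: the penalty for predicting
#' class `j` when the true class is `i`. The diagonal is fixed at 0; the
#' default off-diagonal cost of 1 reduces the cost-sensitive criterion to
#' standard C4.5.
#'
#' @param costs An `m x m` numeric matrix with zero diagonal and non-negative
#'   off-diagonal entries; dimnames are taken as class labels.
#' @param labels Class labels (required if `costs` has no dimnames).
#' @return An object of class `cost_matrix`.
#' @seealso [uniform_cost_matrix()], [load_cost_matrix()], [cost_totals()]
#' @export
cost_matrix <- function(costs, labels = NULL) {
  costs <- as.matrix(costs)
  if (nrow(costs) != ncol(costs)) stop("cost matrix must be square")
  if (is.null(labels)) labels <- rownames(costs)
  if (is.null(labels)) stop("cost matrix needs class labels")
  if (length(labels) != nrow(costs)) stop("labels length must match matrix size")
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("costs must be finite and non-negative")
  }
  if (any(abs(diag(costs)) > 0)) stop("diagonal costs cost(i,i) must be 0")
  dimnames(costs) <- list(labels, labels)
  structure(list(labels = as.character(labels), costs = costs),
            class = "cost_matrix")
}

#' @rdname cost_matrix
#' @param cost Common off-diagonal cost (default 1).
#' @export
uniform_cost_matrix <- function(labels, cost = 1) {
  m <- length(labels)
  costs <- matrix(cost, m, m) - diag(cost, m)
  cost_matrix(costs, labels = labels)
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("Misclassification cost matrix (rows = true class):\n")
  print(x$costs)
  invisible(x)
}

#' Load a cost matrix from a JSON configuration
#'
#' The configuration maps true classes to predicted classes to costs:
#' `{"true": {"predicted": cost, ...}, ...}`. Omitted off-diagonal cells
#' default to 1 and the diagonal to 0; any explicit diagonal entry must be 0.
#'
#' @param config Path to a JSON file, or an already-parsed named list.
#' @param labels Optional full label set (supplements labels mentioned in the
#'   config).
#' @return A [cost_matrix()].
#' @export
load_cost_matrix <- function(config, labels = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config)) stop("cost config must be a JSON object or list")
  mentioned <- union(names(config),
                     unlist(lapply(config, names), use.names = FALSE))
  labels <- union(as.character(labels %||% character()), mentioned)
  if (length(labels) < 1L) stop("cost config mentions no classes")
  cm <- matrix(1, length(labels), length(labels),
               dimnames = list(labels, labels))
  diag(cm) <- 0
  for (ti in names(config)) {
    row <- config[[ti]]
    if (!is.list(row) && !is.numeric(row)) {
      stop("cost config entry for '", ti, "' must map predicted classes to numbers")
    }
    for (pj in names(row)) {
      v <- row[[pj]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
        stop("cost(", ti, ",", pj, ") must be a non-negative number")
      }
      if (ti == pj && v != 0) stop("diagonal cost(", ti, ",", ti, ") must be 0")
      cm[ti, pj] <- v
    }
  }
  cost_matrix(cm)
}

#' Per-class total misclassification cost C(i)
#'
#' Row sums of the cost matrix: \eqn{C(i) = \sum_j cost(i, j)}, the total cost
#' of misclassifying class `i`.
#'
#' @param costs A [cost_matrix()].
#' @return Named numeric vector of row-sum costs.
#' @export
cost_totals <- function(costs) {
  stopifnot(inherits(costs, "cost_matrix"))
  rowSums(costs$costs)
}

#' Cost-derived class weights
#'
#' Computes the per-class weights
#' \eqn{w(i) = C(i) n / \sum_k C(k) n_k}, where \eqn{C(i)} is the row-sum
#' misclassification cost and \eqn{n_i} the class counts, normalized so that
#' \eqn{\sum_i w(i) n_i = n}. With uniform off-diagonal costs all weights are
#' 1 and the weighted criterion collapses to the standard one.
#'
#' @param costs A [cost_matrix()] covering every class in `dist`.
#' @param dist The [class_distribution()] of the (training) sample set.
#' @return Named numeric weight vector, class `weight_vector`.
#' @examples
#' d <- class_distribution(c(a = 90, b = 10))
#' cw <- cost_matrix(matrix(c(0, 1, 9, 0), 2, byrow = TRUE), labels = c("a", "b"))
#' class_weights(cw, d) # c(a = 0.5556, b = 5)
#' @export
class_weights <- function(costs, dist) {
  stopifnot(inherits(costs, "cost_matrix"), inherits(dist, "class_distribution"))
  missing_lab <- setdiff(dist$labels, costs$labels)
  if (length(missing_lab) > 0) {
    stop("classes missing from cost matrix: ", paste(missing_lab, collapse = ", "))
  }
  C <- cost_totals(costs)[dist$labels]
  n <- dist$total
  denom <- sum(C * dist$counts)
  if (denom <= 0) {
    stop("all-zero cost normalization: no class has both C(i) > 0 and n_i > 0")
  }
  w <- C * n / denom
  names(w) <- dist$labels
  class(w) <- c("weight_vector", class(w))
  w
}

# Coerce a weight vector argument and check its length.
as_weight_vector <- function(weights, m) {
  w <- as.numeric(weights)
  if (length(w) != m) stop("weight vector length must equal the number of classes")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and non-negative")
  w
}

#' Cost-weighted class distribution
#'
#' Rescales class probabilities by cost weights:
#' \eqn{p_i = w_i n_i / \sum_k w_k n_k} (and \eqn{p_{ij}} analogously within a
#' subset). Feeding the result into [expected_information()] /
#' [conditional_entropy()] yields the cost-sensitive split criterion. With all
#' weights 1 the distribution is unchanged.
#'
#' @param dist A [class_distribution()].
#' @param weights Per-class weights aligned with `dist$labels`
#'   (see [class_weights()]).
#' @return A [class_distribution()] with the same counts and weighted
#'   probabilities.
#' @export
weighted_class_distribution <- function(dist, weights) {
  stopifnot(inherits(dist, "class_distribution"))
  w <- as_weight_vector(weights, length(dist$counts))
  mass <- w * dist$counts
  tot <- sum(mass)
  if (tot <= 0) stop("zero total weighted mass")
  class_distribution(dist$counts, labels = dist$labels, probs = mass / tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
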