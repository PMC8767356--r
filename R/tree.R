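#' Declare a labelled training dataset
#'
#' Wraps a data frame with the attribute declarations the inducer needs:
#' which columns are split candidates, whether each is continuous or
#' categorical, and which column holds the class label. Records with missing
#' values in any declared column are rejected (no fractional instances or
#' surrogate splits).
#'
#' @param data A data frame of records.
#' @param attributes Named character vector mapping attribute column names to
#'   kinds, e.g. `c(bmi = "continuous", gender = "categorical")`. Declaration
#'   order is the tie-break order during split selection.
#' @param label Name of the class label column.
#' @return An object of class `fit_dataset`.
#' @export
fit_dataset <- function(data, attributes, label) {
  stopifnot(is.data.frame(data))
  if (is.null(names(attributes)) || any(names(attributes) == "")) {
    stop("attributes must be a named vector of kinds")
  }
  bad_kind <- setdiff(unique(attributes), c("continuous", "categorical"))
  if (length(bad_kind) > 0) {
    stop("unknown attribute kind(s): ", paste(bad_kind, collapse = ", "))
  }
  missing_cols <- setdiff(c(names(attributes), label), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  used <- data[, c(names(attributes), label), drop = FALSE]
  if (anyNA(used)) {
    stop("missing values in declared attribute or label columns; ",
         "clean the records before training")
  }
  for (a in names(attributes)) {
    if (attributes[[a]] == "continuous" && !is.numeric(data[[a]])) {
      stop("attribute '", a, "' declared continuous but is not numeric")
    }
  }
  lab <- as.character(data[[label]])
  structure(
    list(data = data, attributes = attributes, label = label,
         labels = lab, classes = sort(unique(lab))),
    class = "fit_dataset"
  )
}

#' Induction configuration
#'
#' @param min_samples_to_split Minimum records at a node to attempt a split
#'   (>= 2).
#' @param max_depth Maximum tree depth (`Inf` for unlimited; root = depth 1).
#' @param cost_sensitive Use cost-weighted class probabilities in the split
#'   criterion and for leaf labelling.
#' @param tie_tol Floating tolerance for criterion ties; ties are broken by
#'   attribute declaration order, then by smaller threshold.
#' @return An object of class `induction_config`.
#' @export
induction_config <- function(min_samples_to_split = 2, max_depth = Inf,
                             cost_sensitive = FALSE, tie_tol = 1e-9) {
  if (min_samples_to_split < 2) stop("min_samples_to_split must be >= 2")
  if (max_depth < 1) stop("max_depth must be >= 1")
  structure(list(min_samples_to_split = min_samples_to_split,
                 max_depth = max_depth,
                 cost_sensitive = isTRUE(cost_sensitive),
                 tie_tol = tie_tol),
            class = "induction_config")
}

#' Candidate thresholds for a continuous attribute
#'
#' Boundary-point reduction: candidate thresholds are midpoints between
#' consecutive distinct attribute values whose adjacent records differ in
#' class. Midpoints interior to a run of one class cannot improve an
#' entropy-based criterion, so they are skipped.
#'
#' @param values Numeric attribute values.
#' @param labels Class labels aligned with `values`.
#' @return Sorted numeric vector of thresholds (empty if all values are equal
#'   or no class change exists across distinct values).
#' @examples
#' candidate_thresholds(c(14, 15, 19, 21), c("a", "a", "b", "b")) # 17
#' @export
candidate_thresholds <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  ord <- order(values)
  v <- values[ord]
  l <- as.character(labels)[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  # classes present at each distinct value; a boundary is eligible when the
  # two adjacent value-groups are not the same single class
  cls <- split(l, match(v, uv))
  keep <- vapply(seq_len(length(uv) - 1L), function(k) {
    a <- unique(cls[[k]]); b <- unique(cls[[k + 1L]])
    length(a) > 1L || length(b) > 1L || a != b
  }, logical(1))
  ((uv[-length(uv)] + uv[-1L]) / 2)[keep]
}

# Class-count matrix (classes x branches) for a proposed split.
split_counts <- function(labels, classes, branch) {
  cm <- table(factor(labels, levels = classes), branch)
  matrix(cm, nrow = length(classes), dimnames = list(classes, colnames(cm)))
}

# Evaluate one candidate partition; returns NULL if invalid (degenerate
# split-info or non-positive gain).
eval_candidate <- function(dist, counts, attribute, kind, threshold,
                           branch_values, weights, tie_tol) {
  part <- attribute_partition(counts, attribute = attribute,
                              branch_values = branch_values)
  g <- information_gain(dist, part, weights = weights)
  si <- split_information(part)
  gr <- gain_ratio(g, si)
  if (is.na(gr)) return(NULL)
  structure(list(attribute = attribute, kind = kind, threshold = threshold,
                 branch_values = branch_values, gain = g, split_info = si,
                 gain_ratio = gr, weighted = !is.null(weights)),
            class = "split_evaluation")
}

#' Best split of a dataset under the gain-ratio criterion
#'
#' Searches every declared attribute (and, for continuous attributes, every
#' candidate threshold) for the split maximizing the gain ratio. Continuous
#' tests send `value <= threshold` to the left branch; categorical tests
#' branch on each observed value. When `config$cost_sensitive` is set, class
#' probabilities are cost-weighted via [class_weights()] before entropies are
#' computed; split information stays size-based. Degenerate candidates
#' (vanishing split information) are rejected; zero-gain candidates are kept
#' so that locally uninformative but jointly separating attribute pairs
#' (XOR-style structure) can still be split. A pure dataset has no split.
#'
#' @param dataset A [fit_dataset()] (non-empty, not pure).
#' @param config An [induction_config()].
#' @param costs A [cost_matrix()] (required when cost-sensitive).
#' @param weights Optional precomputed class weights aligned with
#'   `dataset$classes`; overrides computing them from `dataset` (used by
#'   [build_tree()] to fix weights at the root).
#' @return A `split_evaluation` (attribute, kind, threshold, gain, split_info,
#'   gain_ratio, weighted) or `NULL` if no valid candidate exists.
#' @export
best_split <- function(dataset, config = induction_config(), costs = NULL,
                       weights = NULL) {
  stopifnot(inherits(dataset, "fit_dataset"))
  labels <- dataset$labels
  classes <- dataset$classes
  if (length(unique(labels)) <= 1L) return(NULL)
  dist <- class_distribution(
    vapply(classes, function(cl) sum(labels == cl), numeric(1)),
    labels = classes)
  if (config$cost_sensitive && is.null(weights)) {
    if (is.null(costs)) stop("cost_sensitive induction needs a cost matrix")
    weights <- class_weights(costs, dist)
  }
  if (!config$cost_sensitive) weights <- NULL
  if (!is.null(weights)) weights <- weights[classes]

  best <- NULL
  for (a in names(dataset$attributes)) {
    kind <- dataset$attributes[[a]]
    x <- dataset$data[[a]]
    if (kind == "continuous") {
      for (thr in candidate_thresholds(x, labels)) {
        branch <- factor(ifelse(x <= thr, "le", "gt"), levels = c("le", "gt"))
        cand <- eval_candidate(dist, split_counts(labels, classes, branch),
                               a, kind, thr, c("le", "gt"), weights,
                               config$tie_tol)
        if (!is.null(cand) &&
            (is.null(best) || cand$gain_ratio > best$gain_ratio + config$tie_tol)) {
          best <- cand
        }
      }
    } else {
      vals <- sort(unique(as.character(x)))
      if (length(vals) < 2L) next
      branch <- factor(as.character(x), levels = vals)
      cand <- eval_candidate(dist, split_counts(labels, classes, branch),
                             a, kind, NA_real_, vals, weights, config$tie_tol)
      if (!is.null(cand) &&
          (is.null(best) || cand$gain_ratio > best$gain_ratio + config$tie_tol)) {
        best <- cand
      }
    }
  }
  best
}

# Leaf node: label = class of maximum (weighted) probability, ties broken by
# class order.
make_leaf <- function(labels, classes, weights) {
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  mass <- if (is.null(weights)) counts else counts * weights[classes]
  probs <- if (sum(mass) > 0) mass / sum(mass) else counts / sum(counts)
  list(type = "leaf", label = classes[which.max(mass)],
       counts = as.list(stats::setNames(counts, classes)),
       probs = as.list(stats::setNames(round(probs, 12), classes)))
}

#' Build a decision tree
#'
#' Recursive partitioning with the (optionally cost-weighted) gain-ratio
#' criterion. Recursion stops at purity, `min_samples_to_split`, `max_depth`,
#' or when no valid split remains; each leaf is labelled by the class of
#' maximum (weighted) probability. No pruning is applied. In the
#' cost-sensitive mode the class weights are computed once from the full
#' training distribution and held fixed down the tree.
#'
#' @param dataset A non-empty [fit_dataset()].
#' @param config An [induction_config()].
#' @param costs A [cost_matrix()] (required when cost-sensitive).
#' @return An object of class `fittree` with fields `version`, `attributes`,
#'   `classes`, `config`, `weights` and `root`.
#' @examples
#' df <- data.frame(x = c(14, 15, 19, 21), y = c("a", "a", "b", "b"))
#' tr <- build_tree(fit_dataset(df, c(x = "continuous"), "y"))
#' predict(tr, data.frame(x = 16))
#' @export
build_tree <- function(dataset, config = induction_config(), costs = NULL) {
  stopifnot(inherits(dataset, "fit_dataset"))
  n <- nrow(dataset$data)
  if (n == 0L) stop("cannot build a tree from an empty dataset")
  classes <- dataset$classes
  weights <- NULL
  if (config$cost_sensitive) {
    if (is.null(costs)) stop("cost_sensitive induction needs a cost matrix")
    full_dist <- class_distribution(
      vapply(classes, function(cl) sum(dataset$labels == cl), numeric(1)),
      labels = classes)
    weights <- class_weights(costs, full_dist)
  }

  grow <- function(idx, depth) {
    labs <- dataset$labels[idx]
    if (length(unique(labs)) == 1L ||
        length(idx) < config$min_samples_to_split ||
        depth >= config$max_depth) {
      return(make_leaf(labs, classes, weights))
    }
    sub <- dataset
    sub$data <- dataset$data[idx, , drop = FALSE]
    sub$labels <- labs
    sp <- best_split(sub, config, costs = costs, weights = weights)
    if (is.null(sp)) return(make_leaf(labs, classes, weights))
    x <- dataset$data[[sp$attribute]][idx]
    if (sp$kind == "continuous") {
      groups <- list(idx[x <= sp$threshold], idx[x > sp$threshold])
    } else {
      groups <- lapply(sp$branch_values,
                       function(v) idx[as.character(x) == v])
    }
    children <- lapply(groups, function(g) grow(g, depth + 1L))
    node <- list(type = "internal", attribute = sp$attribute, kind = sp$kind,
                 n = length(idx), children = children)
    if (sp$kind == "continuous") {
      node$threshold <- sp$threshold
    } else {
      node$values <- as.list(sp$branch_values)
      # fallback branch for values unseen at this node during prediction
      node$majority_branch <- which.max(vapply(groups, length, numeric(1)))
    }
    node
  }

  structure(
    list(version = TREE_FORMAT_VERSION,
         attributes = as.list(dataset$attributes),
         classes = classes,
         config = list(min_samples_to_split = config$min_samples_to_split,
                       max_depth = config$max_depth,
                       cost_sensitive = config$cost_sensitive,
                       tie_tol = config$tie_tol),
         weights = if (is.null(weights)) NULL else
           as.list(stats::setNames(unname(weights), classes)),
         root = grow(seq_len(n), 1L)),
    class = "fittree"
  )
}

TREE_FORMAT_VERSION <- "fittree-1"

# Route one record to its leaf.
route_record <- function(node, record, attributes) {
  while (node$type == "internal") {
    a <- node$attribute
    if (!a %in% names(record) || is.na(record[[a]])) {
      stop("record is missing tested attribute '", a, "'")
    }
    if (node$kind == "continuous") {
      node <- if (record[[a]] <= node$threshold) node$children[[1L]]
              else node$children[[2L]]
    } else {
      i <- match(as.character(record[[a]]), unlist(node$values))
      if (is.na(i)) {
        warning("unseen value '", record[[a]], "' for attribute '", a,
                "'; routing to majority branch", call. = FALSE)
        i <- node$majority_branch
      }
      node <- node$children[[i]]
    }
  }
  node
}

#' Predict with a decision tree
#'
#' Routes each record deterministically from the root to a leaf. A record
#' lying exactly on a continuous threshold follows the `<=` branch; a
#' categorical value unseen at a node is routed to the node's majority branch
#' with a warning. Missing tested attributes are an error.
#'
#' @param object A `fittree` from [build_tree()] or [deserialize_tree()].
#' @param newdata Data frame of records.
#' @param type `"class"` for labels, `"prob"` for the leaf class
#'   distributions (matrix, one row per record).
#' @param ... Unused.
#' @return Character vector of labels, or a probability matrix.
#' @export
predict.fittree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  leaves <- lapply(seq_len(nrow(newdata)), function(i) {
    route_record(object$root, newdata[i, , drop = FALSE], object$attributes)
  })
  if (type == "class") {
    vapply(leaves, function(l) l$label, character(1))
  } else {
    t(vapply(leaves,
             function(l) unlist(l$probs)[object$classes],
             numeric(length(object$classes))))
  }
}

#' @export
print.fittree <- function(x, ...) {
  cat("Decision tree (", if (isTRUE(x$config$cost_sensitive)) "cost-sensitive"
      else "standard", " gain-ratio criterion)\n", sep = "")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "-> ", node$label, "  (",
          paste(names(node$counts), unlist(node$counts),
                sep = ":", collapse = " "), ")\n", sep = "")
    } else if (node$kind == "continuous") {
      cat(pad, node$attribute, " <= ", format(node$threshold), ":\n", sep = "")
      show(node$children[[1]], indent + 1)
      cat(pad, node$attribute, " >  ", format(node$threshold), ":\n", sep = "")
      show(node$children[[2]], indent + 1)
    } else {
      for (i in seq_along(node$values)) {
        cat(pad, node$attribute, " = ", node$values[[i]], ":\n", sep = "")
        show(node$children[[i]], indent + 1)
      }
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Serialize a decision tree to JSON
#'
#' Writes a versioned, human-readable JSON document that round-trips
#' losslessly through [deserialize_tree()]. Serialization is byte-stable:
#' identical trees produce identical documents.
#'
#' @param tree A `fittree`.
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON document as a character scalar (invisibly when `path` is
#'   given).
#' @export
serialize_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "fittree"))
  doc <- unclass(tree)
  doc$config$max_depth <- if (is.infinite(doc$config$max_depth)) "unlimited"
                          else doc$config$max_depth
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

# Validate one node of a parsed tree document; `where` names the path for
# error messages.
check_node <- function(node, where) {
  if (!is.list(node) || is.null(node$type)) {
    stop("tree document: missing 'type' at ", where)
  }
  if (node$type == "leaf") {
    if (is.null(node$label) || is.null(node$counts) || is.null(node$probs)) {
      stop("tree document: leaf at ", where,
           " needs 'label', 'counts' and 'probs'")
    }
  } else if (node$type == "internal") {
    if (is.null(node$attribute) || is.null(node$kind) ||
        is.null(node$children)) {
      stop("tree document: internal node at ", where,
           " needs 'attribute', 'kind' and 'children'")
    }
    if (node$kind == "continuous") {
      if (!is.numeric(node$threshold)) {
        stop("tree document: numeric 'threshold' missing at ", where)
      }
      if (length(node$children) != 2L) {
        stop("tree document: continuous node at ", where,
             " must have exactly 2 children")
      }
    } else if (node$kind == "categorical") {
      if (length(node$values) != length(node$children)) {
        stop("tree document: values/children mismatch at ", where)
      }
    } else {
      stop("tree document: unknown split kind '", node$kind, "' at ", where)
    }
    for (i in seq_along(node$children)) {
      check_node(node$children[[i]], paste0(where, "/children[", i, "]"))
    }
  } else {
    stop("tree document: unknown node type '", node$type, "' at ", where)
  }
  invisible(TRUE)
}

#' @rdname serialize_tree
#' @param document JSON string or path to a JSON file produced by
#'   [serialize_tree()].
#' @export
deserialize_tree <- function(document) {
  txt <- if (length(document) == 1L && file.exists(document)) {
    paste(readLines(document, warn = FALSE), collapse = "\n")
  } else {
    paste(document, collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("tree document: invalid JSON: ",
                                           conditionMessage(e)))
  if (!identical(doc$version, TREE_FORMAT_VERSION)) {
    stop("tree document: unsupported or missing 'version' ",
         "(expected '", TREE_FORMAT_VERSION, "')")
  }
  for (f in c("attributes", "classes", "config", "root")) {
    if (is.null(doc[[f]])) stop("tree document: missing '", f, "'")
  }
  check_node(doc$root, "root")
  doc$classes <- unlist(doc$classes)
  if (identical(doc$config$max_depth, "unlimited")) doc$config$max_depth <- Inf
  structure(doc, class = "fittree")
}
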