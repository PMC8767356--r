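GRADES  <- c("freshman", "sophomore", "junior", "senior")
GENDERS <- c("male", "female")
BAND_LABELS <- c("low weight", "normal", "overweight", "obesity")

#' Body mass index
#'
#' BMI = weight (kg) / height (m) squared.
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in metres (> 0).
#' @return BMI in kg/m2 (vectorized).
#' @examples
#' compute_bmi(70, 1.75)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive (metres)")
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive (kilograms)")
  }
  weight / height^2
}

#' Load a scoring standard from a JSON configuration
#'
#' A scoring standard maps an index value (e.g. BMI) to a band label and a
#' score, per (grade, gender) stratum. The configuration holds ordered bands
#' with inclusive bounds printed at one-decimal resolution; an absent `min`
#' means an open lower bound ("<= max") and an absent `max` an open upper
#' bound (">= min"). Validation checks that within each stratum the bands are
#' ordered, non-overlapping and — after rounding to the configured resolution
#' — jointly cover the whole index axis (consecutive bounds differ by exactly
#' one resolution step). Grades from the standard vocabulary with no entry at
#' all trigger a warning; lookups for missing strata fail loudly later.
#'
#' @param config Path to a JSON file, or a parsed list. Defaults to the
#'   shipped national BMI standard (exactly the four printed strata:
#'   male bands for freshman/sophomore/junior, female bands for senior).
#' @return An object of class `scoring_standard`.
#' @seealso [score_index()], [score_cohort()], [default_bmi_standard()]
#' @export
load_scoring_standard <- function(config = default_standard_path()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config) || is.null(config$index) || is.null(config$standards)) {
    stop("scoring config must be an object with 'index' and 'standards'")
  }
  res <- config$resolution %||% 0.1
  if (!is.numeric(res) || res <= 0) stop("resolution must be a positive number")
  entries <- list()
  bad <- character(0)
  for (st in config$standards) {
    if (is.null(st$grade) || is.null(st$gender) || is.null(st$bands)) {
      stop("each standard entry needs 'grade', 'gender' and 'bands'")
    }
    key <- paste(st$grade, st$gender, sep = "/")
    bands <- do.call(rbind, lapply(st$bands, function(b) {
      if (is.null(b$label) || is.null(b$score)) {
        stop("band in '", key, "' needs 'label' and 'score'")
      }
      if (!is.numeric(b$score) || b$score <= 0) {
        stop("band score in '", key, "' must be positive")
      }
      data.frame(lo = as.numeric(b$min %||% -Inf),
                 hi = as.numeric(b$max %||% Inf),
                 label = as.character(b$label),
                 score = as.numeric(b$score))
    }))
    if (any(bands$lo > bands$hi)) bad <- c(bad, paste0(key, " (min > max)"))
    if (nrow(bands) > 1L) {
      steps <- bands$lo[-1L] - bands$hi[-nrow(bands)]
      if (any(steps <= 1e-9)) {
        bad <- c(bad, paste0(key, " (overlapping or unordered bands)"))
      } else if (any(abs(steps - res) > 1e-9)) {
        bad <- c(bad, paste0(key, " (coverage gap wider than one ", res,
                             " step)"))
      }
    }
    if (!is.infinite(bands$lo[1L]) || !is.infinite(bands$hi[nrow(bands)])) {
      bad <- c(bad, paste0(key, " (outer bands must be open-ended)"))
    }
    entries[[key]] <- bands
  }
  if (length(bad) > 0) {
    stop("invalid scoring standard for: ", paste(bad, collapse = "; "))
  }
  covered_grades <- unique(vapply(strsplit(names(entries), "/"), `[`,
                                  character(1), 1L))
  missing_grades <- setdiff(GRADES, covered_grades)
  if (length(missing_grades) > 0) {
    warning("scoring standard has no bands for grade(s): ",
            paste(missing_grades, collapse = ", "), call. = FALSE)
  }
  structure(list(index = as.character(config$index),
                 units = config$units %||% NA_character_,
                 resolution = res, entries = entries),
            class = "scoring_standard")
}

default_standard_path <- function() {
  system.file("extdata", "bmi_standard.json", package = "fittree",
              mustWork = TRUE)
}

#' The shipped national BMI scoring standard
#'
#' Convenience loader for the default BMI band table: four strata
#' (freshman/sophomore/junior male, senior female), four bands each
#' (low weight 80, normal 100, overweight 80, obesity 60 points).
#'
#' @return A `scoring_standard`.
#' @export
default_bmi_standard <- function() load_scoring_standard()

#' @export
print.scoring_standard <- function(x, ...) {
  cat("Scoring standard for ", x$index, " (resolution ", x$resolution,
      ")\n", sep = "")
  for (key in names(x$entries)) {
    b <- x$entries[[key]]
    cat("  ", key, ": ",
        paste(sprintf("%s[%s,%s]=%g", b$label,
                      ifelse(is.infinite(b$lo), "-Inf", format(b$lo)),
                      ifelse(is.infinite(b$hi), "Inf", format(b$hi)),
                      b$score),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Score an index value against a standard
#'
#' Rounds the value to the standard's resolution (one decimal by default) and
#' looks up its band for the given (grade, gender) stratum.
#'
#' @param value Index value (e.g. BMI in kg/m2).
#' @param grade One of `"freshman"`, `"sophomore"`, `"junior"`, `"senior"`.
#' @param gender `"male"` or `"female"`.
#' @param standard A [load_scoring_standard()] object (default: shipped BMI
#'   standard).
#' @return A list with `band` (label) and `score` (points).
#' @examples
#' score_index(15.0, "freshman", "male") # normal, 100
#' @export
score_index <- function(value, grade, gender,
                        standard = default_bmi_standard()) {
  stopifnot(inherits(standard, "scoring_standard"))
  key <- paste(grade, gender, sep = "/")
  bands <- standard$entries[[key]]
  if (is.null(bands)) {
    stop("no standard for stratum '", key, "' in the ", standard$index,
         " scoring standard")
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("value must be a single finite number")
  }
  res <- standard$resolution
  v <- round(value / res) * res
  i <- which(v >= bands$lo - 1e-9 & v <= bands$hi + 1e-9)
  if (length(i) != 1L) {
    stop("value ", value, " matched ", length(i), " bands in '", key,
         "' (standard coverage violated)")
  }
  list(band = bands$label[i], score = bands$score[i])
}

#' Score a cohort of student records
#'
#' Applies [score_index()] to every record. Records that fail validation
#' (unknown grade/gender, no BMI and no height/weight to derive it, missing
#' stratum in the standard) are routed to a separate error table, never
#' silently dropped.
#'
#' @param records Data frame with columns `id`, `grade`, `gender` and either
#'   `bmi` or both `height` (m) and `weight` (kg).
#' @param standard A `scoring_standard`.
#' @return A list with `scored` (data frame: id, index, value, band, score)
#'   and `errors` (data frame: id, reason).
#' @export
score_cohort <- function(records, standard = default_bmi_standard()) {
  stopifnot(is.data.frame(records), inherits(standard, "scoring_standard"))
  scored <- list()
  errors <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    id <- if ("id" %in% names(r)) r$id else i
    reason <- NULL
    value <- NA_real_
    if (!("grade" %in% names(r)) || !(r$grade %in% GRADES)) {
      reason <- "unknown or missing grade"
    } else if (!("gender" %in% names(r)) || !(r$gender %in% GENDERS)) {
      reason <- "unknown or missing gender"
    } else {
      value <- if ("bmi" %in% names(r) && is.finite(r$bmi)) r$bmi
        else if (all(c("height", "weight") %in% names(r)) &&
                 is.finite(r$height) && is.finite(r$weight) && r$height > 0 &&
                 r$weight > 0) compute_bmi(r$weight, r$height)
        else NA_real_
      if (!is.finite(value)) reason <- "no BMI and no usable height/weight"
    }
    if (is.null(reason)) {
      hit <- tryCatch(score_index(value, r$grade, r$gender, standard),
                      error = function(e) conditionMessage(e))
      if (is.character(hit)) {
        reason <- hit
      } else {
        scored[[length(scored) + 1L]] <- data.frame(
          id = id, index = standard$index, value = value,
          band = hit$band, score = hit$score)
      }
    }
    if (!is.null(reason)) {
      errors[[length(errors) + 1L]] <- data.frame(id = id, reason = reason)
    }
  }
  empty_scored <- data.frame(id = character(0), index = character(0),
                             value = numeric(0), band = character(0),
                             score = numeric(0))
  list(scored = if (length(scored)) do.call(rbind, scored) else empty_scored,
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(id = character(0), reason = character(0)))
}
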