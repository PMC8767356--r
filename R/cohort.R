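#' Synthetic full-coverage BMI standard
#'
#' The printed national BMI table defines bands for only one gender per grade
#' (male for freshman-junior, female for senior). The synthetic cohort
#' generator needs a band label for every grade x gender stratum, so this
#' helper extends each grade's printed bands to both genders. It is a
#' synthetic construct for data generation only — the shipped scoring
#' standard ([default_bmi_standard()]) keeps exactly the printed strata.
#'
#' @return A `scoring_standard` with 8 strata.
#' @export
synthetic_bmi_standard <- function() {
  cfg <- jsonlite::read_json(default_standard_path(), simplifyVector = FALSE)
  both <- list()
  for (st in cfg$standards) {
    for (g in GENDERS) {
      st2 <- st
      st2$gender <- g
      both[[length(both) + 1L]] <- st2
    }
  }
  cfg$standards <- both
  suppressWarnings(load_scoring_standard(cfg))
}

# BMI distribution parameters per grade: truncated normal centred inside the
# "normal" band, wide enough to populate all four bands.
default_bmi_params <- function() {
  list(
    freshman  = list(mean = 16.0, sd = 2.6, lower = 8,  upper = 30),
    sophomore = list(mean = 16.2, sd = 2.6, lower = 8,  upper = 30),
    junior    = list(mean = 21.5, sd = 3.6, lower = 10, upper = 40),
    senior    = list(mean = 21.0, sd = 3.6, lower = 10, upper = 40)
  )
}

#' Synthetic cohort configuration
#'
#' Describes the student population the generator emulates: a four-grade,
#' two-gender university cohort split into tested and untested groups, with
#' tested boys the largest group, then tested girls, untested boys, untested
#' girls. The numeric default proportions (0.40/0.30/0.18/0.12, spread
#' uniformly over grades) are declared synthetic: they mimic the qualitative
#' ordering of the study population, not its unpublished percentages.
#'
#' @param n Cohort size (>= 0).
#' @param gender_tested_props Named proportions over the four gender x tested
#'   cells; must sum to 1.
#' @param grade_props Proportions over grades; must sum to 1.
#' @param bmi_params Per-grade truncated-normal BMI parameters
#'   (`mean`, `sd`, `lower`, `upper`).
#' @param standard `scoring_standard` used as the label rule (band of the
#'   true BMI). Defaults to [synthetic_bmi_standard()] so every stratum is
#'   labelable.
#' @param noise Label noise rate in `[0, 1)`: each label is flipped to a
#'   uniformly chosen other band with this probability. Default 0.05, a
#'   realistic measurement/data-entry error rate.
#' @param seed Integer RNG seed; the full cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1000,
                          gender_tested_props = c("male/tested" = 0.40,
                                                  "female/tested" = 0.30,
                                                  "male/untested" = 0.18,
                                                  "female/untested" = 0.12),
                          grade_props = c(freshman = 0.25, sophomore = 0.25,
                                          junior = 0.25, senior = 0.25),
                          bmi_params = default_bmi_params(),
                          standard = synthetic_bmi_standard(),
                          noise = 0.05,
                          seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (abs(sum(gender_tested_props) - 1) > 1e-9) {
    stop("gender_tested_props must sum to 1")
  }
  if (any(gender_tested_props < 0) || any(grade_props < 0)) {
    stop("proportions must be non-negative")
  }
  if (abs(sum(grade_props) - 1) > 1e-9) stop("grade_props must sum to 1")
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)")
  missing_p <- setdiff(GRADES, names(bmi_params))
  if (length(missing_p) > 0) {
    stop("bmi_params missing grade(s): ", paste(missing_p, collapse = ", "))
  }
  structure(list(n = as.integer(n),
                 gender_tested_props = gender_tested_props,
                 grade_props = grade_props[GRADES],
                 bmi_params = bmi_params,
                 standard = standard,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated-normal draws by rejection; bounds are several sd wide so the
# acceptance rate is high.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic student cohort
#'
#' Draws exactly `n` records: stratum membership (grade x gender x tested) is
#' multinomial with the configured proportions; BMI comes from the grade's
#' truncated normal (recorded at one decimal, like fitness-test entry forms);
#' height is drawn per gender and weight back-computed from BMI; vital
#' capacity is drawn per gender. The class label is the BMI band of the
#' record under the config's scoring standard, flipped to a random other band
#' with probability `noise`. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns id, grade, gender, tested, height, weight,
#'   bmi, vital_capacity, label.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  cols <- c("id", "grade", "gender", "tested", "height", "weight", "bmi",
            "vital_capacity", "label")
  if (n == 0L) {
    df <- data.frame(id = character(0), grade = character(0),
                     gender = character(0), tested = logical(0),
                     height = numeric(0), weight = numeric(0),
                     bmi = numeric(0), vital_capacity = numeric(0),
                     label = character(0))
    return(df)
  }
  gt <- config$gender_tested_props
  strata <- expand.grid(grade = GRADES, gt = names(gt),
                        stringsAsFactors = FALSE)
  strata$prop <- config$grade_props[strata$grade] * gt[strata$gt]

  with_seed(config$seed, {
    counts <- as.vector(stats::rmultinom(1, n, strata$prop))
    grade <- rep(strata$grade, counts)
    gt_cell <- rep(strata$gt, counts)
    gender <- sub("/.*", "", gt_cell)
    tested <- sub(".*/", "", gt_cell) == "tested"

    bmi <- numeric(n)
    for (g in GRADES) {
      idx <- which(grade == g)
      p <- config$bmi_params[[g]]
      bmi[idx] <- rtruncnorm(length(idx), p$mean, p$sd, p$lower, p$upper)
    }
    bmi <- round(bmi, 1)
    height <- round(rtruncnorm(n, ifelse(gender == "male", 1.72, 1.61),
                               0.06, 1.45, 2.00), 2)
    weight <- round(bmi * height^2, 1)
    vital_capacity <- round(rtruncnorm(n, ifelse(gender == "male", 3600, 2700),
                                       500, 1200, 7000))

    label <- vapply(seq_len(n), function(i) {
      score_index(bmi[i], grade[i], gender[i], config$standard)$band
    }, character(1))
    if (config$noise > 0) {
      flip <- stats::runif(n) < config$noise
      for (i in which(flip)) {
        others <- setdiff(BAND_LABELS, label[i])
        label[i] <- sample(others, 1L)
      }
    }
    data.frame(id = sprintf("S%05d", seq_len(n)), grade = grade,
               gender = gender, tested = tested, height = height,
               weight = weight, bmi = bmi, vital_capacity = vital_capacity,
               label = label)
  })
}

#' Stratum summary of a cohort
#'
#' Counts and proportions by grade x gender x tested status.
#'
#' @param cohort Data frame with `grade`, `gender`, `tested` columns.
#' @return Data frame with one row per observed stratum; proportions sum to 1
#'   (empty for an empty cohort).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) {
    return(data.frame(grade = character(0), gender = character(0),
                      tested = logical(0), count = integer(0),
                      proportion = numeric(0)))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(cohort))),
                          by = list(grade = cohort$grade,
                                    gender = cohort$gender,
                                    tested = cohort$tested),
                          FUN = sum)
  agg <- agg[order(agg$grade, agg$gender, agg$tested), , drop = FALSE]
  agg$proportion <- agg$count / sum(agg$count)
  rownames(agg) <- NULL
  agg
}

#' Write a cohort with a provenance manifest
#'
#' Writes the cohort as CSV and a JSON manifest (config echo, seed, package
#' version) alongside it. Output is byte-identical for identical seed and
#' config.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param config The [cohort_config()] that produced it.
#' @param path CSV output path.
#' @param manifest_path Manifest path (default: `path` with `.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, config, path,
                         manifest_path = paste0(path, ".manifest.json")) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    format = "fittree-cohort-1",
    package_version = as.character(utils::packageVersion("fittree")),
    seed = config$seed,
    n = config$n,
    noise = config$noise,
    gender_tested_props = as.list(config$gender_tested_props),
    grade_props = as.list(config$grade_props),
    bmi_params = config$bmi_params,
    standard_index = config$standard$index
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
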