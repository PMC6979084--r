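#' Cohort design for synthetic exam records
#'
#' Describes the shape of a simulated study: the number of exercised events
#' with paired TBE and lavage, and a repeat-lavage arm of sedentary horses
#' (no TBE, EIPH absent by design).  Defaults mirror the study structure:
#' 102 exercised Thoroughbred events and 9 sedentary horses lavaged twice,
#' 24 hours apart.
#'
#' @param n_exercised Number of exercised events (>= 0).
#' @param n_sedentary_horses Number of sedentary horses (>= 0).
#' @param n_occasions Lavages per sedentary horse (>= 1).
#' @param seed Integer master seed; all draws in [simulate_cohort()] flow
#'   from it.
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_exercised = 102, n_sedentary_horses = 9,
                          n_occasions = 2, seed = 20191L) {
  stopifnot(n_exercised >= 0, n_sedentary_horses >= 0, n_occasions >= 1)
  structure(list(n_exercised = as.integer(n_exercised),
                 n_sedentary_horses = as.integer(n_sedentary_horses),
                 n_occasions = as.integer(n_occasions),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Severity grades 1-4 for synthetic TBE positives, proportional to the
# observed per-score counts among positives (59, 54, 18, 4).  Descriptive
# only: the model uses positive/negative.
tbe_grade_probs <- function() {
  n <- c(59, 54, 18, 4)
  n / sum(n)
}

#' Simulate a synthetic exam cohort
#'
#' Generates exam records with exactly the statistical structure the
#' latent-class model assumes.  Each exercised event draws a latent EIPH
#' status `Bernoulli(prev)`; log BALFRBC then comes from the matching normal
#' component and TBE positivity from the matching Bernoulli (`se_tbe` given
#' EIPH, `fpr_tbe` given none).  Positive TBE outcomes receive a severity
#' grade 1-4 with fixed probabilities proportional to the observed per-score
#' counts; negatives are scored 0.  Sedentary lavages have EIPH absent by
#' design, draw log BALFRBC from the negative component, and carry no TBE
#' score.  Identical `(params, design)` input (including `design$seed`)
#' yields identical output.
#'
#' @param params An [lca_params()] object (the generating truth).
#' @param design A [cohort_design()] object.
#' @return A data frame with one row per event and columns `horse_id`,
#'   `group` ("exercised"/"sedentary"), `modality` ("treadmill",
#'   "racetrack", or "none"), `occasion`, `tbe_score` (integer 0-4, `NA`
#'   for sedentary rows), `balf_rbc` (cells/uL, > 0) and `latent_eiph`
#'   (logical; the simulated truth, unknowable in real data).
#' @examples
#' cohort <- simulate_cohort(default_study_params(), cohort_design(seed = 1))
#' table(cohort$group)
#' @export
simulate_cohort <- function(params, design) {
  if (!inherits(params, "lca_params")) params <- do.call(lca_params, as.list(params))
  validate_lca_params(params)
  stopifnot(inherits(design, "cohort_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  ex <- NULL
  if (design$n_exercised > 0) {
    n <- design$n_exercised
    eiph <- stats::runif(n) < params$prev
    mu <- ifelse(eiph, params$mu_pos, params$mu_neg)
    sg <- ifelse(eiph, params$sigma_pos, params$sigma_neg)
    y  <- stats::rnorm(n, mu, sg)
    p_pos <- ifelse(eiph, params$se_tbe, params$fpr_tbe)
    tbe_pos <- stats::runif(n) < p_pos
    score <- integer(n)
    if (any(tbe_pos))
      score[tbe_pos] <- sample.int(4L, sum(tbe_pos), replace = TRUE,
                                   prob = tbe_grade_probs())
    modality <- sample(c("treadmill", "racetrack"), n, replace = TRUE)
    ex <- data.frame(horse_id = sprintf("EX%03d", seq_len(n)),
                     group = "exercised", modality = modality,
                     occasion = 1L, tbe_score = score,
                     balf_rbc = exp(y), latent_eiph = eiph,
                     stringsAsFactors = FALSE)
  }

  sed <- NULL
  if (design$n_sedentary_horses > 0) {
    nh <- design$n_sedentary_horses
    no <- design$n_occasions
    y <- stats::rnorm(nh * no, params$mu_neg, params$sigma_neg)
    sed <- data.frame(horse_id = rep(sprintf("SED%02d", seq_len(nh)), each = no),
                      group = "sedentary", modality = "none",
                      occasion = rep(seq_len(no), times = nh),
                      tbe_score = NA_integer_,
                      balf_rbc = exp(y), latent_eiph = FALSE,
                      stringsAsFactors = FALSE)
  }

  out <- rbind(ex, sed)
  if (is.null(out))
    out <- data.frame(horse_id = character(), group = character(),
                      modality = character(), occasion = integer(),
                      tbe_score = integer(), balf_rbc = numeric(),
                      latent_eiph = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

cohort_columns <- function() {
  c("horse_id", "group", "modality", "occasion", "tbe_score",
    "balf_rbc", "latent_eiph")
}

#' Write an exam cohort to delimited text
#'
#' Comma-separated, UTF-8, with a header row; `tbe_score` is left empty for
#' sedentary rows.
#'
#' @param records Cohort data frame as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  utils::write.csv(records[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an exam cohort from delimited text
#'
#' Reads and validates the cohort format written by [write_cohort()].  Every
#' row is checked: BALFRBC counts must be strictly positive, TBE scores must
#' be integers 0-4 (or empty), group and modality tokens must be known, and
#' sedentary rows must have no TBE score.  Errors name the offending row.
#'
#' @param path Path to a cohort CSV file.
#' @return A validated cohort data frame (see [simulate_cohort()] for the
#'   schema); `latent_eiph` is `NA` if the file does not carry it.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  need <- setdiff(cohort_columns(), c("latent_eiph"))
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"latent_eiph" %in% names(raw)) raw$latent_eiph <- NA
  validate_cohort(raw[, cohort_columns()])
}

validate_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(setdiff(cohort_columns(), "latent_eiph"), names(records))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"latent_eiph" %in% names(records)) records$latent_eiph <- NA
  records$occasion <- as.integer(records$occasion)
  records$tbe_score <- as.integer(records$tbe_score)
  records$balf_rbc <- as.numeric(records$balf_rbc)
  records$latent_eiph <- as.logical(records$latent_eiph)

  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(what, " in row(s) ", paste(utils::head(i, 5), collapse = ", "),
           call. = FALSE)
  }
  bad_row(!records$group %in% c("exercised", "sedentary"),
          "unknown group token")
  bad_row(!records$modality %in% c("treadmill", "racetrack", "barrel", "none"),
          "unknown modality token")
  bad_row(!is.finite(records$balf_rbc) | records$balf_rbc <= 0,
          "non-positive balf_rbc")
  sc <- records$tbe_score
  bad_row(!is.na(sc) & (sc < 0L | sc > 4L), "tbe_score outside 0-4")
  sed <- records$group == "sedentary"
  bad_row(sed & !is.na(sc), "sedentary record with a TBE score")
  bad_row(sed & records$modality != "none",
          "sedentary record with an exercise modality")
  bad_row(sed & !is.na(records$latent_eiph) & records$latent_eiph,
          "sedentary record marked EIPH-positive")
  records
}
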