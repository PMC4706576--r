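#' Cohort of centile width profiles
#'
#' Container for a subjects x 99 width matrix with group labels, ages and an
#' optional case-control pairing.
#'
#' @param widths numeric matrix, one row per subject, 99 columns of centile
#'   widths in mm (anterior to posterior).
#' @param group character/factor with levels `case` and `control`.
#' @param age numeric ages in years (optional).
#' @param pairing integer match index: subjects sharing a value form an
#'   age-matched case-control pair; `NULL` for unpaired cohorts.
#' @param subject_id optional character ids.
#' @param config the generator configuration that produced the cohort, if any.
#' @return An object of class `cc_cohort`.
#' @export
cc_cohort <- function(widths, group, age = NULL, pairing = NULL,
                      subject_id = NULL, config = NULL) {
  widths <- as.matrix(widths)
  if (ncol(widths) != 99L)
    cc_stop("bad-cohort", "width matrix must have exactly 99 columns")
  if (anyNA(widths)) cc_stop("bad-cohort", "missing widths are not allowed")
  group <- factor(as.character(group), levels = c("case", "control"))
  if (anyNA(group)) cc_stop("bad-cohort", "group labels must be case/control")
  if (length(group) != nrow(widths))
    cc_stop("bad-cohort", "group length must match the number of subjects")
  colnames(widths) <- sprintf("w%02d", 1:99)
  if (is.null(subject_id))
    subject_id <- sprintf("s%03d", seq_len(nrow(widths)))
  rownames(widths) <- subject_id
  structure(list(widths = widths, group = group,
                 age = if (!is.null(age)) as.numeric(age),
                 pairing = if (!is.null(pairing)) as.integer(pairing),
                 subject_id = subject_id, config = config),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("<cc_cohort> %d subjects (%d case / %d control), %s\n",
              nrow(x$widths), sum(x$group == "case"),
              sum(x$group == "control"),
              if (is.null(x$pairing)) "unpaired" else "paired"))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' The schema is one row per subject: `subject_id, group, age, pairing,
#' w01..w99` plus any extra global-measure columns present (`area`,
#' `perimeter`, `centreline_length`, `convergence_iters`).
#'
#' @param cohort a [cc_cohort()].
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a [cc_cohort()] with any global-measure columns attached as the
#'   `globals` attribute.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cc_cohort"))
  df <- data.frame(subject_id = cohort$subject_id,
                   group = as.character(cohort$group),
                   age = if (is.null(cohort$age)) NA_real_ else cohort$age,
                   pairing = if (is.null(cohort$pairing)) NA_integer_
                             else cohort$pairing,
                   cohort$widths, check.names = FALSE)
  g <- attr(cohort, "globals")
  if (!is.null(g)) df <- cbind(df, g)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wcols <- sprintf("w%02d", 1:99)
  if (!all(wcols %in% names(df)))
    cc_stop("bad-cohort", "CSV lacks the 99 width columns w01..w99")
  pairing <- if (all(is.na(df$pairing))) NULL else df$pairing
  age <- if (all(is.na(df$age))) NULL else df$age
  out <- cc_cohort(as.matrix(df[, wcols]), df$group, age = age,
                   pairing = pairing, subject_id = df$subject_id)
  extra <- setdiff(names(df), c("subject_id", "group", "age", "pairing", wcols))
  if (length(extra)) attr(out, "globals") <- df[, extra, drop = FALSE]
  out
}
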