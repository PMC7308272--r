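#' Validate LOCS III photograding records
#'
#' LOCS III assigns decimal grades to four cataract components: Nuclear
#' Opalescence (NO) and Nuclear Colour (NC) on a 0.1–6.9 scale (0.1 means
#' complete nuclear transparency) and Cortical (C) and Posterior
#' subcapsular (P) on a 0.1–5.9 scale. Grades are printed to one decimal
#' place; range checks use exact decimal semantics (`round(10 * grade)`)
#' so a stored 1.9999 never passes as 2.0.
#'
#' @param grades A data frame with columns `NO`, `NC`, `C`, `P` (and
#'   optionally `eye_id`).
#'
#' @return The input as a tibble, invisibly-checked; errors name the
#'   offending component (and eye, when `eye_id` is present).
#' @export
validate_locs <- function(grades) {
  grades <- tibble::as_tibble(grades)
  need <- c("NO", "NC", "C", "P")
  missing <- setdiff(need, names(grades))
  if (length(missing) > 0) {
    stop(sprintf("missing LOCS III component column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  limits <- list(NO = c(1L, 69L), NC = c(1L, 69L),
                 C = c(1L, 59L), P = c(1L, 59L))
  for (comp in need) {
    g10 <- round(10 * grades[[comp]])
    bad <- which(is.na(g10) | g10 < limits[[comp]][1] | g10 > limits[[comp]][2])
    if (length(bad) > 0) {
      who <- if ("eye_id" %in% names(grades)) {
        sprintf(" (eye %s)", paste(grades$eye_id[bad], collapse = ", "))
      } else {
        sprintf(" (row %s)", paste(bad, collapse = ", "))
      }
      stop(sprintf(
        "%s grade out of range [%.1f, %.1f]%s",
        comp, limits[[comp]][1] / 10, limits[[comp]][2] / 10, who
      ), call. = FALSE)
    }
  }
  grades
}

#' Clinical-significance rule for LOCS III grades
#'
#' A cataract is flagged clinically significant when Cortical >= 2.0, or
#' Posterior subcapsular >= 2.0, or Nuclear Opalescence or Nuclear Colour
#' >= 2.5 (inclusive thresholds). Comparisons use exact decimal semantics.
#'
#' `is_clinically_significant()` is the vectorized predicate;
#' `flag_clinical_significance()` validates a grade table and appends a
#' logical `clinically_significant` column.
#'
#' @param NO,NC,C,P Numeric grade vectors.
#' @param thresholds Named vector of inclusive thresholds
#'   (default `c(C = 2.0, P = 2.0, NO = 2.5, NC = 2.5)`).
#'
#' @return A logical vector (predicate) or the augmented tibble (flagger).
#' @examples
#' is_clinically_significant(NO = 2.5, NC = 0.1, C = 0.1, P = 0.1) # TRUE
#' @export
is_clinically_significant <- function(NO, NC, C, P,
                                      thresholds = locs_thresholds()) {
  d <- function(x) round(10 * x)
  d(C) >= d(thresholds[["C"]]) |
    d(P) >= d(thresholds[["P"]]) |
    d(NO) >= d(thresholds[["NO"]]) |
    d(NC) >= d(thresholds[["NC"]])
}

#' @rdname is_clinically_significant
#' @param grades A data frame with `NO`, `NC`, `C`, `P` columns.
#' @export
flag_clinical_significance <- function(grades,
                                       thresholds = locs_thresholds()) {
  grades <- validate_locs(grades)
  dplyr::mutate(grades, clinically_significant = is_clinically_significant(
    .data$NO, .data$NC, .data$C, .data$P, thresholds = thresholds))
}

#' @rdname is_clinically_significant
#' @export
locs_thresholds <- function() {
  c(C = 2.0, P = 2.0, NO = 2.5, NC = 2.5)
}

#' Inter-grader bias of LOCS III scores
#'
#' Mean signed difference (grader A minus grader B), per component, over
#' eyes graded by both. A well-trained pair of graders shows less than 0.1
#' LOCS III units of bias on every component.
#'
#' @param grader_a,grader_b Data frames with `eye_id`, `NO`, `NC`, `C`, `P`;
#'   must cover the same eyes.
#'
#' @return A tibble with columns `component` and `bias` (mean a - b).
#' @export
grading_bias <- function(grader_a, grader_b) {
  a <- validate_locs(grader_a)
  b <- validate_locs(grader_b)
  if (!"eye_id" %in% names(a) || !"eye_id" %in% names(b)) {
    stop("both grade tables need an `eye_id` column", call. = FALSE)
  }
  if (nrow(a) != nrow(b) || !setequal(a$eye_id, b$eye_id) ||
      anyDuplicated(a$eye_id) || anyDuplicated(b$eye_id)) {
    stop("grader tables must cover the same set of eyes exactly once each",
         call. = FALSE)
  }
  j <- dplyr::inner_join(a, b, by = "eye_id", suffix = c("_a", "_b"))
  tibble::tibble(
    component = c("NO", "NC", "C", "P"),
    bias = unname(vapply(c("NO", "NC", "C", "P"), function(comp) {
      mean(j[[paste0(comp, "_a")]] - j[[paste0(comp, "_b")]])
    }, numeric(1)))
  )
}
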