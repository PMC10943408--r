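#' Load the packaged national youth PA / anthropometry strata table
#'
#' Reads the packaged fixture of 2021 National Survey of Children's Health
#' estimates: for each of the 24 strata (sex x age band x federal-poverty-level
#' category), the population count, the mean (and standard error) number of
#' days per week with at least 60 minutes of physical activity, and the
#' overweight and obesity prevalence in percent.
#'
#' @param path Optional path to an alternative CSV with the same columns;
#'   defaults to the packaged fixture.
#' @return A `strata_table`: a data.frame with columns `sex`, `age_band`,
#'   `fpl`, `population`, `pa_days_mean`, `pa_days_se`, `overweight_prev`,
#'   `obesity_prev`, exactly 24 rows.
#' @examples
#' tab <- load_table1()
#' subset(tab, sex == "male" & age_band == "6-10")
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_nsch2021.csv", package = "paequity")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("strata fixture not found: inst/extdata/table1_nsch2021.csv", call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_strata_table(tab, path)
  class(tab) <- c("strata_table", "data.frame")
  tab
}

validate_strata_table <- function(tab, path = "<in-memory>") {
  need <- c("sex", "age_band", "fpl", "population",
            "pa_days_mean", "pa_days_se", "overweight_prev", "obesity_prev")
  if (!all(need %in% names(tab))) {
    stop(sprintf("corrupt strata table '%s': missing columns %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) != 24L) {
    stop(sprintf("corrupt strata table '%s': expected 24 rows, got %d", path, nrow(tab)),
         call. = FALSE)
  }
  key <- interaction(tab$sex, tab$age_band, tab$fpl, drop = TRUE)
  if (anyDuplicated(key)) {
    stop(sprintf("corrupt strata table '%s': duplicated strata", path), call. = FALSE)
  }
  if (!all(tab$sex %in% SEX_LEVELS) || !all(tab$age_band %in% AGE_BANDS) ||
      !all(tab$fpl %in% FPL_LEVELS)) {
    stop(sprintf("corrupt strata table '%s': unknown sex/age_band/fpl levels", path),
         call. = FALSE)
  }
  with(tab, {
    stopifnot(all(population > 0),
              all(pa_days_mean >= 0 & pa_days_mean <= 7),
              all(pa_days_se >= 0),
              all(overweight_prev >= 0), all(obesity_prev >= 0),
              all(overweight_prev + obesity_prev <= 100))
  })
  invisible(tab)
}

# Row index helper (single stratum).
stratum_row <- function(tab, sex, age_band, fpl) {
  i <- which(tab$sex == sex & tab$age_band == age_band & tab$fpl == fpl)
  if (length(i) != 1L) stop("stratum not found: ", sex, "/", age_band, "/", fpl)
  i
}
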