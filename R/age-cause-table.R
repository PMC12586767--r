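#' Aggregate death counts and person-years by age and cause
#'
#' The central input container: one row per (single year of age, cause
#' category) holding the number of deaths and the person-years at risk.
#' Cause labels must come from a declared category set that partitions all
#' deaths; within each age the person-years are shared by all causes (the
#' same people are at risk of every cause), so `person_years` must agree
#' across rows of the same age.
#'
#' @param data data.frame with columns `age`, `cause`, `deaths`,
#'   `person_years`.
#' @param causes character vector of declared cause categories; defaults to
#'   the labels present in `data`.
#' @return An object of class `age_cause_table`: the validated data.frame,
#'   ordered by (cause, age), with attribute `causes`.
#' @export
age_cause_table <- function(data, causes = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c("age", "cause", "deaths", "person_years")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[needed]
  data$age <- as.integer(data$age)
  data$cause <- as.character(data$cause)
  if (is.null(causes)) causes <- sort(unique(data$cause))
  validate_age_cause_table(data, causes)
  data <- data[order(match(data$cause, causes), data$age), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, causes = causes, class = c("age_cause_table", "data.frame"))
}

# row-level validation with offending row numbers in the error message
validate_age_cause_table <- function(data, causes) {
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s (rows %s)", what,
                   paste(utils::head(which(cond), 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!data$cause %in% causes,
      sprintf("unknown cause label; declared: %s",
              paste(causes, collapse = ", ")))
  bad(is.na(data$age) | data$age < AGE_START | data$age > AGE_END,
      sprintf("age outside modelled range [%d, %d]", AGE_START, AGE_END))
  bad(is.na(data$deaths) | data$deaths < 0 |
        data$deaths != round(data$deaths), "deaths must be a non-negative integer")
  bad(is.na(data$person_years) | data$person_years < 0 |
        !is.finite(data$person_years), "person_years must be non-negative and finite")
  bad(duplicated(data[c("age", "cause")]), "duplicate (age, cause) pair")
  bad(data$person_years == 0 & data$deaths > 0,
      "deaths recorded where person_years is zero")
  py <- tapply(data$person_years, data$age, function(x) diff(range(x)))
  if (any(py > 1e-8 * (1 + abs(py)))) {
    stop("person_years differ across causes within the same age", call. = FALSE)
  }
}

#' @export
print.age_cause_table <- function(x, ...) {
  causes <- attr(x, "causes")
  cat(sprintf("age_cause_table: ages %d-%d, %d causes, %s deaths, %s person-years\n",
              min(x$age), max(x$age), length(causes),
              format(sum(x$deaths), big.mark = " ", scientific = FALSE),
              format(round(sum(x$person_years[!duplicated(x$age)])),
                     big.mark = " ", scientific = FALSE)))
  cat("causes:", paste(causes, collapse = ", "), "\n")
  invisible(x)
}

#' Declared cause categories of a table
#' @param table an `age_cause_table`.
#' @return Character vector of cause labels.
#' @export
causes_of <- function(table) attr(table, "causes")

# deaths as an age x cause matrix (ages 18..69 on rows, zero-filled)
counts_matrix <- function(table) {
  causes <- causes_of(table)
  ages <- model_ages()
  m <- matrix(0, length(ages), length(causes),
              dimnames = list(ages, causes))
  m[cbind(match(table$age, ages), match(table$cause, causes))] <- table$deaths
  m
}

# person-years by age (zero where unobserved)
person_years_vector <- function(table) {
  ages <- model_ages()
  first <- table[!duplicated(table$age), ]
  py <- stats::setNames(numeric(length(ages)), ages)
  py[as.character(first$age)] <- first$person_years
  py
}

#' Read an aggregate counts table from CSV
#'
#' Expects a comma-separated UTF-8 file with one row per (age, cause). The
#' default column names are `age`, `cause`, `deaths`, `person_years`; a
#' `column_map` adapts files with different headers without editing them,
#' e.g. `c(age = "ageyrs", person_years = "pyears")`.
#'
#' @param path file path.
#' @param causes declared cause set (default: labels found in the file).
#' @param column_map named character vector mapping standard names to the
#'   file's actual column names.
#' @return An [age_cause_table()].
#' @export
read_counts_csv <- function(path, causes = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) stop("column_map source column not in file: ", src)
      names(raw)[names(raw) == src] <- std
    }
  }
  age_cause_table(raw, causes = causes)
}

#' Write an aggregate counts table to CSV
#'
#' Writes the same dialect [read_counts_csv()] reads, so synthetic and real
#' data are interchangeable.
#'
#' @param table an `age_cause_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(table, path) {
  out <- as.data.frame(table)
  # %.17g round-trips doubles exactly; write.csv would stop at 15 digits
  out$person_years <- sprintf("%.17g", out$person_years)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
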