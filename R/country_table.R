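#' Load a country-year input table
#'
#' Reads the model's country-year input table from CSV or JSON. One row
#' describes one (country, year, condition) cell: target population sizes,
#' condition incidence, the home/clinic/hospital mix of where cases present,
#' baseline standard-of-care coverage and effectiveness per setting, case
#' fatality rates for effectively treated and untreated cases, and per-case
#' treatment costs. Per-setting fields are suffixed `_home`, `_clinic`,
#' `_hospital`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble with one row per (country, year, condition), sorted by
#'   country then year, with class `country_table`. Loading performs schema
#'   checks only; run [validate_inputs()] for the substantive invariants.
#' @seealso [validate_inputs()], [write_country_table()],
#'   [generate_country_inputs()]
#' @export
load_country_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     abort(sprintf("Cannot guess format of '%s'; pass `format`.", path)))
  }
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                         stringsAsFactors = FALSE)
  )
  as_country_table(df)
}

#' Coerce a data frame to a country table
#'
#' Checks the schema (all required columns present, parseable numerics),
#' coerces types, and sorts by country, condition, year.
#'
#' @param df A data frame with the columns of [country_table_template()].
#' @return A `country_table` tibble.
#' @export
as_country_table <- function(df) {
  required <- country_table_columns()
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Country table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[required]
  num_cols <- setdiff(required, c("country_code", "condition_id"))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad) > 0) {
        abort(sprintf("Unparseable value in column '%s' at row(s) %s.",
                      col, paste(head(bad, 5L), collapse = ", ")))
      }
      v <- parsed
    }
    df[[col]] <- v
  }
  df$country_code <- as.character(df$country_code)
  df$condition_id <- as.character(df$condition_id)
  df$year <- as.integer(df$year)
  df <- dplyr::arrange(df, .data$country_code, .data$condition_id, .data$year)
  class(df) <- c("country_table", class(df))
  df
}

#' @rdname load_country_table
#' @param table A `country_table` (or compatible data frame).
#' @export
write_country_table <- function(table, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     abort(sprintf("Cannot guess format of '%s'; pass `format`.", path)))
  }
  df <- as.data.frame(table)[country_table_columns()]
  if (format == "csv") {
    # full double precision so write -> load round-trips losslessly
    for (col in names(df)) {
      if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  switch(format,
    csv = utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(df, path, digits = I(17), na = "null")
  )
  invisible(path)
}

#' An empty country table with the right schema
#'
#' @return A zero-row `country_table` tibble, useful as a template when
#'   assembling inputs programmatically.
#' @export
country_table_template <- function() {
  cols <- country_table_columns()
  df <- tibble::as_tibble(setNames(
    lapply(cols, function(col) {
      if (col %in% c("country_code", "condition_id")) character(0)
      else if (col == "year") integer(0)
      else numeric(0)
    }), cols
  ))
  class(df) <- c("country_table", class(df))
  df
}

#' Validate country-year inputs
#'
#' Checks every substantive invariant of the input contract and reports all
#' violations (not only the first) as data, never as exceptions:
#' setting mix sums to 1 (tolerance 1e-9); every fraction lies in \[0, 1\];
#' incidence is non-negative (diarrhea episodes per child-year may exceed 1);
#' treated CFR does not exceed untreated CFR in any setting; population
#' counts and costs are non-negative; years fall within the model horizon;
#' condition identifiers are known.
#'
#' @param records A `country_table` (or compatible data frame).
#' @param horizon Length-2 integer vector of allowed years, default
#'   `c(2015, 2030)`.
#' @return A `validation_report`: list with tibbles `errors` and `warnings`
#'   (columns `row`, `country_code`, `year`, `condition_id`, `rule`,
#'   `message`) and logical `valid`. Empty `errors` means downstream
#'   operations accept the input.
#' @export
validate_inputs <- function(records, horizon = c(2015L, 2030L)) {
  df <- tibble::as_tibble(records)
  n <- nrow(df)
  errs <- list()
  warns <- list()
  note <- function(rows, rule, message) {
    if (length(rows) == 0) return(NULL)
    tibble::tibble(
      row = as.integer(rows),
      country_code = df$country_code[rows],
      year = df$year[rows],
      condition_id = df$condition_id[rows],
      rule = rule,
      message = message
    )
  }

  mix <- df$setting_mix_home + df$setting_mix_clinic + df$setting_mix_hospital
  errs <- c(errs, list(note(which(abs(mix - 1) > 1e-9), "setting_mix_sum",
                            "setting_mix fractions must sum to 1")))

  frac_cols <- c(setting_cols("setting_mix"), setting_cols("baseline_coverage"),
                 setting_cols("baseline_effectiveness"), setting_cols("cfr_treated"),
                 setting_cols("cfr_untreated"), "eligible_fraction")
  for (col in frac_cols) {
    bad <- which(!is_fraction(df[[col]]))
    errs <- c(errs, list(note(bad, paste0("fraction_bounds:", col),
                              sprintf("%s must be in [0, 1]", col))))
  }

  errs <- c(errs, list(note(which(is.na(df$incidence) | df$incidence < 0),
                            "incidence_nonneg", "incidence must be >= 0")))

  for (s in .settings) {
    ct <- df[[paste0("cfr_treated_", s)]]
    cu <- df[[paste0("cfr_untreated_", s)]]
    bad <- which(!is.na(ct) & !is.na(cu) & ct > cu)
    errs <- c(errs, list(note(bad, paste0("cfr_order:", s),
                              sprintf("cfr_treated_%s must not exceed cfr_untreated_%s", s, s))))
  }

  count_cols <- c("live_births", "neonates", "under5_population", "pregnancies",
                  setting_cols("treatment_cost_per_case"))
  for (col in count_cols) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    errs <- c(errs, list(note(bad, paste0("nonneg:", col),
                              sprintf("%s must be >= 0", col))))
  }

  bad_year <- which(is.na(df$year) | df$year < horizon[1] | df$year > horizon[2])
  errs <- c(errs, list(note(bad_year, "year_in_horizon",
                            sprintf("year must be in [%d, %d]", horizon[1], horizon[2]))))

  bad_cond <- which(!df$condition_id %in% condition_ids())
  errs <- c(errs, list(note(bad_cond, "known_condition",
                            sprintf("condition_id must be one of: %s",
                                    paste(condition_ids(), collapse = ", ")))))

  bad_code <- which(!grepl("^[A-Z]{3}$", df$country_code))
  warns <- c(warns, list(note(bad_code, "country_code_format",
                              "country_code is not ISO-3166 alpha-3 (AAA)")))

  dup <- which(duplicated(df[c("country_code", "year", "condition_id")]))
  errs <- c(errs, list(note(dup, "duplicate_key",
                            "duplicate (country, year, condition) row")))

  empty <- tibble::tibble(row = integer(0), country_code = character(0),
                          year = integer(0), condition_id = character(0),
                          rule = character(0), message = character(0))
  errors <- dplyr::bind_rows(c(list(empty), errs))
  warnings <- dplyr::bind_rows(c(list(empty), warns))
  structure(
    list(errors = dplyr::arrange(errors, .data$row),
         warnings = dplyr::arrange(warnings, .data$row),
         n_records = n,
         valid = nrow(errors) == 0L),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d record(s): %s\n", x$n_records,
              if (x$valid) "valid" else sprintf("%d error(s)", nrow(x$errors))))
  if (nrow(x$errors) > 0) {
    print(x$errors, n = 20)
  }
  if (nrow(x$warnings) > 0) {
    cat(sprintf("%d warning(s)\n", nrow(x$warnings)))
  }
  invisible(x)
}

# Stop unless a table validates cleanly; used by engine entry points.
assert_valid_inputs <- function(records, horizon = c(2015L, 2030L)) {
  report <- validate_inputs(records, horizon = horizon)
  if (!report$valid) {
    first <- report$errors[1, ]
    abort(sprintf(
      "Country table failed validation with %d error(s); first: row %d (%s %s %s): %s.",
      nrow(report$errors), first$row, first$country_code, first$year,
      first$condition_id, first$message
    ))
  }
  invisible(records)
}
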