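#' Default identifying-field schema
#'
#' The standard field set used for record linkage on personal identifying
#' information (PII): given name, family name, the three date-of-birth
#' components, postal code and city. Date components are carried as separate
#' fields so that a single wrong component (a common data-entry error) only
#' perturbs one comparison.
#'
#' @return Character vector of field names.
#' @export
default_field_schema <- function() {
  c("first_name", "last_name", "birth_day", "birth_month", "birth_year",
    "zip", "city")
}

#' Normalize a PII field value for comparison
#'
#' Uppercases, transliterates Unicode to ASCII (diacritics stripped), and
#' removes every non-alphanumeric character. Empty results and `NA` input
#' are returned as `NA` (missing). Vectorized.
#'
#' @param x Character vector of raw values.
#' @return Character vector of normalized values (`NA` = missing).
#' @export
#' @examples
#' normalize_value(c("Müller-Lüdenscheidt", " anna ", ""))
normalize_value <- function(x) {
  x <- as.character(x)
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]", "", x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Split an ISO-8601 date into linkage components
#'
#' @param x Character or `Date` vector (`YYYY-MM-DD`).
#' @return Tibble with `birth_day`, `birth_month`, `birth_year` as
#'   zero-padded strings (`NA` where unparseable).
#' @export
split_birth_date <- function(x) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  tibble::tibble(
    birth_day   = ifelse(is.na(d), NA_character_, format(d, "%d")),
    birth_month = ifelse(is.na(d), NA_character_, format(d, "%m")),
    birth_year  = ifelse(is.na(d), NA_character_, format(d, "%Y"))
  )
}

#' Normalize a named record against a field schema
#'
#' Unknown field names are an error; schema fields absent from the input are
#' carried as missing. A `birth_date` convenience field is split into its
#' three components before normalization.
#'
#' @param fields Named character vector or list of raw field values.
#' @param schema Character vector of allowed field names.
#' @return Named character vector covering `schema` (`NA` = missing).
#' @export
normalize_record <- function(fields, schema = default_field_schema()) {
  fields <- unlist(fields)
  if (is.null(names(fields)) && length(fields) > 0) {
    stop("record fields must be named", call. = FALSE)
  }
  fields <- fields[!is.na(names(fields))]
  if ("birth_date" %in% names(fields)) {
    comp <- split_birth_date(fields[["birth_date"]])
    fields <- fields[names(fields) != "birth_date"]
    fields <- c(fields, birth_day = comp$birth_day[1],
                birth_month = comp$birth_month[1],
                birth_year = comp$birth_year[1])
  }
  unknown <- setdiff(names(fields), schema)
  if (length(unknown) > 0) {
    stop("unknown field name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(rep(NA_character_, length(schema)), schema)
  out[names(fields)] <- normalize_value(unname(fields))
  out
}
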