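# Synthetic name pools. Built deterministically (no RNG) from syllable
# enumeration; entirely synthetic stand-ins for real name-frequency lists.
# Frequencies follow a flattened Zipf law 1/(rank + 20), which puts the most
# common name near 1.2% — consistent with the default EpiLink f values.
.pool_cache <- new.env(parent = emptyenv())

#' Synthetic name-frequency pool
#'
#' Deterministic pools of ~1,000 pronounceable synthetic first and last
#' names (and ~60 city names with postal codes), with rank-based sampling
#' frequencies. Synthetic by construction: no list of real persons or places
#' is shipped.
#'
#' @param kind `"first"`, `"last"` or `"city"`.
#' @return Tibble with `name`, `freq` (and `zip` for cities).
#' @export
name_pool <- function(kind = c("first", "last", "city")) {
  kind <- match.arg(kind)
  if (!is.null(.pool_cache[[kind]])) return(.pool_cache[[kind]])
  zipf <- function(n) { w <- 1 / (seq_len(n) + 20); w / sum(w) }
  out <- switch(kind,
    first = {
      on <- c("AN", "BE", "CARO", "DA", "ELI", "FRE", "GRE", "HAN", "IRE",
              "JO", "KA", "LEO", "MARI", "NI", "OT", "PAU", "RO", "SIMO",
              "THE", "ULI", "VERA", "WIL", "XE", "YAS", "ZO")
      off <- c("NA", "LA", "RA", "SA", "TAS", "NE", "LIE", "REK", "NES",
               "TA", "KO", "MIR", "DIN", "LON", "BEL", "RIT", "GON", "VAN",
               "NIS", "LET", "MON", "DRA", "SEL", "TIN", "REN", "KAS", "LIN",
               "NOR", "MAT", "VES", "RIN", "TEL", "DAN", "SON", "LIT", "NAK",
               "REL", "MIS", "TOR", "BEN")
      names <- as.vector(outer(on, off, paste0))
      tibble::tibble(name = names, freq = zipf(length(names)))
    },
    last = {
      st <- c("BACH", "KORN", "LIND", "HOF", "BERG", "WALD", "STEIN", "FELD",
              "GRUN", "ROTH", "NEU", "ALT", "KLEIN", "GROSS", "WEIS", "SCHWARZ",
              "BRAUN", "KRAUS", "VOGEL", "FUCHS", "WOLF", "HIRSCH", "ADLER",
              "LOWEN", "FINK")
      sf <- c("MANN", "ER", "NER", "LER", "MEIER", "HUBER", "BAUER", "HAUS",
              "HAGEN", "FELS", "GARTEN", "BRUCK", "THAL", "DORF", "HEIM",
              "WIESE", "ECK", "RICH", "HARDT", "BERGER", "MULLER", "SCHMID",
              "WEBER", "BECKER", "KELLER", "NAGEL", "RIED", "STETTER", "WIRT",
              "FORST", "HOLZ", "KAMP", "LOHR", "MOOR", "PFAD", "QUELL",
              "RAIN", "SAND", "TANN", "UFER")
      names <- as.vector(outer(st, sf, paste0))
      tibble::tibble(name = names, freq = zipf(length(names)))
    },
    city = {
      a <- c("NORD", "SUED", "OST", "WEST", "NEU", "ALT", "OBER", "UNTER",
             "GROSS", "KLEIN", "HOHEN", "NIEDER")
      b <- c("STADT", "BERG", "DORF", "HAUSEN", "FELDEN")
      names <- as.vector(outer(a, b, paste0))
      tibble::tibble(name = names, freq = zipf(length(names)),
                     zip = sprintf("%05d", 10000 + 731 * seq_along(names)))
    })
  .pool_cache[[kind]] <- out
  out
}

#' Error model for synthetic duplicate records
#'
#' Per-field, per-duplicate corruption rates emulating data-entry noise:
#' character substitution, insertion, deletion and adjacent transposition on
#' string fields; dropped optional fields; and wrong date components. All
#' rates are probabilities in `[0, 1]`; the model is fully determined by the
#' RNG state it is applied under.
#'
#' @param substitution,insertion,deletion,transposition Per-string-field
#'   rates.
#' @param field_missing Rate at which an optional field (city, zip) is
#'   dropped.
#' @param date_component_error Per-component rate of a wrong birth-date
#'   part.
#' @return An `error_model` object.
#' @export
error_model <- function(substitution = 0.02, insertion = 0.01,
                        deletion = 0.01, transposition = 0.01,
                        field_missing = 0.01, date_component_error = 0.01) {
  rates <- c(substitution = substitution, insertion = insertion,
             deletion = deletion, transposition = transposition,
             field_missing = field_missing,
             date_component_error = date_component_error)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(as.list(rates), class = "error_model")
}

.str_fields <- c("first_name", "last_name", "city", "zip")
.optional_fields <- c("city", "zip")
.date_fields <- c("birth_day", "birth_month", "birth_year")

.field_alphabet <- function(field) {
  if (field == "zip") strsplit("0123456789", "")[[1]]
  else strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
}

#' Corrupt a record under an error model
#'
#' Applies each corruption kind independently per configured rate and
#' reports which were applied. Uncorrupted fields are returned unchanged, so
#' they stay comparable. Uses the current RNG state; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param fields Named character vector (schema fields).
#' @param model An [error_model()].
#' @return List with `fields` (corrupted record) and `corruptions`
#'   (character vector of `field:kind` tags).
#' @export
corrupt_record <- function(fields, model = error_model()) {
  stopifnot(inherits(model, "error_model"))
  tags <- character(0)
  for (f in intersect(.str_fields, names(fields))) {
    v <- fields[[f]]
    if (is.na(v)) next
    ab <- .field_alphabet(f)
    if (stats::runif(1) < model$substitution && nchar(v) >= 1) {
      pos <- sample.int(nchar(v), 1)
      old <- substr(v, pos, pos)
      substr(v, pos, pos) <- sample(setdiff(ab, old), 1)
      tags <- c(tags, paste0(f, ":substitution"))
    }
    if (stats::runif(1) < model$insertion) {
      pos <- sample.int(nchar(v) + 1, 1)
      v <- paste0(substr(v, 1, pos - 1), sample(ab, 1),
                  substr(v, pos, nchar(v)))
      tags <- c(tags, paste0(f, ":insertion"))
    }
    if (stats::runif(1) < model$deletion && nchar(v) > 1) {
      pos <- sample.int(nchar(v), 1)
      v <- paste0(substr(v, 1, pos - 1), substr(v, pos + 1, nchar(v)))
      tags <- c(tags, paste0(f, ":deletion"))
    }
    if (stats::runif(1) < model$transposition && nchar(v) >= 2) {
      pos <- sample.int(nchar(v) - 1, 1)
      pair <- substr(v, pos, pos + 1)
      substr(v, pos, pos + 1) <- paste0(substr(pair, 2, 2), substr(pair, 1, 1))
      tags <- c(tags, paste0(f, ":transposition"))
    }
    fields[[f]] <- v
  }
  for (f in intersect(.optional_fields, names(fields))) {
    if (!is.na(fields[[f]]) && stats::runif(1) < model$field_missing) {
      fields[[f]] <- NA_character_
      tags <- c(tags, paste0(f, ":missing"))
    }
  }
  for (f in intersect(.date_fields, names(fields))) {
    if (is.na(fields[[f]])) next
    if (stats::runif(1) < model$date_component_error) {
      rng <- switch(f, birth_day = 1:28, birth_month = 1:12,
                    birth_year = 1935:2004)
      old <- as.integer(fields[[f]])
      new <- sample(setdiff(rng, old), 1)
      fields[[f]] <- if (f == "birth_year") sprintf("%04d", new)
                     else sprintf("%02d", new)
      tags <- c(tags, paste0(f, ":date_component"))
    }
  }
  list(fields = fields, corruptions = tags)
}

#' Generate a synthetic cohort with ground-truth duplicates
#'
#' Draws `n_base` unique persons from the synthetic name pools (names
#' sampled proportional to pool frequency, birth dates uniform over
#' 1935-2004, city/zip linked), then produces `n_duplicates` additional
#' records by corrupting sampled base records under `model`. Byte-identical
#' output for a fixed seed.
#'
#' @param n_base Number of base records.
#' @param n_duplicates Number of corrupted duplicate records
#'   (`<= n_base`).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @return List with `records` (tibble, base rows first, column `row`) and
#'   `truth` (tibble `base_row`, `dup_row`, `corruptions`).
#' @export
generate_cohort <- function(n_base, n_duplicates = 0, model = error_model(),
                            seed = 1) {
  if (n_duplicates > n_base) stop("n_duplicates must not exceed n_base",
                                  call. = FALSE)
  if (n_base < 1) stop("n_base must be positive", call. = FALSE)
  fp <- name_pool("first"); lp <- name_pool("last"); cp <- name_pool("city")
  withr::with_seed(seed, {
    first <- sample(fp$name, n_base, replace = TRUE, prob = fp$freq)
    last <- sample(lp$name, n_base, replace = TRUE, prob = lp$freq)
    ci <- sample.int(nrow(cp), n_base, replace = TRUE, prob = cp$freq)
    dates <- as.Date("1935-01-01") +
      sample.int(as.integer(as.Date("2005-01-01") - as.Date("1935-01-01")),
                 n_base, replace = TRUE) - 1L
    base <- tibble::tibble(
      row = seq_len(n_base),
      first_name = first, last_name = last,
      birth_day = format(dates, "%d"), birth_month = format(dates, "%m"),
      birth_year = format(dates, "%Y"),
      zip = cp$zip[ci], city = cp$name[ci]
    )
    if (n_duplicates > 0) {
      base_rows <- sample.int(n_base, n_duplicates, replace = TRUE)
      dup_list <- vector("list", n_duplicates)
      tags <- character(n_duplicates)
      for (i in seq_len(n_duplicates)) {
        src <- as.list(base[base_rows[i], -1])
        cr <- corrupt_record(unlist(src), model)
        dup_list[[i]] <- tibble::as_tibble_row(as.list(cr$fields))
        tags[i] <- paste(cr$corruptions, collapse = ";")
      }
      dups <- dplyr::bind_rows(dup_list)
      dups$row <- n_base + seq_len(n_duplicates)
      records <- dplyr::bind_rows(base, dups)
      truth <- tibble::tibble(base_row = base_rows,
                              dup_row = n_base + seq_len(n_duplicates),
                              corruptions = tags)
    } else {
      records <- base
      truth <- tibble::tibble(base_row = integer(), dup_row = integer(),
                              corruptions = character())
    }
    list(records = records, truth = truth)
  })
}
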