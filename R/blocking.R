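#' American Soundex code of a name
#'
#' Classic 4-character phonetic code (first letter + three digits): digit
#' classes B/F/P/V=1, C/G/J/K/Q/S/X/Z=2, D/T=3, L=4, M/N=5, R=6; H and W are
#' transparent (a repeated digit separated only by H/W collapses); vowels are
#' dropped but break a run; the result is zero-padded. Homophones such as
#' MEIER/MAYER map to the same code, which is what makes it useful as a
#' blocking key. Vectorized.
#'
#' @param value Character vector; non-letters are removed first. Empty or
#'   missing values yield the sentinel code `"0000"`.
#' @return Character vector of 4-character codes.
#' @export
#' @examples
#' soundex_encode(c("Robert", "Rupert", "Meier", "Mayer"))
soundex_encode <- function(value) {
  value <- toupper(as.character(value))
  value <- gsub("[^A-Z]", "", value)
  digit <- rep("0", 26)
  names(digit) <- LETTERS
  digit[c("B", "F", "P", "V")] <- "1"
  digit[c("C", "G", "J", "K", "Q", "S", "X", "Z")] <- "2"
  digit[c("D", "T")] <- "3"
  digit["L"] <- "4"
  digit[c("M", "N")] <- "5"
  digit["R"] <- "6"
  digit[c("H", "W")] <- "-"
  vapply(value, function(v) {
    if (is.na(v) || !nzchar(v)) return("0000")
    ch <- strsplit(v, "")[[1]]
    codes <- digit[ch]
    out <- character(0)
    prev <- codes[1]
    for (c in codes[-1]) {
      if (c == "-") next          # H/W: transparent, run continues
      if (c == "0") { prev <- "0"; next }  # vowel: drop, break run
      if (c != prev) out <- c(out, c)
      prev <- c
      if (length(out) >= 3) break
    }
    paste0(ch[1], paste(c(out, "0", "0", "0")[1:3], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Blocking configuration
#'
#' Blocking clusters records into buckets keyed by cheap approximate codes so
#' that only within-bucket pairs get scored. Keys from all configured
#' variables are combined with union (OR) semantics: a typo that breaks one
#' blocked field cannot hide a record from the others. A record missing all
#' blocked fields produces no keys and falls back to full comparison.
#'
#' @param variables List of `list(field =, method =)` pairs; methods are
#'   `"SOUNDEX"` (phonetic code of a name field), `"EXACT"` (verbatim value,
#'   e.g. birth year) and `"LSH"` (locality-sensitive bands of the field's
#'   Bloom encoding).
#' @param enabled Disable to force exhaustive comparison (the oracle path).
#' @param bands,band_bits,lsh_seed LSH parameters (see [lsh_keys()]).
#' @return A `blocking_config` object.
#' @export
blocking_config <- function(variables = list(
                              list(field = "last_name", method = "SOUNDEX"),
                              list(field = "birth_year", method = "EXACT"),
                              list(field = "first_name", method = "LSH")
                            ),
                            enabled = TRUE,
                            bands = 8, band_bits = 32, lsh_seed = 42) {
  if (enabled && length(variables) == 0) {
    stop("blocking requires at least one variable when enabled", call. = FALSE)
  }
  for (v in variables) {
    if (!all(c("field", "method") %in% names(v)) ||
        !v$method %in% c("SOUNDEX", "EXACT", "LSH")) {
      stop("each blocking variable needs a field and a method in SOUNDEX/EXACT/LSH",
           call. = FALSE)
    }
  }
  structure(
    list(variables = variables, enabled = enabled, bands = bands,
         band_bits = band_bits, lsh_seed = lsh_seed),
    class = "blocking_config"
  )
}

#' Blocking keys of one identity
#'
#' One tagged key per configured variable per non-missing field (several for
#' LSH bands). Missing fields simply contribute no key.
#'
#' @param fields Named character vector of normalized field values.
#' @param config A [blocking_config()].
#' @param bloom_cfg A [bloom_config()]; required when any variable uses LSH.
#' @return Character vector of tagged keys (possibly empty).
#' @export
block_keys <- function(fields, config, bloom_cfg = NULL) {
  stopifnot(inherits(config, "blocking_config"))
  keys <- character(0)
  for (v in config$variables) {
    val <- fields[[v$field]]
    if (is.null(val) || is.na(val)) next
    tag <- paste0(v$field, "~", v$method, "=")
    if (v$method == "SOUNDEX") {
      keys <- c(keys, paste0(tag, soundex_encode(val)))
    } else if (v$method == "EXACT") {
      keys <- c(keys, paste0(tag, val))
    } else {
      if (is.null(bloom_cfg)) {
        stop("LSH blocking requires a bloom_config", call. = FALSE)
      }
      bf <- bloom_encode(val, bloom_cfg)
      keys <- c(keys, paste0(tag, lsh_keys(bf, config$bands, config$band_bits,
                                           config$lsh_seed)))
    }
  }
  unique(keys)
}
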