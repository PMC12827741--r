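#' Per-field comparator configuration
#'
#' Each linkage field carries a comparator and two probabilities: the error
#' rate `e` (chance that the field disagrees for records of the same person,
#' e.g. through typos) and the frequency `f` (chance that two different
#' people agree by coincidence, roughly the frequency of the most common
#' value). These give the field its agreement weight
#' `w = log2((1 - e) / f)`: rare, reliable fields (last name) weigh more than
#' common, error-prone ones (birth month).
#'
#' @param field_name Schema field the comparator applies to.
#' @param comparator `"NGRAM_DICE"` (Dice similarity of padded bigram
#'   multisets, typo-tolerant), `"EXACT"`, or `"DATE_COMPONENT"` (exact
#'   comparison of an already-split date component).
#' @param e Error rate in (0, 1).
#' @param f Agreement-by-chance frequency in (0, 1); `(1 - e) / f` must
#'   exceed 1 so the weight is positive.
#' @return A one-row tibble.
#' @export
field_comparator <- function(field_name,
                             comparator = c("NGRAM_DICE", "EXACT", "DATE_COMPONENT"),
                             e = 0.01, f) {
  comparator <- match.arg(comparator)
  if (!(e > 0 && e < 1)) stop("e must be in (0,1)", call. = FALSE)
  if (!(f > 0 && f < 1)) stop("f must be in (0,1)", call. = FALSE)
  if ((1 - e) / f <= 1) {
    stop("(1-e)/f must exceed 1 so the field weight is positive", call. = FALSE)
  }
  tibble::tibble(field = field_name, comparator = comparator, e = e, f = f,
                 w = log2((1 - e) / f))
}

#' Default comparators for the standard field schema
#'
#' Frequencies reflect typical most-common-value frequencies: ~1% for a
#' given name, ~0.5% for a family name, uniform 1/31, 1/12 and 1/70 for the
#' birth-date components, ~1% for a postal code and ~5% for a city.
#'
#' @return Tibble of comparator rows (see [field_comparator()]).
#' @export
default_comparators <- function() {
  dplyr::bind_rows(
    field_comparator("first_name", "NGRAM_DICE", e = 0.01, f = 0.01),
    field_comparator("last_name", "NGRAM_DICE", e = 0.01, f = 0.005),
    field_comparator("birth_day", "DATE_COMPONENT", e = 0.01, f = 1 / 31),
    field_comparator("birth_month", "DATE_COMPONENT", e = 0.01, f = 1 / 12),
    field_comparator("birth_year", "DATE_COMPONENT", e = 0.01, f = 1 / 70),
    field_comparator("zip", "NGRAM_DICE", e = 0.01, f = 0.01),
    field_comparator("city", "NGRAM_DICE", e = 0.01, f = 0.05)
  )
}

#' Record-linkage configuration
#'
#' The weighted similarity score of two identities lies in `[0, 1]`; two
#' thresholds cut it into three zones: at or above `threshold_match` the pair
#' is a match, below `threshold_nonmatch` a non-match, and in between a
#' tentative match queued for human conflict resolution. With
#' `auto_reject_tentative`, tentative pairs are instead reported as rejected
#' non-matches (the submitter must double-check the data and retry).
#'
#' @param comparators Tibble of [field_comparator()] rows.
#' @param threshold_nonmatch,threshold_match Lower and upper threshold in
#'   `[0, 1]`, lower <= upper. Boundaries are inclusive upward: a score equal
#'   to `threshold_match` is a match.
#' @param auto_reject_tentative Report tentative matches as rejected
#'   non-matches instead of queueing them.
#' @return A `linkage_config` object.
#' @export
linkage_config <- function(comparators = default_comparators(),
                           threshold_nonmatch = 0.80,
                           threshold_match = 0.95,
                           auto_reject_tentative = FALSE) {
  if (!(threshold_nonmatch >= 0 && threshold_nonmatch <= threshold_match &&
        threshold_match <= 1)) {
    stop("require 0 <= threshold_nonmatch <= threshold_match <= 1", call. = FALSE)
  }
  structure(
    list(comparators = comparators,
         threshold_nonmatch = threshold_nonmatch,
         threshold_match = threshold_match,
         auto_reject_tentative = auto_reject_tentative,
         # plain-vector view of the comparator table for the scoring hot path
         fast = list(fields = comparators$field,
                     dice = comparators$comparator == "NGRAM_DICE",
                     w = comparators$w)),
    class = "linkage_config"
  )
}

#' Compare two field values
#'
#' Symmetric; 1 for equal non-missing values; `NA` (missing) when either
#' side is absent. `b` may be a vector. Values are assumed normalized
#' (see [normalize_value()]).
#'
#' @param a Single value.
#' @param b Value or vector of values.
#' @param comparator One of `"NGRAM_DICE"`, `"EXACT"`, `"DATE_COMPONENT"`.
#' @return Numeric vector of similarities in `[0, 1]` with `NA` = missing.
#' @export
#' @examples
#' compare_field("ANNA", "ANA", "NGRAM_DICE")  # 8/9
compare_field <- function(a, b, comparator = "NGRAM_DICE") {
  if (comparator %in% c("EXACT", "DATE_COMPONENT")) {
    out <- as.numeric(a == b)
    out[is.na(a) | is.na(b)] <- NA_real_
    return(out)
  }
  if (comparator != "NGRAM_DICE") stop("unknown comparator", call. = FALSE)
  if (is.na(a)) return(rep(NA_real_, length(b)))
  ga <- extract_ngrams(a)
  vapply(b, function(bv) {
    if (is.na(bv)) return(NA_real_)
    dice_grams(ga, extract_ngrams(bv))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Weighted similarity score of two identities
#'
#' `sum(w_i * s_i) / sum(w_i)` over the fields non-missing on both sides,
#' with per-field weights `w_i = log2((1 - e_i) / f_i)`. Symmetric, bounded
#' in `[0, 1]`, and equal to 1 when all shared fields agree. Fields missing
#' on either side are excluded from numerator and denominator alike.
#'
#' @param a,b Named character vectors of normalized field values
#'   (`NA` = missing).
#' @param config A [linkage_config()].
#' @param detail Also return per-field similarities.
#' @return Score, or (with `detail`) a list with `score` and
#'   `per_field` (named numeric, `NA` where not comparable).
#' @export
epilink_score <- function(a, b, config, detail = FALSE) {
  stopifnot(inherits(config, "linkage_config"))
  a <- as.list(a)
  b <- as.list(b)
  cmp <- config$comparators
  sims <- numeric(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    av <- a[[cmp$field[i]]]
    bv <- b[[cmp$field[i]]]
    sims[i] <- if (is.null(av) || is.null(bv) || is.na(av) || is.na(bv)) {
      NA_real_
    } else {
      compare_field(av, bv, cmp$comparator[i])
    }
  }
  present <- !is.na(sims)
  if (!any(present)) stop("no comparable fields between the two identities",
                          call. = FALSE)
  score <- sum(cmp$w[present] * sims[present]) / sum(cmp$w[present])
  if (!detail) return(score)
  list(score = score,
       per_field = stats::setNames(sims, cmp$field))
}

#' Classify a similarity score against the two thresholds
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param config A [linkage_config()].
#' @return Tibble with `score`, `decision` (`MATCH`/`TENTATIVE`/`NON_MATCH`)
#'   and `rejected_tentative` (`TRUE` when an auto-rejected tentative score
#'   was reported as `NON_MATCH`).
#' @export
classify <- function(score, config) {
  stopifnot(inherits(config, "linkage_config"))
  decision <- ifelse(score >= config$threshold_match, "MATCH",
                     ifelse(score >= config$threshold_nonmatch, "TENTATIVE",
                            "NON_MATCH"))
  rejected <- rep(FALSE, length(score))
  if (config$auto_reject_tentative) {
    rejected <- decision == "TENTATIVE"
    decision[rejected] <- "NON_MATCH"
  }
  tibble::tibble(score = score, decision = decision,
                 rejected_tentative = rejected)
}

# --- internal fast scoring path used by the store -------------------------

# Precompute the comparison representation of a normalized identity: field
# values in comparator order, plus occurrence-indexed gram multisets for
# NGRAM_DICE fields (make.unique turns multiset intersection into plain
# match()-based set intersection).
.prepare_identity <- function(norm, config) {
  fast <- config$fast
  vals <- unname(norm[fast$fields])
  grams <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    if (fast$dice[i] && !is.na(vals[i])) {
      grams[[i]] <- make.unique(extract_ngrams(vals[i]), sep = "\x1f")
    }
  }
  list(norm = norm, vals = vals, grams = grams)
}

# Score one prepared probe against one prepared identity entry. Returns a
# bare numeric score (NA_real_ if no comparable fields).
.score_prepared <- function(probe, entry, fast) {
  va <- probe$vals
  vb <- entry$vals
  w <- fast$w
  num <- 0
  den <- 0
  for (i in seq_along(w)) {
    av <- va[i]
    bv <- vb[i]
    if (is.na(av) || is.na(bv)) next
    if (fast$dice[i]) {
      ia <- probe$grams[[i]]
      ib <- entry$grams[[i]]
      s <- 2 * sum(match(ia, ib, 0L) > 0L) / (length(ia) + length(ib))
    } else {
      s <- if (av == bv) 1 else 0
    }
    num <- num + w[i] * s
    den <- den + w[i]
  }
  if (den == 0) return(NA_real_)
  num / den
}
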