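#' Create a patient store
#'
#' The store is the central, mutable registry: patients with their (append
#' only) identities, pseudonyms, tenants, tentative-match pairs, consents
#' and an audit trail. One identity per patient is the MAIN identity shown
#' to users; earlier identities are kept as ALIAS identities and still take
#' part in record linkage.
#'
#' @param schema Field schema (see [default_field_schema()]).
#' @param linkage A [linkage_config()].
#' @param blocking A [blocking_config()].
#' @param secret Master secret string; the PID mixing key, per-type
#'   pseudonym keys and the Bloom/LSH hash key are derived from it.
#' @param pid_payload_length Payload length of internally generated PIDs.
#' @return A `patient_store` (environment-backed; modified in place).
#' @export
patient_store <- function(schema = default_field_schema(),
                          linkage = linkage_config(),
                          blocking = blocking_config(),
                          secret = "pseudolink-dev-secret",
                          pid_payload_length = 6) {
  st <- new.env(parent = emptyenv())
  st$schema <- schema
  st$linkage <- linkage
  st$blocking <- blocking
  st$secret <- secret
  st$patients <- list()
  st$entries <- list()            # per patient: list of prepared identities
  st$pseud_index <- new.env(parent = emptyenv())   # "type\x1fvalue" -> key
  st$block_index <- new.env(parent = emptyenv())   # block key -> patient keys
  st$tentative <- list()          # list of list(a, b, score, resolved)
  st$exclusions <- new.env(parent = emptyenv())    # "a|b" -> TRUE after split
  st$audit <- list()
  st$consent_templates <- new.env(parent = emptyenv())
  st$consents <- list()           # per patient key: list of consent records
  st$counters <- new.env(parent = emptyenv())
  st$counters$patient <- 0L
  st$ptypes <- list()
  st$bloom <- bloom_config(hmac_secret = paste0("bloom:", secret))
  class(st) <- "patient_store"
  register_pseudonym_type(st, "pid", kind = "internal",
                          payload_length = pid_payload_length)
  st
}

#' @export
print.patient_store <- function(x, ...) {
  cat(sprintf("<patient_store> %d patients, %d tentative pair(s), %d pseudonym type(s)\n",
              n_patients(x), nrow(list_tentative_pairs(x)), length(x$ptypes)))
  invisible(x)
}

#' Number of non-absorbed, non-deleted patients
#' @param store A [patient_store()].
#' @return Integer count.
#' @export
n_patients <- function(store) {
  sum(vapply(store$patients, function(p) is.na(p$duplicate_of) && !p$deleted,
             logical(1)))
}

#' Register a pseudonym type
#'
#' Internal types are generated by the store from a per-type counter through
#' the keyed PID code and are immutable; external types are supplied by other
#' systems and stay editable. Multi-valued types (e.g. biosample IDs) may
#' hold several values per patient.
#'
#' @param store A [patient_store()].
#' @param name Type name (e.g. `"pid"`, `"study_a_id"`).
#' @param kind `"internal"` or `"external"`.
#' @param multi Allow multiple values of this type per patient.
#' @param payload_length PID payload length for internal types.
#' @return The store, invisibly.
#' @export
register_pseudonym_type <- function(store, name, kind = c("internal", "external"),
                                    multi = FALSE, payload_length = 6) {
  kind <- match.arg(kind)
  if (!is.null(store$ptypes[[name]])) return(invisible(store))
  cfg <- NULL
  if (kind == "internal") {
    cfg <- pid_config(mixing_key = paste0("type:", name, ":", store$secret),
                      payload_length = payload_length)
    store$counters[[paste0("type:", name)]] <- 0L
  }
  store$ptypes[[name]] <- list(name = name, kind = kind, multi = multi,
                               pid = cfg)
  invisible(store)
}

.audit <- function(store, operation, details = list(), actor = NA_character_) {
  store$audit <- c(store$audit, list(c(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         actor = actor, operation = operation), details
  )))
  invisible(NULL)
}

#' Audit trail of a store
#'
#' @param store A [patient_store()].
#' @return Tibble, one row per audited operation (append-only).
#' @export
audit_trail <- function(store) {
  if (length(store$audit) == 0) {
    return(tibble::tibble(timestamp = character(), actor = character(),
                          operation = character(), details = character()))
  }
  tibble::tibble(
    timestamp = vapply(store$audit, `[[`, character(1), "timestamp"),
    actor = vapply(store$audit, `[[`, character(1), "actor"),
    operation = vapply(store$audit, `[[`, character(1), "operation"),
    details = vapply(store$audit, function(a) {
      extra <- a[setdiff(names(a), c("timestamp", "actor", "operation"))]
      if (length(extra) == 0) "" else
        paste(names(extra), unlist(lapply(extra, paste, collapse = "+")),
              sep = "=", collapse = " ")
    }, character(1))
  )
}

.now_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Add a prepared identity to the matching and blocking indexes.
.index_identity <- function(store, key, prepared) {
  cur <- if (key <= length(store$entries)) store$entries[[key]] else NULL
  store$entries[[key]] <- c(cur, list(prepared))
  if (store$blocking$enabled) {
    keys <- block_keys(prepared$norm, store$blocking, store$bloom)
    for (k in keys) {
      store$block_index[[k]] <- c(store$block_index[[k]], key)
    }
  }
  invisible(NULL)
}

#' Create a patient record directly (no linkage)
#'
#' Building block used by ingestion and tests: registers the identity as
#' MAIN, mints the internal PID and, when a tenant is given, enrolls the
#' patient (which mints the tenant's project pseudonym).
#'
#' @param store A [patient_store()].
#' @param fields Named raw field values (normalized internally).
#' @param tenant Optional tenant/domain name.
#' @param tentative Mark the new record as a tentative match.
#' @return The new patient's internal key (integer).
#' @export
create_patient <- function(store, fields, tenant = NULL, tentative = FALSE) {
  norm <- normalize_record(fields, store$schema)
  if (all(is.na(norm))) stop("identity has no non-missing field", call. = FALSE)
  key <- store$counters$patient + 1L
  store$counters$patient <- key
  store$patients[[key]] <- list(
    key = key,
    identities = list(list(fields = norm, kind = "MAIN",
                           created_at = .now_iso())),
    pseudonyms = tibble::tibble(type = character(), value = character(),
                                origin = character()),
    tenants = character(0),
    duplicate_of = NA_integer_,
    tentative = tentative,
    deleted = FALSE
  )
  store$consents[[key]] <- list()
  .index_identity(store, key, .prepare_identity(norm, store$linkage))
  assign_pseudonym(store, key, "pid")
  if (!is.null(tenant)) enroll_tenant(store, key, tenant)
  key
}

#' Enroll a patient into a tenant (project)
#'
#' Enrollment always mints the tenant's project pseudonym
#' (type `"<tenant>_id"`) if the patient does not have one yet.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param tenant Tenant/domain name.
#' @return The project pseudonym value, invisibly.
#' @export
enroll_tenant <- function(store, patient, tenant) {
  p <- .get_patient(store, patient)
  type <- paste0(tenant, "_id")
  register_pseudonym_type(store, type, kind = "internal")
  if (!tenant %in% p$tenants) {
    p$tenants <- c(p$tenants, tenant)
    store$patients[[p$key]] <- p
  }
  existing <- p$pseudonyms$value[p$pseudonyms$type == type]
  if (length(existing) > 0) return(invisible(existing[1]))
  invisible(assign_pseudonym(store, p$key, type))
}

.get_patient <- function(store, key) {
  if (!is.numeric(key) || length(key) != 1 || key < 1 ||
      key > length(store$patients) || is.null(store$patients[[key]])) {
    stop("unknown patient key", call. = FALSE)
  }
  store$patients[[as.integer(key)]]
}

# Follow duplicate_of chains to the surviving record.
.resolve_key <- function(store, key) {
  seen <- 0L
  while (!is.na(store$patients[[key]]$duplicate_of)) {
    key <- store$patients[[key]]$duplicate_of
    seen <- seen + 1L
    if (seen > length(store$patients)) stop("duplicate_of cycle", call. = FALSE)
  }
  key
}

#' Retrieve a patient snapshot
#'
#' @param store A [patient_store()].
#' @param key Patient key.
#' @param resolve Follow merge (duplicate-of) chains to the survivor.
#' @return A list describing the patient (identities, pseudonyms, tenants,
#'   flags).
#' @export
get_patient <- function(store, key, resolve = TRUE) {
  p <- .get_patient(store, key)
  if (resolve) p <- store$patients[[.resolve_key(store, p$key)]]
  p
}

#' Assign a pseudonym to a patient
#'
#' Internal types draw the next counter value and encode it through the
#' type's keyed PID code; external types store the supplied value.
#' `(type, value)` is unique across the store; non-multi types allow at most
#' one value per patient.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param type_name Registered pseudonym type.
#' @param value Externally supplied value (external types only).
#' @return The assigned value.
#' @export
assign_pseudonym <- function(store, patient, type_name, value = NULL) {
  pt <- store$ptypes[[type_name]]
  if (is.null(pt)) stop("unknown pseudonym type: ", type_name, call. = FALSE)
  p <- .get_patient(store, patient)
  if (!pt$multi && any(p$pseudonyms$type == type_name)) {
    stop(sprintf("patient already holds a '%s' pseudonym", type_name),
         call. = FALSE)
  }
  if (pt$kind == "internal") {
    ctr_name <- paste0("type:", type_name)
    ctr <- store$counters[[ctr_name]]
    value <- pid_encode(ctr, pt$pid)
    store$counters[[ctr_name]] <- ctr + 1L
    origin <- "INTERNAL"
  } else {
    if (is.null(value)) stop("external pseudonyms need a value", call. = FALSE)
    origin <- "EXTERNAL"
  }
  idx_key <- paste(type_name, value, sep = "\x1f")
  if (!is.null(store$pseud_index[[idx_key]])) {
    stop(sprintf("pseudonym (%s, %s) already assigned", type_name, value),
         call. = FALSE)
  }
  p$pseudonyms <- dplyr::bind_rows(
    p$pseudonyms,
    tibble::tibble(type = type_name, value = value, origin = origin)
  )
  store$patients[[p$key]] <- p
  store$pseud_index[[idx_key]] <- p$key
  value
}

#' Look up the patient owning a pseudonym
#'
#' Follows merge chains to the surviving record, so pseudonyms of absorbed
#' records keep resolving.
#'
#' @param store A [patient_store()].
#' @param type_name Registered pseudonym type.
#' @param value Pseudonym value.
#' @return Patient snapshot, or `NULL` if unknown.
#' @export
lookup_by_pseudonym <- function(store, type_name, value) {
  if (is.null(store$ptypes[[type_name]])) {
    stop("unknown pseudonym type: ", type_name, call. = FALSE)
  }
  key <- store$pseud_index[[paste(type_name, value, sep = "\x1f")]]
  if (is.null(key)) return(NULL)
  get_patient(store, key, resolve = TRUE)
}

#' Edit an external pseudonym
#'
#' Internally generated pseudonyms are immutable; externally supplied ones
#' may be corrected to track the source system. Uniqueness is re-checked.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param type_name Pseudonym type.
#' @param old_value,new_value Current and replacement value.
#' @return The store, invisibly.
#' @export
edit_external_pseudonym <- function(store, patient, type_name, old_value,
                                    new_value) {
  p <- .get_patient(store, patient)
  row <- which(p$pseudonyms$type == type_name & p$pseudonyms$value == old_value)
  if (length(row) == 0) stop("no such pseudonym on this patient", call. = FALSE)
  if (p$pseudonyms$origin[row[1]] != "EXTERNAL") {
    stop("internal pseudonyms are immutable", call. = FALSE)
  }
  new_key <- paste(type_name, new_value, sep = "\x1f")
  if (!is.null(store$pseud_index[[new_key]])) {
    stop("new value collides with an existing pseudonym", call. = FALSE)
  }
  rm(list = paste(type_name, old_value, sep = "\x1f"),
     envir = store$pseud_index)
  store$pseud_index[[new_key]] <- p$key
  p$pseudonyms$value[row[1]] <- new_value
  store$patients[[p$key]] <- p
  .audit(store, "edit_external_pseudonym",
         list(type = type_name, value = new_value, patient = p$key))
  invisible(store)
}

#' Add an identity to a patient
#'
#' Identities are append-only. With `as_main`, the new identity becomes the
#' MAIN identity and the previous MAIN is demoted to ALIAS; otherwise it is
#' stored as an ALIAS. Alias identities take part in record linkage but are
#' hidden from ordinary display and export.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param fields Named raw field values.
#' @param as_main Promote the new identity to MAIN.
#' @return The store, invisibly.
#' @export
add_identity <- function(store, patient, fields, as_main = FALSE) {
  p <- .get_patient(store, patient)
  if (!is.na(p$duplicate_of)) {
    stop("cannot add identities to an absorbed record", call. = FALSE)
  }
  norm <- normalize_record(fields, store$schema)
  if (all(is.na(norm))) stop("identity has no non-missing field", call. = FALSE)
  kind <- if (as_main) "MAIN" else "ALIAS"
  if (as_main) {
    for (i in seq_along(p$identities)) {
      if (p$identities[[i]]$kind == "MAIN") p$identities[[i]]$kind <- "ALIAS"
    }
  }
  p$identities <- c(p$identities,
                    list(list(fields = norm, kind = kind,
                              created_at = .now_iso())))
  store$patients[[p$key]] <- p
  .index_identity(store, p$key, .prepare_identity(norm, store$linkage))
  invisible(store)
}

# Candidate patient keys for a prepared probe. Returns resolved, active,
# unique keys; NULL means "no blocking keys — fall back to all patients".
.candidate_keys <- function(store, prepared, use_blocking = TRUE) {
  active <- function(keys) {
    keys <- unique(vapply(keys, function(k) .resolve_key(store, k), integer(1)))
    keys[!vapply(keys, function(k) store$patients[[k]]$deleted, logical(1))]
  }
  all_keys <- function() {
    keys <- which(!vapply(store$patients, is.null, logical(1)))
    active(keys)
  }
  if (!use_blocking || !store$blocking$enabled) return(all_keys())
  bk <- block_keys(prepared$norm, store$blocking, store$bloom)
  if (length(bk) == 0) return(all_keys())
  hit <- unlist(lapply(bk, function(k) store$block_index[[k]]), use.names = FALSE)
  if (length(hit) == 0) return(integer(0))
  active(hit)
}

#' Candidate patients for a probe identity
#'
#' The union of all patients sharing at least one blocking key with the
#' probe (resolved to surviving records). A probe without any blocking key
#' — or a store with blocking disabled — falls back to all active patients,
#' so no record can be hidden by missing blocked fields.
#'
#' @param store A [patient_store()].
#' @param fields Named raw field values of the probe identity.
#' @param use_blocking Set `FALSE` to force the full-store fallback.
#' @return Integer vector of candidate patient keys.
#' @export
candidate_patients <- function(store, fields, use_blocking = TRUE) {
  norm <- normalize_record(fields, store$schema)
  prepared <- .prepare_identity(norm, store$linkage)
  sort(.candidate_keys(store, prepared, use_blocking))
}

#' Match an identity against the store
#'
#' Scores the probe against every identity (MAIN and ALIAS) of every
#' candidate patient produced by blocking (or all patients when blocking is
#' disabled). A patient's score is the maximum over its identities; ties on
#' the best score go to the lowest internal key so results are reproducible.
#'
#' @param store A [patient_store()].
#' @param fields Named raw field values of the probe identity.
#' @param use_blocking Set `FALSE` to force exhaustive comparison.
#' @return A `match_result`: list with `decision`, `score`, `best_patient`
#'   (key or `NULL`), `rejected_tentative`, `per_field` similarities against
#'   the best identity, and `n_candidates`.
#' @export
match_candidate <- function(store, fields, use_blocking = TRUE) {
  norm <- normalize_record(fields, store$schema)
  if (all(is.na(norm))) stop("empty probe identity", call. = FALSE)
  prepared <- .prepare_identity(norm, store$linkage)
  cand <- .candidate_keys(store, prepared, use_blocking)
  cmp <- store$linkage$comparators
  fast <- store$linkage$fast
  best_key <- NULL
  best_score <- -Inf
  for (k in sort(cand)) {
    for (entry in store$entries[[k]]) {
      s <- .score_prepared(prepared, entry, fast)
      if (!is.na(s) && s > best_score) {
        best_score <- s
        best_key <- k
      }
    }
  }
  if (is.null(best_key)) {
    return(structure(list(decision = "NON_MATCH", score = 0,
                          best_patient = NULL, rejected_tentative = FALSE,
                          per_field = NULL, n_candidates = length(cand)),
                     class = "match_result"))
  }
  cls <- classify(best_score, store$linkage)
  detail <- NULL
  for (entry in store$entries[[best_key]]) {
    s <- .score_prepared(prepared, entry, fast)
    if (!is.na(s) && s == best_score) {
      detail <- vapply(seq_len(nrow(cmp)), function(i) {
        av <- prepared$norm[[cmp$field[i]]]
        bv <- entry$norm[[cmp$field[i]]]
        if (is.na(av) || is.na(bv)) NA_real_
        else if (cmp$comparator[i] == "NGRAM_DICE")
          dice_grams(prepared$grams[[i]], entry$grams[[i]])
        else as.numeric(av == bv)
      }, numeric(1))
      names(detail) <- cmp$field
      break
    }
  }
  structure(list(decision = cls$decision,
                 score = best_score,
                 best_patient = best_key,
                 rejected_tentative = cls$rejected_tentative,
                 per_field = detail,
                 n_candidates = length(cand)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s (score %.3f, %d candidate(s))\n",
              x$decision, x$score, x$n_candidates))
  invisible(x)
}

#' Ingest an identity through the full linkage pipeline
#'
#' Normalize, block, score, classify, then act: a match returns the existing
#' patient (enrolling it into `tenant` if needed); a tentative match creates
#' a separate flagged record and queues the pair for conflict resolution
#' (or, in auto-reject mode, creates nothing and reports rejection); a
#' non-match creates a new patient.
#'
#' @param store A [patient_store()].
#' @param fields Named raw field values.
#' @param tenant Optional tenant to enroll the resulting patient into.
#' @param use_blocking Set `FALSE` for exhaustive comparison.
#' @return List with `outcome` (`"created"`, `"matched"`, `"tentative"`,
#'   `"rejected"`), `patient` (key or `NA`), `score`, `decision` and
#'   `n_candidates`.
#' @export
ingest_identity <- function(store, fields, tenant = NULL, use_blocking = TRUE) {
  res <- match_candidate(store, fields, use_blocking = use_blocking)
  if (res$decision == "MATCH") {
    key <- res$best_patient
    if (!is.null(tenant)) enroll_tenant(store, key, tenant)
    store$counters$last_touched <- key
    return(list(outcome = "matched", patient = key, score = res$score,
                decision = res$decision, n_candidates = res$n_candidates))
  }
  if (res$rejected_tentative) {
    return(list(outcome = "rejected", patient = NA_integer_, score = res$score,
                decision = "NON_MATCH", n_candidates = res$n_candidates))
  }
  if (res$decision == "TENTATIVE") {
    key <- create_patient(store, fields, tenant = tenant, tentative = TRUE)
    other <- res$best_patient
    p <- store$patients[[other]]
    p$tentative <- TRUE
    store$patients[[other]] <- p
    store$tentative <- c(store$tentative,
                         list(list(a = min(key, other), b = max(key, other),
                                   score = res$score, resolved = FALSE)))
    store$counters$last_touched <- key
    return(list(outcome = "tentative", patient = key, score = res$score,
                decision = res$decision, n_candidates = res$n_candidates))
  }
  key <- create_patient(store, fields, tenant = tenant)
  store$counters$last_touched <- key
  list(outcome = "created", patient = key, score = res$score,
       decision = res$decision, n_candidates = res$n_candidates)
}

#' List unresolved tentative-match pairs
#'
#' @param store A [patient_store()].
#' @return Tibble with `a`, `b` (patient keys, `a < b`) and `score`, one row
#'   per unresolved pair.
#' @export
list_tentative_pairs <- function(store) {
  open <- Filter(function(tp) !tp$resolved, store$tentative)
  if (length(open) == 0) {
    return(tibble::tibble(a = integer(), b = integer(), score = numeric()))
  }
  tibble::tibble(
    a = vapply(open, `[[`, numeric(1), "a"),
    b = vapply(open, `[[`, numeric(1), "b"),
    score = vapply(open, `[[`, numeric(1), "score")
  ) |> dplyr::distinct(.data$a, .data$b, .keep_all = TRUE)
}

.find_tentative <- function(store, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  for (i in seq_along(store$tentative)) {
    tp <- store$tentative[[i]]
    if (!tp$resolved && tp$a == lo && tp$b == hi) return(i)
  }
  NULL
}

.mark_resolved <- function(store, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  for (i in seq_along(store$tentative)) {
    tp <- store$tentative[[i]]
    if (tp$a == lo && tp$b == hi) {
      store$tentative[[i]]$resolved <- TRUE
    }
  }
  for (k in c(a, b)) {
    others <- Filter(function(tp) !tp$resolved && (tp$a == k || tp$b == k),
                     store$tentative)
    if (length(others) == 0) {
      p <- store$patients[[k]]
      p$tentative <- FALSE
      store$patients[[k]] <- p
    }
  }
  invisible(NULL)
}

#' Merge two patient records
#'
#' The absorbed record's identities become ALIAS identities of the survivor
#' and its pseudonyms keep resolving (to the survivor) through the recorded
#' duplicate-of link. The survivor keeps its MAIN identity.
#'
#' @param store A [patient_store()].
#' @param survivor,absorbed Patient keys.
#' @param actor Actor recorded in the audit trail.
#' @return The surviving patient snapshot.
#' @export
merge_patients <- function(store, survivor, absorbed, actor = NA_character_) {
  if (survivor == absorbed) stop("cannot merge a patient with itself", call. = FALSE)
  ps <- .get_patient(store, survivor)
  pa <- .get_patient(store, absorbed)
  if (!is.na(ps$duplicate_of) || !is.na(pa$duplicate_of)) {
    stop("cannot merge already-absorbed records", call. = FALSE)
  }
  for (i in seq_along(pa$identities)) {
    id <- pa$identities[[i]]
    id$kind <- "ALIAS"
    ps$identities <- c(ps$identities, list(id))
  }
  # absorbed identities now match on behalf of the survivor
  store$entries[[survivor]] <- c(store$entries[[survivor]],
                                 store$entries[[absorbed]])
  store$entries[[absorbed]] <- list()
  pa$duplicate_of <- as.integer(survivor)
  pa$tentative <- FALSE
  ps$tentative <- FALSE
  store$patients[[survivor]] <- ps
  store$patients[[absorbed]] <- pa
  .mark_resolved(store, survivor, absorbed)
  .audit(store, "merge_patients",
         list(survivor = survivor, absorbed = absorbed), actor = actor)
  store$patients[[survivor]]
}

#' Split a tentative pair (declare a definitive non-match)
#'
#' Both records persist independently; the pair is recorded as a permanent
#' exclusion so the same conflict is never proposed again.
#'
#' @param store A [patient_store()].
#' @param a,b Patient keys of a recorded tentative pair.
#' @param actor Actor recorded in the audit trail.
#' @return The store, invisibly.
#' @export
split_patients <- function(store, a, b, actor = NA_character_) {
  if (is.null(.find_tentative(store, a, b))) {
    stop("(a, b) is not a recorded tentative pair", call. = FALSE)
  }
  store$exclusions[[paste(min(a, b), max(a, b), sep = "|")]] <- TRUE
  .mark_resolved(store, a, b)
  .audit(store, "split_patients", list(a = a, b = b), actor = actor)
  invisible(store)
}

#' Resolve a tentative-match conflict
#'
#' @param store A [patient_store()].
#' @param a,b Patient keys of an unresolved tentative pair.
#' @param decision `"MERGE"` (records belong to the same person; `a` is kept
#'   as survivor) or `"SPLIT"` (definitive non-match).
#' @param actor Actor recorded in the audit trail.
#' @return The store, invisibly.
#' @export
resolve_conflict <- function(store, a, b, decision = c("MERGE", "SPLIT"),
                             actor = NA_character_) {
  decision <- match.arg(decision)
  if (is.null(.find_tentative(store, a, b))) {
    stop("(a, b) is not an unresolved tentative pair", call. = FALSE)
  }
  .audit(store, "resolve_conflict",
         list(a = a, b = b, decision = decision), actor = actor)
  if (decision == "MERGE") merge_patients(store, a, b, actor = actor)
  else split_patients(store, a, b, actor = actor)
  invisible(store)
}

#' Delete (deactivate) a patient record
#'
#' The record is excluded from linkage and lookups but the slot is retained
#' so keys stay stable.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param actor Actor recorded in the audit trail.
#' @return The store, invisibly.
#' @export
delete_patient <- function(store, patient, actor = NA_character_) {
  p <- .get_patient(store, patient)
  p$deleted <- TRUE
  store$patients[[p$key]] <- p
  store$entries[[p$key]] <- list()
  for (i in seq_len(nrow(p$pseudonyms))) {
    rm(list = paste(p$pseudonyms$type[i], p$pseudonyms$value[i], sep = "\x1f"),
       envir = store$pseud_index)
  }
  .audit(store, "delete_patient", list(patient = p$key), actor = actor)
  invisible(store)
}

#' Tabulate a store as one row per (patient, identity)
#'
#' @param store A [patient_store()].
#' @param main_only Keep only MAIN identities (the user-visible view).
#' @param tenant Optionally restrict to patients enrolled in one tenant.
#' @return Tibble with patient key, identity kind, schema fields, the
#'   internal PID and tenant list.
#' @export
patients_tibble <- function(store, main_only = FALSE, tenant = NULL) {
  rows <- list()
  for (p in store$patients) {
    if (is.null(p) || p$deleted || !is.na(p$duplicate_of)) next
    if (!is.null(tenant) && !tenant %in% p$tenants) next
    pid <- p$pseudonyms$value[p$pseudonyms$type == "pid"]
    for (id in p$identities) {
      if (main_only && id$kind != "MAIN") next
      rows[[length(rows) + 1L]] <- tibble::as_tibble_row(c(
        list(patient = p$key, kind = id$kind,
             pid = if (length(pid)) pid[1] else NA_character_,
             tenants = paste(p$tenants, collapse = ";"),
             created_at = id$created_at),
        as.list(id$fields)
      ))
    }
  }
  if (length(rows) == 0) {
    return(tibble::as_tibble(c(
      list(patient = integer(), kind = character(), pid = character(),
           tenants = character(), created_at = character()),
      stats::setNames(rep(list(character()), length(store$schema)),
                      store$schema)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Export a store to CSV
#'
#' RFC 4180, UTF-8, header row; one row per (patient, identity).
#'
#' @param store A [patient_store()].
#' @param path Output file path.
#' @param ... Passed to [patients_tibble()].
#' @return The exported tibble, invisibly.
#' @export
export_patients <- function(store, path, ...) {
  tb <- patients_tibble(store, ...)
  readr::write_csv(tb, path, na = "")
  invisible(tb)
}
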