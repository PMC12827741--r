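#' Create a CSV/tabular bulk-import job
#'
#' Each row runs the full pipeline (normalize, block, score, classify,
#' create/match/queue). Jobs model the asynchronous batch interface: they
#' start `PENDING` and are executed by [run_batch_job()]; `run = TRUE`
#' (the default, used in tests and scripts) executes synchronously.
#' Rows are processed in input order and may match earlier rows of the same
#' batch. Malformed rows are recorded per-row and do not abort the job.
#'
#' @param store A [patient_store()].
#' @param records Tibble/data frame of records, or path to a CSV file
#'   (RFC 4180, UTF-8, header row).
#' @param mapping Optional named character vector renaming input columns to
#'   schema fields, e.g. `c(surname = "last_name")`.
#' @param tenant Optional tenant to enroll created/matched patients into.
#' @param use_blocking Set `FALSE` for exhaustive comparison.
#' @param run Execute immediately.
#' @return A `batch_job` (environment-backed).
#' @export
batch_import <- function(store, records, mapping = NULL, tenant = NULL,
                         use_blocking = TRUE, run = TRUE) {
  if (is.character(records) && length(records) == 1) {
    records <- readr::read_csv(records, col_types = readr::cols(
      .default = readr::col_character()))
  }
  records <- tibble::as_tibble(records)
  if (!is.null(mapping)) {
    bad <- setdiff(names(mapping), names(records))
    if (length(bad) > 0) {
      stop("mapping names absent from input header: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    names(records)[match(names(mapping), names(records))] <- unname(mapping)
  }
  usable <- intersect(names(records), c(store$schema, "birth_date"))
  if (length(usable) == 0) {
    stop("no input column maps onto the field schema", call. = FALSE)
  }
  job <- new.env(parent = emptyenv())
  job$job_id <- paste0("job-", substr(paste(as.character(
    openssl::rand_bytes(8)), collapse = ""), 1, 12))
  job$state <- "PENDING"
  job$store <- store
  job$records <- records[usable]
  job$tenant <- tenant
  job$use_blocking <- use_blocking
  job$outcomes <- NULL
  class(job) <- "batch_job"
  if (run) run_batch_job(job)
  job
}

#' Execute a pending batch job
#'
#' @param job A `batch_job` from [batch_import()].
#' @return The job, invisibly (state `DONE`, per-row outcomes filled in).
#' @export
run_batch_job <- function(job) {
  stopifnot(inherits(job, "batch_job"))
  if (job$state != "PENDING") stop("job is not PENDING", call. = FALSE)
  job$state <- "RUNNING"
  n <- nrow(job$records)
  outcome <- character(n); patient <- rep(NA_integer_, n)
  score <- rep(NA_real_, n); pid <- rep(NA_character_, n)
  error <- rep(NA_character_, n); ncand <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- as.list(job$records[i, ])
    res <- tryCatch(
      ingest_identity(job$store, row, tenant = job$tenant,
                      use_blocking = job$use_blocking),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      outcome[i] <- "error"
      error[i] <- conditionMessage(res)
    } else {
      outcome[i] <- res$outcome
      patient[i] <- res$patient
      score[i] <- res$score
      ncand[i] <- res$n_candidates
      if (!is.na(res$patient)) {
        ps <- job$store$patients[[res$patient]]$pseudonyms
        v <- ps$value[ps$type == "pid"]
        pid[i] <- if (length(v)) v[1] else NA_character_
      }
    }
  }
  job$outcomes <- tibble::tibble(
    row = seq_len(n), outcome = outcome, patient = patient, score = score,
    pid = pid, n_candidates = ncand, error = error
  )
  job$state <- "DONE"
  invisible(job)
}

#' Per-row outcomes and counters of a batch job
#'
#' @param job A `batch_job`.
#' @return Tibble of per-row outcomes (`NULL` until the job has run).
#' @export
batch_outcomes <- function(job) job$outcomes

#' @export
print.batch_job <- function(x, ...) {
  cat(sprintf("<batch_job %s> state=%s, %d row(s)\n", x$job_id, x$state,
              nrow(x$records)))
  if (!is.null(x$outcomes)) print(dplyr::count(x$outcomes, .data$outcome))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::glance
glance.batch_job <- function(x, ...) {
  counts <- if (is.null(x$outcomes)) {
    tibble::tibble(created = NA_integer_, matched = NA_integer_,
                   tentative = NA_integer_, rejected = NA_integer_,
                   error = NA_integer_)
  } else {
    tibble::tibble(
      created = sum(x$outcomes$outcome == "created"),
      matched = sum(x$outcomes$outcome == "matched"),
      tentative = sum(x$outcomes$outcome == "tentative"),
      rejected = sum(x$outcomes$outcome == "rejected"),
      error = sum(x$outcomes$outcome == "error")
    )
  }
  dplyr::bind_cols(
    tibble::tibble(job_id = x$job_id, state = x$state,
                   rows = nrow(x$records)),
    counts
  )
}

#' @exportS3Method generics::tidy
tidy.batch_job <- function(x, ...) {
  if (is.null(x$outcomes)) stop("job has not run yet", call. = FALSE)
  x$outcomes
}

#' Export visible patients as a column-selected table
#'
#' One row per visible patient, MAIN identity only (alias identities are
#' never exported). Columns may be schema fields or pseudonym type names.
#' When a service and role are given, every requested column must be covered
#' by the role's grants (`read-field:<field>` / `read-idtype:<type>`), and
#' only patients of the role's tenants are visible.
#'
#' @param store A [patient_store()].
#' @param columns Character vector of schema fields and/or pseudonym types.
#' @param tenant Optional tenant filter.
#' @param service,role Optional [link_service()] and role name enforcing
#'   column grants and tenant visibility.
#' @param path Optional CSV output path.
#' @return Tibble with the requested columns.
#' @export
batch_export <- function(store, columns, tenant = NULL, service = NULL,
                         role = NULL, path = NULL) {
  if (!is.null(service)) {
    stopifnot(!is.null(role))
    for (col in columns) {
      action <- if (col %in% store$schema) "read-field" else "read-idtype"
      if (check_permission(service, role, action, col) != "allow") {
        stop(sprintf("role '%s' lacks %s:%s", role, action, col), call. = FALSE)
      }
    }
    rt <- .role_tenants(service, role)
    if (is.null(tenant)) {
      if (length(rt) > 0) tenant <- rt[1]
    } else if (length(rt) > 0 && !tenant %in% rt) {
      stop("role has no access to tenant ", tenant, call. = FALSE)
    }
  }
  rows <- list()
  for (p in store$patients) {
    if (is.null(p) || p$deleted || !is.na(p$duplicate_of)) next
    if (!is.null(tenant) && !tenant %in% p$tenants) next
    main <- Filter(function(id) id$kind == "MAIN", p$identities)[[1]]
    vals <- lapply(columns, function(col) {
      if (col %in% store$schema) {
        main$fields[[col]]
      } else {
        v <- p$pseudonyms$value[p$pseudonyms$type == col]
        if (length(v)) paste(v, collapse = ";") else NA_character_
      }
    })
    rows[[length(rows) + 1L]] <- tibble::as_tibble_row(
      stats::setNames(vals, columns))
  }
  out <- if (length(rows) == 0) {
    tibble::as_tibble(stats::setNames(rep(list(character()), length(columns)),
                                      columns))
  } else {
    dplyr::bind_rows(rows)
  }
  if (!is.null(path)) readr::write_csv(out, path, na = "")
  out
}

#' Evaluate linkage decisions against ground truth
#'
#' Precision and recall of MATCH decisions from a batch import of a
#' generated cohort: a duplicate row counts as recalled when its ingest
#' decision was MATCH into the cluster of its base row; a MATCH decision
#' counts as correct under the same condition. Clusters are defined by the
#' truth table (each base row and its duplicates form one person).
#'
#' @param job A completed `batch_job` over the cohort's records (base rows
#'   first, in cohort order).
#' @param truth Truth tibble from [generate_cohort()].
#' @return A `linkage_eval` object (see [tidy()] / [glance()] /
#'   [autoplot()]).
#' @export
evaluate_linkage <- function(job, truth) {
  out <- batch_outcomes(job)
  if (is.null(out)) stop("job has not run yet", call. = FALSE)
  cluster <- seq_len(nrow(out))
  cluster[truth$dup_row] <- truth$base_row
  # patient key -> cluster of the row that created it
  creator <- out[out$outcome %in% c("created", "tentative"), ]
  pat_cluster <- stats::setNames(cluster[creator$row], creator$patient)
  matched <- out[out$outcome == "matched", ]
  correct <- 0L
  if (nrow(matched) > 0) {
    mc <- pat_cluster[as.character(matched$patient)]
    correct <- sum(!is.na(mc) & mc == cluster[matched$row])
  }
  n_match <- nrow(matched)
  dup_rows <- truth$dup_row
  dup_out <- out[match(dup_rows, out$row), ]
  dup_ok <- dup_out$outcome == "matched" &
    !is.na(pat_cluster[as.character(dup_out$patient)]) &
    pat_cluster[as.character(dup_out$patient)] == cluster[dup_rows]
  structure(
    list(
      precision = if (n_match == 0) NA_real_ else correct / n_match,
      recall = if (length(dup_rows) == 0) NA_real_ else
        sum(dup_ok, na.rm = TRUE) / length(dup_rows),
      n_match = n_match, n_correct_match = correct,
      n_duplicates = length(dup_rows),
      n_records = nrow(out),
      outcomes = out
    ),
    class = "linkage_eval"
  )
}

#' @export
print.linkage_eval <- function(x, ...) {
  cat(sprintf("<linkage_eval> precision %.4f, recall %.4f (%d MATCH decisions, %d true duplicates)\n",
              x$precision, x$recall, x$n_match, x$n_duplicates))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.linkage_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("precision", "recall"),
    value = c(x$precision, x$recall)
  )
}

#' @exportS3Method generics::glance
glance.linkage_eval <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 n_match = x$n_match, n_correct_match = x$n_correct_match,
                 n_duplicates = x$n_duplicates, n_records = x$n_records)
}

#' Measure blocking quality on a cohort with ground truth
#'
#' Inserts the records sequentially into a scratch store (no linkage) and,
#' before each insertion, retrieves the candidate set for the incoming
#' record. Reports the fraction of true duplicate pairs whose base record
#' was among the candidates (blocking recall) and the number of generated
#' candidate pairs relative to all `n (n - 1) / 2` pairs (candidate
#' fraction; 1 minus it is the reduction ratio).
#'
#' @param records Cohort records tibble (base rows first).
#' @param truth Truth tibble from [generate_cohort()].
#' @param store Optional template [patient_store()] supplying the schema and
#'   blocking configuration; a default store is created otherwise.
#' @return A `blocking_eval` list: `blocking_recall`, `candidate_fraction`,
#'   `reduction_ratio`, `n_candidate_pairs`, `n_pairs`.
#' @export
evaluate_blocking <- function(records, truth, store = NULL) {
  if (is.null(store)) store <- patient_store()
  n <- nrow(records)
  row_patient <- integer(n)
  n_cand_pairs <- 0
  base_hit <- logical(nrow(truth))
  dup_of <- stats::setNames(truth$base_row, truth$dup_row)
  for (i in seq_len(n)) {
    fields <- as.list(records[i, setdiff(names(records), "row")])
    norm <- normalize_record(fields, store$schema)
    prepared <- .prepare_identity(norm, store$linkage)
    cand <- .candidate_keys(store, prepared)
    n_cand_pairs <- n_cand_pairs + length(cand)
    base <- dup_of[as.character(i)]
    if (!is.na(base)) {
      ti <- which(truth$dup_row == i)
      base_hit[ti] <- row_patient[base] %in% cand
    }
    row_patient[i] <- create_patient(store, fields)
  }
  n_pairs <- n * (n - 1) / 2
  structure(
    list(blocking_recall = mean(base_hit),
         candidate_fraction = n_cand_pairs / n_pairs,
         reduction_ratio = 1 - n_cand_pairs / n_pairs,
         n_candidate_pairs = n_cand_pairs, n_pairs = n_pairs),
    class = "blocking_eval"
  )
}

#' @export
print.blocking_eval <- function(x, ...) {
  cat(sprintf("<blocking_eval> recall %.4f, candidate fraction %.4f (reduction %.4f)\n",
              x$blocking_recall, x$candidate_fraction, x$reduction_ratio))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.blocking_eval <- function(x, ...) {
  tibble::tibble(blocking_recall = x$blocking_recall,
                 candidate_fraction = x$candidate_fraction,
                 reduction_ratio = x$reduction_ratio,
                 n_candidate_pairs = x$n_candidate_pairs,
                 n_pairs = x$n_pairs)
}
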