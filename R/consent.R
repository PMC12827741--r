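#' Define a reusable consent template
#'
#' A template models a modular consent form: each module corresponds to a
#' checkbox the patient can permit or deny, and grants one or more data-use
#' policies when permitted. Templates are registered once per store and
#' reused across patients (and, in practice, across studies).
#'
#' @param store A [patient_store()].
#' @param template_id Template identifier.
#' @param modules Tibble/data frame with columns `module_id`,
#'   `policy_ids` (list-column or `;`-separated string), `required`
#'   (logical) and optional `text_ref`.
#' @param version Template version (integer).
#' @param validity_days Optional validity period: consents expire this many
#'   days after signing (expired consent is denied, fail-safe).
#' @return The template definition, invisibly.
#' @export
consent_template <- function(store, template_id, modules, version = 1,
                             validity_days = NULL) {
  modules <- tibble::as_tibble(modules)
  if (anyDuplicated(modules$module_id)) {
    stop("module_ids must be unique within a template", call. = FALSE)
  }
  if (!is.list(modules$policy_ids)) {
    modules$policy_ids <- strsplit(as.character(modules$policy_ids), ";")
  }
  if (any(lengths(modules$policy_ids) == 0)) {
    stop("every module must map to at least one policy", call. = FALSE)
  }
  if (!"required" %in% names(modules)) modules$required <- FALSE
  tpl <- list(template_id = template_id, version = version,
              modules = modules, validity_days = validity_days)
  store$consent_templates[[template_id]] <- tpl
  invisible(tpl)
}

.get_template <- function(store, template_id) {
  tpl <- store$consent_templates[[template_id]]
  if (is.null(tpl)) stop("unknown consent template: ", template_id, call. = FALSE)
  tpl
}

.patient_consents <- function(store, patient, template_id = NULL) {
  recs <- store$consents[[patient]]
  if (is.null(recs)) recs <- list()
  if (!is.null(template_id)) {
    recs <- Filter(function(r) r$template_id == template_id, recs)
  }
  recs
}

#' Record a patient consent
#'
#' Creates a new ACTIVE consent record from a registered template; any prior
#' ACTIVE record for the same (patient, template) becomes SUPERSEDED and the
#' per-patient version counter is incremented. History is append-only.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param template_id Registered template.
#' @param choices Named character vector `module_id -> "PERMIT"/"DENY"`;
#'   must cover all required modules (uncovered optional modules default to
#'   DENY).
#' @param signed_date Date of signature.
#' @param scan Optional scanned document: `list(content = <raw>,
#'   media_type = "application/pdf" | "image/png")`.
#' @return The new consent record (a list), invisibly.
#' @export
record_consent <- function(store, patient, template_id, choices,
                           signed_date = Sys.Date(), scan = NULL) {
  tpl <- .get_template(store, template_id)
  .get_patient(store, patient)
  choices <- unlist(choices)
  unknown <- setdiff(names(choices), tpl$modules$module_id)
  if (length(unknown) > 0) {
    stop("choices for unknown module(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  req <- tpl$modules$module_id[tpl$modules$required]
  missing_req <- setdiff(req, names(choices))
  if (length(missing_req) > 0) {
    stop("missing choice for required module(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  if (!all(choices %in% c("PERMIT", "DENY"))) {
    stop("choices must be PERMIT or DENY", call. = FALSE)
  }
  full <- stats::setNames(rep("DENY", nrow(tpl$modules)), tpl$modules$module_id)
  full[names(choices)] <- choices
  if (!is.null(scan)) {
    if (!is.raw(scan$content) ||
        !scan$media_type %in% c("application/pdf", "image/png")) {
      stop("scan must be raw content with media type application/pdf or image/png",
           call. = FALSE)
    }
  }
  prior <- .patient_consents(store, patient, template_id)
  version <- 1L
  for (i in seq_along(store$consents[[patient]])) {
    r <- store$consents[[patient]][[i]]
    if (r$template_id == template_id) {
      version <- max(version, r$version + 1L)
      if (r$status == "ACTIVE") {
        store$consents[[patient]][[i]]$status <- "SUPERSEDED"
      }
    }
  }
  rec <- list(patient = patient, template_id = template_id, version = version,
              choices = full, signed_date = as.Date(signed_date),
              status = "ACTIVE", withdrawal_date = NULL, scan = scan)
  store$consents[[patient]] <- c(store$consents[[patient]], list(rec))
  .audit(store, "record_consent",
         list(patient = patient, template = template_id, version = version))
  invisible(rec)
}

#' Withdraw a consent (fully or per module)
#'
#' Full withdrawal marks the ACTIVE record WITHDRAWN effective from
#' `withdrawal_date`; checks before that date still see the original
#' decision. Partial withdrawal creates a successor version with the named
#' modules set to DENY. History is preserved either way.
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param template_id Registered template.
#' @param withdrawal_date Effective date.
#' @param modules Optional subset of module ids for partial withdrawal.
#' @return The affected consent record, invisibly.
#' @export
withdraw_consent <- function(store, patient, template_id,
                             withdrawal_date = Sys.Date(), modules = NULL) {
  .get_template(store, template_id)
  idx <- NULL
  for (i in seq_along(store$consents[[patient]])) {
    r <- store$consents[[patient]][[i]]
    if (r$template_id == template_id && r$status == "ACTIVE") idx <- i
  }
  if (is.null(idx)) stop("no active consent to withdraw", call. = FALSE)
  if (is.null(modules)) {
    store$consents[[patient]][[idx]]$status <- "WITHDRAWN"
    store$consents[[patient]][[idx]]$withdrawal_date <- as.Date(withdrawal_date)
    .audit(store, "withdraw_consent",
           list(patient = patient, template = template_id, scope = "full"))
    return(invisible(store$consents[[patient]][[idx]]))
  }
  cur <- store$consents[[patient]][[idx]]
  new_choices <- cur$choices
  unknown <- setdiff(modules, names(new_choices))
  if (length(unknown) > 0) {
    stop("unknown module(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_choices[modules] <- "DENY"
  rec <- record_consent(store, patient, template_id, new_choices,
                        signed_date = as.Date(withdrawal_date),
                        scan = NULL)
  .audit(store, "withdraw_consent",
         list(patient = patient, template = template_id,
              scope = paste(modules, collapse = "+")))
  invisible(rec)
}

#' Check a data-use policy for a patient
#'
#' Evaluates the highest-version record (across templates) whose signature
#' date is on or before `at_date` and whose template grants the policy
#' through at least one module. Withdrawal is effective from its date;
#' an elapsed validity period denies (fail-safe); with no applicable record
#' the outcome is UNKNOWN so callers can distinguish "never asked" from
#' "refused".
#'
#' @param store A [patient_store()].
#' @param patient Patient key.
#' @param policy_id Policy to check.
#' @param at_date Evaluation date.
#' @return List with `outcome` (`"PERMIT"`/`"DENY"`/`"UNKNOWN"`), `source`
#'   (template id + version, or `NULL`), `evaluated_at`.
#' @export
check_policy <- function(store, patient, policy_id, at_date = Sys.Date()) {
  at_date <- as.Date(at_date)
  recs <- .patient_consents(store, patient)
  best <- NULL
  for (r in recs) {
    if (r$signed_date > at_date) next
    tpl <- store$consent_templates[[r$template_id]]
    if (is.null(tpl)) next
    governs <- any(vapply(tpl$modules$policy_ids,
                          function(ps) policy_id %in% ps, logical(1)))
    if (!governs) next
    if (is.null(best) || r$version > best$version ||
        (r$version == best$version && r$signed_date > best$signed_date)) {
      best <- r
    }
  }
  if (is.null(best)) {
    return(list(outcome = "UNKNOWN", source = NULL, evaluated_at = at_date))
  }
  src <- sprintf("%s/v%d", best$template_id, best$version)
  tpl <- store$consent_templates[[best$template_id]]
  if (best$status == "WITHDRAWN" && !is.null(best$withdrawal_date) &&
      best$withdrawal_date <= at_date) {
    return(list(outcome = "DENY", source = src, evaluated_at = at_date))
  }
  if (!is.null(tpl$validity_days) &&
      at_date > best$signed_date + tpl$validity_days) {
    return(list(outcome = "DENY", source = src, evaluated_at = at_date))
  }
  granting <- tpl$modules$module_id[vapply(tpl$modules$policy_ids,
                                           function(ps) policy_id %in% ps,
                                           logical(1))]
  permit <- any(best$choices[granting] == "PERMIT")
  list(outcome = if (permit) "PERMIT" else "DENY", source = src,
       evaluated_at = at_date)
}

# ---- FHIR serialization ---------------------------------------------------

#' Serialize a consent record as a FHIR-style bundle
#'
#' Produces a collection bundle with a Consent resource (one provision per
#' module, `permit`/`deny`; ACTIVE maps to `active`, WITHDRAWN to
#' `inactive`), a DocumentReference with the Base64-embedded scan when one
#' is attached, and a Provenance resource linking the digital and scanned
#' consent. Structural conformance with the base resources is targeted, not
#' validation against any national profile.
#'
#' @param record A consent record from [record_consent()].
#' @param as_json Return a JSON string instead of a list.
#' @return List (or JSON string) representing the bundle.
#' @export
consent_to_fhir <- function(record, as_json = FALSE) {
  consent_id <- sprintf("consent-%s-%s-v%d", record$patient,
                        record$template_id, record$version)
  provisions <- lapply(names(record$choices), function(m) {
    list(type = if (record$choices[[m]] == "PERMIT") "permit" else "deny",
         code = list(list(coding = list(list(
           system = "urn:pseudolink:consent-module", code = m)))))
  })
  consent <- list(
    resourceType = "Consent",
    id = consent_id,
    status = switch(record$status, ACTIVE = "active", WITHDRAWN = "inactive",
                    SUPERSEDED = "inactive"),
    patient = list(reference = paste0("Patient/", record$patient)),
    dateTime = format(record$signed_date, "%Y-%m-%d"),
    policy = list(list(uri = paste0("urn:pseudolink:template:",
                                    record$template_id, ":v", record$version))),
    provision = list(type = "deny", provision = provisions)
  )
  if (!is.null(record$withdrawal_date)) {
    consent$extension <- list(list(
      url = "urn:pseudolink:withdrawal-date",
      valueDate = format(record$withdrawal_date, "%Y-%m-%d")))
  }
  entries <- list(list(resource = consent))
  if (!is.null(record$scan)) {
    doc_id <- paste0(consent_id, "-scan")
    doc <- list(
      resourceType = "DocumentReference",
      id = doc_id,
      status = "current",
      subject = list(reference = paste0("Patient/", record$patient)),
      content = list(list(attachment = list(
        contentType = record$scan$media_type,
        data = openssl::base64_encode(record$scan$content))))
    )
    prov <- list(
      resourceType = "Provenance",
      id = paste0(consent_id, "-provenance"),
      target = list(list(reference = paste0("Consent/", consent_id)),
                    list(reference = paste0("DocumentReference/", doc_id))),
      recorded = format(record$signed_date, "%Y-%m-%d")
    )
    entries <- c(entries, list(list(resource = doc), list(resource = prov)))
  }
  bundle <- list(resourceType = "Bundle", type = "collection",
                 entry = entries)
  if (as_json) {
    return(jsonlite::toJSON(bundle, auto_unbox = TRUE, pretty = TRUE))
  }
  bundle
}

#' Parse a FHIR-style consent bundle back into a consent record
#'
#' Inverse of [consent_to_fhir()] up to semantic content: patient, template,
#' version, per-module choices, status, dates and the embedded scan.
#'
#' @param bundle Bundle list or JSON string.
#' @return A consent record list.
#' @export
consent_from_fhir <- function(bundle) {
  if (is.character(bundle)) {
    bundle <- jsonlite::fromJSON(bundle, simplifyVector = FALSE)
  }
  if (!identical(bundle$resourceType, "Bundle")) {
    stop("not a Bundle", call. = FALSE)
  }
  resources <- lapply(bundle$entry, `[[`, "resource")
  types <- vapply(resources, `[[`, character(1), "resourceType")
  ci <- which(types == "Consent")
  if (length(ci) != 1) stop("bundle must contain exactly one Consent", call. = FALSE)
  consent <- resources[[ci]]
  policy_uri <- consent$policy[[1]]$uri
  mm <- regmatches(policy_uri,
                   regexec("^urn:pseudolink:template:(.+):v(\\d+)$", policy_uri))[[1]]
  if (length(mm) != 3) stop("unrecognized policy URI", call. = FALSE)
  choices <- character(0)
  for (p in consent$provision$provision) {
    code <- p$code[[1]]$coding[[1]]$code
    if (is.null(code)) stop("provision without module code", call. = FALSE)
    choices[code] <- if (identical(p$type, "permit")) "PERMIT" else "DENY"
  }
  withdrawal <- NULL
  for (ext in consent$extension) {
    if (identical(ext$url, "urn:pseudolink:withdrawal-date")) {
      withdrawal <- as.Date(ext$valueDate)
    }
  }
  scan <- NULL
  di <- which(types == "DocumentReference")
  if (length(di) == 1) {
    att <- resources[[di]]$content[[1]]$attachment
    scan <- list(content = openssl::base64_decode(att$data),
                 media_type = att$contentType)
  }
  status <- if (identical(consent$status, "active")) "ACTIVE"
            else if (!is.null(withdrawal)) "WITHDRAWN" else "SUPERSEDED"
  list(
    patient = as.integer(sub("^Patient/", "", consent$patient$reference)),
    template_id = mm[2],
    version = as.integer(mm[3]),
    choices = choices,
    signed_date = as.Date(consent$dateTime),
    status = status,
    withdrawal_date = withdrawal,
    scan = scan
  )
}
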