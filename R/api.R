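#' Service configuration: clients, roles, tenants, callbacks
#'
#' @param clients Tibble/data frame with columns `api_key`, `client`,
#'   `role`.
#' @param roles Named list: role name -> character vector of grants of the
#'   form `action` or `action:qualifier` (wildcard `action:*` allowed), e.g.
#'   `create-token:ADD_PATIENT`, `read-idtype:study_a_id`,
#'   `tenant:study_a`. A grant may carry a consent gate suffix
#'   `?requires-policy=<policy_id>`; it then only applies to patients for
#'   whom that policy currently evaluates to PERMIT. Evaluation is
#'   deny-by-default.
#' @param callback_allowlist Character vector of allowed callback URL
#'   prefixes.
#' @param audit_required Require (and log) a reason for every token.
#' @param session_ttl Session idle lifetime in seconds (default 600).
#' @return A `service_config` object.
#' @export
service_config <- function(clients, roles, callback_allowlist = character(0),
                           audit_required = TRUE, session_ttl = 600) {
  clients <- tibble::as_tibble(clients)
  stopifnot(all(c("api_key", "client", "role") %in% names(clients)))
  structure(
    list(clients = clients, roles = roles,
         callback_allowlist = callback_allowlist,
         audit_required = audit_required, session_ttl = session_ttl),
    class = "service_config"
  )
}

#' Create an in-process pseudonymization service
#'
#' The service front-ends a patient store with the delegation model: clients
#' authenticate with an API key, open sessions, create single-purpose tokens
#' within them, and redeem each token for exactly the operation class it
#' authorizes. All authorization logic lives here, in-process, so it is
#' testable without networking; an HTTP facade can be layered on top.
#'
#' @param store A [patient_store()].
#' @param config A [service_config()].
#' @return A `link_service` (environment-backed).
#' @export
link_service <- function(store, config) {
  stopifnot(inherits(store, "patient_store"), inherits(config, "service_config"))
  sv <- new.env(parent = emptyenv())
  sv$store <- store
  sv$config <- config
  sv$sessions <- new.env(parent = emptyenv())
  sv$tokens <- new.env(parent = emptyenv())
  sv$deliveries <- list()  # recorded callback payloads
  class(sv) <- "link_service"
  sv
}

.rand_id <- function() {
  paste(as.character(openssl::rand_bytes(16)), collapse = "")
}

.role_grants <- function(service, role) {
  g <- service$config$roles[[role]]
  if (is.null(g)) character(0) else g
}

.role_tenants <- function(service, role) {
  g <- .role_grants(service, role)
  sub("^tenant:", "", g[startsWith(g, "tenant:")])
}

#' Check a role's permission for an action
#'
#' Deny-by-default: allow only when an exact grant (`action:qualifier`), a
#' wildcard (`action:*`) or an unqualified grant (`action`) matches.
#' Consent-gated grants (`...?requires-policy=<id>`) additionally require
#' the policy to evaluate to PERMIT for the patient at hand.
#'
#' @param service A [link_service()].
#' @param role Role name.
#' @param action Action string (e.g. `"create-token"`, `"read-idtype"`).
#' @param qualifier Optional resource qualifier (token type, id type, field
#'   name or tenant).
#' @param patient Optional patient key for consent-gated grants.
#' @return `"allow"` or `"deny"`.
#' @export
check_permission <- function(service, role, action, qualifier = NULL,
                             patient = NULL) {
  grants <- .role_grants(service, role)
  if (length(grants) == 0) return("deny")
  for (g in grants) {
    gate <- NULL
    if (grepl("?requires-policy=", g, fixed = TRUE)) {
      parts <- strsplit(g, "?requires-policy=", fixed = TRUE)[[1]]
      g <- parts[1]
      gate <- parts[2]
    }
    matches <- if (is.null(qualifier)) {
      g == action || g == paste0(action, ":*")
    } else {
      g == paste0(action, ":", qualifier) || g == paste0(action, ":*")
    }
    if (!matches) next
    if (!is.null(gate)) {
      if (is.null(patient)) return("deny")
      pd <- check_policy(service$store, patient, gate)
      if (pd$outcome != "PERMIT") return("deny")
    }
    return("allow")
  }
  "deny"
}

#' Open a session for an authenticated client
#'
#' @param service A [link_service()].
#' @param api_key Pre-shared client API key.
#' @return Session id (unguessable 128-bit string).
#' @export
create_session <- function(service, api_key) {
  cl <- service$config$clients
  hit <- which(cl$api_key == api_key)
  if (length(hit) != 1) stop("authentication failed: unknown API key",
                             call. = FALSE)
  sid <- .rand_id()
  service$sessions[[sid]] <- list(
    session_id = sid, client = cl$client[hit], role = cl$role[hit],
    created = Sys.time(),
    expiry = Sys.time() + service$config$session_ttl,
    valid = TRUE, tokens = character(0)
  )
  sid
}

.live_session <- function(service, session_id) {
  s <- service$sessions[[session_id]]
  if (is.null(s) || !s$valid) stop("invalid session", call. = FALSE)
  if (Sys.time() > s$expiry) stop("session expired", call. = FALSE)
  s
}

#' Create a single-purpose token within a session
#'
#' The token's type fixes the one operation class it can be redeemed for.
#' The role must hold the matching `create-token:<TYPE>` grant; when the
#' audit trail is enabled a reason must be supplied and is logged; callback
#' URLs must match the configured allow-list.
#'
#' @param service A [link_service()].
#' @param session_id Live session id.
#' @param type `"ADD_PATIENT"`, `"READ_PATIENT"`, `"EDIT_PATIENT"` or
#'   `"DELETE_PATIENT"`.
#' @param payload Supplementary data: `id_types` (pseudonym types the
#'   redeemer may see), `external_pseudonyms` (named list type -> value to
#'   attach on ADD), `target` (list(type, value) identifying the patient for
#'   READ/EDIT/DELETE), `redirect` (opaque redirect target echoed back).
#' @param callback Optional `list(url =, id_types =)`: after redemption the
#'   named pseudonym types are delivered to the URL (recorded in the
#'   service's delivery log) rather than to the redeemer.
#' @param reason Reason string, logged in the audit trail.
#' @param single_use Tokens are single-use by default.
#' @return Token id.
#' @export
create_token <- function(service, session_id, type, payload = list(),
                         callback = NULL, reason = NULL, single_use = TRUE) {
  s <- .live_session(service, session_id)
  if (!type %in% c("ADD_PATIENT", "READ_PATIENT", "EDIT_PATIENT",
                   "DELETE_PATIENT")) {
    stop("unknown token type: ", type, call. = FALSE)
  }
  if (check_permission(service, s$role, "create-token", type) != "allow") {
    stop(sprintf("role '%s' may not create %s tokens", s$role, type),
         call. = FALSE)
  }
  if (service$config$audit_required && (is.null(reason) || !nzchar(reason))) {
    stop("a reason is required when the audit trail is enabled", call. = FALSE)
  }
  if (!is.null(callback)) {
    ok <- any(vapply(service$config$callback_allowlist,
                     function(p) startsWith(callback$url, p), logical(1)))
    if (!ok) stop("callback URL is not allow-listed", call. = FALSE)
  }
  tid <- .rand_id()
  service$tokens[[tid]] <- list(
    token_id = tid, type = type, session_id = session_id, payload = payload,
    callback = callback, reason = reason, single_use = single_use,
    state = "ISSUED"
  )
  s$tokens <- c(s$tokens, tid)
  service$sessions[[session_id]] <- s
  .audit(service$store, "create_token",
         list(token = substr(tid, 1, 8), type = type,
              reason = if (is.null(reason)) "" else reason),
         actor = s$client)
  tid
}

# Pseudonym values of the given types for a patient (named list).
.pseudonyms_of <- function(store, patient, types) {
  p <- get_patient(store, patient, resolve = TRUE)
  out <- list()
  for (t in types) {
    v <- p$pseudonyms$value[p$pseudonyms$type == t]
    if (length(v) > 0) out[[t]] <- v
  }
  out
}

#' Redeem a token
#'
#' Validates the token (issued, session live, type matches the request),
#' executes exactly the authorized operation, consumes single-use tokens,
#' dispatches any callback with only the pseudonym types named in the
#' callback spec, writes one audit record, and returns to the redeemer only
#' the pseudonyms the token authorizes. A validation failure does not
#' consume the token; failure during execution does.
#'
#' @param service A [link_service()].
#' @param token_id Token id.
#' @param request Operation input: for ADD_PATIENT a `fields` list; for
#'   READ/EDIT/DELETE the target comes from the token payload (EDIT also
#'   takes `fields`).
#' @return Operation result list (contents depend on the token type).
#' @export
redeem_token <- function(service, token_id, request = list()) {
  tk <- service$tokens[[token_id]]
  if (is.null(tk)) stop("unknown token", call. = FALSE)
  if (tk$state != "ISSUED") stop("token already redeemed or invalidated",
                                 call. = FALSE)
  s <- .live_session(service, tk$session_id)
  if (!is.null(request$type) && request$type != tk$type) {
    stop("request type does not match token type", call. = FALSE)
  }
  consume <- function() {
    if (tk$single_use) {
      tk$state <- "REDEEMED"
      service$tokens[[token_id]] <- tk
    }
  }
  store <- service$store
  role <- s$role
  tenants <- .role_tenants(service, role)
  tenant <- if (length(tenants) > 0) tenants[1] else NULL
  result <- tryCatch({
    switch(tk$type,
      ADD_PATIENT = {
        if (is.null(request$fields)) stop("ADD_PATIENT needs fields", call. = FALSE)
        res <- ingest_identity(store, request$fields, tenant = tenant)
        if (!is.na(res$patient) && !is.null(tk$payload$external_pseudonyms)) {
          for (t in names(tk$payload$external_pseudonyms)) {
            register_pseudonym_type(store, t, kind = "external")
            assign_pseudonym(store, res$patient, t,
                             tk$payload$external_pseudonyms[[t]])
          }
        }
        visible_types <- tk$payload$id_types
        visible <- if (is.na(res$patient) || is.null(visible_types)) list()
                   else .pseudonyms_of(store, res$patient, visible_types)
        list(outcome = res$outcome, score = res$score,
             pseudonyms = visible, redirect = tk$payload$redirect)
      },
      READ_PATIENT = {
        tgt <- tk$payload$target
        if (is.null(tgt)) stop("READ_PATIENT token lacks a target", call. = FALSE)
        p <- lookup_by_pseudonym(store, tgt$type, tgt$value)
        if (is.null(p)) stop("no such patient", call. = FALSE)
        if (length(tenants) > 0 && length(intersect(p$tenants, tenants)) == 0) {
          stop("patient not visible to this role's tenants", call. = FALSE)
        }
        want <- tk$payload$id_types
        fields <- NULL
        if (isTRUE(tk$payload$include_fields)) {
          readable <- Filter(function(f)
            check_permission(service, role, "read-field", f,
                             patient = p$key) == "allow", store$schema)
          main <- Filter(function(id) id$kind == "MAIN", p$identities)[[1]]
          fields <- main$fields[unlist(readable)]
        }
        want_ok <- Filter(function(t)
          check_permission(service, role, "read-idtype", t,
                           patient = p$key) == "allow",
          if (is.null(want)) character(0) else want)
        list(patient = p$key, fields = fields,
             pseudonyms = .pseudonyms_of(store, p$key, unlist(want_ok)))
      },
      EDIT_PATIENT = {
        tgt <- tk$payload$target
        if (is.null(tgt)) stop("EDIT_PATIENT token lacks a target", call. = FALSE)
        p <- lookup_by_pseudonym(store, tgt$type, tgt$value)
        if (is.null(p)) stop("no such patient", call. = FALSE)
        if (length(tenants) > 0 && length(intersect(p$tenants, tenants)) == 0) {
          stop("patient not visible to this role's tenants", call. = FALSE)
        }
        add_identity(store, p$key, request$fields, as_main = TRUE)
        list(patient = p$key, edited = TRUE)
      },
      DELETE_PATIENT = {
        tgt <- tk$payload$target
        if (is.null(tgt)) stop("DELETE_PATIENT token lacks a target", call. = FALSE)
        p <- lookup_by_pseudonym(store, tgt$type, tgt$value)
        if (is.null(p)) stop("no such patient", call. = FALSE)
        if (length(tenants) > 0 && length(intersect(p$tenants, tenants)) == 0) {
          stop("patient not visible to this role's tenants", call. = FALSE)
        }
        delete_patient(store, p$key, actor = s$client)
        list(patient = p$key, deleted = TRUE)
      }
    )
  }, error = function(e) e)
  consume()
  if (inherits(result, "error")) {
    .audit(store, "redeem_token_failed",
           list(token = substr(token_id, 1, 8), type = tk$type,
                reason = if (is.null(tk$reason)) "" else tk$reason,
                error = conditionMessage(result)),
           actor = s$client)
    stop(result)
  }
  if (!is.null(tk$callback) && tk$type == "ADD_PATIENT" &&
      !is.null(result$outcome) && result$outcome %in% c("created", "matched")) {
    delivered <- list()
    if (!is.null(tk$callback$id_types) && !is.null(.last_patient(store))) {
      delivered <- .pseudonyms_of(store, .last_patient(store),
                                  tk$callback$id_types)
    }
    service$deliveries <- c(service$deliveries, list(list(
      url = tk$callback$url, token = substr(token_id, 1, 8),
      pseudonyms = delivered
    )))
  }
  .audit(store, "redeem_token",
         list(token = substr(token_id, 1, 8), type = tk$type,
              reason = if (is.null(tk$reason)) "" else tk$reason),
         actor = s$client)
  result
}

# Key of the most recently created or matched patient (helper for callback
# delivery after ADD_PATIENT).
.last_patient <- function(store) {
  store$counters$last_touched
}

#' Invalidate a session and all its tokens
#'
#' Idempotent: invalidating an unknown or already-invalid session is a
#' logged no-op.
#'
#' @param service A [link_service()].
#' @param session_id Session id.
#' @return Invisibly, `TRUE` if a live session was invalidated.
#' @export
invalidate_session <- function(service, session_id) {
  s <- service$sessions[[session_id]]
  if (is.null(s) || !s$valid) {
    .audit(service$store, "invalidate_session_noop", list())
    return(invisible(FALSE))
  }
  s$valid <- FALSE
  service$sessions[[session_id]] <- s
  for (tid in s$tokens) {
    tk <- service$tokens[[tid]]
    if (!is.null(tk) && tk$state == "ISSUED") {
      tk$state <- "INVALID"
      service$tokens[[tid]] <- tk
    }
  }
  .audit(service$store, "invalidate_session", list(), actor = s$client)
  invisible(TRUE)
}

#' Recorded callback deliveries
#'
#' @param service A [link_service()].
#' @return List of deliveries (`url`, `token`, `pseudonyms`).
#' @export
callback_deliveries <- function(service) service$deliveries

#' @export
print.link_service <- function(x, ...) {
  cat(sprintf("<link_service> %d client(s), %d session(s), %d token(s)\n",
              nrow(x$config$clients), length(ls(x$sessions)),
              length(ls(x$tokens))))
  invisible(x)
}
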