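# Request lifecycle: submission (with optional auto-generated secondary
# requests), forward-only status transitions with notifications, and
# per-kind priority queues over Pending requests.

pt_pending_count <- function(store, kind) {
  DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) n FROM request WHERE kind = ? AND status = 'Pending'",
    params = list(kind))$n
}

# subject record type each request kind must reference
REQUEST_SUBJECT_TYPE <- c(transfection = "dna", stable_supe = "cell_line",
                          dna = "dna", purification = "supe",
                          aliquot = "batch")

pt_insert_request <- function(store, kind, subject_id, requestor_email,
                              quantity_type, quantity, cell_type,
                              parent_id = NA_character_) {
  id <- next_id(store, "REQ")
  rec <- pt_record("request", list(
    id = id, kind = kind, status = "Pending",
    requestor_email = requestor_email,
    priority_rank = pt_pending_count(store, kind) + 1L,
    subject_record_id = subject_id, parent_request_id = parent_id,
    quantity_type = quantity_type, quantity = quantity,
    cell_type = cell_type, created_at = pt_tick(store)))
  pt_insert_record(store, rec)
  pt_notify(store, store$config$request_group,
            sprintf("New %s request %s", kind, id),
            sprintf("Request %s (%s) was submitted and is Pending at rank %d.",
                    id, kind, rec$priority_rank),
            external_link(id))
  get_record(store, id)
}

#' Submit a reagent request
#'
#' Request kinds and their subjects: `transfection` (a DNA construct,
#' with a culture quantity), `stable_supe` (a stable cell line), `dna`
#' (a construct, for plasmid production), `purification` (a supe),
#' `aliquot` (a purified batch).  A new request enters its kind's queue
#' at the lowest priority with status `Pending`, and the
#' request-management group is notified.  Submission is open to any
#' role; administration of the request afterwards is not.
#'
#' @param store A `protrack_store`.
#' @param kind One of `"transfection"`, `"stable_supe"`, `"dna"`,
#'   `"purification"`, `"aliquot"`.
#' @param subject_id Id of the record the request is about.
#' @param requestor_email Optional; when present the submitter is
#'   notified of every status change.
#' @param cell_type For transfection requests: `"suspension"` or
#'   `"adherent"`, selecting whether `quantity` is a volume (mL) or a
#'   flask count.
#' @param quantity Volume in mL (suspension) or number of flasks
#'   (adherent); required for transfection requests.
#' @return The created request record.
#' @export
submit_request <- function(store, kind, subject_id,
                           requestor_email = NA_character_,
                           cell_type = NA_character_, quantity = NA_real_) {
  kind <- match.arg(kind, REQUEST_KINDS)
  want <- REQUEST_SUBJECT_TYPE[[kind]]
  if (!pt_exists(store, subject_id, want))
    pt_abort("not_found",
             sprintf("%s request needs an existing %s record; %s not found",
                     kind, want, subject_id))
  quantity_type <- NA_character_
  if (kind == "transfection") {
    if (is.na(quantity))
      pt_abort("missing_quantity",
               "transfection request requires a volume (suspension) or flask count (adherent)")
    cell_type <- match.arg(cell_type, c("suspension", "adherent"))
    quantity_type <- if (cell_type == "suspension") "volume_ml" else "flasks"
  }
  pt_insert_request(store, kind, subject_id, requestor_email,
                    quantity_type, quantity, cell_type)
}

#' Submit a transfection request with optional secondary requests
#'
#' Alongside the transfection itself, a plasmid-DNA request and/or a
#' purification request can be auto-generated and bidirectionally
#' associated with it.  Secondaries enter their own kind's queues.  The
#' auto-generated purification secondary has no supe yet (the supe is
#' what the transfection will produce), so it carries no subject record
#' and is defined by its parent.
#'
#' @inheritParams submit_request
#' @param construct_id DNA construct to transfect.
#' @param want_dna,want_purification Generate the secondary requests?
#' @return A list with `primary` (the transfection request) and
#'   `secondary` (list of generated secondary requests).
#' @export
submit_transfection_request <- function(store, construct_id, cell_type,
                                        quantity, want_dna = FALSE,
                                        want_purification = FALSE,
                                        requestor_email = NA_character_) {
  primary <- submit_request(store, "transfection", construct_id,
                            requestor_email = requestor_email,
                            cell_type = cell_type, quantity = quantity)
  secondary <- list()
  if (isTRUE(want_dna)) {
    if (!pt_exists(store, construct_id, "dna"))
      pt_abort("not_found", sprintf("construct %s not found", construct_id))
    secondary <- c(secondary, list(
      pt_insert_request(store, "dna", construct_id, requestor_email,
                        NA_character_, NA_real_, NA_character_,
                        parent_id = primary$id)))
  }
  if (isTRUE(want_purification)) {
    secondary <- c(secondary, list(
      pt_insert_request(store, "purification", NA_character_,
                        requestor_email, NA_character_, NA_real_,
                        NA_character_, parent_id = primary$id)))
  }
  list(primary = get_record(store, primary$id), secondary = secondary)
}

# remove a request from its Pending queue, closing the rank gap
pt_compact_queue <- function(store, kind, rank) {
  DBI::dbExecute(store$con,
    "UPDATE request SET priority_rank = priority_rank - 1
     WHERE kind = ? AND status = 'Pending' AND priority_rank > ?",
    params = list(kind, rank))
}

#' Advance a request's status
#'
#' Transitions are forward-only and may not skip:
#' `Pending -> Started -> Fulfilled`.  On leaving `Pending` the request
#' drops out of its priority queue and the remaining ranks close up.
#' When a requestor email is on file, every status change sends exactly
#' one notification with an embedded link to the request.
#'
#' @param store A `protrack_store`.
#' @param request_id Request id.
#' @param new_status `"Started"` or `"Fulfilled"`.
#' @param role Must be `"request_admin"`.
#' @return The updated request record.
#' @export
update_status <- function(store, request_id, new_status, role = "reader") {
  pt_check_role(role, "request_admin")
  req <- get_record(store, request_id)
  if (record_type(req) != "request")
    pt_abort("not_found", sprintf("%s is not a request", request_id))
  new_status <- match.arg(new_status, REQUEST_STATUSES)
  from <- match(req$status, REQUEST_STATUSES)
  to <- match(new_status, REQUEST_STATUSES)
  if (to != from + 1L)
    pt_abort("illegal_transition",
             sprintf("illegal transition %s -> %s (forward one step only)",
                     req$status, new_status))
  if (req$status == "Pending") {
    pt_compact_queue(store, req$kind, req$priority_rank)
    DBI::dbExecute(store$con,
      "UPDATE request SET status = ?, priority_rank = NULL WHERE id = ?",
      params = list(new_status, request_id))
  } else {
    DBI::dbExecute(store$con,
      "UPDATE request SET status = ? WHERE id = ?",
      params = list(new_status, request_id))
  }
  if (!is.na(req$requestor_email)) {
    pt_notify(store, req$requestor_email,
              sprintf("Request %s is now %s", request_id, new_status),
              sprintf("Your %s request %s changed status: %s -> %s.",
                      req$kind, request_id, req$status, new_status),
              external_link(request_id))
  }
  get_record(store, request_id)
}

#' The Pending priority queue for one request kind
#'
#' @param store A `protrack_store`.
#' @param kind Request kind.
#' @return A list with `kind` and `ids` (rank order, rank 1 first).
#' @export
request_queue <- function(store, kind) {
  kind <- match.arg(kind, REQUEST_KINDS)
  ids <- DBI::dbGetQuery(store$con,
    "SELECT id FROM request WHERE kind = ? AND status = 'Pending'
     ORDER BY priority_rank", params = list(kind))$id
  structure(list(kind = kind, ids = ids), class = "protrack_queue")
}

#' @export
print.protrack_queue <- function(x, ...) {
  cat(sprintf("<%s queue> %d pending\n", x$kind, length(x$ids)))
  if (length(x$ids) > 0L)
    cat(paste(sprintf("  %2d. %s", seq_along(x$ids), x$ids), collapse = "\n"),
        "\n")
  invisible(x)
}

#' Move a Pending request up or down its queue
#'
#' Swaps the request with its neighbour in the given direction; a move
#' at the boundary is a no-op.  Only Pending requests ("work has not
#' yet begun") may be prioritized.
#'
#' @param store A `protrack_store`.
#' @param request_id Request id.
#' @param direction `"up"` (towards rank 1) or `"down"`.
#' @param role Must be `"request_admin"`.
#' @return The kind's [request_queue()] after the move.
#' @export
prioritize <- function(store, request_id, direction = c("up", "down"),
                       role = "reader") {
  pt_check_role(role, "request_admin")
  direction <- match.arg(direction)
  req <- get_record(store, request_id)
  if (req$status != "Pending")
    pt_abort("not_pending",
             sprintf("request %s is %s; only Pending requests can be prioritized",
                     request_id, req$status))
  n <- pt_pending_count(store, req$kind)
  target <- req$priority_rank + if (direction == "up") -1L else 1L
  if (target >= 1L && target <= n) {
    neighbour <- DBI::dbGetQuery(store$con,
      "SELECT id FROM request WHERE kind = ? AND status = 'Pending'
       AND priority_rank = ?", params = list(req$kind, target))$id
    DBI::dbExecute(store$con,
      "UPDATE request SET priority_rank = ? WHERE id = ?",
      params = list(req$priority_rank, neighbour))
    DBI::dbExecute(store$con,
      "UPDATE request SET priority_rank = ? WHERE id = ?",
      params = list(target, request_id))
  }
  request_queue(store, req$kind)
}

#' List requests of one kind, grouped by status
#'
#' @param store A `protrack_store`.
#' @param kind Request kind.
#' @return A list of three lists of request records: `Pending` in
#'   priority order, `Started` and `Fulfilled` in creation order.
#' @export
list_requests <- function(store, kind) {
  kind <- match.arg(kind, REQUEST_KINDS)
  fetch <- function(status, order_by) {
    ids <- DBI::dbGetQuery(store$con, sprintf(
      "SELECT id FROM request WHERE kind = ? AND status = ?
       ORDER BY %s, id", order_by), params = list(kind, status))$id
    lapply(ids, get_record, store = store)
  }
  list(Pending = fetch("Pending", "priority_rank"),
       Started = fetch("Started", "created_at"),
       Fulfilled = fetch("Fulfilled", "created_at"))
}

#' Delete a Pending request
#'
#' Requests may be deleted only while Pending and only by a request
#' administrator; the queue ranks close up.  A deleted secondary simply
#' drops off its parent's association list; deleting a parent detaches
#' (but keeps) its secondaries.
#'
#' @inheritParams update_status
#' @return `TRUE` invisibly on success.
#' @export
delete_request <- function(store, request_id, role = "reader") {
  pt_check_role(role, "request_admin")
  req <- get_record(store, request_id)
  if (record_type(req) != "request")
    pt_abort("not_found", sprintf("%s is not a request", request_id))
  if (req$status != "Pending")
    pt_abort("not_pending",
             sprintf("request %s is %s; only Pending requests can be deleted",
                     request_id, req$status))
  DBI::dbExecute(store$con,
    "UPDATE request SET parent_request_id = NULL WHERE parent_request_id = ?",
    params = list(request_id))
  DBI::dbExecute(store$con, "DELETE FROM request WHERE id = ?",
                 params = list(request_id))
  pt_compact_queue(store, req$kind, req$priority_rank)
  invisible(TRUE)
}
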