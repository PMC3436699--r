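# Link rules of the reagent lineage.  Links only point from later
# record classes to earlier ones (batch -> supe -> cell line ->
# construct), so the lineage graph is acyclic by construction.

pt_exists <- function(store, id, type = NULL) {
  if (is.null(type)) type <- tryCatch(pt_type_of_id(id),
                                      protrack_error = function(e) NA)
  if (is.na(type)) return(FALSE)
  n <- DBI::dbGetQuery(store$con,
    sprintf("SELECT COUNT(*) n FROM %s WHERE id = ?", PT_TYPES[[type]]$table),
    params = list(id))$n
  n > 0L
}

#' Effective DNA constructs of a supe or batch
#'
#' A transient supe's effective constructs are the constructs it was
#' transfected with; a stable-line supe's are its cell line's; a batch's
#' are the union over its supes, deduplicated, in id order.
#'
#' @param store A `protrack_store`.
#' @param record A supe/batch record or its id.
#' @param ids_only Return just the construct ids?
#' @return A list of DNA construct records named by id (or a character
#'   vector of ids).
#' @export
effective_constructs <- function(store, record, ids_only = FALSE) {
  if (is.character(record)) record <- get_record(store, record)
  type <- record_type(record)
  ids <- switch(type,
    supe = {
      if (length(record$transfection_construct_ids) > 0L) {
        record$transfection_construct_ids
      } else {
        cl <- DBI::dbGetQuery(store$con,
          "SELECT construct_id v FROM cellline_construct WHERE cell_line_id = ?",
          params = list(record$cell_line_id))$v
        if (!pt_exists(store, record$cell_line_id, "cell_line"))
          pt_abort("broken_lineage",
                   sprintf("supe %s references missing cell line %s",
                           record$id, record$cell_line_id))
        cl
      }
    },
    batch = {
      out <- character()
      for (sid in record$supe_ids) {
        if (!pt_exists(store, sid, "supe"))
          pt_abort("broken_lineage",
                   sprintf("batch %s references missing supe %s",
                           record$id %||% "(unsaved)", sid))
        out <- c(out, effective_constructs(store, sid, ids_only = TRUE))
      }
      out
    },
    pt_abort("not_found", "effective_constructs applies to supes and batches"))
  ids <- sort(unique(ids))
  missing <- ids[!vapply(ids, pt_exists, logical(1), store = store, type = "dna")]
  if (length(missing) > 0L)
    pt_abort("broken_lineage",
             sprintf("dangling construct link(s): %s",
                     paste(missing, collapse = ", ")))
  if (ids_only) return(ids)
  out <- lapply(ids, get_record, store = store)
  names(out) <- ids
  out
}

# violations for a single (possibly unsaved) record; returns character()
pt_validate_record <- function(store, record) {
  type <- record_type(record)
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  ref_ok <- function(id, ref_type) pt_exists(store, id, ref_type)

  if (type == "dna") {
    ok <- tryCatch({normalize_sequence(record$mature_sequence); TRUE},
                   protrack_error = function(e) {add(conditionMessage(e)); FALSE})
  } else if (type == "cell_line") {
    if (!record$cell_type %in% CELL_TYPES)
      add(sprintf("unknown cell_type '%s'", record$cell_type))
    if (identical(record$cell_type, "stable") &&
        length(record$construct_ids) == 0L)
      add("stable cell line requires at least one DNA construct")
    if (record$cell_type %in% c("parental", "hybridoma") &&
        length(record$construct_ids) > 0L)
      add(sprintf("%s cell line must not link constructs", record$cell_type))
    for (cid in record$construct_ids)
      if (!ref_ok(cid, "dna")) add(sprintf("construct %s does not exist", cid))
  } else if (type == "supe") {
    if (!ref_ok(record$cell_line_id, "cell_line")) {
      add(sprintf("cell line %s does not exist", record$cell_line_id))
    } else {
      cl <- get_record(store, record$cell_line_id)
      if (identical(cl$cell_type, "parental") &&
          length(record$transfection_construct_ids) == 0L)
        add("supe from a parental line requires transfection construct(s)")
      if (identical(cl$cell_type, "stable") &&
          length(record$transfection_construct_ids) > 0L)
        add("supe from a stable line must not list transfection constructs")
    }
    for (cid in record$transfection_construct_ids)
      if (!ref_ok(cid, "dna")) add(sprintf("construct %s does not exist", cid))
    if (!is.na(record$concentration) && record$concentration < 0)
      add("concentration must be non-negative")
  } else if (type == "batch") {
    if (length(record$supe_ids) == 0L)
      add("batch requires at least one supe")
    for (sid in record$supe_ids) {
      if (!ref_ok(sid, "supe")) {
        add(sprintf("supe %s does not exist", sid))
      } else if (length(effective_constructs(store, sid, ids_only = TRUE)) == 0L) {
        add(sprintf("supe %s has no lineage to a DNA construct", sid))
      }
    }
    if (is.na(record$concentration) || record$concentration < 0)
      add("concentration must be non-negative")
    if (is.na(record$volume) || record$volume < 0)
      add("volume must be non-negative")
    if (is.na(record$original_aliquots) || record$original_aliquots < 1)
      add("original_aliquots must be at least 1")
    if (is.na(record$current_aliquots) || record$current_aliquots < 0 ||
        (!is.na(record$original_aliquots) &&
         record$current_aliquots > record$original_aliquots))
      add("current_aliquots must lie in [0, original_aliquots]")
  } else if (type == "request") {
    if (!record$kind %in% REQUEST_KINDS)
      add(sprintf("unknown request kind '%s'", record$kind))
    if (!record$status %in% REQUEST_STATUSES)
      add(sprintf("unknown request status '%s'", record$status))
    if (!is.na(record$subject_record_id) &&
        !pt_exists(store, record$subject_record_id))
      add(sprintf("subject record %s does not exist", record$subject_record_id))
    if (!is.na(record$parent_request_id) &&
        !ref_ok(record$parent_request_id, "request"))
      add(sprintf("parent request %s does not exist", record$parent_request_id))
    if (identical(record$kind, "transfection") && is.na(record$quantity))
      add("transfection request requires a volume or flask count")
  }
  v
}

#' Check link rules
#'
#' With a record, checks that record against the store (used before
#' insert/update); with only a store, checks every record plus the
#' store-wide queue-rank invariant.  Violations are returned as data,
#' not raised.
#'
#' @param store A `protrack_store`.
#' @param record Optional record (saved or unsaved).
#' @return Character vector of violations; empty when all rules hold.
#' @export
validate_links <- function(store, record = NULL) {
  if (!is.null(record)) return(pt_validate_record(store, record))
  v <- character()
  # set-based referential checks, then per-record rule checks
  dangling <- list(
    c("cellline_construct", "construct_id", "dna_construct"),
    c("supe_construct", "construct_id", "dna_construct"),
    c("supe", "cell_line_id", "cell_line"),
    c("batch_supe", "supe_id", "supe"),
    c("batch_supe", "batch_id", "protein_batch"))
  for (d in dangling) {
    n <- DBI::dbGetQuery(store$con, sprintf(
      "SELECT COUNT(*) n FROM %s a LEFT JOIN %s b ON a.%s = b.id
       WHERE b.id IS NULL", d[1L], d[3L], d[2L]))$n
    if (n > 0L) v <- c(v, sprintf("%d dangling %s.%s link(s)", n, d[1L], d[2L]))
  }
  for (type in names(PT_TYPES)) {
    ids <- DBI::dbGetQuery(store$con,
      sprintf("SELECT id FROM %s ORDER BY id", PT_TYPES[[type]]$table))$id
    for (id in ids) {
      rv <- pt_validate_record(store, get_record(store, id))
      if (length(rv) > 0L) v <- c(v, paste0(id, ": ", rv))
    }
  }
  # per-kind Pending ranks must form a contiguous 1..n permutation
  for (kind in REQUEST_KINDS) {
    ranks <- DBI::dbGetQuery(store$con,
      "SELECT priority_rank r FROM request WHERE kind = ? AND status = 'Pending'
       ORDER BY priority_rank", params = list(kind))$r
    if (length(ranks) > 0L && !identical(as.integer(ranks), seq_along(ranks)))
      v <- c(v, sprintf("pending '%s' ranks are not a contiguous 1..n permutation",
                        kind))
  }
  v
}
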