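# CRUD, search/pagination and import/export against the embedded store.

#' Create a record
#'
#' Validates link rules, assigns the next id for the type's prefix,
#' computes all derived fields (sequence properties for constructs,
#' mass bookkeeping and read-only properties for batches, the map-file
#' check) and inserts the record.
#'
#' @param store A `protrack_store`.
#' @param record An unsaved record from [dna_construct()], [cell_line()],
#'   [supe()] or [protein_batch()].
#' @param role Must be `"record_admin"`; the default `"reader"` role is
#'   rejected.
#' @return The assigned record id.
#' @export
create_record <- function(store, record, role = "reader") {
  pt_check_role(role, "record_admin")
  stopifnot(inherits(record, "protrack_record"))
  type <- record_type(record)
  if (type == "request")
    pt_abort("validation_failed", "requests are created with submit_request()",
             violations = "requests are created with submit_request()")
  violations <- validate_links(store, record)
  if (length(violations) > 0L)
    pt_abort("validation_failed",
             paste0("validation failed: ",
                    paste(violations, collapse = "; ")),
             violations = violations)
  record <- pt_finalize(store, record)
  record$id <- next_id(store, PT_PREFIXES[[type]])
  record$created_at <- pt_tick(store)
  pt_insert_record(store, record)
  record$id
}

#' Fetch a record by id
#'
#' The id prefix selects the table, so a single call serves the quick
#' navigation fields ("open DNA-00012").
#'
#' @param store A `protrack_store`.
#' @param id A record id such as `"DNA-00001"` or `"REQ-00003"`.
#' @return The record as a classed list.
#' @export
get_record <- function(store, id) {
  type <- pt_type_of_id(id)
  row <- DBI::dbGetQuery(store$con,
    sprintf("SELECT * FROM %s WHERE id = ?", PT_TYPES[[type]]$table),
    params = list(id))
  if (nrow(row) == 0L)
    pt_abort("not_found", sprintf("no record with id %s", id))
  pt_row_to_record(store, type, row)
}

#' Update a record
#'
#' Applies the given field changes, recomputes every derived field and
#' re-validates before writing.  Identifier, creation time and derived
#' fields cannot be set directly.
#'
#' @param store A `protrack_store`.
#' @param id Record id.
#' @param changes Named list of field changes.
#' @param role `"record_admin"` for reagent records, `"request_admin"`
#'   for request records (status and rank are managed through
#'   [update_status()] / [prioritize()], not here).
#' @return The updated record, invisibly.
#' @export
update_record <- function(store, id, changes, role = "reader") {
  record <- get_record(store, id)
  type <- record_type(record)
  pt_check_role(role, if (type == "request") "request_admin" else "record_admin")
  derived <- c("id", "created_at", "molecular_weight", "extinction_reduced",
               "extinction_oxidized", "absorbance_0_1pct", "n_glyc_sites",
               "map_file_found", "total_mass", "remaining_mass",
               if (type == "request") c("status", "priority_rank",
                                        "secondary_request_ids"))
  bad <- intersect(names(changes), derived)
  if (length(bad) > 0L)
    pt_abort("validation_failed",
             paste0("field(s) not directly updatable: ",
                    paste(bad, collapse = ", ")),
             violations = paste("not directly updatable:", bad))
  unknown <- setdiff(names(changes), names(record))
  if (length(unknown) > 0L)
    pt_abort("unknown_field",
             paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  tp <- PT_TYPES[[type]]
  for (f in names(changes)) {
    record[[f]] <- if (f %in% names(tp$scalar))
      pt_cast(changes[[f]], tp$scalar[[f]]) else as.character(changes[[f]])
  }
  violations <- validate_links(store, record)
  if (length(violations) > 0L)
    pt_abort("validation_failed",
             paste0("validation failed: ", paste(violations, collapse = "; ")),
             violations = violations)
  record <- pt_finalize(store, record)
  sets <- paste(sprintf("%s = ?", names(tp$scalar)), collapse = ", ")
  vals <- lapply(names(tp$scalar), function(f) {
    v <- record[[f]]
    if (is.logical(v)) as.integer(v) else v
  })
  DBI::dbExecute(store$con,
    sprintf("UPDATE %s SET %s WHERE id = ?", tp$table, sets),
    params = c(vals, list(id)))
  pt_write_lists(store, record)
  invisible(get_record(store, id))
}

# ids of records that still reference `id` (delete refusal set)
pt_referencing_ids <- function(store, id) {
  type <- pt_type_of_id(id)
  q <- function(sql) DBI::dbGetQuery(store$con, sql, params = list(id))[[1L]]
  refs <- switch(type,
    dna = c(q("SELECT cell_line_id FROM cellline_construct WHERE construct_id = ?"),
            q("SELECT supe_id FROM supe_construct WHERE construct_id = ?")),
    cell_line = q("SELECT id FROM supe WHERE cell_line_id = ?"),
    supe = q("SELECT batch_id FROM batch_supe WHERE supe_id = ?"),
    batch = character(),
    request = q("SELECT id FROM request WHERE parent_request_id = ?"))
  refs <- c(refs,
            q("SELECT id FROM request WHERE subject_record_id = ?"))
  sort(unique(refs))
}

#' Delete a record
#'
#' Deletion is refusal-based: a record still referenced by any
#' downstream record (or by a request) cannot be removed, which keeps
#' the chain of custody intact.  Serials are never reused.
#'
#' @inheritParams get_record
#' @param role `"record_admin"` (requests are deleted with
#'   [delete_request()]).
#' @return `TRUE` invisibly on success.
#' @export
delete_record <- function(store, id, role = "reader") {
  record <- get_record(store, id)
  type <- record_type(record)
  if (type == "request")
    pt_abort("validation_failed", "requests are deleted with delete_request()",
             violations = "requests are deleted with delete_request()")
  pt_check_role(role, "record_admin")
  refs <- pt_referencing_ids(store, id)
  if (length(refs) > 0L)
    pt_abort("referenced_record",
             sprintf("%s is still referenced by: %s", id,
                     paste(refs, collapse = ", ")),
             referencing = refs)
  tp <- PT_TYPES[[type]]
  for (f in names(tp$lists)) {
    spec <- tp$lists[[f]]
    DBI::dbExecute(store$con,
      sprintf("DELETE FROM %s WHERE %s = ?", spec[["table"]], spec[["key"]]),
      params = list(id))
  }
  DBI::dbExecute(store$con,
    sprintf("DELETE FROM %s WHERE id = ?", tp$table), params = list(id))
  invisible(TRUE)
}

pt_check_field <- function(type, field) {
  if (!field %in% c("id", names(PT_TYPES[[type]]$scalar)))
    pt_abort("unknown_field",
             sprintf("'%s' is not a sortable/searchable field of %s records",
                     field, type))
  field
}

pt_page <- function(store, type, where = "", params = list(),
                    sort_by = "id", sort_dir = c("asc", "desc"),
                    page = 1L, page_size = NULL) {
  sort_dir <- match.arg(sort_dir)
  pt_check_field(type, sort_by)
  page_size <- as.integer(page_size %||% store$config$page_size_default)
  stopifnot(page >= 1L, page_size >= 1L)
  tab <- PT_TYPES[[type]]$table
  total <- DBI::dbGetQuery(store$con,
    sprintf("SELECT COUNT(*) n FROM %s %s", tab, where),
    params = if (length(params) > 0L) params else NULL)$n
  rows <- DBI::dbGetQuery(store$con,
    sprintf("SELECT * FROM %s %s ORDER BY %s %s, id ASC LIMIT ? OFFSET ?",
            tab, where, sort_by, toupper(sort_dir)),
    params = c(params, list(page_size, (page - 1L) * page_size)))
  items <- lapply(seq_len(nrow(rows)), function(i)
    pt_row_to_record(store, type, rows[i, , drop = FALSE]))
  structure(list(items = items, page_number = as.integer(page),
                 page_size = page_size, total_count = as.integer(total),
                 sort_key = sort_by, sort_dir = sort_dir),
            class = "protrack_page")
}

#' @export
print.protrack_page <- function(x, ...) {
  cat(sprintf("<page %d> %d of %d records (sorted by %s %s)\n",
              x$page_number, length(x$items), x$total_count,
              x$sort_key, x$sort_dir))
  for (r in x$items) cat("  ", r$id, "\n", sep = "")
  invisible(x)
}

#' List records of one type, paged and sorted
#'
#' Ordering is deterministic: the sort key with id as tie-break, stable
#' across calls on an unchanged store.
#'
#' @param store A `protrack_store`.
#' @param type `"dna"`, `"cell_line"`, `"supe"`, `"batch"` or
#'   `"request"`.
#' @param sort_by Field to sort on (default `id`).
#' @param sort_dir `"asc"` or `"desc"`.
#' @param page 1-based page number.
#' @param page_size Rows per page; defaults to the store configuration.
#' @return A `protrack_page`: `items` (list of records), `page_number`,
#'   `page_size`, `total_count`, `sort_key`, `sort_dir`.
#' @export
list_records <- function(store, type, sort_by = "id",
                         sort_dir = c("asc", "desc"), page = 1L,
                         page_size = NULL) {
  type <- match.arg(type, names(PT_TYPES))
  pt_page(store, type, sort_by = sort_by, sort_dir = match.arg(sort_dir),
          page = page, page_size = page_size)
}

#' Search records
#'
#' Filters are conjunctive.  Operators: `equals` (exact), `contains`
#' (case-insensitive substring) and `range` (inclusive bounds,
#' `value = c(lo, hi)`).
#'
#' @inheritParams list_records
#' @param filters A list of `list(field =, op =, value =)` filters; an
#'   empty list reproduces [list_records()].
#' @return A `protrack_page`.
#' @examples
#' \dontrun{
#' search_records(st, "dna",
#'                filters = list(list(field = "project", op = "equals",
#'                                    value = "P1")))
#' }
#' @export
search_records <- function(store, type, filters = list(), sort_by = "id",
                           sort_dir = c("asc", "desc"), page = 1L,
                           page_size = NULL) {
  type <- match.arg(type, names(PT_TYPES))
  clauses <- character()
  params <- list()
  for (f in filters) {
    field <- pt_check_field(type, f$field)
    op <- match.arg(f$op, c("equals", "contains", "range"))
    if (op == "equals") {
      clauses <- c(clauses, sprintf("%s = ?", field))
      params <- c(params, list(f$value))
    } else if (op == "contains") {
      clauses <- c(clauses, sprintf("instr(lower(%s), lower(?)) > 0", field))
      params <- c(params, list(as.character(f$value)))
    } else {
      stopifnot(length(f$value) == 2L)
      clauses <- c(clauses, sprintf("%s BETWEEN ? AND ?", field))
      params <- c(params, list(f$value[[1L]], f$value[[2L]]))
    }
  }
  where <- if (length(clauses) > 0L)
    paste("WHERE", paste(clauses, collapse = " AND ")) else ""
  pt_page(store, type, where = where, params = params, sort_by = sort_by,
          sort_dir = match.arg(sort_dir), page = page, page_size = page_size)
}

#' Check a construct-map file reference
#'
#' A pure existence check under the configured construct-map directory.
#' A missing file is a warning carried on the record (`map_file_found`),
#' never a rejection.  Filenames with path components escaping the map
#' directory (absolute paths, `..`) are treated as not found.
#'
#' @param filename File name as entered on the construct record.
#' @param config A `protrack_config` (or a store, whose config is used).
#' @return `TRUE` if the file exists under the map directory.
#' @export
check_map_file <- function(filename, config) {
  if (inherits(config, "protrack_store")) config <- config$config
  if (is.null(filename) || is.na(filename) || !nzchar(filename)) return(NA)
  parts <- strsplit(filename, "[/\\\\]")[[1L]]
  if (grepl("^([/\\\\]|[A-Za-z]:)", filename) || any(parts == "..")) {
    warning(sprintf("map filename '%s' escapes the construct map directory",
                    filename), call. = FALSE)
    return(FALSE)
  }
  file.exists(file.path(config$construct_map_dir, filename))
}

# -- export / import ---------------------------------------------------

pt_all_records <- function(store, type) {
  ids <- DBI::dbGetQuery(store$con,
    sprintf("SELECT id FROM %s ORDER BY id", PT_TYPES[[type]]$table))$id
  lapply(ids, get_record, store = store)
}

#' Export records of one type as CSV
#'
#' One row per record in id order; columns are `id` followed by the
#' type's documented field order; multi-valued fields (construct ids,
#' supe ids, purification steps) are semicolon-joined.
#'
#' @inheritParams list_records
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(store, type, path) {
  type <- match.arg(type, names(PT_TYPES))
  recs <- pt_all_records(store, type)
  tp <- PT_TYPES[[type]]
  cols <- c("id", names(tp$scalar), names(tp$lists),
            if (type == "request") "secondary_request_ids")
  rows <- lapply(recs, function(r) {
    vals <- lapply(cols, function(f) {
      v <- r[[f]]
      if (f %in% c(names(tp$lists), "secondary_request_ids"))
        paste(v, collapse = ";")
      else v
    })
    names(vals) <- cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else {
    empty <- as.data.frame(matrix(character(), ncol = length(cols)))
    names(empty) <- cols
    empty
  }
  ok <- tryCatch({utils::write.csv(df, path, row.names = FALSE, na = ""); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    pt_abort("io_failure", paste0("CSV export failed: ", conditionMessage(ok)))
  invisible(path)
}

#' Export construct sequences as FASTA
#'
#' Headers are `>RecordID construct_name`.
#'
#' @inheritParams list_records
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(store, path) {
  recs <- pt_all_records(store, "dna")
  seqs <- Biostrings::AAStringSet(vapply(recs, `[[`, "", "mature_sequence"))
  names(seqs) <- vapply(recs, function(r)
    trimws(paste(r$id, r$construct_name)), "")
  ok <- tryCatch({Biostrings::writeXStringSet(seqs, path); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    pt_abort("io_failure", paste0("FASTA export failed: ", conditionMessage(ok)))
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param first_only Keep only the first record (single-construct
#'   submission); batch import uses all records.
#' @return A data.frame with columns `name` and `sequence`.
#' @export
import_fasta <- function(path, first_only = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (first_only && length(seqs) > 1L) seqs <- seqs[1L]
  data.frame(name = names(seqs), sequence = as.character(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}
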