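# Store lifecycle: an embedded single-file SQLite database plus a small
# configuration (construct-map directory, notification sink, default
# page size).  The schema DDL ships with the package (inst/sql); it is
# applied idempotently on open, so creating and reopening are the same
# call.

#' Store configuration
#'
#' @param database_path Path of the SQLite database file.  Its parent
#'   directory must exist.
#' @param construct_map_dir Directory holding DNA construct map files
#'   (managed by external software); used only for the
#'   filename-exists check at construct submission.
#' @param notification_sink `"log"` (default) appends one JSON line per
#'   event to `notification_log`; `"file"` is an alias for the same
#'   mechanism with an explicit path; `"smtp-stub"` records events in
#'   the store only (delivery is intentionally a stub).
#' @param notification_log Path of the JSON-lines notification log;
#'   defaults to `<database_path>.notifications.jsonl`.
#' @param page_size_default Rows per page when listing/searching
#'   without an explicit page size.
#' @param request_group Recipient strings notified on every request
#'   submission (the request-management group).
#' @return A `protrack_config` list.
#' @export
store_config <- function(database_path,
                         construct_map_dir = dirname(database_path),
                         notification_sink = c("log", "file", "smtp-stub"),
                         notification_log = paste0(database_path, ".notifications.jsonl"),
                         page_size_default = 20L,
                         request_group = "request-management-group") {
  notification_sink <- match.arg(notification_sink)
  stopifnot(page_size_default >= 1L)
  if (!dir.exists(dirname(database_path)))
    pt_abort("io_failure",
             sprintf("parent directory of '%s' does not exist", database_path))
  structure(list(database_path = database_path,
                 construct_map_dir = construct_map_dir,
                 notification_sink = notification_sink,
                 notification_log = notification_log,
                 page_size_default = as.integer(page_size_default),
                 request_group = request_group),
            class = "protrack_config")
}

#' Read/write a store configuration file (YAML)
#'
#' @param path Path of the YAML config file.
#' @return `read_store_config()` returns a `protrack_config`;
#'   `write_store_config()` returns `path` invisibly.
#' @export
read_store_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(store_config, raw[intersect(names(raw), names(formals(store_config)))])
}

#' @rdname read_store_config
#' @param config A `protrack_config`.
#' @export
write_store_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Open (or create) a protrack store
#'
#' Applies the package's schema DDL idempotently, so the first open
#' creates the database.
#'
#' @param config A `protrack_config` (see [store_config()]), or a path:
#'   either a YAML config file or a SQLite database path.
#' @param ... When `config` is a database path, further arguments to
#'   [store_config()].
#' @return A `protrack_store` handle.
#' @examples
#' st <- open_store(tempfile(fileext = ".sqlite"))
#' close_store(st)
#' @export
open_store <- function(config, ...) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$|\\.cfg$", config)) read_store_config(config)
              else store_config(config, ...)
  }
  stopifnot(inherits(config, "protrack_config"))
  con <- DBI::dbConnect(RSQLite::SQLite(), config$database_path)
  DBI::dbExecute(con, "PRAGMA synchronous = OFF")
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  ddl <- readLines(system.file("sql", "schema.sql", package = "protrack"))
  ddl <- sub("--.*$", "", ddl)
  for (stmt in strsplit(paste(ddl, collapse = "\n"), ";", fixed = TRUE)[[1L]]) {
    if (grepl("[A-Za-z]", stmt)) DBI::dbExecute(con, stmt)
  }
  store <- new.env(parent = emptyenv())
  store$con <- con
  store$config <- config
  class(store) <- "protrack_store"
  store
}

#' Close a store
#'
#' @param store A `protrack_store`.
#' @export
close_store <- function(store) {
  if (DBI::dbIsValid(store$con)) DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.protrack_store <- function(x, ...) {
  counts <- vapply(PT_TYPES, function(tp) {
    DBI::dbGetQuery(x$con, sprintf("SELECT COUNT(*) n FROM %s", tp$table))$n
  }, numeric(1))
  cat("<protrack store> ", x$config$database_path, "\n", sep = "")
  cat(paste(sprintf("  %-10s %d", names(counts), counts), collapse = "\n"), "\n")
  invisible(x)
}

# -- meta table helpers (counters, logical clock) ----------------------

pt_meta_get <- function(store, key, default = NULL) {
  r <- DBI::dbGetQuery(store$con, "SELECT value FROM meta WHERE key = ?",
                       params = list(key))
  if (nrow(r) == 0L) default else r$value[[1L]]
}

pt_meta_set <- function(store, key, value) {
  DBI::dbExecute(store$con,
    "INSERT INTO meta (key, value) VALUES (?, ?)
     ON CONFLICT(key) DO UPDATE SET value = excluded.value",
    params = list(key, as.character(value)))
  invisible(NULL)
}

# Monotone logical clock: record/request/notification timestamps are
# synthetic counters so that ordering is deterministic and independent
# of wall-clock time.
pt_tick <- function(store) {
  t <- as.integer(pt_meta_get(store, "clock", "0")) + 1L
  pt_meta_set(store, "clock", t)
  t
}

# run `expr` inside a single SQLite transaction (used by bulk loads)
pt_with_transaction <- function(store, expr) {
  DBI::dbBegin(store$con)
  ok <- FALSE
  on.exit(if (ok) DBI::dbCommit(store$con) else DBI::dbRollback(store$con))
  res <- force(expr)
  ok <- TRUE
  res
}

#' Allocate the next record identifier
#'
#' Identifiers are `<PREFIX>-<5-digit serial>` with per-prefix counters
#' (DNA, CL, SUP, PB, REQ).  Counters are persisted and never reuse a
#' serial, even after deletion.
#'
#' @param store A `protrack_store`.
#' @param prefix One of `"DNA"`, `"CL"`, `"SUP"`, `"PB"`, `"REQ"`.
#' @return The rendered id string, e.g. `"DNA-00001"`.
#' @export
next_id <- function(store, prefix) {
  prefix <- match.arg(prefix, unname(PT_PREFIXES))
  key <- paste0("serial_", prefix)
  serial <- as.integer(pt_meta_get(store, key, "0")) + 1L
  pt_meta_set(store, key, serial)
  sprintf("%s-%05d", prefix, serial)
}

# -- roles -------------------------------------------------------------

ROLES <- c("reader", "record_admin", "request_admin")

pt_check_role <- function(role, needed) {
  role <- match.arg(role, ROLES)
  if (role != needed)
    pt_abort("permission_denied",
             sprintf("role '%s' may not perform this operation (needs '%s')",
                     role, needed))
  invisible(role)
}

# -- notifications -----------------------------------------------------

pt_notify <- function(store, recipient, subject, body, link) {
  for (r in recipient) {
    ts <- pt_tick(store)
    DBI::dbExecute(store$con,
      "INSERT INTO notification (recipient, subject, body, link, timestamp)
       VALUES (?, ?, ?, ?, ?)",
      params = list(r, subject, body, link, ts))
    if (store$config$notification_sink %in% c("log", "file")) {
      line <- jsonlite::toJSON(list(timestamp = ts, recipient = r,
                                    subject = subject, body = body,
                                    link = link),
                               auto_unbox = TRUE)
      cat(line, "\n", sep = "", file = store$config$notification_log,
          append = TRUE)
    }
  }
  invisible(NULL)
}

#' Notification history
#'
#' Every request submission notifies the request-management group, and
#' every status change notifies the submitter when a requestor email is
#' on the request.  Events are recorded in the store and (for the log
#' sink) appended as JSON lines to the notification log.
#'
#' @param store A `protrack_store`.
#' @return A data.frame with columns `seq`, `recipient`, `subject`,
#'   `body`, `link`, `timestamp`.
#' @export
notifications <- function(store) {
  DBI::dbGetQuery(store$con,
    "SELECT seq, recipient, subject, body, link, timestamp
     FROM notification ORDER BY seq")
}
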