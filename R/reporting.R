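# Chain-of-custody traversal, printable reports, and the stable
# external-link format used in notifications and documents.

LINK_SCHEME <- "proteintracker://"
ID_REGEX <- "^(DNA|CL|SUP|PB|REQ)-[0-9]{5,}$"

#' Render / parse an external record link
#'
#' Links have the form `proteintracker://<record-or-request-id>` and are
#' a bijection with ids: `resolve_link(external_link(x)) == x`.
#'
#' @param id A record or request id.
#' @return `external_link()` the rendered link; `resolve_link()` the id.
#' @examples
#' external_link("PB-00002")                      # "proteintracker://PB-00002"
#' resolve_link("proteintracker://PB-00002")      # "PB-00002"
#' @export
external_link <- function(id) {
  if (!is.character(id) || length(id) != 1L || !grepl(ID_REGEX, id))
    pt_abort("malformed_link", sprintf("'%s' is not a valid record id", id))
  paste0(LINK_SCHEME, id)
}

#' @rdname external_link
#' @param link A link string.
#' @export
resolve_link <- function(link) {
  if (!is.character(link) || length(link) != 1L ||
      !startsWith(link, LINK_SCHEME))
    pt_abort("malformed_link", sprintf("'%s' is not a protrack link", link))
  id <- substring(link, nchar(LINK_SCHEME) + 1L)
  if (!grepl(ID_REGEX, id))
    pt_abort("malformed_link", sprintf("'%s' carries an invalid id", link))
  id
}

# one-line summary for a lineage node
pt_node_summary <- function(record) {
  switch(record_type(record),
    dna = sprintf("%s (MW %.2f Da)", record$construct_name,
                  record$molecular_weight),
    cell_line = sprintf("%s [%s]", record$name, record$cell_type),
    supe = sprintf("from %s", record$cell_line_id),
    batch = sprintf("%.2f mg total", record$total_mass),
    record$id)
}

pt_lineage_node <- function(store, id, visited) {
  if (id %in% ls(visited)) return(NULL)
  assign(id, TRUE, envir = visited)
  record <- get_record(store, id)
  type <- record_type(record)
  children <- list()
  if (type == "batch") {
    children <- lapply(record$supe_ids, pt_lineage_node, store = store,
                       visited = visited)
  } else if (type == "supe") {
    cl_node <- pt_lineage_node(store, record$cell_line_id, visited)
    tc_nodes <- lapply(sort(record$transfection_construct_ids),
                       pt_lineage_node, store = store, visited = visited)
    if (!is.null(cl_node)) {
      # a transient supe's constructs hang off its (parental) cell
      # line, where they were introduced
      cl_node$children <- c(cl_node$children,
                            Filter(Negate(is.null), tc_nodes))
      children <- list(cl_node)
    } else {
      # the line was already shown under an earlier supe; keep any
      # not-yet-seen transfection constructs directly under this supe
      children <- tc_nodes
    }
  } else if (type == "cell_line") {
    children <- lapply(record$construct_ids, pt_lineage_node,
                       store = store, visited = visited)
  }
  children <- Filter(Negate(is.null), children)
  structure(list(id = id, type = type, summary = pt_node_summary(record),
                 children = children),
            class = "protrack_lineage_node")
}

#' Chain-of-custody lineage of a record
#'
#' Walks the lineage upstream (batch -> supes -> cell lines ->
#' constructs).  Shared ancestors are deduplicated: each node appears
#' once, the first time it is reached.  A construct's tree is a single
#' node.
#'
#' @param store A `protrack_store`.
#' @param id Record id.
#' @return A `protrack_lineage` tree of nodes
#'   `list(id, type, summary, children)`.
#' @export
chain_of_custody <- function(store, id) {
  get_record(store, id)   # NotFound if absent
  visited <- new.env(parent = emptyenv())
  tree <- pt_lineage_node(store, id, visited)
  class(tree) <- c("protrack_lineage", class(tree))
  tree
}

#' Flatten a lineage tree
#'
#' @param tree A `protrack_lineage`.
#' @return `lineage_ids()`: ids of all nodes in depth-first order;
#'   `lineage_leaves()`: ids of the DNA construct nodes — the terminal
#'   records of the lineage graph.  (When supes share an ancestor the
#'   printed tree truncates the repeated subtree, so terminality is
#'   defined on the underlying graph, not on the rendered tree.)
#' @export
lineage_ids <- function(tree) {
  c(tree$id, unlist(lapply(tree$children, lineage_ids), use.names = FALSE))
}

#' @rdname lineage_ids
#' @export
lineage_leaves <- function(tree) {
  own <- if (identical(tree$type, "dna")) tree$id else character()
  c(own, unlist(lapply(tree$children, lineage_leaves), use.names = FALSE))
}

pt_tree_lines <- function(node, depth = 0L) {
  c(paste0(strrep("  ", depth), node$id, "  ", node$summary),
    unlist(lapply(node$children, pt_tree_lines, depth = depth + 1L),
           use.names = FALSE))
}

#' @export
print.protrack_lineage <- function(x, ...) {
  cat(pt_tree_lines(x), sep = "\n")
  invisible(x)
}

# "Field: value" block for one record, in documented field order
pt_field_block <- function(record) {
  type <- record_type(record)
  tp <- PT_TYPES[[type]]
  fields <- c("id", names(tp$scalar), names(tp$lists),
              if (type == "request") "secondary_request_ids")
  vapply(fields, function(f) {
    v <- record[[f]]
    v <- if (length(v) == 0L) "" else paste(format(v), collapse = ", ")
    sprintf("%s: %s", f, v)
  }, "")
}

#' Printable report for a reagent record
#'
#' A deterministic structured-text document listing every stored field;
#' for supes and protein batches the upstream lineage (related cell
#' lines and constructs) is appended section by section.  Rendering the
#' same store twice yields identical bytes.
#'
#' @param store A `protrack_store`.
#' @param id Record id.
#' @return The report as a single string (lines joined by `\n`).
#' @export
record_report <- function(store, id) {
  record <- get_record(store, id)
  type <- record_type(record)
  if (type == "request") return(request_report(store, id))
  lines <- c(sprintf("=== %s record %s ===", toupper(type), id),
             sprintf("link: %s", external_link(id)),
             pt_field_block(record))
  if (type %in% c("supe", "batch")) {
    tree <- chain_of_custody(store, id)
    ancestors <- setdiff(lineage_ids(tree), id)
    lines <- c(lines, "", "--- lineage (chain of custody) ---",
               pt_tree_lines(tree))
    for (aid in ancestors) {
      arec <- get_record(store, aid)
      lines <- c(lines, "",
                 sprintf("--- related %s %s ---", record_type(arec), aid),
                 pt_field_block(arec))
    }
    if (type == "batch") {
      cl_ids <- unique(vapply(record$supe_ids, function(sid)
        get_record(store, sid)$cell_line_id, ""))
      if (length(cl_ids) > 1L)
        lines <- c(lines, "",
                   sprintf("NOTE: batch spans supes from %d different cell lines (%s)",
                           length(cl_ids), paste(sort(cl_ids), collapse = ", ")))
    }
  }
  paste(lines, collapse = "\n")
}

#' Printable report for a request
#'
#' Shows kind, status, queue rank (while Pending only), quantity,
#' linked secondary requests and the external link.
#'
#' @inheritParams record_report
#' @return The report as a single string.
#' @export
request_report <- function(store, id) {
  req <- get_record(store, id)
  if (record_type(req) != "request")
    pt_abort("not_found", sprintf("%s is not a request", id))
  lines <- c(sprintf("=== REQUEST %s ===", id),
             sprintf("link: %s", external_link(id)),
             sprintf("kind: %s", req$kind),
             sprintf("status: %s", req$status))
  if (req$status == "Pending")
    lines <- c(lines, sprintf("queue rank: %d", req$priority_rank))
  fields <- pt_field_block(req)
  drop <- c("id", "kind", "status", "priority_rank", "secondary_request_ids")
  lines <- c(lines, fields[!sub(":.*$", "", fields) %in% drop])
  if (length(req$secondary_request_ids) > 0L)
    lines <- c(lines, sprintf("secondary requests: %s",
                              paste(req$secondary_request_ids, collapse = ", ")))
  paste(lines, collapse = "\n")
}
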