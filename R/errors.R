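#' @keywords internal
"_PACKAGE"

# Classed conditions used across the package.  Every error raised by
# protrack carries class c("protrack_<kind>", "protrack_error", "error")
# so callers can handle a specific failure (e.g. protrack_not_found)
# or any package error at once.
pt_abort <- function(kind, msg, ...) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("protrack_", kind), "protrack_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

#' Errors raised by protrack
#'
#' All package errors are classed conditions inheriting from
#' `protrack_error`.  The specific classes are:
#'
#' * `protrack_empty_sequence` — nothing left after normalization
#' * `protrack_illegal_residue` — non-standard amino-acid code (B, J, O,
#'   U, X, Z and anything else outside the 20-letter alphabet)
#' * `protrack_negative_quantity` — negative concentration or volume
#' * `protrack_aliquot_bounds` — current aliquots outside `[0, original]`
#' * `protrack_permission_denied` — role does not permit the mutation
#' * `protrack_validation_failed` — link-rule violations (the violations
#'   are attached as the `violations` field of the condition)
#' * `protrack_not_found` — no record with the given id
#' * `protrack_referenced_record` — delete refused: downstream records
#'   still reference this one
#' * `protrack_unknown_field` — sort/search field not on the record type
#' * `protrack_illegal_transition` — request status may only move
#'   Pending -> Started -> Fulfilled
#' * `protrack_not_pending` — prioritization/deletion allowed only while
#'   work has not begun
#' * `protrack_missing_quantity` — transfection request without a volume
#'   or flask count
#' * `protrack_broken_lineage` — a lineage link dangles
#' * `protrack_malformed_link` — external link not in
#'   `proteintracker://<ID>` form
#' * `protrack_store_not_empty` — fixture population requires an empty
#'   store
#' * `protrack_io_failure` — export could not be written
#'
#' @name protrack-errors
#' @keywords internal
NULL
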