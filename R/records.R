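# Record constructors and the row <-> record mapping.  A record is a
# named list tagged with its type; derived fields (sequence properties,
# batch mass) are recomputed by the store on every create/update and
# never accepted from the caller.

pt_record <- function(type, fields) {
  tp <- PT_TYPES[[type]]
  rec <- list(id = pt_cast(fields$id, "chr"))
  for (f in names(tp$scalar)) rec[[f]] <- pt_cast(fields[[f]], tp$scalar[[f]])
  for (f in names(tp$lists))  rec[[f]] <- as.character(fields[[f]] %||% character())
  structure(rec, class = c(paste0("protrack_", type), "protrack_record"),
            type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_type <- function(record) attr(record, "type")

#' Build a DNA construct record
#'
#' The mature sequence is normalized and its derived properties
#' (molecular weight, extinction coefficients, 0.1% absorbance, sequon
#' count) are calculated at submission; the map-file reference, when
#' given, is checked against the configured construct-map directory.
#'
#' @param construct_name,project,vector,tag,insert_name,notebook_ref
#'   Free-text descriptive fields.
#' @param mature_sequence Mature protein amino-acid sequence (free text;
#'   normalized on submission).
#' @param construct_map_filename Optional file name of the construct map
#'   held in the configured map directory.
#' @return An unsaved record to pass to [create_record()].
#' @export
dna_construct <- function(construct_name, mature_sequence, project = "",
                          vector = "", tag = "", insert_name = "",
                          notebook_ref = "", construct_map_filename = NA) {
  pt_record("dna", list(
    construct_name = construct_name, project = project, vector = vector,
    tag = tag, insert_name = insert_name, notebook_ref = notebook_ref,
    mature_sequence = mature_sequence,
    construct_map_filename = construct_map_filename))
}

#' Build a cell line record
#'
#' Stable lines must name the integrated construct(s) (more than one for
#' a co-transfection); parental and hybridoma lines carry no construct
#' links.
#'
#' @param name Cell line name.
#' @param cell_type `"parental"`, `"stable"` or `"hybridoma"`.
#' @param construct_ids DNA construct ids for stable lines.
#' @param origin,freezer_location,mycoplasma_result,annotations,bank_date,culture_time
#'   Descriptive/QC fields.
#' @return An unsaved record to pass to [create_record()].
#' @export
cell_line <- function(name, cell_type, construct_ids = character(),
                      origin = "", freezer_location = "",
                      mycoplasma_result = "", annotations = "",
                      bank_date = "", culture_time = "") {
  pt_record("cell_line", list(
    name = name, cell_type = cell_type, construct_ids = construct_ids,
    origin = origin, freezer_location = freezer_location,
    mycoplasma_result = mycoplasma_result, annotations = annotations,
    bank_date = bank_date, culture_time = culture_time))
}

#' Build a supe (conditioned media) record
#'
#' A transient transfection names a parental cell line plus the
#' construct(s) transfected; a stable-line supe names the stable line
#' and inherits its constructs.
#'
#' @param cell_line_id Id of the producing cell line.
#' @param transfection_construct_ids Construct ids for transient
#'   transfections (empty for stable lines).
#' @param expression_level,quality,western_blot_link,endotoxin_result,harvest_info,location,culture_media,notebook_ref,qc_file_link,remaining_quantity
#'   Descriptive/QC fields.
#' @param concentration Protein concentration, mg/mL.
#' @param aliquot_count Number of aliquots in the freezer.
#' @return An unsaved record to pass to [create_record()].
#' @export
supe <- function(cell_line_id, transfection_construct_ids = character(),
                 expression_level = "", quality = "",
                 western_blot_link = "", endotoxin_result = "",
                 harvest_info = "", location = "", culture_media = "",
                 notebook_ref = "", qc_file_link = "",
                 concentration = NA_real_, remaining_quantity = "",
                 aliquot_count = NA_integer_) {
  pt_record("supe", list(
    cell_line_id = cell_line_id,
    transfection_construct_ids = transfection_construct_ids,
    expression_level = expression_level, quality = quality,
    western_blot_link = western_blot_link,
    endotoxin_result = endotoxin_result, harvest_info = harvest_info,
    location = location, culture_media = culture_media,
    notebook_ref = notebook_ref, qc_file_link = qc_file_link,
    concentration = concentration, remaining_quantity = remaining_quantity,
    aliquot_count = aliquot_count))
}

#' Build a purified protein batch record
#'
#' Total mass (concentration x volume) and remaining mass (scaled by the
#' remaining aliquot fraction) are calculated at submission and on every
#' update; the sequence-derived read-only properties are copied from the
#' batch's first effective construct.
#'
#' @param supe_ids Ids of the supe(s) the batch was purified from.
#' @param concentration mg/mL.
#' @param volume mL.
#' @param original_aliquots,current_aliquots Aliquot bookkeeping.
#' @param purification_steps Ordered character vector of steps.
#' @param formulation_buffer,endotoxin_result,qc_notes,gel_qc_link
#'   Descriptive/QC fields.
#' @return An unsaved record to pass to [create_record()].
#' @export
protein_batch <- function(supe_ids, concentration, volume,
                          original_aliquots, current_aliquots,
                          purification_steps = character(),
                          formulation_buffer = "", endotoxin_result = "",
                          qc_notes = "", gel_qc_link = "") {
  pt_record("batch", list(
    supe_ids = supe_ids, concentration = concentration, volume = volume,
    original_aliquots = original_aliquots,
    current_aliquots = current_aliquots,
    purification_steps = purification_steps,
    formulation_buffer = formulation_buffer,
    endotoxin_result = endotoxin_result, qc_notes = qc_notes,
    gel_qc_link = gel_qc_link))
}

#' @export
print.protrack_record <- function(x, ...) {
  cat("<", record_type(x), "> ", x$id %||% "(unsaved)", "\n", sep = "")
  for (f in setdiff(names(x), "id")) {
    v <- x[[f]]
    cat(sprintf("  %-26s %s\n", f,
                if (length(v) == 0L) "" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# -- derived-field recomputation (store-side) --------------------------

pt_finalize <- function(store, record) {
  type <- record_type(record)
  if (type == "dna") {
    record$mature_sequence <- normalize_sequence(record$mature_sequence)
    props <- sequence_properties(record$mature_sequence)
    record[names(props)] <- props
    record$map_file_found <-
      if (is.na(record$construct_map_filename)) NA
      else check_map_file(record$construct_map_filename, store$config)
  } else if (type == "batch") {
    record$total_mass <- batch_mass(record$concentration, record$volume)
    record$remaining_mass <- remaining_mass(record$total_mass,
                                            record$original_aliquots,
                                            record$current_aliquots)
    eff <- tryCatch(effective_constructs(store, record),
                    protrack_error = function(e) list())
    if (length(eff) > 0L) {
      # single scalar display fields come from the first effective
      # construct in id order; reports list all of them
      props <- eff[[1L]][c("molecular_weight", "extinction_reduced",
                           "extinction_oxidized", "absorbance_0_1pct",
                           "n_glyc_sites")]
      record[names(props)] <- props
    }
  }
  record
}

# -- SQL row <-> record ------------------------------------------------

pt_insert_record <- function(store, record) {
  type <- record_type(record)
  tp <- PT_TYPES[[type]]
  cols <- c("id", names(tp$scalar))
  # RSQLite maps NA -> NULL
  vals <- lapply(cols, function(f) {
    v <- record[[f]]
    if (is.logical(v)) as.integer(v) else v
  })
  sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", tp$table,
                 paste(cols, collapse = ", "),
                 paste(rep("?", length(cols)), collapse = ", "))
  DBI::dbExecute(store$con, sql, params = vals)
  pt_write_lists(store, record)
  invisible(record$id)
}

pt_write_lists <- function(store, record) {
  type <- record_type(record)
  for (f in names(PT_TYPES[[type]]$lists)) {
    spec <- PT_TYPES[[type]]$lists[[f]]
    DBI::dbExecute(store$con,
      sprintf("DELETE FROM %s WHERE %s = ?", spec[["table"]], spec[["key"]]),
      params = list(record$id))
    vals <- record[[f]]
    if (length(vals) > 0L) {
      DBI::dbExecute(store$con,
        sprintf("INSERT INTO %s (%s, %s, ord) VALUES (?, ?, ?)",
                spec[["table"]], spec[["key"]], spec[["value"]]),
        params = list(rep(record$id, length(vals)), vals,
                      seq_along(vals)))
    }
  }
}

pt_row_to_record <- function(store, type, row, load_lists = TRUE) {
  tp <- PT_TYPES[[type]]
  fields <- list(id = row$id)
  for (f in names(tp$scalar)) fields[[f]] <- row[[f]]
  rec <- pt_record(type, fields)
  if (load_lists) {
    for (f in names(tp$lists)) {
      spec <- tp$lists[[f]]
      rec[[f]] <- DBI::dbGetQuery(store$con,
        sprintf("SELECT %s v FROM %s WHERE %s = ? ORDER BY ord",
                spec[["value"]], spec[["table"]], spec[["key"]]),
        params = list(row$id))$v
    }
    if (type == "request") {
      rec$secondary_request_ids <- DBI::dbGetQuery(store$con,
        "SELECT id FROM request WHERE parent_request_id = ? ORDER BY id",
        params = list(row$id))$id
    }
  }
  rec
}
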