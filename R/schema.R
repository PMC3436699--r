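# Field inventory per record type: the single source of truth for SQL
# column mapping, JSON/CSV serialization, report field listings, and
# search/sort field validation.  `scalar` maps field -> storage type
# (chr/int/dbl/lgl); `lists` maps multi-valued fields to their junction
# table and value column (ordered by `ord`).

PT_PREFIXES <- c(dna = "DNA", cell_line = "CL", supe = "SUP",
                 batch = "PB", request = "REQ")

PT_TYPES <- list(
  dna = list(
    table = "dna_construct",
    scalar = c(construct_name = "chr", project = "chr", vector = "chr",
               tag = "chr", insert_name = "chr", notebook_ref = "chr",
               mature_sequence = "chr", construct_map_filename = "chr",
               map_file_found = "lgl", molecular_weight = "dbl",
               extinction_reduced = "dbl", extinction_oxidized = "dbl",
               absorbance_0_1pct = "dbl", n_glyc_sites = "int",
               created_at = "int"),
    lists = list()
  ),
  cell_line = list(
    table = "cell_line",
    scalar = c(name = "chr", cell_type = "chr", origin = "chr",
               freezer_location = "chr", mycoplasma_result = "chr",
               annotations = "chr", bank_date = "chr", culture_time = "chr",
               created_at = "int"),
    lists = list(construct_ids = c(table = "cellline_construct",
                                   key = "cell_line_id",
                                   value = "construct_id"))
  ),
  supe = list(
    table = "supe",
    scalar = c(cell_line_id = "chr", expression_level = "chr",
               quality = "chr", western_blot_link = "chr",
               endotoxin_result = "chr", harvest_info = "chr",
               location = "chr", culture_media = "chr", notebook_ref = "chr",
               qc_file_link = "chr", concentration = "dbl",
               remaining_quantity = "chr", aliquot_count = "int",
               created_at = "int"),
    lists = list(transfection_construct_ids = c(table = "supe_construct",
                                                key = "supe_id",
                                                value = "construct_id"))
  ),
  batch = list(
    table = "protein_batch",
    scalar = c(formulation_buffer = "chr", concentration = "dbl",
               volume = "dbl", original_aliquots = "int",
               current_aliquots = "int", endotoxin_result = "chr",
               qc_notes = "chr", gel_qc_link = "chr", total_mass = "dbl",
               remaining_mass = "dbl", molecular_weight = "dbl",
               extinction_reduced = "dbl", extinction_oxidized = "dbl",
               absorbance_0_1pct = "dbl", n_glyc_sites = "int",
               created_at = "int"),
    lists = list(supe_ids = c(table = "batch_supe", key = "batch_id",
                              value = "supe_id"),
                 purification_steps = c(table = "batch_step",
                                        key = "batch_id", value = "step"))
  ),
  request = list(
    table = "request",
    scalar = c(kind = "chr", status = "chr", requestor_email = "chr",
               priority_rank = "int", subject_record_id = "chr",
               parent_request_id = "chr", quantity_type = "chr",
               quantity = "dbl", cell_type = "chr", created_at = "int"),
    lists = list()   # secondary_request_ids is derived from parent links
  )
)

REQUEST_KINDS <- c("transfection", "stable_supe", "dna", "purification", "aliquot")
REQUEST_STATUSES <- c("Pending", "Started", "Fulfilled")
CELL_TYPES <- c("parental", "stable", "hybridoma")

pt_type_of_id <- function(id) {
  prefix <- sub("-.*$", "", id)
  type <- names(PT_PREFIXES)[match(prefix, PT_PREFIXES)]
  if (is.na(type))
    pt_abort("not_found", sprintf("'%s' is not a recognised record id", id))
  type
}

pt_na_of <- function(storage) {
  switch(storage, chr = NA_character_, int = NA_integer_,
         dbl = NA_real_, lgl = NA)
}

pt_cast <- function(x, storage) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(pt_na_of(storage))
  switch(storage,
         chr = as.character(x),
         int = as.integer(x),
         dbl = as.numeric(x),
         lgl = as.logical(x))
}
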