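# Deterministic synthetic-store generator: coherent linked stores
# (constructs -> cell lines -> supes -> batches -> requests) at
# arbitrary scale for tests and demos.  Sequence composition is uniform
# over the 20-letter alphabet (the invariants under test are
# combinatorial, not biological), and timestamps come from the store's
# logical clock, so a seed fully determines the store content.

# run code under a temporary RNG state without touching the caller's
pt_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

pick1 <- function(pool) pool[[sample.int(length(pool), 1L)]]

#' Random amino-acid sequence(s)
#'
#' Uniform over the 20 standard residues; driven by the current RNG
#' state, so a fixed seed reproduces the same sequences.
#'
#' @param length Integer vector of sequence lengths (each at least 1);
#'   one sequence is returned per element.
#' @return Character vector of sequences.
#' @export
random_sequence <- function(length) {
  if (any(length < 1L))
    pt_abort("empty_sequence", "sequence length must be at least 1")
  vapply(length, function(n)
    paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""), "")
}

#' Specification for a synthetic store
#'
#' @param seed Master seed; the same seed and counts reproduce a
#'   field-identical store.
#' @param n_constructs,n_cell_lines,n_supes,n_batches,n_requests Record
#'   counts per type.
#' @param seq_length Length range for generated mature sequences.
#' @param frac_transient Fraction of supes produced by transient
#'   transfection (the rest come from stable lines).
#' @param status_fractions Named fractions of requests left Pending,
#'   advanced to Started, or driven to Fulfilled.
#' @param scale `"small"` or `"production"` presets; `"production"`
#'   yields a 9,000-record store mirroring a multi-year deployment.
#' @return A `protrack_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_constructs = 12L, n_cell_lines = 6L,
                         n_supes = 10L, n_batches = 5L, n_requests = 12L,
                         seq_length = c(30L, 300L), frac_transient = 0.5,
                         status_fractions = c(Pending = 0.5, Started = 0.3,
                                              Fulfilled = 0.2),
                         scale = NULL) {
  if (!is.null(scale)) {
    scale <- match.arg(scale, c("small", "production"))
    if (scale == "production") {
      n_constructs <- 2600L; n_cell_lines <- 1300L; n_supes <- 2600L
      n_batches <- 1300L; n_requests <- 1200L
    }
  }
  stopifnot(n_constructs >= 1L, abs(sum(status_fractions) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n_constructs = as.integer(n_constructs),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_supes = as.integer(n_supes),
                 n_batches = as.integer(n_batches),
                 n_requests = as.integer(n_requests),
                 seq_length = as.integer(seq_length),
                 frac_transient = frac_transient,
                 status_fractions = status_fractions),
            class = "protrack_fixture_spec")
}

#' Populate an empty store with coherent synthetic records
#'
#' Generates constructs, cell lines (parental/stable/hybridoma mix,
#' with at least one parental and one stable when counts allow), supes
#' split between transient transfections and stable lines, multi-supe
#' batches, and requests distributed across kinds and statuses through
#' the real workflow operations (so ranks, notifications and status
#' histories are genuine).  The populated store passes
#' [validate_links()] by construction.
#'
#' @param store An empty `protrack_store`.
#' @param spec A [fixture_spec()].
#' @return Named integer vector of created record counts.
#' @export
populate_store <- function(store, spec = fixture_spec()) {
  stopifnot(inherits(spec, "protrack_fixture_spec"))
  existing <- sum(vapply(PT_TYPES, function(tp)
    DBI::dbGetQuery(store$con,
      sprintf("SELECT COUNT(*) n FROM %s", tp$table))$n, numeric(1)))
  if (existing > 0L)
    pt_abort("store_not_empty", "populate_store() requires an empty store")

  pt_local_seed(spec$seed, pt_with_transaction(store, {
    projects <- paste0("P", 1:5)
    vectors <- c("pCDNA3.1", "pTT5", "pET28a", "pFUSE")
    tags <- c("His6", "FLAG", "Fc", "none")

    dna_ids <- character(spec$n_constructs)
    for (i in seq_len(spec$n_constructs)) {
      dna_ids[i] <- create_record(store, dna_construct(
        construct_name = sprintf("construct-%04d", i),
        mature_sequence = random_sequence(
          sample(spec$seq_length[1L]:spec$seq_length[2L], 1L)),
        project = pick1(projects), vector = pick1(vectors),
        tag = pick1(tags), insert_name = sprintf("insert-%04d", i),
        notebook_ref = sprintf("NB-%04d", i)), role = "record_admin")
    }

    cl_types <- sample(CELL_TYPES, spec$n_cell_lines, replace = TRUE,
                       prob = c(0.35, 0.55, 0.10))
    if (spec$n_cell_lines >= 1L) cl_types[1L] <- "parental"
    if (spec$n_cell_lines >= 2L) cl_types[2L] <- "stable"
    cl_ids <- character(spec$n_cell_lines)
    for (i in seq_len(spec$n_cell_lines)) {
      ctype <- cl_types[i]
      cids <- if (ctype == "stable")
        sample(dna_ids, min(length(dna_ids), sample(1:2, 1L))) else character()
      cl_ids[i] <- create_record(store, cell_line(
        name = sprintf("line-%04d", i), cell_type = ctype,
        construct_ids = cids, origin = pick1(c("CHO", "HEK293", "NS0")),
        freezer_location = sprintf("LN2-rack-%d", sample(1:12, 1L)),
        mycoplasma_result = pick1(c("negative", "pending")),
        bank_date = sprintf("2025-%02d-%02d", sample(1:12, 1L),
                            sample(1:28, 1L))), role = "record_admin")
    }
    parental <- cl_ids[cl_types == "parental"]
    stable <- cl_ids[cl_types == "stable"]

    supe_ids <- character(spec$n_supes)
    for (i in seq_len(spec$n_supes)) {
      transient <- (length(stable) == 0L) ||
        (length(parental) > 0L && stats::runif(1) < spec$frac_transient)
      if (transient && length(parental) > 0L) {
        supe_ids[i] <- create_record(store, supe(
          cell_line_id = pick1(parental),
          transfection_construct_ids =
            sample(dna_ids, min(length(dna_ids), sample(1:2, 1L))),
          expression_level = pick1(c("low", "medium", "high")),
          location = sprintf("-80C-box-%d", sample(1:30, 1L)),
          concentration = round(stats::runif(1, 0.01, 0.5), 3),
          aliquot_count = sample(1:10, 1L)), role = "record_admin")
      } else {
        supe_ids[i] <- create_record(store, supe(
          cell_line_id = pick1(stable),
          expression_level = pick1(c("low", "medium", "high")),
          location = sprintf("-80C-box-%d", sample(1:30, 1L)),
          concentration = round(stats::runif(1, 0.01, 0.5), 3),
          aliquot_count = sample(1:10, 1L)), role = "record_admin")
      }
    }

    batch_ids <- character(spec$n_batches)
    steps <- c("Protein A", "IMAC", "SEC", "IEX", "dialysis")
    for (i in seq_len(spec$n_batches)) {
      orig <- sample(4:24, 1L)
      batch_ids[i] <- create_record(store, protein_batch(
        supe_ids = sample(supe_ids, min(length(supe_ids), sample(1:2, 1L))),
        concentration = round(stats::runif(1, 0.1, 5), 2),
        volume = round(stats::runif(1, 1, 50), 1),
        original_aliquots = orig, current_aliquots = sample(0:orig, 1L),
        purification_steps = sample(steps, sample(1:3, 1L)),
        formulation_buffer = pick1(c("PBS", "HEPES", "Tris"))),
        role = "record_admin")
    }

    req_ids <- character(spec$n_requests)
    for (i in seq_len(spec$n_requests)) {
      kind <- pick1(REQUEST_KINDS)
      if (kind == "stable_supe" && length(stable) == 0L) kind <- "dna"
      if (kind == "purification" && length(supe_ids) == 0L) kind <- "dna"
      if (kind == "aliquot" && length(batch_ids) == 0L) kind <- "dna"
      subject <- switch(kind,
        transfection = pick1(dna_ids), dna = pick1(dna_ids),
        stable_supe = pick1(stable), purification = pick1(supe_ids),
        aliquot = pick1(batch_ids))
      email <- if (stats::runif(1) < 0.6)
        sprintf("user%02d@example.org", sample(1:8, 1L)) else NA_character_
      if (kind == "transfection") {
        ct <- pick1(c("suspension", "adherent"))
        qty <- if (ct == "suspension") round(stats::runif(1, 50, 2000))
               else sample(1:20, 1L)
        req_ids[i] <- submit_request(store, kind, subject,
                                     requestor_email = email,
                                     cell_type = ct, quantity = qty)$id
      } else {
        req_ids[i] <- submit_request(store, kind, subject,
                                     requestor_email = email)$id
      }
    }
    # drive sampled requests through the real transitions
    n_started <- floor(spec$status_fractions[["Started"]] * spec$n_requests)
    n_fulfilled <- floor(spec$status_fractions[["Fulfilled"]] * spec$n_requests)
    advance <- sample(req_ids, min(length(req_ids), n_started + n_fulfilled))
    for (rid in advance)
      update_status(store, rid, "Started", role = "request_admin")
    for (rid in utils::head(advance, n_fulfilled))
      update_status(store, rid, "Fulfilled", role = "request_admin")
  }))

  c(constructs = spec$n_constructs, cell_lines = spec$n_cell_lines,
    supes = spec$n_supes, batches = spec$n_batches,
    requests = spec$n_requests)
}
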