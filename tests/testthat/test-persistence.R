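# CRUD, search/pagination, the map-file check, export and durability.

test_that("create wires the calculators, roles and link validation", {
  st <- new_test_store()
  id <- create_record(st, dna_construct("g1", "NGT"), role = "record_admin")
  rec <- get_record(st, id)
  expect_identical(rec$n_glyc_sites, 1L)
  expect_equal(rec$molecular_weight, molecular_weight("NGT"))

  expect_error(create_record(st, dna_construct("g2", "NGT")),
               class = "protrack_permission_denied")
  err <- tryCatch(create_record(st, cell_line("L", "stable",
                                              construct_ids = "DNA-09999"),
                                role = "record_admin"),
                  condition = identity)
  expect_s3_class(err, "protrack_validation_failed")
  expect_gte(length(err$violations), 1L)
})

test_that("records round-trip field-for-field and updates recompute derived fields", {
  st <- new_test_store()
  ids <- make_chain(st)
  rec <- get_record(st, ids$d1)
  expect_identical(rec$id, ids$d1)
  expect_identical(rec$construct_name, "alpha")

  # updating the sequence recomputes every property
  update_record(st, ids$d1, list(mature_sequence = "WW"),
                role = "record_admin")
  rec <- get_record(st, ids$d1)
  expect_equal(rec$extinction_reduced, 11000)
  expect_identical(rec$n_glyc_sites, 0L)

  # aliquot consumption rescales remaining mass proportionally
  b <- get_record(st, ids$b)
  update_record(st, ids$b, list(current_aliquots = 4L), role = "record_admin")
  b2 <- get_record(st, ids$b)
  expect_equal(b2$remaining_mass, 0.4 * b2$total_mass)

  # derived fields are not directly writable
  expect_error(update_record(st, ids$b, list(total_mass = 1),
                             role = "record_admin"),
               class = "protrack_validation_failed")
  expect_error(update_record(st, ids$d1, list(nonexistent = 1),
                             role = "record_admin"),
               class = "protrack_unknown_field")
})

test_that("deletion is refused while downstream references exist", {
  st <- new_test_store()
  ids <- make_chain(st)
  expect_error(delete_record(st, ids$d1, role = "record_admin"),
               class = "protrack_referenced_record")
  expect_error(delete_record(st, ids$s1, role = "record_admin"),
               class = "protrack_referenced_record")
  # unwinding from the batch down succeeds
  delete_record(st, ids$b, role = "record_admin")
  delete_record(st, ids$s1, role = "record_admin")
  delete_record(st, ids$s2, role = "record_admin")
  delete_record(st, ids$stable, role = "record_admin")
  delete_record(st, ids$d1, role = "record_admin")
  expect_error(get_record(st, ids$d1), class = "protrack_not_found")
  expect_length(validate_links(st), 0L)
})

test_that("listing is paged, sorted deterministically, with id tie-break", {
  st <- new_test_store()
  for (i in 1:25)
    create_record(st, dna_construct(sprintf("c%02d", 26 - i), "MKV"),
                  role = "record_admin")
  pg <- list_records(st, "dna", page = 3, page_size = 10)
  expect_length(pg$items, 5L)
  expect_identical(pg$total_count, 25L)

  asc <- list_records(st, "dna", sort_by = "construct_name", page_size = 25)
  desc <- list_records(st, "dna", sort_by = "construct_name",
                       sort_dir = "desc", page_size = 25)
  expect_identical(vapply(asc$items, `[[`, "", "id"),
                   rev(vapply(desc$items, `[[`, "", "id")))

  empty <- new_test_store()
  pg0 <- list_records(empty, "dna")
  expect_length(pg0$items, 0L)
  expect_identical(pg0$total_count, 0L)
  expect_error(list_records(st, "dna", sort_by = "nope"),
               class = "protrack_unknown_field")
})

test_that("pagination partitions the full sorted list without gaps or duplicates", {
  st <- new_test_store()
  populate_store(st, fixture_spec(seed = 3, n_constructs = 23))
  full <- vapply(list_records(st, "dna", page_size = 1000)$items, `[[`, "", "id")
  for (ps in c(1, 3, 10, 1000)) {
    got <- character()
    page <- 1
    repeat {
      pg <- list_records(st, "dna", page = page, page_size = ps)
      if (length(pg$items) == 0) break
      got <- c(got, vapply(pg$items, `[[`, "", "id"))
      page <- page + 1
    }
    expect_identical(got, full)
  }
})

test_that("search filters conjunctively and matches a brute-force filter", {
  st <- new_test_store()
  projects <- c(rep("P1", 3), rep("P2", 7))
  for (i in 1:10)
    create_record(st, dna_construct(paste0("c", i), "MKV",
                                    project = projects[i],
                                    tag = ifelse(i %% 2 == 0, "His6", "FLAG")),
                  role = "record_admin")
  pg <- search_records(st, "dna", filters = list(
    list(field = "project", op = "equals", value = "P1")))
  expect_identical(pg$total_count, 3L)

  # contains is case-insensitive substring
  pg <- search_records(st, "dna", filters = list(
    list(field = "tag", op = "contains", value = "his")))
  expect_identical(pg$total_count, 5L)

  # empty filter list is the neutral element
  expect_identical(search_records(st, "dna")$total_count,
                   list_records(st, "dna")$total_count)

  # conjunctive filters against an in-memory brute force
  pg <- search_records(st, "dna", page_size = 100, filters = list(
    list(field = "project", op = "equals", value = "P2"),
    list(field = "tag", op = "contains", value = "his")))
  all_recs <- list_records(st, "dna", page_size = 100)$items
  brute <- Filter(function(r) r$project == "P2" &&
                    grepl("his", r$tag, ignore.case = TRUE), all_recs)
  expect_identical(vapply(pg$items, `[[`, "", "id"),
                   vapply(brute, `[[`, "", "id"))

  expect_error(search_records(st, "dna", filters = list(
    list(field = "bogus", op = "equals", value = 1))),
    class = "protrack_unknown_field")
})

test_that("the map-file check notifies but never rejects", {
  st <- new_test_store()
  mapdir <- st$config$construct_map_dir
  writeLines("x", file.path(mapdir, "present.map"))
  expect_true(check_map_file("present.map", st))
  expect_false(check_map_file("absent.map", st))
  expect_warning(found <- check_map_file("../escape.map", st),
                 "escapes")
  expect_false(found)

  id <- create_record(st, dna_construct("c", "MKV",
                                        construct_map_filename = "absent.map"),
                      role = "record_admin")
  rec <- get_record(st, id)            # record still created
  expect_false(rec$map_file_found)
  id2 <- create_record(st, dna_construct("c2", "MKV",
                                         construct_map_filename = "present.map"),
                       role = "record_admin")
  expect_true(get_record(st, id2)$map_file_found)
})

test_that("CSV and FASTA exports are complete and FASTA round-trips", {
  st <- new_test_store()
  make_chain(st)
  csv <- file.path(withr::local_tempdir(), "dna.csv")
  export_csv(st, "dna", csv)
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(nrow(df), 2L)
  expect_identical(df$id, c("DNA-00001", "DNA-00002"))
  expect_true(all(c("mature_sequence", "molecular_weight") %in% names(df)))

  fa <- file.path(withr::local_tempdir(), "out.fasta")
  export_fasta(st, fa)
  back <- import_fasta(fa)
  expect_identical(back$sequence,
                   vapply(list_records(st, "dna")$items, `[[`, "",
                          "mature_sequence"))
  expect_match(back$name[1], "^DNA-00001 ")

  empty <- new_test_store()
  csv0 <- file.path(withr::local_tempdir(), "empty.csv")
  export_csv(empty, "dna", csv0)
  expect_identical(nrow(utils::read.csv(csv0)), 0L)
})

test_that("a store survives close and reopen field-for-field", {
  st <- new_test_store()
  populate_store(st, fixture_spec(seed = 5))
  before <- all_store_records(st)
  path <- st$config$database_path
  close_store(st)
  st2 <- open_store(path)
  withr::defer(close_store(st2))
  expect_records_equal(before, all_store_records(st2))
})
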