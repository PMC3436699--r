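# Store fixtures built in code at test time.

new_test_store <- function(env = parent.frame(), ...) {
  dir <- withr::local_tempdir(.local_envir = env)
  st <- open_store(store_config(file.path(dir, "store.sqlite"),
                                construct_map_dir = dir, ...))
  withr::defer(try(close_store(st), silent = TRUE), envir = env)
  st
}

# a minimal fully linked chain: two constructs, a stable and a parental
# line, a stable-line supe and a transient supe, one batch over both
make_chain <- function(st) {
  d1 <- create_record(st, dna_construct("alpha", "NGTWY", project = "P1",
                                        tag = "His6"), role = "record_admin")
  d2 <- create_record(st, dna_construct("beta", "MKVCCWY", project = "P2"),
                      role = "record_admin")
  stable <- create_record(st, cell_line("stbl", "stable", construct_ids = d1),
                          role = "record_admin")
  parental <- create_record(st, cell_line("host", "parental"),
                            role = "record_admin")
  s1 <- create_record(st, supe(stable), role = "record_admin")
  s2 <- create_record(st, supe(parental,
                               transfection_construct_ids = c(d2, d1)),
                      role = "record_admin")
  b <- create_record(st, protein_batch(c(s1, s2), concentration = 2,
                                       volume = 5, original_aliquots = 10,
                                       current_aliquots = 4,
                                       purification_steps = c("IMAC", "SEC")),
                     role = "record_admin")
  list(d1 = d1, d2 = d2, stable = stable, parental = parental,
       s1 = s1, s2 = s2, b = b)
}

# record lists compared field-for-field (attributes included)
expect_records_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) expect_equal(a[[i]], b[[i]])
}

all_store_records <- function(st) {
  out <- list()
  for (type in c("dna", "cell_line", "supe", "batch", "request")) {
    pg <- list_records(st, type, page_size = 100000L)
    out <- c(out, pg$items)
  }
  out
}
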