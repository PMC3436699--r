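# Request lifecycle: submission, transitions, queues, notifications.

test_that("submission appends to the kind's queue with status Pending", {
  st <- new_test_store()
  ids <- make_chain(st)
  r1 <- submit_request(st, "dna", ids$d1)
  expect_identical(r1$status, "Pending")
  expect_identical(r1$priority_rank, 1L)
  r2 <- submit_request(st, "dna", ids$d2)
  expect_identical(r2$priority_rank, 2L)
  expect_identical(request_queue(st, "dna")$ids, c(r1$id, r2$id))

  expect_error(submit_request(st, "aliquot", "PB-99999"),
               class = "protrack_not_found")
  expect_error(submit_request(st, "transfection", ids$d1,
                              cell_type = "suspension"),
               class = "protrack_missing_quantity")
  # subject types are enforced per kind
  expect_error(submit_request(st, "purification", ids$d1),
               class = "protrack_not_found")
})

test_that("transfection fan-out creates linked secondaries in their own queues", {
  st <- new_test_store()
  ids <- make_chain(st)
  res <- submit_transfection_request(st, ids$d1, "suspension", 500,
                                     want_dna = TRUE,
                                     want_purification = TRUE,
                                     requestor_email = "who@lab.org")
  expect_length(res$secondary, 2L)
  expect_identical(res$primary$secondary_request_ids,
                   sort(vapply(res$secondary, `[[`, "", "id")))
  for (sec in res$secondary)
    expect_identical(sec$parent_request_id, res$primary$id)
  kinds <- vapply(res$secondary, `[[`, "", "kind")
  expect_setequal(kinds, c("dna", "purification"))
  expect_identical(request_queue(st, "transfection")$ids, res$primary$id)
  expect_true(res$secondary[[1]]$id %in%
                request_queue(st, kinds[1])$ids)
  expect_identical(res$primary$quantity_type, "volume_ml")

  none <- submit_transfection_request(st, ids$d1, "adherent", 3)
  expect_length(none$secondary, 0L)
  expect_identical(none$primary$quantity_type, "flasks")
})

test_that("every forward transition is accepted, every other rejected", {
  st <- new_test_store()
  ids <- make_chain(st)
  fresh <- function(status) {
    r <- submit_request(st, "dna", ids$d1)
    if (status != "Pending")
      r <- update_status(st, r$id, "Started", role = "request_admin")
    if (status == "Fulfilled")
      r <- update_status(st, r$id, "Fulfilled", role = "request_admin")
    r
  }
  statuses <- c("Pending", "Started", "Fulfilled")
  for (from in statuses) {
    for (to in statuses) {
      r <- fresh(from)
      legal <- match(to, statuses) == match(from, statuses) + 1L
      if (legal) {
        expect_identical(update_status(st, r$id, to,
                                       role = "request_admin")$status, to)
      } else {
        expect_error(update_status(st, r$id, to, role = "request_admin"),
                     class = "protrack_illegal_transition")
        expect_identical(get_record(st, r$id)$status, from)
      }
    }
  }
  expect_error(update_status(st, fresh("Pending")$id, "Started"),
               class = "protrack_permission_denied")
})

test_that("notifications: one to the group per submission, one to the requestor per status change", {
  st <- new_test_store()
  ids <- make_chain(st)
  r1 <- submit_request(st, "dna", ids$d1, requestor_email = "a@lab.org")
  r2 <- submit_request(st, "dna", ids$d2)         # no email on file
  update_status(st, r1$id, "Started", role = "request_admin")
  update_status(st, r1$id, "Fulfilled", role = "request_admin")
  update_status(st, r2$id, "Started", role = "request_admin")

  nts <- notifications(st)
  expect_identical(sum(nts$recipient == st$config$request_group), 2L)
  expect_identical(sum(nts$recipient == "a@lab.org"), 2L)
  expect_true(all(grepl("^proteintracker://REQ-", nts$link)))

  # the log sink wrote one parseable JSON line per event
  lines <- readLines(st$config$notification_log)
  expect_length(lines, nrow(nts))
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_identical(vapply(parsed, `[[`, "", "recipient"), nts$recipient)
})

test_that("prioritization swaps neighbours, is gated on Pending and on role", {
  st <- new_test_store()
  ids <- make_chain(st)
  r <- replicate(3, submit_request(st, "dna", ids$d1)$id)
  q <- prioritize(st, r[3], "up", role = "request_admin")
  expect_identical(q$ids, c(r[1], r[3], r[2]))
  # boundary moves are no-ops
  expect_identical(prioritize(st, r[1], "up", role = "request_admin")$ids,
                   c(r[1], r[3], r[2]))
  expect_identical(prioritize(st, r[2], "down", role = "request_admin")$ids,
                   c(r[1], r[3], r[2]))
  expect_error(prioritize(st, r[1], "up"),
               class = "protrack_permission_denied")
  update_status(st, r[1], "Started", role = "request_admin")
  expect_error(prioritize(st, r[1], "up", role = "request_admin"),
               class = "protrack_not_pending")
  # leaving Pending compacted the remaining ranks
  expect_identical(request_queue(st, "dna")$ids, c(r[3], r[2]))
  expect_length(validate_links(st), 0L)
})

test_that("list_requests partitions by status with queue-consistent Pending order", {
  st <- new_test_store()
  ids <- make_chain(st)
  r <- replicate(3, submit_request(st, "dna", ids$d1)$id)
  update_status(st, r[2], "Started", role = "request_admin")
  update_status(st, r[2], "Fulfilled", role = "request_admin")
  grp <- list_requests(st, "dna")
  expect_identical(lengths(grp), c(Pending = 2L, Started = 0L, Fulfilled = 1L))
  prioritize(st, r[3], "up", role = "request_admin")
  grp <- list_requests(st, "dna")
  expect_identical(vapply(grp$Pending, `[[`, "", "id"),
                   request_queue(st, "dna")$ids)
  empty <- list_requests(st, "aliquot")
  expect_identical(lengths(empty), c(Pending = 0L, Started = 0L, Fulfilled = 0L))
})

test_that("only Pending requests can be deleted, and ranks close up", {
  st <- new_test_store()
  ids <- make_chain(st)
  r <- replicate(3, submit_request(st, "dna", ids$d1)$id)
  delete_request(st, r[2], role = "request_admin")
  expect_identical(request_queue(st, "dna")$ids, c(r[1], r[3]))
  expect_identical(get_record(st, r[3])$priority_rank, 2L)
  update_status(st, r[1], "Started", role = "request_admin")
  expect_error(delete_request(st, r[1], role = "request_admin"),
               class = "protrack_not_pending")
  expect_error(delete_request(st, r[3]), class = "protrack_permission_denied")
  expect_length(validate_links(st), 0L)
})

test_that("a random operation stream keeps every queue a contiguous permutation", {
  st <- new_test_store()
  ids <- make_chain(st)
  # brute-force model: plain per-kind lists of pending ids
  model <- sapply(c("dna", "transfection", "aliquot"), function(k) character(),
                  simplify = FALSE)
  statuses <- list()
  set.seed(99)
  for (i in 1:200) {
    op <- sample(c("submit", "start", "prioritize", "delete"), 1,
                 prob = c(0.4, 0.2, 0.3, 0.1))
    kind <- sample(names(model), 1)
    if (op == "submit") {
      subject <- switch(kind, dna = ids$d1, transfection = ids$d1,
                        aliquot = ids$b)
      r <- if (kind == "transfection")
        submit_request(st, kind, subject, cell_type = "adherent", quantity = 2)
      else submit_request(st, kind, subject)
      model[[kind]] <- c(model[[kind]], r$id)
      statuses[[r$id]] <- "Pending"
    } else if (op == "start" && length(model[[kind]]) > 0) {
      pick <- sample(length(model[[kind]]), 1)
      rid <- model[[kind]][pick]
      update_status(st, rid, "Started", role = "request_admin")
      model[[kind]] <- model[[kind]][-pick]
      statuses[[rid]] <- "Started"
    } else if (op == "prioritize" && length(model[[kind]]) > 0) {
      pick <- sample(length(model[[kind]]), 1)
      dir <- sample(c("up", "down"), 1)
      rid <- model[[kind]][pick]
      prioritize(st, rid, dir, role = "request_admin")
      j <- pick + if (dir == "up") -1L else 1L
      if (j >= 1 && j <= length(model[[kind]])) {
        model[[kind]][pick] <- model[[kind]][j]
        model[[kind]][j] <- rid
      }
    } else if (op == "delete" && length(model[[kind]]) > 0) {
      pick <- sample(length(model[[kind]]), 1)
      delete_request(st, model[[kind]][pick], role = "request_admin")
      model[[kind]] <- model[[kind]][-pick]
    }
    for (k in names(model))
      expect_identical(request_queue(st, k)$ids, unname(model[[k]]))
  }
  expect_length(validate_links(st), 0L)
})
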