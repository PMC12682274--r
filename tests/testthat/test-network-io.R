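make_records <- function(...) {
  tibble::tribble(~group_id, ~actor_id, ~receiver_id, ~weight, ...)
}

test_that("interaction records aggregate repeated dyads and reject malformed rows", {
  recs <- read_interactions(make_records(
    "g", "A", "B", 2,
    "g", "A", "B", 3,
    "g", "B", "A", 1
  ))
  expect_equal(nrow(recs), 2)
  expect_equal(recs$weight[recs$actor_id == "A"], 5)

  expect_error(read_interactions(make_records("g", "A", "A", 1)), "self")
  expect_error(read_interactions(make_records("g", "A", "B", 0)), "positive")
  expect_error(read_interactions(make_records("g", "A", "B", -2)), "positive")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("group_id,actor_id,receiver_id,weight", tmp)
  expect_equal(nrow(read_interactions(tmp)), 0)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group_id,actor_id,weight", "g,A,1"), tmp2)
  expect_error(read_interactions(tmp2), class = "groomcircles_schema_error")
  expect_error(read_interactions("no/such/file.csv"),
               class = "groomcircles_schema_error")
})

test_that("group networks carry demographic size and keep directions separate", {
  meta <- tibble::tibble(
    individual_id = paste0("m", 1:6), group_id = "g",
    species = "bonobo", sex = "female", age = 10, habitat = "zoo"
  )
  recs <- read_interactions(make_records(
    "g", "m1", "m2", 4,
    "g", "m2", "m1", 1,
    "g", "m1", "m3", 2
  ))
  nets <- build_group_networks(recs, meta)
  expect_equal(nets$group_size, 6) # inactive members still count
  g <- nets$graph[[1]]
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 3) # A->B and B->A kept separately
  expect_setequal(extract_ego(g, "m1"), c(4, 2))
  expect_equal(unname(extract_ego(g, "m2")), 1)
  expect_length(extract_ego(g, "m5"), 0) # isolated individual
  expect_equal(unname(extract_ego(g, "m2", direction = "in")), 4)
  expect_error(extract_ego(g, "zz"), "not a member")

  bad <- make_records("g", "m1", "outsider", 1)
  expect_error(build_group_networks(read_interactions(bad), meta),
               "not in metadata")
  wrong_group <- make_records("h", "m1", "m2", 1)
  expect_error(build_group_networks(read_interactions(wrong_group), meta),
               "group")
})

test_that("filters reproduce the hand counts on the packaged fixture", {
  toy <- toy_tables()
  egos <- ego_table(toy$interactions, toy$metadata)
  expect_equal(nrow(egos), 18)
  retained <- apply_filters(egos)
  audit <- filter_audit(retained)
  expect_equal(audit$groups_in, 3)
  expect_equal(audit$groups_retained, 2) # the 5-member group is dropped whole
  expect_equal(audit$egos_in, 18)
  expect_equal(audit$egos_retained, 9)
  expect_equal(nrow(retained), 9)
  reasons <- table(audit$exclusions$reason)
  expect_equal(unname(reasons[["min_group_size"]]), 5)
  expect_equal(unname(reasons[["min_partners"]]), 3)
  expect_equal(unname(reasons[["degenerate_weights"]]), 1)
  # counts reconcile
  expect_equal(audit$egos_in - audit$egos_retained, nrow(audit$exclusions))
  # the degenerate ego is c7 (five equal-weight ties)
  expect_true("c7" %in% audit$exclusions$ego_id[
    audit$exclusions$reason == "degenerate_weights"])
  expect_equal(glance(audit)$egos_retained, 9)
})

test_that("no interaction weight is lost between records and ego table", {
  toy <- toy_tables()
  egos <- ego_table(toy$interactions, toy$metadata)
  expect_equal(sum(purrr::map_dbl(egos$weights, sum)),
               sum(toy$interactions$weight))
})

test_that("filtering is idempotent and insensitive to row order", {
  toy <- toy_tables()
  egos <- ego_table(toy$interactions, toy$metadata)
  once <- apply_filters(egos)
  twice <- apply_filters(once)
  strip_audit <- function(x) {
    attr(x, "audit") <- NULL
    as.data.frame(x)
  }
  expect_equal(strip_audit(twice), strip_audit(once))
  expect_equal(filter_audit(twice)$egos_retained,
               filter_audit(once)$egos_retained)
  expect_equal(nrow(filter_audit(twice)$exclusions), 0)

  shuffled <- toy$interactions[sample(nrow(toy$interactions)), ]
  egos2 <- ego_table(read_interactions(shuffled), toy$metadata)
  expect_equal(
    as.data.frame(egos2 %>% dplyr::arrange(ego_id)),
    as.data.frame(egos %>% dplyr::arrange(ego_id))
  )
})

test_that("metadata validation catches duplicates and bad values", {
  meta <- tibble::tibble(
    individual_id = c("a", "a"), group_id = "g", species = "bonobo",
    sex = "female", age = 5, habitat = "zoo"
  )
  expect_error(read_metadata(meta), "more than once")
  meta2 <- tibble::tibble(
    individual_id = "a", group_id = "g", species = "gorilla",
    sex = "female", age = 5, habitat = "zoo"
  )
  expect_error(read_metadata(meta2), "species")
  meta3 <- tibble::tibble(
    individual_id = "a", group_id = "g", species = "bonobo",
    sex = "female", age = -1, habitat = "zoo"
  )
  expect_error(read_metadata(meta3), "age")
})

test_that("fitting the retained fixture egos yields finite estimates with regimes", {
  toy <- toy_tables()
  fits <- fit_egos(apply_filters(ego_table(toy$interactions, toy$metadata)))
  expect_equal(nrow(fits), 9)
  expect_true(all(is.finite(fits$eta)))
  expect_true(all(fits$ci_low <= fits$eta & fits$eta <= fits$ci_high))
  expect_true(all(fits$regime %in% c("normal", "inverted", "boundary")))
  expect_true(all(fits$L >= 5))
})
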