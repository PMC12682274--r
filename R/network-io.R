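#' Read grooming interaction records
#'
#' Reads a delimited file of directed grooming interactions with header
#' columns `group_id`, `actor_id`, `receiver_id`, `weight` (one aggregated
#' row per directed dyad, or one row per event with weight 1). Repeated rows
#' for the same directed dyad are summed; self-loops and non-positive
#' weights are rejected with the offending line numbers.
#'
#' @param path Path to a CSV or TSV file (delimiter auto-detected by
#'   extension; `.tsv`/`.txt` read as tab-separated), or a data frame
#'   already in the same schema.
#' @return A tibble with one row per directed dyad: `group_id`, `actor_id`,
#'   `receiver_id`, `weight` (summed over records).
#' @export
read_interactions <- function(path) {
  raw <- read_delimited(path, c("group_id", "actor_id", "receiver_id", "weight"))
  raw$weight <- as.numeric(raw$weight)
  bad_w <- which(!is.finite(raw$weight) | raw$weight <= 0)
  if (length(bad_w) > 0) {
    abort(paste0("interaction weights must be positive numbers; bad rows: ",
                 paste(head(bad_w, 5), collapse = ", ")))
  }
  loops <- which(raw$actor_id == raw$receiver_id)
  if (length(loops) > 0) {
    abort(paste0("self-grooming records (actor = receiver) are malformed; ",
                 "rows: ", paste(head(loops, 5), collapse = ", ")))
  }
  raw %>%
    mutate(across(c(group_id, actor_id, receiver_id), as.character)) %>%
    group_by(group_id, actor_id, receiver_id) %>%
    summarise(weight = sum(weight), .groups = "drop") %>%
    arrange(group_id, actor_id, receiver_id)
}

#' Read individual metadata
#'
#' Reads the demographic table: `individual_id`, `group_id`, `species`
#' (`bonobo`/`chimpanzee`), `sex` (`male`/`female`), `age` (years),
#' `habitat` (`zoo`/`sanctuary`). Each individual must belong to exactly
#' one group.
#'
#' @inheritParams read_interactions
#' @return A tibble with one row per individual.
#' @export
read_metadata <- function(path) {
  meta <- read_delimited(
    path, c("individual_id", "group_id", "species", "sex", "age", "habitat")
  ) %>%
    mutate(
      across(c(individual_id, group_id, species, sex, habitat), as.character),
      age = as.numeric(age)
    )
  dup <- meta$individual_id[duplicated(meta$individual_id)]
  if (length(dup) > 0) {
    abort(paste0("individuals listed more than once in metadata: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(meta$age) | meta$age < 0)) {
    abort("`age` must be a non-negative number of years")
  }
  bad_sp <- setdiff(unique(meta$species), c("bonobo", "chimpanzee"))
  if (length(bad_sp) > 0) {
    abort(paste0("unknown species: ", paste(bad_sp, collapse = ", ")))
  }
  meta
}

read_delimited <- function(path, required_cols) {
  if (is.data.frame(path)) {
    tbl <- as_tibble(path)
  } else {
    if (!file.exists(path)) {
      abort(paste0("file not found: '", path, "'"), class = "groomcircles_schema_error")
    }
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  missing <- setdiff(required_cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "groomcircles_schema_error")
  }
  tbl[required_cols]
}

#' Build directed weighted group networks
#'
#' Combines aggregated interaction records with metadata into one directed
#' weighted grooming graph per group. Group size is demographic: it counts
#' every individual listed in the metadata for that group, including
#' socially inactive ones (which appear as isolated nodes). Mutual grooming
#' is already two directed records, so both directions are kept separately.
#'
#' @param records Interaction tibble from [read_interactions()].
#' @param meta Metadata tibble from [read_metadata()].
#' @return A tibble with one row per group: `group_id`, `group_size`,
#'   `members` (list of ids) and `graph` (list of directed weighted
#'   [igraph][igraph::graph_from_data_frame] objects with a `weight` edge
#'   attribute).
#' @export
build_group_networks <- function(records, meta) {
  unknown <- setdiff(
    unique(c(records$actor_id, records$receiver_id)), meta$individual_id
  )
  if (length(unknown) > 0) {
    abort(paste0("individual(s) in interaction records but not in metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  grp_of <- setNames(meta$group_id, meta$individual_id)
  cross <- records$actor_id[
    grp_of[records$actor_id] != records$group_id |
      grp_of[records$receiver_id] != records$group_id
  ]
  if (length(cross) > 0) {
    abort(paste0("interaction(s) whose members do not belong to the stated ",
                 "group: actors ", paste(unique(cross), collapse = ", ")))
  }
  meta %>%
    group_by(group_id) %>%
    summarise(members = list(sort(individual_id)), .groups = "drop") %>%
    mutate(
      group_size = lengths(members),
      graph = purrr::map2(group_id, members, function(g, mem) {
        edges <- records %>%
          filter(group_id == g) %>%
          select(actor_id, receiver_id, weight) %>%
          as.data.frame()
        igraph::graph_from_data_frame(edges, directed = TRUE, vertices = mem)
      })
    ) %>%
    select(group_id, group_size, members, graph)
}

#' Extract one ego's outgoing tie weights
#'
#' An ego's social-resource distribution is its *given* (outgoing) grooming:
#' the aggregate weight from the ego to each distinct partner it groomed.
#' Set `direction = "in"` for the received-grooming sensitivity variant.
#'
#' @param graph A directed weighted igraph object (one group's network).
#' @param individual_id Vertex name of the ego.
#' @param direction `"out"` (default; grooming given) or `"in"` (received).
#' @return A named numeric vector of tie weights (names are partner ids);
#'   length 0 for an individual with no ties in that direction.
#' @export
extract_ego <- function(graph, individual_id, direction = c("out", "in")) {
  direction <- match.arg(direction)
  if (!individual_id %in% igraph::V(graph)$name) {
    abort(paste0("'", individual_id, "' is not a member of this group"))
  }
  es <- igraph::incident(graph, individual_id,
                         mode = if (direction == "out") "out" else "in")
  if (length(es) == 0) return(setNames(numeric(0), character(0)))
  ends <- igraph::ends(graph, es)
  partner <- if (direction == "out") ends[, 2] else ends[, 1]
  setNames(igraph::edge_attr(graph, "weight", es), partner)
}

#' Ego table: one row per individual with its tie-weight vector
#'
#' Joins each individual in the metadata to its outgoing grooming weights,
#' producing the per-ego input of the estimation stage.
#'
#' @inheritParams build_group_networks
#' @param direction Passed to [extract_ego()].
#' @return A tibble with one row per individual: `ego_id`, `group_id`,
#'   `species`, `sex`, `age`, `habitat`, `group_size`, `L` (number of
#'   distinct partners groomed) and `weights` (list column of named
#'   numeric vectors).
#' @export
ego_table <- function(records, meta, direction = "out") {
  networks <- build_group_networks(records, meta)
  graph_of <- setNames(networks$graph, networks$group_id)
  size_of <- setNames(networks$group_size, networks$group_id)
  meta %>%
    mutate(
      ego_id = individual_id,
      group_size = unname(size_of[group_id]),
      weights = purrr::map2(individual_id, group_id, function(id, g) {
        extract_ego(graph_of[[g]], id, direction = direction)
      }),
      L = lengths(weights)
    ) %>%
    select(ego_id, group_id, species, sex, age, habitat, group_size, L, weights)
}

#' Apply the standard inclusion filters with an audit trail
#'
#' Drops whole groups with fewer than `min_group_size` individuals, then,
#' within retained groups, drops egos that groomed fewer than `min_partners`
#' distinct partners and egos whose tie weights are all equal (degenerate:
#' the normalized-distance model is undefined). Every exclusion is recorded
#' with its reason.
#'
#' @param egos Ego tibble from [ego_table()] (must carry `group_size` and
#'   `L`; `weights` used for the degeneracy check when present).
#' @param min_group_size Minimum group size (default 6).
#' @param min_partners Minimum number of distinct groomed partners
#'   (default 5).
#' @return The retained ego tibble, with the audit attached as attribute
#'   `"audit"`; retrieve it with [filter_audit()].
#' @export
apply_filters <- function(egos, min_group_size = 6, min_partners = 5) {
  stopifnot(all(c("ego_id", "group_id", "group_size", "L") %in% names(egos)))
  degenerate <- if ("weights" %in% names(egos)) {
    purrr::map_lgl(egos$weights, function(w) {
      length(w) >= 2 && max(w) == min(w)
    })
  } else {
    rep(FALSE, nrow(egos))
  }
  reason <- dplyr::case_when(
    egos$group_size < min_group_size ~ "min_group_size",
    egos$L < min_partners ~ "min_partners",
    degenerate ~ "degenerate_weights",
    TRUE ~ NA_character_
  )
  exclusions <- tibble(
    ego_id = egos$ego_id[!is.na(reason)],
    group_id = egos$group_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  retained <- egos[is.na(reason), , drop = FALSE]
  audit <- structure(
    list(
      groups_in = dplyr::n_distinct(egos$group_id),
      groups_retained = dplyr::n_distinct(retained$group_id),
      egos_in = nrow(egos),
      egos_retained = nrow(retained),
      exclusions = exclusions
    ),
    class = "filter_audit"
  )
  attr(retained, "audit") <- audit
  retained
}

#' @rdname apply_filters
#' @param x An object returned by [apply_filters()].
#' @export
filter_audit <- function(x) {
  audit <- attr(x, "audit")
  if (is.null(audit)) abort("no filter audit attached; run apply_filters() first")
  audit
}

#' @export
print.filter_audit <- function(x, ...) {
  cat(sprintf("Filter audit: %d/%d groups retained, %d/%d egos retained\n",
              x$groups_retained, x$groups_in, x$egos_retained, x$egos_in))
  if (nrow(x$exclusions) > 0) {
    print(count(x$exclusions, reason))
  }
  invisible(x)
}

#' @rdname apply_filters
#' @param ... Unused.
#' @export
tidy.filter_audit <- function(x, ...) x$exclusions

#' @rdname apply_filters
#' @export
glance.filter_audit <- function(x, ...) {
  tibble(
    groups_in = x$groups_in, groups_retained = x$groups_retained,
    egos_in = x$egos_in, egos_retained = x$egos_retained
  )
}
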