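#' Build a complete session design
#'
#' Generates one participant's full session for the 'What was where?' task:
#' a practice block of 10 trials followed by two test blocks of 50 trials
#' each. Every test block holds 10 one-item and 40 three-item trials with
#' the 1 s / 4 s retention delays balanced within load (5/5 and 20/20), and
#' every stimulus identity used in a block's memory arrays appears in 2 or 3
#' distinct trials of that block. The practice block mirrors the test-block
#' mix at one-fifth scale (2 one-item, 8 three-item trials, delays balanced)
#' and is exempt from the identity-repeat constraint. Item locations are
#' drawn with [sample_locations()] under the task's spatial constraints; the
#' probed (target) item is chosen uniformly per trial and the two-choice
#' foil uniformly from the stimulus library excluding that trial's items.
#'
#' @param geometry A [screen_geometry()].
#' @param library_size Number of stimulus identities in the fractal library
#'   (default 60; at least 44 so the per-block repeat constraint is
#'   satisfiable).
#' @param participant_id Identifier recorded in every row.
#' @param seed Optional integer seed; identical seeds give identical plans.
#' @return A tibble with one row per (trial, item):
#'   `participant_id`, `trial_id`, `phase` (practice/block1/block2),
#'   `block` (1, 2, or NA for practice), `n_items`, `delay_s`, `item_slot`,
#'   `item_id`, `x_deg`, `y_deg`, `is_target`, `foil_id`.
#' @examples
#' plan <- build_session(seed = 1)
#' dplyr::count(plan[!duplicated(plan$trial_id), ], phase, n_items, delay_s)
#' @export
build_session <- function(geometry = screen_geometry(), library_size = 60,
                          participant_id = "P001", seed = NULL) {
  if (library_size < 44) {
    abort("library_size must be at least 44 to satisfy the per-block identity-repeat constraint")
  }
  build <- function() .build_session_impl(geometry, as.integer(library_size), participant_id)
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

.stim_library <- function(library_size) sprintf("F%02d", seq_len(library_size))

.build_session_impl <- function(geometry, library_size, participant_id) {
  library_ids <- .stim_library(library_size)

  # trial-level frame: practice then two test blocks
  practice <- tibble::tibble(
    phase = "practice", block = NA_integer_,
    n_items = c(1L, 1L, rep(3L, 8)),
    delay_s = c(1L, 4L, rep(c(1L, 4L), 4))
  )
  test_block <- function(b) {
    tibble::tibble(
      phase = paste0("block", b), block = b,
      n_items = c(rep(1L, 10), rep(3L, 40)),
      delay_s = c(rep(c(1L, 4L), each = 5), rep(c(1L, 4L), each = 20))
    )
  }
  shuffle <- function(df) df[sample.int(nrow(df)), ]
  trials <- dplyr::bind_rows(
    shuffle(practice), shuffle(test_block(1L)), shuffle(test_block(2L))
  )
  trials$trial_id <- seq_len(nrow(trials))

  # identity assignment: per test block, each used identity in 2-3 trials
  trials$items <- vector("list", nrow(trials))
  for (ti in which(trials$phase == "practice")) {
    trials$items[[ti]] <- sample(library_ids, trials$n_items[ti])
  }
  for (b in 1:2) {
    idx <- which(!is.na(trials$block) & trials$block == b)
    trials$items[idx] <- .assign_block_identities(
      trials$n_items[idx], library_ids
    )
  }

  trials$foil_id <- vapply(trials$items, function(ids) {
    sample(setdiff(library_ids, ids), 1L)
  }, character(1))
  trials$target_slot <- vapply(trials$n_items, function(n) sample.int(n, 1L), integer(1))

  # locations: batch by load for vectorised rejection sampling
  trials$locs <- vector("list", nrow(trials))
  for (n in unique(trials$n_items)) {
    idx <- which(trials$n_items == n)
    arr <- .sample_arrays(length(idx), n, geometry)
    split_xy <- split(arr[, c("x_deg", "y_deg")], arr$array_id)
    trials$locs[idx] <- split_xy
  }

  rep_i <- rep(seq_len(nrow(trials)), trials$n_items)
  slot <- sequence(trials$n_items)
  tibble::tibble(
    participant_id = participant_id,
    trial_id = trials$trial_id[rep_i],
    phase = trials$phase[rep_i],
    block = trials$block[rep_i],
    n_items = trials$n_items[rep_i],
    delay_s = trials$delay_s[rep_i],
    item_slot = slot,
    item_id = unlist(trials$items, use.names = FALSE),
    x_deg = unlist(lapply(trials$locs, `[[`, "x_deg"), use.names = FALSE),
    y_deg = unlist(lapply(trials$locs, `[[`, "y_deg"), use.names = FALSE),
    is_target = slot == trials$target_slot[rep_i],
    foil_id = trials$foil_id[rep_i]
  )
}

# Assign identities to one test block's memory arrays so each used identity
# occurs in 2-3 distinct trials and identities are distinct within a trial.
# Greedy most-remaining-first with random tie-breaks; retried on the rare
# dead end.
.assign_block_identities <- function(sizes, library_ids, max_retry = 50) {
  slots <- sum(sizes)                      # 130 for the default block
  k <- min(length(library_ids), slots %/% 2)
  n_three <- slots - 2L * k                # identities used three times
  if (n_three < 0 || n_three > k) abort("identity-repeat assignment infeasible for this block composition")
  for (retry in seq_len(max_retry)) {
    used <- sample(library_ids, k)
    remaining <- setNames(c(rep(3L, n_three), rep(2L, k - n_three)), used)
    order_t <- sample.int(length(sizes))
    out <- vector("list", length(sizes))
    ok <- TRUE
    for (ti in order_t) {
      s <- sizes[ti]
      avail <- remaining[remaining > 0L]
      if (length(avail) < s) { ok <- FALSE; break }
      pick <- names(sort(rank(-avail, ties.method = "random"))[seq_len(s)])
      out[[ti]] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok && all(remaining == 0L)) return(out)
  }
  abort("identity-repeat assignment failed after retries; increase library_size")
}

#' Validate a session plan against the task constraints
#'
#' Checks every structural invariant of a session design and reports all
#' violations as data, never as errors: spatial constraints per trial (edge
#' margin, centre exclusion, pairwise separation), per-trial content (one
#' target, distinct identities, foil outside the memory array), block
#' composition (10 practice trials; 10 one-item + 40 three-item per test
#' block with balanced delays), and the 2-3 per-block identity-repeat rule.
#'
#' @param plan A session plan as returned by [build_session()].
#' @param geometry The [screen_geometry()] the plan must satisfy.
#' @return A tibble of violations with columns `trial_id` (NA for
#'   block-level problems), `constraint`, and `detail`; zero rows if and
#'   only if the plan is valid.
#' @examples
#' validate_session(build_session(seed = 1))
#' @export
validate_session <- function(plan, geometry = screen_geometry()) {
  v <- list()
  add <- function(trial_id, constraint, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      trial_id = as.integer(trial_id), constraint = constraint, detail = detail
    )
  }

  hx <- geometry$width_deg / 2 - geometry$edge_margin_deg
  hy <- geometry$height_deg / 2 - geometry$edge_margin_deg
  bad_edge <- abs(plan$x_deg) > hx + 1e-9 | abs(plan$y_deg) > hy + 1e-9
  for (i in which(bad_edge)) {
    add(plan$trial_id[i], "edge_margin",
        sprintf("item %d at (%.2f, %.2f) closer than %.1f deg to a screen edge",
                plan$item_slot[i], plan$x_deg[i], plan$y_deg[i], geometry$edge_margin_deg))
  }
  r <- sqrt(plan$x_deg^2 + plan$y_deg^2)
  for (i in which(r < geometry$centre_exclusion_deg - 1e-9)) {
    add(plan$trial_id[i], "centre_exclusion",
        sprintf("item %d only %.2f deg from screen centre", plan$item_slot[i], r[i]))
  }

  by_trial <- split(seq_len(nrow(plan)), plan$trial_id)
  for (tid in names(by_trial)) {
    idx <- by_trial[[tid]]
    n <- length(idx)
    if (n >= 2) {
      d <- as.matrix(stats::dist(cbind(plan$x_deg[idx], plan$y_deg[idx])))
      dmin <- min(d[upper.tri(d)])
      if (dmin <= geometry$min_separation_deg - 1e-9) {
        add(tid, "min_separation",
            sprintf("pairwise item distance %.2f deg below %.1f deg", dmin, geometry$min_separation_deg))
      }
    }
    if (sum(plan$is_target[idx]) != 1L) add(tid, "target", "trial must have exactly one target item")
    if (anyDuplicated(plan$item_id[idx])) add(tid, "distinct_identities", "duplicate identity within a memory array")
    if (plan$foil_id[idx][1] %in% plan$item_id[idx]) add(tid, "foil", "foil identity present in the memory array")
    if (plan$n_items[idx][1] != n) add(tid, "n_items", "n_items does not match number of item rows")
  }

  tr <- plan[!duplicated(plan$trial_id), c("trial_id", "phase", "block", "n_items", "delay_s")]
  if (sum(tr$phase == "practice") != 10L) {
    add(NA, "block_composition", sprintf("expected 10 practice trials, found %d", sum(tr$phase == "practice")))
  }
  for (b in 1:2) {
    tb <- tr[!is.na(tr$block) & tr$block == b, ]
    counts <- table(factor(tb$n_items, c(1, 3)), factor(tb$delay_s, c(1, 4)))
    want <- matrix(c(5, 20, 5, 20), 2, 2, dimnames = dimnames(counts))
    if (sum(tb$n_items == 1) != 10L || sum(tb$n_items == 3) != 40L) {
      add(NA, "block_composition",
          sprintf("block %d: expected 10 one-item and 40 three-item trials, found %d and %d",
                  b, sum(tb$n_items == 1), sum(tb$n_items == 3)))
    }
    if (!all(counts == want)) {
      add(NA, "delay_balance",
          sprintf("block %d: load x delay cells are %s, expected 5/5/20/20",
                  b, paste(counts, collapse = "/")))
    }
    occ <- table(plan$item_id[!is.na(plan$block) & plan$block == b])
    bad <- occ[occ < 2 | occ > 3]
    for (nm in names(bad)) {
      add(NA, "identity_repeats",
          sprintf("block %d: identity %s appears %d time(s), expected 2-3", b, nm, bad[[nm]]))
    }
  }

  if (length(v) == 0) {
    tibble::tibble(trial_id = integer(), constraint = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Read and write session-plan and response tables
#'
#' Delimited-text (CSV) serialisation of the package's tabular formats:
#' session plans (one row per trial-item), response tables (one row per
#' trial), and subject covariate tables. Columns and types are fixed;
#' reading a file written by the matching writer round-trips exactly.
#'
#' @param plan,responses,subjects Tibbles in the package's standard schemas.
#' @param file Path to a CSV file.
#' @return Writers return the input invisibly; readers return a tibble.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_session_csv <- function(plan, file) {
  readr::write_csv(plan, file)
  invisible(plan)
}

#' @rdname session_io
#' @export
read_session_csv <- function(file) {
  readr::read_csv(file, col_types = readr::cols(
    participant_id = "c", trial_id = "i", phase = "c", block = "i",
    n_items = "i", delay_s = "i", item_slot = "i", item_id = "c",
    x_deg = "d", y_deg = "d", is_target = "l", foil_id = "c"
  ))
}

#' @rdname session_io
#' @export
write_responses_csv <- function(responses, file) {
  readr::write_csv(responses, file)
  invisible(responses)
}

#' @rdname session_io
#' @export
read_responses_csv <- function(file) {
  readr::read_csv(file, col_types = readr::cols(
    participant_id = "c", trial_id = "i", chosen_id = "c",
    x_deg = "d", y_deg = "d"
  ))
}

#' @rdname session_io
#' @export
write_subjects_csv <- function(subjects, file) {
  drop <- intersect("params", names(subjects))
  readr::write_csv(subjects[setdiff(names(subjects), drop)], file)
  invisible(subjects)
}

#' @rdname session_io
#' @export
read_subjects_csv <- function(file) {
  readr::read_csv(file, col_types = readr::cols(
    participant_id = "c", group = "c", age = "d", sex = "c", nart = "d",
    hippo_volume_cm3 = "d", tiv_cm3 = "d"
  ))
}
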