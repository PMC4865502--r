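# Independent oracles used across tests. These deliberately avoid the
# package's samplers and scorers: plain loop-based rejection sampling and
# direct arithmetic, so they can cross-check the vectorised implementation.

# one feasible point by naive rejection (independent of .sample_next_point)
oracle_point <- function(geom, existing = NULL) {
  hx <- geom$width_deg / 2 - geom$edge_margin_deg
  hy <- geom$height_deg / 2 - geom$edge_margin_deg
  repeat {
    p <- c(runif(1, -hx, hx), runif(1, -hy, hy))
    if (sqrt(sum(p^2)) < geom$centre_exclusion_deg) next
    ok <- TRUE
    if (!is.null(existing)) {
      for (i in seq_len(nrow(existing))) {
        if (sqrt(sum((p - existing[i, ])^2)) <= geom$min_separation_deg) { ok <- FALSE; break }
      }
    }
    if (ok) return(p)
  }
}

oracle_array <- function(n, geom) {
  pts <- matrix(NA_real_, 0, 2)
  for (k in seq_len(n)) pts <- rbind(pts, oracle_point(geom, pts))
  pts
}

# grid integration of the feasible single-point region at `res` degrees;
# returns the fraction of the edge-margin rectangle that `predicate` covers
# within the feasible region
oracle_area_fraction <- function(geom, predicate, res = 0.1) {
  hx <- geom$width_deg / 2 - geom$edge_margin_deg
  hy <- geom$height_deg / 2 - geom$edge_margin_deg
  xs <- seq(-hx + res / 2, hx - res / 2, by = res)
  ys <- seq(-hy + res / 2, hy - res / 2, by = res)
  g <- expand.grid(x = xs, y = ys)
  feas <- sqrt(g$x^2 + g$y^2) >= geom$centre_exclusion_deg
  mean(predicate(g$x[feas], g$y[feas]))
}

# direct Monte-Carlo of the report mixture on fresh random 3-item arrays:
# returns the expected probability that a correctly identified report is
# classified as a swap (within swap_radius of a non-target)
oracle_swap_classification_prob <- function(p_swap, p_guess, sigma, geom, nsim = 20000) {
  hw <- geom$width_deg / 2
  hh <- geom$height_deg / 2
  hits <- logical(nsim)
  for (i in seq_len(nsim)) {
    arr <- oracle_array(3, geom)
    t_idx <- sample(3, 1)
    nts <- arr[-t_idx, , drop = FALSE]
    u <- runif(1)
    if (u < p_swap) {
      anchor <- nts[sample(2, 1), ]
    } else if (u < p_swap + p_guess) {
      rep_xy <- c(runif(1, -hw, hw), runif(1, -hh, hh))
      hits[i] <- any(sqrt(rowSums((nts - rep(rep_xy, each = 2))^2)) <= geom$swap_radius_deg)
      next
    } else {
      anchor <- arr[t_idx, ]
    }
    repeat {
      rep_xy <- anchor + rnorm(2, 0, sigma)
      if (abs(rep_xy[1]) <= hw && abs(rep_xy[2]) <= hh) break
    }
    hits[i] <- any(sqrt(rowSums((nts - rep(rep_xy, each = 2))^2)) <= geom$swap_radius_deg)
  }
  mean(hits)
}

# a minimal hand-built plan: one participant, explicit trial geometry
make_manual_plan <- function(trials) {
  # trials: list of lists with fields n_items, delay_s, phase, block,
  # items (ids), xs, ys, target_slot, foil_id
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    tibble::tibble(
      participant_id = "T01",
      trial_id = i,
      phase = tr$phase %||% "block1",
      block = tr$block %||% 1L,
      n_items = tr$n_items,
      delay_s = tr$delay_s %||% 1L,
      item_slot = seq_len(tr$n_items),
      item_id = tr$items,
      x_deg = tr$xs,
      y_deg = tr$ys,
      is_target = seq_len(tr$n_items) == tr$target_slot,
      foil_id = tr$foil_id
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_response <- function(plan, trial_id, chosen_id, x, y) {
  tibble::tibble(
    participant_id = plan$participant_id[1], trial_id = trial_id,
    chosen_id = chosen_id, x_deg = x, y_deg = y
  )
}

flat_params <- function(p_ident = 1, p_swap = 0, sigma = 1e-6, p_guess = 0) {
  response_model_params(
    p_ident = expand.grid(n_items = c(1, 3), delay_s = c(1, 4), block = 1:2, p = p_ident),
    p_swap = expand.grid(delay_s = c(1, 4), block = 1:2, p = p_swap),
    sigma_deg = sigma, p_guess = p_guess
  )
}

# stack one plan across many participant ids (shared design)
stack_plan <- function(plan, ids) {
  dplyr::bind_rows(lapply(ids, function(id) {
    p <- plan
    p$participant_id <- id
    p
  }))
}
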