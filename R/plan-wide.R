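# Internal wide representation of a session plan: one row per trial with
# item coordinates/identities as matrices, so simulation and scoring are
# plain vectorised matrix operations.
.plan_wide <- function(plan) {
  key <- paste(plan$participant_id, plan$trial_id, sep = "\r")
  ukey <- unique(key)
  g <- match(key, ukey)
  first <- !duplicated(g)
  m <- length(ukey)
  K <- max(plan$item_slot)

  X <- matrix(NA_real_, m, K)
  Y <- matrix(NA_real_, m, K)
  IDS <- matrix(NA_character_, m, K)
  idx <- cbind(g, plan$item_slot)
  X[idx] <- plan$x_deg
  Y[idx] <- plan$y_deg
  IDS[idx] <- plan$item_id

  target_slot <- integer(m)
  target_slot[g[plan$is_target]] <- plan$item_slot[plan$is_target]
  if (any(target_slot == 0)) abort("plan has trial(s) without a target item")

  meta <- tibble::tibble(
    participant_id = plan$participant_id[first],
    trial_id = plan$trial_id[first],
    phase = plan$phase[first],
    block = plan$block[first],
    n_items = plan$n_items[first],
    delay_s = plan$delay_s[first],
    foil_id = plan$foil_id[first],
    target_slot = target_slot
  )
  meta$target_id <- IDS[cbind(seq_len(m), target_slot)]
  meta$tx <- X[cbind(seq_len(m), target_slot)]
  meta$ty <- Y[cbind(seq_len(m), target_slot)]
  list(meta = meta, X = X, Y = Y, IDS = IDS, key = ukey)
}
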