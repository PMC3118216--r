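# Iterative, seed-anchored agglomeration of a qualified promoter set.
#
# Starting from a single seed promoter whose binding site occupies a known
# window (the anchor), each iteration motif-samples the qualified set plus
# one pool promoter at a time, keeps the pool promoter whose motif scores
# best while placing an instance exactly on the anchor, and prunes the pool:
# candidates below the 30th percentile of the iteration's anchored scores,
# and candidates not improving on the previous iteration's winning score,
# are eliminated. The procedure halts when the pool is exhausted or no
# candidate improves.

#' Agglomeration parameter set
#'
#' @param anchor_seq_id id of the seed promoter carrying the known site.
#' @param anchor_window half-open 0-based index interval of the seed site;
#'   the default `c(66, 86)` is offsets -184..-165 under the -250..+30
#'   promoter window.
#' @param percentile_cut percentile (0-100) of each iteration's anchored
#'   scores below which candidates are pruned (default 30).
#' @param min_overlap anchor-overlap fraction passed to
#'   [window_anchored_ll()] (default 1: exact coincidence).
#' @param sampler a [sampler_params()] list.
#' @return an `agglomeration_params` list.
#' @export
agglomeration_params <- function(anchor_seq_id,
                                 anchor_window = c(66L, 86L),
                                 percentile_cut = 30,
                                 min_overlap = 1,
                                 sampler = sampler_params()) {
  stopifnot(percentile_cut >= 0, percentile_cut < 100,
            anchor_window[2] - anchor_window[1] == sampler$width)
  structure(list(anchor_seq_id = anchor_seq_id,
                 anchor_window = as.integer(anchor_window),
                 percentile_cut = percentile_cut,
                 min_overlap = min_overlap,
                 sampler = sampler),
            class = "agglomeration_params")
}

new_agglomeration_state <- function(qualified, pool, prev_best_ll = NA_real_) {
  structure(list(qualified = qualified, pool = pool,
                 prev_best_ll = prev_best_ll, iteration = 0L,
                 history = list()),
            class = "agglomeration_state")
}

#' Score every pool promoter against the current qualified set
#'
#' For each pool promoter p, runs [sample_motif()] on qualified + p and
#' records the best motif together with its anchored ll score (`NA` when the
#' motif has no instance exactly on the seed anchor window). Per-candidate
#' seeds are derived by hashing (global seed, iteration, promoter id), so
#' results do not depend on pool order.
#'
#' @param state an `agglomeration_state` (lists `qualified` and `pool` of
#'   named sequences).
#' @param params an [agglomeration_params()] list.
#' @param bg background model, trained once on the initial pool.
#' @param global_seed integer master seed.
#' @param precomp precomputed candidate structures for all promoters.
#' @return named list: per promoter id, `list(motif, anchored_ll)`.
#' @export
score_candidates <- function(state, params, bg, global_seed = 1L,
                             precomp = NULL) {
  out <- list()
  for (pid in names(state$pool)) {
    seqs <- c(state$qualified, state$pool[pid])
    seed_p <- derive_seed(global_seed, state$iteration, pid)
    pc <- if (!is.null(precomp)) precomp[names(seqs)] else NULL
    motif <- sample_motif(seqs, params$sampler, bg, seed = seed_p,
                          precomp = pc)
    anch <- window_anchored_ll(motif, params$anchor_seq_id,
                               params$anchor_window,
                               min_overlap = params$min_overlap %||% 1)
    out[[pid]] <- list(motif = motif, ll = motif$ll_score,
                       anchored_ll = anch)
  }
  out
}

#' Apply one agglomeration step to scored candidates
#'
#' Rules, in order: (1) the candidate with the maximum position-anchored ll
#' (ties: lexicographically smallest id) is the winner; if its score fails
#' to improve on the previous iteration's (`<=`), the procedure terminates
#' with no addition. (2) Candidates whose motif ll score falls strictly
#' below the `percentile_cut` percentile (linear interpolation) of this
#' iteration's motif ll scores -- all candidates' scores, anchored or not --
#' are pruned. (3) Anchored candidates not improving on the previous best
#' anchored score (`<=`) are pruned. The winner then moves from the pool to
#' the qualified set and its anchored score becomes the new best.
#' Candidates without an anchored instance cannot win but stay in the pool
#' until the percentile rule removes them or the procedure terminates.
#'
#' @param state an `agglomeration_state`.
#' @param scores output of [score_candidates()] on the same state.
#' @param params an [agglomeration_params()] list.
#' @return the updated state; `state$terminated` is `TRUE` when no candidate
#'   could be added.
#' @export
agglomeration_step <- function(state, scores, params) {
  anch <- vapply(scores, function(s) s$anchored_ll, numeric(1))
  raw <- vapply(scores, function(s) s$ll %||% s$anchored_ll, numeric(1))
  finite <- anch[!is.na(anch)]
  rec <- list(iteration = state$iteration + 1L,
              scores = anch, raw_scores = raw, winner = NA_character_,
              pruned = character(0), prune_reason = character(0))
  if (length(finite) == 0L) {
    state$terminated <- TRUE
    rec$note <- "no candidate produced an anchored motif"
    state$history <- c(state$history, list(rec))
    return(state)
  }
  ids <- names(anch)
  best_val <- max(finite)
  winner <- sort(ids[!is.na(anch) & anch == best_val])[1L]
  if (!is.na(state$prev_best_ll) && best_val <= state$prev_best_ll) {
    state$terminated <- TRUE
    rec$note <- sprintf(
      "best candidate %s (ll %.4f) does not improve on previous best %.4f",
      winner, best_val, state$prev_best_ll)
    state$history <- c(state$history, list(rec))
    return(state)
  }
  cut <- unname(quantile(raw[!is.na(raw)], params$percentile_cut / 100,
                         type = 7))
  pruned <- character(0)
  reason <- character(0)
  for (pid in ids) {
    if (pid == winner) next
    if (!is.na(raw[[pid]]) && raw[[pid]] < cut) {
      pruned <- c(pruned, pid); reason <- c(reason, "percentile")
    } else if (!is.na(anch[[pid]]) && !is.na(state$prev_best_ll) &&
               anch[[pid]] <= state$prev_best_ll) {
      pruned <- c(pruned, pid); reason <- c(reason, "nonimproving")
    }
  }
  rec$winner <- winner
  rec$winner_ll <- best_val
  rec$percentile_cut_value <- cut
  rec$pruned <- pruned
  rec$prune_reason <- reason
  state$qualified <- c(state$qualified, state$pool[winner])
  state$pool <- state$pool[setdiff(names(state$pool), c(winner, pruned))]
  state$prev_best_ll <- best_val
  state$iteration <- state$iteration + 1L
  state$winner_motifs <- c(state$winner_motifs,
                           setNames(list(scores[[winner]]$motif), winner))
  state$history <- c(state$history, list(rec))
  state$terminated <- FALSE
  state
}

#' Run the full seed-anchored agglomeration
#'
#' Iterates [score_candidates()] and [agglomeration_step()] until the pool is
#' empty or no candidate improves, then samples the final motif over the
#' final qualified set. The history records, for every initial pool
#' promoter, whether it was qualified, pruned (and why) or survived to
#' termination.
#'
#' @param seed_promoter named length-1 character vector (or 1-row
#'   `promoter_set`): the seed sequence containing the anchor window.
#' @param pool named character vector (or `promoter_set`) of candidate
#'   promoters.
#' @param params an [agglomeration_params()] list.
#' @param bg optional background model; trained (order
#'   `params$sampler$bg_order`) on seed + initial pool when missing.
#' @param global_seed integer master seed for the whole procedure.
#' @return list with `state` (final `agglomeration_state`), `motif` (final
#'   `motif_result` over the qualified set) and `audit` (per-promoter fate).
#' @export
run_agglomeration <- function(seed_promoter, pool, params, bg = NULL,
                              global_seed = 1L) {
  seed_promoter <- as_seq_vector(seed_promoter)
  pool <- as_seq_vector(pool)
  stopifnot(length(seed_promoter) == 1L)
  if (params$anchor_window[2] > nchar(seed_promoter[[1L]])) {
    abort_seedmotif("seed promoter does not contain the anchor window",
                    "seedmotif_range_error")
  }
  if (is.null(names(seed_promoter)) ||
      names(seed_promoter) != params$anchor_seq_id) {
    names(seed_promoter) <- params$anchor_seq_id
  }
  pool <- pool[setdiff(names(pool), names(seed_promoter))]
  if (is.null(bg)) {
    bg <- train_background(unname(c(seed_promoter, pool)),
                           order = params$sampler$bg_order)
  }
  all_seqs <- c(seed_promoter, pool)
  precomp <- lapply(all_seqs, precompute_candidates,
                    W = params$sampler$width, bg = bg,
                    strands = params$sampler$strands)
  names(precomp) <- names(all_seqs)
  state <- new_agglomeration_state(seed_promoter, pool)
  initial_pool_ids <- names(pool)
  while (length(state$pool) > 0L) {
    scores <- score_candidates(state, params, bg, global_seed, precomp)
    state <- agglomeration_step(state, scores, params)
    if (isTRUE(state$terminated)) break
  }
  final_motif <- sample_motif(state$qualified, params$sampler, bg,
                              seed = derive_seed(global_seed, "final"),
                              precomp = precomp[names(state$qualified)])
  audit <- audit_agglomeration(state, initial_pool_ids)
  list(state = state, motif = final_motif, audit = audit, background = bg)
}

# Classify the fate of every initial pool promoter from the history.
audit_agglomeration <- function(state, initial_pool_ids) {
  fate <- setNames(rep("surviving-at-termination", length(initial_pool_ids)),
                   initial_pool_ids)
  for (rec in state$history) {
    if (!is.na(rec$winner)) fate[rec$winner] <- "qualified"
    if (length(rec$pruned) > 0L) {
      fate[rec$pruned] <- paste0("pruned-", rec$prune_reason)
    }
  }
  data.frame(promoter_id = names(fate), fate = unname(fate),
             stringsAsFactors = FALSE)
}

#' Serialize an agglomeration history to JSON
#'
#' @param result value of [run_agglomeration()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_agglomeration_history <- function(result, path) {
  hist <- lapply(result$state$history, function(rec) {
    rec$scores <- as.list(rec$scores)
    rec
  })
  obj <- list(qualified = names(result$state$qualified),
              prev_best_ll = result$state$prev_best_ll,
              iterations = hist,
              audit = result$audit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
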