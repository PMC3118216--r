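# Fixed-width, both-strand Gibbs site sampler with multi-restart selection.
#
# Model: at most one motif occurrence per sequence. Visiting a sequence, the
# PSPM is rebuilt from all other sequences' current sites, every length-W
# window on both strands is scored by its likelihood ratio w = P(x|motif) /
# P(x|background), and the site is resampled from a two-component model with
# sequence-level prior pi: presence probability q = pi*m / (pi*m + 1 - pi)
# with m the mean candidate weight; given presence, position i is drawn with
# probability w_i / sum(w).
#
# Candidate selection uses inverse-CDF sampling over candidates in a
# canonical order (descending weight, ties broken by segment string), so
# every random choice depends only on the candidate segment multiset. That
# multiset is invariant under reverse-complementing the input sequences,
# which makes runs deterministic given the seed and orientation-canonical.

#' Sampler parameter set
#'
#' @param runs independent restarts of which the best-scoring motif is kept
#'   (default 100).
#' @param width motif width W (default 20).
#' @param strands `"both"` or `"forward"`.
#' @param bg_order Markov order used when the caller trains a background
#'   (default 3); recorded for provenance.
#' @param prior sequence-level prior probability pi that a sequence carries a
#'   site (default 0.5).
#' @param sweeps_max maximum Gibbs sweeps per run (default 100).
#' @param sweeps_stable stop after this many consecutive sweeps with an
#'   unchanged site configuration (default 5).
#' @param pspm_pseudocount total pseudocount mass per PSPM column.
#' @param shift_max after every sweep, a phase-shift move proposes sliding
#'   all current sites coherently by up to this many positions (in reading
#'   orientation) and samples among the shifts by relative likelihood;
#'   without it the sampler is prone to locking into registrations offset by
#'   a few bases from the optimum. 0 disables the move.
#' @return a `sampler_params` list.
#' @export
sampler_params <- function(runs = 100L, width = 20L,
                           strands = c("both", "forward"),
                           bg_order = 3L, prior = 0.5,
                           sweeps_max = 100L, sweeps_stable = 5L,
                           pspm_pseudocount = 0.1, shift_max = 3L) {
  strands <- match.arg(strands)
  stopifnot(prior > 0, prior < 1, width >= 4L, runs >= 1L,
            sweeps_max >= 1L, sweeps_stable >= 1L, shift_max >= 0L)
  structure(list(runs = as.integer(runs), width = as.integer(width),
                 strands = strands, bg_order = as.integer(bg_order),
                 prior = prior, sweeps_max = as.integer(sweeps_max),
                 sweeps_stable = as.integer(sweeps_stable),
                 pspm_pseudocount = pspm_pseudocount,
                 shift_max = as.integer(shift_max)),
            class = "sampler_params")
}

# Evaluate expr with a private, explicitly seeded RNG stream, restoring the
# caller's RNG state afterwards.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  force(expr)
}

# Per-sequence candidate precompute shared across restarts (and, in the
# agglomeration, across iterations): segment strings, background log-probs
# and PSPM lookup indices for every window on the requested strands.
precompute_candidates <- function(seq, W, bg, strands = "both") {
  enc <- encode_dna(seq)
  L <- length(enc)
  n <- L - W + 1L
  if (n < 1L) return(NULL)
  segs_f <- substring(seq, 1:n, W:L)
  bg_f <- bg_window_logprobs(enc, bg, W)
  both <- identical(strands, "both")
  if (both) {
    rcseq <- revcomp(seq)
    renc <- encode_dna(rcseq)
    segs_r <- rev(substring(rcseq, 1:n, W:L))
    bg_r <- rev(bg_window_logprobs(renc, bg, W))
  }
  # linear indices into a 4 x W matrix, candidate-major layout (ncand x W)
  lin <- matrix(NA_integer_, nrow = if (both) 2L * n else n, ncol = W)
  for (j in seq_len(W)) {
    cf <- enc[(1:n) + j - 1L]
    lin[1:n, j] <- (j - 1L) * 4L + cf
    if (both) {
      cr <- 5L - enc[(1:n) + W - j]
      lin[n + (1:n), j] <- (j - 1L) * 4L + cr
    }
  }
  seg <- if (both) c(segs_f, segs_r) else segs_f
  bgl <- if (both) c(bg_f, bg_r) else bg_f
  strand <- if (both) rep(c(1L, -1L), each = n) else rep(1L, n)
  start0 <- if (both) c(0:(n - 1L), 0:(n - 1L)) else 0:(n - 1L)
  valid <- !is.na(bgl) & rowSums(is.na(lin)) == 0L
  if (!any(valid)) return(NULL)
  # keep valid (N-free, scorable) candidates only; canonical integer
  # segment rank gives a fast, orientation-invariant tie-break
  seg <- seg[valid]
  strand_v <- strand[valid]
  start_v <- start0[valid]
  # (strand, start) -> candidate row, for the phase-shift move
  lookup <- matrix(NA_integer_, nrow = 2L, ncol = n)
  lookup[cbind(ifelse(strand_v == 1L, 1L, 2L), start_v + 1L)] <-
    seq_along(start_v)
  list(seq = seq, L = L, ncand = sum(valid), seg = seg,
       seg_rank = match(seg, sort(unique(seg), method = "radix")),
       bgl = bgl[valid], strand = strand_v, start0 = start_v,
       lin = lin[valid, , drop = FALSE], lookup = lookup)
}

# Candidate motif-vs-background log weights for one precomputed sequence.
# logm may be the 4 x W log matrix or its flattened vector; indexing is
# always by flat position so a 2-column lin matrix is never misread as
# (row, col) pairs.
candidate_log_weights <- function(pc, logm) {
  vals <- as.vector(logm)[pc$lin]
  dim(vals) <- dim(pc$lin)
  rowSums(vals) - pc$bgl
}

# Site counts are kept as a length-4W vector addressed by the precomputed
# linear indices (base, column) of each candidate.

#' One seeded Gibbs sampling run
#'
#' Runs the sampler once on a set of sequences and returns the motif found:
#' at most one occurrence per sequence, re-scored with the final PSPM.
#' Deterministic given `seed`. Sequences shorter than the motif width are
#' skipped with a message; segments containing `N` are never candidates.
#'
#' @param seqs named character vector of DNA sequences, or a `promoter_set`.
#' @param params a [sampler_params()] list.
#' @param bg a `background_model` (train once with [train_background()]).
#' @param seed integer seed for the run's private RNG stream.
#' @param precomp optional precomputed candidate structures (internal reuse).
#' @return a `motif_result`: `pspm`, `instances` (seq_id, start, strand,
#'   segment, log_weight, posterior), `ll_score`, `consensus`.
#' @export
gibbs_run <- function(seqs, params = sampler_params(), bg, seed = 1L,
                      precomp = NULL) {
  seqs <- as_seq_vector(seqs)
  W <- params$width
  if (is.null(precomp)) {
    precomp <- lapply(seqs, precompute_candidates, W = W, bg = bg,
                      strands = params$strands)
    names(precomp) <- names(seqs)
  }
  short <- vapply(precomp, is.null, logical(1))
  if (all(short)) {
    abort_seedmotif(
      "no sequence offers a scorable window of the motif width",
      "seedmotif_empty_input")
  }
  if (any(short)) {
    message("skipping ", sum(short),
            " sequence(s) without a scorable window of width ", W)
  }
  pcs <- precomp[!short]
  ids <- names(pcs)
  ns <- length(pcs)
  pi0 <- params$prior
  pseudo <- params$pspm_pseudocount
  pseudo_cell <- pseudo * 0.25
  with_rng(seed, {
    # initialization: every sequence gets a uniformly random site, candidates
    # taken in segment-canonical order (orientation-invariant)
    site <- rep(NA_integer_, ns) # candidate row index, NA = absent
    counts <- numeric(4L * W) # addressed by the lin indices
    n_pres <- 0L
    for (i in seq_len(ns)) {
      pc <- pcs[[i]]
      ord0 <- order(pc$seg_rank)
      u <- runif(1)
      pick <- ord0[ceiling(u * pc$ncand)]
      site[i] <- pick
      counts[pc$lin[pick, ]] <- counts[pc$lin[pick, ]] + 1
      n_pres <- n_pres + 1L
    }
    config <- vapply(seq_len(ns), function(i) pcs[[i]]$seg[site[i]],
                     character(1))
    stable <- 0L
    for (sweep in seq_len(params$sweeps_max)) {
      changed <- FALSE
      for (i in seq_len(ns)) {
        pc <- pcs[[i]]
        u1 <- runif(1)
        u2 <- runif(1)
        if (!is.na(site[i])) {
          counts[pc$lin[site[i], ]] <- counts[pc$lin[site[i], ]] - 1
          n_pres <- n_pres - 1L
        }
        logm <- log((counts + pseudo_cell) / (n_pres + pseudo))
        vals <- logm[pc$lin]
        dim(vals) <- dim(pc$lin)
        lw <- rowSums(vals) - pc$bgl
        w <- exp(pmin(lw, 700))
        m <- mean(w)
        q <- pi0 * m / (pi0 * m + (1 - pi0))
        new_seg <- ""
        if (u1 < q && m > 0) {
          ord <- order(-w, pc$seg_rank)
          cum <- cumsum(w[ord])
          tot <- cum[length(cum)]
          pick <- ord[min(findInterval(u2 * tot, cum) + 1L, length(ord))]
          site[i] <- pick
          counts[pc$lin[pick, ]] <- counts[pc$lin[pick, ]] + 1
          n_pres <- n_pres + 1L
          new_seg <- pc$seg[pick]
        } else {
          site[i] <- NA_integer_
        }
        if (!identical(new_seg, config[i])) {
          changed <- TRUE
          config[i] <- new_seg
        }
      }
      # phase-shift move: slide all present sites coherently in reading
      # orientation, sampling among available shifts by relative likelihood
      if (params$shift_max > 0L) {
        present <- which(!is.na(site))
        if (length(present) > 0L) {
          sm <- params$shift_max
          deltas <- c(0L, as.vector(rbind(seq_len(sm), -seq_len(sm))))
          lls <- rep(NA_real_, length(deltas))
          shift_rows <- vector("list", length(deltas))
          for (d in seq_along(deltas)) {
            delta <- deltas[d]
            rows <- rep(NA_integer_, ns)
            ok <- TRUE
            for (i in present) {
              pc <- pcs[[i]]
              k <- site[i]
              new_start <- pc$start0[k] +
                (if (pc$strand[k] == 1L) delta else -delta)
              r <- if (new_start < 0L || new_start + 1L > ncol(pc$lookup)) {
                NA_integer_
              } else {
                pc$lookup[if (pc$strand[k] == 1L) 1L else 2L, new_start + 1L]
              }
              if (is.na(r)) { ok <- FALSE; break }
              rows[i] <- r
            }
            if (!ok) next
            cnt <- numeric(4L * W)
            for (i in present) {
              cnt[pcs[[i]]$lin[rows[i], ]] <- cnt[pcs[[i]]$lin[rows[i], ]] + 1
            }
            logm_d <- log((cnt + pseudo_cell) / (length(present) + pseudo))
            ll <- 0
            for (i in present) {
              pc <- pcs[[i]]
              ll <- ll + sum(logm_d[pc$lin[rows[i], ]]) - pc$bgl[rows[i]]
            }
            lls[d] <- ll
            shift_rows[[d]] <- rows
          }
          # greedy: accept the best available shift (ties favor delta 0,
          # then the proposal order 1, -1, 2, -2, ...)
          lls[is.na(lls)] <- -Inf
          pickd <- which.max(lls)
          if (deltas[pickd] != 0L) {
            rows <- shift_rows[[pickd]]
            counts <- numeric(4L * W)
            for (i in present) {
              site[i] <- rows[i]
              counts[pcs[[i]]$lin[rows[i], ]] <-
                counts[pcs[[i]]$lin[rows[i], ]] + 1
              config[i] <- pcs[[i]]$seg[rows[i]]
            }
            changed <- TRUE
          }
        }
      }
      if (changed) stable <- 0L else stable <- stable + 1L
      if (stable >= params$sweeps_stable) break
    }
    finalize_motif(pcs, ids, site, counts, pseudo, bg, pi0, W)
  })
}

finalize_motif <- function(pcs, ids, site, counts, pseudo, bg, pi0, W) {
  present <- which(!is.na(site))
  pspm <- pspm_from_counts(matrix(counts, nrow = 4L, ncol = W), pseudo)
  if (length(present) == 0L) {
    inst <- data.frame(seq_id = character(), start = integer(),
                       strand = integer(), segment = character(),
                       log_weight = numeric(), posterior = numeric(),
                       stringsAsFactors = FALSE)
    res <- new_motif_result(pspm, inst, 0)
    attr(res, "seq_ids") <- ids
    return(res)
  }
  logm <- log(pspm$matrix)
  rows <- lapply(present, function(i) {
    pc <- pcs[[i]]
    k <- site[i]
    lw <- candidate_log_weights(pc, logm)[k]
    w <- exp(lw)
    data.frame(seq_id = ids[i], start = pc$start0[k], strand = pc$strand[k],
               segment = pc$seg[k], log_weight = lw,
               posterior = pi0 * w / (pi0 * w + (1 - pi0)),
               stringsAsFactors = FALSE)
  })
  inst <- do.call(rbind, rows)
  rownames(inst) <- NULL
  res <- new_motif_result(pspm, inst, sum(inst$log_weight))
  attr(res, "seq_ids") <- ids
  res
}

as_seq_vector <- function(seqs) {
  if (inherits(seqs, "promoter_set")) return(promoter_seqs(seqs))
  if (inherits(seqs, "DNAStringSet")) {
    return(setNames(as.character(seqs), names(seqs)))
  }
  if (is.character(seqs)) {
    if (length(seqs) == 1L && file.exists(seqs) &&
        grepl("\\.(fa|fasta|fna)$", seqs, ignore.case = TRUE)) {
      dss <- Biostrings::readDNAStringSet(seqs)
      return(setNames(toupper(as.character(dss)),
                      sub("\\s.*$", "", names(dss))))
    }
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    return(toupper(seqs))
  }
  abort_seedmotif("unsupported sequence input", "seedmotif_shape_error")
}

#' Multi-restart motif sampling
#'
#' Runs [gibbs_run()] `params$runs` times with seeds `seed, seed + 1, ...`
#' and returns the highest-scoring motif; ties are broken by the lowest seed.
#'
#' @inheritParams gibbs_run
#' @return the best `motif_result` across restarts.
#' @export
sample_motif <- function(seqs, params = sampler_params(), bg, seed = 1L,
                         precomp = NULL) {
  seqs <- as_seq_vector(seqs)
  if (is.null(precomp)) {
    precomp <- lapply(seqs, precompute_candidates, W = params$width, bg = bg,
                      strands = params$strands)
    names(precomp) <- names(seqs)
  }
  best <- NULL
  for (r in seq_len(params$runs) - 1L) {
    res <- gibbs_run(seqs, params, bg, seed = seed + r, precomp = precomp)
    if (is.null(best) || res$ll_score > best$ll_score) best <- res
  }
  best
}

#' Position-anchored log-likelihood score of a motif
#'
#' Returns the motif's `ll_score` iff the motif places an instance on the
#' anchor sequence exactly at the given half-open index window (either
#' strand); `NA` otherwise. This realizes "maximum ll-score within the
#' specified position" of the seed promoter: with the default -250..+30
#' window, seed offsets -184..-165 are indices `[66, 86)`.
#'
#' @param motif a `motif_result`.
#' @param anchor_seq_id id of the anchor sequence (must have been in the
#'   sampled set).
#' @param window half-open 0-based index interval `c(start, end)` with
#'   `end - start` equal to the motif width.
#' @param min_overlap minimum fraction of the anchor window the instance
#'   must cover. The default 1 demands exact coincidence; values below 1
#'   tolerate small registration shifts, which pair-wise sampling of noisy
#'   sites cannot resolve (two aligned instances determine their common
#'   phase only up to a few bases).
#' @return the motif's ll score, or `NA_real_` when no instance sits on the
#'   anchor window.
#' @export
window_anchored_ll <- function(motif, anchor_seq_id, window = c(66L, 86L),
                               min_overlap = 1) {
  seq_ids <- attr(motif, "seq_ids")
  if (!is.null(seq_ids) && !(anchor_seq_id %in% seq_ids)) {
    abort_seedmotif(paste("unknown anchor sequence id:", anchor_seq_id),
                    "seedmotif_key_error")
  }
  W <- motif$pspm$width
  if (window[2] - window[1] != W) {
    abort_seedmotif("anchor window length must equal the motif width",
                    "seedmotif_shape_error")
  }
  stopifnot(min_overlap > 0, min_overlap <= 1)
  inst <- motif$instances
  on_anchor <- inst$seq_id == anchor_seq_id
  ov <- pmin(inst$start + W, window[2]) - pmax(inst$start, window[1])
  hit <- on_anchor & ov >= ceiling(min_overlap * W)
  if (any(hit)) motif$ll_score else NA_real_
}
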