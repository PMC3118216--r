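# Shared fixtures and independent oracles, all generated in code.

BASES <- c("A", "C", "G", "T")

# A reference 20-mer used as the planted binding-site consensus throughout.
FIX_MOTIF20 <- "GCTATGCGGTTATTTGCACA"

# PSPM with a fixed dominant-base probability per column. The default 0.95
# emulates a well-conserved bacterial regulator half-site.
fix_pspm <- function(motif = FIX_MOTIF20, dom = 0.95) {
  m <- vapply(strsplit(motif, "")[[1]], function(b) {
    v <- rep((1 - dom) / 3, 4)
    v[match(b, BASES)] <- dom
    v
  }, numeric(4))
  seedmotif:::new_pspm(unname(m))
}

fix_random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                    collapse = "")

# Background trained on fixed iid sequence; deterministic given the seed.
fix_background <- function(order = 3L, seed = 1L, total = 10000L) {
  withr::with_seed(seed, {
    seqs <- vapply(1:5, function(i) fix_random_seq(total %/% 5), character(1))
  })
  suppressWarnings(train_background(seqs, order = order))
}

# Promoters with an identical planted 20-mer at random positions (the
# strongest recoverable signal; used for sampler recovery checks).
fix_identical_planted <- function(n = 20L, len = 300L, seed = 1L,
                                  motif = FIX_MOTIF20) {
  W <- nchar(motif)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      s <- fix_random_seq(len)
      pos <- sample(len - W + 1L, 1L)
      paste0(substr(s, 1L, pos - 1L), motif, substr(s, pos + W, len))
    }, character(1))
  })
  setNames(seqs, sprintf("s%02d", seq_len(n)))
}

# Agglomeration fixture: a seed promoter anchored at index 66, `n_planted`
# pool promoters carrying instances drawn from a common PSPM at random
# positions, and noise promoters, over an order-3 background.
fix_agglom_pool <- function(fseed, n_pool = 30L, n_planted = 5L,
                            dom = 0.95) {
  pp <- fix_pspm(dom = dom)
  bgu <- fix_background(order = 3L, seed = 1L)
  gen <- simulate_promoters(n_pool, 281L, bgu, plant = NULL, seed = fseed)
  pool <- gen$seqs
  plantgen <- simulate_promoters(
    n_planted + 1L, 281L, bgu,
    plant = plant_spec(pp, occupancy = 1, position_mode = "fixed",
                       offset = 66L),
    seed = fseed + 1000L)
  seedprom <- plantgen$seqs[1]
  names(seedprom) <- "seedP"
  planted_ids <- sprintf("prom%03d", seq_len(n_planted))
  withr::with_seed(fseed + 2000L, {
    for (i in seq_len(n_planted)) {
      seg <- plantgen$truth$segment[i + 1L]
      if (plantgen$truth$strand[i + 1L] == -1L) seg <- revcomp(seg)
      pos <- sample(281L - 20L + 1L, 1L)
      s <- pool[[planted_ids[i]]]
      pool[planted_ids[i]] <- paste0(substr(s, 1L, pos - 1L), seg,
                                     substr(s, pos + 20L, 281L))
    }
  })
  list(seed = seedprom, pool = pool, planted_ids = planted_ids,
       pspm = pp,
       bg = suppressWarnings(train_background(unname(c(seedprom, pool)),
                                              order = 3L)))
}

# Sampler setting used for recovery experiments: restarts and sweep budget
# scaled for minute-scale suites (defaults in the package mirror the
# production 100-run setting).
fix_sampler <- function(runs = 15L, width = 20L) {
  sampler_params(runs = runs, width = width, sweeps_max = 100L,
                 sweeps_stable = 5L)
}

fix_agglom_params <- function(runs = 15L) {
  agglomeration_params("seedP", c(66L, 86L), percentile_cut = 30,
                       min_overlap = 0.75, sampler = fix_sampler(runs))
}

# Column agreement between a consensus string and a reference motif, taking
# the better of the two orientations (a both-strand sampler reports the
# motif up to reverse complement).
consensus_agreement <- function(consensus, motif) {
  score <- function(a, b) {
    sum(toupper(strsplit(a, "")[[1]]) == strsplit(b, "")[[1]])
  }
  max(score(consensus, motif), score(revcomp(consensus), motif))
}

# Independent brute-force threshold scan: enumerate every position and
# strand via log_weight and keep w > (1-pi)/pi (no overlap resolution).
brute_threshold_scan <- function(seqs, pspm, bg, prior) {
  W <- pspm$width
  thr <- (1 - prior) / prior
  rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < W) next
    for (p in seq_len(L - W + 1L)) {
      seg_f <- substr(s, p, p + W - 1L)
      if (grepl("N", seg_f)) next
      for (st in c(1L, -1L)) {
        sg <- if (st == 1L) seg_f else revcomp(seg_f)
        w <- exp(log_weight(sg, pspm, bg))
        if (!is.na(w) && w > thr) {
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = id, start = p - 1L, strand = st, w = w,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      strand = integer(), w = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$seq_id, df$start, -df$strand), , drop = FALSE]
}

# Check the scanner output against the brute-force threshold set: the
# reported hits must be exactly the threshold crossers that survive a
# greedy best-weight-first same-strand overlap resolution. Tie order at
# numerically equal weights is not pinned; instead we verify the greedy
# optimality conditions directly.
expect_scan_matches_brute <- function(hits, seqs, pspm, bg, prior) {
  W <- pspm$width
  ref <- brute_threshold_scan(seqs, pspm, bg, prior)
  # every reported hit crosses the threshold at the brute-force weight
  expect_true(all(hit_key(hits) %in% hit_key(ref)))
  # no same-strand overlap among reported hits
  for (id in unique(hits$seq_id)) {
    for (st in c(1L, -1L)) {
      ss <- sort(hits$start[hits$seq_id == id & hits$strand == st])
      if (length(ss) > 1L) expect_true(all(diff(ss) >= W))
    }
  }
  # every threshold crosser not reported overlaps a reported hit of
  # at-least-equal weight (within fp tolerance) on the same strand
  dropped <- ref[!(hit_key(ref) %in% hit_key(hits)), , drop = FALSE]
  if (nrow(dropped) > 0L) {
    for (i in seq_len(nrow(dropped))) {
      near <- hits$seq_id == dropped$seq_id[i] &
        hits$strand == dropped$strand[i] &
        abs(hits$start - dropped$start[i]) < W
      expect_true(any(near))
      expect_gte(max(exp(hits$log_weight[near])) + 1e-9, dropped$w[i])
    }
  }
  invisible(ref)
}

# Exhaustive hypergeometric upper tail by subset enumeration.
brute_hypergeom <- function(x, n, M, N) {
  if (n == 0L) return(if (x == 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  carriers <- seq_len(M)
  mean(apply(subsets, 2L, function(s) sum(s %in% carriers) >= x))
}

hit_key <- function(df) paste(df$seq_id, df$start, df$strand)
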