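# PSPM / background mathematics.

test_that("background training reproduces hand-counted models", {
  bg0 <- train_background("ACGTACGT", order = 0, pseudocount = 0)
  expect_equal(unname(bg0$transition[1, ]), rep(0.25, 4))

  bg1 <- suppressWarnings(train_background("AACA", order = 1,
                                           pseudocount = 0))
  expect_equal(bg1$transition["A", "A"], 0.5)
  expect_equal(bg1$transition["A", "C"], 0.5)
  expect_equal(bg1$transition["C", "A"], 1)
  # initial = marginal 1-mer frequency: A 3/4, C 1/4
  expect_equal(unname(bg1$initial[c("A", "C")]), c(0.75, 0.25))

  expect_error(train_background(character(0)),
               class = "seedmotif_empty_input")
})

test_that("order-3 training is consistent on data simulated from the model", {
  set.seed(11)
  truth_mat <- matrix(stats::rgamma(64 * 4, 2), ncol = 4)
  truth_mat <- truth_mat / rowSums(truth_mat)
  init <- rep(1 / 64, 64)
  truth <- seedmotif:::new_background_model(3L, truth_mat, init)
  rownames(truth$transition) <- seedmotif:::context_kmers(3L)
  colnames(truth$transition) <- BASES
  # 100 kb gives ~1500 observations per context, enough for a uniform
  # 0.05 bound on every one of the 256 transition cells
  withr::with_seed(12, {
    seqs <- vapply(1:4, function(i)
      seedmotif:::sample_from_background(25000L, truth), character(1))
  })
  est <- train_background(seqs, order = 3)
  expect_lt(max(abs(est$transition - truth_mat)), 0.05)
  expect_lt(mean(abs(est$transition - truth_mat)), 0.02)
})

test_that("background log-probabilities match the factorized model", {
  bg0 <- train_background("ACGTACGT", order = 0, pseudocount = 0)
  expect_equal(bg_logprob("ACGT", bg0), 4 * log(0.25))
  bg1 <- suppressWarnings(train_background("AACA", order = 1,
                                           pseudocount = 0))
  expect_equal(bg_logprob("AA", bg1), log(3 / 4) + log(1 / 2))
  expect_true(is.na(bg_logprob("ANA", bg0)))
})

test_that("vectorized window log-probabilities agree with per-window scoring", {
  for (ord in c(0L, 1L, 3L)) {
    bg <- fix_background(order = ord, seed = 20 + ord)
    withr::with_seed(30 + ord, {
      s <- paste(sample(c(BASES, "N"), 150, replace = TRUE,
                        prob = c(rep(0.24, 4), 0.04)), collapse = "")
    })
    W <- 7L
    vec <- seedmotif:::bg_window_logprobs(seedmotif:::encode_dna(s), bg, W)
    ref <- vapply(seq_len(nchar(s) - W + 1L), function(p)
      bg_logprob(substr(s, p, p + W - 1L), bg), numeric(1))
    expect_equal(vec, ref)
  }
})

test_that("PSPM construction counts and smooths correctly", {
  p <- build_pspm(rep("ACGTA", 5), pseudocount = 0)
  expect_equal(unname(p$matrix[cbind(c(1, 2, 3, 4, 1), 1:5)]), rep(1, 5))
  p2 <- build_pspm(c("AA", "AC"), pseudocount = 0)
  expect_equal(unname(p2$matrix[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p2$matrix[, 2]), c(0.5, 0.5, 0, 0))
  p3 <- build_pspm(c("AA", "AC"), pseudocount = 1)
  expect_true(all(p3$matrix > 0))
  expect_equal(colSums(p3$matrix), rep(1, 2), tolerance = 1e-12)
  expect_error(build_pspm(c("AA", "ACG")), class = "seedmotif_shape_error")
  expect_error(build_pspm(character(0)),
               class = "seedmotif_degenerate_input")
})

test_that("log weights equal brute-force likelihood ratios for all 4^W segments", {
  bgU <- fix_background(order = 0, seed = 5)
  withr::with_seed(41, {
    m <- matrix(stats::runif(4 * 3) + 0.02, 4, 3)
  })
  m <- sweep(m, 2, colSums(m), "/")
  pp <- seedmotif:::new_pspm(m)
  segs <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  for (s in segs) {
    code <- match(strsplit(s, "")[[1]], BASES)
    direct <- sum(log(m[cbind(code, 1:3)])) - bg_logprob(s, bgU)
    expect_equal(log_weight(s, pp, bgU), direct)
  }
  # likelihood ratio 1 => 0 (against an exactly uniform background)
  bg_exact <- train_background("ACGTACGT", order = 0, pseudocount = 0)
  punif <- seedmotif:::new_pspm(matrix(0.25, 4, 3))
  expect_equal(log_weight("ACG", punif, bg_exact), 0, tolerance = 1e-12)
  # point-mass mismatch => -Inf
  ppoint <- build_pspm(c("AAA"), pseudocount = 0)
  expect_identical(log_weight("CAA", ppoint, bgU), -Inf)
  expect_error(log_weight("AC", pp, bgU), class = "seedmotif_shape_error")
})

test_that("ll score is the additive sum over instances", {
  bgU <- fix_background(order = 0, seed = 5)
  pp <- build_pspm(c("AC", "AG", "AC"), pseudocount = 0.4)
  expect_identical(ll_score(character(0), pp, bgU), 0)
  inst <- c("AC", "AG", "AC")
  hand <- sum(vapply(inst, log_weight, numeric(1), pspm = pp, bg = bgU))
  expect_equal(ll_score(inst, pp, bgU), hand)
  expect_equal(ll_score(c(inst, inst), pp, bgU), 2 * hand)
})

test_that("IUPAC consensus follows the single/pair thresholds", {
  expect_equal(consensus_iupac(build_pspm(rep("ACGTA", 4), pseudocount = 0)),
               "ACGTA")
  r_col <- seedmotif:::new_pspm(matrix(c(0.5, 0.05, 0.4, 0.05), 4, 1))
  expect_equal(consensus_iupac(r_col), "r")
  expect_equal(consensus_iupac(seedmotif:::new_pspm(matrix(0.25, 4, 1))), "n")
})

test_that("information content has its closed-form values", {
  expect_equal(information_content(seedmotif:::new_pspm(matrix(0.25, 4, 2))), 0)
  one <- seedmotif:::new_pspm(matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(information_content(one), 2)
  two <- seedmotif:::new_pspm(matrix(c(0.5, 0.5, 0, 0, 1, 0, 0, 0), 4, 2))
  expect_equal(information_content(two), 3)
})

test_that("KL distance is a symmetric premetric with RC orientation handling", {
  a <- seedmotif:::new_pspm(matrix(c(0.7, 0.1, 0.1, 0.1), 4, 1))
  b <- seedmotif:::new_pspm(matrix(0.25, 4, 1))
  hand <- (sum(c(0.7, 0.1, 0.1, 0.1) * log(c(0.7, 0.1, 0.1, 0.1) / 0.25)) +
             sum(0.25 * log(0.25 / c(0.7, 0.1, 0.1, 0.1)))) / 2
  expect_equal(kl_distance(a, b), hand)
  expect_equal(kl_distance(a, a), 0)
  withr::with_seed(7, {
    for (i in 1:10) {
      ma <- matrix(stats::runif(4 * 6) + 0.05, 4, 6)
      mb <- matrix(stats::runif(4 * 6) + 0.05, 4, 6)
      pa <- seedmotif:::new_pspm(sweep(ma, 2, colSums(ma), "/"))
      pb <- seedmotif:::new_pspm(sweep(mb, 2, colSums(mb), "/"))
      expect_equal(kl_distance(pa, pb), kl_distance(pb, pa))
      expect_gte(kl_distance(pa, pb), 0)
      # a PSPM is at distance 0 from its own reverse complement
      expect_equal(kl_distance(pa, seedmotif:::rc_pspm(pa)), 0)
    }
  })
  wrong <- seedmotif:::new_pspm(matrix(0.25, 4, 2))
  expect_error(kl_distance(a, wrong), class = "seedmotif_shape_error")
  zero <- seedmotif:::new_pspm(matrix(c(1, 0, 0, 0), 4, 1))
  expect_error(kl_distance(zero, b), class = "seedmotif_degenerate_input")
})

test_that("motif ranking groups perturbed families at the KL threshold", {
  bgU <- fix_background(order = 0, seed = 5)
  mk <- function(pspm, ll) seedmotif:::new_motif_result(
    pspm, data.frame(), ll)
  base_a <- fix_pspm(dom = 0.9)
  base_b <- fix_pspm(motif = "TTTTTTTTTTGGGGGGGGGG", dom = 0.9)
  perturb <- function(p, eps, seed) {
    withr::with_seed(seed, {
      m <- p$matrix + matrix(stats::runif(length(p$matrix), 0, eps),
                             nrow = 4)
    })
    seedmotif:::new_pspm(sweep(m, 2, colSums(m), "/"))
  }
  fam_a <- lapply(1:3, function(i) perturb(base_a, 0.02, i))
  fam_b <- lapply(1:2, function(i) perturb(base_b, 0.02, 10 + i))
  # construction check: within-family < 0.9 < between-family
  expect_lt(kl_distance(fam_a[[1]], fam_a[[2]]), 0.9)
  expect_gt(kl_distance(fam_a[[1]], fam_b[[1]]), 0.9)
  motifs <- c(lapply(seq_along(fam_a), function(i) mk(fam_a[[i]], 10 - i)),
              lapply(seq_along(fam_b), function(i) mk(fam_b[[i]], 5 - i)))
  groups <- rank_motifs(motifs, kl_threshold = 0.9)
  expect_length(groups, 2)
  expect_equal(sort(vapply(groups, length, integer(1))), c(2L, 3L))
  # identical motifs fall into one group; distant ones stay apart
  expect_length(rank_motifs(list(mk(base_a, 2), mk(base_a, 1))), 1)
  expect_length(rank_motifs(list(mk(base_a, 2), mk(base_b, 1))), 2)
})

test_that("INCLUSive matrix files round-trip and reject malformed rows", {
  withr::with_seed(3, {
    ps <- lapply(1:3, function(i) {
      m <- matrix(stats::runif(4 * 5) + 0.05, 4, 5)
      seedmotif:::new_pspm(sweep(m, 2, colSums(m), "/"))
    })
  })
  names(ps) <- paste0("motif_", 1:3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_inclusive_matrix(ps, f, scores = list(motif_1 = 1.5, motif_2 = 2,
                                              motif_3 = 0))
  back <- read_inclusive_matrix(f)
  expect_equal(names(back), names(ps))
  for (i in 1:3) {
    expect_lt(max(abs(back[[i]]$matrix - ps[[i]]$matrix)), 1e-5)
  }
  # hand-written W=2 block
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#INCLUSive Motif Model", "", "#ID = toy", "#Score = 1",
               "#W = 2", "0.1 0.2 0.3 0.4", "0.7 0.1 0.1 0.1"), f2)
  toy <- read_inclusive_matrix(f2)
  expect_equal(unname(toy$toy$matrix[, 1]), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(toy$toy$matrix[, 2]), c(0.7, 0.1, 0.1, 0.1))
  # row summing to 0.9 is rejected, naming the line
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#ID = bad", "#W = 1", "0.2 0.3 0.2 0.2"), f3)
  err <- expect_error(read_inclusive_matrix(f3),
                      class = "seedmotif_parse_error")
  expect_match(conditionMessage(err), "line 3")
})

test_that("distribution-valued objects renormalize after any construction", {
  bg <- fix_background(order = 3, seed = 2)
  expect_equal(rowSums(bg$transition), rep(1, 64), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(bg$initial), 1, tolerance = 1e-9)
  p <- build_pspm(c("ACGT", "AGGT", "ACGA"))
  expect_equal(colSums(p$matrix), rep(1, 4), tolerance = 1e-9)
  f <- withr::local_tempfile()
  write_background_json(bg, f)
  bg2 <- read_background_json(f)
  expect_equal(bg2$transition, bg$transition, tolerance = 1e-12)
  expect_equal(bg2$order, bg$order)
})
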