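# Motif scanning, hit attribution, and GO-term enrichment statistics.

test_that("posterior-threshold scanning matches brute-force enumeration", {
  withr::with_seed(19, {
    m <- matrix(stats::runif(4 * 5) + 0.05, 4, 5)
  })
  pp <- seedmotif:::new_pspm(sweep(m, 2, colSums(m), "/"))
  bg <- fix_background(order = 2, seed = 3)
  withr::with_seed(20, {
    seqs <- setNames(vapply(1:12, function(i) fix_random_seq(60),
                            character(1)), sprintf("q%02d", 1:12))
  })
  hits <- scan_sequences(seqs, pp, bg, scan_params(prior = 0.7))
  expect_scan_matches_brute(hits, seqs, pp, bg, prior = 0.7)
  expect_true(all(hits$posterior > 0.5))
  # hit condition w > (1-pi)/pi verified on the reported weights
  expect_true(all(exp(hits$log_weight) > 3 / 7))
})

test_that("a planted consensus yields exactly one forward hit; tiny priors none", {
  pp <- fix_pspm(motif = "GCTATGCGGT", dom = 0.97)
  bg <- fix_background(order = 0, seed = 4)
  withr::with_seed(22, s <- fix_random_seq(120))
  s <- paste0(substr(s, 1, 49), "GCTATGCGGT", substr(s, 60, 120))
  hits <- scan_sequences(c(one = s), pp, bg, scan_params(prior = 0.7))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 49L)
  expect_equal(hits$strand, 1L)
  # a prior so small that no window can pass
  toy <- seedmotif:::new_pspm(matrix(c(0.4, 0.3, 0.2, 0.1,
                                       0.1, 0.2, 0.3, 0.4), 4, 2))
  none <- scan_sequences(c(one = s), toy, bg, scan_params(prior = 1e-9))
  expect_equal(nrow(none), 0)
})

test_that("hits are attributed to genes through promoters with sharing", {
  df <- seedmotif:::empty_promoter_df()
  ps <- rbind(df, data.frame(
    promoter_id = c("pA", "pAB"), start = c(0L, 400L), end = c(281L, 700L),
    strand = c(1L, 1L), sequence = c(strrep("A", 281), strrep("C", 300)),
    win_start = c(-250L, NA), win_end = c(30L, NA),
    shared = c(FALSE, TRUE)))
  ps$gene_ids <- list("gA", c("gX", "gY"))
  ps <- seedmotif:::new_promoter_set(ps, "toy")
  hits2 <- data.frame(seq_id = c("pA", "pA"), start = c(1L, 30L),
                      strand = 1L, segment = "x", log_weight = 1,
                      posterior = 0.9)
  expect_equal(attribute_hits(hits2, ps), "gA")
  hit_shared <- data.frame(seq_id = "pAB", start = 5L, strand = -1L,
                           segment = "x", log_weight = 1, posterior = 0.9)
  expect_equal(attribute_hits(hit_shared, ps), c("gX", "gY"))
  expect_equal(attribute_hits(hits2[0, ], ps), character(0))
  bad <- data.frame(seq_id = "nope", start = 1L, strand = 1L, segment = "x",
                    log_weight = 1, posterior = 0.9)
  expect_error(attribute_hits(bad, ps), class = "seedmotif_key_error")
})

test_that("hypergeometric upper tails are exact", {
  expect_equal(hypergeom_pvalue(0, 5, 3, 10), 1)
  expect_equal(hypergeom_pvalue(1, 1, 4, 10), 0.4)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / choose(10, 5))
  expect_error(hypergeom_pvalue(6, 5, 5, 10),
               class = "seedmotif_domain_error")
  # non-increasing in x
  p_seq <- vapply(0:5, hypergeom_pvalue, numeric(1), n = 5, M = 6, N = 12)
  expect_true(all(diff(p_seq) <= 0))
  # spot subset-enumeration checks (the full sweep runs in the acceptance
  # suite)
  for (case in list(c(2, 3, 4, 9), c(1, 2, 5, 8), c(3, 4, 4, 10))) {
    expect_equal(hypergeom_pvalue(case[1], case[2], case[3], case[4]),
                 brute_hypergeom(case[1], case[2], case[3], case[4]))
  }
})

toy_annotation <- function(n_genes = 60, seed = 31) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  sim <- simulate_go_annotation(genes, n_terms = 8,
                                target_genes = genes[1:10],
                                enrichment_prob = 0.9,
                                background_prob = 0.05, seed = seed)
  go_annotation(sim$gaf, sim$obo, population = genes)
}

test_that("GAF and OBO parse and ancestors propagate", {
  genes <- sprintf("g%03d", 1:40)
  td <- withr::local_tempdir()
  sim <- simulate_go_annotation(genes, n_terms = 6,
                                target_genes = genes[1:8],
                                enrichment_prob = 1, background_prob = 0,
                                seed = 8, out_dir = td)
  obo <- read_obo(file.path(td, "ontology.obo"))
  expect_true(all(sim$obo$terms %in% obo$terms))
  gaf <- read_gaf(file.path(td, "annotation.gaf"))
  expect_equal(sort(unique(gaf$term_id)), sort(unique(sim$gaf$term_id)))
  ann <- go_annotation(gaf, obo, population = genes)
  # propagation closure: each gene carrying a term carries its ancestors
  anc <- seedmotif:::obo_ancestors(obo)
  for (g in utils::head(names(ann$gene2terms), 10)) {
    terms <- ann$gene2terms[[g]]
    expect_true(all(unlist(anc[terms]) %in% terms))
  }
})

test_that("permutation correction is deterministic, monotone and conservative", {
  ann <- toy_annotation()
  study <- ann$population[1:10]
  pars <- enrichment_params(permutation_runs = 60, seed = 5)
  c1 <- permutation_correct(study, ann, pars)
  c2 <- permutation_correct(study, ann, pars)
  expect_identical(c1, c2)
  raw <- seedmotif:::term_pvalues(study, ann)$p
  expect_true(all(c1 >= raw - 1e-12))
  expect_true(all(c1 > 0 & c1 <= 1))
  # a term with raw p = 1 stays at 1
  expect_true(all(abs(c1[raw == 1] - 1) < 1e-12))
  expect_error(permutation_correct(sprintf("zz%04d", 1:1000), ann, pars),
               class = "seedmotif_domain_error")
})

test_that("simulation FDR behaves at its boundaries", {
  ann <- toy_annotation()
  study <- ann$population[1:10]
  pars <- enrichment_params(permutation_runs = 80, seed = 6)
  fdr <- fdr_percent(study, ann, pars)
  raw <- seedmotif:::term_pvalues(study, ann)$p
  expect_true(all(fdr >= 0 & fdr <= 100))
  # the planted term's p beats every simulated minimum: FDR 0
  expect_equal(unname(fdr[which.min(raw)]), 0)
})

test_that("the enrichment table mirrors the published layout and truncation", {
  ann <- toy_annotation()
  study <- ann$population[1:10]
  et <- enrichment_table(study, ann,
                         enrichment_params(permutation_runs = 50, seed = 2))
  expect_true(all(et$x_hits >= 1))
  expect_true(all(et$x_hits <= et$n_hits))
  expect_true(all(et$M_genome <= et$N_genome))
  expect_equal(et$pct_hits,
               floor(et$x_hits / et$n_hits * 1e4 + 1e-9) / 100)
  expect_equal(et$pct_genome,
               floor(et$M_genome / et$N_genome * 1e4 + 1e-9) / 100)
  expect_true(is.logical(attr(et, "qualified")))
  # saturated term: x = n, M = N
  genes <- sprintf("s%02d", 1:12)
  gaf <- data.frame(gene_id = genes, term_id = "GO:0000111")
  obo <- list(terms = "GO:0000111", name = c("GO:0000111" = "all"),
              parents = list("GO:0000111" = character(0)))
  ann_sat <- go_annotation(gaf, obo, population = genes)
  et_sat <- enrichment_table(genes, ann_sat,
                             enrichment_params(permutation_runs = 20,
                                               seed = 1))
  expect_equal(et_sat$p_raw, 1)
  expect_equal(et_sat$pct_hits, 100)
  expect_equal(et_sat$pct_genome, 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(et, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(nrow(back), nrow(et))
  expect_equal(names(back)[1:2], c("GO id", "Term"))
})

test_that("planted enrichment is detected and terms below 2 genes never qualify", {
  genes <- sprintf("g%03d", 1:300)
  sim <- simulate_go_annotation(genes, n_terms = 12,
                                target_genes = genes[1:25],
                                enrichment_prob = 0.6,
                                background_prob = 0.05, seed = 41)
  ann <- go_annotation(sim$gaf, sim$obo, population = genes)
  et <- enrichment_table(genes[1:25], ann,
                         enrichment_params(permutation_runs = 100, seed = 3))
  expect_true(sim$truth$enriched_term %in% et$term_id[et$qualified])
  expect_true(all(et$M_genome[et$qualified] >= 2))
})
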