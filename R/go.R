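# Gene Ontology machinery: OBO parsing, GAF reading, ancestor propagation,
# and the motif-qualification statistic -- hypergeometric term
# over-representation with permutation-corrected p-values and a simulation
# false-discovery rate.

#' Parse a (minimal) OBO ontology
#'
#' Reads `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of` lines; obsolete terms are dropped. This is the
#' subset needed for ancestor propagation.
#'
#' @param path OBO file path.
#' @return list with `terms` (ids), `name` (id -> name), `parents`
#'   (id -> character vector of is_a/part_of parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0)
  name <- character(0)
  parents <- list()
  cur <- NULL
  cur_name <- NA_character_
  cur_par <- character(0)
  obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      name[cur] <<- cur_name
      parents[[cur]] <<- cur_par
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_name <- NA_character_
      cur_par <- character(0); obsolete <- FALSE
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # some other stanza type
      flush()
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur_name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      cur_par <- c(cur_par, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      cur_par <- c(cur_par, trimws(sub("!.*$", "",
                                       sub("^relationship:\\s*part_of", "", ln))))
    } else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
  }
  flush()
  list(terms = terms, name = name, parents = parents)
}

# Transitive closure of ancestors (is_a / part_of), self excluded.
obo_ancestors <- function(obo) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- obo$parents[[t]] %||% character(0)
    ps <- ps[ps %in% obo$terms]
    anc <- ps
    for (p in ps) anc <- union(anc, get_anc(p))
    memo[[t]] <- anc
    anc
  }
  setNames(lapply(obo$terms, get_anc), obo$terms)
}

#' Read a GAF 2.x annotation file
#'
#' Comment lines (`!`) are skipped; column 2 (DB object id) is the gene id
#' and column 5 the GO term id. `NOT`-qualified rows are dropped.
#'
#' @param path GAF file path.
#' @return data frame with `gene_id` and `term_id`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(fields, `[`, character(1), 2L)
  qual <- vapply(fields, `[`, character(1), 4L)
  term <- vapply(fields, `[`, character(1), 5L)
  keep <- !grepl("NOT", qual)
  data.frame(gene_id = gene[keep], term_id = term[keep],
             stringsAsFactors = FALSE)
}

#' Build a propagated GO annotation object
#'
#' Direct gene-term pairs are propagated up the ontology (is_a / part_of
#' closure), so a gene annotated with a term is annotated with every
#' ancestor. The population is the set of annotated genes unless given.
#'
#' @param gaf data frame (`gene_id`, `term_id`) or GAF path.
#' @param obo parsed ontology from [read_obo()] or OBO path.
#' @param population optional character vector fixing the gene population;
#'   defaults to all annotated genes.
#' @return a `go_annotation`: `gene2terms` (list), `term2genes` (list),
#'   `term_name`, `population`, `membership` (logical gene x term matrix).
#' @export
go_annotation <- function(gaf, obo, population = NULL) {
  if (is.character(gaf)) gaf <- read_gaf(gaf)
  if (is.character(obo)) obo <- read_obo(obo)
  anc <- obo_ancestors(obo)
  gaf <- gaf[gaf$term_id %in% obo$terms, , drop = FALSE]
  pairs <- split(gaf$term_id, gaf$gene_id)
  gene2terms <- lapply(pairs, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  genes <- names(gene2terms)
  if (is.null(population)) population <- genes
  population <- sort(unique(population))
  terms <- sort(unique(unlist(gene2terms, use.names = FALSE)))
  member <- matrix(FALSE, nrow = length(population), ncol = length(terms),
                   dimnames = list(population, terms))
  for (g in intersect(genes, population)) {
    member[g, gene2terms[[g]]] <- TRUE
  }
  structure(list(gene2terms = gene2terms,
                 term2genes = apply(member, 2L, function(v)
                   population[v], simplify = FALSE),
                 term_name = obo$name,
                 population = population,
                 membership = member),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("GO annotation:", length(x$population), "population genes,",
      ncol(x$membership), "terms (propagated)\n")
  invisible(x)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, M, n)`: drawing `n` genes from a
#' population of `N` of which `M` carry the term, the probability of seeing
#' at least the observed `x` carriers.
#'
#' @param x observed count of term-carrying genes in the study set.
#' @param n study-set size.
#' @param M term-carrying genes in the population.
#' @param N population size.
#' @return exact upper-tail probability.
#' @export
hypergeom_pvalue <- function(x, n, M, N) {
  if (any(x < 0 | n < 0 | M < 0 | N < 0) || any(x > pmin(n, M)) ||
      any(n > N) || any(M > N)) {
    abort_seedmotif("invalid hypergeometric arguments", "seedmotif_domain_error")
  }
  phyper(x - 1, M, N - M, n, lower.tail = FALSE)
}

# Raw p-values for every term given a study gene set (vectorized over the
# membership matrix). Genes outside the population are ignored.
term_pvalues <- function(study_genes, annotation) {
  member <- annotation$membership
  study <- intersect(unique(study_genes), annotation$population)
  n <- length(study)
  N <- length(annotation$population)
  M <- colSums(member)
  x <- if (n > 0L) colSums(member[study, , drop = FALSE]) else rep(0L, ncol(member))
  p <- phyper(x - 1, M, N - M, n, lower.tail = FALSE)
  list(p = p, x = x, n = n, M = M, N = N)
}

#' Enrichment parameter set
#'
#' @param p_threshold_raw raw hypergeometric p-value filter (default 0.1).
#' @param p_threshold_corrected corrected p-value threshold for the
#'   qualification verdict (default 0.05).
#' @param permutation_runs number of simulated study sets (default 1000).
#' @param seed RNG seed for the permutations.
#' @return an `enrichment_params` list.
#' @export
enrichment_params <- function(p_threshold_raw = 0.1,
                              p_threshold_corrected = 0.05,
                              permutation_runs = 1000L, seed = 1L) {
  stopifnot(p_threshold_raw > 0, p_threshold_raw < 1,
            p_threshold_corrected > 0, p_threshold_corrected < 1,
            permutation_runs >= 1L)
  structure(list(p_threshold_raw = p_threshold_raw,
                 p_threshold_corrected = p_threshold_corrected,
                 permutation_runs = as.integer(permutation_runs),
                 seed = as.integer(seed)),
            class = "enrichment_params")
}

# Simulated raw p-value matrix: one row per permutation run, one column per
# term, for study sets drawn uniformly without replacement from the
# population. Shared by the corrected-p and FDR estimators.
simulate_null_pvalues <- function(n_study, annotation, runs, seed) {
  member <- annotation$membership
  N <- length(annotation$population)
  M <- colSums(member)
  with_rng(seed, {
    t(vapply(seq_len(runs), function(r) {
      idx <- sample.int(N, n_study)
      x <- colSums(member[idx, , drop = FALSE])
      phyper(x - 1, M, N - M, n_study, lower.tail = FALSE)
    }, numeric(ncol(member))))
  })
}

#' Permutation-corrected p-values for GO terms
#'
#' For each simulation run a study set of the same size is drawn uniformly
#' without replacement from the population and the minimum raw p over terms
#' recorded; the corrected p of term t is
#' `(1 + #\{runs with min p <= p_raw(t)\}) / (runs + 1)` -- a family-wise
#' estimate that is always at least the raw p.
#'
#' @param study_genes character vector of study gene ids (must lie in the
#'   population).
#' @param annotation a `go_annotation`.
#' @param params an [enrichment_params()] list.
#' @param null_p optional precomputed matrix from the internal simulator
#'   (reused by [enrichment_table()]).
#' @return named numeric vector of corrected p-values per term.
#' @export
permutation_correct <- function(study_genes, annotation,
                                params = enrichment_params(),
                                null_p = NULL) {
  study <- intersect(unique(study_genes), annotation$population)
  if (length(unique(study_genes)) >
      length(annotation$population)) {
    abort_seedmotif("study set larger than the population",
                    "seedmotif_domain_error")
  }
  obs <- term_pvalues(study, annotation)
  if (is.null(null_p)) {
    null_p <- simulate_null_pvalues(obs$n, annotation,
                                    params$permutation_runs, params$seed)
  }
  minp <- apply(null_p, 1L, min)
  runs <- nrow(null_p)
  corrected <- vapply(obs$p, function(p0) {
    (1 + sum(minp <= p0)) / (runs + 1)
  }, numeric(1))
  pmax(corrected, obs$p) # monotone: corrected >= raw
}

#' Simulation false-discovery rate (percent) for GO terms
#'
#' GO::TermFinder-style: for term t with raw p-value p(t) and rank r(t)
#' among observed terms ordered by raw p, FDR% is 100 times the mean number
#' of simulated terms per run with p <= p(t), divided by r(t).
#'
#' @inheritParams permutation_correct
#' @return named numeric vector of FDR percentages per term.
#' @export
fdr_percent <- function(study_genes, annotation,
                        params = enrichment_params(), null_p = NULL) {
  study <- intersect(unique(study_genes), annotation$population)
  obs <- term_pvalues(study, annotation)
  if (is.null(null_p)) {
    null_p <- simulate_null_pvalues(obs$n, annotation,
                                    params$permutation_runs, params$seed)
  }
  rank_t <- vapply(obs$p, function(p0) sum(obs$p <= p0), numeric(1))
  fp_mean <- vapply(obs$p, function(p0) mean(rowSums(null_p <= p0)),
                    numeric(1))
  pct <- 100 * fp_mean / pmax(rank_t, 1)
  pmin(pmax(pct, 0), 100) # a rate: clamped to [0, 100]
}

#' Build a Table-4-style GO enrichment table
#'
#' One row per term annotating at least one study gene: term, raw and
#' permutation-corrected p-values, simulation FDR%, study counts `x/n` and
#' population counts `M/N` with percentages truncated (not rounded) to two
#' decimals. A term is `qualified` when its raw p passes
#' `p_threshold_raw`, its corrected p passes `p_threshold_corrected`, and it
#' annotates at least 2 population genes; the motif is qualified iff any
#' term is.
#'
#' @inheritParams permutation_correct
#' @return data frame of `enrichment_row`s sorted by raw p, with attribute
#'   `qualified` (logical motif verdict).
#' @export
enrichment_table <- function(study_genes, annotation,
                             params = enrichment_params()) {
  study <- intersect(unique(study_genes), annotation$population)
  obs <- term_pvalues(study, annotation)
  null_p <- simulate_null_pvalues(obs$n, annotation,
                                  params$permutation_runs, params$seed)
  corrected <- permutation_correct(study, annotation, params, null_p)
  fdr <- fdr_percent(study, annotation, params, null_p)
  keep <- obs$x >= 1L
  terms <- colnames(annotation$membership)[keep]
  df <- data.frame(
    term_id = terms,
    term_name = unname(annotation$term_name[terms]),
    p_raw = unname(obs$p[keep]),
    p_corrected = unname(corrected[keep]),
    fdr_pct = unname(fdr[keep]),
    x_hits = unname(as.integer(obs$x[keep])),
    n_hits = obs$n,
    pct_hits = truncate_pct(unname(obs$x[keep]) / obs$n),
    M_genome = unname(as.integer(obs$M[keep])),
    N_genome = obs$N,
    pct_genome = truncate_pct(unname(obs$M[keep]) / obs$N),
    stringsAsFactors = FALSE)
  df$qualified <- df$p_raw <= params$p_threshold_raw &
    df$p_corrected <= params$p_threshold_corrected &
    df$M_genome >= 2L
  df <- df[order(df$p_raw, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "qualified") <- any(df$qualified)
  df
}

#' Write an enrichment table as TSV (Table-4 column order)
#'
#' @param table data frame from [enrichment_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  out <- data.frame(
    `GO id` = table$term_id, Term = table$term_name,
    `Corrected p-value` = table$p_corrected, `FDR (%)` = table$fdr_pct,
    `Enrichment in hits` = paste0(table$x_hits, "/", table$n_hits),
    `Percentage in hits` = table$pct_hits,
    `Enrichment in genome` = paste0(table$M_genome, "/", table$N_genome),
    `Percentage in genome` = table$pct_genome,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
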