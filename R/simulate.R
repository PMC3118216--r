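# Synthetic-data generators: toy genomes with planted gene layouts, promoter
# pools with motif instances planted from a known PSPM, and GO annotations
# with controlled term enrichment. Every generator is a pure function of its
# parameters and seed and emits machine-readable ground truth alongside the
# data, so downstream tests consume truth rather than re-deriving it.

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# Draw one sequence of given length from a background model.
sample_from_background <- function(length, bg) {
  k <- bg$order
  if (length == 0L) return("")
  code <- integer(length)
  if (k == 0L) {
    code <- sample.int(4L, length, replace = TRUE, prob = bg$transition[1L, ])
  } else {
    first <- sample.int(4L^k, 1L, prob = bg$initial)
    # decode k-mer id to base codes, first base most significant
    rem <- first - 1L
    kmer <- integer(k)
    for (j in k:1) {
      kmer[j] <- rem %% 4L + 1L
      rem <- rem %/% 4L
    }
    code[seq_len(min(k, length))] <- kmer[seq_len(min(k, length))]
    if (length > k) {
      for (i in (k + 1L):length) {
        ctx <- context_id(code[(i - k):(i - 1L)], k)
        code[i] <- sample.int(4L, 1L, prob = bg$transition[ctx, ])
      }
    }
  }
  decode_dna(code)
}

sample_from_pspm <- function(pspm) {
  paste(vapply(seq_len(pspm$width), function(j) {
    sample(DNA_BASES, 1L, prob = pspm$matrix[, j])
  }, character(1)), collapse = "")
}

#' Plant specification for motif instances
#'
#' @param pspm the motif model instances are drawn from.
#' @param occupancy fraction of sequences carrying an instance (Bernoulli per
#'   sequence).
#' @param position_mode `"uniform"` or `"fixed"` (plant at `offset`).
#' @param offset 0-based planting index used when `position_mode = "fixed"`;
#'   index 66 of a 281-long promoter is seed offset -184.
#' @param strand_mode `"both"` (random strand) or `"forward"`.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(pspm, occupancy = 1, position_mode = c("uniform", "fixed"),
                       offset = 66L, strand_mode = c("both", "forward")) {
  position_mode <- match.arg(position_mode)
  strand_mode <- match.arg(strand_mode)
  stopifnot(occupancy >= 0, occupancy <= 1)
  structure(list(pspm = pspm, occupancy = occupancy,
                 position_mode = position_mode, offset = as.integer(offset),
                 strand_mode = strand_mode),
            class = "plant_spec")
}

#' Simulate a toy annotated genome
#'
#' Genes are packed left to right with controlled strandedness: about
#' `divergent_fraction` of disjoint adjacent gene pairs are laid out
#' divergently (strands -,+) with an intergenic gap under 500 bp, so the
#' shared-promoter rule fires; all other gaps are kept wide enough that
#' plain -250..+30 windows neither overlap each other nor the divergent
#' gaps. The truth lists the promoter intervals the extractor is expected to
#' produce.
#'
#' @param n_genes number of genes.
#' @param length genome length in bp (enlarged if the layout cannot pack).
#' @param divergent_fraction target fraction of adjacent disjoint pairs laid
#'   out divergently.
#' @param seed RNG seed.
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `genes.gff3` and `truth.json` into it.
#' @return list with `sequence`, `genes` data frame, `truth` (expected
#'   promoters), and `paths` when written.
#' @export
simulate_genome <- function(n_genes, length = NULL, divergent_fraction = 0.5,
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_genes >= 0, divergent_fraction >= 0, divergent_fraction <= 1)
  with_rng(seed, {
    genes <- data.frame(gene_id = character(), strand = integer(),
                        tss = integer(), start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
    truth_shared <- list()
    pos <- 400L # room for the first gene's upstream window
    if (n_genes > 0L) {
      n_pairs <- floor(n_genes / 2)
      divergent_pair <- rep(FALSE, n_pairs)
      if (n_pairs > 0L && divergent_fraction > 0) {
        k <- round(divergent_fraction * n_pairs)
        if (k > 0L) divergent_pair[sample.int(n_pairs, k)] <- TRUE
      }
      gi <- 0L
      make_gene <- function(id, strand, start, len) {
        data.frame(gene_id = id, strand = strand, tss = NA_integer_,
                   start = start, end = start + len,
                   stringsAsFactors = FALSE)
      }
      i <- 1L
      while (gi < n_genes) {
        pair_idx <- (gi %/% 2L) + 1L
        two_left <- (n_genes - gi) >= 2L
        if (two_left && pair_idx <= n_pairs && divergent_pair[pair_idx]) {
          len1 <- sample(300:900, 1L)
          len2 <- sample(300:900, 1L)
          gap <- sample(100:480, 1L)
          g1 <- make_gene(sprintf("g%03d", gi + 1L), -1L, pos, len1)
          g2 <- make_gene(sprintf("g%03d", gi + 2L), 1L, pos + len1 + gap, len2)
          genes <- rbind(genes, g1, g2)
          truth_shared[[length(truth_shared) + 1L]] <- list(
            gene_ids = c(g1$gene_id, g2$gene_id),
            start = g1$end, end = g2$start)
          pos <- g2$end + 700L # clearance: no window/window interactions
          gi <- gi + 2L
        } else {
          len1 <- sample(300:900, 1L)
          strand <- sample(c(-1L, 1L), 1L)
          g1 <- make_gene(sprintf("g%03d", gi + 1L), strand, pos, len1)
          genes <- rbind(genes, g1)
          pos <- g1$end + 700L
          gi <- gi + 1L
        }
      }
    }
    need <- pos + 400L
    L <- max(length %||% need, need)
    seq <- random_dna(L)
    genes$tss <- ifelse(genes$strand == 1L, genes$start, genes$end - 1L)
    # expected promoter intervals under the -250..+30 window (independent
    # re-application of the layout arithmetic; the wide clearances make
    # truncation a non-event except inside divergent pairs, whose windowed
    # promoters are replaced by the shared gap)
    shared_genes <- unlist(lapply(truth_shared, `[[`, "gene_ids"))
    truth_prom <- list()
    for (s in truth_shared) {
      truth_prom[[paste(s$gene_ids, collapse = "-")]] <- list(
        gene_ids = s$gene_ids, start = s$start, end = s$end, shared = TRUE)
    }
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      if (gid %in% shared_genes) next
      tss <- genes$tss[i]
      if (genes$strand[i] == 1L) {
        iv <- c(max(0L, tss - 250L), min(L, tss + 31L))
      } else {
        iv <- c(max(0L, tss - 30L), min(L, tss + 251L))
      }
      truth_prom[[gid]] <- list(gene_ids = gid, start = iv[1], end = iv[2],
                                shared = FALSE)
    }
    truth <- list(genome_length = L, promoters = truth_prom)
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(out_dir, "genome.fa")
      gff <- file.path(out_dir, "genes.gff3")
      tj <- file.path(out_dir, "truth.json")
      dss <- Biostrings::DNAStringSet(seq)
      names(dss) <- "toygenome"
      Biostrings::writeXStringSet(dss, fa)
      write_gff3_genes(genes, "toygenome", gff)
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- list(genome = fa, gff = gff, truth = tj)
    }
    list(genome_id = "toygenome", sequence = seq, genes = genes,
         truth = truth, paths = paths)
  })
}

write_gff3_genes <- function(genes, seqid, path) {
  header <- "##gff-version 3"
  body <- sprintf(
    "%s\tseedmotif\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
    seqid, genes$start + 1L, genes$end,
    ifelse(genes$strand == 1L, "+", "-"),
    genes$gene_id, genes$gene_id)
  writeLines(c(header, header_region(seqid, genes), body), path)
  invisible(path)
}

header_region <- function(seqid, genes) {
  if (nrow(genes) == 0L) return(character(0))
  sprintf("##sequence-region %s 1 %d", seqid, max(genes$end) + 400L)
}

#' Simulate a promoter pool with optional planted motif instances
#'
#' Background sequence is drawn from a Markov background model; when a
#' [plant_spec()] is given, each sequence independently carries a motif
#' instance (probability `occupancy`) sampled column-wise from the PSPM,
#' placed uniformly or at a fixed index, on a random or forward strand.
#'
#' @param n number of promoters.
#' @param length promoter length in bp (default 281, the -250..+30 window).
#' @param bg a `background_model` for the non-motif sequence.
#' @param plant a [plant_spec()] or `NULL`.
#' @param seed RNG seed.
#' @param ids optional sequence ids (default `prom001`...).
#' @param out_dir optional directory for `promoters.fa` + `truth.json`.
#' @return list with `seqs` (named character vector) and `truth` (data frame
#'   `seq_id`, `planted`, `start`, `strand`, `segment`).
#' @export
simulate_promoters <- function(n, length = 281L, bg, plant = NULL, seed = 1L,
                               ids = NULL, out_dir = NULL) {
  if (!is.null(plant) && plant$pspm$width > length) {
    abort_seedmotif("motif width exceeds promoter length",
                    "seedmotif_generator_error")
  }
  ids <- ids %||% sprintf("prom%03d", seq_len(n))
  with_rng(seed, {
    seqs <- vapply(seq_len(n), function(i) sample_from_background(length, bg),
                   character(1))
    truth <- data.frame(seq_id = ids, planted = FALSE, start = NA_integer_,
                        strand = NA_integer_, segment = NA_character_,
                        stringsAsFactors = FALSE)
    if (!is.null(plant)) {
      W <- plant$pspm$width
      for (i in seq_len(n)) {
        if (runif(1) >= plant$occupancy) next
        seg <- sample_from_pspm(plant$pspm)
        pos0 <- if (plant$position_mode == "fixed") plant$offset
        else sample.int(length - W + 1L, 1L) - 1L
        strand <- if (plant$strand_mode == "both") sample(c(1L, -1L), 1L)
        else 1L
        ins <- if (strand == 1L) seg else revcomp(seg)
        seqs[i] <- paste0(substr(seqs[i], 1L, pos0),
                          ins,
                          substr(seqs[i], pos0 + W + 1L, length))
        truth$planted[i] <- TRUE
        truth$start[i] <- pos0
        truth$strand[i] <- strand
        truth$segment[i] <- seg
      }
    }
    names(seqs) <- ids
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(out_dir, "promoters.fa")
      tj <- file.path(out_dir, "truth.json")
      dss <- Biostrings::DNAStringSet(seqs)
      Biostrings::writeXStringSet(dss, fa)
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "rows")
      paths <- list(fasta = fa, truth = tj)
    }
    list(seqs = seqs, truth = truth, paths = paths)
  })
}

#' Simulate a GO annotation with one controlled-enrichment term
#'
#' Writes a minimal two-level ontology (leaf terms `is_a` mid-level terms
#' `is_a` a root, so propagation is exercised) and a GAF in which
#' `enriched_term` is attached to `target_genes` with probability
#' `enrichment_prob` and to other genes with `background_prob`; the other
#' terms are attached uniformly at a moderate rate.
#'
#' @param genes character vector of gene ids (the population).
#' @param n_terms number of leaf terms (>= 1).
#' @param enriched_term id of the controlled term (defaults to the first
#'   leaf term id).
#' @param target_genes subset of `genes` the enriched term favors.
#' @param enrichment_prob attach probability on target genes.
#' @param background_prob attach probability on non-target genes.
#' @param other_prob attach probability of every other leaf term on every
#'   gene (default 0.08).
#' @param seed RNG seed.
#' @param out_dir optional directory for `annotation.gaf`, `ontology.obo`,
#'   `truth.json`.
#' @return list with `gaf` data frame, `obo` structure, `truth`, `paths`.
#' @export
simulate_go_annotation <- function(genes, n_terms = 20L,
                                   enriched_term = NULL,
                                   target_genes = character(0),
                                   enrichment_prob = 0.5,
                                   background_prob = 0.05,
                                   other_prob = 0.08,
                                   seed = 1L, out_dir = NULL) {
  stopifnot(all(target_genes %in% genes),
            enrichment_prob >= 0, enrichment_prob <= 1,
            background_prob >= 0, background_prob <= 1, n_terms >= 1L)
  leaf_ids <- sprintf("GO:%07d", 100L + seq_len(n_terms))
  mid_ids <- sprintf("GO:%07d", 10L + seq_len(max(1L, ceiling(n_terms / 5))))
  root_id <- "GO:0000001"
  enriched_term <- enriched_term %||% leaf_ids[1L]
  stopifnot(enriched_term %in% leaf_ids)
  leaf_parent <- mid_ids[((seq_len(n_terms) - 1L) %% length(mid_ids)) + 1L]
  with_rng(seed, {
    rows <- list()
    is_target <- genes %in% target_genes
    for (t in seq_len(n_terms)) {
      tid <- leaf_ids[t]
      pr <- if (tid == enriched_term) {
        ifelse(is_target, enrichment_prob, background_prob)
      } else rep(other_prob, length(genes))
      attach <- runif(length(genes)) < pr
      if (any(attach)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes[attach], term_id = tid, stringsAsFactors = FALSE)
      }
    }
    gaf <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), term_id = character(),
                 stringsAsFactors = FALSE)
    gaf <- gaf[order(gaf$gene_id, gaf$term_id), , drop = FALSE]
    rownames(gaf) <- NULL
    obo <- list(
      terms = c(root_id, mid_ids, leaf_ids),
      name = setNames(c("root", paste0("mid_", seq_along(mid_ids)),
                        paste0("leaf_", seq_len(n_terms))),
                      c(root_id, mid_ids, leaf_ids)),
      parents = c(setNames(list(character(0)), root_id),
                  setNames(lapply(mid_ids, function(x) root_id), mid_ids),
                  setNames(as.list(leaf_parent), leaf_ids)))
    truth <- list(enriched_term = enriched_term,
                  target_genes = target_genes,
                  enrichment_prob = enrichment_prob,
                  background_prob = background_prob,
                  population = genes)
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      gaf_path <- file.path(out_dir, "annotation.gaf")
      obo_path <- file.path(out_dir, "ontology.obo")
      tj <- file.path(out_dir, "truth.json")
      write_gaf(gaf, gaf_path)
      write_obo(obo, obo_path)
      jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
      paths <- list(gaf = gaf_path, obo = obo_path, truth = tj)
    }
    list(gaf = gaf, obo = obo, truth = truth, paths = paths)
  })
}

#' Write a minimal GAF 2.2 / OBO file
#'
#' Unused GAF columns are filled with fixed placeholders; output is
#' byte-stable for a given annotation.
#'
#' @param gaf data frame with `gene_id`, `term_id`.
#' @param obo ontology structure as in [read_obo()]'s return value.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gaf <- function(gaf, path) {
  header <- "!gaf-version: 2.2"
  body <- sprintf(paste0("SEEDMOTIF\t%s\t%s\t\t%s\tSM_REF:0000001\tIEA\t\t",
                         "F\t\t\tprotein\ttaxon:83333\t20240101\tSEEDMOTIF\t\t"),
                  gaf$gene_id, gaf$gene_id, gaf$term_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_gaf
#' @export
write_obo <- function(obo, path) {
  out <- c("format-version: 1.2", "ontology: seedmotif-toy", "")
  for (t in obo$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", obo$name[[t]]))
    for (p in obo$parents[[t]] %||% character(0)) {
      out <- c(out, paste0("is_a: ", p, " ! ", obo$name[[p]]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
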