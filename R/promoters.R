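# Promoter extraction: parse a genome plus gene annotation and produce the
# TSS-relative promoter windows the whole pipeline consumes.
#
# Coordinate conventions: 0-based half-open everywhere inside the package;
# 1-based inclusive only at the GFF3/GenBank/TSS-table boundary. TSS-relative
# offsets run -250..+30 by default with no position 0 (-1 is immediately 5'
# of the TSS base at +1 -- the TSS base itself is offset +1).

#' Read a genome sequence and its gene annotation
#'
#' Accepts a FASTA genome plus a GFF3 annotation, or a GenBank flat file
#' carrying both. Protein-coding features (CDS) become gene records; the TSS
#' defaults to the strand-appropriate start of the coding span and can be
#' overridden with a TSS table (`gene_id`, `tss` 1-based, `strand`).
#'
#' @param genome_source path to a FASTA or GenBank file.
#' @param annotation_source optional path to a GFF3 file (required with FASTA
#'   input unless the GenBank file carries features).
#' @param tss_table optional data frame or TSV path with columns `gene_id`,
#'   `tss` (1-based genomic position of the TSS base) and `strand` (`+`/`-`).
#' @return list with `genome_id`, `sequence` (uppercase character string) and
#'   `genes` (data frame: `gene_id`, `strand` in \{+1,-1\}, `tss`, `start`,
#'   `end`, all genomic 0-based half-open).
#' @export
read_genome_annotation <- function(genome_source, annotation_source = NULL,
                                   tss_table = NULL) {
  first <- readLines(genome_source, n = 1L)
  if (grepl("^LOCUS", first)) {
    parsed <- parse_genbank(genome_source)
    genome_id <- parsed$genome_id
    seq <- parsed$sequence
    genes <- parsed$genes
  } else if (grepl("^>", first)) {
    dss <- Biostrings::readDNAStringSet(genome_source)
    if (length(dss) == 0L || Biostrings::width(dss)[1L] == 0L) {
      abort_seedmotif("empty genome sequence", "seedmotif_empty_input")
    }
    genome_id <- sub("\\s.*$", "", names(dss)[1L])
    seq <- toupper(as.character(dss[[1L]]))
    if (is.null(annotation_source)) {
      abort_seedmotif("FASTA input requires a GFF3 annotation_source",
                      "seedmotif_malformed_annotation")
    }
    genes <- read_gff3_genes(annotation_source)
  } else {
    abort_seedmotif("genome_source is neither FASTA nor GenBank",
                    "seedmotif_malformed_annotation")
  }
  if (nchar(seq) == 0L) {
    abort_seedmotif("empty genome sequence", "seedmotif_empty_input")
  }
  if (!grepl("^[ACGTN]*$", seq)) {
    abort_seedmotif("genome alphabet must be within {A,C,G,T,N}",
                    "seedmotif_malformed_annotation")
  }
  L <- nchar(seq)
  if (nrow(genes) > 0L &&
      (any(genes$start < 0L) || any(genes$end > L) ||
       any(genes$end <= genes$start))) {
    abort_seedmotif("feature coordinates outside the genome sequence",
                    "seedmotif_malformed_annotation")
  }
  # default TSS: strand-appropriate end of the coding span
  genes$tss <- ifelse(genes$strand == 1L, genes$start, genes$end - 1L)
  if (!is.null(tss_table)) {
    tt <- if (is.character(tss_table)) {
      utils::read.table(tss_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else tss_table
    m <- match(genes$gene_id, tt$gene_id)
    hit <- !is.na(m)
    genes$tss[hit] <- as.integer(tt$tss[m[hit]]) - 1L
    genes$strand[hit] <- ifelse(tt$strand[m[hit]] %in% c("+", "+1", "1"),
                                1L, -1L)
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genome_id = genome_id, sequence = seq, genes = genes)
}

read_gff3_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      abort_seedmotif(paste("malformed GFF3 annotation:",
                            conditionMessage(e)),
                      "seedmotif_malformed_annotation")
    })
  types <- as.character(gr$type)
  keep <- types == "CDS"
  if (!any(keep)) keep <- types == "gene"
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$locus_tag %||% gr$Name
    if (is.null(ids)) ids <- alt else ids[is.na(ids)] <- alt[is.na(ids)]
  }
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*")) {
    abort_seedmotif("feature without a strand in GFF3",
                    "seedmotif_malformed_annotation")
  }
  data.frame(
    gene_id = as.character(ids),
    strand = ifelse(strands == "+", 1L, -1L),
    tss = NA_integer_,
    start = BiocGenerics::start(gr) - 1L, # to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file parser: LOCUS name, CDS/gene features with
# optional complement(), /locus_tag or /gene qualifiers, ORIGIN sequence.
parse_genbank <- function(path) {
  lines <- readLines(path)
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]][2L]
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) != 1L) {
    abort_seedmotif("GenBank file lacks a single ORIGIN block",
                    "seedmotif_malformed_annotation")
  }
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_at <- grep("^FEATURES", lines)
  genes <- data.frame(gene_id = character(), strand = integer(),
                      tss = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(feat_at) == 1L) {
    block <- lines[(feat_at + 1L):(origin_at - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (i in seq_along(idx)) {
      hdr <- block[idx[i]]
      parts <- strsplit(trimws(hdr), "\\s+")[[1L]]
      key <- parts[1L]
      if (!key %in% c("CDS")) next
      loc <- parts[2L]
      strand <- if (grepl("complement", loc)) -1L else 1L
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      if (length(nums) < 2L) {
        abort_seedmotif(paste("unparseable GenBank location:", loc),
                        "seedmotif_malformed_annotation")
      }
      from <- min(nums); to <- max(nums)
      quals <- block[(idx[i] + 1L):(if (i < length(idx)) idx[i + 1L] - 1L
                                    else length(block))]
      tag <- NA_character_
      for (q in quals) {
        m <- regmatches(q, regexec('/(locus_tag|gene)="?([^"]+)"?', q))[[1L]]
        if (length(m) == 3L) { tag <- m[3L]; break }
      }
      if (is.na(tag)) tag <- paste0("gene", nrow(genes) + 1L)
      genes <- rbind(genes, data.frame(
        gene_id = tag, strand = strand, tss = NA_integer_,
        start = from - 1L, end = to, stringsAsFactors = FALSE))
    }
  }
  list(genome_id = locus, sequence = seq, genes = genes)
}

new_promoter_set <- function(df, genome_id) {
  structure(df, genome_id = genome_id,
            class = c("promoter_set", "data.frame"))
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set (", nrow(x), " promoters, genome ",
      attr(x, "genome_id") %||% "?", ")\n", sep = "")
  print.data.frame(utils::head(
    x[, c("promoter_id", "start", "end", "strand", "win_start", "win_end")]))
  invisible(x)
}

#' Extract TSS-relative promoter windows from a genome
#'
#' One promoter per gene, spanning offsets `window[1]..window[2]` relative to
#' the TSS (inclusive, no offset 0; default -250..+30, length 281), oriented
#' 5' to 3' toward the gene. Two rules modify the plain windows:
#' * divergent gene pairs (strands -,+ in genome order) whose intergenic gap
#'   is shorter than 500 bp are represented by a single shared promoter
#'   covering the whole gap, attributed to both genes (replacing their
#'   windowed promoters);
#' * no two promoter intervals may overlap: any residual overlap is resolved
#'   by truncating both promoters at the midpoint of the overlapping stretch
#'   (symmetric, hence independent of processing order).
#' Windows are clipped at the genome boundaries; empty results are dropped
#' with a message.
#'
#' @param genes gene data frame as returned by [read_genome_annotation()]
#'   (sorted by `start`).
#' @param genome genome sequence (uppercase character string).
#' @param window inclusive TSS-relative offset pair, default `c(-250, 30)`.
#' @param divergent_max_gap gaps strictly below this (default 500) trigger the
#'   shared-promoter rule.
#' @param genome_id identifier stored on the result.
#' @return a `promoter_set` data frame with columns `promoter_id`, `gene_ids`
#'   (list column), `start`, `end`, `strand`, `sequence`, `win_start`,
#'   `win_end`, `shared`.
#' @export
extract_promoters <- function(genes, genome, window = c(-250L, 30L),
                              divergent_max_gap = 500L, genome_id = "genome") {
  stopifnot(window[1] < window[2])
  L <- nchar(genome)
  n <- nrow(genes)
  if (n == 0L) {
    return(new_promoter_set(empty_promoter_df(), genome_id))
  }
  stopifnot(!is.unsorted(genes$start))
  # pass 1: divergent shared promoters
  shared_idx <- integer(0)
  shared <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      gap_start <- genes$end[i]
      gap_end <- genes$start[i + 1L]
      gap <- gap_end - gap_start
      if (genes$strand[i] == -1L && genes$strand[i + 1L] == 1L &&
          gap > 0L && gap < divergent_max_gap) {
        shared_idx <- c(shared_idx, i, i + 1L)
        shared[[length(shared) + 1L]] <- list(
          gene_ids = c(genes$gene_id[i], genes$gene_id[i + 1L]),
          start = gap_start, end = gap_end)
      }
    }
  }
  rows <- list()
  for (s in shared) {
    rows[[length(rows) + 1L]] <- data.frame(
      promoter_id = paste(s$gene_ids, collapse = "-"),
      start = s$start, end = s$end, strand = 1L,
      win_start = NA_integer_, win_end = NA_integer_,
      shared = TRUE, stringsAsFactors = FALSE)
    rows[[length(rows)]]$gene_ids <- list(s$gene_ids)
  }
  # pass 2: plain windowed promoters for all other genes
  for (i in setdiff(seq_len(n), unique(shared_idx))) {
    tss <- genes$tss[i]
    st <- genes$strand[i]
    if (st == 1L) {
      g_start <- tss + window[1]
      g_end <- tss + window[2] + 1L
    } else {
      g_start <- tss - window[2]
      g_end <- tss - window[1] + 1L
    }
    c_start <- max(0L, g_start)
    c_end <- min(L, g_end)
    if (c_end <= c_start) {
      message("promoter of gene ", genes$gene_id[i],
              " is empty after clipping; dropped")
      next
    }
    # clipped genomic edges pull the stored window offsets in
    if (st == 1L) {
      w_lo <- window[1] + (c_start - g_start)
      w_hi <- window[2] - (g_end - c_end)
    } else {
      w_lo <- window[1] + (g_end - c_end)
      w_hi <- window[2] - (c_start - g_start)
    }
    rows[[length(rows) + 1L]] <- {
      df <- data.frame(
        promoter_id = genes$gene_id[i],
        start = c_start, end = c_end, strand = st,
        win_start = w_lo, win_end = w_hi,
        shared = FALSE, stringsAsFactors = FALSE)
      df$gene_ids <- list(genes$gene_id[i])
      df
    }
  }
  if (length(rows) == 0L) {
    return(new_promoter_set(empty_promoter_df(), genome_id))
  }
  prom <- do.call(rbind, rows)
  prom <- prom[order(prom$start, prom$end), , drop = FALSE]
  # pass 3: midpoint truncation of residual overlaps
  repeat {
    changed <- FALSE
    ord <- order(prom$start, prom$end)
    prom <- prom[ord, , drop = FALSE]
    for (i in seq_len(nrow(prom) - 1L)) {
      a <- i; b <- i + 1L
      if (nrow(prom) < 2L) break
      if (prom$start[b] < prom$end[a]) {
        mid <- (prom$start[b] + prom$end[a]) %/% 2L
        prom <- truncate_promoter(prom, a, new_end = mid)
        prom <- truncate_promoter(prom, b, new_start = mid)
        changed <- TRUE
      }
    }
    keep <- prom$end > prom$start
    if (any(!keep)) {
      message("dropped ", sum(!keep), " promoter(s) emptied by overlap trimming")
      prom <- prom[keep, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  prom$sequence <- vapply(seq_len(nrow(prom)), function(i) {
    sl <- substr(genome, prom$start[i] + 1L, prom$end[i])
    if (prom$strand[i] == -1L) revcomp(sl) else sl
  }, character(1))
  rownames(prom) <- NULL
  new_promoter_set(
    prom[, c("promoter_id", "gene_ids", "start", "end", "strand",
             "sequence", "win_start", "win_end", "shared")],
    genome_id)
}

empty_promoter_df <- function() {
  df <- data.frame(promoter_id = character(), start = integer(),
                   end = integer(), strand = integer(),
                   sequence = character(), win_start = integer(),
                   win_end = integer(), shared = logical(),
                   stringsAsFactors = FALSE)
  df$gene_ids <- list()
  df[, c("promoter_id", "gene_ids", "start", "end", "strand", "sequence",
         "win_start", "win_end", "shared")]
}

# Truncate one promoter row at a new genomic edge, updating its TSS-relative
# window so offset -> index mapping stays exact.
truncate_promoter <- function(prom, i, new_start = NULL, new_end = NULL) {
  if (!is.null(new_start) && new_start > prom$start[i]) {
    d <- new_start - prom$start[i]
    prom$start[i] <- new_start
    if (!prom$shared[i]) {
      if (prom$strand[i] == 1L) prom$win_start[i] <- prom$win_start[i] + d
      else prom$win_end[i] <- prom$win_end[i] - d
    }
  }
  if (!is.null(new_end) && new_end < prom$end[i]) {
    d <- prom$end[i] - new_end
    prom$end[i] <- new_end
    if (!prom$shared[i]) {
      if (prom$strand[i] == 1L) prom$win_end[i] <- prom$win_end[i] - d
      else prom$win_start[i] <- prom$win_start[i] + d
    }
  }
  prom
}

#' Map a TSS-relative offset to a 0-based promoter sequence index
#'
#' `index = offset - win_start`; the inverse mapping is exact. The default
#' window makes offset -250 index 0 and the seed anchor -184..-165 the
#' half-open index interval `[66, 86)`.
#'
#' @param promoter one row of a `promoter_set` (or any list with `win_start`,
#'   `win_end`).
#' @param offset TSS-relative offset within the promoter window.
#' @return 0-based index into the promoter sequence.
#' @export
offset_to_index <- function(promoter, offset) {
  ws <- promoter$win_start
  we <- promoter$win_end
  if (is.na(ws)) {
    abort_seedmotif("shared promoters have no TSS-relative window",
                    "seedmotif_range_error")
  }
  if (offset < ws || offset > we) {
    abort_seedmotif(sprintf("offset %d outside window [%d, %d]",
                            offset, ws, we),
                    "seedmotif_range_error")
  }
  as.integer(offset - ws)
}

#' Promoter set writers
#'
#' FASTA ids are promoter ids; descriptions carry the gene ids and the
#' genomic interval. BED6 intervals are 0-based half-open with the promoter
#' strand.
#'
#' @param promoters a `promoter_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- paste0(
    promoters$promoter_id, " ",
    vapply(promoters$gene_ids, paste, character(1), collapse = ","),
    " ", attr(promoters, "genome_id") %||% "genome",
    ":", promoters$start, "-", promoters$end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
write_promoters_bed <- function(promoters, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   attr(promoters, "genome_id") %||% "genome",
                   promoters$start, promoters$end, promoters$promoter_id,
                   0L, ifelse(promoters$strand == 1L, "+", "-"))
  writeLines(lines, path)
  invisible(path)
}

# Named character vector of promoter sequences (the sampler's input form).
promoter_seqs <- function(promoters) {
  setNames(promoters$sequence, promoters$promoter_id)
}
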