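# Genome-wide motif scanning at a fixed prior and attribution of hits to
# genes. A position/strand is a hit when its posterior probability of being a
# motif occurrence exceeds 0.5, i.e. when the likelihood ratio w exceeds
# (1 - pi) / pi; at the screening prior pi = 0.7 that is w > 3/7.

#' Scan parameter set
#'
#' @param prior prior probability pi of the motif component (default 0.7, the
#'   genome-screening setting).
#' @param strands `"both"` or `"forward"`.
#' @return a `scan_params` list.
#' @export
scan_params <- function(prior = 0.7, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(prior > 0, prior < 1)
  structure(list(prior = prior, strands = strands), class = "scan_params")
}

#' Scan sequences for motif occurrences
#'
#' Scores every length-W window on the requested strands by its likelihood
#' ratio `w = exp(log_weight)` and reports positions with posterior
#' `pi * w / (pi * w + 1 - pi) > 0.5`. Overlapping hits on the same strand of
#' the same sequence are resolved greedily by descending `w` (ties:
#' leftmost, forward first). Windows containing `N` are unscorable and never
#' hit.
#'
#' @param seqs named character vector, `promoter_set`, FASTA path or
#'   `DNAStringSet`.
#' @param pspm a smoothed `pspm`.
#' @param bg a `background_model`.
#' @param params a [scan_params()] list.
#' @return hits data frame: `seq_id`, `start` (0-based), `end`, `strand`,
#'   `segment`, `log_weight`, `posterior`.
#' @export
scan_sequences <- function(seqs, pspm, bg, params = scan_params()) {
  seqs <- as_seq_vector(seqs)
  W <- pspm$width
  pi0 <- params$prior
  thr <- (1 - pi0) / pi0
  logm <- log(pspm$matrix)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    pc <- precompute_candidates(seqs[[i]], W, bg, params$strands)
    if (is.null(pc)) next
    lw <- candidate_log_weights(pc, logm)
    w <- exp(pmin(lw, 700))
    sel <- which(!is.na(w) & w > thr)
    if (length(sel) == 0L) next
    # greedy overlap resolution per strand: best w first, ties leftmost
    keep <- logical(length(sel))
    for (st in unique(pc$strand[sel])) {
      cand <- sel[pc$strand[sel] == st]
      ord <- cand[order(-w[cand], pc$start0[cand])]
      taken_start <- integer(0)
      for (k in ord) {
        s0 <- pc$start0[k]
        if (!any(abs(taken_start - s0) < W)) {
          keep[match(k, sel)] <- TRUE
          taken_start <- c(taken_start, s0)
        }
      }
    }
    sel <- sel[keep]
    rows[[i]] <- data.frame(
      seq_id = names(seqs)[i],
      start = pc$start0[sel], end = pc$start0[sel] + W,
      strand = pc$strand[sel], segment = pc$seg[sel],
      log_weight = lw[sel],
      posterior = pi0 * w[sel] / (pi0 * w[sel] + (1 - pi0)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = integer(),
                      segment = character(), log_weight = numeric(),
                      posterior = numeric(), stringsAsFactors = FALSE)
  }
  ord <- order(out$seq_id, out$start, -out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute scan hits to genes through their promoters
#'
#' Returns the deduplicated union of gene ids over promoters carrying at
#' least one hit; a shared divergent promoter contributes both flanking
#' genes.
#'
#' @param hits data frame from [scan_sequences()] (hit `seq_id`s must be
#'   promoter ids of `promoter_set`).
#' @param promoter_set a `promoter_set`.
#' @return character vector of gene ids, sorted.
#' @export
attribute_hits <- function(hits, promoter_set) {
  if (nrow(hits) == 0L) return(character(0))
  ids <- unique(hits$seq_id)
  m <- match(ids, promoter_set$promoter_id)
  if (anyNA(m)) {
    abort_seedmotif(paste("hit sequence id(s) not found in promoter set:",
                          paste(ids[is.na(m)], collapse = ", ")),
                    "seedmotif_key_error")
  }
  sort(unique(unlist(promoter_set$gene_ids[m])))
}

#' Write hits as BED6 / TSV
#'
#' BED score column carries the log weight.
#'
#' @param hits hits data frame.
#' @param path output file.
#' @param chrom chromosome/sequence name column to use (`seq_id` default).
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, path, chrom = hits$seq_id) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t%s",
                   chrom, hits$start, hits$end, hits$segment,
                   hits$log_weight, ifelse(hits$strand == 1L, "+", "-"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hits_bed
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
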