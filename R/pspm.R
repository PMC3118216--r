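# Position-specific probability matrices (PSPMs) and motif-model arithmetic:
# construction from aligned sites, log-likelihood-ratio scoring against a
# Markov background, IUPAC consensus, information content, Kullback-Leibler
# ranking, and INCLUSive-format I/O.

new_pspm <- function(mat, pseudocount = NA_real_) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    abort_seedmotif("PSPM columns must each sum to 1", "seedmotif_invalid_pspm")
  }
  rownames(mat) <- DNA_BASES
  structure(list(width = ncol(mat), matrix = mat, pseudocount = pseudocount),
            class = "pspm")
}

#' Build a PSPM from aligned motif instances
#'
#' Column j of the matrix is `(count_j + pseudocount * bg0) / (n + pseudocount)`
#' where `bg0` is an order-0 base distribution (uniform by default). With
#' `pseudocount > 0` every entry is strictly positive.
#'
#' @param instances character vector of equal-length DNA strings over ACGT.
#' @param pseudocount total pseudocount mass per column (default 0.1, spread
#'   over the bases by `bg0`).
#' @param bg0 length-4 base distribution used to spread the pseudocount.
#' @return a `pspm` object.
#' @export
build_pspm <- function(instances, pseudocount = 0.1,
                       bg0 = rep(0.25, 4)) {
  if (length(instances) == 0L) {
    abort_seedmotif("cannot build a PSPM from zero instances",
                    "seedmotif_degenerate_input")
  }
  W <- unique(nchar(instances))
  if (length(W) != 1L) {
    abort_seedmotif("motif instances must all have the same length",
                    "seedmotif_shape_error")
  }
  codes <- lapply(instances, encode_dna)
  if (anyNA(unlist(codes))) {
    abort_seedmotif("motif instances must be over the ACGT alphabet",
                    "seedmotif_shape_error")
  }
  counts <- matrix(0, nrow = 4L, ncol = W)
  for (code in codes) {
    counts[cbind(code, seq_len(W))] <- counts[cbind(code, seq_len(W))] + 1
  }
  pspm_from_counts(counts, pseudocount, bg0)
}

pspm_from_counts <- function(counts, pseudocount = 0.1, bg0 = rep(0.25, 4)) {
  n <- colSums(counts)
  mat <- sweep(counts, 2L, n + pseudocount, "/") +
    outer(pseudocount * bg0, n + pseudocount, "/")
  new_pspm(mat, pseudocount)
}

#' @export
print.pspm <- function(x, ...) {
  cat("PSPM, width", x$width, " consensus:", consensus_iupac(x), "\n")
  invisible(x)
}

rc_pspm <- function(pspm) {
  m <- pspm$matrix[4:1, pspm$width:1, drop = FALSE]
  new_pspm(m, pspm$pseudocount)
}

# Motif log-probabilities of all windows of an encoded sequence (forward
# reading). Windows containing N are NA.
pspm_window_logprobs <- function(code, pspm) {
  W <- pspm$width
  L <- length(code)
  n <- L - W + 1L
  if (n < 1L) return(numeric(0L))
  logm <- log(pspm$matrix)
  idx_base <- rep(seq_len(n), W) + rep(0L:(W - 1L), each = n)
  b <- code[idx_base]
  cols <- rep(seq_len(W), each = n)
  vals <- rep(NA_real_, n * W)
  ok <- !is.na(b)
  vals[ok] <- logm[cbind(b[ok], cols[ok])]
  rowSums(matrix(vals, nrow = n, ncol = W))
}

#' Log likelihood ratio of one segment: motif vs background
#'
#' `ln P(x | pspm) - ln P(x | bg)`. The segment is scored as given; reverse
#' strand handling (reverse-complementing the segment) is the caller's job.
#' A base with zero motif probability yields `-Inf`, treated downstream as a
#' non-candidate.
#'
#' @param segment DNA string of length equal to the PSPM width, no `N`.
#' @param pspm a `pspm`.
#' @param bg a `background_model`.
#' @return finite float, or `-Inf` for a zero-likelihood segment.
#' @export
log_weight <- function(segment, pspm, bg) {
  code <- encode_dna(segment)
  if (length(code) != pspm$width) {
    abort_seedmotif("segment length does not match PSPM width",
                    "seedmotif_shape_error")
  }
  if (anyNA(code)) {
    abort_seedmotif("segment contains N and is unscorable",
                    "seedmotif_unscorable")
  }
  lp_m <- sum(log(pspm$matrix[cbind(code, seq_len(pspm$width))]))
  lp_b <- bg_logprob_code(code, bg)
  lp_m - lp_b
}

#' Total log-likelihood score of a motif's instance set
#'
#' Sum over instances of [log_weight()]; an informative index of both motif
#' conservation and the number of occurrences. An empty set scores 0.
#'
#' @param instances character vector of instance segments (strand-oriented),
#'   or a hits data frame with a `segment` column.
#' @param pspm,bg motif and background models.
#' @return the summed log likelihood ratio.
#' @export
ll_score <- function(instances, pspm, bg) {
  if (is.data.frame(instances)) instances <- instances$segment
  if (length(instances) == 0L) return(0)
  sum(vapply(instances, log_weight, numeric(1), pspm = pspm, bg = bg))
}

IUPAC2 <- c(AC = "m", AG = "r", AT = "w", CG = "s", CT = "y", GT = "k")

#' IUPAC consensus string of a PSPM
#'
#' Per column: the single base (uppercase) when its probability is at least
#' `single`; else the lowercase two-base IUPAC code when the top two
#' probabilities sum to at least `pair`; else `n`.
#'
#' @param pspm a `pspm`.
#' @param single threshold for an uppercase single-base call (default 0.66).
#' @param pair threshold for a lowercase two-base call (default 0.75).
#' @return consensus string of length `pspm$width`.
#' @export
consensus_iupac <- function(pspm, single = 0.66, pair = 0.75) {
  vapply(seq_len(pspm$width), function(j) {
    p <- pspm$matrix[, j]
    o <- order(p, decreasing = TRUE)
    if (p[o[1L]] >= single) return(DNA_BASES[o[1L]])
    if (p[o[1L]] + p[o[2L]] >= pair) {
      key <- paste(sort(DNA_BASES[o[1:2]]), collapse = "")
      return(IUPAC2[[key]])
    }
    "n"
  }, character(1)) |> paste(collapse = "")
}

#' Information content of a PSPM in bits
#'
#' `sum_j sum_b p_jb * log2(p_jb / bg0_b)`; non-negative against a uniform
#' base distribution.
#'
#' @param pspm a `pspm`.
#' @param bg0 length-4 reference base distribution (default uniform).
#' @return total information content in bits.
#' @export
information_content <- function(pspm, bg0 = rep(0.25, 4)) {
  p <- pspm$matrix
  terms <- p * log2(sweep(p, 1L, bg0, "/"))
  terms[p == 0] <- 0
  sum(terms)
}

#' Kullback-Leibler distance between two PSPMs
#'
#' Column-averaged symmetrized KL divergence,
#' `(1 / 2W) * sum_j [KL(a_j || b_j) + KL(b_j || a_j)]`, evaluated against
#' both `b` and its reverse complement; the smaller of the two orientations
#' is returned. Motifs closer than the ranking threshold are treated as the
#' same motif family.
#'
#' @param a,b smoothed `pspm` objects of equal width (no zero entries).
#' @return non-negative distance; 0 iff equal in the best orientation.
#' @export
kl_distance <- function(a, b) {
  if (a$width != b$width) {
    abort_seedmotif("KL distance requires equal-width PSPMs",
                    "seedmotif_shape_error")
  }
  if (any(a$matrix == 0) || any(b$matrix == 0)) {
    abort_seedmotif("KL distance requires smoothed PSPMs (no zero entries)",
                    "seedmotif_degenerate_input")
  }
  one <- function(x, y) {
    sum(x$matrix * log(x$matrix / y$matrix) +
          y$matrix * log(y$matrix / x$matrix)) / (2 * x$width)
  }
  min(one(a, b), one(a, rc_pspm(b)))
}

#' Rank motifs by score and group them by Kullback-Leibler similarity
#'
#' Motifs are sorted by descending `ll_score`; each motif joins the first
#' existing group whose representative (its highest-scoring member) lies
#' within `kl_threshold`, else founds a new group.
#'
#' @param motifs list of `motif_result` objects of a common width.
#' @param kl_threshold similarity threshold (default 0.9).
#' @return list of groups; each group is a list of `motif_result`s, ordered
#'   by descending score within and across groups.
#' @export
rank_motifs <- function(motifs, kl_threshold = 0.9) {
  stopifnot(kl_threshold > 0)
  if (length(motifs) == 0L) return(list())
  lls <- vapply(motifs, function(m) m$ll_score, numeric(1))
  motifs <- motifs[order(lls, decreasing = TRUE)]
  groups <- list()
  for (m in motifs) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      rep_m <- groups[[g]][[1L]]
      if (kl_distance(m$pspm, rep_m$pspm) < kl_threshold) {
        groups[[g]] <- c(groups[[g]], list(m))
        placed <- TRUE
        break
      }
    }
    if (!placed) groups <- c(groups, list(list(m)))
  }
  groups
}

#' Read / write motif matrices in the INCLUSive text format
#'
#' The INCLUSive motif model dialect: a `#INCLUSive Motif Model` header, then
#' per motif an `#ID`, `#Score`, `#W` block followed by W rows of 4
#' whitespace-separated probabilities (A C G T). Round-trips losslessly to 6
#' significant digits.
#'
#' @param path file path.
#' @param pspms named list of `pspm` objects (names become `#ID`s).
#' @param scores optional numeric scores written to `#Score` lines.
#' @return `read_inclusive_matrix` returns a named list of `pspm`s with a
#'   `scores` attribute.
#' @export
read_inclusive_matrix <- function(path) {
  lines <- readLines(path)
  pspms <- list()
  scores <- numeric(0)
  i <- 1L
  cur_id <- NULL
  cur_score <- NA_real_
  cur_w <- NA_integer_
  n <- length(lines)
  parse_fail <- function(i, why) {
    abort_seedmotif(sprintf("INCLUSive parse error at line %d: %s", i, why),
                    "seedmotif_parse_error")
  }
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^#INCLUSive", ln, ignore.case = TRUE)) {
      i <- i + 1L
      next
    }
    if (grepl("^#ID", ln)) {
      cur_id <- sub("^#ID\\s*=\\s*", "", ln)
      i <- i + 1L
      next
    }
    if (grepl("^#Score", ln)) {
      cur_score <- suppressWarnings(as.numeric(sub("^#Score\\s*=\\s*", "", ln)))
      i <- i + 1L
      next
    }
    if (grepl("^#W", ln)) {
      cur_w <- suppressWarnings(as.integer(sub("^#W\\s*=\\s*", "", ln)))
      if (is.na(cur_w) || cur_w < 1L) parse_fail(i, "bad #W value")
      if (is.null(cur_id)) parse_fail(i, "#W before #ID")
      if (i + cur_w > n) parse_fail(i, "matrix block truncated")
      rows <- lapply(seq_len(cur_w), function(j) {
        vals <- suppressWarnings(as.numeric(strsplit(
          trimws(lines[i + j]), "\\s+")[[1]]))
        if (length(vals) != 4L || anyNA(vals)) {
          parse_fail(i + j, "expected 4 numeric probabilities")
        }
        if (abs(sum(vals) - 1) > 0.02) {
          parse_fail(i + j, sprintf("row sums to %.4f, not 1", sum(vals)))
        }
        vals / sum(vals)
      })
      mat <- t(do.call(rbind, rows))
      pspms[[cur_id]] <- new_pspm(mat)
      scores[cur_id] <- cur_score
      cur_id <- NULL
      cur_score <- NA_real_
      i <- i + cur_w + 1L
      next
    }
    parse_fail(i, paste("unexpected content:", ln))
  }
  attr(pspms, "scores") <- scores
  pspms
}

#' @rdname read_inclusive_matrix
#' @export
write_inclusive_matrix <- function(pspms, path, scores = NULL) {
  if (inherits(pspms, "pspm")) pspms <- list(motif = pspms)
  ids <- names(pspms) %||% paste0("motif_", seq_along(pspms))
  if (is.null(names(pspms))) names(pspms) <- ids
  out <- c("#INCLUSive Motif Model v1.0", "")
  for (id in names(pspms)) {
    p <- pspms[[id]]
    sc <- if (!is.null(scores) && !is.null(scores[[id]])) scores[[id]] else 0
    out <- c(out,
             paste0("#ID = ", id),
             paste0("#Score = ", format(sc, digits = 10)),
             paste0("#W = ", p$width),
             vapply(seq_len(p$width), function(j) {
               paste(formatC(p$matrix[, j], format = "f", digits = 6),
                     collapse = "\t")
             }, character(1)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

new_motif_result <- function(pspm, instances, ll, consensus = NULL) {
  structure(
    list(pspm = pspm, instances = instances, ll_score = ll,
         consensus = consensus %||% consensus_iupac(pspm)),
    class = "motif_result"
  )
}

#' @export
print.motif_result <- function(x, ...) {
  cat("Motif: width", x$pspm$width,
      " instances:", nrow(x$instances),
      " ll:", format(x$ll_score, digits = 6), "\n")
  cat(" consensus:", x$consensus, "\n")
  invisible(x)
}
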