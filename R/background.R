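# Order-k Markov background models of promoter composition.
#
# A background model factorizes P(segment) as P(first k bases) times a product
# of order-k transition probabilities. It is the denominator of every
# motif-vs-background likelihood ratio in the package.

new_background_model <- function(order, transition, initial) {
  stopifnot(is.matrix(transition), ncol(transition) == 4L,
            nrow(transition) == 4L^order,
            length(initial) == 4L^order)
  structure(
    list(order = as.integer(order), transition = transition, initial = initial),
    class = "background_model"
  )
}

# Integer context ids: a length-k base-code vector (1..4) -> 1..4^k, first
# base the most significant digit. k = 0 has the single empty context, id 1.
context_id <- function(codes, k) {
  if (k == 0L) return(1L)
  as.integer(sum((codes - 1L) * 4L^((k - 1L):0L)) + 1L)
}

context_kmers <- function(k) {
  if (k == 0L) return("")
  grid <- do.call(expand.grid, rep(list(DNA_BASES), k))
  apply(grid[, k:1, drop = FALSE], 1L, paste, collapse = "")
}

# Context id of the k-mer ending at each position of an encoded sequence;
# NA where the k-mer is incomplete or contains N.
sliding_context_ids <- function(code, k) {
  L <- length(code)
  ids <- rep(NA_integer_, L)
  if (k == 0L) {
    ids[] <- 1L
    return(ids)
  }
  if (L < k) return(ids)
  pow <- 4L^((k - 1L):0L)
  base0 <- code - 1L
  nwin <- L - k + 1L
  acc <- rep(0, nwin)
  valid <- rep(TRUE, nwin)
  for (j in seq_len(k)) {
    seg <- base0[j:(L - k + j)]
    acc <- acc + ifelse(is.na(seg), 0, seg) * pow[j]
    valid <- valid & !is.na(seg)
  }
  ids[k:L] <- ifelse(valid, as.integer(acc) + 1L, NA_integer_)
  ids
}

#' Train an order-k Markov background model
#'
#' Counts length-k context to next-base transitions over the given strand of
#' the input sequences (windows containing `N` are skipped) and smooths every
#' cell with a pseudocount. The initial distribution is the smoothed marginal
#' frequency of all k-mers, used for the first k bases of a scored segment.
#'
#' @param seqs character vector of DNA sequences.
#' @param order Markov order k (default 3, the setting used for bacterial
#'   promoter pools).
#' @param pseudocount added to every transition / k-mer count cell.
#' @return a `background_model` object.
#' @export
train_background <- function(seqs, order = 3L, pseudocount = 1) {
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    abort_seedmotif("no sequence data to train a background model on",
                    "seedmotif_empty_input")
  }
  k <- as.integer(order)
  stopifnot(k >= 0L, pseudocount >= 0)
  total_len <- sum(nchar(seqs))
  if (total_len <= 4^(k + 1)) {
    warning("total sequence length ", total_len,
            " is small for an order-", k, " background (< 4^(k+1) = ",
            4^(k + 1), "); estimates will lean on the pseudocount")
  }
  nctx <- 4L^k
  trans <- matrix(0, nrow = nctx, ncol = 4L)
  init <- numeric(nctx)
  for (s in seqs) {
    code <- encode_dna(s)
    L <- length(code)
    if (L < k + 1L) next
    ids <- sliding_context_ids(code, k)
    kmer_ids <- ids[k:L]
    if (k > 0L) init <- init + tabulate(kmer_ids[!is.na(kmer_ids)], nbins = nctx)
    else init[1L] <- init[1L] + L
    # context ending just before each scored position (empty context for k=0)
    from <- if (k == 0L) rep(1L, L) else ids[((k + 1L):L) - 1L]
    to <- code[(k + 1L):L]
    if (k == 0L) to <- code
    keep <- !is.na(from) & !is.na(to)
    if (any(keep)) {
      cell <- (to[keep] - 1L) * nctx + from[keep]
      tab <- tabulate(cell, nbins = nctx * 4L)
      trans <- trans + matrix(tab, nrow = nctx)
    }
  }
  trans <- trans + pseudocount
  # unobserved contexts (possible only at pseudocount 0) fall back to uniform
  zero_rows <- rowSums(trans) == 0
  trans[zero_rows, ] <- 1
  trans <- trans / rowSums(trans)
  init <- init + pseudocount
  init <- init / sum(init)
  rownames(trans) <- context_kmers(k)
  colnames(trans) <- DNA_BASES
  names(init) <- context_kmers(k)
  new_background_model(k, trans, init)
}

#' Log-probability of a DNA segment under a background model
#'
#' Natural log of P(segment) under the initial-distribution times transition
#' factorization. Segments containing `N` are unscorable and return `NA`
#' (never a numeric value): callers treat them as non-candidates.
#'
#' @param segment single DNA string, length >= 1.
#' @param bg a `background_model`.
#' @return log-probability, or `NA_real_` when the segment contains `N`.
#' @export
bg_logprob <- function(segment, bg) {
  bg_logprob_code(encode_dna(segment), bg)
}

bg_logprob_code <- function(code, bg) {
  L <- length(code)
  stopifnot(L >= 1L)
  if (anyNA(code)) return(NA_real_)
  k <- bg$order
  if (L < k) {
    # marginalize the k-mer initial distribution down to the first L bases
    ids0 <- seq_len(4L^k) - 1L
    prefix <- ids0 %/% 4L^(k - L)
    target <- context_id(code, L) - 1L
    return(log(sum(bg$initial[prefix == target])))
  }
  lp <- if (k == 0L) 0 else log(bg$initial[[context_id(code[seq_len(k)], k)]])
  if (L > k) {
    for (i in (k + 1L):L) {
      ctx <- if (k == 0L) 1L else context_id(code[(i - k):(i - 1L)], k)
      lp <- lp + log(bg$transition[ctx, code[i]])
    }
  }
  lp
}

# Vectorized background log-probabilities of every length-W window of an
# encoded sequence. Returns a vector of length L - W + 1 (positions are
# window starts); windows containing N are NA. Requires W >= order.
bg_window_logprobs <- function(code, bg, W) {
  L <- length(code)
  n <- L - W + 1L
  if (n < 1L) return(numeric(0L))
  k <- bg$order
  stopifnot(W >= k)
  ids <- sliding_context_ids(code, k)
  # per-position transition log-prob lt[i] = log T[ctx ending at i-1, code[i]]
  lt <- rep(NA_real_, L)
  if (L > k || k == 0L) {
    pos <- if (k == 0L) 1:L else (k + 1L):L
    ctx <- if (k == 0L) rep(1L, L) else ids[pos - 1L]
    tocode <- code[pos]
    okp <- !is.na(ctx) & !is.na(tocode)
    lt[pos[okp]] <- log(bg$transition[cbind(ctx[okp], tocode[okp])])
  }
  # initial log-prob of the k-mer starting at p (ends at p + k - 1)
  li <- rep(NA_real_, n)
  if (k > 0L) {
    start_ids <- ids[k:(k + n - 1L)]
    ok0 <- !is.na(start_ids)
    li[ok0] <- log(bg$initial[start_ids[ok0]])
  } else {
    li[] <- 0
  }
  # padded cumulative sums so windows can be differenced even at k = 0
  relevant <- seq_len(L) > k
  ltz <- ifelse(is.na(lt) | !relevant, 0, lt)
  na_flag <- as.integer(is.na(lt) & relevant)
  CS <- c(0, cumsum(ltz))
  NAC <- c(0L, cumsum(na_flag))
  hi <- (seq_len(n) + W - 1L) + 1L # index into padded arrays
  lo <- (seq_len(n) + k - 1L) + 1L
  res <- li + (CS[hi] - CS[lo])
  res[(NAC[hi] - NAC[lo]) > 0L] <- NA_real_
  res
}

#' @export
print.background_model <- function(x, ...) {
  cat("Markov background model, order", x$order, "\n")
  cat(" contexts:", nrow(x$transition), "\n")
  invisible(x)
}

#' Write / read a background model as JSON
#'
#' @param bg a `background_model`.
#' @param path file path.
#' @return `read_background_json` returns a `background_model`.
#' @export
write_background_json <- function(bg, path) {
  obj <- list(order = bg$order,
              contexts = rownames(bg$transition),
              transition = unname(apply(bg$transition, 1L, as.numeric,
                                        simplify = FALSE)),
              initial = as.numeric(bg$initial))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_json
#' @export
read_background_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trans <- if (is.matrix(obj$transition)) obj$transition else
    do.call(rbind, obj$transition)
  rownames(trans) <- obj$contexts
  colnames(trans) <- DNA_BASES
  init <- as.numeric(obj$initial)
  names(init) <- obj$contexts
  new_background_model(obj$order, trans, init)
}
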