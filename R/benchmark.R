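# Library benchmarking: reciprocal-coverage true positives at a length
# threshold (sensitivity / precision / FDR / F1), Perfect/Good/Present
# categorisation of gold families, and terminal position-frequency matrices.

# per-pair merged coverage between a test and a gold library
bm_pairs <- function(test, gold, min_identity = 0.8) {
  tseq <- stats::setNames(test$consensus, test$family_id)
  gseq <- stats::setNames(gold$consensus, gold$family_id)
  db <- blast_db(gseq)
  hits <- blast_search(tseq, db, task = "blastn", min_identity = min_identity,
                       min_len = 30L, max_targets = length(gseq) + 10L)
  pairs <- if (nrow(hits) == 0L) {
    data.frame(q = character(0), t = character(0), cov_q = numeric(0),
               cov_t = numeric(0), identity = numeric(0))
  } else {
    key <- paste(hits$query_id, hits$target_id, sep = "\r")
    res <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
      h <- hits[ix, , drop = FALSE]
      q <- h$query_id[[1L]]; t <- h$target_id[[1L]]
      data.frame(q = q, t = t,
                 cov_q = union_len(h$q_start, h$q_end) / nchar(tseq[[q]]),
                 cov_t = union_len(h$t_start, h$t_end) / nchar(gseq[[t]]),
                 identity = stats::weighted.mean(h$identity, h$aln_len),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  }
  list(pairs = pairs, hits = hits)
}

#' Benchmark a test library against a gold library at a coverage threshold
#'
#' A test entry is a true positive only when some gold entry is matched with
#' merged aligned coverage strictly exceeding `threshold` on BOTH the test
#' and the gold sequence; everything else (shifted, over-long, fragmented
#' sequences) counts as a false positive.  A gold entry is found when a
#' true-positive test entry matches it.
#'
#' @param test,gold library data.frames (`family_id`, `classification`,
#'   `consensus`).
#' @param threshold coverage threshold in (0, 1), e.g. 0.80, 0.95, 0.99.
#' @param pairs optional precomputed [bm_pairs()] result (reused across
#'   thresholds).
#' @return object of class `bm_result`: threshold, tp, fp, fn, sensitivity,
#'   precision, fdr, f1, and `per_family` (best test match per gold family).
#' @export
bm_library <- function(test, gold, threshold = 0.95, pairs = NULL) {
  if (nrow(test) == 0L || nrow(gold) == 0L) stop("empty library")
  pr <- (pairs %||% bm_pairs(test, gold))$pairs
  ok <- pr[pr$cov_q > threshold & pr$cov_t > threshold, , drop = FALSE]
  tp_entries <- unique(ok$q)
  found_gold <- unique(ok$t)
  tp <- length(tp_entries)
  fp <- nrow(test) - tp
  fn <- nrow(gold) - length(found_gold)
  sens <- length(found_gold) / nrow(gold)
  prec <- tp / nrow(test)
  fdr <- 1 - prec
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  per_family <- do.call(rbind, lapply(gold$family_id, function(g) {
    sub <- pr[pr$t == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(gold_family = g, best_test = NA_character_,
                        coverage_gold = 0, coverage_test = 0))
    b <- sub[which.max(pmin(sub$cov_q, sub$cov_t)), ]
    data.frame(gold_family = g, best_test = b$q, coverage_gold = b$cov_t,
               coverage_test = b$cov_q)
  }))
  structure(list(threshold = threshold, tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, precision = prec, fdr = fdr, f1 = f1,
                 per_family = per_family),
            class = "bm_result")
}

#' @export
print.bm_result <- function(x, ...) {
  cat(sprintf(
    "library benchmark @ %.2f: TP %d  FP %d  FN %d | sens %.4f  prec %.4f  FDR %.4f  F1 %.4f\n",
    x$threshold, x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$fdr, x$f1))
  invisible(x)
}

#' Categorise gold families as Perfect / Good / Present / Not_found
#'
#' Perfect: a single test entry matches the gold family at > 95% identity
#' and > 95% coverage of the gold length.  Good: the union of test matches
#' (>= 80% identity) covers > 95% of the gold family.  Present: union
#' coverage > 50%.  Otherwise Not_found.
#'
#' @inheritParams bm_library
#' @return named character vector: gold family -> category.
#' @export
rm2_categorize <- function(test, gold) {
  if (nrow(test) == 0L || nrow(gold) == 0L) stop("empty library")
  bp <- bm_pairs(test, gold, min_identity = 0.8)
  pr <- bp$pairs; hits <- bp$hits
  out <- stats::setNames(rep("Not_found", nrow(gold)), gold$family_id)
  for (g in gold$family_id) {
    sub <- pr[pr$t == g, , drop = FALSE]
    perfect <- any(sub$cov_t > 0.95 & sub$identity > 0.95)
    h <- hits[hits$target_id == g & hits$identity >= 0.8, , drop = FALSE]
    ucov <- if (nrow(h) == 0L) 0 else
      union_len(h$t_start, h$t_end) /
        nchar(gold$consensus[gold$family_id == g])
    out[[g]] <- if (perfect) "Perfect"
      else if (ucov > 0.95) "Good"
      else if (ucov > 0.5) "Present"
      else "Not_found"
  }
  out
}

#' Terminal position-frequency matrices (sequence-logo input)
#'
#' Nucleotide usage at each of the first and last `end_len` positions over
#' all copies of the given models (copies oriented 5'->3'); each column sums
#' to 1.
#'
#' @param models list of `te_model`s.
#' @param genome named character vector of sequences.
#' @param end_len terminal length profiled (default 30 bp).
#' @return list with `five` and `three`: 4 x `end_len` matrices (rows
#'   A, C, G, T).
#' @export
terminal_profile <- function(models, genome, end_len = 30L) {
  if (length(models) == 0L) stop("no models")
  five <- matrix(0, nrow = 4L, ncol = end_len,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  three <- five
  add <- function(mat, s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in seq_len(min(length(ch), end_len))) {
      b <- ch[[p]]
      if (b %in% rownames(mat)) mat[b, p] <- mat[b, p] + 1
    }
    mat
  }
  for (m in models) {
    cps <- m$copies
    if (is.null(cps) || nrow(cps) == 0L)
      cps <- data.frame(seq_id = m$seq_id, start = m$start, end = m$end,
                        strand = m$strand)
    for (i in seq_len(nrow(cps))) {
      if (cps$end[i] - cps$start[i] < end_len) next
      x <- extract_with_flanks(genome, cps[i, ], 0L, orient = TRUE)
      s <- x$seq
      five <- add(five, substr(s, 1L, end_len))
      # 3' matrix in sense orientation: column j is position len-end_len+j
      three <- add(three, substr(s, nchar(s) - end_len + 1L, nchar(s)))
    }
  }
  norm <- function(mat) {
    cs <- colSums(mat)
    cs[cs == 0] <- 1
    sweep(mat, 2L, cs, "/")
  }
  list(five = norm(five), three = norm(three))
}
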