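# Fault-tolerant mapping expansion (FMEA): convert fragmented local-alignment
# hits into coarse-grained full-length TE candidates by bridging the gaps that
# substitutions, indels and nested insertions open between alignment segments.

#' Partition hits into clusters by (query, target, strand)
#'
#' Within each cluster hits are sorted ascending by target start (minus-strand
#' hits carry + strand target coordinates and are clustered separately).
#'
#' @param hits internal hit table in global coordinates.
#' @return list of clusters; each is a hit data.frame sorted by `t_start`.
#' @export
cluster_hits <- function(hits) {
  if (nrow(hits) == 0L) return(list())
  key <- paste(hits$query_id, hits$target_id, hits$strand, sep = "\r")
  idx <- split(seq_len(nrow(hits)), key)
  lapply(idx, function(i) {
    cl <- hits[i, , drop = FALSE]
    cl <- cl[order(cl$t_start, cl$t_end), , drop = FALSE]
    rownames(cl) <- NULL
    cl
  })
}

# can `nxt` extend a chain ending at (q_end_pos / q_start_pos, t_end_pos)?
# plus strand: query advances with target; minus strand: query retreats.
chainable <- function(strand, cq_lo, cq_hi, ct_hi, h, max_gap_q, max_gap_t,
                      overlap_tol = 20L) {
  gap_t <- h$t_start - ct_hi
  if (gap_t < -overlap_tol || gap_t > max_gap_t) return(FALSE)
  if (strand == "+") {
    gap_q <- h$q_start - cq_hi
    gap_q >= -overlap_tol && gap_q <= max_gap_q
  } else {
    gap_q <- cq_lo - h$q_end
    gap_q >= -overlap_tol && gap_q <= max_gap_q
  }
}

#' Expand a hit cluster into coarse candidates by greedy gap bridging
#'
#' Hits are chained left-to-right along the target axis; a growing chain
#' absorbs the next hit iff its query-side and target-side gaps are both at
#' most `max_gap` and the hit is colinear with the chain (starts after the
#' chain end on both axes, with a 20 bp overlap tolerance; on the minus
#' strand the query axis runs backwards).  Each maximal chain emits one
#' candidate spanning min query start to max query end.  Candidates shorter
#' than 80 bp (the family-definition floor) are dropped.
#'
#' @param cluster one cluster from [cluster_hits()].
#' @param max_gap_q maximum bridged gap on the query, bp (default 1000).
#' @param max_gap_t maximum bridged gap on the target, bp (default 1000).
#' @return data.frame of coarse candidates: `seq_id`, `start`, `end`
#'   (query axis), `support`, `bridged_gap_total`, `t_lo`, `t_hi`, `strand`.
#' @export
fmea_expand <- function(cluster, max_gap_q = 1000L, max_gap_t = 1000L) {
  n <- nrow(cluster)
  if (n == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      bridged_gap_total = integer(0), t_lo = integer(0),
                      t_hi = integer(0), strand = character(0)))
  strand <- cluster$strand[[1L]]
  qs_v <- cluster$q_start; qe_v <- cluster$q_end
  ts_v <- cluster$t_start; te_v <- cluster$t_end
  o_start <- integer(0); o_end <- integer(0); o_sup <- integer(0)
  o_gap <- integer(0); o_tlo <- integer(0); o_thi <- integer(0)
  flush <- function(idx, gap_total) {
    o_start <<- c(o_start, min(qs_v[idx])); o_end <<- c(o_end, max(qe_v[idx]))
    o_sup <<- c(o_sup, length(idx)); o_gap <<- c(o_gap, gap_total)
    o_tlo <<- c(o_tlo, min(ts_v[idx])); o_thi <<- c(o_thi, max(te_v[idx]))
  }
  chain <- 1L
  cq_lo <- qs_v[1L]; cq_hi <- qe_v[1L]; ct_hi <- te_v[1L]
  gap_total <- 0L
  for (i in seq_len(n)[-1L]) {
    h <- list(q_start = qs_v[i], q_end = qe_v[i],
              t_start = ts_v[i], t_end = te_v[i])
    if (chainable(strand, cq_lo, cq_hi, ct_hi, h, max_gap_q, max_gap_t)) {
      gq <- if (strand == "+") h$q_start - cq_hi else cq_lo - h$q_end
      gap_total <- gap_total + max(0L, gq)
      chain <- c(chain, i)
      cq_lo <- min(cq_lo, h$q_start); cq_hi <- max(cq_hi, h$q_end)
      ct_hi <- max(ct_hi, h$t_end)
    } else {
      flush(chain, gap_total)
      chain <- i
      cq_lo <- h$q_start; cq_hi <- h$q_end; ct_hi <- h$t_end
      gap_total <- 0L
    }
  }
  flush(chain, gap_total)
  cands <- data.frame(seq_id = cluster$query_id[[1L]], start = o_start,
                      end = o_end, support = o_sup,
                      bridged_gap_total = o_gap, t_lo = o_tlo, t_hi = o_thi,
                      strand = strand, stringsAsFactors = FALSE)
  cands <- cands[cands$end - cands$start >= 80L, , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Remove candidates contained in longer candidates
#'
#' A candidate whose interval is covered at >= 95% by a longer candidate on
#' the same sequence is dropped ("the longest sequences are taken"); among
#' equal-length ties the earlier-starting one is kept.
#'
#' @param cands data.frame of coarse candidates (one query sequence or many;
#'   containment is only tested within a sequence).
#' @return filtered candidate data.frame.
#' @export
deredundant <- function(cands) {
  if (nrow(cands) <= 1L) return(cands)
  ord <- order(-(cands$end - cands$start), cands$start)
  cands <- cands[ord, , drop = FALSE]
  n <- nrow(cands)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (j == i || !keep[j]) next
      if (cands$seq_id[j] != cands$seq_id[i]) next
      li <- cands$end[i] - cands$start[i]
      lj <- cands$end[j] - cands$start[j]
      if (lj > li) next
      if (lj == li && (cands$start[j] < cands$start[i] ||
                       (cands$start[j] == cands$start[i] && j < i))) next
      ov <- min(cands$end[i], cands$end[j]) - max(cands$start[i], cands$start[j])
      if (ov >= 0.95 * lj) keep[j] <- FALSE
    }
  }
  res <- cands[keep, , drop = FALSE]
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run FMEA over a full hit table
#'
#' Clusters hits, expands each cluster, and removes redundant candidates per
#' query sequence.
#'
#' @param hits internal hit table in global coordinates.
#' @param max_gap maximum bridged gap (both axes), bp.
#' @return data.frame of coarse candidates.
#' @export
fmea_candidates <- function(hits, max_gap = 1000L) {
  cls <- cluster_hits(hits)
  cands <- do.call(rbind, lapply(cls, fmea_expand,
                                 max_gap_q = max_gap, max_gap_t = max_gap))
  if (is.null(cands) || nrow(cands) == 0L)
    return(fmea_expand(empty_hits()))
  deredundant(cands)
}
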