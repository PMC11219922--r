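# Genome chunking, the pluggable local-alignment engine (an adapter over NCBI
# BLAST+ producing the internal hit schema), mask bookkeeping for the
# iterative mask-identify-mask loop, and the desk-scale tandem detector used
# both for genome pre-masking and for the terminal tandem filter.

#' Split assembly sequences into overlapping chunks
#'
#' Consecutive chunks overlap by `overlap` bp so that no element shorter than
#' the overlap can be split undetectably.  Each chunk carries its global
#' offset; sequences shorter than `chunk_len` yield a single chunk.
#'
#' @param records named character vector of sequences.
#' @param chunk_len chunk length in bp (>= 10000), default 100 kb.
#' @param overlap overlap between consecutive chunks, default 10 kb.
#' @return list of chunks, each `list(seq_id, offset, seq, chunk_id)`.
#' @export
chunk_genome <- function(records, chunk_len = 100000L, overlap = 10000L) {
  if (chunk_len < 10000L) stop("chunk_len must be >= 10000")
  if (overlap >= chunk_len) stop("overlap must be < chunk_len")
  step <- chunk_len - overlap
  chunks <- list()
  for (sid in names(records)) {
    len <- nchar(records[[sid]])
    offs <- if (len <= chunk_len) 0L else {
      o <- seq(0L, len, by = step)
      o[o < len - overlap]
    }
    for (o in offs) {
      e <- min(o + chunk_len, len)
      chunks[[length(chunks) + 1L]] <- list(
        seq_id = sid, offset = as.integer(o),
        seq = subseq0(records[[sid]], o, e),
        chunk_id = sprintf("%s:%d-%d", sid, o, e))
    }
  }
  chunks
}

## ---- BLAST adapter -------------------------------------------------------

#' Build a BLAST database for a genome (or any sequence set)
#'
#' The database is the engine-side representation of the target sequences;
#' build it once and reuse it across searches.
#'
#' @param records named character vector of sequences.
#' @param type `"nucl"` or `"prot"`.
#' @param dir directory to create the database in (default: a tempdir).
#' @return an object of class `tinyte_blastdb`.
#' @export
blast_db <- function(records, type = c("nucl", "prot"), dir = NULL) {
  type <- match.arg(type)
  check_tool("makeblastdb")
  if (is.null(dir)) dir <- tinyte_tmp("blastdb")
  fa <- file.path(dir, "db.fa")
  write_fasta(records, fa)
  prefix <- file.path(dir, "db")
  out <- system2("makeblastdb",
                 c("-in", fa, "-dbtype", type, "-out", prefix),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(paste0(prefix, if (type == "nucl") ".nin" else ".pin")))
    stop("makeblastdb failed: ", paste(out, collapse = "\n"))
  structure(list(prefix = prefix, fasta = fa, type = type,
                 seq_len = nchar(records)),
            class = "tinyte_blastdb")
}

#' Local alignment of query sequences against a BLAST database
#'
#' Thin adapter over `blastn` producing the internal hit schema (0-based
#' half-open coordinates, minus-strand target coordinates reported on the +
#' strand with the strand flag set).
#'
#' @param query named character vector of query sequences.
#' @param db a `tinyte_blastdb` (nucleotide).
#' @param task blastn task: `"megablast"` (fast, high identity) or
#'   `"blastn"` (sensitive, 11 bp words).
#' @param min_identity identity floor in [0,1].
#' @param min_len minimum alignment length in bp.
#' @param evalue e-value cutoff.
#' @param max_targets blast `max_target_seqs`.
#' @param dust low-complexity filtering (`"yes"`/`"no"`); off by default
#'   because TE termini are often low complexity.
#' @return internal hit table (see [read_hits()]).
#' @export
blast_search <- function(query, db, task = "blastn", min_identity = 0.8,
                         min_len = 80L, evalue = 1e-5, max_targets = 2000L,
                         dust = "no") {
  stopifnot(inherits(db, "tinyte_blastdb"), db$type == "nucl")
  check_tool("blastn")
  qfa <- tempfile("q", fileext = ".fa")
  on.exit(unlink(qfa), add = TRUE)
  write_fasta(query, qfa)
  out <- tempfile("hits", fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c("-query", qfa, "-db", db$prefix, "-task", task,
            "-outfmt", "6", "-out", out,
            "-evalue", format(evalue, scientific = TRUE),
            "-perc_identity", format(min_identity * 100),
            "-max_target_seqs", max_targets,
            "-dust", dust, "-num_threads", "1")
  st <- system2("blastn", args, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) stop("blastn failed: ", paste(st, collapse = "\n"))
  hits <- read_hits(out)
  hits <- hits[hits$aln_len >= min_len & hits$identity >= min_identity, ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## ---- mask state ----------------------------------------------------------

#' Create an empty mask state
#'
#' A mask state stores, per sequence, the merged interval set of
#' already-annotated full-length TE copies (and pre-masked tandem arrays).
#'
#' @param records named character vector of sequences.
#' @return object of class `tinyte_mask` (named list of IRanges).
#' @export
mask_state <- function(records) {
  m <- stats::setNames(
    lapply(names(records), function(x) IRanges::IRanges()),
    names(records))
  structure(list(iv = m), class = "tinyte_mask")
}

#' Add intervals to a mask state
#'
#' The mask grows monotonically; stored intervals are kept merged, so the
#' operation is idempotent.
#'
#' @param mask a `tinyte_mask`.
#' @param intervals data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @return the updated mask.
#' @export
mask_add <- function(mask, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(mask)
  for (sid in unique(intervals$seq_id)) {
    sub <- intervals[intervals$seq_id == sid, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    if (is.null(mask$iv[[sid]])) mask$iv[[sid]] <- IRanges::IRanges()
    mask$iv[[sid]] <- IRanges::reduce(c(mask$iv[[sid]], ir))
  }
  mask
}

#' Grow the mask with the full-length copies of confirmed TE models
#'
#' @param mask a `tinyte_mask`.
#' @param confirmed list of TE models (each carrying a `copies` data.frame).
#' @return the updated mask.
#' @export
update_mask <- function(mask, confirmed) {
  if (length(confirmed) == 0L) return(mask)
  cps <- do.call(rbind, lapply(confirmed, function(m) {
    cp <- m$copies
    if (is.null(cp) || nrow(cp) == 0L) {
      data.frame(seq_id = m$seq_id, start = m$start, end = m$end,
                 stringsAsFactors = FALSE)
    } else {
      # only full-length copies are masked (>= 95% of the exemplar length)
      el <- m$end - m$start
      keep <- (cp$end - cp$start) >= 0.95 * el
      cp[keep, c("seq_id", "start", "end"), drop = FALSE]
    }
  }))
  mask_add(mask, cps)
}

# total masked bp overlapping [start, end) on seq_id
mask_overlap <- function(mask, seq_id, start, end) {
  iv <- mask$iv[[seq_id]]
  if (is.null(iv) || length(iv) == 0L) return(0L)
  q <- IRanges::IRanges(start = start + 1L, end = end)
  sum(IRanges::width(IRanges::intersect(iv, q)))
}

# mask intervals as a data.frame (0-based half-open)
mask_as_df <- function(mask) {
  out <- lapply(names(mask$iv), function(sid) {
    iv <- mask$iv[[sid]]
    if (length(iv) == 0L) return(NULL)
    data.frame(seq_id = sid, start = IRanges::start(iv) - 1L,
               end = IRanges::end(iv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(seq_id = character(0), start = integer(0),
                               end = integer(0)) else out
}

# hard-mask (N) the masked intervals of one sequence segment
# seg covers [offset, offset + nchar(seg)) of seq_id
apply_mask <- function(mask, seq_id, seg, offset = 0L) {
  iv <- mask$iv[[seq_id]]
  if (is.null(iv) || length(iv) == 0L) return(seg)
  seg_ir <- IRanges::IRanges(start = offset + 1L, end = offset + nchar(seg))
  ov <- IRanges::intersect(iv, seg_ir)
  if (length(ov) == 0L) return(seg)
  for (i in seq_along(ov)) {
    s <- IRanges::start(ov)[i] - offset   # 1-based in seg
    e <- IRanges::end(ov)[i] - offset
    substr(seg, s, e) <- strrep("N", e - s + 1L)
  }
  seg
}

## ---- all-vs-all ----------------------------------------------------------

#' All-vs-all sensitive alignment of genome chunks against the assembly
#'
#' Queries are the (mask-hardened) chunks, targets the full assembly; hits
#' are reported in global coordinates.  Trivial self-hits (identical query
#' and target interval) are removed, as are hits whose target interval is
#' mostly (> 80%) inside the mask.
#'
#' @param chunks list of chunks from [chunk_genome()] (possibly a subset).
#' @param db nucleotide `tinyte_blastdb` of the full assembly.
#' @param mask a `tinyte_mask`.
#' @param min_identity identity floor (default 0.8, the family-definition
#'   floor).
#' @param min_len minimum hit length (default 80 bp).
#' @param task blastn task (default `"megablast"`: fragmented hits at lower
#'   identity are expected and are bridged downstream by FMEA).
#' @return internal hit table in global coordinates.
#' @export
all_vs_all <- function(chunks, db, mask, min_identity = 0.8, min_len = 80L,
                       task = "megablast") {
  if (length(chunks) == 0L) stop("chunks must be non-empty")
  qseqs <- character(0)
  offs <- list()
  for (ch in chunks) {
    seg <- apply_mask(mask, ch$seq_id, ch$seq, ch$offset)
    qseqs[[ch$chunk_id]] <- seg
    offs[[ch$chunk_id]] <- list(seq_id = ch$seq_id, offset = ch$offset)
  }
  if (all(grepl("^N*$", qseqs))) return(empty_hits())
  hits <- blast_search(qseqs, db, task = task, min_identity = min_identity,
                       min_len = min_len)
  if (nrow(hits) == 0L) return(hits)
  # globalize query coordinates
  qsid <- vapply(hits$query_id, function(q) offs[[q]]$seq_id, character(1))
  qoff <- vapply(hits$query_id, function(q) offs[[q]]$offset, integer(1))
  hits$query_id <- qsid
  hits$q_start <- hits$q_start + qoff
  hits$q_end <- hits$q_end + qoff
  # trivial self-hits: same sequence, identical intervals, + strand
  self <- hits$query_id == hits$target_id & hits$strand == "+" &
    hits$q_start == hits$t_start & hits$q_end == hits$t_end
  hits <- hits[!self, , drop = FALSE]
  if (nrow(hits) > 0L) {
    tmask <- mapply(function(sid, s, e) mask_overlap(mask, sid, s, e),
                    hits$target_id, hits$t_start, hits$t_end)
    hits <- hits[tmask <= 0.8 * (hits$t_end - hits$t_start), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

## ---- tandem detector -----------------------------------------------------

# TRUE if `seq` contains a tandem run (period <= max_period, >= 3 units,
# total run length >= min_run bp)
has_tandem_run <- function(seq, max_period = 6L, min_run = 11L) {
  nrow(tandem_runs(seq, max_period = max_period, min_run = min_run)) > 0L
}

# All tandem runs of period 1..max_period with >= 3 units and total length
# >= min_run, as data.frame(start, end, period), 0-based half-open.
tandem_runs <- function(seq, max_period = 6L, min_run = 11L) {
  n <- nchar(seq)
  out <- list()
  if (n >= 2L) {
    v <- utf8ToInt(seq)
    for (p in 1:min(max_period, n - 1L)) {
      w <- which(v[(p + 1L):n] == v[1:(n - p)])
      if (length(w) == 0L) next
      br <- which(diff(w) > 1L)
      starts <- w[c(1L, br + 1L)]
      lens <- w[c(br, length(w))] - starts + 1L
      total <- lens + p          # run length incl. the first unit
      keep <- total >= min_run & total >= 3L * p
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          start = starts[keep] - 1L, end = starts[keep] - 1L + total[keep],
          period = p)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0), period = integer(0)))
  do.call(rbind, out)
}

#' Pre-mask tandem repeats in a genome
#'
#' Desk-scale tandem masking with the internal run detector (the published
#' TRF parameter intent is recorded in the run config for provenance).
#'
#' @param records named character vector of sequences.
#' @param mask a `tinyte_mask` to grow.
#' @param max_period maximum repeat period considered (default 12 bp).
#' @param min_run minimum total run length to mask (default 50 bp).
#' @return the updated mask.
#' @export
mask_tandem <- function(records, mask, max_period = 12L, min_run = 50L) {
  for (sid in names(records)) {
    tr <- tandem_runs(records[[sid]], max_period = max_period, min_run = min_run)
    if (nrow(tr) > 0L) {
      mask <- mask_add(mask, data.frame(seq_id = sid, start = tr$start,
                                        end = tr$end))
    }
  }
  mask
}
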