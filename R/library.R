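# Library construction: nested-TE unwrapping, redundancy clustering under
# the 95-95-80-80 rule, FMEA-bridged clustering for deletion-bearing LTR
# copies, majority-rule consensus calling, rule-based classification, and
# protein-domain mapping.

#' Serialize / deserialize TE models as JSON
#'
#' @param models list of `te_model`s.
#' @param path JSON path.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    x <- unclass(m)
    x$copies <- if (is.null(x$copies)) NULL else as.list(x$copies)
    x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(x) {
    cp <- if (is.null(x$copies)) NULL else
      as.data.frame(x$copies, stringsAsFactors = FALSE)
    te_model(x$te_class, x$seq_id, x$start, x$end,
             strand = x$strand %||% "+",
             terminal_len = x$terminal_len %||% 0L,
             tsd = x$tsd, copies = cp, consensus = x$consensus,
             terminal_identity = x$terminal_identity %||% NA_real_,
             family_id = x$family_id %||% NA_character_)
  })
}

# pairwise merged-coverage table among a set of sequences (blastn all-vs-all)
pairwise_coverage <- function(seqs, min_identity = 0.8, min_aln = 80L,
                              task = "blastn") {
  db <- blast_db(seqs)
  hits <- blast_search(seqs, db, task = task, min_identity = min_identity,
                       min_len = min_aln, max_targets = length(seqs) + 10L)
  hits <- hits[hits$query_id != hits$target_id, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(q = character(0), t = character(0), cov_q = numeric(0),
                      cov_t = numeric(0), identity = numeric(0)))
  key <- paste(hits$query_id, hits$target_id, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  out <- lapply(parts, function(ix) {
    h <- hits[ix, , drop = FALSE]
    q <- h$query_id[[1L]]; t <- h$target_id[[1L]]
    data.frame(q = q, t = t,
               cov_q = union_len(h$q_start, h$q_end) / nchar(seqs[[q]]),
               cov_t = union_len(h$t_start, h$t_end) / nchar(seqs[[t]]),
               identity = stats::weighted.mean(h$identity, h$aln_len),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Unwrap nested TEs
#'
#' Iteratively excises, from every model sequence, embedded spans matching
#' another (shorter) model at > 95% coverage of the embedded model and
#' > 95% identity, rejoins the flanks, and drops post-join sequences shorter
#' than 100 bp; iterates to a fixpoint or at most `max_iter` times.
#'
#' @param seqs named character vector of model sequences.
#' @param cfg a [tinyte_config()].
#' @param max_iter maximum iterations (default `cfg$unwrap_max_iter`).
#' @return named character vector of unwrapped sequences (dropped entries
#'   removed); the number of iterations used is in attribute `"iterations"`.
#' @export
unwrap_nested <- function(seqs, cfg = tinyte_config(), max_iter = NULL) {
  max_iter <- max_iter %||% cfg$unwrap_max_iter
  it <- 0L
  repeat {
    it <- it + 1L
    changed <- FALSE
    if (length(seqs) < 2L) break
    db <- blast_db(seqs)
    hits <- blast_search(seqs, db, task = "blastn",
                         min_identity = cfg$unwrap_identity, min_len = 80L,
                         max_targets = length(seqs) + 10L)
    hits <- hits[hits$query_id != hits$target_id, , drop = FALSE]
    lens <- nchar(seqs)
    excise <- stats::setNames(vector("list", length(seqs)), names(seqs))
    if (nrow(hits) > 0L) {
      key <- paste(hits$query_id, hits$target_id, sep = "\r")
      for (ix in split(seq_len(nrow(hits)), key)) {
        h <- hits[ix, , drop = FALSE]
        emb <- h$query_id[[1L]]; host <- h$target_id[[1L]]
        if (lens[[emb]] >= lens[[host]]) next
        cov <- union_len(h$q_start, h$q_end) / lens[[emb]]
        if (cov <= cfg$unwrap_cov) next
        # the embedded match must be one contiguous span on the host: a
        # match fragmented across a large host-side gap means the HOST
        # carries an insertion inside a copy of the embedded element, and
        # it is that insertion (matched by its own model) that is excised
        tiv <- IRanges::reduce(IRanges::IRanges(h$t_start + 1L, h$t_end),
                               min.gapwidth = 50L)
        if (length(tiv) != 1L) next
        excise[[host]] <- c(excise[[host]],
                            list(data.frame(start = IRanges::start(tiv) - 1L,
                                            end = IRanges::end(tiv))))
      }
    }
    new_seqs <- seqs
    for (nm in names(seqs)) {
      ex <- excise[[nm]]
      if (is.null(ex)) next
      ex <- do.call(rbind, ex)
      ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      keepir <- IRanges::setdiff(IRanges::IRanges(1L, lens[[nm]]), ir)
      pieces <- vapply(seq_along(keepir), function(i) {
        substr(seqs[[nm]], IRanges::start(keepir)[i], IRanges::end(keepir)[i])
      }, character(1))
      joined <- paste(pieces, collapse = "")
      if (nchar(joined) != lens[[nm]]) changed <- TRUE
      new_seqs[[nm]] <- joined
    }
    drop <- nchar(new_seqs) < cfg$unwrap_min_len
    if (any(drop)) changed <- TRUE
    seqs <- new_seqs[!drop]
    if (!changed || it >= max_iter) break
  }
  attr(seqs, "iterations") <- it
  seqs
}

#' Split an LTR model into its 5' LTR, internal region and 3' LTR
#'
#' @param model an LTR `te_model` with `terminal_len > 0`.
#' @param seq the element sequence (default: the model consensus).
#' @return `list(five_ltr, internal, three_ltr)`; the concatenation
#'   reproduces the element.
#' @export
split_ltr <- function(model, seq = NULL) {
  if (model$te_class != "LTR") stop("split_ltr requires an LTR model")
  if (model$terminal_len <= 0L) stop("LTR model lacks terminal_len")
  seq <- seq %||% model$consensus
  if (is.null(seq)) stop("no sequence available to split")
  n <- nchar(seq)
  t <- model$terminal_len
  if (2L * t >= n) stop("terminal_len too large for element length")
  list(five_ltr = substr(seq, 1L, t),
       internal = substr(seq, t + 1L, n - t),
       three_ltr = substr(seq, n - t + 1L, n))
}

# greedy longest-first clustering given a pairwise coverage table
greedy_cluster <- function(seqs, cov, join_rule) {
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  covkey <- paste(cov$q, cov$t, sep = "\r")
  reps <- character(0)
  members <- list()
  for (nm in ord) {
    placed <- FALSE
    for (ri in seq_along(reps)) {
      r <- reps[[ri]]
      i <- match(paste(nm, r, sep = "\r"), covkey)
      if (!is.na(i) && join_rule(cov[i, ])) {
        members[[ri]] <- c(members[[ri]], nm)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, nm)
      members[[length(members) + 1L]] <- nm
    }
  }
  lapply(seq_along(reps), function(i) {
    structure(list(representative = reps[[i]], members = members[[i]]),
              class = "family_cluster")
  })
}

#' Cluster model sequences under the 95-95-80-80 rule
#'
#' Greedy longest-first clustering (stable tie-break on name): a sequence
#' joins the first existing cluster whose representative it matches at
#' >= 80% identity over an aligned region >= 80 bp covering >= 95% of both
#' sequences.  LTR elements should be clustered per split part (see
#' [split_ltr()], [ltr_consensus_merge()]).
#'
#' @param seqs named character vector of model/part sequences.
#' @param cfg a [tinyte_config()].
#' @return list of `family_cluster` objects (`representative`, `members`).
#' @export
cluster_95958080 <- function(seqs, cfg = tinyte_config()) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  if (length(seqs) == 1L)
    return(list(structure(list(representative = names(seqs),
                               members = names(seqs)),
                          class = "family_cluster")))
  cov <- pairwise_coverage(seqs, min_identity = cfg$cluster_identity,
                           min_aln = cfg$cluster_min_aln)
  greedy_cluster(seqs, cov, function(row) {
    row$cov_q >= cfg$cluster_cov && row$cov_t >= cfg$cluster_cov &&
      row$identity >= cfg$cluster_identity
  })
}

#' Cluster sequences under the conventional 80-80-80 family rule
#'
#' Same greedy scheme, joining when >= 80% of the shorter sequence is
#' covered at >= 80% identity (aligned region >= 80 bp).
#'
#' @inheritParams cluster_95958080
#' @export
cluster_808080 <- function(seqs, cfg = tinyte_config()) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  if (length(seqs) == 1L)
    return(list(structure(list(representative = names(seqs),
                               members = names(seqs)),
                          class = "family_cluster")))
  cov <- pairwise_coverage(seqs, min_identity = 0.8, min_aln = 80L)
  greedy_cluster(seqs, cov, function(row) {
    cov_short <- max(row$cov_q, row$cov_t)
    cov_short >= 0.8 && row$identity >= 0.8
  })
}

#' Cluster LTR exemplars, bridging large internal deletions with FMEA
#'
#' All-vs-all alignment among LTR exemplar sequences; fragmented hit pairs
#' are bridged with [fmea_expand()], an edge connects two exemplars when the
#' bridged chain spans >= 90% of both, and connected components become
#' clusters.
#'
#' @param seqs named character vector of LTR exemplar sequences.
#' @param cfg a [tinyte_config()].
#' @return list of `family_cluster` objects.
#' @export
ltr_consensus_merge <- function(seqs, cfg = tinyte_config()) {
  if (length(seqs) == 0L) return(list())
  singleton <- function(nm) structure(
    list(representative = nm, members = nm), class = "family_cluster")
  if (length(seqs) == 1L) return(list(singleton(names(seqs))))
  db <- blast_db(seqs)
  hits <- blast_search(seqs, db, task = "blastn", min_identity = 0.8,
                       min_len = 80L, max_targets = length(seqs) + 10L)
  hits <- hits[hits$query_id != hits$target_id, , drop = FALSE]
  edges <- character(0)
  for (cl in cluster_hits(hits)) {
    cands <- fmea_expand(cl, max_gap_q = cfg$fmea_max_gap,
                         max_gap_t = cfg$fmea_max_gap)
    if (nrow(cands) == 0L) next
    q <- cl$query_id[[1L]]; t <- cl$target_id[[1L]]
    span_q <- max(cands$end - cands$start)
    span_t <- max(cands$t_hi - cands$t_lo)
    if (span_q >= 0.9 * nchar(seqs[[q]]) && span_t >= 0.9 * nchar(seqs[[t]]))
      edges <- c(edges, q, t)
  }
  g <- igraph::make_graph(edges = edges, isolates = setdiff(names(seqs),
                                                            edges),
                          directed = FALSE)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  lapply(memb, function(ms) {
    ms <- ms[order(-nchar(seqs[ms]), ms)]
    structure(list(representative = ms[[1L]], members = ms),
              class = "family_cluster")
  })
}

#' Majority-rule consensus of a cluster
#'
#' For a single member, the member itself; otherwise an MSA of the members
#' is taken and, per column, the modal non-gap residue is emitted when
#' non-gap rows are at least half of the rows (other columns are skipped).
#'
#' @param members named character vector of member sequences.
#' @return consensus DNA string.
#' @export
call_consensus <- function(members) {
  if (length(members) == 0L) stop("empty cluster")
  if (length(members) == 1L) return(unname(members[[1L]]))
  rows <- run_mafft(members)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nr <- nrow(mat)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, c("A", "C", "G", "T")))
  nongap <- rowSums(counts)
  keep <- nongap >= nr / 2
  base <- c("A", "C", "G", "T")[max.col(counts, ties.method = "first")]
  paste(base[keep], collapse = "")
}

#' Rule-based classification label for a TE model
#'
#' Class comes from the structural search; the superfamily from TSD length
#' and terminal motifs (TA TSD: Tc1-Mariner; 9-11 bp TSD: Mutator;
#' CACT(A/G) termini: EnSpm; TG...CA repeats: LTR, refined to Copia/Gypsy
#' from protein-domain order when domains are available).  `"Unknown"` when
#' no rule fires.
#'
#' @param model a `te_model`.
#' @param domain_hits optional domain-hit table for the family
#'   (see [domain_map()]).
#' @param seq element sequence (default: consensus).
#' @return classification label string.
#' @export
classify_te <- function(model, domain_hits = NULL, seq = NULL) {
  seq <- seq %||% model$consensus
  switch(model$te_class,
    TIR = {
      if (!is.null(seq) && grepl("^CACT[AG]", seq)) return("DNA/TIR/EnSpm")
      if (!is.null(model$tsd)) {
        if (model$tsd$len == 2L && model$tsd$seq == "TA")
          return("DNA/TIR/Tc1-Mariner")
        if (model$tsd$len >= 9L && model$tsd$len <= 11L)
          return("DNA/TIR/Mutator")
      }
      "DNA/TIR"
    },
    Helitron = "Helitron",
    NonLTR = "LINE",
    LTR = {
      if (!is.null(domain_hits) && nrow(domain_hits) > 0L) {
        rt <- domain_hits[grepl("RT|RVT", domain_hits$peptide_id), , drop = FALSE]
        int <- domain_hits[grepl("INT", domain_hits$peptide_id), , drop = FALSE]
        if (nrow(rt) > 0L && nrow(int) > 0L) {
          return(if (min(int$fam_start) < min(rt$fam_start)) "LTR/Copia"
                 else "LTR/Gypsy")
        }
      }
      "LTR"
    },
    "Unknown")
}

#' Map protein domains onto library consensus sequences
#'
#' Six-frame translated search (BLASTX adapter) of every consensus against
#' a TE peptide library; hits with e-value above the cutoff are dropped and
#' colinear fragmented hits to the same peptide with gaps <= `bridge_gap`
#' bp are merged into one continuous domain area.
#'
#' @param library data.frame with `family_id`, `consensus`.
#' @param peptides named character vector of peptide sequences.
#' @param evalue_cut e-value cutoff (default 1e-20).
#' @param bridge_gap maximum bridged gap on the consensus, bp (default 300).
#' @return data.frame `family_id`, `peptide_id`, `fam_start`, `fam_end`
#'   (bp, 0-based half-open on the consensus), `frame`, `evalue`,
#'   `pep_start`, `pep_end` (aa).
#' @export
domain_map <- function(library, peptides, evalue_cut = 1e-20,
                       bridge_gap = 300L) {
  if (length(peptides) == 0L) stop("peptides must be non-empty")
  check_tool("blastx")
  pdb <- blast_db(peptides, type = "prot")
  qfa <- tempfile("dom", fileext = ".fa")
  out <- tempfile("dom", fileext = ".tsv")
  on.exit(unlink(c(qfa, out)), add = TRUE)
  seqs <- stats::setNames(library$consensus, library$family_id)
  write_fasta(seqs, qfa)
  st <- system2("blastx",
                c("-query", qfa, "-db", pdb$prefix, "-outfmt",
                  shQuote(paste("6 qseqid sseqid pident length mismatch",
                                "gapopen qstart qend sstart send evalue",
                                "bitscore qframe")),
                  "-evalue", format(evalue_cut, scientific = TRUE),
                  "-out", out, "-num_threads", "1"),
                stdout = TRUE, stderr = TRUE)
  empty <- data.frame(family_id = character(0), peptide_id = character(0),
                      fam_start = integer(0), fam_end = integer(0),
                      frame = integer(0), evalue = numeric(0),
                      pep_start = integer(0), pep_end = integer(0))
  if (!file.exists(out) || file.size(out) == 0L) return(empty)
  df <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("q", "s", "pident", "len", "mism",
                                        "gap", "qstart", "qend", "sstart",
                                        "send", "evalue", "bits", "frame"))
  df <- df[df$evalue <= evalue_cut, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  df$q_lo <- pmin(df$qstart, df$qend) - 1L
  df$q_hi <- pmax(df$qstart, df$qend)
  key <- paste(df$q, df$s, sign(df$frame), sep = "\r")
  out_rows <- list()
  for (ix in split(seq_len(nrow(df)), key)) {
    h <- df[ix, , drop = FALSE]
    h <- h[order(h$q_lo), , drop = FALSE]
    cur <- h[1L, ]
    flushes <- list()
    for (i in seq_len(nrow(h))[-1L]) {
      nx <- h[i, ]
      if (nx$q_lo - cur$q_hi <= bridge_gap) {
        cur$q_hi <- max(cur$q_hi, nx$q_hi)
        cur$sstart <- min(cur$sstart, nx$sstart)
        cur$send <- max(cur$send, nx$send)
        cur$evalue <- min(cur$evalue, nx$evalue)
      } else {
        flushes <- c(flushes, list(cur)); cur <- nx
      }
    }
    flushes <- c(flushes, list(cur))
    for (f in flushes) {
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        family_id = f$q, peptide_id = f$s, fam_start = f$q_lo,
        fam_end = f$q_hi, frame = f$frame, evalue = f$evalue,
        pep_start = min(f$sstart, f$send), pep_end = max(f$sstart, f$send),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out_rows)
  res <- res[order(res$family_id, res$fam_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Partition a test library into novel and known families
#'
#' Joint clustering of test and known entries under the 80-80-80 rule:
#' clusters containing any known entry mark their test members as
#' `known_matched`; pure-test clusters are `novel`.  Novel families whose
#' terminal 30 bp match a known terminal at >= 80% identity are additionally
#' reported as `novel_with_known_terminals` (non-autonomous elements
#' carrying autonomous-partner termini).
#'
#' @param library test library data.frame (`family_id`, `classification`,
#'   `consensus`).
#' @param known known library data.frame (same schema).
#' @param cfg a [tinyte_config()].
#' @return list of three data.frames: `novel`, `known_matched`,
#'   `novel_with_known_terminals` (subset of novel).
#' @export
partition_novel <- function(library, known, cfg = tinyte_config()) {
  if (nrow(library) == 0L || nrow(known) == 0L)
    stop("both libraries must be non-empty")
  tseq <- stats::setNames(library$consensus, paste0("test::", library$family_id))
  kseq <- stats::setNames(known$consensus, paste0("known::", known$family_id))
  clusters <- cluster_808080(c(tseq, kseq), cfg)
  novel_ids <- character(0); matched_ids <- character(0)
  for (cl in clusters) {
    is_known <- startsWith(cl$members, "known::")
    test_ids <- sub("^test::", "", cl$members[!is_known])
    if (any(is_known)) matched_ids <- c(matched_ids, test_ids)
    else novel_ids <- c(novel_ids, test_ids)
  }
  novel <- library[library$family_id %in% novel_ids, , drop = FALSE]
  matched <- library[library$family_id %in% matched_ids, , drop = FALSE]
  term30 <- function(s) c(substr(s, 1L, 30L),
                          substr(s, max(1L, nchar(s) - 29L), nchar(s)))
  kt <- unlist(lapply(known$consensus, term30))
  kt <- c(kt, revcomp(kt))
  shared <- vapply(novel$consensus, function(s) {
    nt <- term30(s)
    any(vapply(nt, function(a) {
      any(vapply(kt, function(b) pair_identity(a, b) >= 0.8, logical(1)))
    }, logical(1)))
  }, logical(1))
  list(novel = novel, known_matched = matched,
       novel_with_known_terminals = novel[shared, , drop = FALSE])
}
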