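# False-positive filtering: terminal tandem filter, TIR-inside-LTR filter,
# and the homology-boundary method — multiple sequence alignment of extended
# copies, sliding-window detection of the column where copy homology begins,
# and dynamic boundary adjustment with structural re-verification.

#' Terminal tandem-repeat filter
#'
#' An element fails when either terminal 20 bp contains a tandem run of
#' period 1-6 bp with at least 3 units and total length strictly greater
#' than 10 bp (fake TIR elements often begin with TA-type simple repeats).
#'
#' @param element DNA string (>= 20 bp).
#' @param cfg a [tinyte_config()].
#' @return `"pass"` or `"fail"`.
#' @export
filter_tandem <- function(element, cfg = tinyte_config()) {
  n <- nchar(element)
  if (n < 20L) stop("element must be >= 20 bp")
  w <- cfg$tandem_terminal
  head <- substr(element, 1L, w)
  tail <- substr(element, n - w + 1L, n)
  bad <- has_tandem_run(head, cfg$tandem_max_period, cfg$tandem_min_run) ||
    has_tandem_run(tail, cfg$tandem_max_period, cfg$tandem_min_run)
  if (bad) "fail" else "pass"
}

#' Remove TIR models lying almost entirely inside LTR retrotransposons
#'
#' Short TIR-like termini with legal TSDs occur inside LTR-RTs by chance;
#' a TIR model whose exemplar overlaps the union of LTR intervals over more
#' than 95% of its length is a false positive and is dropped.
#'
#' @param tir_models list of TIR `te_model`s.
#' @param ltr_models list of LTR `te_model`s.
#' @return filtered list of TIR models.
#' @export
filter_tir_in_ltr <- function(tir_models, ltr_models) {
  if (length(ltr_models) == 0L || length(tir_models) == 0L) return(tir_models)
  ltr_iv <- list()
  for (m in ltr_models) {
    ltr_iv[[m$seq_id]] <- c(ltr_iv[[m$seq_id]],
                            list(IRanges::IRanges(m$start + 1L, m$end)))
  }
  ltr_iv <- lapply(ltr_iv, function(l) IRanges::reduce(do.call(c, l)))
  keep <- vapply(tir_models, function(m) {
    iv <- ltr_iv[[m$seq_id]]
    if (is.null(iv)) return(TRUE)
    q <- IRanges::IRanges(m$start + 1L, m$end)
    ov <- sum(IRanges::width(IRanges::intersect(iv, q)))
    ov <= 0.95 * (m$end - m$start)
  }, logical(1))
  tir_models[keep]
}

#' Multiple sequence alignment via the external MSA engine
#'
#' Deterministic MAFFT invocation (`--retree 2 --maxiterate 0`); input order
#' is preserved, output is uppercased.
#'
#' @param seqs named character vector.
#' @return named character vector of aligned rows (equal widths).
#' @export
run_mafft <- function(seqs) {
  check_tool("mafft")
  if (length(seqs) < 2L) stop("need >= 2 sequences for an MSA")
  inf <- tempfile("msa", fileext = ".fa")
  outf <- tempfile("msa", fileext = ".aln.fa")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  write_fasta(seqs, inf)
  st <- system2("mafft", c("--quiet", "--retree", "2", "--maxiterate", "0",
                           inf), stdout = outf, stderr = FALSE)
  if (st != 0L) stop("mafft failed with status ", st)
  aln <- Biostrings::readBStringSet(outf)
  out <- toupper(as.character(aln))
  names(out) <- sub("\\s.*$", "", names(aln))
  out[names(seqs)]
}

#' Build the extended copy alignment block for a model
#'
#' Retrieves up to `max_copies` genome copies of the exemplar (80-80 floor),
#' extends each by `ext` bp on both sides (clipped at contig ends), and
#' aligns them.  Returns `NULL` when fewer than 2 copies exist (a transposon
#' must occur at least twice in the genome).
#'
#' @param genome named character vector of sequences.
#' @param model a `te_model` (its `copies` are used when present).
#' @param cfg a [tinyte_config()].
#' @param db assembly `tinyte_blastdb` (needed when copies are absent).
#' @param ext flank extension in bp (default `cfg$msa_ext`).
#' @return object of class `copy_alignment` — `rows` (aligned strings),
#'   `el_cols` (element span in alignment columns), `exemplar_row`,
#'   `row_meta`, `ext` — or `NULL`.
#' @export
build_copy_alignment <- function(genome, model, cfg = tinyte_config(),
                                 db = NULL, ext = NULL) {
  ext <- as.integer(ext %||% cfg$msa_ext)
  copies <- model$copies
  if (is.null(copies) || nrow(copies) == 0L) {
    if (is.null(db)) db <- blast_db(genome)
    exemplar <- subseq0(genome[[model$seq_id]], model$start, model$end)
    copies <- find_copies(exemplar, db, cfg)
  }
  if (nrow(copies) < 2L) return(NULL)
  # boundary detection works on full-length copies when enough exist:
  # truncated copies put their random flank inside the element columns and
  # blur the conservation signal
  el_len <- model$end - model$start
  qc <- if (is.null(copies$q_cov)) rep(NA_real_, nrow(copies)) else copies$q_cov
  full <- !is.na(qc) & qc >= 0.95 &
    (copies$end - copies$start) >= 0.9 * el_len &
    (copies$end - copies$start) <= 1.1 * el_len
  if (sum(full) >= 2L) copies <- copies[full, , drop = FALSE]
  copies <- copies[order(copies$seq_id, copies$start), , drop = FALSE]
  if (nrow(copies) > cfg$msa_max_copies)
    copies <- copies[seq_len(cfg$msa_max_copies), , drop = FALSE]
  # exemplar row: the copy containing the model interval
  ov <- copies$seq_id == model$seq_id &
    pmin(copies$end, model$end) - pmax(copies$start, model$start) >=
      0.8 * (model$end - model$start)
  if (!any(ov)) {
    # ensure the exemplar locus itself is present
    copies <- rbind(copies, data.frame(
      seq_id = model$seq_id, start = model$start, end = model$end,
      strand = "+", identity = 1, q_cov = 1))
    copies <- copies[order(copies$seq_id, copies$start), , drop = FALSE]
    ov <- copies$seq_id == model$seq_id &
      pmin(copies$end, model$end) - pmax(copies$start, model$start) >=
        0.8 * (model$end - model$start)
  }
  ex_row <- which(ov)[1L]
  seqs <- character(nrow(copies))
  fl <- integer(nrow(copies))
  clipped <- logical(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    x <- extract_with_flanks(genome, copies[i, ], ext,
                             orient = copies$strand[i] == "-" && i != ex_row)
    seqs[i] <- x$seq
    fl[i] <- x$flank_left
    clipped[i] <- x$flank_left < ext || x$flank_right < ext
  }
  names(seqs) <- sprintf("copy_%03d", seq_len(nrow(copies)))
  rows <- run_mafft(seqs)
  row_meta <- cbind(copies, flank_left = fl, clipped = clipped)
  # element span of the exemplar in alignment columns
  lo <- copies$start[ex_row] - fl[ex_row]
  es_bp <- model$start - lo + 1L            # 1-based within the exemplar row
  ee_bp <- model$end - lo
  ex_chars <- strsplit(rows[[ex_row]], "", fixed = TRUE)[[1]]
  bp_of_col <- cumsum(ex_chars != "-")
  cs <- which(bp_of_col == es_bp & ex_chars != "-")[1L]
  ce <- which(bp_of_col == ee_bp & ex_chars != "-")[1L]
  structure(list(rows = rows, el_cols = c(cs, ce), exemplar_row = ex_row,
                 row_meta = row_meta, ext = ext, row_lo = lo),
            class = "copy_alignment")
}

#' Detect homology boundaries in a copy alignment block
#'
#' A column is conserved when its modal residue frequency among non-gap rows
#' is >= `col_conservation` and at least half the rows are non-gap.  Scanning
#' inward from each alignment edge, the homology boundary is the first window
#' of `window` consecutive conserved columns.  When that window lies more
#' than `ext/2` columns outside the element span the flanks themselves are
#' homologous — the hallmark of a segmental duplication or over-extended
#' candidate — and the verdict is `fail_homologous_flank`.
#'
#' @param block a `copy_alignment`.
#' @param window sliding-window width in columns (default 10).
#' @param col_conservation modal-residue threshold (default 0.8).
#' @return a `boundary_call` list: `left_col`, `right_col`, `left_shift`,
#'   `right_shift` (bp relative to the element ends), `verdict`.
#' @export
detect_homology_boundary <- function(block, window = 10L,
                                     col_conservation = 0.8) {
  if (is.null(block) || length(block$rows) < 2L)
    stop("alignment block must have >= 2 rows")
  mat <- do.call(rbind, strsplit(block$rows, "", fixed = TRUE))
  nr <- nrow(mat)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  nongap <- rowSums(counts) + colSums(mat == "N")
  modal <- apply(counts, 1L, max)
  conserved <- nongap >= pmax(2, nr / 2) & modal / pmax(nongap, 1L) >=
    col_conservation
  nc <- length(conserved)
  roll <- if (nc >= window) {
    cs <- cumsum(c(0L, conserved))
    (cs[(window + 1L):(nc + 1L)] - cs[1:(nc - window + 1L)]) == window
  } else logical(0)
  win_starts <- which(roll)
  res <- list(left_col = NA_integer_, right_col = NA_integer_,
              left_shift = NA_integer_, right_shift = NA_integer_,
              verdict = "fail_structure")
  class(res) <- "boundary_call"
  if (length(win_starts) == 0L) return(res)
  left_col <- win_starts[[1L]]
  right_col <- max(win_starts) + window - 1L
  cs_el <- block$el_cols[[1L]]; ce_el <- block$el_cols[[2L]]
  half <- block$ext / 2
  if ((cs_el - left_col) > half || (right_col - ce_el) > half) {
    res$left_col <- left_col; res$right_col <- right_col
    res$verdict <- "fail_homologous_flank"
    return(res)
  }
  ex_chars <- mat[block$exemplar_row, ]
  bp_of_col <- cumsum(ex_chars != "-")
  bpL <- bp_of_col[[left_col]] + (if (ex_chars[[left_col]] == "-") 1L else 0L)
  bpR <- bp_of_col[[right_col]]
  es_bp <- bp_of_col[[cs_el]]
  ee_bp <- bp_of_col[[ce_el]]
  res$left_col <- left_col; res$right_col <- right_col
  res$left_shift <- bpL - es_bp
  res$right_shift <- bpR - ee_bp
  res$verdict <- "pass"
  res
}

#' Adjust model boundaries to the homology boundary and re-verify structure
#'
#' The element ends are moved to the homology boundary (mapped back to
#' genome coordinates on the exemplar) and the class-specific structure is
#' re-checked there: TIR needs identical TSDs plus a terminal inverted
#' repeat, Helitron the A|TC...CTRR|T termini plus hairpin, non-LTR a TSD
#' plus polyA.  Models whose re-check fails are rejected
#' (`fail_structure`); LTR models pass through unchanged (their structure
#' is anchored by the LTR search itself).
#'
#' @param model a `te_model`.
#' @param call a `boundary_call` with verdict `"pass"`.
#' @param genome named character vector of sequences.
#' @param block the `copy_alignment` the call was made on.
#' @param cfg a [tinyte_config()].
#' @return the adjusted `te_model`, or a list with element
#'   `verdict = "fail_structure"`.
#' @export
adjust_and_verify <- function(model, call, genome, block,
                              cfg = tinyte_config()) {
  stopifnot(call$verdict == "pass")
  if (model$te_class == "LTR") return(model)
  gb_left <- model$start + call$left_shift
  gb_right <- model$end + call$right_shift
  # family-level TSD-length vote for TIR models: only the true length
  # recurs copy after copy, chance matches of other lengths do not
  k_star <- NULL
  if (model$te_class == "TIR" && !is.null(model$copies) &&
      nrow(model$copies) >= 2L) {
    votes <- integer(0)
    for (i in seq_len(nrow(model$copies))) {
      votes <- c(votes, tir_copy_best_k(genome, model$copies[i, ], cfg))
    }
    if (length(votes)) {
      tab <- table(votes)
      ks <- as.integer(names(tab))
      k_star <- ks[order(-as.integer(tab), -ks)[1L]]   # ties: longer TSD
    }
  }
  # Fixed point: a homology boundary at or just OUTSIDE the structural ends
  # (TSDs shared across all copies, e.g. TA target sites, pull the boundary
  # a few columns into the flanks) confirms the ends when the structure
  # re-validates there.  A boundary strictly INSIDE the ends means the
  # structural call overshot (e.g. a TSD-prefix shadow match) and the ends
  # are re-derived around the boundary.
  if (call$left_shift >= -3L && call$left_shift <= 0L &&
      call$right_shift <= 3L && call$right_shift >= 0L &&
      (is.null(k_star) || (!is.null(model$tsd) && model$tsd$len == k_star)) &&
      verify_structure_at(genome, model, cfg)) {
    return(model)
  }
  cfg2 <- cfg
  cfg2$tsd_ext <- cfg$adjust_ext
  cand2 <- list(seq_id = model$seq_id, start = gb_left, end = gb_right)
  # non-LTR 3' ends are anchored by the polyA tail; the homopolymer aligns
  # raggedly, so the right homology boundary is not trusted for them
  if (model$te_class == "NonLTR") cand2$end <- model$end
  res <- switch(model$te_class,
    TIR = call_tir(genome, cand2, cfg2, k_prefer = k_star),
    Helitron = call_helitron(genome, cand2, cfg2),
    NonLTR = call_nonltr(genome, cand2, cfg2, db = NULL,
                         k_prefer = if (!is.null(model$tsd)) model$tsd$len),
    list())
  if (length(res) == 0L) return(list(verdict = "fail_structure"))
  new <- res[[1L]]
  new$family_id <- model$family_id
  new$copies <- model$copies
  new$consensus <- model$consensus
  new
}

# does the class-specific structure hold exactly at the model's current ends?
verify_structure_at <- function(genome, model, cfg = tinyte_config()) {
  seq <- genome[[model$seq_id]]
  s <- model$start; e <- model$end
  el <- subseq0(seq, s, e)
  switch(model$te_class,
    TIR = {
      if (is.null(model$tsd)) return(FALSE)
      k <- model$tsd$len
      if (s < k || e + k > nchar(seq)) return(FALSE)
      if (subseq0(seq, s - k, s) != subseq0(seq, e, e + k)) return(FALSE)
      !is.null(find_itr(el, min_len = cfg$itr_min_len,
                        max_len = cfg$itr_max_len,
                        max_mismatch_frac = cfg$itr_max_mismatch,
                        band = cfg$itr_band))
    },
    Helitron = {
      s >= 1L && e < nchar(seq) &&
        char_at0(seq, s - 1L) == "A" && char_at0(seq, e) == "T" &&
        substr(el, 1L, 2L) == "TC" &&
        grepl("^CT[AG][AG]$", substr(el, nchar(el) - 3L, nchar(el))) &&
        has_hairpin(el)
    },
    NonLTR = {
      if (!grepl(sprintf("A{%d}$", cfg$polya_min_run), el)) return(FALSE)
      if (is.null(model$tsd)) return(FALSE)
      k <- model$tsd$len
      s >= k && e + k <= nchar(seq) &&
        subseq0(seq, s - k, s) == subseq0(seq, e, e + k)
    },
    TRUE)
}

#' Run the full false-positive filter chain on one model
#'
#' Terminal tandem filter (TIR models), copy-alignment construction
#' (fail_low_copy when the element occurs fewer than twice), homology
#' boundary detection, and boundary adjustment with structural
#' re-verification.
#'
#' @param genome named character vector of sequences.
#' @param model a `te_model`.
#' @param cfg a [tinyte_config()].
#' @param db assembly `tinyte_blastdb`.
#' @return list with `model` (adjusted, or `NULL` when rejected),
#'   `verdict`, `left_shift`, `right_shift`.
#' @export
filter_model <- function(genome, model, cfg = tinyte_config(), db = NULL) {
  el <- subseq0(genome[[model$seq_id]], model$start, model$end)
  if (model$te_class == "TIR" && filter_tandem(el, cfg) == "fail") {
    return(list(model = NULL, verdict = "fail_tandem",
                left_shift = NA_integer_, right_shift = NA_integer_))
  }
  block <- build_copy_alignment(genome, model, cfg, db = db)
  if (is.null(block)) {
    return(list(model = NULL, verdict = "fail_low_copy",
                left_shift = NA_integer_, right_shift = NA_integer_))
  }
  if (is.null(model$copies) || nrow(model$copies) == 0L) {
    model$copies <- block$row_meta[, c("seq_id", "start", "end", "strand",
                                       "identity", "q_cov")]
  }
  call <- detect_homology_boundary(block, window = cfg$msa_window,
                                   col_conservation = cfg$msa_col_conservation)
  if (call$verdict != "pass") {
    return(list(model = NULL, verdict = call$verdict,
                left_shift = call$left_shift, right_shift = call$right_shift))
  }
  adj <- adjust_and_verify(model, call, genome, block, cfg)
  if (!inherits(adj, "te_model")) {
    return(list(model = NULL, verdict = adj$verdict,
                left_shift = call$left_shift, right_shift = call$right_shift))
  }
  list(model = adj, verdict = "pass",
       left_shift = call$left_shift, right_shift = call$right_shift)
}
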