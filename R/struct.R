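# Signature-based fine-boundary TE identification inside FMEA coarse
# candidates: TSD enumeration, terminal-inverted-repeat search, and the
# class-specific callers for TIR, Helitron, non-LTR and (structural) LTR
# elements, plus insertion-time dating and homology annotation.

#' Construct a TE model
#'
#' @param te_class one of `"LTR"`, `"TIR"`, `"Helitron"`, `"NonLTR"`.
#' @param seq_id,start,end exemplar copy interval (0-based half-open).
#' @param strand exemplar strand.
#' @param terminal_len TIR/LTR terminal repeat length (0 otherwise).
#' @param tsd `list(seq, len)` or `NULL`.
#' @param copies data.frame of genome copies or `NULL`.
#' @param consensus consensus string or `NULL` (filled by library building).
#' @param terminal_identity identity between the exemplar's two termini.
#' @param family_id family name (assigned by the pipeline).
#' @return object of class `te_model`.
#' @export
te_model <- function(te_class, seq_id, start, end, strand = "+",
                     terminal_len = 0L, tsd = NULL, copies = NULL,
                     consensus = NULL, terminal_identity = NA_real_,
                     family_id = NA_character_) {
  stopifnot(start < end)
  structure(list(
    family_id = family_id, te_class = te_class, seq_id = seq_id,
    start = as.integer(start), end = as.integer(end), strand = strand,
    terminal_len = as.integer(terminal_len), tsd = tsd, copies = copies,
    consensus = consensus, terminal_identity = terminal_identity
  ), class = "te_model")
}

# fast reverse complement on an integer (utf8) DNA vector
comp_int <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- utf8ToInt("T"); m[utf8ToInt("T")] <- utf8ToInt("A")
  m[utf8ToInt("C")] <- utf8ToInt("G"); m[utf8ToInt("G")] <- utf8ToInt("C")
  m[utf8ToInt("N")] <- utf8ToInt("N")
  function(v) m[v]
})

#' Enumerate identical flanking TSD pairs around a coarse candidate
#'
#' Both boundaries are allowed to move within `ext` bp of the coarse
#' boundaries; every pair of identical k-mers (k in `legal_lens`) with the
#' left copy ending at the element start and the right copy beginning at the
#' element end is reported, ordered by total boundary shift
#' |new start - coarse start| + |new end - coarse end| ascending (ties:
#' longer TSD first).
#'
#' @param genome named character vector of sequences.
#' @param cand one coarse candidate (list or one-row data.frame with
#'   `seq_id`, `start`, `end`).
#' @param ext search extension in bp (>= max legal TSD length).
#' @param legal_lens integer vector of legal TSD lengths.
#' @return data.frame with `tsd`, `k`, `start`, `end`, `shift` (element
#'   interval in genome coordinates).
#' @export
find_tsds <- function(genome, cand, ext = 50L, legal_lens = 2:11) {
  seq <- genome[[cand$seq_id]]
  n <- nchar(seq)
  kmax <- max(legal_lens)
  if (ext < kmax) stop("ext must be >= max(legal_lens)")
  s_lo <- cand$start - ext; s_hi <- cand$start + ext
  e_lo <- cand$end - ext; e_hi <- cand$end + ext
  clipped <- FALSE
  if (s_lo < kmax) { s_lo <- kmax; clipped <- TRUE }
  if (e_hi > n - kmax) { e_hi <- n - kmax; clipped <- TRUE }
  if (clipped) warning("find_tsds: search window clipped at contig bounds")
  out <- list()
  for (k in sort(legal_lens, decreasing = TRUE)) {
    ss <- s_lo:s_hi
    ee <- e_lo:e_hi
    left <- substring(seq, ss - k + 1L, ss)        # k-mer ending at element start
    right <- substring(seq, ee + 1L, ee + k)       # k-mer starting at element end
    li <- split(ss, left)
    ri <- split(ee, right)
    shared <- intersect(names(li), names(ri))
    shared <- shared[nchar(shared) == k & !grepl("N", shared, fixed = TRUE)]
    for (w in shared) {
      grid <- expand.grid(s = li[[w]], e = ri[[w]])
      grid <- grid[grid$e - grid$s >= 80L, , drop = FALSE]
      if (nrow(grid) == 0L) next
      # Superfamilies with fixed target sites (2-3 bp TSDs: TA, TAA/TTA)
      # carry the same TSD at every copy, so alignment/homology-derived
      # reference boundaries conventionally include the TSD; the distance
      # is then measured TSD-inclusively.
      d_s <- if (k <= 3L) abs(grid$s - k - cand$start)
             else abs(grid$s - cand$start)
      d_e <- if (k <= 3L) abs(grid$e + k - cand$end)
             else abs(grid$e - cand$end)
      out[[length(out) + 1L]] <- data.frame(
        tsd = w, k = k, start = grid$s, end = grid$e, shift = d_s + d_e,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(tsd = character(0), k = integer(0), start = integer(0),
                      end = integer(0), shift = integer(0)))
  res <- do.call(rbind, out)
  # near-ties (3 bp buckets) resolved in favour of the longer TSD: prefix /
  # suffix fragments of the true TSD always match too and must not shadow it
  res <- res[order(res$shift %/% 3L, -res$k, res$shift, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Search for a terminal inverted repeat
#'
#' Finds the longest L in `[min_len, max_len]` such that the element prefix
#' of length L aligns to the reverse complement of its suffix of length L
#' with identity >= 1 - `max_mismatch_frac`, using a banded edit alignment
#' (band `band`).  A cheap diagonal (mismatch-only) screen skips hopeless
#' elements before the DP.
#'
#' @param element DNA string (length >= 2 * min_len).
#' @param min_len,max_len ITR length bounds.
#' @param max_mismatch_frac maximum mismatch fraction (default 0.2).
#' @param band edit-alignment band width.
#' @return `list(tir_len, identity)` or `NULL`.
#' @export
find_itr <- function(element, min_len = 7L, max_len = 300L,
                     max_mismatch_frac = 0.2, band = 5L) {
  n <- nchar(element)
  if (n < 2L * min_len) stop("element shorter than 2 * min_len")
  maxL <- min(max_len, n %/% 2L)
  v <- utf8ToInt(element)
  pre <- v[1:maxL]
  suf_rc <- rev(comp_int(v))[1:maxL]       # revcomp of element, first maxL
  # screen: mismatch-only identity along the diagonal
  mm <- cumsum(pre != suf_rc)
  L_all <- seq_len(maxL)
  id_h <- 1 - mm / L_all
  if (!any(id_h[min_len:maxL] >= 1 - max_mismatch_frac - 0.15)) return(NULL)
  d <- banded_diag_edit(intToUtf8(pre), intToUtf8(suf_rc), band = band)
  idty <- 1 - d / L_all
  ok <- which(idty >= 1 - max_mismatch_frac)
  ok <- ok[ok >= min_len]
  if (length(ok) == 0L) return(NULL)
  L <- max(ok)
  list(tir_len = L, identity = idty[[L]])
}

#' Call a TIR element inside a coarse candidate
#'
#' Composes [find_tsds()] (legal lengths 2-11 bp) and [find_itr()]; among
#' TSD/ITR-consistent boundary pairs the one minimising the total shift from
#' the coarse boundaries is returned.
#'
#' @param genome named character vector of sequences.
#' @param cand one coarse candidate.
#' @param cfg a [tinyte_config()].
#' @return list of 0 or 1 `te_model` (class TIR).
#' @export
call_tir <- function(genome, cand, cfg = tinyte_config(), k_prefer = NULL) {
  tsds <- find_tsds(genome, cand, ext = cfg$tsd_ext,
                    legal_lens = cfg$tir_tsd_lens)
  # superfamily TSD constraints: 2 bp TSDs are TA (Tc1-Mariner), 3 bp TSDs
  # are TAA/TTA (Tourist-like); chance dimer/trimer repeats are not TSDs
  keep <- (tsds$k >= 4L) | (tsds$k == 2L & tsds$tsd == "TA") |
    (tsds$k == 3L & tsds$tsd %in% c("TAA", "TTA"))
  tsds <- tsds[keep, , drop = FALSE]
  if (nrow(tsds) == 0L) return(list())
  # a family-level TSD-length vote (from the copies) overrides the
  # shift-based ranking: chance matches of other lengths shadow the true
  # TSD by a base or two, but only the true length recurs copy after copy
  if (!is.null(k_prefer) && any(tsds$k == k_prefer)) {
    tsds <- rbind(tsds[tsds$k == k_prefer, , drop = FALSE],
                  tsds[tsds$k != k_prefer, , drop = FALSE])
  }
  n_eval <- min(nrow(tsds), cfg$max_tsd_eval)
  seq <- genome[[cand$seq_id]]
  for (i in seq_len(n_eval)) {
    s <- tsds$start[i]; e <- tsds$end[i]
    el <- subseq0(seq, s, e)
    if (nchar(el) < 2L * cfg$itr_min_len) next
    itr <- find_itr(el, min_len = cfg$itr_min_len, max_len = cfg$itr_max_len,
                    max_mismatch_frac = cfg$itr_max_mismatch,
                    band = cfg$itr_band)
    if (!is.null(itr)) {
      return(list(te_model(
        "TIR", cand$seq_id, s, e, terminal_len = itr$tir_len,
        tsd = list(seq = tsds$tsd[i], len = tsds$k[i]),
        terminal_identity = itr$identity)))
    }
  }
  list()
}

# the TSD length of one genome copy's best ITR-consistent call (one vote
# per copy for the family-level TSD-length vote)
tir_copy_best_k <- function(genome, cp, cfg, ext = 12L, max_eval = 8L) {
  cand <- list(seq_id = cp$seq_id, start = cp$start, end = cp$end)
  tsds <- tryCatch(find_tsds(genome, cand, ext = ext,
                             legal_lens = cfg$tir_tsd_lens),
                   error = function(e) NULL)
  if (is.null(tsds) || nrow(tsds) == 0L) return(integer(0))
  keep <- (tsds$k >= 4L) | (tsds$k == 2L & tsds$tsd == "TA") |
    (tsds$k == 3L & tsds$tsd %in% c("TAA", "TTA"))
  tsds <- tsds[keep, , drop = FALSE]
  seq <- genome[[cp$seq_id]]
  for (i in seq_len(min(nrow(tsds), max_eval))) {
    el <- subseq0(seq, tsds$start[i], tsds$end[i])
    if (nchar(el) < 2L * cfg$itr_min_len) next
    itr <- find_itr(el, min_len = cfg$itr_min_len, max_len = cfg$itr_max_len,
                    max_mismatch_frac = cfg$itr_max_mismatch,
                    band = cfg$itr_band)
    if (!is.null(itr)) return(tsds$k[i])
  }
  integer(0)
}

# palindromic hairpin (stem >= min_stem, loop 3-8 bp) whose 3' end lies
# within `within` bp of the element 3' end
has_hairpin <- function(element, min_stem = 6L, max_stem = 12L,
                        loop_range = 3:8, within = 30L) {
  n <- nchar(element)
  w0 <- max(1L, n - (within + 2L * max_stem + max(loop_range)))
  tail <- substr(element, w0, n)
  v <- utf8ToInt(tail)
  cv <- comp_int(v)
  m <- length(v)
  for (sl in min_stem:max_stem) {
    for (lp in loop_range) {
      span <- 2L * sl + lp
      if (span > m) next
      for (i in 1:(m - span + 1L)) {
        # hairpin 3' end must be within `within` of element end
        hp_end_global <- w0 - 1L + i + span - 1L    # 1-based in element
        if (n - hp_end_global > within) next
        s1 <- v[i:(i + sl - 1L)]
        s2 <- cv[(i + sl + lp + sl - 1L):(i + sl + lp)]   # revcomp of stem2
        if (all(s1 == s2)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Call a Helitron element inside a coarse candidate
#'
#' Looks for element spans whose base before the start is A and base after
#' the end is T, starting `TC`, ending `CT[AG][AG]`, and containing a
#' palindromic hairpin (stem >= 6 bp, loop 3-8 bp) within 30 bp of the 3'
#' end; the span closest to the coarse boundaries is returned.
#'
#' @inheritParams call_tir
#' @return list of 0 or 1 `te_model` (class Helitron, no TSD).
#' @export
call_helitron <- function(genome, cand, cfg = tinyte_config()) {
  seq <- genome[[cand$seq_id]]
  n <- nchar(seq)
  ext <- cfg$tsd_ext
  s_rng <- max(1L, cand$start - ext):min(n - 90L, cand$start + ext)
  e_rng <- max(90L, cand$end - ext):min(n - 1L, cand$end + ext)
  s_ok <- s_rng[char_at0(seq, s_rng - 1L) == "A" &
                  substring(seq, s_rng + 1L, s_rng + 2L) == "TC"]
  term <- substring(seq, e_rng - 3L, e_rng)
  e_ok <- e_rng[char_at0(seq, e_rng) == "T" & grepl("^CT[AG][AG]$", term)]
  if (length(s_ok) == 0L || length(e_ok) == 0L) return(list())
  grid <- expand.grid(s = s_ok, e = e_ok)
  grid <- grid[grid$e - grid$s >= 80L, , drop = FALSE]
  if (nrow(grid) == 0L) return(list())
  grid$shift <- abs(grid$s - cand$start) + abs(grid$e - cand$end)
  grid <- grid[order(grid$shift), , drop = FALSE]
  for (i in seq_len(min(nrow(grid), cfg$max_tsd_eval))) {
    el <- subseq0(seq, grid$s[i], grid$e[i])
    if (has_hairpin(el)) {
      return(list(te_model("Helitron", cand$seq_id, grid$s[i], grid$e[i])))
    }
  }
  list()
}

# locate a polyA run (>= min_run) whose end is nearest `around` (0-based
# position); search restricted to [around - window, around + window];
# returns list(start, end) of the run in 0-based coordinates, or NULL
find_polya <- function(seq, around, window = 50L, min_run = 7L) {
  lo <- max(0L, around - window - 30L)
  hi <- min(nchar(seq), around + window)
  sub <- subseq0(seq, lo, hi)
  runs <- char_runs(sub, "A", min_run)
  if (nrow(runs) == 0L) return(NULL)
  runs$start <- runs$start + lo
  runs$end <- runs$end + lo
  runs <- runs[abs(runs$end - around) <= window, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  best <- runs[order(abs(runs$end - around)), ][1L, ]
  list(start = best$start, end = best$end)
}

# enumerate non-LTR (element start, element end, tsd) candidates given a
# polyA run: the element 3' end may sit up to 5 bp before the run end when
# the TSD itself begins with A (the TSD match disambiguates)
nonltr_tsd_scan <- function(seq, run, s_center, ext, legal_lens, min_run,
                            e_anchor = NULL, all_e = FALSE) {
  n <- nchar(seq)
  e_lo <- max(run$start + min_run, run$end - 5L)
  if (e_lo > run$end) return(NULL)
  # The A bases wandering between the polyA tail and an A-leading TSD make
  # the 3' split ambiguous from a single copy; candidate ends are tried in
  # order of distance from the anchor (the raw/homology 3' end), outermost
  # first on ties.  The first end admitting any TSD match wins; within an
  # end, ties on 5' shift prefer the longest TSD (prefix matches of the true
  # TSD are always present and must not shadow it).
  e_anchor <- min(max(e_anchor %||% run$end, e_lo), run$end)
  e_cand <- seq(run$end, e_lo, by = -1L)
  e_cand <- e_cand[order(abs(e_cand - e_anchor), -e_cand)]
  variants <- list()
  for (e in e_cand) {
    e_best <- NULL
    for (k in sort(legal_lens, decreasing = TRUE)) {
      if (e + k > n) next
      right <- subseq0(seq, e, e + k)
      if (grepl("N", right, fixed = TRUE)) next
      s_rng <- max(k, s_center - ext):(s_center + ext)
      left <- substring(seq, s_rng - k + 1L, s_rng)
      hit <- s_rng[left == right & (e - s_rng) >= 80L]
      if (length(hit)) {
        s <- hit[which.min(abs(hit - s_center))]
        sh <- abs(s - s_center)
        v <- list(s = s, e = e, k = k, tsd = right, shift = sh,
                  t = e - run$start)   # implied element-terminal A length
        variants[[length(variants) + 1L]] <- v
        # 3 bp buckets, longer TSD first within a bucket (TSD-prefix
        # shadows must not win on a 1-2 bp centre bias)
        if (is.null(e_best) || (sh %/% 3L) < (e_best$shift %/% 3L)) {
          e_best <- v
        }
      }
    }
    if (!is.null(e_best) && !all_e) return(e_best)
  }
  if (all_e) variants else NULL
}

#' The non-LTR copy-count acceptance rule
#'
#' A family is genuine when the number of copies with intact TSDs exceeds
#' half of all copies, or exceeds 5.
#'
#' @param n_tsd copies with intact TSD (and polyA).
#' @param n_total all retrieved copies.
#' @return logical.
#' @export
nonltr_copy_rule <- function(n_tsd, n_total) {
  (n_tsd > n_total / 2) || (n_tsd > 5)
}

# per-copy non-LTR structure check on an oriented copy with `flank` bp of
# flanking sequence on both sides
nonltr_copy_ok <- function(seq_fl, flank, copy_len, cfg) {
  run <- find_polya(seq_fl, flank + copy_len, window = cfg$polya_window,
                    min_run = cfg$polya_min_run)
  if (is.null(run)) return(FALSE)
  !is.null(nonltr_tsd_scan(seq_fl, run, flank, cfg$tsd_ext,
                           cfg$nonltr_tsd_lens, cfg$polya_min_run))
}

#' Call a non-LTR element inside a coarse candidate
#'
#' Fixes the 3' end just after a polyA run (>= 7 bp) near the raw 3' end,
#' enumerates 3' TSDs (8-20 bp) and searches for the matching 5' TSD near
#' the raw 5' end; the exemplar is then realigned genome-wide and each copy
#' re-checked, and the family is accepted only when the TSD-bearing copy
#' count exceeds half of all copies or exceeds 5.  Candidates failing the
#' copy rule survive if a supplied peptide library yields an intact LINE
#' domain hit (e-value <= 1e-20 covering >= 50% of a peptide).
#'
#' @inheritParams call_tir
#' @param db nucleotide `tinyte_blastdb` of the assembly (copy retrieval).
#' @param peptides optional named character vector of TE peptides.
#' @return list of 0 or 1 `te_model` (class NonLTR).
#' @export
call_nonltr <- function(genome, cand, cfg = tinyte_config(), db = NULL,
                        peptides = NULL, k_prefer = NULL) {
  seq <- genome[[cand$seq_id]]
  run <- find_polya(seq, cand$end, window = cfg$polya_window,
                    min_run = cfg$polya_min_run)
  if (is.null(run)) return(list())
  variants <- nonltr_tsd_scan(seq, run, cand$start, cfg$tsd_ext,
                              cfg$nonltr_tsd_lens, cfg$polya_min_run,
                              e_anchor = cand$end, all_e = TRUE)
  if (length(variants) == 0L) return(list())
  pick <- function(vs) {
    # minimal total shift (counting the 3' distance from the anchor),
    # ties toward larger e
    d <- vapply(vs, function(v) v$shift + abs(v$e - min(cand$end, run$end)),
                0)
    vs[[order(d, -vapply(vs, `[[`, 0L, "e"))[1L]]]
  }
  best <- if (!is.null(k_prefer) &&
              any(vapply(variants, `[[`, 0L, "k") == k_prefer)) {
    pick(Filter(function(v) v$k == k_prefer, variants))
  } else pick(variants)
  model <- te_model("NonLTR", cand$seq_id, best$s, best$e,
                    tsd = list(seq = best$tsd, len = best$k))
  if (is.null(db)) return(list(model))
  exemplar <- subseq0(seq, best$s, best$e)
  copies <- find_copies(exemplar, db, cfg)
  # Both the TSD length and the element-terminal A-run length are family
  # properties, while chance matches (TSD prefix shadows, A bases wandering
  # between tail and an A-leading TSD, flank-base absorption) vary copy by
  # copy; when several splits are admissible the copies vote.
  if (length(variants) > 1L && nrow(copies) > 1L && is.null(k_prefer)) {
    fl <- cfg$tsd_ext + max(cfg$nonltr_tsd_lens)
    votes_k <- integer(0); votes_t <- integer(0)
    for (i in seq_len(nrow(copies))) {
      cp <- copies[i, ]
      if (cp$seq_id == model$seq_id &&
          min(cp$end, model$end) - max(cp$start, model$start) > 0) next
      cseq <- extract_with_flanks(genome, cp, fl,
                                  orient = cfg$nonltr_strand_aware)
      crun <- find_polya(cseq$seq, cseq$flank_left + (cp$end - cp$start),
                         window = cfg$polya_window,
                         min_run = cfg$polya_min_run)
      if (is.null(crun)) next
      cv <- nonltr_tsd_scan(cseq$seq, crun, cseq$flank_left, cfg$tsd_ext,
                            cfg$nonltr_tsd_lens, cfg$polya_min_run,
                            all_e = TRUE)
      if (length(cv) == 0L) next
      # k vote: one vote per copy, its best call only — every copy also
      # admits all TSD-prefix lengths, which must not vote
      votes_k <- c(votes_k, cv[[1L]]$k)
      votes_t <- c(votes_t, unique(vapply(cv, `[[`, 0L, "t")))
    }
    cand_set <- variants
    if (length(votes_k)) {
      ks <- vapply(cand_set, `[[`, 0L, "k")
      sc <- vapply(ks, function(k) sum(votes_k == k), 0L)
      if (max(sc) > 0L) cand_set <- cand_set[sc == max(sc)]
    }
    if (length(votes_t)) {
      ts <- vapply(cand_set, `[[`, 0L, "t")
      sc <- vapply(ts, function(t) sum(votes_t == t), 0L)
      if (max(sc) > 0L) cand_set <- cand_set[sc == max(sc)]
    }
    best2 <- pick(cand_set)
    if (!identical(best2[c("s", "e")], best[c("s", "e")])) {
      best <- best2
      model <- te_model("NonLTR", cand$seq_id, best$s, best$e,
                        tsd = list(seq = best$tsd, len = best$k))
      exemplar <- subseq0(seq, best$s, best$e)
    }
  }
  n_tot <- nrow(copies)
  n_tsd <- 0L
  fl <- cfg$tsd_ext + max(cfg$nonltr_tsd_lens)
  for (i in seq_len(n_tot)) {
    cp <- copies[i, ]
    cseq <- extract_with_flanks(genome, cp, fl,
                                orient = cfg$nonltr_strand_aware)
    if (nonltr_copy_ok(cseq$seq, cseq$flank_left, cp$end - cp$start, cfg))
      n_tsd <- n_tsd + 1L
  }
  if (!nonltr_copy_rule(n_tsd, n_tot)) {
    rescued <- FALSE
    if (!is.null(peptides)) {
      dh <- domain_map(data.frame(family_id = "cand", classification = "LINE",
                                  consensus = exemplar,
                                  stringsAsFactors = FALSE),
                       peptides, evalue_cut = cfg$domain_evalue,
                       bridge_gap = cfg$domain_bridge_gap)
      if (nrow(dh) > 0L) {
        plen <- nchar(peptides[dh$peptide_id])
        cov <- (dh$pep_end - dh$pep_start) / plen
        rescued <- any(cov >= 0.5)
      }
    }
    if (!rescued) return(list())
  }
  model$copies <- copies
  list(model)
}

# extract a copy interval with `fl` bp flanks; if orient and strand == "-",
# reverse-complement so the copy reads 5'->3'
extract_with_flanks <- function(genome, cp, fl, orient = TRUE) {
  seq <- genome[[cp$seq_id]]
  n <- nchar(seq)
  lo <- max(0L, cp$start - fl)
  hi <- min(n, cp$end + fl)
  s <- subseq0(seq, lo, hi)
  flank_left <- cp$start - lo
  flank_right <- hi - cp$end
  if (orient && !is.null(cp$strand) && cp$strand == "-") {
    s <- revcomp(s)
    tmp <- flank_left; flank_left <- flank_right; flank_right <- tmp
  }
  list(seq = s, flank_left = flank_left, flank_right = flank_right)
}

#' Retrieve genome copies of an exemplar sequence
#'
#' Homology search of the exemplar against the assembly at the 80-80 floor:
#' hits are chained per locus (gaps <= `copy_chain_gap`), and a locus is a
#' copy when the chained hits cover >= `copy_min_cov` of the exemplar.
#' Overlapping loci are merged (best-covered kept).
#'
#' @param exemplar DNA string.
#' @param db nucleotide `tinyte_blastdb` of the assembly.
#' @param cfg a [tinyte_config()].
#' @param max_copies cap on returned copies.
#' @return data.frame `seq_id`, `start`, `end`, `strand`, `identity`,
#'   `q_cov`, sorted by genome position.
#' @export
find_copies <- function(exemplar, db, cfg = tinyte_config(),
                        max_copies = NULL) {
  max_copies <- max_copies %||% cfg$msa_max_copies
  qlen <- nchar(exemplar)
  hits <- blast_search(c(q = exemplar), db, task = cfg$task_copy,
                       min_identity = cfg$copy_min_identity,
                       min_len = min(80L, qlen))
  if (nrow(hits) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), q_cov = numeric(0)))
  loci <- list()
  for (cl in cluster_hits(hits)) {
    idx_chains <- chain_indices(cl, cfg$copy_chain_gap, cfg$copy_chain_gap)
    for (ix in idx_chains) {
      qcov <- union_len(cl$q_start[ix], cl$q_end[ix]) / qlen
      if (qcov < cfg$copy_min_cov) next
      loci[[length(loci) + 1L]] <- data.frame(
        seq_id = cl$target_id[[1L]],
        start = min(cl$t_start[ix]), end = max(cl$t_end[ix]),
        strand = cl$strand[[1L]],
        identity = stats::weighted.mean(cl$identity[ix], cl$aln_len[ix]),
        q_cov = qcov, stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), q_cov = numeric(0)))
  cp <- do.call(rbind, loci)
  # merge overlapping loci: keep the better-covered of any overlapping pair
  cp <- cp[order(-cp$q_cov, cp$seq_id, cp$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cp))
  for (i in seq_len(nrow(cp))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cp))) {
      if (j <= i || !keep[j]) next
      if (cp$seq_id[j] != cp$seq_id[i]) next
      ov <- min(cp$end[i], cp$end[j]) - max(cp$start[i], cp$start[j])
      if (ov > 0.5 * min(cp$end[i] - cp$start[i], cp$end[j] - cp$start[j]))
        keep[j] <- FALSE
    }
  }
  cp <- cp[keep, , drop = FALSE]
  cp <- cp[order(cp$seq_id, cp$start), , drop = FALSE]
  if (nrow(cp) > max_copies) cp <- cp[seq_len(max_copies), , drop = FALSE]
  rownames(cp) <- NULL
  cp
}

# greedy chain membership (same rule as fmea_expand), returning index lists
chain_indices <- function(cluster, max_gap_q, max_gap_t) {
  n <- nrow(cluster)
  if (n == 0L) return(list())
  strand <- cluster$strand[[1L]]
  chains <- list()
  cur <- 1L
  cq_lo <- cluster$q_start[1L]; cq_hi <- cluster$q_end[1L]
  ct_hi <- cluster$t_end[1L]
  for (i in seq_len(n)[-1L]) {
    h <- cluster[i, ]
    if (chainable(strand, cq_lo, cq_hi, ct_hi, h, max_gap_q, max_gap_t)) {
      cur <- c(cur, i)
      cq_lo <- min(cq_lo, h$q_start); cq_hi <- max(cq_hi, h$q_end)
      ct_hi <- max(ct_hi, h$t_end)
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- i
      cq_lo <- h$q_start; cq_hi <- h$q_end; ct_hi <- h$t_end
    }
  }
  chains[[length(chains) + 1L]] <- cur
  chains
}

#' Structural genome-wide LTR retrotransposon search
#'
#' Finds pairs of direct repeats (85-5000 bp, identity >= 0.85, separated by
#' 1-15 kb) from genome self-alignment hits, requires both repeats to start
#' `TG` and end `CA`, and identical flanking 4-6 bp TSDs; boundary offsets
#' of up to 10 bp around the alignment ends are searched to anchor the
#' TG...CA / TSD structure.
#'
#' @param genome named character vector of sequences.
#' @param cfg a [tinyte_config()].
#' @param db nucleotide `tinyte_blastdb` of the assembly; built on the fly
#'   when `NULL`.
#' @param hits optional precomputed genome self-alignment hit table.
#' @return list of `te_model` (class LTR); `terminal_identity` carries the
#'   5'-3' LTR identity used for insertion dating.
#' @export
call_ltr <- function(genome, cfg = tinyte_config(), db = NULL, hits = NULL) {
  if (is.null(db)) db <- blast_db(genome)
  if (is.null(hits)) {
    hits <- blast_search(genome, db, task = cfg$task_genome,
                         min_identity = cfg$ltr_min_identity,
                         min_len = cfg$ltr_min_repeat)
  }
  h <- hits[hits$query_id == hits$target_id & hits$strand == "+", , drop = FALSE]
  if (nrow(h) == 0L) return(list())
  # canonical orientation: left repeat = query interval before target interval
  h <- h[h$q_end <= h$t_start, , drop = FALSE]
  rl <- h$q_end - h$q_start
  rr <- h$t_end - h$t_start
  gap <- h$t_start - h$q_end
  ok <- rl >= cfg$ltr_min_repeat & rl <= cfg$ltr_max_repeat &
    rr >= cfg$ltr_min_repeat & rr <= cfg$ltr_max_repeat &
    h$identity >= cfg$ltr_min_identity &
    gap >= cfg$ltr_min_internal & gap <= cfg$ltr_max_internal
  h <- h[ok, , drop = FALSE]
  if (nrow(h) == 0L) return(list())
  models <- list()
  for (i in seq_len(nrow(h))) {
    sid <- h$query_id[i]
    seq <- genome[[sid]]
    anchor <- ltr_anchor(seq, h$q_start[i], h$q_end[i], h$t_start[i],
                         h$t_end[i], cfg)
    if (is.null(anchor)) next
    models[[length(models) + 1L]] <- te_model(
      "LTR", sid, anchor$s, anchor$e,
      terminal_len = anchor$ltr_len,
      tsd = list(seq = anchor$tsd, len = nchar(anchor$tsd)),
      terminal_identity = h$identity[i])
  }
  if (length(models) <= 1L) return(models)
  # deredundant overlapping calls: keep the highest-identity, earliest
  iv <- data.frame(seq_id = vapply(models, `[[`, "", "seq_id"),
                   start = vapply(models, `[[`, 0L, "start"),
                   end = vapply(models, `[[`, 0L, "end"),
                   idty = vapply(models, `[[`, 0, "terminal_identity"))
  ord <- order(-iv$idty, iv$start)
  keep <- rep(TRUE, nrow(iv))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (b <= a || !keep[j] || iv$seq_id[j] != iv$seq_id[i]) next
      ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
      if (ov > 0.5 * min(iv$end[i] - iv$start[i], iv$end[j] - iv$start[j]))
        keep[j] <- FALSE
    }
  }
  models[keep]
}

# anchor TG...CA + TSD structure near alignment-derived repeat boundaries
ltr_anchor <- function(seq, ls, le, rs, re, cfg, wobble = 10L) {
  n <- nchar(seq)
  for (ds in 0:wobble) for (sgn_s in c(1L, -1L)) {
    s <- ls + sgn_s * ds
    if (s < 7L || substring(seq, s + 1L, s + 2L) != "TG" ||
        substring(seq, rs + (s - ls) + 1L, rs + (s - ls) + 2L) != "TG") next
    for (de in 0:wobble) for (sgn_e in c(1L, -1L)) {
      e <- re + sgn_e * de
      if (e > n - 7L || substring(seq, e - 1L, e) != "CA" ||
          substring(seq, le + (e - re) - 1L, le + (e - re)) != "CA") next
      for (k in sort(cfg$ltr_tsd_lens, decreasing = TRUE)) {
        lt <- subseq0(seq, s - k, s)
        rt <- subseq0(seq, e, e + k)
        if (lt == rt && !grepl("N", lt, fixed = TRUE)) {
          return(list(s = s, e = e, tsd = lt,
                      ltr_len = (le + (e - re)) - s))
        }
      }
    }
  }
  NULL
}

#' Date a TE insertion from its terminal-repeat identity
#'
#' The two LTRs are identical at insertion; divergence K = 1 - identity
#' (optionally Jukes-Cantor corrected) accumulates at 2 * mu per year, so
#' T = K / (2 * mu).
#'
#' @param terminal_identity identity in [0, 1].
#' @param mu per-site per-year mutation rate (default 1.3e-8).
#' @param jc apply the Jukes-Cantor correction K = -3/4 log(1 - 4d/3).
#' @return insertion age in years.
#' @export
date_insertion <- function(terminal_identity, mu = 1.3e-8, jc = FALSE) {
  if (any(terminal_identity < 0 | terminal_identity > 1))
    stop("terminal_identity must be in [0, 1]")
  d <- 1 - terminal_identity
  K <- if (jc) -3 / 4 * log(1 - 4 * d / 3) else d
  K / (2 * mu)
}

#' Annotate a genome with a known TE library
#'
#' Homology scan of every library consensus against the assembly; merged
#' match loci covering >= 80% of the consensus at >= 80% identity are
#' reported per family.
#'
#' @param genome named character vector of sequences.
#' @param library data.frame with `family_id`, `classification`, `consensus`.
#' @param cfg a [tinyte_config()].
#' @param db optional prebuilt assembly `tinyte_blastdb`.
#' @return data.frame `seq_id`, `start`, `end`, `strand`, `family_id`,
#'   `score` (mean identity).
#' @export
annotate_with_library <- function(genome, library, cfg = tinyte_config(),
                                  db = NULL) {
  if (is.null(library) || nrow(library) == 0L) stop("library is empty")
  if (is.null(db)) db <- blast_db(genome)
  out <- list()
  for (i in seq_len(nrow(library))) {
    cp <- find_copies(library$consensus[i], db, cfg)
    if (nrow(cp) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      seq_id = cp$seq_id, start = cp$start, end = cp$end, strand = cp$strand,
      family_id = library$family_id[i], score = round(cp$identity, 4),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family_id = character(0), score = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
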