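# Synthetic genome simulator: plants multi-copy TE families of each class with
# class-correct structural signatures (termini, TSDs, hairpins, polyA tails),
# per-copy degradation (substitutions, indels, truncation), nested insertions,
# and non-TE confounders (tandem arrays, segmental duplications), and records
# exhaustive ground truth.

TE_CLASSES <- c("LTR", "TIR", "Helitron", "NonLTR")

#' Specify a TE family for the simulator
#'
#' TSD lengths are constrained per class: TIR 2-11 bp, non-LTR 8-20 bp,
#' LTR 4-6 bp; Helitrons insert between an A and a T without a TSD.
#'
#' @param family_id family name.
#' @param te_class one of `"LTR"`, `"TIR"`, `"Helitron"`, `"NonLTR"`.
#' @param length progenitor length in bp.
#' @param n_copies number of copies to plant (>= 1).
#' @param tsd_len TSD length in bp (class-legal; ignored for Helitron).
#' @param divergence maximum substitutions/site applied to a copy, in [0, 0.3].
#' @param indel_rate indel events per site per copy.
#' @param truncation_prob probability a copy is 5' or 3' truncated.
#' @param tir_len terminal-inverted-repeat length (TIR class), 10-300 bp.
#' @param ltr_len long-terminal-repeat length (LTR class), 85-5000 bp.
#' @param terminal_motif optional 5' terminal motif for TIR families
#'   (e.g. `"CACTA"` for EnSpm-like termini); the 3' terminus is its
#'   reverse complement.
#' @return a `family_spec` list.
#' @export
family_spec <- function(family_id, te_class, length, n_copies = 5L,
                        tsd_len = NULL, divergence = 0.05, indel_rate = 0.002,
                        truncation_prob = 0, tir_len = 15L, ltr_len = NULL,
                        terminal_motif = NULL) {
  te_class <- match.arg(te_class, TE_CLASSES)
  if (is.null(tsd_len)) {
    tsd_len <- switch(te_class, LTR = 5L, TIR = 9L, Helitron = 0L, NonLTR = 14L)
  }
  legal <- switch(te_class,
    TIR = tsd_len >= 2L && tsd_len <= 11L,
    NonLTR = tsd_len >= 8L && tsd_len <= 20L,
    LTR = tsd_len >= 4L && tsd_len <= 6L,
    Helitron = TRUE
  )
  if (!legal) stop("illegal tsd_len ", tsd_len, " for class ", te_class)
  if (n_copies < 1L) stop("n_copies must be >= 1")
  if (divergence < 0 || divergence > 0.3) stop("divergence must be in [0, 0.3]")
  if (is.null(ltr_len)) ltr_len <- max(85L, min(5000L, as.integer(round(0.15 * length))))
  structure(list(
    family_id = family_id, te_class = te_class, length = as.integer(length),
    n_copies = as.integer(n_copies), tsd_len = as.integer(tsd_len),
    divergence = divergence, indel_rate = indel_rate,
    truncation_prob = truncation_prob, tir_len = as.integer(tir_len),
    ltr_len = as.integer(ltr_len), terminal_motif = terminal_motif
  ), class = "family_spec")
}

# Terminal 20-mers must not be simple tandem runs (real TIR/LTR termini are
# not), otherwise the planted element would be indistinguishable from the
# tandem-repeat false positives the filter is built to remove.
clean_terminal <- function(n) {
  for (i in 1:50) {
    s <- random_dna(n)
    if (!has_tandem_run(substr(s, 1, min(20L, n)), max_period = 6L, min_run = 11L))
      return(s)
  }
  s
}

#' Build a progenitor TE element with its class signature
#'
#' LTR: identical direct repeats (85-5000 bp) starting `TG` and ending `CA`
#' at both element ends.  TIR: perfect terminal inverted repeats.  Helitron:
#' starts `TC`, ends `CTRR`, with a palindromic hairpin (stem 6-10 bp,
#' loop 3-8 bp) ending 5-15 bp upstream of the terminal `CTRR`.  NonLTR:
#' ends with a polyA run (>= 7 bp, default 10).
#'
#' @param spec a [family_spec()].
#' @param rng_seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return a single DNA string.
#' @export
build_element <- function(spec, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  len <- spec$length
  switch(spec$te_class,
    LTR = {
      ltr <- spec$ltr_len
      if (len < 2L * ltr + 100L)
        stop("LTR spec length ", len, " too short for two ", ltr, " bp repeats")
      unit <- paste0("TG", clean_terminal(ltr - 4L), "CA")
      paste0(unit, random_dna(len - 2L * ltr), unit)
    },
    TIR = {
      tl <- spec$tir_len
      if (tl < 10L || tl > 300L) stop("tir_len must be in [10, 300]")
      if (len < 2L * tl + 30L)
        stop("TIR spec length ", len, " too short for two ", tl, " bp termini")
      tir <- clean_terminal(tl)
      if (!is.null(spec$terminal_motif)) {
        m <- toupper(spec$terminal_motif)
        if (nchar(m) > tl) stop("terminal_motif longer than tir_len")
        tir <- paste0(m, substr(tir, nchar(m) + 1L, tl))
      }
      paste0(tir, random_dna(len - 2L * tl), revcomp(tir))
    },
    Helitron = {
      stem_len <- sample(6:10, 1L)
      loop_len <- sample(3:8, 1L)
      spacer <- sample(5:15, 1L)
      hp_len <- 2L * stem_len + loop_len
      head_len <- len - 2L - hp_len - spacer - 4L
      if (head_len < 10L) stop("Helitron spec length ", len, " too short")
      stem <- random_dna(stem_len)
      hairpin <- paste0(stem, random_dna(loop_len), revcomp(stem))
      rr <- paste(sample(c("A", "G"), 2L, replace = TRUE), collapse = "")
      paste0("TC", random_dna(head_len), hairpin, random_dna(spacer), "CT", rr)
    },
    NonLTR = {
      pa <- 16L
      if (len < pa + 30L) stop("NonLTR spec length ", len, " too short")
      body <- random_dna(len - pa)
      # terminal base before the polyA run must not extend it ambiguously
      if (substr(body, nchar(body), nchar(body)) == "A")
        substr(body, nchar(body), nchar(body)) <- "G"
      paste0(body, strrep("A", pa))
    }
  )
}

# apply substitutions / indels / truncation to one copy
degrade_copy <- function(element, divergence, indel_rate, truncation_prob) {
  seq <- element
  full <- TRUE
  if (truncation_prob > 0 && stats::runif(1) < truncation_prob) {
    frac <- stats::runif(1, 0.1, 0.5)
    n <- nchar(seq)
    cut <- as.integer(round(frac * n))
    seq <- if (stats::runif(1) < 0.5) substr(seq, cut + 1L, n)
           else substr(seq, 1L, n - cut)
    full <- FALSE
  }
  n <- nchar(seq)
  if (divergence > 0) {
    nsub <- stats::rbinom(1L, n, divergence)
    if (nsub > 0) {
      pos <- sample.int(n, min(nsub, n))
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      seq <- paste(ch, collapse = "")
    }
  }
  if (indel_rate > 0) {
    nind <- stats::rpois(1L, indel_rate * n)
    for (i in seq_len(nind)) {
      n <- nchar(seq)
      if (n < 40L) break
      ilen <- stats::rgeom(1L, 1 / 3) + 1L
      p <- sample(10:(n - 10L), 1L)
      if (stats::runif(1) < 0.5) {
        seq <- paste0(substr(seq, 1L, p), random_dna(ilen), substr(seq, p + 1L, n))
      } else {
        seq <- paste0(substr(seq, 1L, p), substr(seq, min(p + ilen, n) + 1L, n))
      }
    }
  }
  list(seq = seq, full_length = full, divergence = divergence)
}

#' Plant TE families and confounders into a random backbone
#'
#' The backbone is i.i.d. uniform A/C/G/T so that regions outside planted
#' elements have no homologs (the premise of the homology-boundary filter).
#' Each insertion duplicates the insertion-site bases as flanking TSDs of the
#' family's TSD length; Helitrons are instead inserted between an A and a T.
#' With probability `nesting_rate` a copy is inserted strictly inside a
#' previously planted TE copy and its parent is recorded.  Confounder
#' segmental duplications are multi-copy non-TE blocks without TSDs or
#' terminal structure; tandem arrays are short-unit repeats.
#'
#' @param specs list of [family_spec()] objects.
#' @param backbone_len backbone length in bp.
#' @param nesting_rate probability in [0,1] that an eligible copy nests.
#' @param confounders list with `tandem_repeats` (count) and `segdup_count`.
#' @param rng_seed integer seed; the run is fully reproducible from it.
#' @param seq_id name of the output sequence.
#' @return list with `records` (named character vector, the genome), `truth`
#'   (data.frame: family_id, class, seq_id, start, end, strand, parent,
#'   full_length, divergence) and `progenitors` (named character vector).
#' @export
plant_genome <- function(specs, backbone_len, nesting_rate = 0,
                         confounders = list(tandem_repeats = 0L, segdup_count = 0L),
                         rng_seed = 1L, seq_id = "chr1") {
  set.seed(rng_seed)
  total <- sum(vapply(specs, function(s) s$length * s$n_copies, numeric(1)))
  if (total >= backbone_len)
    stop("total planted length (", total, ") must be < backbone_len (",
         backbone_len, ")")
  genome <- random_dna(backbone_len)
  truth <- list()   # each: list(family_id, class, start, end, strand, parent, full_length, divergence)

  shift_truth <- function(pos, ins_len) {
    for (i in seq_along(truth)) {
      r <- truth[[i]]
      if (r$start >= pos) {
        r$start <- r$start + ins_len; r$end <- r$end + ins_len
      } else if (r$end > pos) {
        r$end <- r$end + ins_len
      }
      truth[[i]] <<- r
    }
  }

  overlaps_truth <- function(a, b, margin = 100L) {
    for (r in truth) {
      if (a < r$end + margin && b > r$start - margin) return(TRUE)
    }
    FALSE
  }

  free_position <- function(need_left = 25L, need_right = 25L) {
    n <- nchar(genome)
    for (att in 1:1000) {
      pos <- sample((need_left + 1L):(n - need_right), 1L)
      if (!overlaps_truth(pos, pos)) return(pos)
    }
    stop("cannot place insertion without overlap after 1000 attempts; ",
         "use a larger backbone")
  }

  nested_position <- function(min_room = 60L) {
    te <- Filter(function(r) r$class %in% TE_CLASSES &&
                   (r$end - r$start) >= 2L * min_room, truth)
    if (length(te) == 0L) return(NULL)
    p <- te[[sample.int(length(te), 1L)]]
    pos <- sample((p$start + min_room):(p$end - min_room), 1L)
    list(pos = pos, parent = p$family_id, parent_end = p$end)
  }

  insert_seq <- function(pos, str) {
    shift_truth(pos, nchar(str))
    genome <<- paste0(substr(genome, 1L, pos), str,
                      substr(genome, pos + 1L, nchar(genome)))
  }

  progenitors <- character(0)
  for (sp in specs) {
    prog <- build_element(sp)
    progenitors[[sp$family_id]] <- prog
    for (j in seq_len(sp$n_copies)) {
      d <- sp$divergence * stats::runif(1)^2   # burst-skewed copy ages
      cp <- degrade_copy(prog, d, sp$indel_rate, sp$truncation_prob)
      parent <- NA_character_
      if (sp$te_class == "Helitron") {
        # find an A|T dinucleotide near a free position
        pos <- NULL
        for (att in 1:1000) {
          p0 <- free_position()
          hit <- regexpr("AT", substr(genome, p0, min(p0 + 500L, nchar(genome))),
                         fixed = TRUE)
          if (hit > 0) {
            cand <- p0 + hit - 1L   # 0-based index of the T
            if (!overlaps_truth(cand, cand)) { pos <- cand; break }
          }
        }
        if (is.null(pos)) stop("cannot find free A|T Helitron insertion site")
        insert_seq(pos, cp$seq)
        truth[[length(truth) + 1L]] <- list(
          family_id = sp$family_id, class = sp$te_class,
          start = pos, end = pos + nchar(cp$seq), strand = "+",
          parent = parent, full_length = cp$full_length, divergence = d)
      } else {
        k <- sp$tsd_len
        # superfamily-specific target sites: 2 bp TIR TSDs arise at TA
        # dinucleotides (Tc1-Mariner), 3 bp ones at TAA/TTA (Tourist-like)
        site_re <- if (sp$te_class == "TIR" && k == 2L) "TA"
          else if (sp$te_class == "TIR" && k == 3L) "T(AA|TA)"
          else NULL
        nest <- NULL
        if (nesting_rate > 0 && stats::runif(1) < nesting_rate) {
          nest <- nested_position()
        }
        if (!is.null(nest)) {
          pos <- nest$pos; parent <- nest$parent
        } else {
          pos <- free_position(need_left = k + 5L)
        }
        if (!is.null(site_re)) {
          pos <- NULL
          for (att in 1:1000) {
            p0 <- if (!is.null(nest)) nest$pos else free_position(need_left = k + 5L)
            hit <- regexpr(site_re, substr(genome, p0, min(p0 + 500L, nchar(genome))))
            if (hit > 0) {
              cand <- p0 + hit - 2L + k   # 0-based: insertion point after the motif
              if (!is.null(nest)) {
                if (cand <= nest$parent_end - 30L) { pos <- cand; break }
                nest <- NULL; parent <- NA_character_   # fall back to a free site
              } else if (!overlaps_truth(cand, cand)) {
                pos <- cand; break
              }
            } else if (!is.null(nest)) {
              nest <- NULL; parent <- NA_character_
            }
          }
          if (is.null(pos)) stop("cannot find ", site_re, " target site")
        }
        tsd <- subseq0(genome, pos - k, pos)
        insert_seq(pos, paste0(cp$seq, tsd))
        truth[[length(truth) + 1L]] <- list(
          family_id = sp$family_id, class = sp$te_class,
          start = pos, end = pos + nchar(cp$seq), strand = "+",
          parent = parent, full_length = cp$full_length, divergence = d)
      }
    }
  }

  n_tand <- as.integer(confounders$tandem_repeats %||% 0L)
  for (i in seq_len(n_tand)) {
    unit <- random_dna(sample(2:10, 1L))
    reps <- ceiling(sample(80:240, 1L) / nchar(unit))
    arr <- strrep(unit, reps)
    pos <- free_position()
    insert_seq(pos, arr)
    truth[[length(truth) + 1L]] <- list(
      family_id = paste0("tandem_", i), class = "Tandem",
      start = pos, end = pos + nchar(arr), strand = "+",
      parent = NA_character_, full_length = TRUE, divergence = 0)
  }

  n_sd <- as.integer(confounders$segdup_count %||% 0L)
  for (i in seq_len(n_sd)) {
    blen <- sample(800:2000, 1L)
    # source block from a TE-free backbone region
    src <- NULL
    for (att in 1:1000) {
      s0 <- sample(1:(nchar(genome) - blen - 1L), 1L)
      if (!overlaps_truth(s0, s0 + blen)) { src <- s0; break }
    }
    if (is.null(src)) stop("cannot find free segdup source block")
    block <- subseq0(genome, src, src + blen)
    truth[[length(truth) + 1L]] <- list(
      family_id = paste0("segdup_", i), class = "SegDup",
      start = src, end = src + blen, strand = "+",
      parent = NA_character_, full_length = TRUE, divergence = 0)
    for (j in 1:2) {
      cp <- degrade_copy(block, 0.01, 0, 0)
      pos <- free_position()
      insert_seq(pos, cp$seq)
      truth[[length(truth) + 1L]] <- list(
        family_id = paste0("segdup_", i), class = "SegDup",
        start = pos, end = pos + nchar(cp$seq), strand = "+",
        parent = NA_character_, full_length = TRUE, divergence = 0.01)
    }
  }

  tdf <- do.call(rbind, lapply(truth, function(r) {
    data.frame(family_id = r$family_id, class = r$class, seq_id = seq_id,
               start = r$start, end = r$end, strand = r$strand,
               parent = r$parent, full_length = r$full_length,
               divergence = r$divergence, stringsAsFactors = FALSE)
  }))
  tdf <- tdf[order(tdf$start), , drop = FALSE]
  rownames(tdf) <- NULL
  records <- stats::setNames(genome, seq_id)
  list(records = records, truth = tdf, progenitors = progenitors)
}

#' Default simulation conditions
#'
#' Twenty families cycling over the four TE classes on a ~2 Mb backbone,
#' 5-10 copies each, per-family maximum divergence uniform in [0.01, 0.10],
#' light indels, 10% truncated copies, 10% nesting, plus tandem and
#' segmental-duplication confounders.
#'
#' @param n_families number of TE families.
#' @param backbone_len backbone length in bp.
#' @param nesting_rate nesting probability.
#' @param tandem_repeats number of tandem-array confounders.
#' @param segdup_count number of segmental-duplication confounders.
#' @param max_divergence upper end of the per-family divergence range.
#' @param truncation_prob per-copy truncation probability.
#' @param rng_seed integer seed.
#' @return list as returned by [plant_genome()], plus `specs`.
#' @export
simulate_genome <- function(n_families = 20L, backbone_len = 2e6,
                            nesting_rate = 0.10, tandem_repeats = 8L,
                            segdup_count = 4L, max_divergence = 0.10,
                            truncation_prob = 0.10, rng_seed = 1L) {
  set.seed(rng_seed)
  classes <- rep(TE_CLASSES, length.out = n_families)
  specs <- lapply(seq_len(n_families), function(i) {
    cl <- classes[[i]]
    len <- switch(cl,
      LTR = sample(1400:2600, 1L),
      TIR = sample(400:1500, 1L),
      Helitron = sample(600:1500, 1L),
      NonLTR = sample(600:2000, 1L))
    tsd <- switch(cl,
      LTR = sample(4:6, 1L),
      TIR = sample(c(2L, 4:11), 1L),
      Helitron = 0L,
      NonLTR = sample(8:20, 1L))
    family_spec(
      family_id = sprintf("fam%02d_%s", i, cl), te_class = cl, length = len,
      n_copies = sample(5:10, 1L), tsd_len = tsd,
      divergence = stats::runif(1, 0.01, max_divergence),
      indel_rate = 0.002, truncation_prob = truncation_prob,
      tir_len = sample(12:40, 1L))
  })
  out <- plant_genome(specs, backbone_len = backbone_len,
                      nesting_rate = nesting_rate,
                      confounders = list(tandem_repeats = tandem_repeats,
                                         segdup_count = segdup_count),
                      rng_seed = rng_seed + 1L)
  out$specs <- specs
  out
}

#' Write / read the simulator ground-truth table
#'
#' Tab-separated columns: family_id, class, seq_id, start, end, strand,
#' parent, full_length, divergence (internal 0-based half-open coordinates).
#'
#' @param truth truth data.frame from [plant_genome()].
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
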