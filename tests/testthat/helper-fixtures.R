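# Shared fixtures: tiny planted genomes, random hit-set generators, and the
# independent chaining oracle used against FMEA.

# a small planted genome with one family per requested class
tiny_genome <- function(classes = c("TIR", "NonLTR"), backbone = 2e5,
                        n_copies = 5L, divergence = 0.02, seed = 7L,
                        confounders = list(tandem_repeats = 0L,
                                           segdup_count = 0L),
                        nesting_rate = 0, indel_rate = 0.002) {
  set.seed(seed)
  specs <- lapply(seq_along(classes), function(i) {
    cl <- classes[[i]]
    family_spec(paste0("fam", i, "_", cl), cl,
                length = switch(cl, LTR = 1600L, TIR = 500L,
                                Helitron = 700L, NonLTR = 600L),
                n_copies = n_copies, divergence = divergence,
                indel_rate = indel_rate, tir_len = 20L)
  })
  plant_genome(specs, backbone, nesting_rate = nesting_rate,
               confounders = confounders, rng_seed = seed)
}

# disrupt every CT[AG][AG]-before-T site in [lo, hi] (0-based, half-open)
# except the one ending at `keep_end`, so Helitron terminal-gate tests have
# a unique legal 3' site in the search window
purge_helitron_sites <- function(seq, lo, hi, keep_end) {
  repeat {
    sub <- substr(seq, lo + 1L, hi + 4L)
    m <- gregexpr("CT[AG][AG]T", sub)[[1]]
    m <- m[m > 0]
    pos <- lo + m - 1L                       # 0-based start of CTRRT
    pos <- pos[pos + 4L != keep_end]         # keep the true terminus
    if (length(pos) == 0L) return(seq)
    substr(seq, pos[1] + 1L, pos[1] + 1L) <- "G"
  }
}

# likewise, disrupt every A|TC start site in [lo, hi] except the one whose
# element start is `keep_start`
purge_helitron_starts <- function(seq, lo, hi, keep_start) {
  repeat {
    sub <- substr(seq, lo + 1L, hi + 3L)
    m <- gregexpr("ATC", sub)[[1]]
    m <- m[m > 0]
    pos <- lo + m - 1L                       # 0-based position of the A
    pos <- pos[pos + 1L != keep_start]
    if (length(pos) == 0L) return(seq)
    substr(seq, pos[1] + 1L, pos[1] + 1L) <- "G"
  }
}

# substitution-only degraded copy at the given per-site rate
degrade_fixture <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- which(stats::runif(length(ch)) < d)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

make_library <- function(...) {
  entries <- list(...)
  do.call(rbind, lapply(entries, function(e) {
    data.frame(family_id = e[[1]], classification = e[[2]], consensus = e[[3]],
               stringsAsFactors = FALSE)
  }))
}

# random hit sets with the fragmented-copy geometry FMEA consumes: per
# cluster, hits are monotone along both axes (chains along a diagonal),
# consecutive chains separated on the target axis by more than max_gap
random_hit_set <- function(n_max = 50L, max_gap = 1000L) {
  n_clusters <- sample(1:3, 1L)
  rows <- list()
  total <- 0L
  for (ci in seq_len(n_clusters)) {
    strand <- sample(c("+", "-"), 1L)
    target <- paste0("t", ci)
    n_chain <- sample(1:3, 1L)
    t_pos <- sample(0:5000, 1L)
    for (ch in seq_len(n_chain)) {
      m <- sample(1:8, 1L)
      q_pos <- sample(0:50000, 1L)
      q_dir <- if (strand == "+") 1L else -1L
      for (i in seq_len(m)) {
        if (total >= n_max) break
        len <- sample(80:400, 1L)
        gq <- sample(c(sample(-20:800, 1L), sample(1200:2500, 1L)), 1L,
                     prob = c(0.8, 0.2))
        gt <- sample(-20:800, 1L)
        t_pos <- t_pos + gt
        qs <- if (q_dir > 0L) q_pos + gq else q_pos - gq - len
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = "q", q_start = qs, q_end = qs + len,
          target_id = target, t_start = t_pos, t_end = t_pos + len,
          strand = strand, identity = round(stats::runif(1, 0.8, 1), 3),
          aln_len = len, evalue = 1e-10, score = len,
          stringsAsFactors = FALSE)
        q_pos <- if (q_dir > 0L) qs + len else qs
        t_pos <- t_pos + len
        total <- total + 1L
      }
      # next chain starts beyond bridging distance on the target axis
      t_pos <- t_pos + max_gap + sample(500:2000, 1L)
    }
  }
  hits <- do.call(rbind, rows)
  hits[sample.int(nrow(hits)), , drop = FALSE]
}

# pairwise chainability mirroring the expansion rule
.chainable_pair <- function(a, b, max_gap, tol = 20L) {
  gt <- b$t_start - a$t_end
  if (gt < -tol || gt > max_gap) return(FALSE)
  if (a$strand == "+") {
    gq <- b$q_start - a$q_end
  } else {
    gq <- a$q_start - b$q_end
  }
  gq >= -tol && gq <= max_gap
}

# Independent chaining oracle: exhaustive DP for the best single-path chain
# (maximal query span, then most hits), extracted repeatedly.
oracle_chain_spans <- function(cluster, max_gap = 1000L) {
  cl <- cluster[order(cluster$t_start, cluster$t_end), , drop = FALSE]
  remaining <- seq_len(nrow(cl))
  spans <- list()
  while (length(remaining)) {
    sub <- cl[remaining, , drop = FALSE]
    m <- nrow(sub)
    q_lo <- sub$q_start; q_hi <- sub$q_end
    n_hit <- rep(1L, m); pred <- rep(NA_integer_, m)
    for (j in seq_len(m)) {
      for (i in seq_len(m)) {
        if (i >= j) next
        if (!.chainable_pair(sub[i, ], sub[j, ], max_gap)) next
        cand_lo <- min(q_lo[i], sub$q_start[j])
        cand_hi <- max(q_hi[i], sub$q_end[j])
        better <- (cand_hi - cand_lo) > (q_hi[j] - q_lo[j]) ||
          ((cand_hi - cand_lo) == (q_hi[j] - q_lo[j]) &&
             n_hit[i] + 1L > n_hit[j])
        if (better) {
          q_lo[j] <- cand_lo; q_hi[j] <- cand_hi
          n_hit[j] <- n_hit[i] + 1L; pred[j] <- i
        }
      }
    }
    best <- order(-(q_hi - q_lo), -n_hit)[1L]
    path <- best
    while (!is.na(pred[path[1L]])) path <- c(pred[path[1L]], path)
    spans[[length(spans) + 1L]] <- c(min(sub$q_start[path]),
                                     max(sub$q_end[path]))
    remaining <- remaining[-path]
  }
  spans
}

# span multiset as a sorted string for comparison
span_key <- function(spans) {
  paste(sort(vapply(spans, function(s) paste(s, collapse = "-"),
                    character(1))), collapse = ";")
}
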