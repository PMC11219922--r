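# Signature search: TSD enumeration against a brute-force oracle, the ITR
# alignment, the class callers' structural gates, dating, and homology
# annotation.

test_that("find_tsds ranks the planted TSD first and matches exhaustive enumeration", {
  # explicit construction with the TSD CATG and flanks free of chance pairs
  set.seed(41)
  tir <- random_dna(15)
  el <- paste0(tir, random_dna(370), revcomp(tir))
  bg <- random_dna(20000)
  # guard G bases around the TSDs forbid any chance extension of the pair
  seq <- paste0(substr(bg, 1, 9999), "G", "CATG", el, "CATG", "G",
                substr(bg, 10001, 20000))
  s0 <- 10004L; e0 <- s0 + nchar(el)
  g <- c(chr1 = seq)
  cand <- list(seq_id = "chr1", start = s0, end = e0)
  tsds <- find_tsds(g, cand, ext = 20L, legal_lens = 2:11)
  expect_identical(tsds$start[[1]], s0)
  expect_identical(tsds$end[[1]], e0)
  expect_identical(tsds$tsd[[1]], "CATG")
  # brute-force oracle over all (k, left end, right start) triples
  ext <- 12L
  got <- find_tsds(g, cand, ext = ext, legal_lens = 4:6)
  want <- character(0)
  for (k in 4:6) {
    for (s in (s0 - ext):(s0 + ext)) {
      for (e in (e0 - ext):(e0 + ext)) {
        if (e - s < 80L) next
        if (substr(seq, s - k + 1L, s) == substr(seq, e + 1L, e + k))
          want <- c(want, paste(k, s, e))
      }
    }
  }
  expect_setequal(paste(got$k, got$start, got$end), want)

  # candidate with no repeated flanking k-mer: empty result
  set.seed(42)
  plain <- c(chr1 = random_dna(2000))
  none <- find_tsds(plain, list(seq_id = "chr1", start = 900L, end = 1100L),
                    ext = 15L, legal_lens = 8:11)
  expect_identical(nrow(none), 0L)
})

test_that("find_itr recovers exact and mismatched terminal inverted repeats", {
  set.seed(43)
  tir <- random_dna(15)
  el <- paste0(tir, revcomp(tir))                # 30 bp, maxL = 15
  hit <- find_itr(el)
  expect_identical(hit$tir_len, 15L)
  expect_equal(hit$identity, 1.0)

  # 1 mismatch in a 20 bp ITR, element length 40 so L is capped at 20;
  # expected values from the banded-DP definition: d = 1, identity = 0.95
  tir20 <- random_dna(20)
  t2 <- tir20
  substr(t2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(t2, 5, 5))[[1]]
  el2 <- paste0(t2, revcomp(tir20))
  hit2 <- find_itr(el2)
  expect_identical(hit2$tir_len, 20L)
  expect_equal(hit2$identity, 0.95)

  expect_error(find_itr("ACGTACGT", min_len = 7L), "shorter")
})

test_that("random sequences almost never contain an ITR (empirical null)", {
  set.seed(44)
  n_none <- 0L
  for (i in 1:100) {
    if (is.null(find_itr(random_dna(500)))) n_none <- n_none + 1L
  }
  expect_gte(n_none, 95L)
})

test_that("call_tir pins planted boundaries to within the flank ambiguity; the filter chain makes them exact", {
  g <- tiny_genome("TIR", n_copies = 3L, divergence = 0, seed = 45L,
                   indel_rate = 0)
  tr <- g$truth
  cand <- list(seq_id = "chr1", start = tr$start[1] - 2L, end = tr$end[1] + 2L)
  m <- call_tir(g$records, cand)
  expect_identical(length(m), 1L)
  # a single candidate is determined up to flank-base coincidences (+- 2 bp)
  expect_lte(abs(m[[1]]$start - tr$start[1]) + abs(m[[1]]$end - tr$end[1]), 2L)
  expect_identical(m[[1]]$te_class, "TIR")
  expect_gte(m[[1]]$terminal_len, 15L)
  # the homology-boundary filter with the family TSD vote resolves the rest
  db <- blast_db(g$records)
  fr <- filter_model(g$records, m[[1]], db = db)
  expect_identical(fr$verdict, "pass")
  expect_identical(fr$model$start, tr$start[1])
  expect_identical(fr$model$end, tr$end[1])

  set.seed(46)
  plain <- c(chr1 = random_dna(5000))
  none <- call_tir(plain, list(seq_id = "chr1", start = 2000L, end = 3000L))
  expect_identical(length(none), 0L)
})

test_that("call_helitron enforces A|TC...CTRR|T termini: exactly 4 of 16 4-mers pass", {
  set.seed(47)
  sp <- family_spec("h", "Helitron", 600, n_copies = 1L, divergence = 0,
                    indel_rate = 0)
  g <- plant_genome(list(sp), 30000, rng_seed = 47L)
  tr <- g$truth
  seq <- g$records[[1]]
  # leave exactly one legal start and one legal end site in the windows
  seq <- purge_helitron_sites(seq, tr$end - 55L, tr$end + 51L, tr$end)
  seq <- purge_helitron_starts(seq, tr$start - 51L, tr$start + 51L, tr$start)
  # pin the bases after the target-site T so no mutated terminal 4-mer can
  # combine with the flank into a new CT[AG][AG]|T site across the boundary
  substr(seq, tr$end + 2L, tr$end + 4L) <- "CCC"
  cand <- list(seq_id = "chr1", start = tr$start, end = tr$end)
  bases <- c("A", "C", "G", "T")
  good <- c("CTAA", "CTAG", "CTGA", "CTGG")
  for (b3 in bases) for (b4 in bases) {
    fourmer <- paste0("CT", b3, b4)
    mod <- seq
    substr(mod, tr$end - 3L, tr$end) <- fourmer
    res <- call_helitron(stats::setNames(c(mod), "chr1"), cand)
    if (fourmer %in% good) {
      expect_identical(length(res), 1L, label = fourmer)
      expect_identical(res[[1]]$start, tr$start)
      expect_identical(res[[1]]$end, tr$end)
    } else {
      expect_identical(length(res), 0L, label = fourmer)
    }
  }
  # non-A|...|T flanks are rejected even with perfect termini
  mod <- seq
  substr(mod, tr$start, tr$start) <- "G"        # base before the element
  expect_identical(length(call_helitron(stats::setNames(c(mod), "chr1"),
                                        cand)), 0L)
  mod2 <- seq
  substr(mod2, tr$end + 1L, tr$end + 1L) <- "C" # base after the element
  expect_identical(length(call_helitron(stats::setNames(c(mod2), "chr1"),
                                        cand)), 0L)
})

test_that("non-LTR calls need a polyA tail strictly longer than 6 bp", {
  set.seed(48)
  backbone <- random_dna(4000)
  tsd <- "GCTTAGCGTAAT"                          # 12 bp TSD, no leading A
  body <- random_dna(300)
  substr(body, 300, 300) <- "G"
  for (n_a in c(6L, 7L)) {
    el <- paste0(body, strrep("A", n_a))
    seq <- paste0(substr(backbone, 1, 2000), tsd, el, tsd,
                  substr(backbone, 2001, 4000))
    s <- 2000L + nchar(tsd)
    cand <- list(seq_id = "chr1", start = s, end = s + nchar(el))
    res <- call_nonltr(stats::setNames(c(seq), "chr1"), cand)
    if (n_a == 6L) expect_identical(length(res), 0L)
    else {
      expect_identical(length(res), 1L)
      expect_identical(res[[1]]$start, s)
      expect_identical(res[[1]]$end, s + nchar(el))
      expect_identical(res[[1]]$tsd$seq, tsd)
    }
  }
})

test_that("the non-LTR copy-count rule is > half or > 5", {
  expect_true(nonltr_copy_rule(6L, 8L))     # 6 > 4
  expect_false(nonltr_copy_rule(2L, 4L))    # 2 !> 2 and 2 <= 5
  expect_true(nonltr_copy_rule(6L, 12L))    # 6 !> 6 but 6 > 5
  expect_false(nonltr_copy_rule(5L, 10L))   # 5 !> 5 and 5 <= 5
  expect_true(nonltr_copy_rule(1L, 1L))     # 1 > 0.5
})

test_that("structural LTR search finds planted elements exactly and enforces its gates", {
  set.seed(49)
  sp <- family_spec("l", "LTR", 2000, n_copies = 1L, tsd_len = 5L,
                    divergence = 0, indel_rate = 0, ltr_len = 250L)
  g <- plant_genome(list(sp), 60000, rng_seed = 49L)
  tr <- g$truth
  models <- call_ltr(g$records)
  expect_gte(length(models), 1L)
  hit <- vapply(models, function(m) any(m$start == tr$start &
                                          m$end == tr$end), logical(1))
  expect_true(any(hit))
  m <- models[[which(hit)[1]]]
  expect_identical(m$terminal_len, 250L)
  expect_identical(nchar(m$tsd$seq), 5L)

  # repeats starting GG instead of TG are rejected
  seq <- g$records[[1]]
  i <- tr$start[1]
  substr(seq, i + 1L, i + 2L) <- "GG"
  substr(seq, i + 1750L + 1L, i + 1750L + 2L) <- "GG"
  models2 <- call_ltr(stats::setNames(c(seq), "chr1"))
  hit2 <- vapply(models2, function(m) any(m$start == tr$start &
                                            m$end == tr$end), logical(1))
  expect_false(any(hit2))

  # direct repeats shorter than 85 bp never qualify; the internal region and
  # TSD are built so the repeat alignment cannot chance-extend past 84 bp
  set.seed(50)
  unit <- paste0("TG", random_dna(80), "CA")     # 84 bp repeat
  tsd <- "GATTC"
  internal <- paste0("A", random_dna(1198), "A") # != tsd first/last (G, C)
  el <- paste0(unit, internal, unit)
  bg <- random_dna(30000)
  seq3 <- paste0(substr(bg, 1, 15000), tsd, el, tsd, substr(bg, 15001, 30000))
  expect_identical(length(call_ltr(c(chr1 = seq3))), 0L)
})

test_that("insertion dating follows T = K / (2 mu)", {
  expect_identical(date_insertion(1.0), 0)
  expect_equal(date_insertion(0.99), 0.01 / (2 * 1.3e-8))
  expect_equal(date_insertion(0.99), 384615.3846, tolerance = 1e-6)
  expect_gte(date_insertion(0.99, jc = TRUE), date_insertion(0.99))
  expect_error(date_insertion(1.2), "must be in")
})

test_that("library homology annotation recovers planted copies at the 80-80 floor", {
  g <- tiny_genome("TIR", n_copies = 4L, divergence = 0.03, seed = 51L)
  lib <- make_library(list("fam1_TIR", "DNA/TIR",
                           g$progenitors[["fam1_TIR"]]))
  ann <- annotate_with_library(g$records, lib)
  tr <- g$truth
  for (i in seq_len(nrow(tr))) {
    ov <- ann[ann$start < tr$end[i] & ann$end > tr$start[i], ]
    expect_gte(nrow(ov), 1L)
  }
  # a family absent from the genome yields nothing
  set.seed(52)
  lib2 <- make_library(list("alien", "LINE", random_dna(800)))
  expect_identical(nrow(annotate_with_library(g$records, lib2)), 0L)
  expect_error(annotate_with_library(g$records, lib2[0, ]), "empty")
})

test_that("halved copies fall below the 80% coverage rule", {
  set.seed(53)
  prog <- random_dna(1000)
  half <- substr(prog, 1, 500)
  bg <- random_dna(40000)
  seq <- paste0(substr(bg, 1, 10000), half, substr(bg, 10001, 20000),
                prog, substr(bg, 20001, 40000))
  g <- c(chr1 = seq)
  lib <- make_library(list("fam", "Unknown", prog))
  ann <- annotate_with_library(g, lib)
  # the full copy is found, the 50% fragment is not reported
  expect_identical(nrow(ann), 1L)
  expect_gte(ann$end[1] - ann$start[1], 900L)
  expect_gte(ann$start[1], 19000L)
})
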