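# Benchmarking statistics: reciprocal-coverage metrics against a per-pair
# DP oracle, threshold monotonicity, Perfect/Good/Present categories, and
# terminal profiles.

# per-pair coverage oracle via full local DP alignment (Biostrings), for
# libraries built from fragments/copies where one local alignment carries
# the whole relationship
oracle_pair_cov <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  list(cov_a = Biostrings::nchar(Biostrings::pattern(pa)) / nchar(a),
       cov_b = Biostrings::nchar(Biostrings::subject(pa)) / nchar(b),
       pid = Biostrings::pid(pa) / 100)
}

test_that("self-benchmark gives all-ones metrics at every threshold", {
  set.seed(101)
  lib <- make_library(
    list("f1", "DNA/TIR", random_dna(800)),
    list("f2", "LINE", random_dna(1200)),
    list("f3", "Helitron", random_dna(600)))
  for (thr in c(0.80, 0.95, 0.99)) {
    r <- bm_library(lib, lib, thr)
    expect_equal(r$sensitivity, 1.0)
    expect_equal(r$precision, 1.0)
    expect_equal(r$fdr, 0.0)
    expect_equal(r$f1, 1.0)
  }
  expect_error(bm_library(lib[0, ], lib), "empty")
})

test_that("fragments count as false positives but metrics match the DP oracle", {
  set.seed(102)
  gold <- make_library(
    list("g1", "DNA/TIR", random_dna(1000)),
    list("g2", "LINE", random_dna(1400)))
  test <- make_library(
    list("t_full", "DNA/TIR", gold$consensus[[1]]),
    list("t_half", "LINE", substr(gold$consensus[[2]], 1, 700)),
    list("t_junk", "Unknown", random_dna(900)))
  r <- bm_library(test, gold, 0.95)
  # t_full is the only TP; the 50% fragment and the junk entry are FPs
  expect_identical(r$tp, 1L)
  expect_identical(r$fp, 2L)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$precision, 1 / 3)
  expect_equal(r$fdr, 1 - r$precision)
  expect_equal(r$f1, 2 * 0.5 * (1 / 3) / (0.5 + 1 / 3))

  # per-pair coverages agree with the full-DP oracle
  pairs <- tinyte:::bm_pairs(test, gold)$pairs
  for (i in seq_len(nrow(pairs))) {
    o <- oracle_pair_cov(test$consensus[test$family_id == pairs$q[i]],
                         gold$consensus[gold$family_id == pairs$t[i]])
    expect_equal(pairs$cov_q[i], o$cov_a, tolerance = 0.02)
    expect_equal(pairs$cov_t[i], o$cov_b, tolerance = 0.02)
  }
})

test_that("metrics equal the oracle on randomized fragment/copy libraries", {
  set.seed(103)
  for (rep in 1:8) {
    progs <- vapply(1:3, function(i) random_dna(sample(500:1500, 1)),
                    character(1))
    gold <- make_library(list("g1", "X", progs[1]), list("g2", "X", progs[2]),
                         list("g3", "X", progs[3]))
    mk_test <- function(i) {
      p <- progs[sample(3, 1)]
      kind <- sample(c("copy", "frag", "junk"), 1)
      seq <- switch(kind,
        copy = degrade_fixture(p, 0.03),
        frag = substr(p, 1, max(120L, as.integer(nchar(p) * runif(1, 0.3, 0.9)))),
        junk = random_dna(sample(300:1200, 1)))
      list(paste0("t", i), "X", seq)
    }
    test <- do.call(make_library, lapply(1:4, mk_test))
    thr <- 0.9
    r <- bm_library(test, gold, thr)
    # oracle: exhaustive per-pair DP coverage
    otp <- 0L; found <- character(0)
    for (i in seq_len(nrow(test))) {
      is_tp <- FALSE
      for (j in seq_len(nrow(gold))) {
        o <- oracle_pair_cov(test$consensus[i], gold$consensus[j])
        if (o$cov_a > thr && o$cov_b > thr && o$pid >= 0.8) {
          is_tp <- TRUE
          found <- union(found, gold$family_id[j])
        }
      }
      otp <- otp + is_tp
    }
    expect_identical(r$tp, otp)
    expect_equal(r$sensitivity, length(found) / nrow(gold))
  }
})

test_that("sensitivity and precision never increase with the threshold", {
  set.seed(104)
  progs <- vapply(1:4, function(i) random_dna(sample(600:1400, 1)),
                  character(1))
  gold <- do.call(make_library, lapply(1:4, function(i)
    list(paste0("g", i), "X", progs[i])))
  test <- do.call(make_library, lapply(1:5, function(i) {
    p <- progs[sample(4, 1)]
    list(paste0("t", i), "X",
         substr(degrade_fixture(p, 0.02), 1,
                as.integer(nchar(p) * runif(1, 0.85, 1))))
  }))
  pairs <- tinyte:::bm_pairs(test, gold)
  res <- lapply(c(0.80, 0.95, 0.99), function(t)
    bm_library(test, gold, t, pairs = pairs))
  sens <- vapply(res, `[[`, 0, "sensitivity")
  prec <- vapply(res, `[[`, 0, "precision")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(prec) <= 0))
})

test_that("gold families are categorised Perfect / Good / Present / Not_found", {
  set.seed(105)
  g1 <- random_dna(1000)   # exact copy in test -> Perfect
  g2 <- random_dna(1200)   # two abutting halves -> Good
  g3 <- random_dna(900)    # single 60% fragment -> Present
  g4 <- random_dna(800)    # absent -> Not_found
  gold <- make_library(list("g1", "X", g1), list("g2", "X", g2),
                       list("g3", "X", g3), list("g4", "X", g4))
  test <- make_library(
    list("t1", "X", g1),
    list("t2a", "X", substr(g2, 1, 600)),
    list("t2b", "X", substr(g2, 601, 1200)),
    list("t3", "X", substr(g3, 100, 640)))
  cat4 <- rm2_categorize(test, gold)
  expect_identical(unname(cat4["g1"]), "Perfect")
  expect_identical(unname(cat4["g2"]), "Good")
  expect_identical(unname(cat4["g3"]), "Present")
  expect_identical(unname(cat4["g4"]), "Not_found")
})

test_that("terminal profiles are column-normalised and motif-dominated", {
  g <- tiny_genome("Helitron", n_copies = 5L, divergence = 0, seed = 106L,
                   indel_rate = 0)
  tr <- g$truth
  m <- te_model("Helitron", "chr1", tr$start[1], tr$end[1],
                copies = data.frame(seq_id = tr$seq_id, start = tr$start,
                                    end = tr$end, strand = tr$strand))
  prof <- terminal_profile(list(m), g$records)
  expect_identical(dim(prof$five), c(4L, 30L))
  expect_equal(unname(colSums(prof$five)), rep(1, 30))
  expect_equal(unname(colSums(prof$three)), rep(1, 30))
  # Helitron: 5' starts TC, 3' ends CT[AG][AG]
  expect_equal(unname(prof$five["T", 1]), 1)
  expect_equal(unname(prof$five["C", 2]), 1)
  expect_equal(unname(prof$three["C", 27]), 1)
  expect_equal(unname(prof$three["T", 28]), 1)
  expect_equal(sum(prof$three[c("A", "G"), 29]), 1)
  expect_equal(sum(prof$three[c("A", "G"), 30]), 1)

  # single copy: one-hot columns
  m1 <- te_model("Helitron", "chr1", tr$start[1], tr$end[1])
  p1 <- terminal_profile(list(m1), g$records)
  expect_true(all(apply(p1$five, 2, max) == 1))
})
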