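# Library construction: nested unwrapping, LTR splitting, clustering rules,
# consensus calling, classification and domain mapping.

test_that("nested TEs are excised and hosts rejoined to progenitor length", {
  set.seed(81)
  host <- random_dna(1500)
  child <- random_dna(500)
  nested_host <- paste0(substr(host, 1, 700), child,
                        substr(host, 701, 1500))
  seqs <- c(host_clean = host, host_nested = nested_host, child = child)
  out <- unwrap_nested(seqs)
  expect_setequal(names(out), names(seqs))
  expect_lte(abs(nchar(out[["host_nested"]]) - 1500L), 5L)
  expect_identical(out[["child"]], child)
  expect_lte(attr(out, "iterations"), 3L)

  # a host reduced below 100 bp after excision is dropped
  tiny_host <- paste0(substr(host, 1, 50), child, substr(host, 1452, 1500))
  out2 <- unwrap_nested(c(h = tiny_host, child = child))
  expect_false("h" %in% names(out2))
  expect_true(all(nchar(out2) >= 100L))
})

test_that("doubly nested TEs resolve within two iterations", {
  set.seed(82)
  a <- random_dna(400)
  b_prog <- random_dna(900)
  c_prog <- random_dna(1600)
  b <- paste0(substr(b_prog, 1, 450), a, substr(b_prog, 451, 900))
  c2 <- paste0(substr(c_prog, 1, 800), b, substr(c_prog, 801, 1600))
  out <- unwrap_nested(c(A = a, B = b, C = c2))
  expect_lte(abs(nchar(out[["B"]]) - 900L), 5L)
  expect_lte(abs(nchar(out[["C"]]) - 1600L), 5L)
  expect_lte(attr(out, "iterations"), 3L)
  expect_true(all(nchar(out) >= 100L))
})

test_that("split_ltr partitions the element exactly", {
  set.seed(83)
  ltr <- random_dna(200)
  internal <- random_dna(1600)
  el <- paste0(ltr, internal, ltr)
  m <- te_model("LTR", "chr1", 0L, 2000L, terminal_len = 200L,
                consensus = el, terminal_identity = 0.97)
  parts <- split_ltr(m)
  expect_identical(nchar(parts$five_ltr), 200L)
  expect_identical(nchar(parts$internal), 1600L)
  expect_identical(nchar(parts$three_ltr), 200L)
  expect_identical(paste0(parts$five_ltr, parts$internal, parts$three_ltr),
                   el)
  # re-alignment of the two repeats recovers the stored terminal identity
  expect_equal(pair_identity(parts$five_ltr, parts$three_ltr), 1.0)
  expect_error(split_ltr(te_model("TIR", "chr1", 0L, 100L)), "LTR")
})

test_that("95-95-80-80 clustering joins near-duplicates, splits fragments", {
  set.seed(84)
  prog <- random_dna(1000)
  copy <- degrade_fixture(prog, 0.05)
  frag <- substr(prog, 1, 600)
  other <- random_dna(900)
  seqs <- c(full_a = prog, full_b = copy, frag = frag, other = other)
  cl <- cluster_95958080(seqs)
  members <- lapply(cl, `[[`, "members")
  expect_identical(length(cl), 3L)
  expect_true(any(vapply(members, function(m)
    setequal(m, c("full_a", "full_b")), logical(1))))
  expect_true(any(vapply(members, identical, logical(1), "frag")))
  expect_true(any(vapply(members, identical, logical(1), "other")))

  # unrelated random sequences stay singletons
  set.seed(85)
  rnd <- stats::setNames(vapply(1:6, function(i) random_dna(500),
                                character(1)), paste0("r", 1:6))
  expect_identical(length(cluster_95958080(rnd)), 6L)
})

test_that("FMEA-bridged LTR clustering joins deletion-bearing copies", {
  set.seed(86)
  full <- random_dna(4000)
  deleted <- paste0(substr(full, 1, 1700), substr(full, 2201, 4000))
  unrelated <- random_dna(3500)
  cl <- ltr_consensus_merge(c(a = full, b = deleted, u = unrelated))
  key <- vapply(cl, function(x) paste(sort(x$members), collapse = "+"),
                character(1))
  expect_setequal(key, c("a+b", "u"))

  # component structure equals brute-force transitive closure via identity
  cl2 <- ltr_consensus_merge(c(x = full, y = full, z = deleted))
  expect_identical(length(cl2), 1L)
})

test_that("majority-rule consensus recovers the progenitor", {
  set.seed(87)
  prog <- random_dna(800)
  expect_identical(call_consensus(c(a = prog)), prog)

  # explicit 5-row majority column
  rows <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT", e = "AGGT")
  expect_identical(call_consensus(rows), "ACGT")

  copies <- vapply(1:10, function(i) degrade_fixture(prog, 0.05),
                   character(1))
  names(copies) <- paste0("c", 1:10)
  cons <- call_consensus(copies)
  expect_gte(pair_identity(cons, prog), 0.99)
})

test_that("classification follows the TSD / terminal-motif rule table", {
  tir_ta <- te_model("TIR", "chr1", 0L, 500L,
                     tsd = list(seq = "TA", len = 2L))
  expect_identical(classify_te(tir_ta), "DNA/TIR/Tc1-Mariner")
  tir_mut <- te_model("TIR", "chr1", 0L, 500L,
                      tsd = list(seq = "GATCGATCG", len = 9L))
  expect_identical(classify_te(tir_mut), "DNA/TIR/Mutator")
  set.seed(88)
  enspm <- te_model("TIR", "chr1", 0L, 500L,
                    tsd = list(seq = "CAT", len = 3L))
  expect_identical(classify_te(enspm, seq = paste0("CACTA", random_dna(495))),
                   "DNA/TIR/EnSpm")
  expect_identical(classify_te(te_model("Helitron", "chr1", 0L, 500L)),
                   "Helitron")
  expect_identical(classify_te(te_model("NonLTR", "chr1", 0L, 500L)), "LINE")
  expect_identical(classify_te(te_model("LTR", "chr1", 0L, 5000L)), "LTR")
})

test_that("domain mapping finds embedded peptides and bridges split hits", {
  set.seed(89)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  pep <- paste(sample(aa, 150, replace = TRUE), collapse = "")
  # reverse-translate with one codon per amino acid
  gc <- Biostrings::GENETIC_CODE
  codon_of <- vapply(strsplit(pep, "")[[1]],
                     function(a) names(gc)[gc == a][1], character(1))
  orf <- paste(codon_of, collapse = "")
  cons <- paste0(random_dna(200), orf, random_dna(200))
  lib <- make_library(list("famX", "LINE", cons))
  hits <- domain_map(lib, c(pepRT = pep))
  expect_identical(nrow(hits), 1L)
  expect_gte(hits$fam_end[1] - hits$fam_start[1], 440L)
  expect_lte(hits$evalue[1], 1e-20)

  # the same ORF split by a 200 bp insertion is bridged into one hit
  split_cons <- paste0(random_dna(200), substr(orf, 1, 225), random_dna(200),
                       substr(orf, 226, 450), random_dna(200))
  hits2 <- domain_map(make_library(list("famY", "LINE", split_cons)),
                      c(pepRT = pep))
  expect_identical(nrow(hits2), 1L)
  expect_gte(hits2$fam_end[1] - hits2$fam_start[1], 600L)

  # shuffled consensus: no hit at the 1e-20 cutoff
  set.seed(90)
  for (i in 1:5) {
    shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    expect_identical(nrow(domain_map(make_library(list("s", "X", shuf)),
                                     c(pepRT = pep))), 0L)
  }
})

test_that("novel/known partitioning separates families and flags shared terminals", {
  set.seed(91)
  known_prog <- random_dna(1200)
  novel_prog <- random_dna(1000)
  # non-autonomous element sharing only its 40 bp terminals with a known one
  shared <- paste0(substr(known_prog, 1, 40), random_dna(700),
                   substr(known_prog, 1161, 1200))
  test_lib <- make_library(
    list("degraded_known", "DNA/TIR", degrade_fixture(known_prog, 0.05)),
    list("pure_novel", "DNA/TIR", novel_prog),
    list("shared_term", "DNA/TIR", shared))
  known_lib <- make_library(list("known1", "DNA/TIR", known_prog))
  p <- partition_novel(test_lib, known_lib)
  expect_identical(p$known_matched$family_id, "degraded_known")
  expect_setequal(p$novel$family_id, c("pure_novel", "shared_term"))
  expect_identical(p$novel_with_known_terminals$family_id, "shared_term")
})
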