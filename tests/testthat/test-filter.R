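# False-positive filtering: terminal tandem filter, TIR-in-LTR overlap rule,
# the copy-alignment homology boundary, and dynamic boundary adjustment.

test_that("terminal tandem filter fails runs > 10 bp and passes exactly 10 bp", {
  set.seed(61)
  clean <- random_dna(60)
  # ensure the random core itself is clean
  while (filter_tandem(clean) == "fail") clean <- random_dna(60)
  bad <- paste0(strrep("TA", 6), substr(clean, 13, 60))     # 12 bp TA run
  expect_identical(filter_tandem(bad), "fail")
  bad2 <- paste0(substr(clean, 1, 48), strrep("AT", 6))     # at the 3' end
  expect_identical(filter_tandem(bad2), "fail")
  # exactly 10 bp of tandem: the rule is strictly greater than 10
  ten <- paste0(strrep("CACAC", 2), substr(clean, 11, 60))
  run <- tandem_runs(substr(ten, 1, 20), 6L, 11L)
  expect_identical(nrow(run), 0L)
  expect_identical(filter_tandem(ten), "pass")
  expect_error(filter_tandem("ACGT"), ">= 20")
})

test_that("random terminals pass the tandem filter almost always", {
  set.seed(62)
  n_pass <- 0L
  for (i in 1:100) {
    if (filter_tandem(random_dna(100)) == "pass") n_pass <- n_pass + 1L
  }
  expect_gte(n_pass, 95L)
})

test_that("TIR models > 95% inside LTR-RTs are dropped, boundary cases kept", {
  ltr <- list(te_model("LTR", "chr1", 1000L, 11000L, terminal_len = 300L))
  tir_in <- te_model("TIR", "chr1", 2000L, 3000L)          # 100% inside
  tir_96 <- te_model("TIR", "chr1", 960L, 1960L)           # 96% inside
  tir_95 <- te_model("TIR", "chr1", 950L, 1950L)           # exactly 95%
  tir_out <- te_model("TIR", "chr1", 20000L, 21000L)
  kept <- filter_tir_in_ltr(list(tir_in, tir_96, tir_95, tir_out), ltr)
  expect_identical(length(kept), 2L)
  expect_identical(vapply(kept, `[[`, 0L, "start"), c(950L, 20000L))
  # no LTR models: identity
  expect_identical(filter_tir_in_ltr(list(tir_in), list()), list(tir_in))
})

test_that("copy alignment blocks need two copies and are deterministic", {
  set.seed(63)
  # single-copy element in an otherwise random genome
  g <- c(chr1 = random_dna(50000))
  m <- te_model("TIR", "chr1", 20000L, 21000L)
  db <- blast_db(g)
  expect_null(build_copy_alignment(g, m, db = db))

  gg <- tiny_genome("TIR", n_copies = 5L, divergence = 0.02, seed = 64L)
  tr <- gg$truth
  mm <- te_model("TIR", "chr1", tr$start[1], tr$end[1])
  db2 <- blast_db(gg$records)
  b1 <- build_copy_alignment(gg$records, mm, db = db2)
  b2 <- build_copy_alignment(gg$records, mm, db = db2)
  expect_gte(length(b1$rows), 2L)
  expect_identical(b1$rows, b2$rows)
  expect_identical(b1$el_cols, b2$el_cols)
  # rows are sorted by genome position
  expect_false(is.unsorted(b1$row_meta$start))
})

test_that("identical copies align without gaps and their block passes cleanly", {
  set.seed(65)
  el <- random_dna(600)
  bg <- random_dna(30000)
  seq <- paste0(substr(bg, 1, 10000), el, substr(bg, 10001, 20000), el,
                substr(bg, 20001, 30000))
  g <- c(chr1 = seq)
  m <- te_model("TIR", "chr1", 10000L, 10600L)
  db <- blast_db(g)
  # with no flank extension the rows are the identical copies themselves
  b0 <- build_copy_alignment(g, m, db = db, ext = 0L)
  expect_false(any(grepl("-", b0$rows, fixed = TRUE)))
  block <- build_copy_alignment(g, m, db = db)
  call <- detect_homology_boundary(block)
  expect_identical(call$verdict, "pass")
  expect_lte(abs(call$left_shift), 3L)
  expect_lte(abs(call$right_shift), 3L)
})

test_that("homology boundaries sit at the element edges for planted families", {
  ok <- 0L; total <- 0L
  for (seed in 1:6) {
    g <- tiny_genome("TIR", n_copies = 5L, divergence = 0.02,
                     seed = 70L + seed)
    db <- blast_db(g$records)
    tr <- g$truth
    m <- te_model("TIR", "chr1", tr$start[1], tr$end[1])
    block <- build_copy_alignment(g$records, m, db = db)
    call <- detect_homology_boundary(block)
    total <- total + 1L
    if (call$verdict == "pass" && abs(call$left_shift) <= 3L &&
        abs(call$right_shift) <= 3L) ok <- ok + 1L
  }
  expect_gte(ok / total, 0.9)
})

test_that("shared flanks flag a homologous-flank failure", {
  set.seed(66)
  # segmental duplication: element AND flanks duplicated together
  core <- random_dna(900)
  bg <- random_dna(40000)
  seq <- paste0(substr(bg, 1, 10000), core, substr(bg, 10001, 25000), core,
                substr(bg, 25001, 40000))
  g <- c(chr1 = seq)
  # candidate under-covers the duplicated block: flanks are homologous too
  m <- te_model("TIR", "chr1", 10200L, 10700L)
  block <- build_copy_alignment(g, m, db = blast_db(g))
  call <- detect_homology_boundary(block)
  expect_identical(call$verdict, "fail_homologous_flank")
})

test_that("boundary adjustment restores overshot ends and rejects bare homology", {
  g <- tiny_genome("TIR", n_copies = 4L, divergence = 0, seed = 67L,
                   indel_rate = 0)
  db <- blast_db(g$records)
  tr <- g$truth
  # model overshooting the true element by 30 bp on the right
  m <- te_model("TIR", "chr1", tr$start[1], tr$end[1] + 30L,
                tsd = list(seq = "XXXX", len = 4L))
  fr <- filter_model(g$records, m, db = db)
  expect_identical(fr$verdict, "pass")
  expect_identical(fr$model$start, tr$start[1])
  expect_identical(fr$model$end, tr$end[1])
  # contraction: the adjusted interval stays within +-ext of the input
  expect_lte(abs(fr$model$start - m$start), 100L)
  expect_lte(abs(fr$model$end - m$end), 100L)

  # intact model is a fixed point
  m2 <- te_model("TIR", "chr1", tr$start[2], tr$end[2],
                 tsd = list(seq = substr(g$records[[1]], tr$start[2] - 8L,
                                         tr$start[2]), len = 9L))
  fr2 <- filter_model(g$records, m2, db = db)
  expect_identical(fr2$verdict, "pass")
  expect_identical(fr2$model$start, tr$start[2])
  expect_identical(fr2$model$end, tr$end[2])

  # multi-copy block without any TE structure at the boundary: rejected
  set.seed(68)
  core <- random_dna(700)
  bg <- random_dna(40000)
  seq <- paste0(substr(bg, 1, 8000), core, substr(bg, 8001, 22000), core,
                substr(bg, 22001, 40000))
  gg <- c(chr1 = seq)
  m3 <- te_model("TIR", "chr1", 8000L, 8700L)
  fr3 <- filter_model(gg, m3, db = blast_db(gg))
  expect_identical(fr3$verdict, "fail_structure")
  expect_null(fr3$model)
})

test_that("filter verdicts are deterministic", {
  g <- tiny_genome("NonLTR", n_copies = 5L, divergence = 0.03, seed = 69L)
  db <- blast_db(g$records)
  tr <- g$truth
  m <- te_model("NonLTR", "chr1", tr$start[1], tr$end[1],
                tsd = list(seq = substr(g$records[[1]], tr$start[1] - 13L,
                                        tr$start[1]), len = 14L))
  a <- filter_model(g$records, m, db = db)
  b <- filter_model(g$records, m, db = db)
  expect_identical(a$verdict, b$verdict)
  expect_identical(a$left_shift, b$left_shift)
  if (!is.null(a$model)) {
    expect_identical(a$model$start, b$model$start)
    expect_identical(a$model$end, b$model$end)
  }
})
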