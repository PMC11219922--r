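# Shared low-level helpers.  All genomic coordinates inside the package are
# 0-based half-open on the + strand of the assembly; conversion to 1-based
# conventions happens only at file boundaries (io.R) and when talking to
# external tools.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; works on plain uppercase DNA strings (A/C/G/T/N
#' and IUPAC codes).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string
#'
#' Uniform i.i.d. A/C/G/T, drawn from the current RNG stream.
#'
#' @param n length in bp.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# substring in 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# single characters at 0-based positions (vectorised over pos)
char_at0 <- function(seq, pos) {
  substring(seq, pos + 1L, pos + 1L)
}

# check an external tool is on PATH
check_tool <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p)) {
    stop("required external tool '", name, "' not found on PATH", call. = FALSE)
  }
  invisible(p)
}

# empty hit table in the internal schema (0-based half-open coordinates)
empty_hits <- function() {
  data.frame(
    query_id = character(0), q_start = integer(0), q_end = integer(0),
    target_id = character(0), t_start = integer(0), t_end = integer(0),
    strand = character(0), identity = numeric(0), aln_len = integer(0),
    evalue = numeric(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
}

# union length of a set of [start, end) intervals
union_len <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# longest run of a given character; returns data.frame(start, end) of all runs
# with length >= min_len, in 0-based half-open coordinates on `seq`
char_runs <- function(seq, ch, min_len) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] == ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# Banded edit distance along the diagonal: returns d[L] = edit distance between
# a[1..L] and b[1..L] within band |i-j| <= band, for L = 1..min(na, nb).
# Used by the terminal-inverted-repeat search (find_itr).
banded_diag_edit <- function(a, b, band = 5L) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  n <- min(length(av), length(bv))
  if (n == 0L) return(integer(0))
  w <- 2L * band + 1L
  BIG <- n + 10L
  # prev[k] = d[i-1][j] with j = (i-1) + (k - band - 1)
  prev <- rep(BIG, w)
  # row i = 0: d[0][j] = j for j in 0..band
  diag_d <- integer(n)
  row0 <- rep(BIG, w)
  for (k in seq_len(w)) {
    j <- 0L + (k - band - 1L)
    if (j >= 0L && j <= n) row0[k] <- j
  }
  prev <- row0
  for (i in 1L:n) {
    cur <- rep(BIG, w)
    for (k in seq_len(w)) {
      j <- i + (k - band - 1L)
      if (j < 0L || j > n) next
      if (j == 0L) { cur[k] <- i; next }
      sub <- if (k >= 1L) prev[k] else BIG              # d[i-1][j-1] same k
      subc <- sub + (if (av[i] == bv[j]) 0L else 1L)
      del <- if (k + 1L <= w) prev[k + 1L] + 1L else BIG  # d[i-1][j] is k+1
      ins <- if (k - 1L >= 1L) cur[k - 1L] + 1L else BIG  # d[i][j-1]
      cur[k] <- min(subc, del, ins)
    }
    diag_d[i] <- cur[band + 1L]
    prev <- cur
  }
  diag_d
}

#' Global pairwise identity between two sequences
#'
#' Needleman-Wunsch alignment (Biostrings); identity in [0,1] over
#' alignment columns.
#'
#' @param a,b DNA strings.
#' @return identity in [0, 1].
#' @export
pair_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  Biostrings::pid(pa, type = "PID1") / 100
}

# stable file-backed temp dir for one R session
tinyte_tmp <- function(prefix = "tinyte") {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
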