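# Readers/writers for the on-disk artifacts of the pipeline.
#
# Conventions: internal coordinates are 0-based half-open everywhere.
# BED is written/read 0-based half-open, GFF3 1-based inclusive; conversion
# happens here and only here.

#' Read a (possibly gzipped) FASTA file
#'
#' Sequences are uppercased on ingestion (soft-masking state is never carried
#' in sequence case) and IUPAC ambiguity codes other than N are mapped to N;
#' the number of converted bases is reported via a message.
#'
#' @param path path to a FASTA file, optionally gzip-compressed.
#' @return named character vector of uppercase DNA sequences; names are the
#'   first whitespace-delimited token of each header, the full headers are
#'   kept in the `"descriptions"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  if (any(ids == "")) stop("empty sequence id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  seqs <- toupper(as.character(ss))
  n_amb <- sum(vapply(seqs, function(s) {
    nchar(s) - nchar(gsub("[^ACGTN]", "", s))
  }, numeric(1)))
  if (n_amb > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    message("read_fasta: mapped ", n_amb, " non-ACGTN bases to N")
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- full
  seqs
}

#' Write sequences to FASTA (60-column wrapping)
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  # BString keeps this generic over DNA and peptide sequences
  ss <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Write a classified TE library
#'
#' Headers are serialized as `family_id#classification`.  Entries whose
#' consensus is shorter than 80 bp (the family-definition length floor) are
#' dropped with a warning and never written.
#'
#' @param entries data.frame with columns `family_id`, `classification`,
#'   `consensus`.
#' @param path output FASTA path.
#' @return invisibly, the entries actually written.
#' @export
write_library <- function(entries, path) {
  stopifnot(all(c("family_id", "classification", "consensus") %in% names(entries)))
  if (nrow(entries) == 0L) {
    warning("write_library: empty library, writing empty file")
    file.create(path)
    return(invisible(entries))
  }
  short <- nchar(entries$consensus) < 80L
  if (any(short)) {
    warning("write_library: dropping ", sum(short),
            " entr", if (sum(short) == 1L) "y" else "ies",
            " with consensus < 80 bp: ",
            paste(entries$family_id[short], collapse = ", "))
    entries <- entries[!short, , drop = FALSE]
  }
  seqs <- entries$consensus
  names(seqs) <- paste0(entries$family_id, "#", entries$classification)
  write_fasta(seqs, path)
  invisible(entries)
}

#' Read a TE library with `family_id#classification` headers
#'
#' Headers without a `#` get classification `"Unknown"`.
#'
#' @param path FASTA path.
#' @return data.frame with columns `family_id`, `classification`, `consensus`.
#' @export
read_library <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  has <- grepl("#", ids, fixed = TRUE)
  fam <- ifelse(has, sub("#.*$", "", ids), ids)
  cls <- ifelse(has, sub("^[^#]*#", "", ids), "Unknown")
  data.frame(family_id = fam, classification = cls,
             consensus = as.vector(unname(seqs)), stringsAsFactors = FALSE)
}

ann_to_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$seq_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    family_id = ann$family_id,
    score = as.numeric(ann$score)
  )
}

granges_to_ann <- function(gr) {
  fam <- if (!is.null(gr$family_id)) gr$family_id else
    if (!is.null(gr$name)) gr$name else
    if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$ID)) gr$ID else NA_character_
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    family_id = as.character(fam),
    score = sc,
    stringsAsFactors = FALSE
  )
}

#' Write genome annotation intervals as BED6 or GFF3
#'
#' Internal 0-based half-open intervals become 0-based half-open BED records
#' or 1-based inclusive GFF3 records (GFF3 start = internal start + 1).
#'
#' @param ann data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `family_id`, `score`.
#' @param path output path.
#' @param dialect `"BED"` or `"GFF3"`.
#' @export
write_annotation <- function(ann, path, dialect = c("GFF3", "BED")) {
  dialect <- match.arg(dialect)
  need <- c("seq_id", "start", "end", "strand", "family_id", "score")
  stopifnot(all(need %in% names(ann)))
  if (nrow(ann) == 0L) {
    writeLines(if (dialect == "GFF3") "##gff-version 3" else character(0), path)
    return(invisible(path))
  }
  if (dialect == "BED") {
    df <- data.frame(
      chrom = ann$seq_id, start = ann$start, end = ann$end,
      name = ann$family_id,
      score = ifelse(is.na(ann$score), 0, round(as.numeric(ann$score), 6)),
      strand = ann$strand
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    attrs <- paste0("ID=te", seq_len(nrow(ann)), ";Name=", ann$family_id)
    df <- data.frame(
      seqid = ann$seq_id, source = "tinyte", type = "dispersed_repeat",
      start = ann$start + 1L, end = ann$end,
      score = ifelse(is.na(ann$score), ".", format(as.numeric(ann$score), trim = TRUE)),
      strand = ann$strand, phase = ".", attributes = attrs
    )
    con <- file(path, "w")
    writeLines("##gff-version 3", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read a BED6 or GFF3 annotation file back into internal coordinates
#'
#' @param path annotation file.
#' @param dialect `"BED"` or `"GFF3"`; default guesses from the extension.
#' @return data.frame in the `write_annotation()` input schema.
#' @export
read_annotation <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  }
  dialect <- match.arg(dialect, c("GFF3", "BED"))
  gr <- if (dialect == "BED") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  ann <- granges_to_ann(gr)
  if (dialect == "GFF3" && !is.null(gr$Name)) ann$family_id <- as.character(gr$Name)
  ann
}

#' Write pairwise hits in the 12-column tabular dialect
#'
#' Columns: query, target, pct_identity, aln_len, mismatches, gap_opens,
#' qstart, qend, tstart, tend, evalue, score — 1-based inclusive coordinates,
#' target start > end on the minus strand (the common tabular pairwise-hit
#' dialect).
#'
#' @param hits internal hit table (0-based half-open, `strand` column).
#' @param path output TSV path.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  mism <- if (!is.null(hits$mismatches)) hits$mismatches
          else round((1 - hits$identity) * hits$aln_len)
  gaps <- if (!is.null(hits$gap_opens)) hits$gap_opens else rep(0L, n)
  tstart <- ifelse(hits$strand == "+", hits$t_start + 1L, hits$t_end)
  tend <- ifelse(hits$strand == "+", hits$t_end, hits$t_start + 1L)
  df <- data.frame(
    query = hits$query_id, target = hits$target_id,
    pct_identity = round(hits$identity * 100, 3), aln_len = hits$aln_len,
    mismatches = mism, gap_opens = gaps,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    tstart = tstart, tend = tend,
    evalue = hits$evalue %||% rep(NA_real_, n),
    score = hits$score %||% rep(NA_real_, n)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit file into the internal hit schema
#'
#' @param path TSV path (e.g. blastn `-outfmt 6` output).
#' @return internal hit table (0-based half-open, strand split out).
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(empty_hits())
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("query", "target", "pident", "length",
                                        "mismatch", "gapopen", "qstart", "qend",
                                        "sstart", "send", "evalue", "bitscore"))
  minus <- df$sstart > df$send
  data.frame(
    query_id = df$query,
    q_start = df$qstart - 1L, q_end = df$qend,
    target_id = df$target,
    t_start = ifelse(minus, df$send, df$sstart) - 1L,
    t_end = ifelse(minus, df$sstart, df$send),
    strand = ifelse(minus, "-", "+"),
    identity = df$pident / 100,
    aln_len = df$length,
    evalue = df$evalue, score = df$bitscore,
    mismatches = df$mismatch, gap_opens = df$gapopen,
    stringsAsFactors = FALSE
  )
}
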