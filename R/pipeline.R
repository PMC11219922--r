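# Pipeline orchestration: the iterative per-chunk mask-identify-mask loop,
# genome-wide LTR search, filtering, nested unwrapping, clustering/consensus,
# classification and domain mapping, with stage logging and resumable
# artifacts.

#' Detect TE models in an assembly (chunked mask-identify-mask loop)
#'
#' For each chunk: sensitive self-alignment against the assembly (mask
#' applied), FMEA coarse candidates, signature search (TIR, then Helitron,
#' then non-LTR), and the false-positive filter chain; the full-length
#' copies of confirmed models are masked before the next chunk.  A
#' genome-wide structural LTR search follows, and TIR models almost entirely
#' inside LTR-RTs are dropped.
#'
#' @param genome named character vector of sequences.
#' @param cfg a [tinyte_config()].
#' @param db optional prebuilt assembly `tinyte_blastdb`.
#' @param peptides optional TE peptide library (LINE-domain rescue).
#' @param log optional function(line) used for stage logging.
#' @return list with `models` (confirmed `te_model`s, family ids assigned),
#'   `rejects` (data.frame: candidate interval, class tried, verdict,
#'   shifts), `mask`.
#' @export
detect_te_models <- function(genome, cfg = tinyte_config(), db = NULL,
                             peptides = NULL, log = NULL) {
  say <- function(...) if (!is.null(log)) log(sprintf(...))
  if (length(genome) == 0L) stop("no sequences")
  mask <- mask_state(genome)
  mask <- mask_tandem(genome, mask,
                      max_period = cfg$genome_tandem_max_period,
                      min_run = cfg$genome_tandem_min_run)
  say("tandem pre-mask: %d intervals (detector period<=%d run>=%d; TRF intent: %s)",
      nrow(mask_as_df(mask)), cfg$genome_tandem_max_period,
      cfg$genome_tandem_min_run, cfg$trf_params)
  if (is.null(db)) db <- blast_db(genome)
  chunks <- chunk_genome(genome, cfg$chunk_len, cfg$chunk_overlap)
  say("chunking: %d chunks (len %d, overlap %d)", length(chunks),
      cfg$chunk_len, cfg$chunk_overlap)
  models <- list()
  rejects <- list()
  for (ch in chunks) {
    hits <- all_vs_all(list(ch), db, mask, min_identity = cfg$min_identity,
                       min_len = cfg$min_len, task = cfg$task_genome)
    cands <- fmea_candidates(hits, max_gap = cfg$fmea_max_gap)
    say("chunk %s: %d hits, %d coarse candidates", ch$chunk_id, nrow(hits),
        nrow(cands))
    confirmed <- list()
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      if (mask_overlap(mask, cand$seq_id, cand$start, cand$end) >
          0.8 * (cand$end - cand$start)) next
      found <- FALSE
      for (klass in c("TIR", "Helitron", "NonLTR")) {
        mod <- switch(klass,
          TIR = call_tir(genome, cand, cfg),
          Helitron = call_helitron(genome, cand, cfg),
          NonLTR = call_nonltr(genome, cand, cfg, db = db,
                               peptides = peptides))
        if (length(mod) == 0L) next
        fr <- filter_model(genome, mod[[1L]], cfg, db = db)
        rejects[[length(rejects) + 1L]] <- data.frame(
          seq_id = cand$seq_id, start = mod[[1L]]$start, end = mod[[1L]]$end,
          te_class = klass, verdict = fr$verdict,
          left_shift = fr$left_shift, right_shift = fr$right_shift,
          stringsAsFactors = FALSE)
        if (!is.null(fr$model)) {
          confirmed[[length(confirmed) + 1L]] <- fr$model
          found <- TRUE
        }
        if (found) break
      }
    }
    models <- c(models, confirmed)
    mask <- update_mask(mask, confirmed)
  }
  ltr <- call_ltr(genome, cfg, db = db)
  say("LTR search: %d structural LTR-RT models", length(ltr))
  for (i in seq_along(ltr)) {
    ex <- subseq0(genome[[ltr[[i]]$seq_id]], ltr[[i]]$start, ltr[[i]]$end)
    ltr[[i]]$copies <- find_copies(ex, db, cfg)
  }
  tir_idx <- vapply(models, function(m) m$te_class == "TIR", logical(1))
  tirs <- filter_tir_in_ltr(models[tir_idx], ltr)
  models <- c(models[!tir_idx], tirs, ltr)
  # stable family ids by genome position
  ord <- order(vapply(models, `[[`, "", "seq_id"),
               vapply(models, `[[`, 0L, "start"))
  models <- models[ord]
  for (i in seq_along(models)) {
    models[[i]]$family_id <- sprintf("te%03d_%s", i, models[[i]]$te_class)
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               te_class = character(0), verdict = character(0),
               left_shift = integer(0), right_shift = integer(0))
  say("detection: %d confirmed models, %d filter decisions", length(models),
      nrow(rejects))
  list(models = models, rejects = rejects, mask = mask)
}

# build the classified consensus library from confirmed models
build_library <- function(genome, models, cfg, db = NULL, peptides = NULL,
                         log = NULL) {
  say <- function(...) if (!is.null(log)) log(sprintf(...))
  if (length(models) == 0L) {
    return(list(library = data.frame(family_id = character(0),
                                     classification = character(0),
                                     consensus = character(0)),
                clusters = list(), domains = NULL))
  }
  exemplars <- stats::setNames(
    vapply(models, function(m) subseq0(genome[[m$seq_id]], m$start, m$end),
           character(1)),
    vapply(models, `[[`, "", "family_id"))
  unwrapped <- unwrap_nested(exemplars, cfg)
  say("nested unwrapping: %d -> %d sequences in %d iteration(s)",
      length(exemplars), length(unwrapped), attr(unwrapped, "iterations"))
  models <- models[vapply(models, `[[`, "", "family_id") %in% names(unwrapped)]
  classes <- vapply(models, `[[`, "", "te_class")
  fam_ids <- vapply(models, `[[`, "", "family_id")
  clusters <- list()
  for (cl in c("TIR", "Helitron", "NonLTR")) {
    sel <- which(classes == cl)
    if (length(sel) == 0L) next
    seqs <- unwrapped[fam_ids[sel]]
    clusters <- c(clusters, cluster_95958080(seqs, cfg))
  }
  if (any(classes == "LTR")) {
    sel <- which(classes == "LTR")
    clusters <- c(clusters, ltr_consensus_merge(unwrapped[fam_ids[sel]], cfg))
  }
  say("clustering: %d model(s) -> %d famil(ies)", length(models),
      length(clusters))
  by_id <- stats::setNames(models, fam_ids)
  entries <- list()
  final_models <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    rep_model <- by_id[[cl$representative]]
    # consensus from the full-length copies of the member models
    cps <- do.call(rbind, lapply(cl$members, function(mm) {
      m <- by_id[[mm]]
      cp <- m$copies
      if (is.null(cp) || nrow(cp) == 0L)
        cp <- data.frame(seq_id = m$seq_id, start = m$start, end = m$end,
                         strand = "+", identity = 1, q_cov = 1)
      el <- m$end - m$start
      cp[(cp$end - cp$start) >= 0.95 * el & (cp$end - cp$start) <= 1.05 * el, ,
         drop = FALSE]
    }))
    cons <- if (is.null(cps) || nrow(cps) < 2L) {
      unname(unwrapped[[cl$representative]])
    } else {
      if (nrow(cps) > 20L) cps <- cps[seq_len(20L), , drop = FALSE]
      seqs <- vapply(seq_len(nrow(cps)), function(i) {
        extract_with_flanks(genome, cps[i, ], 0L, orient = TRUE)$seq
      }, character(1))
      names(seqs) <- sprintf("m%02d", seq_len(nrow(cps)))
      call_consensus(seqs)
    }
    fam <- sprintf("tinyte_fam%03d", ci)
    m2 <- rep_model
    m2$family_id <- fam
    m2$consensus <- cons
    final_models[[length(final_models) + 1L]] <- m2
    entries[[length(entries) + 1L]] <- data.frame(
      family_id = fam, classification = NA_character_, consensus = cons,
      stringsAsFactors = FALSE)
  }
  library <- do.call(rbind, entries)
  domains <- NULL
  if (!is.null(peptides)) {
    domains <- domain_map(library, peptides, evalue_cut = cfg$domain_evalue,
                          bridge_gap = cfg$domain_bridge_gap)
    say("domain mapping: %d merged domain hit(s)", nrow(domains))
  }
  for (i in seq_along(final_models)) {
    dh <- if (!is.null(domains))
      domains[domains$family_id == library$family_id[i], , drop = FALSE]
    else NULL
    library$classification[i] <- classify_te(final_models[[i]], dh,
                                             seq = library$consensus[i])
  }
  keep <- nchar(library$consensus) >= 80L
  library <- library[keep, , drop = FALSE]
  final_models <- final_models[keep]
  list(library = library, clusters = clusters, domains = domains,
       models = final_models)
}

#' Run the full TE annotation pipeline
#'
#' Executes tandem pre-masking, the iterative chunked mask-identify-mask
#' detection loop, the genome-wide LTR search, false-positive filtering,
#' nested unwrapping, clustering and consensus calling, classification and
#' (optionally) domain mapping, then annotates the genome with the final
#' library.  When `out_dir` is given, stage artifacts are written
#' (`models.json`, `rejects.tsv`, `library.fasta`, `annotation.gff3`,
#' `log.txt`); with `resume = TRUE` stages whose artifacts already exist
#' are skipped and reloaded.
#'
#' @param genome FASTA path or named character vector of sequences.
#' @param cfg a [tinyte_config()].
#' @param known_library optional known-TE library (path or data.frame) used
#'   for additional homology annotation.
#' @param peptides optional TE peptide FASTA (path or named vector).
#' @param out_dir optional output directory.
#' @param resume skip stages whose artifacts exist in `out_dir`.
#' @return object of class `tinyte_run`.
#' @export
run_pipeline <- function(genome, cfg = tinyte_config(), known_library = NULL,
                         peptides = NULL, out_dir = NULL, resume = FALSE) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(line) {
    log_lines <<- c(log_lines, sprintf("[%6.1fs] %s",
                                       as.numeric(Sys.time() - t0, units = "secs"),
                                       line))
  }
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) stop("genome file not found: ", genome)
    genome <- read_fasta(genome)
  }
  if (length(genome) == 0L) stop("no sequences")
  if (is.null(names(genome))) stop("genome sequences must be named")
  if (is.character(known_library) && length(known_library) == 1L &&
      file.exists(known_library)) known_library <- read_library(known_library)
  if (is.character(peptides) && length(peptides) == 1L &&
      file.exists(peptides)) peptides <- read_fasta(peptides)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  set.seed(cfg$seed)
  art <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)
  db <- blast_db(genome)

  models_f <- art("models.json"); rejects_f <- art("rejects.tsv")
  if (resume && !is.null(models_f) && file.exists(models_f) &&
      file.exists(rejects_f)) {
    say("stage detect: resumed from models.json")
    models <- read_models(models_f)
    rejects <- utils::read.table(rejects_f, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  } else {
    det <- detect_te_models(genome, cfg, db = db, peptides = peptides,
                            log = say)
    models <- det$models
    rejects <- det$rejects
    if (!is.null(models_f)) {
      write_models(models, models_f)
      utils::write.table(rejects, rejects_f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  lib_f <- art("library.fasta"); ann_f <- art("annotation.gff3")
  if (resume && !is.null(lib_f) && file.exists(lib_f) &&
      file.exists(ann_f)) {
    say("stage library: resumed from library.fasta")
    library <- read_library(lib_f)
    annotation <- read_annotation(ann_f)
    lib <- list(library = library, clusters = NULL, domains = NULL,
                models = models)
  } else {
    lib <- build_library(genome, models, cfg, db = db, peptides = peptides,
                         log = say)
    library <- lib$library
    annotation <- if (nrow(library) > 0L)
      annotate_with_library(genome, library, cfg, db = db)
    else data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    family_id = character(0), score = numeric(0))
    if (!is.null(known_library)) {
      ka <- annotate_with_library(genome, known_library, cfg, db = db)
      if (nrow(ka) > 0L) {
        ka$family_id <- paste0("known:", ka$family_id)
        annotation <- rbind(annotation, ka)
        annotation <- annotation[order(annotation$seq_id, annotation$start), ,
                                 drop = FALSE]
      }
      say(sprintf("known-library homology annotation: %d interval(s)",
                  nrow(ka)))
    }
    if (!is.null(lib_f)) {
      write_library(library, lib_f)
      write_annotation(annotation, ann_f, dialect = "GFF3")
    }
  }
  say(sprintf("library: %d famil(ies); annotation: %d interval(s)",
              nrow(library), nrow(annotation)))
  if (!is.null(out_dir)) writeLines(log_lines, file.path(out_dir, "log.txt"))
  structure(list(library = library, models = lib$models %||% models,
                 annotation = annotation, rejects = rejects,
                 clusters = lib$clusters, domains = lib$domains,
                 log = log_lines, config = cfg, out_dir = out_dir),
            class = "tinyte_run")
}

#' @export
print.tinyte_run <- function(x, ...) {
  cat("tinyte TE annotation run\n")
  cat(sprintf("  library families : %d\n", nrow(x$library)))
  if (nrow(x$library) > 0L) {
    tab <- table(x$library$classification)
    cat(sprintf("    %-20s %d\n", names(tab), as.integer(tab)), sep = "")
  }
  cat(sprintf("  annotation intervals: %d\n", nrow(x$annotation)))
  cat(sprintf("  filter decisions    : %d (%d rejected)\n",
              nrow(x$rejects), sum(x$rejects$verdict != "pass")))
  invisible(x)
}

#' @export
summary.tinyte_run <- function(object, ...) {
  cat("== tinyte run summary ==\n")
  print(object)
  if (nrow(object$rejects) > 0L) {
    cat("  filter verdicts:\n")
    tab <- table(object$rejects$verdict)
    cat(sprintf("    %-22s %d\n", names(tab), as.integer(tab)), sep = "")
  }
  if (nrow(object$library) > 0L) {
    len <- nchar(object$library$consensus)
    cat(sprintf("  consensus length: min %d / median %d / max %d bp\n",
                min(len), as.integer(stats::median(len)), max(len)))
  }
  invisible(object)
}
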