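# Run configuration: every tunable parameter of the pipeline with its
# default.  Unknown keys are rejected both at construction and when reading
# a config file.

#' Pipeline configuration
#'
#' All module parameters with their defaults.  Lengths are in bp, identities
#' and fractions in [0,1].  Unknown arguments are rejected.
#'
#' @param chunk_len genome chunk length (default 100 kb).
#' @param chunk_overlap overlap between consecutive chunks (default 10 kb).
#' @param min_identity engine identity floor (default 0.8, the family rule).
#' @param min_len engine minimum hit length (default 80 bp).
#' @param task_genome blastn task for genome self-alignment.
#' @param task_copy blastn task for model-vs-genome copy retrieval.
#' @param fmea_max_gap maximum FMEA bridged gap on both axes (default 1000).
#' @param tsd_ext extension around coarse boundaries for TSD search (50 bp).
#' @param tir_tsd_lens legal TIR TSD lengths (2-11 bp).
#' @param nonltr_tsd_lens legal non-LTR TSD lengths (8-20 bp).
#' @param ltr_tsd_lens legal LTR TSD lengths (4-6 bp).
#' @param itr_min_len,itr_max_len terminal-inverted-repeat length bounds.
#' @param itr_max_mismatch maximum ITR mismatch fraction (default 0.2).
#' @param itr_band band width of the ITR edit alignment.
#' @param max_tsd_eval maximum TSD candidates evaluated per coarse candidate.
#' @param polya_min_run minimum polyA run length (> 6, i.e. >= 7).
#' @param polya_window search window around the raw 3' end (50 bp).
#' @param ltr_min_repeat,ltr_max_repeat direct-repeat length bounds (85-5000).
#' @param ltr_min_identity minimum identity between the two LTRs (0.85).
#' @param ltr_min_internal,ltr_max_internal separation between the repeats.
#' @param msa_ext flank extension for the copy alignment block (100 bp).
#' @param msa_window homology-boundary sliding window (10 columns).
#' @param msa_col_conservation modal-residue fraction for a conserved column.
#' @param msa_max_copies maximum copies in an alignment block (100).
#' @param adjust_ext structural re-check window around the homology boundary.
#' @param tandem_max_period,tandem_min_run,tandem_terminal terminal tandem
#'   filter: period 1-6, run > 10 bp, tested in the first/last 20 bp.
#' @param genome_tandem_max_period,genome_tandem_min_run genome pre-masking.
#' @param trf_params the published tandem-masking parameter string, recorded
#'   for provenance.
#' @param copy_chain_gap hit-chaining gap for copy retrieval (500 bp).
#' @param copy_min_cov,copy_min_identity the 80-80 copy retrieval floor.
#' @param cluster_cov,cluster_identity,cluster_min_aln the 95-95-80-80
#'   clustering rule.
#' @param unwrap_max_iter,unwrap_cov,unwrap_identity,unwrap_min_len nested-TE
#'   unwrapping: 95% coverage of the embedded model, 95% identity, fragments
#'   < 100 bp dropped, at most 3 iterations.
#' @param domain_evalue,domain_bridge_gap protein-domain mapping cutoffs.
#' @param mu per-site per-year mutation rate used for insertion dating.
#' @param jc_correction apply the Jukes-Cantor transform before dating.
#' @param nonltr_strand_aware search polyA on the oriented copy strand.
#' @param seed default RNG seed for stochastic stages.
#' @return a named list of class `tinyte_config`.
#' @export
tinyte_config <- function(chunk_len = 100000L, chunk_overlap = 10000L,
                          min_identity = 0.8, min_len = 80L,
                          task_genome = "megablast",
                          task_copy = "dc-megablast",
                          fmea_max_gap = 1000L,
                          tsd_ext = 50L, tir_tsd_lens = 2:11,
                          nonltr_tsd_lens = 8:20, ltr_tsd_lens = 4:6,
                          itr_min_len = 7L, itr_max_len = 300L,
                          itr_max_mismatch = 0.2, itr_band = 5L,
                          max_tsd_eval = 60L,
                          polya_min_run = 7L, polya_window = 50L,
                          ltr_min_repeat = 85L, ltr_max_repeat = 5000L,
                          ltr_min_identity = 0.85,
                          ltr_min_internal = 1000L, ltr_max_internal = 15000L,
                          msa_ext = 100L, msa_window = 10L,
                          msa_col_conservation = 0.8, msa_max_copies = 100L,
                          adjust_ext = 20L,
                          tandem_max_period = 6L, tandem_min_run = 11L,
                          tandem_terminal = 20L,
                          genome_tandem_max_period = 12L,
                          genome_tandem_min_run = 50L,
                          trf_params = "2 7 7 80 10 50 500 -f -d -m",
                          copy_chain_gap = 500L, copy_min_cov = 0.8,
                          copy_min_identity = 0.8,
                          cluster_cov = 0.95, cluster_identity = 0.8,
                          cluster_min_aln = 80L,
                          unwrap_max_iter = 3L, unwrap_cov = 0.95,
                          unwrap_identity = 0.95, unwrap_min_len = 100L,
                          domain_evalue = 1e-20, domain_bridge_gap = 300L,
                          mu = 1.3e-8, jc_correction = FALSE,
                          nonltr_strand_aware = TRUE,
                          seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "tinyte_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Reading rejects unknown keys.
#'
#' @param cfg a [tinyte_config()].
#' @param path YAML file path.
#' @export
config_write <- function(cfg, path) {
  stopifnot(inherits(cfg, "tinyte_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tinyte_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(tinyte_config, vals)
}
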