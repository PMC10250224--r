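# End-to-end orchestration of the analysis on one simulated experiment:
# simulate all libraries, detect and count BSJs, quantify genes, normalize,
# and apply the classification rules. Used by the command-line interface and
# by the acceptance experiments; each stage remains callable on its own.

#' Run the full pipeline on a simulated experiment
#'
#' Simulates every library of the design from `truth`, detects BSJ reads
#' against the annotation-derived junction library, counts genes in polyA
#' (for TPM) and R- (for the library-size reduction), normalizes, and applies
#' the reliability / differential expression / sex-specificity / differential
#' back-splicing / alternative back-splicing rules.
#'
#' @param gen result of [generate_genome()].
#' @param truth result of [plant_truth()] over the same models.
#' @param depths named vector of reads per fraction
#'   (`c(polyA=, Rminus=, Rplus=)`).
#' @param seed integer; per-sample seeds are derived deterministically.
#' @param max_mm mismatch allowance for scanning and gene counting.
#' @param check_linear run the linear-locus tie check during scanning
#'   (slower; guarantees BSJ precision against genomic repeats).
#' @param min_fold,min_reads,min_support classification thresholds.
#' @return list with the junction library, per-sample simulations and
#'   assignments, `calls`, count matrices, size factors, TPM, levels, and the
#'   classification results.
#' @export
run_circ_pipeline <- function(gen, truth, depths, seed, max_mm = 1L,
                              check_linear = FALSE, min_fold = 4,
                              min_reads = 15, min_support = 15) {
  design <- truth$design
  lib <- suppressWarnings(build_bsj_library(gen$models, gen$genome,
                                            read_length = truth$params$read_length))
  sims <- list(); asn <- list(); gc_list <- list()
  for (i in seq_len(nrow(design))) {
    s <- design$sample_id[i]
    fr <- design$fraction[i]
    sim <- simulate_rnaseq(truth, gen$models, gen$genome, s, depths[[fr]],
                           seed = (seed * 131L + i) %% 2147483647L)
    sims[[s]] <- sim$truth
    if (fr == "polyA") {
      gc_list[[s]] <- gene_counts(sim$reads, gen$models, gen$genome,
                                  stranded = FALSE, max_mm = max_mm)
    } else {
      asn[[s]] <- scan_reads(sim$reads, lib, max_mm = max_mm,
                             genome = if (check_linear) gen$genome else NULL)
      if (fr == "Rminus")
        gc_list[[s]] <- gene_counts(sim$reads, gen$models, gen$genome,
                                    stranded = TRUE, max_mm = max_mm)
    }
  }
  agg <- aggregate_calls(asn, lib, gen$models)
  rplus <- agg$counts[, design$sample_id[design$fraction == "Rplus"], drop = FALSE]
  rminus <- agg$counts[, design$sample_id[design$fraction == "Rminus"], drop = FALSE]

  rm_ids <- grep("Rminus", names(gc_list), value = TRUE)
  sf <- size_factors(rminus, lib_stats = library_stats(gc_list[rm_ids]))
  rminus_norm <- normalize_counts(rminus, sf)

  lens <- vapply(gen$models, function(m)
    exonic_length(canonical_transcript(m)), integer(1))
  pa_ids <- grep("polyA", names(gc_list), value = TRUE)
  tpm_mat <- tpm(do.call(cbind, gc_list[pa_ids]), lens)

  lev <- suppressMessages(backsplice_level(rplus, tpm_mat, agg$calls, design))
  rel <- reliable_filter(rplus, rminus, design)
  reliable_ids <- names(which(rel$reliable))
  de <- diff_expression(rplus, rminus_norm, design, make_comparisons("both"),
                        min_fold = min_fold, reliable = reliable_ids)
  ss <- sex_specific(rplus, rminus, design, min_reads = min_reads,
                     reliable = reliable_ids)
  db <- diff_backsplicing(lev, rplus, rminus_norm, design,
                          min_fold = min_fold, min_support = min_support,
                          reliable = reliable_ids)
  ab <- alt_backsplicing(agg$calls[agg$calls$junction_id %in% reliable_ids, ,
                                   drop = FALSE], rplus)
  list(library = lib, sims = sims, assignments = asn, calls = agg$calls,
       counts = agg$counts, rplus = rplus, rminus = rminus,
       size_factors = sf, rminus_norm = rminus_norm, tpm = tpm_mat,
       levels = lev, reliable = rel, diff_expr = de, sex_spec = ss,
       diff_bs = db, altbs = ab, gene_counts = gc_list)
}

#' Run the PAR-CLIP arm on a simulated experiment
#'
#' Simulates SXL and IgG libraries over the planted binding sites, aligns,
#' calls peaks, annotates CIMS, applies the two-branch significance rule and
#' assigns genomic and circRNA-relative regions.
#'
#' @param gen result of [generate_genome()].
#' @param truth a `truth_set` with planted sites.
#' @param depth_sxl,depth_igg library sizes.
#' @param seed integer seed.
#' @param n_perm CIMS permutation rounds.
#' @return list with alignments, the annotated peak table (`peaks`), the
#'   significant subset (`significant`), genomic-region densities and
#'   circRNA-relative assignments.
#' @export
run_parclip_pipeline <- function(gen, truth, depth_sxl, depth_igg, seed,
                                 n_perm = 1000L) {
  sxl <- simulate_parclip(truth, gen$genome, "SXL", depth_sxl,
                          seed = (seed * 131L + 1001L) %% 2147483647L)
  igg <- simulate_parclip(truth, gen$genome, "IgG", depth_igg,
                          seed = (seed * 131L + 1002L) %% 2147483647L)
  sa <- align_clip_reads(sxl$reads, gen$genome)
  ia <- align_clip_reads(igg$reads, gen$genome)
  pk <- call_peaks(sa, ia)
  pk <- annotate_cims(pk, sa, gen$genome, n_perm = n_perm, seed = seed)
  pk <- significant_peaks(pk)
  sig <- pk[pk$significant, , drop = FALSE]
  region <- assign_genomic_region(sig, gen$models, gen$genome)
  circ <- assign_circ_region(sig, calls_from_truth(truth), gen$models)
  list(sxl_truth = sxl$truth, igg_truth = igg$truth, sxl_aln = sa,
       igg_aln = ia, peaks = pk, significant = region$peaks,
       density = region$density, circ_regions = circ)
}
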