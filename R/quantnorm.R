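# Count matrices, size factors and TPM. The size-factor estimator is the
# median-of-ratios method (geometric-mean reference over all-nonzero rows),
# with an adjusted-library-size fallback (total - mRNA - rRNA reads) when too
# few rows are informative.

#' Count reads per gene by exact transcript-space alignment
#'
#' A read counts toward a gene iff it aligns contiguously (<= `max_mm`
#' mismatches) within the gene's canonical mature mRNA; reads matching two or
#' more genes equally well are discarded. rRNA-gene reads are tallied
#' separately for the library-size reduction step.
#'
#' @param reads named character vector or FASTQ path.
#' @param models gene models.
#' @param genome a [genome_ref()].
#' @param stranded if `FALSE` (polyA chemistry) the reverse complement is
#'   also tried.
#' @param max_mm maximum mismatches.
#' @return named integer vector of per-gene counts, with attributes
#'   `n_total`, `n_assigned`, `rrna` (reads on rRNA genes) and `mrna`
#'   (reads on coding genes).
#' @export
gene_counts <- function(reads, models, genome, stranded = TRUE, max_mm = 1L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  refs <- vapply(models, function(m) transcript_sequence(m, genome), character(1))
  gene_ids <- names(models)
  biot <- vapply(models, `[[`, character(1), "biotype")

  n <- length(reads)
  orientations <- if (stranded) list(reads) else list(reads, revcomp(reads))
  per <- lapply(orientations, function(seqs) {
    h <- linear_align_cpp(unname(seqs), unname(refs), as.integer(max_mm), 0L)$hits
    v <- list(ref = rep(NA_integer_, n), mm = rep(NA_integer_, n),
              nb = rep(0L, n))
    v$ref[h$read] <- h$ref; v$mm[h$read] <- h$mm; v$nb[h$read] <- h$n_best
    v
  })
  b <- per[[1L]]
  if (length(per) == 2L) {
    o <- per[[2L]]
    use_o <- !is.na(o$mm) & (is.na(b$mm) | o$mm < b$mm)
    use_o[is.na(use_o)] <- FALSE
    tie <- !is.na(b$mm) & !is.na(o$mm) & b$mm == o$mm & b$ref != o$ref
    b$ref <- ifelse(use_o, o$ref, b$ref)
    b$nb <- as.integer(ifelse(use_o, o$nb, b$nb) + ifelse(tie, ifelse(use_o, b$nb, o$nb), 0L))
    b$mm <- ifelse(use_o, o$mm, b$mm)
  }
  hit <- !is.na(b$mm) & b$nb == 1L
  counts <- table(factor(gene_ids[b$ref[hit]], levels = gene_ids))
  out <- setNames(as.integer(counts), gene_ids)
  attr(out, "n_total") <- length(reads)
  attr(out, "n_assigned") <- sum(hit)
  attr(out, "rrna") <- sum(out[biot == "rRNA"])
  attr(out, "mrna") <- sum(out[biot == "coding"])
  out
}

#' Library statistics for the adjusted-library-size fallback
#'
#' Assembles total / mRNA / rRNA read counts per sample from [gene_counts()]
#' results, for the "total reads minus mRNA and rRNA reads" normalization.
#'
#' @param counts_list named list (sample_id -> vector from [gene_counts()]).
#' @return data.frame sample_id/total/mrna/rrna.
#' @export
library_stats <- function(counts_list) {
  data.frame(sample_id = names(counts_list),
             total = vapply(counts_list, attr, numeric(1), "n_total"),
             mrna = vapply(counts_list, attr, numeric(1), "mrna"),
             rrna = vapply(counts_list, attr, numeric(1), "rrna"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcripts per million
#'
#' `rate_g = count_g / length_g; TPM_g = rate_g / sum(rate) * 1e6`. Columns
#' with zero total count come back all-zero and are recorded in attribute
#' `zero_samples`.
#'
#' @param counts gene x sample matrix (or single named vector) of counts.
#' @param effective_lengths named vector of exonic lengths (nt) per gene.
#' @return matrix (or vector) of TPM values.
#' @export
tpm <- function(counts, effective_lengths) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, ncol = 1L, dimnames = list(names(counts), "s"))
       else counts
  len <- effective_lengths[rownames(m)]
  if (any(is.na(len) | len <= 0))
    stop("tpm: missing or non-positive effective length")
  rate <- m / len
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- 1
  out <- sweep(rate, 2L, tot, "/") * 1e6
  out[, zero] <- 0
  attr(out, "zero_samples") <- colnames(m)[zero]
  if (vec) setNames(as.numeric(out), rownames(m)) else out
}

#' Size factors for a count matrix
#'
#' Median-of-ratios against a geometric-mean reference computed over rows
#' nonzero in every sample, rescaled to geometric mean 1. When fewer than
#' `min_nonzero_rows` rows qualify, falls back to adjusted library sizes
#' (total - mRNA - rRNA reads from `lib_stats`); the method used is recorded
#' in attribute `method`.
#'
#' @param mat count matrix (>= 2 columns).
#' @param min_nonzero_rows minimum all-nonzero rows for median-of-ratios.
#' @param lib_stats optional data.frame sample_id/total/mrna/rrna for the
#'   fallback.
#' @return named numeric vector of positive factors (geometric mean 1).
#' @export
size_factors <- function(mat, min_nonzero_rows = 10L, lib_stats = NULL) {
  if (ncol(mat) < 2L) stop("size_factors: need at least two samples")
  nz <- rowSums(mat > 0) == ncol(mat)
  if (sum(nz) >= min_nonzero_rows) {
    lm <- log(mat[nz, , drop = FALSE])
    ref <- rowMeans(lm)
    f <- exp(apply(lm - ref, 2L, median))  # log-space median of ratios
    method <- "median-of-ratios"
  } else {
    if (is.null(lib_stats))
      stop(sprintf("size_factors: only %d all-nonzero rows (< %d) and no lib_stats for the library-size fallback",
                   sum(nz), min_nonzero_rows))
    adj <- lib_stats$total - lib_stats$mrna - lib_stats$rrna
    f <- setNames(adj, lib_stats$sample_id)[colnames(mat)]
    if (anyNA(f)) stop("size_factors: lib_stats does not cover all samples")
    method <- "library-size"
  }
  f <- f / exp(mean(log(f)))
  attr(f, "method") <- method
  f
}

#' Normalize a count matrix by size factors
#' @param mat count matrix; `factors` named factors covering all columns.
#' @param factors named numeric vector of size factors.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(mat, factors) {
  f <- factors[colnames(mat)]
  if (anyNA(f)) stop("normalize_counts: missing factor for some sample")
  sweep(mat, 2L, f, "/")
}

#' TPM-normalized back-splicing level
#'
#' `level = (BSJ_R+ + pseudocount) / max(TPM_cognate, eps)` per biosample,
#' pairing each R+ column with the polyA sample of the same sex and tissue.
#' The pseudocount sits on the read scale, where it stabilizes zeros without
#' depending on the TPM scale of the transcriptome; level fold changes are
#' then plain ratios. Junctions without
#' a cognate gene are dropped (attribute `excluded_no_gene`); junctions whose
#' cognate TPM is below `eps` in every sample are flagged low-expression
#' (attribute `flagged_low_expr`) and should be excluded from differential
#' back-splicing.
#'
#' @param rplus junction x R+ sample count matrix.
#' @param tpm_table gene x polyA sample TPM matrix.
#' @param calls a [circ_calls()] table giving each junction's cognate gene.
#' @param design sample sheet.
#' @param eps TPM floor for the denominator.
#' @param pseudocount added to the BSJ count before the TPM division.
#' @param size_factors optional named factors applied to `rplus` before the
#'   TPM division (off by default).
#' @return junction x R+ sample numeric matrix of levels.
#' @export
backsplice_level <- function(rplus, tpm_table, calls, design, eps = 1,
                             pseudocount = 0.5, size_factors = NULL) {
  gene <- setNames(calls$gene_id, calls$junction_id)[rownames(rplus)]
  keep <- !is.na(gene)
  excluded <- rownames(rplus)[!keep]
  if (length(excluded))
    message(sprintf("backsplice_level: %d junction(s) without cognate gene excluded",
                    length(excluded)))
  rp <- rplus[keep, , drop = FALSE]
  if (!is.null(size_factors)) rp <- normalize_counts(rp, size_factors)
  gene <- gene[keep]

  bs_of <- setNames(biosample_of(design$sex, design$tissue), design$sample_id)
  polyA <- design$sample_id[design$fraction == "polyA"]
  polyA_of_bs <- setNames(polyA, bs_of[polyA])

  lev <- matrix(0, nrow(rp), ncol(rp), dimnames = dimnames(rp))
  tpm_used <- matrix(0, nrow(rp), ncol(rp), dimnames = dimnames(rp))
  for (s in colnames(rp)) {
    pa <- polyA_of_bs[[bs_of[[s]]]]
    if (is.null(pa) || !pa %in% colnames(tpm_table))
      stop(sprintf("backsplice_level: no polyA TPM column for sample %s", s))
    tg <- tpm_table[gene, pa]
    tpm_used[, s] <- tg
    lev[, s] <- (rp[, s] + pseudocount) / pmax(tg, eps)
  }
  low <- rownames(rp)[apply(tpm_used < eps, 1L, all)]
  attr(lev, "flagged_low_expr") <- low
  attr(lev, "excluded_no_gene") <- excluded
  lev
}
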