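# PAR-CLIP analysis: exact-scan alignment with T>C-exempt mismatches,
# coverage-run peak calling with a Poisson enrichment test against the IgG
# control, CIMS detection with within-peak permutation FDR, the two-branch
# significance rule, and genomic/circRNA-relative region assignment.

#' Align CLIP reads to the genome
#'
#' Unique best contiguous match with at most `max_mm` non-T>C mismatches;
#' T>C mismatches (transcript orientation) are unlimited and recorded as
#' conversions. Multi-mappers are discarded.
#'
#' @param reads named character vector or FASTQ path.
#' @param genome a [genome_ref()].
#' @param max_mm maximum non-conversion mismatches.
#' @return data.frame: read_id, contig, start, end (0-based half-open),
#'   strand, mm, n_conv, plus list column `conversions` of genomic positions.
#' @export
align_clip_reads <- function(reads, genome, max_mm = 2L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  contigs <- names(genome$seqs)
  n <- length(reads)
  per_orient <- lapply(c("+", "-"), function(orient) {
    seqs <- if (orient == "+") reads else revcomp(reads)
    res <- linear_align_cpp(unname(seqs), unname(genome$seqs),
                            as.integer(max_mm), if (orient == "+") 1L else 2L)
    h <- res$hits
    v <- list(ref = rep(NA_integer_, n), pos = rep(NA_integer_, n),
              mm = rep(NA_integer_, n), conv = rep(NA_integer_, n),
              nb = rep(0L, n), convpos = res$conversions)
    v$ref[h$read] <- h$ref; v$pos[h$read] <- h$pos; v$mm[h$read] <- h$mm
    v$conv[h$read] <- h$n_conv; v$nb[h$read] <- h$n_best
    v
  })
  f <- per_orient[[1L]]; r <- per_orient[[2L]]
  tf <- f$mm + f$conv; tr <- r$mm + r$conv
  use_r <- !is.na(r$mm) & (is.na(f$mm) | r$mm < f$mm | (r$mm == f$mm & tr < tf))
  use_r[is.na(use_r)] <- FALSE
  tie <- !is.na(f$mm) & !is.na(r$mm) & f$mm == r$mm & tf == tr
  pick <- function(a, b) ifelse(use_r, b, a)
  ref <- pick(f$ref, r$ref); pos <- pick(f$pos, r$pos)
  mm <- pick(f$mm, r$mm); conv <- pick(f$conv, r$conv)
  nb <- as.integer(pick(f$nb, r$nb) + ifelse(tie, pick(r$nb, f$nb), 0L))
  strand <- ifelse(use_r, "-", "+")
  keep <- which(!is.na(mm) & nb == 1L)
  rl <- nchar(reads[keep])
  out <- data.frame(read_id = names(reads)[keep], contig = contigs[ref[keep]],
                    start = pos[keep], end = pos[keep] + rl,
                    strand = strand[keep], mm = mm[keep], n_conv = conv[keep],
                    stringsAsFactors = FALSE)
  out$conversions <- lapply(keep, function(i)
    if (use_r[i]) r$convpos[[i]] else f$convpos[[i]])
  out
}

#' Call candidate peaks from SXL vs IgG coverage
#'
#' Candidates are maximal runs of positions with SXL coverage at least
#' `min_cov` (per contig and strand), with runs closer than `merge_gap`
#' merged. The enrichment p-value is the upper tail of a Poisson law with
#' mean `(igg_count + 1) * N_sxl / N_igg`; the score is the library-size
#' normalized ratio `(sxl/N_sxl) / ((igg+1)/N_igg)`.
#'
#' @param sxl_aln,igg_aln alignment tables from [align_clip_reads()].
#' @param min_cov coverage threshold defining candidate runs.
#' @param merge_gap runs closer than this many nt are merged.
#' @return data.frame of peaks with counts, ratio, p_value and an empty
#'   `cims_sites` list column.
#' @export
call_peaks <- function(sxl_aln, igg_aln, min_cov = 5L, merge_gap = 10L) {
  n_sxl <- nrow(sxl_aln); n_igg <- nrow(igg_aln)
  empty <- data.frame(peak_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      sxl_count = integer(0), igg_count = integer(0),
                      ratio = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_sxl == 0L) {
    message("call_peaks: empty SXL library")
    empty$cims_sites <- list(); return(empty)
  }
  rows <- list()
  for (ct in unique(sxl_aln$contig)) for (st in c("+", "-")) {
    sel <- sxl_aln$contig == ct & sxl_aln$strand == st
    if (!any(sel)) next
    ir <- IRanges::IRanges(sxl_aln$start[sel] + 1L, sxl_aln$end[sel])
    cov <- IRanges::coverage(ir)
    runs <- IRanges::reduce(as(IRanges::slice(cov, lower = min_cov), "IRanges"),
                            min.gapwidth = merge_gap)
    if (length(runs) == 0L) next
    isel <- igg_aln$contig == ct & igg_aln$strand == st
    iir <- IRanges::IRanges(igg_aln$start[isel] + 1L, igg_aln$end[isel])
    sc <- IRanges::countOverlaps(runs, ir)
    ic <- IRanges::countOverlaps(runs, iir)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = ct, start = BiocGenerics::start(runs) - 1L,
      end = BiocGenerics::end(runs), strand = st, sxl_count = sc,
      igg_count = ic, stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, rows)
  if (is.null(pk)) { empty$cims_sites <- list(); return(empty) }
  pk <- pk[order(pk$contig, pk$start), , drop = FALSE]
  pk$ratio <- (pk$sxl_count / n_sxl) / ((pk$igg_count + 1) / max(n_igg, 1L))
  lambda <- (pk$igg_count + 1) * n_sxl / max(n_igg, 1L)
  pk$p_value <- ppois(pk$sxl_count - 1L, lambda, lower.tail = FALSE)
  pk <- cbind(peak_id = sprintf("peak_%05d", seq_len(nrow(pk))), pk,
              stringsAsFactors = FALSE)
  pk$cims_sites <- rep(list(NULL), nrow(pk))
  rownames(pk) <- NULL
  pk
}

#' Crosslink-induced mutation sites within one peak
#'
#' For each reference-T position (transcript orientation) in the peak with at
#' least 2 conversions, the FDR is estimated by permutation: in each round
#' every overlapping read redistributes its conversions uniformly over the
#' reference-T positions it covers, and the mean number of within-peak
#' positions reaching the site's conversion count, divided by the observed
#' number, is the FDR (clamped to \[0, 1\]).
#'
#' @param peak one row of the peak table.
#' @param sxl_aln alignment table from [align_clip_reads()].
#' @param genome a [genome_ref()].
#' @param n_perm permutation rounds.
#' @param seed integer seed.
#' @return data.frame: position, k (conversions), m (coverage), fdr.
#' @export
find_cims <- function(peak, sxl_aln, genome, n_perm = 1000L, seed = 1L) {
  emptysites <- data.frame(position = integer(0), k = integer(0),
                           m = integer(0), fdr = numeric(0))
  ov <- sxl_aln$contig == peak$contig & sxl_aln$strand == peak$strand &
    sxl_aln$start < peak$end & sxl_aln$end > peak$start
  rd <- sxl_aln[ov, , drop = FALSE]
  if (nrow(rd) == 0L) return(emptysites)
  tbase <- if (peak$strand == "+") "T" else "A"
  lo <- min(rd$start); hi <- max(rd$end)
  region <- strsplit(genome_seq(genome, peak$contig, lo, hi, "+"), "")[[1L]]
  tpos <- lo + which(region == tbase) - 1L
  in_peak <- tpos >= peak$start & tpos < peak$end
  if (!any(in_peak)) return(emptysites)

  convs <- unlist(rd$conversions)
  kobs <- table(factor(convs[convs %in% tpos[in_peak]],
                       levels = as.character(tpos[in_peak])))
  kobs <- setNames(as.integer(kobs), tpos[in_peak])
  mcov <- vapply(tpos[in_peak], function(p)
    sum(rd$start <= p & rd$end > p), integer(1))
  names(mcov) <- tpos[in_peak]
  sites <- names(kobs)[kobs >= 2L]
  if (length(sites) == 0L) return(emptysites)

  # per-conversion candidate positions: reference Ts covered by the read
  conv_reads <- rep(seq_len(nrow(rd)), vapply(rd$conversions, length, integer(1)))
  read_ts <- lapply(seq_len(nrow(rd)), function(i)
    tpos[tpos >= rd$start[i] & tpos < rd$end[i]])
  peak_set <- tpos[in_peak]

  with_seed(seed, {
    ks <- kobs[sites]
    cand <- read_ts[conv_reads]  # per conversion: T positions its read covers
    keep_conv <- vapply(cand, length, integer(1)) > 0L
    cand <- cand[keep_conv]
    # one row per conversion, one column per permutation round
    draws <- vapply(cand, function(v)
      v[sample.int(length(v), n_perm, replace = TRUE)], integer(n_perm))
    idx <- matrix(match(draws, peak_set), nrow = n_perm)
    exceed <- matrix(0L, n_perm, length(sites))
    for (b in seq_len(n_perm)) {
      kt <- tabulate(idx[b, !is.na(idx[b, ])], nbins = length(peak_set))
      exceed[b, ] <- vapply(ks, function(k) sum(kt >= k), integer(1))
    }
    fdr <- colMeans(exceed) / vapply(ks, function(k) sum(kobs >= k), integer(1))
    data.frame(position = as.integer(sites), k = as.integer(ks),
               m = as.integer(mcov[sites]), fdr = pmin(pmax(fdr, 0), 1))
  })
}

#' Annotate all peaks with CIMS sites
#' @param peaks peak table; other arguments as [find_cims()]. Each peak gets
#'   a deterministic per-peak seed derived from `seed`.
#' @param sxl_aln alignment table.
#' @param genome a [genome_ref()].
#' @param n_perm permutation rounds.
#' @param seed integer base seed.
#' @return the peak table with `cims_sites` filled.
#' @export
annotate_cims <- function(peaks, sxl_aln, genome, n_perm = 1000L, seed = 1L) {
  for (i in seq_len(nrow(peaks)))
    peaks$cims_sites[[i]] <- find_cims(peaks[i, , drop = FALSE], sxl_aln,
                                       genome, n_perm,
                                       seed = (seed + i) %% .Machine$integer.max)
  peaks
}

#' Two-branch peak significance rule
#'
#' Significant iff (ratio >= 10, p < 1e-4 and some CIMS site with FDR <= 0.3)
#' or (ratio >= 100 and p < 1e-4 regardless of CIMS).
#'
#' @param peaks peak table with `cims_sites` filled.
#' @param min_ratio,high_ratio,max_p,max_cims_fdr rule thresholds.
#' @return the peak table with a logical `significant` column.
#' @export
significant_peaks <- function(peaks, min_ratio = 10, high_ratio = 100,
                              max_p = 1e-4, max_cims_fdr = 0.3) {
  has_cims <- vapply(peaks$cims_sites, function(s)
    !is.null(s) && nrow(s) > 0L && min(s$fdr) <= max_cims_fdr, logical(1))
  peaks$significant <- (peaks$ratio >= min_ratio & peaks$p_value < max_p & has_cims) |
    (peaks$ratio >= high_ratio & peaks$p_value < max_p)
  peaks
}

#' Genomic region of each peak, with per-category densities
#'
#' Labels each peak by its midpoint with precedence exon > intron >
#' intergenic (strand-matched); inside coding-gene exons the label is refined
#' to 5'UTR / CDS / 3'UTR by the canonical transcript. Densities are peaks
#' per kb of total annotated length per category.
#'
#' @param peaks peak table.
#' @param models gene models.
#' @param genome a [genome_ref()] (for the intergenic total).
#' @return list: `peaks` (with `region` column) and `density` (data.frame
#'   category/n_peaks/kb/peaks_per_kb).
#' @export
assign_genomic_region <- function(peaks, models, genome) {
  cats <- c("5'UTR", "CDS", "3'UTR", "exon_noncoding", "intron", "intergenic")
  lens <- setNames(numeric(length(cats)), cats)
  feat <- list()
  for (m in models) {
    tx <- canonical_transcript(m)
    if (m$biotype == "coding" && !is.null(tx$cds)) {
      u <- tx_utrs(m, tx)
      for (nm in c("utr5", "cds", "utr3")) {
        lab <- c(utr5 = "5'UTR", cds = "CDS", utr3 = "3'UTR")[[nm]]
        iv <- u[[nm]]
        if (nrow(iv)) {
          lens[lab] <- lens[lab] + sum(iv[, 2L] - iv[, 1L])
          feat[[length(feat) + 1L]] <- data.frame(
            contig = m$contig, strand = m$strand, start = iv[, 1L],
            end = iv[, 2L], lab = lab, stringsAsFactors = FALSE)
        }
      }
    } else {
      iv <- tx$exons
      lens["exon_noncoding"] <- lens["exon_noncoding"] + sum(iv[, 2L] - iv[, 1L])
      feat[[length(feat) + 1L]] <- data.frame(
        contig = m$contig, strand = m$strand, start = iv[, 1L], end = iv[, 2L],
        lab = "exon_noncoding", stringsAsFactors = FALSE)
    }
    intr <- tx_introns(tx$exons)
    if (nrow(intr)) {
      lens["intron"] <- lens["intron"] + sum(intr[, 2L] - intr[, 1L])
      feat[[length(feat) + 1L]] <- data.frame(
        contig = m$contig, strand = m$strand, start = intr[, 1L],
        end = intr[, 2L], lab = "intron", stringsAsFactors = FALSE)
    }
  }
  feat <- do.call(rbind, feat)
  exon_labs <- c("5'UTR", "CDS", "3'UTR", "exon_noncoding")
  lens["intergenic"] <- sum(contig_lengths(genome)) - sum(lens[names(lens) != "intergenic"])

  region <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    hit <- feat$contig == peaks$contig[i] & feat$strand == peaks$strand[i] &
      feat$start <= mid & feat$end > mid
    labs <- feat$lab[hit]
    region[i] <- if (any(labs %in% exon_labs)) labs[labs %in% exon_labs][1L]
    else if ("intron" %in% labs) "intron" else "intergenic"
  }
  peaks$region <- region
  density <- data.frame(category = cats,
                        n_peaks = as.integer(table(factor(region, levels = cats))),
                        kb = as.numeric(lens) / 1000,
                        stringsAsFactors = FALSE)
  density$peaks_per_kb <- ifelse(density$kb > 0, density$n_peaks / density$kb, NA)
  list(peaks = peaks, density = density)
}

#' Assign peaks to circRNA-relative regions
#'
#' For each (peak, exonic call) on the same gene and strand: back-spliced
#' exon when the peak overlaps an exon of the circle's chain; flanking intron
#' when it overlaps the intron immediately upstream of the acceptor or
#' downstream of the donor; flanking exon when it overlaps the nearest
#' annotated exon outside the circle on either side. One peak may receive
#' several categories across calls.
#'
#' @param peaks peak table (typically significant peaks).
#' @param calls exonic [circ_calls()] with cognate genes.
#' @param models gene models.
#' @return data.frame: peak_id, junction_id, category.
#' @export
assign_circ_region <- function(peaks, calls, models) {
  out <- list()
  skipped <- 0L
  ex_calls <- calls[calls$circ_type == "exonic" & !is.na(calls$gene_id), ,
                    drop = FALSE]
  for (i in seq_len(nrow(ex_calls))) {
    m <- models[[ex_calls$gene_id[i]]]
    ex <- canonical_transcript(m)$exons
    intr <- tx_introns(ex)
    feats <- list()
    chain <- ex_calls$exon_chain[[i]]
    for (k in seq_len(nrow(chain)))
      feats[[length(feats) + 1L]] <- c(chain[k, 1L], chain[k, 2L], 1L)
    up_in <- which(intr[, 2L] == ex_calls$acceptor[i])
    dn_in <- which(intr[, 1L] == ex_calls$donor[i])
    for (k in c(up_in, dn_in))
      feats[[length(feats) + 1L]] <- c(intr[k, 1L], intr[k, 2L], 2L)
    up_ex <- if (length(up_in)) which(ex[, 2L] == intr[up_in, 1L]) else integer(0)
    dn_ex <- if (length(dn_in)) which(ex[, 1L] == intr[dn_in, 2L]) else integer(0)
    for (k in c(up_ex, dn_ex))
      feats[[length(feats) + 1L]] <- c(ex[k, 1L], ex[k, 2L], 3L)
    skipped <- skipped + (length(up_in) == 0L) + (length(dn_in) == 0L)
    labs <- c("back-spliced exon", "flanking intron", "flanking exon")
    psel <- which(peaks$contig == m$contig & peaks$strand == m$strand)
    for (f in feats) {
      hit <- psel[peaks$start[psel] < f[2L] & peaks$end[psel] > f[1L]]
      for (pi in hit)
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[pi], junction_id = ex_calls$junction_id[i],
          category = labs[f[3L]], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(peak_id = character(0), junction_id = character(0),
               category = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_terminal_sides_skipped") <- skipped
  res
}
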