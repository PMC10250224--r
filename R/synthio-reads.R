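# Fraction-aware read simulator. Per-read category probabilities are
# compositional: the three fractions of one biosample share the same
# underlying mass, polyA restricted to coding mRNA, R- adding circles and
# residual rRNA, R+ down-weighting all linear mass by the RNase-R survival
# fraction and renormalizing (library yield is what gets sequenced).

circle_sequences <- function(circles, genome) {
  vapply(seq_len(nrow(circles)), function(i)
    mature_sequence(circles[i, , drop = FALSE], genome), character(1))
}

#' Per-read category probabilities for one sample
#'
#' The generative composition of a library: one row per read category
#' (linear gene, rRNA gene, circle BSJ fragment, circle internal fragment)
#' with its per-read probability. This is the ground-truth rate table tests
#' use as a binomial oracle for expected counts.
#'
#' @param truth a `truth_set`; `models` the gene models.
#' @param models gene models.
#' @param sample one row of the design (or a sample_id present in it).
#' @return data.frame with columns kind, unit, prob.
#' @export
sample_composition <- function(truth, models, sample) {
  if (is.character(sample))
    sample <- truth$design[truth$design$sample_id == sample, , drop = FALSE]
  if (nrow(sample) != 1L) stop("sample_composition: unknown sample")
  p <- truth$params
  bs <- biosample_of(sample$sex, sample$tissue)
  fraction <- sample$fraction

  biot <- vapply(models, `[[`, character(1), "biotype")
  len <- vapply(models, function(m) exonic_length(canonical_transcript(m)), integer(1))
  eligible <- len >= p$read_length
  lin_ok <- eligible & (if (fraction == "polyA") biot == "coding"
                        else biot %in% c("coding", "noncoding"))
  lin_w <- truth$expression[names(models)[lin_ok], bs] * len[lin_ok]
  lin_w <- lin_w / sum(lin_w)

  if (fraction == "polyA") {
    return(data.frame(kind = "linear", unit = names(lin_w),
                      prob = as.numeric(lin_w), stringsAsFactors = FALSE))
  }

  rr_ok <- eligible & biot == "rRNA"
  rr_w <- truth$expression[names(models)[rr_ok], bs] * len[rr_ok]
  rr_w <- rr_w / sum(rr_w) * p$rrna_residual / (1 - p$rrna_residual)

  # fixed circle scale: mean total circle mass over biosamples hits the
  # configured R- circle fraction; per-sample mass then varies with the
  # planted effects, as composition should
  bw <- truth$bsj_weight
  mean_mass <- mean(colSums(bw) * (1 + p$internal_factor))
  cscale <- p$circ_mass_rminus / (1 - p$circ_mass_rminus) *
    (1 + p$rrna_residual / (1 - p$rrna_residual)) / mean_mass
  bsj_w <- cscale * bw[, bs]
  int_w <- p$internal_factor * bsj_w

  surv <- if (fraction == "Rplus") p$rnaseR_linear_survival else 1
  jn_kind <- ifelse(truth$circles$circ_type == "ciRNA", "ciRNA-junction", "BSJ")
  raw <- c(surv * lin_w, surv * rr_w, bsj_w, int_w)
  out <- data.frame(
    kind = c(rep("linear", length(lin_w)), rep("rRNA", length(rr_w)),
             jn_kind, rep("circ-internal", length(int_w))),
    unit = c(names(lin_w), names(rr_w), rownames(bw), rownames(bw)),
    prob = raw / sum(raw), stringsAsFactors = FALSE)
  out[out$prob > 0, , drop = FALSE]
}

#' True per-read BSJ probability of each planted circle in a sample
#' @param truth,models,sample as in [sample_composition()].
#' @return named numeric vector (junction id -> probability).
#' @export
true_bsj_prob <- function(truth, models, sample) {
  comp <- sample_composition(truth, models, sample)
  j <- comp[comp$kind %in% c("BSJ", "ciRNA-junction"), , drop = FALSE]
  setNames(j$prob, j$unit)
}

#' Depth at which every planted circle expects at least `min_reads` BSJ reads
#' @param truth,models as in [sample_composition()].
#' @param sample sample id or design row.
#' @param min_reads target expected BSJ read count.
#' @return integer depth.
#' @export
depth_for_min_bsj <- function(truth, models, sample, min_reads) {
  pr <- true_bsj_prob(truth, models, sample)
  as.integer(ceiling(min_reads / min(pr[pr > 0])))
}

apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  total <- sum(rl)
  nmut <- rbinom(1L, total, rate)
  if (nmut == 0L) return(reads)
  at <- sort(sample.int(total, nmut))
  ends <- cumsum(rl)
  ri <- findInterval(at - 1L, ends) + 1L
  pos <- at - c(0L, ends)[ri]
  for (k in seq_len(nmut)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    substr(reads[ri[k]], pos[k], pos[k]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  reads
}

#' Simulate one fractionated RNA-seq library
#'
#' Draws `depth` single-end reads (fixed length, already merged) from the
#' sample's compositional mixture; BSJ reads place the junction uniformly
#' with at least 1 nt on each side; polyA reads take a random orientation,
#' R-/R+ reads are emitted in transcript orientation (stranded protocol).
#' Sequencing errors are uniform substitutions at the configured rate.
#'
#' @param truth a `truth_set`; `models`, `genome` the toy annotation/genome.
#' @param models gene models.
#' @param genome a [genome_ref()].
#' @param sample sample id or design row.
#' @param depth number of reads.
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read_id/source/unit/junction_offset).
#' @export
simulate_rnaseq <- function(truth, models, genome, sample, depth, seed) {
  if (is.character(sample))
    sample <- truth$design[truth$design$sample_id == sample, , drop = FALSE]
  p <- truth$params
  rl <- p$read_length
  comp <- sample_composition(truth, models, sample)
  if (depth == 0L)
    return(list(reads = setNames(character(0), character(0)),
                truth = data.frame(read_id = character(0), source = character(0),
                                   unit = character(0),
                                   junction_offset = integer(0))))

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, depth, comp$prob))
    kind <- rep(comp$kind, counts)
    unit <- rep(comp$unit, counts)
    n <- length(kind)

    # mature sequences per unit
    gene_units <- unique(unit[kind %in% c("linear", "rRNA")])
    gseq <- vapply(gene_units, function(g)
      transcript_sequence(models[[g]], genome), character(1))
    circ_units <- unique(unit[kind %in% c("BSJ", "ciRNA-junction", "circ-internal")])
    cidx <- match(circ_units, truth$circles$junction_id)
    cseq <- setNames(circle_sequences(truth$circles[cidx, , drop = FALSE], genome),
                     circ_units)

    reads <- character(n)
    offsets <- rep(NA_integer_, n)
    is_lin <- kind %in% c("linear", "rRNA")
    if (any(is_lin)) {
      ms <- gseq[unit[is_lin]]
      start <- floor(runif(sum(is_lin)) * (nchar(ms) - rl + 1))
      reads[is_lin] <- substr(ms, start + 1L, start + rl)
    }
    is_int <- kind == "circ-internal"
    if (any(is_int)) {
      ms <- cseq[unit[is_int]]
      start <- floor(runif(sum(is_int)) * (nchar(ms) - rl + 1))
      reads[is_int] <- substr(ms, start + 1L, start + rl)
    }
    is_bsj <- kind %in% c("BSJ", "ciRNA-junction")
    if (any(is_bsj)) {
      ms <- cseq[unit[is_bsj]]
      dd <- paste0(ms, ms)
      o <- 1L + floor(runif(sum(is_bsj)) * (rl - 1L))  # nt left of the junction
      reads[is_bsj] <- substr(dd, nchar(ms) - o + 1L, nchar(ms) - o + rl)
      offsets[is_bsj] <- o
    }
    if (sample$fraction == "polyA") {
      flip <- runif(n) < 0.5
      reads[flip] <- revcomp(reads[flip])
    }
    reads <- apply_seq_errors(reads, p$error_rate)
    ids <- sprintf("%s_r%06d", sample$sample_id, seq_len(n))
    list(reads = setNames(reads, ids),
         truth = data.frame(read_id = ids, source = kind, unit = unit,
                            junction_offset = offsets, stringsAsFactors = FALSE))
  })
}

#' Write a simulated library to disk
#'
#' Emits `<prefix>.fastq` (Phred 33, fixed quality) and the truth table as
#' `<prefix>.truth.tsv`.
#'
#' @param sim result of [simulate_rnaseq()] or [simulate_parclip()].
#' @param prefix output path prefix.
#' @export
write_simulated <- function(sim, prefix) {
  write_fastq(sim$reads, paste0(prefix, ".fastq"))
  write.table(sim$truth, paste0(prefix, ".truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
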