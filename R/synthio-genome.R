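# Seeded toy-genome generator. Genes are laid out sequentially on one contig
# with intergenic gaps; splice-site dinucleotides (GT..AG in transcript
# orientation) are planted at every intron boundary.

#' Default generator configuration
#'
#' Bounds follow the toy-scale study design: 3-8 exons per gene, exon length
#' 80-300 nt, intron length 60-2000 nt, intergenic gaps >= 500 nt.
#'
#' @return named list of generator parameters.
#' @export
genome_config <- function() {
  list(
    contig = "chrT",
    exons_per_gene = c(3L, 8L),
    exon_len = c(80L, 300L),
    intron_len = c(60L, 2000L),
    intergenic_gap = c(500L, 1500L),
    n_rrna = 2L,
    n_noncoding = 2L,
    utr_len = c(20L, 60L)  # UTR carved from terminal exons of coding genes
  )
}

check_bounds <- function(b, name, lo = 1L) {
  if (length(b) != 2L || b[1L] > b[2L] || b[1L] < lo)
    stop(sprintf("generate_genome: infeasible bounds for %s", name))
}

runif_int <- function(n, lo, hi) as.integer(lo + floor(runif(n) * (hi - lo + 1L)))

#' Generate a random genome with annotated genes
#'
#' Produces a uniform-composition random contig carrying `n_genes` genes
#' (random strand, one transcript each) whose introns start with GT and end
#' with AG in transcript orientation. Coding genes get a CDS leaving a 5' and
#' 3' UTR inside the terminal exons; a configurable number of rRNA-biotype
#' and noncoding genes are included. Byte-deterministic under `seed`.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @param config list as from [genome_config()]; partial overrides allowed.
#' @return list with `genome` ([genome_ref()]), `models` (list of
#'   [gene_model()]) and the resolved `config`.
#' @export
generate_genome <- function(n_genes, seed, config = list()) {
  cfg <- utils::modifyList(genome_config(), config)
  stopifnot(n_genes >= 1L)
  check_bounds(cfg$exons_per_gene, "exons_per_gene")
  check_bounds(cfg$exon_len, "exon_len", lo = 10L)
  check_bounds(cfg$intron_len, "intron_len")
  check_bounds(cfg$intergenic_gap, "intergenic_gap")
  check_bounds(cfg$utr_len, "utr_len")
  if (cfg$n_rrna < 1L) stop("generate_genome: need >= 1 rRNA gene")
  if (cfg$n_rrna + cfg$n_noncoding > n_genes)
    stop("generate_genome: more rRNA/noncoding genes than genes")
  # each UTR sits inside its own terminal exon (single-exon genes need both)
  need_utr <- if (cfg$exons_per_gene[1L] == 1L) cfg$utr_len[2L] * 2L
              else cfg$utr_len[2L]
  if (need_utr >= cfg$exon_len[1L])
    stop("generate_genome: UTRs cannot exceed the smallest exon")

  with_seed(seed, {
    biotypes <- sample(c(rep("rRNA", cfg$n_rrna), rep("noncoding", cfg$n_noncoding),
                         rep("coding", n_genes - cfg$n_rrna - cfg$n_noncoding)))
    models <- vector("list", n_genes)
    pieces <- character(0)
    cursor <- 0L

    for (g in seq_len(n_genes)) {
      gap <- runif_int(1L, cfg$intergenic_gap[1L], cfg$intergenic_gap[2L])
      pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                                collapse = ""))
      cursor <- cursor + gap

      n_ex <- runif_int(1L, cfg$exons_per_gene[1L], cfg$exons_per_gene[2L])
      ex_len <- runif_int(n_ex, cfg$exon_len[1L], cfg$exon_len[2L])
      in_len <- if (n_ex > 1L) runif_int(n_ex - 1L, cfg$intron_len[1L], cfg$intron_len[2L])
                else integer(0)
      strand <- sample(c("+", "-"), 1L)

      span <- sum(ex_len) + sum(in_len)
      seq <- sample(c("A", "C", "G", "T"), span, replace = TRUE)
      starts <- ends <- integer(n_ex)  # local 0-based
      pos <- 0L
      for (i in seq_len(n_ex)) {
        starts[i] <- pos; pos <- pos + ex_len[i]; ends[i] <- pos
        if (i < n_ex) {
          # splice dinucleotides, transcript-orientation GT..AG
          if (strand == "+") {
            seq[pos + 1:2] <- c("G", "T")                   # donor GT
            seq[pos + in_len[i] - 1:0] <- c("A", "G")       # acceptor AG
          } else {
            seq[pos + 1:2] <- c("C", "T")                   # revcomp of AG
            seq[pos + in_len[i] - 1:0] <- c("A", "C")       # revcomp of GT
          }
          pos <- pos + in_len[i]
        }
      }
      pieces <- c(pieces, paste(seq, collapse = ""))

      exons <- cbind(start = cursor + starts, end = cursor + ends)
      gid <- sprintf("g%04d", g)
      cds <- NULL
      if (biotypes[g] == "coding") {
        u1 <- runif_int(1L, cfg$utr_len[1L], cfg$utr_len[2L])
        u2 <- runif_int(1L, cfg$utr_len[1L], cfg$utr_len[2L])
        cds <- c(exons[1L, 1L] + u1, exons[n_ex, 2L] - u2)
      }
      models[[g]] <- gene_model(gid, cfg$contig, strand, biotypes[g],
                                setNames(list(list(transcript_id = paste0(gid, ".t1"),
                                                   exons = exons, cds = cds)),
                                         paste0(gid, ".t1")))
      cursor <- cursor + span
    }
    tail_gap <- runif_int(1L, cfg$intergenic_gap[1L], cfg$intergenic_gap[2L])
    pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), tail_gap, replace = TRUE),
                              collapse = ""))
    genome <- genome_ref(setNames(paste(pieces, collapse = ""), cfg$contig))
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    list(genome = genome, models = models, config = cfg)
  })
}

#' Mature (spliced) transcript sequence of a gene's canonical transcript
#' @param model a [gene_model()]; `genome` a [genome_ref()].
#' @param genome a [genome_ref()].
#' @param tx transcript element (default canonical).
#' @return character scalar in transcript orientation.
#' @export
transcript_sequence <- function(model, genome, tx = canonical_transcript(model)) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_seq(genome, model$contig, tx$exons[i, 1L], tx$exons[i, 2L], "+"),
    character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}
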