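#' @useDynLib circdimorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median ppois rbinom rlnorm rnorm runif setNames quantile sd
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

# All internal coordinates are 0-based, half-open (BED convention).
# GTF I/O converts from/to 1-based inclusive at the boundary.

BIOTYPES <- c("coding", "noncoding", "rRNA")

#' Reference genome container
#'
#' Wraps a set of contig sequences (uppercase A/C/G/T/N) behind a small
#' accessor API. Slices are 0-based, half-open; minus-strand slices return
#' the reverse complement.
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet` of contig
#'   sequences; every contig must be non-empty.
#' @return an object of class `genome_ref`.
#' @export
genome_ref <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("genome_ref: contigs must be named")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("genome_ref: empty contig")
  structure(list(seqs = seqs), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("genome_ref: %d contig(s), %s nt total\n",
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

contig_lengths <- function(genome) nchar(genome$seqs)

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a genomic slice
#'
#' @param genome a [genome_ref()].
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return character scalar.
#' @export
genome_seq <- function(genome, contig, start, end, strand = "+") {
  if (is.na(match(contig, names(genome$seqs))))
    stop(sprintf("genome_seq: unknown contig '%s'", contig))
  seq <- genome$seqs[[contig]]
  if (start < 0 || end > nchar(seq) || start >= end)
    stop(sprintf("genome_seq: interval [%d,%d) out of bounds on %s", start, end, contig))
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

#' Gene model
#'
#' A gene with one or more transcripts, each an exon interval chain
#' (0-based, half-open, sorted, non-overlapping) with an optional genomic
#' CDS span. Introns are derived as the gaps between consecutive exons.
#'
#' @param gene_id,contig,strand,biotype gene-level fields; `biotype` one of
#'   `"coding"`, `"noncoding"`, `"rRNA"`.
#' @param transcripts named list; each element a list with `transcript_id`,
#'   `exons` (2-column matrix of start/end) and optional `cds`
#'   (length-2 vector, genomic span, 0-based half-open).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, biotype, transcripts) {
  stopifnot(strand %in% c("+", "-"), biotype %in% BIOTYPES, length(transcripts) >= 1L)
  transcripts <- lapply(transcripts, function(tx) {
    storage.mode(tx$exons) <- "integer"
    if (!is.null(tx$cds)) tx$cds <- as.integer(tx$cds)
    tx
  })
  for (tx in transcripts) {
    ex <- tx$exons
    if (is.null(ex) || nrow(ex) == 0L)
      stop(sprintf("gene_model: transcript '%s' of '%s' has no exons",
                   tx$transcript_id, gene_id))
    if (is.unsorted(ex[, 1L], strictly = TRUE) && nrow(ex) > 1L)
      stop(sprintf("gene_model: exons of '%s' not sorted by start", tx$transcript_id))
    if (any(ex[, 2L] <= ex[, 1L]))
      stop(sprintf("gene_model: empty exon in '%s'", tx$transcript_id))
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop(sprintf("gene_model: overlapping exons in '%s'", tx$transcript_id))
    if (nrow(ex) > 1L && any(ex[-1L, 1L] - ex[-nrow(ex), 2L] < 1L))
      stop(sprintf("gene_model: intron of length < 1 in '%s'", tx$transcript_id))
    if (!is.null(tx$cds)) {
      if (tx$cds[1L] >= tx$cds[2L]) stop("gene_model: empty CDS")
      if (tx$cds[1L] < ex[1L, 1L] || tx$cds[2L] > ex[nrow(ex), 2L])
        stop(sprintf("gene_model: CDS outside exon span in '%s'", tx$transcript_id))
    }
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 biotype = biotype, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s, %s strand, %s): %d transcript(s)\n",
              x$gene_id, x$contig, x$strand, x$biotype, length(x$transcripts)))
  invisible(x)
}

#' Introns of an exon chain
#'
#' @param exons 2-column matrix of sorted exon intervals.
#' @return 2-column matrix of intron intervals (0 rows for single-exon chains).
#' @export
tx_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

#' Canonical transcript of a gene
#'
#' Longest CDS wins; ties and CDS-less genes fall back to the longest
#' exonic length, then to transcript id for a stable order.
#'
#' @param model a [gene_model()].
#' @return the transcript element (list) of the canonical transcript.
#' @export
canonical_transcript <- function(model) {
  txs <- model$transcripts
  cds_len <- vapply(txs, function(tx) {
    if (is.null(tx$cds)) 0L else sum(pmax(0L, pmin(tx$exons[, 2L], tx$cds[2L]) -
                                            pmax(tx$exons[, 1L], tx$cds[1L])))
  }, integer(1))
  ex_len <- vapply(txs, function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L]), integer(1))
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  txs[[order(-cds_len, -ex_len, ids)[1L]]]
}

#' Exonic (mature) length of a transcript
#' @param tx a transcript element of a [gene_model()].
#' @return integer, sum of exon lengths.
#' @export
exonic_length <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L])

#' UTR and CDS exonic intervals of a coding transcript
#'
#' Splits the exon chain at the CDS span into 5'UTR / CDS / 3'UTR exonic
#' pieces, strand-aware: on the minus strand the 5'UTR is the exonic region
#' at coordinates above the CDS end.
#'
#' @param model a [gene_model()]; `tx` one of its transcripts (default
#'   canonical). Returns `NULL` components when no CDS is annotated.
#' @param tx transcript element.
#' @return list with 2-column matrices `utr5`, `cds`, `utr3`.
#' @export
tx_utrs <- function(model, tx = canonical_transcript(model)) {
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (is.null(tx$cds)) return(list(utr5 = empty, cds = empty, utr3 = empty))
  clip <- function(lo, hi) {
    s <- pmax(tx$exons[, 1L], lo); e <- pmin(tx$exons[, 2L], hi)
    keep <- e > s
    cbind(start = s[keep], end = e[keep])
  }
  low  <- clip(0L, tx$cds[1L])          # exonic region below CDS
  mid  <- clip(tx$cds[1L], tx$cds[2L])
  high <- clip(tx$cds[2L], .Machine$integer.max)
  if (model$strand == "+") list(utr5 = low, cds = mid, utr3 = high)
  else                     list(utr5 = high, cds = mid, utr3 = low)
}

#' Back-splice junction identifier
#'
#' Junction identity is genomic: `(contig, strand, acceptor, donor)` with
#' `acceptor < donor` (0-based half-open circle interval).
#'
#' @param contig,strand,acceptor,donor junction fields (vectorized).
#' @return character vector of junction ids.
#' @export
junction_id <- function(contig, strand, acceptor, donor) {
  stopifnot(all(acceptor < donor))
  sprintf("%s:%s:%d-%d", contig, strand, as.integer(acceptor), as.integer(donor))
}

#' Parse junction ids back into fields
#' @param id character vector of ids from [junction_id()].
#' @return data.frame with contig, strand, acceptor, donor.
#' @export
parse_junction_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([+-]):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("parse_junction_id: malformed id(s): ",
                     paste(head(id[bad], 3), collapse = ", "))
  data.frame(contig = vapply(m, `[`, character(1), 2L),
             strand = vapply(m, `[`, character(1), 3L),
             acceptor = as.integer(vapply(m, `[`, character(1), 4L)),
             donor = as.integer(vapply(m, `[`, character(1), 5L)),
             stringsAsFactors = FALSE)
}

#' Experimental design sheet
#'
#' The full fractionated design: 2 sexes x 3 tissues x 3 fractions.
#' R- and R+ libraries are stranded; polyA is not.
#'
#' @param sexes,tissues,fractions factors of the design grid.
#' @return data.frame with columns sample_id, sex, tissue, fraction, stranded.
#' @export
make_design <- function(sexes = c("F", "M"),
                        tissues = c("head", "body", "gonad"),
                        fractions = c("polyA", "Rminus", "Rplus")) {
  g <- expand.grid(fraction = fractions, tissue = tissues, sex = sexes,
                   stringsAsFactors = FALSE)
  d <- data.frame(sample_id = paste(g$sex, g$tissue, g$fraction, sep = "_"),
                  sex = g$sex, tissue = g$tissue, fraction = g$fraction,
                  stranded = g$fraction %in% c("Rminus", "Rplus"),
                  stringsAsFactors = FALSE)
  validate_design(d)
  d
}

validate_design <- function(design) {
  need <- c("sample_id", "sex", "tissue", "fraction")
  if (!all(need %in% names(design))) stop("sample sheet must have columns: ",
                                          paste(need, collapse = ", "))
  if (anyDuplicated(design[, c("sex", "tissue", "fraction")]))
    stop("sample sheet: duplicated (sex, tissue, fraction) combination")
  if (!all(design$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(design$tissue %in% c("head", "body", "gonad"))) stop("unknown tissue")
  if (!all(design$fraction %in% c("polyA", "Rminus", "Rplus"))) stop("unknown fraction")
  if (is.null(design$stranded))
    design$stranded <- design$fraction %in% c("Rminus", "Rplus")
  if (any(design$stranded & design$fraction == "polyA") ||
      any(!design$stranded & design$fraction != "polyA"))
    stop("R-/R+ libraries are stranded, polyA is not")
  invisible(design)
}

# restore RNG state on exit so library code does not clobber the session RNG
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
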