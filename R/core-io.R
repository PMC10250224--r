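# Readers/writers for the on-disk formats shared by the pipeline.
# FASTA/FASTQ through Biostrings, GTF/BED12 parsing through rtracklayer;
# internal coordinates are converted at these boundaries only.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a [genome_ref()].
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  genome_ref(x)
}

#' Write a genome FASTA
#' @param genome a [genome_ref()]; `path` output file.
#' @param path output FASTA path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), path, width = 70L)
  invisible(path)
}

#' Write reads as FASTQ (Phred 33, fixed quality "I")
#' @param reads named character vector (names are read ids).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ into a named character vector
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# ---- annotation ------------------------------------------------------------

biotype_to_gtf <- c(coding = "protein_coding", noncoding = "ncRNA", rRNA = "rRNA")

gtf_to_biotype <- function(x) {
  ifelse(x == "protein_coding", "coding", ifelse(x == "rRNA", "rRNA", "noncoding"))
}

#' Read gene models from a GTF file
#'
#' Parses gene/transcript/exon (and optional CDS) features; introns are
#' derived as the gaps between consecutive exons of each transcript.
#' Coordinates are converted from GTF's 1-based inclusive to the package's
#' 0-based half-open convention.
#'
#' @param path GTF file with `gene_id`/`transcript_id` attributes.
#' @param genome optional [genome_ref()]; when given, exons are validated
#'   against contig bounds.
#' @return named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (is.null(df$gene_id) || is.null(df$transcript_id))
    stop("read_annotation: GTF lacks gene_id/transcript_id attributes")
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  tx_rows <- df[df$type == "transcript", , drop = FALSE]
  declared_tx <- unique(tx_rows$transcript_id)
  with_exons <- unique(ex$transcript_id)
  orphan <- setdiff(declared_tx, with_exons)
  if (length(orphan))
    stop("read_annotation: transcript(s) with zero exon records: ",
         paste(head(orphan, 5), collapse = ", "))
  if (nrow(ex) == 0L) stop("read_annotation: no exon features in ", path)
  if (!is.null(genome)) {
    len <- contig_lengths(genome)
    bad <- !(ex$seqnames %in% names(len)) | ex$end > len[as.character(ex$seqnames)]
    if (any(bad))
      stop("read_annotation: exon outside declared contig (first: ",
           ex$seqnames[which(bad)[1L]], ":", ex$start[which(bad)[1L]], ")")
  }
  models <- list()
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, , drop = FALSE]
    gc <- cds[cds$gene_id == gid, , drop = FALSE]
    bt <- if (!is.null(ge$gene_biotype)) gtf_to_biotype(ge$gene_biotype[1L]) else "coding"
    txs <- list()
    for (tid in unique(ge$transcript_id)) {
      te <- ge[ge$transcript_id == tid, , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]
      exons <- cbind(start = te$start - 1L, end = te$end)  # to 0-based half-open
      tc <- gc[gc$transcript_id == tid, , drop = FALSE]
      cds_iv <- if (nrow(tc)) c(min(tc$start) - 1L, max(tc$end)) else NULL
      txs[[tid]] <- list(transcript_id = tid, exons = exons, cds = cds_iv)
    }
    models[[gid]] <- gene_model(gid, as.character(ge$seqnames[1L]),
                                as.character(ge$strand[1L]), bt, txs)
  }
  models
}

#' Write gene models to a GTF file
#'
#' Emits gene/transcript/exon/CDS records (1-based inclusive coordinates)
#' with `gene_id`, `transcript_id` and `gene_biotype` attributes, so that
#' [read_annotation()] composed with this writer is the identity on exon
#' intervals.
#'
#' @param models list of [gene_model()].
#' @param path output GTF path.
#' @export
write_annotation <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    span <- range(unlist(lapply(m$transcripts, function(tx) tx$exons)))
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', m$gene_id,
                      biotype_to_gtf[[m$biotype]])
    lines <- c(lines, sprintf("%s\tcircdimorph\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              m$contig, span[1L] + 1L, span[2L], m$strand, attr_g))
    for (tx in m$transcripts) {
      a <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   m$gene_id, tx$transcript_id, biotype_to_gtf[[m$biotype]])
      lines <- c(lines, sprintf("%s\tcircdimorph\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                                m$contig, tx$exons[1L, 1L] + 1L,
                                tx$exons[nrow(tx$exons), 2L], m$strand, a))
      lines <- c(lines, sprintf("%s\tcircdimorph\texon\t%d\t%d\t.\t%s\t.\t%s",
                                m$contig, tx$exons[, 1L] + 1L, tx$exons[, 2L],
                                m$strand, a))
      if (!is.null(tx$cds)) {
        pieces <- tx_utrs(m, tx)$cds
        lines <- c(lines, sprintf("%s\tcircdimorph\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  m$contig, pieces[, 1L] + 1L, pieces[, 2L],
                                  m$strand, a))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- circular RNA calls ----------------------------------------------------

#' Construct a circRNA call table
#'
#' One row per back-splice junction. `exon_chain` is a list column of
#' 2-column matrices (present for exonic calls, single-interval for ciRNAs).
#'
#' @param contig,strand,acceptor,donor junction fields (vectors).
#' @param circ_type `"exonic"`, `"ciRNA"` or `"unassigned"`.
#' @param gene_id cognate gene or `NA`.
#' @param exon_chain list of 2-column interval matrices.
#' @return data.frame of class `circ_calls` keyed by `junction_id`.
#' @export
circ_calls <- function(contig, strand, acceptor, donor, circ_type, gene_id,
                       exon_chain) {
  stopifnot(all(circ_type %in% c("exonic", "ciRNA", "unassigned")))
  n <- length(contig)
  mature <- integer(n)
  for (i in seq_len(n)) {
    if (circ_type[i] == "exonic") {
      if (is.null(exon_chain[[i]]) || nrow(exon_chain[[i]]) == 0L)
        stop("circ_calls: exonic call without exon chain")
      mature[i] <- sum(exon_chain[[i]][, 2L] - exon_chain[[i]][, 1L])
    } else {
      mature[i] <- donor[i] - acceptor[i]
      if (is.null(exon_chain[[i]]))
        exon_chain[[i]] <- cbind(start = acceptor[i], end = donor[i])
    }
  }
  out <- data.frame(junction_id = junction_id(contig, strand, acceptor, donor),
                    contig = contig, strand = strand,
                    acceptor = as.integer(acceptor), donor = as.integer(donor),
                    circ_type = circ_type, gene_id = gene_id,
                    mature_length = mature, stringsAsFactors = FALSE)
  out$exon_chain <- exon_chain
  class(out) <- c("circ_calls", "data.frame")
  out
}

#' Write circRNA calls as BED12
#'
#' `chromStart`/`chromEnd` are the junction acceptor/donor; blocks encode
#' the exon chain (ciRNAs are single-block rows). The name field encodes
#' junction id, type and cognate gene, so [read_circ_bed()] round-trips the
#' call set losslessly.
#'
#' @param calls a [circ_calls()] table.
#' @param path output BED12 path.
#' @export
write_circ_bed <- function(calls, path) {
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ch <- calls$exon_chain[[i]]
    if (any(ch[, 1L] < calls$acceptor[i]) || any(ch[, 2L] > calls$donor[i]))
      stop("write_circ_bed: block outside [chromStart, chromEnd) for ",
           calls$junction_id[i])
    sizes <- paste(ch[, 2L] - ch[, 1L], collapse = ",")
    starts <- paste(ch[, 1L] - calls$acceptor[i], collapse = ",")
    name <- paste(calls$junction_id[i], calls$circ_type[i],
                  ifelse(is.na(calls$gene_id[i]), ".", calls$gene_id[i]), sep = "|")
    rows[i] <- paste(calls$contig[i], calls$acceptor[i], calls$donor[i], name, 0L,
                     calls$strand[i], calls$acceptor[i], calls$donor[i], "0",
                     nrow(ch), sizes, starts, sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read circRNA calls from BED12
#' @param path BED12 file written by [write_circ_bed()].
#' @return a [circ_calls()] table.
#' @export
read_circ_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  meta <- strsplit(df$name, "|", fixed = TRUE)
  circ_type <- vapply(meta, `[`, character(1), 2L)
  gene_id <- vapply(meta, `[`, character(1), 3L)
  gene_id[gene_id == "."] <- NA_character_
  acceptor <- df$start - 1L
  blocks <- gr$blocks  # 1-based, relative to chromStart
  chains <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    cbind(start = acceptor[i] + BiocGenerics::start(b) - 1L,
          end = acceptor[i] + BiocGenerics::end(b))
  })
  circ_calls(as.character(df$seqnames), as.character(df$strand),
             acceptor, df$end, circ_type, gene_id, chains)
}

#' Mature sequence of a circular RNA call
#'
#' Concatenation of the exon-chain sequences in transcript orientation
#' (reverse order + reverse complement on the minus strand); for ciRNAs this
#' is the contiguous genomic slice of the lariat-derived circle.
#'
#' @param call one row of a [circ_calls()] table.
#' @param genome a [genome_ref()].
#' @return character scalar of length `mature_length`.
#' @export
mature_sequence <- function(call, genome) {
  ch <- call$exon_chain[[1L]]
  parts <- vapply(seq_len(nrow(ch)), function(i)
    genome_seq(genome, call$contig, ch[i, 1L], ch[i, 2L], "+"), character(1))
  s <- paste(parts, collapse = "")
  if (call$strand == "-") revcomp(s) else s
}

# ---- tabular ---------------------------------------------------------------

#' Write / read a count matrix as TSV
#'
#' First column `id` holds row identifiers (junction or gene ids); remaining
#' columns are samples.
#'
#' @param mat numeric matrix with row and column names.
#' @param path TSV path.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Read / write the sample sheet
#' @param path TSV with header sample_id/sex/tissue/fraction.
#' @return validated design data.frame (see [make_design()]).
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(d$stranded)) d$stranded <- d$fraction %in% c("Rminus", "Rplus")
  validate_design(d)
  d
}

#' @rdname read_sample_sheet
#' @param design design data.frame.
#' @export
write_sample_sheet <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write PAR-CLIP peaks as BED6+4
#'
#' Columns: chrom, start, end, name, score (enrichment ratio), strand,
#' then p_value, best CIMS FDR, significant flag and genomic region.
#'
#' @param peaks peak table from [call_peaks()] (after significance/region
#'   annotation).
#' @param path output path.
#' @export
write_peak_bed <- function(peaks, path) {
  best_fdr <- vapply(peaks$cims_sites, function(s)
    if (is.null(s) || nrow(s) == 0L) NA_real_ else min(s$fdr), numeric(1))
  df <- data.frame(chrom = peaks$contig, start = peaks$start, end = peaks$end,
                   name = peaks$peak_id, score = signif(peaks$ratio, 6),
                   strand = peaks$strand, p_value = signif(peaks$p_value, 6),
                   cims_fdr = best_fdr,
                   significant = if (is.null(peaks$significant)) NA else peaks$significant,
                   region = if (is.null(peaks$region)) NA_character_ else peaks$region,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
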