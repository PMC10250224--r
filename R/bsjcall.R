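# Back-splice junction detection against an annotation-derived junction
# library. A probe is the junction-spanning sequence (last L nt upstream of
# the donor ++ first L nt downstream of the acceptor in transcript
# orientation, L = read_length - min_anchor); reads are assigned by exact
# anchor seeding plus full verification in compiled code.

#' Build the back-splice junction probe library
#'
#' One exonic-BSJ probe for every ordered pair of canonical-transcript exon
#' boundaries (i <= j) within a gene and a genomic span limit, and one lariat
#' probe per intron and branch-point offset (the intron 5' end joined to a
#' position 15-50 nt upstream of its 3' end).
#'
#' @param models gene models.
#' @param genome a [genome_ref()].
#' @param read_length read length the probes must cover.
#' @param min_anchor minimum anchor on each side of the junction (nt).
#' @param bp_offsets branch-point offsets (nt upstream of the intron 3' end).
#' @param max_span maximum genomic span (donor - acceptor) of a junction.
#' @return data.frame of class `bsj_library` (one row per junction).
#' @export
build_bsj_library <- function(models, genome, read_length = 100L,
                              min_anchor = 10L, bp_offsets = seq(15L, 50L, 5L),
                              max_span = 1e5) {
  stopifnot(min_anchor >= 1L, read_length > 2L * min_anchor)
  L <- read_length - min_anchor
  rows <- list()
  n_trunc <- 0L
  add <- function(contig, strand, acceptor, donor, kind, gene_id, mat, chain) {
    if (nchar(mat) < L) n_trunc <<- n_trunc + 1L
    side <- min(L, nchar(mat))
    probe <- paste0(substr(mat, nchar(mat) - side + 1L, nchar(mat)),
                    substr(mat, 1L, side))
    rows[[length(rows) + 1L]] <<- list(
      junction_id = junction_id(contig, strand, acceptor, donor),
      contig = contig, strand = strand, acceptor = as.integer(acceptor),
      donor = as.integer(donor), kind = kind, gene_id = gene_id,
      probe = probe, jpos = side, mature_length = nchar(mat), chain = chain)
  }
  for (m in models) {
    if (m$biotype == "rRNA") next
    tx <- canonical_transcript(m)
    ex <- tx$exons
    n <- nrow(ex)
    for (i in seq_len(n)) for (j in i:n) {
      if (ex[j, 2L] - ex[i, 1L] > max_span) next
      chain <- ex[i:j, , drop = FALSE]
      parts <- vapply(seq_len(nrow(chain)), function(k)
        genome_seq(genome, m$contig, chain[k, 1L], chain[k, 2L], "+"), character(1))
      mat <- paste(parts, collapse = "")
      if (m$strand == "-") mat <- revcomp(mat)
      add(m$contig, m$strand, ex[i, 1L], ex[j, 2L], "exonic-BSJ", m$gene_id,
          mat, chain)
    }
    intr <- tx_introns(ex)
    for (i in seq_len(nrow(intr))) {
      for (d in bp_offsets) {
        if (intr[i, 2L] - intr[i, 1L] - d < 1L) next
        if (m$strand == "+") {
          acc <- intr[i, 1L]; don <- intr[i, 2L] - d
        } else {
          acc <- intr[i, 1L] + d; don <- intr[i, 2L]
        }
        mat <- genome_seq(genome, m$contig, acc, don, m$strand)
        add(m$contig, m$strand, acc, don, "lariat", m$gene_id, mat,
            cbind(start = acc, end = don))
      }
    }
  }
  if (n_trunc > 0L)
    warning(sprintf("build_bsj_library: %d probe(s) truncated (mature < %d nt)",
                    n_trunc, L))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "chain")], stringsAsFactors = FALSE)))
  df$chain <- lapply(rows, `[[`, "chain")
  dup <- duplicated(df$junction_id)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- df$junction_id
  attr(df, "read_length") <- as.integer(read_length)
  attr(df, "min_anchor") <- as.integer(min_anchor)
  class(df) <- c("bsj_library", "data.frame")
  df
}

#' Scan reads for back-splice junctions
#'
#' A read is assigned when some probe alignment places the junction with at
#' least `min_anchor` nt on each side and at most `max_mm` mismatches; the
#' fewest-mismatch assignment wins. Ties between junctions, and equal-quality
#' contiguous matches to the linear genome (checked when `genome` is given),
#' mark the read `unique_best = FALSE`, which excludes it from counting.
#'
#' @param reads named character vector of read sequences, or a FASTQ path.
#' @param library a `bsj_library`.
#' @param min_anchor minimum anchor length (default from the library).
#' @param max_mm maximum mismatches over the full read.
#' @param stranded if `FALSE`, the reverse complement is also scanned.
#' @param genome optional [genome_ref()] for the linear-locus tie check.
#' @return data.frame: read_id, junction_id, offset (nt left of the junction),
#'   mm, unique_best. Reads shorter than `2 * min_anchor` are skipped and
#'   counted in attribute `n_skipped`.
#' @export
scan_reads <- function(reads, library, min_anchor = attr(library, "min_anchor"),
                       max_mm = 1L, stranded = TRUE, genome = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  ok <- nchar(reads) >= 2L * min_anchor
  n_skipped <- sum(!ok)
  reads <- reads[ok]

  scan1 <- function(seqs, orient) {
    h <- bsj_scan_cpp(unname(seqs), library$probe, library$jpos,
                      as.integer(min_anchor), as.integer(max_mm))
    if (nrow(h) == 0L) return(NULL)
    data.frame(read_id = names(seqs)[h$read],
               junction_id = library$junction_id[h$probe],
               offset = h$offset, mm = h$mm, n_best = h$n_best,
               orient = orient, stringsAsFactors = FALSE)
  }
  hits <- scan1(reads, "+")
  if (!stranded) {
    rc <- scan1(setNames(revcomp(reads), names(reads)), "-")
    if (!is.null(rc)) {
      hits <- rbind(hits, rc)
      # per read keep the better orientation; equal quality across
      # orientations to different junctions is a tie
      hits <- do.call(rbind, lapply(split(hits, hits$read_id), function(g) {
        g <- g[order(g$mm), , drop = FALSE]
        if (nrow(g) > 1L && g$mm[2L] == g$mm[1L] &&
            g$junction_id[2L] != g$junction_id[1L])
          g$n_best[1L] <- g$n_best[1L] + g$n_best[2L]
        g[1L, , drop = FALSE]
      }))
    }
  }
  if (is.null(hits))
    hits <- data.frame(read_id = character(0), junction_id = character(0),
                       offset = integer(0), mm = integer(0),
                       n_best = integer(0), orient = character(0),
                       stringsAsFactors = FALSE)
  hits$unique_best <- hits$n_best == 1L

  if (!is.null(genome) && nrow(hits) > 0L) {
    sub <- reads[hits$read_id]
    for (seqs in list(sub, revcomp(sub))) {
      lin <- linear_align_cpp(unname(seqs), unname(genome$seqs),
                              as.integer(max_mm), 0L)$hits
      if (nrow(lin) > 0L) {
        worse <- lin$mm <= hits$mm[lin$read]
        hits$unique_best[lin$read[worse]] <- FALSE
      }
    }
  }
  rownames(hits) <- NULL
  out <- hits[, c("read_id", "junction_id", "offset", "mm", "unique_best")]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Aggregate per-sample assignments into circRNA calls
#'
#' @param assignments named list (sample_id -> data.frame from
#'   [scan_reads()]); only `unique_best` assignments are counted.
#' @param library the `bsj_library` used for scanning.
#' @param models gene models (for typing and gene-ambiguity checks).
#' @return list with `calls` (a [circ_calls()] table) and `counts`
#'   (junction x sample integer matrix).
#' @export
aggregate_calls <- function(assignments, library, models) {
  samples <- names(assignments)
  tabs <- lapply(assignments, function(a) {
    a <- a[a$unique_best, , drop = FALSE]
    table(factor(a$junction_id, levels = library$junction_id))
  })
  counts <- do.call(cbind, lapply(tabs, as.integer))
  dimnames(counts) <- list(library$junction_id, samples)
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  lib <- library[keep, , drop = FALSE]
  if (nrow(lib) == 0L)
    return(list(calls = circ_calls(character(0), character(0), integer(0),
                                   integer(0), character(0), character(0),
                                   list()),
                counts = counts))
  spans <- do.call(rbind, lapply(models, function(m) {
    r <- range(unlist(lapply(m$transcripts, function(tx) tx$exons)))
    data.frame(gene_id = m$gene_id, contig = m$contig, start = r[1L],
               end = r[2L], stringsAsFactors = FALSE)
  }))
  gene_id <- lib$gene_id
  ambiguous <- logical(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    inside <- spans$contig == lib$contig[i] & spans$start <= lib$acceptor[i] &
      spans$end >= lib$donor[i]
    if (sum(inside) > 1L) { gene_id[i] <- NA_character_; ambiguous[i] <- TRUE }
  }
  circ_type <- classify_call(lib$contig, lib$strand, lib$acceptor, lib$donor,
                             models)
  calls <- circ_calls(lib$contig, lib$strand, lib$acceptor, lib$donor,
                      circ_type, gene_id, lib$chain)
  calls$gene_ambiguous <- ambiguous
  list(calls = calls, counts = counts)
}

#' Classify junctions as exonic circRNA, ciRNA or unassigned
#'
#' Exonic iff both boundaries coincide exactly with annotated exon boundaries
#' of one gene; ciRNA iff the interval starts at an intron 5' end
#' (strand-aware) and ends within the branch-point window upstream of the
#' intron 3' end; otherwise unassigned.
#'
#' @param contig,strand,acceptor,donor junction fields (vectors).
#' @param models gene models.
#' @param bp_window branch-point window (nt upstream of the intron 3' end).
#' @return character vector of types.
#' @export
classify_call <- function(contig, strand, acceptor, donor, models,
                          bp_window = c(15L, 50L)) {
  n <- length(contig)
  out <- rep("unassigned", n)
  for (i in seq_len(n)) {
    for (m in models) {
      if (m$contig != contig[i] || m$strand != strand[i]) next
      starts <- unlist(lapply(m$transcripts, function(tx) tx$exons[, 1L]))
      ends <- unlist(lapply(m$transcripts, function(tx) tx$exons[, 2L]))
      if (acceptor[i] %in% starts && donor[i] %in% ends) {
        out[i] <- "exonic"; break
      }
      intr <- tx_introns(canonical_transcript(m)$exons)
      for (k in seq_len(nrow(intr))) {
        if (acceptor[i] < intr[k, 1L] || donor[i] > intr[k, 2L]) next
        hit <- if (m$strand == "+") {
          acceptor[i] == intr[k, 1L] &&
            (intr[k, 2L] - donor[i]) >= bp_window[1L] &&
            (intr[k, 2L] - donor[i]) <= bp_window[2L]
        } else {
          donor[i] == intr[k, 2L] &&
            (acceptor[i] - intr[k, 1L]) >= bp_window[1L] &&
            (acceptor[i] - intr[k, 1L]) <= bp_window[2L]
        }
        if (hit) { out[i] <- "ciRNA"; break }
      }
      if (out[i] != "unassigned") break
    }
  }
  out
}

#' Structural summaries of a call set
#'
#' Per-call exon count and mature length, plus cohort summaries: gene-region
#' origin fractions (position of the circle within its host transcript),
#' circles-per-gene distribution, exon-count histogram and median length.
#'
#' @param calls a [circ_calls()] table.
#' @param models gene models (for origin classification).
#' @return list with `per_call`, `origin`, `circ_per_gene`,
#'   `exon_count_hist`, `median_length`.
#' @export
summarize_structure <- function(calls, models) {
  exonic <- calls$circ_type == "exonic"
  n_exons <- ifelse(exonic, vapply(calls$exon_chain, nrow, integer(1)),
                    NA_integer_)
  origin <- rep(NA_character_, nrow(calls))
  for (i in which(exonic & !is.na(calls$gene_id))) {
    m <- models[[calls$gene_id[i]]]
    if (m$biotype != "coding") { origin[i] <- "noncoding gene"; next }
    ex <- canonical_transcript(m)$exons
    first <- calls$acceptor[i] == ex[1L, 1L]
    last <- calls$donor[i] == ex[nrow(ex), 2L]
    # strand-aware terminal labels
    if (m$strand == "-") { tmp <- first; first <- last; last <- tmp }
    origin[i] <- if (first && last) "full-length" else if (first) "5' terminal"
    else if (last) "3' terminal" else "middle exons"
  }
  origin[calls$circ_type == "ciRNA"] <- "intron (ciRNA)"
  per_call <- data.frame(junction_id = calls$junction_id,
                         circ_type = calls$circ_type, gene_id = calls$gene_id,
                         n_exons = n_exons, mature_length = calls$mature_length,
                         origin = origin, stringsAsFactors = FALSE)
  cpg <- table(table(calls$gene_id[exonic & !is.na(calls$gene_id)]))
  list(per_call = per_call,
       origin = prop.table(table(origin)),
       circ_per_gene = cpg,
       exon_count_hist = table(n_exons[exonic]),
       median_length = median(calls$mature_length))
}
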