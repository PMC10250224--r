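# K-mer enrichment against a dinucleotide-preserving shuffle background
# (Altschul-Erikson style: random Eulerian re-walk of the dinucleotide graph,
# preserving first/last base and the full dinucleotide composition).

dinuc_shuffle <- function(seq, max_tries = 10000L) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < 3L) return(seq)
  verts <- unique(chars)
  succ <- split(chars[-1L], factor(chars[-n], levels = verts))
  for (try in seq_len(max_tries)) {
    edges <- lapply(succ, function(v) if (length(v)) sample(v) else v)
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- chars[1L]
    cur <- chars[1L]
    ok <- TRUE
    for (i in 2:n) {
      e <- edges[[cur]]
      k <- ptr[[cur]]
      if (k > length(e)) { ok <- FALSE; break }
      ptr[[cur]] <- k + 1L
      cur <- e[k]
      out[i] <- cur
    }
    if (ok) return(paste(out, collapse = ""))
  }
  stop("dinuc_shuffle: no Eulerian walk found (degenerate sequence?)")
}

#' K-mer enrichment in peak sequences
#'
#' Observed k-mer counts are compared with `n_shuffle` dinucleotide-preserving
#' shuffles of the same sequences; the z-score is
#' `(observed - mean_shuffle) / sd_shuffle`, ranked descending. Sequences
#' shorter than `k` are skipped.
#'
#' @param seqs character vector of peak sequences (DNA alphabet; U-rich RNA
#'   motifs appear as T-rich k-mers).
#' @param k k-mer size.
#' @param n_shuffle shuffle rounds.
#' @param seed integer seed.
#' @return data.frame: kmer, observed, mean_shuffle, sd_shuffle, z.
#' @export
kmer_enrichment <- function(seqs, k = 5L, n_shuffle = 100L, seed = 1L) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) stop("kmer_enrichment: no sequence of length >= k")
  count_k <- function(ss) colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(ss), width = k))
  obs <- count_k(seqs)
  with_seed(seed, {
    null_counts <- vapply(seq_len(n_shuffle), function(b)
      count_k(vapply(seqs, dinuc_shuffle, character(1))),
      numeric(length(obs)))
    mu <- rowMeans(null_counts)
    s <- apply(null_counts, 1L, sd)
    z <- (obs - mu) / pmax(s, 1e-9)
    out <- data.frame(kmer = names(obs), observed = as.numeric(obs),
                      mean_shuffle = mu, sd_shuffle = s, z = z,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$z), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Extract peak sequences (transcript orientation)
#' @param peaks peak table; `genome` a [genome_ref()].
#' @param genome a [genome_ref()].
#' @return character vector named by peak_id.
#' @export
peak_sequences <- function(peaks, genome) {
  setNames(vapply(seq_len(nrow(peaks)), function(i)
    genome_seq(genome, peaks$contig[i], peaks$start[i], peaks$end[i],
               peaks$strand[i]), character(1)),
    peaks$peak_id)
}
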