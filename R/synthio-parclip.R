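# PAR-CLIP read simulator: signal reads pile up on planted binding sites with
# Gaussian jitter and carry T>C conversions at covered site Ts (transcript
# orientation); background reads are uniform over the genome. The IgG control
# library is background only.

#' Simulate a PAR-CLIP library
#'
#' Per-site signal mass is `clip_enrichment x affinity x (site_width +
#' read_length) / genome_length` of the library, i.e. the expected
#' library-size-normalized SXL:IgG read-count ratio over the site window that
#' peak calling measures. Each signal read converts every covered site T to C
#' independently with probability `conversion_rate`; background reads carry
#' conversions only through the sequencing error process.
#'
#' @param truth a `truth_set` with planted `sites`.
#' @param genome a [genome_ref()].
#' @param library `"SXL"` (signal + background) or `"IgG"` (background only).
#' @param depth number of reads.
#' @param seed integer seed.
#' @return list with `reads` (named character) and `truth` (read_id, source,
#'   unit = site id or NA).
#' @export
simulate_parclip <- function(truth, genome, library = c("SXL", "IgG"),
                             depth, seed) {
  library <- match.arg(library)
  p <- truth$params
  rl <- p$read_length
  sites <- truth$sites
  clens <- contig_lengths(genome)
  G <- sum(clens)

  p_sig <- if (library == "SXL")
    p$clip_enrichment * sites$affinity * (sites$end - sites$start + rl) / G
  else rep(0, nrow(sites))
  if (sum(p_sig) >= 0.9)
    stop("simulate_parclip: planted signal mass >= 90% of the library; ",
         "reduce sites/enrichment or enlarge the genome")
  probs <- c(p_sig, 1 - sum(p_sig))

  if (depth == 0L)
    return(list(reads = setNames(character(0), character(0)),
                truth = data.frame(read_id = character(0), source = character(0),
                                   unit = character(0))))

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, depth, probs))
    n_bg <- counts[length(counts)]
    site_idx <- rep(seq_len(nrow(sites)), counts[-length(counts)])
    n_sig <- length(site_idx)

    reads <- character(n_sig + n_bg)
    src <- c(rep("CLIP-signal", n_sig), rep("CLIP-background", n_bg))
    unitv <- c(sites$site_id[site_idx], rep(NA_character_, n_bg))

    if (n_sig > 0L) {
      s <- sites[site_idx, , drop = FALSE]
      center <- (s$start + s$end) %/% 2L + round(rnorm(n_sig, 0, p$clip_jitter_sd))
      start <- pmin(pmax(center - rl %/% 2L, 0L), clens[s$contig] - rl)
      sig <- substr(genome$seqs[s$contig], start + 1L, start + rl)
      # convert covered site Ts (forward space: T>C on +, A>G on -) per
      # site-T position, vectorized over reads
      for (si in unique(site_idx)) {
        st <- sites[si, ]
        rsel <- which(site_idx == si)
        tbase <- if (st$strand == "+") "T" else "A"
        cbase <- if (st$strand == "+") "C" else "G"
        site_seq <- strsplit(genome_seq(genome, st$contig, st$start, st$end,
                                        "+"), "")[[1L]]
        for (tp in st$start + which(site_seq == tbase) - 1L) {
          covered <- rsel[start[rsel] <= tp & start[rsel] + rl > tp]
          conv <- covered[runif(length(covered)) < p$conversion_rate]
          if (length(conv))
            substr(sig[conv], tp - start[conv] + 1L, tp - start[conv] + 1L) <- cbase
        }
      }
      minus <- s$strand == "-"
      sig[minus] <- revcomp(sig[minus])
      reads[seq_len(n_sig)] <- sig
    }
    if (n_bg > 0L) {
      ct <- sample(names(clens), n_bg, replace = TRUE, prob = clens)
      start <- floor(runif(n_bg) * (clens[ct] - rl + 1))
      strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      bg <- substr(genome$seqs[ct], start + 1L, start + rl)
      bg[strand == "-"] <- revcomp(bg[strand == "-"])
      reads[n_sig + seq_len(n_bg)] <- bg
    }
    reads <- apply_seq_errors(reads, p$error_rate)
    ids <- sprintf("%s_r%06d", library, seq_along(reads))
    list(reads = setNames(reads, ids),
         truth = data.frame(read_id = ids, source = src, unit = unitv,
                            stringsAsFactors = FALSE))
  })
}
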