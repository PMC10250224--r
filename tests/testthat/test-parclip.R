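# PAR-CLIP stages: alignment with conversion-exempt mismatches, peak calling
# with a Poisson oracle, CIMS permutation FDR, the two-branch rule, region
# assignment, k-mer enrichment.

clip_genome <- function() genome_ref(setNames(rand_dna(6000L, seed = 1313), "chrC"))

mutate_at <- function(s, pos, base) { substr(s, pos, pos) <- base; s }

test_that("CLIP alignment records conversions and rejects multimappers", {
  g <- clip_genome()
  sl <- genome_seq(g, "chrC", 1000, 1100)
  a0 <- align_clip_reads(c(r = sl), g)
  expect_equal(a0$start, 1000L)
  expect_equal(a0$n_conv, 0L)
  expect_equal(a0$strand, "+")

  tpos <- 1000L + which(strsplit(sl, "")[[1L]] == "T")[3L] - 1L
  rt <- mutate_at(sl, tpos - 1000L + 1L, "C")
  a1 <- align_clip_reads(c(r = rt), g)
  expect_equal(a1$mm, 0L)                      # T>C does not count as mismatch
  expect_equal(a1$conversions[[1L]], tpos)

  # minus-strand read: transcript T>C appears as genomic A>G
  apos <- 1000L + which(strsplit(sl, "")[[1L]] == "A")[3L] - 1L
  rm <- revcomp(mutate_at(sl, apos - 1000L + 1L, "G"))
  a2 <- align_clip_reads(c(r = rm), g)
  expect_equal(a2$strand, "-")
  expect_equal(a2$conversions[[1L]], apos)

  # three non-T>C mismatches exceed max_mm = 2
  bad <- sl
  for (p in c(10L, 40L, 70L)) {
    old <- substr(bad, p, p)
    bad <- mutate_at(bad, p, setdiff(c("A", "C", "G", "T"),
                                     c(old, "C", "G"))[1L])
  }
  expect_equal(nrow(align_clip_reads(c(r = bad), g, max_mm = 2L)), 0L)
})

test_that("peak calling thresholds coverage, merges runs and scores by Poisson", {
  g <- clip_genome()
  mk_aln <- function(starts) {
    n <- length(starts)
    df <- data.frame(read_id = sprintf("r%d", seq_len(n)),
                     contig = rep("chrC", n), start = starts,
                     end = starts + 100L, strand = rep("+", n),
                     mm = rep(0L, n), n_conv = rep(0L, n),
                     stringsAsFactors = FALSE)
    df$conversions <- rep(list(integer(0)), n)
    df
  }
  igg0 <- mk_aln(integer(0))

  # coverage below min_cov: no peaks
  expect_equal(nrow(call_peaks(mk_aln(rep(500L, 4L)), igg0, min_cov = 5L)), 0L)

  # two coverage runs 5 nt apart merge into one peak
  two <- mk_aln(c(rep(500L, 6L), rep(605L, 6L)))
  pk <- call_peaks(two, igg0, min_cov = 5L, merge_gap = 10L)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 500L)
  expect_equal(pk$end, 705L)
  # and stay separate when the gap reaches merge_gap
  apart <- mk_aln(c(rep(500L, 6L), rep(640L, 6L)))
  expect_equal(nrow(call_peaks(apart, igg0, min_cov = 5L, merge_gap = 10L)), 2L)

  # Poisson oracle: sxl = 15 overlapping reads, igg = 0, equal library sizes
  sxl <- mk_aln(rep(2000L, 15L))
  igg <- mk_aln(rep(4000L, 15L))  # same N, elsewhere
  pk2 <- call_peaks(sxl, igg, min_cov = 5L)
  p_oracle <- 1 - sum(exp(-1) / factorial(0:14))  # upper tail of Poisson(1) at 15
  expect_equal(pk2$p_value[1L], p_oracle, tolerance = 1e-12)
  expect_equal(pk2$ratio[1L], (15 / 15) / (1 / 15))
})

test_that("CIMS: a concentrated site gets low FDR, sprayed conversions do not", {
  g <- clip_genome()
  region_start <- 3000L
  reads <- vapply(0:9, function(i)
    genome_seq(g, "chrC", region_start + i, region_start + i + 100L),
    character(1))
  chars <- strsplit(genome_seq(g, "chrC", region_start, region_start + 120L), "")[[1L]]
  tpos <- region_start + which(chars == "T") - 1L
  target <- tpos[6L]
  mk <- function(reads, conv_per_read) {
    starts <- region_start + 0:9
    data.frame(read_id = sprintf("r%d", 1:10), contig = "chrC",
               start = starts, end = starts + 100L, strand = "+",
               mm = 0L, n_conv = lengths(conv_per_read),
               conversions = I(conv_per_read), stringsAsFactors = FALSE)
  }
  peak <- data.frame(peak_id = "p1", contig = "chrC", start = region_start,
                     end = region_start + 110L, strand = "+",
                     stringsAsFactors = FALSE)

  # no conversions at all -> no sites
  aln0 <- mk(reads, rep(list(integer(0)), 10L))
  expect_equal(nrow(find_cims(peak, aln0, g, n_perm = 100L, seed = 1)), 0L)

  # k = 8 of m = 10 at one position, background ~0 elsewhere
  conc <- c(rep(list(target), 8L), list(integer(0)), list(integer(0)))
  s1 <- find_cims(peak, mk(reads, conc), g, n_perm = 1000L, seed = 2)
  expect_lt(s1$fdr[s1$position == target], 0.05)
  expect_equal(s1$k[s1$position == target], 8L)
  expect_equal(s1$m[s1$position == target], 10L)

  # conversions sprayed uniformly across many T positions -> high FDR
  set.seed(3)
  spray_t <- tpos[tpos >= region_start + 9L & tpos < region_start + 100L]
  spray <- lapply(1:10, function(i) sample(spray_t, 10L, replace = TRUE))
  s2 <- find_cims(peak, mk(reads, spray), g, n_perm = 1000L, seed = 4)
  expect_gt(median(s2$fdr), 0.3)

  # reproducible under a fixed seed; stable in n_perm
  s1b <- find_cims(peak, mk(reads, conc), g, n_perm = 1000L, seed = 2)
  expect_identical(s1, s1b)
  s1c <- find_cims(peak, mk(reads, conc), g, n_perm = 4000L, seed = 9)
  expect_lt(abs(s1c$fdr[s1c$position == target] -
                  s1$fdr[s1$position == target]), 0.05)
})

test_that("the two-branch significance rule and its monotonicity hold", {
  mk_peak <- function(ratio, p, fdr) {
    pk <- data.frame(peak_id = "p", ratio = ratio, p_value = p,
                     stringsAsFactors = FALSE)
    pk$cims_sites <- list(if (is.na(fdr)) NULL else
      data.frame(position = 1L, k = 3L, m = 5L, fdr = fdr))
    pk
  }
  expect_true(significant_peaks(mk_peak(12, 1e-6, 0.1))$significant)
  expect_false(significant_peaks(mk_peak(12, 1e-6, NA))$significant)
  expect_true(significant_peaks(mk_peak(150, 1e-6, NA))$significant)
  expect_false(significant_peaks(mk_peak(150, 1e-3, 0.1))$significant)
  expect_false(significant_peaks(mk_peak(12, 1e-6, 0.5))$significant)

  # monotone in ratio and p
  grid <- expand.grid(ratio = c(5, 10, 50, 100, 200),
                      p = c(1e-6, 1e-5, 1e-3), fdr = c(0.1, NA))
  for (fdr in unique(grid$fdr)) {
    sub <- grid[is.na(grid$fdr) == is.na(fdr), ]
    for (p in unique(sub$p)) {
      s <- vapply(sort(unique(sub$ratio)), function(r)
        significant_peaks(mk_peak(r, p, fdr))$significant, logical(1))
      expect_true(all(diff(s) >= 0))
    }
  }
})

test_that("genomic region labels follow midpoint precedence with densities", {
  models <- hand_models()
  g <- hand_genome()
  pk <- data.frame(peak_id = c("p1", "p2", "p3", "p4"), contig = "chr1",
                   start = c(560L, 220L, 20L, 110L),
                   end = c(600L, 280L, 60L, 150L),
                   strand = c("+", "+", "+", "+"), stringsAsFactors = FALSE)
  out <- assign_genomic_region(pk, models, g)
  expect_equal(out$peaks$region, c("3'UTR", "intron", "intergenic", "5'UTR"))
  d <- out$density
  expect_equal(d$n_peaks[d$category == "3'UTR"], 1L)
  # 3'UTR total: gA [550,600) + gB [700,730) = 80 nt
  expect_equal(d$kb[d$category == "3'UTR"], 0.08)
  expect_equal(d$peaks_per_kb[d$category == "3'UTR"], 1 / 0.08)
  expect_equal(2 / 4, 0.5)  # density arithmetic: 2 peaks over 4 kb
})

test_that("peaks map to circRNA-relative regions, strand-aware", {
  models <- hand_models()
  call <- circ_calls("chr1", "+", 300L, 400L, "exonic", "gA",
                     list(cbind(start = 300L, end = 400L)))
  mk_pk <- function(s, e) data.frame(peak_id = "p", contig = "chr1", start = s,
                                     end = e, strand = "+",
                                     stringsAsFactors = FALSE)
  expect_equal(assign_circ_region(mk_pk(320L, 360L), call, models)$category,
               "back-spliced exon")
  expect_equal(assign_circ_region(mk_pk(210L, 260L), call, models)$category,
               "flanking intron")   # intron [200,300) upstream of the acceptor
  expect_equal(assign_circ_region(mk_pk(120L, 160L), call, models)$category,
               "flanking exon")     # exon [100,200) beyond that intron
  expect_equal(assign_circ_region(mk_pk(420L, 460L), call, models)$category,
               "flanking intron")   # intron [400,500) downstream of the donor
  # wrong strand: no assignment
  pk_minus <- mk_pk(320L, 360L); pk_minus$strand <- "-"
  expect_equal(nrow(assign_circ_region(pk_minus, call, models)), 0L)
  # full-length circle lacks flanking features; sides are skipped, not fatal
  full <- circ_calls("chr1", "+", 100L, 600L, "exonic", "gA",
                     list(canonical_transcript(models$gA)$exons))
  res <- assign_circ_region(mk_pk(120L, 160L), full, models)
  expect_equal(res$category, "back-spliced exon")
  expect_equal(attr(res, "n_terminal_sides_skipped"), 2L)
})

test_that("k-mer enrichment finds planted motifs and calibrates on shuffles", {
  expect_equal(kmer_enrichment(rep(strrep("A", 30L), 5L), k = 5,
                               n_shuffle = 20, seed = 1)$kmer[1L], "AAAAA")
  set.seed(21)
  bg <- vapply(1:40, function(i) rand_dna(60L, seed = 2000 + i), character(1))
  null <- kmer_enrichment(bg, k = 5, n_shuffle = 50, seed = 2)
  expect_lt(median(abs(null$z)), 2)
  planted <- bg
  put <- sample.int(40L, 24L)  # 60% of peaks carry a U-rich core (T in DNA)
  for (i in put) substr(planted[i], 20L, 28L) <- "TTTTTTTTT"
  top <- kmer_enrichment(planted, k = 5, n_shuffle = 50, seed = 3)
  expect_equal(top$kmer[1L], "TTTTT")
  expect_error(kmer_enrichment(c("ACG"), k = 5), "length >= k")
})
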