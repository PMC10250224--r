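# The synthetic-data generator: determinism, construction invariants,
# statistical properties of emitted reads against closed-form oracles.

test_that("generator output is byte-identical under a fixed seed", {
  g1 <- generate_genome(15, seed = 42)
  g2 <- generate_genome(15, seed = 42)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gt1 <- withr::local_tempfile(fileext = ".gtf")
  gt2 <- withr::local_tempfile(fileext = ".gtf")
  write_genome(g1$genome, fa1); write_genome(g2$genome, fa2)
  write_annotation(g1$models, gt1); write_annotation(g2$models, gt2)
  expect_identical(md5_of(fa1), md5_of(fa2))
  expect_identical(md5_of(gt1), md5_of(gt2))
})

test_that("every generated intron starts GT and ends AG in transcript orientation", {
  gen <- toy_gen()
  for (m in gen$models) {
    for (iv in seq_len(nrow(tx_introns(canonical_transcript(m)$exons)))) {
      intr <- tx_introns(canonical_transcript(m)$exons)[iv, ]
      s <- genome_seq(gen$genome, m$contig, intr[1L], intr[2L], m$strand)
      expect_equal(substr(s, 1L, 2L), "GT")
      expect_equal(substr(s, nchar(s) - 1L, nchar(s)), "AG")
    }
  }
})

test_that("exon counts are uniform on the configured range", {
  gen <- generate_genome(200, seed = 99)
  n_ex <- vapply(gen$models, function(m)
    nrow(canonical_transcript(m)$exons), integer(1))
  expect_true(all(n_ex >= 3L & n_ex <= 8L))
  p <- chisq.test(table(factor(n_ex, levels = 3:8)))$p.value
  expect_gt(p, 0.01)
})

test_that("infeasible generator configuration errors out", {
  expect_error(generate_genome(5, seed = 1, config = list(exon_len = c(300L, 80L))),
               "infeasible")
  expect_error(generate_genome(5, seed = 1, config = list(n_rrna = 0L)),
               "rRNA")
})

test_that("planted classes build the configured rate structure exactly", {
  truth <- toy_truth()
  circ <- truth$circles
  eff <- truth$effects
  fb <- circ$class == "female_biased"
  expect_equal(sum(fb), 20L)
  expect_true(all(eff[fb, "F_head"] / eff[fb, "M_head"] == 8))
  nul <- circ$class == "null"
  expect_true(all(eff[nul, ] == 1))  # identical rates across samples
  fs <- circ$class == "female_specific"
  expect_true(all(eff[fs, c("M_head", "M_body", "M_gonad")] == 0))
  # junctions sit on annotated boundaries / intron 5' ends
  expect_true(all(classify_call(circ$contig, circ$strand, circ$acceptor,
                                circ$donor, toy_gen()$models) == circ$circ_type))
})

test_that("requesting more circles than available boundary pairs errors", {
  gen <- generate_genome(5, seed = 3)
  expect_error(plant_truth(gen$models, gen$genome, make_design(), seed = 1,
                           config = list(n_null = 5000, n_sites_per_role = NULL)),
               "boundary pairs")
})

test_that("zero depth yields an empty library and fractions behave", {
  gen <- toy_gen(); truth <- toy_truth_exact()
  sim0 <- simulate_rnaseq(truth, gen$models, gen$genome, "F_head_Rplus", 0L, 1)
  expect_length(sim0$reads, 0L)

  # survival 0, error 0: every R+ read comes from a planted circle and maps
  # inside its (doubled) mature sequence
  tr0 <- plant_truth(gen$models, gen$genome, make_design(), seed = 11,
                     config = list(n_sites_per_role = NULL, error_rate = 0,
                                   rnaseR_linear_survival = 0))
  sim <- simulate_rnaseq(tr0, gen$models, gen$genome, "M_body_Rplus", 2000L, 2)
  expect_setequal(unique(sim$truth$source),
                  intersect(unique(sim$truth$source),
                            c("BSJ", "ciRNA-junction", "circ-internal")))
  idx <- match(sim$truth$unit, tr0$circles$junction_id)
  for (i in sample.int(length(sim$reads), 50L)) {
    mat <- mature_sequence(tr0$circles[idx[i], , drop = FALSE], gen$genome)
    expect_true(grepl(sim$reads[[i]], paste0(mat, mat), fixed = TRUE))
  }

  # polyA holds coding-gene mRNA only
  simA <- simulate_rnaseq(truth, gen$models, gen$genome, "F_head_polyA", 3000L, 3)
  expect_true(all(simA$truth$source == "linear"))
  biot <- vapply(gen$models[unique(simA$truth$unit)], `[[`, character(1), "biotype")
  expect_true(all(biot == "coding"))
})

test_that("per-sample truth label counts sum to depth", {
  gen <- toy_gen(); truth <- toy_truth()
  sim <- simulate_rnaseq(truth, gen$models, gen$genome, "F_gonad_Rminus", 5000L, 4)
  expect_equal(sum(table(sim$truth$source)), 5000L)
  expect_length(sim$reads, 5000L)
})

test_that("RNase-R contract: linear:circular mass ratio scales by survival", {
  gen <- toy_gen(); truth <- toy_truth()
  ratio_of <- function(sample) {
    comp <- sample_composition(truth, gen$models, sample)
    circ <- comp$kind %in% c("BSJ", "ciRNA-junction", "circ-internal")
    sum(comp$prob[!circ]) / sum(comp$prob[circ])
  }
  surv <- truth$params$rnaseR_linear_survival
  expect_equal(ratio_of("F_head_Rplus"), surv * ratio_of("F_head_Rminus"),
               tolerance = 1e-10)
})

test_that("BSJ read counts match the binomial oracle across seeds", {
  gen <- toy_gen(); truth <- toy_truth()
  depth <- 4000L
  pr <- true_bsj_prob(truth, gen$models, "M_head_Rplus")
  j <- names(pr)[which.max(pr)]
  inside <- 0L
  for (s in 1:20) {
    sim <- simulate_rnaseq(truth, gen$models, gen$genome, "M_head_Rplus",
                           depth, seed = 1000 + s)
    obs <- sum(sim$truth$unit == j &
                 sim$truth$source %in% c("BSJ", "ciRNA-junction"))
    mu <- depth * pr[[j]]
    hw <- 1.96 * sqrt(depth * pr[[j]] * (1 - pr[[j]]))
    inside <- inside + (obs >= mu - hw && obs <= mu + hw)
  }
  expect_gte(inside, 16L)  # 95% CI coverage, with slack for 20 draws
})

test_that("simulated FASTQ files are byte-identical under a fixed seed", {
  gen <- toy_gen(); truth <- toy_truth()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_simulated(simulate_rnaseq(truth, gen$models, gen$genome,
                                  "F_body_Rminus", 2000L, 77), p1)
  write_simulated(simulate_rnaseq(truth, gen$models, gen$genome,
                                  "F_body_Rminus", 2000L, 77), p2)
  expect_identical(md5_of(paste0(p1, ".fastq")), md5_of(paste0(p2, ".fastq")))
  expect_identical(md5_of(paste0(p1, ".truth.tsv")), md5_of(paste0(p2, ".truth.tsv")))
})

test_that("PAR-CLIP simulator honours conversion and affinity contracts", {
  gen <- generate_genome(30, seed = 5)
  design <- make_design()
  truth <- plant_truth(gen$models, gen$genome, design, seed = 6,
                       config = list(n_null = 20, n_female_biased = 0,
                                     n_male_biased = 0, n_female_specific = 0,
                                     n_male_specific = 0, n_cirna = 0,
                                     one_circle_per_gene = TRUE,
                                     error_rate = 0,
                                     n_sites_per_role = c("back-spliced exon" = 5L,
                                                          "flanking intron" = 5L)))
  # IgG with error rate 0: zero T>C conversions
  igg <- simulate_parclip(truth, gen$genome, "IgG", 3000L, seed = 8)
  aln <- align_clip_reads(igg$reads, gen$genome)
  expect_equal(sum(aln$n_conv), 0L)

  # affinity 0: no signal reads
  t0 <- truth
  t0$sites$affinity <- 0
  sxl0 <- simulate_parclip(t0, gen$genome, "SXL", 2000L, seed = 9)
  expect_true(all(sxl0$truth$source == "CLIP-background"))

  # closed form: P(read carries >= 1 conversion) = 1 - (1 - rate)^t for a
  # read covering t site Ts; with jitter 0 every signal read covers the site
  tj <- truth
  tj$params$clip_jitter_sd <- 0
  site <- tj$sites[1L, ]
  site_seq <- genome_seq(gen$genome, site$contig, site$start, site$end, site$strand)
  tcount <- sum(strsplit(site_seq, "")[[1L]] == "T")
  expected <- 1 - (1 - tj$params$conversion_rate)^tcount
  fr <- vapply(1:10, function(s) {
    sim <- simulate_parclip(tj, gen$genome, "SXL", 4000L, seed = 100 + s)
    sig <- sim$truth$read_id[sim$truth$unit %in% site$site_id &
                               !is.na(sim$truth$unit)]
    al <- align_clip_reads(sim$reads[sig], gen$genome)
    mean(al$n_conv >= 1L)
  }, numeric(1))
  expect_equal(mean(fr), expected, tolerance = 0.05)
})
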