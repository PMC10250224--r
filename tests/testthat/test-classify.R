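# Threshold rules: reliability, differential expression, sex specificity,
# differential back-splicing groups, alternative back-splicing (with a
# brute-force oracle), and monotonicity/exclusivity properties.

mk_counts <- function(values, junctions, samples)
  matrix(values, length(junctions), length(samples),
         dimnames = list(junctions, samples), byrow = TRUE)

design <- make_design()
RP <- design$sample_id[design$fraction == "Rplus"]
RM <- design$sample_id[design$fraction == "Rminus"]

test_that("reliability rule: R+ >= 2 R- with an R+ >= 2 floor", {
  rp <- mk_counts(c(10, 7, 3, 1, 0, 2), sprintf("j%d", 1:6), RP[1L])
  rp <- matrix(rp, 6L, 6L, dimnames = list(sprintf("j%d", 1:6), RP))
  rm <- matrix(c(4, 4, 0, 0, 0, 1), 6L, 6L,
               dimnames = list(sprintf("j%d", 1:6), RM))
  rel <- reliable_filter(rp, rm, design)
  expect_true(rel$reliable["j1"])    # 10 >= 8
  expect_false(rel$reliable["j2"])   # 7 < 8
  expect_true(rel$reliable["j3"])    # 3 >= 0 and >= 2
  expect_false(rel$reliable["j4"])   # 1 < floor
  expect_false(rel$reliable["j5"])   # 0 reads
  expect_true(rel$reliable["j6"])    # 2 >= 2 and 2 >= 2*1
  bad <- rm[, -1L, drop = FALSE]
  expect_error(reliable_filter(rp, bad, design), "no matched R-")
})

test_that("differential expression needs fold and agreeing R- direction", {
  juncs <- c("j1", "j2", "j3")
  rp <- matrix(0, 3L, 6L, dimnames = list(juncs, RP))
  rm <- matrix(0, 3L, 6L, dimnames = list(juncs, RM))
  rp[, "F_head_Rplus"] <- c(40, 40, 12)
  rp[, "M_head_Rplus"] <- c(8, 8, 12)
  rm[, "F_head_Rminus"] <- c(6, 2, 5)
  rm[, "M_head_Rminus"] <- c(2, 6, 5)
  cmp <- make_comparisons("between-sex")
  de <- diff_expression(rp, rm, design, cmp)
  expect_equal(unname(de["j1", "head_FvsM"]), "a")    # 40.5/8.5 >= 4, agrees
  expect_equal(unname(de["j2", "head_FvsM"]), "none") # direction conflicts
  expect_equal(unname(de["j3", "head_FvsM"]), "none") # identical columns
  # reliable restriction zeroes other junctions
  de2 <- diff_expression(rp, rm, design, cmp, reliable = "j2")
  expect_true(all(de2["j1", ] == "none"))
})

test_that("sex specificity needs the read floor and zero opposite-sex counts", {
  juncs <- sprintf("j%d", 1:3)
  rp <- matrix(0, 3L, 6L, dimnames = list(juncs, RP))
  rm <- matrix(0, 3L, 6L, dimnames = list(juncs, RM))
  rp[c("j1", "j2"), "F_head_Rplus"] <- c(20, 14)
  rp["j3", "F_head_Rplus"] <- 20
  rm["j3", "M_body_Rminus"] <- 1
  ss <- sex_specific(rp, rm, design)
  expect_true(ss["j1", "F"])
  expect_false(ss["j2", "F"])        # 14 < 15
  expect_false(ss["j3", "F"])        # detected in a male R- sample
  expect_true(all(!ss[, "M"]))
  # the R+-only reading tolerates opposite-sex R- detection
  ss2 <- sex_specific(rp, rm, design, opposite_fractions = "Rplus")
  expect_true(ss2["j3", "F"])
})

test_that("differential back-splicing assigns the tissue x direction groups", {
  juncs <- c("j1", "j2", "j3", "j4")
  lev <- matrix(0, 4L, 6L, dimnames = list(juncs, RP))
  rp <- matrix(20, 4L, 6L, dimnames = list(juncs, RP))
  rm <- matrix(0, 4L, 6L, dimnames = list(juncs, RM))
  lev[, "F_head_Rplus"] <- c(60, 12, 10, 50)
  lev[, "M_head_Rplus"] <- c(10, 2, 58, 50)
  lev[, "F_gonad_Rplus"] <- c(1, 1, 1, 8)
  lev[, "M_gonad_Rplus"] <- c(1, 1, 1, 60)
  rm[, "F_head_Rminus"] <- c(5, 5, 1, 2)
  rm[, "M_head_Rminus"] <- c(1, 1, 5, 2)
  rm[, "F_gonad_Rminus"] <- c(1, 1, 1, 1)
  rm[, "M_gonad_Rminus"] <- c(1, 1, 1, 6)
  db <- diff_backsplicing(lev, rp, rm, design, min_support = 15)
  g <- setNames(db$groups$group, db$groups$junction_id)
  expect_equal(unname(g["j1"]), "G1")    # head F > M, 60/10 = 6
  expect_equal(unname(g["j3"]), "G2")    # head M > F
  expect_equal(unname(g["j4"]), "G5")    # testis > ovary
  expect_equal(unname(g["j2"]), "G1")    # 12/2 = 6 with support floor met
  # optional normalized-level floor (levels must reach min_level)
  db2 <- diff_backsplicing(lev, rp, rm, design, min_support = NULL,
                           min_level = 15)
  g2 <- setNames(db2$groups$group, db2$groups$junction_id)
  expect_equal(unname(g2["j2"]), "none") # max level 12 < 15
  expect_equal(unname(g2["j1"]), "G1")   # 60 >= 15
  # raw-support floor blocks when R+ reads are scarce
  rp2 <- rp; rp2[, ] <- 5
  db3 <- diff_backsplicing(lev, rp2, rm, design, min_support = 15)
  expect_true(all(db3$groups$group == "none"))
})

test_that("threshold filters are monotone and sides exclusive", {
  set.seed(123)
  juncs <- sprintf("j%02d", 1:40)
  rp <- matrix(rpois(240L, 20), 40L, 6L, dimnames = list(juncs, RP))
  rm <- matrix(rpois(240L, 5), 40L, 6L, dimnames = list(juncs, RM))
  cmp <- make_comparisons("both")
  sizes <- vapply(c(2, 4, 8, 16), function(f)
    sum(diff_expression(rp, rm, design, cmp, min_fold = f) != "none"),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  de <- diff_expression(rp, rm, design, cmp, min_fold = 2)
  expect_true(all(de %in% c("a", "b", "none")))  # one side per comparison
  ss_sizes <- vapply(c(5, 15, 40), function(k)
    sum(sex_specific(rp, rm, design, min_reads = k)), numeric(1))
  expect_true(all(diff(ss_sizes) <= 0))
  lev <- rp / 2
  db_sizes <- vapply(c(5, 15, 60), function(k)
    sum(diff_backsplicing(lev, rp, rm, design, min_support = k)$flags != "none"),
    numeric(1))
  expect_true(all(diff(db_sizes) <= 0))
  # sex_specific implies the floor in the expressing sex
  ss <- sex_specific(rp, rm, design, min_reads = 15)
  expect_true(all(!ss))  # every junction detected everywhere here
})

test_that("alternative back-splicing matches the exhaustive pairing oracle", {
  mk_calls <- function(acc, don, strand = "+", gene = "gX") circ_calls(
    rep("chr1", length(acc)), rep(strand, length(acc)), acc, don,
    rep("exonic", length(acc)), rep(gene, length(acc)),
    lapply(seq_along(acc), function(i) cbind(acc[i], don[i])))
  rp1 <- function(calls) matrix(1L, nrow(calls), 2L,
                                dimnames = list(calls$junction_id,
                                                c("F_head_Rplus", "M_head_Rplus")))
  c1 <- mk_calls(c(100L, 100L), c(500L, 700L))
  ev1 <- alt_backsplicing(c1, rp1(c1))
  expect_equal(ev1$kind, "alt5")
  expect_equal(ev1$shared_pos, 100L)

  c2 <- mk_calls(c(100L, 200L), c(700L, 700L))
  ev2 <- alt_backsplicing(c2, rp1(c2))
  expect_equal(ev2$kind, "alt3")

  c3 <- mk_calls(c(100L, 100L, 200L), c(500L, 700L, 700L))
  ev3 <- alt_backsplicing(c3, rp1(c3))
  expect_equal(sort(ev3$kind), c("alt3", "alt5"))

  # minus strand: roles flip (shared 3'SS is the high coordinate)
  c4 <- mk_calls(c(100L, 200L), c(700L, 700L), strand = "-")
  ev4 <- alt_backsplicing(c4, rp1(c4))
  expect_equal(ev4$kind, "alt5")

  # observation rule: a sample counts when >= 2 members have a read
  rp <- rp1(c1); rp[2L, 2L] <- 0L
  ev5 <- alt_backsplicing(c1, rp)
  expect_equal(ev5$samples_observed, "F_head_Rplus")

  # random call sets against the exhaustive pairing oracle
  set.seed(77)
  for (rep in 1:10) {
    genes <- sample(c("g1", "g2", "g3"), 12L, replace = TRUE)
    strands <- setNames(sample(c("+", "-"), 3L, replace = TRUE),
                        c("g1", "g2", "g3"))
    acc <- sample(seq(100L, 400L, 100L), 12L, replace = TRUE)
    don <- acc + sample(seq(200L, 600L, 200L), 12L, replace = TRUE)
    calls <- circ_calls("chr1", strands[genes], acc, don, rep("exonic", 12L),
                        genes, lapply(seq_len(12L), function(i)
                          cbind(acc[i], don[i])))
    calls <- calls[!duplicated(calls$junction_id), ]
    got <- alt_backsplicing(calls, rp1(calls))
    want <- alt_bs_oracle(calls)
    got_key <- sort(paste(got$gene_id, got$kind, got$shared_pos))
    want_key <- sort(paste(want$gene_id, want$kind, want$shared_pos))
    expect_equal(got_key, want_key)
  }
})
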