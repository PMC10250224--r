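# Shared fixtures, built in code. hand_models()/hand_genome() give a tiny
# fully hand-specified two-gene annotation with known sequences; toy_*()
# build seeded medium fixtures once per test run (cached in an environment).

.fix <- new.env(parent = emptyenv())

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plus-strand coding gene: exons [100,200) [300,400) [500,600), CDS [150,550)
# minus-strand coding gene: exons [700,760) [820,900), CDS [730,880)
hand_models <- function() {
  list(
    gA = gene_model("gA", "chr1", "+", "coding", list(
      "gA.t1" = list(transcript_id = "gA.t1",
                     exons = cbind(start = c(100L, 300L, 500L),
                                   end = c(200L, 400L, 600L)),
                     cds = c(150L, 550L)))),
    gB = gene_model("gB", "chr1", "-", "coding", list(
      "gB.t1" = list(transcript_id = "gB.t1",
                     exons = cbind(start = c(700L, 820L),
                                   end = c(760L, 900L)),
                     cds = c(730L, 880L)))))
}

hand_genome <- function() genome_ref(setNames(rand_dna(1000L, seed = 424242), "chr1"))

toy_gen <- function() {
  if (is.null(.fix$gen)) .fix$gen <- generate_genome(40, seed = 7)
  .fix$gen
}

toy_truth <- function() {
  if (is.null(.fix$truth))
    .fix$truth <- plant_truth(toy_gen()$models, toy_gen()$genome, make_design(),
                              seed = 11, config = list(n_sites_per_role = NULL))
  .fix$truth
}

# an error-free variant used by exactness oracles
toy_truth_exact <- function() {
  if (is.null(.fix$truth_exact))
    .fix$truth_exact <- plant_truth(toy_gen()$models, toy_gen()$genome,
                                    make_design(), seed = 11,
                                    config = list(n_sites_per_role = NULL,
                                                  error_rate = 0))
  .fix$truth_exact
}

toy_lib <- function() {
  if (is.null(.fix$lib))
    .fix$lib <- suppressWarnings(build_bsj_library(toy_gen()$models,
                                                   toy_gen()$genome))
  .fix$lib
}

# independent brute-force enumeration of alternative back-splicing events,
# used as the oracle for alt_backsplicing
alt_bs_oracle <- function(calls) {
  ex <- calls[calls$circ_type == "exonic" & !is.na(calls$gene_id), , drop = FALSE]
  res <- list()
  for (g in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == g, , drop = FALSE]
    ss3 <- ifelse(sub$strand == "+", sub$acceptor, sub$donor)
    ss5 <- ifelse(sub$strand == "+", sub$donor, sub$acceptor)
    # alt5: all pairs sharing ss3 with different ss5, grouped by shared ss3
    for (kind in c("alt5", "alt3")) {
      shared_vec <- if (kind == "alt5") ss3 else ss5
      other_vec <- if (kind == "alt5") ss5 else ss3
      for (sv in unique(shared_vec)) {
        members <- sub$junction_id[shared_vec == sv]
        others <- other_vec[shared_vec == sv]
        pairs <- 0L
        if (length(members) >= 2L)
          for (i in seq_along(members)) for (j in seq_along(members))
            if (i < j && others[i] != others[j]) pairs <- pairs + 1L
        if (pairs > 0L)
          res[[length(res) + 1L]] <- data.frame(
            gene_id = g, kind = kind, shared_pos = sv,
            members = paste(sort(unique(members[duplicated(c(members)) | TRUE])),
                            collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(0), kind = character(0),
                                      shared_pos = integer(0),
                                      members = character(0))
  out[order(out$gene_id, out$kind, out$shared_pos), , drop = FALSE]
}

md5_of <- function(path) unname(tools::md5sum(path))
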