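# Planting of ground truth: circles with class-structured abundance effects,
# gene expression, and CLIP binding sites in circRNA-relative role categories.

BIOSAMPLES <- c("F_head", "F_body", "F_gonad", "M_head", "M_body", "M_gonad")

biosample_of <- function(sex, tissue) paste(sex, tissue, sep = "_")

#' Default truth configuration
#'
#' Class counts define the planted circle population (the study conditions);
#' rates, survival and conversion probabilities are the generative stand-ins
#' for the unobserved quantities of the fractionation/PAR-CLIP experiment.
#'
#' @return named list of truth parameters.
#' @export
truth_config <- function() {
  list(
    # exonic circle classes
    n_null = 70L, n_female_biased = 20L, n_male_biased = 20L,
    n_female_specific = 10L, n_male_specific = 10L,
    n_cirna = 20L,                  # lariat-derived circles, always null class
    one_circle_per_gene = FALSE,    # spread exonic circles over distinct genes
    fold = 8, biased_tissue = "head",
    circ_weight_sdlog = 0.4,        # spread of per-circle base abundance
    circ_mass_rminus = 0.005,       # circle-derived fraction of R- reads
    internal_factor = 1,            # internal:junction fragment weight ratio
    rnaseR_linear_survival = 0.02,
    rrna_residual = 0.02,           # residual rRNA fraction in R-/R+
    error_rate = 0.001,
    read_length = 100L,
    expr_meanlog = 0, expr_sdlog = 1,
    lariat_branch_offset = 25L,     # branch point, nt upstream of intron 3' end
    # PAR-CLIP
    conversion_rate = 0.25,
    clip_enrichment = 20,
    clip_jitter_sd = 10,
    site_width = 21L,
    site_margin = 80L,              # margin inside circ-role features
    site_margin_other = 2L,         # margin inside 3'UTR / intergenic features
    min_site_ts = 4L,               # minimum Ts (transcript orientation) in a site
    n_sites_per_role = c("back-spliced exon" = 20L, "flanking intron" = 20L,
                         "flanking exon" = 20L, "3'UTR" = 20L, "other" = 20L)
  )
}

# enumerate candidate exonic junctions (gene, i <= j over canonical exons)
# circles are planted on coding hosts only: the TPM denominator of the
# back-splicing level comes from polyA libraries, which do not measure
# noncoding genes (and nearly all known circRNAs arise from protein-coding
# genes)
exonic_candidates <- function(models, min_mature, max_span = 1e5) {
  out <- list()
  for (m in models) {
    if (m$biotype != "coding") next
    ex <- canonical_transcript(m)$exons
    n <- nrow(ex)
    for (i in seq_len(n)) for (j in i:n) {
      chain <- ex[i:j, , drop = FALSE]
      mat <- sum(chain[, 2L] - chain[, 1L])
      if (mat < min_mature) next
      if (ex[j, 2L] - ex[i, 1L] > max_span) next
      out[[length(out) + 1L]] <- list(gene_id = m$gene_id, contig = m$contig,
                                      strand = m$strand, acceptor = ex[i, 1L],
                                      donor = ex[j, 2L], chain = chain)
    }
  }
  out
}

cirna_candidates <- function(models, min_mature, branch_offset) {
  out <- list()
  for (m in models) {
    if (m$biotype != "coding") next
    intr <- tx_introns(canonical_transcript(m)$exons)
    for (i in seq_len(nrow(intr))) {
      len <- intr[i, 2L] - intr[i, 1L]
      if (len - branch_offset < min_mature) next
      if (m$strand == "+") {
        acc <- intr[i, 1L]; don <- intr[i, 2L] - branch_offset
      } else {
        acc <- intr[i, 1L] + branch_offset; don <- intr[i, 2L]
      }
      out[[length(out) + 1L]] <- list(gene_id = m$gene_id, contig = m$contig,
                                      strand = m$strand, acceptor = acc,
                                      donor = don, chain = NULL)
    }
  }
  out
}

#' Plant ground truth over a toy genome
#'
#' Assigns each planted exonic circle to a class (null, female/male-biased at
#' `fold`, female/male-specific), draws per-circle base weights and per-gene
#' expression, plants lariat-derived ciRNAs, and places CLIP binding sites in
#' the five role categories relative to the planted circles.
#'
#' @param models gene models (from [generate_genome()]).
#' @param genome the matching [genome_ref()] (sites are placed only where the
#'   site sequence carries enough Ts to crosslink).
#' @param design sample sheet (see [make_design()]); must cover all six
#'   sex-tissue combinations in all three fractions.
#' @param seed integer seed.
#' @param config list overriding [truth_config()] entries.
#' @return object of class `truth_set`: `circles` (a [circ_calls()] table with
#'   `class` and `weight`), `effects` and `bsj_weight` (circle x biosample),
#'   `expression` (gene x biosample), `sites`, `params`, `design`.
#' @export
plant_truth <- function(models, genome, design, seed, config = list()) {
  p <- utils::modifyList(truth_config(), config, keep.null = TRUE)
  validate_design(design)
  combos <- unique(design[, c("sex", "tissue")])
  if (nrow(combos) != 6L || !all(table(design$fraction) == 6L))
    stop("plant_truth: design must cover 6 sex x tissue combinations x 3 fractions")

  with_seed(seed, {
    n_exonic <- p$n_null + p$n_female_biased + p$n_male_biased +
      p$n_female_specific + p$n_male_specific
    ecand <- exonic_candidates(models, p$read_length)
    if (p$one_circle_per_gene && length(ecand)) {
      by_gene <- split(ecand, vapply(ecand, `[[`, character(1), "gene_id"))
      ecand <- lapply(by_gene, function(g) g[[sample.int(length(g), 1L)]])
    }
    if (n_exonic > length(ecand))
      stop(sprintf("plant_truth: %d exonic circles requested, only %d boundary pairs available",
                   n_exonic, length(ecand)))
    ccand <- cirna_candidates(models, p$read_length, p$lariat_branch_offset)
    if (p$n_cirna > length(ccand))
      stop(sprintf("plant_truth: %d ciRNAs requested, only %d eligible introns",
                   p$n_cirna, length(ccand)))

    picks <- c(sample(ecand, n_exonic), sample(ccand, p$n_cirna))
    classes <- c(rep("null", p$n_null),
                 rep("female_biased", p$n_female_biased),
                 rep("male_biased", p$n_male_biased),
                 rep("female_specific", p$n_female_specific),
                 rep("male_specific", p$n_male_specific),
                 rep("null", p$n_cirna))
    types <- c(rep("exonic", n_exonic), rep("ciRNA", p$n_cirna))
    # drop duplicate junctions (possible when two genes share boundaries)
    circles <- circ_calls(
      contig = vapply(picks, `[[`, character(1), "contig"),
      strand = vapply(picks, `[[`, character(1), "strand"),
      acceptor = vapply(picks, function(x) as.integer(x$acceptor), integer(1)),
      donor = vapply(picks, function(x) as.integer(x$donor), integer(1)),
      circ_type = types,
      gene_id = vapply(picks, `[[`, character(1), "gene_id"),
      exon_chain = lapply(picks, `[[`, "chain"))
    circles$class <- classes
    if (anyDuplicated(circles$junction_id)) {
      keep <- !duplicated(circles$junction_id)
      circles <- circles[keep, , drop = FALSE]
    }
    nc <- nrow(circles)
    circles$weight <- rlnorm(nc, meanlog = 0, sdlog = p$circ_weight_sdlog)
    rownames(circles) <- circles$junction_id

    effects <- matrix(1, nc, 6L, dimnames = list(circles$junction_id, BIOSAMPLES))
    bt <- p$biased_tissue
    effects[circles$class == "female_biased", paste0("F_", bt)] <- p$fold
    effects[circles$class == "male_biased", paste0("M_", bt)] <- p$fold
    effects[circles$class == "female_specific", c("M_head", "M_body", "M_gonad")] <- 0
    effects[circles$class == "male_specific", c("F_head", "F_body", "F_gonad")] <- 0
    bsj_weight <- circles$weight * effects

    gene_ids <- names(models)
    base_expr <- rlnorm(length(gene_ids), p$expr_meanlog, p$expr_sdlog)
    expression <- matrix(base_expr, length(gene_ids), 6L,
                         dimnames = list(gene_ids, BIOSAMPLES))

    sites <- plant_sites(models, genome, circles, p)

    structure(list(circles = circles, effects = effects, bsj_weight = bsj_weight,
                   expression = expression, sites = sites, params = p,
                   design = design),
              class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d circles (%s), %d binding sites\n",
              nrow(x$circles),
              paste(sprintf("%s=%d", names(table(x$circles$class)),
                            table(x$circles$class)), collapse = ", "),
              nrow(x$sites)))
  invisible(x)
}

# Place binding sites in the five role categories. Circ-role sites are kept
# site_margin nt clear of feature edges so the resulting peak overlaps its
# planted feature and no neighbouring one; circ-role features come only from
# circles whose gene hosts a single circle, so categories stay unambiguous.
# Sites are placed only where the site sequence carries at least min_site_ts
# Ts in transcript orientation (4SU crosslinks need uridines).
plant_sites <- function(models, genome, circles, p) {
  empty_sites <- data.frame(site_id = character(0), contig = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), affinity = numeric(0),
                            role = character(0), junction_id = character(0),
                            stringsAsFactors = FALSE)
  if (is.null(p$n_sites_per_role) || sum(p$n_sites_per_role) == 0L)
    return(empty_sites)
  n_wanted <- function(role)
    if (role %in% names(p$n_sites_per_role)) p$n_sites_per_role[[role]] else 0L
  w <- p$site_width
  need <- function(margin) w + 2L * margin
  feats <- list()  # rows: contig,start,end,strand,role,junction_id
  add <- function(contig, start, end, strand, role, jid) {
    feats[[length(feats) + 1L]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      role = role, junction_id = jid, stringsAsFactors = FALSE)
  }
  single <- names(which(table(circles$gene_id) == 1L))
  exo <- circles[circles$circ_type == "exonic" & circles$gene_id %in% single, ,
                 drop = FALSE]
  for (i in seq_len(nrow(exo))) {
    m <- models[[exo$gene_id[i]]]
    ex <- canonical_transcript(m)$exons
    intr <- tx_introns(ex)
    jid <- exo$junction_id[i]
    chain <- exo$exon_chain[[i]]
    for (k in seq_len(nrow(chain)))
      if (chain[k, 2L] - chain[k, 1L] >= need(p$site_margin))
        add(m$contig, chain[k, 1L], chain[k, 2L], m$strand, "back-spliced exon", jid)
    up_in <- which(intr[, 2L] == exo$acceptor[i])
    dn_in <- which(intr[, 1L] == exo$donor[i])
    for (k in c(up_in, dn_in))
      if (intr[k, 2L] - intr[k, 1L] >= need(p$site_margin))
        add(m$contig, intr[k, 1L], intr[k, 2L], m$strand, "flanking intron", jid)
    up_ex <- if (length(up_in)) which(ex[, 2L] == intr[up_in, 1L]) else integer(0)
    dn_ex <- if (length(dn_in)) which(ex[, 1L] == intr[dn_in, 2L]) else integer(0)
    for (k in c(up_ex, dn_ex))
      if (ex[k, 2L] - ex[k, 1L] >= need(p$site_margin))
        add(m$contig, ex[k, 1L], ex[k, 2L], m$strand, "flanking exon", jid)
  }
  # prefer 3'UTRs of genes without planted circles (keeps role categories
  # clean), fall back to any coding gene
  circle_genes <- unique(circles$gene_id)
  for (pass in 1:2) {
    n_utr <- if (length(feats))
      sum(vapply(feats, function(f) f$role[1L] == "3'UTR", logical(1))) else 0L
    if (pass == 2L && n_utr >= n_wanted("3'UTR")) break
    for (m in models) {
      if (m$biotype != "coding") next
      hosts <- m$gene_id %in% circle_genes
      if ((pass == 1L && hosts) || (pass == 2L && !hosts)) next
      u3 <- tx_utrs(m)$utr3
      for (k in seq_len(nrow(u3)))
        if (u3[k, 2L] - u3[k, 1L] >= need(p$site_margin_other))
          add(m$contig, u3[k, 1L], u3[k, 2L], m$strand, "3'UTR", NA_character_)
    }
  }
  # intergenic gaps for the 'other' role
  for (ct in unique(vapply(models, `[[`, character(1), "contig"))) {
    spans <- do.call(rbind, lapply(models, function(m) {
      if (m$contig != ct) return(NULL)
      r <- range(unlist(lapply(m$transcripts, function(tx) tx$exons)))
      cbind(r[1L], r[2L])
    }))
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    gaps <- cbind(start = spans[-nrow(spans), 2L], end = spans[-1L, 1L])
    for (k in seq_len(nrow(gaps)))
      if (gaps[k, 2L] - gaps[k, 1L] >= need(p$site_margin))
        add(ct, gaps[k, 1L], gaps[k, 2L], sample(c("+", "-"), 1L), "other",
            NA_character_)
  }
  feats <- do.call(rbind, feats)

  # start positions inside a feature where the site holds enough Ts
  valid_starts <- function(f, margin) {
    lo <- f$start + margin
    hi <- f$end - margin - w
    if (hi < lo) return(integer(0))
    seq_chars <- strsplit(genome_seq(genome, f$contig, lo, hi + w, "+"),
                          "")[[1L]]
    tbase <- if (f$strand == "+") "T" else "A"
    is_t <- as.integer(seq_chars == tbase)
    cs <- cumsum(is_t)
    nt <- cs[w:length(cs)] - c(0L, cs)[1:(length(cs) - w + 1L)]
    (lo:hi)[nt >= p$min_site_ts]
  }

  out <- list()
  for (role in names(p$n_sites_per_role)) {
    n <- p$n_sites_per_role[[role]]
    if (n == 0L) next
    cand <- feats[feats$role == role, , drop = FALSE]
    margin <- if (role %in% c("3'UTR", "other")) p$site_margin_other else p$site_margin
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]  # random order
    chosen <- list()
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) == n) break
      vs <- valid_starts(cand[i, ], margin)
      if (length(vs) == 0L) next
      start <- vs[sample.int(length(vs), 1L)]
      chosen[[length(chosen) + 1L]] <- data.frame(
        contig = cand$contig[i], start = as.integer(start),
        end = as.integer(start + w), strand = cand$strand[i], affinity = 1,
        role = role, junction_id = cand$junction_id[i],
        stringsAsFactors = FALSE)
    }
    if (length(chosen) < n)
      stop(sprintf("plant_sites: %d '%s' sites requested, only %d placeable features",
                   n, role, length(chosen)))
    out[[role]] <- do.call(rbind, chosen)
  }
  sites <- do.call(rbind, out)
  if (is.null(sites))
    return(data.frame(site_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      affinity = numeric(0), role = character(0),
                      junction_id = character(0), stringsAsFactors = FALSE))
  rownames(sites) <- NULL
  sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
  sites[, c("site_id", "contig", "start", "end", "strand", "affinity",
            "role", "junction_id")]
}

#' Build a call table directly from planted truth
#'
#' Convenience for tests and downstream stages that need the planted circles
#' in [circ_calls()] form without running detection.
#'
#' @param truth a `truth_set`.
#' @return the `circles` table (already a [circ_calls()] data.frame).
#' @export
calls_from_truth <- function(truth) truth$circles
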