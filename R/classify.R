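# Threshold rules: RNase-R reliability, differential
# expression (raw R+ fold with R- direction agreement), sex specificity,
# TPM-normalized differential back-splicing with G1-G6 group assignment, and
# alternative back-splicing enumeration. All rules are totalized with a 0.5
# pseudocount in fold changes and an R+ >= 2 floor for zero denominators.

#' The standard comparison grid
#'
#' Between-sex comparisons pair identical tissues (head F vs M, body F vs M,
#' ovary vs testis); between-tissue comparisons pair tissues within a sex.
#'
#' @param kind which comparisons to build.
#' @return data.frame: name, sex_a, tissue_a, sex_b, tissue_b, kind.
#' @export
make_comparisons <- function(kind = c("both", "between-sex", "between-tissue")) {
  kind <- match.arg(kind)
  sex <- data.frame(name = paste0(c("head", "body", "gonad"), "_FvsM"),
                    sex_a = "F", tissue_a = c("head", "body", "gonad"),
                    sex_b = "M", tissue_b = c("head", "body", "gonad"),
                    kind = "between-sex", stringsAsFactors = FALSE)
  pairs <- rbind(c("head", "body"), c("head", "gonad"), c("body", "gonad"))
  tis <- do.call(rbind, lapply(c("F", "M"), function(s)
    data.frame(name = paste0(s, "_", pairs[, 1L], "_vs_", pairs[, 2L]),
               sex_a = s, tissue_a = pairs[, 1L], sex_b = s,
               tissue_b = pairs[, 2L], kind = "between-tissue",
               stringsAsFactors = FALSE)))
  switch(kind, "between-sex" = sex, "between-tissue" = tis, rbind(sex, tis))
}

sample_for <- function(design, sex, tissue, fraction) {
  id <- design$sample_id[design$sex == sex & design$tissue == tissue &
                           design$fraction == fraction]
  if (length(id) != 1L)
    stop(sprintf("no unique sample for %s/%s/%s", sex, tissue, fraction))
  id
}

#' RNase-R reliability filter
#'
#' A junction is reliable in a sample when its R+ BSJ count is at least twice
#' its matched R- count and at least 2 (the floor makes the rule total when
#' R- is zero); globally reliable means reliable in at least one sample.
#'
#' @param rplus,rminus junction x sample count matrices (R+ and R- samples).
#' @param design sample sheet.
#' @return list: `per_sample` (junction x biosample logical matrix) and
#'   `reliable` (named logical vector).
#' @export
reliable_filter <- function(rplus, rminus, design) {
  bs_of <- setNames(biosample_of(design$sex, design$tissue), design$sample_id)
  per <- matrix(FALSE, nrow(rplus), ncol(rplus),
                dimnames = list(rownames(rplus), unname(bs_of[colnames(rplus)])))
  rm_of_bs <- setNames(design$sample_id[design$fraction == "Rminus"],
                       bs_of[design$sample_id[design$fraction == "Rminus"]])
  for (k in seq_len(ncol(rplus))) {
    s <- colnames(rplus)[k]
    rm_id <- rm_of_bs[[bs_of[[s]]]]
    if (is.null(rm_id) || !rm_id %in% colnames(rminus))
      stop(sprintf("reliable_filter: no matched R- sample for %s", s))
    per[, k] <- rplus[, s] >= 2 * rminus[rownames(rplus), rm_id] & rplus[, s] >= 2
  }
  list(per_sample = per, reliable = rowSums(per) >= 1L)
}

fold_flags <- function(a, b, dir_a, dir_b, min_fold, pseudo = 0.5,
                       extra_a = TRUE, extra_b = TRUE) {
  fa <- (a + pseudo) / (b + pseudo)
  ifelse(fa >= min_fold & dir_a > dir_b & extra_a, "a",
         ifelse(1 / fa >= min_fold & dir_b > dir_a & extra_b, "b", "none"))
}

#' Differential circRNA expression between samples
#'
#' Differential toward side a iff the R+ fold change (0.5 pseudocount) is at
#' least `min_fold` and the normalized R- counts agree in direction
#' (strictly); symmetric for side b.
#'
#' @param rplus raw R+ count matrix; `rminus_norm` size-factor-normalized R-
#'   matrix.
#' @param rminus_norm normalized R- count matrix.
#' @param design sample sheet.
#' @param comparisons data.frame from [make_comparisons()].
#' @param min_fold fold-change threshold.
#' @param reliable optional character vector of reliable junction ids; other
#'   junctions come back "none".
#' @return junction x comparison character matrix with values "a"/"b"/"none".
#' @export
diff_expression <- function(rplus, rminus_norm, design, comparisons,
                            min_fold = 4, reliable = NULL) {
  out <- matrix("none", nrow(rplus), nrow(comparisons),
                dimnames = list(rownames(rplus), comparisons$name))
  for (k in seq_len(nrow(comparisons))) {
    cc <- comparisons[k, ]
    pa <- sample_for(design, cc$sex_a, cc$tissue_a, "Rplus")
    pb <- sample_for(design, cc$sex_b, cc$tissue_b, "Rplus")
    ma <- sample_for(design, cc$sex_a, cc$tissue_a, "Rminus")
    mb <- sample_for(design, cc$sex_b, cc$tissue_b, "Rminus")
    out[, k] <- fold_flags(rplus[, pa], rplus[, pb],
                           rminus_norm[rownames(rplus), ma],
                           rminus_norm[rownames(rplus), mb], min_fold)
  }
  if (!is.null(reliable)) out[!rownames(out) %in% reliable, ] <- "none"
  out
}

#' Sex-specific circRNA expression
#'
#' A junction is female-specific when some female R+ sample holds at least
#' `min_reads` BSJ reads and the junction is undetected (zero reads) in every
#' male sample; symmetric for male. "Every sample" covers both R+ and R-
#' fractions by default (`opposite_fractions = "both"`), or R+ only.
#'
#' @param rplus,rminus junction x sample count matrices.
#' @param design sample sheet.
#' @param min_reads detection floor in the expressing sex.
#' @param opposite_fractions fractions required to be zero in the other sex.
#' @param reliable optional reliable-set restriction.
#' @return junction x c("F","M") logical matrix.
#' @export
sex_specific <- function(rplus, rminus, design, min_reads = 15,
                         opposite_fractions = c("both", "Rplus"),
                         reliable = NULL) {
  opposite_fractions <- match.arg(opposite_fractions)
  sex_of <- setNames(design$sex, design$sample_id)
  out <- matrix(FALSE, nrow(rplus), 2L,
                dimnames = list(rownames(rplus), c("F", "M")))
  for (sx in c("F", "M")) {
    opp <- setdiff(c("F", "M"), sx)
    own_p <- colnames(rplus)[sex_of[colnames(rplus)] == sx]
    opp_p <- colnames(rplus)[sex_of[colnames(rplus)] == opp]
    hi <- apply(rplus[, own_p, drop = FALSE], 1L, max) >= min_reads
    zero <- rowSums(rplus[, opp_p, drop = FALSE]) == 0
    if (opposite_fractions == "both") {
      opp_m <- colnames(rminus)[sex_of[colnames(rminus)] == opp]
      zero <- zero &
        rowSums(rminus[rownames(rplus), opp_m, drop = FALSE]) == 0
    }
    out[, sx] <- hi & zero
  }
  if (!is.null(reliable)) out[!rownames(out) %in% reliable, ] <- FALSE
  out
}

#' Differential back-splicing and G1-G6 group assignment
#'
#' Fold changes are computed on TPM-normalized levels (0.5 pseudocount) with
#' the R- direction check; a junction additionally needs raw R+ BSJ support
#' of at least `min_support` reads on one side (the detection floor applied
#' on the read scale, where it is independent of transcriptome size). Setting
#' `min_level` applies the floor on the normalized-level scale instead (or in
#' addition). Groups follow the tissue x direction grid: G1 head F>M, G2 head
#' M>F, G3 body F>M, G4 body M>F, G5 gonad M>F, G6 gonad F>M.
#'
#' @param levels level matrix from [backsplice_level()] (junction x R+
#'   samples); its low-expression flag is honoured.
#' @param rplus raw R+ count matrix (for the support floor).
#' @param rminus_norm normalized R- matrix (direction check).
#' @param design sample sheet.
#' @param comparisons defaults to the three between-sex comparisons.
#' @param min_fold fold threshold on levels.
#' @param min_support read floor on raw R+ counts (max over the two sides).
#' @param min_level optional floor on the normalized level itself.
#' @param reliable optional reliable-set restriction.
#' @return list: `flags` (junction x comparison "a"/"b"/"none"), `groups`
#'   (data.frame junction_id/group, ";"-joined when a junction is grouped in
#'   several tissues).
#' @export
diff_backsplicing <- function(levels, rplus, rminus_norm, design,
                              comparisons = make_comparisons("between-sex"),
                              min_fold = 4, min_support = 15, min_level = NULL,
                              reliable = NULL) {
  low <- attr(levels, "flagged_low_expr")
  keep <- setdiff(rownames(levels), low)
  if (!is.null(reliable)) keep <- intersect(keep, reliable)
  lv <- levels[keep, , drop = FALSE]
  out <- matrix("none", nrow(levels), nrow(comparisons),
                dimnames = list(rownames(levels), comparisons$name))
  for (k in seq_len(nrow(comparisons))) {
    cc <- comparisons[k, ]
    pa <- sample_for(design, cc$sex_a, cc$tissue_a, "Rplus")
    pb <- sample_for(design, cc$sex_b, cc$tissue_b, "Rplus")
    ma <- sample_for(design, cc$sex_a, cc$tissue_a, "Rminus")
    mb <- sample_for(design, cc$sex_b, cc$tissue_b, "Rminus")
    floor_ok <- rep(TRUE, length(keep))
    if (!is.null(min_support))
      floor_ok <- pmax(rplus[keep, pa], rplus[keep, pb]) >= min_support
    if (!is.null(min_level))
      floor_ok <- floor_ok & pmax(lv[, pa], lv[, pb]) >= min_level
    # levels already carry the read-scale pseudocount; fold is a plain ratio
    out[keep, k] <- fold_flags(lv[, pa], lv[, pb],
                               rminus_norm[keep, ma], rminus_norm[keep, mb],
                               min_fold, pseudo = 0,
                               extra_a = floor_ok, extra_b = floor_ok)
  }
  grid <- c(head_a = "G1", head_b = "G2", body_a = "G3", body_b = "G4",
            gonad_b = "G5", gonad_a = "G6")
  groups <- vapply(rownames(out), function(j) {
    gs <- character(0)
    for (k in seq_len(nrow(comparisons))) {
      cc <- comparisons[k, ]
      if (cc$kind != "between-sex") next
      side <- out[j, k]
      if (side == "none") next
      key <- paste0(cc$tissue_a, "_", side)
      if (!is.na(grid[key])) gs <- c(gs, grid[[key]])
    }
    if (length(gs)) paste(gs, collapse = ";") else "none"
  }, character(1))
  list(flags = out,
       groups = data.frame(junction_id = rownames(out), group = unname(groups),
                           stringsAsFactors = FALSE))
}

#' Enumerate alternative back-splicing events
#'
#' Within each gene, junctions sharing the back-splice 3' splice site while
#' differing at the 5' splice site form one alt5 event (and symmetrically for
#' alt3). Splice-site roles are strand-aware: on the plus strand the 3'SS is
#' the acceptor (low) coordinate, on the minus strand the donor (high)
#' coordinate. An event is observed in a sample when at least two members
#' have an R+ read there.
#'
#' @param calls a [circ_calls()] table (use reliable exonic calls).
#' @param rplus junction x R+ sample count matrix.
#' @return data.frame: gene_id, kind (alt5/alt3), shared_pos, n_members,
#'   members, samples_observed.
#' @export
alt_backsplicing <- function(calls, rplus) {
  ex <- calls[calls$circ_type == "exonic" & !is.na(calls$gene_id), , drop = FALSE]
  if (nrow(ex) == 0L)
    return(data.frame(gene_id = character(0), kind = character(0),
                      shared_pos = integer(0), n_members = integer(0),
                      members = character(0), samples_observed = character(0),
                      stringsAsFactors = FALSE))
  ss3 <- ifelse(ex$strand == "+", ex$acceptor, ex$donor)
  ss5 <- ifelse(ex$strand == "+", ex$donor, ex$acceptor)
  events <- list()
  emit <- function(kind, shared, members) {
    obs <- character(0)
    if (all(members %in% rownames(rplus))) {
      cnt <- rplus[members, , drop = FALSE]
      obs <- colnames(rplus)[colSums(cnt >= 1) >= 2L]
    }
    events[[length(events) + 1L]] <<- data.frame(
      gene_id = ex$gene_id[match(members[1L], ex$junction_id)], kind = kind,
      shared_pos = shared, n_members = length(members),
      members = paste(sort(members), collapse = ","),
      samples_observed = paste(obs, collapse = ","), stringsAsFactors = FALSE)
  }
  for (g in unique(ex$gene_id)) {
    gi <- ex$gene_id == g
    for (shared in unique(ss3[gi])) {
      sel <- gi & ss3 == shared
      if (length(unique(ss5[sel])) >= 2L)
        emit("alt5", shared, ex$junction_id[sel])
    }
    for (shared in unique(ss5[gi])) {
      sel <- gi & ss5 == shared
      if (length(unique(ss3[sel])) >= 2L)
        emit("alt3", shared, ex$junction_id[sel])
    }
  }
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), kind = character(0),
                      shared_pos = integer(0), n_members = integer(0),
                      members = character(0), samples_observed = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
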