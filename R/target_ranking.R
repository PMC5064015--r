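#' Resolve a clinical subset rule to sample ids
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param rule `"er_pos"` (oestrogen-receptor-positive samples), `"er_neg"`,
#'   or `"all"`.
#' @return Character vector of sample ids.
#' @export
clinical_subset <- function(clinical, rule = c("er_pos", "er_neg", "all")) {
  if (!is.character(rule) || !rule[1] %in% c("er_pos", "er_neg", "all")) {
    abort(paste0("unknown subset rule: ", rule[1]), class = "consigamp_validation_error")
  }
  rule <- rule[1]
  switch(rule,
         er_pos = clinical$sample_id[clinical$er_status == "pos"],
         er_neg = clinical$sample_id[clinical$er_status == "neg"],
         all = clinical$sample_id)
}

#' Dosage correlation between expression and copy number for one gene
#'
#' Spearman rank correlation between a gene's expression and its gene-level
#' copy number over the pairwise-complete samples of a subset. Ranks use
#' average (midrank) tie handling and the coefficient is the Pearson
#' correlation of the two rank vectors.
#'
#' @param expr Genes x samples expression matrix.
#' @param cn Genes x samples copy-number matrix.
#' @param gene Gene symbol present in both matrices.
#' @param sample_subset Sample ids to use; defaults to the shared columns.
#' @return Spearman's rho (length-1 numeric), or `NA` with attribute
#'   `reason` when undefined (fewer than 3 pairs, or a constant vector).
#' @export
spearman_dosage_correlation <- function(expr, cn, gene,
                                        sample_subset = intersect(colnames(expr),
                                                                  colnames(cn))) {
  if (!gene %in% rownames(expr) || !gene %in% rownames(cn)) {
    abort(paste0("gene absent from expression or copy-number matrix: ", gene),
          class = "consigamp_validation_error")
  }
  shared <- intersect(intersect(colnames(expr), colnames(cn)), sample_subset)
  e <- expr[gene, shared]
  c_ <- cn[gene, shared]
  keep <- !is.na(e) & !is.na(c_)
  if (sum(keep) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 pairwise-complete samples"))
  }
  e <- e[keep]; c_ <- c_[keep]
  if (stats::sd(e) == 0 || stats::sd(c_) == 0) {
    return(structure(NA_real_, reason = "constant vector"))
  }
  unname(cor(rank(e, ties.method = "average"), rank(c_, ties.method = "average")))
}

#' The amplification-driver priority score
#'
#' Product of the cancer-concept association (ConSig) score and the
#' expression/copy-number dosage correlation. The sign of the correlation is
#' preserved: genes whose expression is unrelated or anti-related to copy
#' number score at or below zero and fall to the bottom of a descending
#' ranking.
#'
#' @param rho Spearman dosage correlation in \[-1, 1\].
#' @param consig Non-negative ConSig score.
#' @return `rho * consig`.
#' @export
consig_amp_score <- function(rho, consig) {
  stopifnot(all(consig >= 0, na.rm = TRUE),
            all(abs(rho) <= 1 + 1e-12, na.rm = TRUE))
  rho * consig
}

#' Nominate druggable amplified driver candidates
#'
#' The full nomination workflow: call amplifications at `amp_threshold` on
#' gene-level copy number, keep genes amplified in strictly more than
#' `min_freq` of the informative samples of the clinical subset, compute the
#' Spearman dosage correlation on the same subset, score each survivor by
#' [consig_amp_score()], optionally restrict to druggable genes, and rank.
#'
#' Genes without a ConSig score, or with an undefined correlation, are
#' excluded; exclusions and their reasons are kept in the `"excluded"`
#' attribute of the result. Sorting is by score descending, ties broken by
#' `|rho|` descending then gene symbol ascending, so the output is
#' deterministic. Gene-symbol joins are case-insensitive exact matches.
#'
#' @param cn Genes x samples copy-number matrix (log2 ratios).
#' @param expr Genes x samples expression matrix.
#' @param consig Tibble `gene`, `consig_score` (non-negative).
#' @param drugs Tibble `gene`, `druggable` (logical), optional `source`.
#' @param clinical Clinical tibble; used to resolve `subset_rule`.
#' @param amp_threshold Amplification cutoff on the log2-ratio scale.
#' @param min_freq Strict lower bound on subset amplification frequency.
#' @param subset_rule Clinical subset for frequency and correlation
#'   (default `"er_pos"`).
#' @param druggable_only Keep only genes flagged druggable.
#' @param top_k Truncate the ranking to the first `top_k` rows (default all).
#' @return A tibble of class `"ranked_targets"` with columns `rank`, `gene`,
#'   `amp_frequency`, `spearman_rho`, `consig`, `consig_amp`, `druggable`.
#' @export
nominate_targets <- function(cn, expr, consig, drugs, clinical,
                             amp_threshold = 0.7, min_freq = 0.05,
                             subset_rule = "er_pos", druggable_only = TRUE,
                             top_k = Inf) {
  subset <- intersect(clinical_subset(clinical, subset_rule),
                      intersect(colnames(cn), colnames(expr)))
  if (length(subset) < 3) {
    abort("fewer than 3 samples shared by copy number, expression and the clinical subset",
          class = "consigamp_validation_error")
  }
  calls <- call_amplifications(cn, amp_threshold)
  freq <- amplification_frequency(calls, subset)
  cand <- freq %>% filter(!is.na(.data$frequency), .data$frequency > min_freq)
  excluded <- tibble(gene = character(), reason = character())
  note_excl <- function(genes, reason) {
    if (length(genes) > 0) {
      excluded <<- bind_rows(excluded, tibble(gene = genes, reason = reason))
    }
  }
  in_expr <- cand$gene %in% rownames(expr)
  note_excl(cand$gene[!in_expr], "no expression data")
  cand <- cand[in_expr, ]
  consig_key <- setNames(consig$consig_score, toupper(consig$gene))
  has_consig <- toupper(cand$gene) %in% names(consig_key)
  note_excl(cand$gene[!has_consig], "no ConSig score")
  cand <- cand[has_consig, ]
  drug_key <- setNames(drugs$druggable, toupper(drugs$gene))
  rows <- tibble(gene = character(), spearman_rho = double(),
                 reason = character())
  rows <- bind_rows(rows, purrr::map(cand$gene, function(g) {
    rho <- spearman_dosage_correlation(expr, cn, g, subset)
    if (is.na(rho)) {
      return(tibble(gene = g, spearman_rho = NA_real_,
                    reason = attr(rho, "reason") %||% "undefined correlation"))
    }
    tibble(gene = g, spearman_rho = as.numeric(rho), reason = NA_character_)
  }))
  note_excl(rows$gene[!is.na(rows$reason)],
            rows$reason[!is.na(rows$reason)])
  scored <- cand %>%
    left_join(rows, by = "gene") %>%
    filter(is.na(.data$reason)) %>%
    mutate(
      consig = unname(consig_key[toupper(.data$gene)]),
      consig_amp = consig_amp_score(.data$spearman_rho, .data$consig),
      druggable = unname(drug_key[toupper(.data$gene)]) %in% TRUE
    )
  if (druggable_only) {
    note_excl(scored$gene[!scored$druggable], "not druggable")
    scored <- scored %>% filter(.data$druggable)
  }
  out <- scored %>%
    arrange(desc(.data$consig_amp), desc(abs(.data$spearman_rho)), .data$gene) %>%
    mutate(rank = row_number()) %>%
    select("rank", "gene", amp_frequency = "frequency",
           "spearman_rho", "consig", "consig_amp", "druggable")
  if (is.finite(top_k)) out <- head(out, top_k)
  if (nrow(out) == 0) warn("no gene survives the nomination filters")
  structure(out, excluded = excluded,
            params = list(amp_threshold = amp_threshold, min_freq = min_freq,
                          subset_rule = subset_rule, druggable_only = druggable_only,
                          n_subset = length(subset)),
            class = c("ranked_targets", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
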