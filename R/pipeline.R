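#' Run the full target-nomination workflow from files
#'
#' Reads every input, maps segments to genes, nominates targets and writes
#' a ranked TSV plus a plain-text run log recording parameter values, gene
#' counts surviving each stage, and per-gene exclusion reasons.
#'
#' @param seg,genes,expr,consig,drugs,clinical Input file paths (see the
#'   corresponding readers).
#' @param out_dir Output directory for `targets.tsv` and `run.log`.
#' @param amp_threshold,min_freq,subset_rule,druggable_only,top_k Passed to
#'   [nominate_targets()].
#' @return The ranked-target tibble, invisibly; files are written as a side
#'   effect.
#' @export
run_nomination <- function(seg, genes, expr, consig, drugs, clinical,
                           out_dir = ".", amp_threshold = 0.7, min_freq = 0.05,
                           subset_rule = "er_pos", druggable_only = TRUE,
                           top_k = 50) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("params: amp_threshold=%g min_freq=%g subset_rule=%s druggable_only=%s top_k=%g",
                         amp_threshold, min_freq, subset_rule, druggable_only, top_k))
  segments <- read_seg(seg)
  gene_models <- read_gene_models(genes)
  expression <- read_matrix(expr, "expression")
  consig_tbl <- read_matrix(consig, "consig")
  drug_tbl <- read_matrix(drugs, "druggability")
  clin <- read_clinical(clinical)
  cn <- map_segments_to_genes(segments, gene_models)
  log_lines <- c(log_lines,
                 sprintf("inputs: %d segments, %d genes, %d expression genes, %d clinical samples",
                         nrow(segments), nrow(gene_models), nrow(expression), nrow(clin)))
  targets <- nominate_targets(cn, expression, consig_tbl, drug_tbl, clin,
                              amp_threshold = amp_threshold, min_freq = min_freq,
                              subset_rule = subset_rule,
                              druggable_only = druggable_only, top_k = top_k)
  excl <- attr(targets, "excluded")
  log_lines <- c(log_lines,
                 sprintf("subset size: %d", attr(targets, "params")$n_subset),
                 sprintf("nominated: %d targets", nrow(targets)),
                 sprintf("excluded: %d genes", nrow(excl)),
                 sprintf("  %s: %s", excl$gene, excl$reason))
  write_ranked_targets(targets, file.path(out_dir, "targets.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(targets)
}

#' Run the expression-stratified survival comparison from files
#'
#' Reads an expression matrix and a clinical table, stratifies samples on
#' one gene at the median + 1 MAD cutoff, caps follow-up, and writes group
#' sizes, both Kaplan-Meier curves and both test results.
#'
#' @param expr,clinical Input file paths.
#' @param gene Gene symbol to stratify on.
#' @param out_dir Output directory for `km.tsv`, `tests.tsv`, `run.log`.
#' @param treatment_filter Optional treatment value to restrict the cohort.
#' @param max_months Follow-up cap in months.
#' @return The [survival_by_expression()] result, invisibly.
#' @export
run_survival <- function(expr, clinical, gene, out_dir = ".",
                         treatment_filter = NULL, max_months = 120) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  expression <- read_matrix(expr, "expression")
  clin <- read_clinical(clinical)
  if (!is.null(treatment_filter)) {
    clin <- clin %>% filter(.data$treatment %in% treatment_filter)
  }
  fit <- survival_by_expression(expression, gene, clin, max_months = max_months)
  curves <- bind_rows(
    tidy(fit$curves$high) %>% mutate(group = "high"),
    tidy(fit$curves$rest) %>% mutate(group = "rest")
  )
  readr::write_tsv(curves, file.path(out_dir, "km.tsv"), progress = FALSE)
  readr::write_tsv(bind_rows(tidy(fit$logrank), tidy(fit$gehan)),
                   file.path(out_dir, "tests.tsv"), progress = FALSE)
  writeLines(c(
    sprintf("gene: %s", gene),
    sprintf("cutoff: %.6g", fit$cutoff),
    sprintf("group sizes: high=%d rest=%d",
            sum(fit$groups$group == "high"), sum(fit$groups$group == "rest")),
    sprintf("log-rank: chisq=%.6g p=%.6g", fit$logrank$statistic, fit$logrank$p),
    sprintf("gehan: chisq=%.6g p=%.6g", fit$gehan$statistic, fit$gehan$p)
  ), file.path(out_dir, "run.log"))
  invisible(fit)
}

#' @export
autoplot.ranked_targets <- function(object, label_top = 5, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$spearman_rho, y = .data$consig)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$amp_frequency), alpha = 0.7) +
    ggplot2::labs(x = "Spearman correlation (expression vs copy number)",
                  y = "ConSig score", size = "Amplification\nfrequency")
  if (label_top > 0 && nrow(object) > 0) {
    top <- head(object, label_top)
    p <- p + ggplot2::geom_text(data = top,
                                ggplot2::aes(label = .data$gene),
                                vjust = -0.8, size = 3)
  }
  p
}

#' @export
tidy.ranked_targets <- function(x, ...) as_tibble(x)

#' @export
glance.ranked_targets <- function(x, ...) {
  params <- attr(x, "params")
  tibble(n_targets = nrow(x),
         n_excluded = nrow(attr(x, "excluded")),
         top_score = if (nrow(x) > 0) x$consig_amp[1] else NA_real_,
         amp_threshold = params$amp_threshold,
         min_freq = params$min_freq,
         subset_rule = params$subset_rule)
}
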