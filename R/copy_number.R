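norm_chrom <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))

#' Map copy-number segments onto genes
#'
#' Converts segment-level log2 copy-number ratios to gene level. For each
#' (gene, sample) pair the value is the overlap-length-weighted mean of the
#' log2 ratios of all segments intersecting the gene body; strand is
#' ignored, and the value is missing when no segment overlaps the gene in
#' that sample. Chromosome names are matched after stripping an optional
#' `"chr"` prefix, case-insensitively.
#'
#' @param segments Internal segment tibble (see [read_seg()]), 0-based
#'   half-open, validated non-overlapping per sample and chromosome.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @return A numeric genes x samples matrix of gene-level log2 ratios with
#'   `NA` where a gene has no overlapping segment.
#' @export
map_segments_to_genes <- function(segments, genes) {
  if (nrow(genes) == 0) {
    abort("gene-model table is empty", class = "consigamp_validation_error")
  }
  samples <- sort(unique(segments$sample))
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene, samples))
  if (nrow(segments) == 0) {
    warn("segment table is empty; gene-level matrix is all-missing")
    return(out)
  }
  # 0-based half-open [start, end) maps to IRanges [start+1, end]
  gene_gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  seg_gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(segments$chrom),
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
  if (length(hits) == 0) return(out)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gene_gr)[gi], IRanges::ranges(seg_gr)[si]))
  sj <- match(segments$sample[si], samples)
  key <- (sj - 1L) * nrow(genes) + gi
  w <- as.numeric(ov)
  wsum <- rowsum(w * segments$log2_ratio[si], key)
  wtot <- rowsum(w, key)
  idx <- as.integer(rownames(wsum))
  out[idx] <- wsum[, 1] / wtot[, 1]
  out
}

#' Call gene-level amplifications
#'
#' A gene is amplification-positive in a sample when its gene-level log2
#' copy-number ratio strictly exceeds `threshold` (default 0.7, the scale of
#' tumour-versus-reference log2 ratios from segmented SNP-array data).
#' Missing copy-number values propagate to missing calls.
#'
#' @param cn Genes x samples numeric matrix of log2 ratios.
#' @param threshold Amplification cutoff on the log2-ratio scale.
#' @return A logical matrix congruent to `cn`.
#' @export
call_amplifications <- function(cn, threshold = 0.7) {
  stopifnot(is.finite(threshold))
  cn > threshold
}

#' Cohort amplification frequency per gene
#'
#' Frequency of amplification-positive samples among the informative
#' (non-missing) samples of a subset, per gene. Genes with no informative
#' sample get a missing frequency.
#'
#' @param calls Logical genes x samples matrix from [call_amplifications()].
#' @param sample_subset Character vector of sample ids; must be a subset of
#'   the matrix columns. Defaults to all columns.
#' @return A tibble with columns `gene`, `n_amplified`, `n_informative`,
#'   `frequency`.
#' @export
amplification_frequency <- function(calls, sample_subset = colnames(calls)) {
  if (length(sample_subset) == 0) {
    abort("sample subset is empty", class = "consigamp_validation_error")
  }
  missing_samples <- setdiff(sample_subset, colnames(calls))
  if (length(missing_samples) > 0) {
    abort(paste0("subset samples absent from call matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")),
          class = "consigamp_validation_error")
  }
  sub <- calls[, sample_subset, drop = FALSE]
  n_amp <- rowSums(sub, na.rm = TRUE)
  n_inf <- rowSums(!is.na(sub))
  tibble(
    gene = rownames(calls),
    n_amplified = as.integer(n_amp),
    n_informative = as.integer(n_inf),
    frequency = unname(ifelse(n_inf > 0, n_amp / n_inf, NA_real_))
  )
}

#' Co-amplification correlation between two genes
#'
#' Pearson correlation of gene-level copy-number values of two genes over
#' samples where both are non-missing. Used to ask whether two loci are
#' co-amplified (e.g. neighbouring genes on one amplicon).
#'
#' @param cn Genes x samples numeric matrix of log2 ratios.
#' @param gene_a,gene_b Row names of the two genes.
#' @return The Pearson correlation (length-1 numeric).
#' @export
coamplification_correlation <- function(cn, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(cn)) {
      abort(paste0("gene not in copy-number matrix: ", g),
            class = "consigamp_validation_error")
    }
  }
  a <- cn[gene_a, ]
  b <- cn[gene_b, ]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) {
    abort("fewer than 3 pairwise-complete samples", class = "consigamp_validation_error")
  }
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("constant copy-number vector; correlation undefined",
          class = "consigamp_degenerate_error")
  }
  unname(cor(a, b))
}
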