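# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: per-base expansion instead of interval arithmetic,
# counting ranks instead of rank(), double loops instead of vectorization.

# per-base mean of segment ratios over the bases of a gene covered by any
# segment of one sample
brute_gene_cn <- function(segments, genes) {
  samples <- sort(unique(segments$sample))
  out <- matrix(NA_real_, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  strip <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))
  for (gi in seq_len(nrow(genes))) {
    bases <- seq(genes$start[gi], genes$end[gi] - 1L)
    for (s in samples) {
      seg <- segments[segments$sample == s &
                        strip(segments$chrom) == strip(genes$chrom[gi]), ]
      ratio <- rep(NA_real_, length(bases))
      for (k in seq_len(nrow(seg))) {
        hit <- bases >= seg$start[k] & bases < seg$end[k]
        ratio[hit] <- seg$log2_ratio[k]
      }
      if (any(!is.na(ratio))) out[gi, s] <- mean(ratio, na.rm = TRUE)
    }
  }
  out
}

# average ranks by O(n^2) counting, then the textbook Pearson formula
brute_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- 1 + sum(x < x[i]) + sum(x[-i] == x[i]) / 2
  }
  r
}

brute_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

brute_spearman <- function(x, y) brute_pearson(brute_rank(x), brute_rank(y))

# off-target count by explicit double loop
brute_off_targets <- function(mat, compound, target) {
  cnt <- 0L
  for (k in colnames(mat)) {
    if (k == target) next
    v <- mat[compound, k]
    if (!is.na(v) && v > mat[compound, target]) cnt <- cnt + 1L
  }
  cnt
}

# random toy genome: partitioned segments (gaps allowed) per sample
random_toy_genome <- function(n_genes = 10, n_samples = 3, chrom_len = 400) {
  genes <- tibble::tibble(
    gene = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(c("1", "chr2"), n_genes, replace = TRUE),
    start = sample.int(chrom_len - 60L, n_genes, replace = TRUE) - 1L,
    strand = "+"
  )
  genes$end <- genes$start + sample(10:50, n_genes, replace = TRUE)
  seg <- list()
  for (s in sprintf("S%d", seq_len(n_samples))) {
    for (ch in c("1", "chr2")) {
      cuts <- sort(sample.int(chrom_len - 1L, sample(3:8, 1)))
      bounds <- c(0L, cuts, chrom_len)
      keep <- runif(length(bounds) - 1L) < 0.8
      if (!any(keep)) keep[1] <- TRUE
      seg[[length(seg) + 1L]] <- tibble::tibble(
        sample = s, chrom = ch,
        start = bounds[-length(bounds)][keep],
        end = bounds[-1][keep],
        n_markers = NA_integer_,
        log2_ratio = round(stats::rnorm(sum(keep), 0, 1), 3)
      )
    }
  }
  list(genes = genes[, c("gene", "chrom", "start", "end", "strand")],
       segments = dplyr::bind_rows(seg))
}
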