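toy_seg <- function(starts, ends, ratios, sample = "S1", chrom = "17") {
  validate_segments(tibble::tibble(
    sample = sample, chrom = chrom, start = as.integer(starts),
    end = as.integer(ends), n_markers = NA_integer_, log2_ratio = ratios))
}
toy_genes <- function(starts, ends, genes = sprintf("g%d", seq_along(starts)),
                      chrom = "17") {
  tibble::tibble(gene = genes, chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), strand = "+")
}

test_that("gene-level copy number is the overlap-length-weighted segment mean", {
  # equal 50-bp overlaps average to the midpoint
  cn <- map_segments_to_genes(toy_seg(c(0, 150), c(150, 300), c(1, 0)),
                              toy_genes(100, 200))
  expect_equal(cn["g1", "S1"], 0.5)
  # a gene inside one segment inherits its ratio
  cn <- map_segments_to_genes(toy_seg(0, 1000, 0.85), toy_genes(100, 200))
  expect_equal(cn["g1", "S1"], 0.85)
  # 25/75 split: (25*2.0 + 75*0.4)/100
  cn <- map_segments_to_genes(toy_seg(c(0, 25), c(25, 100), c(2.0, 0.4)),
                              toy_genes(0, 100))
  expect_equal(cn["g1", "S1"], 0.8)
})

test_that("chromosome matching strips the chr prefix case-insensitively", {
  seg <- toy_seg(0, 1000, 0.5, chrom = "chr17")
  cn <- map_segments_to_genes(seg, toy_genes(100, 200, chrom = "17"))
  expect_equal(cn["g1", "S1"], 0.5)
})

test_that("segment-to-gene mapping equals the per-base brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    toy <- random_toy_genome()
    seg <- validate_segments(toy$segments)
    expect_equal(map_segments_to_genes(seg, toy$genes),
                 brute_gene_cn(seg, toy$genes), tolerance = 1e-12)
  }
})

test_that("degenerate mapping inputs are handled explicitly", {
  seg <- toy_seg(0, 100, 0.5)
  expect_error(map_segments_to_genes(seg, toy_genes(integer(0), integer(0))),
               "empty")
  empty <- seg[0, ]
  expect_warning(cn <- map_segments_to_genes(empty, toy_genes(0, 10)),
                 "all-missing")
  expect_true(all(is.na(cn)))
  # gene with zero overlap stays missing
  cn <- map_segments_to_genes(toy_seg(0, 100, 0.5), toy_genes(200, 300))
  expect_true(is.na(cn["g1", "S1"]))
})

test_that("amplification calls use a strict threshold and propagate missingness", {
  cn <- matrix(c(0.71, 0.70, NA), nrow = 3,
               dimnames = list(c("a", "b", "c"), "S1"))
  calls <- call_amplifications(cn, 0.7)
  expect_true(calls["a", "S1"])
  expect_false(calls["b", "S1"])
  expect_true(is.na(calls["c", "S1"]))
})

test_that("raising the threshold never adds an amplified call", {
  set.seed(11)
  cn <- matrix(rnorm(200, 0.5, 0.6), 20,
               dimnames = list(sprintf("g%d", 1:20), sprintf("S%d", 1:10)))
  cn[sample(200, 15)] <- NA
  prev <- call_amplifications(cn, 0.2)
  for (thr in c(0.4, 0.7, 1.1)) {
    cur <- call_amplifications(cn, thr)
    expect_false(any(cur & !prev, na.rm = TRUE))
    prev <- cur
  }
})

test_that("amplification frequency counts amplified over informative samples", {
  calls <- matrix(FALSE, 2, 20,
                  dimnames = list(c("g1", "g2"), sprintf("S%d", 1:20)))
  calls["g1", 1:2] <- TRUE
  calls["g2", ] <- NA
  fr <- amplification_frequency(calls, colnames(calls))
  expect_equal(fr$frequency[fr$gene == "g1"], 0.10)
  expect_true(is.na(fr$frequency[fr$gene == "g2"]))
  expect_equal(fr$n_informative[fr$gene == "g2"], 0L)
  expect_error(amplification_frequency(calls, character(0)), "empty")
  expect_error(amplification_frequency(calls, "nope"), "absent")
})

test_that("frequencies are invariant to sample column order", {
  set.seed(3)
  calls <- matrix(runif(60) > 0.7, 6, 10,
                  dimnames = list(sprintf("g%d", 1:6), sprintf("S%d", 1:10)))
  perm <- sample(colnames(calls))
  f1 <- amplification_frequency(calls, colnames(calls))
  f2 <- amplification_frequency(calls[, perm], colnames(calls))
  expect_equal(f1, f2)
})

test_that("co-amplification correlation is Pearson over pairwise-complete samples", {
  set.seed(5)
  a <- rnorm(5); b <- 2 * a + rnorm(5, 0, 0.5)
  cn <- rbind(A = a, B = b, C = a, D = -a)
  colnames(cn) <- sprintf("S%d", 1:5)
  expect_equal(coamplification_correlation(cn, "A", "C"), 1.0)
  expect_equal(coamplification_correlation(cn, "A", "D"), -1.0)
  expect_equal(coamplification_correlation(cn, "A", "B"), brute_pearson(a, b))
  cn2 <- rbind(A = a, K = rep(1, 5))
  colnames(cn2) <- colnames(cn)
  expect_error(coamplification_correlation(cn2, "A", "K"), "constant")
  expect_error(coamplification_correlation(cn, "A", "ZZ"), "ZZ")
})
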