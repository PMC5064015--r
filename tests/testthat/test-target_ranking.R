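named_mat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples),
         byrow = TRUE)
}

test_that("dosage correlation is Spearman with average-rank ties", {
  samples <- sprintf("S%d", 1:6)
  cn <- named_mat(c(0, 1, 2, 3, 4, 5), "g", samples)
  up <- named_mat(c(1, 4, 9, 16, 25, 36), "g", samples)
  down <- named_mat(-c(1, 4, 9, 16, 25, 36), "g", samples)
  expect_equal(spearman_dosage_correlation(up, cn, "g"), 1.0)
  expect_equal(spearman_dosage_correlation(down, cn, "g"), -1.0)

  # tied values: must match the O(n^2) counting-rank oracle
  e <- c(2.0, 2.0, 3.5, 1.0, 3.5, 5.0)
  c_ <- c(0.1, 0.4, 0.4, 0.2, 0.9, 1.5)
  expect_equal(
    spearman_dosage_correlation(named_mat(e, "g", samples),
                                named_mat(c_, "g", samples), "g"),
    brute_spearman(e, c_))
})

test_that("undefined correlations return NA with a reason instead of a number", {
  samples <- sprintf("S%d", 1:4)
  expr <- named_mat(c(1, 2, 3, 4), "g", samples)
  const <- named_mat(c(1, 1, 1, 1), "g", samples)
  r <- spearman_dosage_correlation(expr, const, "g")
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "constant")
  r2 <- spearman_dosage_correlation(expr, expr, "g", sample_subset = c("S1", "S2"))
  expect_true(is.na(r2))
  expect_match(attr(r2, "reason"), "fewer than 3")
})

test_that("the priority score is the signed product of rho and the concept score", {
  expect_equal(consig_amp_score(0.775, 2.0), 1.55)
  expect_equal(consig_amp_score(0, 5), 0)
  expect_equal(consig_amp_score(-0.5, 2.0), -1.0)
  set.seed(2)
  rho <- runif(50, -1, 1); cs <- runif(50, 0, 2.5)
  expect_true(all(abs(consig_amp_score(rho, cs)) <= cs + 1e-12))
})

make_tiny_inputs <- function() {
  set.seed(9)
  samples <- sprintf("S%d", 1:20)
  cn <- rbind(
    hot = c(rep(1.5, 4), rnorm(16, 0, 0.1)),          # amplified in 4/20
    edge = c(rep(1.5, 1), rnorm(19, 0, 0.1)),         # amplified in exactly 1/20
    cold = rnorm(20, 0, 0.1)                          # never amplified
  )
  colnames(cn) <- samples
  expr <- rbind(hot = 5 + 2 * cn["hot", ] + rnorm(20, 0, 0.1),
                edge = rnorm(20), cold = rnorm(20))
  colnames(expr) <- samples
  clinical <- tibble::tibble(sample_id = samples, er_status = "pos",
                             subtype = NA_character_, treatment = NA_character_,
                             time_months = 10, event = 0L)
  consig <- tibble::tibble(gene = c("hot", "edge", "cold"),
                           consig_score = c(2, 2, 2))
  drugs <- tibble::tibble(gene = c("hot", "edge"), druggable = TRUE)
  list(cn = cn, expr = expr, clinical = clinical, consig = consig, drugs = drugs)
}

test_that("nomination applies strict frequency and druggability filters", {
  x <- make_tiny_inputs()
  tg <- nominate_targets(x$cn, x$expr, x$consig, x$drugs, x$clinical,
                         min_freq = 0.05)
  # edge: frequency exactly 0.05 -> excluded by the strict inequality
  expect_false("edge" %in% tg$gene)
  expect_true("hot" %in% tg$gene)
  # cold never passes frequency; and a gene without a druggability entry is
  # dropped when druggable_only is on
  drugs2 <- tibble::tibble(gene = "edge", druggable = TRUE)
  tg2 <- suppressWarnings(
    nominate_targets(x$cn, x$expr, x$consig, drugs2, x$clinical, min_freq = 0.05))
  expect_false("hot" %in% tg2$gene)
  excl <- attr(tg2, "excluded")
  expect_true(any(excl$gene == "hot" & excl$reason == "not druggable"))
})

test_that("genes without a concept score are excluded with a logged reason", {
  x <- make_tiny_inputs()
  consig <- x$consig[x$consig$gene != "hot", ]
  tg <- suppressWarnings(
    nominate_targets(x$cn, x$expr, consig, x$drugs, x$clinical, min_freq = 0.05))
  excl <- attr(tg, "excluded")
  expect_true(any(excl$gene == "hot" & excl$reason == "no ConSig score"))
})

test_that("gene-symbol joins are case-insensitive", {
  x <- make_tiny_inputs()
  consig <- tibble::tibble(gene = "HOT", consig_score = 2)
  drugs <- tibble::tibble(gene = "Hot", druggable = TRUE)
  tg <- nominate_targets(x$cn, x$expr, consig, drugs, x$clinical, min_freq = 0.05)
  expect_true("hot" %in% tg$gene)
})

test_that("ranking is deterministic with a total tie-break", {
  samples <- sprintf("S%d", 1:10)
  cn <- matrix(rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 3), 3, byrow = TRUE,
               dimnames = list(c("b", "a", "c"), samples))
  expr <- rbind(b = cn[1, ] + (1:10) * 1e-3,
                a = cn[1, ] + (1:10) * 1e-3,
                c = cn[1, ] + (1:10) * 1e-3)
  colnames(expr) <- samples
  clinical <- tibble::tibble(sample_id = samples, er_status = "pos",
                             subtype = NA_character_, treatment = NA_character_,
                             time_months = 1, event = 0L)
  consig <- tibble::tibble(gene = c("a", "b", "c"), consig_score = 2)
  drugs <- tibble::tibble(gene = c("a", "b", "c"), druggable = TRUE)
  tg <- nominate_targets(cn, expr, consig, drugs, clinical, min_freq = 0.05)
  # identical scores and |rho|: alphabetical order decides
  expect_equal(tg$gene, c("a", "b", "c"))
  expect_equal(tg$rank, 1:3)
  tg2 <- nominate_targets(cn[c(3, 1, 2), ], expr[c(3, 1, 2), ], consig, drugs,
                          clinical, min_freq = 0.05)
  expect_equal(tg2$gene, tg$gene)
})

test_that("an unknown subset rule is rejected and empty results warn", {
  x <- make_tiny_inputs()
  expect_error(nominate_targets(x$cn, x$expr, x$consig, x$drugs, x$clinical,
                                subset_rule = "her2_pos"), "unknown subset rule")
  expect_warning(nominate_targets(x$cn, x$expr, x$consig, x$drugs, x$clinical,
                                  min_freq = 1.0), "no gene survives")
})

test_that("shuffling expression sample labels destroys planted dosage signal", {
  b <- get_cohort(101)
  drivers <- b$truth$drivers
  set.seed(77)
  rhos <- replicate(20, {
    perm <- sample(colnames(b$expression))
    shuf <- b$expression
    colnames(shuf) <- perm
    mean(vapply(drivers, function(g)
      as.numeric(spearman_dosage_correlation(shuf, b$cn, g)), numeric(1)))
  })
  # expected rho under the permutation null is 0
  expect_lt(abs(mean(rhos)), 0.05)
  # and a shuffled cohort no longer ranks the drivers at the top
  shuf <- b$expression
  set.seed(78)
  colnames(shuf) <- sample(colnames(b$expression))
  tg <- nominate_targets(b$cn, shuf, b$consig, b$druggability, b$clinical)
  expect_lt(sum(drivers %in% tg$gene[1:10]), 3)
})
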