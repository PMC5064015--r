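#' Configuration for a synthetic tumour cohort
#'
#' Assembles and validates the parameters of [generate_cohort()]. The
#' defaults describe a desk-scale cohort with the statistical structure the
#' nomination workflow assumes: a small genome of evenly spaced genes,
#' recurrent focal amplicons at fixed prevalences whose log2 ratios stand
#' well above segment noise, expression with a strong copy-number dosage
#' effect at the planted driver of each amplicon and essentially none
#' elsewhere, concept scores that favour drivers, and exponential survival
#' with a multiplicative hazard ratio for expression-high patients.
#'
#' @param n_samples Cohort size.
#' @param n_chroms,genes_per_chrom,gene_length,gene_spacing Genome layout in
#'   base pairs; genes are laid head-to-tail with fixed spacing.
#' @param amplicons Tibble with one row per planted amplicon: `chrom`
#'   (integer index), `first_gene` (1-based index within the chromosome),
#'   `n_genes`, `prevalence` in (0,1), `log2_lo`, `log2_hi` (amplified ratio
#'   range), `driver_offset` (which gene of the region is the dosage
#'   driver).
#' @param background_sd SD of background segment log2 ratios.
#' @param breaks_range Integer range of background breakpoints per
#'   chromosome per sample (drawn uniformly); breakpoint positions are drawn
#'   per sample so segment boundaries do not align across samples.
#' @param baseline_mean,baseline_sd Per-gene expression baseline.
#' @param beta_driver Dosage slope of planted drivers (expression units per
#'   log2 copy-number unit).
#' @param beta_background_sd SD of the near-zero background dosage slopes.
#' @param expr_noise_sd Residual expression noise.
#' @param consig_driver,consig_background Score ranges (length-2) for
#'   drivers and all other genes.
#' @param druggable_background_rate Probability a non-driver gene is
#'   flagged druggable (drivers always are).
#' @param er_pos_frac Fraction of oestrogen-receptor-positive samples.
#' @param baseline_hazard Exponential event hazard per month for the
#'   reference group.
#' @param hazard_ratio Hazard multiplier for the expression-high group of
#'   `survival_gene` (group defined by the median + 1 MAD cutoff).
#' @param censor_max Upper bound of the independent uniform censoring time
#'   (months).
#' @param survival_gene Gene whose expression drives the survival contrast;
#'   defaults to the first planted driver.
#' @param seed Integer seed; required, all randomness flows from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 200,
                          n_chroms = 5,
                          genes_per_chrom = 100,
                          gene_length = 10000,
                          gene_spacing = 10000,
                          amplicons = tibble(
                            chrom = 1:5,
                            first_gene = 41L,
                            n_genes = 8L,
                            prevalence = c(0.12, 0.15, 0.18, 0.21, 0.25),
                            log2_lo = 1.0,
                            log2_hi = 2.0,
                            driver_offset = 4L
                          ),
                          background_sd = 0.15,
                          breaks_range = c(4L, 12L),
                          baseline_mean = 8,
                          baseline_sd = 1.5,
                          beta_driver = 1.5,
                          beta_background_sd = 0.05,
                          expr_noise_sd = 0.5,
                          consig_driver = c(2.0, 2.5),
                          consig_background = c(0.05, 1.8),
                          druggable_background_rate = 0.25,
                          er_pos_frac = 0.75,
                          baseline_hazard = 0.015,
                          hazard_ratio = 2,
                          censor_max = 180,
                          survival_gene = NULL,
                          seed) {
  if (missing(seed)) abort("cohort_config requires a seed", class = "consigamp_validation_error")
  stopifnot(all(amplicons$prevalence > 0), all(amplicons$prevalence < 1),
            background_sd >= 0, expr_noise_sd >= 0, baseline_sd >= 0,
            all(amplicons$first_gene >= 1),
            all(amplicons$first_gene + amplicons$n_genes - 1 <= genes_per_chrom),
            all(amplicons$driver_offset >= 1),
            all(amplicons$driver_offset <= amplicons$n_genes))
  # amplicons on the same chromosome must not overlap
  by_chrom <- split(amplicons, amplicons$chrom)
  for (blk in by_chrom) {
    if (nrow(blk) > 1) {
      blk <- blk[order(blk$first_gene), ]
      if (any(blk$first_gene[-1] <= blk$first_gene[-nrow(blk)] + blk$n_genes[-nrow(blk)] - 1)) {
        abort("overlapping amplicon regions on one chromosome",
              class = "consigamp_validation_error")
      }
    }
  }
  cfg <- list(n_samples = n_samples, n_chroms = n_chroms,
              genes_per_chrom = genes_per_chrom, gene_length = gene_length,
              gene_spacing = gene_spacing, amplicons = amplicons,
              background_sd = background_sd, breaks_range = breaks_range,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              beta_driver = beta_driver, beta_background_sd = beta_background_sd,
              expr_noise_sd = expr_noise_sd, consig_driver = consig_driver,
              consig_background = consig_background,
              druggable_background_rate = druggable_background_rate,
              er_pos_frac = er_pos_frac, baseline_hazard = baseline_hazard,
              hazard_ratio = hazard_ratio, censor_max = censor_max,
              survival_gene = survival_gene, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic sub-stream seeds, kept within 32-bit integer range
substream <- function(seed, k) (as.integer(seed) + 1000L * k) %% .Machine$integer.max

#' Generate a synthetic cohort with planted ground truth
#'
#' Emits every input the nomination and survival analyses consume, plus a
#' truth record sufficient to score recovery. Per sample, each chromosome is
#' cut at random breakpoints into background segments with
#' `Normal(0, background_sd)` log2 ratios; each amplicon is present
#' independently with its prevalence and overrides its region with a
#' `Uniform(log2_lo, log2_hi)` ratio. Expression is
#' `baseline + beta * copy_number + noise` per gene and sample, with the
#' gene-level copy number taken from the generated segments. Survival times
#' are exponential with hazard `baseline_hazard * hazard_ratio^high`, where
#' `high` is the median + 1 MAD call on the survival gene's expression, and
#' censoring is by an independent uniform time.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `segments`, `gene_models`, `expression`
#'   (matrix), `cn` (gene-level matrix), `consig`, `druggability`,
#'   `clinical`, and `truth` (planted drivers, prevalences, presence matrix,
#'   dosage slopes, survival gene and hazard ratio).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gene_pitch <- config$gene_length + config$gene_spacing
  chrom_len <- config$genes_per_chrom * gene_pitch
  genes <- tidyr::expand_grid(chrom = seq_len(config$n_chroms),
                              idx = seq_len(config$genes_per_chrom)) %>%
    mutate(gene = sprintf("G%d_%03d", .data$chrom, .data$idx),
           start = (.data$idx - 1L) * gene_pitch,
           end = .data$start + config$gene_length,
           strand = "+",
           chrom = as.character(.data$chrom)) %>%
    select("gene", "chrom", "start", "end", "strand")
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  amp <- config$amplicons %>%
    mutate(amp_id = sprintf("amp%d", dplyr::row_number()),
           driver = sprintf("G%d_%03d", .data$chrom,
                            .data$first_gene + .data$driver_offset - 1L),
           region_start = (.data$first_gene - 1L) * gene_pitch,
           region_end = (.data$first_gene + .data$n_genes - 1L) * gene_pitch -
             config$gene_spacing)

  # amplicon presence per sample
  set.seed(substream(config$seed, 1L))
  presence <- vapply(amp$prevalence,
                     function(p) rbinom(config$n_samples, 1L, p) == 1L,
                     logical(config$n_samples))
  dimnames(presence) <- list(samples, amp$amp_id)

  # segments
  set.seed(substream(config$seed, 2L))
  seg_list <- vector("list", config$n_samples * config$n_chroms)
  k <- 0L
  for (s in seq_len(config$n_samples)) {
    for (ch in seq_len(config$n_chroms)) {
      nb <- sample(config$breaks_range[1]:config$breaks_range[2], 1L)
      cuts <- sort(sample.int(chrom_len - 1L, nb))
      bounds <- c(0L, cuts, chrom_len)
      st <- bounds[-length(bounds)]
      en <- bounds[-1]
      lr <- rnorm(length(st), 0, config$background_sd)
      amp_here <- amp[amp$chrom == ch, , drop = FALSE]
      amp_here <- amp_here[presence[s, amp_here$amp_id], , drop = FALSE]
      for (i in seq_len(nrow(amp_here))) {
        a0 <- amp_here$region_start[i]; a1 <- amp_here$region_end[i]
        li <- st < a0
        ri <- en > a1
        st <- c(st[li], a0, pmax(st[ri], a1))
        en <- c(pmin(en[li], a0), a1, en[ri])
        lr <- c(lr[li], runif(1, amp_here$log2_lo[i], amp_here$log2_hi[i]), lr[ri])
        o <- order(st)
        st <- st[o]; en <- en[o]; lr <- lr[o]
      }
      k <- k + 1L
      seg_list[[k]] <- tibble(
        sample = samples[s], chrom = as.character(ch),
        start = as.integer(st), end = as.integer(en),
        n_markers = pmax(2L, as.integer(round((en - st) / 2000))),
        log2_ratio = lr)
    }
  }
  segments <- bind_rows(seg_list) %>%
    select("sample", "chrom", "start", "end", "n_markers", "log2_ratio") %>%
    validate_segments()

  cn <- map_segments_to_genes(segments, genes)

  # expression
  set.seed(substream(config$seed, 3L))
  n_genes <- nrow(genes)
  baseline <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  beta <- rnorm(n_genes, 0, config$beta_background_sd)
  names(baseline) <- names(beta) <- genes$gene
  beta[amp$driver] <- config$beta_driver
  cn0 <- cn; cn0[is.na(cn0)] <- 0
  noise <- matrix(rnorm(n_genes * config$n_samples, 0, config$expr_noise_sd),
                  nrow = n_genes)
  expression <- baseline + beta * cn0 + noise
  dimnames(expression) <- dimnames(cn)

  # annotations
  set.seed(substream(config$seed, 4L))
  is_driver <- genes$gene %in% amp$driver
  consig_scores <- ifelse(is_driver,
                          runif(n_genes, config$consig_driver[1], config$consig_driver[2]),
                          runif(n_genes, config$consig_background[1], config$consig_background[2]))
  consig <- tibble(gene = genes$gene, consig_score = consig_scores)
  druggable <- is_driver | (runif(n_genes) < config$druggable_background_rate)
  drugs <- tibble(gene = genes$gene, druggable = druggable,
                  source = ifelse(druggable, "synthetic-db", NA_character_))

  # clinical + survival
  set.seed(substream(config$seed, 5L))
  surv_gene <- config$survival_gene %||% amp$driver[1]
  strat <- stratify_high(expression[surv_gene, ])
  high <- setNames(strat$group == "high", strat$sample)[samples]
  hazard <- config$baseline_hazard * ifelse(high, config$hazard_ratio, 1)
  event_time <- rexp(config$n_samples, rate = hazard)
  censor_time <- runif(config$n_samples, 0, config$censor_max)
  clinical <- tibble(
    sample_id = samples,
    er_status = ifelse(runif(config$n_samples) < config$er_pos_frac, "pos", "neg"),
    subtype = sample(c("LumA", "LumB", "Her2", "Basal"), config$n_samples,
                     replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15)),
    treatment = sample(c("none", "endocrine"), config$n_samples,
                       replace = TRUE, prob = c(0.4, 0.6)),
    time_months = pmin(event_time, censor_time),
    event = as.integer(event_time <= censor_time)
  )

  truth <- list(
    drivers = amp$driver,
    amplicons = amp %>% select("amp_id", "chrom", "first_gene", "n_genes",
                               "prevalence", "driver"),
    presence = presence,
    beta = beta,
    survival_gene = surv_gene,
    survival_high = high,
    hazard_ratio = config$hazard_ratio,
    seed = config$seed
  )
  list(segments = segments, gene_models = genes, expression = expression,
       cn = cn, consig = consig, druggability = drugs, clinical = clinical,
       truth = truth)
}

#' Write a generated cohort bundle to disk
#'
#' Writes every file in the dialects the readers of this package consume:
#' `segments.seg`, `gene_models.bed`, `expression.tsv`, `consig.tsv`,
#' `druggability.tsv`, `clinical.tsv` and `truth.json`.
#'
#' @param bundle Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_seg(bundle$segments, file.path(dir, "segments.seg"))
  write_gene_models(bundle$gene_models, file.path(dir, "gene_models.bed"))
  write_matrix(bundle$expression, file.path(dir, "expression.tsv"), id_name = "gene")
  readr::write_tsv(bundle$consig, file.path(dir, "consig.tsv"), progress = FALSE)
  readr::write_tsv(bundle$druggability, file.path(dir, "druggability.tsv"),
                   na = "NA", progress = FALSE)
  write_clinical(bundle$clinical, file.path(dir, "clinical.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- bundle$truth
    truth$presence <- NULL
    truth$beta <- NULL
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

# contaminated-normal spot noise: a tight core plus occasional outlier
# spots, the regime triplicate medians are designed for
rspot_noise <- function(n, core_sd, outlier_sd, outlier_rate) {
  out <- runif(n) < outlier_rate
  rnorm(n, 0, ifelse(out, outlier_sd, core_sd))
}

#' Generate synthetic reverse-phase protein array data
#'
#' Builds spot-level data for a multi-model knockdown experiment: per
#' antibody a lognormal baseline, per spot a contaminated-normal
#' measurement noise (tight core plus occasional outlier spots — the error
#' regime that motivates triplicate medians), and for the planted
#' antibodies a shift of `effect_size` times the total spot-noise SD in the
#' perturbed arm of every comparison, in one fixed direction. Foreground,
#' local background, negative control and total protein are constructed so
#' that [normalize_spot()] recovers the simulated normalized intensity.
#'
#' @param n_antibodies Number of antibodies.
#' @param n_planted Number of antibodies given a real shift.
#' @param effect_size Shift in units of the total spot-noise SD; must be
#'   non-negative (direction is a separate flag).
#' @param n_per_arm Samples per arm of each comparison.
#' @param n_comparisons Number of knockdown model comparisons.
#' @param n_replicates Spot replicates per (antibody, sample).
#' @param direction `"down"` (knockdown lowers the protein) or `"up"`.
#' @param core_sd,outlier_sd,outlier_rate Contaminated-normal noise
#'   parameters on the normalized-intensity scale.
#' @param seed Integer seed.
#' @return A list with `spots` (long tibble), `design` (sample, comparison,
#'   arm) and `truth` (planted antibodies, direction, effect size, total
#'   spot-noise SD).
#' @export
generate_rppa <- function(n_antibodies = 200, n_planted = 5, effect_size = 2,
                          n_per_arm = 3, n_comparisons = 2, n_replicates = 3,
                          direction = c("down", "up"),
                          core_sd = 0.0875, outlier_sd = 0.55, outlier_rate = 0.15,
                          seed) {
  direction <- match.arg(direction)
  if (missing(seed)) abort("generate_rppa requires a seed", class = "consigamp_validation_error")
  if (effect_size < 0) {
    abort("effect_size must be non-negative; use `direction` for the sign",
          class = "consigamp_validation_error")
  }
  stopifnot(n_planted <= n_antibodies)
  set.seed(seed %% .Machine$integer.max)
  antibodies <- sprintf("Ab%03d", seq_len(n_antibodies))
  planted <- sort(sample(antibodies, n_planted))
  spot_sd <- sqrt((1 - outlier_rate) * core_sd^2 + outlier_rate * outlier_sd^2)
  shift <- effect_size * spot_sd * ifelse(direction == "down", -1, 1)
  mu <- stats::rlnorm(n_antibodies, meanlog = 0.6, sdlog = 0.4)
  names(mu) <- antibodies
  design <- tidyr::expand_grid(comparison = sprintf("cmp%d", seq_len(n_comparisons)),
                               arm = c("control", "perturbed"),
                               i = seq_len(n_per_arm)) %>%
    mutate(sample = sprintf("%s_%s_%d", .data$comparison, .data$arm, .data$i)) %>%
    select("sample", "comparison", "arm")
  spots <- tidyr::expand_grid(antibody = antibodies, sample = design$sample,
                              replicate = seq_len(n_replicates)) %>%
    left_join(design, by = "sample") %>%
    mutate(
      z = mu[.data$antibody] +
        ifelse(.data$antibody %in% planted & .data$arm == "perturbed", shift, 0) +
        rspot_noise(dplyr::n(), core_sd, outlier_sd, outlier_rate),
      total_protein = runif(dplyr::n(), 300, 700),
      local_bg = rnorm(dplyr::n(), 100, 10),
      negctrl = rnorm(dplyr::n(), 50, 5),
      fg = .data$z * .data$total_protein + .data$local_bg + .data$negctrl
    ) %>%
    select("antibody", "sample", "replicate", "fg", "local_bg", "negctrl",
           "total_protein")
  list(spots = spots, design = design,
       truth = list(planted = planted, direction = direction,
                    effect_size = effect_size, spot_sd = spot_sd, seed = seed))
}

#' Generate a synthetic compound x kinase inhibition matrix
#'
#' Background percent inhibition is drawn from a scaled Beta distribution on
#' \[0, 100\]; planted selective compounds are overwritten exactly: the
#' target cell gets the requested inhibition, exactly `n_off_targets`
#' kinases get values strictly above it, and every remaining kinase of that
#' compound is capped strictly below it, so the planted off-target count
#' holds by construction.
#'
#' @param n_compounds,n_kinases Matrix dimensions.
#' @param target Column name used as the intended target kinase.
#' @param planted Tibble with columns `compound`, `target_inhibition` (in
#'   \[0, 100\]), `n_off_targets` (< `n_kinases`). May be empty.
#' @param seed Integer seed.
#' @return A list with `matrix` (compound x kinase percent inhibition) and
#'   `truth` (the planted tibble and target name).
#' @export
generate_kinase_matrix <- function(n_compounds = 158, n_kinases = 234,
                                   target = "KIN001",
                                   planted = tibble(compound = "CPD001",
                                                    target_inhibition = 98,
                                                    n_off_targets = 3L),
                                   seed) {
  if (missing(seed)) abort("generate_kinase_matrix requires a seed",
                           class = "consigamp_validation_error")
  stopifnot(nrow(planted) == 0 ||
              (all(planted$n_off_targets < n_kinases - 1)))
  if (nrow(planted) > 0 &&
      any(planted$target_inhibition < 0 | planted$target_inhibition > 100)) {
    abort("planted target inhibition outside [0, 100]",
          class = "consigamp_validation_error")
  }
  if (nrow(planted) > 0 &&
      any(planted$n_off_targets > 0 & planted$target_inhibition > 99.5)) {
    abort("cannot plant off-targets strictly above a target inhibition > 99.5",
          class = "consigamp_validation_error")
  }
  set.seed(seed %% .Machine$integer.max)
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  kinases <- sprintf("KIN%03d", seq_len(n_kinases))
  if (!target %in% kinases) kinases[1] <- target
  mat <- matrix(100 * rbeta(n_compounds * n_kinases, 1.5, 6),
                nrow = n_compounds, dimnames = list(compounds, kinases))
  for (i in seq_len(nrow(planted))) {
    cp <- planted$compound[i]
    ti <- planted$target_inhibition[i]
    k_off <- planted$n_off_targets[i]
    if (!cp %in% compounds) {
      abort(paste0("planted compound outside the matrix: ", cp),
            class = "consigamp_validation_error")
    }
    others <- setdiff(kinases, target)
    off <- sample(others, k_off)
    rest <- setdiff(others, off)
    mat[cp, target] <- ti
    mat[cp, off] <- pmin(100, ti + runif(k_off, 0.5, 2))
    mat[cp, rest] <- pmin(mat[cp, rest], ti * 0.95)
  }
  list(matrix = mat,
       truth = list(planted = planted, target = target, seed = seed))
}

#' Xenograft tumour volume from caliper measurements
#'
#' `volume = 1/2 * length * width^2`, in cubic millimetres.
#'
#' @param length_mm,width_mm Positive caliper measurements in millimetres.
#' @return Volume in mm^3.
#' @export
tumour_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    abort("tumour dimensions must be positive", class = "consigamp_validation_error")
  }
  0.5 * length_mm * width_mm^2
}
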