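#' Normalize one reverse-phase protein array spot
#'
#' Background-corrected foreground minus the matched negative-control signal
#' (no-primary-antibody slide, already background-subtracted), divided by the
#' total-protein stain of the same spot:
#' `((fg - local_bg) - negctrl) / total_protein`. Negative results are
#' retained (downstream medians are robust to them); use the `flag` column
#' of [normalize_spots()] to inspect them.
#'
#' @param fg Foreground signal intensity.
#' @param local_bg Local background of the antibody slide.
#' @param negctrl Negative-control slide signal for the same position.
#' @param total_protein Total-protein stain intensity, strictly positive.
#' @return Normalized signal intensity (may be negative).
#' @export
normalize_spot <- function(fg, local_bg, negctrl, total_protein) {
  if (any(total_protein <= 0)) {
    abort("total_protein must be strictly positive", class = "consigamp_validation_error")
  }
  ((fg - local_bg) - negctrl) / total_protein
}

#' Normalize a long-format spot table
#'
#' @param spots Tibble with columns `antibody`, `sample`, `replicate`, `fg`,
#'   `local_bg`, `negctrl`, `total_protein`.
#' @return The input with added `normalized` and logical `flag` (negative
#'   normalized intensity) columns.
#' @export
normalize_spots <- function(spots) {
  spots %>%
    mutate(normalized = normalize_spot(.data$fg, .data$local_bg,
                                       .data$negctrl, .data$total_protein),
           flag = .data$normalized < 0)
}

#' Summarize replicate spot values
#'
#' Median of the replicate normalized intensities for one (antibody, sample)
#' pair; the average of the middle two for even replicate counts.
#'
#' @param values Numeric vector, length >= 1.
#' @return The median.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("no replicate values to summarize", class = "consigamp_validation_error")
  }
  median(values)
}

#' Per-antibody two-group comparison
#'
#' Two-sided Welch (unequal-variance) t-test between control (`groupA`) and
#' perturbed (`groupB`) replicate summaries; direction is the sign of
#' `mean(groupB) - mean(groupA)`. With zero variance in both groups and
#' equal means the comparison is declared null (`t = 0`, `p = 1`,
#' direction `"none"`).
#'
#' @param groupA,groupB Numeric vectors with at least two values each.
#' @param antibody,comparison Optional labels carried into the result.
#' @return A one-row tibble: `antibody`, `comparison`, `direction`
#'   (up/down/none), `t`, `p`, `mean_diff`.
#' @export
protein_ttest <- function(groupA, groupB, antibody = NA_character_,
                          comparison = NA_character_) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  diff <- mean(groupB) - mean(groupA)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (diff == 0) {
      return(tibble(antibody = antibody, comparison = comparison,
                    direction = "none", t = 0, p = 1, mean_diff = 0))
    }
    # perfectly separated constant groups
    return(tibble(antibody = antibody, comparison = comparison,
                  direction = ifelse(diff > 0, "up", "down"),
                  t = sign(diff) * Inf, p = 0, mean_diff = diff))
  }
  tt <- t.test(groupB, groupA, var.equal = FALSE)
  tibble(antibody = antibody, comparison = comparison,
         direction = ifelse(diff > 0, "up", ifelse(diff < 0, "down", "none")),
         t = unname(tt$statistic), p = tt$p.value, mean_diff = diff)
}

#' Cross-model consistency screen
#'
#' Keeps antibodies whose two-group comparison is significant (`p < alpha`,
#' strict) in every model comparison *and* changes in the same direction in
#' every comparison, then sorts by the mean p-value across comparisons
#' (most consistent first). No multiplicity correction is applied: the
#' screen is descriptive.
#'
#' @param results Tibble of per-antibody comparison rows as returned by
#'   [protein_ttest()] (columns `antibody`, `comparison`, `direction`, `p`),
#'   with every antibody present in every comparison.
#' @param alpha Per-comparison significance level (default 0.1).
#' @return A tibble `antibody`, `direction`, `mean_p`, `p_values`
#'   (list-column), sorted by `mean_p` ascending.
#' @export
consistency_screen <- function(results, alpha = 0.1) {
  counts <- results %>% dplyr::count(.data$antibody)
  n_comp <- length(unique(results$comparison))
  bad <- counts$antibody[counts$n != n_comp]
  if (length(bad) > 0) {
    abort(paste0("antibodies missing from some comparisons: ",
                 paste(head(sort(bad), 10), collapse = ", ")),
          class = "consigamp_validation_error")
  }
  results %>%
    group_by(.data$antibody) %>%
    summarise(
      all_sig = all(.data$p < alpha),
      same_dir = dplyr::n_distinct(.data$direction) == 1 &&
        .data$direction[1] != "none",
      direction = .data$direction[1],
      mean_p = mean(.data$p),
      p_values = list(.data$p),
      .groups = "drop"
    ) %>%
    filter(.data$all_sig, .data$same_dir) %>%
    arrange(.data$mean_p) %>%
    select("antibody", "direction", "mean_p", "p_values")
}

#' Run the full RPPA screen from spot level
#'
#' Normalizes spots, takes replicate medians per (antibody, sample),
#' performs the per-comparison Welch tests according to a design table, and
#' applies [consistency_screen()].
#'
#' @param spots Long-format spot tibble (see [normalize_spots()]).
#' @param design Tibble mapping `sample` to `comparison` and `arm`
#'   (`"control"` or `"perturbed"`).
#' @param alpha Per-comparison significance level.
#' @return A list with `comparisons` (all per-antibody test rows) and
#'   `hits` (the consistency-screen result).
#' @export
rppa_screen <- function(spots, design, alpha = 0.1) {
  stopifnot(all(design$arm %in% c("control", "perturbed")))
  summarized <- normalize_spots(spots) %>%
    group_by(.data$antibody, .data$sample) %>%
    summarise(value = summarize_replicates(.data$normalized), .groups = "drop") %>%
    left_join(design, by = "sample")
  comparisons <- summarized %>%
    filter(!is.na(.data$comparison)) %>%
    group_by(.data$antibody, .data$comparison) %>%
    summarise(res = list(protein_ttest(
      .data$value[.data$arm == "control"],
      .data$value[.data$arm == "perturbed"],
      antibody = .data$antibody[1], comparison = .data$comparison[1]
    )), .groups = "drop") %>%
    dplyr::pull("res") %>%
    bind_rows()
  list(comparisons = comparisons, hits = consistency_screen(comparisons, alpha))
}
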