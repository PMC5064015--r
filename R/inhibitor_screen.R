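#' Count off-target kinases for one compound
#'
#' Number of kinases, other than the target, that a compound inhibits
#' strictly more strongly than the target kinase, in a compound x kinase
#' percent-inhibition matrix. Missing cells are not counted.
#'
#' @param matrix Compound x kinase numeric matrix, values in \[0, 100\]
#'   percent inhibition at a fixed dose.
#' @param compound Row name.
#' @param target Column name of the intended target kinase.
#' @return Integer count.
#' @export
off_target_count <- function(matrix, compound, target) {
  if (!compound %in% rownames(matrix)) {
    abort(paste0("compound not in matrix: ", compound),
          class = "consigamp_validation_error")
  }
  if (!target %in% colnames(matrix)) {
    abort(paste0("target kinase not in matrix: ", target),
          class = "consigamp_validation_error")
  }
  row <- matrix[compound, ]
  tv <- row[[target]]
  if (is.na(tv)) {
    abort(paste0("missing target inhibition for compound ", compound),
          class = "consigamp_validation_error")
  }
  others <- row[setdiff(colnames(matrix), target)]
  sum(others > tv, na.rm = TRUE)
}

#' Rank compounds by on-target activity and selectivity
#'
#' Compounds with a non-missing target value are sorted by target inhibition
#' descending, ties broken by off-target count ascending then compound id,
#' after optional filtering on minimum target inhibition and maximum number
#' of off-targets.
#'
#' @inheritParams off_target_count
#' @param min_target_inhibition Keep compounds with target inhibition at or
#'   above this percent.
#' @param max_off_targets Keep compounds with at most this many off-targets.
#' @param remaining_activity Set `TRUE` when the matrix reports percent
#'   *remaining* kinase activity instead of percent inhibition; values are
#'   converted via `100 - x` before ranking.
#' @return A tibble of class `"inhibitor_ranking"`: `rank`, `compound`,
#'   `target_inhibition`, `off_target_count`.
#' @export
rank_inhibitors <- function(matrix, target, min_target_inhibition = 0,
                            max_off_targets = Inf, remaining_activity = FALSE) {
  if (!target %in% colnames(matrix)) {
    abort(paste0("target kinase not in matrix: ", target),
          class = "consigamp_validation_error")
  }
  if (remaining_activity) matrix <- 100 - matrix
  keep <- rownames(matrix)[!is.na(matrix[, target])]
  out <- tibble(
    compound = keep,
    target_inhibition = unname(matrix[keep, target]),
    off_target_count = vapply(keep, function(cp) off_target_count(matrix, cp, target),
                              numeric(1)) |> as.integer()
  ) %>%
    filter(.data$target_inhibition >= min_target_inhibition,
           .data$off_target_count <= max_off_targets) %>%
    arrange(desc(.data$target_inhibition), .data$off_target_count, .data$compound) %>%
    mutate(rank = row_number()) %>%
    select("rank", "compound", "target_inhibition", "off_target_count")
  structure(out, target = target,
            class = c("inhibitor_ranking", class(out)))
}

#' @export
autoplot.inhibitor_ranking <- function(object, top_n = 20, ...) {
  df <- head(object, top_n) %>%
    mutate(compound = factor(.data$compound, levels = rev(.data$compound)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_inhibition, y = .data$compound)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$off_target_count), colour = "red") +
    ggplot2::labs(
      x = "% target inhibition (bars) / off-target count (points)",
      y = NULL,
      title = paste0("Inhibitor selectivity against ", attr(object, "target")))
}
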