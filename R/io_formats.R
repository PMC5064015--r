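#' Read a SEG file of copy-number segments
#'
#' Reads a tab-delimited segment file (circular-binary-segmentation output)
#' with header columns `Sample`, `Chromosome`, `Start`, `End`, `Num_Probes`
#' (optional) and `Segment_Mean`. On disk coordinates are 1-based inclusive;
#' internally the package uses 0-based half-open intervals, so `start` is
#' shifted down by one base and `end` is kept.
#'
#' Chromosome names keep their spelling but are matched elsewhere after
#' stripping an optional `"chr"` prefix, case-insensitively.
#'
#' @param path Path to a SEG file.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `log2_ratio`, sorted by (sample, chrom, start), with
#'   0-based half-open coordinates. Segments of a sample on one chromosome
#'   are guaranteed non-overlapping.
#' @seealso [write_seg()], [map_segments_to_genes()]
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  required <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("SEG file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "consigamp_format_error")
  }
  if (nrow(raw) == 0) {
    return(tibble(sample = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_markers = integer(), log2_ratio = double()))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(x %in% c("NA", "")))
    bad <- union(bad, which(x %in% c("NA", "") & what != "Num_Probes"))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s at line %d of %s: '%s'",
                    what, bad[1] + 1L, path, x[bad[1]]),
            class = "consigamp_format_error")
    }
    v
  }
  seg <- tibble(
    sample = raw$Sample,
    chrom = raw$Chromosome,
    start = as.integer(num(raw$Start, "Start")) - 1L,
    end = as.integer(num(raw$End, "End")),
    n_markers = if ("Num_Probes" %in% names(raw)) {
      as.integer(suppressWarnings(as.numeric(raw$Num_Probes)))
    } else NA_integer_,
    log2_ratio = num(raw$Segment_Mean, "Segment_Mean")
  )
  validate_segments(seg)
}

#' Validate an internal segment table
#'
#' Checks the internal segment contract: non-empty chromosome names,
#' `end > start` in 0-based half-open coordinates, finite log2 ratios, and no
#' overlapping segments within a (sample, chromosome) pair. Returns the table
#' sorted by (sample, chrom, start).
#'
#' @param seg A tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `log2_ratio` in internal coordinates.
#' @return The validated, sorted tibble.
#' @export
validate_segments <- function(seg) {
  stopifnot(all(c("sample", "chrom", "start", "end", "log2_ratio") %in% names(seg)))
  if (nrow(seg) == 0) return(seg)
  if (any(is.na(seg$chrom) | seg$chrom == "")) {
    abort("segment table has empty chromosome names", class = "consigamp_validation_error")
  }
  if (any(!is.finite(seg$log2_ratio))) {
    abort("segment table has missing or non-finite log2 ratios",
          class = "consigamp_validation_error")
  }
  bad <- which(seg$end <= seg$start)
  if (length(bad) > 0) {
    abort(sprintf("segment with end <= start (internal coordinates): sample %s, %s:%d-%d",
                  seg$sample[bad[1]], seg$chrom[bad[1]], seg$start[bad[1]], seg$end[bad[1]]),
          class = "consigamp_validation_error")
  }
  seg <- dplyr::arrange(seg, .data$sample, .data$chrom, .data$start)
  ov <- seg %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(prev_end = dplyr::lag(.data$end),
           overlaps_prev = !is.na(.data$prev_end) & .data$start < .data$prev_end) %>%
    ungroup()
  if (any(ov$overlaps_prev)) {
    i <- which(ov$overlaps_prev)[1]
    abort(sprintf(
      "overlapping segments for sample %s on chromosome %s: [%d,%d) overlaps [%d,%d)",
      ov$sample[i], ov$chrom[i], ov$start[i - 1L], ov$end[i - 1L], ov$start[i], ov$end[i]),
      class = "consigamp_validation_error")
  }
  seg
}

#' Write an internal segment table as a SEG file
#'
#' Inverse of [read_seg()]: converts internal 0-based half-open coordinates
#' back to 1-based inclusive on disk, so a write/read round trip reproduces
#' the table exactly.
#'
#' @param seg Internal segment tibble (see [read_seg()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- tibble(
    Sample = seg$sample,
    Chromosome = seg$chrom,
    Start = seg$start + 1L,
    End = seg$end,
    Num_Probes = seg$n_markers,
    Segment_Mean = seg$log2_ratio
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a BED-like gene-model table
#'
#' Reads a header-less tab-delimited table with columns chrom, start, end,
#' gene symbol, strand; coordinates are 0-based half-open on disk (BED
#' convention) and kept as-is internally. Gene symbols must be unique.
#'
#' @param path Path to the gene-model file.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "gene", "strand"),
                         col_types = "ciicc", na = character(), progress = FALSE)
  if (any(is.na(raw$start) | is.na(raw$end))) {
    abort("non-integer coordinate in gene-model file", class = "consigamp_format_error")
  }
  bad <- which(raw$start >= raw$end)
  if (length(bad) > 0) {
    abort(sprintf("gene %s has start >= end (%d >= %d)",
                  raw$gene[bad[1]], raw$start[bad[1]], raw$end[bad[1]]),
          class = "consigamp_validation_error")
  }
  dup <- unique(raw$gene[duplicated(raw$gene)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene symbol(s): ", paste(dup, collapse = ", ")),
          class = "consigamp_validation_error")
  }
  if (!all(raw$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'", class = "consigamp_format_error")
  }
  dplyr::select(raw, "gene", "chrom", "start", "end", "strand")
}

#' Write gene models in the BED-like dialect read by [read_gene_models()]
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  readr::write_tsv(genes[, c("chrom", "start", "end", "gene", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a named numeric matrix or keyed score table from TSV
#'
#' The first column holds row identifiers and the header row holds column
#' identifiers. `kind` documents the matrix role and selects the return
#' shape: `"consig"` and `"druggability"` are two-column keyed tables and
#' return a tibble; the other kinds return a numeric matrix with dimnames.
#' Cells equal to `"NA"` or the empty string are parsed as missing values.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"expression"`, `"consig"`, `"druggability"`, `"rppa"`,
#'   `"inhibition"`.
#' @return A numeric matrix (rows x columns with dimnames), or for keyed
#'   kinds a tibble: `gene`, `consig_score` for `"consig"`; `gene`,
#'   `druggable` (logical) for `"druggability"`.
#' @export
read_matrix <- function(path, kind = c("expression", "consig", "druggability",
                                       "rppa", "inhibition")) {
  kind <- match.arg(kind)
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0) abort("empty matrix file", class = "consigamp_format_error")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  ragged <- which(vapply(cells, length, integer(1)) != width)
  if (length(ragged) > 0) {
    abort(sprintf("ragged row at line %d of %s (expected %d fields)",
                  ragged[1], path, width),
          class = "consigamp_format_error")
  }
  header <- cells[[1]]
  body <- cells[-1]
  row_ids <- vapply(body, `[[`, character(1), 1L)
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicated row id(s): ", paste(dup, collapse = ", ")),
          class = "consigamp_format_error")
  }
  col_ids <- header[-1]
  if (anyDuplicated(col_ids)) {
    abort("duplicated column ids in matrix header", class = "consigamp_format_error")
  }
  parse_cell <- function(x) {
    ifelse(x %in% c("NA", ""), NA, x)
  }
  vals <- if (length(body) == 0) {
    matrix(numeric(0), nrow = 0, ncol = length(col_ids))
  } else {
    do.call(rbind, lapply(body, function(r) {
      v <- parse_cell(r[-1])
      out <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(out) & !is.na(v))
      if (length(bad) > 0 && kind != "druggability") {
        abort(sprintf("non-numeric cell '%s' in row '%s'", v[bad[1]], r[[1]]),
              class = "consigamp_format_error")
      }
      if (kind == "druggability") return(rep(NA_real_, length(v)))
      out
    }))
  }
  if (kind == "consig") {
    if (length(col_ids) != 1) abort("a consig table must have exactly two columns",
                                    class = "consigamp_format_error")
    scores <- vals[, 1]
    if (any(is.na(scores) | scores < 0)) {
      abort("consig scores must be non-negative and non-missing",
            class = "consigamp_format_error")
    }
    return(tibble(gene = row_ids, consig_score = scores))
  }
  if (kind == "druggability") {
    if (length(col_ids) < 1) abort("a druggability table needs a druggable column",
                                   class = "consigamp_format_error")
    flag_raw <- vapply(body, `[[`, character(1), 2L)
    flag <- toupper(flag_raw) %in% c("TRUE", "T", "1", "YES")
    src <- if (length(col_ids) >= 2) vapply(body, `[[`, character(1), 3L) else NA_character_
    return(tibble(gene = row_ids, druggable = flag, source = src))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  vals
}

#' Write a named numeric matrix as TSV (readable by [read_matrix()])
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_name Name of the leading id column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_name = "id") {
  df <- as.data.frame(mat, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(mat), stringsAsFactors = FALSE), id_name), df)
  readr::write_tsv(as_tibble(df), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Expects TSV columns `sample_id`, `er_status`, `subtype`, `treatment`,
#' `time_months`, `event`. Oestrogen-receptor status must be `pos`, `neg` or
#' `unknown`; survival time is in months and non-negative; the event
#' indicator is 0 (censored), 1 (event) or missing.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with those columns, `sample_id` unique.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    er_status = readr::col_character(),
    subtype = readr::col_character(),
    treatment = readr::col_character(),
    time_months = readr::col_double(),
    event = readr::col_integer()
  ), na = c("NA", ""), progress = FALSE)
  if (anyDuplicated(raw$sample_id)) {
    abort("duplicate sample_id in clinical table", class = "consigamp_validation_error")
  }
  raw$er_status[is.na(raw$er_status)] <- "unknown"
  if (!all(raw$er_status %in% c("pos", "neg", "unknown"))) {
    abort("er_status must be 'pos', 'neg' or 'unknown'",
          class = "consigamp_validation_error")
  }
  if (any(raw$time_months < 0, na.rm = TRUE)) {
    abort("negative survival time in clinical table",
          class = "consigamp_validation_error")
  }
  if (!all(raw$event %in% c(0L, 1L, NA_integer_))) {
    abort("event must be 0, 1 or missing", class = "consigamp_validation_error")
  }
  raw
}

#' Write a clinical table in the dialect read by [read_clinical()]
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a ranked-target table as TSV
#'
#' Columns: `rank`, `gene`, `amp_frequency`, `spearman_rho`, `consig`,
#' `consig_amp`, `druggable`. Scores survive a write/read round trip to six
#' significant digits.
#'
#' @param targets A ranked-target tibble from [nominate_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_targets <- function(targets, path) {
  out <- tibble(
    rank = targets$rank,
    gene = targets$gene,
    amp_frequency = signif(targets$amp_frequency, 6),
    spearman_rho = signif(targets$spearman_rho, 6),
    consig = signif(targets$consig, 6),
    consig_amp = signif(targets$consig_amp, 6),
    druggable = targets$druggable
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a ranked-target table written by [write_ranked_targets()]
#' @param path Path to the TSV.
#' @return A ranked-target tibble.
#' @export
read_ranked_targets <- function(path) {
  readr::read_tsv(path, col_types = "icddddl", na = c("NA", ""), progress = FALSE)
}
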