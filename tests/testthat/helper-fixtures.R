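# Shared, lazily built synthetic fixtures (one cohort per seed per test run)
.fixtures <- new.env(parent = emptyenv())

get_cohort <- function(seed = 101) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(cohort_config(seed = seed))
  }
  .fixtures[[key]]
}

get_rppa <- function(seed = 202, ...) {
  key <- paste0("rppa_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_rppa(seed = seed, ...)
  }
  .fixtures[[key]]
}

write_tmp_seg <- function(lines) {
  path <- withr::local_tempfile(fileext = ".seg",
                                .local_envir = parent.frame())
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean", lines),
             path)
  path
}
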