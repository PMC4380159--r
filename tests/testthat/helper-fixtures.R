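# Fixtures shared across test files; everything is built in code.

# A small two-species table: 3 spike genes, 2 background genes,
# 4 libraries at mixture levels 0/5/10/20%.
toy_table <- function(levels = c(0, 0.05, 0.10, 0.20)) {
  q <- levels
  counts <- rbind(
    `Dvir\\g1` = round(1000 * q / max(q)),       # strong linear responder
    `Dvir\\g2` = round(100 * q / max(q)),
    `Dvir\\g3` = c(0, 1, 2, 5),                  # weak responder
    bgA        = c(500, 480, 510, 495),
    bgB        = c(50, 55, 47, 52)
  )
  colnames(counts) <- sprintf("lib%d", seq_along(q))
  count_table(counts,
              libraries = data.frame(library_id = colnames(counts),
                                     protocol = "toy", spike_fraction = q,
                                     preamp_id = "p1",
                                     stringsAsFactors = FALSE))
}

# Write HTSeq-dialect lines to a temp file, returning the path.
htseq_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Small generator configuration for fast synthetic experiments.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_background_genes = 300, n_spike_genes = 120,
                   dynamic_range = 1e3, levels = c(0, 0.05, 0.10, 0.20),
                   depth = 2e5, seed = 11)
  do.call(generator_config, utils::modifyList(defaults, args))
}
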