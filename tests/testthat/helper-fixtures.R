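# Small in-code fixtures shared across test files.

# A three-node toy graph: O -> A (2 enzymes) -> B (3), plus a bypass O -> B.
tiny_graph <- function() {
  pathway_graph(
    metabolites = data.frame(id = c("O", "A", "B"),
                             label = c("origin", "mid", "end")),
    local_paths = data.frame(
      source = c("O", "A", "O"),
      target = c("A", "B", "B"),
      delta_ne = c(2L, 3L, 1L),
      is_bypass = c(FALSE, FALSE, TRUE)),
    origin = "O"
  )
}

tiny_record <- function(aa = "B", route = c("O", "A", "B"), delta_na = 0L) {
  list(aa = aa, route = route, delta_na = delta_na)
}

canonical_g <- canonical_pathway_graph()
canonical_tab <- canonical_aa_table()
canonical_nt <- ne_table(canonical_g, canonical_tab)

# Write a 19-row (Thr removed) copy of the canonical table, return the path.
write_truncated_table <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- readLines(system.file("extdata", "amino_acids.tsv",
                                 package = "pathNE"))
  writeLines(lines[!startsWith(lines, "Thr\t")], path)
  path
}
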