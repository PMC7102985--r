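test_that("packaged graph fixture loads with the text-anchored segments", {
  g <- canonical_g
  expect_s3_class(g, "pathway_graph")
  expect_identical(g$origin, "F6P")

  lp <- g$local_paths
  f6p_g3p <- lp[lp$source == "F6P" & lp$target == "G3P", ]
  expect_identical(f6p_g3p$delta_ne, 4L)
  expect_length(f6p_g3p$enzymes[[1]], 4L)

  # upstream glycolytic chain F6P -> G3P -> PEP -> Pyrv totals 7 enzymes
  glyco <- resolve_route(g, c("F6P", "G3P", "PEP", "Pyrv"))
  expect_identical(sum(glyco$delta_ne), 7L)

  # the TCA-tagged circuit contributes 8; formation from F6P totals 16
  tca <- lp[!is.na(lp$circuit_tag) & lp$circuit_tag == "TCA", ]
  expect_identical(sum(tca$delta_ne), 8L)
  to_tca <- resolve_route(g, c("F6P", "G3P", "PEP", "Pyrv", "AcCoA", "TCA"))
  expect_identical(sum(to_tca$delta_ne), 16L)
})

test_that("minimal and malformed graph files behave per contract", {
  minimal <- withr::local_tempfile(fileext = ".json")
  writeLines('{"origin":"F6P","metabolites":[{"id":"F6P","label":"origin"}],"local_paths":[]}',
             minimal)
  g <- load_pathway_graph(minimal)
  expect_identical(nrow(g$local_paths), 0L)
  expect_identical(g$metabolites$id, "F6P")

  dangling <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"origin":"F6P","metabolites":[{"id":"F6P","label":"o"}],',
                    '"local_paths":[{"source":"F6P","target":"XXX","delta_ne":1}]}'),
             dangling)
  expect_error(load_pathway_graph(dangling), "XXX")

  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"origin": "F6P",', bad_json)
  expect_error(load_pathway_graph(bad_json), "parse failure")

  unknown_key <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"origin":"F6P","metabolites":[{"id":"F6P","label":"o"}],',
                    '"local_paths":[],"extra":1}'), unknown_key)
  expect_error(load_pathway_graph(unknown_key), "unknown top-level key")
  expect_silent(load_pathway_graph(unknown_key, schema_check = FALSE))

  expect_error(load_pathway_graph(file.path(tempdir(), "nope.json")),
               "no such file")
})

test_that("validate_graph enumerates violations without raising", {
  expect_length(validate_graph(canonical_g), 0L)

  g <- tiny_graph()
  g$local_paths$delta_ne[1] <- -1L
  expect_match(validate_graph(g), "negative or missing delta_ne", all = FALSE)

  g2 <- tiny_graph()
  g2$origin <- "ZZZ"
  expect_match(validate_graph(g2), "origin", all = FALSE)

  g3 <- tiny_graph()
  g3$local_paths$enzymes[[1]] <- c("only-one")
  expect_match(validate_graph(g3), "enzyme list length", all = FALSE)
})

test_that("graph JSON round-trips to an identical object", {
  out <- withr::local_tempfile(fileext = ".json")
  write_pathway_graph(canonical_g, out)
  g2 <- load_pathway_graph(out)
  expect_identical(g2$origin, canonical_g$origin)
  expect_identical(g2$metabolites, canonical_g$metabolites)
  expect_identical(g2$local_paths, canonical_g$local_paths)

  # and a generated graph with decoys round-trips too
  sim <- generate_pathway_graph(synthetic_spec(n_aa = 4, seed = 11))
  out2 <- withr::local_tempfile(fileext = ".json")
  write_pathway_graph(sim$graph, out2)
  expect_identical(load_pathway_graph(out2)$local_paths,
                   sim$graph$local_paths)
})

test_that("amino-acid table loads with the canonical contract", {
  tab <- canonical_tab
  expect_identical(nrow(tab), 20L)
  expect_identical(sum(tab$class == "I"), 10L)
  expect_identical(sum(tab$class == "II"), 10L)
  expect_identical(as.vector(table(tab$group)[c("GA", "GB", "GC")]),
                   c(8L, 8L, 4L))

  thr <- tab[tab$aa == "Thr", ]
  expect_identical(thr$class, "II")
  expect_identical(thr$group, "GA")
  expect_identical(thr$route[[1]], c("F6P", "G3P", "Ser", "Gly", "Thr"))
  expect_identical(thr$delta_na, 0L)
  expect_identical(thr$n_sa, 3L)

  expect_setequal(tab$aa[tab$group == "GC"], c("Phe", "Tyr", "Trp", "His"))
  # GA class membership as stated for the group
  expect_setequal(tab$aa[tab$group == "GA" & tab$class == "I"],
                  c("Cys", "Val", "Leu", "Ile"))
  expect_setequal(tab$aa[tab$group == "GA" & tab$class == "II"],
                  c("Ser", "Gly", "Ala", "Thr"))
})

test_that("aa-table validation rejects broken inputs", {
  expect_error(load_aa_table(write_truncated_table()), "20 records")

  tab <- as.data.frame(canonical_tab)
  tab$class[tab$aa == "His"] <- "III"
  expect_error(as_aa_table(tab, canonical = FALSE), "unknown class")

  tab2 <- as.data.frame(canonical_tab)
  tab2$aa[1] <- tab2$aa[2]
  expect_error(as_aa_table(tab2, canonical = FALSE), "duplicate")

  tab3 <- as.data.frame(canonical_tab)
  tab3$delta_na[tab3$aa == "Ser"] <- 5L
  expect_error(as_aa_table(tab3), "GA and GB")
})

test_that("aa table round-trips through TSV", {
  out <- withr::local_tempfile(fileext = ".tsv")
  write_aa_table(canonical_tab, out)
  tab2 <- load_aa_table(out)
  expect_identical(as.data.frame(tab2), as.data.frame(canonical_tab))
})
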