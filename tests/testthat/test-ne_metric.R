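test_that("resolve_route returns the declared segments in order", {
  seg <- resolve_route(canonical_g, c("F6P", "G3P", "Ser", "Gly", "Thr"))
  expect_identical(seg$delta_ne, c(4L, 3L, 1L, 1L))
  expect_identical(seg$source, c("F6P", "G3P", "Ser", "Gly"))

  expect_error(resolve_route(canonical_g, "F6P"), "at least two")
  expect_error(resolve_route(canonical_g, c("G3P", "PEP")), "origin")
  expect_error(resolve_route(canonical_g, c("F6P", "G3P", "Ala")),
               "no local path.*G3P -> Ala")
})

test_that("bypass paths are never selected and bypass-only pairs error", {
  g <- tiny_graph()
  # O -> B exists only as a bypass
  expect_error(resolve_route(g, c("O", "B")), "bypass")
  seg <- resolve_route(g, c("O", "A", "B"))
  expect_identical(seg$delta_ne, c(2L, 3L))
})

test_that("compute_ne reproduces the worked examples", {
  tab <- canonical_tab
  rec <- function(aa) tab[tab$aa == aa, ]

  thr <- compute_ne(canonical_g, rec("Thr"))
  expect_identical(thr$ne_net, 9L)
  expect_identical(thr$ne_compensated, 9L)
  expect_identical(thr$segments$delta_ne, c(4L, 3L, 1L, 1L))

  expect_identical(compute_ne(canonical_g, rec("Arg"))$ne_net, 25L)

  his <- compute_ne(canonical_g, rec("His"))
  expect_identical(his$ne_net, 19L)
  expect_identical(his$ne_compensated, 39L)

  phe <- compute_ne(canonical_g, rec("Phe"))
  tyr <- compute_ne(canonical_g, rec("Tyr"))
  expect_identical(phe$ne_net, 19L)
  expect_identical(tyr$ne_net, phe$ne_net)
  expect_identical(phe$ne_compensated, 29L)

  # delta_na override yields the uncompensated view
  expect_identical(compute_ne(canonical_g, rec("His"), delta_na = 0)$ne_compensated,
                   19L)

  # self-consistency: ne_net equals the sum of its own segments
  for (aa in tab$aa) {
    res <- compute_ne(canonical_g, rec(aa))
    expect_identical(res$ne_net, sum(res$segments$delta_ne))
  }
})

test_that("apply_compensation follows the assigned circuit lags", {
  expect_identical(apply_compensation(19L, 20L), 39L)
  expect_identical(apply_compensation(19L, 10L), 29L)
  expect_identical(apply_compensation(13L, 0L), 13L)
  expect_error(apply_compensation(-1L, 0L), "non-negative")
  expect_error(apply_compensation(3L, -2L), "non-negative")
})

test_that("time lag is linear in N_E", {
  expect_identical(time_lag(9, timescale_model(1)), 9)
  expect_identical(time_lag(0, timescale_model(17.3)), 0)
  expect_identical(time_lag(25, timescale_model(2)), 50)
  m <- timescale_model(0.37)
  for (pair in list(c(3, 4), c(0, 11), c(25, 14)))
    expect_equal(time_lag(sum(pair), m),
                 time_lag(pair[1], m) + time_lag(pair[2], m))
  expect_error(timescale_model(0), "positive")
})

test_that("ne_table orders by compensated value with alphabetical ties", {
  nt <- canonical_nt
  expect_identical(nt$aa[1], "Ser")
  expect_identical(nt$ne_net[1], 7L)
  expect_false(is.unsorted(nt$ne_compensated))
  # within equal keys, codes are alphabetical
  for (v in unique(nt$ne_compensated)) {
    codes <- nt$aa[nt$ne_compensated == v]
    expect_identical(codes, sort(codes))
  }
  expect_identical(nt$ne_net[nt$aa == "Phe"], nt$ne_net[nt$aa == "Tyr"])

  empty <- ne_table(canonical_g, canonical_tab[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("N_E is additive under route splitting", {
  tab <- canonical_tab
  for (i in seq_len(nrow(tab))) {
    route <- tab$route[[i]]
    if (length(route) < 3L) next
    full <- sum(resolve_route(canonical_g, route)$delta_ne)
    for (cut in 2:(length(route) - 1L)) {
      prefix <- route[1:cut]
      suffix <- route[cut:length(route)]
      g_cut <- canonical_g
      g_cut$origin <- route[cut]  # re-root so the suffix is a valid route
      expect_identical(
        sum(resolve_route(canonical_g, prefix)$delta_ne) +
          sum(resolve_route(g_cut, suffix)$delta_ne),
        full)
    }
  }
})

test_that("compensation is monotone and tight exactly for GA/GB", {
  nt <- canonical_nt
  expect_true(all(nt$ne_compensated >= nt$ne_net))
  equal <- nt$ne_compensated == nt$ne_net
  expect_identical(sort(nt$group[!equal]), rep("GC", 4))
  expect_true(all(equal == (nt$delta_na == 0L)))
})

test_that("compute_ne matches the planted oracle on synthetic graphs", {
  for (seed in c(3, 42, 99)) {
    sim <- generate_pathway_graph(synthetic_spec(n_aa = 8, max_segments = 4,
                                                 seed = seed))
    for (aa in names(sim$routes)) {
      res <- compute_ne(sim$graph,
                        list(aa = aa, route = sim$routes[[aa]], delta_na = 0L))
      expect_identical(res$ne_net, unname(sim$planted_ne[aa]))
    }
  }
})
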