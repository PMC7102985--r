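#' Specification for the synthetic generators
#'
#' Controls both the planted-route graph generator and the correlated
#' (N_E, N_SA) table generator. Defaults mirror the canonical world:
#' 20 amino acids; routes of up to 5 segments with per-segment enzyme
#' counts uniform on 1..9 (the span of the non-zero canonical segments);
#' side-chain size linear in N_E with slope 0.3 (the canonical table's
#' empirical slope) and unit Gaussian noise.
#'
#' @param n_aa number of terminal amino acids (>= 1).
#' @param max_segments maximum number of route segments (>= 1).
#' @param delta_ne_range integer pair `(low, high)`, `0 <= low <= high`.
#' @param alpha intercept of the N_SA | N_E relation.
#' @param beta slope of the N_SA | N_E relation.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_aa = 20L, max_segments = 5L,
                           delta_ne_range = c(1L, 9L),
                           alpha = 0, beta = 0.3, sigma = 1, seed = 1L) {
  if (!is_count(n_aa) || n_aa < 1L) stop("n_aa must be >= 1", call. = FALSE)
  if (!is_count(max_segments) || max_segments < 1L)
    stop("max_segments must be >= 1", call. = FALSE)
  rng <- as.integer(delta_ne_range)
  if (length(rng) != 2L || any(rng < 0L) || rng[1L] > rng[2L])
    stop("delta_ne_range must be non-negative (low, high) with low <= high",
         call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(n_aa = as.integer(n_aa),
                 max_segments = as.integer(max_segments),
                 delta_ne_range = rng, alpha = alpha, beta = beta,
                 sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a pathway graph with planted routes
#'
#' Builds a graph with one origin and `n_aa` terminal metabolites, each
#' reached by a planted chain of 1..`max_segments` local paths whose
#' `delta_ne` are drawn uniformly from `delta_ne_range`. The planted
#' ground-truth N_E equals the segment sum by construction, giving an
#' exhaustive oracle for [compute_ne()]. Decoy bypass edges
#' (`is_bypass = TRUE`) are added between random node pairs and must never
#' influence the counts.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `graph` (a `pathway_graph`), `planted_ne` (named
#'   integer vector) and `routes` (named list of waypoint vectors).
#' @export
generate_pathway_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    lo <- spec$delta_ne_range[1L]; hi <- spec$delta_ne_range[2L]
    origin <- "ORI"
    src <- character(); tgt <- character(); dne <- integer()
    planted <- integer(spec$n_aa)
    routes <- vector("list", spec$n_aa)
    aa_ids <- sprintf("AA%02d", seq_len(spec$n_aa))
    names(planted) <- aa_ids; names(routes) <- aa_ids
    for (i in seq_len(spec$n_aa)) {
      k <- sample.int(spec$max_segments, 1L)
      mids <- if (k > 1L) sprintf("M%02d_%d", i, seq_len(k - 1L)) else character()
      wp <- c(origin, mids, aa_ids[i])
      d <- lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
      src <- c(src, wp[-length(wp)]); tgt <- c(tgt, wp[-1L])
      dne <- c(dne, d)
      planted[i] <- sum(d)
      routes[[i]] <- wp
    }
    nodes <- unique(c(origin, src, tgt))
    n_real <- length(src)
    # decoy bypasses between random distinct nodes
    n_decoy <- spec$n_aa
    bsrc <- sample(nodes, n_decoy, replace = TRUE)
    btgt <- vapply(bsrc, function(s) sample(setdiff(nodes, s), 1L), character(1))
    bdne <- lo + sample.int(hi - lo + 1L, n_decoy, replace = TRUE) - 1L
    lp <- data.frame(source = c(src, bsrc), target = c(tgt, btgt),
                     delta_ne = c(dne, bdne),
                     is_bypass = rep(c(FALSE, TRUE), c(n_real, n_decoy)),
                     stringsAsFactors = FALSE)
    g <- pathway_graph(data.frame(id = nodes, label = nodes,
                                  stringsAsFactors = FALSE),
                       lp, origin = origin)
    list(graph = g, planted_ne = planted, routes = routes)
  })
}

#' Generate synthetic (N_E, N_SA) pairs with controlled linear structure
#'
#' N_E is drawn as a planted segment sum (as in
#' [generate_pathway_graph()]); the side-chain size is then
#' `alpha + beta * ne + Normal(0, sigma)`. The population correlation is
#' \eqn{\rho = \beta\, sd(ne) / \sqrt{\beta^2 var(ne) + \sigma^2}}, which
#' the tests use for Monte-Carlo calibration.
#'
#' @param spec a [synthetic_spec()].
#' @param round_n_sa if `TRUE`, round `n_sa` to integers (side-chain-like
#'   values); default `FALSE` keeps the statistics exact.
#' @return data.frame with columns `ne` (integer) and `n_sa` (numeric).
#' @export
generate_correlated_table <- function(spec, round_n_sa = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    lo <- spec$delta_ne_range[1L]; hi <- spec$delta_ne_range[2L]
    k <- sample.int(spec$max_segments, spec$n_aa, replace = TRUE)
    ne <- vapply(k, function(ki)
      sum(lo + sample.int(hi - lo + 1L, ki, replace = TRUE) - 1L), integer(1))
    n_sa <- spec$alpha + spec$beta * ne + stats::rnorm(spec$n_aa, 0, spec$sigma)
    if (round_n_sa) n_sa <- pmax(0, round(n_sa))
    data.frame(ne = ne, n_sa = n_sa)
  })
}
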