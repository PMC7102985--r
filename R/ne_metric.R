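#' Resolve a declared route to its local-path segments
#'
#' Routes are declared inputs (ordered waypoint lists starting at the graph
#' origin), not shortest paths: step counting follows the specific
#' biological route of each amino acid, which need not be graph-minimal.
#' Bypass paths are never selected.
#'
#' @param g a `pathway_graph`.
#' @param route character vector of metabolite ids; must start at
#'   `g$origin` and have length at least 2.
#' @return data.frame with one row per consecutive waypoint pair, in route
#'   order, columns `source`, `target`, `delta_ne`, `spontaneous_steps`,
#'   `circuit_tag`.
#' @examples
#' g <- canonical_pathway_graph()
#' resolve_route(g, c("F6P", "G3P", "Ser", "Gly", "Thr"))$delta_ne
#' @export
resolve_route <- function(g, route) {
  stopifnot(inherits(g, "pathway_graph"))
  route <- as.character(route)
  if (length(route) < 2L)
    stop("route must have at least two waypoints", call. = FALSE)
  if (route[1L] != g$origin)
    stop("route must start at the graph origin '", g$origin, "', got '",
         route[1L], "'", call. = FALSE)
  lp <- g$local_paths
  idx <- integer(length(route) - 1L)
  for (i in seq_along(idx)) {
    s <- route[i]; t <- route[i + 1L]
    hit <- which(lp$source == s & lp$target == t & !lp$is_bypass)
    if (length(hit) == 0L) {
      if (any(lp$source == s & lp$target == t & lp$is_bypass))
        stop("only a bypass path exists for ", s, " -> ", t,
             " (bypasses are excluded from N_E counting)", call. = FALSE)
      stop("no local path for route segment ", s, " -> ", t, call. = FALSE)
    }
    idx[i] <- hit[1L]
  }
  out <- lp[idx, c("source", "target", "delta_ne", "spontaneous_steps",
                   "circuit_tag")]
  rownames(out) <- NULL
  out
}

#' Compute the enzyme-step count N_E for one amino acid
#'
#' \eqn{N_E = \sum_s \Delta N_{E,s}} over the segments of the declared
#' route from the origin to the amino acid; spontaneous reaction steps are
#' excluded by construction. The compensated value adds the
#' circuit-formation lag: `ne_compensated = ne_net + delta_na`.
#'
#' @param g a `pathway_graph`.
#' @param rec one amino-acid record: a one-row `aa_table` subset or a list
#'   with elements `aa`, `route`, `delta_na`.
#' @param delta_na optional override of the record's compensation (e.g.
#'   `0` to obtain the uncompensated value for a GC amino acid).
#' @return An object of class `ne_result`: list with `aa`, `segments`
#'   (data.frame `source`, `target`, `delta_ne`), `ne_net`, `delta_na`,
#'   `ne_compensated`.
#' @examples
#' g <- canonical_pathway_graph()
#' tab <- canonical_aa_table()
#' compute_ne(g, tab[tab$aa == "Thr", ])$ne_net   # 9
#' compute_ne(g, tab[tab$aa == "His", ])          # net 19, compensated 39
#' @export
compute_ne <- function(g, rec, delta_na = NULL) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- list(aa = rec$aa, route = rec$route[[1L]], delta_na = rec$delta_na)
  }
  segments <- resolve_route(g, rec$route)
  ne_net <- sum(segments$delta_ne)
  dna <- as.integer(delta_na %||% rec$delta_na %||% 0L)
  structure(
    list(aa = rec$aa,
         segments = segments[, c("source", "target", "delta_ne")],
         ne_net = as.integer(ne_net),
         delta_na = dna,
         ne_compensated = apply_compensation(ne_net, dna)),
    class = "ne_result"
  )
}

#' @export
print.ne_result <- function(x, ...) {
  cat(sprintf("N_E(%s): net %d, compensation %d, compensated %d\n  [%s] = %s\n",
              x$aa, x$ne_net, x$delta_na, x$ne_compensated,
              paste(c(x$segments$source[1L], x$segments$target), collapse = "-"),
              paste(x$segments$delta_ne, collapse = "+")))
  invisible(x)
}

#' Add the circuit-formation compensation to a net N_E
#'
#' The time lag for assembling multi-circuit machinery is charged as an
#' additive enzyme-count equivalent: 20 for routes requiring the completed
#' pentose-phosphate core (twice the core's 9 steps, rounded up as
#' assigned), 10 for aromatic routes branching off at E4P before core
#' completion, 0 elsewhere.
#'
#' @param ne_net non-negative integer net step count.
#' @param delta_na non-negative integer compensation.
#' @return `ne_net + delta_na` as an integer.
#' @export
apply_compensation <- function(ne_net, delta_na) {
  if (!is_count(ne_net) || !is_count(delta_na))
    stop("ne_net and delta_na must be non-negative integers", call. = FALSE)
  as.integer(ne_net + delta_na)
}

#' Constant-lag timescale model
#'
#' One new enzyme is assumed to take a constant time `d` to appear, so a
#' pathway of \eqn{N_E} enzymes forms in \eqn{T = N_E \times d}. With `d`
#' unknown but constant, \eqn{N_E} itself orders appearance times.
#'
#' @param d positive per-enzyme appearance lag (arbitrary time units).
#' @return An object of class `timescale_model`.
#' @export
timescale_model <- function(d = 1) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("d must be a positive real", call. = FALSE)
  structure(list(d = as.numeric(d)), class = "timescale_model")
}

#' Pathway formation time under the constant-lag model
#'
#' @param ne non-negative enzyme-step count.
#' @param model a [timescale_model()].
#' @return `ne * model$d`.
#' @export
time_lag <- function(ne, model = timescale_model()) {
  stopifnot(inherits(model, "timescale_model"))
  if (!is.numeric(ne) || any(ne < 0))
    stop("ne must be non-negative", call. = FALSE)
  ne * model$d
}

#' N_E table for a collection of amino acids
#'
#' Computes net and compensated \eqn{N_E} for every record and returns the
#' rows ordered by `ne_compensated` ascending, ties broken alphabetically
#' by amino-acid code (a deterministic stand-in for the presentational
#' ordering of equal values).
#'
#' @param g a `pathway_graph`.
#' @param table an `aa_table` (or compatible data.frame).
#' @return data.frame of class `ne_table` with columns `aa`, `group`,
#'   `class`, `ne_net`, `delta_na`, `ne_compensated`, `segments` (the
#'   per-segment counts joined with `+`).
#' @examples
#' nt <- ne_table(canonical_pathway_graph(), canonical_aa_table())
#' head(nt, 3)  # Ser first with ne_net 7
#' @export
ne_table <- function(g, table) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    res <- compute_ne(g, table[i, ])
    data.frame(aa = res$aa, group = table$group[i], class = table$class[i],
               ne_net = res$ne_net, delta_na = res$delta_na,
               ne_compensated = res$ne_compensated,
               segments = paste(res$segments$delta_ne, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(aa = character(), group = character(), class = character(),
                  ne_net = integer(), delta_na = integer(),
                  ne_compensated = integer(), segments = character(),
                  stringsAsFactors = FALSE)
  out <- out[order(out$ne_compensated, out$aa), ]
  rownames(out) <- NULL
  class(out) <- c("ne_table", "data.frame")
  out
}
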