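#' Construct a pathway graph
#'
#' A pathway graph holds metabolite nodes and directed "local paths" between
#' key metabolites. Each local path carries `delta_ne`, the number of
#' enzymes (= counted reaction steps) of that segment; spontaneous reactions
#' are recorded separately in `spontaneous_steps` and never enter any
#' \eqn{N_E} sum. Paths flagged `is_bypass` represent shortcuts presumed to
#' have formed later and are excluded from route resolution. `circuit_tag`
#' marks membership in a reaction circuit ("TCA", "UCycle", "PPPcore").
#' Edges are directed in the biosynthetic direction.
#'
#' @param metabolites data.frame with columns `id` and `label`.
#' @param local_paths data.frame with columns `source`, `target`,
#'   `delta_ne` and optionally `enzymes` (list column of character
#'   vectors), `spontaneous_steps`, `is_bypass`, `circuit_tag`.
#' @param origin metabolite id of the common route origin (default `"F6P"`,
#'   the glycolytic branch point shared by all amino-acid routes).
#' @param validate if `TRUE`, stop on any invariant violation.
#' @return An object of class `pathway_graph`.
#' @seealso [load_pathway_graph()], [validate_graph()], [resolve_route()]
#' @export
pathway_graph <- function(metabolites, local_paths, origin = "F6P",
                          validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(metabolites))) {
    if ("id" %in% names(metabolites)) metabolites$label <- metabolites$id
    else stop("`metabolites` needs at least an `id` column", call. = FALSE)
  }
  metabolites <- metabolites[, c("id", "label")]
  local_paths <- normalize_local_paths(local_paths)
  g <- structure(
    list(origin = as.character(origin),
         metabolites = metabolites,
         local_paths = local_paths),
    class = "pathway_graph"
  )
  if (validate) {
    v <- validate_graph(g)
    if (length(v)) stop("invalid pathway graph:\n  - ",
                        paste(v, collapse = "\n  - "), call. = FALSE)
  }
  g
}

normalize_local_paths <- function(lp) {
  lp <- as.data.frame(lp, stringsAsFactors = FALSE)
  if (nrow(lp) == 0L) {
    return(data.frame(source = character(), target = character(),
                      delta_ne = integer(), spontaneous_steps = integer(),
                      is_bypass = logical(), circuit_tag = character(),
                      stringsAsFactors = FALSE))
  }
  for (col in c("source", "target")) lp[[col]] <- as.character(lp[[col]])
  lp$delta_ne <- as.integer(lp$delta_ne)
  lp$spontaneous_steps <-
    if (is.null(lp$spontaneous_steps)) 0L else {
      s <- lp$spontaneous_steps; s[is.na(s)] <- 0L; as.integer(s)
    }
  lp$is_bypass <-
    if (is.null(lp$is_bypass)) FALSE else {
      b <- lp$is_bypass; b[is.na(b)] <- FALSE; as.logical(b)
    }
  lp$circuit_tag <-
    if (is.null(lp$circuit_tag)) NA_character_ else as.character(lp$circuit_tag)
  if (is.null(lp$enzymes)) lp$enzymes <- replicate(nrow(lp), NULL)
  lp[, c("source", "target", "delta_ne", "enzymes", "spontaneous_steps",
         "is_bypass", "circuit_tag")]
}

#' Validate a pathway graph
#'
#' Checks every structural invariant and returns the violations instead of
#' raising: unique non-empty metabolite ids, origin present, no dangling
#' path endpoints, non-negative integer `delta_ne` and
#' `spontaneous_steps`, and `length(enzymes) == delta_ne` wherever an
#' enzyme list is given.
#'
#' @param g a `pathway_graph` (invariants may be violated).
#' @return Character vector of human-readable violations; empty when clean.
#' @export
validate_graph <- function(g) {
  v <- character()
  ids <- g$metabolites$id
  if (any(!nzchar(ids) | is.na(ids)))
    v <- c(v, "metabolite ids must be non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, paste0("duplicate metabolite id(s): ", paste(dup, collapse = ", ")))
  if (!g$origin %in% ids)
    v <- c(v, paste0("origin '", g$origin, "' is not a declared metabolite"))
  lp <- g$local_paths
  if (nrow(lp)) {
    pair <- paste0(lp$source, "->", lp$target)
    dangling <- !(lp$source %in% ids) | !(lp$target %in% ids)
    if (any(dangling))
      v <- c(v, paste0("local path with undeclared endpoint: ",
                       paste(pair[dangling], collapse = ", ")))
    bad_ne <- is.na(lp$delta_ne) | lp$delta_ne < 0L
    if (any(bad_ne))
      v <- c(v, paste0("negative or missing delta_ne: ",
                       paste(pair[bad_ne], collapse = ", ")))
    bad_sp <- is.na(lp$spontaneous_steps) | lp$spontaneous_steps < 0L
    if (any(bad_sp))
      v <- c(v, paste0("negative spontaneous_steps: ",
                       paste(pair[bad_sp], collapse = ", ")))
    n_enz <- vapply(lp$enzymes, length, integer(1))
    has_enz <- !vapply(lp$enzymes, is.null, logical(1))
    mismatch <- has_enz & !is.na(lp$delta_ne) & n_enz != lp$delta_ne
    if (any(mismatch))
      v <- c(v, paste0("enzyme list length != delta_ne: ",
                       paste(pair[mismatch], collapse = ", ")))
    dup_pair <- duplicated(pair[!lp$is_bypass])
    if (any(dup_pair))
      v <- c(v, paste0("duplicate non-bypass local path: ",
                       paste(unique(pair[!lp$is_bypass][dup_pair]),
                             collapse = ", ")))
  }
  v
}

GRAPH_KEYS <- c("origin", "metabolites", "local_paths")
PATH_KEYS <- c("source", "target", "delta_ne", "enzymes",
               "spontaneous_steps", "is_bypass", "circuit_tag")

#' Read a pathway graph from its JSON file
#'
#' The on-disk dialect is a single UTF-8 JSON document with keys exactly
#' `origin` (string), `metabolites` (array of `{id, label}`) and
#' `local_paths` (array of
#' `{source, target, delta_ne, enzymes?, spontaneous_steps?, is_bypass?, circuit_tag?}`).
#'
#' @param path file to read.
#' @param schema_check reject unknown keys when `TRUE` (default).
#' @return A validated [pathway_graph()].
#' @examples
#' g <- load_pathway_graph(system.file("extdata", "pathway_graph_f6p.json",
#'                                     package = "pathNE"))
#' g
#' @export
load_pathway_graph <- function(path, schema_check = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  missing_keys <- setdiff(GRAPH_KEYS, names(doc))
  if (length(missing_keys))
    stop("graph file lacks key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  if (schema_check) {
    extra <- setdiff(names(doc), GRAPH_KEYS)
    if (length(extra))
      stop("unknown top-level key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    for (p in doc$local_paths) {
      bad <- setdiff(names(p), PATH_KEYS)
      if (length(bad))
        stop("unknown local_path key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    label = vapply(doc$metabolites,
                   function(m) as.character(m$label %||% m$id), character(1)),
    stringsAsFactors = FALSE
  )
  lp <- data.frame(
    source = vapply(doc$local_paths, function(p) as.character(p$source), character(1)),
    target = vapply(doc$local_paths, function(p) as.character(p$target), character(1)),
    delta_ne = vapply(doc$local_paths, function(p) as.integer(p$delta_ne), integer(1)),
    spontaneous_steps = vapply(doc$local_paths,
                               function(p) as.integer(p$spontaneous_steps %||% 0L),
                               integer(1)),
    is_bypass = vapply(doc$local_paths,
                       function(p) isTRUE(p$is_bypass), logical(1)),
    circuit_tag = vapply(doc$local_paths,
                         function(p) as.character(p$circuit_tag %||% NA_character_),
                         character(1)),
    stringsAsFactors = FALSE
  )
  lp$enzymes <- lapply(doc$local_paths, function(p)
    if (is.null(p$enzymes)) NULL else as.character(unlist(p$enzymes)))
  pathway_graph(mets, lp, origin = as.character(doc$origin))
}

#' Write a pathway graph to JSON
#'
#' Inverse of [load_pathway_graph()]; a written graph reloads to an
#' identical object (same ids, `delta_ne` values and flags).
#'
#' @param g a `pathway_graph`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  paths <- lapply(seq_len(nrow(g$local_paths)), function(i) {
    row <- g$local_paths[i, ]
    out <- list(source = row$source, target = row$target,
                delta_ne = row$delta_ne)
    enz <- row$enzymes[[1]]
    if (!is.null(enz)) out$enzymes <- as.list(enz)
    if (row$spontaneous_steps > 0L) out$spontaneous_steps <- row$spontaneous_steps
    if (isTRUE(row$is_bypass)) out$is_bypass <- TRUE
    if (!is.na(row$circuit_tag)) out$circuit_tag <- row$circuit_tag
    out
  })
  doc <- list(
    origin = g$origin,
    metabolites = lapply(seq_len(nrow(g$metabolites)), function(i)
      list(id = g$metabolites$id[i], label = g$metabolites$label[i])),
    local_paths = paths
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @export
print.pathway_graph <- function(x, ...) {
  lp <- x$local_paths
  cat(sprintf("pathway_graph: %d metabolites, %d local paths (%d bypass), origin '%s'\n",
              nrow(x$metabolites), nrow(lp), sum(lp$is_bypass), x$origin))
  if (nrow(lp)) {
    tags <- unique(stats::na.omit(lp$circuit_tag))
    if (length(tags)) cat("  circuits:", paste(tags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' The packaged F6P-rooted pathway graph
#'
#' Loads the packaged fixture transcribing the amino-acid biosynthesis map:
#' glycolytic segments F6P to G3P (4 enzymes), G3P to PEP (2), PEP to
#' pyruvate (1); the citric-acid-cycle entry (1) and circuit (8, tagged
#' `TCA`); the urea-cycle-bearing Glu to Arg segment (8, tagged `UCycle`);
#' the pentose phosphate core (9, tagged `PPPcore`) with its E4P/R5P ports;
#' and the remaining amino-acid branches.
#'
#' @return A `pathway_graph`.
#' @export
canonical_pathway_graph <- function() {
  load_pathway_graph(system.file("extdata", "pathway_graph_f6p.json",
                                 package = "pathNE", mustWork = TRUE))
}
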