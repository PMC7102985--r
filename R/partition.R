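#' Class-by-group partition counts
#'
#' Tabulates aminoacyl-tRNA synthetase classes (I/II) within each pathway
#' group. "Equi-partition" is formalised as exact equality of the two
#' class counts in every group (canonically 4:4, 4:4, 2:2 for GA, GB, GC,
#' hence 10:10 overall).
#'
#' @param table an `aa_table` (or compatible data.frame with `class` and
#'   `group` columns).
#' @return Object of class `partition_table`: list with
#'   `per_group_counts` (matrix, groups x classes), `overall` (named
#'   length-2 vector) and `is_equipartitioned` (logical).
#' @examples
#' partition_counts(canonical_aa_table())
#' @export
partition_counts <- function(table) {
  grp <- factor(table$group, levels = AA_GROUPS)
  cls <- factor(table$class, levels = AA_CLASSES)
  counts <- table(grp, cls)
  m <- matrix(as.integer(counts), nrow = length(AA_GROUPS),
              dimnames = list(group = AA_GROUPS, class = AA_CLASSES))
  overall <- stats::setNames(as.integer(colSums(m)), AA_CLASSES)
  structure(
    list(per_group_counts = m,
         overall = overall,
         is_equipartitioned = all(m[, "I"] == m[, "II"])),
    class = "partition_table"
  )
}

#' @export
print.partition_table <- function(x, ...) {
  cat("aaRS class partition by pathway group\n")
  print(x$per_group_counts)
  cat(sprintf("overall I:II = %d:%d; equi-partitioned: %s\n",
              x$overall[["I"]], x$overall[["II"]],
              x$is_equipartitioned))
  invisible(x)
}

#' Appearance ranking along the N_E timescale
#'
#' Orders amino acids by compensated \eqn{N_E} ascending (alphabetical
#' tie-break), i.e. by the proxy appearance time of their biosynthetic
#' pathways, and records the initial run of class II amino acids preceding
#' the first class I entry.
#'
#' @param ne_results an `ne_table` (from [ne_table()]).
#' @param table the matching `aa_table`; must cover the same amino acids.
#' @return Object of class `appearance_ranking`: list with `ordered`
#'   (data.frame `aa`, `class`, `group`, `ne_compensated`) and
#'   `first_class_II_block` (character vector of codes).
#' @examples
#' g <- canonical_pathway_graph(); tab <- canonical_aa_table()
#' rank_appearance(ne_table(g, tab), tab)$ordered$aa[1]  # "Ser"
#' @export
rank_appearance <- function(ne_results, table) {
  if (!setequal(ne_results$aa, table$aa))
    stop("ne_results and table cover different amino-acid sets", call. = FALSE)
  ord <- ne_results[order(ne_results$ne_compensated, ne_results$aa),
                    c("aa", "class", "group", "ne_compensated")]
  rownames(ord) <- NULL
  first_I <- match("I", ord$class)
  block <- if (is.na(first_I)) ord$aa else ord$aa[seq_len(first_I - 1L)]
  structure(list(ordered = ord, first_class_II_block = block),
            class = "appearance_ranking")
}

#' @export
print.appearance_ranking <- function(x, ...) {
  cat("appearance ranking (compensated N_E ascending):\n")
  cat(" ", paste(sprintf("%s(%d,%s)", x$ordered$aa, x$ordered$ne_compensated,
                         x$ordered$class), collapse = " "), "\n")
  cat("leading class II block:",
      paste(x$first_class_II_block, collapse = ", "), "\n")
  invisible(x)
}

#' Does class II reach a group before class I?
#'
#' Within one pathway group, compares the minimum compensated \eqn{N_E}
#' of class II members with that of class I members. Strict inequality is
#' required, so a shared minimum returns `FALSE`.
#'
#' @param ranking an `appearance_ranking` built over the full table.
#' @param group one of `"GA"`, `"GB"`, `"GC"` (must be present).
#' @return `TRUE` iff the class II minimum is strictly below the class I
#'   minimum in that group.
#' @export
earliest_class_test <- function(ranking, group) {
  stopifnot(inherits(ranking, "appearance_ranking"))
  ord <- ranking$ordered
  if (!group %in% ord$group)
    stop("group '", group, "' not present in ranking", call. = FALSE)
  sub <- ord[ord$group == group, ]
  if (!all(AA_CLASSES %in% sub$class))
    stop("group '", group, "' lacks one of the classes", call. = FALSE)
  min(sub$ne_compensated[sub$class == "II"]) <
    min(sub$ne_compensated[sub$class == "I"])
}

#' Binomial sign test for the overall class split (extra diagnostic)
#'
#' Not part of the core analysis: the equi-partition itself is stated as
#' an exact-count observation. This utility attaches an exact binomial
#' test of the overall I:II split against 1/2 for context.
#'
#' @param table an `aa_table`.
#' @return htest object from [stats::binom.test()].
#' @export
equipartition_sign_test <- function(table) {
  n_I <- sum(table$class == "I")
  stats::binom.test(n_I, nrow(table), p = 0.5)
}
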