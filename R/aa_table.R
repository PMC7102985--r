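AA_CODES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
              "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
              "Thr", "Trp", "Tyr", "Val")
AA_CLASSES <- c("I", "II")
AA_GROUPS <- c("GA", "GB", "GC")
AA_TABLE_HEADER <- c("aa", "class", "group", "route", "delta_na", "n_sa")

#' Read the amino-acid annotation table
#'
#' Tab-separated with header
#' `aa  class  group  route  delta_na  n_sa`. Per record: the three-letter
#' amino-acid code; its aminoacyl-tRNA synthetase class (`I` or `II`); its
#' pathway group (`GA` glycolysis-proximal, `GB` citric-acid-cycle derived,
#' `GC` pentose-phosphate/aromatic); the declared route as a comma-joined
#' waypoint list starting at the graph origin; the circuit-formation
#' compensation `delta_na` (0 for GA/GB, 10 for Phe/Tyr/Trp which branch
#' before completion of the PPP core, 20 for His which requires the full
#' core plus the ATP branch); and `n_sa`, the number of non-hydrogen
#' side-chain atoms.
#'
#' @param path file to read.
#' @param canonical enforce the canonical contract: exactly 20 records,
#'   class counts 10/10, group sizes 8/8/4, `delta_na = 0` for GA and GB.
#'   Set to `FALSE` for synthetic or partial tables.
#' @return A data.frame of class `aa_table`; `route` is a list column of
#'   character waypoint vectors.
#' @examples
#' tab <- load_aa_table(system.file("extdata", "amino_acids.tsv",
#'                                  package = "pathNE"))
#' subset(tab, group == "GC")$aa
#' @export
load_aa_table <- function(path, canonical = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(names(raw), AA_TABLE_HEADER))
    stop("amino-acid table header must be exactly: ",
         paste(AA_TABLE_HEADER, collapse = "\t"), call. = FALSE)
  tab <- data.frame(aa = raw$aa, class = raw$class, group = raw$group,
                    stringsAsFactors = FALSE)
  tab$route <- lapply(strsplit(raw$route, ",", fixed = TRUE), trimws)
  tab$delta_na <- as.integer(raw$delta_na)
  tab$n_sa <- as.integer(raw$n_sa)
  as_aa_table(tab, canonical = canonical)
}

#' Validate and classify an in-memory amino-acid table
#'
#' @param tab data.frame with the [load_aa_table()] columns (`route` as a
#'   list column).
#' @param canonical see [load_aa_table()].
#' @return The validated table with class `aa_table`.
#' @export
as_aa_table <- function(tab, canonical = TRUE) {
  v <- character()
  if (anyDuplicated(tab$aa)) v <- c(v, "duplicate amino-acid code(s)")
  bad_cls <- setdiff(unique(tab$class), AA_CLASSES)
  if (length(bad_cls))
    v <- c(v, paste0("unknown class token(s): ", paste(bad_cls, collapse = ", ")))
  bad_grp <- setdiff(unique(tab$group), AA_GROUPS)
  if (length(bad_grp))
    v <- c(v, paste0("unknown group token(s): ", paste(bad_grp, collapse = ", ")))
  if (any(is.na(tab$delta_na) | tab$delta_na < 0L))
    v <- c(v, "delta_na must be a non-negative integer")
  if (any(is.na(tab$n_sa) | tab$n_sa < 0L))
    v <- c(v, "n_sa must be a non-negative integer")
  if (canonical) {
    if (nrow(tab) != 20L)
      v <- c(v, paste0("canonical table must have 20 records, found ", nrow(tab)))
    missing_aa <- setdiff(AA_CODES, tab$aa)
    if (length(missing_aa))
      v <- c(v, paste0("missing amino acid(s): ", paste(missing_aa, collapse = ", ")))
    n_I <- sum(tab$class == "I"); n_II <- sum(tab$class == "II")
    if (n_I != 10L || n_II != 10L)
      v <- c(v, sprintf("class counts must be 10/10, found %d/%d", n_I, n_II))
    sizes <- c(GA = 8L, GB = 8L, GC = 4L)
    for (gname in names(sizes)) {
      n_g <- sum(tab$group == gname)
      if (n_g != sizes[[gname]])
        v <- c(v, sprintf("group %s must have %d records, found %d",
                          gname, sizes[[gname]], n_g))
    }
    if (any(tab$group %in% c("GA", "GB") & tab$delta_na != 0L))
      v <- c(v, "delta_na must be 0 for every GA and GB record")
  }
  if (length(v))
    stop("invalid amino-acid table:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  class(tab) <- c("aa_table", "data.frame")
  tab
}

#' Write an amino-acid table as TSV
#'
#' @param tab an `aa_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_aa_table <- function(tab, path) {
  out <- data.frame(
    aa = tab$aa, class = tab$class, group = tab$group,
    route = vapply(tab$route, paste, character(1), collapse = ","),
    delta_na = tab$delta_na, n_sa = tab$n_sa,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged canonical amino-acid table
#'
#' Twenty records with aaRS class, pathway group, declared route from F6P,
#' circuit compensation and side-chain heavy-atom count. Side-chain counts
#' are derived from molecular formulas (non-hydrogen atoms beyond the
#' backbone): Gly 0, Ala 1, up to Trp 10.
#'
#' @return An `aa_table` with 20 rows.
#' @export
canonical_aa_table <- function() {
  load_aa_table(system.file("extdata", "amino_acids.tsv",
                            package = "pathNE", mustWork = TRUE))
}
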