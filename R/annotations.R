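#' Construct an annotation table
#'
#' The protein-to-term association structure: an ordered list of N proteins,
#' a term set per protein, and the term universe in scope. Term sets may be
#' empty (real GOA releases contain proteins without a single non-electronic
#' annotation); such proteins are retained but skipped by masking.
#'
#' @param proteins ordered character vector of protein identifiers.
#' @param term_sets list of character vectors, one per protein.
#' @param universe character vector of terms in scope; defaults to the union
#'   of the term sets.
#' @return an object of class `annotation_table`.
#' @export
annotation_table <- function(proteins, term_sets,
                             universe = sort(unique(unlist(term_sets, use.names = FALSE)))) {
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) stop("duplicate protein identifiers")
  if (length(term_sets) != length(proteins)) {
    stop("`term_sets` must have one element per protein")
  }
  term_sets <- lapply(term_sets, function(x) sort(unique(as.character(x))))
  names(term_sets) <- proteins
  universe <- sort(unique(as.character(universe)))
  stray <- setdiff(unlist(term_sets, use.names = FALSE), universe)
  if (length(stray) > 0L) {
    stop("annotated term(s) outside the universe: ", paste(stray, collapse = ", "))
  }
  structure(list(proteins = proteins, term_sets = term_sets, universe = universe),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  sizes <- lengths(x$term_sets)
  cat(sprintf(
    "<annotation_table> %d proteins, %d terms in universe, %d associations (%d unannotated proteins)\n",
    length(x$proteins), length(x$universe), sum(sizes), sum(sizes == 0L)
  ))
  invisible(x)
}

#' Parse a GAF gene-association file
#'
#' Reads GAF 2.x tab-separated records into direct (unpropagated)
#' annotations. Records whose evidence code is in `excluded_evidence` are
#' dropped, as are NOT-qualified records and duplicate (protein, term)
#' pairs. When `dag` is supplied, records pointing at terms absent from the
#' ontology (obsolete or unknown) are dropped with a message.
#'
#' @param path path to a GAF file, or a character vector of lines.
#' @param excluded_evidence evidence codes to exclude; the default drops
#'   electronic (IEA), not-recorded (NR), no-data (ND) and curator-inferred
#'   (IC) annotations.
#' @param dag optional [ontology_dag] used to validate term identifiers.
#' @return an [annotation_table] of direct annotations. The universe is the
#'   set of annotated terms (plus nothing else); apply
#'   [propagate_true_path()] before analysis.
#' @export
parse_gaf <- function(path, excluded_evidence = c("IEA", "NR", "ND", "IC"),
                      dag = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  prot <- character(); term <- character()
  dropped_unknown <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "!")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L || length(f) > 17L) {
      stop(sprintf("GAF line %d has %d columns (expected 15-17)", i, length(f)))
    }
    if (grepl("\\bNOT\\b", f[[4L]])) next
    if (f[[7L]] %in% excluded_evidence) next
    if (!is.null(dag) && !(f[[5L]] %in% dag$terms)) {
      dropped_unknown <- dropped_unknown + 1L
      next
    }
    prot <- c(prot, f[[2L]])
    term <- c(term, f[[5L]])
  }
  if (dropped_unknown > 0L) {
    message(dropped_unknown, " GAF record(s) to obsolete/unknown terms dropped")
  }
  keep <- !duplicated(paste(prot, term, sep = "\r"))
  prot <- prot[keep]; term <- term[keep]
  proteins <- sort(unique(prot))
  sets <- split(term, factor(prot, levels = proteins))
  annotation_table(proteins, sets)
}

#' Restrict the universe to sufficiently supported terms
#'
#' Drops terms annotated to fewer than `min_proteins` proteins and
#' intersects every protein's term set with the surviving universe.
#' Conventionally applied to the true-path-propagated table, so support
#' counts include implicit ancestor annotations.
#'
#' @param table an [annotation_table].
#' @param min_proteins minimum number of annotated proteins (>= 1).
#' @return a filtered [annotation_table].
#' @export
filter_terms_by_support <- function(table, min_proteins = 3L) {
  stopifnot(inherits(table, "annotation_table"), min_proteins >= 1L)
  freq <- term_frequency(table)
  keep <- names(freq)[freq >= min_proteins]
  sets <- lapply(table$term_sets, intersect, y = keep)
  annotation_table(table$proteins, sets, universe = sort(keep))
}

#' Per-term annotation frequency
#'
#' @param table an [annotation_table].
#' @return named integer vector over the universe: the number of proteins
#'   annotated with each term (zero for unused terms).
#' @export
term_frequency <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  counts <- table(factor(unlist(table$term_sets, use.names = FALSE),
                         levels = table$universe))
  out <- as.integer(counts)
  names(out) <- table$universe
  out
}

#' Sparsity strata of terms
#'
#' Assigns each universe term to the support stratum used when reporting
#' per-term accuracy: `[3,10)`, `[10,30)`, or `>=30` annotated proteins.
#' Terms supported by fewer than 3 proteins are labelled `below`.
#'
#' @param table an [annotation_table] (propagated).
#' @return named character vector over the universe.
#' @export
sparsity_strata <- function(table) {
  freq <- term_frequency(table)
  out <- ifelse(freq >= 30L, ">=30",
                ifelse(freq >= 10L, "[10,30)",
                       ifelse(freq >= 3L, "[3,10)", "below")))
  names(out) <- names(freq)
  out
}

#' Write an annotation table as two-column TSV
#'
#' One `(protein, term)` row per association; round-trips through
#' [read_annotation_tsv()].
#' @param table an [annotation_table].
#' @param path output file path.
#' @export
write_annotation_tsv <- function(table, path) {
  rows <- do.call(rbind, c(list(matrix(character(), ncol = 2L)),
                           lapply(table$proteins, function(p) {
    ts <- table$term_sets[[p]]
    if (length(ts) == 0L) return(NULL)
    cbind(p, ts)
  })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("protein", "term"))
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  proteins <- sort(unique(df$protein))
  sets <- split(df$term, factor(df$protein, levels = proteins))
  annotation_table(proteins, sets)
}
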