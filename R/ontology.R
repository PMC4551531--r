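#' Construct an ontology DAG
#'
#' Builds the in-memory representation of a Gene Ontology (sub-)hierarchy:
#' a directed acyclic graph whose edges point from parent (more general)
#' to child (more specific) terms.
#'
#' @param terms character vector of term identifiers.
#' @param edges two-column character matrix or data.frame of
#'   `(parent, child)` pairs; both endpoints must appear in `terms`.
#' @param name optional named character vector of term labels.
#' @param namespace optional named character vector assigning each term to
#'   a sub-ontology (`biological_process`, `molecular_function`,
#'   `cellular_component`, or `synthetic`). Defaults to `"synthetic"`.
#' @return an object of class `ontology_dag` with components `terms`
#'   (sorted), `name`, `namespace`, `parents`, `children` (named lists of
#'   character vectors) and `roots` (terms with no parent).
#' @export
ontology_dag <- function(terms, edges, name = NULL, namespace = NULL) {
  terms <- sort(unique(as.character(terms)))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("`edges` must have two columns (parent, child)")
  bad <- setdiff(c(edges), terms)
  if (length(bad) > 0L) {
    stop("edge endpoint(s) not in `terms`: ", paste(bad, collapse = ", "))
  }
  if (nrow(edges) > 0L) {
    edges <- unique(edges)
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge detected")
  }
  parents <- split(edges[, 1L], factor(edges[, 2L], levels = terms))
  children <- split(edges[, 2L], factor(edges[, 1L], levels = terms))
  parents <- lapply(parents, function(x) sort(unique(x)))
  children <- lapply(children, function(x) sort(unique(x)))
  dag <- structure(
    list(
      terms = terms,
      name = resolve_term_attr(name, terms, paste("term", terms)),
      namespace = resolve_term_attr(namespace, terms, "synthetic"),
      parents = parents,
      children = children,
      roots = terms[vapply(parents, length, 1L) == 0L]
    ),
    class = "ontology_dag"
  )
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology graph is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }
  dag
}

resolve_term_attr <- function(x, terms, default) {
  out <- rep_len(default, length(terms))
  names(out) <- terms
  if (!is.null(x)) {
    keep <- intersect(names(x), terms)
    out[keep] <- x[keep]
  }
  out
}

# Kahn's algorithm; returns NULL when acyclic, otherwise one cycle as a
# character vector of term ids.
find_cycle <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in dag$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(dag$terms)) return(NULL)
  # walk backwards through still-cyclic nodes until one repeats
  rem <- names(indeg)[indeg > 0L]
  v <- rem[[1L]]
  path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(dag$parents[[v]], rem)[[1L]]
  }
  i <- match(v, path)
  c(path[seq(i, length(path))], v)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf(
    "<ontology_dag> %d terms, %d edges, %d root(s), namespaces: %s\n",
    length(x$terms), sum(vapply(x$children, length, 1L)),
    length(x$roots), paste(sort(unique(x$namespace)), collapse = ", ")
  ))
  invisible(x)
}

#' Parse an OBO ontology file
#'
#' Reads OBO 1.2/1.4 stanza text into an [ontology_dag]. Terms flagged
#' `is_obsolete: true` are dropped, together with any edge touching them.
#' Edges are taken from `is_a:` lines and, optionally, from
#' `relationship: part_of` lines; both conventionally participate in
#' true-path propagation over GO.
#'
#' @param path path to an OBO file, or a character vector of lines.
#' @param relations which relationship types become parent->child edges;
#'   default `c("is_a", "part_of")`, restrict to `"is_a"` to ignore
#'   partonomy.
#' @return an [ontology_dag] containing only non-obsolete terms.
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    ln <- sub("\\s*!.*$", "", lines[[i]])  # trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- identical(ln, "[Term]")
      cur <- list(id = NULL, obsolete = FALSE, parents = character(),
                  name = NA_character_, namespace = NA_character_)
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop(sprintf("malformed OBO line %d: '%s'", i, lines[[i]]))
    key <- m[[2L]]; val <- trimws(m[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (key == "is_a" && "is_a" %in% relations) {
      if (val == "") stop(sprintf("malformed is_a on line %d (missing target)", i))
      cur$parents <- c(cur$parents, strsplit(val, "\\s+")[[1L]][[1L]])
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) < 2L) stop(sprintf("malformed relationship on line %d", i))
      if (parts[[1L]] %in% relations) cur$parents <- c(cur$parents, parts[[2L]])
    }
  }
  if (in_term) flush()
  if (length(stanzas) == 0L) stop("no [Term] stanzas found")
  obs <- vapply(stanzas, `[[`, TRUE, "obsolete")
  ids <- vapply(stanzas, `[[`, "", "id")
  keep <- stanzas[!obs]
  terms <- vapply(keep, `[[`, "", "id")
  edges <- do.call(rbind, lapply(keep, function(s) {
    ps <- intersect(s$parents, terms)   # edges to obsolete/foreign terms drop
    if (length(ps) == 0L) return(NULL)
    cbind(ps, s$id)
  }))
  nm <- vapply(keep, `[[`, "", "name")
  ns <- vapply(keep, `[[`, "", "namespace")
  names(nm) <- terms; names(ns) <- terms
  ns[is.na(ns)] <- "synthetic"
  nm[is.na(nm)] <- paste("term", terms[is.na(nm)])
  ontology_dag(terms, if (is.null(edges)) matrix(character(), ncol = 2L) else edges,
               name = nm, namespace = ns)
}

check_terms <- function(dag, t) {
  bad <- setdiff(t, dag$terms)
  if (length(bad) > 0L) {
    stop("unknown term(s): ", paste(bad, collapse = ", "))
  }
  invisible(t)
}

reachable <- function(adj, t) {
  out <- character()
  frontier <- adj[[t]]
  while (length(frontier) > 0L) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(adj[new], use.names = FALSE))
  }
  sort(out)
}

#' Descendants of a term
#'
#' All terms reachable from `t` by one or more downward (parent->child)
#' edges; `t` itself is excluded.
#' @param dag an [ontology_dag].
#' @param t a term identifier in `dag`.
#' @return sorted character vector (possibly empty).
#' @export
descendants <- function(dag, t) {
  check_terms(dag, t)
  reachable(dag$children, t)
}

#' Ancestors of a term
#'
#' All terms reachable from `t` by one or more upward (child->parent)
#' edges; `t` itself is excluded.
#' @inheritParams descendants
#' @return sorted character vector (possibly empty).
#' @export
ancestors <- function(dag, t) {
  check_terms(dag, t)
  reachable(dag$parents, t)
}

#' Apply the true path rule to an annotation table
#'
#' A protein annotated with a term is implicitly annotated with every
#' ancestor of that term; this closes each protein's term set upward.
#' The operation is idempotent.
#'
#' @param dag an [ontology_dag].
#' @param table an [annotation_table]; every annotated term must be in `dag`.
#' @return an [annotation_table] with upward-closed term sets. The universe
#'   is extended with any ancestors it did not already contain.
#' @export
propagate_true_path <- function(dag, table) {
  stopifnot(inherits(table, "annotation_table"))
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- ancestors(dag, t)
    anc_cache[[t]]
  }
  sets <- lapply(seq_along(table$proteins), function(i) {
    ts <- table$term_sets[[i]]
    if (length(ts) == 0L) return(character())
    bad <- setdiff(ts, dag$terms)
    if (length(bad) > 0L) {
      stop(sprintf("protein %s annotated to term(s) absent from the ontology: %s",
                   table$proteins[[i]], paste(bad, collapse = ", ")))
    }
    sort(unique(c(ts, unlist(lapply(ts, anc_of), use.names = FALSE))))
  })
  names(sets) <- table$proteins
  annotation_table(table$proteins, sets,
                   universe = sort(unique(c(table$universe,
                                            unlist(sets, use.names = FALSE)))))
}

#' Leaf terms of a protein-specific sub-hierarchy
#'
#' Given an upward-closed term set, returns its frontier: the members with
#' no child (per the DAG) inside the set. Only these terms can be masked
#' without breaking upward closure, and only below them can annotations be
#' extended.
#'
#' @param dag an [ontology_dag].
#' @param terms an upward-closed character vector of terms.
#' @return sorted character vector, a subset of `terms`.
#' @export
protein_leaf_terms <- function(dag, terms) {
  if (length(terms) == 0L) return(character())
  check_terms(dag, terms)
  keep <- vapply(terms, function(t) {
    length(intersect(dag$children[[t]], terms)) == 0L
  }, TRUE)
  sort(terms[keep])
}
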