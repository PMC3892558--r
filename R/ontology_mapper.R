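#' Load a molecular-function ontology from an OBO file
#'
#' Parses `[Term]` stanzas (fields `id`, `name`, `is_a`, `is_obsolete`) from
#' an OBO file into a directed acyclic graph of is_a edges.  Only is_a
#' edges are modelled: the level-1 parent mapping is a hierarchy climb, and
#' other relationship types (part_of, regulates) are out of scope.
#' Obsolete terms are skipped with a logged count.  The root is the unique
#' term with no is_a parent; level-1 terms are the root's direct children.
#'
#' No full-featured OBO parser ships with the package's R dependencies, so
#' a minimal stanza parser for this subset is implemented here.
#'
#' @param path path to the OBO file.
#' @return an object of class `ontology_dag`: a list with elements
#'   `terms` (data.frame `id`, `name`), `parents` (named list: term id ->
#'   character vector of direct is_a parents), `root` (term id), `level1`
#'   (character vector of level-1 term ids) and `n_obsolete`.
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # strip OBO trailing comments ("! ...") and whitespace
  lines <- trimws(sub("\\s*!.*$", "", lines))

  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0)
    stop("no [Term] stanzas found in OBO file: ", path, call. = FALSE)
  other_headers <- grep("^\\[", lines)
  ends <- vapply(stanza_starts, function(s) {
    nxt <- other_headers[other_headers > s]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }, integer(1))

  ids <- character(0); names_ <- character(0)
  parents <- list(); n_obsolete <- 0L
  for (k in seq_along(stanza_starts)) {
    block <- lines[seq(stanza_starts[k] + 1L, ends[k])]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- field("id")
    if (length(id) != 1 || !nzchar(id))
      stop("OBO [Term] stanza without a single id (stanza ", k, ")", call. = FALSE)
    if (any(tolower(field("is_obsolete")) == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    nm <- field("name")
    isa <- field("is_a")
    isa <- isa[nzchar(isa)]
    if (length(isa))
      isa <- vapply(strsplit(isa, "\\s+"), `[`, character(1), 1)  # drop inline names
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1] else id)
    parents[[id]] <- isa[nzchar(isa)]
  }
  if (anyDuplicated(ids))
    stop("duplicate term id(s) in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  ontology_dag(data.frame(id = ids, name = names_, stringsAsFactors = FALSE),
               parents, n_obsolete = n_obsolete)
}

#' Construct a validated ontology DAG
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param parents named list mapping each term id to the character vector of
#'   its direct is_a parents (empty for the root).
#' @param n_obsolete count of obsolete terms skipped during parsing.
#' @return an `ontology_dag` (see [load_ontology()]).
#' @export
ontology_dag <- function(terms, parents, n_obsolete = 0L) {
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)

  known <- unlist(parents, use.names = FALSE) %in% terms$id
  if (length(known) && !all(known))
    stop("is_a parent(s) reference unknown term(s): ",
         paste(unique(unlist(parents, use.names = FALSE)[!known]), collapse = ", "),
         call. = FALSE)

  edges <- do.call(rbind, lapply(terms$id, function(id) {
    p <- parents[[id]]
    if (length(p)) cbind(child = id, parent = p) else NULL
  }))
  g <- if (is.null(edges)) {
    igraph::make_empty_graph(directed = TRUE) + igraph::vertices(terms$id)
  } else {
    igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                  vertices = terms$id)
  }
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    cyc_lab <- apply(igraph::ends(g, cyc), 1, paste, collapse = " -> ")
    stop("ontology is_a graph contains a cycle (e.g. edge ",
         paste(cyc_lab, collapse = "; "), ")", call. = FALSE)
  }

  roots <- terms$id[vapply(parents, length, integer(1)) == 0]
  if (length(roots) == 0)
    stop("ontology has no root (every term has an is_a parent)", call. = FALSE)
  if (length(roots) > 1)
    stop("ontology has multiple roots: ", paste(roots, collapse = ", "),
         call. = FALSE)
  root <- roots[1]
  level1 <- terms$id[vapply(parents, function(p) root %in% p, logical(1))]

  structure(
    list(terms = terms, parents = parents, root = root, level1 = level1,
         n_obsolete = as.integer(n_obsolete)),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, root %s, %d level-1 terms, %d obsolete skipped\n",
              nrow(x$terms), x$root, length(x$level1), x$n_obsolete))
  invisible(x)
}

#' Map a term to its level-1 ancestors
#'
#' Climbs is_a edges from the term to the root and returns the set of
#' level-1 terms (direct children of the root) encountered; a level-1 term
#' maps to itself.  An empty set means the term is the root or is
#' disconnected from the root.
#'
#' @param term a term id present in the DAG.
#' @param dag an `ontology_dag`.
#' @return character vector of level-1 term ids (possibly empty).
#' @export
map_to_level1 <- function(term, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms$id)
    stop("unknown term id: ", term, call. = FALSE)
  # BFS over is_a ancestors, term included (level-1 maps to itself)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  intersect(dag$level1, seen)
}

#' Level-1 breakdown of terminal terms by Venn group
#'
#' Maps each submitted terminal term to its level-1 parent categories and
#' cross-tabulates against the terms' Venn taxonomic groups.  A terminal
#' with several level-1 parents contributes one count to each parent (so
#' the table total can exceed the number of mapped terminals).  A terminal
#' that is itself level-1 has no level-1 *parent* and is reported as
#' unmapped with reason `"is_level1"`; a terminal with no level-1 ancestor
#' at all is unmapped with reason `"disconnected"`.  "Terminal" status is
#' taken from the caller's list, not recomputed from DAG leaves.
#'
#' @param terminals data.frame with columns `trait_id` (term ids) and
#'   `venn_group` -- typically a subset of [assign_venn_groups()] output.
#' @param dag an `ontology_dag`.
#' @return an object of class `level1_breakdown`: a list with `table`
#'   (data.frame: `level1_id`, `level1_name`, one count column per Venn
#'   group, `total`), `n_mapped`, `n_unmapped`, `unmapped` (data.frame
#'   `trait_id`, `reason`), and `group_presence` (named list: level1 id ->
#'   Venn groups contributing at least one terminal).
#' @export
level1_breakdown <- function(terminals, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (anyDuplicated(terminals$trait_id))
    stop("duplicate terminal term(s): ",
         paste(unique(terminals$trait_id[duplicated(terminals$trait_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(terminals$venn_group), VENN_GROUPS)
  if (length(bad))
    stop("invalid Venn group label(s): ", paste(bad, collapse = ", "), call. = FALSE)

  counts <- matrix(0L, nrow = length(dag$level1), ncol = length(VENN_GROUPS),
                   dimnames = list(dag$level1, VENN_GROUPS))
  unmapped_id <- character(0); unmapped_reason <- character(0)
  n_mapped <- 0L
  for (i in seq_len(nrow(terminals))) {
    id <- terminals$trait_id[i]
    grp <- terminals$venn_group[i]
    if (id %in% dag$level1) {
      unmapped_id <- c(unmapped_id, id)
      unmapped_reason <- c(unmapped_reason, "is_level1")
      next
    }
    l1 <- map_to_level1(id, dag)
    if (length(l1) == 0) {
      unmapped_id <- c(unmapped_id, id)
      unmapped_reason <- c(unmapped_reason, "disconnected")
      next
    }
    n_mapped <- n_mapped + 1L
    counts[l1, grp] <- counts[l1, grp] + 1L
  }
  stopifnot(n_mapped + length(unmapped_id) == nrow(terminals))
  stopifnot(sum(counts) >= n_mapped)

  tab <- data.frame(
    level1_id = dag$level1,
    level1_name = dag$terms$name[match(dag$level1, dag$terms$id)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (g in VENN_GROUPS) tab[[g]] <- counts[, g]
  tab$total <- as.integer(rowSums(counts))
  presence <- lapply(dag$level1, function(l1) VENN_GROUPS[counts[l1, ] > 0])
  names(presence) <- dag$level1

  structure(
    list(table = tab, n_mapped = n_mapped, n_unmapped = length(unmapped_id),
         unmapped = data.frame(trait_id = unmapped_id, reason = unmapped_reason,
                               stringsAsFactors = FALSE),
         group_presence = presence),
    class = "level1_breakdown"
  )
}

#' @export
print.level1_breakdown <- function(x, ...) {
  cat(sprintf("level1_breakdown: %d mapped, %d unmapped (%.2f%% mapped)\n",
              x$n_mapped, x$n_unmapped, mapped_percentage(x)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Percentage of terminal terms mapped to a level-1 parent
#'
#' @param breakdown a `level1_breakdown`.
#' @return `100 * n_mapped / (n_mapped + n_unmapped)`, reported at 2
#'   decimals under the package's truncation display convention
#'   (see [report_precision()]): 1,871 of 1,924 reports as 97.24.
#' @export
mapped_percentage <- function(breakdown) {
  stopifnot(inherits(breakdown, "level1_breakdown"))
  total <- breakdown$n_mapped + breakdown$n_unmapped
  if (total == 0)
    stop("mapped percentage undefined: no terminals submitted", call. = FALSE)
  report_precision(100 * breakdown$n_mapped / total, 2)
}

#' Venn groups uniquely coding for each level-1 term
#'
#' A level-1 term is uniquely coded by a Venn group when every terminal
#' contributing to it belongs to that single group.
#'
#' @param breakdown a `level1_breakdown`.
#' @return named character vector: level1 id -> unique coding group, only
#'   for level-1 terms with exactly one contributing group.
#' @export
unique_coding_groups <- function(breakdown) {
  stopifnot(inherits(breakdown, "level1_breakdown"))
  single <- vapply(breakdown$group_presence, length, integer(1)) == 1L
  vapply(breakdown$group_presence[single], `[`, character(1), 1)
}
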