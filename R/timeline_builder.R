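#' Relative evolutionary age (nd) of tree leaves
#'
#' Node distance (nd) places every leaf of a rooted trait tree on a relative
#' age scale from 0 (most ancient, adjacent to the root) to 1 (most
#' derived).  For a leaf, let k be the number of internal nodes on its
#' root-to-leaf path, root included; then `nd = (k - 1) / (K - 1)` where K
#' is the maximum k over all leaves.  A star tree (K = 1) gives nd = 0 for
#' every leaf.  Branch lengths are ignored: nd counts cladogenic events,
#' not time, so it is invariant to any rescaling of the branches.
#'
#' @param tree a rooted `ape::phylo` tree whose tip labels are trait ids, or
#'   a path to a newick file read with [ape::read.tree()].  Basal
#'   polytomies are accepted; each polytomy contributes one node to the
#'   path count.
#' @return named numeric vector: trait id -> nd in [0, 1].
#' @export
node_distance <- function(tree) {
  if (is.character(tree) && length(tree) == 1) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo"))
    stop("tree must be an ape 'phylo' object or a newick file path", call. = FALSE)
  if (ape::Ntip(tree) < 2)
    stop("tree must have at least 2 leaves", call. = FALSE)
  # structural rootedness: every non-root node has exactly one parent.
  # (A basal polytomy is fine -- it is still a single root.)
  if (anyDuplicated(tree$edge[, 2]))
    stop("tree is not a rooted tree: node(s) with multiple parents", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)

  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L

  k <- vapply(seq_len(ntip), function(tip) {
    n <- 0L
    node <- parent[tip]
    while (node != 0L) {
      n <- n + 1L
      if (node == root) break
      node <- parent[node]
    }
    if (node != root)
      stop("leaf '", tree$tip.label[tip], "' does not reach the root", call. = FALSE)
    n
  }, integer(1))

  K <- max(k)
  nd <- if (K == 1L) rep(0, ntip) else (k - 1) / (K - 1)
  setNames(nd, tree$tip.label)
}

#' Build an evolutionary timeline
#'
#' Joins nd ages with Venn groups and per-superkingdom abundance totals
#' into a timeline: traits ordered from most ancient (nd = 0) to most
#' derived (nd = 1), with ties broken by trait id for determinism.  Traits
#' present in the assignments but absent from the nd map (i.e. not in the
#' tree) are dropped, with the count recorded in the `n_dropped` attribute.
#'
#' @param nd named numeric vector from [node_distance()].
#' @param assignments `venn_assignments` for the matrix traits.
#' @param matrix a [trait_matrix()].
#' @param metadata organism metadata.
#' @return a data.frame of class `timeline` with columns `trait_id`, `nd`,
#'   `venn_group`, `abundance_A`, `abundance_B`, `abundance_E`, sorted by
#'   ascending nd; attribute `n_dropped` counts matrix traits missing from
#'   the tree.
#' @export
build_timeline <- function(nd, assignments, matrix, metadata) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (!identical(assignments$trait_id, trait_ids(matrix)))
    stop("assignments do not match the matrix traits", call. = FALSE)
  meta <- match_metadata(matrix, metadata)
  ab <- unclass(matrix)

  keep <- assignments$trait_id %in% names(nd)
  n_dropped <- sum(!keep)
  ids <- assignments$trait_id[keep]

  by_sk <- vapply(SK_LEVELS, function(sk) {
    rowSums(ab[ids, meta$superkingdom == sk, drop = FALSE])
  }, numeric(length(ids)))
  if (length(ids) == 1L) by_sk <- matrix(by_sk, nrow = 1, dimnames = list(NULL, SK_LEVELS))

  out <- data.frame(
    trait_id = ids,
    nd = unname(nd[ids]),
    venn_group = assignments$venn_group[keep],
    abundance_A = as.integer(by_sk[, "A"]),
    abundance_B = as.integer(by_sk[, "B"]),
    abundance_E = as.integer(by_sk[, "E"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$nd, out$trait_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("timeline", "data.frame")
  out
}

#' Most ancient trait per Venn group
#'
#' For each Venn group present in the timeline, the trait with the minimum
#' nd; ties are broken by maximum total abundance (summed over
#' superkingdoms), remaining ties by trait id.
#'
#' @param entries a `timeline` data.frame from [build_timeline()].
#' @return named character vector: Venn group -> trait id, covering only
#'   groups with at least one entry.
#' @export
most_ancient_per_group <- function(entries) {
  total <- entries$abundance_A + entries$abundance_B + entries$abundance_E
  groups <- intersect(VENN_GROUPS, unique(entries$venn_group))
  vapply(setNames(groups, groups), function(g) {
    sub <- entries[entries$venn_group == g, , drop = FALSE]
    tot <- total[entries$venn_group == g]
    ord <- order(sub$nd, -tot, sub$trait_id)
    sub$trait_id[ord[1]]
  }, character(1))
}
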