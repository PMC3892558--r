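#' Assign traits to Venn taxonomic groups
#'
#' A trait is "present" in a superkingdom when at least one organism of that
#' superkingdom carries it (abundance >= 1); the Venn group is the
#' concatenation of the present superkingdom letters in fixed A < B < E
#' order, giving the seven mutually exclusive groups
#' A, B, E, AB, AE, BE, ABE.
#'
#' @param matrix a [trait_matrix()]; traits with zero occurrence everywhere
#'   must have been removed upstream (see [filter_dataset()]).
#' @param metadata organism metadata covering every matrix organism; each of
#'   the three superkingdoms must have at least one organism, otherwise the
#'   groups are undefined.
#' @return a data.frame of class `venn_assignments` with columns `trait_id`,
#'   `present_A`, `present_B`, `present_E` (logical) and `venn_group`.
#' @export
assign_venn_groups <- function(matrix, metadata) {
  stopifnot(inherits(matrix, "trait_matrix"))
  meta <- match_metadata(matrix, metadata)
  sk_sizes <- table(factor(meta$superkingdom, levels = SK_LEVELS))
  if (any(sk_sizes == 0))
    stop("superkingdom(s) with zero organisms: ",
         paste(names(sk_sizes)[sk_sizes == 0], collapse = ", "),
         " -- Venn groups are undefined", call. = FALSE)

  occ <- occurrence(matrix)
  present <- vapply(SK_LEVELS, function(sk) {
    rowSums(occ[, meta$superkingdom == sk, drop = FALSE]) > 0
  }, logical(nrow(matrix)))
  if (nrow(matrix) == 1L) present <- matrix(present, nrow = 1, dimnames = list(NULL, SK_LEVELS))

  if (any(rowSums(present) == 0))
    stop("trait(s) with zero occurrence in every superkingdom: ",
         paste(head(trait_ids(matrix)[rowSums(present) == 0], 5), collapse = ", "),
         " -- remove them with filter_dataset() first", call. = FALSE)

  group <- apply(present, 1, function(p) paste(SK_LEVELS[p], collapse = ""))
  out <- data.frame(
    trait_id = trait_ids(matrix),
    present_A = present[, "A"],
    present_B = present[, "B"],
    present_E = present[, "E"],
    venn_group = group,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("venn_assignments", "data.frame")
  out
}

# align metadata rows to matrix organisms, failing loudly on gaps
match_metadata <- function(matrix, metadata) {
  idx <- match(organism_ids(matrix), metadata$organism_id)
  if (anyNA(idx))
    stop("organism(s) in matrix but absent from metadata: ",
         paste(organism_ids(matrix)[is.na(idx)], collapse = ", "), call. = FALSE)
  metadata[idx, , drop = FALSE]
}

#' Tabulate Venn group sizes
#'
#' @param assignments a `venn_assignments` data.frame from
#'   [assign_venn_groups()].
#' @return an object of class `venn_counts`: a named integer vector over the
#'   seven groups (in A, B, E, AB, AE, BE, ABE order) with attribute `total`.
#'   The seven counts always sum to the total number of assigned traits.
#' @export
venn_counts <- function(assignments) {
  if (anyDuplicated(assignments$trait_id))
    stop("duplicate trait id(s) in assignments: ",
         paste(unique(assignments$trait_id[duplicated(assignments$trait_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(assignments$venn_group), VENN_GROUPS)
  if (length(bad))
    stop("invalid Venn group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(assignments$venn_group, levels = VENN_GROUPS))
  out <- setNames(as.integer(counts), VENN_GROUPS)
  stopifnot(sum(out) == nrow(assignments))
  structure(out, total = nrow(assignments), class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn taxonomic group census (total", attr(x, "total"), "traits):\n")
  for (g in VENN_GROUPS) {
    cat(sprintf("  %-3s %6d  (%d%%)\n", g, x[[g]],
                percentage_share(x[[g]], attr(x, "total"))))
  }
  invisible(x)
}

#' Percentage share of a count
#'
#' Returns `100 * count / total`, rounded to the nearest integer for
#' display-style reporting of group shares.
#'
#' @param count non-negative count, at most `total`.
#' @param total positive total.
#' @param digits rounding digits (default 0, i.e. whole percent).
#' @return the percentage share.
#' @examples
#' percentage_share(786, 1733)  # 45
#' @export
percentage_share <- function(count, total, digits = 0) {
  if (length(total) != 1 || is.na(total) || total <= 0)
    stop("percentage share undefined: total must be a positive count", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]", call. = FALSE)
  round(100 * count / total, digits = digits)
}
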