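#' Per-organism abundance totals by Venn group
#'
#' Older traits have had more time to duplicate in genomes, so the total
#' abundance an organism devotes to the traits of a Venn group is a proxy
#' for the group's relative age.  For every organism this sums abundance
#' over the traits assigned to each of the seven groups; the seven totals
#' always sum to the organism's total abundance (column sum).
#'
#' @param matrix a [trait_matrix()].
#' @param assignments `venn_assignments` computed on this matrix.
#' @param metadata organism metadata.
#' @return a data.frame of class `group_abundance` with columns
#'   `organism_id`, `superkingdom`, then `abundance_A` ... `abundance_ABE`
#'   (canonical group order) and `abundance_total`.
#' @export
group_abundance <- function(matrix, assignments, metadata) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (!identical(assignments$trait_id, trait_ids(matrix)))
    stop("assignments do not match the matrix traits", call. = FALSE)
  meta <- match_metadata(matrix, metadata)
  ab <- unclass(matrix)
  by_group <- vapply(VENN_GROUPS, function(g) {
    colSums(ab[assignments$venn_group == g, , drop = FALSE])
  }, numeric(ncol(ab)))
  if (ncol(ab) == 1L) by_group <- matrix(by_group, nrow = 1, dimnames = list(NULL, VENN_GROUPS))
  totals <- colSums(ab)
  stopifnot(all(rowSums(by_group) == totals))
  out <- data.frame(
    organism_id = organism_ids(matrix),
    superkingdom = meta$superkingdom,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (g in VENN_GROUPS) out[[paste0("abundance_", g)]] <- as.integer(by_group[, g])
  out$abundance_total <- as.integer(totals)
  class(out) <- c("group_abundance", "data.frame")
  out
}

#' Five-number summary of log-abundance per group and superkingdom
#'
#' Summarises the distribution of `log10(x + 1)`-transformed group totals
#' over the organisms of one superkingdom (one boxplot panel).  The +1
#' offset keeps organisms with zero abundance in a group on the scale
#' instead of dropping them.  Outliers follow the Tukey 1.5 x IQR whisker
#' rule on the transformed scale, and the organisms attaining the maximum
#' and minimum are named.
#'
#' @param profiles a `group_abundance` data.frame.
#' @param group a Venn group label.
#' @param superkingdom superkingdom label.
#' @return a one-row data.frame: `group`, `superkingdom`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max` (log10 scale), `outlier_ids` (comma-joined, ""
#'   when none), `argmax_id`, `argmin_id`.  Empty superkingdom returns an
#'   `n = 0` sentinel row.
#' @export
summarize_abundance <- function(profiles, group, superkingdom) {
  group <- match.arg(group, VENN_GROUPS)
  sk <- normalize_superkingdom(superkingdom)
  sub <- profiles[profiles$superkingdom == sk, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(group = group, superkingdom = sk, n = 0L,
                      min = NA_real_, q1 = NA_real_, median = NA_real_,
                      q3 = NA_real_, max = NA_real_, outlier_ids = "",
                      argmax_id = NA_character_, argmin_id = NA_character_,
                      stringsAsFactors = FALSE))
  }
  raw <- sub[[paste0("abundance_", group)]]
  x <- log10(raw + 1)
  qs <- quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  iqr <- qs[4] - qs[2]
  lo <- qs[2] - 1.5 * iqr
  hi <- qs[4] + 1.5 * iqr
  out_ids <- sub$organism_id[x < lo | x > hi]
  data.frame(
    group = group, superkingdom = sk, n = length(x),
    min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
    outlier_ids = paste(out_ids, collapse = ","),
    argmax_id = sub$organism_id[which.max(x)],
    argmin_id = sub$organism_id[which.min(x)],
    stringsAsFactors = FALSE
  )
}

#' All abundance summaries (one per boxplot panel)
#'
#' One row per (Venn group, member superkingdom) pair: only the
#' superkingdoms named in a group's label are reported for that group.
#'
#' @param profiles a `group_abundance` data.frame.
#' @return a data.frame of stacked [summarize_abundance()] rows.
#' @export
abundance_summary_table <- function(profiles) {
  rows <- list()
  for (g in VENN_GROUPS) {
    for (sk in SK_LEVELS) {
      if (grepl(sk, g, fixed = TRUE))
        rows[[length(rows) + 1L]] <- summarize_abundance(profiles, g, sk)
    }
  }
  do.call(rbind, rows)
}
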