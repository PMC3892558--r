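#' f-value: spread of a trait in a superkingdom
#'
#' The f-value of a trait in a superkingdom is the number of organisms of
#' that superkingdom harbouring the trait (abundance >= 1) divided by the
#' total number of organisms of that superkingdom.  It ranges from 0
#' (absent) to 1 (omnipresent).  Full precision is kept internally; report
#' output truncates to 3 decimals (see [report_precision()]).
#'
#' @param trait trait identifier present in the matrix.
#' @param superkingdom superkingdom label (long or short form).
#' @param matrix a [trait_matrix()].
#' @param metadata organism metadata covering the matrix organisms.
#' @return the f-value, a fraction in [0, 1].
#' @export
f_value <- function(trait, superkingdom, matrix, metadata) {
  stopifnot(inherits(matrix, "trait_matrix"))
  sk <- normalize_superkingdom(superkingdom)
  if (!trait %in% trait_ids(matrix))
    stop("unknown trait id: ", trait, call. = FALSE)
  meta <- match_metadata(matrix, metadata)
  in_sk <- meta$superkingdom == sk
  if (!any(in_sk))
    stop("f-value undefined: superkingdom ", sk, " has zero organisms", call. = FALSE)
  sum(unclass(matrix)[trait, in_sk] >= 1L) / sum(in_sk)
}

#' Display precision for fractions and percentages
#'
#' Truncates toward zero at the given number of decimals.  This is the
#' package's display convention for per-trait f-values (3 decimals) and
#' mapped percentages (2 decimals): truncation never overstates the spread
#' of a scarce trait -- a trait found in 1 of 652 organisms reports as
#' f = 0.001, not 0.002.  All decisions (thresholds, calls) use full
#' precision; truncation applies only to reported values.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return `x` truncated toward zero at `digits` decimals.
#' @examples
#' report_precision(1 / 652, 3)   # 0.001
#' @export
report_precision <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

#' Per-trait spread profiles
#'
#' Computes, for every trait, the f-value in each superkingdom named in its
#' Venn group label; f is reported as NA for superkingdoms outside the
#' group label (where it is 0 by definition of the group).
#'
#' @param matrix a [trait_matrix()].
#' @param metadata organism metadata.
#' @param assignments Venn assignments computed on this matrix with
#'   [assign_venn_groups()]; computed on the fly when omitted.
#' @return a data.frame of class `spread_profiles` with columns `trait_id`,
#'   `venn_group`, `f_A`, `f_B`, `f_E` (NA when the superkingdom is not in
#'   the group label).
#' @export
spread_profiles <- function(matrix, metadata, assignments = NULL) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (is.null(assignments)) assignments <- assign_venn_groups(matrix, metadata)
  if (!identical(assignments$trait_id, trait_ids(matrix)))
    stop("assignments do not match the matrix traits", call. = FALSE)
  meta <- match_metadata(matrix, metadata)
  occ <- occurrence(matrix)

  f <- vapply(SK_LEVELS, function(sk) {
    in_sk <- meta$superkingdom == sk
    if (!any(in_sk)) return(rep(NA_real_, nrow(matrix)))
    rowSums(occ[, in_sk, drop = FALSE]) / sum(in_sk)
  }, numeric(nrow(matrix)))
  if (nrow(matrix) == 1L) f <- matrix(f, nrow = 1, dimnames = list(NULL, SK_LEVELS))

  # mask superkingdoms outside the group label (f is 0 there by construction)
  in_group <- vapply(SK_LEVELS, function(sk) grepl(sk, assignments$venn_group, fixed = TRUE),
                     logical(nrow(matrix)))
  if (nrow(matrix) == 1L) in_group <- matrix(in_group, nrow = 1, dimnames = list(NULL, SK_LEVELS))
  f[!in_group] <- NA_real_

  out <- data.frame(
    trait_id = assignments$trait_id,
    venn_group = assignments$venn_group,
    f_A = f[, "A"], f_B = f[, "B"], f_E = f[, "E"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("spread_profiles", "data.frame")
  out
}

#' Summarise f-value distributions per Venn group and superkingdom
#'
#' Mirrors one boxplot panel: the median and quartiles of the f-values of
#' the group's traits in one superkingdom, plus the count of widespread
#' traits with f strictly above the tail threshold.  Quartiles use the
#' linear-interpolation convention (R quantile type 7), held fixed for
#' reproducibility.
#'
#' @param profiles a `spread_profiles` data.frame.
#' @param group a Venn group label whose letters include `superkingdom`.
#' @param superkingdom superkingdom label.
#' @param tail_threshold threshold for the widespread tail count
#'   (strict `f > tail_threshold`), default 0.8.
#' @return a one-row data.frame with columns `group`, `superkingdom`,
#'   `n_traits`, `q1`, `median_f`, `q3`, `n_tail`.  When the group is empty
#'   an empty-summary sentinel row is returned (`n_traits = 0`, NA
#'   statistics) rather than an error.
#' @export
summarize_spread <- function(profiles, group, superkingdom, tail_threshold = 0.8) {
  sk <- normalize_superkingdom(superkingdom)
  group <- match.arg(group, VENN_GROUPS)
  if (!grepl(sk, group, fixed = TRUE))
    stop("superkingdom ", sk, " is not part of group ", group, call. = FALSE)
  fs <- profiles[profiles$venn_group == group, paste0("f_", sk)]
  fs <- fs[!is.na(fs)]
  if (length(fs) == 0) {
    return(data.frame(group = group, superkingdom = sk, n_traits = 0L,
                      q1 = NA_real_, median_f = NA_real_, q3 = NA_real_,
                      n_tail = 0L, stringsAsFactors = FALSE))
  }
  qs <- quantile(fs, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(
    group = group, superkingdom = sk, n_traits = length(fs),
    q1 = qs[1], median_f = qs[2], q3 = qs[3],
    n_tail = sum(fs > tail_threshold),
    stringsAsFactors = FALSE
  )
}

#' All spread summaries (one per boxplot panel)
#'
#' @param profiles a `spread_profiles` data.frame.
#' @param tail_threshold see [summarize_spread()].
#' @return a data.frame with one row per (Venn group, member superkingdom)
#'   pair, in canonical group order.
#' @export
spread_summary_table <- function(profiles, tail_threshold = 0.8) {
  rows <- list()
  for (g in VENN_GROUPS) {
    for (sk in SK_LEVELS) {
      if (grepl(sk, g, fixed = TRUE))
        rows[[length(rows) + 1L]] <- summarize_spread(profiles, g, sk, tail_threshold)
    }
  }
  do.call(rbind, rows)
}

#' Universal trait core
#'
#' Traits present in every retained organism (equivalently, f = 1 in all
#' three superkingdoms): the candidate trait core of the urancestor.
#'
#' @param matrix a [trait_matrix()].
#' @param metadata organism metadata (unused beyond validation; universality
#'   over all organisms implies f = 1 per superkingdom).
#' @return character vector of trait ids.
#' @export
universal_core <- function(matrix, metadata = NULL) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (!is.null(metadata)) match_metadata(matrix, metadata)
  trait_ids(matrix)[rowSums(occurrence(matrix)) == ncol(matrix)]
}

#' Near-universal traits
#'
#' Traits whose overall spread -- occurrences across all retained organisms
#' divided by the number of retained organisms -- strictly exceeds the
#' threshold.  Near-universal presence suggests reductive loss in the small
#' complement of organisms lacking the trait.
#'
#' @param matrix a [trait_matrix()].
#' @param threshold overall-f threshold, strict `>`; default 0.90.
#' @return character vector of trait ids.
#' @export
near_universal <- function(matrix, threshold = 0.90) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0,1]", call. = FALSE)
  f_overall <- rowSums(occurrence(matrix)) / ncol(matrix)
  trait_ids(matrix)[f_overall > threshold]
}
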