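#' Call directional HGT candidates by the f-difference rule
#'
#' For traits in the two-superkingdom Venn groups (AB, AE, BE), an absolute
#' difference between the two superkingdoms' f-values strictly greater than
#' the threshold marks the trait as a probable horizontal gene transfer: a
#' trait nearly ubiquitous in one superkingdom but scarce in the other is
#' more parsimoniously explained by transfer than by vertical descent.  The
#' donor is the superkingdom with the larger f-value, the recipient the
#' smaller.  `f_former` and `f_latter` refer to the first and second letter
#' of the group label (e.g. A then B in AB), and
#' `f_difference = f_former - f_latter` is signed.  Decisions are made on
#' full-precision f-values; rounding applies only to display.
#'
#' @param profiles a `spread_profiles` data.frame from [spread_profiles()].
#'   One- and three-superkingdom traits present in `profiles` are ignored;
#'   passing a single-row profile from such a group is an error.
#' @param threshold f-difference threshold, strict `>`; default 0.6.
#' @return a data.frame of class `hgt_calls` with one row per called trait:
#'   `trait_id`, `group`, `f_former`, `f_latter`, `f_difference`, `donor`,
#'   `recipient`.  Zero rows when nothing is called.
#' @export
detect_hgt <- function(profiles, threshold = 0.6) {
  if (is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0,1]", call. = FALSE)
  two_sk <- c("AB", "AE", "BE")
  if (nrow(profiles) > 0 && all(!profiles$venn_group %in% two_sk))
    stop("f-difference rule is not applicable: no trait belongs to a ",
         "two-superkingdom group (AB, AE, BE)", call. = FALSE)
  cand <- profiles[profiles$venn_group %in% two_sk, , drop = FALSE]

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$venn_group[i]
    former <- substr(g, 1, 1)
    latter <- substr(g, 2, 2)
    f_former <- cand[[paste0("f_", former)]][i]
    f_latter <- cand[[paste0("f_", latter)]][i]
    diff <- f_former - f_latter
    # strict >, with a 1e-9 guard so binary representation error in the
    # subtraction cannot promote an exact-boundary difference to a call
    if (abs(diff) > threshold + 1e-9) {
      donor <- if (diff > 0) former else latter
      recipient <- if (diff > 0) latter else former
      rows[[i]] <- data.frame(
        trait_id = cand$trait_id[i], group = g,
        f_former = f_former, f_latter = f_latter, f_difference = diff,
        donor = donor, recipient = recipient,
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait_id = character(), group = character(),
               f_former = numeric(), f_latter = numeric(),
               f_difference = numeric(), donor = character(),
               recipient = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hgt_calls", "data.frame")
  out
}

#' Tally horizontal flux per Venn group and direction
#'
#' Resolves HGT calls into per-group directional counts plus the residual
#' count of group traits not called -- traits whose balanced spread is
#' consistent with vertical inheritance (or independent gain).  For each
#' two-superkingdom group, the two directional counts and the vertical
#' residual always sum to the group size.
#'
#' @param calls an `hgt_calls` data.frame from [detect_hgt()].
#' @param assignments the `venn_assignments` the calls derive from.
#' @return a data.frame of class `flux_tally` with one row per
#'   two-superkingdom group: `group`, `n_traits`,
#'   `n_forward` (donor = first letter), `n_reverse` (donor = second
#'   letter), `forward`, `reverse` (direction labels like `"A->B"`),
#'   `n_vertical`.
#' @export
tally_flux <- function(calls, assignments) {
  grp <- setNames(assignments$venn_group, assignments$trait_id)
  if (nrow(calls) > 0) {
    stated <- grp[calls$trait_id]
    bad <- is.na(stated) | stated != calls$group
    if (any(bad))
      stop("call(s) inconsistent with assignments for trait(s): ",
           paste(calls$trait_id[bad], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(c("AB", "AE", "BE"), function(g) {
    former <- substr(g, 1, 1)
    latter <- substr(g, 2, 2)
    size <- sum(assignments$venn_group == g)
    in_g <- calls[calls$group == g, , drop = FALSE]
    n_fwd <- sum(in_g$donor == former)
    n_rev <- sum(in_g$donor == latter)
    data.frame(
      group = g, n_traits = size,
      n_forward = n_fwd, n_reverse = n_rev,
      forward = paste0(former, "->", latter),
      reverse = paste0(latter, "->", former),
      n_vertical = size - n_fwd - n_rev,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$n_forward + out$n_reverse + out$n_vertical == out$n_traits))
  class(out) <- c("flux_tally", "data.frame")
  out
}
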