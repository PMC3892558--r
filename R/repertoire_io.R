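#' Construct a trait matrix
#'
#' A trait matrix records the genomic abundance (redundant copy count) of
#' each trait in each organism.  Occurrence (presence/absence) is always
#' derived as `abundance >= 1` and never stored separately.
#'
#' @param abundance integer matrix, rows = traits, columns = organisms, with
#'   both dimnames set.  All cells must be non-negative integers.
#' @param id_scheme one of `"SCOP_FSF"`, `"GO_TERM"`, `"GENERIC"`; controls
#'   syntactic validation of trait identifiers.
#' @return an object of class `trait_matrix` (an integer matrix with an
#'   `id_scheme` attribute).
#' @seealso [load_trait_matrix()], [occurrence()]
#' @export
trait_matrix <- function(abundance, id_scheme = c("GENERIC", "SCOP_FSF", "GO_TERM")) {
  id_scheme <- match.arg(id_scheme)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have trait ids as rownames and organism ids as colnames",
         call. = FALSE)
  validate_trait_ids(rownames(abundance), id_scheme)
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate trait id(s): ",
         paste(unique(rownames(abundance)[duplicated(rownames(abundance))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate organism id(s): ",
         paste(unique(colnames(abundance)[duplicated(colnames(abundance))]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(abundance)))
    stop("abundance matrix contains missing values", call. = FALSE)
  if (any(abundance < 0) || any(abundance != round(abundance)))
    stop("abundance values must be non-negative integers", call. = FALSE)
  storage.mode(abundance) <- "integer"
  structure(abundance, id_scheme = id_scheme, class = c("trait_matrix", "matrix", "array"))
}

#' @rdname trait_matrix
#' @param x a `trait_matrix`.
#' @export
trait_ids <- function(x) rownames(x)

#' @rdname trait_matrix
#' @export
organism_ids <- function(x) colnames(x)

#' Derived occurrence (presence/absence) view
#'
#' @param x a `trait_matrix`.
#' @return logical matrix of the same shape: `TRUE` where abundance >= 1.
#' @export
occurrence <- function(x) {
  unclass(x) >= 1L
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d traits x %d organisms (id scheme %s)\n",
              nrow(x), ncol(x), attr(x, "id_scheme")))
  cat(sprintf("  total abundance %d, occupied cells %d (%.1f%%)\n",
              sum(x), sum(x >= 1L), 100 * mean(x >= 1L)))
  invisible(x)
}

# id syntax per scheme; GENERIC only forbids empty/whitespace ids
validate_trait_ids <- function(ids, id_scheme) {
  if (any(!nzchar(trimws(ids))))
    stop("empty trait id", call. = FALSE)
  pattern <- switch(id_scheme,
    SCOP_FSF = "^[a-z]\\.[0-9]+\\.[0-9]+$",   # e.g. c.37.1: class.fold.FSF
    GO_TERM  = "^GO:[0-9]{7}$",               # e.g. GO:0008658
    GENERIC  = NULL
  )
  if (!is.null(pattern)) {
    bad <- ids[!grepl(pattern, ids)]
    if (length(bad))
      stop("trait id(s) do not match the ", id_scheme, " scheme: ",
           paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
           call. = FALSE)
  }
  invisible(ids)
}

#' Read a trait matrix from a TSV file
#'
#' The expected layout is a UTF-8 tab-separated table whose first column
#' (header `trait_id`) holds trait identifiers and whose remaining column
#' headers are organism identifiers; cells are base-10 non-negative
#' integer abundance counts.
#'
#' @param path path to the TSV file.
#' @param id_scheme trait identifier scheme, see [trait_matrix()].
#' @return a [trait_matrix()].
#' @export
load_trait_matrix <- function(path, id_scheme = c("GENERIC", "SCOP_FSF", "GO_TERM")) {
  id_scheme <- match.arg(id_scheme)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2)
    stop("trait matrix file needs a trait_id column plus at least one organism column: ",
         path, call. = FALSE)
  ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "malformed abundance cell at trait '%s', organism '%s' (value '%s'): must be a non-negative integer",
      ids[bad[1, 1]], colnames(cells)[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]),
      call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(cells))
  trait_matrix(num, id_scheme = id_scheme)
}

#' Write a trait matrix to a TSV file
#'
#' Inverse of [load_trait_matrix()]: `load(write(x))` reproduces `x` exactly.
#'
#' @param x a [trait_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(x, path) {
  df <- data.frame(trait_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read organism metadata
#'
#' Metadata is a TSV with header columns `organism_id`, `superkingdom`,
#' `lifestyle` and `annotation_coverage`.  Superkingdoms may be given in
#' long or short form (case-insensitive) and are normalised to A/B/E.
#' `annotation_coverage` is the fraction of gene products annotated to
#' ontology terms; it may be empty/NA when unknown (e.g. for structure
#' datasets, where no such coverage notion applies).
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `organism_id`, `superkingdom`
#'   (one of "A","B","E"), `lifestyle` (one of "free_living", "parasitic",
#'   "unknown") and `annotation_coverage` (numeric in [0,1] or NA).
#' @export
load_organism_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  required <- c("organism_id", "superkingdom", "lifestyle", "annotation_coverage")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  organism_metadata(
    organism_id = df$organism_id,
    superkingdom = df$superkingdom,
    lifestyle = df$lifestyle,
    annotation_coverage = suppressWarnings(as.numeric(df$annotation_coverage))
  )
}

#' Construct validated organism metadata
#'
#' @param organism_id character vector of unique organism identifiers.
#' @param superkingdom superkingdom labels (long or short form).
#' @param lifestyle `"free_living"`, `"parasitic"` or `"unknown"`; defaults
#'   to `"free_living"`.
#' @param annotation_coverage numeric in [0,1] or NA; defaults to NA.
#' @return validated metadata data.frame (see [load_organism_metadata()]).
#' @export
organism_metadata <- function(organism_id, superkingdom,
                              lifestyle = "free_living",
                              annotation_coverage = NA_real_) {
  organism_id <- as.character(organism_id)
  if (anyDuplicated(organism_id))
    stop("duplicate organism id(s) in metadata: ",
         paste(unique(organism_id[duplicated(organism_id)]), collapse = ", "),
         call. = FALSE)
  sk <- normalize_superkingdom(superkingdom)
  lifestyle <- rep_len(as.character(lifestyle), length(organism_id))
  ok_life <- lifestyle %in% c("free_living", "parasitic", "unknown")
  if (!all(ok_life))
    stop("invalid lifestyle value(s): ",
         paste(unique(lifestyle[!ok_life]), collapse = ", "),
         " (expected free_living/parasitic/unknown)", call. = FALSE)
  cov <- rep_len(as.numeric(annotation_coverage), length(organism_id))
  bad_cov <- !is.na(cov) & (cov < 0 | cov > 1)
  if (any(bad_cov))
    stop("annotation_coverage outside [0,1] for organism(s): ",
         paste(organism_id[bad_cov], collapse = ", "), call. = FALSE)
  data.frame(
    organism_id = organism_id,
    superkingdom = sk,
    lifestyle = lifestyle,
    annotation_coverage = cov,
    stringsAsFactors = FALSE
  )
}

#' Read a trait exclusion list
#'
#' Plain text, one trait id per line; `#` starts a comment, blank lines are
#' ignored.
#'
#' @param path path to the exclusion-list file.
#' @return character vector of unique trait ids.
#' @export
load_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Dataset filtering configuration
#'
#' Collects the thresholds used across the pipeline: annotation-coverage
#' threshold for retaining organisms (applied inclusively: an organism at
#' exactly the threshold is kept), the free-living-only flag, the trait
#' exclusion list, the f-difference threshold for HGT calls, the f tail
#' threshold used in spread summaries, and the near-universal f threshold.
#'
#' @param coverage_threshold minimum annotation coverage, default 0.5.
#' @param free_living_only if TRUE, keep only organisms with lifestyle
#'   `free_living`.
#' @param exclusion_list character vector of trait ids to remove.
#' @param hgt_threshold f-difference threshold for HGT calls (strict >),
#'   default 0.6.
#' @param tail_threshold f threshold for "widespread" tail counts (strict >),
#'   default 0.8.
#' @param near_universal_threshold overall-f threshold for near-universal
#'   traits (strict >), default 0.90.
#' @return an object of class `dataset_config`.
#' @export
dataset_config <- function(coverage_threshold = 0.5,
                           free_living_only = FALSE,
                           exclusion_list = character(),
                           hgt_threshold = 0.6,
                           tail_threshold = 0.8,
                           near_universal_threshold = 0.90) {
  thr <- c(coverage = coverage_threshold, hgt = hgt_threshold,
           tail = tail_threshold, near_universal = near_universal_threshold)
  if (any(is.na(thr)) || any(thr < 0) || any(thr > 1))
    stop("all thresholds must lie in [0,1]", call. = FALSE)
  structure(
    list(
      coverage_threshold = coverage_threshold,
      free_living_only = isTRUE(free_living_only),
      exclusion_list = unique(as.character(exclusion_list)),
      hgt_threshold = hgt_threshold,
      tail_threshold = tail_threshold,
      near_universal_threshold = near_universal_threshold
    ),
    class = "dataset_config"
  )
}

#' @export
print.dataset_config <- function(x, ...) {
  cat("dataset_config:\n")
  cat(sprintf("  coverage_threshold: %g (inclusive)\n", x$coverage_threshold))
  cat(sprintf("  free_living_only:   %s\n", x$free_living_only))
  cat(sprintf("  exclusion_list:     %d trait id(s)\n", length(x$exclusion_list)))
  cat(sprintf("  hgt_threshold:      %g\n", x$hgt_threshold))
  cat(sprintf("  tail_threshold:     %g\n", x$tail_threshold))
  cat(sprintf("  near_universal:     %g\n", x$near_universal_threshold))
  invisible(x)
}

#' Filter a dataset by organism quality and trait exclusion rules
#'
#' Applies, in order: (1) drop organisms whose annotation coverage is known
#' and below the coverage threshold (comparison is inclusive: coverage equal
#' to the threshold is retained; unknown/NA coverage is not penalised);
#' (2) if `free_living_only`, drop organisms whose lifestyle is not
#' `free_living`; (3) drop traits on the exclusion list; (4) drop traits
#' left with zero occurrence over the retained organisms.  Counts of each
#' removal class are attached to the result as the `filter_report`
#' attribute, and the identity
#' `retained = input - exclusion_hits - zero_occurrence` always holds.
#'
#' @param matrix a [trait_matrix()].
#' @param metadata organism metadata covering every matrix organism.
#' @param config a [dataset_config()].
#' @return the filtered `trait_matrix`, with attribute `filter_report`
#'   (a list with elements `n_traits_in`, `n_excluded`, `n_zero_occurrence`,
#'   `n_traits_out`, `n_organisms_in`, `n_dropped_coverage`,
#'   `n_dropped_lifestyle`, `n_organisms_out`).
#' @export
filter_dataset <- function(matrix, metadata, config = dataset_config()) {
  stopifnot(inherits(matrix, "trait_matrix"))
  absent <- setdiff(organism_ids(matrix), metadata$organism_id)
  if (length(absent))
    stop("organism(s) in matrix but absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  meta <- metadata[match(organism_ids(matrix), metadata$organism_id), ]

  keep_cov <- is.na(meta$annotation_coverage) |
    meta$annotation_coverage >= config$coverage_threshold
  keep_life <- if (config$free_living_only) meta$lifestyle == "free_living" else TRUE
  keep_org <- keep_cov & keep_life

  n_dropped_coverage <- sum(!keep_cov)
  # lifestyle drops counted among organisms that passed the coverage filter,
  # so the two counts partition the dropped set
  n_dropped_lifestyle <- sum(keep_cov & !(keep_org))

  kept <- unclass(matrix)[, keep_org, drop = FALSE]

  excl_hit <- rownames(kept) %in% config$exclusion_list
  kept <- kept[!excl_hit, , drop = FALSE]
  zero_occ <- rowSums(kept >= 1L) == 0L
  kept <- kept[!zero_occ, , drop = FALSE]

  report <- list(
    n_traits_in = nrow(matrix),
    n_excluded = sum(excl_hit),
    n_zero_occurrence = sum(zero_occ),
    n_traits_out = nrow(kept),
    n_organisms_in = ncol(matrix),
    n_dropped_coverage = n_dropped_coverage,
    n_dropped_lifestyle = n_dropped_lifestyle,
    n_organisms_out = ncol(kept)
  )
  stopifnot(report$n_traits_out ==
              report$n_traits_in - report$n_excluded - report$n_zero_occurrence)

  out <- trait_matrix(kept, id_scheme = attr(matrix, "id_scheme"))
  attr(out, "filter_report") <- report
  out
}

#' Write a run manifest echoing the applied configuration
#'
#' Records the configuration, input digests and package version as JSON for
#' provenance.
#'
#' @param config a [dataset_config()].
#' @param path output JSON path.
#' @param inputs named character vector of input file paths to digest
#'   (md5), may be empty.
#' @param seed optional integer seed used for any randomness.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(config, path, inputs = character(), seed = NULL) {
  digests <- if (length(inputs)) {
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  } else NULL
  manifest <- list(
    package = "traitvenn",
    version = as.character(utils::packageVersion("traitvenn")),
    config = unclass(config),
    input_md5 = as.list(digests),
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
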