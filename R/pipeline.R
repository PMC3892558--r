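#' Run the full comparative pipeline
#'
#' Executes all applicable stages in fixed order -- filter, Venn census,
#' spread analysis, HGT detection, abundance summaries, ontology mapping,
#' timelines -- writing each stage's outputs to `out_dir` before the next
#' stage runs, and finishing with a machine-readable JSON report and a run
#' manifest.  Ontology and tree inputs are optional: stages needing them
#' are skipped with a notice in the report.  Cross-module conservation
#' identities (Venn counts sum to total; flux counts sum to group sizes;
#' per-organism group abundances sum to column totals) are audited
#' automatically and any violation aborts the run.
#'
#' @param config a named list, or a path to a JSON or YAML file holding
#'   one.  Recognised keys: `matrix` (path, required), `metadata` (path,
#'   required), `exclusion` (path, optional), `ontology` (OBO path,
#'   optional), `tree` (newick path, optional), `id_scheme`
#'   (default "GENERIC"), `coverage_threshold`, `free_living_only`,
#'   `hgt_threshold`, `tail_threshold`, `near_universal_threshold`, `seed`.
#' @param out_dir output directory, created if needed.
#' @return the report, an object of class `trait_run_report` (a list),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  for (key in c("matrix", "metadata")) {
    if (is.null(config[[key]]))
      stop("configuration is missing mandatory input: ", key, call. = FALSE)
    if (!file.exists(config[[key]]))
      stop("configured ", key, " file does not exist: ", config[[key]], call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get <- function(key, default) if (is.null(config[[key]])) default else config[[key]]

  cfg <- dataset_config(
    coverage_threshold = get("coverage_threshold", 0.5),
    free_living_only = get("free_living_only", FALSE),
    exclusion_list = if (!is.null(config$exclusion))
      load_exclusion_list(config$exclusion) else character(),
    hgt_threshold = get("hgt_threshold", 0.6),
    tail_threshold = get("tail_threshold", 0.8),
    near_universal_threshold = get("near_universal_threshold", 0.90)
  )

  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }

  # --- load + filter -------------------------------------------------------
  mat_raw <- load_trait_matrix(config$matrix, id_scheme = get("id_scheme", "GENERIC"))
  metadata <- load_organism_metadata(config$metadata)
  mat <- filter_dataset(mat_raw, metadata, cfg)
  filter_report <- attr(mat, "filter_report")
  write_trait_matrix(mat, file.path(out_dir, "filtered_matrix.tsv"))

  inputs <- c(matrix = config$matrix, metadata = config$metadata)
  for (key in c("exclusion", "ontology", "tree"))
    if (!is.null(config[[key]])) inputs[key] <- config[[key]]
  write_run_manifest(cfg, file.path(out_dir, "manifest.json"),
                     inputs = inputs, seed = get("seed", NULL))

  # --- Venn census ---------------------------------------------------------
  assignments <- assign_venn_groups(mat, metadata)
  counts <- venn_counts(assignments)
  if (sum(counts) != attr(counts, "total"))
    stop("conservation audit failed: Venn counts do not sum to total", call. = FALSE)
  shares <- setNames(as.numeric(percentage_share(as.integer(counts), attr(counts, "total"))),
                     VENN_GROUPS)
  tsv(assignments, "venn_assignments.tsv")
  json(list(counts = as.list(setNames(as.integer(counts), VENN_GROUPS)),
            total = attr(counts, "total"),
            share_percent = as.list(shares)), "venn_counts.json")

  # --- spread --------------------------------------------------------------
  profiles <- spread_profiles(mat, metadata, assignments)
  spread_summary <- spread_summary_table(profiles, tail_threshold = cfg$tail_threshold)
  core <- universal_core(mat, metadata)
  near <- near_universal(mat, threshold = cfg$near_universal_threshold)
  prof_out <- profiles
  for (col in c("f_A", "f_B", "f_E")) prof_out[[col]] <- report_precision(prof_out[[col]], 3)
  tsv(prof_out, "spread_profiles.tsv")
  tsv(spread_summary, "spread_summary.tsv")
  json(list(universal_core = core, near_universal = near), "trait_cores.json")

  # --- HGT -----------------------------------------------------------------
  has_two_sk <- any(assignments$venn_group %in% c("AB", "AE", "BE"))
  calls <- if (has_two_sk) detect_hgt(profiles, threshold = cfg$hgt_threshold) else
    detect_hgt(profiles[0, , drop = FALSE], threshold = cfg$hgt_threshold)
  flux <- tally_flux(calls, assignments)
  if (!all(flux$n_forward + flux$n_reverse + flux$n_vertical == flux$n_traits))
    stop("conservation audit failed: flux tally does not partition groups", call. = FALSE)
  calls_out <- calls
  for (col in c("f_former", "f_latter"))
    calls_out[[col]] <- report_precision(calls_out[[col]], 3)
  calls_out$f_difference <- sign(calls$f_difference) *
    report_precision(abs(calls$f_difference), 3)
  tsv(calls_out, "hgt_calls.tsv")
  json(flux, "flux_tally.json")

  # --- abundance -----------------------------------------------------------
  abundance <- group_abundance(mat, assignments, metadata)
  col_tot <- colSums(unclass(mat))
  if (!all(abundance$abundance_total == col_tot[abundance$organism_id]))
    stop("conservation audit failed: group abundances do not sum to column totals",
         call. = FALSE)
  ab_summary <- abundance_summary_table(abundance)
  tsv(abundance, "abundance_profiles.tsv")
  tsv(ab_summary, "abundance_summary.tsv")

  # --- ontology mapping (optional) -----------------------------------------
  breakdown <- NULL; mapping_note <- "skipped: no ontology configured"
  if (!is.null(config$ontology)) {
    dag <- load_ontology(config$ontology)
    in_dag <- assignments$trait_id %in% dag$terms$id
    if (any(in_dag)) {
      breakdown <- level1_breakdown(assignments[in_dag, c("trait_id", "venn_group")], dag)
      tsv(breakdown$table, "level1_breakdown.tsv")
      tsv(breakdown$unmapped, "level1_unmapped.tsv")
      mapping_note <- sprintf("%d terminals mapped (%.2f%%), %d matrix traits not in DAG",
                              breakdown$n_mapped, mapped_percentage(breakdown),
                              sum(!in_dag))
    } else {
      mapping_note <- "skipped: no matrix trait id found in the ontology"
    }
  }

  # --- timeline (optional) -------------------------------------------------
  timeline <- NULL; ancient <- NULL
  timeline_note <- "skipped: no tree configured"
  if (!is.null(config$tree)) {
    nd <- node_distance(config$tree)
    timeline <- build_timeline(nd, assignments, mat, metadata)
    ancient <- most_ancient_per_group(timeline)
    tsv(timeline, "timeline.tsv")
    json(as.list(ancient), "most_ancient.json")
    timeline_note <- sprintf("%d traits placed, %d not in tree",
                             nrow(timeline), attr(timeline, "n_dropped"))
  }

  report <- structure(
    list(
      schema_version = "1.0",
      filter = filter_report,
      venn_counts = setNames(as.integer(counts), VENN_GROUPS),
      venn_total = attr(counts, "total"),
      venn_share_percent = shares,
      universal_core = core,
      near_universal = near,
      spread_summary = spread_summary,
      hgt_calls = calls,
      flux_tally = flux,
      abundance_summary = ab_summary,
      level1_breakdown = breakdown,
      mapping_note = mapping_note,
      timeline = timeline,
      most_ancient = ancient,
      timeline_note = timeline_note,
      config = unclass(cfg)
    ),
    class = "trait_run_report"
  )
  json(list(schema_version = report$schema_version,
            filter = filter_report,
            venn_counts = as.list(report$venn_counts),
            venn_total = report$venn_total,
            venn_share_percent = as.list(shares),
            n_universal = length(core),
            n_near_universal = length(near),
            n_hgt_calls = nrow(calls),
            mapping_note = mapping_note,
            timeline_note = timeline_note),
       "report.json")
  invisible(report)
}

#' @export
print.trait_run_report <- function(x, ...) {
  cat("trait_run_report (schema", x$schema_version, ")\n")
  cat(sprintf("  traits: %d retained of %d (%d excluded, %d zero-occurrence)\n",
              x$filter$n_traits_out, x$filter$n_traits_in,
              x$filter$n_excluded, x$filter$n_zero_occurrence))
  cat("  Venn counts:", paste(sprintf("%s=%d", names(x$venn_counts), x$venn_counts),
                              collapse = " "), "\n")
  cat(sprintf("  universal core: %d traits; near-universal: %d traits\n",
              length(x$universal_core), length(x$near_universal)))
  cat(sprintf("  HGT calls: %d; mapping: %s; timeline: %s\n",
              nrow(x$hgt_calls), x$mapping_note, x$timeline_note))
  invisible(x)
}
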