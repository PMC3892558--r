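#' Parameters for the superkingdom-diversification simulator
#'
#' The simulator emulates the scenario the comparative analysis is designed
#' to detect: an urancestral core of traits shared by all organisms; early
#' loss on the archaeal stem converting part of that core into BE traits;
#' ordered superkingdom-specific innovation (Bacteria first, then Archaea
#' and Eukarya jointly); duplication-driven abundance growth so that older
#' traits are more abundant; late reductive loss in bacterial genomes; and
#' sparse planted HGT events with a wide-donor / narrow-recipient spread
#' pattern.
#'
#' @param n_organisms named integer triple `c(A=, B=, E=)`; defaults
#'   `c(A=70, B=652, E=259)`, the proteome sample sizes of the three
#'   superkingdoms.
#' @param n_core number of urancestral traits (epoch 0), default 150.
#' @param n_specific named triple of superkingdom-specific trait counts,
#'   default `c(A=10, B=60, E=120)` (Eukarya-specific novelties outnumber
#'   bacterial ones, which outnumber archaeal ones).
#' @param birth_epochs named numeric vector giving the birth epoch of each
#'   trait class; default `c(core=0, specific_B=1, specific_A=2, specific_E=2)`
#'   encodes the canonical ordering (bacterial novelties first, archaeal
#'   and eukaryal jointly later).
#' @param archaeal_loss_rate per-trait probability that an urancestral
#'   trait is lost from the entire archaeal stem (creating a true BE
#'   trait), default 0.25.
#' @param late_bacterial_loss_rate per-organism probability that a
#'   bacterial genome undergoes reductive loss, default 0.05.
#' @param reduction_severity within a reduced genome, per-trait probability
#'   of loss, default 0.3.
#' @param specific_spread range (length-2) of the fraction of the home
#'   superkingdom's organisms carrying a superkingdom-specific trait,
#'   default `c(0.05, 0.6)` (specific traits are unevenly spread).
#' @param duplication_growth per-epoch multiplicative abundance factor
#'   (>= 1), default 2: a trait born e epochs before the present has mean
#'   abundance `abundance_base_mean * duplication_growth^e`.
#' @param abundance_base_mean mean copy number of a newborn trait, default 2.
#' @param n_hgt number of planted horizontal transfers, default 10.
#' @param hgt_donor_spread range of donor-superkingdom spread for planted
#'   transfers, default `c(0.9, 1.0)`.
#' @param hgt_recipient_spread range of recipient-superkingdom spread,
#'   default `c(0.0, 0.2)` (at least one recipient organism is always
#'   used, so the trait belongs to the two-superkingdom group).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return an object of class `scenario_params`.
#' @export
scenario_params <- function(n_organisms = c(A = 70L, B = 652L, E = 259L),
                            n_core = 150L,
                            n_specific = c(A = 10L, B = 60L, E = 120L),
                            birth_epochs = c(core = 0, specific_B = 1,
                                             specific_A = 2, specific_E = 2),
                            archaeal_loss_rate = 0.25,
                            late_bacterial_loss_rate = 0.05,
                            reduction_severity = 0.3,
                            specific_spread = c(0.05, 0.6),
                            duplication_growth = 2,
                            abundance_base_mean = 2,
                            n_hgt = 10L,
                            hgt_donor_spread = c(0.9, 1.0),
                            hgt_recipient_spread = c(0.0, 0.2),
                            seed = 1L) {
  stopifnot(
    all(SK_LEVELS %in% names(n_organisms)), all(n_organisms >= 1),
    n_core >= 0, all(SK_LEVELS %in% names(n_specific)), all(n_specific >= 0),
    all(c("core", "specific_A", "specific_B", "specific_E") %in% names(birth_epochs)),
    birth_epochs["specific_B"] < birth_epochs["specific_A"],
    birth_epochs["specific_B"] < birth_epochs["specific_E"],
    archaeal_loss_rate >= 0, archaeal_loss_rate <= 1,
    late_bacterial_loss_rate >= 0, late_bacterial_loss_rate <= 1,
    reduction_severity >= 0, reduction_severity <= 1,
    length(specific_spread) == 2, all(specific_spread >= 0), all(specific_spread <= 1),
    duplication_growth >= 1, abundance_base_mean >= 1,
    n_hgt >= 0,
    length(hgt_donor_spread) == 2, all(hgt_donor_spread >= 0), all(hgt_donor_spread <= 1),
    length(hgt_recipient_spread) == 2, all(hgt_recipient_spread >= 0),
    all(hgt_recipient_spread <= 1)
  )
  structure(
    list(n_organisms = n_organisms[SK_LEVELS], n_core = as.integer(n_core),
         n_specific = n_specific[SK_LEVELS], birth_epochs = birth_epochs,
         archaeal_loss_rate = archaeal_loss_rate,
         late_bacterial_loss_rate = late_bacterial_loss_rate,
         reduction_severity = reduction_severity,
         specific_spread = sort(specific_spread),
         duplication_growth = duplication_growth,
         abundance_base_mean = abundance_base_mean,
         n_hgt = as.integer(n_hgt),
         hgt_donor_spread = sort(hgt_donor_spread),
         hgt_recipient_spread = sort(hgt_recipient_spread),
         seed = as.integer(seed)),
    class = "scenario_params"
  )
}

# draw an abundance for each of n present cells of a trait born `age` epochs
# before the present: 1 + geometric, with mean base * growth^age
draw_abundance <- function(n, age, params) {
  m <- params$abundance_base_mean * params$duplication_growth^age
  1L + rgeom(n, prob = 1 / m)
}

#' Simulate ground-truthed trait repertoires
#'
#' Generates a trait matrix, organism metadata and a ground-truth record
#' under [scenario_params()].  Urancestral traits start present in every
#' organism; with probability `archaeal_loss_rate` each is lost from the
#' whole archaeal block (true class `be_stem`).  Superkingdom-specific
#' traits are born in their epoch into their home block with a spread drawn
#' from `specific_spread`.  Bacterial genomes flagged for late reduction
#' lose core/stem/specific traits independently at `reduction_severity`
#' (planted HGT spread patterns are left untouched so their construction
#' is exact).  Every present cell receives an abundance draw whose mean
#' grows geometrically with the trait's age.  Planted HGT traits occupy a
#' two-superkingdom group with donor spread and recipient spread drawn from
#' their configured ranges (recipient gets at least one organism).
#'
#' @param params a [scenario_params()] object.
#' @return a list with elements `matrix` (a [trait_matrix()]), `metadata`
#'   (organism metadata data.frame) and `truth` (list with data.frames
#'   `traits`: trait_id, class, birth_epoch, venn_expected, hgt_donor,
#'   hgt_recipient; and `organisms`: organism_id, superkingdom, reduced).
#' @export
simulate_repertoires <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)

  n_org <- params$n_organisms
  org_ids <- unlist(lapply(SK_LEVELS, function(sk) {
    sprintf("%s%04d", sk, seq_len(n_org[[sk]]))
  }), use.names = FALSE)
  org_sk <- rep(SK_LEVELS, times = n_org[SK_LEVELS])
  sk_cols <- lapply(setNames(SK_LEVELS, SK_LEVELS), function(sk) which(org_sk == sk))

  n_traits <- params$n_core + sum(params$n_specific) + params$n_hgt
  if (n_traits == 0)
    stop("scenario generates no traits: increase n_core, n_specific or n_hgt",
         call. = FALSE)
  trait_ids <- sprintf("T%04d", seq_len(n_traits))
  mat <- matrix(0L, nrow = n_traits, ncol = length(org_ids),
                dimnames = list(trait_ids, org_ids))

  max_epoch <- max(params$birth_epochs)
  cls <- character(n_traits); epoch <- numeric(n_traits)
  hgt_donor <- rep(NA_character_, n_traits)
  hgt_recipient <- rep(NA_character_, n_traits)
  venn_expected <- character(n_traits)
  row <- 0L

  # urancestral core, with archaeal stem loss
  if (params$n_core > 0) {
    lost_A <- runif(params$n_core) < params$archaeal_loss_rate
    for (i in seq_len(params$n_core)) {
      row <- row + 1L
      cls[row] <- if (lost_A[i]) "be_stem" else "urancestral"
      epoch[row] <- params$birth_epochs[["core"]]
      venn_expected[row] <- if (lost_A[i]) "BE" else "ABE"
      cols <- if (lost_A[i]) which(org_sk != "A") else seq_along(org_ids)
      mat[row, cols] <- draw_abundance(length(cols), max_epoch - epoch[row], params)
    }
  }

  # superkingdom-specific innovation in epoch order
  for (sk in SK_LEVELS) {
    n_sk_traits <- params$n_specific[[sk]]
    if (n_sk_traits == 0) next
    e <- params$birth_epochs[[paste0("specific_", sk)]]
    pool <- sk_cols[[sk]]
    for (i in seq_len(n_sk_traits)) {
      row <- row + 1L
      cls[row] <- paste0("specific_", sk)
      epoch[row] <- e
      venn_expected[row] <- sk
      spread <- runif(1, params$specific_spread[1], params$specific_spread[2])
      n_carry <- max(1L, round(spread * length(pool)))
      cols <- sample(pool, n_carry)
      mat[row, cols] <- draw_abundance(n_carry, max_epoch - e, params)
    }
  }

  # late bacterial reduction (applied before HGT planting so planted spread
  # patterns stay exactly as constructed)
  reduced <- org_sk == "B" & runif(length(org_ids)) < params$late_bacterial_loss_rate
  if (any(reduced) && row > 0) {
    for (j in which(reduced)) {
      present <- which(mat[seq_len(row), j] > 0L)
      drop <- present[runif(length(present)) < params$reduction_severity]
      mat[drop, j] <- 0L
    }
  }

  # planted HGT: donor-wide, recipient-narrow two-superkingdom traits
  if (params$n_hgt > 0) {
    two_sk <- c("AB", "AE", "BE")
    for (i in seq_len(params$n_hgt)) {
      row <- row + 1L
      g <- sample(two_sk, 1)
      pair <- strsplit(g, "")[[1]]
      donor <- sample(pair, 1)
      recipient <- setdiff(pair, donor)
      cls[row] <- "hgt"
      epoch[row] <- params$birth_epochs[["specific_B"]]
      venn_expected[row] <- g
      hgt_donor[row] <- donor
      hgt_recipient[row] <- recipient

      s_d <- runif(1, params$hgt_donor_spread[1], params$hgt_donor_spread[2])
      s_r <- runif(1, params$hgt_recipient_spread[1], params$hgt_recipient_spread[2])
      d_pool <- sk_cols[[donor]]; r_pool <- sk_cols[[recipient]]
      d_cols <- sample(d_pool, min(length(d_pool), ceiling(s_d * length(d_pool))))
      r_cols <- sample(r_pool, max(1L, floor(s_r * length(r_pool))))
      age <- max_epoch - epoch[row]
      mat[row, d_cols] <- draw_abundance(length(d_cols), age, params)
      mat[row, r_cols] <- draw_abundance(length(r_cols), age, params)
    }
  }

  # reduction must not have emptied any trait entirely (possible only at
  # extreme severity); drop such traits from matrix and truth alike
  alive <- rowSums(mat >= 1L) > 0L
  mat <- mat[alive, , drop = FALSE]

  truth <- list(
    traits = data.frame(
      trait_id = trait_ids[alive], class = cls[alive],
      birth_epoch = epoch[alive], venn_expected = venn_expected[alive],
      hgt_donor = hgt_donor[alive], hgt_recipient = hgt_recipient[alive],
      stringsAsFactors = FALSE
    ),
    organisms = data.frame(
      organism_id = org_ids, superkingdom = org_sk, reduced = reduced,
      stringsAsFactors = FALSE
    )
  )

  list(
    matrix = trait_matrix(mat, id_scheme = "GENERIC"),
    metadata = organism_metadata(org_ids, org_sk,
                                 lifestyle = "free_living",
                                 annotation_coverage = 1.0),
    truth = truth
  )
}

#' Simulate an is_a ontology DAG with known level-1 structure
#'
#' Builds a GO-like DAG: a single root, `n_level1` level-1 children, one
#' intermediate node per level-1 subtree, and terminal terms attached under
#' the intermediates (depth 3, so every mapped terminal has a proper
#' level-1 ancestor).  With probability `multi_parent_prob` a terminal
#' gains a second is_a parent in another level-1 subtree.  Optionally,
#' `n_unmappable` extra terminals are created as level-1 terms themselves
#' (direct children of the root), which the mapper reports as unmapped.
#'
#' @param n_level1 number of level-1 terms (>= 1).
#' @param n_terminal number of mappable terminal terms.
#' @param multi_parent_prob probability of a second level-1 ancestry per
#'   terminal, default 0.1.
#' @param n_unmappable number of level-1 terminals, default 0.
#' @param seed integer seed.
#' @return list with `dag` (an [ontology_dag()]) and `terminals` (character
#'   vector of terminal term ids, mappable first).
#' @export
simulate_ontology <- function(n_level1, n_terminal, multi_parent_prob = 0.1,
                              n_unmappable = 0L, seed = 1L) {
  stopifnot(n_level1 >= 1, n_terminal >= 0, n_unmappable >= 0,
            multi_parent_prob >= 0, multi_parent_prob <= 1)
  set.seed(seed)
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  root <- next_id()
  level1 <- vapply(seq_len(n_level1), function(i) next_id(), character(1))
  inter <- vapply(seq_len(n_level1), function(i) next_id(), character(1))
  terminals <- if (n_terminal > 0)
    vapply(seq_len(n_terminal), function(i) next_id(), character(1)) else character(0)
  unmappable <- if (n_unmappable > 0)
    vapply(seq_len(n_unmappable), function(i) next_id(), character(1)) else character(0)

  parents <- list()
  parents[[root]] <- character(0)
  for (i in seq_len(n_level1)) {
    parents[[level1[i]]] <- root
    parents[[inter[i]]] <- level1[i]
  }
  home <- if (n_terminal > 0) sample.int(n_level1, n_terminal, replace = TRUE) else integer(0)
  for (j in seq_len(n_terminal)) {
    p <- inter[home[j]]
    if (n_level1 > 1 && runif(1) < multi_parent_prob) {
      other <- sample(setdiff(seq_len(n_level1), home[j]), 1)
      p <- c(p, inter[other])
    }
    parents[[terminals[j]]] <- p
  }
  for (u in unmappable) parents[[u]] <- root

  ids <- c(root, level1, inter, terminals, unmappable)
  terms <- data.frame(
    id = ids,
    name = c("molecular_function root",
             sprintf("level1 category %d", seq_len(n_level1)),
             sprintf("intermediate %d", seq_len(n_level1)),
             if (n_terminal > 0) sprintf("terminal activity %d", seq_len(n_terminal)),
             if (n_unmappable > 0) sprintf("level1 terminal %d", seq_len(n_unmappable))),
    stringsAsFactors = FALSE
  )
  list(dag = ontology_dag(terms, parents),
       terminals = c(terminals, unmappable))
}

#' Write an ontology DAG to OBO format
#'
#' Emits the `[Term]` stanza subset (id, name, is_a) that [load_ontology()]
#' reads back; the round trip reproduces the DAG.
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    p <- dag$parents[[id]]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 if (length(p)) paste0("is_a: ", p),
                 ""), con)
  }
  invisible(path)
}

#' Simulate a trait tree consistent with birth order
#'
#' Builds a pectinate-backbone rooted tree in which the number of internal
#' nodes on a leaf's root path strictly increases with the trait's birth
#' epoch: traits of the earliest epoch hang directly off the root, each
#' later epoch hangs one node deeper.  Within an epoch the leaf order is
#' randomised by the seed.  By construction, [node_distance()] on the
#' result is a monotone function of birth epoch (Spearman correlation 1),
#' and a single-epoch truth yields a star tree with all nd = 0.
#'
#' @param truth the `truth` element of [simulate_repertoires()] output (or
#'   any list with a `traits` data.frame holding `trait_id` and
#'   `birth_epoch`).
#' @param seed integer seed.
#' @return an `ape::phylo` tree whose tips are the trait ids.
#' @export
simulate_trait_tree <- function(truth, seed = 1L) {
  traits <- truth$traits
  stopifnot(nrow(traits) >= 2)
  set.seed(seed)

  epochs <- sort(unique(traits$birth_epoch))
  m <- length(epochs)
  tips <- unlist(lapply(epochs, function(e) {
    ids <- traits$trait_id[traits$birth_epoch == e]
    if (length(ids) > 1) sample(ids) else ids
  }), use.names = FALSE)
  ntip <- length(tips)
  tip_epoch_idx <- match(traits$birth_epoch[match(tips, traits$trait_id)], epochs)

  # internal node j (= ntip + j) carries epoch j; backbone chain node_j -> node_{j+1}
  edges <- matrix(0L, nrow = ntip + m - 1L, ncol = 2)
  r <- 0L
  for (j in seq_len(m - 1L)) {
    r <- r + 1L
    edges[r, ] <- c(ntip + j, ntip + j + 1L)
  }
  for (tip in seq_len(ntip)) {
    r <- r + 1L
    edges[r, ] <- c(ntip + tip_epoch_idx[tip], tip)
  }

  tree <- structure(
    list(edge = edges, tip.label = tips, Nnode = m),
    class = "phylo", order = "cladewise"
  )
  tree
}

#' Write a complete simulated fixture bundle
#'
#' Emits the exact file formats the pipeline consumes -- matrix TSV,
#' metadata TSV, exclusion list, OBO ontology, newick tree -- plus a
#' ground-truth JSON, into a directory.
#'
#' @param dir output directory (created if needed).
#' @param params a [scenario_params()].
#' @param n_level1 level-1 terms of the simulated ontology, default 16.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, params = scenario_params(), n_level1 = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_repertoires(params)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    exclusion = file.path(dir, "exclusion.txt"),
    ontology = file.path(dir, "ontology.obo"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_trait_matrix(sim$matrix, paths[["matrix"]])
  write.table(sim$metadata, paths[["metadata"]], sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  writeLines("# trait exclusion list (one id per line)", paths[["exclusion"]])

  onto <- simulate_ontology(n_level1 = n_level1,
                            n_terminal = nrow(sim$truth$traits),
                            seed = params$seed)
  # alias each trait to an ontology terminal so the mapping stage is exercised
  write_ontology_obo(onto$dag, paths[["ontology"]])

  tree <- simulate_trait_tree(sim$truth, seed = params$seed)
  ape::write.tree(tree, paths[["tree"]])

  jsonlite::write_json(
    list(traits = sim$truth$traits, organisms = sim$truth$organisms,
         term_alias = data.frame(trait_id = sim$truth$traits$trait_id,
                                 term_id = onto$terminals[seq_len(nrow(sim$truth$traits))],
                                 stringsAsFactors = FALSE)),
    paths[["truth"]], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
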