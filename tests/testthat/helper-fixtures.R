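# Shared fixture builders and independent brute-force oracles.

# metadata for nA + nB + nE organisms named A1.., B1.., E1..
make_meta <- function(nA, nB, nE, ...) {
  ids <- c(if (nA) paste0("A", seq_len(nA)), if (nB) paste0("B", seq_len(nB)),
           if (nE) paste0("E", seq_len(nE)))
  sks <- c(rep("A", nA), rep("B", nB), rep("E", nE))
  organism_metadata(ids, sks, ...)
}

# trait matrix from a list of named abundance rows, columns per make_meta ids
make_matrix <- function(rows, meta, id_scheme = "GENERIC") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- meta$organism_id
  trait_matrix(m, id_scheme = id_scheme)
}

# random matrix + metadata pair for property tests
random_dataset <- function(n_traits, nA, nB, nE, density = 0.4, max_abundance = 5) {
  meta <- make_meta(nA, nB, nE)
  n_org <- nA + nB + nE
  m <- matrix(0L, n_traits, n_org,
              dimnames = list(sprintf("t%03d", seq_len(n_traits)), meta$organism_id))
  repeat {
    cells <- matrix(runif(n_traits * n_org) < density, n_traits, n_org)
    if (all(rowSums(cells) > 0)) break
  }
  m[cells] <- sample.int(max_abundance, sum(cells), replace = TRUE)
  list(matrix = trait_matrix(m), meta = meta)
}

# brute-force Venn oracle: explicit per-superkingdom trait sets + set algebra
venn_oracle <- function(matrix, meta) {
  sets <- lapply(c(A = "A", B = "B", E = "E"), function(sk) {
    orgs <- meta$organism_id[meta$superkingdom == sk]
    ids <- character(0)
    for (tr in trait_ids(matrix)) {
      for (o in orgs) if (unclass(matrix)[tr, o] >= 1) { ids <- c(ids, tr); break }
    }
    ids
  })
  all_ids <- trait_ids(matrix)
  groups <- c(
    ABE = length(intersect(intersect(sets$A, sets$B), sets$E)),
    AB  = length(setdiff(intersect(sets$A, sets$B), sets$E)),
    AE  = length(setdiff(intersect(sets$A, sets$E), sets$B)),
    BE  = length(setdiff(intersect(sets$B, sets$E), sets$A)),
    A   = length(setdiff(setdiff(sets$A, sets$B), sets$E)),
    B   = length(setdiff(setdiff(sets$B, sets$A), sets$E)),
    E   = length(setdiff(setdiff(sets$E, sets$A), sets$B))
  )
  groups[c("A", "B", "E", "AB", "AE", "BE", "ABE")]
}

# brute-force f-value: explicit loop over one superkingdom's organisms
f_oracle <- function(trait, sk, matrix, meta) {
  orgs <- meta$organism_id[meta$superkingdom == sk]
  n <- 0L
  for (o in orgs) if (unclass(matrix)[trait, o] >= 1) n <- n + 1L
  n / length(orgs)
}

# write a tiny OBO file from id -> parents mapping (names optional)
write_toy_obo <- function(parents, path, obsolete = character(0)) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2\n", con)
  for (id in names(parents)) {
    writeLines(c("[Term]", paste0("id: ", id), paste0("name: name of ", id),
                 paste0("is_a: ", parents[[id]], " ! parent"),
                 if (id %in% obsolete) "is_obsolete: true",
                 ""), con)
  }
  invisible(path)
}

# random single-rooted DAG as a parents list; node 1 is the root
random_dag_parents <- function(n, max_parents = 3) {
  ids <- sprintf("N%04d", seq_len(n))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (i in seq(2, n)) {
    k <- sample.int(min(max_parents, i - 1), 1)
    parents[[ids[i]]] <- ids[sample.int(i - 1, k)]
  }
  parents
}

# transitive-closure oracle for level-1 ancestors: full ancestor sets by
# dynamic programming over the construction order (parents precede children)
level1_closure_oracle <- function(parents, level1) {
  anc <- list()
  for (id in names(parents)) {
    a <- parents[[id]]
    for (p in parents[[id]]) a <- union(a, anc[[p]])
    anc[[id]] <- a
  }
  lapply(names(parents), function(id) {
    intersect(level1, union(id, anc[[id]]))
  }) |> setNames(names(parents))
}
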