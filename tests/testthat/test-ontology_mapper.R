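toy_dag <- function() {
  # root -> {l1a, l1b}; l1a -> leaf1; l1b -> leaf2; leafboth under both
  parents <- list(root = character(0), l1a = "root", l1b = "root",
                  leaf1 = "l1a", leaf2 = "l1b", leafboth = c("l1a", "l1b"))
  terms <- data.frame(id = names(parents), name = paste("term", names(parents)),
                      stringsAsFactors = FALSE)
  ontology_dag(terms, parents)
}

test_that("OBO parsing builds the DAG, skips obsolete terms, rejects cycles", {
  path <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(list(root = character(0), l1a = "root", l1b = "root",
                     leaf1 = "l1a", leafboth = c("l1a", "l1b")), path,
                obsolete = character(0))
  dag <- load_ontology(path)
  expect_setequal(dag$level1, c("l1a", "l1b"))
  expect_equal(dag$root, "root")
  expect_equal(length(dag$parents[["leafboth"]]), 2L)  # two is_a parents

  write_toy_obo(list(root = character(0), l1a = "root", dead = "l1a",
                     leaf1 = "l1a"), path, obsolete = "dead")
  dag2 <- load_ontology(path)
  expect_equal(dag2$n_obsolete, 1L)
  expect_false("dead" %in% dag2$terms$id)

  write_toy_obo(list(root = character(0), a = c("root", "b"), b = "a"), path)
  expect_error(load_ontology(path), "cycle")
})

test_that("DAGs without a unique root are configuration errors", {
  terms <- data.frame(id = c("r1", "r2", "x"), name = c("r1", "r2", "x"),
                      stringsAsFactors = FALSE)
  expect_error(ontology_dag(terms, list(r1 = character(0), r2 = character(0), x = "r1")),
               "multiple roots")
})

test_that("level-1 mapping climbs is_a edges, handles multi-parents and self", {
  dag <- toy_dag()
  expect_equal(map_to_level1("leaf1", dag), "l1a")
  expect_setequal(map_to_level1("leafboth", dag), c("l1a", "l1b"))
  expect_equal(map_to_level1("l1a", dag), "l1a")  # level-1 maps to itself
  expect_equal(length(map_to_level1("root", dag)), 0L)
  expect_error(map_to_level1("nope", dag), "unknown term")
})

test_that("breakdown counts multi-parent terminals once per parent and accounts for unmapped", {
  dag <- toy_dag()
  terminals <- data.frame(
    trait_id = c("leaf1", "leaf2", "leafboth", "l1a"),
    venn_group = c("ABE", "BE", "E", "E"),
    stringsAsFactors = FALSE)
  bd <- level1_breakdown(terminals, dag)
  expect_equal(bd$n_mapped, 3L)
  expect_equal(bd$n_unmapped, 1L)
  expect_equal(bd$unmapped$reason, "is_level1")
  expect_equal(bd$n_mapped + bd$n_unmapped, nrow(terminals))
  expect_gte(sum(bd$table$total), bd$n_mapped)  # leafboth counted twice
  expect_equal(sum(bd$table$total), 4L)
  expect_equal(mapped_percentage(bd), 75.00)

  # order invariance
  bd2 <- level1_breakdown(terminals[c(3, 1, 4, 2), ], dag)
  expect_equal(bd2$table, bd$table)
})

test_that("traversal equals the transitive-closure oracle on random DAGs", {
  set.seed(99)
  for (n in c(20, 100, 500)) {
    parents <- random_dag_parents(n)
    terms <- data.frame(id = names(parents), name = names(parents),
                        stringsAsFactors = FALSE)
    dag <- ontology_dag(terms, parents)
    want <- level1_closure_oracle(parents, dag$level1)
    for (id in sample(names(parents), min(n, 60))) {
      expect_setequal(map_to_level1(id, dag), want[[id]])
    }
  }
})

test_that("splicing out an intermediate term leaves level-1 sets unchanged", {
  set.seed(123)
  parents <- random_dag_parents(80)
  terms <- data.frame(id = names(parents), name = names(parents),
                      stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, parents)
  # pick an intermediate: not root, not level-1, and with children
  has_child <- unique(unlist(parents, use.names = FALSE))
  mid <- setdiff(intersect(has_child, names(parents)), c(dag$root, dag$level1))
  skip_if(length(mid) == 0, "random DAG produced no intermediate with children")
  victim <- mid[1]
  spliced <- parents
  for (id in names(spliced)) {
    if (victim %in% spliced[[id]])
      spliced[[id]] <- union(setdiff(spliced[[id]], victim), parents[[victim]])
  }
  spliced[[victim]] <- NULL
  dag2 <- ontology_dag(terms[terms$id != victim, ], spliced)
  expect_setequal(dag2$level1, dag$level1)
  for (id in setdiff(names(spliced), dag$root)) {
    expect_setequal(map_to_level1(id, dag2), map_to_level1(id, dag))
  }
})

test_that("simulated ontologies respect multi-parent probability and pass validation", {
  one <- simulate_ontology(n_level1 = 4, n_terminal = 30, multi_parent_prob = 0,
                           seed = 2)
  n_parents <- vapply(one$terminals, function(t) length(map_to_level1(t, one$dag)),
                      integer(1))
  expect_true(all(n_parents == 1L))

  sixteen <- simulate_ontology(n_level1 = 16, n_terminal = 50, seed = 3)
  bd <- level1_breakdown(data.frame(trait_id = sixteen$terminals,
                                    venn_group = "ABE", stringsAsFactors = FALSE),
                         sixteen$dag)
  expect_equal(nrow(bd$table), 16L)

  # OBO round trip reproduces the DAG
  path <- withr::local_tempfile(fileext = ".obo")
  write_ontology_obo(sixteen$dag, path)
  back <- load_ontology(path)
  expect_equal(back$root, sixteen$dag$root)
  expect_setequal(back$level1, sixteen$dag$level1)
  expect_identical(back$parents, sixteen$dag$parents)
})

test_that("unique-coding-group logic reproduces the ABE/BE/E-only pattern", {
  sim <- simulate_ontology(n_level1 = 6, n_terminal = 60, multi_parent_prob = 0,
                           seed = 8)
  # construct contributions so that every level-1 term receives terminals
  # only from ABE, BE or E groups
  groups <- sample(c("ABE", "BE", "E"), length(sim$terminals), replace = TRUE)
  bd <- level1_breakdown(data.frame(trait_id = sim$terminals, venn_group = groups,
                                    stringsAsFactors = FALSE), sim$dag)
  uniq <- unique_coding_groups(bd)
  expect_true(all(uniq %in% c("ABE", "BE", "E")))
  expect_false(any(uniq %in% c("A", "B", "AB", "AE")))
})
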