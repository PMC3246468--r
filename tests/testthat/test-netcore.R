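test_that("TSV reaction records load into validated networks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible",
               "R1\tA + B\tC\t0"), path)
  net <- load_network(path)
  expect_equal(nrow(net$compounds), 3)
  expect_length(net$reactions, 1)
  expect_false(net$reactions$R1$reversible)
  expect_setequal(net$reactions$R1$substrates$id, c("A", "B"))

  writeLines(c("reaction_id\tsubstrates\tproducts\treversible",
               "R1\t2*A\tC\t1"), path)
  net2 <- load_network(path)
  expect_equal(net2$reactions$R1$substrates$coef, 2)
  expect_true(net2$reactions$R1$reversible)
})

test_that("duplicate reaction ids and undeclared compounds are rejected", {
  expect_error(metabolic_network(list(
    reaction("R1", "A", "B"), reaction("R1", "B", "C"))),
    "duplicate reaction id")
  expect_error(
    metabolic_network(list(reaction("R1", "A", "B")),
                      compounds = compound("A"), strict = TRUE),
    "undeclared")
  expect_error(reaction("R1", character(0), "B"), "empty")
  expect_error(reaction("R1", c(A = -1), "B"), "non-positive")
})

test_that("tsv and json round trips reproduce the network exactly", {
  set.seed(11)
  net <- random_raw_network(12, 15)
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, path, fmt)
    back <- load_network(path)
    expect_identical(names(back$reactions), names(net$reactions))
    for (rid in names(net$reactions)) {
      expect_identical(back$reactions[[rid]]$substrates,
                       net$reactions[[rid]]$substrates)
      expect_identical(back$reactions[[rid]]$products,
                       net$reactions[[rid]]$products)
      expect_identical(back$reactions[[rid]]$reversible,
                       net$reactions[[rid]]$reversible)
    }
    expect_setequal(back$compounds$id, net$compounds$id)
  }
})

test_that("a generated network loads with manifest-matching counts", {
  gen <- generate_network(n_compounds = 20, n_inputs = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(gen$network, path, "tsv")
  back <- load_network(path)
  expect_equal(nrow(back$compounds), gen$manifest$n_compounds)
  expect_length(back$reactions, gen$manifest$n_reactions)
})

test_that("a minimal SBML subset loads, warning on ignored constructs", {
  sbml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    "<model><listOfSpecies>",
    '<species id="A" name="cpdA"/><species id="B"/><species id="C"/>',
    "</listOfSpecies><listOfRules/><listOfReactions>",
    '<reaction id="R1" reversible="true"><listOfReactants>',
    '<speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/>',
    '<speciesReference species="C"/></listOfProducts></reaction>',
    "</listOfReactions></model></sbml>")
  path <- withr::local_tempfile(fileext = ".sbml")
  writeLines(sbml, path)
  expect_warning(net <- load_network(path), "ignored")
  expect_equal(nrow(net$compounds), 3)
  expect_true(net$reactions$R1$reversible)
  expect_equal(net$reactions$R1$substrates$coef, 2)
  expect_equal(net$compounds$name[net$compounds$id == "A"], "cpdA")
})

test_that("side-compound filtering removes currency metabolites", {
  net <- metabolic_network(list(
    reaction("R1", c("A", "ATP"), c("B", "ADP"))))
  res <- filter_side_compounds(net, c("ATP", "ADP"))
  expect_setequal(res$removed, c("ATP", "ADP"))
  expect_equal(res$network$reactions$R1$substrates$id, "A")
  expect_equal(res$network$reactions$R1$products$id, "B")

  # empty side list is the identity
  res0 <- filter_side_compounds(net, character(0))
  expect_identical(res0$removed, character(0))
  expect_identical(res0$network$reactions$R1, net$reactions$R1)

  # reactions left one-sided are dropped and logged
  net2 <- metabolic_network(list(reaction("R1", "ATP", "B")))
  res2 <- filter_side_compounds(net2, "ATP")
  expect_identical(res2$dropped_reactions, "R1")
  expect_length(res2$network$reactions, 0)
})

test_that("filtering matches set intersection and composes as union", {
  set.seed(7)
  for (rep in 1:10) {
    net <- random_raw_network(30, 25)
    side <- sample(sprintf("M%02d", 1:40), 10)
    res <- filter_side_compounds(net, side)
    expect_setequal(res$removed, intersect(side, net$compounds$id))

    s1 <- sample(side, 5); s2 <- setdiff(side, s1)
    seq_filtered <- filter_side_compounds(
      filter_side_compounds(net, s1)$network, s2)$network
    union_filtered <- filter_side_compounds(net, union(s1, s2))$network
    expect_setequal(seq_filtered$compounds$id, union_filtered$compounds$id)
    expect_setequal(names(seq_filtered$reactions),
                    names(union_filtered$reactions))
  }
})

test_that("compound-graph edges follow the substrate-product definition", {
  net <- metabolic_network(list(reaction("R", c("A", "B"), "C")))
  g <- build_compound_graph(net)
  expect_setequal(paste(g$edges$from, g$edges$to, sep = "->"),
                  c("A->C", "B->C"))

  netr <- metabolic_network(list(reaction("R", "A", "B", reversible = TRUE)))
  gr <- build_compound_graph(netr)
  expect_setequal(paste(gr$edges$from, gr$edges$to, sep = "->"),
                  c("A->B", "B->A"))
})

test_that("graph construction matches brute-force pair enumeration", {
  set.seed(21)
  for (rep in 1:10) {
    net <- random_raw_network(15, 20, p_rev = 0.3)
    g <- build_compound_graph(net)
    expect_identical(sort(paste(g$edges$from, g$edges$to, sep = "->")),
                     naive_edges(net))
    # provenance integrity and node containment
    expect_true(all(unlist(g$edges$reactions) %in% names(net$reactions)))
    expect_true(all(g$nodes %in% net$compounds$id))
  }
})
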