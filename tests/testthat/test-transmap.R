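tab <- load_repertoire()
cmp <- load_boundary_compounds()

cand_ids <- function(assignments, compound, membrane) {
  row <- which(assignments$compound == compound)
  assignments$candidates[[row]][[membrane]]$system_id
}

test_that("membrane models enforce the strain organisations", {
  expect_setequal(default_membrane_model("BAp")$bacterial_membranes,
                  c("inner", "outer"))
  expect_identical(default_membrane_model("BBp")$bacterial_membranes, "inner")
  expect_error(membrane_model("X", "outer"), "inner")
})

test_that("glucose import routes through the PTS and the porin", {
  asg <- assign_transporters(cmp, tab, "BAp", include_speculative = TRUE)
  expect_true("PtsG" %in% cand_ids(asg, "glucose", "inner"))
  expect_true("OmpF" %in% cand_ids(asg, "glucose", "outer"))
  row <- which(asg$compound == "glucose")
  expect_true(asg$route_complete[row])
  expect_false(asg$orphan_inner[row])
})

test_that("nucleoside import is orphaned at the inner membrane", {
  asg <- assign_transporters(cmp, tab, "BAp", include_speculative = TRUE)
  row <- which(asg$compound == "guanosine")
  expect_true("OmpF" %in% cand_ids(asg, "guanosine", "outer"))
  expect_length(cand_ids(asg, "guanosine", "inner"), 0)
  expect_true(asg$orphan_inner[row])
  expect_false(asg$route_complete[row])
})

test_that("amino-acid import candidates are the speculative NAAT permeases", {
  asg <- assign_transporters(cmp, tab, "BAp", include_speculative = TRUE)
  inner <- asg$candidates[[which(asg$compound == "Ala")]]$inner
  expect_setequal(inner$system_id, c("YchE", "YhgN"))
  expect_true(all(inner$speculative))
  # without speculative systems alanine import loses all inner candidates
  asg0 <- assign_transporters(cmp, tab, "BAp", include_speculative = FALSE)
  expect_length(cand_ids(asg0, "Ala", "inner"), 0)
})

test_that("an empty repertoire orphans every non-diffusing compound", {
  empty <- generate_repertoire(strains = "BAp", seed = 2)$table
  empty$entries <- empty$entries[0, ]
  asg <- assign_transporters(cmp, tab = empty, "BAp")
  expect_true(all(asg$orphan_inner[!asg$diffusion]))
  expect_true(all(asg$orphan_outer[!asg$diffusion]))
  expect_false(any(asg$orphan_inner[asg$diffusion]))
})

test_that("unknown compound classes are rejected by name", {
  bad <- data.frame(compound = "x", class = "mystery", direction = "import",
                    diffusion = FALSE)
  expect_error(assign_transporters(bad, tab, "BAp"), "mystery")
})

test_that("non-speculative inner import coverage reduces to sugars, phosphate and zinc", {
  asg <- assign_transporters(cmp, tab, "BAp", include_speculative = FALSE)
  imp <- asg[asg$direction == "import" & !asg$diffusion, ]
  covered <- imp$compound[!imp$orphan_inner]
  expect_setequal(covered, c("glucose", "mannitol", "phosphate", "zinc"))
  rep <- orphan_report(asg)
  expect_equal(rep$inner_import_orphan_fraction,
               1 - length(covered) / nrow(imp))
  inner_imp <- rep$by_membrane_direction
  inner_imp <- inner_imp[inner_imp$membrane == "inner" &
                           inner_imp$direction == "import", ]
  expect_equal(inner_imp$n_orphans, nrow(imp) - length(covered))
})

test_that("excluding speculative candidates never decreases orphan counts", {
  for (strain in c("BAp", "BSg", "BBp", "BCc")) {
    with_spec <- assign_transporters(cmp, tab, strain,
                                     include_speculative = TRUE)
    without <- assign_transporters(cmp, tab, strain,
                                   include_speculative = FALSE)
    for (mem in attr(with_spec, "membranes")) {
      col <- paste0("orphan_", mem)
      expect_true(all(without[[col]] >= with_spec[[col]]))
    }
  }
})

test_that("the BBp model never reports outer-membrane orphans", {
  asg <- assign_transporters(cmp, tab, "BBp")
  expect_false("orphan_outer" %in% names(asg))
  expect_identical(attr(asg, "membranes"), "inner")
  rep <- orphan_report(asg)
  expect_false("outer" %in% rep$by_membrane_direction$membrane)
})

test_that("adding a transport system never breaks a complete route", {
  # drop the PTS from BAp and check glucose loses completeness, then
  # restore and check monotone recovery
  no_pts <- tab
  no_pts$entries <- no_pts$entries[!(no_pts$entries$system_id %in%
                                       c("PtsG", "MtlA")), ]
  asg_small <- assign_transporters(cmp, no_pts, "BAp")
  asg_full <- assign_transporters(cmp, tab, "BAp")
  expect_true(all(asg_full$route_complete >= asg_small$route_complete))
})

test_that("capability diagrams group intact systems by TC class", {
  d <- strain_capability_diagram(tab, "BAp")
  expect_true(all(c("GlpF", "YggB", "OmpF") %in% d$groups[["1"]]$system_id))
  expect_true(all(c("PtsG", "MtlA") %in% d$groups[["4"]]$system_id))
  expect_true(d$groups[["1"]]$conserved_in_all[
    d$groups[["1"]]$system_id == "YggB"])

  dcc <- strain_capability_diagram(tab, "BCc")
  expect_false("2" %in% names(dcc$groups))  # no secondary transporters
  expect_false("4" %in% names(dcc$groups))  # no PTS

  empty <- generate_repertoire(strains = "BCc", seed = 3)$table
  empty$entries <- empty$entries[0, ]
  dempty <- strain_capability_diagram(empty, "BCc")
  expect_length(dempty$groups, 0)
})

test_that("assignment reports serialise candidates and orphan flags", {
  asg <- assign_transporters(cmp, tab, "BAp", include_speculative = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignment_report(asg, path, preamble = "# x: y")
  out <- read.delim(path, comment.char = "#")
  glc <- out[out$compound == "glucose", ]
  expect_match(glc$candidates_inner, "PtsG")
  expect_match(glc$candidates_outer, "OmpF")
  ala <- out[out$compound == "Ala", ]
  expect_match(ala$candidates_inner, "YchE\\?")  # speculative marker
})
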