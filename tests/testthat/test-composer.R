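test_that("the RNAi evaluator wires into one connected model with a full manifest", {
  fx <- build_rnai_evaluator()
  m <- wire_circuit(fx$circuit)
  # every transcription unit contributes promoter + nuclear part + pool
  mods <- m$manifest$module
  for (u in fx$circuit$units)
    expect_true(u$promoter$name %in% mods)
  expect_true(all(c("and1_pool", "and2_pool", "pool_gfp", "pool_RNAP",
                    "pool_RISC", "si_a_nuc", "si_a_pool") %in% mods))
  # printed per-part complexities surface in the report
  rep <- circuit_report(m)
  and1 <- rep$modules[rep$modules$module == "and1_pool", ]
  expect_equal(c(and1$n_species, and1$n_reactions, and1$n_terminals), c(17, 45, 5))
  # connectivity: every species participates in some reaction or is a seed
  used <- unique(unlist(lapply(m$reactions, function(r) c(r$reactants, r$products))))
  expect_true(all(seq_len(nrow(m$species)) %in% c(used, which(m$species$copies > 0))))
})

test_that("the transcriptional evaluator manifest shows the printed promoter counts", {
  m <- wire_circuit(build_transcriptional_evaluator()$circuit)
  rep <- circuit_report(m)
  p1 <- rep$modules[rep$modules$module == "p_and1", ]
  expect_equal(c(p1$n_species, p1$n_reactions, p1$n_terminals), c(65, 834, 12))
  p2 <- rep$modules[rep$modules$module == "p_and2", ]
  expect_equal(c(p2$n_species, p2$n_terminals), c(17, 7))
  pna <- rep$modules[rep$modules$module == "p_rep_na", ]
  expect_equal(c(pna$n_species, pna$n_reactions, pna$n_terminals), c(5, 22, 6))
})

test_that("flattening conserves species and reaction counts", {
  m <- wire_circuit(build_rnai_evaluator()$circuit)
  total_part_species <- sum(vapply(m$parts, function(p) nrow(p$network$species), numeric(1)))
  expect_equal(nrow(m$species), total_part_species - m$merges)
  expect_equal(length(m$reactions),
               sum(vapply(m$parts, function(p) length(p$network$reactions), numeric(1))))
  # reaction multiset equality against the union of the part networks
  key <- function(rx, labels) paste(paste(sort(labels[rx$reactants]), collapse = "+"),
                                    paste(sort(labels[rx$products]), collapse = "+"),
                                    signif(rx$rate, 10))
  flat_keys <- sort(vapply(m$reactions, function(rx) key(rx, m$species$label), character(1)))
  part_keys <- sort(unname(unlist(lapply(m$parts, function(p)
    vapply(p$network$reactions, function(rx)
      paste(paste(sort(rx$reactants), collapse = "+"),
            paste(sort(rx$products), collapse = "+"), signif(rx$rate, 10)),
      character(1))))))
  expect_identical(flat_keys, part_keys)
})

test_that("wiring is deterministic", {
  circ <- build_rnai_evaluator()$circuit
  m1 <- wire_circuit(circ)
  m2 <- wire_circuit(circ)
  expect_identical(m1$species, m2$species)
  expect_identical(vapply(m1$reactions, function(r) r$rate, numeric(1)),
                   vapply(m2$reactions, function(r) r$rate, numeric(1)))
})

test_that("a single constitutive unit wires into the full expression chain", {
  q <- stats::setNames(default_parameters("cascade")$value,
                       default_parameters("cascade")$parameter)
  circ <- circuit_spec(
    units = list(transcription_unit(
      "u1", promoter_spec("p1"),
      coding_region_spec("c1", "gfp", "reporter"), terminator_spec("t1"))),
    pools = list(pool_spec("RNAP", "RNA_polymerase", "nucleus", 300, conserved = TRUE),
                 pool_spec("ribosome", "ribosome", "cytoplasm", 2000, conserved = TRUE),
                 pool_spec("spliceosome", "machinery", "nucleus", 200, conserved = TRUE)))
  m <- wire_circuit(circ)
  expect_setequal(m$manifest$module,
                  c("p1", "c1_nuc", "c1_pool", "pool_gfp",
                    "pool_RNAP", "pool_ribosome", "pool_spliceosome"))
  # promoter PoPS-out feeds the nuclear part, whose export feeds the pool,
  # whose release feeds the protein pool
  expect_true("PolCl_u1()" %in% m$species$label)
  expect_true("PR_gfp()" %in% m$species$label)
})

test_that("two units producing the same protein share one product pool", {
  m <- wire_circuit(build_transcriptional_evaluator()$circuit)
  gfp <- which(m$species$label == "PR_gfp()")
  expect_length(gfp, 1L)
  producing <- unique(vapply(Filter(function(r) gfp %in% r$products, m$reactions),
                             function(r) r$module, character(1)))
  expect_true(all(c("and1_pool", "and2_pool") %in% producing))
})

test_that("missing machinery pools surface as unmatched terminals", {
  circ <- circuit_spec(
    units = list(transcription_unit(
      "u1", promoter_spec("p1"),
      coding_region_spec("c1", "gfp", "reporter"), terminator_spec("t1"))),
    pools = list(pool_spec("RNAP", "RNA_polymerase", "nucleus", 300, conserved = TRUE),
                 pool_spec("spliceosome", "machinery", "nucleus", 200, conserved = TRUE)))
  expect_error(wire_circuit(circ), "unmatched terminal.*ribosome")
})

test_that("an empty circuit yields an empty manifest", {
  m <- wire_circuit(circuit_spec())
  rep <- circuit_report(m)
  expect_equal(nrow(rep$modules), 0L)
  expect_equal(unname(rep$total), c(0, 0))
})

test_that("a circuit that fails validation is refused", {
  circ <- build_rnai_evaluator()$circuit
  circ$pools <- circ$pools[-which(vapply(circ$pools, function(p) p$name, character(1)) == "act_a")]
  expect_error(wire_circuit(circ), "does not validate")
})
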