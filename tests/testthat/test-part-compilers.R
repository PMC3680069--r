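# Closed-form count oracles for the all-repressor, all-strippable promoter
# family and the mRNA-pool affine law, checked against full rule expansion.

promoter_family_counts <- function(n) {
  list(species = 2^n + 1, reactions = 4 * n * 2^(n - 1) + (2^n - 1) + 3)
}

all_rep_promoter <- function(name, tfs, ops_each, strippable = TRUE) {
  promoter_spec(name, lapply(seq_len(tfs), function(i)
    tf_binding(paste0("r", i), "repressor", n_operators = ops_each,
               effector_chemical = if (strippable) paste0("x", i))))
}

reachable_from_seeds <- function(part) {
  net <- part$network
  have <- net$species$label[net$species$seed]
  repeat {
    new <- FALSE
    for (r in net$reactions) {
      if (all(r$reactants %in% have)) {
        add <- setdiff(r$products, have)
        if (length(add)) { have <- c(have, add); new <- TRUE }
      }
    }
    if (!new) break
  }
  setdiff(net$species$label, have)
}

test_that("promoter compiler reproduces the printed part complexities", {
  # single repressor, two operators, chemically strippable
  p <- compile_promoter(all_rep_promoter("p_na", 1, 2))
  expect_equal(unname(p$counts), c(5, 22, 6))
  # three repressors x two operators (the AND1 promoter)
  pa <- compile_promoter(all_rep_promoter("p_and1", 3, 2))
  expect_equal(unname(pa$counts), c(65, 834, 12))
  # two repressors x two operators, not chemically regulated (AND2): the
  # printed species and flux counts; its reaction count is not asserted
  pb <- compile_promoter(all_rep_promoter("p_and2", 2, 2, strippable = FALSE))
  expect_equal(unname(pb$counts[c(1, 3)]), c(17, 7))
  # constitutive promoter
  pc <- compile_promoter(promoter_spec("pc"))
  expect_equal(unname(pc$counts), c(2, 3, 3))
})

test_that("closed-form promoter counts equal rule expansion up to eight operators", {
  cases <- list(c(1, 1), c(1, 3), c(3, 1), c(2, 2), c(1, 6), c(2, 4))
  for (cs in cases) {
    n <- cs[1] * cs[2]
    p <- compile_promoter(all_rep_promoter(sprintf("p%d_%d", cs[1], cs[2]), cs[1], cs[2]))
    oracle <- promoter_family_counts(n)
    expect_equal(unname(p$counts["n_species"]), oracle$species)
    expect_equal(unname(p$counts["n_reactions"]), oracle$reactions)
  }
  p8 <- compile_promoter(all_rep_promoter("p8", 2, 4))
  expect_equal(unname(p8$counts["n_species"]), promoter_family_counts(8)$species)
})

test_that("promoter rates follow the affinity gradient and cooperativity", {
  p <- compile_promoter(promoter_spec("pg", list(
    tf_binding("r", "repressor", n_operators = 3, base_bind_rate = 1e-3,
               affinity_gradient = 4))))
  rates <- vapply(paste0("tf_bind.r.o1_", 1:3), function(rl) {
    rx <- Filter(function(r) r$rule == rl, p$network$reactions)
    # pick the binding from the all-free configuration
    rx <- Filter(function(r) any(grepl("pol~f", r$reactants) &
                                 !grepl("TF_", r$reactants)), rx)
    rx[[1]]$rate
  }, numeric(1))
  # repressors: the strongest operator is the one closest to the TSS
  expect_equal(unname(rates), 1e-3 * 4^-(0:2))

  pcoop <- compile_promoter(promoter_spec("pco", list(
    tf_binding("r", "repressor", n_operators = 2, base_bind_rate = 1e-3,
               cooperative = TRUE, cooperativity_factor = 10))))
  bind2 <- Filter(function(r) r$rule == "tf_bind.r.o1_2", pcoop$network$reactions)
  r_free  <- Filter(function(r) !grepl("TF_r.*TF_r|!1.*TF", paste(r$reactants, collapse = " ")), bind2)
  rates2 <- sort(vapply(bind2, function(r) r$rate, numeric(1)))
  # binding next to an occupied adjacent operator is boosted tenfold
  expect_equal(rates2[1] * 10, rates2[2])
})

test_that("activator promoters gate polymerase on the activation condition", {
  # one activator, one operator, strippable: polymerase binds only the
  # activator-bound configuration; leak fires from the bare one
  p <- compile_promoter(promoter_spec("pact", list(
    tf_binding("A", "activator", n_operators = 1, effector_chemical = "x"))),
    unit = "u1")
  expect_equal(unname(p$counts["n_species"]), 3)
  leaks <- Filter(function(r) r$rule == "leak", p$network$reactions)
  expect_length(leaks, 1L)
  expect_false(any(grepl("TF_A", leaks[[1]]$reactants)))
  binds <- Filter(function(r) r$rule == "rnap_bind", p$network$reactions)
  expect_length(binds, 1L)
  expect_true(any(grepl("TF_A", binds[[1]]$reactants)))
  # stripping the lone activator off a polymerase-bound promoter ejects RNAP
  ej <- Filter(function(r) grepl("tf_strip_poleject", r$rule), p$network$reactions)
  expect_length(ej, 1L)
  expect_true(any(grepl("RNAP", ej[[1]]$products)))
})

test_that("mixed promoters with several cooperative activator species are rejected", {
  spec <- promoter_spec("bad", list(
    tf_binding("A1", "activator", 2, cooperative = TRUE),
    tf_binding("A2", "activator", 2),
    tf_binding("R1", "repressor", 2)))
  expect_error(compile_promoter(spec), "unsupported")
})

test_that("mRNA pool counts follow the affine law over sites and species", {
  term <- terminator_spec("t")
  base <- compile_coding_region(coding_region_spec("c0", "p0", "reporter"), term)
  expect_equal(unname(base$pool$counts), c(5, 9, 2))
  expect_equal(unname(base$nuclear$counts[1:2]), c(3, 6))

  # the two AND-gate pools of the RNAi evaluator
  and1 <- compile_coding_region(coding_region_spec("and1", "gfp", "reporter",
    sirna_targets = list(sirna_target_spec("sa", 2), sirna_target_spec("sb", 2),
                         sirna_target_spec("sd", 2))), term)
  expect_equal(unname(and1$pool$counts), c(17, 45, 5))
  and2 <- compile_coding_region(coding_region_spec("and2", "gfp", "reporter",
    sirna_targets = list(sirna_target_spec("sna", 2), sirna_target_spec("sc", 2))), term)
  expect_equal(unname(and2$pool$counts), c(13, 33, 4))

  # affine law (5 + 2s, 9 + 6s, 2 + k) by expansion, s up to 10
  cases <- list(c(1, 1), c(2, 1), c(2, 2), c(5, 3), c(10, 2), c(10, 10))
  for (cs in cases) {
    s <- cs[1]; k <- cs[2]
    sites_per <- rep(s %/% k, k); sites_per[seq_len(s %% k)] <- sites_per[seq_len(s %% k)] + 1
    tg <- lapply(seq_len(k), function(i)
      sirna_target_spec(paste0("s", i), n_sites = sites_per[i]))
    pool <- compile_coding_region(coding_region_spec("cx", "px", "reporter",
                                                     sirna_targets = tg), term)$pool
    expect_equal(unname(pool$counts), c(5 + 2 * s, 9 + 6 * s, 2 + k))
  }
})

test_that("no mRNA species carries two bound siRNAs and only loaded RISC binds sites", {
  term <- terminator_spec("t")
  pool <- compile_coding_region(coding_region_spec("and1", "gfp", "reporter",
    sirna_targets = list(sirna_target_spec("sa", 2), sirna_target_spec("sb", 2),
                         sirna_target_spec("sd", 2))), term)$pool
  for (g in pool$network$graphs) {
    mi <- partpool:::find_mol_of_type(g, "M_and1")
    if (!length(mi)) next
    states <- g$mols[[mi]]$states
    nb <- sum(states[grepl("^u", names(states))] == "b")
    expect_lte(nb, 1L)
  }
  binds <- Filter(function(r) startsWith(r$rule, "site_bind"), pool$network$reactions)
  expect_true(all(vapply(binds, function(r) any(grepl("^RS_", r$reactants)), logical(1))))
  # cleavage from a ribosome-carrying state releases the ribosome
  clv <- Filter(function(r) startsWith(r$rule, "cleave_rib"), pool$network$reactions)
  expect_true(all(vapply(clv, function(r) "Rib()" %in% r$products, logical(1))))
})

test_that("riboswitches gate ribosome recruitment on the on state", {
  term <- terminator_spec("t")
  pool <- compile_coding_region(coding_region_spec("cr", "pr", "reporter",
    riboswitches = list(riboswitch_spec("single", "th"))), term)$pool
  binds <- Filter(function(r) r$rule == "rib_bind", pool$network$reactions)
  expect_true(length(binds) >= 1L)
  # every ribosome-binding reactant mRNA is in the switched-on state
  expect_true(all(vapply(binds, function(r)
    any(grepl("w1~on", r$reactants)), logical(1))))
  # tandem hetero riboswitch: aptamer binding reactions exist for both chemicals
  pool2 <- compile_coding_region(coding_region_spec("cr2", "pr2", "reporter",
    riboswitches = list(riboswitch_spec("tandem", c("u", "v"),
                                        cooperativity = "hetero"))), term)$pool
  ab <- Filter(function(r) startsWith(r$rule, "aptamer_bind"), pool2$network$reactions)
  chems <- unique(unlist(lapply(ab, function(r) grep("^CH_", r$reactants, value = TRUE))))
  expect_setequal(chems, c("CH_u()", "CH_v()"))
})

test_that("siRNA gene compiles to the six nuclear reactions and a loading pool", {
  term <- terminator_spec("t")
  sg <- compile_sirna_gene(sirna_gene_spec("sa"), term, unit = "u_sa", targets = "and1")
  expect_equal(unname(sg$nuclear$counts[2]), 6)
  rules <- sort(unique(vapply(sg$nuclear$network$reactions, function(r) r$rule, character(1))))
  expect_setequal(rules, c("transcribe", "dicer_bind", "dicer_unbind", "dicer_cat",
                           "export", "nuclear_decay"))
  prules <- vapply(sg$pool$network$reactions, function(r) r$rule, character(1))
  expect_true(all(c("pool_entry", "risc_load", "sirna_decay", "risc_turnover") %in% prules))
})

test_that("all generated rates are positive and species reachable from seeds", {
  term <- terminator_spec("t")
  parts <- list(
    compile_promoter(all_rep_promoter("pp", 2, 2)),
    compile_coding_region(coding_region_spec("cc", "pp2", "reporter",
      sirna_targets = list(sirna_target_spec("s1", 2))), term)$pool,
    compile_sirna_gene(sirna_gene_spec("s1"), term)$nuclear)
  for (part in parts) {
    expect_true(all(vapply(part$network$reactions, function(r) r$rate > 0, logical(1))))
    expect_length(reachable_from_seeds(part), 0L)
  }
})

test_that("pool compilers produce the documented storages", {
  fx <- build_rnai_evaluator()
  pools <- compile_tf_and_protein_pools(fx$circuit)
  names(pools) <- vapply(pools, function(p) p$name, character(1))
  # reporter pool: 1 species, 1 reaction (degradation), 1 intake terminal
  rep <- pools[["pool_gfp"]]
  expect_equal(unname(rep$counts), c(1, 1, 1))
  expect_equal(rep$network$reactions[[1]]$rule, "degrade")
  # machinery pools are conserved storages without reactions
  expect_equal(length(pools[["pool_RNAP"]]$network$reactions), 0L)
  expect_equal(length(pools[["pool_RISC"]]$network$reactions), 0L)
  # input activator pool: free and chemical-bound forms, homeostatic
  act <- pools[["pool_act_a"]]
  expect_setequal(act$internal, c("TF_act_a(d~u)", "TFC_act_a()"))
  arules <- vapply(act$network$reactions, function(r) r$rule, character(1))
  expect_true(all(c("synthesis", "chem_bind", "chem_unbind",
                    "degrade_tf", "degrade_tfc") %in% arules))
})

test_that("a transcription-factor product pool has import, inactivation and turnover", {
  fx <- build_transcriptional_evaluator()
  pools <- compile_tf_and_protein_pools(fx$circuit)
  names(pools) <- vapply(pools, function(p) p$name, character(1))
  pa <- pools[["pool_rep_a"]]
  expect_setequal(pa$internal, c("TF_rep_a(d~u)", "TFC_rep_a()"))
  rules <- sort(vapply(pa$network$reactions, function(r) r$rule, character(1)))
  expect_setequal(unique(rules), c("import", "chem_bind", "chem_unbind",
                                   "degrade_tf", "degrade_tfc"))
})
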