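mt_demo <- function() {
  list(
    Prom = molecule_type("Prom", components = stats::setNames(
      lapply(1:6, function(i) list(states = "s", bindable = TRUE)), paste0("o", 1:6))),
    TF = molecule_type("TF", components = list(d = list(states = "u", bindable = TRUE))),
    Rib = molecule_type("Rib"),
    A = molecule_type("A", components = list(x = list(states = "s", bindable = TRUE)))
  )
}

test_that("canonical labels identify isomorphic graphs and separate distinct ones", {
  mt <- mt_demo()
  expect_equal(canonical_label(species_graph(list(mol("Rib"))), mt), "Rib()")

  # same two-molecule complex, instance order swapped
  g1 <- species_graph(list(mol("TF"), mol("Prom")), bonds = list(c(1, "d", 2, "o2")))
  g2 <- species_graph(list(mol("Prom"), mol("TF")), bonds = list(c(2, "d", 1, "o2")))
  expect_identical(canonical_label(g1, mt), canonical_label(g2, mt))
  expect_true(brute_isomorphic(g1, g2, mt))

  # operators (1,3) bound, bond list order reversed, vs (1,2) bound
  g13 <- species_graph(list(mol("Prom"), mol("TF"), mol("TF")),
                       bonds = list(c(2, "d", 1, "o1"), c(3, "d", 1, "o3")))
  g31 <- species_graph(list(mol("Prom"), mol("TF"), mol("TF")),
                       bonds = list(c(3, "d", 1, "o1"), c(2, "d", 1, "o3")))
  g12 <- species_graph(list(mol("Prom"), mol("TF"), mol("TF")),
                       bonds = list(c(2, "d", 1, "o1"), c(3, "d", 1, "o2")))
  expect_identical(canonical_label(g13, mt), canonical_label(g31, mt))
  expect_false(identical(canonical_label(g13, mt), canonical_label(g12, mt)))
  expect_true(brute_isomorphic(g13, g31, mt))
  expect_false(brute_isomorphic(g13, g12, mt))

  # label is invariant to component states listed in different order
  ga <- species_graph(list(mol("TF", c(d = "u"))))
  expect_identical(canonical_label(ga, mt), canonical_label(species_graph(list(mol("TF"))), mt))

  # malformed bond: two bonds on one component
  bad <- species_graph(list(mol("Prom"), mol("TF"), mol("TF")),
                       bonds = list(c(2, "d", 1, "o1"), c(3, "d", 1, "o1")))
  expect_error(canonical_label(bad, mt), "more than one bond")
})

test_that("pattern matching enumerates embeddings and respects wildcards", {
  mt <- mt_demo()
  # promoter with operators 1 and 2 taken, 3..6 free
  g <- species_graph(list(mol("Prom"), mol("TF"), mol("TF")),
                     bonds = list(c(2, "d", 1, "o1"), c(3, "d", 1, "o2")))
  hits <- lapply(paste0("o", 1:6), function(o)
    match_pattern(species_graph(list(mol("Prom")), free = list(c(1, o)), pattern = TRUE), g, mt))
  expect_equal(vapply(hits, length, integer(1)), c(0L, 0L, 1L, 1L, 1L, 1L))

  # molecule type absent from the graph
  expect_length(match_pattern(species_graph(list(mol("Rib")), pattern = TRUE), g, mt), 0L)

  # symmetric dimer: two embeddings, automorphism count 2
  dimer <- species_graph(list(mol("A"), mol("A")), bonds = list(c(1, "x", 2, "x")))
  pat <- species_graph(list(mol("A"), mol("A")), bonds = list(c(1, "x", 2, "x")), pattern = TRUE)
  expect_length(match_pattern(pat, dimer, mt), 2L)
  expect_equal(partpool:::pattern_automorphisms(pat, mt), 2L)
})

test_that("symmetric embeddings collapse to a single unit-factor reaction", {
  mt <- list(A = molecule_type("A", components = list(x = list(states = "s", bindable = TRUE))))
  pat <- species_graph(list(mol("A"), mol("A")), bonds = list(c(1, "x", 2, "x")), pattern = TRUE)
  dissoc <- rule("dissoc", list(pat), rate = 2,
                 effects = list(list(op = "unbond", mol = 1, comp = "x")))
  rs <- rule_set(mt, seeds = list(list(graph = species_graph(
    list(mol("A"), mol("A")), bonds = list(c(1, "x", 2, "x"))), copies = 10)),
    rules = list(dissoc))
  net <- expand_rules(rs)
  dis <- Filter(function(r) r$rule == "dissoc", net$reactions)
  expect_length(dis, 1L)
  # 2 embeddings / 2 automorphisms -> symmetry factor 1
  expect_equal(dis[[1]]$rate, 2)
})

test_that("expansion closes operator-occupancy space and matches enumeration", {
  # 2 operators: 4 configurations, 4 binding and 4 unbinding reactions
  rs2 <- raw_promoter_ruleset(2)
  net2 <- expand_rules(rs2)
  expect_equal(count_species_with(net2, "Prom"), 4L)
  expect_equal(count_reactions_by_rule(net2, "bind_"), 4L)
  expect_equal(count_reactions_by_rule(net2, "unbind_"), 4L)

  # six operators: the combinatorial-explosion benchmark
  net6 <- expand_rules(raw_promoter_ruleset(6))
  expect_equal(count_species_with(net6, "Prom"), 64L)
  expect_equal(count_reactions_by_rule(net6, "bind_"), 192L)

  # exhaustive-enumeration oracle for several n
  for (n in c(1L, 3L, 5L, 8L)) {
    net <- expand_rules(raw_promoter_ruleset(n))
    oracle <- enumerate_occupancy(n)
    expect_equal(count_species_with(net, "Prom"), oracle$configs)
    expect_equal(count_reactions_by_rule(net, "bind_"), oracle$bind)
    expect_equal(count_reactions_by_rule(net, "unbind_"), oracle$unbind)
  }
})

test_that("empty rule list yields seeds only and zero reactions", {
  mt <- list(Rib = molecule_type("Rib"))
  rs <- rule_set(mt, seeds = list(list(graph = species_graph(list(mol("Rib"))), copies = 7)),
                 rules = list())
  net <- expand_rules(rs)
  expect_equal(net$species$label, "Rib()")
  expect_equal(net$species$copies, 7)
  expect_length(net$reactions, 0L)
})

test_that("expansion is invariant under permutation of rules and seeds", {
  rs <- raw_promoter_ruleset(3)
  net <- expand_rules(rs)
  set.seed(11)
  rs_perm <- rs
  rs_perm$rules <- rs$rules[sample(seq_along(rs$rules))]
  rs_perm$seeds <- rs$seeds[sample(seq_along(rs$seeds))]
  net_perm <- expand_rules(rs_perm)
  expect_identical(net$species$label, net_perm$species$label)
  expect_identical(reaction_multiset(net), reaction_multiset(net_perm))
})

test_that("re-expanding an expanded network's species is a fixed point", {
  rs <- raw_promoter_ruleset(2)
  net <- expand_rules(rs)
  rs2 <- rs
  rs2$seeds <- lapply(names(net$graphs), function(lab)
    list(graph = net$graphs[[lab]], copies = 1))
  net2 <- expand_rules(rs2)
  expect_identical(net$species$label, net2$species$label)
  expect_identical(reaction_multiset(net), reaction_multiset(net2))
})

test_that("expansion aborts with the offending rule when the closure is unbounded", {
  mt <- list(A = molecule_type("A", components = list(x = list(states = c("s0", "s1")))))
  grow <- rule("spawn", list(species_graph(list(mol("A")), pattern = TRUE)), rate = 1,
               effects = list(list(op = "create",
                                   graph = species_graph(list(mol("A"), mol("A"))))))
  # every application creates a bigger disconnected pile -> components of A
  # stay identical, but let the rule flip states so species keep growing
  mt2 <- list(Chain = molecule_type("Chain", components = list(
    x = list(states = "s", bindable = TRUE), y = list(states = "s", bindable = TRUE))))
  ext <- rule("extend",
              list(species_graph(list(mol("Chain")), free = list(c(1, "y")), pattern = TRUE)),
              rate = 1,
              effects = list(list(op = "create", graph = species_graph(list(mol("Chain")))),
                             list(op = "bond", m1 = 1, c1 = "y", m2 = 2, c2 = "x")))
  rs <- rule_set(mt2, seeds = list(list(graph = species_graph(list(mol("Chain"))), copies = 1)),
                 rules = list(ext))
  expect_error(expand_rules(rs, max_species = 25), "max_species.*extend")
})

test_that("bngl-flavoured listing round-trips counts", {
  rs <- raw_promoter_ruleset(2)
  net <- expand_rules(rs)
  path <- tempfile(fileext = ".bngl")
  write_bngl(rs, net, path)
  txt <- readLines(path)
  sp <- grep("^  \\d+ ", txt[seq(which(txt == "begin species") + 1, which(txt == "end species") - 1)])
  expect_equal(length(sp), nrow(net$species))
  expect_true(any(grepl("begin reactions", txt)))
})
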