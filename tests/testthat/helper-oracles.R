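# Independent oracles used across the suite.  These deliberately avoid the
# package's own canonicalization/expansion code paths.

# Brute-force graph isomorphism over all vertex bijections.
brute_isomorphic <- function(g1, g2, mtypes) {
  g1 <- partpool:::resolve_states(g1, mtypes)
  g2 <- partpool:::resolve_states(g2, mtypes)
  n <- length(g1$mols)
  if (n != length(g2$mols)) return(FALSE)
  if (nrow(g1$bm) != nrow(g2$bm)) return(FALSE)
  bondset <- function(g, perm) {
    if (!nrow(g$bm)) return(character(0))
    sort(apply(cbind(g$bm, g$bc), 1, function(row) {
      a <- paste0(perm[as.integer(row[1])], ":", row[3])
      b <- paste0(perm[as.integer(row[2])], ":", row[4])
      paste(sort(c(a, b)), collapse = "--")
    }))
  }
  target_bonds <- bondset(g2, seq_len(n))
  molsig <- function(m) paste(m$type, paste(names(m$states), m$states, collapse = ";"))
  sig2 <- vapply(g2$mols, molsig, character(1))
  perms <- partpool:::permutations_of(seq_len(n))
  for (perm in perms) {
    # perm[i] = image of g1 molecule i in g2
    ok <- all(vapply(seq_len(n), function(i) molsig(g1$mols[[i]]) == sig2[perm[i]], logical(1)))
    if (!ok) next
    if (identical(bondset(g1, perm), target_bonds)) return(TRUE)
  }
  FALSE
}

# Exhaustive enumeration over operator-occupancy bitstrings for a promoter
# with n operators and a single transcription-factor species: counts of
# configurations, binding reactions (one per configuration x free operator)
# and unbinding reactions (one per configuration x bound operator).
enumerate_occupancy <- function(n) {
  configs <- 0L; bind <- 0L; unbind <- 0L
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[1:n])
    configs <- configs + 1L
    bind <- bind + sum(bits == 0L)
    unbind <- unbind + sum(bits == 1L)
  }
  list(configs = configs, bind = bind, unbind = unbind)
}

# Build the raw rule set for an n-operator single-TF promoter (bind/unbind
# only), used to exercise the engine directly without the part compilers.
raw_promoter_ruleset <- function(n, tf_copies = 50) {
  ops <- paste0("o", seq_len(n))
  prom <- molecule_type("Prom", components = stats::setNames(
    lapply(ops, function(o) list(states = "s", bindable = TRUE)), ops))
  tf <- molecule_type("TF", components = list(d = list(states = "u", bindable = TRUE)))
  rules <- list()
  for (i in seq_len(n)) {
    p_tf <- species_graph(list(mol("TF")), free = list(c(1, "d")), pattern = TRUE)
    p_pr <- species_graph(list(mol("Prom")), free = list(c(1, ops[i])), pattern = TRUE)
    rules[[length(rules) + 1L]] <- rule(
      paste0("bind_", ops[i]), list(p_tf, p_pr), rate = 1e-3,
      effects = list(list(op = "bond", m1 = 1, c1 = "d", m2 = 2, c2 = ops[i])))
    p_cx <- species_graph(list(mol("TF"), mol("Prom")),
                          bonds = list(c(1, "d", 2, ops[i])), pattern = TRUE)
    rules[[length(rules) + 1L]] <- rule(
      paste0("unbind_", ops[i]), list(p_cx), rate = 1e-2,
      effects = list(list(op = "unbond", mol = 1, comp = "d")))
  }
  rule_set(list(prom, tf),
           seeds = list(list(graph = species_graph(list(mol("Prom"))), copies = 1),
                        list(graph = species_graph(list(mol("TF"))), copies = tf_copies)),
           rules = rules)
}

count_species_with <- function(net, type) {
  sum(vapply(net$graphs, function(g) any(vapply(g$mols, function(m) m$type == type, logical(1))),
             logical(1)))
}

count_reactions_by_rule <- function(net, prefix) {
  sum(vapply(net$reactions, function(r) startsWith(r$rule, prefix), logical(1)))
}

reaction_multiset <- function(net) {
  sort(vapply(net$reactions, function(r)
    paste(paste(sort(r$reactants), collapse = "+"), "->",
          paste(r$products, collapse = "+"), "@", signif(r$rate, 10), r$rule),
    character(1)))
}

# Algebraic steady-state oracle for a constitutive expression chain
# (promoter -> spliceosome processing -> export -> translation), solved as a
# self-consistent linear fixed point with machinery depletion, independent
# of the ODE integrator.
default_q <- function() {
  tbl <- default_parameters("cascade")
  stats::setNames(tbl$value, tbl$parameter)
}

constitutive_chain_oracle <- function(q = default_q()) {
  R0 <- q[["pool_RNAP"]]; S0 <- q[["pool_spliceosome"]]; Rib0 <- q[["pool_ribosome"]]
  b <- q[["rnap_bind"]]; u <- q[["rnap_unbind"]]; cl <- q[["clearing"]]
  ksb <- q[["splice_bind"]]; ksu <- q[["splice_unbind"]]; ksc <- q[["splice_cat"]]
  kex <- q[["export"]]; krb <- q[["rib_bind"]]; kru <- q[["rib_unbind"]]
  kt <- q[["translation"]]; krel <- 1
  d <- q[["mrna_decay"]]; dp <- q[["protein_deg"]]
  Rf <- R0; Sf <- S0; Ribf <- Rib0
  P <- NA; y <- rep(0, 4); theta <- 0
  for (iter in 1:200) {
    theta <- b * Rf / (b * Rf + u + cl)
    Rf <- R0 - theta
    phi <- cl * theta
    A <- matrix(c(-(d + ksb * Sf), ksu,
                  ksb * Sf, -(ksu + ksc)), 2, 2, byrow = TRUE)
    x <- solve(A, c(-phi, 0))
    C <- x[2]
    Sf <- S0 - C
    psi <- ksc * C
    M <- rbind(c(-(krb * Ribf + d), kru, 0, krel),
               c(krb * Ribf, -(kru + kt + d), 0, 0),
               c(0, kt, -(kt + d), 0),
               c(0, 0, kt, -krel))
    y <- solve(M, c(-psi, 0, 0, 0))
    Ribf <- Rib0 - sum(y[2:4])
    P <- krel * y[4] / dp
  }
  list(protein = unname(P), mrna_states = unname(y), initiation = unname(cl * theta))
}

# protein level produced by a given initiation flux through the same chain
chain_gain_oracle <- function(phi, q = default_q()) {
  S0 <- q[["pool_spliceosome"]]; Rib0 <- q[["pool_ribosome"]]
  ksb <- q[["splice_bind"]]; ksu <- q[["splice_unbind"]]; ksc <- q[["splice_cat"]]
  krb <- q[["rib_bind"]]; kru <- q[["rib_unbind"]]; kt <- q[["translation"]]; krel <- 1
  d <- q[["mrna_decay"]]; dp <- q[["protein_deg"]]
  Sf <- S0; Ribf <- Rib0; P <- NA
  for (iter in 1:200) {
    A <- matrix(c(-(d + ksb * Sf), ksu, ksb * Sf, -(ksu + ksc)), 2, 2, byrow = TRUE)
    x <- solve(A, c(-phi, 0)); C <- x[2]; Sf <- S0 - C
    psi <- ksc * C
    M <- rbind(c(-(krb * Ribf + d), kru, 0, krel),
               c(krb * Ribf, -(kru + kt + d), 0, 0),
               c(0, kt, -(kt + d), 0),
               c(0, 0, kt, -krel))
    y <- solve(M, c(-psi, 0, 0, 0))
    Ribf <- Rib0 - sum(y[2:4])
    P <- krel * y[4] / dp
  }
  unname(P)
}

constitutive_test_circuit <- function() {
  circuit_spec(
    units = list(transcription_unit(
      "u1", promoter_spec("p1"),
      coding_region_spec("c1", "gfp", "reporter"), terminator_spec("t1"))),
    pools = list(pool_spec("RNAP", "RNA_polymerase", "nucleus", 300, conserved = TRUE),
                 pool_spec("ribosome", "ribosome", "cytoplasm", 2000, conserved = TRUE),
                 pool_spec("spliceosome", "machinery", "nucleus", 200, conserved = TRUE)))
}
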