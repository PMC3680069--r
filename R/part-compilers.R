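# Part compilers: translate each part/pool specification into a rule set,
# expand it with the rule engine, and wrap the result as a part model with
# typed flux terminals.
#
# Molecule-type naming conventions (shared across parts so that boundary
# species unify at wiring):
#   P_<prom>    promoter molecule (operator components o<i>_<j>, pol ~ f/b)
#   TF_<t>      free transcription factor (component d, bindable)
#   TFC_<t>     chemical-inactivated factor (lumped complex)
#   CH_<x>      chemical
#   RNAP        free RNA polymerase;  PolCl_<unit>  cleared polymerase (PoPS)
#   TR_<c>      nuclear transcript (st ~ imm/spl, s bindable); SPL spliceosome
#   TRX_<c>     mature transcript in transit to the cytoplasmic pool
#   M_<c>       cytoplasmic mRNA (st ~ f/i/e/t/s, site components u<k>,
#               riboswitch state w<r> and aptamer components a<r>_<k>)
#   Rib         free ribosome;  PR_<p>  protein product
#   DS_<s>      nuclear double-stranded siRNA (st ~ ds/proc); DCR Dicer
#   SIX_<s>     siRNA in transit; SI_<s> free cytoplasmic siRNA
#   RISC        free RISC;  RS_<s>  RISC-loaded siRNA

#' Construct a part model from a rule set
#'
#' Expands the rule set and classifies species as internal (containing one
#' of the part's core molecule types) or boundary (pool-side species shared
#' with other modules through terminals).
#'
#' @param name Part name.
#' @param kind Part kind tag (promoter, coding_nuclear, mrna_pool, ...).
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param rs The [rule_set()].
#' @param core_types Molecule-type names owned by this part.
#' @param terminals List of [terminal()] descriptors.
#' @param max_species Expansion bound.
#' @return A `pp_part` with the expanded network and a `counts` vector
#'   `(n_species, n_reactions, n_terminals)` over internal species.
#' @export
part_model <- function(name, kind, compartment, rs, core_types, terminals,
                       max_species = 10000) {
  net <- expand_rules(rs, max_species = max_species)
  internal <- vapply(net$graphs, function(g)
    any(vapply(g$mols, function(m) m$type %in% core_types, logical(1))), logical(1))
  bad <- vapply(net$reactions, function(r) r$rate <= 0, logical(1))
  if (any(bad))
    stop(sprintf("part '%s': reaction with non-positive rate from rule '%s'",
                 name, net$reactions[[which(bad)[1]]]$rule))
  structure(list(name = name, kind = kind, compartment = compartment,
                 ruleset = rs, network = net,
                 internal = names(net$graphs)[internal],
                 boundary = names(net$graphs)[!internal],
                 terminals = terminals,
                 counts = c(n_species = sum(internal),
                            n_reactions = length(net$reactions),
                            n_terminals = length(terminals))),
            class = "pp_part")
}

#' @export
print.pp_part <- function(x, ...) {
  cat(sprintf("<pp_part> %s [%s, %s]: %d species, %d reactions, %d terminals\n",
              x$name, x$kind, x$compartment,
              x$counts["n_species"], x$counts["n_reactions"], x$counts["n_terminals"]))
  invisible(x)
}

find_mol_of_type <- function(g, type) {
  which(vapply(g$mols, function(m) m$type == type, logical(1)))
}

# shared molecule types
mt_tf    <- function(t) molecule_type(paste0("TF_", t),
                                      list(d = list(states = "u", bindable = TRUE)))
mt_tfc   <- function(t) molecule_type(paste0("TFC_", t))
mt_chem  <- function(x) molecule_type(paste0("CH_", x))
mt_rnap  <- function()  molecule_type("RNAP")
mt_polcl <- function(u) molecule_type(paste0("PolCl_", u))
mt_rib   <- function()  molecule_type("Rib")
mt_spl   <- function()  molecule_type("SPL", list(s = list(states = "u", bindable = TRUE)))
mt_dcr   <- function()  molecule_type("DCR", list(s = list(states = "u", bindable = TRUE)))
mt_risc  <- function()  molecule_type("RISC")
mt_rs    <- function(s) molecule_type(paste0("RS_", s))
mt_pr    <- function(p) molecule_type(paste0("PR_", p))

lab1 <- function(type) paste0(type, "()")

seed0 <- function(...) {
  lapply(list(...), function(tp) list(graph = species_graph(list(mol(tp))), copies = 0))
}

# ---------------------------------------------------------------------------
# Promoter compiler
# ---------------------------------------------------------------------------

#' Compile a promoter specification into a part model
#'
#' Expands the full operator-occupancy state space of the promoter. For
#' every transcription factor and operator the compiler emits binding
#' (affinity-graded, optionally cooperative), unbinding, chemical stripping
#' (if an effector chemical is declared), and bound-factor turnover
#' reactions — one reaction per (configuration, operator) pair. Leak
#' transcription fires once per non-permissive polymerase-free
#' configuration; RNA polymerase binds permissive configurations and
#' initiation emits a cleared polymerase on the outgoing PoPS terminal.
#'
#' For an all-repressor promoter with `n` operators, all chemically
#' regulated, the part holds `2^n + 1` species and
#' `4 n 2^(n-1) + (2^n - 1) + 3` reactions.
#'
#' @param spec A [promoter_spec()].
#' @param unit Name of the transcription unit (names the PoPS flux);
#'   defaults to the promoter name.
#' @param gene_copies Seed copy number of the promoter (DNA template count).
#' @param fourth_family Identity of the fourth per-(configuration, bound
#'   operator) reaction family: `"turnover"` (degradation of the DNA-bound
#'   factor, the default) or `"strip_reverse"` (re-binding of the
#'   inactivated factor with release of its chemical).
#' @param turnover_rate Per-second rate of the fourth family.
#' @return A `pp_part` (see [part_model()]).
#' @export
compile_promoter <- function(spec, unit = spec$name, gene_copies = 1,
                             fourth_family = c("turnover", "strip_reverse"),
                             turnover_rate = 1e-5) {
  fourth_family <- match.arg(fourth_family)
  ptype <- paste0("P_", spec$name)
  bindings <- spec$tf_bindings
  n_act_species <- sum(vapply(bindings, function(b) b$role == "activator", logical(1)))
  n_rep_species <- length(bindings) - n_act_species
  if (n_rep_species > 0 && n_act_species > 1 &&
      any(vapply(bindings, function(b) b$role == "activator" && b$cooperative, logical(1))))
    stop(sprintf("promoter '%s': mixed promoters with more than one cooperative activator species are unsupported", spec$name))

  # operator components per binding: o<bi>_<i>, i = 1 closest to the TSS
  opcomps <- lapply(seq_along(bindings), function(bi)
    paste0("o", bi, "_", seq_len(bindings[[bi]]$n_operators)))
  comps <- list(pol = list(states = c("f", "b"), bindable = FALSE))
  for (oc in unlist(opcomps)) comps[[oc]] <- list(states = "s", bindable = TRUE)
  mtypes <- c(list(molecule_type(ptype, comps), mt_rnap(), mt_polcl(unit)),
              lapply(bindings, function(b) mt_tf(b$tf_name)))
  chems <- unique(unlist(lapply(bindings, function(b) b$effector_chemical)))
  mtypes <- c(mtypes, lapply(chems, mt_chem),
              lapply(bindings[!vapply(bindings, function(b) is.null(b$effector_chemical), logical(1))],
                     function(b) mt_tfc(b$tf_name)))

  bound_ops <- function(g, pm, ops) {
    vapply(ops, function(o) bond_index_at(g, pm, o) > 0L, logical(1))
  }
  # activation/permissiveness of the configuration carried by a species graph
  permissive <- function(g) {
    pm <- find_mol_of_type(g, ptype)[1]
    for (bi in seq_along(bindings)) {
      b <- bindings[[bi]]
      occ <- bound_ops(g, pm, opcomps[[bi]])
      if (b$role == "repressor" && any(occ)) return(FALSE)
    }
    if (n_act_species == 0) return(TRUE)
    any_act <- FALSE
    for (bi in seq_along(bindings)) {
      b <- bindings[[bi]]
      if (b$role != "activator") next
      occ <- bound_ops(g, pm, opcomps[[bi]])
      if (b$cooperative) {
        if (all(occ)) any_act <- TRUE
      } else if (any(occ)) any_act <- TRUE
    }
    any_act
  }

  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r

  for (bi in seq_along(bindings)) {
    b <- bindings[[bi]]
    tft <- paste0("TF_", b$tf_name)
    tfct <- paste0("TFC_", b$tf_name)
    cht <- if (!is.null(b$effector_chemical)) paste0("CH_", b$effector_chemical)
    n <- b$n_operators
    for (i in seq_len(n)) local({
      bi <- bi; b <- b; i <- i
      o <- opcomps[[bi]][i]
      # affinity rank: repressors strongest nearest the TSS, activators
      # strongest furthest from it
      rank <- if (b$role == "repressor") i - 1L else n - i
      bind_rate <- b$base_bind_rate * b$affinity_gradient^(-rank)
      coop_fn <- if (b$cooperative && n > 1L) {
        neigh <- opcomps[[bi]][intersect(c(i - 1L, i + 1L), seq_len(n))]
        function(gl, embs) {
          g <- gl[[2]]; pm <- embs[[2]][1]
          if (any(bound_ops(g, pm, neigh))) b$cooperativity_factor else 1
        }
      } else NULL
      # (a) binding: repressors compete with polymerase (pol must be free),
      # activators may bind a polymerase-bound promoter
      p_tf <- species_graph(list(mol(tft)), free = list(c(1, "d")), pattern = TRUE)
      p_pr <- species_graph(list(mol(ptype,
                                     if (b$role == "repressor") c(pol = "f") else character(0))),
                            free = list(c(1, o)), pattern = TRUE)
      add(rule(sprintf("tf_bind.%s.%s", b$tf_name, o), list(p_tf, p_pr),
               rate = bind_rate,
               effects = list(list(op = "bond", m1 = 1, c1 = "d", m2 = 2, c2 = o)),
               rate_fn = coop_fn))

      # helper guards for removal events from polymerase-bound configurations
      acts_after_removal <- function(g, pm) {
        # activation condition after this operator is freed
        occ_all <- FALSE
        for (bj in seq_along(bindings)) {
          bb <- bindings[[bj]]
          if (bb$role != "activator") next
          occ <- bound_ops(g, pm, opcomps[[bj]])
          if (bj == bi) occ[i] <- FALSE
          if (bb$cooperative) { if (all(occ)) occ_all <- TRUE } else if (any(occ)) occ_all <- TRUE
        }
        occ_all
      }
      ejects <- function(g, pm) {
        if (b$role != "activator") return(FALSE)
        if (b$cooperative) i == n  # freeing the rightmost operator
        else !acts_after_removal(g, pm)
      }

      # removal family generator: pol-free plain removal, pol-bound with and
      # without polymerase ejection
      p_cx  <- function(pol) species_graph(list(mol(ptype, c(pol = pol)), mol(tft)),
                                           bonds = list(c(2, "d", 1, o)), pattern = TRUE)
      removal <- function(tag, rate, pre_reactants, extra_effects, del_tf) {
        base_eff <- c(extra_effects,
                      if (del_tf) list(list(op = "delete", mol = length(pre_reactants) + 2L))
                      else list(list(op = "unbond", mol = length(pre_reactants) + 2L, comp = "d")))
        if (b$role == "repressor") {
          add(rule(sprintf("%s.%s.%s", tag, b$tf_name, o),
                   c(pre_reactants, list(p_cx("f"))), rate = rate, effects = base_eff))
        } else {
          add(rule(sprintf("%s.%s.%s", tag, b$tf_name, o),
                   c(pre_reactants, list(p_cx("f"))), rate = rate, effects = base_eff))
          pi <- length(pre_reactants) + 1L  # promoter pattern molecule index
          add(rule(sprintf("%s_polkeep.%s.%s", tag, b$tf_name, o),
                   c(pre_reactants, list(p_cx("b"))), rate = rate, effects = base_eff,
                   guard = function(gl, embs) {
                     g <- gl[[length(gl)]]; pm <- embs[[length(embs)]][1]
                     !ejects(g, pm)
                   }))
          add(rule(sprintf("%s_poleject.%s.%s", tag, b$tf_name, o),
                   c(pre_reactants, list(p_cx("b"))), rate = rate,
                   effects = c(base_eff,
                               list(list(op = "state", mol = pi, comp = "pol", state = "f"),
                                    list(op = "create", graph = species_graph(list(mol("RNAP")))))),
                   guard = function(gl, embs) {
                     g <- gl[[length(gl)]]; pm <- embs[[length(embs)]][1]
                     ejects(g, pm)
                   }))
        }
      }

      # (b) unbinding
      removal("tf_unbind", b$unbind_rate, list(), list(), del_tf = FALSE)
      # (c) chemical stripping: chem + prom.TF -> prom + TF.chem
      if (!is.null(cht)) {
        p_ch <- species_graph(list(mol(cht)), pattern = TRUE)
        removal("tf_strip", b$base_bind_rate, list(p_ch),
                list(list(op = "delete", mol = 1),
                     list(op = "create", graph = species_graph(list(mol(tfct))))),
                del_tf = TRUE)
      }
      # (d) fourth family
      if (fourth_family == "turnover") {
        removal("tf_turnover", turnover_rate, list(), list(), del_tf = TRUE)
      } else if (!is.null(cht)) {
        p_tfc <- species_graph(list(mol(tfct)), pattern = TRUE)
        p_fr  <- species_graph(list(mol(ptype, c(pol = "f"))), free = list(c(1, o)),
                               pattern = TRUE)
        add(rule(sprintf("tf_restrip.%s.%s", b$tf_name, o), list(p_tfc, p_fr),
                 rate = turnover_rate,
                 effects = list(list(op = "delete", mol = 1),
                                list(op = "create", graph = species_graph(list(mol(tft)))),
                                list(op = "bond", m1 = 3, c1 = "d", m2 = 2, c2 = o),
                                list(op = "create", graph = species_graph(list(mol(paste0("CH_", b$effector_chemical))))))))
      }
    })
  }

  # (e) leak transcription: a free polymerase initiates at a tiny rate from
  # every non-permissive polymerase-free configuration (one reaction per
  # leaky configuration; consuming RNAP keeps the polymerase pool conserved)
  p_any <- species_graph(list(mol(ptype, c(pol = "f"))), pattern = TRUE)
  p_rnap <- species_graph(list(mol("RNAP")), pattern = TRUE)
  add(rule("leak", list(p_rnap, p_any), rate = spec$leak_rate,
           effects = list(list(op = "delete", mol = 1),
                          list(op = "create",
                               graph = species_graph(list(mol(paste0("PolCl_", unit)))))),
           guard = function(gl, embs) !permissive(gl[[2]])))
  # (f) polymerase recruitment on permissive configurations
  add(rule("rnap_bind", list(p_rnap, p_any), rate = spec$rnap_bind_rate,
           effects = list(list(op = "delete", mol = 1),
                          list(op = "state", mol = 2, comp = "pol", state = "b")),
           guard = function(gl, embs) permissive(gl[[2]])))
  p_polb <- species_graph(list(mol(ptype, c(pol = "b"))), pattern = TRUE)
  add(rule("rnap_unbind", list(p_polb), rate = spec$rnap_unbind_rate,
           effects = list(list(op = "state", mol = 1, comp = "pol", state = "f"),
                          list(op = "create", graph = species_graph(list(mol("RNAP")))))))
  add(rule("initiate", list(p_polb), rate = spec$clearing_rate,
           effects = list(list(op = "state", mol = 1, comp = "pol", state = "f"),
                          list(op = "create",
                               graph = species_graph(list(mol(paste0("PolCl_", unit))))))))

  seeds <- c(list(list(graph = species_graph(list(mol(ptype))), copies = gene_copies)),
             seed0("RNAP"),
             lapply(bindings, function(b)
               list(graph = species_graph(list(mol(paste0("TF_", b$tf_name)))), copies = 0)),
             lapply(chems, function(x) list(graph = species_graph(list(mol(paste0("CH_", x)))), copies = 0)))

  terminals <- c(list(terminal("RNAP", "RNA_polymerase", "in", "RNAP()"),
                      terminal("RNAP", "RNA_polymerase", "out", "RNAP()"),
                      terminal(unit, "RNA_polymerase", "out", lab1(paste0("PolCl_", unit)))),
                 unlist(lapply(bindings, function(b) {
                   tl <- list(terminal(b$tf_name, "transcription_factor", "in",
                                       paste0("TF_", b$tf_name, "(d~u)")),
                              terminal(b$tf_name, "transcription_factor", "out",
                                       paste0("TF_", b$tf_name, "(d~u)")))
                   if (!is.null(b$effector_chemical))
                     tl <- c(tl, list(terminal(b$effector_chemical, "chemical", "in",
                                               c(lab1(paste0("CH_", b$effector_chemical)),
                                                 lab1(paste0("TFC_", b$tf_name))))))
                   tl
                 }), recursive = FALSE))

  part_model(spec$name, "promoter", "nucleus",
             rule_set(mtypes, seeds, rules, terminals),
             core_types = ptype, terminals = terminals)
}

# ---------------------------------------------------------------------------
# Coding region compiler (nuclear part + cytoplasmic mRNA pool)
# ---------------------------------------------------------------------------

#' Compile a coding region into its nuclear part and cytoplasmic mRNA pool
#'
#' The nuclear part converts incoming cleared polymerases into immature
#' transcripts, processes them through an elementary-reaction
#' Michaelis--Menten spliceosome scheme, and exports the mature mRNA through
#' a single lumped maturation-and-transport reaction. The cytoplasmic pool
#' carries translation (ribosome recruitment, initiation-to-elongation,
#' termination with product release), transcript decay at the terminator
#' rate, riboswitch gating of ribosome binding, and RISC-mediated
#' RNA-interference on the declared 3'-UTR sites (states with more than one
#' bound siRNA are forbidden).
#'
#' With `s` total siRNA sites over `k` siRNA species and no riboswitches the
#' pool holds `5 + 2 s` species, `9 + 6 s` reactions and `2 + k` terminals.
#'
#' @param spec A [coding_region_spec()].
#' @param term The unit's [terminator_spec()] (transcript decay rate).
#' @param unit Transcription-unit name (PoPS flux name).
#' @return `list(nuclear =, pool =)`, two `pp_part` objects.
#' @export
compile_coding_region <- function(spec, term, unit = spec$name) {
  nm <- spec$name
  trt <- paste0("TR_", nm); trxt <- paste0("TRX_", nm); mt <- paste0("M_", nm)
  prt <- paste0("PR_", spec$product_name)
  polcl <- paste0("PolCl_", unit)
  decay <- term$transcript_decay_rate

  ## --- nuclear part -------------------------------------------------------
  mtypes_n <- list(molecule_type(trt, list(st = list(states = c("imm", "spl")),
                                           s = list(states = "u", bindable = TRUE))),
                   mt_spl(), mt_rnap(), mt_polcl(unit),
                   molecule_type(trxt))
  r_n <- list(
    rule("transcribe", list(species_graph(list(mol(polcl)), pattern = TRUE)), rate = 1,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol("RNAP")))),
                        list(op = "create", graph = species_graph(list(mol(trt)))))),
    rule("splice_bind",
         list(species_graph(list(mol("SPL")), free = list(c(1, "s")), pattern = TRUE),
              species_graph(list(mol(trt, c(st = "imm"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = spec$splice_bind_rate,
         effects = list(list(op = "bond", m1 = 1, c1 = "s", m2 = 2, c2 = "s"))),
    rule("splice_unbind",
         list(species_graph(list(mol(trt, c(st = "imm")), mol("SPL")),
                            bonds = list(c(1, "s", 2, "s")), pattern = TRUE)),
         rate = spec$splice_unbind_rate,
         effects = list(list(op = "unbond", mol = 1, comp = "s"))),
    rule("splice_cat",
         list(species_graph(list(mol(trt, c(st = "imm")), mol("SPL")),
                            bonds = list(c(1, "s", 2, "s")), pattern = TRUE)),
         rate = spec$splice_cat_rate,
         effects = list(list(op = "unbond", mol = 1, comp = "s"),
                        list(op = "state", mol = 1, comp = "st", state = "spl"))),
    rule("export",
         list(species_graph(list(mol(trt, c(st = "spl"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = spec$export_rate,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol(trxt)))))),
    rule("nuclear_decay",
         list(species_graph(list(mol(trt, c(st = "imm"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = decay,
         effects = list(list(op = "delete", mol = 1))))
  seeds_n <- c(list(list(graph = species_graph(list(mol(trt))), copies = 0)),
               seed0(polcl, "RNAP", "SPL"))
  term_n <- list(terminal(unit, "RNA_polymerase", "in", lab1(polcl)),
                 terminal("RNAP", "RNA_polymerase", "out", "RNAP()"),
                 terminal("spliceosome", "machinery", "in", "SPL(s~u)"),
                 terminal(nm, "transcript", "out", lab1(trxt)))
  nuclear <- part_model(paste0(nm, "_nuc"), "coding_nuclear", "nucleus",
                        rule_set(mtypes_n, seeds_n, r_n, term_n),
                        core_types = trt, terminals = term_n)

  ## --- cytoplasmic mRNA pool ---------------------------------------------
  sirnas <- spec$sirna_targets
  riboswitches <- spec$riboswitches
  comps <- list(st = list(states = c("f", "i", "e", "t", "s")))
  site_comps <- list(); site_of <- list()
  for (si in seq_along(sirnas)) {
    for (j in seq_len(sirnas[[si]]$n_sites)) {
      u <- sprintf("u%d_%d", si, j)
      comps[[u]] <- list(states = c("f", "b"))
      site_comps[[length(site_comps) + 1L]] <- u
      site_of[[length(site_of) + 1L]] <- si
    }
  }
  for (ri in seq_along(riboswitches)) {
    comps[[sprintf("w%d", ri)]] <- list(states = c("off", "on"))
    for (k in seq_along(riboswitches[[ri]]$aptamer_chemicals))
      comps[[sprintf("a%d_%d", ri, k)]] <- list(states = c("f", "b"))
  }
  rs_chems <- unique(unlist(lapply(riboswitches, function(r) r$aptamer_chemicals)))
  mtypes_p <- c(list(molecule_type(mt, comps), molecule_type(trxt),
                     mt_rib(), mt_pr(spec$product_name)),
                lapply(unique(vapply(sirnas, function(s) s$sirna_name, character(1))), mt_rs),
                lapply(rs_chems, mt_chem))
  site_names <- unlist(site_comps)

  no_site_bound <- function(g, mm) {
    !length(site_names) ||
      all(vapply(site_names, function(u) g$mols[[mm]]$states[[u]] == "f", logical(1)))
  }
  all_switches_on <- function(g, mm) {
    !length(riboswitches) ||
      all(vapply(seq_along(riboswitches), function(ri)
        g$mols[[mm]]$states[[sprintf("w%d", ri)]] == "on", logical(1)))
  }
  m_pat <- function(st = NULL, set = character(0)) {
    stv <- c(if (!is.null(st)) c(st = st), set)
    species_graph(list(mol(mt, stv)), pattern = TRUE)
  }

  r_p <- list(
    rule("pool_entry", list(species_graph(list(mol(trxt)), pattern = TRUE)), rate = 1,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol(mt)))))),
    rule("rib_bind",
         list(species_graph(list(mol("Rib")), pattern = TRUE), m_pat("f")),
         rate = spec$ribosome_bind_rate,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "state", mol = 2, comp = "st", state = "i")),
         guard = function(gl, embs)
           no_site_bound(gl[[2]], embs[[2]][1]) && all_switches_on(gl[[2]], embs[[2]][1])),
    rule("rib_unbind", list(m_pat("i")), rate = spec$ribosome_unbind_rate,
         effects = list(list(op = "state", mol = 1, comp = "st", state = "f"),
                        list(op = "create", graph = species_graph(list(mol("Rib")))))),
    rule("elongate", list(m_pat("i")), rate = spec$translation_rate,
         effects = list(list(op = "state", mol = 1, comp = "st", state = "e"))),
    rule("terminate", list(m_pat("e")), rate = spec$translation_rate,
         effects = list(list(op = "state", mol = 1, comp = "st", state = "t"))),
    rule("release", list(m_pat("t")), rate = 1,
         effects = list(list(op = "state", mol = 1, comp = "st", state = "f"),
                        list(op = "create", graph = species_graph(list(mol("Rib")))),
                        list(op = "create", graph = species_graph(list(mol(prt)))))),
    rule("decay_free", list(m_pat("f")), rate = decay,
         effects = list(list(op = "delete", mol = 1)),
         guard = function(gl, embs) no_site_bound(gl[[1]], embs[[1]][1])),
    rule("decay_initiating", list(m_pat("i")), rate = decay,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol("Rib")))))),
    rule("decay_elongating", list(m_pat("e")), rate = decay,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol("Rib"))))))
  )
  add_p <- function(r) r_p[[length(r_p) + 1L]] <<- r

  # RNA interference: the loaded RISC binds any single free site; a bound
  # site triggers cleavage with rapid degradation releasing the machinery
  for (kk in seq_along(site_names)) local({
    u <- site_names[kk]; si <- site_of[[kk]]
    sp <- sirnas[[si]]
    rst <- paste0("RS_", sp$sirna_name)
    p_rs <- species_graph(list(mol(rst)), pattern = TRUE)
    for (st_from in c("f", "i", "e", "t")) local({
      st_from <- st_from
      eff <- list(list(op = "delete", mol = 1),
                  list(op = "state", mol = 2, comp = u, state = "b"))
      if (st_from != "f")
        eff <- c(eff, list(list(op = "state", mol = 2, comp = "st", state = "s")))
      add_p(rule(sprintf("site_bind.%s.%s", u, st_from),
                 list(p_rs, m_pat(st_from, stats::setNames("f", u))),
                 rate = sp$bind_rate, effects = eff,
                 guard = function(gl, embs) no_site_bound(gl[[2]], embs[[2]][1])))
    })
    add_p(rule(sprintf("cleave.%s", u), list(m_pat("f", stats::setNames("b", u))),
               rate = sp$cleavage_rate,
               effects = list(list(op = "delete", mol = 1),
                              list(op = "create", graph = species_graph(list(mol(rst)))))))
    add_p(rule(sprintf("cleave_rib.%s", u), list(m_pat("s", stats::setNames("b", u))),
               rate = sp$cleavage_rate,
               effects = list(list(op = "delete", mol = 1),
                              list(op = "create", graph = species_graph(list(mol(rst)))),
                              list(op = "create", graph = species_graph(list(mol("Rib")))))))
  })

  # riboswitch gating: aptamer occupancy drives the conformational switch
  for (ri in seq_along(riboswitches)) local({
    ri <- ri; rsw <- riboswitches[[ri]]
    w <- sprintf("w%d", ri)
    aps <- sprintf("a%d_%d", ri, seq_along(rsw$aptamer_chemicals))
    for (k in seq_along(rsw$aptamer_chemicals)) local({
      k <- k
      cht <- paste0("CH_", rsw$aptamer_chemicals[k])
      other <- setdiff(seq_along(aps), k)
      coop_fn <- if (rsw$cooperativity != "none" && length(other)) {
        function(gl, embs) {
          g <- gl[[2]]; mm <- embs[[2]][1]
          if (all(g$mols[[mm]]$states[aps[other]] == "b")) rsw$cooperativity_factor else 1
        }
      } else NULL
      add_p(rule(sprintf("aptamer_bind.%d.%d", ri, k),
                 list(species_graph(list(mol(cht)), pattern = TRUE),
                      m_pat(set = stats::setNames("f", aps[k]))),
                 rate = rsw$chem_bind_rate,
                 effects = list(list(op = "delete", mol = 1),
                                list(op = "state", mol = 2, comp = aps[k], state = "b")),
                 rate_fn = coop_fn))
      add_p(rule(sprintf("aptamer_unbind.%d.%d", ri, k),
                 list(m_pat(set = stats::setNames("b", aps[k]))),
                 rate = rsw$chem_unbind_rate,
                 effects = list(list(op = "state", mol = 1, comp = aps[k], state = "f"),
                                list(op = "create", graph = species_graph(list(mol(cht)))))))
    })
    add_p(rule(sprintf("switch_on.%d", ri), list(m_pat(set = stats::setNames("off", w))),
               rate = rsw$switch_on_rate,
               effects = list(list(op = "state", mol = 1, comp = w, state = "on")),
               guard = function(gl, embs)
                 all(gl[[1]]$mols[[embs[[1]][1]]]$states[aps] == "b")))
    add_p(rule(sprintf("switch_off.%d", ri), list(m_pat(set = stats::setNames("on", w))),
               rate = rsw$switch_off_rate,
               effects = list(list(op = "state", mol = 1, comp = w, state = "off")),
               guard = function(gl, embs)
                 !all(gl[[1]]$mols[[embs[[1]][1]]]$states[aps] == "b")))
  })

  sirna_names <- unique(vapply(sirnas, function(s) s$sirna_name, character(1)))
  seeds_p <- c(list(list(graph = species_graph(list(mol(trxt))), copies = 0)),
               seed0("Rib", prt),
               lapply(sirna_names, function(s)
                 list(graph = species_graph(list(mol(paste0("RS_", s)))), copies = 0)),
               lapply(rs_chems, function(x)
                 list(graph = species_graph(list(mol(paste0("CH_", x)))), copies = 0)))
  term_p <- c(list(terminal("ribosome", "ribosome", "in", "Rib()"),
                   terminal(spec$product_name, "protein", "out", lab1(prt))),
              lapply(sirna_names, function(s)
                terminal(s, "small_RNA", "in", lab1(paste0("RS_", s)))),
              lapply(rs_chems, function(x)
                terminal(x, "chemical", "in", lab1(paste0("CH_", x)))))
  pool <- part_model(paste0(nm, "_pool"), "mrna_pool", "cytoplasm",
                     rule_set(mtypes_p, seeds_p, r_p, term_p),
                     core_types = c(mt, trxt), terminals = term_p)
  list(nuclear = nuclear, pool = pool)
}

# ---------------------------------------------------------------------------
# siRNA gene compiler (nuclear part + cytoplasmic siRNA pool)
# ---------------------------------------------------------------------------

#' Compile an siRNA gene into its nuclear part and cytoplasmic siRNA pool
#'
#' The nuclear part converts incoming cleared polymerases into
#' double-stranded siRNA, processes it through an elementary-reaction
#' Michaelis--Menten Dicer scheme, and exports the processed guide through a
#' single lumped maturation-and-transport reaction. The cytoplasmic pool
#' holds the free siRNA, loads it onto free RISC, decays the free siRNA at
#' the terminator rate, and turns the loaded complex back over to free RISC.
#'
#' @param spec An [sirna_gene_spec()].
#' @param term The unit's [terminator_spec()].
#' @param unit Transcription-unit name.
#' @param targets Names of the coding regions whose mRNA pools this siRNA
#'   targets (used for terminal declarations).
#' @return `list(nuclear =, pool =)`, two `pp_part` objects.
#' @export
compile_sirna_gene <- function(spec, term, unit = spec$sirna_name,
                               targets = character(0)) {
  s <- spec$sirna_name
  dst <- paste0("DS_", s); sixt <- paste0("SIX_", s); sit <- paste0("SI_", s)
  rst <- paste0("RS_", s); polcl <- paste0("PolCl_", unit)
  decay <- term$transcript_decay_rate

  mtypes_n <- list(molecule_type(dst, list(st = list(states = c("ds", "proc")),
                                           s = list(states = "u", bindable = TRUE))),
                   mt_dcr(), mt_rnap(), mt_polcl(unit), molecule_type(sixt))
  r_n <- list(
    rule("transcribe", list(species_graph(list(mol(polcl)), pattern = TRUE)), rate = 1,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol("RNAP")))),
                        list(op = "create", graph = species_graph(list(mol(dst)))))),
    rule("dicer_bind",
         list(species_graph(list(mol("DCR")), free = list(c(1, "s")), pattern = TRUE),
              species_graph(list(mol(dst, c(st = "ds"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = spec$dicer_bind_rate,
         effects = list(list(op = "bond", m1 = 1, c1 = "s", m2 = 2, c2 = "s"))),
    rule("dicer_unbind",
         list(species_graph(list(mol(dst, c(st = "ds")), mol("DCR")),
                            bonds = list(c(1, "s", 2, "s")), pattern = TRUE)),
         rate = spec$dicer_unbind_rate,
         effects = list(list(op = "unbond", mol = 1, comp = "s"))),
    rule("dicer_cat",
         list(species_graph(list(mol(dst, c(st = "ds")), mol("DCR")),
                            bonds = list(c(1, "s", 2, "s")), pattern = TRUE)),
         rate = spec$dicer_cat_rate,
         effects = list(list(op = "unbond", mol = 1, comp = "s"),
                        list(op = "state", mol = 1, comp = "st", state = "proc"))),
    rule("export",
         list(species_graph(list(mol(dst, c(st = "proc"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = spec$export_rate,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol(sixt)))))),
    rule("nuclear_decay",
         list(species_graph(list(mol(dst, c(st = "ds"))), free = list(c(1, "s")), pattern = TRUE)),
         rate = decay,
         effects = list(list(op = "delete", mol = 1))))
  seeds_n <- c(list(list(graph = species_graph(list(mol(dst))), copies = 0)),
               seed0(polcl, "RNAP", "DCR"))
  term_n <- list(terminal(unit, "RNA_polymerase", "in", lab1(polcl)),
                 terminal("RNAP", "RNA_polymerase", "out", "RNAP()"),
                 terminal("Dicer", "machinery", "in", "DCR(s~u)"),
                 terminal(s, "transcript", "out", lab1(sixt)))
  nuclear <- part_model(paste0(s, "_nuc"), "sirna_nuclear", "nucleus",
                        rule_set(mtypes_n, seeds_n, r_n, term_n),
                        core_types = dst, terminals = term_n)

  mtypes_p <- list(molecule_type(sixt), molecule_type(sit), mt_risc(), mt_rs(s))
  r_p <- list(
    rule("pool_entry", list(species_graph(list(mol(sixt)), pattern = TRUE)), rate = 1,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol(sit)))))),
    rule("risc_load",
         list(species_graph(list(mol("RISC")), pattern = TRUE),
              species_graph(list(mol(sit)), pattern = TRUE)),
         rate = spec$risc_load_rate,
         effects = list(list(op = "delete", mol = 1), list(op = "delete", mol = 2),
                        list(op = "create", graph = species_graph(list(mol(rst)))))),
    rule("sirna_decay", list(species_graph(list(mol(sit)), pattern = TRUE)), rate = decay,
         effects = list(list(op = "delete", mol = 1))),
    rule("risc_turnover", list(species_graph(list(mol(rst)), pattern = TRUE)),
         rate = spec$risc_unload_rate,
         effects = list(list(op = "delete", mol = 1),
                        list(op = "create", graph = species_graph(list(mol("RISC")))))))
  seeds_p <- c(seed0(sixt, sit, "RISC", rst))
  term_p <- c(list(terminal("RISC", "machinery", "in", "RISC()")),
              lapply(targets, function(tg) terminal(s, "small_RNA", "out", lab1(rst))))
  pool <- part_model(paste0(s, "_pool"), "sirna_pool", "cytoplasm",
                     rule_set(mtypes_p, seeds_p, r_p, term_p),
                     core_types = c(sit, sixt), terminals = term_p)
  list(nuclear = nuclear, pool = pool)
}

# ---------------------------------------------------------------------------
# Transcription factor, product, machinery and chemical pools
# ---------------------------------------------------------------------------

mk_simple_rules <- function(entries) Filter(Negate(is.null), entries)

#' Compile the circuit's factor, product, machinery and chemical pools
#'
#' For each transcription-factor product: a cytoplasmic synthesis intake
#' terminal, first-order nuclear import, and a nuclear free-factor pool with
#' chemical binding/unbinding and first-order degradation of both forms.
#' Reporters get a cytoplasmic pool with degradation only. Pools declared in
#' the circuit (input factors) get optional zero-order production,
#' degradation and chemical inactivation. Machinery pools (RNAP, ribosome,
#' spliceosome, Dicer, RISC) are conserved storages without synthesis or
#' degradation; chemical pools are the clamped interface to the
#' environment.
#'
#' @param circuit A validated [circuit_spec()].
#' @param import_rate,degradation_rate Defaults for product pools that have
#'   no explicit [pool_spec()] override in `circuit$pools`.
#' @return List of `pp_part` objects.
#' @export
compile_tf_and_protein_pools <- function(circuit, import_rate = 2e-3,
                                         degradation_rate = 1e-4) {
  parts <- list()
  declared <- stats::setNames(circuit$pools,
                              vapply(circuit$pools, function(p) p$name, character(1)))
  # effector chemical of a factor, as referenced by any promoter
  effector_of <- function(tf) {
    for (u in circuit$units) for (b in u$promoter$tf_bindings)
      if (b$tf_name == tf && !is.null(b$effector_chemical))
        return(list(chem = b$effector_chemical,
                    bind = b$base_bind_rate, unbind = b$unbind_rate))
    NULL
  }

  tf_pool_part <- function(t, decl, intake) {
    tft <- paste0("TF_", t); tfct <- paste0("TFC_", t)
    eff <- if (!is.null(decl) && !is.null(decl$effector_chemical))
      list(chem = decl$effector_chemical, bind = decl$chem_bind_rate,
           unbind = decl$chem_unbind_rate)
    else effector_of(t)
    deg <- if (!is.null(decl) && !is.null(decl$degradation_rate)) decl$degradation_rate else degradation_rate
    imp <- if (!is.null(decl) && !is.null(decl$import_rate)) decl$import_rate else import_rate
    prod_rate <- if (!is.null(decl)) decl$production_rate else NULL
    mtypes <- c(list(mt_tf(t), mt_tfc(t)),
                if (intake) list(mt_pr(t)),
                if (!is.null(eff)) list(mt_chem(eff$chem)))
    rules <- mk_simple_rules(list(
      if (intake)
        rule("import", list(species_graph(list(mol(paste0("PR_", t))), pattern = TRUE)),
             rate = imp,
             effects = list(list(op = "delete", mol = 1),
                            list(op = "create", graph = species_graph(list(mol(tft)))))),
      if (!is.null(prod_rate))
        rule("synthesis", list(), rate = prod_rate,
             effects = list(list(op = "create", graph = species_graph(list(mol(tft)))))),
      if (!is.null(eff))
        rule("chem_bind",
             list(species_graph(list(mol(paste0("CH_", eff$chem))), pattern = TRUE),
                  species_graph(list(mol(tft)), free = list(c(1, "d")), pattern = TRUE)),
             rate = eff$bind,
             effects = list(list(op = "delete", mol = 1), list(op = "delete", mol = 2),
                            list(op = "create", graph = species_graph(list(mol(tfct)))))),
      if (!is.null(eff))
        rule("chem_unbind", list(species_graph(list(mol(tfct)), pattern = TRUE)),
             rate = eff$unbind,
             effects = list(list(op = "delete", mol = 1),
                            list(op = "create", graph = species_graph(list(mol(tft)))),
                            list(op = "create",
                                 graph = species_graph(list(mol(paste0("CH_", eff$chem))))))),
      if (deg > 0)
        rule("degrade_tf", list(species_graph(list(mol(tft)), free = list(c(1, "d")),
                                              pattern = TRUE)),
             rate = deg, effects = list(list(op = "delete", mol = 1))),
      if (deg > 0)
        rule("degrade_tfc", list(species_graph(list(mol(tfct)), pattern = TRUE)),
             rate = deg, effects = list(list(op = "delete", mol = 1)))))
    seeds <- c(list(list(graph = species_graph(list(mol(tft))),
                         copies = if (!is.null(decl)) decl$initial_copies else 0),
                    list(graph = species_graph(list(mol(tfct))), copies = 0)),
               if (intake) seed0(paste0("PR_", t)),
               if (!is.null(eff)) seed0(paste0("CH_", eff$chem)))
    terms <- c(if (intake) list(terminal(t, "protein", "in", lab1(paste0("PR_", t)))),
               list(terminal(t, "transcription_factor", "out", paste0("TF_", t, "(d~u)")),
                    terminal(t, "transcription_factor", "in",
                             c(paste0("TF_", t, "(d~u)"), lab1(tfct)))),
               if (!is.null(eff)) list(terminal(eff$chem, "chemical", "in",
                                                lab1(paste0("CH_", eff$chem)))))
    part_model(paste0("pool_", t), "tf_pool", "nucleus",
               rule_set(mtypes, seeds, rules, terms),
               core_types = c(tft, tfct), terminals = terms)
  }

  seen_products <- character(0)
  for (u in circuit$units) {
    if (!inherits(u$cargo, "pp_coding_region")) next
    p <- u$cargo$product_name
    if (p %in% seen_products) next
    seen_products <- c(seen_products, p)
    if (u$cargo$product_kind == "transcription_factor") {
      parts[[length(parts) + 1L]] <- tf_pool_part(p, declared[[p]], intake = TRUE)
    } else {
      decl <- declared[[p]]
      deg <- if (!is.null(decl) && !is.null(decl$degradation_rate)) decl$degradation_rate else degradation_rate
      prt <- paste0("PR_", p)
      rules <- list(rule("degrade", list(species_graph(list(mol(prt)), pattern = TRUE)),
                         rate = deg, effects = list(list(op = "delete", mol = 1))))
      terms <- list(terminal(p, "protein", "in", lab1(prt)))
      parts[[length(parts) + 1L]] <-
        part_model(paste0("pool_", p), "reporter_pool", "cytoplasm",
                   rule_set(list(mt_pr(p)), seed0(prt), rules, terms),
                   core_types = prt, terminals = terms)
    }
  }
  # declared pools: machinery and input factors
  for (p in circuit$pools) {
    if (p$name %in% seen_products) next
    if (p$name %in% MACHINERY) {
      mtype <- switch(p$name, RNAP = mt_rnap(), ribosome = mt_rib(),
                      spliceosome = mt_spl(), Dicer = mt_dcr(), RISC = mt_risc())
      stlab <- canonical_label(species_graph(list(mol(mtype$name))), stats::setNames(list(mtype), mtype$name))
      carr <- switch(p$name, RNAP = "RNA_polymerase", ribosome = "ribosome", "machinery")
      terms <- list(terminal(p$name, carr, "out", stlab),
                    terminal(p$name, carr, "in", stlab))
      parts[[length(parts) + 1L]] <-
        part_model(paste0("pool_", p$name), "machinery_pool", p$compartment,
                   rule_set(list(mtype),
                            list(list(graph = species_graph(list(mol(mtype$name))),
                                      copies = p$initial_copies)),
                            list(), terms),
                   core_types = mtype$name, terminals = terms)
    } else if (p$carrier == "transcription_factor") {
      parts[[length(parts) + 1L]] <- tf_pool_part(p$name, p, intake = FALSE)
    } else {
      stop(sprintf("pool '%s': only machinery and transcription-factor pools may be declared explicitly", p$name))
    }
  }
  # chemical input pools (clamped by the simulation schedule)
  for (x in circuit$chemical_inputs) {
    cht <- paste0("CH_", x)
    terms <- list(terminal(x, "chemical", "out", lab1(cht)))
    parts[[length(parts) + 1L]] <-
      part_model(paste0("pool_", x), "chemical_pool", "cytoplasm",
                 rule_set(list(mt_chem(x)), seed0(cht), list(), terms),
                 core_types = cht, terminals = terms)
  }
  parts
}
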