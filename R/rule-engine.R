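# Generic rule-based reaction-network expansion: molecule types with typed
# components, species graphs with bonds, pattern matching, and breadth-first
# closure of seed species under rewrite rules.

#' Define a molecule type
#'
#' A molecule type declares the named components a molecule carries, the
#' finite set of internal states each component may take, and whether the
#' component can form bonds with components of other molecules.
#'
#' @param name Molecule type name (character scalar).
#' @param components Named list; each element is a list with entries
#'   `states` (character vector of allowed states; the first is the default)
#'   and `bindable` (logical). An empty list declares a structureless
#'   molecule.
#' @return An object of class `pp_moltype`.
#' @examples
#' molecule_type("TF", components = list(dna = list(states = "u", bindable = TRUE)))
#' @export
molecule_type <- function(name, components = list()) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  if (length(components)) {
    if (is.null(names(components)) || anyDuplicated(names(components)))
      stop("component names must be present and unique within a molecule type")
    components <- lapply(components, function(cc) {
      list(states = as.character(cc$states %||% "s"),
           bindable = isTRUE(cc$bindable))
    })
  }
  structure(list(name = name, comps = components,
                 comp_order = names(components) %||% character(0)),
            class = "pp_moltype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pp_moltype <- function(x, ...) {
  comps <- vapply(seq_along(x$comps), function(i) {
    cc <- x$comps[[i]]
    paste0(names(x$comps)[i], "~{", paste(cc$states, collapse = ","), "}",
           if (cc$bindable) "!" else "")
  }, character(1))
  cat(sprintf("%s(%s)\n", x$name, paste(comps, collapse = ", ")))
  invisible(x)
}

# --- molecule instances and species graphs ---------------------------------

#' Construct a molecule instance
#'
#' @param type Molecule type name.
#' @param states Named character vector of component states; components left
#'   out take the type's default (first listed) state. `NA` states are only
#'   meaningful inside patterns, where they act as wildcards.
#' @return A molecule instance (plain list) for use in [species_graph()].
#' @export
mol <- function(type, states = character(0)) {
  list(type = type, states = states)
}

#' Construct a species graph
#'
#' A species graph is a connected (or to-be-connected) multiset of molecule
#' instances plus bonds between bindable components. Bonds are given as
#' 4-element vectors `c(mol_index_1, component_1, mol_index_2, component_2)`.
#'
#' @param mols List of molecule instances from [mol()].
#' @param bonds List of 4-element bond descriptors.
#' @param free Only for patterns: list of `c(mol_index, component)` pairs that
#'   are required to be unbound in a match.
#' @param pattern Logical; if `TRUE`, unspecified component states stay `NA`
#'   (wildcards) instead of defaulting.
#' @return An object of class `pp_sgraph`.
#' @export
species_graph <- function(mols, bonds = list(), free = list(), pattern = FALSE) {
  structure(list(mols = mols,
                 bm = if (length(bonds)) t(vapply(bonds, function(b) as.integer(b[c(1, 3)]), integer(2))) else matrix(integer(0), 0, 2),
                 bc = if (length(bonds)) t(vapply(bonds, function(b) as.character(b[c(2, 4)]), character(2))) else matrix(character(0), 0, 2),
                 free = free,
                 pattern = isTRUE(pattern)),
            class = "pp_sgraph")
}

# Resolve full state vectors against the molecule-type registry.
# For non-patterns, unspecified components take defaults; for patterns NA.
resolve_states <- function(g, mtypes) {
  if (isTRUE(attr(g, "resolved"))) return(g)
  g$mols <- lapply(g$mols, function(m) {
    mt <- mtypes[[m$type]]
    if (is.null(mt)) stop(sprintf("unknown molecule type '%s'", m$type))
    full <- stats::setNames(rep(NA_character_, length(mt$comp_order)), mt$comp_order)
    if (!g$pattern)
      full[] <- vapply(mt$comps, function(cc) cc$states[1], character(1))
    if (length(m$states)) {
      bad <- setdiff(names(m$states), mt$comp_order)
      if (length(bad)) stop(sprintf("molecule '%s' has no component '%s'", m$type, bad[1]))
      full[names(m$states)] <- m$states
    }
    m$states <- full
    m
  })
  attr(g, "resolved") <- TRUE
  g
}

bond_index_at <- function(g, m, comp) {
  if (!nrow(g$bm)) return(0L)
  hit <- which((g$bm[, 1] == m & g$bc[, 1] == comp) | (g$bm[, 2] == m & g$bc[, 2] == comp))
  if (length(hit)) hit[1] else 0L
}

check_graph <- function(g, mtypes) {
  if (isTRUE(attr(g, "checked"))) return(g)
  g <- resolve_states(g, mtypes)
  if (nrow(g$bm)) {
    seen <- character(0)
    for (k in seq_len(nrow(g$bm))) {
      for (side in 1:2) {
        m <- g$bm[k, side]; comp <- g$bc[k, side]
        if (m < 1L || m > length(g$mols)) stop("bond references missing molecule")
        mt <- mtypes[[g$mols[[m]]$type]]
        if (!comp %in% mt$comp_order) stop(sprintf("bond references missing component '%s' on '%s'", comp, mt$name))
        if (!mt$comps[[comp]]$bindable) stop(sprintf("component '%s' of '%s' is not bindable", comp, mt$name))
        key <- paste(m, comp)
        if (key %in% seen) stop(sprintf("component '%s' of molecule %d carries more than one bond", comp, m))
        seen <- c(seen, key)
      }
    }
  }
  attr(g, "checked") <- TRUE
  g
}

# --- canonicalization -------------------------------------------------------

mol_base_sig <- function(m) {
  paste0(m$type, "(", paste(names(m$states), "~",
                            ifelse(is.na(m$states), "?", m$states),
                            sep = "", collapse = ","), ")")
}

# One round of neighbourhood refinement: a molecule's signature is its own
# type+states plus the sorted multiset of (own component, partner base
# signature, partner component) over its bonds.  Ties after refinement are
# resolved by exhaustive permutation, which keeps labelling exact.
mol_refined_sig <- function(g, base) {
  n <- length(g$mols)
  out <- character(n)
  for (i in seq_len(n)) {
    descr <- character(0)
    if (nrow(g$bm)) {
      for (k in seq_len(nrow(g$bm))) {
        if (g$bm[k, 1] == i)
          descr <- c(descr, paste0(g$bc[k, 1], ">", base[g$bm[k, 2]], "@", g$bc[k, 2]))
        if (g$bm[k, 2] == i)
          descr <- c(descr, paste0(g$bc[k, 2], ">", base[g$bm[k, 1]], "@", g$bc[k, 1]))
      }
    }
    out[i] <- paste0(base[i], "|", paste(sort(descr), collapse = ";"))
  }
  out
}

serialize_ordering <- function(g, ord, mtypes) {
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  bond_id <- integer(nrow(g$bm))
  next_id <- 0L
  pieces <- character(length(ord))
  for (p in seq_along(ord)) {
    i <- ord[p]
    m <- g$mols[[i]]
    mt <- mtypes[[m$type]]
    cs <- character(length(mt$comp_order))
    for (ci in seq_along(mt$comp_order)) {
      comp <- mt$comp_order[ci]
      s <- m$states[[comp]]
      lab <- paste0(comp, "~", if (is.na(s)) "?" else s)
      bk <- bond_index_at(g, i, comp)
      if (bk > 0L) {
        if (bond_id[bk] == 0L) { next_id <- next_id + 1L; bond_id[bk] <- next_id }
        lab <- paste0(lab, "!", bond_id[bk])
      }
      cs[ci] <- lab
    }
    pieces[p] <- paste0(m$type, "(", paste(cs, collapse = ","), ")")
  }
  paste(pieces, collapse = ".")
}

perm_expand <- function(groups) {
  # cartesian product of within-group permutations -> list of full orderings
  orderings <- list(integer(0))
  for (grp in groups) {
    perms <- permutations_of(grp)
    orderings <- unlist(lapply(orderings, function(o) lapply(perms, function(p) c(o, p))),
                        recursive = FALSE)
  }
  orderings
}

permutations_of <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Canonical label of a species graph
#'
#' Equal labels are returned exactly for isomorphic graphs (same molecule
#' types, component states, and bond topology, irrespective of the order in
#' which molecules and bonds were listed).
#'
#' @param g A [species_graph()].
#' @param mtypes Named list of [molecule_type()] objects.
#' @return Character scalar.
#' @export
canonical_label <- function(g, mtypes) {
  g <- check_graph(g, mtypes)
  n <- length(g$mols)
  if (n == 0L) return("")
  base <- vapply(g$mols, mol_base_sig, character(1))
  if (n == 1L) return(serialize_ordering(g, 1L, mtypes))
  sig <- mol_refined_sig(g, base)
  # iterate neighbourhood refinement until the partition stabilizes; ties
  # that survive are genuinely symmetric and handled by permutation below
  while (anyDuplicated(sig)) {
    nxt <- mol_refined_sig(g, sig)
    if (length(unique(nxt)) == length(unique(sig))) break
    sig <- nxt
  }
  o <- order(sig)
  if (!anyDuplicated(sig)) return(serialize_ordering(g, o, mtypes))
  groups <- split(o, factor(sig[o], levels = unique(sig[o])))
  if (prod(vapply(groups, function(grp) factorial(length(grp)), numeric(1))) > 50000)
    stop("complex too symmetric for exhaustive canonicalization")
  labels <- vapply(perm_expand(groups), function(ord) serialize_ordering(g, ord, mtypes),
                   character(1))
  min(labels)
}

# --- pattern matching -------------------------------------------------------

states_compatible <- function(pat_s, g_s) {
  all(is.na(pat_s) | (!is.na(g_s) & pat_s == g_s))
}

#' Match a pattern against a species graph
#'
#' Enumerates every embedding (injective map of pattern molecules onto graph
#' molecules) consistent with molecule types, non-wildcard component states,
#' pattern bonds, and `free` constraints.
#'
#' @param pattern A pattern built with [species_graph()] (`pattern = TRUE`).
#' @param g Target species graph.
#' @param mtypes Molecule-type registry.
#' @param exact If `TRUE`, wildcard states only match wildcard states (used
#'   for automorphism counting).
#' @return List of integer vectors; element `i` of an embedding is the graph
#'   molecule matched by pattern molecule `i`.
#' @export
match_pattern <- function(pattern, g, mtypes, exact = FALSE) {
  pattern <- resolve_states(pattern, mtypes)
  g <- resolve_states(g, mtypes)
  np <- length(pattern$mols); ng <- length(g$mols)
  if (np == 0L) return(list(integer(0)))
  cand <- vector("list", np)
  for (i in seq_len(np)) {
    pm <- pattern$mols[[i]]
    ok <- which(vapply(g$mols, function(gm) {
      gm$type == pm$type &&
        (if (exact) identical(is.na(pm$states), is.na(gm$states)) &&
           all(pm$states[!is.na(pm$states)] == gm$states[!is.na(gm$states)])
         else states_compatible(pm$states, gm$states))
    }, logical(1)))
    if (!length(ok)) return(list())
    cand[[i]] <- ok
  }
  res <- list()
  emb <- integer(np)
  recurse <- function(i) {
    if (i > np) {
      # verify bonds and free constraints
      if (nrow(pattern$bm)) {
        for (k in seq_len(nrow(pattern$bm))) {
          gm1 <- emb[pattern$bm[k, 1]]; gm2 <- emb[pattern$bm[k, 2]]
          c1 <- pattern$bc[k, 1]; c2 <- pattern$bc[k, 2]
          hit <- FALSE
          if (nrow(g$bm)) {
            hit <- any((g$bm[, 1] == gm1 & g$bc[, 1] == c1 & g$bm[, 2] == gm2 & g$bc[, 2] == c2) |
                       (g$bm[, 2] == gm1 & g$bc[, 2] == c1 & g$bm[, 1] == gm2 & g$bc[, 1] == c2))
          }
          if (!hit) return(invisible(NULL))
        }
      }
      for (fr in pattern$free) {
        if (bond_index_at(g, emb[as.integer(fr[1])], fr[2]) > 0L) return(invisible(NULL))
      }
      res[[length(res) + 1L]] <<- emb
      return(invisible(NULL))
    }
    for (cnd in cand[[i]]) {
      if (cnd %in% emb[seq_len(i - 1L)]) next
      emb[i] <<- cnd
      recurse(i + 1L)
    }
    emb[i] <<- 0L
  }
  recurse(1L)
  res
}

pattern_automorphisms <- function(pattern, mtypes) {
  length(match_pattern(pattern, pattern, mtypes, exact = TRUE))
}

# --- rules ------------------------------------------------------------------

#' Define a rewrite rule
#'
#' A rule has zero, one, or two reactant patterns and a list of primitive
#' effects executed on the (disjoint union of the) matched reactants.
#' Molecule indices inside effects address pattern molecules: pattern 1's
#' molecules first, then pattern 2's.
#'
#' Supported effects (each a list with an `op` entry):
#' \describe{
#'   \item{`state`}{`list(op="state", mol=, comp=, state=)` set a component state.}
#'   \item{`bond`}{`list(op="bond", m1=, c1=, m2=, c2=)` create a bond.}
#'   \item{`unbond`}{`list(op="unbond", mol=, comp=)` break the bond at a component.}
#'   \item{`delete`}{`list(op="delete", mol=)` remove a molecule and its bonds.}
#'   \item{`create`}{`list(op="create", graph=)` add the molecules of a species graph.}
#' }
#'
#' @param name Rule name (provenance tag on generated reactions).
#' @param reactants List of 0--2 patterns.
#' @param rate Rate constant (per second, or per molecule per second for
#'   bimolecular rules).
#' @param effects List of effect descriptors.
#' @param guard Optional `function(graphs, embeddings)` returning `FALSE` to
#'   veto an application (used e.g. to restrict a rule to configurations
#'   satisfying a global condition such as "at least one repressor bound").
#' @param rate_fn Optional `function(graphs, embeddings)` returning a
#'   dimensionless multiplier on `rate` (e.g. cooperativity factors).
#' @return An object of class `pp_rule`.
#' @export
rule <- function(name, reactants, rate, effects = list(), guard = NULL, rate_fn = NULL) {
  stopifnot(length(reactants) <= 2L)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop(sprintf("rule '%s': rate must be a single non-negative number", name))
  structure(list(name = name, reactants = reactants, rate = rate,
                 effects = effects, guard = guard, rate_fn = rate_fn),
            class = "pp_rule")
}

#' Assemble a rule set
#'
#' @param molecule_types List of [molecule_type()] objects (named or not).
#' @param seeds List of `list(graph=, copies=)` seed species.
#' @param rules List of [rule()] objects.
#' @param terminals List of terminal descriptors (see [terminal()]).
#' @return An object of class `pp_ruleset`.
#' @export
rule_set <- function(molecule_types, seeds, rules, terminals = list()) {
  mt <- stats::setNames(molecule_types,
                        vapply(molecule_types, function(m) m$name, character(1)))
  structure(list(mtypes = mt, seeds = seeds, rules = rules, terminals = terminals),
            class = "pp_ruleset")
}

#' Declare a flux terminal
#'
#' Terminals are the typed boundary objects through which a part or pool
#' model exchanges signal-carrier molecules with the rest of a circuit.
#'
#' @param name Terminal name (used for wiring; by convention the name of the
#'   signal-carrier pool or of the downstream transcription unit).
#' @param carrier One of the five signal-carrier kinds (see [carrier_kinds()])
#'   or `"protein"` for product outflow.
#' @param direction `"in"` or `"out"`.
#' @param species Canonical label(s) of the boundary species attached to the
#'   terminal.
#' @return A terminal descriptor.
#' @export
terminal <- function(name, carrier, direction, species = character(0)) {
  stopifnot(direction %in% c("in", "out"))
  list(name = name, carrier = carrier, direction = direction, species = species)
}

apply_rule_once <- function(r, graphs, embs, mtypes) {
  # union graph
  mols <- list(); bm <- matrix(integer(0), 0, 2); bc <- matrix(character(0), 0, 2)
  offset <- integer(length(graphs)); off <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    offset[gi] <- off
    mols <- c(mols, g$mols)
    if (nrow(g$bm)) { bm <- rbind(bm, g$bm + off); bc <- rbind(bc, g$bc) }
    off <- off + length(g$mols)
  }
  # map pattern molecule index (global across patterns) -> union index
  pmap <- integer(0)
  for (gi in seq_along(graphs)) pmap <- c(pmap, embs[[gi]] + offset[gi])
  u <- structure(list(mols = mols, bm = bm, bc = bc, free = list(), pattern = FALSE),
                 class = "pp_sgraph")
  deleted <- logical(length(u$mols))
  for (e in r$effects) {
    if (e$op == "state") {
      i <- pmap[e$mol]
      u$mols[[i]]$states[[e$comp]] <- e$state
    } else if (e$op == "bond") {
      u$bm <- rbind(u$bm, c(pmap[e$m1], pmap[e$m2]))
      u$bc <- rbind(u$bc, c(e$c1, e$c2))
    } else if (e$op == "unbond") {
      i <- pmap[e$mol]
      k <- bond_index_at(u, i, e$comp)
      if (k == 0L) stop(sprintf("rule '%s': unbond at unbound component", r$name))
      u$bm <- u$bm[-k, , drop = FALSE]; u$bc <- u$bc[-k, , drop = FALSE]
    } else if (e$op == "delete") {
      deleted[pmap[e$mol]] <- TRUE
    } else if (e$op == "create") {
      cg <- resolve_states(e$graph, mtypes)
      off2 <- length(u$mols)
      u$mols <- c(u$mols, cg$mols)
      deleted <- c(deleted, logical(length(cg$mols)))
      if (nrow(cg$bm)) { u$bm <- rbind(u$bm, cg$bm + off2); u$bc <- rbind(u$bc, cg$bc) }
      # created molecules become addressable by subsequent effects, indexed
      # after the pattern molecules in creation order
      pmap <- c(pmap, off2 + seq_len(length(cg$mols)))
    } else stop(sprintf("rule '%s': unknown effect '%s'", r$name, e$op))
  }
  if (any(deleted)) {
    keepmap <- cumsum(!deleted)
    drop_bond <- apply(u$bm, 1, function(b) any(deleted[b]))
    if (length(drop_bond) && any(drop_bond)) {
      u$bm <- u$bm[!drop_bond, , drop = FALSE]; u$bc <- u$bc[!drop_bond, , drop = FALSE]
    }
    u$mols <- u$mols[!deleted]
    if (nrow(u$bm)) u$bm <- matrix(keepmap[u$bm], ncol = 2)
  }
  split_components(u)
}

split_components <- function(u) {
  n <- length(u$mols)
  if (n == 0L) return(list())
  comp_id <- seq_len(n)
  find <- function(i) { while (comp_id[i] != i) { comp_id[i] <<- comp_id[comp_id[i]]; i <- comp_id[i] }; i }
  if (nrow(u$bm)) for (k in seq_len(nrow(u$bm))) {
    a <- find(u$bm[k, 1]); b <- find(u$bm[k, 2])
    if (a != b) comp_id[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(rt) {
    idx <- which(roots == rt)
    remap <- integer(n); remap[idx] <- seq_along(idx)
    keep <- if (nrow(u$bm)) apply(u$bm, 1, function(b) all(b %in% idx)) else logical(0)
    structure(list(mols = u$mols[idx],
                   bm = if (any(keep)) matrix(remap[u$bm[keep, , drop = FALSE]], ncol = 2) else matrix(integer(0), 0, 2),
                   bc = u$bc[keep, , drop = FALSE],
                   free = list(), pattern = FALSE),
              class = "pp_sgraph", resolved = TRUE, checked = TRUE)
  })
}

#' Expand a rule set into a reaction network
#'
#' Breadth-first fixed-point computation: starting from the seed species,
#' every rule is applied to every (pair of) known species until no new
#' species or reactions appear. The output species list is sorted by
#' canonical label and reactions by (reactants, products, rule), so the
#' result is invariant under permutation of rules and seeds.
#'
#' A rule matching one reactant tuple through several symmetric embeddings
#' yields a single reaction whose rate carries the embedding multiplicity
#' divided by the pattern automorphism count (deterministic mass-action
#' convention). Duplicate reactions arising from the same rule are merged;
#' identical reactions from distinct rules are kept separate to preserve
#' provenance.
#'
#' @param rs A [rule_set()].
#' @param max_species Abort (with the offending rule named) if the closure
#'   grows beyond this many species.
#' @return An object of class `pp_network` with elements `species`
#'   (data.frame: label, copies, seed), `graphs` (named list of species
#'   graphs), `reactions` (list of `list(reactants, products, rate, rule)`),
#'   `terminals`, `mtypes`.
#' @export
expand_rules <- function(rs, max_species = 10000) {
  mtypes <- rs$mtypes
  graphs <- list(); copies <- numeric(0)
  add_species <- function(label, g, n0 = 0) {
    if (!label %in% names(graphs)) {
      graphs[[label]] <<- g
      copies[label] <<- n0
      TRUE
    } else FALSE
  }
  for (sd in rs$seeds) {
    g <- check_graph(sd$graph, mtypes)
    lab <- canonical_label(g, mtypes)
    if (lab %in% names(graphs)) copies[lab] <- copies[lab] + sd$copies
    else add_species(lab, g, sd$copies)
  }
  seed_labels <- names(graphs)
  # pre-resolve pattern states once
  rs$rules <- lapply(rs$rules, function(r) {
    r$reactants <- lapply(r$reactants, resolve_states, mtypes)
    r
  })
  autos <- vapply(rs$rules, function(r) {
    if (!length(r$reactants)) return(1)
    prod(vapply(r$reactants, function(p) pattern_automorphisms(p, mtypes), numeric(1)))
  }, numeric(1))

  reactions <- list()
  rx_keys <- character(0)
  match_cache <- new.env(parent = emptyenv())
  cached_match <- function(ri, pi, lab) {
    key <- paste(ri, pi, lab)
    hit <- match_cache[[key]]
    if (is.null(hit)) {
      hit <- match_pattern(rs$rules[[ri]]$reactants[[pi]], graphs[[lab]], mtypes)
      match_cache[[key]] <- hit
    }
    hit
  }
  repeat {
    changed <- FALSE
    species_now <- sort(names(graphs))
    # per-rule, per-pattern candidate embeddings
    for (ri in seq_along(rs$rules)) {
      r <- rs$rules[[ri]]
      np <- length(r$reactants)
      if (np == 0L) {
        tuples <- list(character(0))
      } else {
        cand <- lapply(seq_len(np), function(pi) {
          hits <- lapply(species_now, function(lab) cached_match(ri, pi, lab))
          names(hits) <- species_now
          hits[vapply(hits, length, integer(1)) > 0L]
        })
        if (any(vapply(cand, length, integer(1)) == 0L)) next
        tuples <- if (np == 1L) as.list(names(cand[[1]]))
                  else { tt <- expand.grid(a = names(cand[[1]]), b = names(cand[[2]]),
                                           stringsAsFactors = FALSE)
                         lapply(seq_len(nrow(tt)), function(i) c(tt$a[i], tt$b[i])) }
      }
      for (tuple in tuples) {
        tkey <- paste(ri, paste(tuple, collapse = "|"))
        if (!is.null(match_cache[[paste0("done ", tkey)]])) next
        match_cache[[paste0("done ", tkey)]] <- TRUE
        gl <- lapply(tuple, function(lab) graphs[[lab]])
        emb_lists <- if (np == 0L) list(list(integer(0))) else
          lapply(seq_len(np), function(pi) cand[[pi]][[tuple[pi]]])
        # cartesian over embeddings of each pattern
        emb_grid <- list(list())
        for (pi in seq_len(np)) {
          emb_grid <- unlist(lapply(emb_grid, function(acc)
            lapply(emb_lists[[pi]], function(e) c(acc, list(e)))), recursive = FALSE)
        }
        if (np == 0L) emb_grid <- list(list(integer(0)))
        # group applications by resulting product multiset
        groups <- list()
        for (embs in emb_grid) {
          if (!is.null(r$guard) && !isTRUE(r$guard(gl, embs))) next
          prods <- apply_rule_once(r, gl, embs, mtypes)
          plabs <- vapply(prods, function(p) canonical_label(p, mtypes), character(1))
          o2 <- order(plabs)
          prods <- prods[o2]; plabs <- plabs[o2]
          key <- paste0("> ", paste(plabs, collapse = " + "))  # "> " so empty product sets keep a valid key
          w <- if (is.null(r$rate_fn)) 1 else r$rate_fn(gl, embs)
          if (is.null(groups[[key]])) groups[[key]] <- list(w = 0, prods = prods, plabs = plabs)
          groups[[key]]$w <- groups[[key]]$w + w
        }
        for (key in names(groups)) {
          grp <- groups[[key]]
          for (pi in seq_along(grp$prods)) {
            lab <- grp$plabs[pi]
            if (!lab %in% names(graphs)) {
              add_species(lab, grp$prods[[pi]])
              changed <- TRUE
              if (length(graphs) > max_species)
                stop(sprintf("network expansion exceeded max_species = %d while applying rule '%s'",
                             max_species, r$name))
            }
          }
          rate <- r$rate * grp$w / autos[ri]
          rxkey <- paste(r$name, paste(sort(tuple), collapse = " + "), "->", key)
          if (!rxkey %in% rx_keys) {
            rx_keys <- c(rx_keys, rxkey)
            reactions[[length(reactions) + 1L]] <-
              list(reactants = as.character(tuple), products = grp$plabs,
                   rate = rate, rule = r$name)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  labs <- sort(names(graphs))
  ord <- order(vapply(reactions, function(x) paste(paste(sort(x$reactants), collapse = "+"),
                                                  paste(x$products, collapse = "+"), x$rule),
                      character(1)))
  structure(list(species = data.frame(label = labs,
                                      copies = as.numeric(copies[labs]),
                                      seed = labs %in% seed_labels,
                                      stringsAsFactors = FALSE),
                 graphs = graphs[labs],
                 reactions = reactions[ord],
                 terminals = rs$terminals,
                 mtypes = mtypes),
            class = "pp_network")
}

#' @export
print.pp_network <- function(x, ...) {
  cat(sprintf("<pp_network> %d species, %d reactions, %d terminals\n",
              nrow(x$species), length(x$reactions), length(x$terminals)))
  invisible(x)
}

#' Write a BNGL-flavoured plain-text listing of a rule set and its expansion
#'
#' Diagnostic output (molecule types, seed species, rules by name, expanded
#' species and reactions); not intended as an interoperability guarantee.
#'
#' @param rs The [rule_set()].
#' @param net Its expansion from [expand_rules()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bngl <- function(rs, net, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("begin molecule types")
  for (mt in rs$mtypes) {
    comps <- vapply(seq_along(mt$comps), function(i)
      paste0(names(mt$comps)[i], "~", paste(mt$comps[[i]]$states, collapse = "~")),
      character(1))
    w("  %s(%s)", mt$name, paste(comps, collapse = ","))
  }
  w("end molecule types")
  w("begin seed species")
  for (sd in rs$seeds) {
    g <- check_graph(sd$graph, rs$mtypes)
    w("  %s %g", canonical_label(g, rs$mtypes), sd$copies)
  }
  w("end seed species")
  w("begin reaction rules")
  for (r in rs$rules) w("  # %s  k = %g", r$name, r$rate)
  w("end reaction rules")
  w("begin species")
  for (i in seq_len(nrow(net$species))) w("  %d %s", i, net$species$label[i])
  w("end species")
  w("begin reactions")
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    w("  %d %s -> %s %g # %s", i,
      if (length(rx$reactants)) paste(rx$reactants, collapse = " + ") else "0",
      if (length(rx$products)) paste(rx$products, collapse = " + ") else "0",
      rx$rate, rx$rule)
  }
  w("end reactions")
  invisible(path)
}
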