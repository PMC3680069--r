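# Composer: compile every part and pool of a circuit and wire them into a
# flattened two-compartment reaction network through typed flux terminals.

#' Wire a circuit specification into a flattened circuit model
#'
#' Compiles all part and pool models, unifies boundary species by canonical
#' label at declared terminals, checks that every part terminal has a
#' counterpart of compatible carrier kind and opposite direction, and
#' assembles the flattened species/reaction network with per-module
#' provenance. Transport reactions (mRNA/siRNA export, factor import) stay
#' under the exporting module. Wiring is deterministic: two runs on the
#' same specification yield identical models.
#'
#' @param circuit A [circuit_spec()]; must validate with no errors.
#' @param gene_copies DNA template copies seeded per promoter.
#' @param turnover_rate Bound-factor turnover rate passed to
#'   [compile_promoter()].
#' @param max_species Expansion bound per part.
#' @return A `pp_model` with elements `species` (data.frame: label,
#'   compartment, module, copies, boundary), `reactions` (list with reactant
#'   and product indices, rate, module, rule), `parts`, `manifest`,
#'   `merges`, `chemicals`, `reporters`, `spec`.
#' @export
wire_circuit <- function(circuit, gene_copies = 1, turnover_rate = 1e-5,
                         max_species = 10000) {
  d <- validate_circuit(circuit)
  if (any(d$severity == "error")) {
    stop(sprintf("circuit does not validate: %s (%s)",
                 d$problem[d$severity == "error"][1],
                 d$element[d$severity == "error"][1]))
  }

  parts <- list()
  addp <- function(p) parts[[length(parts) + 1L]] <<- p
  sirna_targets <- function(s) {
    unlist(lapply(circuit$units, function(u)
      if (inherits(u$cargo, "pp_coding_region") &&
          s %in% vapply(u$cargo$sirna_targets, function(x) x$sirna_name, character(1)))
        u$cargo$name))
  }
  for (u in circuit$units) {
    addp(compile_promoter(u$promoter, unit = u$name, gene_copies = gene_copies,
                          turnover_rate = turnover_rate))
    if (inherits(u$cargo, "pp_coding_region")) {
      two <- compile_coding_region(u$cargo, u$terminator, unit = u$name)
    } else {
      two <- compile_sirna_gene(u$cargo, u$terminator, unit = u$name,
                                targets = sirna_targets(u$cargo$sirna_name))
    }
    addp(two$nuclear); addp(two$pool)
  }
  for (p in compile_tf_and_protein_pools(circuit)) addp(p)
  names(parts) <- vapply(parts, function(p) p$name, character(1))

  # molecule-type registry consistency across parts
  mtypes <- list()
  for (p in parts) for (tn in names(p$ruleset$mtypes)) {
    mt <- p$ruleset$mtypes[[tn]]
    if (is.null(mtypes[[tn]])) mtypes[[tn]] <- mt
    else if (!identical(mtypes[[tn]], mt))
      stop(sprintf("molecule type '%s' declared inconsistently across parts", tn))
  }

  # terminal matching: every part-side terminal needs a counterpart with the
  # same name, the same carrier kind and the opposite direction.  Pool-side
  # terminals may fan out to several parts (or sit idle for an unused
  # machinery storage); 'transcript' terminals are the intra-part hand-off
  # between a nuclear part and its cytoplasmic pool and are matched by
  # construction.
  pool_kinds <- c("tf_pool", "reporter_pool", "machinery_pool", "chemical_pool")
  all_terms <- do.call(rbind, lapply(parts, function(p) {
    if (!length(p$terminals)) return(NULL)
    data.frame(part = p$name, kind = p$kind,
               name = vapply(p$terminals, function(t) t$name, character(1)),
               carrier = vapply(p$terminals, function(t) t$carrier, character(1)),
               direction = vapply(p$terminals, function(t) t$direction, character(1)),
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(if (is.null(all_terms)) 0L else nrow(all_terms))) {
    tm <- all_terms[i, ]
    if (tm$kind %in% pool_kinds || tm$carrier == "transcript") next
    opp <- all_terms$name == tm$name & all_terms$direction != tm$direction &
      all_terms$part != tm$part
    if (!any(opp)) {
      same_name <- all_terms$name == tm$name & all_terms$part != tm$part
      if (any(same_name))
        stop(sprintf("wiring type error: terminal '%s' (%s, %s) of part '%s' only meets terminals of incompatible direction or carrier",
                     tm$name, tm$carrier, tm$direction, tm$part))
      stop(sprintf("unmatched terminal '%s' (%s, %s) of part '%s'",
                   tm$name, tm$carrier, tm$direction, tm$part))
    }
    if (!any(opp & all_terms$carrier == tm$carrier))
      stop(sprintf("wiring type error: terminal '%s' of part '%s' expects carrier %s",
                   tm$name, tm$part, tm$carrier))
  }

  # flatten species, unifying shared boundary species by canonical label
  lab2id <- new.env(parent = emptyenv())
  labels <- character(0); compartment <- character(0); module <- character(0)
  copies <- numeric(0); boundary <- logical(0)
  merges <- 0L
  for (p in parts) {
    sp <- p$network$species
    for (si in seq_len(nrow(sp))) {
      lab <- sp$label[si]
      isb <- lab %in% p$boundary
      id <- lab2id[[lab]]
      if (is.null(id)) {
        labels <- c(labels, lab)
        id <- length(labels)
        lab2id[[lab]] <- id
        compartment[id] <- p$compartment
        module[id] <- p$name
        copies[id] <- sp$copies[si]
        boundary[id] <- isb
      } else {
        merges <- merges + 1L
        copies[id] <- copies[id] + sp$copies[si]
        # a part that owns the species internally takes over provenance and
        # compartment (pool side of the boundary)
        if (!isb && boundary[id]) {
          module[id] <- p$name; compartment[id] <- p$compartment; boundary[id] <- FALSE
        }
      }
    }
  }
  reactions <- list()
  for (p in parts) for (rx in p$network$reactions) {
    reactions[[length(reactions) + 1L]] <-
      list(reactants = vapply(rx$reactants, function(l) lab2id[[l]], integer(1)),
           products = if (length(rx$products))
             vapply(rx$products, function(l) lab2id[[l]], integer(1)) else integer(0),
           rate = rx$rate, rule = rx$rule, module = p$name)
  }

  species <- data.frame(label = labels, compartment = compartment,
                        module = module, copies = copies, boundary = boundary,
                        stringsAsFactors = FALSE)
  chem_ids <- stats::setNames(
    vapply(circuit$chemical_inputs, function(x) lab2id[[paste0("CH_", x, "()")]], integer(1)),
    circuit$chemical_inputs)
  reporters <- unique(unlist(lapply(circuit$units, function(u)
    if (inherits(u$cargo, "pp_coding_region") && u$cargo$product_kind == "reporter")
      paste0("PR_", u$cargo$product_name, "()"))))
  reporter_ids <- vapply(reporters, function(l) lab2id[[l]], integer(1))

  manifest <- data.frame(
    module = vapply(parts, function(p) p$name, character(1)),
    kind = vapply(parts, function(p) p$kind, character(1)),
    compartment = vapply(parts, function(p) p$compartment, character(1)),
    n_species = vapply(parts, function(p) unname(p$counts["n_species"]), numeric(1)),
    n_reactions = vapply(parts, function(p) unname(p$counts["n_reactions"]), numeric(1)),
    n_terminals = vapply(parts, function(p) unname(p$counts["n_terminals"]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL

  structure(list(species = species, reactions = reactions, parts = parts,
                 mtypes = mtypes, manifest = manifest, merges = merges,
                 chemicals = chem_ids, reporters = reporter_ids,
                 spec = circuit),
            class = "pp_model")
}

#' @export
print.pp_model <- function(x, ...) {
  cat(sprintf("<pp_model> %d modules | %d species (%d boundary merges) | %d reactions | compartments: %s\n",
              nrow(x$manifest), nrow(x$species), x$merges, length(x$reactions),
              paste(names(x$spec$compartments), collapse = "/")))
  invisible(x)
}

#' Per-module and whole-circuit complexity report
#'
#' @param model A wired `pp_model` from [wire_circuit()].
#' @return A list with `modules` (per-part species/reaction/terminal
#'   counts), `total` (whole-circuit species and reaction counts after
#'   flattening), and `merges` (boundary species unified at wiring).
#' @export
circuit_report <- function(model) {
  list(modules = model$manifest,
       total = c(n_species = nrow(model$species),
                 n_reactions = length(model$reactions)),
       merges = model$merges)
}

# machinery content of one species (for conservation accounting)
composition_counts <- function(g) {
  out <- c(RNAP = 0, ribosome = 0, spliceosome = 0, Dicer = 0, RISC = 0)
  for (m in g$mols) {
    tp <- m$type
    if (tp == "RNAP" || startsWith(tp, "PolCl_")) out["RNAP"] <- out["RNAP"] + 1
    else if (startsWith(tp, "P_") && identical(unname(m$states["pol"]), "b"))
      out["RNAP"] <- out["RNAP"] + 1
    else if (tp == "Rib") out["ribosome"] <- out["ribosome"] + 1
    else if (startsWith(tp, "M_")) {
      if (m$states[["st"]] %in% c("i", "e", "t", "s"))
        out["ribosome"] <- out["ribosome"] + 1
      if (any(m$states[startsWith(names(m$states), "u")] == "b"))
        out["RISC"] <- out["RISC"] + 1
    }
    else if (tp == "SPL") out["spliceosome"] <- out["spliceosome"] + 1
    else if (tp == "DCR") out["Dicer"] <- out["Dicer"] + 1
    else if (tp == "RISC" || startsWith(tp, "RS_")) out["RISC"] <- out["RISC"] + 1
  }
  out
}

#' Machinery-content matrix of a wired model
#'
#' @param model A `pp_model`.
#' @return Matrix (species x machinery kinds) giving how many RNAP,
#'   ribosome, spliceosome, Dicer and RISC molecules each species contains;
#'   the product with a state vector yields the conserved totals.
#' @export
machinery_matrix <- function(model) {
  graphs <- list()
  for (p in model$parts) for (lab in names(p$network$graphs))
    if (is.null(graphs[[lab]])) graphs[[lab]] <- p$network$graphs[[lab]]
  t(vapply(model$species$label, function(lab) composition_counts(graphs[[lab]]),
           numeric(5)))
}
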