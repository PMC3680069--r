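# User-facing specification layer: declarative descriptions of promoters,
# coding regions, siRNA genes, terminators, pools, transcription units and
# whole two-compartment circuits.

#' The five signal-carrier kinds and their flux names
#'
#' Signal carriers are the molecule classes exchanged between parts and
#' pools; each kind has a canonical flux name (molecules per second across a
#' module terminal).
#'
#' @return A data.frame with columns `kind` and `flux_name`.
#' @examples
#' carrier_kinds()
#' @export
carrier_kinds <- function() {
  data.frame(
    kind = c("RNA_polymerase", "ribosome", "transcription_factor",
             "small_RNA", "chemical"),
    flux_name = c("PoPS", "RiPS", "FaPS", "RNAPS", "SiPS"),
    stringsAsFactors = FALSE)
}

MACHINERY <- c("RNAP", "ribosome", "spliceosome", "Dicer", "RISC")

chk_rate <- function(x, what, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || (strict && x == 0))
    stop(sprintf("%s must be a single %s number", what,
                 if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

#' Describe the binding of one transcription-factor species to a promoter
#'
#' @param tf_name Transcription-factor identifier.
#' @param role `"activator"` or `"repressor"`.
#' @param n_operators Number of operators for this factor (>= 1).
#' @param cooperative Whether same-factor binding is cooperative.
#' @param effector_chemical Optional chemical that strips the DNA-bound
#'   factor from its operator.
#' @param effector_mode `"inducer_strips"` (chemical inactivates the factor)
#'   or `"corepressor_strips"` (only meaningful for activators).
#' @param base_bind_rate Per-molecule per-second binding rate at the
#'   strongest operator.
#' @param unbind_rate Per-second unbinding rate.
#' @param affinity_gradient Factor (>= 1) by which affinity decays per
#'   operator rank; rank 0 is the strongest operator (closest to the TSS for
#'   repressors, furthest for activators).
#' @param cooperativity_factor Multiplier (>= 1) on the binding rate when a
#'   rank-adjacent operator of the same factor is occupied; used only if
#'   `cooperative`.
#' @return A `pp_tf_binding` object.
#' @export
tf_binding <- function(tf_name, role = c("repressor", "activator"),
                       n_operators = 1L, cooperative = FALSE,
                       effector_chemical = NULL,
                       effector_mode = c("inducer_strips", "corepressor_strips"),
                       base_bind_rate = 1e-3, unbind_rate = 1e-2,
                       affinity_gradient = 1, cooperativity_factor = 1) {
  role <- match.arg(role)
  effector_mode <- match.arg(effector_mode)
  structure(list(tf_name = tf_name, role = role,
                 n_operators = as.integer(n_operators),
                 cooperative = isTRUE(cooperative),
                 effector_chemical = effector_chemical,
                 effector_mode = effector_mode,
                 base_bind_rate = chk_rate(base_bind_rate, "base_bind_rate"),
                 unbind_rate = chk_rate(unbind_rate, "unbind_rate"),
                 affinity_gradient = affinity_gradient,
                 cooperativity_factor = cooperativity_factor),
            class = "pp_tf_binding")
}

#' Describe a promoter part
#'
#' @param name Promoter name (unique within a circuit).
#' @param tf_bindings List of [tf_binding()] descriptors (empty for a
#'   constitutive promoter).
#' @param rnap_bind_rate,rnap_unbind_rate Per-molecule-per-second /
#'   per-second RNA-polymerase binding and unbinding rates.
#' @param clearing_rate Per-second initiation rate producing a cleared
#'   polymerase on the outgoing PoPS terminal.
#' @param leak_rate Per-molecule-per-second rate at which a free polymerase
#'   initiates leakily from each non-permissive configuration.
#' @return A `pp_promoter` object.
#' @export
promoter_spec <- function(name, tf_bindings = list(),
                          rnap_bind_rate = 1e-3, rnap_unbind_rate = 1e-1,
                          clearing_rate = 5e-2, leak_rate = 1e-8) {
  tfs <- vapply(tf_bindings, function(b) b$tf_name, character(1))
  if (anyDuplicated(tfs)) stop(sprintf("promoter '%s': duplicated TF '%s'",
                                       name, tfs[duplicated(tfs)][1]))
  structure(list(name = name, tf_bindings = tf_bindings,
                 rnap_bind_rate = chk_rate(rnap_bind_rate, "rnap_bind_rate"),
                 rnap_unbind_rate = chk_rate(rnap_unbind_rate, "rnap_unbind_rate"),
                 clearing_rate = chk_rate(clearing_rate, "clearing_rate"),
                 leak_rate = chk_rate(leak_rate, "leak_rate")),
            class = "pp_promoter")
}

#' Describe a riboswitch on a coding region's 5'-UTR
#'
#' Riboswitches carry one (single) or two (tandem) aptamers; all aptamers of
#' a riboswitch must be chemical-bound for it to switch on, and translation
#' requires every riboswitch on the transcript to be on.
#'
#' @param kind `"single"` or `"tandem"`.
#' @param aptamer_chemicals One chemical for single riboswitches, two for
#'   tandem ones (equal for homo-cooperative, different for hetero).
#' @param cooperativity `"none"`, `"homo"` or `"hetero"`.
#' @param switch_on_rate,switch_off_rate Per-second conformational switch
#'   rates (on requires all aptamers occupied; off requires a free aptamer).
#' @param chem_bind_rate,chem_unbind_rate Aptamer occupancy rates.
#' @param cooperativity_factor Multiplier on the second tandem aptamer's
#'   binding rate once the first is occupied.
#' @return A `pp_riboswitch` object.
#' @export
riboswitch_spec <- function(kind = c("single", "tandem"), aptamer_chemicals,
                            cooperativity = c("none", "homo", "hetero"),
                            switch_on_rate = 1e-1, switch_off_rate = 1e-2,
                            chem_bind_rate = 1e-4, chem_unbind_rate = 1e-3,
                            cooperativity_factor = 5) {
  kind <- match.arg(kind); cooperativity <- match.arg(cooperativity)
  nc <- length(aptamer_chemicals)
  if (kind == "single" && nc != 1L) stop("single riboswitch needs exactly one aptamer chemical")
  if (kind == "tandem" && nc != 2L) stop("tandem riboswitch needs exactly two aptamer chemicals")
  if (cooperativity == "homo" && (kind != "tandem" || aptamer_chemicals[1] != aptamer_chemicals[2]))
    stop("homo-cooperativity requires a tandem riboswitch with one chemical species")
  if (cooperativity == "hetero" && (kind != "tandem" || aptamer_chemicals[1] == aptamer_chemicals[2]))
    stop("hetero-cooperativity requires a tandem riboswitch with two different chemicals")
  structure(list(kind = kind, aptamer_chemicals = as.character(aptamer_chemicals),
                 cooperativity = cooperativity,
                 switch_on_rate = chk_rate(switch_on_rate, "switch_on_rate"),
                 switch_off_rate = chk_rate(switch_off_rate, "switch_off_rate"),
                 chem_bind_rate = chk_rate(chem_bind_rate, "chem_bind_rate"),
                 chem_unbind_rate = chk_rate(chem_unbind_rate, "chem_unbind_rate"),
                 cooperativity_factor = cooperativity_factor),
            class = "pp_riboswitch")
}

#' Describe the siRNA binding sites of one siRNA species on an mRNA 3'-UTR
#'
#' @param sirna_name siRNA species identifier.
#' @param n_sites Number of binding sites (>= 1).
#' @param bind_rate Per-molecule per-second RISC-loaded-siRNA binding rate
#'   per site.
#' @param cleavage_rate Per-second cleavage-and-rapid-degradation rate from
#'   a bound site.
#' @return A `pp_sirna_target` object.
#' @export
sirna_target_spec <- function(sirna_name, n_sites = 2L,
                              bind_rate = 1e-4, cleavage_rate = 5e-3) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  structure(list(sirna_name = sirna_name, n_sites = as.integer(n_sites),
                 bind_rate = chk_rate(bind_rate, "bind_rate"),
                 cleavage_rate = chk_rate(cleavage_rate, "cleavage_rate")),
            class = "pp_sirna_target")
}

#' Describe a protein-coding region part
#'
#' A coding region compiles into a nuclear part (transcription, spliceosome
#' processing, lumped maturation + export) and a cytoplasmic mRNA pool
#' (translation, riboswitch gating, RNA-interference).
#'
#' @param name Coding-region name (also names its mRNA pool).
#' @param product_name Name of the protein product.
#' @param product_kind `"transcription_factor"` or `"reporter"`.
#' @param riboswitches List of [riboswitch_spec()].
#' @param sirna_targets List of [sirna_target_spec()].
#' @param splice_bind_rate,splice_unbind_rate,splice_cat_rate Elementary
#'   Michaelis--Menten constants of the spliceosome interaction.
#' @param export_rate Per-second lumped maturation-and-transport rate.
#' @param ribosome_bind_rate,ribosome_unbind_rate Per-molecule-per-second /
#'   per-second ribosome recruitment rates.
#' @param translation_rate Per-second progression rate through the
#'   initiation-to-elongation and elongation-to-termination steps.
#' @return A `pp_coding_region` object.
#' @export
coding_region_spec <- function(name, product_name,
                               product_kind = c("transcription_factor", "reporter"),
                               riboswitches = list(), sirna_targets = list(),
                               splice_bind_rate = 1e-3, splice_unbind_rate = 1e-1,
                               splice_cat_rate = 5e-2, export_rate = 1e-2,
                               ribosome_bind_rate = 1e-4, ribosome_unbind_rate = 1e-2,
                               translation_rate = 1e-1) {
  product_kind <- match.arg(product_kind)
  sn <- vapply(sirna_targets, function(s) s$sirna_name, character(1))
  if (anyDuplicated(sn)) stop(sprintf("coding region '%s': duplicated siRNA target '%s'",
                                      name, sn[duplicated(sn)][1]))
  structure(list(name = name, product_name = product_name,
                 product_kind = product_kind,
                 riboswitches = riboswitches, sirna_targets = sirna_targets,
                 splice_bind_rate = chk_rate(splice_bind_rate, "splice_bind_rate"),
                 splice_unbind_rate = chk_rate(splice_unbind_rate, "splice_unbind_rate"),
                 splice_cat_rate = chk_rate(splice_cat_rate, "splice_cat_rate"),
                 export_rate = chk_rate(export_rate, "export_rate"),
                 ribosome_bind_rate = chk_rate(ribosome_bind_rate, "ribosome_bind_rate"),
                 ribosome_unbind_rate = chk_rate(ribosome_unbind_rate, "ribosome_unbind_rate"),
                 translation_rate = chk_rate(translation_rate, "translation_rate")),
            class = "pp_coding_region")
}

#' Describe an siRNA-coding region part
#'
#' Drives formation of double-stranded small interfering RNA in the nucleus
#' (Dicer processing, lumped maturation + export) and a cytoplasmic siRNA
#' pool that loads the RISC.
#'
#' @param sirna_name siRNA species identifier.
#' @param dicer_bind_rate,dicer_unbind_rate,dicer_cat_rate Elementary
#'   Michaelis--Menten constants of the Dicer interaction.
#' @param export_rate Per-second lumped maturation-and-transport rate.
#' @param risc_load_rate Per-molecule-per-second RISC loading rate.
#' @param risc_unload_rate Per-second turnover of the loaded RISC complex
#'   back to free RISC (the guide strand is degraded).
#' @return A `pp_sirna_gene` object.
#' @export
sirna_gene_spec <- function(sirna_name,
                            dicer_bind_rate = 1e-3, dicer_unbind_rate = 1e-1,
                            dicer_cat_rate = 5e-2, export_rate = 1e-2,
                            risc_load_rate = 1e-3, risc_unload_rate = 2e-4) {
  structure(list(sirna_name = sirna_name,
                 dicer_bind_rate = chk_rate(dicer_bind_rate, "dicer_bind_rate"),
                 dicer_unbind_rate = chk_rate(dicer_unbind_rate, "dicer_unbind_rate"),
                 dicer_cat_rate = chk_rate(dicer_cat_rate, "dicer_cat_rate"),
                 export_rate = chk_rate(export_rate, "export_rate"),
                 risc_load_rate = chk_rate(risc_load_rate, "risc_load_rate"),
                 risc_unload_rate = chk_rate(risc_unload_rate, "risc_unload_rate")),
            class = "pp_sirna_gene")
}

#' Describe a terminator part
#'
#' Eukaryotic terminators set the stability of the transcript they end:
#' the part is characterized by the decay rate of the mRNA or siRNA.
#'
#' @param name Terminator name.
#' @param transcript_decay_rate Per-second transcript decay rate (> 0).
#' @return A `pp_terminator` object.
#' @export
terminator_spec <- function(name, transcript_decay_rate = 2e-4) {
  structure(list(name = name,
                 transcript_decay_rate = chk_rate(transcript_decay_rate,
                                                  "transcript_decay_rate", strict = TRUE)),
            class = "pp_terminator")
}

#' Describe a pool of free signal-carrier molecules
#'
#' @param name Pool name. Machinery pools use the reserved names `"RNAP"`,
#'   `"ribosome"`, `"spliceosome"`, `"Dicer"`, `"RISC"`.
#' @param carrier One of the five [carrier_kinds()] or `"machinery"` for the
#'   spliceosome/Dicer/RISC processing machineries.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param initial_copies Initial free copy number (>= 0).
#' @param conserved Machinery pools: no synthesis or degradation reactions
#'   are generated and the total (free + engaged) is a conserved quantity.
#' @param import_rate Optional per-second nuclear-import rate (TF pools fed
#'   by a cytoplasmic product).
#' @param degradation_rate Optional per-second first-order degradation.
#' @param production_rate Optional zero-order synthesis (copies per second);
#'   together with `degradation_rate` this keeps an input-factor pool
#'   homeostatic.
#' @param effector_chemical Optional chemical that binds and inactivates the
#'   pooled factor (`TF + chem <-> TF.chem`).
#' @param chem_bind_rate,chem_unbind_rate Per-molecule-per-second /
#'   per-second rates of the pooled factor-chemical interaction.
#' @return A `pp_pool` object.
#' @export
pool_spec <- function(name, carrier, compartment = c("nucleus", "cytoplasm"),
                      initial_copies = 0, conserved = FALSE,
                      import_rate = NULL, degradation_rate = NULL,
                      production_rate = NULL, effector_chemical = NULL,
                      chem_bind_rate = 1e-3, chem_unbind_rate = 1e-3) {
  compartment <- match.arg(compartment)
  ok_car <- c(carrier_kinds()$kind, "machinery")
  if (!carrier %in% ok_car)
    stop(sprintf("pool '%s': unknown carrier '%s'", name, carrier))
  if (initial_copies < 0) stop(sprintf("pool '%s': negative initial copies", name))
  structure(list(name = name, carrier = carrier, compartment = compartment,
                 initial_copies = as.numeric(initial_copies),
                 conserved = isTRUE(conserved),
                 import_rate = if (!is.null(import_rate)) as.numeric(import_rate),
                 degradation_rate = if (!is.null(degradation_rate)) as.numeric(degradation_rate),
                 production_rate = if (!is.null(production_rate)) as.numeric(production_rate),
                 effector_chemical = effector_chemical,
                 chem_bind_rate = chk_rate(chem_bind_rate, "chem_bind_rate"),
                 chem_unbind_rate = chk_rate(chem_unbind_rate, "chem_unbind_rate")),
            class = "pp_pool")
}

#' Describe a transcription unit
#'
#' @param name Unit name (unique; names the PoPS flux between its promoter
#'   and its cargo).
#' @param promoter A [promoter_spec()].
#' @param cargo A [coding_region_spec()] or [sirna_gene_spec()].
#' @param terminator A [terminator_spec()].
#' @return A `pp_unit` object (transcription units live in the nucleus).
#' @export
transcription_unit <- function(name, promoter, cargo, terminator) {
  if (!inherits(promoter, "pp_promoter")) stop("promoter must be a promoter_spec()")
  if (!inherits(cargo, "pp_coding_region") && !inherits(cargo, "pp_sirna_gene"))
    stop("cargo must be a coding_region_spec() or sirna_gene_spec()")
  if (!inherits(terminator, "pp_terminator")) stop("terminator must be a terminator_spec()")
  structure(list(name = name, promoter = promoter, cargo = cargo,
                 terminator = terminator, compartment = "nucleus"),
            class = "pp_unit")
}

#' Describe a whole two-compartment circuit
#'
#' @param units List of [transcription_unit()]s.
#' @param pools List of [pool_spec()]s (machinery pools and input-factor
#'   pools; product pools are derived from the units).
#' @param chemical_inputs Character vector of input chemical identifiers
#'   (the complement of an input `a` is spelled `not_a`).
#' @param compartments Named numeric vector of compartment volumes in liters
#'   (defaults: 3 fL nucleus, 30 fL cytoplasm). Bimolecular rate constants
#'   are interpreted as per-molecule stochastic rates already scaled to
#'   their compartment, so volumes enter only through
#'   [molar_to_stochastic()].
#' @return A `pp_circuit` object.
#' @export
circuit_spec <- function(units = list(), pools = list(),
                         chemical_inputs = character(0),
                         compartments = c(nucleus = 3e-15, cytoplasm = 3e-14)) {
  structure(list(compartments = compartments, units = units, pools = pools,
                 chemical_inputs = as.character(chemical_inputs)),
            class = "pp_circuit")
}

#' Convert a molar association constant to a per-molecule stochastic rate
#'
#' @param k_molar Association rate in 1/(M s).
#' @param volume Compartment volume in liters.
#' @return Per-molecule per-second rate `k_molar / (N_A * volume)`.
#' @export
molar_to_stochastic <- function(k_molar, volume) {
  k_molar / (6.02214076e23 * volume)
}

#' @export
print.pp_circuit <- function(x, ...) {
  cat(sprintf("<pp_circuit> %d units, %d pools, inputs: %s\n",
              length(x$units), length(x$pools),
              if (length(x$chemical_inputs)) paste(x$chemical_inputs, collapse = ", ") else "none"))
  invisible(x)
}

diag_row <- function(element, problem, severity = "error") {
  data.frame(element = element, problem = problem,
             severity = rep(severity, length(element)), stringsAsFactors = FALSE)
}

#' Validate a circuit specification
#'
#' Checks all structural invariants: name resolution (every transcription
#' factor, chemical, and siRNA referenced anywhere must resolve to a pool,
#' a unit product, or a declared chemical input), uniqueness of pool, unit
#' and promoter names, machinery-pool uniqueness, rate signs, and
#' per-part invariants.
#'
#' @param circuit A [circuit_spec()].
#' @return A data.frame of diagnostics with columns `element`, `problem` and
#'   `severity` (`"error"` or `"warning"`); zero error rows iff the circuit
#'   is valid. Validation is side-effect free and idempotent.
#' @export
validate_circuit <- function(circuit) {
  d <- diag_row(character(0), character(0), character(0))
  pools <- circuit$pools
  pool_names <- vapply(pools, function(p) p$name, character(1))
  if (anyDuplicated(pool_names))
    d <- rbind(d, diag_row(pool_names[duplicated(pool_names)][1], "duplicated pool"))
  for (mk in MACHINERY) {
    n <- sum(pool_names == mk)
    if (n > 1L) d <- rbind(d, diag_row(mk, "more than one pool for this machinery kind"))
  }
  unit_names <- vapply(circuit$units, function(u) u$name, character(1))
  if (anyDuplicated(unit_names))
    d <- rbind(d, diag_row(unit_names[duplicated(unit_names)][1], "duplicated unit name"))
  prom_names <- vapply(circuit$units, function(u) u$promoter$name, character(1))
  if (anyDuplicated(prom_names))
    d <- rbind(d, diag_row(prom_names[duplicated(prom_names)][1], "duplicated promoter name"))

  tf_products <- unlist(lapply(circuit$units, function(u)
    if (inherits(u$cargo, "pp_coding_region") &&
        u$cargo$product_kind == "transcription_factor") u$cargo$product_name))
  sirna_products <- unlist(lapply(circuit$units, function(u)
    if (inherits(u$cargo, "pp_sirna_gene")) u$cargo$sirna_name))
  tf_available <- c(pool_names[vapply(pools, function(p)
    p$carrier == "transcription_factor", logical(1))], tf_products)
  chems <- circuit$chemical_inputs

  for (u in circuit$units) {
    pr <- u$promoter
    for (b in pr$tf_bindings) {
      if (b$n_operators < 1L)
        d <- rbind(d, diag_row(sprintf("%s/%s", pr$name, b$tf_name),
                               "invariant violation: n_operators must be >= 1"))
      if (!b$tf_name %in% tf_available)
        d <- rbind(d, diag_row(sprintf("%s/%s", pr$name, b$tf_name),
                               "unresolved transcription-factor name"))
      if (!is.null(b$effector_chemical) && !b$effector_chemical %in% chems)
        d <- rbind(d, diag_row(sprintf("%s/%s", pr$name, b$effector_chemical),
                               "unresolved chemical name"))
      if (b$effector_mode == "corepressor_strips" && b$role != "activator")
        d <- rbind(d, diag_row(sprintf("%s/%s", pr$name, b$tf_name),
                               "corepressor stripping only applies to activators"))
    }
    if (inherits(u$cargo, "pp_coding_region")) {
      for (st in u$cargo$sirna_targets) {
        if (!st$sirna_name %in% sirna_products)
          d <- rbind(d, diag_row(sprintf("%s/%s", u$cargo$name, st$sirna_name),
                                 "unresolved siRNA name (no siRNA gene produces it)"))
      }
      for (rs in u$cargo$riboswitches) {
        miss <- setdiff(rs$aptamer_chemicals, chems)
        if (length(miss))
          d <- rbind(d, diag_row(sprintf("%s/%s", u$cargo$name, miss[1]),
                                 "unresolved chemical name"))
      }
    }
  }
  for (p in pools) {
    if (!is.null(p$effector_chemical) && !p$effector_chemical %in% chems)
      d <- rbind(d, diag_row(sprintf("%s/%s", p$name, p$effector_chemical),
                             "unresolved chemical name"))
  }
  # siRNA genes with no declared target: legal but inert
  for (s in sirna_products) {
    targeted <- any(vapply(circuit$units, function(u)
      inherits(u$cargo, "pp_coding_region") &&
        s %in% vapply(u$cargo$sirna_targets, function(x) x$sirna_name, character(1)),
      logical(1)))
    if (!targeted)
      d <- rbind(d, diag_row(s, "siRNA has no declared mRNA target (legal but inert)",
                             severity = "warning"))
  }
  d
}
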