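# Fixture builders: the example circuits (activator/siRNA cascade, the
# RNA-interference logic evaluator and its transcription-repression
# counterpart computing (a AND b AND d) OR (NOT a AND c)) and the default
# parameter set used to simulate them.

pp_param_table <- function() {
  p <- function(parameter, value, unit, note) data.frame(
    parameter = parameter, value = value, unit = unit, note = note,
    stringsAsFactors = FALSE)
  rbind(
    p("gene_copies",       1,     "copies", "DNA templates per transcription unit"),
    p("rnap_bind",         1e-3,  "1/(molecule s)", "RNA polymerase recruitment"),
    p("rnap_unbind",       1e-1,  "1/s",    "RNA polymerase dissociation"),
    p("clearing",          5e-2,  "1/s",    "initiation / promoter clearing"),
    p("leak",              1e-8,  "1/(molecule s)", "leaky initiation per polymerase and non-permissive configuration"),
    p("tf_bind",           1e-3,  "1/(molecule s)", "factor-operator association (strongest operator)"),
    p("tf_unbind",         1e-1,  "1/s",    "factor-operator dissociation"),
    p("tf_turnover",       1e-5,  "1/s",    "degradation of the DNA-bound factor"),
    p("r0_bind",           2e-2,  "1/(molecule s)", "input repressor R0-operator association"),
    p("chem_bind",         5e-3,  "1/(molecule s)", "chemical-factor association (pool and DNA)"),
    p("chem_unbind",       1e-3,  "1/s",    "chemical-factor dissociation"),
    p("splice_bind",       1e-3,  "1/(molecule s)", "spliceosome-transcript association"),
    p("splice_unbind",     1e-1,  "1/s",    "spliceosome dissociation"),
    p("splice_cat",        5e-2,  "1/s",    "splicing catalysis"),
    p("export",            1e-2,  "1/s",    "lumped maturation and nuclear export"),
    p("rib_bind",          1e-4,  "1/(molecule s)", "ribosome recruitment"),
    p("rib_unbind",        1e-2,  "1/s",    "ribosome dissociation before commitment"),
    p("translation",       1e-1,  "1/s",    "initiation-to-elongation / elongation-to-termination"),
    p("mrna_decay",        2e-4,  "1/s",    "terminator-determined transcript decay"),
    p("dicer_bind",        1e-3,  "1/(molecule s)", "Dicer-dsRNA association"),
    p("dicer_unbind",      1e-1,  "1/s",    "Dicer dissociation"),
    p("dicer_cat",         5e-2,  "1/s",    "Dicer processing"),
    p("risc_load",         1e-3,  "1/(molecule s)", "RISC loading of free siRNA"),
    p("risc_unload",       2e-4,  "1/s",    "loaded-RISC turnover to free RISC"),
    p("site_bind",         1e-3,  "1/(molecule s)", "loaded RISC binding one 3'-UTR site"),
    p("cleavage",          5e-3,  "1/s",    "cleavage and rapid degradation of bound mRNA"),
    p("import",            2e-3,  "1/s",    "nuclear import of factor products"),
    p("protein_deg",       1e-4,  "1/s",    "protein degradation (factors and reporters)"),
    p("tf_pool_copies",    500,   "copies", "input-factor pool steady level"),
    p("tf_pool_production", 5e-2, "copies/s", "input-factor zero-order synthesis"),
    p("tf_pool_degradation", 1e-4, "1/s",   "input-factor degradation"),
    p("pool_RNAP",         300,   "copies", "free RNA polymerase (nucleus)"),
    p("pool_ribosome",     2000,  "copies", "free ribosomes (cytoplasm)"),
    p("pool_spliceosome",  200,   "copies", "free spliceosomes (nucleus)"),
    p("pool_Dicer",        200,   "copies", "free Dicer (nucleus)"),
    p("pool_RISC",         2000,  "copies", "free RISC (cytoplasm)"),
    p("chem_level",        2000,  "copies", "clamped copy number of a present input chemical"))
}

#' Default parameter set for the packaged example circuits
#'
#' Order-of-magnitude kinetic defaults chosen from typical literature ranges
#' for yeast/mammalian transcription, translation and RNA-interference
#' kinetics; every value is a design default of this package, documented
#' with units in the returned table. The same set drives all three fixture
#' circuits.
#'
#' @param fixture One of `"cascade"`, `"rnai"`, `"transcriptional"`.
#' @return data.frame with columns `parameter`, `value`, `unit`, `note`.
#' @export
default_parameters <- function(fixture = c("rnai", "transcriptional", "cascade")) {
  fixture <- match.arg(fixture)
  pp_param_table()
}

P <- function(tbl) stats::setNames(tbl$value, tbl$parameter)

machinery_pools <- function(q) list(
  pool_spec("RNAP", "RNA_polymerase", "nucleus", q["pool_RNAP"], conserved = TRUE),
  pool_spec("ribosome", "ribosome", "cytoplasm", q["pool_ribosome"], conserved = TRUE),
  pool_spec("spliceosome", "machinery", "nucleus", q["pool_spliceosome"], conserved = TRUE),
  pool_spec("Dicer", "machinery", "nucleus", q["pool_Dicer"], conserved = TRUE),
  pool_spec("RISC", "machinery", "cytoplasm", q["pool_RISC"], conserved = TRUE))

input_tf_pool <- function(name, chem, q) {
  pool_spec(name, "transcription_factor", "nucleus",
            initial_copies = q["tf_pool_copies"],
            production_rate = q["tf_pool_production"],
            degradation_rate = q["tf_pool_degradation"],
            effector_chemical = chem,
            chem_bind_rate = q["chem_bind"], chem_unbind_rate = q["chem_unbind"])
}

fx_promoter <- function(name, bindings, q) {
  promoter_spec(name, bindings,
                rnap_bind_rate = q["rnap_bind"], rnap_unbind_rate = q["rnap_unbind"],
                clearing_rate = q["clearing"], leak_rate = q["leak"])
}

fx_tf <- function(tf, role, n_op, chem, q, bind = q["tf_bind"]) {
  tf_binding(tf, role, n_operators = n_op, effector_chemical = chem,
             base_bind_rate = bind, unbind_rate = q["tf_unbind"])
}

fx_coding <- function(name, product, kind, targets, q) {
  coding_region_spec(name, product, kind,
                     sirna_targets = lapply(targets, function(s)
                       sirna_target_spec(s, n_sites = 2L,
                                         bind_rate = q["site_bind"],
                                         cleavage_rate = q["cleavage"])),
                     splice_bind_rate = q["splice_bind"],
                     splice_unbind_rate = q["splice_unbind"],
                     splice_cat_rate = q["splice_cat"], export_rate = q["export"],
                     ribosome_bind_rate = q["rib_bind"],
                     ribosome_unbind_rate = q["rib_unbind"],
                     translation_rate = q["translation"])
}

fx_sirna <- function(name, q) {
  sirna_gene_spec(name, dicer_bind_rate = q["dicer_bind"],
                  dicer_unbind_rate = q["dicer_unbind"],
                  dicer_cat_rate = q["dicer_cat"], export_rate = q["export"],
                  risc_load_rate = q["risc_load"], risc_unload_rate = q["risc_unload"])
}

fx_term <- function(name, q) terminator_spec(name, q["mrna_decay"])

#' Build the activator/siRNA cascade example circuit
#'
#' A reporter transcription unit under the control of an activator, silenced
#' by an siRNA expressed from a second, constitutive unit (two binding sites
#' on the reporter's 3'-UTR).
#'
#' @return A [circuit_spec()] that validates cleanly.
#' @export
build_cascade_example <- function() {
  q <- P(default_parameters("cascade"))
  units <- list(
    transcription_unit("u_gfp",
      fx_promoter("p_gfp", list(fx_tf("act1", "activator", 1, NULL, q)), q),
      fx_coding("gfp_cds", "gfp", "reporter", "si_r", q),
      fx_term("t_gfp", q)),
    transcription_unit("u_sir",
      fx_promoter("p_sir", list(), q),
      fx_sirna("si_r", q),
      fx_term("t_sir", q)))
  pools <- c(machinery_pools(q), list(input_tf_pool("act1", NULL, q)))
  circuit_spec(units = units, pools = pools, chemical_inputs = character(0))
}

#' Build the RNA-interference logic evaluator fixture
#'
#' Implements (a AND b AND d) OR (NOT a AND c) with five siRNA units and two
#' constitutive AND transcription units producing one shared fluorescent
#' reporter. siRNA-a/b/c/d are each driven by an activator stripped by the
#' corresponding input chemical (one operator each); siRNA-not-a is driven
#' by a repressor stripped by chemical a, so input a silences siRNA-a and
#' switches siRNA-not-a on. Each siRNA has two binding sites on its target
#' mRNA: six sites on the AND1 transcript, four on AND2.
#'
#' @return An evaluator fixture: list with `circuit`, `boolean_fn`,
#'   `inputs`, `reporter`, `parameters`.
#' @export
build_rnai_evaluator <- function() {
  q <- P(default_parameters("rnai"))
  un <- function(x) transcription_unit(
    paste0("u_si_", x),
    fx_promoter(paste0("p_si_", x),
                list(fx_tf(paste0("act_", x), "activator", 1, x, q)), q),
    fx_sirna(paste0("si_", x), q),
    fx_term(paste0("t_si_", x), q))
  units <- list(
    un("a"), un("b"), un("c"), un("d"),
    transcription_unit("u_si_na",
      fx_promoter("p_si_na", list(fx_tf("R0", "repressor", 2, "a", q, bind = q["r0_bind"])), q),
      fx_sirna("si_na", q),
      fx_term("t_si_na", q)),
    transcription_unit("u_and1",
      fx_promoter("p_and1c", list(), q),
      fx_coding("and1", "gfp", "reporter", c("si_a", "si_b", "si_d"), q),
      fx_term("t_and1", q)),
    transcription_unit("u_and2",
      fx_promoter("p_and2c", list(), q),
      fx_coding("and2", "gfp", "reporter", c("si_na", "si_c"), q),
      fx_term("t_and2", q)))
  pools <- c(machinery_pools(q),
             lapply(c("a", "b", "c", "d"), function(x)
               input_tf_pool(paste0("act_", x), x, q)),
             list(input_tf_pool("R0", "a", q)))
  fixture <- list(circuit = circuit_spec(units = units, pools = pools,
                                         chemical_inputs = c("a", "b", "c", "d")),
                  boolean_fn = function(a, b, c, d) (a & b & d) | (!a & c),
                  inputs = c("a", "b", "c", "d"),
                  reporter = "gfp", parameters = "rnai")
  class(fixture) <- "pp_fixture"
  fixture
}

#' Build the transcription-repression logic evaluator fixture
#'
#' The repressor-based counterpart of the RNA-interference evaluator: each
#' siRNA is replaced by a repressor. The AND1 promoter carries three
#' repressors on two operators each (six operators, chemically strippable by
#' a, b and d), the AND2 promoter two repressors on two operators each.
#' Upstream units convert the chemicals into repressors: rep-a/b/c/d are
#' expressed from activator promoters stripped by their chemical, rep-not-a
#' from a two-operator repressor promoter stripped by a.
#'
#' @return An evaluator fixture (see [build_rnai_evaluator()]).
#' @export
build_transcriptional_evaluator <- function() {
  q <- P(default_parameters("transcriptional"))
  un <- function(x) transcription_unit(
    paste0("u_rep_", x),
    fx_promoter(paste0("p_rep_", x),
                list(fx_tf(paste0("act_", x), "activator", 1, x, q)), q),
    fx_coding(paste0("rep_", x, "_cds"), paste0("rep_", x), "transcription_factor",
              character(0), q),
    fx_term(paste0("t_rep_", x), q))
  units <- list(
    un("a"), un("b"), un("c"), un("d"),
    transcription_unit("u_rep_na",
      fx_promoter("p_rep_na", list(fx_tf("R0", "repressor", 2, "a", q, bind = q["r0_bind"])), q),
      fx_coding("rep_na_cds", "rep_na", "transcription_factor", character(0), q),
      fx_term("t_rep_na", q)),
    transcription_unit("u_and1",
      fx_promoter("p_and1", list(fx_tf("rep_a", "repressor", 2, "a", q),
                                 fx_tf("rep_b", "repressor", 2, "b", q),
                                 fx_tf("rep_d", "repressor", 2, "d", q)), q),
      fx_coding("and1", "gfp", "reporter", character(0), q),
      fx_term("t_and1", q)),
    transcription_unit("u_and2",
      fx_promoter("p_and2", list(fx_tf("rep_na", "repressor", 2, NULL, q),
                                 fx_tf("rep_c", "repressor", 2, NULL, q)), q),
      fx_coding("and2", "gfp", "reporter", character(0), q),
      fx_term("t_and2", q)))
  pools <- c(machinery_pools(q),
             lapply(c("a", "b", "c", "d"), function(x)
               input_tf_pool(paste0("act_", x), x, q)),
             list(input_tf_pool("R0", "a", q)))
  fixture <- list(circuit = circuit_spec(units = units, pools = pools,
                                         chemical_inputs = c("a", "b", "c", "d")),
                  boolean_fn = function(a, b, c, d) (a & b & d) | (!a & c),
                  inputs = c("a", "b", "c", "d"),
                  reporter = "gfp", parameters = "transcriptional")
  class(fixture) <- "pp_fixture"
  fixture
}

#' @export
print.pp_fixture <- function(x, ...) {
  cat(sprintf("<pp_fixture> %s evaluator: %d units, reporter '%s', inputs %s\n",
              x$parameters, length(x$circuit$units), x$reporter,
              paste(x$inputs, collapse = ",")))
  invisible(x)
}

#' Fetch a packaged fixture by name
#'
#' @param name `"cascade"`, `"rnai"` or `"transcriptional"`.
#' @return The fixture (cascade: a bare [circuit_spec()]; evaluators: a
#'   fixture list).
#' @export
get_fixture <- function(name = c("rnai", "transcriptional", "cascade")) {
  name <- match.arg(name)
  switch(name,
         cascade = build_cascade_example(),
         rnai = build_rnai_evaluator(),
         transcriptional = build_transcriptional_evaluator())
}
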