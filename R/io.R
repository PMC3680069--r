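# Circuit description files and report serialization.
#
# The circuit dialect is a YAML document with a versioned header
# (`format: partpool-circuit`, `version: 1`) and the sections
# `compartments`, `pools`, `units` and `parameters`.  One dialect; parsing
# and serialization round-trip.

CIRCUIT_FORMAT <- "partpool-circuit"
CIRCUIT_VERSION <- 1L

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Serialize a circuit specification to a circuit description file
#'
#' @param circuit A [circuit_spec()].
#' @param path Output path.
#' @param parameters Optional named list documented in the file's
#'   `parameters` section (carried through parsing untouched).
#' @return `path`, invisibly.
#' @export
serialize_circuit <- function(circuit, path, parameters = NULL) {
  ser_tfb <- function(b) {
    out <- list(tf_name = b$tf_name, role = b$role, n_operators = b$n_operators,
                cooperative = b$cooperative,
                base_bind_rate = b$base_bind_rate, unbind_rate = b$unbind_rate,
                affinity_gradient = b$affinity_gradient,
                cooperativity_factor = b$cooperativity_factor)
    if (!is.null(b$effector_chemical)) {
      out$effector_chemical <- b$effector_chemical
      out$effector_mode <- b$effector_mode
    }
    out
  }
  ser_cargo <- function(cg) {
    if (inherits(cg, "pp_coding_region")) {
      c(list(type = "coding_region"),
        cg[c("name", "product_name", "product_kind")],
        list(riboswitches = lapply(cg$riboswitches, function(r)
          r[c("kind", "aptamer_chemicals", "cooperativity", "switch_on_rate",
              "switch_off_rate", "chem_bind_rate", "chem_unbind_rate",
              "cooperativity_factor")]),
          sirna_targets = lapply(cg$sirna_targets, function(s)
            s[c("sirna_name", "n_sites", "bind_rate", "cleavage_rate")])),
        cg[c("splice_bind_rate", "splice_unbind_rate", "splice_cat_rate",
             "export_rate", "ribosome_bind_rate", "ribosome_unbind_rate",
             "translation_rate")])
    } else {
      c(list(type = "sirna_gene"),
        cg[c("sirna_name", "dicer_bind_rate", "dicer_unbind_rate",
             "dicer_cat_rate", "export_rate", "risc_load_rate",
             "risc_unload_rate")])
    }
  }
  ser_pool <- function(p) {
    out <- p[c("name", "carrier", "compartment", "initial_copies", "conserved")]
    for (f in c("import_rate", "degradation_rate", "production_rate",
                "effector_chemical"))
      if (!is.null(p[[f]])) out[[f]] <- p[[f]]
    out$chem_bind_rate <- p$chem_bind_rate
    out$chem_unbind_rate <- p$chem_unbind_rate
    out
  }
  doc <- list(
    format = CIRCUIT_FORMAT, version = CIRCUIT_VERSION,
    compartments = as.list(circuit$compartments),
    chemical_inputs = as.list(circuit$chemical_inputs),
    pools = lapply(circuit$pools, ser_pool),
    units = lapply(circuit$units, function(u) list(
      name = u$name,
      promoter = c(list(name = u$promoter$name),
                   list(tf_bindings = lapply(u$promoter$tf_bindings, ser_tfb)),
                   u$promoter[c("rnap_bind_rate", "rnap_unbind_rate",
                                "clearing_rate", "leak_rate")]),
      cargo = ser_cargo(u$cargo),
      terminator = list(name = u$terminator$name,
                        transcript_decay_rate = u$terminator$transcript_decay_rate))),
    parameters = if (is.null(parameters)) list() else parameters)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

need <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop(sprintf("circuit file: missing required field '%s' in %s", field, where))
  x[[field]]
}

#' Parse a circuit description file
#'
#' Parsing is round-trip stable with [serialize_circuit()]: serializing and
#' re-parsing yields an equal specification. Unknown sections, missing
#' required fields and duplicated identifiers are reported as errors;
#' syntax errors carry the line/column information of the YAML reader.
#'
#' @param path Path to a circuit description file.
#' @return A [circuit_spec()].
#' @examples
#' path <- system.file("extdata", "cascade_circuit.yaml", package = "partpool")
#' circ <- parse_circuit_file(path)
#' validate_circuit(circ)
#' @export
parse_circuit_file <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || !length(doc))
    stop("circuit file: empty document (missing sections)")
  if (!identical(doc$format, CIRCUIT_FORMAT))
    stop(sprintf("circuit file: missing or unknown format header (expected '%s')",
                 CIRCUIT_FORMAT))
  if (is.null(doc$version) || doc$version != CIRCUIT_VERSION)
    stop(sprintf("circuit file: unsupported version '%s'", doc$version))
  known <- c("format", "version", "compartments", "chemical_inputs",
             "pools", "units", "parameters")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("circuit file: unknown section '%s'", unknown[1]))
  for (sec in c("compartments", "units"))
    if (is.null(doc[[sec]])) stop(sprintf("circuit file: missing section '%s'", sec))

  par_tfb <- function(b) {
    tf_binding(need(b, "tf_name", "tf_binding"), need(b, "role", "tf_binding"),
               n_operators = as.integer(need(b, "n_operators", "tf_binding")),
               cooperative = isTRUE(b$cooperative),
               effector_chemical = b$effector_chemical,
               effector_mode = b$effector_mode %||% "inducer_strips",
               base_bind_rate = as.numeric(need(b, "base_bind_rate", "tf_binding")),
               unbind_rate = as.numeric(need(b, "unbind_rate", "tf_binding")),
               affinity_gradient = as.numeric(b$affinity_gradient %||% 1),
               cooperativity_factor = as.numeric(b$cooperativity_factor %||% 1))
  }
  par_cargo <- function(cg, un) {
    type <- need(cg, "type", sprintf("unit '%s' cargo", un))
    if (type == "coding_region") {
      coding_region_spec(
        need(cg, "name", "coding_region"), need(cg, "product_name", "coding_region"),
        need(cg, "product_kind", "coding_region"),
        riboswitches = lapply(cg$riboswitches, function(r)
          riboswitch_spec(need(r, "kind", "riboswitch"),
                          unlist(need(r, "aptamer_chemicals", "riboswitch")),
                          r$cooperativity %||% "none",
                          as.numeric(r$switch_on_rate), as.numeric(r$switch_off_rate),
                          as.numeric(r$chem_bind_rate), as.numeric(r$chem_unbind_rate),
                          as.numeric(r$cooperativity_factor %||% 1))),
        sirna_targets = lapply(cg$sirna_targets, function(s)
          sirna_target_spec(need(s, "sirna_name", "sirna_target"),
                            as.integer(need(s, "n_sites", "sirna_target")),
                            as.numeric(s$bind_rate), as.numeric(s$cleavage_rate))),
        splice_bind_rate = as.numeric(cg$splice_bind_rate),
        splice_unbind_rate = as.numeric(cg$splice_unbind_rate),
        splice_cat_rate = as.numeric(cg$splice_cat_rate),
        export_rate = as.numeric(cg$export_rate),
        ribosome_bind_rate = as.numeric(cg$ribosome_bind_rate),
        ribosome_unbind_rate = as.numeric(cg$ribosome_unbind_rate),
        translation_rate = as.numeric(cg$translation_rate))
    } else if (type == "sirna_gene") {
      sirna_gene_spec(need(cg, "sirna_name", "sirna_gene"),
                      as.numeric(cg$dicer_bind_rate), as.numeric(cg$dicer_unbind_rate),
                      as.numeric(cg$dicer_cat_rate), as.numeric(cg$export_rate),
                      as.numeric(cg$risc_load_rate), as.numeric(cg$risc_unload_rate))
    } else stop(sprintf("circuit file: unknown cargo type '%s' in unit '%s'", type, un))
  }
  pools <- lapply(doc$pools, function(p) {
    pool_spec(need(p, "name", "pool"), need(p, "carrier", "pool"),
              need(p, "compartment", "pool"),
              initial_copies = as.numeric(p$initial_copies %||% 0),
              conserved = isTRUE(p$conserved),
              import_rate = num_or_null(p$import_rate),
              degradation_rate = num_or_null(p$degradation_rate),
              production_rate = num_or_null(p$production_rate),
              effector_chemical = p$effector_chemical,
              chem_bind_rate = as.numeric(p$chem_bind_rate %||% 1e-3),
              chem_unbind_rate = as.numeric(p$chem_unbind_rate %||% 1e-3))
  })
  pn <- vapply(pools, function(p) p$name, character(1))
  if (anyDuplicated(pn))
    stop(sprintf("circuit file: duplicated pool identifier '%s'", pn[duplicated(pn)][1]))
  units <- lapply(doc$units, function(u) {
    un <- need(u, "name", "unit")
    pr <- need(u, "promoter", sprintf("unit '%s'", un))
    tm <- need(u, "terminator", sprintf("unit '%s'", un))
    transcription_unit(
      un,
      promoter_spec(need(pr, "name", "promoter"),
                    lapply(pr$tf_bindings, par_tfb),
                    as.numeric(pr$rnap_bind_rate), as.numeric(pr$rnap_unbind_rate),
                    as.numeric(pr$clearing_rate), as.numeric(pr$leak_rate)),
      par_cargo(need(u, "cargo", sprintf("unit '%s'", un)), un),
      terminator_spec(need(tm, "name", "terminator"),
                      as.numeric(need(tm, "transcript_decay_rate", "terminator"))))
  })
  un <- vapply(units, function(u) u$name, character(1))
  if (anyDuplicated(un))
    stop(sprintf("circuit file: duplicated unit identifier '%s'", un[duplicated(un)][1]))
  circuit_spec(units = units, pools = pools,
               chemical_inputs = unlist(doc$chemical_inputs) %||% character(0),
               compartments = unlist(doc$compartments))
}

#' Write the per-part complexity report as JSON and/or CSV
#'
#' @param model A `pp_model`.
#' @param json,csv Optional output paths.
#' @return The report list from [circuit_report()], invisibly.
#' @export
write_report <- function(model, json = NULL, csv = NULL) {
  rep <- circuit_report(model)
  if (!is.null(json)) {
    jsonlite::write_json(list(modules = rep$modules,
                              total = as.list(rep$total),
                              merges = rep$merges),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv)) utils::write.csv(rep$modules, csv, row.names = FALSE)
  invisible(rep)
}

#' Write a truth table as CSV
#'
#' @param table A `pp_truthtable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(table, path) {
  df <- as.data.frame(table)
  df$separation <- attr(table, "separation")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @param species Optional subset of species labels.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, species = NULL) {
  st <- traj$states
  if (!is.null(species)) st <- st[, species, drop = FALSE]
  utils::write.csv(data.frame(time_s = traj$times, st, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
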