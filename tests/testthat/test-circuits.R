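test_that("all packaged fixtures validate cleanly", {
  expect_equal(sum(validate_circuit(build_cascade_example())$severity == "error"), 0L)
  expect_equal(sum(validate_circuit(build_rnai_evaluator()$circuit)$severity == "error"), 0L)
  expect_equal(sum(validate_circuit(build_transcriptional_evaluator()$circuit)$severity == "error"), 0L)
  expect_error(get_fixture("nonsense"))
})

test_that("fixtures carry the documented structure", {
  rn <- build_rnai_evaluator()
  expect_length(rn$circuit$units, 7L)       # 5 siRNA units + 2 AND gates
  and1 <- rn$circuit$units[[6]]$cargo
  expect_equal(sum(vapply(and1$sirna_targets, function(s) s$n_sites, integer(1))), 6L)
  and2 <- rn$circuit$units[[7]]$cargo
  expect_equal(sum(vapply(and2$sirna_targets, function(s) s$n_sites, integer(1))), 4L)
  tx <- build_transcriptional_evaluator()
  expect_length(tx$circuit$units, 7L)
  p1 <- tx$circuit$units[[6]]$promoter
  expect_equal(sum(vapply(p1$tf_bindings, function(b) b$n_operators, integer(1))), 6L)
  expect_true(all(vapply(p1$tf_bindings, function(b) !is.null(b$effector_chemical), logical(1))))
  p2 <- tx$circuit$units[[7]]$promoter
  expect_equal(sum(vapply(p2$tf_bindings, function(b) b$n_operators, integer(1))), 4L)
  # chemical a acts on two different transcription factors (activator and repressor)
  tfs_of_a <- unique(unlist(lapply(rn$circuit$pools, function(p)
    if (identical(p$effector_chemical, "a")) p$name)))
  expect_setequal(tfs_of_a, c("act_a", "R0"))
})

test_that("the default parameter table is complete and positive", {
  for (fx in c("cascade", "rnai", "transcriptional")) {
    tbl <- default_parameters(fx)
    expect_true(all(tbl$value > 0))
    expect_false(anyDuplicated(tbl$parameter) > 0)
    expect_true(all(nzchar(tbl$unit)))
  }
  # every rate the fixtures reference resolves: wiring both evaluators
  # exercises the full table
  expect_s3_class(wire_circuit(build_rnai_evaluator()$circuit), "pp_model")
})

test_that("the cascade responds to its activator and its siRNA", {
  base <- build_cascade_example()
  m <- wire_circuit(base)
  gfp_sil <- reporter_output(simulate_circuit(m, simulation_schedule(96, 0)))

  # siRNA unit deleted (and the now-inert sites removed): reporter ON
  no_si <- base
  no_si$units <- no_si$units[1]
  no_si$units[[1]]$cargo$sirna_targets <- list()
  m_on <- wire_circuit(no_si)
  gfp_on <- reporter_output(simulate_circuit(m_on, simulation_schedule(96, 0)))
  expect_gt(gfp_on, 1000)
  expect_lt(gfp_sil, gfp_on / 10)

  # activator pool zeroed: leak-level output only, bounded by the leak-only
  # closed form of the expression chain (silencing can only push it lower)
  off <- base
  off$pools <- lapply(off$pools, function(p) {
    if (p$name == "act1") { p$initial_copies <- 0; p$production_rate <- NULL }
    p
  })
  m_off <- wire_circuit(off)
  tr_off <- simulate_circuit(m_off, simulation_schedule(96, 0))
  gfp_off <- reporter_output(tr_off)
  q <- default_q()
  leak_flux <- q[["leak"]] * q[["pool_RNAP"]]
  bound <- chain_gain_oracle(leak_flux)
  expect_lt(gfp_off, bound * 1.05)
  expect_lt(gfp_off, gfp_on / 100)
})

test_that("chemical a alone flips siRNA-a off and siRNA-not-a on", {
  fx <- build_rnai_evaluator()
  m <- wire_circuit(fx$circuit)
  tr <- simulate_circuit(m, simulation_schedule(96, 48, input_levels = c(a = 2000)))
  yend <- tr$states[nrow(tr$states), ]
  y0 <- tr$states[1, ]
  # before induction the loaded pools carry siRNA-a; afterwards siRNA-not-a
  expect_gt(yend[["RS_si_na()"]], 10)
  expect_lt(yend[["RS_si_a()"]], 1)
  expect_gt(yend[["RS_si_b()"]], 10)   # b absent, so siRNA-b stays up
})
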