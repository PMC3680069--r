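test_that("zero machinery pools give identically zero expression", {
  circ <- build_cascade_example()
  circ$pools <- lapply(circ$pools, function(p) {
    if (p$name %in% partpool:::MACHINERY) p$initial_copies <- 0
    p
  })
  m <- wire_circuit(circ)
  tr <- simulate_circuit(m, simulation_schedule(4, 0))
  expr_cols <- grep("^(TR_|M_|DS_|SI_|PR_|PolCl_)", colnames(tr$states))
  expect_true(all(abs(tr$states[, expr_cols]) < 1e-12))
})

test_that("machinery totals are conserved along the full schedule", {
  m <- wire_circuit(build_cascade_example())
  tr <- simulate_circuit(m, simulation_schedule(96, 48))
  tot <- machinery_totals(tr)
  drift <- apply(tot, 2, function(v) diff(range(v)) / max(v[1], 1))
  expect_true(all(drift < 1e-6))
})

test_that("a constitutive unit reaches the closed-form steady state", {
  m <- wire_circuit(constitutive_test_circuit())
  tr <- simulate_circuit(m, simulation_schedule(96, 0))
  oracle <- constitutive_chain_oracle()
  sim_protein <- reporter_output(tr)
  expect_equal(sim_protein, oracle$protein, tolerance = 0.01)
  # mRNA-state levels agree too
  yend <- tr$states[nrow(tr$states), ]
  sim_mrna <- sum(yend[c("M_c1(st~f)", "M_c1(st~i)", "M_c1(st~e)", "M_c1(st~t)")])
  expect_equal(sim_mrna, sum(oracle$mrna_states), tolerance = 0.01)
})

test_that("normalization pins the minimal ON row at one and is scale invariant", {
  tab <- data.frame(entry = c("00", "01", "10", "11"),
                    output = c(3, 250, 500, 1000),
                    expected = c(FALSE, TRUE, TRUE, TRUE))
  tt <- partpool:::finish_truth_table(tab)
  expect_equal(min(tt$normalized[tt$expected]), 1)
  expect_equal(attr(tt, "separation"), 247)
  expect_false(attr(tt, "failed"))
  # doubling every raw output leaves the normalized column unchanged
  tab2 <- tab; tab2$output <- tab2$output * 2
  tt2 <- partpool:::finish_truth_table(tab2)
  expect_equal(tt2$normalized, tt$normalized)
  # all-equal outputs: separation 0 and the failed-classification flag
  tab3 <- tab; tab3$output <- rep(7, 4)
  tt3 <- normalize_truth_table(partpool:::finish_truth_table(tab3))
  expect_equal(tt3$normalized, rep(1, 4))
  expect_equal(attr(tt3, "separation"), 0)
  expect_true(attr(tt3, "failed"))
})

test_that("the evaluator Boolean function matches direct evaluation", {
  f <- build_rnai_evaluator()$boolean_fn
  expect_true(f(1, 1, 0, 1))    # a AND b AND d
  expect_false(f(0, 0, 0, 0))
  expect_true(f(0, 0, 1, 0))    # NOT a AND c: the weakest ON branch
  expect_false(f(1, 0, 1, 0))   # a blocks the NOT-a branch
})

test_that("clamped inputs stay constant while a bolus is consumed", {
  m <- wire_circuit(build_rnai_evaluator()$circuit)
  sch_clamp <- simulation_schedule(0.5, 0.5, input_levels = c(a = 2000), clamped = TRUE)
  tr1 <- simulate_circuit(m, sch_clamp)
  expect_equal(unname(tr1$states[nrow(tr1$states), "CH_a()"]), 2000)
  sch_bolus <- simulation_schedule(0.5, 0.5, input_levels = c(a = 2000), clamped = FALSE)
  tr2 <- simulate_circuit(m, sch_bolus)
  expect_lt(tr2$states[nrow(tr2$states), "CH_a()"], 2000)
})

test_that("an input level for an unknown chemical is rejected", {
  m <- wire_circuit(build_cascade_example())
  expect_error(simulate_circuit(m, simulation_schedule(0.1, 0.1, input_levels = c(z = 10))),
               "not a circuit input")
})
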