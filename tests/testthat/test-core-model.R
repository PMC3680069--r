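test_that("carrier kinds and flux names are in bijection", {
  ck <- carrier_kinds()
  expect_equal(nrow(ck), 5L)
  expect_false(anyDuplicated(ck$kind) > 0)
  expect_false(anyDuplicated(ck$flux_name) > 0)
  expect_equal(ck$flux_name[ck$kind == "RNA_polymerase"], "PoPS")
  expect_equal(ck$flux_name[ck$kind == "ribosome"], "RiPS")
  expect_equal(ck$flux_name[ck$kind == "chemical"], "SiPS")
})

test_that("spec constructors enforce their invariants", {
  expect_error(riboswitch_spec("single", c("a", "b")), "one aptamer")
  expect_error(riboswitch_spec("tandem", "a"), "two aptamer")
  expect_error(riboswitch_spec("tandem", c("a", "b"), cooperativity = "homo"), "homo")
  expect_error(riboswitch_spec("tandem", c("a", "a"), cooperativity = "hetero"), "hetero")
  expect_error(terminator_spec("t", transcript_decay_rate = 0), "positive")
  expect_error(promoter_spec("p", rnap_bind_rate = -1), "non-negative")
  expect_error(promoter_spec("p", list(tf_binding("r"), tf_binding("r"))), "duplicated TF")
  expect_error(sirna_target_spec("s", n_sites = 0), "n_sites")
  expect_error(pool_spec("x", carrier = "nonsense"), "unknown carrier")
})

test_that("validation flags unresolved names, duplicates and bad operator counts", {
  circ <- build_rnai_evaluator()$circuit
  expect_equal(nrow(validate_circuit(circ)), 0L)

  # siRNA target with no gene producing it
  bad <- circ
  bad$units[[6]]$cargo$sirna_targets[[1]]$sirna_name <- "ghost"
  d <- validate_circuit(bad)
  expect_true(any(grepl("unresolved siRNA", d$problem)))

  # zero operators
  bad2 <- circ
  bad2$units[[1]]$promoter$tf_bindings[[1]]$n_operators <- 0L
  d2 <- validate_circuit(bad2)
  expect_true(any(grepl("n_operators", d2$problem)))

  # duplicated pool
  bad3 <- circ
  bad3$pools <- c(bad3$pools, bad3$pools[1])
  d3 <- validate_circuit(bad3)
  expect_true(any(grepl("duplicated pool", d3$problem)))

  # validation is idempotent and side-effect free
  expect_identical(validate_circuit(circ), validate_circuit(circ))
})

test_that("an untargeted siRNA gene is a warning, not an error", {
  circ <- build_rnai_evaluator()$circuit
  drop_target <- function(u) {
    if (inherits(u$cargo, "pp_coding_region") && length(u$cargo$sirna_targets)) {
      u$cargo$sirna_targets <- u$cargo$sirna_targets[-1]
    }
    u
  }
  circ$units <- lapply(circ$units, drop_target)
  d <- validate_circuit(circ)
  expect_true(any(d$severity == "warning" & grepl("inert", d$problem)))
  expect_false(any(d$severity == "error"))
})

test_that("molar rate conversion scales with compartment volume", {
  expect_equal(molar_to_stochastic(6.02214076e23, 1), 1)
  expect_equal(molar_to_stochastic(1e6, 3e-15) / molar_to_stochastic(1e6, 3e-14), 10)
})
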