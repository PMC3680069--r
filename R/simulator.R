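# Deterministic mass-action simulation of a wired circuit model and
# Boolean truth-table evaluation.
#
# Protocol: the circuit equilibrates for a fixed horizon in the absence of
# chemicals, inputs are applied (clamped at a constant copy number by
# default) at the equilibration boundary, and outputs are read at the end
# of the evaluation horizon.

#' Define a simulation schedule
#'
#' @param equilibration_hours Hours of chemical-free equilibration (default
#'   96).
#' @param evaluation_hours Hours of simulation after the inputs are applied
#'   (default 48).
#' @param input_levels Named numeric vector: copy number at which each
#'   present chemical is applied.
#' @param clamped If `TRUE` (default) chemicals are held at their level for
#'   the whole evaluation; if `FALSE` they are applied as a one-time bolus
#'   and then evolve freely.
#' @return A `pp_schedule` object.
#' @export
simulation_schedule <- function(equilibration_hours = 96, evaluation_hours = 48,
                                input_levels = numeric(0), clamped = TRUE) {
  structure(list(equilibration_hours = equilibration_hours,
                 evaluation_hours = evaluation_hours,
                 input_levels = input_levels, clamped = isTRUE(clamped)),
            class = "pp_schedule")
}

# precompute the mass-action right-hand side and analytic Jacobian
assemble_odes <- function(model) {
  ns <- nrow(model$species)
  nr <- length(model$reactions)
  S <- matrix(0, ns, nr)
  i1 <- integer(nr); i2 <- integer(nr); k <- numeric(nr)
  for (r in seq_len(nr)) {
    rx <- model$reactions[[r]]
    k[r] <- rx$rate
    re <- rx$reactants
    if (length(re) >= 1L) i1[r] <- re[1]
    if (length(re) >= 2L) i2[r] <- re[2]
    for (s in re) S[s, r] <- S[s, r] - 1
    for (s in rx$products) S[s, r] <- S[s, r] + 1
  }
  list(S = S, i1 = i1, i2 = i2, k = k, ns = ns, nr = nr)
}

make_rhs <- function(ode, clamp_ids) {
  S <- ode$S
  if (length(clamp_ids)) S[clamp_ids, ] <- 0
  i1 <- ode$i1; i2 <- ode$i2; k <- ode$k
  has1 <- which(i1 > 0L); has2 <- which(i2 > 0L)
  nr <- ode$nr; ns <- ode$ns
  # mass action is a smooth polynomial: no clipping, so the analytic
  # Jacobian is exact and negative excursions stay at the tolerance scale
  rhs <- function(t, y, parms) {
    v <- k
    v[has1] <- v[has1] * y[i1[has1]]
    v[has2] <- v[has2] * y[i2[has2]]
    list(as.numeric(S %*% v))
  }
  D <- matrix(0, nr, ns)
  idx1 <- cbind(has1, i1[has1])
  idx2 <- cbind(has2, i2[has2])
  jac <- function(t, y, parms) {
    D[] <- 0
    # d v_r / d y_{i1} = k * y_{i2}; d v_r / d y_{i2} = k * y_{i1}
    d1 <- k[has1]
    both1 <- i2[has1] > 0L
    d1[both1] <- d1[both1] * y[i2[has1][both1]]
    D[idx1] <- d1
    D[idx2] <- k[has2] * y[i1[has2]]
    S %*% D
  }
  list(rhs = rhs, jac = jac)
}

#' Simulate a wired circuit model
#'
#' Integrates the mass-action ODE system (stiff solver, analytic Jacobian)
#' over the equilibration-plus-evaluation schedule. Chemical inputs are
#' zero during equilibration and applied at the boundary.
#'
#' @param model A `pp_model` from [wire_circuit()].
#' @param schedule A [simulation_schedule()].
#' @param n_out Number of output time points per phase.
#' @param rtol,atol Solver tolerances (defaults 1e-8 / 1e-12).
#' @return A `pp_trajectory`: list with `times` (seconds), `states` (time x
#'   species matrix, columns named by species label), and `model`.
#' @export
simulate_circuit <- function(model, schedule = simulation_schedule(),
                             n_out = 25, rtol = 1e-8, atol = 1e-12) {
  ode <- assemble_odes(model)
  clamp_ids <- unname(model$chemicals)
  y0 <- model$species$copies
  t_eq <- schedule$equilibration_hours * 3600
  t_ev <- schedule$evaluation_hours * 3600

  run <- function(y, tmax, clamped_now) {
    f <- make_rhs(ode, if (clamped_now) clamp_ids else integer(0))
    times <- seq(0, tmax, length.out = max(2L, n_out))
    out <- deSolve::ode(y = y, times = times, func = f$rhs, parms = NULL,
                        jacfunc = f$jac, jactype = "fullusr", method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 500000)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integration failure at t = %g s", out[nrow(out), 1]))
    out
  }

  states <- NULL; times <- numeric(0)
  if (t_eq > 0) {
    out <- run(y0, t_eq, clamped_now = TRUE)  # chemicals clamped at zero
    states <- unname(out[, -1, drop = FALSE])
    times <- out[, 1]
    y0 <- pmax(states[nrow(states), ], 0)
  }
  if (t_ev > 0) {
    lv <- schedule$input_levels
    if (length(lv)) {
      ids <- model$chemicals[names(lv)]
      if (anyNA(ids)) stop("input level for a chemical that is not a circuit input")
      y0[ids] <- y0[ids] + unname(lv)
    }
    out <- run(y0, t_ev, clamped_now = schedule$clamped)
    states <- rbind(states, unname(out[, -1, drop = FALSE]))
    times <- c(times, t_eq + out[, 1])
  }
  colnames(states) <- model$species$label
  structure(list(times = times, states = states, model = model),
            class = "pp_trajectory")
}

#' Conserved machinery totals along a trajectory
#'
#' @param traj A `pp_trajectory`.
#' @return Matrix (time x machinery kind) of free-plus-engaged totals.
#' @export
machinery_totals <- function(traj) {
  cm <- machinery_matrix(traj$model)
  traj$states %*% cm
}

#' Reporter output of a trajectory
#'
#' @param traj A `pp_trajectory`.
#' @param at Time index (default: last).
#' @return Total reporter copy number.
#' @export
reporter_output <- function(traj, at = nrow(traj$states)) {
  sum(traj$states[at, traj$model$reporters])
}

#' Evaluate a circuit's Boolean truth table
#'
#' Runs the chemical-free equilibration once, then one evaluation per input
#' combination with the present chemicals clamped at `input_level` copies.
#' Rows are classified by thresholding the reporter output at the midpoint
#' between the largest expected-OFF and the smallest expected-ON output;
#' the signal separation is min(ON) - max(OFF) in reporter copies.
#'
#' @param model A `pp_model`.
#' @param boolean_fn Expected Boolean function, `function(a, b, c, d)` (or
#'   however many inputs the circuit has).
#' @param schedule A [simulation_schedule()]; its `input_levels` give the
#'   clamped copy number per input (chemicals missing from it default to
#'   `input_level`).
#' @param inputs Input names, defaulting to the circuit's chemical inputs.
#' @param input_level Default clamped copy number for a present chemical.
#' @param rtol,atol Solver tolerances.
#' @return A `pp_truthtable` data.frame with one row per input combination:
#'   input bits, `output` (reporter copies), `expected`, `call`,
#'   `normalized`; attributes `separation` (copies), `threshold` and
#'   `failed` (separation <= 0).
#' @export
truth_table <- function(model, boolean_fn, schedule = simulation_schedule(),
                        inputs = names(model$chemicals), input_level = 2000,
                        rtol = 1e-8, atol = 1e-12) {
  ni <- length(inputs)
  ode <- assemble_odes(model)
  clamp_ids <- unname(model$chemicals)
  lv <- stats::setNames(rep(input_level, ni), inputs)
  if (length(schedule$input_levels)) lv[names(schedule$input_levels)] <- schedule$input_levels

  run <- function(y, tmax, clamped_now) {
    f <- make_rhs(ode, if (clamped_now) clamp_ids else integer(0))
    out <- deSolve::ode(y = y, times = c(0, tmax), func = f$rhs, parms = NULL,
                        jacfunc = f$jac, jactype = "fullusr", method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 500000)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integration failure at t = %g s", out[nrow(out), 1]))
    pmax(out[nrow(out), -1], 0)
  }
  y_eq <- run(model$species$copies, schedule$equilibration_hours * 3600, TRUE)

  combos <- expand.grid(rep(list(0:1), ni))[, ni:1, drop = FALSE]
  colnames(combos) <- inputs
  outputs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    y <- y_eq
    on <- inputs[combos[i, ] == 1]
    if (length(on)) y[model$chemicals[on]] <- y[model$chemicals[on]] + lv[on]
    yf <- run(y, schedule$evaluation_hours * 3600, schedule$clamped)
    outputs[i] <- sum(yf[model$reporters])
  }
  expected <- apply(combos, 1, function(row) do.call(boolean_fn, as.list(row == 1)))
  tab <- data.frame(combos, entry = apply(combos, 1, paste, collapse = ""),
                    output = outputs, expected = expected,
                    stringsAsFactors = FALSE)
  finish_truth_table(tab)
}

finish_truth_table <- function(tab) {
  on <- tab$output[tab$expected]; off <- tab$output[!tab$expected]
  separation <- if (length(on) && length(off)) min(on) - max(off) else NA_real_
  threshold <- if (length(on) && length(off)) (min(on) + max(off)) / 2 else NA_real_
  tab$call <- tab$output > threshold
  tab$normalized <- if (length(on)) tab$output / min(on) else rep(NA_real_, nrow(tab))
  structure(tab, class = c("pp_truthtable", "data.frame"),
            separation = separation, threshold = threshold,
            failed = !is.na(separation) && separation <= 0)
}

#' Normalize a truth table to its minimal ON output
#'
#' Each row's output is divided by the smallest expected-ON output, so the
#' minimal ON row is exactly 1. The operation is invariant under rescaling
#' of the raw outputs.
#'
#' @param table A `pp_truthtable`.
#' @return The table with its `normalized` column (re)computed.
#' @export
normalize_truth_table <- function(table) {
  finish_truth_table(as.data.frame(table))
}

#' @export
print.pp_truthtable <- function(x, ...) {
  df <- as.data.frame(x)
  df$output <- signif(df$output, 4)
  df$normalized <- signif(df$normalized, 4)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("separation: %.1f copies | threshold: %.1f | %s\n",
              attr(x, "separation"), attr(x, "threshold"),
              if (attr(x, "failed")) "CLASSIFICATION FAILED" else "classified"))
  invisible(x)
}
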