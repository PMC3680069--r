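---
title: "Rule-based design of eukaryotic gene circuits with partpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based design of eukaryotic gene circuits with partpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partpool)
```

## The modeling framework

partpool builds dynamic models of synthetic eukaryotic gene circuits from
*composable parts* (promoters, coding regions, siRNA genes, terminators)
and *pools* of free signal-carrier molecules. Five signal carriers connect
the modules: RNA polymerases (flux PoPS), ribosomes (RiPS), transcription
factors (FaPS), small RNAs (RNAPS) and chemicals (SiPS). Parts exchange
these carriers through typed flux terminals; pools are the storages that
drive circuit activity and the interface between a circuit and its
environment. The cell is two compartments — nucleus and cytoplasm — with
transcription, splicing and Dicer processing nuclear, and translation and
RNA interference cytoplasmic.

The difficulty this package addresses is combinatorial: a promoter with
$n$ operators has $2^n$ occupancy configurations, and a promoter bound by
one factor species on six operators already generates 64 configurations
and 192 binding reactions. Writing such networks by hand does not scale,
so every part is specified declaratively (binding-site counts, regulator
roles, cooperativity, chemical regulation, kinetic constants) and compiled
into its full mass-action reaction network by a generic rule engine.

## The rule engine

A part model starts from molecule types (named components with finite
state sets, optionally bindable), seed species, and rewrite rules
(patterns with wildcards plus primitive effects: bind, unbind, state
change, create, delete). `expand_rules()` closes the seed set under rule
application to a fixed point, emitting every induced reaction exactly
once. Three conventions matter for reproducibility:

* **Canonical labels.** Species are graphs of molecules and bonds;
  isomorphic graphs receive identical labels. Canonicalization refines
  per-molecule signatures by neighbourhood (Weisfeiler–Lehman style) and
  resolves residual ties by exhaustive permutation. Complexes here are
  small (a promoter plus at most eight factors), so the exhaustive
  fallback is cheap; there is no need for nauty-style optimization.
* **Symmetry factors.** A rule matching one reactant tuple through $k$
  symmetric embeddings yields a single reaction whose rate carries
  $k$ divided by the pattern automorphism count — the deterministic
  mass-action convention (a symmetric dimer dissociates with factor 1,
  not 2).
* **Determinism.** Output species are sorted by canonical label and
  reactions by (reactants, products, rule), so expansion is invariant
  under permutation of rules and seeds, and re-expanding an expanded
  network is a fixed point. The closure is bounded by `max_species`
  (default 10,000) and aborts naming the offending rule if exceeded.

Duplicate reactions produced by the same rule are merged; identical
reactions from different rules are kept apart so provenance survives into
the flattened circuit.

## Part models

### Promoters

Operator position is not modeled explicitly, but affinity ranks are:
repressors bind strongest closest to the transcription start site,
activators strongest furthest from it; rank $r$ scales the binding rate by
`affinity_gradient^(-r)`. Cooperativity multiplies the rate by
`cooperativity_factor` when a rank-adjacent operator of the same factor is
occupied. Repression follows the competition model — a DNA-bound repressor
excludes polymerase, and polymerase occludes the operators — while
activators recruit polymerase (any operator bound suffices without
cooperativity; all of them with it) and may bind alongside it.

Each (configuration, operator) pair yields four reactions: factor binding,
unbinding, chemical stripping (`chemical + promoter·TF -> promoter +
TF·chemical`, a single bimolecular event with no DNA-ternary
intermediate), and bound-factor turnover (degradation of the factor on the
DNA). Turnover is the package's reading of the fourth per-operator
reaction family; re-binding of the inactivated factor (the reverse of
stripping) fits the same counts and is available behind
`compile_promoter(fourth_family = "strip_reverse")`. Leak transcription is
one reaction per non-permissive polymerase-free configuration, modeled as
a free polymerase initiating at the small per-molecule rate `leak_rate`;
making leak consume a polymerase keeps the polymerase pool exactly
conserved. Permissive configurations support polymerase binding,
unbinding, and initiation, which releases a cleared polymerase onto the
outgoing PoPS terminal. For an all-repressor promoter with $n$ operators,
all chemically regulated, this gives $2^n + 1$ species and
$4n\,2^{n-1} + (2^n - 1) + 3$ reactions — 5 species / 22 reactions at one
repressor on two operators, 65 / 834 at three repressors on two operators
each. When a chemical strips the last activator holding a polymerase, the
polymerase is ejected (with cooperativity, freeing the rightmost operator
suffices).

Promoters mixing repressors with more than one cooperative activator
species are rejected as unsupported: the activation and ejection semantics
of that combination are not defined in this framework.

### Coding regions and mRNA pools

A coding region compiles to two coupled models. The nuclear part turns
each arriving cleared polymerase into an immature transcript (returning
the polymerase to its pool), splices it through an explicit three-reaction
Michaelis–Menten spliceosome scheme (bind, unbind, catalyze — full mass
action, never a lumped hyperbolic rate), and exports the mature mRNA in
one lumped maturation-and-transport reaction, keeping the parameter count
low. The cytoplasmic mRNA pool holds five base species — the transcript in
transit, free mRNA, and ribosome-bound mRNA in initiation, elongation and
termination phases — and nine base reactions: pool entry, ribosome
binding/unbinding, initiation-to-elongation, elongation-to-termination,
release (protein plus ribosome), and decay of the free, initiating and
elongating states with machinery release. The termination state is
treated as too short-lived to decay, and the released protein is a
pool-side (boundary) species. This composition is one of several
consistent with the documented totals; the count constraints, not the
bookkeeping identities, are the load-bearing choice.

Each siRNA binding site adds exactly two species (site-bound mRNA with and
without a ribosome; the ribosome phase is lumped once a site is occupied)
and six reactions: the RISC-loaded siRNA binds any of the four base states
of an otherwise-unoccupied transcript, and cleavage from either bound
state destroys the mRNA while releasing the loaded RISC and any ribosome.
States with more than one bound siRNA are forbidden, which is why an mRNA
with six sites stays at 17 species while a promoter with six operators
explodes to 65. With $s$ sites over $k$ siRNA species the pool has
$5 + 2s$ species, $9 + 6s$ reactions and $2 + k$ terminals.

Riboswitches gate ribosome recruitment: each carries one (single) or two
(tandem) aptamers, switches on only when all its aptamers are
chemical-bound (`switch_on_rate`/`switch_off_rate` govern the
conformational step), and translation requires every riboswitch on the
transcript to be on. Tandem riboswitches support homo- and
hetero-cooperative binding through a rate multiplier on the second
aptamer. This is a chemical-activated family; chemical-repressed
riboswitches are outside the current scope.

### siRNA genes and pools

The nuclear siRNA part mirrors the coding region with Dicer in place of
the spliceosome (production, three-reaction Michaelis–Menten processing,
lumped export, nuclear decay — six reactions). The cytoplasmic siRNA pool
receives the guide, loads it onto free RISC, and decays free siRNA at the
terminator rate. A fourth reaction turns the loaded complex back over to
free RISC: without any sink on RISC·siRNA, even leak-level siRNA
production would monotonically sequester the (conserved, finite) RISC
pool over a 96-hour equilibration and silence gates that should be on.
The turnover rate (`risc_unload_rate`) doubles as the effective lifetime
of the silencing signal.

### Factor, product, machinery and chemical pools

Transcription-factor products are synthesized in the cytoplasm, imported
into the nucleus first-order, and inactivated there by their chemical
(`TF + chem <-> TF·chem`), with first-order degradation of both forms.
Reporters stay cytoplasmic and only degrade. Input factors (those not
produced by any unit) live in homeostatic nuclear pools with zero-order
synthesis balancing degradation — necessary because bound-factor turnover
on DNA is a slow, persistent sink. Machinery pools (RNAP, ribosome,
spliceosome, Dicer, RISC) are conserved storages: no synthesis, no
degradation, and the free-plus-engaged total is an exact invariant used as
a correctness check. Chemical pools are the circuit's environment
interface and are clamped by the simulation schedule.

## Composition and flux terminals

`wire_circuit()` compiles every part, verifies that each part-side
terminal finds a counterpart of the same name and carrier kind with
opposite direction (pool-side terminals may fan out or sit idle), and
flattens the networks, unifying boundary species by canonical label at the
declared terminals only — systematic molecule-type naming makes accidental
collision impossible. Flattening is lossless: circuit species equal the
sum of module species minus reported merges, and the circuit reaction
multiset equals the union of the module networks. Transport reactions
(mRNA/siRNA export, factor import) are attributed to the exporting module.
Terminal counting follows the framework's flux convention: a promoter
exposes three polymerase-side terminals (RNAP in, RNAP out, PoPS out) plus
factor in/out per regulator and one stripping terminal per chemically
regulated factor; pool-type parts expose one terminal per connected
external pool, with transcript influx attributed to the nuclear part.

## Simulation and truth tables

The flattened network is integrated as deterministic mass-action ODEs
(`deSolve::lsoda`, analytic Jacobian, relative tolerance $10^{-8}$,
absolute $10^{-12}$; up to $5 \times 10^5$ internal steps per phase for
the stiff stripping transients). Deterministic simulation is appropriate here
because both packaged evaluators separate ON from OFF by far more than 100
reporter molecules, the regime in which Boolean circuits are insensitive
to stochastic noise. The protocol is horizon-based rather than
residual-based: 96 hours of chemical-free equilibration, inputs applied at
the boundary (clamped at a constant copy number by default; a bolus mode
exists behind `clamped = FALSE`), outputs read after 48 hours. All state
is in molecule copies per compartment; bimolecular rate constants are
per-molecule stochastic rates already scaled to their compartment, so
compartment volumes only enter through the `molar_to_stochastic()` helper.

`truth_table()` runs the equilibration once and one evaluation per input
combination, classifies rows by thresholding at the midpoint between the
largest expected-OFF and smallest expected-ON output, reports the
separation min(ON) − max(OFF) in reporter copies, and normalizes each row
by the minimal ON output (so the weakest ON entry is exactly 1, and the
table is invariant under rescaling). A non-positive separation raises the
failed-classification flag rather than an error.

## The packaged circuits and the default parameters

Three fixtures exercise the whole pipeline. The cascade is an
activator-driven reporter silenced by a constitutively expressed siRNA.
The two logic evaluators compute $(a \wedge b \wedge d) \vee (\neg a
\wedge c)$ over four chemical inputs: the RNAi version converts each
input into an siRNA (inputs strip the activators driving siRNA-a/b/c/d;
input $a$ also strips the repressor guarding siRNA-not-a, so $a$ silences
siRNA-a and switches siRNA-not-a on) and silences two constitutive AND
transcription units producing one shared fluorescent reporter, six siRNA
sites on the AND1 transcript and four on AND2. The transcriptional
version replaces each siRNA with a repressor: upstream units convert
chemicals into repressors, the AND1 promoter carries three repressors on
two operators each (strippable by a, b, d — each of those chemicals acts
on two different factors), the AND2 promoter two repressors on two
operators each. Where the circuit literature leaves sub-structures open,
the fixtures choose once: activator-controlled upstream promoters carry
one operator; the repressor-controlled not-a unit carries two (matching
its transcriptional analog) and binds its repressor more tightly
(`r0_bind`), since with the shared default that unit's OFF state leaked
well above promoter leak and corrupted the AND2-driven entries.

The default parameter table (`default_parameters()`) is a set of
order-of-magnitude literature defaults — initiation, splicing and export
on the $10^{-2}$–$10^{-1}\,s^{-1}$ scale, transcript half-life about an
hour, protein half-life about two hours, machinery pools of hundreds to
thousands of copies, inputs clamped at 2000 molecules. They are design
defaults of this package, documented with units and chosen once so the
circuits function as drawn; they are not fitted to any measured
fluorescence data, and absolute output levels should be read as
illustrative, not predictive.

What the fixtures do and do not emulate: they reproduce the wiring logic,
the combinatorial part complexity, and a wide ON/OFF separation under
clean, deterministic conditions with clamped inputs and homogeneous
parameter values across parts of the same type. They do not emulate
cell-to-cell variability, growth and dilution, positional operator
effects, transcription squelching, saturation of shared machinery under
load, or measured reporter calibrations — so a passing truth table shows
the design logic and the compiler are sound, not that a wet-lab
implementation would show these exact levels.

## Numerical choices and degenerate inputs

* Expansion bound 10,000 species; exceeding it names the last rule.
* Canonicalization refuses complexes whose residual symmetry would need
  more than 50,000 permutations — far beyond anything a gene-circuit part
  produces.
* The transit and release steps (`pool_entry`, `release`, `transcribe`)
  use a fixed 1 s⁻¹ bookkeeping rate: fast against every regulated step,
  so they add no effective parameter.
* Empty circuits wire to an empty manifest; a speciesless model is
  refused by the SBML exporter. The right-hand side is the raw
  mass-action polynomial — deliberately not clipped at zero, so the
  analytic Jacobian is exact and Newton iterations converge; negative
  excursions are self-correcting and stay at the tolerance scale, and
  conserved machinery totals drift by less than $10^{-6}$ relative over
  a full 144-hour schedule.
* Ties in truth-table thresholding (identical ON and OFF outputs) yield
  separation 0 and the failed flag, never a silent call.

The automated checks run the full protocol at the study scale: both
16-entry truth tables under 96 h + 48 h, promoter families to eight
operators and mRNA pools to ten siRNA sites verified against closed-form
counts and exhaustive enumeration, and a constitutive expression chain
compared with an algebraic fixed-point solution of the same kinetics.

## Known limitations

* Operator positional effects and squelching are not modeled; activator
  and repressor zones are implicit in the affinity-rank convention.
* Bacterial ribosome-binding-site parts are out of scope; this is the
  eukaryotic part family only.
* The riboswitch family is chemical-activated; chemical-repressed
  switches and ribozymes are not implemented.
* The SBML export targets Level 3 core with mass-action kinetic laws; it
  is a faithful dump of the flattened network, not a round-trip carrier
  of the part/pool module structure.
* Whole-circuit totals depend on sub-structures (upstream operator
  counts, pool bookkeeping) that the framework leaves open; the module
  report prints them, but only per-part counts are treated as reference
  values.
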