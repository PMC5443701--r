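## Shared fixtures: all built in code, deterministic.

cond_100mM <- function(pH = 7) solution_conditions(pH, 0.1)
cond_1mM <- function(pH = 8.8) solution_conditions(pH, 0.001)

acid_group <- function(pKa = 4) ionizable_group(pKa, -1, label = "acid")
base_group <- function(pKa = 10.4) ionizable_group(pKa, +1, label = "base")

## the compact-protein regulation benchmark: Q/R = 2.5 1/nm at R = 5.1 nm,
## eps_p = 20, Born term on, pKa 4 acids, pH 7, 100 mM
regulation_benchmark_model <- function() {
  gs <- group_set(list(acid_group(4)), 12.75)
  sphere_model(5.1, 20, gs)
}

## coarse-but-adequate control for solver tests
fast_control <- function(...) pb_control(...)
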