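# Scenario runs are expensive relative to the rest of the suite; memoise
# them so each scenario integrates once per test run, at the default
# resolution (30/5/10/200 cells).
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, cells = c(30, 5, 10, 200)) {
  key <- paste(name, paste(cells, collapse = "x"), sep = "@")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_scenario(name, cells_per_segment = cells)
  .run_cache[[key]]
}

# saline composition carrying some HOCl, at dissociation/water equilibrium
equilibrated_composition <- function(hocl = 1, pH = 3,
                                     chem = chem_params()) {
  c0 <- initial_composition(pH0 = pH, Ka_H2O = chem$Ka_H2O)
  c0["HOCl"] <- hocl
  c0["ClO"] <- chem$Ka_HOCl * c0["HOCl"] / c0["H"]
  c0
}
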