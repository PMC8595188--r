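# The reciprocal-flow ensemble shared by the acceptance checks (built on
# first use, ~15 min; reused by the ratio and per-seed structure tests).

acceptance_ensemble <- function() cached("acceptance_ensemble", {
  cfg <- sim_config(geometry = list(length = 150, target_edge = 7, seed = 1))
  geom <- build_geometry(cfg)
  run_ensemble(cfg, n_seeds = 5, geom = geom)
})

# tether-free control runs on the same geometry, drive and relaxation
# protocol (no steady state exists without tethers)
acceptance_controls <- function() cached("acceptance_controls", {
  cfg <- sim_config(geometry = list(length = 150, target_edge = 7, seed = 1),
                    tethers = list(active = FALSE))
  geom <- acceptance_ensemble()$geom
  list(pos = run_simulation(cfg, 1, geom = geom),
       neg = run_simulation(cfg, -1, geom = geom))
})
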