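# Scaled study artifacts shared by the acceptance checks: computed once per
# test session. Problem sizes are desk-scale: they resolve signs and bounds,
# not publication-grade statistics.

.study_cache <- new.env(parent = emptyenv())

study_artifacts <- function() {
  if (!is.null(.study_cache$art)) return(.study_cache$art)
  K <- protein_k()
  U <- protein_u()
  setup_c <- folding_setup("plane_tether", anchored_bead = 1L)
  setup_n <- folding_setup("plane_tether", anchored_bead = 41L)

  ## melting temperatures, each protein from its own replica-exchange run
  grid <- build_temperature_grid(0.5, 1.0, 24)
  re_bulk <- run_replica_exchange(K, grid, sweep_steps = 4000, n_sweeps = 800,
                                  seed = 9101)
  tm <- estimate_tm(heat_capacity(re_bulk))
  re_bulk_u <- run_replica_exchange(U, grid, sweep_steps = 4000, n_sweeps = 800,
                                    seed = 9102)
  tm_u <- estimate_tm(heat_capacity(re_bulk_u))

  harvest_curve <- function(runs, q_values, native, n_per_bin = 200L) {
    ens <- list()
    for (q in q_values) {
      e <- suppressWarnings(harvest_ensemble(runs, q, native, n = n_per_bin,
                                             gap = 5e4))
      if (length(e$conformations) > 0L)
        ens[[sprintf("%.10g", q)]] <- e$conformations
    }
    p_knot_curve(ens)
  }

  ## late-knotting ensembles
  bulk_runs <- lapply(1:80, function(r)
    run_folding(K, tm, 4e6, record_interval = 4e6, snapshot_interval = 2000,
                seed = 9200 + 13L * r, stop_at_fold = FALSE))
  curve_bulk <- harvest_curve(bulk_runs, (0:15) / 40, K$native_map)
  curve_full <- harvest_curve(bulk_runs, c(38, 39, 40) / 40, K$native_map,
                              n_per_bin = 100L)
  teth_runs <- lapply(1:16, function(r)
    run_folding(K, tm, 8e6, record_interval = 8e6, snapshot_interval = 2000,
                setup = setup_c, seed = 9300 + 13L * r, stop_at_fold = FALSE))
  curve_teth <- harvest_curve(teth_runs, (0:32) / 40, K$native_map)

  ## bulk folding rates of K and U at Tm
  rate_of <- function(native, temp, seed0, n_runs = 300L, budget = 2e7,
                      snapshot_interval = 2e4) {
    runs <- lapply(seq_len(n_runs), function(r)
      run_folding(native, temp, budget, record_interval = budget,
                  snapshot_interval = snapshot_interval,
                  seed = seed0 + 17L * r))
    res <- fit_rate(collect_fpts(runs))
    list(rate = res$rate, runs = runs, result = res)
  }
  kin_k <- rate_of(K, tm, 9400)
  kin_u <- rate_of(U, tm_u, 9500, snapshot_interval = 0)

  ## tethered foldicity at a shared scaled budget
  fold_frac <- function(setup, seed0, n_runs = 24L, budget = 4e7,
                        snapshot_interval = 2e4) {
    runs <- lapply(seq_len(n_runs), function(r)
      run_folding(K, tm, budget, record_interval = budget,
                  snapshot_interval = snapshot_interval,
                  setup = setup, seed = seed0 + 17L * r))
    list(foldicity = mean(vapply(runs, `[[`, logical(1), "folded")),
         runs = runs)
  }
  teth_n <- fold_frac(setup_n, 9600)
  teth_c <- fold_frac(setup_c, 9700, snapshot_interval = 4e4)

  ## non-native contact profiles from the kinetic trajectories
  nn_bulk <- nonnative_profile(kin_k$runs, K$native_map)
  nn_teth <- nonnative_profile(teth_c$runs, K$native_map)

  ## tethered free-energy profile at Tm, averaged over three RE replicates
  re_teth <- pool_replica_exchange(lapply(1:3, function(r)
    run_replica_exchange(K, grid, sweep_steps = 4000, n_sweeps = 800,
                         setup = setup_c, seed = 9800 + r)))
  tm_teth <- estimate_tm(heat_capacity(re_teth))
  f_of_q_teth <- wham(re_teth, "q", t_target = tm_teth)

  .study_cache$art <- list(
    tm = tm, tm_u = tm_u, tm_teth = tm_teth,
    curve_bulk = curve_bulk, curve_teth = curve_teth,
    p_knot_native = max(curve_full$p_knot[curve_full$q == 1], 0),
    rate_k = kin_k$rate, rate_u = kin_u$rate,
    foldicity_n = teth_n$foldicity, foldicity_c = teth_c$foldicity,
    nn_bulk = nn_bulk, nn_teth = nn_teth,
    f_of_q_teth = f_of_q_teth)
  .study_cache$art
}
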