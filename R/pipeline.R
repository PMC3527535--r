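#' Study configuration
#'
#' Collects every knob of an end-to-end scaled reproduction of the tethered
#' folding study: which model systems and folding setups to run, the
#' replica-exchange, kinetics and ensemble budgets, and the seeds. All
#' randomness derives from the single `seed`. The default budgets are
#' desk-scale: they resolve the qualitative behaviour in minutes rather than
#' reproducing the publication-scale statistics.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param systems subset of `c("K", "U")`.
#' @param setups subset of `c("bulk", "tether_c", "tether_n", "point_c",
#'   "point_n")`: bulk folding, plane tethering by the C-/N-terminus, and
#'   the point-tether controls.
#' @param re replica-exchange budgets: `n_temps`, `t_low`, `t_high`,
#'   `sweep_steps`, `n_sweeps`, `swaps_per_sweep`.
#' @param kinetics fixed-temperature kinetics budgets: `n_runs`,
#'   `max_steps`, `record_interval`, `snapshot_interval`, `temperature`
#'   (`NULL` = use the estimated Tm).
#' @param ensembles ensemble/clustering controls: `q` values, `n` per
#'   ensemble, `max_clusters`.
#' @param p_crank crankshaft attempt probability used throughout.
#' @return A list of class `study_config`.
#' @export
study_config <- function(out_dir, seed = 1L, systems = "K",
                         setups = c("bulk", "tether_c", "tether_n"),
                         re = list(), kinetics = list(), ensembles = list(),
                         p_crank = 0.2) {
  re_def <- list(n_temps = 16L, t_low = 0.5, t_high = 1.4,
                 sweep_steps = 4000, n_sweeps = 500, swaps_per_sweep = 16L)
  kin_def <- list(n_runs = 50L, max_steps = 2e7, record_interval = 5e4,
                  snapshot_interval = 5e4, temperature = NULL)
  ens_def <- list(q = c(0.25, 0.5, 0.75), n = 100L, max_clusters = 8L)
  re <- utils::modifyList(re_def, re)
  kinetics <- utils::modifyList(kin_def, kinetics)
  ensembles <- utils::modifyList(ens_def, ensembles)
  structure(list(out_dir = out_dir, seed = as.integer(seed), systems = systems,
                 setups = setups, re = re, kinetics = kinetics,
                 ensembles = ensembles, p_crank = p_crank),
            class = "study_config")
}

#' Resolve a folding setup by its study name
#'
#' @param name one of `"bulk"`, `"tether_c"`, `"tether_n"`, `"point_c"`,
#'   `"point_n"` (C = bead 1, N = last bead).
#' @param n_beads chain length.
#' @return A [folding_setup()].
#' @export
setup_by_name <- function(name, n_beads) {
  switch(name,
    bulk = folding_setup("bulk"),
    tether_c = folding_setup("plane_tether", anchored_bead = 1L),
    tether_n = folding_setup("plane_tether", anchored_bead = n_beads),
    point_c = folding_setup("point_tether", anchored_bead = 1L),
    point_n = folding_setup("point_tether", anchored_bead = n_beads),
    stop("unknown setup name: ", name))
}

#' Run the scaled study end to end
#'
#' Executes design (fixture verification) -> replica-exchange thermodynamics
#' (heat capacity, Tm, F(Q) at Tm) -> fixed-temperature kinetics at Tm ->
#' knotting-probability and ensemble clustering analyses, for every
#' requested system and setup, writing a TSV/JSON report tree under
#' `config$out_dir` plus a manifest with per-stage seeds and durations. Any
#' stage failure halts the study naming the stage.
#'
#' @param config a [study_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a nested result list (`thermo`, `kinetics`, `knots`,
#'   `clusters` per system/setup).
#' @export
run_study <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "study.log")
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    say("stage %-22s done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  results <- list()
  systems <- list()

  systems <- stage("design", {
    out <- list()
    for (sys in config$systems) {
      s <- if (sys == "K") protein_k() else protein_u()
      stopifnot(length(verify_native(s)) == 0L)
      write_conformation(s$conformation,
                         file.path(config$out_dir, sprintf("protein_%s.conf", sys)))
      out[[sys]] <- s
    }
    out
  })
  manifest <- list(seed = config$seed, config = unclass(config),
                   package_version = as.character(utils::packageVersion("knotfold")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(config$setups) == 0L) {
    say("no setups requested: design-only study")
    return(invisible(list(systems = systems)))
  }

  for (sys in names(systems)) {
    native <- systems[[sys]]
    n_beads <- nrow(native$conformation)
    for (sname in config$setups) {
      setup <- setup_by_name(sname, n_beads)
      tag <- sprintf("%s_%s", sys, sname)
      dir.create(file.path(config$out_dir, tag), showWarnings = FALSE)
      seed0 <- config$seed + 101L * match(sys, c("K", "U")) +
               1009L * match(sname, c("bulk", "tether_c", "tether_n",
                                      "point_c", "point_n"))

      th <- stage(paste0("thermo/", tag), {
        grid <- build_temperature_grid(config$re$t_low, config$re$t_high,
                                       config$re$n_temps)
        re <- run_replica_exchange(native, grid, config$re$sweep_steps,
                                   config$re$n_sweeps,
                                   config$re$swaps_per_sweep, setup = setup,
                                   p_crank = config$p_crank, seed = seed0)
        cv <- heat_capacity(re)
        tm <- estimate_tm(cv)
        fq <- wham(re, "q", t_target = tm)
        write.table(cv, file.path(config$out_dir, tag, "cv.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(fq, file.path(config$out_dir, tag, "f_of_q.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(tm = tm, swap_acceptance = mean(re$swap_acceptance),
                                  round_trips = sum(re$round_trips)),
                             file.path(config$out_dir, tag, "thermo.json"),
                             auto_unbox = TRUE, digits = NA)
        list(re = re, cv = cv, tm = tm, f_of_q = fq)
      })

      kin <- stage(paste0("kinetics/", tag), {
        temp <- if (is.null(config$kinetics$temperature)) th$tm
                else config$kinetics$temperature
        runs <- lapply(seq_len(config$kinetics$n_runs), function(r)
          run_folding(native, temp, config$kinetics$max_steps,
                      record_interval = config$kinetics$record_interval,
                      snapshot_interval = config$kinetics$snapshot_interval,
                      setup = setup, p_crank = config$p_crank,
                      seed = seed0 + 17L * r))
        res <- collect_fpts(runs)
        res <- tryCatch(fit_rate(res), error = function(e) res)
        sc <- survival_curve(res)
        write.table(sc, file.path(config$out_dir, tag, "survival.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(temperature = temp,
                                  n_attempted = res$n_attempted,
                                  n_folded = res$n_folded,
                                  foldicity = res$foldicity,
                                  rate = res$rate),
                             file.path(config$out_dir, tag, "kinetics.json"),
                             auto_unbox = TRUE, digits = NA)
        list(runs = runs, result = res)
      })

      kn <- stage(paste0("knots/", tag), {
        n_native <- nrow(native$native_map)
        qs <- (0:n_native) / n_native
        ens <- list()
        for (q in qs) {
          e <- suppressWarnings(harvest_ensemble(kin$runs, q, native$native_map,
                                                 n = config$ensembles$n))
          if (length(e$conformations) > 0L)
            ens[[sprintf("%.10g", q)]] <- e$conformations
        }
        pk <- p_knot_curve(ens)
        write.table(pk, file.path(config$out_dir, tag, "p_knot.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        nn <- nonnative_profile(kin$runs, native$native_map)
        write.table(nn, file.path(config$out_dir, tag, "nonnative.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(p_knot = pk, nonnative = nn)
      })

      cl <- stage(paste0("cluster/", tag), {
        out <- list()
        for (q in config$ensembles$q) {
          e <- suppressWarnings(harvest_ensemble(kin$runs, q, native$native_map,
                                                 n = config$ensembles$n))
          if (length(e$conformations) < 2L) next
          cs <- cluster_ensemble(e, config$ensembles$max_clusters,
                                 native = native$native_map)
          qtag <- sprintf("q%03d", round(100 * q))
          write.table(data.frame(member = seq_along(cs$assignment),
                                 cluster = cs$assignment),
                      file.path(config$out_dir, tag,
                                sprintf("clusters_%s.tsv", qtag)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          for (ci in seq_along(cs$representatives))
            write_conformation(cs$representatives[[ci]],
                               file.path(config$out_dir, tag,
                                         sprintf("rep_%s_c%d.conf", qtag, ci)))
          pm <- do.call(rbind, lapply(seq_along(cs$probability_maps), function(ci)
            cbind(cluster = ci, cs$probability_maps[[ci]])))
          write.table(pm, file.path(config$out_dir, tag,
                                    sprintf("probability_map_%s.tsv", qtag)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          out[[qtag]] <- cs
        }
        out
      })

      results[[tag]] <- list(thermo = th[c("cv", "tm", "f_of_q")],
                             kinetics = kin$result, knots = kn, clusters = cl)
    }
  }
  say("study complete")
  invisible(c(list(systems = systems), results))
}
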