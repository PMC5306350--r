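#' Load an experiment plan from a plain-text config file
#'
#' A plan is a YAML file with optional top-level keys `seed` (global seed,
#' default 1) and `out_dir`, and a mandatory `runs:` list whose entries
#' hold per-run keys accepted by [run_config()] (`N`, `n_chains`, `L`,
#' `layers`, `n_timesteps`, `measure_every`, `max_loop`).  Unknown keys are
#' rejected; every run is validated for feasibility.  Per-run seeds are
#' derived deterministically from the global seed and the run index.
#'
#' @param path Path to the YAML config.
#' @return Object of class `experiment_plan`: list with `seed`, `out_dir`
#'   and `configs` (a list of [run_config()]s).
#' @export
load_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  top_known <- c("seed", "out_dir", "runs")
  bad <- setdiff(names(raw), top_known)
  if (length(bad))
    stop("config error: unknown top-level key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(raw$runs) || !length(raw$runs))
    stop("config error: plan must contain a non-empty 'runs' list",
         call. = FALSE)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  run_known <- c("N", "n_chains", "L", "layers", "n_timesteps",
                 "measure_every", "max_loop")
  configs <- vector("list", length(raw$runs))
  for (i in seq_along(raw$runs)) {
    r <- raw$runs[[i]]
    # YAML 1.1 reads an unquoted key `N` as the boolean FALSE; map it back
    names(r)[names(r) == "FALSE"] <- "N"
    bad <- setdiff(names(r), run_known)
    if (length(bad))
      stop(sprintf("config error in run %d: unknown key(s): %s", i,
                   paste(bad, collapse = ", ")), call. = FALSE)
    for (k in c("N", "n_chains", "L"))
      if (is.null(r[[k]]))
        stop(sprintf("config error in run %d: missing '%s'", i, k),
             call. = FALSE)
    configs[[i]] <- tryCatch(
      run_config(N = r$N, n_chains = r$n_chains, L = r$L,
                 layers = if (is.null(r$layers)) 1L else r$layers,
                 seed = derive_seed(seed, i),
                 n_timesteps = if (is.null(r$n_timesteps)) 1000L else r$n_timesteps,
                 measure_every = if (is.null(r$measure_every)) 10L else r$measure_every,
                 max_loop = if (is.null(r$max_loop)) 100L else r$max_loop),
      error = function(e)
        stop(sprintf("config error in run %d: %s", i, conditionMessage(e)),
             call. = FALSE))
  }
  structure(list(seed = seed,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 configs = configs),
            class = "experiment_plan")
}

# deterministic per-run seed below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("Experiment plan: %d run(s), global seed %d, out_dir '%s'\n",
              length(x$configs), x$seed, x$out_dir))
  for (i in seq_along(x$configs)) {
    cfg <- x$configs[[i]]
    cat(sprintf("  run %d: N = %d, chains = %d, L = %d, layers = %d, phi = %.4g\n",
                i, cfg$N, cfg$n_chains, cfg$L, cfg$layers,
                concentration(cfg$n_chains, cfg$N, cfg$spec)))
  }
  invisible(x)
}

#' Execute an experiment plan
#'
#' Runs every configuration of the plan (initial build, then a production
#' run with measurements) and writes, per run, the measurement CSV, the
#' final snapshot and a provenance file (resolved config, seed, package
#' version) into `out_dir`.
#'
#' @param plan An `experiment_plan` from [load_plan()].
#' @param out_dir Output directory (default: the plan's).
#' @return Invisibly, a list of [cma_run()] results.
#' @export
run_plan <- function(plan, out_dir = plan$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", length(plan$configs))
  for (i in seq_along(plan$configs)) {
    cfg <- plan$configs[[i]]
    state <- build_initial(cfg)
    run <- cma_run(state, cfg$n_timesteps, seed = cfg$seed,
                   measure_every = cfg$measure_every, max_len = cfg$max_loop)
    tag <- sprintf("run%03d_N%d_phi%s", i, cfg$N,
                   gsub("[.]", "p", format(state$phi, digits = 4)))
    write.csv(run$measurements, file.path(out_dir, paste0(tag, ".csv")),
              row.names = FALSE)
    write_snapshot(run$state, file.path(out_dir, paste0(tag, ".snap")))
    writeLines(c(sprintf("N %d", cfg$N), sprintf("n_chains %d", cfg$n_chains),
                 sprintf("L %d", cfg$L), sprintf("layers %d", cfg$layers),
                 sprintf("seed %d", cfg$seed),
                 sprintf("n_timesteps %g", cfg$n_timesteps),
                 sprintf("measure_every %d", cfg$measure_every),
                 sprintf("max_loop %d", cfg$max_loop),
                 sprintf("package_version %s",
                         as.character(utils::packageVersion("cma2d")))),
               file.path(out_dir, paste0(tag, ".config")))
    out[[i]] <- run
  }
  invisible(out)
}
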