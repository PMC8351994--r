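#' Seed a random initial community or population
#'
#' Draws `n` phenotypes i.i.d. uniform on the box (per axis), the standard
#' initial condition of both evolutionary frameworks; seeding with more than
#' one phenotype emulates standing variation at the start of a radiation.
#'
#' @param n number of phenotypes.
#' @param box per-axis interval (default \eqn{[-2, 2]}, roughly the viable
#'   region of both carrying capacities).
#' @param d trait dimension.
#' @param min_viable initial abundance per phenotype (community variant).
#' @param type `"community"` (adaptive dynamics: distinct phenotypes at
#'   abundance `min_viable`) or `"individuals"` (an [ibm_population()]).
#' @return a [community()] or [ibm_population()].
#' @export
seed_initial_community <- function(n, box = c(-2, 2), d = 2L,
                                   min_viable = 1e-4,
                                   type = c("community", "individuals")) {
  type <- match.arg(type)
  stopifnot(n >= 1)
  Z <- matrix(runif(n * d, box[1], box[2]), ncol = d)
  if (type == "community") community(Z, rep(min_viable, n))
  else ibm_population(Z)
}

# ---- configuration files: flat dotted keys ---------------------------------

fmt_val <- function(v) {
  if (is.character(v)) paste(v, collapse = ",")
  else if (is.logical(v)) paste(ifelse(v, "true", "false"), collapse = ",")
  else paste(sprintf("%.17g", v), collapse = ",")
}

config_keys <- function(framework) {
  model <- paste0("model.", c("carrying", "sigma_alpha", "b", "r", "d",
                              "printed_form"))
  fw <- switch(framework,
    ad = paste0("ad.", setdiff(names(formals(ad_config)), "seed")),
    ibm = paste0("ibm.", setdiff(names(formals(ibm_config)), "seed")),
    pde = paste0("pde.", c("n", "L", "diffusion", "t_end", "dt",
                           "init_center", "init_width", "init_mass",
                           "noise_floor")))
  c("framework", "seed", model, fw)
}

#' Assemble a run configuration
#'
#' @param framework `"ad"`, `"ibm"` or `"pde"`.
#' @param model a [model_params()] object.
#' @param settings framework settings: an [ad_config()], an [ibm_config()],
#'   or for `"pde"` a named list (n, L, diffusion, t_end, dt, init_center,
#'   init_width, init_mass, noise_floor).
#' @param seed run seed (overrides any seed inside `settings`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(framework = c("ad", "ibm", "pde"), model,
                       settings = NULL, seed = 1L) {
  framework <- match.arg(framework)
  if (is.null(settings))
    settings <- switch(framework, ad = ad_config(), ibm = ibm_config(),
      pde = list(n = 64L, L = 2.5, diffusion = 1e-3, t_end = 100,
                 dt = NA_real_, init_center = c(-1, 0.5), init_width = 0.2,
                 init_mass = 1, noise_floor = NA_real_))
  seed <- as.integer(seed)
  if (!is.null(settings$seed)) settings$seed <- seed
  structure(list(framework = framework, model = model, settings = settings,
                 seed = seed), class = "run_config")
}

#' Write a run configuration as flat key = value text
#'
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  m <- config$model
  lines <- c(paste("framework =", config$framework),
             paste("seed =", config$seed),
             paste("model.carrying =", m$carrying),
             paste("model.sigma_alpha =", fmt_val(m$sigma_alpha)),
             paste("model.b =", fmt_val(as.vector(t(m$b)))),
             paste("model.r =", fmt_val(m$r)),
             paste("model.d =", m$d),
             paste("model.printed_form =", fmt_val(m$printed_form)))
  pre <- paste0(config$framework, ".")
  for (k in names(config$settings)) {
    if (k == "seed") next
    v <- config$settings[[k]]
    lines <- c(lines, paste0(pre, k, " = ",
                             if (length(v) == 0 || all(is.na(v))) "NA"
                             else fmt_val(v)))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_val <- function(s, proto) {
  if (identical(s, "NA")) {
    return(if (is.character(proto)) NA_character_
           else if (is.logical(proto)) NA
           else if (is.integer(proto)) NA_integer_ else NA_real_)
  }
  parts <- trimws(strsplit(s, ",")[[1]])
  if (is.character(proto)) parts
  else if (is.logical(proto)) parts %in% c("true", "TRUE", "1")
  else if (is.integer(proto)) as.integer(parts)
  else as.numeric(parts)
}

#' Load a run configuration
#'
#' Strict parser for the flat dotted-key format written by [write_config()]:
#' unknown keys and missing required fields are reported by name; writing a
#' configuration and loading it back yields an equal object.
#'
#' @param path configuration file.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  bad <- !grepl("=", raw)
  if (any(bad)) stop("malformed config line(s): ",
                     paste(raw[bad], collapse = "; "))
  key <- trimws(sub("=.*", "", raw))
  val <- trimws(sub("^[^=]*=", "", raw))
  if (anyDuplicated(key)) stop("duplicate keys: ",
                               paste(unique(key[duplicated(key)]),
                                     collapse = ", "))
  kv <- setNames(as.list(val), key)
  if (is.null(kv$framework)) stop("missing required field: framework")
  framework <- kv$framework
  allowed <- config_keys(framework)
  unknown <- setdiff(key, allowed)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  getv <- function(k, proto, default) {
    if (is.null(kv[[k]])) default else parse_val(kv[[k]], proto)
  }
  d <- getv("model.d", 1L, 2L)
  b <- getv("model.b", 1.0, rep(0, d * d))
  model <- model_params(carrying = getv("model.carrying", "c", "quartic"),
                        sigma_alpha = getv("model.sigma_alpha", 1.0, 0.5),
                        b = matrix(b, d, d, byrow = TRUE),
                        r = getv("model.r", 1.0, 1), d = d,
                        printed_form = getv("model.printed_form", TRUE, FALSE))
  seed <- getv("seed", 1L, 1L)
  pre <- paste0(framework, ".")
  fkeys <- grep(paste0("^", pre), allowed, value = TRUE)
  proto <- switch(framework, ad = ad_config(), ibm = ibm_config(),
                  pde = run_config("pde", model)$settings)
  settings <- proto
  for (k in fkeys) {
    short <- sub(pre, "", k)
    if (!is.null(kv[[k]])) {
      pr <- proto[[short]]
      if (is.null(pr) || all(is.na(pr))) pr <- 1.0
      settings[[short]] <- parse_val(kv[[k]], pr)
    }
  }
  if (framework == "ad") {
    settings$seed <- seed
    settings <- do.call(ad_config, settings[names(formals(ad_config))])
  } else if (framework == "ibm") {
    settings$seed <- seed
    settings <- do.call(ibm_config, settings[names(formals(ibm_config))])
  }
  run_config(framework, model, settings, seed = seed)
}

#' Execute a run configuration
#'
#' @param config a [run_config()].
#' @return the framework trajectory object.
#' @export
run_simulation <- function(config) {
  switch(config$framework,
    ad = run_ad(config$model, config$settings),
    ibm = run_ibm(config$model, config$settings),
    pde = {
      s <- config$settings
      set.seed(config$seed)
      f0 <- density_field(n = s$n, L = s$L, diffusion = s$diffusion)
      f0 <- field_gaussian_blob(f0, center = s$init_center,
                                width = s$init_width, mass = s$init_mass)
      if (!is.null(s$noise_floor) && !all(is.na(s$noise_floor)))
        f0$noise_floor <- s$noise_floor
      run_pde(config$model, f0, t_end = s$t_end,
              dt = if (is.null(s$dt) || all(is.na(s$dt))) NULL else s$dt)
    })
}

#' Write run outputs as delimited text with a metadata sidecar
#'
#' Adaptive-dynamics runs produce `trajectory.tsv` (time, label, trait
#' coordinates, abundance for every snapshot row) and `events.tsv`;
#' individual-based runs produce `records.tsv` and `snapshots.tsv`; density
#' runs produce `field.tsv` and `peaks.tsv`.  Every directory gets
#' `metadata.txt` (the full configuration plus seed and package version),
#' sufficient to re-run bit-identically.
#'
#' @param trajectory an `ad_trajectory`, `ibm_trajectory` or
#'   `pde_trajectory`.
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] written into the metadata.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(trajectory, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  if (inherits(trajectory, "ad_trajectory")) {
    rows <- do.call(rbind, lapply(trajectory$snapshots, function(s) {
      co <- s$community
      if (n_species(co) == 0L) return(NULL)
      data.frame(time = s$time, label = co$labels, co$phenotypes,
                 N = co$abundances)
    }))
    names(rows)[3:(2 + trajectory$model$d)] <-
      paste0("z", seq_len(trajectory$model$d))
    tsv(rows, "trajectory.tsv")
    tsv(trajectory$events, "events.tsv")
    cfg <- config
    if (is.null(cfg)) cfg <- run_config("ad", trajectory$model,
                                        trajectory$config,
                                        seed = trajectory$config$seed)
  } else if (inherits(trajectory, "ibm_trajectory")) {
    tsv(trajectory$records, "records.tsv")
    rows <- do.call(rbind, lapply(seq_along(trajectory$snapshots),
      function(i) {
        Z <- trajectory$snapshots[[i]]
        cl <- cluster_species(Z, trajectory$config$cluster_delta)
        data.frame(time = trajectory$snapshot_times[i],
                   id = seq_len(nrow(Z)), Z, cluster = cl$labels)
      }))
    if (!is.null(rows))
      names(rows)[3:(2 + trajectory$model$d)] <-
        paste0("z", seq_len(trajectory$model$d))
    tsv(rows, "snapshots.tsv")
    cfg <- config
    if (is.null(cfg)) cfg <- run_config("ibm", trajectory$model,
                                        trajectory$config,
                                        seed = trajectory$config$seed)
  } else if (inherits(trajectory, "pde_trajectory")) {
    write.table(trajectory$final$values, file.path(dir, "field.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    pk <- trajectory$peaks
    tsv(data.frame(z1 = pk$positions[, 1], z2 = pk$positions[, 2]),
        "peaks.tsv")
    cfg <- config
  } else stop("unsupported trajectory object")
  if (!is.null(cfg)) write_config(cfg, file.path(dir, "metadata.txt"))
  writeLines(paste("nichepack_version =",
                   as.character(utils::packageVersion("nichepack"))),
             file.path(dir, "version.txt"))
  invisible(dir)
}

#' Final diversity summary of a trajectory
#'
#' Clustered species count of the final state (median of the record tail for
#' individual-based runs) plus a limit-cycle flag from the trailing
#' snapshots.
#'
#' @param trajectory a framework trajectory.
#' @param delta clustering distance (defaults to the run's own).
#' @return list with `count` and `cyclic`.
#' @export
final_diversity <- function(trajectory, delta = NULL) {
  if (inherits(trajectory, "ad_trajectory")) {
    if (is.null(delta)) delta <- trajectory$config$cluster_delta
    count <- cluster_species(trajectory$final$phenotypes, delta)$count
    tail_sn <- trajectory$snapshots
    n <- length(tail_sn)
    cyc <- if (n >= 20L) {
      w <- list(times = vapply(tail_sn, `[[`, 0, "time"),
                points = lapply(tail_sn, function(s) s$community$phenotypes))
      suppressWarnings(detect_limit_cycle(w, delta = delta)$is_cyclic)
    } else FALSE
    list(count = count, cyclic = cyc)
  } else if (inherits(trajectory, "ibm_trajectory")) {
    list(count = as.numeric(trajectory$final_clusters), cyclic = NA)
  } else if (inherits(trajectory, "pde_trajectory")) {
    list(count = trajectory$peaks$count, cyclic = NA)
  } else stop("unsupported trajectory object")
}

#' Sweep one or more configuration axes
#'
#' Runs every combination of the axis values and seeds from a base
#' configuration and tabulates the final diversity of each run, the layout
#' used to study how initial standing variation, mutation scale or
#' environmental richness select among alternative metastable diversity
#' levels.
#'
#' @param base a [run_config()].
#' @param axis named list: one or more settings fields, each with the vector
#'   of values to sweep (e.g. `list(initial_n = c(1, 10, 100))`).
#' @param seeds integer vector of seeds per axis point.
#' @param progress print one line per run.
#' @return data frame with the axis columns, `seed`, `final_count`, `cyclic`
#'   and `status`; individual run failures are recorded and the sweep
#'   continues.
#' @export
sweep_runs <- function(base, axis, seeds = 1:3, progress = FALSE) {
  stopifnot(length(axis) >= 1, !is.null(names(axis)))
  grid <- expand.grid(c(axis, list(seed = seeds)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    for (k in names(axis)) cfg$settings[[k]] <- grid[[k]][i]
    cfg$seed <- as.integer(grid$seed[i])
    if (!is.null(cfg$settings$seed)) cfg$settings$seed <- cfg$seed
    res <- tryCatch({
      tr <- run_simulation(cfg)
      fd <- final_diversity(tr)
      data.frame(grid[i, , drop = FALSE], final_count = fd$count,
                 cyclic = fd$cyclic, status = "ok")
    }, error = function(e)
      data.frame(grid[i, , drop = FALSE], final_count = NA_real_,
                 cyclic = NA, status = conditionMessage(e)))
    out[[i]] <- res
    if (progress)
      message(sprintf("run %d/%d: %s", i, nrow(grid),
                      paste(res$final_count, collapse = " ")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference asymmetric-competition coefficients
#'
#' A package-chosen 2 x 2 asymmetry matrix with a rotational (antisymmetric)
#' component strong enough to sustain Red Queen limit cycles at low diversity
#' while higher-diversity states remain reachable from diverse seeding.
#' The published experiments used supplementary coefficients that are not
#' reproduced here; this matrix is the package's own working standard.
#'
#' @return a 2 x 2 numeric matrix.
#' @export
asymmetric_b <- function() matrix(c(0, 0.8, -0.8, 0), 2, 2, byrow = TRUE)

#' Shipped scenario configurations
#'
#' Ready-made [run_config()]s for the package's standard experiments:
#' `quartic-symmetric` and `radial-symmetric` radiations from a single
#' ancestor, the `redqueen` asymmetric radial scenario started from 10
#' species, and bases for the `seeding-sweep`, `mutation-sweep` and
#' `kmax-sweep` experiments.
#'
#' @param seed seed stamped into every configuration.
#' @return named list of `run_config` objects.
#' @export
scenario_configs <- function(seed = 1L) {
  quartic <- model_params("quartic", sigma_alpha = 0.5)
  radial <- model_params("radial", sigma_alpha = 0.5)
  asym_q <- model_params("quartic", sigma_alpha = 0.5, b = asymmetric_b())
  asym_r <- model_params("radial", sigma_alpha = 0.5, b = asymmetric_b())
  list(
    "quartic-symmetric" = run_config("ad", quartic,
      ad_config(n_attempts = 20000L, seed = seed), seed = seed),
    "radial-symmetric" = run_config("ad", radial,
      ad_config(n_attempts = 100000L, seed = seed), seed = seed),
    "redqueen" = run_config("ad", asym_r,
      ad_config(n_attempts = 20000L, initial_n = 10L, seed = seed),
      seed = seed),
    "seeding-sweep" = run_config("ad", asym_q,
      ad_config(n_attempts = 20000L, seed = seed), seed = seed),
    "mutation-sweep" = run_config("ad", asym_q,
      ad_config(n_attempts = 20000L, sigma_mut = 0.05, seed = seed),
      seed = seed),
    "kmax-sweep" = run_config("ibm", asym_q,
      ibm_config(k_max = 200, max_events = 2e6, seed = seed), seed = seed))
}

# ---- command-line interface ------------------------------------------------

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    out[[key]] <- if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      i <- i + 1L; args[i]
    } else TRUE
    i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (`--framework ad|ibm|pde --config FILE --seed N
#' --out DIR`), `analyze` (`--dir RUNDIR [--delta D]`: clustering, landscape
#' maximum, cycle detection on a written run), `sweep` (`--config FILE --axis
#' FIELD --values V1,V2,... --seeds S1,S2,... --out FILE`), and `fixtures`
#' (`--out DIR`: write the shipped scenario configurations).
#'
#' @param args character vector, default the trailing command line.
#' @return exit status 0, invisibly.
#' @export
nichepack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: simulate|analyze|sweep|fixtures [--options]")
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  if (cmd == "simulate") {
    cfg <- load_config(opt$config)
    if (!is.null(opt$framework) && !identical(opt$framework, cfg$framework))
      stop("--framework disagrees with the config file")
    if (!is.null(opt$seed)) {
      cfg$seed <- as.integer(opt$seed)
      if (!is.null(cfg$settings$seed)) cfg$settings$seed <- cfg$seed
    }
    tr <- run_simulation(cfg)
    write_outputs(tr, opt$out, config = cfg)
    fd <- final_diversity(tr)
    cat("final_count =", fd$count, "\n")
  } else if (cmd == "analyze") {
    cfg <- load_config(file.path(opt$dir, "metadata.txt"))
    tr <- run_simulation(cfg)
    delta <- if (is.null(opt$delta)) NULL else as.numeric(opt$delta)
    fd <- final_diversity(tr, delta = delta)
    cat("final_count =", fd$count, "\n")
    cat("cyclic =", fd$cyclic, "\n")
    if (inherits(tr, "ad_trajectory")) {
      ls <- fitness_landscape(tr$final, tr$model)
      cat("landscape_max =", ls$max, "\n")
    }
  } else if (cmd == "sweep") {
    cfg <- load_config(opt$config)
    axis <- setNames(list(as.numeric(strsplit(opt$values, ",")[[1]])),
                     opt$axis)
    seeds <- as.integer(strsplit(opt$seeds, ",")[[1]])
    res <- sweep_runs(cfg, axis, seeds = seeds)
    write.table(res, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
    cat("wrote", opt$out, "\n")
  } else if (cmd == "fixtures") {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    sc <- scenario_configs()
    for (nm in names(sc))
      write_config(sc[[nm]], file.path(opt$out, paste0(nm, ".cfg")))
    cat("wrote", length(sc), "scenario configs to", opt$out, "\n")
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
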