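# Experiment orchestration and command-line entry point. Every run writes
# machine-readable outputs (CSV tables, summary JSON) plus a reproducibility
# manifest (full config echo, seed, package version) into the output
# directory; all randomness flows from the single root seed via per-
# realization stream splitting.

#' Experiment configuration
#'
#' Bundles and validates the parameters of one of the headline experiments:
#' `"explorability"` (V_E distributions over connectivities),
#' `"robustness"` (perturbed-abscissa distributions and R),
#' `"optimize"` (hill climbing), `"fit"` (inverse-scaling fit of a CSV),
#' `"synth-table"` (synthetic scaling table), `"may-demo"` (instability
#' fractions).
#'
#' @param experiment One of `"explorability"`, `"robustness"`, `"optimize"`,
#'   `"fit"`, `"synth-table"`, `"may-demo"`.
#' @param params Named list of experiment parameters; defaults are filled in
#'   per experiment.
#' @param seed Root seed.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, params = list(), seed = 1L,
                              out_dir = NULL) {
  experiment <- match.arg(experiment,
                          c("explorability", "robustness", "optimize",
                            "fit", "synth-table", "may-demo"))
  defaults <- switch(experiment,
    explorability = list(S = 20, loop_length = 3, C = c(0.1, 0.25, 0.5, 0.75),
                         sigma_eps = 0.1, n_samples = 1000,
                         heterogeneous = FALSE, sigma_x = 0.1,
                         sigma_alpha = 0.1),
    robustness = list(S = 20, loop_length = 3, C = c(0.1, 0.25, 0.5, 0.75),
                      sigma_eps = 0.1, n_eps = 1000, n_xi = 1000,
                      percentile = 5),
    optimize = list(S = 10, loop_length = 3, C = 0.5, sigma_eps = 0.1,
                    objective = "explorability", steps = 200,
                    delta_eps = 0.01, n_xi = 200),
    `fit` = list(input = NULL, method = "origin-ols"),
    `synth-table` = list(c1 = 3.8, n = 83, S_range = c(10, 1000),
                         noise_cv = 0.3),
    `may-demo` = list(S = c(50, 100, 200), c1 = 3.8, sigma = 1, d = 1,
                      n_matrices = 100)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown parameter(s) for experiment '%s': %s",
                 experiment, paste(unknown, collapse = ", ")), call. = FALSE)
  params <- utils::modifyList(defaults, params)
  if (experiment == "optimize" && params$delta_eps != 0 &&
      (params$delta_eps < 1e-3 || params$delta_eps > 1e-1))
    stop("delta_eps outside the supported range [1e-3, 1e-1]", call. = FALSE)
  if (!is.null(params$sigma_eps) && params$sigma_eps < 0)
    stop("sigma_eps must be >= 0", call. = FALSE)
  structure(list(experiment = experiment, params = params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

write_outputs <- function(cfg, tables, summary) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(cfg$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  manifest <- list(experiment = cfg$experiment, params = cfg$params,
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("explora")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run a configured experiment
#'
#' Dispatches to the owning module, collects result tables and a summary,
#' and (when `out_dir` is set) writes CSV tables, `summary.json` and a
#' reproducibility manifest.
#'
#' @param cfg An [experiment_config()].
#' @return The summary list, invisibly; tables are attached as
#'   `attr(, "tables")`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  p <- cfg$params
  seeds <- derive_seeds(cfg$seed, 64L)
  out <- switch(cfg$experiment,
    explorability = {
      topo <- make_tree_like(p$S, p$loop_length, seed = seeds[1])
      tabs <- list()
      summ <- list()
      for (i in seq_along(p$C)) {
        sm <- sample_explorability_distribution(topo, p$C[i], p$sigma_eps,
                                                p$n_samples, seed = seeds[1 + i])
        tabs[[sprintf("explorability_C%03d", round(1000 * p$C[i]))]] <- sm$samples
        summ[[sprintf("C_%g", p$C[i])]] <-
          list(mean_V_E = sm$mean_V_E,
               fraction_single_crossing = sm$fraction_single_crossing,
               skip_rate = 1 - sm$fraction_single_crossing)
      }
      list(tables = tabs, summary = summ)
    },
    robustness = {
      topo <- make_tree_like(p$S, p$loop_length, seed = seeds[1])
      tabs <- list()
      summ <- list()
      for (i in seq_along(p$C)) {
        rs <- sample_robustness_distribution(topo, p$C[i], p$sigma_eps,
                                             p$n_eps, p$n_xi,
                                             seed = seeds[1 + i],
                                             percentile = p$percentile)
        tabs[[sprintf("robustness_C%03d", round(1000 * p$C[i]))]] <- rs$abscissas
        summ[[sprintf("C_%g", p$C[i])]] <-
          list(R = rs$R, percentile = rs$percentile, skip_rate = rs$skip_rate)
      }
      list(tables = tabs, summary = summ)
    },
    optimize = {
      topo <- make_tree_like(p$S, p$loop_length, seed = seeds[1])
      ex0 <- add_random_links(topo, p$C, p$sigma_eps, seed = seeds[2])
      ocfg <- optimization_config(p$objective, p$steps, p$delta_eps,
                                  seed = seeds[3], n_xi = p$n_xi)
      tr <- if (p$objective %in% c("both", "alternating"))
        multi_objective_climb(topo, ex0, ocfg) else hill_climb(topo, ex0, ocfg)
      if (!is.null(cfg$out_dir)) {
        # final optimized network at its edge-of-stability point, if defined
        em <- tryCatch(edge_matrix(topo, tr$final_extra),
                       error = function(e) NULL)
        if (!is.null(em)) {
          dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
          write_edge_list(unclass(em$weights),
                          file.path(cfg$out_dir, "final_network.tsv"))
        }
      }
      list(tables = list(trace = tr$trace),
           summary = list(final_V_E = tr$final[["V_E"]],
                          final_R = tr$final[["R"]],
                          acceptance_rate = tr$acceptance_rate))
    },
    `fit` = {
      if (is.null(p$input)) stop("fit experiment needs params$input (CSV path)",
                                 call. = FALSE)
      d <- utils::read.csv(p$input)
      ft <- fit_inverse_scaling(d, p$method)
      list(tables = list(),
           summary = list(c1 = ft$c1, c1_stderr = ft$c1_stderr,
                          n_records = ft$n_records, method = ft$method))
    },
    `synth-table` = {
      tab <- generate_scaling_table(p$c1, p$n, p$S_range, p$noise_cv,
                                    seed = seeds[1])
      list(tables = list(scaling_table = tab),
           summary = list(c1_true = p$c1, n = p$n,
                          n_clipped = attr(tab, "n_clipped")))
    },
    `may-demo` = {
      frac <- vapply(seq_along(p$S), function(i)
        may_instability_probability(p$S[i], p$c1 / p$S[i], p$sigma, p$d,
                                    p$n_matrices, seed = seeds[i]),
        numeric(1))
      tab <- data.frame(S = p$S, C = p$c1 / p$S, fraction_unstable = frac)
      list(tables = list(may_demo = tab),
           summary = list(fractions = as.list(stats::setNames(frac, paste0("S", p$S))),
                          max_minus_min = max(frac) - min(frac)))
    }
  )
  write_outputs(cfg, out$tables, out$summary)
  res <- out$summary
  attr(res, "tables") <- out$tables
  invisible(res)
}

# minimal --flag value parser for the CLI; flags map to config fields
parse_cli_flags <- function(args) {
  vals <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop(sprintf("flag '%s' needs a value", a), call. = FALSE)
    val <- args[i + 1L]
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    vals[[key]] <- if (anyNA(num)) val else num
    i <- i + 2L
  }
  vals
}

#' Command-line entry point
#'
#' Subcommands: `explorability`, `robustness`, `optimize`, `fit`,
#' `synth-table`, `may-demo`. Global flags: `--seed`, `--out-dir`,
#' `--config` (JSON file of parameters; explicit flags override it). All
#' other flags are experiment parameters, e.g.
#' `explorability --size 20 --connectivity 0.5 --sigma-eps 0.1 --n-samples 1000`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
explora_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: explora <explorability|robustness|optimize|fit|synth-table|may-demo> [--flags]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  flags <- parse_cli_flags(args[-1])
  seed <- if (!is.null(flags$seed)) flags$seed else 1L
  out_dir <- flags$out_dir
  flags$seed <- NULL
  flags$out_dir <- NULL
  if (!is.null(flags$config)) {
    file_params <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    flags$config <- NULL
    flags <- utils::modifyList(file_params, flags)
  }
  # CLI-friendly aliases
  alias <- c(size = "S", connectivity = "C", n_samples = "n_samples",
             loop_length = "loop_length")
  for (nm in names(alias))
    if (!is.null(flags[[nm]]) && nm != alias[[nm]]) {
      flags[[alias[[nm]]]] <- flags[[nm]]
      flags[[nm]] <- NULL
    }
  cfg <- experiment_config(sub, flags, seed = seed, out_dir = out_dir)
  summ <- run_experiment(cfg)
  cat(jsonlite::toJSON(summ, auto_unbox = TRUE, pretty = TRUE, digits = NA), "\n")
  invisible(0L)
}
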