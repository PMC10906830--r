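#' Load an experiment configuration
#'
#' Reads a JSON or YAML configuration file, fills preset defaults, validates
#' every key, and returns an experiment specification ready for
#' \code{\link{run_experiment}}. Unknown keys are rejected with the offending
#' key named.
#'
#' Presets: \code{"coop-curve"} (cooperation vs p over the nine monitoring
#' combinations), \code{"bifurcation"} (singular-point sweeps over eta),
#' \code{"pip"} (pairwise invasibility matrices), \code{"simplex"}
#' (replicator flow fields and equilibria), \code{"abm"} (finite-population
#' runs).
#'
#' @param path path to a JSON (.json) or YAML (.yml/.yaml) file; may be an
#'   empty file, in which case the preset defaults are used unchanged.
#' @param preset experiment preset; may also be given by a \code{preset} key
#'   in the file.
#' @return object of class \code{experiment_spec}: the fully resolved
#'   configuration list.
#' @export
load_config <- function(path = NULL, preset = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(raw)) raw <- list()
  }
  if (!is.null(raw$preset)) {
    preset <- raw$preset
    raw$preset <- NULL
  }
  if (is.null(preset)) stop("no preset given (in call or config file)",
                            call. = FALSE)
  experiment_spec(preset, overrides = raw)
}

#' @rdname load_config
#' @param overrides named list of parameter overrides applied on top of the
#'   preset defaults.
#' @export
experiment_spec <- function(preset, overrides = list()) {
  presets <- c("coop-curve", "bifurcation", "pip", "simplex", "abm")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    norm = "SternJudging",
    individual_scale = "all", stereotype_scale = "all",
    K = 2L, nu = NULL,
    b = 3, c = 1, eta = 0.3, u_e = 0.02, u_a = 0.02,
    p_grid = seq(0, 1, length.out = 101),
    eta_grid = seq(0, 1, length.out = 101),
    resolution = 101L,
    pip_resolution = 21L,
    density = 10L,
    strategies = "ALLD,0DISC,1DISC",
    background = NULL,
    N = 50L, p0 = 0.5, rounds_per_generation = 2500L,
    generations = 100L, w = 1, replicates = 1L,
    seed = 1L, out_dir = "."
  )
  spec <- defaults
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) {
      stop("unknown config key '", key, "'", call. = FALSE)
    }
    spec[[key]] <- overrides[[key]]
  }
  # validation via the constructors (they name the offending field)
  check_rate(spec$u_a, "u_a"); check_rate(spec$u_e, "u_e")
  if (spec$b <= spec$c || spec$c <= 0) {
    stop("config key 'b'/'c': need b > c > 0", call. = FALSE)
  }
  if (spec$eta < 0) stop("config key 'eta': must be >= 0", call. = FALSE)
  spec$norm <- social_norm(spec$norm)$name
  for (s in c("individual_scale", "stereotype_scale")) {
    if (!identical(spec[[s]], "all")) spec[[s]] <- match_scale(spec[[s]])
  }
  spec$preset <- preset
  structure(spec, class = "experiment_spec")
}

scales_for <- function(x) if (identical(x, "all")) {
  c("private", "group-wise", "public")
} else x

#' Run an experiment preset
#'
#' Executes the preset described by an \code{experiment_spec} and writes
#' plotting-ready CSV files (one per monitoring combination where relevant)
#' plus a JSON manifest recording the fully resolved configuration, package
#' version, and runtime. Deterministic given the spec's seed.
#'
#' @param spec an \code{experiment_spec} from \code{\link{load_config}}.
#' @return invisibly, the vector of files written.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  set.seed(spec$seed)
  files <- character(0)
  structure_ <- if (is.null(spec$nu)) population_structure(spec$K) else
    population_structure(spec$K, spec$nu)
  mp <- function(is, ss, eta = spec$eta) {
    model_params(spec$norm, is, ss, structure_,
                 b = spec$b, c = spec$c, eta = eta,
                 u_e = spec$u_e, u_a = spec$u_a)
  }
  combo_files <- function(tag, fn) {
    for (is in scales_for(spec$individual_scale)) {
      for (ss in scales_for(spec$stereotype_scale)) {
        f <- file.path(spec$out_dir,
                       sprintf("%s_%s_%s.csv", tag, gsub("-", "", is),
                               gsub("-", "", ss)))
        utils::write.csv(fn(is, ss), f, row.names = FALSE)
        files <<- c(files, f)
      }
    }
  }
  if (spec$preset == "coop-curve") {
    combo_files("coop_curve", function(is, ss) {
      cooperation_curve(mp(is, ss), spec$p_grid)
    })
  } else if (spec$preset == "bifurcation") {
    combo_files("bifurcation", function(is, ss) {
      bifurcation_sweep(mp(is, ss), "eta", spec$eta_grid,
                        background = spec$background,
                        resolution = spec$resolution)
    })
  } else if (spec$preset == "pip") {
    combo_files("pip", function(is, ss) {
      pg <- pip_grid(mp(is, ss), spec$pip_resolution,
                     background = spec$background)
      data.frame(p_R = rep(pg$p, times = length(pg$p)),
                 p_Q = rep(pg$p, each = length(pg$p)),
                 invades = as.vector(pg$invades))
    })
  } else if (spec$preset == "simplex") {
    mix <- parse_strategies(spec$strategies)
    pars <- mp(scales_for(spec$individual_scale)[1],
               scales_for(spec$stereotype_scale)[1])
    flow <- simplex_flow_field(mix, pars, spec$density)
    eqs <- classify_equilibria(mix, pars)
    f1 <- file.path(spec$out_dir, "simplex_flow.csv")
    f2 <- file.path(spec$out_dir, "simplex_equilibria.csv")
    utils::write.csv(flow, f1, row.names = FALSE)
    utils::write.csv(eqs, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  } else if (spec$preset == "abm") {
    cfg <- abm_config(N = spec$N, K = spec$K, norm = spec$norm,
                      individual_scale = scales_for(spec$individual_scale)[1],
                      stereotype_scale = scales_for(spec$stereotype_scale)[1],
                      b = spec$b, c = spec$c, eta = spec$eta,
                      u_e = spec$u_e, u_a = spec$u_a, p0 = spec$p0,
                      rounds_per_generation = spec$rounds_per_generation,
                      generations = spec$generations, w = spec$w,
                      seed = spec$seed)
    rec <- run_abm_replicates(cfg, spec$replicates)
    f <- file.path(spec$out_dir, "abm_timeseries.csv")
    utils::write.csv(rec, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    preset = spec$preset,
    config = unclass(spec),
    package_version = as.character(utils::packageVersion("stereorecip")),
    runtime_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = basename(files)
  )
  mf <- file.path(spec$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, mf))
}

#' Parse a strategy-set string like "ALLC,ALLD,DISC:0.67"
#'
#' DISC entries may carry a propensity after a colon; bare \code{0DISC} /
#' \code{1DISC} / \code{pDISC:<p>} spellings are also accepted.
#'
#' @param s comma-separated strategy descriptor.
#' @return a \code{strategy_mix} with equal frequencies.
#' @export
parse_strategies <- function(s) {
  parts <- trimws(strsplit(s, ",")[[1]])
  kinds <- character(0); p <- numeric(0)
  for (part in parts) {
    if (grepl(":", part)) {
      bits <- strsplit(part, ":")[[1]]
      kinds <- c(kinds, gsub("^p", "", bits[1], ignore.case = TRUE))
      p <- c(p, as.numeric(bits[2]))
    } else if (grepl("^[01](\\.[0-9]+)?DISC$", part, ignore.case = TRUE)) {
      kinds <- c(kinds, "DISC")
      p <- c(p, as.numeric(sub("DISC$", "", part, ignore.case = TRUE)))
    } else {
      kinds <- c(kinds, part)
      p <- c(p, 0)
    }
  }
  strategy_mix(kinds, p = p)
}
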