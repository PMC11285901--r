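# Configuration loading, presets, CSV/JSON output and the command-line
# entry point. The pipeline is fully deterministic: no random number
# generation anywhere, so identical configs give byte-identical outputs.

.config_keys <- c("command", "param_preset", "params", "init_preset", "init",
                  "d", "I0", "m0", "t_end", "n_out", "axis",
                  "d_grid", "x_grid", "out", "log_level")

#' Load and validate a run configuration
#'
#' A configuration is a flat JSON mapping (or an equivalent named list) with
#' symbol-named keys auditable one-to-one against the published tables:
#' `param_preset` (`"table2"`) and `params` (named overrides such as `r1`,
#' `gamma0`, `tauS`, and the mandatory degradation rate `d`), `init_preset`
#' (`"table3"`/`"table4"`) and `init` (overrides `u`, `up`, `m`, `M`, `I`),
#' plus command-specific keys `command`, `t_end`, `n_out`, `axis`,
#' `d_grid`/`x_grid` (either an explicit array or `[from, to, n]`), `out`
#' and `log_level`. Unknown keys are rejected; explicit values win over
#' preset values. Shorthand keys `d`, `I0` and `m0` set the degradation rate
#' and the variable initial fields of the two presets.
#'
#' @param path Path to a JSON config file, or `NULL`.
#' @param overrides Named list merged over the file contents (explicit
#'   wins), e.g. from command-line flags.
#' @return An object of class `ad_config`: list with resolved `params`
#'   ([ad_params()]), `init` ([ad_state()] or `NULL` if underdetermined for
#'   the command), and the remaining keys.
#' @examples
#' cfg <- load_config(overrides = list(param_preset = "table2", d = 0.15,
#'                                     init_preset = "table3", I0 = 0.4))
#' cfg$params[["d"]]
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (length(overrides)) raw <- modifyList(raw, overrides)
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))

  par_over <- as.list(raw[["params"]] %||% list())
  if (!is.null(raw[["d"]])) par_over$d <- raw[["d"]]
  params <- do.call(ad_params, c(list(preset = raw[["param_preset"]] %||% NULL),
                                 par_over))

  init <- NULL
  init_over <- as.list(raw[["init"]] %||% list())
  if (!is.null(raw[["I0"]])) init_over$I <- raw[["I0"]]
  if (!is.null(raw[["m0"]])) init_over$m <- raw[["m0"]]
  if (!is.null(raw[["init_preset"]]) || length(init_over)) {
    init <- tryCatch(
      do.call(ad_state,
              c(list(preset = raw[["init_preset"]] %||% NULL), init_over)),
      error = function(e) stop("initial state: ", conditionMessage(e),
                               call. = FALSE))
  }

  grids <- lapply(raw[intersect(c("d_grid", "x_grid"), names(raw))], .as_grid)
  structure(c(list(params = params, init = init),
              grids,
              raw[setdiff(names(raw),
                          c("params", "d", "init", "init_preset", "I0", "m0",
                            "param_preset", "d_grid", "x_grid"))],
              list(param_preset = raw$param_preset %||% NULL,
                   init_preset = raw$init_preset %||% NULL)),
            class = "ad_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A grid is either an explicit numeric vector (length != 3 or unsorted
# triple) or a [from, to, n] triple with integer n > 3 boundary ambiguity
# resolved in favour of the explicit vector only when n is not a whole
# number or n < 2.
.as_grid <- function(g) {
  g <- as.numeric(g)
  if (length(g) == 3 && g[3] >= 2 && g[3] == round(g[3]) && g[2] > g[1])
    seq(g[1], g[2], length.out = g[3])
  else g
}

#' Write a result to CSV with a JSON sidecar
#'
#' Writes any tabular result (a trajectory, an equilibria list, a
#' bifurcation branch, a threshold curve or a basin grid) as a
#' comma-separated, header-bearing UTF-8 file with floats at 12 significant
#' digits, plus a `<path>.json` sidecar recording the resolved configuration
#' and the package version. Deterministic: the same result writes
#' byte-identical files.
#'
#' @param result An `ad_trajectory`, `ad_equilibria`, `ad_bifurcation`,
#'   `ad_threshold` or `ad_basin` object (or plain data frame).
#' @param path Output CSV path.
#' @param config Optional `ad_config` (or named list) recorded in the
#'   sidecar.
#' @return Invisibly, the paths written (csv, sidecar).
#' @export
write_outputs <- function(result, path, config = NULL) {
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    # signif-style formatting at 12 digits, locale-independent
    ifelse(is.na(x), "none", sprintf("%.12g", x))
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)

  sidecar <- paste0(path, ".json")
  meta <- list(package = "abetadyn",
               version = as.character(utils::packageVersion("abetadyn")),
               config = .config_as_list(config))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(csv = path, sidecar = sidecar))
}

.config_as_list <- function(config) {
  if (is.null(config)) return(NULL)
  out <- lapply(unclass(config), function(v) {
    if (inherits(v, "ad_params") || inherits(v, "ad_state"))
      as.list(unclass(v))
    else v
  })
  out[!vapply(out, is.null, logical(1))]
}

.log <- function(level, threshold, ...) {
  lv <- c(DEBUG = 1, INFO = 2, WARN = 3, QUIET = 4)
  if (lv[[level]] >= lv[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `equilibria`, `bifurcate` and
#' `basin` with shared flags `--config FILE`, `--preset NAME`,
#' `--init-preset NAME`, `--param key=value` (repeatable), `--init
#' key=value` (repeatable), `--d X`, `--I0 X`, `--m0 X`, `--t-end X`,
#' `--axis I0|m0`, `--d-grid from,to,n`, `--x-grid from,to,n`, `--out FILE`
#' and `--log-level LEVEL`. Installed as the `admodel` script under
#' `system.file("cli", package = "abetadyn")`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the result object of the subcommand.
#' @export
admodel_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: admodel <simulate|equilibria|bifurcate|basin> [flags]",
    "flags: --config FILE --preset NAME --init-preset NAME",
    "       --param key=value ... --init key=value ...",
    "       --d X --I0 X --m0 X --t-end X --axis I0|m0",
    "       --d-grid from,to,n --x-grid from,to,n --out FILE",
    "       --log-level DEBUG|INFO|WARN|QUIET", sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- match.arg(args[1], c("simulate", "equilibria", "bifurcate", "basin"))
  flags <- .parse_flags(args[-1])

  over <- list(command = cmd)
  if (!is.null(flags$preset)) over$param_preset <- flags$preset
  if (!is.null(flags$`init-preset`)) over$init_preset <- flags$`init-preset`
  if (length(flags$param)) over$params <- flags$param
  if (length(flags$init)) over$init <- flags$init
  for (k in c("d", "I0", "m0")) if (!is.null(flags[[k]]))
    over[[k]] <- as.numeric(flags[[k]])
  if (!is.null(flags$`t-end`)) over$t_end <- as.numeric(flags$`t-end`)
  if (!is.null(flags$axis)) over$axis <- flags$axis
  for (k in c("d-grid", "x-grid")) if (!is.null(flags[[k]]))
    over[[sub("-", "_", k)]] <- as.numeric(strsplit(flags[[k]], ",")[[1]])
  if (!is.null(flags$out)) over$out <- flags$out
  if (!is.null(flags$`log-level`)) over$log_level <- flags$`log-level`

  cfg <- load_config(flags$config, over)
  lvl <- cfg$log_level %||% "INFO"
  p <- cfg$params

  result <- switch(cmd,
    simulate = {
      if (is.null(cfg$init)) stop("simulate needs an initial state (e.g. --init-preset table3 --I0 0.4)")
      t_end <- cfg$t_end %||% 2000
      .log("INFO", lvl, "integrating to t = ", t_end, " months")
      simulate_model(cfg$init, p, t_end, n_out = cfg$n_out %||% 500L)
    },
    equilibria = {
      .log("INFO", lvl, "enumerating steady states at d = ", p[["d"]])
      st <- steady_state_table(p)
      cbind(d = p[["d"]], st)
    },
    bifurcate = {
      dg <- cfg$d_grid %||% seq(0.02, 0.6, length.out = 30)
      .log("INFO", lvl, "sweeping ", length(dg), " degradation rates")
      sweep_bifurcation(dg, p)
    },
    basin = {
      dg <- cfg$d_grid %||% seq(0.02, 0.6, length.out = 30)
      xg <- cfg$x_grid %||% seq(0, 2, length.out = 41)
      axis <- cfg$axis %||% "I0"
      .log("INFO", lvl, "classifying ", length(dg) * length(xg), " runs (",
           axis, " axis)")
      bm <- basin_map(dg, xg, axis = axis, p = p, base_init = cfg$init)
      tc <- threshold_curve(dg, axis = axis, p = p, base_init = cfg$init)
      attr(bm, "threshold") <- tc
      bm
    })

  if (!is.null(cfg$out)) {
    paths <- write_outputs(result, cfg$out, cfg)
    if (cmd == "basin") {
      tpath <- sub("(\\.[^.]+)?$", "_threshold.csv", cfg$out)
      write_outputs(attr(result, "threshold"), tpath, cfg)
      .log("INFO", lvl, "wrote ", paths[["csv"]], " and ", tpath)
    } else {
      .log("INFO", lvl, "wrote ", paths[["csv"]])
    }
  } else {
    print(utils::head(as.data.frame(result), 20))
  }
  invisible(result)
}

.parse_flags <- function(args) {
  out <- list(param = list(), init = list())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args)) stop("flag --", key, " needs a value")
    val <- args[i + 1]
    if (key %in% c("param", "init")) {
      kv <- strsplit(val, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("--", key, " expects key=value, got: ", val)
      out[[key]][[kv[1]]] <- as.numeric(kv[2])
    } else out[[key]] <- val
    i <- i + 2
  }
  out
}
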