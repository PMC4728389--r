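# -- minimal TOML subset ------------------------------------------------------
# The parameter files use flat tables of scalar keys ([source], [initial],
# [transport], ...). This reader/writer covers exactly that subset: [table]
# headers, key = value with numbers, booleans, double-quoted strings, and
# one-dimensional numeric/string arrays; '#' comments.

.parse_toml_value <- function(txt, where) {
  txt <- trimws(txt)
  if (txt == "") stop_config("empty value %s", where)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(substr(txt, 2, nchar(txt) - 1))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, .parse_toml_value, where = where)))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl('^".*"$', txt)) return(substr(txt, 2, nchar(txt) - 1))
  if (txt == "inf") return(Inf)
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) stop_config("cannot parse TOML value '%s' %s", txt, where)
  val
}

#' Read a TOML parameter file (flat-table subset)
#'
#' @param path TOML file path.
#' @return Nested named list: one element per \code{[table]}, plus any
#'   top-level keys.
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) stop_config("config file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  table <- NULL
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    s <- trimws(raw)
    if (s == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", s)) {
      table <- substr(s, 2, nchar(s) - 1)
      if (is.null(out[[table]])) out[[table]] <- list()
      next
    }
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop_config("line %d of '%s' is not 'key = value'", ln, path)
    key <- trimws(substr(s, 1, eq - 1))
    val <- .parse_toml_value(substr(s, eq + 1, nchar(s)),
                             sprintf("(line %d of '%s')", ln, path))
    if (is.null(table)) out[[key]] <- val else out[[table]][[key]] <- val
  }
  out
}

.format_toml_value <- function(v) {
  one <- function(x) {
    if (is.character(x)) sprintf('"%s"', x)
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 17)
  }
  if (length(v) == 1) one(v)
  else sprintf("[%s]", paste(vapply(v, one, character(1)), collapse = ", "))
}

#' @rdname read_toml
#' @param x nested named list of flat tables.
#' @export
write_toml <- function(x, path) {
  lines <- character(0)
  scalars <- x[!vapply(x, is.list, logical(1))]
  for (k in names(scalars))
    lines <- c(lines, sprintf("%s = %s", k, .format_toml_value(scalars[[k]])))
  for (tb in names(x)[vapply(x, is.list, logical(1))]) {
    lines <- c(lines, sprintf("[%s]", tb))
    for (k in names(x[[tb]]))
      lines <- c(lines, sprintf("%s = %s", k, .format_toml_value(x[[tb]][[k]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

# -- config -> model objects --------------------------------------------------

.take_keys <- function(tab, allowed, where) {
  extra <- setdiff(names(tab), allowed)
  if (length(extra))
    stop_config("unknown key(s) %s in [%s]", paste(extra, collapse = ", "),
                where)
  tab
}

#' Build model parameter objects from a configuration
#'
#' Accepts a TOML path or an equivalent nested list with tables
#' \code{[source]} (A, k, lam, T, R), \code{[initial]} (c0, c1, a, alpha)
#' and \code{[transport]} (D); optional \code{[quadrature]} and \code{[fd]}
#' tables configure the solvers. Unknown keys are rejected. Units are fixed
#' (mm, day); no conversion is performed.
#'
#' @param config path to a TOML file, or a nested list.
#' @return List with \code{source}, \code{initial}, \code{transport},
#'   \code{quadrature} ([quadrature_config()]), \code{fd} (list dr/dt/r_max)
#'   and the raw \code{config}.
#' @export
load_params <- function(config) {
  cfg <- if (is.character(config)) read_toml(config) else config
  for (tb in c("source", "initial", "transport"))
    if (is.null(cfg[[tb]]))
      stop_config("configuration is missing the [%s] table", tb)
  s <- .take_keys(cfg$source, c("A", "k", "lam", "T", "R"), "source")
  src <- weibull_source(A = s$A %||% 500, k = s$k %||% 1.5,
                        lam = s$lam %||% 10, T_ = s$T %||% 1.5,
                        R = s$R %||% 0.42)
  i <- .take_keys(cfg$initial, c("c0", "c1", "a", "alpha"), "initial")
  ic <- initial_condition(c0 = i$c0 %||% 0.1, c1 = i$c1 %||% 0.8,
                          a = i$a %||% 0.16, alpha = i$alpha %||% 1.5)
  tconf <- .take_keys(cfg$transport, "D", "transport")
  if (is.null(tconf$D)) stop_config("[transport] must provide D")
  qt <- .take_keys(cfg$quadrature %||% list(),
                   c("beta_max", "n_panels", "panel_rule_order",
                     "tau_steps", "rel_tol"), "quadrature")
  q <- do.call(quadrature_config, qt)
  fd <- .take_keys(cfg$fd %||% list(), c("dr", "dt", "r_max"), "fd")
  fd <- list(dr = fd$dr %||% 0.05, dt = fd$dt %||% 0.01,
             r_max = fd$r_max %||% 120)
  list(source = src, initial = ic, transport = transport(tconf$D),
       quadrature = q, fd = fd, config = cfg)
}

.provenance <- function(out_dir, name, cfg, seed = NULL) {
  rec <- list(config = cfg,
              package = "geldiff",
              version = as.character(utils::packageVersion("geldiff")),
              seed = seed,
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(out_dir, paste0(name, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.study_radii <- c(2.475, 4.243, 6.790, 8.770, 11.170)

# -- pipeline drivers ---------------------------------------------------------

#' Simulate the concentration field to CSV
#'
#' Evaluates the model on a radius-time grid with either the analytic
#' Hankel-transform solver or the finite-difference solver (identical output
#' schema: \code{r_mm}, \code{t_day}, \code{concentration}) and writes
#' \code{concentration_<backend>.csv} plus a provenance record.
#'
#' Optional \code{[simulate]} config keys: \code{backend} ("analytic" or
#' "fd"), \code{radii}, \code{times}.
#'
#' @param config TOML path or nested list (see [load_params()]).
#' @param out_dir output directory (created if needed).
#' @param backend overrides the configured backend.
#' @return The simulated long-format data frame, invisibly; attribute
#'   \code{path} holds the CSV location.
#' @export
run_simulate <- function(config, out_dir = ".", backend = NULL) {
  p <- load_params(config)
  sim <- .take_keys(p$config$simulate %||% list(),
                    c("backend", "radii", "times"), "simulate")
  backend <- backend %||% sim$backend %||% "analytic"
  if (!backend %in% c("analytic", "fd"))
    stop_config("backend must be 'analytic' or 'fd', got '%s'", backend)
  radii <- sim$radii %||% .study_radii
  times <- sim$times %||% seq(0, 60)
  if (backend == "analytic") {
    conc <- solve_concentration(radii, times, p$source, p$initial,
                                p$transport, p$quadrature, drop = FALSE)
  } else {
    grid <- radial_grid(r_max = p$fd$r_max,
                        n_r = round(p$fd$r_max / p$fd$dr) + 1)
    tg <- time_grid(t_final = max(times, p$fd$dt), dt = p$fd$dt,
                    output_times = times)
    sol <- solve_fd(p$source, p$initial, p$transport, grid, tg)
    conc <- vapply(seq_along(sol$times),
                   function(j) stats::approx(sol$r, sol$u[, j],
                                             xout = radii)$y,
                   numeric(length(radii))) + p$initial$c0
    conc <- matrix(conc, nrow = length(radii))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(r_mm = rep(radii, length(times)),
                   t_day = rep(times, each = length(radii)),
                   concentration = as.vector(conc))
  path <- file.path(out_dir, sprintf("concentration_%s.csv", backend))
  utils::write.csv(df, path, row.names = FALSE)
  .provenance(out_dir, paste0("simulate_", backend), p$config)
  attr(df, "path") <- path
  invisible(df)
}

#' Generate a synthetic image stack to TIFF + sidecar
#'
#' Optional \code{[imaging]} keys mirror [imaging_config()]; optional
#' \code{[synth]} keys: \code{times} (acquisition days, default daily 0-60),
#' \code{file} (TIFF name, default \code{stack.tiff}).
#'
#' @inheritParams run_simulate
#' @param seed overrides the configured imaging seed.
#' @return The [generate_stack()] object, invisibly; attribute \code{path}
#'   holds the TIFF location.
#' @export
run_synth <- function(config, out_dir = ".", seed = NULL) {
  p <- load_params(config)
  im <- .take_keys(p$config$imaging %||% list(),
                   c("n_px", "pixel_size", "center", "psf_sigma", "noise_rel",
                     "noise_add", "background", "seed"), "imaging")
  if (!is.null(seed)) im$seed <- seed
  cfg <- do.call(imaging_config, im)
  sy <- .take_keys(p$config$synth %||% list(), c("times", "file"), "synth")
  times <- sy$times %||% seq(0, 60)
  if (length(times) == 0 || any(!is.finite(times)))
    stop_config("[synth] times must be a non-empty finite vector")
  stack <- generate_stack(p$source, p$initial, p$transport, times, cfg,
                          p$quadrature)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, sy$file %||% "stack.tiff")
  write_stack(stack, path)
  .provenance(out_dir, "synth", p$config, seed = cfg$seed)
  attr(stack, "path") <- path
  invisible(stack)
}

#' Extract radial intensity time series from a stack to CSV
#'
#' Optional \code{[extract]} keys: \code{radii} (default the five reference
#' radii), \code{annulus_width} (mm, default two pixels), \code{center}
#' ("sidecar" to trust the stored centre, "estimate" to locate it with
#' [estimate_center()] on the first frame).
#'
#' @param config TOML path or nested list.
#' @param stack an \code{image_stack} or a path to a TIFF written by
#'   [write_stack()].
#' @param out_dir output directory.
#' @return The extracted [observations()], invisibly; attribute \code{path}
#'   holds the CSV location.
#' @export
run_extract <- function(config, stack, out_dir = ".") {
  cfg <- if (is.character(config)) read_toml(config) else config
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"))
  ex <- .take_keys(cfg$extract %||% list(),
                   c("radii", "annulus_width", "center"), "extract")
  radii <- ex$radii %||% .study_radii
  centre <- switch(ex$center %||% "sidecar",
                   sidecar = stack$config$center,
                   estimate = estimate_center(stack$frames[[1]],
                                              pixel_size = stack$config$pixel_size),
                   stop_config("[extract] center must be 'sidecar' or 'estimate'"))
  obs <- stack_observations(stack, radii,
                            annulus_width = ex$annulus_width, center = centre)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "observations.csv")
  write_observations(obs, path)
  .provenance(out_dir, "extract", cfg)
  attr(obs, "path") <- path
  invisible(obs)
}

#' Fit the apparent diffusivity from observations, writing a JSON report
#'
#' Optional \code{[fit]} keys: \code{init_D} (default 1 mm^2/day),
#' \code{bounds}, \code{ci} (logical: add a residual-bootstrap interval),
#' \code{n_boot}, \code{level}, \code{seed}. The JSON result is written even
#' when the fit does not converge; a non-converged fit then raises a
#' numerical error (condition class \code{geldiff_numerical_error}).
#'
#' @param config TOML path or nested list.
#' @param obs an [observations()] object or a CSV path.
#' @param out_dir output directory.
#' @return The [fit_diffusivity()] result, invisibly; attribute \code{path}
#'   holds the JSON location.
#' @export
run_fit <- function(config, obs, out_dir = ".") {
  p <- load_params(config)
  if (is.character(obs)) obs <- read_observations(obs)
  ft <- .take_keys(p$config$fit %||% list(),
                   c("init_D", "bounds", "ci", "n_boot", "level", "seed"),
                   "fit")
  fit <- fit_diffusivity(obs, p$source, p$initial,
                         init_D = ft$init_D %||% 1,
                         bounds = ft$bounds %||% c(1e-3, 1e3),
                         q = p$quadrature)
  if (isTRUE(ft$ci) && fit$converged)
    fit <- bootstrap_ci(obs, fit, n_boot = ft$n_boot %||% 200,
                        level = ft$level %||% 0.9, seed = ft$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "fit.json")
  report <- list(estimates = as.list(fit$estimates),
                 residual_norm = fit$residual_norm,
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 ci = if (!is.null(fit$ci))
                   as.list(as.data.frame(fit$ci)),
                 seed = fit$seed,
                 config = p$config)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .provenance(out_dir, "fit", p$config, seed = ft$seed %||% NULL)
  attr(fit, "path") <- path
  if (!fit$converged)
    stop_numerical("diffusivity fit did not converge (report written to %s)",
                   path)
  invisible(fit)
}

#' Run the model-validation suite, writing a JSON report
#'
#' Four checks of the numerical machinery at the configured parameters:
#' \describe{
#'   \item{inversion_identity}{the analytic solution at \eqn{t = 0}
#'     reproduces the initial profile (threshold 1e-4 relative).}
#'   \item{oracle_equivalence}{analytic vs Crank-Nicolson fields within 1\%
#'     relative sup-norm over \eqn{r \le 12} mm, \eqn{t \in [1, 60]} day.}
#'   \item{mass_balance}{discrete mass tracks initial + released mass within
#'     0.5\% over the outflow-free window.}
#'   \item{peak_time_monotonic}{excess peak times strictly increase with
#'     radius and each curve rises then falls (diffusive-wave signature).}
#' }
#' Optional \code{[validate]} keys: \code{r_max_check}, \code{times}
#' (defaults 12 mm, 1..60 day) and the \code{[fd]} table for the oracle
#' resolution. All checks are written to \code{validation.json}; any failure
#' then raises a numerical error.
#'
#' @param config TOML path or nested list; \code{NULL} uses [gel_params()].
#' @param out_dir output directory.
#' @return The report list, invisibly.
#' @export
run_validate <- function(config = NULL, out_dir = ".") {
  p <- if (is.null(config)) {
    gp <- gel_params()
    list(source = gp$source, initial = gp$initial, transport = gp$transport,
         quadrature = quadrature_config(),
         fd = list(dr = 0.05, dt = 0.01, r_max = 120),
         config = list())
  } else load_params(config)
  va <- .take_keys(p$config$validate %||% list(),
                   c("r_max_check", "times"), "validate")
  r_check <- seq(0, va$r_max_check %||% 12, by = 0.5)
  times <- va$times %||% seq(1, 60)

  op <- hankel_operator(p$source, p$initial, p$quadrature)
  checks <- list()

  r_inv <- c(0, 1, 5, 10)
  v0 <- solve_concentration(r_inv, 0, p$source, p$initial, p$transport,
                            p$quadrature, op = op, drop = FALSE)
  inv_err <- max(abs(v0[, 1] - initial_condition_profile(r_inv, p$initial)) /
                   initial_condition_profile(r_inv, p$initial))
  checks$inversion_identity <- list(value = inv_err, threshold = 1e-4,
                                    pass = inv_err < 1e-4)

  grid <- radial_grid(r_max = p$fd$r_max,
                      n_r = round(p$fd$r_max / p$fd$dr) + 1)
  tg <- time_grid(t_final = max(times), dt = p$fd$dt, output_times = times)
  sol <- solve_fd(p$source, p$initial, p$transport, grid, tg)
  ana <- solve_concentration(r_check, sol$times, p$source, p$initial,
                             p$transport, p$quadrature,
                             include_baseline = FALSE, op = op, drop = FALSE)
  ir <- vapply(r_check, function(r) which.min(abs(sol$r - r)), integer(1))
  oe <- max(abs(ana - sol$u[ir, , drop = FALSE])) / max(sol$u[ir, ])
  checks$oracle_equivalence <- list(value = oe, threshold = 0.01,
                                    pass = oe < 0.01)

  mb <- mass_balance_report(sol)
  checks$mass_balance <- list(value = mb$max_rel_dev, threshold = 0.005,
                              pass = is.finite(mb$max_rel_dev) &&
                                mb$max_rel_dev < 0.005,
                              boundary_contaminated = mb$boundary_contaminated)

  prof <- solve_concentration(.study_radii, seq(0, 60, by = 0.5), p$source,
                              p$initial, p$transport, p$quadrature,
                              include_baseline = FALSE, op = op, drop = FALSE)
  peak_idx <- apply(prof, 1, which.max)
  rise_fall <- all(apply(prof, 1, function(u) {
    k <- which.max(u)
    k > 1 && k < length(u) && all(diff(u[1:k]) > 0) && all(diff(u[k:length(u)]) < 0)
  }))
  mono <- !is.unsorted(peak_idx, strictly = TRUE)
  checks$peak_time_monotonic <- list(value = unname(peak_idx), threshold = NA,
                                     pass = mono && rise_fall)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(checks, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .provenance(out_dir, "validate", if (is.null(config)) list() else p$config)
  failed <- names(checks)[!vapply(checks, function(x) isTRUE(x$pass), logical(1))]
  if (length(failed))
    stop_numerical("validation failed: %s (report written to %s)",
                   paste(failed, collapse = ", "), path)
  invisible(checks)
}
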