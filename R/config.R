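# Run configuration: a YAML file with sections `hazard`, `network`, `solver`
# and `coupling`. Unknown keys are rejected so typos fail loudly; defaults
# are filled and every run records its seed.

cfg_schema <- list(
  hazard = c("form", "T_ref", "tau", "eps", "omega", "alpha"),
  network = c("N", "J_s", "tau_s", "I_ext", "dt", "seed"),
  solver = c("dt", "r_max", "t_transient", "t_measure", "adjoint_tol",
             "n_cycles"),
  coupling = c("G_s", "d"),
  output_dir = NULL,
  name = NULL
)

cfg_defaults <- function(cfg) {
  Tr <- cfg$hazard$T_ref %||% 0
  cfg$hazard$tau <- cfg$hazard$tau %||% 0
  cfg$network$seed <- cfg$network$seed %||% 0L
  cfg$network$dt <- cfg$network$dt %||% 0.05
  cfg$solver$dt <- cfg$solver$dt %||% 0.05
  cfg$solver$r_max <- cfg$solver$r_max %||% (1.25 * Tr)
  cfg$solver$t_transient <- cfg$solver$t_transient %||% 500
  cfg$solver$t_measure <- cfg$solver$t_measure %||% 300
  cfg$solver$adjoint_tol <- cfg$solver$adjoint_tol %||% 1e-6
  cfg$solver$n_cycles <- cfg$solver$n_cycles %||% 400L
  cfg
}

cfg_validate <- function(cfg) {
  for (sec in names(cfg)) {
    if (!sec %in% names(cfg_schema))
      stop("unknown config section: ", sec)
    allowed <- cfg_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown config key: ", sec, "$", bad[1L])
  }
  pos <- list(c("network", "tau_s"), c("network", "dt"), c("network", "N"),
              c("solver", "dt"), c("solver", "r_max"),
              c("solver", "adjoint_tol"), c("hazard", "T_ref"))
  for (p in pos) {
    v <- cfg[[p[1L]]][[p[2L]]]
    if (!is.null(v) && v <= 0 && !(p[2L] == "T_ref" && v == 0))
      stop("config key ", p[1L], "$", p[2L], " must be positive")
  }
  if (!is.null(cfg$hazard$tau) && cfg$hazard$tau < 0)
    stop("config key hazard$tau must be nonnegative")
  invisible(cfg)
}

#' Load, validate and complete a YAML run configuration
#'
#' @param path path to a YAML file with sections `hazard` (form and
#'   parameters), `network` (`N`, `J_s`, `tau_s`, `I_ext`, `dt`, `seed`),
#'   `solver` (`dt`, `r_max`, tolerances) and optionally `coupling`
#'   (`G_s`, `d`). Unknown keys raise an error naming the key; missing
#'   values get defaults (`dt = 0.05`, `r_max = 1.25 T_ref`, `seed = 0`).
#' @return object of class `run_config` (nested list), with `$hazard_model`
#'   the constructed [hazard_model()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key `N` as boolean FALSE; undo that
  if (!is.null(cfg$network)) {
    names(cfg$network)[names(cfg$network) == "FALSE"] <- "N"
    names(cfg$network)[names(cfg$network) == "no"] <- "N"
  }
  cfg_validate(cfg)
  cfg <- cfg_defaults(cfg)
  cfg_validate(cfg)
  hz <- cfg$hazard
  cfg$hazard_model <- hazard_model(hz$form, T_ref = hz$T_ref %||% 0,
                                   tau = hz$tau %||% 0, eps = hz$eps,
                                   omega = hz$omega, alpha = hz$alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration back to YAML
#'
#' `load_config(dump_config(cfg, path))` reproduces `cfg`.
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$hazard_model <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  hazard:", x$hazard$form, "(T_ref =", x$hazard$T_ref %||% 0,
      "ms, tau =", x$hazard$tau %||% 0, "ms)\n")
  cat("  network: N =", x$network$N, ", J_s =", x$network$J_s,
      ", tau_s =", x$network$tau_s, ", I_ext =", x$network$I_ext,
      ", dt =", x$network$dt, ", seed =", x$network$seed, "\n")
  if (!is.null(x$coupling))
    cat("  coupling: G_s =", x$coupling$G_s, ", d =", x$coupling$d, "\n")
  invisible(x)
}

#' Named parameter presets
#'
#' Returns the parameter sets of the worked study conditions by name:
#' \describe{
#'   \item{fig1}{recurrent excitatory network, soft threshold:
#'     `exp_relax` with `T_ref = 10`, `tau = 5`; `tau_s = 10`, `J_s = 15`,
#'     `N = 5000`, `dt = 0.05`, `I_ext = 2`.}
#'   \item{fig2}{hard threshold (`tau = 0`), `T_ref = 8`, `tau_s = 10`,
#'     `N = 5000`, `dt = 0.1`; `J_s = 1` (asynchronous reference). The
#'     regime exemplars are `I_ext = 2` with `J_s = 1` (asynchronous) and
#'     `J_s = 15` (oscillatory).}
#'   \item{fig3}{the oscillatory mPRC benchmark: `exp_relax`, `I_ext = 2`,
#'     `T_ref = 10`, `tau = 5`, `tau_s = 10`, `J_s = 15`, `N = 5000`,
#'     `dt = 0.05`. Pulses: spiking 3 mV for 5 ms; mean-field 0.8 mV for
#'     8 ms.}
#'   \item{fig4a}{`ramp` hazard, `eps = 3`, `T_ref = 6`, `I_ext = 2.5`,
#'     `tau_s = 10`, `J_s = 4`, `dt = 0.05`.}
#'   \item{fig4b}{`tanh` hazard, `T_ref = 5`, `I_ext = 2.5`, `tau_s = 10`,
#'     `J_s = 3`, `dt = 0.05`.}
#'   \item{fig4c}{`tanh_cos` hazard, `eps = 3`, `omega = 1`, `T_ref = 10`,
#'     `I_ext = 2.5`, `tau_s = 3`, `J_s = 15`, `dt = 0.05`.}
#'   \item{fig5}{fig3 plus cross-coupling `G_s = 0.2` mV ms, `dt = 0.005`,
#'     delays `d` in {0.5, 2.5, 4.5} ms.}
#' }
#'
#' @param name one of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4a"`, `"fig4b"`,
#'   `"fig4c"`, `"fig5"`.
#' @return a `run_config`.
#' @export
make_fixture <- function(name = c("fig1", "fig2", "fig3", "fig4a", "fig4b",
                                  "fig4c", "fig5")) {
  name <- match.arg(name)
  cfg <- switch(name,
    fig1 = list(
      hazard = list(form = "exp_relax", T_ref = 10, tau = 5),
      network = list(N = 5000L, J_s = 15, tau_s = 10, I_ext = 2, dt = 0.05)),
    fig2 = list(
      hazard = list(form = "exp_relax", T_ref = 8, tau = 0),
      network = list(N = 5000L, J_s = 1, tau_s = 10, I_ext = 2, dt = 0.1),
      solver = list(dt = 0.01)),
    fig3 = list(
      hazard = list(form = "exp_relax", T_ref = 10, tau = 5),
      network = list(N = 5000L, J_s = 15, tau_s = 10, I_ext = 2, dt = 0.05)),
    fig4a = list(
      hazard = list(form = "ramp", T_ref = 6, eps = 3),
      network = list(N = 5000L, J_s = 4, tau_s = 10, I_ext = 2.5, dt = 0.05)),
    fig4b = list(
      hazard = list(form = "tanh", T_ref = 5),
      network = list(N = 5000L, J_s = 3, tau_s = 10, I_ext = 2.5, dt = 0.05)),
    fig4c = list(
      hazard = list(form = "tanh_cos", T_ref = 10, eps = 3, omega = 1),
      network = list(N = 5000L, J_s = 15, tau_s = 3, I_ext = 2.5, dt = 0.05)),
    fig5 = list(
      hazard = list(form = "exp_relax", T_ref = 10, tau = 5),
      network = list(N = 5000L, J_s = 15, tau_s = 10, I_ext = 2, dt = 0.005),
      solver = list(dt = 0.005),
      coupling = list(G_s = 0.2, d = c(0.5, 2.5, 4.5)))
  )
  cfg <- cfg_defaults(cfg)
  cfg_validate(cfg)
  hz <- cfg$hazard
  cfg$hazard_model <- hazard_model(hz$form, T_ref = hz$T_ref %||% 0,
                                   tau = hz$tau %||% 0, eps = hz$eps,
                                   omega = hz$omega, alpha = hz$alpha)
  cfg$name <- name
  class(cfg) <- "run_config"
  cfg
}
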