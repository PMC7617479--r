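#' Run a processing command from a configuration list
#'
#' Programmatic counterpart of the `poremri` command line. Each command
#' consumes paths/parameters from `config`, runs the corresponding package
#' functions and returns a report list (also written as JSON when
#' `config$out` is set). Reports are deterministic given the seeds in the
#' config and embed the config itself, so any report can be regenerated.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{draw a preset phantom and write NIfTI/bval/bvec/TE
#'     table/radii CSV to `config$out_dir`. Keys: `preset`, `seed`, `snr`,
#'     `n_voxels`.}
#'   \item{sem-reff}{numerical effective radii from a radius CSV
#'     (`radii`): relaxation and diffusion branch plus moment
#'     approximations. Keys: `rho2`, `t2b`.}
#'   \item{calibrate}{surface relaxivity from a measured TE series CSV
#'     (`series`) and radius CSV (`radii`). Key: `t2b`.}
#'   \item{fit-t2}{mono-exponential T2 fit of a TE series and conversion to
#'     a radius. Keys: `series`, `rho2`, `t2b`.}
#'   \item{fit-dmri}{spherical-mean power-law radius from a b series CSV.}
#'   \item{compare}{OLS comparison of two radius lists given as CSV with
#'     columns `x`, `y` (`pairs`).}
#' }
#'
#' @param config named list of options
#' @param command one of simulate, sem-reff, calibrate, fit-t2, fit-dmri,
#'   compare
#' @return the report, invisibly when written to file
#' @export
run_pipeline <- function(config, command = c("simulate", "sem-reff",
                                             "calibrate", "fit-t2",
                                             "fit-dmri", "compare")) {
  command <- match.arg(command)
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  t2b <- as.numeric(cfg("t2b", 3000))
  report <- switch(command,
    "simulate" = {
      out_dir <- cfg("out_dir") %||% stop_domain("simulate needs out_dir")
      spec <- phantom_preset(cfg("preset", "phantom1"))
      seed <- as.integer(cfg("seed", 1))
      smp <- sample_radii(spec, seed = seed)
      ds <- simulate_dwi(smp, spec, protocol_preset(cfg("protocol", "t2_block")),
                         snr = as.numeric(cfg("snr", Inf)),
                         n_voxels = as.integer(cfg("n_voxels", 1)),
                         seed = seed + 1L)
      paths <- write_dataset(ds, out_dir, prefix = spec$label)
      paths$radii <- file.path(out_dir, paste0(spec$label, "_radii.csv"))
      write_radius_csv(smp, paths$radii)
      list(command = command, preset = spec$label, sigma = ds$sigma,
           files = lapply(paths, normalizePath))
    },
    "sem-reff" = {
      smp <- read_radius_csv(cfg("radii") %||% stop_domain("needs radii"))
      relax <- relaxation_params(T2b = t2b, rho2 = as.numeric(cfg("rho2", 3.7)))
      prot_t2 <- protocol_preset("t2_block")
      prot_d <- protocol_preset("dmri_block")
      fr <- fit_single_cylinder_relaxation(
        synth_relaxation_series(smp, prot_t2$TE, relax), relax)
      fd <- fit_single_cylinder_diffusion(
        synth_diffusion_series(smp, prot_d), prot_d)
      list(command = command,
           r_eff_sem_r = fr$r_eff, r_eff_sem_d = fd$r_eff,
           moment_ratio = moment_ratio_radius(smp),
           neuman_moment = neuman_moment_radius(smp),
           converged = fr$converged && fd$converged,
           flagged = fr$bounds_hit || fd$bounds_hit)
    },
    "calibrate" = {
      ser <- read_series_csv(cfg("series") %||% stop_domain("needs series"))
      smp <- read_radius_csv(cfg("radii") %||% stop_domain("needs radii"))
      cal <- calibrate_rho2(ser, smp, T2b = t2b)
      list(command = command, rho2 = cal$rho2, K = cal$K, loss = cal$loss,
           flagged = cal$bounds_hit)
    },
    "fit-t2" = {
      ser <- read_series_csv(cfg("series") %||% stop_domain("needs series"))
      fit <- fit_monoexp_t2(ser)
      rho2 <- cfg("rho2")
      r <- if (is.null(rho2)) NA_real_ else
        radius_from_t2(fit$T2i, relaxation_params(T2b = t2b,
                                                  rho2 = as.numeric(rho2)))
      list(command = command, K = fit$K, T2i = fit$T2i,
           r_eff_mri_r = r, flagged = fit$bounds_hit)
    },
    "fit-dmri" = {
      ser <- read_series_csv(cfg("series") %||% stop_domain("needs series"))
      fit <- fit_diffusion_radius(ser, protocol_preset("dmri_block"))
      list(command = command, beta = fit$scale, r_eff_mri_d = fit$r_eff,
           loss = fit$loss, flagged = fit$bounds_hit)
    },
    "compare" = {
      df <- utils::read.csv(cfg("pairs") %||% stop_domain("needs pairs"))
      rep <- compare_radii(df$x, df$y)
      list(command = command, slope = rep$slope, intercept = rep$intercept,
           R = rep$R, p = rep$p, n = rep$n)
    })
  report$package_version <- as.character(utils::packageVersion("poremri"))
  report$config <- config
  out <- cfg("out")
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
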