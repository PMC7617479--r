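#' Spherical-mean signal series
#'
#' An orientation-averaged signal decay, either along echo time at fixed b
#' (`axis_kind = "TE"`) or along b-value at fixed TE (`axis_kind = "b"`),
#' optionally with a per-point dispersion across voxels.
#'
#' @param axis_kind `"TE"` (ms) or `"b"` (s/mm^2)
#' @param axis strictly increasing axis values
#' @param mean_signal positive mean signal per axis point
#' @param sd_signal optional per-point SD (across voxels)
#' @param n_voxels number of voxels averaged
#' @return object of class `"spherical_mean_series"`
#' @export
spherical_mean_series <- function(axis_kind = c("TE", "b"), axis, mean_signal,
                                  sd_signal = NULL, n_voxels = 1L) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis); mean_signal <- as.numeric(mean_signal)
  if (length(axis) != length(mean_signal))
    stop_domain("axis and mean_signal lengths differ")
  if (any(diff(axis) <= 0)) stop_domain("axis must be strictly increasing")
  if (any(!is.finite(mean_signal)) || any(mean_signal <= 0))
    stop_domain("signals must be positive and finite")
  if (!is.null(sd_signal) && length(sd_signal) != length(axis))
    stop_domain("sd_signal length mismatch")
  structure(list(axis_kind = axis_kind, axis = axis,
                 mean_signal = mean_signal, sd_signal = sd_signal,
                 n_voxels = as.integer(n_voxels)),
            class = "spherical_mean_series")
}

#' @export
print.spherical_mean_series <- function(x, ...) {
  cat(sprintf("spherical-mean series along %s (%d points, %d voxel%s)\n",
              x$axis_kind, length(x$axis), x$n_voxels,
              if (x$n_voxels == 1) "" else "s"))
  df <- data.frame(axis = x$axis, signal = signif(x$mean_signal, 6))
  names(df)[1] <- if (x$axis_kind == "TE") "TE_ms" else "b_s_mm2"
  if (!is.null(x$sd_signal)) df$sd <- signif(x$sd_signal, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.spherical_mean_series <- function(x, ...) {
  df <- data.frame(axis = x$axis, signal = x$mean_signal)
  df$sd <- if (is.null(x$sd_signal)) NA_real_ else x$sd_signal
  attr(df, "axis_kind") <- x$axis_kind
  df
}
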