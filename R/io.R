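#' Read a radius sample from CSV
#'
#' Expected columns: `radius_um` (required) and optionally `count` for
#' binned histograms. A header row is required.
#'
#' @param path CSV file
#' @param label provenance tag (defaults to the file name)
#' @return a [radius_sample()]
#' @export
read_radius_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!"radius_um" %in% names(df))
    stop_domain("radius CSV must have a 'radius_um' column")
  radius_sample(df$radius_um,
                counts = if ("count" %in% names(df)) df$count else NULL,
                label = label)
}

#' @rdname read_radius_csv
#' @param sample a [radius_sample()] to write
#' @export
write_radius_csv <- function(sample, path) {
  df <- data.frame(radius_um = sample$radii)
  if (!all(sample$counts == 1)) df$count <- sample$counts
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a spherical-mean series as CSV
#'
#' Columns: `axis` name is `TE_ms` or `b_s_mm2` (this chooses the axis
#' kind), `signal`, optional `sd`. Loose unit sanity checks reject series
#' whose axis looks mis-scaled (e.g. b in ms/um^2 instead of s/mm^2) unless
#' `check_units = FALSE`.
#'
#' @param path CSV file
#' @param check_units apply range sanity checks?
#' @return a [spherical_mean_series()]
#' @export
read_series_csv <- function(path, check_units = TRUE) {
  df <- utils::read.csv(path)
  kind <- if ("TE_ms" %in% names(df)) "TE"
  else if ("b_s_mm2" %in% names(df)) "b"
  else stop_domain("series CSV needs a 'TE_ms' or 'b_s_mm2' column")
  axis <- df[[if (kind == "TE") "TE_ms" else "b_s_mm2"]]
  if (check_units) {
    if (kind == "TE" && (any(axis < 1) || any(axis > 2000)))
      stop_domain("TE values outside 1-2000 ms; wrong units? (override with check_units = FALSE)")
    if (kind == "b" && max(axis) < 50)
      stop_domain("b-values look like ms/um^2; expected s/mm^2 (override with check_units = FALSE)")
  }
  o <- order(axis)
  spherical_mean_series(kind, axis[o], df$signal[o],
                        sd_signal = if ("sd" %in% names(df)) df$sd[o] else NULL)
}

#' @rdname read_series_csv
#' @param series a [spherical_mean_series()] to write
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(axis = series$axis, signal = series$mean_signal)
  names(df)[1] <- if (series$axis_kind == "TE") "TE_ms" else "b_s_mm2"
  if (!is.null(series$sd_signal)) df$sd <- series$sd_signal
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset as NIfTI + bval/bvec + TE table
#'
#' Lays the voxels out on a flat 2D grid and writes a 4D NIfTI volume, an
#' FSL-style `.bval` row and 3 x N `.bvec` file (zero vectors for b0
#' volumes), a per-volume TE table (`volume_index, TE_ms, b_s_mm2`) and a
#' binary mask covering the voxels, matching what [load_dataset()] reads.
#'
#' @param ds a `"simulated_dataset"`
#' @param dir output directory (created if needed)
#' @param prefix file name stem
#' @return invisibly, the named list of file paths
#' @export
write_dataset <- function(ds, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nvox <- nrow(ds$signal); nvol <- ncol(ds$signal)
  nx <- ceiling(sqrt(nvox)); ny <- ceiling(nvox / nx)
  arr <- array(0, c(nx, ny, 1, nvol))
  msk <- array(0L, c(nx, ny, 1))
  for (v in seq_len(nvox)) {
    i <- (v - 1) %% nx + 1; j <- (v - 1) %/% nx + 1
    arr[i, j, 1, ] <- ds$signal[v, ]
    msk[i, j, 1] <- 1L
  }
  paths <- list(
    nifti = file.path(dir, paste0(prefix, ".nii.gz")),
    bval = file.path(dir, paste0(prefix, ".bval")),
    bvec = file.path(dir, paste0(prefix, ".bvec")),
    te_table = file.path(dir, paste0(prefix, "_te.csv")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(arr), paths$nifti)
  RNifti::writeNifti(RNifti::asNifti(msk), paths$mask)
  writeLines(paste(format(ds$volumes$b, trim = TRUE), collapse = " "),
             paths$bval)
  bvec <- matrix(0, 3, nvol)
  sel <- ds$volumes$dir > 0
  bvec[, sel] <- t(ds$directions[ds$volumes$dir[sel], , drop = FALSE])
  writeLines(apply(bvec, 1, function(row)
    paste(format(row, trim = TRUE), collapse = " ")), paths$bvec)
  utils::write.csv(data.frame(volume_index = seq_len(nvol),
                              TE_ms = ds$volumes$TE,
                              b_s_mm2 = ds$volumes$b),
                   paths$te_table, row.names = FALSE)
  invisible(paths)
}

#' Load a directional dataset and compute spherical means
#'
#' Reads a 4D NIfTI volume with FSL-style bval/bvec files, a per-volume TE
#' table and a binary mask; groups volumes by (b, TE) shell; and returns
#' the voxel-aggregated spherical-mean series plus the masked b0 stack. The
#' file set round-trips with [write_dataset()]. Volume order is free: the
#' grouping uses only the per-volume tables.
#'
#' @param nifti_path 4D NIfTI file
#' @param bval_path whitespace-separated b-values, one row
#' @param bvec_path 3 x N whitespace-separated unit vectors
#' @param te_table_path CSV with `volume_index, TE_ms, b_s_mm2`
#' @param mask_path binary NIfTI mask (0/1)
#' @param b0_threshold b-values at or below this count as b0, s/mm^2
#' @param check_units apply b/TE range sanity checks?
#' @return list with `series`, `b0_stack`, `volumes`, `directions`
#' @export
load_dataset <- function(nifti_path, bval_path, bvec_path, te_table_path,
                         mask_path, b0_threshold = 50, check_units = TRUE) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop_domain("expected a 4D NIfTI volume")
  nvol <- dim(arr)[4]
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  te <- utils::read.csv(te_table_path)
  if (!all(c("volume_index", "TE_ms") %in% names(te)))
    stop_domain("TE table needs 'volume_index' and 'TE_ms' columns")
  if (length(bval) != nvol || ncol(bvec) != nvol || nrow(te) != nvol)
    stop_domain(sprintf(
      "volume count mismatch: nifti %d, bval %d, bvec %d, TE table %d",
      nvol, length(bval), ncol(bvec), nrow(te)))
  te <- te[order(te$volume_index), ]
  if (check_units) {
    if (max(bval) < b0_threshold)
      stop_domain("all b-values below the b0 threshold; wrong units? (s/mm^2 expected)")
    if (any(te$TE_ms < 1) || any(te$TE_ms > 2000))
      stop_domain("TE values outside 1-2000 ms; wrong units?")
  }
  msk <- as.array(RNifti::readNifti(mask_path))
  if (length(msk) * nvol != length(arr))
    stop_domain("mask geometry does not match the 4D volume")
  if (!all(msk %in% c(0, 1))) stop_domain("mask must be binary (0/1)")
  vox <- which(msk == 1)
  if (length(vox) == 0) stop_domain("mask is empty")
  flat <- matrix(arr, ncol = nvol)          # voxels x volumes
  sig <- flat[vox, , drop = FALSE]
  is_b0 <- bval <= b0_threshold
  dir_idx <- integer(nvol)
  dir_idx[!is_b0] <- seq_len(sum(!is_b0))
  ds <- list(signal = sig,
             volumes = data.frame(b = ifelse(is_b0, 0, bval), TE = te$TE_ms,
                                  G = NA_real_, dir = dir_idx),
             directions = t(bvec[, !is_b0, drop = FALSE]))
  out <- dataset_series(ds)
  c(out, list(volumes = ds$volumes, directions = ds$directions))
}
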