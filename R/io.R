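#' Read an ion-coordinate (or voltage) time series
#'
#' Reads two-or-more-column time series in TSV, CSV, or GROMACS
#' xvg-dialect (lines starting with '#' or '@' are comments). Column 1
#' is time (ps), column 2 the ion z coordinate (Angstrom); an optional
#' third column is an aligned membrane voltage (mV). The time grid
#' must be uniform (relative tolerance 1e-6) and strictly increasing.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or
#'   `"xvg"`.
#' @return a [trajectory1d].
#' @export
read_timeseries <- function(path, format = c("auto", "tsv", "csv", "xvg")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv")) "csv"
              else if (ext %in% c("xvg")) "xvg" else "tsv"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("need >= 2 data rows in ", path)
  sep <- if (format == "csv") "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          col.names = paste0("V", 1:10), fill = TRUE)
  df <- df[, colSums(!is.na(df)) > 0, drop = FALSE]
  if (ncol(df) < 2) stop("need at least two columns (time, z)")
  if (anyNA(df)) stop("ragged rows in ", path)
  tt <- df[[1]]; z <- df[[2]]
  if (any(diff(tt) <= 0)) stop("non-monotone time column")
  dts <- diff(tt)
  bad <- which(abs(dts - dts[1]) > 1e-6 * abs(dts[1]))
  if (length(bad))
    stop(sprintf("non-uniform time spacing at row %d (dt %.6g vs %.6g)",
                 bad[1] + 1L, dts[bad[1]], dts[1]))
  vm <- if (ncol(df) >= 3) df[[3]] else NULL
  trajectory1d(z, dt = dts[1], vm = vm, meta = list(path = path, t0 = tt[1]))
}

#' Write a trajectory as TSV or xvg dialect
#'
#' @param traj a [trajectory1d].
#' @param path output path.
#' @param format `"tsv"` or `"xvg"` ('@'-style headers).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("tsv", "xvg")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory1d"))
  tt <- (seq_along(traj$z) - 1) * traj$dt
  m <- cbind(tt, traj$z)
  if (!is.null(traj$vm)) m <- cbind(m, traj$vm)
  header <- if (format == "xvg")
    c("@    title \"ion z trajectory\"",
      "@    xaxis  label \"Time (ps)\"",
      "@    yaxis  label \"z (A)\"")
  else "# time_ps\tz_A"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(m, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write umbrella windows as per-window TSVs plus a manifest
#'
#' One two-column (time, z) TSV per window, named
#' `window_<i>.tsv`, and a `manifest.tsv` with columns file, center,
#' kappa, temperature (the common pullx-style layout).
#'
#' @param windows an `umbrella_set`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  stopifnot(inherits(windows, "umbrella_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- windows$meta$dt %||% 1
  rows <- lapply(seq_along(windows$windows), function(i) {
    w <- windows$windows[[i]]
    f <- sprintf("window_%03d.tsv", i)
    tr <- trajectory1d(w$samples, dt = dt)
    write_trajectory(tr, file.path(dir, f))
    data.frame(file = f, center = w$center, kappa = w$kappa,
               temperature = w$temperature)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read umbrella windows written by [write_umbrella_windows]
#'
#' @param dir directory containing `manifest.tsv` and the per-window
#'   TSVs.
#' @return an `umbrella_set`.
#' @export
read_umbrella_windows <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) stop("no manifest.tsv in ", dir)
  mf <- utils::read.table(manifest, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  windows <- lapply(seq_len(nrow(mf)), function(i) {
    tr <- read_timeseries(file.path(dir, mf$file[i]), "tsv")
    list(center = mf$center[i], kappa = mf$kappa[i],
         temperature = mf$temperature[i], samples = tr$z)
  })
  structure(list(windows = windows, meta = list(manifest = manifest)),
            class = "umbrella_set")
}

#' Write / read Q-V series as CSV
#'
#' Long-format CSV with columns position_z, imbalance_e, vm_mV, se_mV
#' (and n when available); one file can hold a whole position scan.
#'
#' @param qv_list list of [qv_series].
#' @param path CSV path.
#' @return `path` invisibly (writer); list of [qv_series] (reader).
#' @export
write_qv_csv <- function(qv_list, path) {
  if (inherits(qv_list, "qv_series")) qv_list <- list(qv_list)
  df <- do.call(rbind, lapply(qv_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qv_csv
#' @export
read_qv_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_z", "imbalance_e", "vm_mV", "se_mV")
  if (!all(need %in% names(df)))
    stop("Q-V CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$position_z), function(d)
    qv_series(d$position_z[1], d$imbalance_e, d$vm_mV, d$se_mV,
              n = if ("n" %in% names(d)) d$n else NA_integer_))
}

#' Write a PMF (or tilted landscape) as TSV
#'
#' Columns z, G and, when present, sd and n_eff.
#'
#' @param curve a [pmf_curve].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "pmf_curve"))
  df <- data.frame(z = curve$z, G = curve$G)
  if (!is.null(curve$sd)) df$sd <- curve$sd
  if (!is.null(curve$n_eff)) df$n_eff <- curve$n_eff
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an electrical-distance profile as TSV
#'
#' @param profile a [delta_profile].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "delta_profile"))
  df <- data.frame(z = profile$z, delta = profile$delta)
  if (!is.null(profile$err)) df$err <- profile$err
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
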