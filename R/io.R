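#' Write a reaction-coordinate time series in pullx (.xvg) dialect
#'
#' Two whitespace-separated columns (time in ns, position in nm) preceded
#' by `#`/`@` comment headers, the dialect written by GROMACS pull code.
#'
#' @param time,xi numeric vectors of equal length.
#' @param path output file path.
#' @param title title line written into the header.
#' @return `path`, invisibly.
#' @export
write_pullx <- function(time, xi, path, title = "reaction coordinate") {
  stopifnot(length(time) == length(xi))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# written by calyx",
               sprintf("@    title \"%s\"", title),
               "@    xaxis  label \"Time (ns)\"",
               "@    yaxis  label \"Position (nm)\""), con)
  writeLines(sprintf("%.6f\t%.8f", time, xi), con)
  invisible(path)
}

#' Read a pullx (.xvg) time series
#'
#' Skips `#` and `@` comment lines and returns the first two numeric
#' columns.
#'
#' @param path file path.
#' @return data.frame with columns `time` (ns) and `xi` (nm).
#' @export
read_pullx <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data lines in ", path)
  dat <- read.table(text = lines[keep], header = FALSE)
  data.frame(time = dat[[1]], xi = dat[[2]])
}

#' Write an umbrella dataset as pullx files plus a manifest
#'
#' @param dataset an `umbrella_dataset`.
#' @param dir output directory (created if missing).  Writes
#'   `window_###.xvg` per window and `manifest.tsv` with columns
#'   `filename`, `center`, `spring_k`.
#' @return the manifest path, invisibly.
#' @export
write_umbrella_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("window_%03d.xvg", seq_along(dataset))
  for (i in seq_along(dataset)) {
    w <- dataset[[i]]
    t <- seq_along(w$samples)  # sample index stands in for time
    write_pullx(t, w$samples, file.path(dir, files[i]),
                title = sprintf("umbrella window %d, center %.4f nm", i, w$center))
  }
  man <- data.frame(filename = files,
                    center = vapply(dataset, `[[`, 1, "center"),
                    spring_k = vapply(dataset, `[[`, 1, "spring_k"))
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Read an umbrella dataset from a window manifest
#'
#' @param manifest_path path to a TSV with columns `filename`, `center`,
#'   `spring_k`; filenames are resolved relative to the manifest.
#' @param temperature temperature attribute attached to the dataset (K).
#' @return an `umbrella_dataset`.
#' @export
read_umbrella_dataset <- function(manifest_path, temperature = 310) {
  man <- read.table(manifest_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("filename", "center", "spring_k")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  windows <- lapply(seq_len(nrow(man)), function(i) {
    xs <- read_pullx(file.path(base, man$filename[i]))$xi
    structure(list(center = man$center[i], spring_k = man$spring_k[i],
                   samples = xs, n_samples = length(xs)),
              class = "umbrella_window")
  })
  structure(windows, class = "umbrella_dataset", temperature = temperature)
}

#' Write / read atom-pairwise force records
#'
#' TSV with columns `frame`, `atom_i`, `atom_j`, `fx`, `fy`, `fz`
#' (forces in kJ/mol/nm).  A documented superset is accepted on reading: a
#' single signed scalar column `f` is expanded to `(f, 0, 0)`.
#'
#' @param records data.frame of pairwise force records.
#' @param path file path.
#' @return `path` (write) or the records data.frame (read).
#' @export
write_pairforce_tsv <- function(records, path) {
  need <- c("frame", "atom_i", "atom_j", "fx", "fy", "fz")
  stopifnot(all(need %in% names(records)))
  write.table(records[, need], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_pairforce_tsv
#' @export
read_pairforce_tsv <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("fx", "fy", "fz") %in% names(dat)) && "f" %in% names(dat)) {
    dat$fx <- dat$f; dat$fy <- 0; dat$fz <- 0
  }
  need <- c("frame", "atom_i", "atom_j", "fx", "fy", "fz")
  if (!all(need %in% names(dat))) {
    stop("pairwise-force table must have columns: ",
         paste(need, collapse = ", "), " (or a scalar column 'f')")
  }
  dat[, need]
}

#' Write a PMF profile as TSV
#'
#' Columns `xi` (nm), `W` (kJ/mol), `stderr` (kJ/mol; NA when no bootstrap
#' was run).
#'
#' @param profile a `pmf_profile` object.
#' @param path file path.
#' @export
write_pmf_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  out <- data.frame(xi = profile$bin_centers, W = profile$W,
                    stderr = if (is.null(profile$stderr)) NA_real_ else profile$stderr)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
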