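#' Write umbrella windows as pull-style XVG files
#'
#' Writes one pair of two-column time-series files per window in the
#' Gromacs pull XVG dialect (`#`/`@` comment headers, whitespace
#' separated rows): `pullx_<i>_<r>.xvg` with positions (nm) and
#' `pullf_<i>_<r>.xvg` with forces (kJ/mol/nm), plus a
#' `manifest.json` recording centres, spring constants, the sampling
#' timestep and file names.
#'
#' @param windows A `window_set` tibble.
#' @param dir Output directory (created if needed).
#' @param forces Also write `pullf` files (default TRUE).
#' @return Invisibly, the manifest as a list.
#' @export
write_pull_xvg <- function(windows, dir, forces = TRUE) {
  check_window_set(windows)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- windows |>
    dplyr::distinct(.data$center, .data$spring, .data$replicate) |>
    dplyr::arrange(.data$replicate, .data$center) |>
    dplyr::mutate(idx = dplyr::row_number())
  dt <- window_dt(windows[windows$center == meta$center[1] &
                            windows$replicate == meta$replicate[1], ])
  entries <- purrr::pmap(meta, function(center, spring, replicate, idx) {
    w <- windows[windows$center == center &
                   windows$replicate == replicate, ]
    fx <- sprintf("pullx_%03d_%s.xvg", idx, replicate)
    write_xvg(file.path(dir, fx), w$time, w$position,
              title = "Pull COM", ylab = "Position (nm)")
    ff <- NULL
    if (forces && !all(is.na(w$force))) {
      ff <- sprintf("pullf_%03d_%s.xvg", idx, replicate)
      write_xvg(file.path(dir, ff), w$time, w$force,
                title = "Pull force", ylab = "Force (kJ/mol/nm)")
    }
    list(center = center, spring = spring,
         replicate = as.character(replicate), pullx = fx, pullf = ff)
  })
  manifest <- list(timestep_between_samples = dt,
                   spacing = attr(windows, "spacing"),
                   windows = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

write_xvg <- function(path, time, value, title = "", ylab = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# written by permflux",
               sprintf("@    title \"%s\"", title),
               "@    xaxis  label \"Time (ps)\"",
               sprintf("@    yaxis  label \"%s\"", ylab)), con)
  writeLines(sprintf("%.6f\t%.8g", time, value), con)
}

read_xvg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@&]", lines) & nzchar(trimws(lines))]
  df <- read.table(text = lines)
  names(df)[1:2] <- c("time", "value")
  df
}

#' Read umbrella windows from pull-style XVG files
#'
#' Reads the `manifest.json` + `pullx`/`pullf` files written by
#' [write_pull_xvg()] (or assembled from Gromacs pull output) back
#' into a `window_set`. Windows without a force file get `NA` forces;
#' downstream diffusion estimates then fall back to the restraint
#' force.
#'
#' @param dir Directory holding `manifest.json` and XVG files.
#' @return A `window_set` tibble.
#' @export
read_pull_xvg <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("No manifest.json in '%s'.", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  out <- purrr::map(manifest$windows, function(e) {
    x <- read_xvg(file.path(dir, e$pullx))
    f <- if (!is.null(e$pullf)) {
      read_xvg(file.path(dir, e$pullf))$value
    } else rep(NA_real_, nrow(x))
    tibble::tibble(center = e$center, spring = e$spring,
                   replicate = e$replicate, time = x$time,
                   position = x$value, force = f)
  })
  new_window_set(dplyr::bind_rows(out),
                 spacing = manifest$spacing %||% NA_real_)
}

#' Write a 3-column profile as plain text
#'
#' @param profile A `pmf_profile`, `diffusion_profile` or
#'   `resistance_profile` tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}
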