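#' Build an unmerged data set
#'
#' An unmerged data set is a tibble of individual intensity observations
#' (`h`, `k`, `l`, `i_obs`, `sig_i`, `dataset_id`, `seq`) carrying the unit
#' cell, Sohncke space group and (optionally) wavelength as attributes. The
#' observation order is significant: splitting into sub-data sets assumes
#' symmetry-related measurements are grouped in order of measurement, so
#' `seq` records file order and is never re-sorted implicitly.
#'
#' @param observations Data frame with columns `h`, `k`, `l`, `i_obs`,
#'   `sig_i`, and optionally `dataset_id` (defaults to `"ds1"`).
#' @param cell A [unit_cell()].
#' @param spacegroup Sohncke space-group symbol or number.
#' @param wavelength Wavelength in angstroms, or `NA`.
#' @return A tibble of class `anomsig_unmerged`.
#' @export
unmerged_dataset <- function(observations, cell, spacegroup, wavelength = NA_real_) {
  obs <- as_tibble(observations)
  req <- c("h", "k", "l", "i_obs", "sig_i")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols)) {
    abort(paste0("observations lack required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"dataset_id" %in% names(obs)) obs$dataset_id <- "ds1"
  if (any(obs$sig_i < 0, na.rm = TRUE)) abort("sig_i must be non-negative")
  sg <- sg_ops(spacegroup)  # validates
  obs$seq <- seq_len(nrow(obs))
  structure(obs[c(req, "dataset_id", "seq")],
            class = c("anomsig_unmerged", class(obs)),
            cell = cell, spacegroup = sg$name, wavelength = wavelength)
}

#' @export
print.anomsig_unmerged <- function(x, ...) {
  cat(sprintf("Unmerged reflection data: %d observations, %d data set(s), %s\n",
              nrow(x), length(unique(x$dataset_id)), attr(x, "spacegroup")))
  print(attr(x, "cell"))
  NextMethod()
}

#' Accessors for reflection-data attributes
#' @param x An `anomsig_unmerged` or merged-data object.
#' @return The unit cell, space-group name, or wavelength.
#' @export
get_cell <- function(x) attr(x, "cell")

#' @rdname get_cell
#' @export
get_spacegroup <- function(x) attr(x, "spacegroup")

#' @rdname get_cell
#' @export
get_wavelength <- function(x) attr(x, "wavelength")

#' Intensity/amplitude conversion
#'
#' Intensities are converted to amplitudes by `F = sqrt(max(I, 0))`
#' (negative intensities are set to zero) and back by squaring. The
#' amplitude uncertainty is propagated as `sig_F = sig_I / (2 F)`, with `F`
#' floored at `sqrt(sig_I)/2` so weak reflections do not blow up.
#'
#' @param i_obs,sig_i Intensities and their uncertainties.
#' @param f Amplitudes.
#' @return `intensity_to_amplitude` returns a tibble with `f` and `sig_f`;
#'   `amplitude_to_intensity` returns a numeric vector of intensities.
#' @export
intensity_to_amplitude <- function(i_obs, sig_i = NULL) {
  f <- sqrt(pmax(i_obs, 0))
  if (is.null(sig_i)) return(tibble(f = f, sig_f = NA_real_))
  denom <- 2 * pmax(f, sqrt(pmax(sig_i, 0)) / 2)
  sig_f <- ifelse(denom > 0, sig_i / denom, 0)
  tibble(f = f, sig_f = sig_f)
}

#' @rdname intensity_to_amplitude
#' @export
amplitude_to_intensity <- function(f) f^2

#' Read and write unmerged reflection files
#'
#' The native format is a whitespace-separated text table
#' (`h k l i_obs sig_i dataset_id`) preceded by comment headers recording the
#' cell, space group, wavelength and the ASU convention. Observation order is
#' preserved exactly; duplicate records are retained (merging is always an
#' explicit step).
#'
#' @param path File path.
#' @return [read_unmerged()] returns an `anomsig_unmerged` tibble.
#' @export
read_unmerged <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^#\\s*", name, ":"), "", m[1]))
  }
  cell_str <- get_field("cell")
  if (is.null(cell_str)) abort(sprintf("%s: missing '# cell:' header", path))
  cp <- as.numeric(strsplit(cell_str, "\\s+")[[1]])
  if (length(cp) != 6 || any(is.na(cp))) abort(sprintf("%s: malformed cell header", path))
  sg <- get_field("spacegroup")
  if (is.null(sg)) abort(sprintf("%s: missing '# spacegroup:' header", path))
  wl <- get_field("wavelength")
  wl <- if (is.null(wl)) NA_real_ else as.numeric(wl)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lapply(body_idx, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 5) abort(sprintf("%s: malformed record at line %d", path, i))
    num <- suppressWarnings(as.numeric(tok[1:5]))
    if (any(is.na(num))) abort(sprintf("%s: malformed record at line %d", path, i))
    tibble(h = as.integer(num[1]), k = as.integer(num[2]), l = as.integer(num[3]),
           i_obs = num[4], sig_i = num[5],
           dataset_id = if (length(tok) >= 6) tok[6] else "ds1")
  })
  obs <- list_rbind(rows)
  unmerged_dataset(obs, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]),
                   sg, wl)
}

#' @rdname read_unmerged
#' @param data An `anomsig_unmerged` tibble (for [write_unmerged()]) or a
#'   merged-data tibble (for [write_merged()]).
#' @export
write_unmerged <- function(data, path) {
  cell <- get_cell(data)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# anomsig unmerged reflections",
    sprintf("# cell: %.6g %.6g %.6g %.6g %.6g %.6g",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    sprintf("# spacegroup: %s", get_spacegroup(data)),
    if (!is.na(get_wavelength(data))) sprintf("# wavelength: %.6g", get_wavelength(data)),
    "# asu_convention: lexicographically-greatest image",
    "# columns: h k l i_obs sig_i dataset_id"
  ), con)
  writeLines(sprintf("%d %d %d %.8g %.8g %s",
                     data$h, data$k, data$l, data$i_obs, data$sig_i,
                     data$dataset_id), con)
  invisible(path)
}

#' @rdname read_unmerged
#' @export
write_merged <- function(data, path) {
  cell <- get_cell(data)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# anomsig merged anomalous data",
    sprintf("# cell: %.6g %.6g %.6g %.6g %.6g %.6g",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    sprintf("# spacegroup: %s", get_spacegroup(data)),
    "# asu_convention: lexicographically-greatest image",
    "# columns: h k l d f_plus sig_plus f_minus sig_minus n_obs"
  ), con)
  writeLines(sprintf("%d %d %d %.6g %.8g %.8g %.8g %.8g %d",
                     data$h, data$k, data$l, data$d, data$f_plus, data$sig_plus,
                     data$f_minus, data$sig_minus, data$n_obs), con)
  invisible(path)
}

#' @rdname read_unmerged
#' @export
read_merged <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  cell_line <- grep("^#\\s*cell:", hdr, value = TRUE)
  if (!length(cell_line)) abort(sprintf("%s: missing '# cell:' header", path))
  cp <- as.numeric(strsplit(trimws(sub("^#\\s*cell:", "", cell_line[1])), "\\s+")[[1]])
  sg <- trimws(sub("^#\\s*spacegroup:", "", grep("^#\\s*spacegroup:", hdr, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  out <- tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]), l = as.integer(m[, 3]),
                d = m[, 4], f_plus = m[, 5], sig_plus = m[, 6],
                f_minus = m[, 7], sig_minus = m[, 8], n_obs = as.integer(m[, 9]))
  new_merged(out, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]), sg)
}

#' Construct merged anomalous data
#'
#' One row per unique acentric ASU reflection, with Bijvoet amplitudes
#' `f_plus`/`f_minus` and their uncertainties. The mean amplitude
#' `f_mean = (f_plus + f_minus)/2` and the anomalous difference
#' `dano = f_plus - f_minus` are derived columns kept consistent with the
#' amplitudes.
#'
#' @param data Tibble with at least `h`, `k`, `l`, `d`, `f_plus`, `sig_plus`,
#'   `f_minus`, `sig_minus`, `n_obs`.
#' @param cell,spacegroup Crystal metadata.
#' @return A tibble of class `anomsig_merged` with derived columns `f_mean`,
#'   `dano` and `sig_dano`.
#' @export
new_merged <- function(data, cell, spacegroup) {
  data <- as_tibble(data)
  data$f_mean <- (data$f_plus + data$f_minus) / 2
  data$dano <- data$f_plus - data$f_minus
  data$sig_dano <- sqrt(data$sig_plus^2 + data$sig_minus^2)
  structure(data, class = c("anomsig_merged", class(data)),
            cell = cell, spacegroup = spacegroup)
}

#' @export
print.anomsig_merged <- function(x, ...) {
  cat(sprintf("Merged anomalous data: %d unique acentric reflections, %s, d_min %.2f A\n",
              nrow(x), attr(x, "spacegroup"), min(x$d)))
  NextMethod()
}
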