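# The binned energy spectrum: particles per incident proton per energy bin.
# This tibble is the lingua franca passed between the beam, nano-target,
# dose and damage stages.

#' Construct a binned energy spectrum
#'
#' @param bin_edges Strictly increasing bin edges in MeV (length n + 1).
#' @param fluence Particles per incident proton per bin (length n, >= 0).
#' @param particle Particle id (`"alpha"`, `"proton"`, ...).
#' @param counts Optional raw sampled counts per bin (for counting
#'   statistics); defaults to `NA`.
#' @param n_protons Number of incident protons the fluence is normalised to.
#' @param seed Seed used to generate the spectrum, if stochastic.
#' @return A tibble of class `energy_spectrum` with columns `bin_low`,
#'   `bin_high`, `fluence`, `count`.
#' @export
#' @examples
#' energy_spectrum(0:3, c(0.1, 0.5, 0.2), particle = "alpha")
energy_spectrum <- function(bin_edges, fluence, particle,
                            counts = NULL, n_protons = NA_real_,
                            seed = NA_integer_) {
  if (any(diff(bin_edges) <= 0)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  if (length(fluence) != length(bin_edges) - 1) {
    abort("`fluence` must have one entry per bin (length(bin_edges) - 1).")
  }
  if (any(fluence < 0)) abort("`fluence` must be non-negative in every bin.")
  if (is.null(counts)) counts <- rep(NA_real_, length(fluence))
  out <- tibble(
    bin_low = head(bin_edges, -1), bin_high = tail(bin_edges, -1),
    fluence = as.numeric(fluence), count = as.numeric(counts)
  )
  structure(out, particle = particle, n_protons = n_protons, seed = seed,
            class = c("energy_spectrum", class(out)))
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum: %s, %d bins over [%g, %g] MeV, total %.4g/proton>\n",
              attr(x, "particle"), nrow(x), min(x$bin_low), max(x$bin_high),
              sum(x$fluence)))
  NextMethod()
}

#' Bin centers of an energy spectrum
#'
#' @param spectrum An [energy_spectrum()].
#' @return Numeric vector of bin mid-energies in MeV.
#' @export
bin_centers <- function(spectrum) (spectrum$bin_low + spectrum$bin_high) / 2

# shared bin grids
alpha_bin_edges  <- function() seq(0, 15, by = 1)
proton_bin_edges <- function() seq(0, 33, by = 1)

# histogram energies (optionally weighted) onto a bin grid
bin_fluence <- function(energies, weights, edges) {
  idx <- findInterval(energies, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(edges) - 1
  w <- vapply(seq_len(length(edges) - 1), function(i) {
    sum(weights[ok & idx == i])
  }, numeric(1))
  n <- tabulate(idx[ok], nbins = length(edges) - 1)
  list(fluence = w, count = n)
}

#' Write / read an energy spectrum as delimited text
#'
#' The file starts with `#key=value` header lines (`particle`, `n_protons`,
#' `seed`) followed by a tab-separated table `bin_low`, `bin_high`,
#' `fluence`, `count`.
#'
#' @param spectrum An [energy_spectrum()].
#' @param path File path.
#' @return `write_energy_spectrum()` returns `path` invisibly;
#'   `read_energy_spectrum()` returns the spectrum.
#' @export
write_energy_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  hdr <- c(
    sprintf("#particle=%s", attr(spectrum, "particle")),
    sprintf("#n_protons=%s", format(attr(spectrum, "n_protons"), digits = 15)),
    sprintf("#seed=%s", attr(spectrum, "seed"))
  )
  writeLines(hdr, path)
  suppressWarnings(write.table(
    as.data.frame(spectrum), path, append = TRUE, sep = "\t",
    row.names = FALSE, quote = FALSE
  ))
  invisible(path)
}

#' @rdname write_energy_spectrum
#' @export
read_energy_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^#", key, "="), "", grep(
    paste0("^#", key, "="), hdr, value = TRUE
  )[1])
  tab <- read.delim(text = lines[!grepl("^#", lines)])
  energy_spectrum(
    bin_edges = c(tab$bin_low, tab$bin_high[nrow(tab)]),
    fluence = tab$fluence, particle = get("particle"), counts = tab$count,
    n_protons = as.numeric(get("n_protons")),
    seed = suppressWarnings(as.integer(get("seed")))
  )
}
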