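#' Construct a phase specification
#'
#' A phase is a solvent (mixture) at a temperature: an ordered list of
#' component names with mole fractions summing to one.
#'
#' @param temperature kelvin, strictly positive.
#' @param components named numeric vector of mole fractions, each in (0, 1],
#'   summing to 1 within 1e-6.
#' @return an object of class `phase_spec`.
#' @export
phase_spec <- function(temperature, components) {
  temperature <- as.numeric(temperature)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("components must be a named vector of mole fractions", call. = FALSE)
  }
  x <- as.numeric(components)
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop("mole fractions must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-6) {
    stop("mole fractions sum to ", format(sum(x), digits = 10),
         ", not 1 (tolerance 1e-6)", call. = FALSE)
  }
  structure(list(temperature = temperature,
                 components = stats::setNames(x, names(components))),
            class = "phase_spec")
}

#' @export
print.phase_spec <- function(x, ...) {
  comp <- paste0(names(x$components), " (",
                 format(x$components, digits = 4), ")", collapse = ", ")
  cat("<phase_spec> ", x$temperature, " K: ", comp, "\n", sep = "")
  invisible(x)
}

#' Read phase definitions from a tab-separated file
#'
#' One phase per line: the first column is the temperature in kelvin, each
#' subsequent pair of columns a component name and its mole fraction. Empty
#' lines and lines starting with `#` are ignored. Mole fractions on a line
#' must sum to 1 within 1e-6; violations are reported with the offending
#' line number rather than silently renormalized.
#'
#' @param path a UTF-8, tab-separated phase file.
#' @return a list of [phase_spec()] objects, in file order.
#' @export
read_phase_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  specs <- list()
  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    if (!nzchar(trimws(raw)) || startsWith(trimws(raw), "#")) next
    cols <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    cols <- trimws(cols)
    cols <- cols[nzchar(cols)]
    if (length(cols) < 3L || length(cols) %% 2L == 0L) {
      stop("line ", i, ": expected temperature followed by (name, fraction) ",
           "pairs, found ", length(cols), " columns", call. = FALSE)
    }
    temp <- suppressWarnings(as.numeric(cols[1L]))
    if (is.na(temp)) stop("line ", i, ": non-numeric temperature '",
                          cols[1L], "'", call. = FALSE)
    nm <- cols[seq(2L, length(cols), by = 2L)]
    fr <- suppressWarnings(as.numeric(cols[seq(3L, length(cols), by = 2L)]))
    if (anyNA(fr)) stop("line ", i, ": non-numeric mole fraction",
                        call. = FALSE)
    spec <- tryCatch(phase_spec(temp, stats::setNames(fr, nm)),
                     error = function(e) {
                       stop("line ", i, ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    specs[[length(specs) + 1L]] <- spec
  }
  specs
}

#' Write phase definitions to a tab-separated file
#'
#' Inverse of [read_phase_tsv()].
#'
#' @param specs a list of [phase_spec()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_tsv <- function(specs, path) {
  if (inherits(specs, "phase_spec")) specs <- list(specs)
  lines <- vapply(specs, function(s) {
    stopifnot(inherits(s, "phase_spec"))
    pairs <- as.vector(rbind(names(s$components),
                             format(s$components, digits = 12,
                                    scientific = FALSE, trim = TRUE)))
    paste(c(format(s$temperature, digits = 12, trim = TRUE), pairs),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
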