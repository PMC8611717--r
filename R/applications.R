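#' Solvent reorganization term of a phase
#'
#' The population-weighted mean solvation energy of the phase's own sites:
#' the free-energy cost of opening a solvent-solvent contact, entering the
#' exchange bookkeeping of the interaction profiles. Zero for an empty
#' phase.
#'
#' @param state a solved `phase_state`.
#' @return kJ mol^-1.
#' @export
solvent_reorganization_term <- function(state) {
  stopifnot(inherits(state, "phase_state"))
  if (!state$converged) {
    stop("phase state is not solved; run solve_speciation() first",
         call. = FALSE)
  }
  if (length(state$theta) == 0L) return(0)
  w <- state$theta / sum(state$theta)
  sum(w * solvation_energy(state$epsilon, state))
}

# Solute-solute exchange free energy for one probe pair in one phase:
# direct contact energy, plus the solvent-solvent contact regained, minus
# the two desolvations. Isolated here so the bookkeeping can be swapped out.
fgip_pair <- function(eps_a, eps_b, state, dg_ss = NULL) {
  cst <- state$constants
  dg_int <- cst$e_vdw + pmin(eps_a * eps_b, 0)
  if (is.null(dg_ss)) dg_ss <- solvent_reorganization_term(state)
  dg_int + dg_ss - solvation_energy(eps_a, state) -
    solvation_energy(eps_b, state)
}

#' Functional group interaction profile
#'
#' For every pair of probe sites (+alpha, -beta) on the grid, the free
#' energy change of bringing the two solutes into contact in the phase:
#' `ddG_FGI = dG_int + dG_ss - dG_solv(+alpha) - dG_solv(-beta)` where
#' `dG_int = E_vdW + min(eps_a eps_b, 0)` is the direct contact energy and
#' `dG_ss` the solvent contact regained ([solvent_reorganization_term()]).
#' Negative values mark solvent environments in which the functional-group
#' pair associates. In the gas limit every solvation term vanishes and the
#' profile reduces to `dG_int`.
#'
#' @param state a solved `phase_state`.
#' @param alpha donor probe values (epsilon = +alpha); default 0 to 5 by 0.1.
#' @param beta acceptor probe magnitudes (epsilon = -beta); default 0 to 10
#'   by 0.2.
#' @return an object of class `fgip_grid` with fields `alpha`, `beta`,
#'   `values` (length(alpha) x length(beta), kJ mol^-1), `phase` and
#'   `temperature`.
#' @export
fgip <- function(state, alpha = seq(0, 5, by = 0.1),
                 beta = seq(0, 10, by = 0.2)) {
  stopifnot(inherits(state, "phase_state"))
  if (!state$converged) {
    stop("phase state is not solved; run solve_speciation() first",
         call. = FALSE)
  }
  if (length(alpha) == 0L || length(beta) == 0L) {
    stop("probe axes must be non-empty", call. = FALSE)
  }
  cst <- state$constants
  dg_ss <- solvent_reorganization_term(state)
  dg_a <- solvation_energy(alpha, state)
  dg_b <- solvation_energy(-beta, state)
  dg_int <- cst$e_vdw + pmin(outer(alpha, -beta), 0)
  values <- dg_int + dg_ss - outer(dg_a, rep(1, length(beta))) -
    outer(rep(1, length(alpha)), dg_b)
  structure(list(alpha = alpha, beta = beta, values = values,
                 phase = state$descriptor, temperature = state$temperature),
            class = "fgip_grid")
}

#' @export
print.fgip_grid <- function(x, ...) {
  cat("<fgip_grid> ", length(x$alpha), " x ", length(x$beta),
      " probes, phase ", x$phase, " at ", x$temperature, " K\n", sep = "")
  cat("  ddG range (kJ/mol): [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Export an interaction profile
#'
#' `csv`: a long table with columns `alpha`, `beta`, `ddg` preceded by
#' `# phase:` / `# temperature:` comment lines. `json`: a structured
#' document with the axes, the value matrix (row-major by alpha) and the
#' metadata. Both round-trip losslessly through [read_fgip()].
#'
#' @param grid an `fgip_grid`.
#' @param path output path.
#' @param format `"csv"` or `"json"`; default by file extension.
#' @return `path`, invisibly.
#' @export
export_fgip <- function(grid, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(grid, "fgip_grid"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (length(grid$alpha) == 0L || length(grid$beta) == 0L) {
    stop("cannot export an empty-axes profile", call. = FALSE)
  }
  if (format == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(paste0("# phase: ", grid$phase),
                 paste0("# temperature: ",
                        format(grid$temperature, digits = 12)),
                 "alpha,beta,ddg"), con)
    long <- expand.grid(ai = seq_along(grid$alpha),
                        bi = seq_along(grid$beta))
    writeLines(sprintf("%s,%s,%s",
                       format(grid$alpha[long$ai], digits = 12, trim = TRUE),
                       format(grid$beta[long$bi], digits = 12, trim = TRUE),
                       format(grid$values[cbind(long$ai, long$bi)],
                              digits = 12, trim = TRUE)), con)
  } else {
    jsonlite::write_json(
      list(phase = grid$phase, temperature = grid$temperature,
           alpha = grid$alpha, beta = grid$beta,
           values = grid$values),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' Read an interaction profile written by [export_fgip()]
#'
#' @param path input path.
#' @param format `"csv"`, `"json"` or `"auto"` (by extension).
#' @return an `fgip_grid`.
#' @export
read_fgip <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    meta <- lines[startsWith(lines, "#")]
    phase <- sub("^# phase: ", "", meta[startsWith(meta, "# phase:")])
    temp <- as.numeric(sub("^# temperature: ", "",
                           meta[startsWith(meta, "# temperature:")]))
    tab <- utils::read.csv(text = lines[!startsWith(lines, "#")])
    alpha <- sort(unique(tab$alpha))
    beta <- sort(unique(tab$beta))
    values <- matrix(NA_real_, length(alpha), length(beta))
    values[cbind(match(tab$alpha, alpha), match(tab$beta, beta))] <- tab$ddg
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    phase <- doc$phase
    temp <- doc$temperature
    alpha <- doc$alpha
    beta <- doc$beta
    values <- if (is.matrix(doc$values)) doc$values
              else matrix(as.numeric(doc$values), length(alpha),
                          length(beta), byrow = TRUE)
  }
  structure(list(alpha = alpha, beta = beta, values = values,
                 phase = phase, temperature = temp),
            class = "fgip_grid")
}

#' Solvent similarity index
#'
#' Two phases are compared through their solvation-energy profiles
#' `D_P(eps) = dG_solv(eps | P)` over a grid of idealized probe sites
#' (default epsilon from -10 to +5 in steps of 0.1, covering strong
#' acceptors through strong donors). The index is the uncentered cosine
#' similarity of the two profiles: 1 for identical solvation behaviour,
#' decreasing as the profiles diverge. Two empty (gas) phases are defined
#' to have similarity 1.
#'
#' @param state1,state2 solved `phase_state`s at the same temperature.
#' @param eps_grid probe grid.
#' @return an object of class `ssi_result` with fields `value`, `eps_grid`
#'   and `phases`.
#' @export
ssi <- function(state1, state2, eps_grid = seq(-10, 5, by = 0.1)) {
  if (abs(state1$temperature - state2$temperature) > 1e-9) {
    stop("phases are at different temperatures (", state1$temperature,
         " vs ", state2$temperature, " K)", call. = FALSE)
  }
  d1 <- solvation_energy(eps_grid, state1)
  d2 <- solvation_energy(eps_grid, state2)
  n1 <- sqrt(sum(d1^2))
  n2 <- sqrt(sum(d2^2))
  value <- if (n1 == 0 && n2 == 0) 1
           else if (n1 == 0 || n2 == 0) 0
           else sum(d1 * d2) / (n1 * n2)
  structure(list(value = value, eps_grid = eps_grid,
                 phases = c(state1$descriptor, state2$descriptor)),
            class = "ssi_result")
}

#' @export
print.ssi_result <- function(x, ...) {
  cat("<ssi_result> SSI(", x$phases[1], ", ", x$phases[2], ") = ",
      signif(x$value, 6), "\n", sep = "")
  invisible(x)
}
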