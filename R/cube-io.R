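#' Read a Gaussian cube file
#'
#' Parses the standard cube layout: two comment lines; a line with the atom
#' count and grid origin; three axis lines (node count + step vector); one
#' line per atom; then the scalar values, up to six per line, with the first
#' grid index slowest and the third fastest. All geometry is in bohr.
#'
#' A negative atom count is accepted: some dialects use it to flag an extra
#' header line (field identifiers) between the atom block and the values.
#' That line is consumed and the `dset_ids` attribute on the returned grid
#' records it.
#'
#' @param path path to a cube file.
#' @return a [volumetric_grid()].
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  need <- function(i, what) {
    if (i > length(lines)) {
      stop("cube file truncated at line ", i, ": expected ", what,
           call. = FALSE)
    }
    lines[[i]]
  }
  numbers <- function(i, what) {
    toks <- strsplit(trimws(need(i, what)), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) == 0L || anyNA(vals)) {
      stop("cube parse error at line ", i, " (", what, "): non-numeric token",
           call. = FALSE)
    }
    vals
  }

  title <- paste(need(1L, "comment"), need(2L, "comment"))
  hdr <- numbers(3L, "atom count and origin")
  if (length(hdr) < 4L) stop("cube parse error at line 3: need N and origin",
                             call. = FALSE)
  natoms_raw <- as.integer(hdr[1L])
  dset_dialect <- natoms_raw < 0L
  natoms <- abs(natoms_raw)
  origin <- hdr[2:4]

  counts <- integer(3L)
  axes <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    ax <- numbers(3L + i, paste0("axis ", i))
    if (length(ax) < 4L) stop("cube parse error at line ", 3L + i,
                              ": need count and step vector", call. = FALSE)
    counts[i] <- abs(as.integer(ax[1L]))
    axes[i, ] <- ax[2:4]
  }

  atoms <- data.frame(number = integer(natoms), charge = numeric(natoms),
                      x = numeric(natoms), y = numeric(natoms),
                      z = numeric(natoms))
  for (a in seq_len(natoms)) {
    at <- numbers(6L + a, paste0("atom ", a))
    if (length(at) < 5L) stop("cube parse error at line ", 6L + a,
                              ": need Z, charge, x, y, z", call. = FALSE)
    atoms[a, ] <- list(as.integer(at[1L]), at[2L], at[3L], at[4L], at[5L])
  }

  cursor <- 6L + natoms
  dset_ids <- NULL
  if (dset_dialect) {
    cursor <- cursor + 1L
    dset_ids <- numbers(cursor, "data set identifier line")
  }

  n_expected <- prod(counts)
  vals <- numeric(0)
  i <- cursor
  while (length(vals) < n_expected) {
    i <- i + 1L
    if (i > length(lines)) {
      stop("cube file truncated at line ", i, ": expected ", n_expected,
           " values, found ", length(vals), call. = FALSE)
    }
    if (!nzchar(trimws(lines[[i]]))) next
    vals <- c(vals, numbers(i, "grid values"))
  }
  if (length(vals) != n_expected) {
    stop("cube value count mismatch: expected ", n_expected, ", found ",
         length(vals), call. = FALSE)
  }

  # file order is x slowest / z fastest; store as values[ix, iy, iz]
  arr <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))
  grid <- volumetric_grid(origin, axes, arr, atoms)
  attr(grid, "title") <- trimws(title)
  attr(grid, "dset_ids") <- dset_ids
  grid
}

#' Write a Gaussian cube file
#'
#' Emits the standard layout (see [read_cube()]); values are written with six
#' significant figures, six per line, so a write/read round trip reproduces
#' the grid to that precision.
#'
#' @param grid a [volumetric_grid()].
#' @param path output path.
#' @param comment one or two comment lines for the header.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, comment = "generated by ssipr") {
  stopifnot(inherits(grid, "volumetric_grid"))
  comment <- rep_len(as.character(comment), 2L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt3 <- function(x) sprintf("%12.6f", x)
  writeLines(comment, con)
  writeLines(sprintf("%5d%s%s%s", nrow(grid$atoms),
                     fmt3(grid$origin[1]), fmt3(grid$origin[2]),
                     fmt3(grid$origin[3])), con)
  for (i in 1:3) {
    writeLines(sprintf("%5d%s%s%s", grid$counts[i],
                       fmt3(grid$axes[i, 1]), fmt3(grid$axes[i, 2]),
                       fmt3(grid$axes[i, 3])), con)
  }
  for (a in seq_len(nrow(grid$atoms))) {
    writeLines(sprintf("%5d%s%s%s%s", grid$atoms$number[a],
                       fmt3(grid$atoms$charge[a]), fmt3(grid$atoms$x[a]),
                       fmt3(grid$atoms$y[a]), fmt3(grid$atoms$z[a])), con)
  }
  # back to file order: x slowest, z fastest
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))
  full <- length(vals) %/% 6L
  if (full > 0L) {
    block <- matrix(sprintf("%13.5E", vals[seq_len(full * 6L)]), ncol = 6L,
                    byrow = TRUE)
    writeLines(apply(block, 1L, paste0, collapse = ""), con)
  }
  rest <- vals[seq_len(length(vals)) > full * 6L]
  if (length(rest) > 0L) {
    writeLines(paste0(sprintf("%13.5E", rest), collapse = ""), con)
  }
  invisible(path)
}
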