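#' Construct a molecular structure
#'
#' Minimal 3-d structure container: element symbols and cartesian positions
#' in angstrom, plus a net charge and a free-text title.
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` (angstrom).
#' @param charge integer net charge.
#' @param title text label.
#' @return an object of class `molecule_structure`.
#' @export
molecule_structure <- function(atoms, charge = 0L, title = "") {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) < 1L) stop("a structure needs at least one atom",
                             call. = FALSE)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("atom positions must be finite",
                                 call. = FALSE)
  atoms$element <- canonical_element(atoms$element)
  structure(list(atoms = atoms, charge = as.integer(charge),
                 title = as.character(title)),
            class = "molecule_structure")
}

#' @export
print.molecule_structure <- function(x, ...) {
  cat("<molecule_structure> ", nrow(x$atoms), " atoms",
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n", sep = "")
  invisible(x)
}

#' Read a molecular structure from XYZ or minimal CML
#'
#' Two input dialects are supported: plain XYZ (count line, comment line,
#' then `element x y z` records in angstrom) and a minimal CML subset
#' (`molecule`/`atomArray`/`atom` nodes with `elementType` and `x3`/`y3`/`z3`
#' attributes, namespaces ignored). Element symbols are canonicalized and
#' validated.
#'
#' @param path input file.
#' @param format one of `"auto"` (by extension), `"xyz"`, `"cml"`.
#' @return a [molecule_structure()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "cml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cml|xml)$", path, ignore.case = TRUE)) "cml"
              else "xyz"
  }
  if (format == "xyz") read_xyz(path) else read_cml(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error: first line must be the atom count", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("XYZ atom count mismatch: declared ", n, ", found ", length(body),
         call. = FALSE)
  }
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 1L) < 4L)) {
    stop("XYZ parse error: each atom line needs element and x y z",
         call. = FALSE)
  }
  el <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[2:4]))
    if (anyNA(v)) stop("XYZ parse error: non-numeric coordinate",
                       call. = FALSE)
    v
  }, numeric(3L)))
  title <- if (length(lines) >= 2L) trimws(lines[[2L]]) else ""
  molecule_structure(
    data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    title = title
  )
}

read_cml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed CML/XML: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  atom_nodes <- xml2::xml_find_all(doc, ".//atomArray/atom")
  if (length(atom_nodes) == 0L) {
    stop("CML file contains no atomArray/atom nodes", call. = FALSE)
  }
  num <- function(attr) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(atom_nodes, attr)))
    if (anyNA(v)) stop("CML atom missing numeric attribute '", attr, "'",
                       call. = FALSE)
    v
  }
  el <- xml2::xml_attr(atom_nodes, "elementType")
  if (anyNA(el)) stop("CML atom missing elementType attribute", call. = FALSE)
  mol <- xml2::xml_find_first(doc, ".//molecule | /molecule")
  title <- xml2::xml_attr(mol, "title")
  chg <- suppressWarnings(as.integer(xml2::xml_attr(mol, "formalCharge")))
  molecule_structure(
    data.frame(element = el, x = num("x3"), y = num("y3"), z = num("z3")),
    charge = if (is.na(chg)) 0L else chg,
    title = if (is.na(title)) "" else title
  )
}
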