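#' Construct a set of surface site interaction points
#'
#' An SSIP set is a molecule's coarse-grained interaction description: one
#' site per equal-area surface footprint, each carrying a position (angstrom)
#' and a signed interaction parameter epsilon. Positive epsilon plays the
#' role of a hydrogen-bond donor parameter (alpha), negative epsilon of an
#' acceptor parameter (-beta); epsilon^2 is a molar energy, so epsilon has
#' units (kJ mol^-1)^(1/2).
#'
#' @param sites data frame with columns `x`, `y`, `z` (angstrom), `epsilon`,
#'   and optionally `area` (angstrom^2 footprint) and `meps` (the surface
#'   potential the site was calibrated from, kJ mol^-1).
#' @param title molecule label.
#' @param total_surface_area total surface area the set covers (angstrom^2);
#'   defaults to the sum of site footprints.
#' @param config optional [footprint_config()] snapshot recording how the set
#'   was generated.
#' @return an object of class `ssip_set`.
#' @export
ssip_set <- function(sites, title = "", total_surface_area = NULL,
                     config = NULL) {
  stopifnot(is.data.frame(sites))
  required <- c("x", "y", "z", "epsilon")
  if (!all(required %in% names(sites))) {
    stop("`sites` needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!("area" %in% names(sites))) sites$area <- rep(NA_real_, nrow(sites))
  if (!("meps" %in% names(sites))) sites$meps <- rep(NA_real_, nrow(sites))
  if (any(!is.na(sites$area) & sites$area <= 0)) {
    stop("footprint areas must be positive", call. = FALSE)
  }
  known <- !is.na(sites$meps)
  if (any(sign(sites$epsilon[known]) * sign(sites$meps[known]) < 0)) {
    stop("epsilon must carry the sign of the surface potential it came from",
         call. = FALSE)
  }
  if (is.null(total_surface_area)) {
    total_surface_area <- sum(sites$area, na.rm = TRUE)
  }
  structure(list(sites = sites, title = as.character(title),
                 total_surface_area = total_surface_area, config = config),
            class = "ssip_set")
}

#' @export
print.ssip_set <- function(x, ...) {
  n <- nrow(x$sites)
  cat("<ssip_set> ", n, " sites",
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n", sep = "")
  if (n > 0L) {
    cat("  epsilon: ", sum(x$sites$epsilon > 0), " positive, ",
        sum(x$sites$epsilon < 0), " negative, ",
        sum(x$sites$epsilon == 0), " zero\n", sep = "")
    cat("  surface area: ", signif(x$total_surface_area, 5),
        " angstrom^2\n", sep = "")
  }
  invisible(x)
}

#' @export
length.ssip_set <- function(x) nrow(x$sites)

#' Write an SSIP set to XML
#'
#' The dialect is a documented minimal schema: a `ssipMolecule` root with an
#' optional `atomArray` (CML-style atoms, angstrom) and a `ssipArray` whose
#' `ssip` children carry `x3`, `y3`, `z3`, `epsilon` and optionally `area`
#' and `meps` attributes. [read_ssip_xml()] inverts it.
#'
#' @param ssips a [ssip_set()].
#' @param path output path.
#' @param structure optional [molecule_structure()] whose atoms are embedded.
#' @return `path`, invisibly.
#' @export
write_ssip_xml <- function(ssips, path, structure = NULL) {
  stopifnot(inherits(ssips, "ssip_set"))
  doc <- xml2::xml_new_root("ssipMolecule", title = ssips$title)
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "molecule_structure"))
    aa <- xml2::xml_add_child(doc, "atomArray")
    for (i in seq_len(nrow(structure$atoms))) {
      xml2::xml_add_child(aa, "atom",
                          elementType = structure$atoms$element[i],
                          x3 = format(structure$atoms$x[i], digits = 10),
                          y3 = format(structure$atoms$y[i], digits = 10),
                          z3 = format(structure$atoms$z[i], digits = 10))
    }
  }
  sa <- xml2::xml_add_child(doc, "ssipArray",
                            surfaceArea = format(ssips$total_surface_area,
                                                 digits = 10))
  s <- ssips$sites
  for (i in seq_len(nrow(s))) {
    node <- xml2::xml_add_child(sa, "ssip",
                                x3 = format(s$x[i], digits = 10),
                                y3 = format(s$y[i], digits = 10),
                                z3 = format(s$z[i], digits = 10),
                                epsilon = format(s$epsilon[i], digits = 10))
    if (!is.na(s$area[i])) {
      xml2::xml_set_attr(node, "area", format(s$area[i], digits = 10))
    }
    if (!is.na(s$meps[i])) {
      xml2::xml_set_attr(node, "meps", format(s$meps[i], digits = 10))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SSIP set from XML
#'
#' @param path a file written by [write_ssip_xml()] or matching its dialect.
#' @return a [ssip_set()]; the embedded atoms, if any, are attached as the
#'   `structure` attribute.
#' @export
read_ssip_xml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//ssipArray/ssip")
  num_attr <- function(attr, required = TRUE) {
    raw <- xml2::xml_attr(nodes, attr)
    if (required && anyNA(raw)) {
      stop("ssip element ", which(is.na(raw))[1L], " is missing the '",
           attr, "' attribute", call. = FALSE)
    }
    suppressWarnings(as.numeric(raw))
  }
  sites <- data.frame(
    x = num_attr("x3"), y = num_attr("y3"), z = num_attr("z3"),
    epsilon = num_attr("epsilon"),
    area = num_attr("area", required = FALSE),
    meps = num_attr("meps", required = FALSE)
  )
  arr <- xml2::xml_find_first(doc, ".//ssipArray")
  total <- suppressWarnings(as.numeric(xml2::xml_attr(arr, "surfaceArea")))
  title <- xml2::xml_attr(xml2::xml_root(doc), "title")
  out <- ssip_set(sites, title = if (is.na(title)) "" else title,
                  total_surface_area = if (is.na(total)) NULL else total)
  atom_nodes <- xml2::xml_find_all(doc, ".//atomArray/atom")
  if (length(atom_nodes) > 0L) {
    attr(out, "structure") <- molecule_structure(data.frame(
      element = xml2::xml_attr(atom_nodes, "elementType"),
      x = as.numeric(xml2::xml_attr(atom_nodes, "x3")),
      y = as.numeric(xml2::xml_attr(atom_nodes, "y3")),
      z = as.numeric(xml2::xml_attr(atom_nodes, "z3"))
    ))
  }
  out
}
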