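test_that("cube files round-trip geometry and values", {
  set.seed(11)
  vals <- array(exp(stats::rnorm(8 * 8 * 8)), dim = c(8, 8, 8))
  atoms <- data.frame(number = c(8L, 1L, 1L), charge = c(8, 1, 1),
                      x = c(0, 1.8, -1.8), y = c(0, 1.2, 1.2), z = 0)
  grid <- volumetric_grid(c(-2, -2, -2), diag(0.5, 3), vals, atoms)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, path)
  back <- read_cube(path)
  expect_equal(back$origin, grid$origin, tolerance = 1e-6)
  expect_equal(back$axes, grid$axes, tolerance = 1e-6)
  expect_equal(back$counts, grid$counts)
  expect_equal(nrow(back$atoms), 3L)
  expect_lt(max(abs(back$values - grid$values) / max(abs(grid$values))),
            1e-5)
})

test_that("negative atom counts flag the extra-header dialect and parse to the same grid", {
  vals <- array(seq_len(8) / 10, dim = c(2, 2, 2))
  grid <- volumetric_grid(c(0, 0, 0), diag(1, 3),
                          vals,
                          data.frame(number = 1L, charge = 1,
                                     x = 0, y = 0, z = 0))
  plain <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, plain)
  lines <- readLines(plain)
  # flip the atom count negative and insert the data-set id line
  lines[3] <- sub("^\\s*1", "   -1", lines[3])
  dialect <- withr::local_tempfile(fileext = ".cube")
  writeLines(append(lines, "    1    1", after = 7L), dialect)

  a <- read_cube(plain)
  b <- read_cube(dialect)
  expect_null(attr(a, "dset_ids"))
  expect_equal(attr(b, "dset_ids"), c(1, 1))
  expect_equal(b$values, a$values)
  expect_equal(b$origin, a$origin)
})

test_that("malformed cube files fail with the line and the counts", {
  vals <- array(seq_len(8), dim = c(2, 2, 2))
  grid <- volumetric_grid(c(0, 0, 0), diag(1, 3), vals)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, path)

  # exactly 8 data tokens for a 2x2x2 grid
  lines <- readLines(path)
  toks <- unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))
  expect_length(toks, 8L)

  # one value short -> truncation error citing expected vs found
  short <- withr::local_tempfile()
  writeLines(c(lines[1:6], paste(toks[1:7], collapse = " ")), short)
  expect_error(read_cube(short), "expected 8 values, found 7")

  # non-numeric token
  bad <- withr::local_tempfile()
  writeLines(c(lines[1:6], "1 2 three 4 5 6 7 8"), bad)
  expect_error(read_cube(bad), "non-numeric")
})

test_that("cube writer accepts an empty atom list", {
  grid <- volumetric_grid(c(0, 0, 0), diag(1, 3),
                          array(stats::runif(27), dim = c(3, 3, 3)))
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, path)
  back <- read_cube(path)
  expect_equal(nrow(back$atoms), 0L)
  expect_equal(back$counts, c(3L, 3L, 3L))
})

test_that("XYZ structures parse with canonical elements and strict counts", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0.0 0.0 0.117", "h 0.757 0.0 -0.468",
               "H -0.757 0.0 -0.468"), path)
  mol <- read_structure(path)
  expect_equal(mol$atoms$element, c("O", "H", "H"))
  expect_equal(mol$title, "water")

  writeLines(c("4", "broken", "O 0 0 0", "H 1 0 0", "H -1 0 0"), path)
  expect_error(read_structure(path), "count mismatch")

  writeLines(c("1", "", "Xq 0 0 0"), path)
  expect_error(read_structure(path), "unknown element")
})

test_that("minimal CML structures parse positions and charge", {
  path <- withr::local_tempfile(fileext = ".cml")
  writeLines(c('<molecule title="probe" formalCharge="0">',
               '  <atomArray>',
               '    <atom elementType="C" x3="0.0" y3="0.0" z3="0.0"/>',
               '    <atom elementType="O" x3="1.21" y3="0.0" z3="0.0"/>',
               '  </atomArray>',
               '</molecule>'), path)
  mol <- read_structure(path)
  expect_equal(nrow(mol$atoms), 2L)
  expect_equal(unlist(mol$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(mol$title, "probe")

  writeLines("<molecule><atomArray></atomArray>", path)
  expect_error(read_structure(path, format = "cml"), "malformed")
})

test_that("SSIP XML round-trips sites, atoms and epsilon to 6 decimals", {
  w <- make_water_like_sample()
  set <- footprint(w, title = "waterlike")
  mol <- molecule_structure(data.frame(element = c("O", "H", "H"),
                                       x = c(0, 0.76, -0.76),
                                       y = c(0, 0.59, 0.59), z = 0))
  path <- withr::local_tempfile(fileext = ".xml")
  write_ssip_xml(set, path, structure = mol)

  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "//ssip"), 4L)

  back <- read_ssip_xml(path)
  expect_equal(back$sites$epsilon, set$sites$epsilon, tolerance = 1e-6)
  expect_equal(back$sites$x, set$sites$x, tolerance = 1e-6)
  expect_equal(back$total_surface_area, set$total_surface_area)
  expect_equal(nrow(attr(back, "structure")$atoms), 3L)

  empty <- ssip_set(data.frame(x = numeric(), y = numeric(), z = numeric(),
                               epsilon = numeric()),
                    total_surface_area = 0)
  write_ssip_xml(empty, path)
  expect_length(read_ssip_xml(path)$sites$epsilon, 0L)
})

test_that("SSIP XML without epsilon attributes names the offending element", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<ssipMolecule><ssipArray>",
               '<ssip x3="0" y3="0" z3="0" epsilon="1.0"/>',
               '<ssip x3="1" y3="0" z3="0"/>',
               "</ssipArray></ssipMolecule>"), path)
  expect_error(read_ssip_xml(path), "element 2 .* 'epsilon'")
})

test_that("the two-line worked phase file parses to the documented phases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_example_phase_tsv(path)
  specs <- read_phase_tsv(path)
  expect_length(specs, 2L)
  expect_equal(specs[[1]]$temperature, 298)
  expect_equal(specs[[1]]$components, c(water = 1.0))
  expect_equal(specs[[2]]$temperature, 298)
  expect_equal(specs[[2]]$components[["water"]], 0.75)
  expect_equal(specs[[2]]$components[["ethanol"]], 0.25)

  writeLines("298\twater\t1.0", path)
  one <- read_phase_tsv(path)
  expect_length(one, 1L)
  expect_equal(one[[1]]$components, c(water = 1.0))
})

test_that("phase files with bad lines fail loudly with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "298\twater\t0.5\tethanol\t0.4"), path)
  expect_error(read_phase_tsv(path), "line 2.*sum to 0.9")

  writeLines("298\twater", path)
  expect_error(read_phase_tsv(path), "pairs")

  writeLines("-10\twater\t1.0", path)
  expect_error(read_phase_tsv(path), "temperature")
})

test_that("random phase specifications survive a tsv round trip", {
  set.seed(42)
  specs <- lapply(1:10, function(i) {
    k <- sample(1:4, 1)
    x <- stats::runif(k)
    phase_spec(stats::runif(1, 100, 500),
               stats::setNames(x / sum(x), paste0("s", seq_len(k))))
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phase_tsv(specs, path)
  back <- read_phase_tsv(path)
  expect_length(back, 10L)
  for (i in seq_along(specs)) {
    expect_equal(back[[i]]$temperature, specs[[i]]$temperature)
    expect_equal(back[[i]]$components, specs[[i]]$components)
  }
})
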