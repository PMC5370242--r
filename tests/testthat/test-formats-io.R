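# Readers and writers for the external formats the pipeline touches.

test_that("read_run loads mzML with RT unit normalization to seconds", {
  p <- withr::local_tempfile(fileext = ".mzML")
  hand_mzml(p, list(list(rt = 0.5, mz = c(100.5, 200.25), int = c(1e5, 3e6)),
                    list(rt = 1.0, mz = 150.1, int = 2e6)),
            rt_unit = "minute")
  run <- read_run(p)
  expect_s3_class(run, "ms_run")
  expect_length(run$scans, 2L)
  # minute-recorded times come back as seconds
  expect_equal(vapply(run$scans, function(s) s$rt_seconds, numeric(1)),
               c(30, 60))
  expect_equal(run$scans[[1]]$peaks[, "mz"], c(100.5, 200.25))

  p2 <- withr::local_tempfile(fileext = ".mzML")
  hand_mzml(p2, list(list(rt = 12.5, mz = 100, int = 1e5)),
            rt_unit = "second")
  expect_equal(read_run(p2)$scans[[1]]$rt_seconds, 12.5)
})

test_that("read_run round-trips a written synthetic run", {
  mini <- mini_plant()
  run <- mini$runs[[1]]
  p <- withr::local_tempfile(fileext = ".mzML")
  write_run(run, p)
  back <- read_run(p, sample_id = run$run_id)
  expect_equal(length(back$scans), length(run$scans))
  expect_equal(vapply(back$scans, function(s) s$rt_seconds, numeric(1)),
               vapply(run$scans, function(s) s$rt_seconds, numeric(1)))
  # peak lists survive the mzML round trip exactly (64-bit encoding)
  for (i in c(1L, 5L, length(run$scans))) {
    expect_equal(back$scans[[i]]$peaks, run$scans[[i]]$peaks)
    expect_equal(back$scans[[i]]$ms_level, run$scans[[i]]$ms_level)
  }
  # mzXML dialect parity on a truncated copy of the same run
  short <- new_run(run$run_id, run$scans[1:50])
  px <- withr::local_tempfile(fileext = ".mzXML")
  write_run(short, px)
  backx <- read_run(px, sample_id = run$run_id)
  expect_equal(length(backx$scans), 50L)
  expect_equal(backx$scans[[2]]$peaks, short$scans[[2]]$peaks)
})

test_that("read_run rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".mzML")
  hand_mzml(p, list(list(rt = 1, mz = 100, int = 1e5),
                    list(rt = 2, mz = 50, int = 10, ms_level = 2L)))
  expect_error(read_run(p), "precursor")
  expect_error(read_run(tempfile(fileext = ".mzML")), "no such file")
  bad <- withr::local_tempfile(fileext = ".mzML")
  writeLines("this is not xml at all", bad)
  expect_error(read_run(bad))
})

test_that("read_spectral_library parses MGF and skips precursor-less records", {
  p <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgf_lines(), p)
  lib <- read_spectral_library(p)
  expect_length(lib, 2L)
  expect_equal(lib[[1]]$precursor_mz, 301.1405)
  expect_equal(lib[[1]]$annotation$compound_name, "compound_one")
  expect_equal(nrow(lib[[2]]$peaks), 2L)

  # drop PEPMASS from the first record -> skipped with a warning
  lines <- mgf_lines()
  p2 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(lines[!grepl("PEPMASS=301", lines)], p2)
  expect_warning(lib2 <- read_spectral_library(p2), "skipped")
  expect_length(lib2, 1L)
  expect_equal(lib2[[1]]$annotation$compound_name, "compound_two")

  # zero valid records is an error
  p3 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(lines[!grepl("PEPMASS", lines)], p3)
  expect_error(suppressWarnings(read_spectral_library(p3)), "no valid records")
})

test_that("read_spectral_library parses MSP and enforces Num Peaks", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: alpha", "PrecursorMZ: 412.15", "Num Peaks: 3",
               "100.1 50", "200.2 999", "300.3 10", "",
               "Name: beta", "PrecursorMZ: 210.08", "Num Peaks: 2",
               "90.0 10; 110.0 20"), p)
  lib <- read_spectral_library(p)
  expect_length(lib, 2L)
  expect_equal(lib[[1]]$annotation$compound_name, "alpha")
  expect_equal(nrow(lib[[2]]$peaks), 2L)

  pbad <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: gamma", "PrecursorMZ: 412.15", "Num Peaks: 4",
               "100.1 50", "200.2 999"), pbad)
  expect_error(read_spectral_library(pbad), "declares 4 peaks but lists 2")
})

test_that("read_mesh_stl handles ASCII and binary cubes identically", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(cube_stl_lines(), p)
  mesh <- read_mesh_stl(p)
  expect_equal(nrow(mesh$vertices), 8L)   # exact-coordinate dedup
  expect_equal(nrow(mesh$faces), 12L)

  pb <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl_binary(mesh, pb)
  mesh_b <- read_mesh_stl(pb)
  expect_equal(mesh_b$vertices, mesh$vertices)
  expect_equal(mesh_b$faces, mesh$faces)

  # ASCII re-export round-trips too
  pa <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl(mesh, pa)
  expect_equal(read_mesh_stl(pa)$vertices, mesh$vertices)
})

test_that("read_mesh_stl rejects empty and truncated files", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid empty", "endsolid empty"), p)
  expect_error(read_mesh_stl(p), "no facets")

  mesh <- cube_mesh()
  pb <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl_binary(mesh, pb)
  full <- readBin(pb, "raw", n = file.info(pb)$size)
  pt <- withr::local_tempfile(fileext = ".stl")
  writeBin(full[1:200], pt)    # cut inside the facet block
  expect_error(read_mesh_stl(pt), "truncated")
})

test_that("binary STL reader rejects single-byte corruption of the header", {
  mesh <- cube_mesh()
  pb <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl_binary(mesh, pb)
  full <- readBin(pb, "raw", n = file.info(pb)$size)
  set.seed(7)
  for (rep in 1:5) {
    mut <- full
    # corrupt a byte of the facet-count field upward -> declared count
    # exceeds the file length
    mut[82] <- as.raw(255)
    pm <- withr::local_tempfile(fileext = ".stl")
    writeBin(mut, pm)
    expect_error(read_mesh_stl(pm), "truncated")
  }
})

test_that("write_ili_table produces the expected CSV shape and quoting", {
  tab <- tibble::tibble(name = c("a", "b"), x = c(1, 2), y = c(0, 0.5),
                        z = c(0.25, 1), radius = c(0.1, 0.1),
                        `mz_100.0000_rt_60.0s` = c(5e6, 0))
  p <- withr::local_tempfile(fileext = ".csv")
  write_ili_table(tab, p)
  lines <- readLines(p)
  expect_length(lines, 3L)                       # header + 2 samples
  expect_equal(strsplit(lines[1], ",")[[1]][1:5],
               c("name", "X", "Y", "Z", "radius"))
  expect_length(strsplit(lines[2], ",")[[1]], 6L)

  # feature names containing commas are quoted and round-trip losslessly
  tab2 <- tab
  names(tab2)[6] <- "feature, with comma"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ili_table(tab2, p2)
  back <- read_ili_table(p2)
  expect_equal(names(back)[6], "feature, with comma")
  expect_equal(back[[6]], tab2[[6]])

  # duplicate sample names rejected
  tab3 <- tab
  tab3$name <- c("a", "a")
  expect_error(write_ili_table(tab3, tempfile()), "duplicate")
})

test_that("ili CSV writing is byte-stable through read-write cycles", {
  mini <- mini_plant()
  m <- align_features(lapply(mini$runs[1:4], find_features))
  eim <- build_eim_table(m, mini$plant$metadata, mini$plant$mesh)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ili_table(eim, p1)
  write_ili_table(read_ili_table(p1), p2)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
  # and a mandatory-field mutation is rejected on re-read
  lines <- readLines(p1)
  lines[1] <- sub("^name,X", "name,W", lines[1])
  pm <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, pm)
  expect_error(read_ili_table(pm), "ili intensity table")
})

test_that("write_network_graphml round-trips node and edge attributes", {
  n1 <- structure(list(node_id = "N0001", precursor_mz = 400.1234,
                       peaks = cbind(mz = c(100, 150), intensity = c(10, 5)),
                       members = tibble::tibble(sample_id = c("s1", "s2"),
                                                scan_id = c("a", "b")),
                       n_members = 2L), class = "consensus_spectrum")
  n2 <- structure(list(node_id = "N0002", precursor_mz = 414.1391,
                       peaks = cbind(mz = c(100, 150), intensity = c(9, 6)),
                       members = tibble::tibble(sample_id = "s1",
                                                scan_id = "c"),
                       n_members = 1L), class = "consensus_spectrum")
  net <- structure(list(
    nodes = list(n1, n2),
    edges = tibble::tibble(node_a = "N0001", node_b = "N0002",
                           cosine = 0.93, n_matched = 5L,
                           delta_mz = -14.0157),
    annotations = tibble::tibble(node_id = "N0001", library_id = "L1",
                                 compound_name = "thing", cosine = 0.99,
                                 n_matched = 6L, precursor_ppm_error = 0.5)),
    class = "molecular_network")
  p <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(sort(igraph::V(g)$precursor_mz), c(400.1234, 414.1391))
  expect_equal(igraph::E(g)$cosine, 0.93, tolerance = 1e-12)
  expect_equal(igraph::E(g)$delta_mz, -14.0157, tolerance = 1e-12)
  expect_setequal(igraph::V(g)$library_hit, c("thing", ""))

  # empty network still yields parseable GraphML
  empty <- structure(list(nodes = list(),
                          edges = tibble::tibble(node_a = character(0),
                                                 node_b = character(0),
                                                 cosine = numeric(0),
                                                 n_matched = integer(0),
                                                 delta_mz = numeric(0)),
                          annotations = NULL),
                     class = "molecular_network")
  p0 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(empty, p0)
  expect_equal(igraph::vcount(igraph::read_graph(p0, format = "graphml")), 0L)
})

test_that("sample metadata validation enforces the required contract", {
  md <- md_fixture(c("a", "b", "blank1"), c("leaf", "stem", "blank"),
                   blanks = c(FALSE, FALSE, TRUE))
  expect_s3_class(md, "sample_metadata")
  expect_error(md_fixture(c("a", "a"), c("leaf", "leaf")), "duplicate")
  expect_error(read_sample_metadata(tibble::tibble(sample_id = "a")),
               "missing required column")
  # non-blank without coordinates
  bad <- tibble::tibble(sample_id = "a", plant = "p", tissue = "leaf",
                        is_blank = FALSE, x = NA_real_, y = 1, z = 1,
                        radius = 0.1)
  expect_error(read_sample_metadata(bad), "coordinates")
  # coordinate outside mesh bbox + radius
  far <- tibble::tibble(sample_id = "a", plant = "p", tissue = "leaf",
                        is_blank = FALSE, x = 5, y = 0.5, z = 0.5,
                        radius = 0.2)
  expect_error(read_sample_metadata(far, mesh = cube_mesh()),
               "outside the mesh")
  # CSV round trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_sample_metadata(md, p)
  back <- read_sample_metadata(p)
  expect_equal(back$sample_id, md$sample_id)
  expect_equal(back$is_blank, md$is_blank)
})
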