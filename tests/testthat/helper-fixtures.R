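# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; nothing binary ships with the package.

spec2 <- function(mz, intensity, precursor, scan_id = "s1",
                  sample_id = "sampleA", rt = 10) {
  new_spectrum(scan_id = scan_id, ms_level = 2L, rt_seconds = rt,
               peaks = cbind(mz = mz, intensity = intensity),
               precursor_mz = precursor, sample_id = sample_id)
}

spec1 <- function(mz, intensity, scan_id = "s1", sample_id = "sampleA",
                  rt = 10) {
  new_spectrum(scan_id = scan_id, ms_level = 1L, rt_seconds = rt,
               peaks = cbind(mz = mz, intensity = intensity),
               sample_id = sample_id)
}

# Unit cube as ASCII STL text (12 triangles, 8 unique vertices).
cube_stl_lines <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  out <- "solid cube"
  for (i in seq_len(nrow(tri))) {
    out <- c(out, "  facet normal 0 0 0", "    outer loop",
             sprintf("      vertex %g %g %g",
                     v[tri[i, ], 1], v[tri[i, ], 2], v[tri[i, ], 3]),
             "    endloop", "  endfacet")
  }
  c(out, "endsolid cube")
}

cube_mesh <- function() {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(cube_stl_lines(), p)
  read_mesh_stl(p)
}

# Two-record MGF text.
mgf_lines <- function() {
  c("BEGIN IONS", "TITLE=compound_one", "PEPMASS=301.1405",
    "SPECTRUMID=LIB00001", "CHARGE=1+",
    "101.02 1500", "155.1 800", "203.5 2200", "END IONS", "",
    "BEGIN IONS", "TITLE=compound_two", "PEPMASS=467.89",
    "SPECTRUMID=LIB00002",
    "88.5 100", "120.0 900", "END IONS")
}

# Independent brute-force modified-cosine oracle: enumerates every valid
# one-to-one assignment of a-peaks to candidate b-peaks by recursion and
# returns the best total weight. Shares no code with cosine_score.
brute_cosine <- function(a, b, frag_tol_da = 0.02, shifted = FALSE,
                         transform = "sqrt") {
  pa <- a$peaks; pb <- b$peaks
  if (!nrow(pa) || !nrow(pb)) return(list(cosine = 0, n_matched = 0L))
  ia <- if (transform == "sqrt") sqrt(pa[, 2]) else pa[, 2]
  ib <- if (transform == "sqrt") sqrt(pb[, 2]) else pb[, 2]
  norm <- sqrt(sum(ia^2)) * sqrt(sum(ib^2))
  shift <- if (shifted) a$precursor_mz - b$precursor_mz else 0
  cand <- lapply(seq_len(nrow(pa)), function(i) {
    d <- abs(pa[i, 1] - pb[, 1])
    ds <- abs((pa[i, 1] - pb[, 1]) - shift)
    which(d <= frag_tol_da | (shifted & ds <= frag_tol_da))
  })
  best <- new.env(); best$w <- 0; best$n <- 0L
  rec <- function(i, used, w, n) {
    if (w > best$w || (w == best$w && n > best$n)) {
      best$w <- w; best$n <- n
    }
    if (i > nrow(pa)) return(invisible())
    rec(i + 1L, used, w, n)                       # leave peak i unmatched
    for (j in setdiff(cand[[i]], used)) {
      rec(i + 1L, c(used, j), w + ia[i] * ib[j], n + 1L)
    }
    invisible()
  }
  rec(1L, integer(0), 0, 0L)
  list(cosine = min(1, best$w / norm), n_matched = best$n)
}

# Random small MS2 spectrum for property tests.
random_spec <- function(n_peaks, precursor = stats::runif(1, 300, 800),
                        mz_lo = 50, mz_hi = 280, id = "r") {
  spec2(mz = sort(stats::runif(n_peaks, mz_lo, mz_hi)),
        intensity = stats::runif(n_peaks, 10, 1000),
        precursor = precursor, scan_id = id)
}

# Session-cached small synthetic plant (2 tissues x 2 spots, 12 metabolites)
# with rendered runs; several test files reuse it.
.fixture_cache <- new.env(parent = emptyenv())

mini_plant <- function() {
  if (is.null(.fixture_cache$mini)) {
    pl <- make_plant(42, n_tissues = 2L, spots_per_tissue = 2L,
                     n_metabolites = 12L)
    runs <- render_runs(pl$truth)
    .fixture_cache$mini <- list(plant = pl, runs = runs)
  }
  .fixture_cache$mini
}

# Feature-matrix builder from explicit per-sample area columns.
fm_fixture <- function(areas, mz = NULL, rt = NULL) {
  n <- nrow(areas)
  out <- tibble::tibble(
    row_id = sprintf("F%04d", seq_len(n)),
    mz = if (is.null(mz)) 200 + seq_len(n) else mz,
    rt_seconds = if (is.null(rt)) 60 + 5 * seq_len(n) else rt)
  out <- dplyr::bind_cols(out, tibble::as_tibble(areas))
  class(out) <- c("feature_matrix", class(out))
  out
}

md_fixture <- function(sample_ids, tissues, blanks = rep(FALSE, length(sample_ids)),
                       plant = "p1") {
  read_sample_metadata(tibble::tibble(
    sample_id = sample_ids, plant = plant, tissue = tissues,
    is_blank = blanks,
    x = ifelse(blanks, NA_real_, 0.5), y = ifelse(blanks, NA_real_, 0.5),
    z = ifelse(blanks, NA_real_, 0.5),
    radius = ifelse(blanks, NA_real_, 0.2)))
}

# Hand-written minimal mzML writer (independent of mzR) used to pin down
# unit handling and malformed-input behaviour of the reader.
b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

hand_mzml <- function(path, scans, rt_unit = "second") {
  # scans: list of list(rt=, mz=, int=, ms_level=1, precursor=NULL)
  unit_acc <- c(second = "UO:0000010", minute = "UO:0000031")[[rt_unit]]
  blocks <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    lvl <- s$ms_level %||% 1L
    prec <- if (lvl == 2L && !is.null(s$precursor)) sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>
         <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>
       </selectedIon></selectedIonList><activation/></precursor></precursorList>',
      s$precursor) else ""
    spectype <- if (lvl == 2L) {
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
    } else {
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
    }
    sprintf(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
        %s
        <scanList count="1"><scan>
          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%g" unitCvRef="UO" unitAccession="%s" unitName="%s"/>
        </scan></scanList>
        %s
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
      i - 1L, i, length(s$mz), lvl, spectype, s$rt, unit_acc, rt_unit, prec,
      nchar(b64_doubles(s$mz)), b64_doubles(s$mz),
      nchar(b64_doubles(s$int)), b64_doubles(s$int))
  }, character(1))
  xml <- sprintf(
    '<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="PSI-MS" URI="x"/>
    <cv id="UO" fullName="UNIT-ONTOLOGY" URI="x"/>
  </cvList>
  <fileDescription><fileContent>
    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
  </fileContent></fileDescription>
  <softwareList count="1"><software id="sw" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">
    <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>
  </instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw">
    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
  </processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp">
%s
    </spectrumList>
  </run>
</mzML>', length(scans), paste(blocks, collapse = "\n"))
  writeLines(xml, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# Session-cached default two-plant study processed once through the full
# pipeline (the end-to-end fixture for the acceptance properties).
study_fixture <- function() {
  if (is.null(.fixture_cache$study)) {
    study <- make_study(1)
    runs <- c(render_runs(study$tomato_like$truth),
              render_runs(study$pepper_like$truth))
    md <- read_sample_metadata(dplyr::bind_rows(study$tomato_like$metadata,
                                                study$pepper_like$metadata))
    out <- file.path(tempdir(), "mscarto_study_out")
    man <- run_pipeline(runs, md, output_dir = out, overwrite = TRUE)
    .fixture_cache$study <- list(study = study, runs = runs, metadata = md,
                                 out = out, manifest = man)
  }
  .fixture_cache$study
}

# Subset a feature matrix to one plant's samples.
fm_subset <- function(m, sample_ids) {
  sub <- m[, c("row_id", "mz", "rt_seconds",
               intersect(fm_sample_ids(m), sample_ids))]
  class(sub) <- class(m)
  sub
}
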