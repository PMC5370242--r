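# Deterministic synthetic plants: a procedural mesh with labeled tissue
# patches, sampling spots, a metabolite panel with known spatial structure,
# and simulated DDA LC-MS/MS runs — the no-download test surface for every
# pipeline stage.

# All generator randomness flows through one seeded Mersenne-Twister stream
# with fixed normal/sample kinds, so (seed, parameters) -> identical output
# on any platform. The caller's RNG state is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

PROTON_NEUTRON_DELTA <- 1.003355  # 13C - 12C mass difference, Da

# Internal standard: spiked into the injection solvent, hence present in
# every run including blanks, at identical abundance (multiplier 1).
IS_ID <- "IS"
IS_MZ <- 466.3158   # glycocholic acid [M+H]+
IS_RT <- 180
IS_SIGMA <- 2.5
IS_HEIGHT <- 5e7

tissue_names <- function(n) {
  base <- c("stem", "leaf", "flower", "fruit")
  if (n <= 4L) base[seq_len(n)]
  else c(base, paste0("tissue", 5:n))
}

# Subdivided-octahedron ellipsoid: 8 * 4^subdiv triangles, closed surface.
ellipsoid_mesh <- function(center, radii, subdiv = 2L) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      mids <- rbind((v[a, ] + v[b, ]) / 2, (v[b, ] + v[c3, ]) / 2,
                    (v[c3, ] + v[a, ]) / 2)
      mids <- mids / sqrt(rowSums(mids^2))
      base <- nrow(v)
      v <- rbind(v, mids)
      ab <- base + 1L; bc <- base + 2L; ca <- base + 3L
      nf[(4L * i - 3L):(4L * i), ] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                            c(ca, bc, c3), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- sweep(sweep(v, 2, radii, `*`), 2, center, `+`)
  list(vertices = v, faces = f)
}

# Tissue patch geometry for up to 8 tissues: a stem-like column plus organs
# attached around it. Deterministic (no RNG).
tissue_geometry <- function(n_tissues) {
  geo <- list(
    stem = list(center = c(0, 0, 5), radii = c(0.6, 0.6, 5)),
    leaf = list(center = c(2.5, 0, 6), radii = c(2.2, 1.2, 0.5)),
    flower = list(center = c(0, 0, 11), radii = c(1.2, 1.2, 0.9)),
    fruit = list(center = c(-2, 0, 4), radii = c(1.4, 1.4, 1.6))
  )
  nm <- tissue_names(n_tissues)
  for (k in seq_along(nm)) {
    if (is.null(geo[[nm[k]]])) {
      ang <- 2 * pi * k / n_tissues
      geo[[nm[k]]] <- list(center = c(2.2 * cos(ang), 2.2 * sin(ang), 2 + k),
                           radii = c(1, 1, 1))
    }
  }
  geo[nm]
}

#' Generate a synthetic plant
#'
#' Builds a procedural plant surface (an ellipsoid-union of labeled tissue
#' patches), places sampling spots on each patch, and draws a metabolite
#' panel with known spatial structure: an all-tissue core (a
#' `shared_fraction` share of the panel, containing the internal standard),
#' tissue-exclusive sets, and pairwise-shared sets. The panel includes two
#' analog families — three metabolites sharing one fragment template with
#' precursors offset by a constant delta — so networking tests have planted
#' molecular families. Everything is a pure function of `seed`.
#'
#' @param seed Integer seed.
#' @param n_tissues Number of tissue patches (default 4: stem, leaf,
#'   flower, fruit).
#' @param spots_per_tissue Sampling spots per tissue (default 6).
#' @param n_metabolites Panel size including the internal standard
#'   (default 60).
#' @param shared_fraction Share of the panel present in all tissues
#'   (default 0.1).
#' @param plant Plant label stamped into sample ids and metadata.
#' @param n_blanks Solvent/system blank runs to add (default 2).
#' @return A list: `mesh` (`ms_mesh`), `metadata` (`sample_metadata`),
#'   `truth` (`plant_truth`).
#' @export
make_plant <- function(seed, n_tissues = 4L, spots_per_tissue = 6L,
                       n_metabolites = 60L, shared_fraction = 0.1,
                       plant = "plantA", n_blanks = 2L) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_tissues >= 1L, spots_per_tissue >= 1L, n_metabolites >= 2L)
  with_seed(seed, {
    tissues <- tissue_names(n_tissues)
    geo <- tissue_geometry(n_tissues)

    parts <- lapply(geo, function(g) ellipsoid_mesh(g$center, g$radii))
    verts <- do.call(rbind, lapply(parts, `[[`, "vertices"))
    offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$vertices),
                                integer(1))))
    faces <- do.call(rbind, lapply(seq_along(parts), function(i) {
      parts[[i]]$faces + offs[i]
    }))
    mesh <- new_mesh(verts, faces)

    spot_radius <- 0.35
    md_rows <- list()
    for (ti in seq_along(tissues)) {
      vt <- parts[[ti]]$vertices
      pick <- sample(nrow(vt), spots_per_tissue)
      for (k in seq_len(spots_per_tissue)) {
        md_rows[[length(md_rows) + 1L]] <- tibble::tibble(
          sample_id = sprintf("%s_%s_%02d", plant, tissues[ti], k),
          plant = plant, tissue = tissues[ti], is_blank = FALSE,
          x = vt[pick[k], 1], y = vt[pick[k], 2], z = vt[pick[k], 3],
          radius = spot_radius)
      }
    }
    for (b in seq_len(n_blanks)) {
      md_rows[[length(md_rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_blank_%d", plant, b),
        plant = plant, tissue = "blank", is_blank = TRUE,
        x = NA_real_, y = NA_real_, z = NA_real_, radius = NA_real_)
    }
    metadata <- read_sample_metadata(dplyr::bind_rows(md_rows), mesh = mesh)

    # ---- metabolite panel ------------------------------------------------
    n_core <- max(1L, round(shared_fraction * n_metabolites))
    n_core <- min(n_core, n_metabolites)
    n_rest <- n_metabolites - n_core
    n_excl <- round(2 / 3 * n_rest)
    n_pair <- n_rest - n_excl

    ids <- c(IS_ID, sprintf("M%03d", seq_len(n_metabolites - 1L)))
    mz <- c(IS_MZ, stats::runif(n_metabolites - 1L, 150, 900))
    rt <- c(IS_RT, stats::runif(n_metabolites - 1L, 60, 540))
    sigma <- c(IS_SIGMA, stats::runif(n_metabolites - 1L, 1, 4))
    height <- c(IS_HEIGHT, 10^stats::runif(n_metabolites - 1L, 6.9, 8.3))

    # membership: core first (starts with IS), then per-tissue exclusives,
    # then pairwise-shared, assigned round-robin
    profile <- matrix(0, nrow = n_metabolites, ncol = n_tissues,
                      dimnames = list(ids, tissues))
    kind <- character(n_metabolites)
    idx <- 1L
    for (k in seq_len(n_core)) {
      profile[idx, ] <- if (ids[idx] == IS_ID) 1 else
        stats::runif(n_tissues, 0.5, 1.5)
      kind[idx] <- "core"
      idx <- idx + 1L
    }
    excl_tissue <- rep(seq_len(n_tissues), length.out = n_excl)
    for (k in seq_len(n_excl)) {
      profile[idx, excl_tissue[k]] <- stats::runif(1, 0.7, 1.3)
      kind[idx] <- paste0("exclusive_", tissues[excl_tissue[k]])
      idx <- idx + 1L
    }
    if (n_pair > 0L && n_tissues >= 2L) {
      prs <- utils::combn(n_tissues, 2L)
      pair_pick <- rep(seq_len(ncol(prs)), length.out = n_pair)
      for (k in seq_len(n_pair)) {
        pr <- prs[, pair_pick[k]]
        profile[idx, pr] <- stats::runif(2, 0.7, 1.3)
        kind[idx] <- paste0("pair_", tissues[pr[1]], "_", tissues[pr[2]])
        idx <- idx + 1L
      }
    } else if (n_pair > 0L) {
      for (k in seq_len(n_pair)) {
        profile[idx, 1L] <- stats::runif(1, 0.7, 1.3)
        kind[idx] <- paste0("exclusive_", tissues[1L])
        idx <- idx + 1L
      }
    }

    # fragment templates: 4-12 peaks in [50, precursor - 25]
    fragments <- vector("list", n_metabolites)
    names(fragments) <- ids
    for (i in seq_len(n_metabolites)) {
      nf <- sample(4:12, 1L)
      fmz <- sort(stats::runif(nf, 50, max(60, mz[i] - 25)))
      fragments[[i]] <- cbind(mz = fmz,
                              rel_intensity = stats::runif(nf, 0.05, 1))
    }

    # two analog families of three, planted among tissue exclusives: members
    # share the base member's template; precursors offset by +14.0157 steps
    families <- list()
    if (n_excl >= 6L) {
      excl_idx <- which(startsWith(kind, "exclusive_"))
      fam_slots <- list(excl_idx[1:3], excl_idx[4:6])
      delta <- 14.0157
      for (fi in seq_along(fam_slots)) {
        slot <- fam_slots[[fi]]
        base <- slot[1]
        base_tissue <- kind[base]
        for (j in seq_along(slot)) {
          i <- slot[j]
          mz[i] <- mz[base] + (j - 1L) * delta
          rt[i] <- rt[base] + (j - 1L) * 25   # separate elution
          fragments[[i]] <- fragments[[base]]
          # family members share the base member's tissue
          profile[i, ] <- 0
          profile[i, sub("exclusive_", "", base_tissue)] <-
            stats::runif(1, 0.7, 1.3)
          kind[i] <- base_tissue
        }
        families[[fi]] <- ids[slot]
      }
    }

    metabolites <- tibble::tibble(
      id = ids, mz = mz, rt_seconds = rt, sigma_seconds = sigma,
      apex_height = height, kind = kind)

    # background ions: solvent/system signal in every run (blanks included),
    # intense enough for DDA selection but below the MS1 feature threshold
    background <- tibble::tibble(
      id = sprintf("BG%02d", 1:3),
      mz = stats::runif(3, 150, 900),
      level = stats::runif(3, 3e4, 8e4))
    bg_fragments <- lapply(seq_len(nrow(background)), function(i) {
      nf <- sample(4:8, 1L)
      cbind(mz = sort(stats::runif(nf, 50, background$mz[i] - 25)),
            rel_intensity = stats::runif(nf, 0.1, 1))
    })
    names(bg_fragments) <- background$id

    # planted per-sample features: abundance = tissue multiplier with mild
    # per-sample biological scatter; IS exactly constant
    planted <- list()
    nb <- metadata[!metadata$is_blank, ]
    for (si in seq_len(nrow(nb))) {
      tis <- nb$tissue[si]
      for (mi in seq_len(n_metabolites)) {
        mult <- profile[mi, tis]
        if (mult <= 0) next
        h <- height[mi] * mult *
          (if (ids[mi] == IS_ID) 1 else exp(stats::rnorm(1, 0, 0.15)))
        planted[[length(planted) + 1L]] <- tibble::tibble(
          sample_id = nb$sample_id[si], metabolite_id = ids[mi],
          mz = mz[mi], rt_seconds = rt[mi], sigma_seconds = sigma[mi],
          height = h, area = h * sigma[mi] * sqrt(2 * pi))
      }
    }
    # IS in blanks (injection solvent)
    for (b in metadata$sample_id[metadata$is_blank]) {
      planted[[length(planted) + 1L]] <- tibble::tibble(
        sample_id = b, metabolite_id = IS_ID, mz = IS_MZ,
        rt_seconds = IS_RT, sigma_seconds = IS_SIGMA, height = IS_HEIGHT,
        area = IS_HEIGHT * IS_SIGMA * sqrt(2 * pi))
    }

    truth <- structure(list(
      plant = plant, seed = seed, tissues = tissues,
      metabolites = metabolites, tissue_profile = profile,
      fragments = fragments, analog_families = families,
      background = background, bg_fragments = bg_fragments,
      samples = metadata,
      planted_features = dplyr::bind_rows(planted)
    ), class = "plant_truth")
    list(mesh = mesh, metadata = metadata, truth = truth)
  })
}

#' @export
print.plant_truth <- function(x, ...) {
  cat(sprintf("<plant_truth> %s (seed %d): %d metabolites, %d tissues, %d samples (%d blanks)\n",
              x$plant, x$seed, nrow(x$metabolites), length(x$tissues),
              nrow(x$samples), sum(x$samples$is_blank)))
  invisible(x)
}

#' Simulate DDA LC-MS/MS runs for a synthetic plant
#'
#' Renders one run per sample (blanks included). MS1 survey scans are
#' generated at `scan_rate_hz` with Gaussian elution profiles for each
#' planted metabolite, a +1 isotopologue companion at a mass-scaled natural
#' ratio, and multiplicative log-normal intensity noise of relative width
#' 1/`snr`. MS2 events follow top-N data-dependent acquisition with dynamic
#' exclusion: after each survey scan, the `dda_top_n` most intense
#' unexcluded precursors are fragmented using the metabolite's template
#' (fragment m/z jittered by at most 0.005 Da); a precursor is excluded
#' after `exclusion_after` selections and released `release_seconds` after
#' its last selection. Blank runs contain only background ions and the
#' internal standard.
#'
#' @param truth A `plant_truth` from [make_plant()].
#' @param scan_rate_hz MS1 scan rate (default 2).
#' @param noise_floor Background point intensity scale (default 1e3).
#' @param snr Signal-to-noise ratio of the multiplicative noise; `Inf`
#'   disables noise (default 100).
#' @param dda_top_n Precursors fragmented per survey scan (default 5).
#' @param exclusion_after Selections before dynamic exclusion (default 3).
#' @param release_seconds Exclusion release time (default 20).
#' @param run_length_seconds Run duration (default 600, a 10-min gradient).
#' @return A named list of `ms_run`, one per sample.
#' @export
render_runs <- function(truth, scan_rate_hz = 2, noise_floor = 1e3,
                        snr = 100, dda_top_n = 5L, exclusion_after = 3L,
                        release_seconds = 20, run_length_seconds = 600) {
  with_seed(truth$seed + 1L, {
    noise_sd <- if (is.finite(snr)) 1 / snr else 0
    scan_times <- seq(0, run_length_seconds, by = 1 / scan_rate_hz)
    runs <- vector("list", nrow(truth$samples))
    names(runs) <- truth$samples$sample_id
    for (si in seq_len(nrow(truth$samples))) {
      sid <- truth$samples$sample_id[si]
      runs[[sid]] <- render_one_run(truth, sid, scan_times, noise_sd,
                                    noise_floor, dda_top_n, exclusion_after,
                                    release_seconds)
    }
    runs
  })
}

render_one_run <- function(truth, sid, scan_times, noise_sd, noise_floor,
                           dda_top_n, exclusion_after, release_seconds) {
  planted <- truth$planted_features[truth$planted_features$sample_id == sid, ]
  n_scan <- length(scan_times)
  dt <- scan_times[2] - scan_times[1]

  # accumulate (scan index, mz, intensity, source id) triplets
  acc_scan <- integer(0); acc_mz <- numeric(0)
  acc_int <- numeric(0); acc_src <- character(0)
  add_pts <- function(scan_idx, mzv, intv, src) {
    acc_scan <<- c(acc_scan, scan_idx)
    acc_mz <<- c(acc_mz, mzv)
    acc_int <<- c(acc_int, intv)
    acc_src <<- c(acc_src, rep(src, length(scan_idx)))
  }

  for (pi in seq_len(nrow(planted))) {
    p <- planted[pi, ]
    lo <- max(1L, ceiling((p$rt_seconds - 5 * p$sigma_seconds) / dt) + 1L)
    hi <- min(n_scan, floor((p$rt_seconds + 5 * p$sigma_seconds) / dt) + 1L)
    if (lo > hi) next
    w <- lo:hi
    base <- p$height * exp(-(scan_times[w] - p$rt_seconds)^2 /
                             (2 * p$sigma_seconds^2))
    noise <- if (noise_sd > 0) exp(stats::rnorm(length(w), 0, noise_sd)) else 1
    inten <- base * noise
    keep <- inten >= noise_floor
    if (any(keep)) {
      add_pts(w[keep], rep(p$mz, sum(keep)), inten[keep], p$metabolite_id)
      # +1 isotopologue at a crude carbon-count ratio, same elution
      iso_ratio <- min(0.6, 5.45e-4 * p$mz)
      iso <- inten[keep] * iso_ratio
      ik <- iso >= noise_floor
      if (any(ik)) {
        add_pts(w[keep][ik], rep(p$mz + PROTON_NEUTRON_DELTA, sum(ik)),
                iso[ik], paste0(p$metabolite_id, "_iso"))
      }
    }
  }
  # background ions in every scan of every run
  for (bi in seq_len(nrow(truth$background))) {
    lvl <- rep(truth$background$level[bi], n_scan)
    if (noise_sd > 0) lvl <- lvl * exp(stats::rnorm(n_scan, 0, noise_sd))
    add_pts(seq_len(n_scan), rep(truth$background$mz[bi], n_scan),
            lvl, truth$background$id[bi])
  }

  frag_templates <- c(truth$fragments, truth$bg_fragments)
  by_scan <- split(seq_along(acc_scan), acc_scan)

  # dynamic exclusion state per selectable source id
  sel_count <- integer(0)
  last_sel <- numeric(0)

  scans <- list()
  scan_no <- 0L
  for (k in seq_len(n_scan)) {
    idx <- by_scan[[as.character(k)]]
    t <- scan_times[k]
    scan_no <- scan_no + 1L
    pk <- if (length(idx)) cbind(mz = acc_mz[idx], intensity = acc_int[idx])
      else matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity")))
    scans[[length(scans) + 1L]] <- new_spectrum(
      scan_id = sprintf("%s_s%05d", sid, scan_no), ms_level = 1L,
      rt_seconds = t, peaks = pk, sample_id = sid)
    if (!length(idx)) next

    # DDA: top-N most intense unexcluded precursors (isotopologues are not
    # selectable; ties broken by lower m/z)
    selectable <- !endsWith(acc_src[idx], "_iso")
    cand <- idx[selectable]
    if (!length(cand)) next
    ord <- cand[order(-acc_int[cand], acc_mz[cand])]
    n_frag_events <- 0L
    for (ci in ord) {
      if (n_frag_events >= dda_top_n) break
      src <- acc_src[ci]
      cnt <- if (src %in% names(sel_count)) sel_count[[src]] else 0L
      last <- if (src %in% names(last_sel)) last_sel[[src]] else -Inf
      if (cnt >= exclusion_after) {
        if (t - last >= release_seconds) cnt <- 0L else next
      }
      tpl <- frag_templates[[src]]
      if (is.null(tpl)) next
      jitter <- stats::runif(nrow(tpl), -0.005, 0.005)
      fint <- tpl[, "rel_intensity"] * acc_int[ci] *
        (if (noise_sd > 0) exp(stats::rnorm(nrow(tpl), 0, noise_sd)) else 1)
      n_frag_events <- n_frag_events + 1L
      scan_no <- scan_no + 1L
      scans[[length(scans) + 1L]] <- new_spectrum(
        scan_id = sprintf("%s_s%05d", sid, scan_no), ms_level = 2L,
        rt_seconds = t + n_frag_events * 0.02,
        peaks = cbind(mz = tpl[, "mz"] + jitter, intensity = fint),
        precursor_mz = acc_mz[ci], sample_id = sid)
      sel_count[[src]] <- cnt + 1L
      last_sel[[src]] <- t
    }
  }
  new_run(run_id = sid, scans = scans)
}

#' Expected-outcome tables for a synthetic plant
#'
#' Derives, from the ground truth alone, what a correct pipeline should
#' report: the expected feature-matrix skeleton, expected MS1 Venn region
#' counts per tissue grouping, expected tissue-exclusive metabolite sets,
#' and expected analog-family memberships. These are the oracles the
#' end-to-end tests compare pipeline output against.
#'
#' @param truth A `plant_truth`.
#' @return A list: `expected_features` (planted per-sample features),
#'   `expected_matrix` (metabolite x sample expected areas, long tibble),
#'   `expected_venn` (region tibble), `expected_center_count`,
#'   `tissue_exclusive` (tibble id/tissue), `analog_families`.
#' @export
truth_report <- function(truth) {
  prof <- truth$tissue_profile
  tissues <- truth$tissues
  region <- apply(prof > 0, 1, function(r) paste(tissues[r], collapse = "+"))
  tab <- table(region)
  expected_venn <- tibble::tibble(
    region = names(tab),
    n_groups = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    count = as.integer(tab)
  ) |> dplyr::arrange(dplyr::desc(.data$n_groups), .data$region)
  center <- paste(tissues, collapse = "+")
  excl <- startsWith(truth$metabolites$kind, "exclusive_")
  list(
    expected_features = truth$planted_features,
    expected_matrix = truth$planted_features[, c("metabolite_id", "sample_id",
                                                 "mz", "rt_seconds", "area")],
    expected_venn = expected_venn,
    expected_center_count = if (center %in% names(tab)) {
      as.integer(tab[[center]])
    } else 0L,
    tissue_exclusive = tibble::tibble(
      id = truth$metabolites$id[excl],
      tissue = sub("exclusive_", "", truth$metabolites$kind[excl])),
    analog_families = truth$analog_families
  )
}

#' Generate the default two-plant synthetic study
#'
#' Two plants (a "tomato-like" and a "pepper-like" habit) from two derived
#' seeds, each with its own mesh, tissue patches, blanks and metabolite
#' panel; the internal standard is common to both. Mirrors a two-organism
#' cartography study where each plant carries plant-exclusive chemistry.
#'
#' @param seed Integer seed.
#' @param ... Passed to [make_plant()].
#' @return A named list of two [make_plant()] results
#'   (`tomato_like`, `pepper_like`).
#' @export
make_study <- function(seed, ...) {
  list(
    tomato_like = make_plant(seed, plant = "tomato_like", ...),
    pepper_like = make_plant(seed + 7919L, plant = "pepper_like", ...)
  )
}

#' Write a synthetic plant to disk as standard files
#'
#' Emits everything the file-based pipeline consumes: one mzML per sample,
#' the mesh as ASCII STL, the metadata CSV, a reference MGF library built
#' from a subset of the metabolite fragment templates (enabling library-
#' search tests), and the ground truth as JSON.
#'
#' @param plant A [make_plant()] result.
#' @param dir Output directory (created if needed).
#' @param runs Optional pre-rendered run list from [render_runs()]; rendered
#'   with defaults when `NULL`.
#' @param library_size Number of metabolites to include in the reference
#'   library (default 20).
#' @return Invisibly, a named list of the written paths.
#' @export
write_plant_fixtures <- function(plant, dir, runs = NULL, library_size = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- plant$truth
  if (is.null(runs)) runs <- render_runs(truth)
  run_paths <- character(0)
  for (sid in names(runs)) {
    p <- file.path(dir, paste0(sid, ".mzML"))
    write_run(runs[[sid]], p)
    run_paths[sid] <- p
  }
  stl <- file.path(dir, paste0(truth$plant, ".stl"))
  write_mesh_stl(plant$mesh, stl)
  mdp <- file.path(dir, "metadata.csv")
  write_sample_metadata(plant$metadata, mdp)
  libp <- file.path(dir, "library.mgf")
  write_mgf(synthetic_library(truth, library_size), libp)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    plant = truth$plant, seed = truth$seed,
    metabolites = truth$metabolites,
    planted_features = truth$planted_features,
    analog_families = truth$analog_families
  ), tj, auto_unbox = TRUE, digits = NA)
  invisible(list(runs = run_paths, mesh = stl, metadata = mdp,
                 library = libp, truth = tj))
}

#' Reference spectra for a subset of a synthetic panel
#'
#' Builds noiseless library spectra from the first `n` metabolite fragment
#' templates; compound "names" are the synthetic metabolite ids.
#'
#' @param truth A `plant_truth`.
#' @param n Number of library records (default 20).
#' @return A list of annotated `ms_spectrum`.
#' @export
synthetic_library <- function(truth, n = 20L) {
  n <- min(n, nrow(truth$metabolites))
  lapply(seq_len(n), function(i) {
    m <- truth$metabolites[i, ]
    tpl <- truth$fragments[[m$id]]
    new_spectrum(scan_id = paste0("LIB_", m$id), ms_level = 2L,
                 rt_seconds = 0,
                 peaks = cbind(mz = tpl[, "mz"],
                               intensity = tpl[, "rel_intensity"] * 1e4),
                 precursor_mz = m$mz, sample_id = "library",
                 annotation = list(compound_name = paste0("synthetic_", m$id),
                                   library_id = paste0("LIB_", m$id)))
  })
}
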