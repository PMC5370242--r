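# Consensus clustering, network construction/pruning, blank subtraction,
# library search and node statistics.

frag_a <- c(81.07, 105.03, 120.10, 151.20, 190.60, 220.05)
int_a <- c(10, 40, 100, 25, 60, 35)

test_that("cluster_spectra merges identical spectra and discards singletons", {
  s1 <- spec2(frag_a, int_a, precursor = 400.00, scan_id = "a",
              sample_id = "s1")
  s2 <- spec2(frag_a, int_a, precursor = 400.00, scan_id = "b",
              sample_id = "s2")
  nodes <- cluster_spectra(list(s1, s2))
  expect_length(nodes, 1L)
  expect_equal(nodes[[1]]$n_members, 2L)
  expect_equal(nodes[[1]]$precursor_mz, 400.00)
  expect_equal(nrow(nodes[[1]]$members), 2L)

  # a lone spectrum yields no node
  expect_length(cluster_spectra(list(s1)), 0L)

  # third spectrum 0.5 Da away stays a singleton and is discarded
  s3 <- spec2(frag_a, int_a, precursor = 400.50, scan_id = "c",
              sample_id = "s3")
  nodes3 <- cluster_spectra(list(s1, s3, s2))
  expect_length(nodes3, 1L)
  expect_equal(nodes3[[1]]$n_members, 2L)
})

test_that("consensus peaks are weighted means of merged member peaks", {
  s1 <- spec2(c(100.000, 150.000), c(100, 300), precursor = 400,
              scan_id = "a", sample_id = "s1")
  s2 <- spec2(c(100.010, 150.000), c(300, 300), precursor = 400,
              scan_id = "b", sample_id = "s2")
  nodes <- cluster_spectra(list(s1, s2))
  expect_length(nodes, 1L)
  pk <- nodes[[1]]$peaks
  expect_equal(nrow(pk), 2L)
  # merged at 0.02 Da: m/z is intensity-weighted, intensity summed
  expect_equal(unname(pk[1, "mz"]), (100.000 * 100 + 100.010 * 300) / 400,
               tolerance = 1e-9)
  expect_equal(unname(pk[, "intensity"]), c(400, 600))
})

test_that("clustering is invariant to input order", {
  withr::local_seed(5)
  specs <- list()
  for (i in 1:4) {      # 3 clusters x 4 members with slight jitter
    for (prec in c(300.0, 350.0, 500.0)) {
      specs[[length(specs) + 1L]] <- spec2(
        frag_a + stats::runif(6, -0.004, 0.004), int_a * stats::runif(1, 0.8, 1.2),
        precursor = prec + stats::runif(1, -0.005, 0.005),
        scan_id = sprintf("sc%02d_%d", i, round(prec)),
        sample_id = sprintf("s%d", i))
    }
  }
  n1 <- cluster_spectra(specs)
  n2 <- cluster_spectra(rev(specs))
  n3 <- cluster_spectra(specs[sample(length(specs))])
  key <- function(nodes) lapply(nodes, function(n) {
    list(round(n$precursor_mz, 6),
         n$members[order(n$members$scan_id), ])
  })
  expect_length(n1, 3L)
  expect_equal(key(n1), key(n2))
  expect_equal(key(n1), key(n3))
})

mk_node <- function(id, mz, frag_mz, frag_int,
                    samples = "s1", scans = NULL) {
  if (is.null(scans)) scans <- paste0(id, "_", seq_along(samples))
  structure(list(node_id = id, precursor_mz = mz,
                 peaks = cbind(mz = frag_mz, intensity = frag_int),
                 members = tibble::tibble(sample_id = samples,
                                          scan_id = scans),
                 n_members = length(samples)),
            class = "consensus_spectrum")
}

test_that("build_network applies cosine and matched-peak thresholds", {
  a <- mk_node("N0001", 400, frag_a, int_a)
  # same fragments shifted by the precursor delta: modified cosine 1
  b <- mk_node("N0002", 414.0157, frag_a + 14.0157, int_a)
  net <- build_network(list(a, b))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$cosine, 1, tolerance = 1e-9)
  expect_equal(net$edges$n_matched, 6L)
  expect_equal(net$edges$delta_mz, -14.0157)

  # only 3 shared fragments -> below the 4-matched-peak floor
  c3 <- mk_node("N0003", 400, frag_a[1:3], int_a[1:3])
  d3 <- mk_node("N0004", 400, c(frag_a[1:3], 250.0), c(int_a[1:3], 1))
  sc <- cosine_score(mscarto:::node_spectrum(c3), mscarto:::node_spectrum(d3),
                     shifted = TRUE)
  expect_equal(sc$n_matched, 3L)
  expect_gt(sc$cosine, 0.7)
  expect_equal(nrow(build_network(list(c3, d3))$edges), 0L)

  expect_length(build_network(list())$nodes, 0L)
})

test_that("mutual top-K pruning caps a hub at K edges", {
  # star of 12 satellites around one hub: satellites have no edges among
  # themselves, so each satellite ranks the hub first and mutual pruning
  # reduces to the hub's own top-10 by cosine
  hub_edges <- tibble::tibble(
    node_a = "N0000", node_b = sprintf("N%04d", 1:12),
    cosine = 0.99 - 0.01 * (0:11), n_matched = 6L, delta_mz = 0)
  pruned <- mscarto:::prune_top_k(hub_edges, 10L)
  expect_equal(nrow(pruned), 10L)
  expect_setequal(pruned$node_b, sprintf("N%04d", 1:10))
})

test_that("mutual pruning matches a brute-force oracle on random graphs", {
  withr::local_seed(13)
  mutual_topk_oracle <- function(edges, k) {
    rank_of <- function(node, partner) {
      inc <- edges[edges$node_a == node | edges$node_b == node, ]
      inc$other <- ifelse(inc$node_a == node, inc$node_b, inc$node_a)
      inc <- inc[order(-inc$cosine, inc$other), ]
      match(partner, inc$other)
    }
    keep <- vapply(seq_len(nrow(edges)), function(r) {
      rank_of(edges$node_a[r], edges$node_b[r]) <= k &&
        rank_of(edges$node_b[r], edges$node_a[r]) <= k
    }, logical(1))
    edges[keep, ]
  }
  for (rep in 1:20) {
    n <- sample(5:14, 1)
    ids <- sprintf("N%04d", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    take <- stats::runif(nrow(pairs)) < 0.6
    edges <- tibble::tibble(
      node_a = ids[pairs[take, 1]], node_b = ids[pairs[take, 2]],
      cosine = round(stats::runif(sum(take), 0.7, 1), 3),
      n_matched = 5L, delta_mz = 0)
    k <- sample(1:4, 1)
    got <- mscarto:::prune_top_k(edges, k)
    want <- mutual_topk_oracle(edges, k)
    expect_equal(paste(got$node_a, got$node_b), paste(want$node_a, want$node_b))
    # pruning is a subset operation and caps per-node degree at k
    expect_true(all(paste(got$node_a, got$node_b) %in%
                      paste(edges$node_a, edges$node_b)))
    if (nrow(got)) {
      expect_true(all(table(c(got$node_a, got$node_b)) <= k))
    }
  }
})

test_that("subtract_blanks removes any node with blank membership, idempotently", {
  md <- md_fixture(c("t1", "t2", "bk"), c("leaf", "stem", "blank"),
                   blanks = c(FALSE, FALSE, TRUE))
  clean <- mk_node("N0001", 400, frag_a, int_a, samples = c("t1", "t2"))
  dirty <- mk_node("N0002", 414.0157, frag_a + 14.0157, int_a,
                   samples = c("t1", "t2", "t1", "t2", "bk"))
  net <- build_network(list(clean, dirty))
  expect_equal(nrow(net$edges), 1L)
  sub <- subtract_blanks(net, md)
  expect_equal(vapply(sub$nodes, function(n) n$node_id, character(1)),
               "N0001")
  expect_equal(nrow(sub$edges), 0L)               # incident edge removed
  # idempotent
  sub2 <- subtract_blanks(sub, md)
  expect_equal(length(sub2$nodes), 1L)
  # no blank-derived nodes -> identity
  net_clean <- build_network(list(clean))
  expect_length(subtract_blanks(net_clean, md)$nodes, 1L)
  # exclusive mode keeps mixed nodes
  subx <- subtract_blanks(net, md, mode = "exclusive")
  expect_length(subx$nodes, 2L)
  # unknown member sample is an error
  ghost <- mk_node("N0003", 500, frag_a, int_a, samples = "nobody")
  expect_error(subtract_blanks(build_network(list(ghost)), md),
               "absent from metadata")
})

test_that("library_search reports the best qualifying hit within tolerances", {
  node <- mk_node("N0001", 400.0000, frag_a, int_a)
  lib_exact <- spec2(frag_a, int_a, precursor = 400.0000, scan_id = "L1")
  lib_exact$annotation <- list(compound_name = "exact", library_id = "L1")
  lib_close <- spec2(frag_a, int_a * c(1, 1, 1, 1, 1, 0.01),
                     precursor = 400.0100, scan_id = "L2")
  lib_close$annotation <- list(compound_name = "close", library_id = "L2")
  lib_far <- spec2(frag_a, int_a, precursor = 400.5, scan_id = "L3")
  lib_far$annotation <- list(compound_name = "far", library_id = "L3")

  hits <- library_search(list(node), list(lib_far, lib_close, lib_exact))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$compound_name, "exact")       # best cosine wins
  expect_equal(hits$cosine, 1, tolerance = 1e-12)
  expect_equal(hits$precursor_ppm_error, 0)

  # 0.5 Da from every record -> no hit
  none <- library_search(list(mk_node("N0002", 455.5, frag_a, int_a)),
                         list(lib_exact, lib_close, lib_far))
  expect_equal(nrow(none), 0L)
  expect_error(library_search(list(node), list()), "empty")
})

test_that("library ppm cap excludes matches with large relative mass error", {
  # small absolute Da offset that is still a large ppm error at low mass
  node <- mk_node("N0001", 100.0021, frag_a[1:4] / 2, int_a[1:4])
  rec <- spec2(frag_a[1:4] / 2, int_a[1:4], precursor = 100.0000,
               scan_id = "L1")
  rec$annotation <- list(compound_name = "lowmass", library_id = "L1")
  # 0.0021 Da at 100 = 21 ppm -> excluded at the 20 ppm cap
  expect_equal(nrow(library_search(list(node), list(rec))), 0L)
  expect_equal(nrow(library_search(list(node), list(rec), ppm_cap = 25)), 1L)
})

test_that("node sample frequency counts distinct samples", {
  n5 <- mk_node("N0001", 400, frag_a, int_a,
                samples = c("s1", "s1", "s2", "s3", "s2"))
  n1 <- mk_node("N0002", 500, frag_a, int_a, samples = "s1")
  freq <- node_sample_frequency(list(n5, n1))
  expect_equal(freq$n_samples, c(3L, 1L))
})

test_that("tissue overlap of nodes equals brute-force set bucketing", {
  md <- md_fixture(paste0("s", 1:6),
                   rep(c("leaf", "stem", "fruit"), each = 2))
  # all single-tissue -> only singleton regions
  nodes1 <- list(mk_node("N0001", 400, frag_a, int_a, samples = c("s1", "s2")),
                 mk_node("N0002", 500, frag_a, int_a, samples = c("s3", "s4")))
  ov1 <- msms_tissue_overlap(nodes1, md)
  expect_true(all(ov1$n_groups == 1L))
  expect_equal(sum(ov1$count), 2L)

  # one node spanning all tissues -> center region 1
  nodes2 <- list(mk_node("N0001", 400, frag_a, int_a,
                         samples = c("s1", "s3", "s5")))
  ov2 <- msms_tissue_overlap(nodes2, md)
  expect_equal(ov2$count[ov2$region == "fruit+leaf+stem"], 1L)

  # random membership vs exhaustive bucketing
  withr::local_seed(17)
  lut <- stats::setNames(md$tissue, md$sample_id)
  nodes3 <- lapply(1:40, function(k) {
    mk_node(sprintf("N%04d", k), 300 + k, frag_a, int_a,
            samples = sample(md$sample_id, sample(1:6, 1)))
  })
  ov3 <- msms_tissue_overlap(nodes3, md)
  expect_equal(sum(ov3$count), 40L)               # regions partition nodes
  want_tab <- table(vapply(nodes3, function(n) {
    paste(sort(unique(lut[unique(n$members$sample_id)])), collapse = "+")
  }, character(1)))
  expect_setequal(ov3$region, names(want_tab))
  expect_equal(ov3$count[match(names(want_tab), ov3$region)],
               as.integer(want_tab))
})

test_that("network components partition the node set", {
  a <- mk_node("N0001", 400, frag_a, int_a)
  b <- mk_node("N0002", 414.0157, frag_a + 14.0157, int_a)
  c0 <- mk_node("N0003", 700, 300 + 7 * (1:6), rev(int_a))  # unrelated
  net <- build_network(list(a, b, c0))
  comp <- network_components(net)
  expect_equal(nrow(comp), 3L)
  expect_equal(comp$component[comp$node_id == "N0001"],
               comp$component[comp$node_id == "N0002"])
  expect_false(comp$component[comp$node_id == "N0003"] ==
                 comp$component[comp$node_id == "N0001"])
})

test_that("exported nodes round-trip through nodes.mgf + members.tsv", {
  dir <- withr::local_tempdir()
  a <- mk_node("N0001", 400.1234, frag_a, int_a, samples = c("s1", "s2"))
  b <- mk_node("N0002", 500.9876, frag_a + 50, int_a, samples = "s2")
  write_mgf(lapply(list(a, b), mscarto:::node_spectrum),
            file.path(dir, "nodes.mgf"), titles = c("N0001", "N0002"))
  members <- dplyr::bind_rows(
    dplyr::mutate(a$members, node_id = "N0001", .before = 1),
    dplyr::mutate(b$members, node_id = "N0002", .before = 1))
  mscarto:::write_tsv_lf(members, file.path(dir, "node_members.tsv"))
  back <- read_network_nodes(file.path(dir, "nodes.mgf"),
                             file.path(dir, "node_members.tsv"))
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mz, a$precursor_mz)
  expect_equal(unname(back[[1]]$peaks), unname(a$peaks))
  expect_equal(back[[1]]$members$sample_id, a$members$sample_id)
  expect_equal(back[[2]]$n_members, 1L)
})
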