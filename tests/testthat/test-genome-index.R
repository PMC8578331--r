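test_that("a single planted site is indexed with exact coordinates", {
  proto <- "ACTACTACTACTACTACTAC"
  g <- plant_genome(paste0(proto, "TGG"), pad = 40, seed = 1)
  idx <- build_target_index(g, k = 20)
  expect_equal(nrow(idx$sites), 1L)
  expect_equal(idx$sites$protospacer, proto)
  expect_equal(idx$sites$pam, "TGG")
  expect_equal(idx$sites$strand, "+")
  expect_equal(idx$sites$start, 40L)  # 0-based, after the left pad
  nb <- hamming_neighbors(idx, proto)
  expect_equal(nb$distance, 0L)
  expect_equal(neighbor_counts(idx, proto),
               c(H0 = 1L, H1 = 0L, H2 = 0L, H3 = 0L))
})

test_that("duplicated protospacers map to one occurrence per locus", {
  proto <- safe_proto(seed = 2)
  g <- plant_genome(rep(paste0(proto, "AGG"), 2), seed = 2)
  idx <- build_target_index(g, k = 20)
  expect_equal(sum(idx$sites$protospacer == proto), 2L)
  expect_equal(unname(neighbor_counts(idx, proto)["H0"]), 2L)
})

test_that("reverse-strand sites are stored as cutting-strand sequences", {
  proto <- safe_proto(seed = 3)
  # plant the reverse complement: CCA + rc(proto) on the + strand
  g <- plant_genome(paste0("CCA", rc(proto)), pad = 35, seed = 3)
  idx <- build_target_index(g, k = 20)
  expect_equal(nrow(idx$sites), 1L)
  expect_equal(idx$sites$strand, "-")
  expect_equal(idx$sites$protospacer, proto)
  expect_equal(idx$sites$pam, "TGG")
  expect_equal(idx$sites$start, 35L + 3L)  # leftmost protospacer base
  # strand symmetry: the reverse-complemented genome gives the same counts
  g_rc <- c(chr1 = rc(g[[1]]))
  idx_rc <- build_target_index(g_rc, k = 20)
  expect_equal(neighbor_counts(idx, proto), neighbor_counts(idx_rc, proto))
})

test_that("windows with non-ACGT characters and non-NGG PAMs are skipped", {
  proto <- safe_proto(seed = 4)
  broken <- paste0(substr(proto, 1, 10), "N", substr(proto, 12, 20))
  g <- plant_genome(c(paste0(broken, "TGG"), paste0(proto, "TGA")), seed = 4)
  idx <- build_target_index(g, k = 20)
  expect_equal(nrow(idx$sites), 0L)
  bf <- brute_force_site_scan(g, proto)
  expect_equal(nrow(bf), 0L)
})

test_that("input validation catches bad genomes, k, and guides", {
  expect_error(build_target_index(character(0)), "genome")
  expect_error(build_target_index(c(chr1 = "ACGT"), k = 18), "19 or 20")
  g <- plant_genome(paste0(safe_proto(seed = 5), "TGG"), seed = 5)
  idx <- build_target_index(g, k = 20)
  expect_error(hamming_neighbors(idx, "ACGT"), "length")
  expect_error(hamming_neighbors(idx, paste(rep("N", 20), collapse = "")),
               "A/C/G/T")
  expect_error(hamming_neighbors(idx, safe_proto(seed = 5), max_distance = 4),
               "max_distance")
  bad_fa <- tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), bad_fa)
  expect_error(build_target_index(bad_fa, k = 20), "dup")
})

test_that("alternative contigs can be excluded by name pattern", {
  proto <- safe_proto(seed = 6)
  el <- paste0(proto, "AGG")
  g <- c(plant_genome(el, seed = 6), setNames(plant_genome(el, seed = 7), "chr1_alt"))
  idx_all <- build_target_index(g, k = 20)
  idx_noalt <- build_target_index(g, k = 20, exclude_alt = TRUE)
  expect_equal(unname(neighbor_counts(idx_all, proto)["H0"]), 2L)
  expect_equal(unname(neighbor_counts(idx_noalt, proto)["H0"]), 1L)
})

test_that("a planted 2-mismatch relative is found at distance 2 only", {
  proto <- "ACTACTACTACTACTACTAC"
  relative <- "TCTACTACTACTACTACTAT"  # differs at positions 1 and 20
  g <- plant_genome(paste0(relative, "TGG"), seed = 8)
  idx <- build_target_index(g, k = 20)
  expect_equal(neighbor_counts(idx, proto),
               c(H0 = 0L, H1 = 0L, H2 = 1L, H3 = 0L))
  expect_equal(nrow(hamming_neighbors(idx, proto, max_distance = 1)), 0L)
  bf <- brute_force_site_scan(g, proto, max_distance = 3)
  expect_equal(bf$distance, 2L)
})

test_that("trie enumeration matches the brute-force oracle on random genomes", {
  set.seed(11)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3e4, TRUE), collapse = ""),
         chr2 = paste(sample(c("A", "C", "G", "T"), 1e4, TRUE), collapse = ""))
  idx <- build_target_index(g, k = 20)
  guides <- c(sample(unique(idx$sites$protospacer), 40),
              replicate(10, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                  collapse = "")))
  bf <- brute_force_site_scan(g, guides, max_distance = 3)
  tq <- speccorr:::.query_index(idx, guides, 3)
  expect_identical(site_key(tq), site_key(bf))
  expect_identical(tq$guide_idx, bf$guide_idx)
  # monotonicity in max_distance, and determinism
  for (d in 0:2) {
    a <- hamming_neighbors(idx, guides[1], d)
    b <- hamming_neighbors(idx, guides[1], d + 1L)
    expect_true(nrow(merge(a, b)) == nrow(a))
  }
  expect_identical(hamming_neighbors(idx, guides[2]),
                   hamming_neighbors(idx, guides[2]))
})

test_that("neighbor output is ordered by chrom, start, strand", {
  set.seed(12)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2e4, TRUE), collapse = ""))
  idx <- build_target_index(g, k = 20)
  gu <- idx$sites$protospacer[1]
  nb <- hamming_neighbors(idx, gu)
  ord <- order(nb$chrom, nb$start, nb$strand, method = "radix")
  expect_equal(ord, seq_len(nrow(nb)))
})

test_that("the index round-trips through its text serialization", {
  set.seed(13)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1e4, TRUE), collapse = ""))
  idx <- build_target_index(g, k = 20, genome_id = "fixture13")
  path <- tempfile(fileext = ".tsv")
  write_target_index(idx, path)
  idx2 <- read_target_index(path)
  expect_equal(idx2$k, idx$k)
  expect_equal(idx2$genome_id, "fixture13")
  expect_equal(idx2$sites, idx$sites)
  gu <- idx$sites$protospacer[5]
  expect_identical(hamming_neighbors(idx, gu), hamming_neighbors(idx2, gu))
  bed <- tempfile(fileext = ".bed")
  write_sites_bed(hamming_neighbors(idx, gu), "guide1", 20, bed)
  rec <- read.delim(bed, header = FALSE)
  expect_equal(rec$V3 - rec$V2, rep(20L, nrow(rec)))
  expect_true(all(rec$V5 %in% 0:3))
})

test_that("the brute-force scanner refuses oversized genomes by default", {
  g <- plant_genome(paste0(safe_proto(seed = 14), "TGG"), seed = 14)
  expect_error(brute_force_site_scan(g, safe_proto(seed = 14),
                                     max_genome_bp = 10), "force")
  expect_silent(brute_force_site_scan(g, safe_proto(seed = 14),
                                      max_genome_bp = 10, force = TRUE))
})
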