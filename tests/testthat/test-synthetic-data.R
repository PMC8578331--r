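test_that("planted repeat families control perfect-target counts", {
  fam <- data.frame(copies = 5L, unit_length = 60L, mutation_rate = 0)
  sim <- simulate_genome(5e4, fam, seed = 71)
  expect_equal(nrow(sim$manifest), 5L)
  # copies do not overlap
  m <- sim$manifest[order(sim$manifest$start), ]
  expect_true(all(diff(m$start) >= 60))
  # the unit's built-in protospacer has exactly 5 perfect targets
  idx <- build_target_index(sim$genome, k = 20)
  unit_proto <- substr(sim$genome[[1]], m$start[1] + 1, m$start[1] + 20)
  expect_equal(unname(neighbor_counts(idx, unit_proto)["H0"]), 5L)
})

test_that("per-copy mutations scatter copies into the H1+ neighborhood", {
  fam <- data.frame(copies = 12L, unit_length = 60L, mutation_rate = 0.03)
  sim <- simulate_genome(8e4, fam, seed = 72)
  expect_true(any(sim$manifest$n_mutations > 0))
  idx <- build_target_index(sim$genome, k = 20)
  m <- sim$manifest[sim$manifest$n_mutations == 0, ]
  expect_gt(nrow(m), 0)
  unit_proto <- substr(sim$genome[[1]], m$start[1] + 1, m$start[1] + 20)
  nc <- neighbor_counts(idx, unit_proto)
  expect_gt(nc[["H0"]], 0)
  expect_gt(sum(nc[c("H1", "H2", "H3")]), 0)
})

test_that("genome simulation validates its inputs", {
  expect_error(simulate_genome(5e3), "10 kb")
  big <- data.frame(copies = 100L, unit_length = 500L, mutation_rate = 0)
  expect_error(simulate_genome(2e4, big, seed = 1), "exceed")
})

test_that("designed libraries have the requested shape and genomic presence", {
  sim <- simulate_genome(3e5, default_repeat_families(20), seed = 73)
  idx <- build_target_index(sim$genome, k = 20)
  lib <- design_library(sim$genome, sim$manifest, n_genes = 100,
                        guides_per_gene = 4, frac_promiscuous = 0.3,
                        index = idx, seed = 73)
  expect_equal(nrow(lib), 400L)
  expect_equal(length(unique(lib$guide_id)), 400L)
  expect_true(all(lib$sequence %in% idx$sites$protospacer))
  ann <- annotate_library(idx, lib)
  prom <- ann$H0 > 1 | (!is.na(ann$specificity) & ann$specificity < 0.16)
  expect_gte(mean(prom), 0.25)
  expect_true(any(!is.na(ann$specificity) & ann$specificity >= 0.16))
})

test_that("a zero promiscuous fraction yields uniquely targeting guides", {
  sim <- simulate_genome(2e5, default_repeat_families(5), seed = 74)
  idx <- build_target_index(sim$genome, k = 20)
  lib <- design_library(sim$genome, sim$manifest, n_genes = 50,
                        guides_per_gene = 4, frac_promiscuous = 0,
                        index = idx, seed = 74)
  ann <- annotate_library(idx, lib)
  expect_true(all(ann$H0 == 1L))
})

test_that("PAM-poor gene regions are reported by name", {
  g <- list(genome = c(chr1 = safe_background(12000, seed = 75)),
            manifest = data.frame(family = integer(0), copy = integer(0),
                                  start = integer(0), end = integer(0),
                                  n_mutations = integer(0)))
  expect_error(design_library(g$genome, g$manifest, n_genes = 4,
                              guides_per_gene = 3, frac_promiscuous = 0,
                              seed = 75),
               "region")
})

test_that("null screens are centered and uncorrelated with specificity", {
  n <- 10000
  prof <- data.frame(guide_id = paste0("g", 1:n), sequence = "N",
                     gene = rep(sprintf("gene%04d", 1:2000), each = 5),
                     H0 = 1L, H1 = 0L, H2 = 0L, H3 = 0L,
                     specificity = sample(c(1, 0.5, 0.25, 0.125), n, TRUE),
                     flags = "")
  scr <- simulate_screen(prof, frac_essential = 0.3,
                         gene_effect_essential = 0, gene_effect_sd = 0,
                         offtarget_beta = 0, seed = 76)
  pre <- suppressMessages(prepare_screen(scr$counts))
  expect_equal(mean(pre$logfc_mean), 0, tolerance = 0.05)
  p <- prof[match(pre$guide_id, prof$guide_id), ]
  expect_lt(abs(cor(p$specificity, pre$logfc_mean)), 0.05)
})

test_that("essential gene effects are recovered by specific guides", {
  n <- 5000
  prof <- data.frame(guide_id = paste0("g", 1:n), sequence = "N",
                     gene = rep(sprintf("gene%04d", 1:1000), each = 5),
                     H0 = 1L, H1 = 0L, H2 = 0L, H3 = 0L,
                     specificity = 1, flags = "")
  # a mostly-neutral library: median-ratio normalization assumes the
  # majority of guides are unchanged
  scr <- simulate_screen(prof, frac_essential = 0.1,
                         gene_effect_essential = -2, gene_effect_sd = 0,
                         offtarget_beta = 0.5, seed = 77)
  pre <- suppressMessages(prepare_screen(scr$counts))
  tr <- scr$truth$guides[match(pre$guide_id, scr$truth$guides$guide_id), ]
  expect_equal(mean(pre$logfc_mean[tr$essential]), -2, tolerance = 0.1)
  expect_equal(mean(pre$logfc_mean[!tr$essential]), 0, tolerance = 0.1)
  # fully specific guides carry no off-target toxicity
  expect_true(all(tr$O == 0))
})

test_that("the one-call generator is deterministic and self-consistent", {
  s1 <- simulate_crispr_screen(seed = 78, n_genes = 25, guides_per_gene = 4,
                               genome_length = 5e4)
  s2 <- simulate_crispr_screen(seed = 78, n_genes = 25, guides_per_gene = 4,
                               genome_length = 5e4)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$profiles, s2$profiles)
  s3 <- simulate_crispr_screen(seed = 79, n_genes = 25, guides_per_gene = 4,
                               genome_length = 5e4)
  expect_false(identical(s1$counts, s3$counts))
  # ground-truth invariant: covariates recomputed from the emitted genome
  # reproduce the stored annotation exactly
  idx <- build_target_index(s1$genome, k = 20,
                            genome_id = s1$index$genome_id)
  re_ann <- annotate_library(idx, s1$library)
  expect_equal(re_ann, s1$profiles)
  # gold sets partition the gene universe
  expect_equal(sort(c(s1$gold$essential, s1$gold$nonessential)),
               sort(unique(s1$library$gene)))
})

test_that("the 30-read filter removes exactly the low-plasmid guides", {
  s <- simulate_crispr_screen(seed = 80, n_genes = 25, guides_per_gene = 4,
                              genome_length = 5e4, depth = 60)
  pre <- suppressMessages(prepare_screen(s$counts))
  expect_equal(sort(pre$guide_id),
               sort(s$counts$guide_id[s$counts$plasmid >= 30]))
})
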