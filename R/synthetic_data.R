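#' Default repeat-family specification
#'
#' Repeat families are the source of guide promiscuity in synthetic
#' genomes: near-identical copies of a unit sequence give guides designed
#' inside the unit multiple perfect (H0 > 1) or near-perfect (H1 > 0)
#' target sites. Copy numbers cycle over 2, 3, 4, 6 and 8 so libraries
#' span specificity scores on both sides of 0.16.
#'
#' @param n_families Number of families.
#' @param unit_length Repeat unit length in bp (default 80).
#' @param mutation_rate Per-base substitution rate applied independently to
#'   each copy (default 0.02), scattering some copies to Hamming distance
#'   1+ of the consensus.
#' @return Data frame with columns copies, unit_length, mutation_rate.
#' @export
default_repeat_families <- function(n_families = 25L, unit_length = 80L,
                                    mutation_rate = 0.02) {
  data.frame(copies = rep_len(c(2L, 3L, 4L, 6L, 8L), n_families),
             unit_length = unit_length, mutation_rate = mutation_rate)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Simulate a mini genome with planted repeat families
#'
#' An i.i.d. ACGT background of `genome_length` bp with non-overlapping
#' planted repeat families. Each family unit is built to contain at least
#' one NGG-adjacent protospacer, so guides designed inside a unit have a
#' controllable number of perfect targets.
#'
#' @param genome_length Genome size in bp (>= 10 kb).
#' @param repeat_families Data frame as from [default_repeat_families()],
#'   or `NULL` for no repeats.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return List with `genome` (named character vector, one sequence
#'   `chr1`) and `manifest` (one row per planted copy: family, copy,
#'   start, end, n_mutations; 0-based half-open coordinates).
#' @export
simulate_genome <- function(genome_length = 2e6,
                            repeat_families = default_repeat_families(),
                            seed = NULL) {
  if (genome_length < 1e4) stop("genome_length must be at least 10 kb")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, genome_length, replace = TRUE)
  rows <- list()
  if (!is.null(repeat_families) && nrow(repeat_families) > 0) {
    total_bp <- sum(repeat_families$copies * repeat_families$unit_length)
    if (total_bp > genome_length / 2)
      stop("planted repeats exceed half the genome length")
    occupied <- logical(genome_length)
    for (f in seq_len(nrow(repeat_families))) {
      ul <- repeat_families$unit_length[f]
      if (ul < 30L) stop("repeat unit_length must be at least 30 bp")
      # unit guaranteed to contain a 20-mer protospacer followed by TGG
      unit <- c(sample(bases, 20L, replace = TRUE), "T", "G", "G",
                sample(bases, ul - 23L, replace = TRUE))
      for (cp in seq_len(repeat_families$copies[f])) {
        placed <- FALSE
        for (try in 1:200) {
          s <- sample.int(genome_length - ul - 2L, 1L)
          if (!any(occupied[s:(s + ul + 1L)])) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place repeat copy; genome too crowded")
        u <- unit
        nmut <- rbinom(1L, ul, repeat_families$mutation_rate[f])
        if (nmut > 0) {
          at <- sample.int(ul, nmut)
          u[at] <- vapply(u[at], function(b)
            sample(setdiff(bases, b), 1L), character(1))
        }
        g[s:(s + ul - 1L)] <- u
        occupied[s:(s + ul + 1L)] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, copy = cp, start = s - 1L, end = s - 1L + ul,
          n_mutations = nmut)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = integer(0), copy = integer(0), start = integer(0),
               end = integer(0), n_mutations = integer(0))
  list(genome = c(chr1 = paste(g, collapse = "")), manifest = manifest)
}

#' Design a guide library over a synthetic genome
#'
#' Partitions the genome into `n_genes` contiguous gene regions and draws
#' `guides_per_gene` NGG-adjacent protospacers per region. A configurable
#' fraction of guide slots is instead drawn from the planted repeat loci,
#' creating promiscuous guides (multiple perfect targets and/or low
#' specificity). Non-promiscuous slots use protospacers that occur exactly
#' once in the genome.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param manifest Planted-repeat manifest from [simulate_genome()].
#' @param n_genes,guides_per_gene Library dimensions.
#' @param frac_promiscuous Fraction of guide slots drawn from repeat loci.
#' @param k Protospacer length (default 20).
#' @param index Optional prebuilt [build_target_index()] for `genome`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Data frame: guide_id, sequence, gene.
#' @export
design_library <- function(genome, manifest, n_genes = 200L,
                           guides_per_gene = 5L, frac_promiscuous = 0.3,
                           k = 20L, index = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_genes <- as.integer(n_genes)
  guides_per_gene <- as.integer(guides_per_gene)
  index <- index %||% build_target_index(genome, k = k)
  sites <- index$sites
  L <- nchar(genome[[1]])
  dupkey <- sites$protospacer %in% sites$protospacer[duplicated(sites$protospacer)]
  in_repeat <- rep(FALSE, nrow(sites))
  if (nrow(manifest) > 0) {
    # repeat copies never overlap, so one findInterval lookup suffices
    mo <- manifest[order(manifest$start), , drop = FALSE]
    iv <- findInterval(sites$start, mo$start)
    hit <- iv >= 1L
    in_repeat[hit] <- sites$start[hit] + k <= mo$end[iv[hit]]
  }
  region <- pmin(floor(sites$start / (L / n_genes)) + 1L, n_genes)

  total <- n_genes * guides_per_gene
  n_prom <- round(frac_promiscuous * total)
  # prefer consensus sequences with multiple exact copies (H0 > 1); fill the
  # remainder with mutation-diverged repeat sequences (H0 = 1, H1+ neighbors)
  pool_multi <- unique(sites$protospacer[in_repeat & dupkey])
  pool_single <- setdiff(unique(sites$protospacer[in_repeat]), pool_multi)
  n_multi <- min(length(pool_multi), round(0.85 * n_prom))
  n_single <- min(length(pool_single), n_prom - n_multi)
  if (n_multi + n_single < n_prom) {
    n_multi <- min(length(pool_multi), n_prom - n_single)
    if (n_multi + n_single < n_prom)
      warning("repeat loci provide only ", n_multi + n_single,
              " distinct promiscuous protospacers (", n_prom, " requested)")
    n_prom <- n_multi + n_single
  }
  prom_seqs <- c(if (n_multi > 0) sample(pool_multi, n_multi),
                 if (n_single > 0) sample(pool_single, n_single))
  if (n_prom > 1) prom_seqs <- sample(prom_seqs)
  # promiscuity clusters by gene, as in real libraries: a subset of
  # promiscuity-prone genes receives most of the repeat-derived guides
  prom_slots <- integer(0)
  if (n_prom > 0) {
    n_prom_genes <- min(n_genes, ceiling(n_prom / (0.8 * guides_per_gene)))
    prom_genes <- sample.int(n_genes, n_prom_genes)
    # rank-major order spreads the promiscuous slots evenly over the
    # promiscuity-prone genes (~80% of each such gene's guides)
    slot_mat <- vapply(prom_genes, function(g)
      (g - 1L) * guides_per_gene + sample.int(guides_per_gene),
      integer(guides_per_gene))
    gene_slots <- as.integer(t(slot_mat))
    prom_slots <- sort(gene_slots[seq_len(min(n_prom, length(gene_slots)))])
    n_prom <- length(prom_slots)
    prom_seqs <- prom_seqs[seq_len(n_prom)]
  }

  # unique, non-repeat candidate protospacers, bucketed by gene region
  cand <- which(!dupkey & !in_repeat)
  avail_by_region <- split(cand, region[cand])
  is_prom_slot <- logical(total)
  is_prom_slot[prom_slots] <- TRUE
  seqs <- character(total)
  slot <- 1L
  for (gene in seq_len(n_genes)) {
    slots <- slot:(slot + guides_per_gene - 1L)
    needed <- sum(!is_prom_slot[slots])
    avail <- avail_by_region[[as.character(gene)]]
    if (is.null(avail) || length(avail) < needed)
      stop("gene region ", gene, " is too PAM-poor: ", length(avail),
           " candidate sites for ", needed, " guides")
    pick <- avail[sample.int(length(avail), needed)]
    seqs[slots[!is_prom_slot[slots]]] <- sites$protospacer[pick]
    slot <- slot + guides_per_gene
  }
  seqs[prom_slots] <- prom_seqs
  keep <- nzchar(seqs)
  data.frame(guide_id = sprintf("g%05d", seq_len(total))[keep],
             sequence = seqs[keep],
             gene = rep(sprintf("gene%04d", seq_len(n_genes)),
                        each = guides_per_gene)[keep],
             stringsAsFactors = FALSE)
}

#' Simulate a pooled essentiality screen over an annotated library
#'
#' The generative model mirrors the additive decomposition the correction
#' assumes: each guide's expected log2 fold change is the sum of its
#' gene-knockout effect G (drawn per gene; 0 for non-essential genes) and
#' its off-target toxicity O computed from the guide's realized
#' specificity, `O = -beta * (1/s - 1)` (0 for fully specific guides;
#' increasingly negative with off-target CFD mass). Counts are negative
#' binomial around a per-guide abundance with per-sample multiplicative
#' size factors, so median-ratio normalization has real work to do.
#'
#' @param profiles Annotation table from [annotate_library()] for the
#'   library (provides the realized covariates).
#' @param frac_essential Fraction of genes that are essential.
#' @param gene_effect_essential Mean log2 fold-change effect of knocking
#'   out an essential gene (default -2).
#' @param gene_effect_sd SD of essential gene effects (default 0.3).
#' @param offtarget_beta Toxicity per unit of excess CFD mass (default
#'   0.5; 0 for null screens).
#' @param misspecified If `TRUE`, toxicity is `-0.15 * H2` instead — a
#'   variant outside the model's covariate form, for robustness checks.
#' @param depth Mean sequencing depth per guide (default 500 reads).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param n_replicates Number of post-screen replicates (default 2).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return List: `counts` (guide_id, gene, plasmid, rep1..repN), `truth`
#'   (per-guide G, O and expected logFC; per-gene table) and `gold`
#'   ([gold_standard()] built from the simulated gene classes).
#' @export
simulate_screen <- function(profiles, frac_essential = 0.3,
                            gene_effect_essential = -2, gene_effect_sd = 0.3,
                            offtarget_beta = 0.5, misspecified = FALSE,
                            depth = 500, nb_dispersion = 0.05,
                            n_replicates = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(frac_essential > 0, frac_essential < 1)
  genes <- sort(unique(profiles$gene))
  n_ess <- max(1L, round(frac_essential * length(genes)))
  ess_genes <- sort(sample(genes, n_ess))
  G_gene <- setNames(numeric(length(genes)), genes)
  G_gene[ess_genes] <- rnorm(n_ess, gene_effect_essential, gene_effect_sd)

  s <- profiles$specificity
  O <- if (misspecified) -0.15 * profiles$H2 else {
    ifelse(is.na(s), 0, -offtarget_beta * (1 / s - 1))
  }
  G <- unname(G_gene[profiles$gene])
  lfc <- G + O

  n <- nrow(profiles)
  size <- 1 / nb_dispersion
  abundance <- exp(rnorm(n, 0, 0.3))           # plasmid composition spread
  sf <- exp(rnorm(n_replicates + 1L, 0, 0.15)) # per-sample size factors
  mu_plasmid <- depth * abundance * sf[1]
  counts <- data.frame(guide_id = profiles$guide_id, gene = profiles$gene,
                       plasmid = rnbinom(n, mu = mu_plasmid, size = size),
                       stringsAsFactors = FALSE)
  if (mean(mu_plasmid < 30) > 0.10)
    warning("expected plasmid counts below 30 for >10% of guides; ",
            "the read filter will remove many of them")
  for (r in seq_len(n_replicates)) {
    mu <- depth * abundance * sf[r + 1L] * 2^lfc
    counts[[paste0("rep", r)]] <- rnbinom(n, mu = mu, size = size)
  }
  truth <- list(
    guides = data.frame(guide_id = profiles$guide_id, gene = profiles$gene,
                        essential = profiles$gene %in% ess_genes,
                        G = G, O = O, expected_logfc = lfc,
                        stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, essential = genes %in% ess_genes,
                       G = unname(G_gene), stringsAsFactors = FALSE),
    size_factors = sf
  )
  list(counts = counts, truth = truth,
       gold = gold_standard(ess_genes, setdiff(genes, ess_genes)))
}

#' One-call synthetic screen: genome, library, annotation, counts, truth
#'
#' Orchestrates [simulate_genome()], [design_library()],
#' [annotate_library()] and [simulate_screen()] under a single seed. The
#' repeat-family content scales with the number of promiscuous guide slots
#' requested so the promiscuous sequence pool is never exhausted.
#'
#' @inheritParams design_library
#' @inheritParams simulate_screen
#' @param genome_length Genome size in bp.
#' @param cfd_table CFD penalty table for the annotation.
#' @param seed Integer seed (required; the whole dataset is a deterministic
#'   function of it).
#' @return List: genome, manifest, index, library, profiles, counts,
#'   truth, gold.
#' @export
simulate_crispr_screen <- function(seed, n_genes = 200L, guides_per_gene = 5L,
                                   frac_promiscuous = 0.3,
                                   genome_length = 2e6, k = 20L,
                                   frac_essential = 0.3,
                                   gene_effect_essential = -2,
                                   gene_effect_sd = 0.3,
                                   offtarget_beta = 0.5, misspecified = FALSE,
                                   depth = 500, nb_dispersion = 0.05,
                                   n_replicates = 2L,
                                   cfd_table = cfd_penalty_table()) {
  set.seed(as.integer(seed))
  n_prom <- round(frac_promiscuous * n_genes * guides_per_gene)
  fams <- default_repeat_families(n_families = max(10L, ceiling(n_prom / 6)))
  sim <- simulate_genome(genome_length, fams, seed = NULL)
  index <- build_target_index(sim$genome, k = k,
                              genome_id = paste0("synthetic_", seed))
  lib <- design_library(sim$genome, sim$manifest, n_genes, guides_per_gene,
                        frac_promiscuous, k = k, index = index, seed = NULL)
  profiles <- annotate_library(index, lib, table = cfd_table)
  scr <- simulate_screen(profiles, frac_essential, gene_effect_essential,
                         gene_effect_sd, offtarget_beta, misspecified,
                         depth, nb_dispersion, n_replicates, seed = NULL)
  c(list(genome = sim$genome, manifest = sim$manifest, index = index,
         library = lib, profiles = profiles), scr)
}
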