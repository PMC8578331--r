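# Shared fixtures: planted genomes with exactly known site content, and
# injectable CFD tables built through the public loader.

# reverse complement of a character string
rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A/T-only background contains no GG or CC, so every NGG site in a planted
# genome comes from a planted element.
safe_background <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
}

# protospacer over {A,C,T} with no CC dinucleotide: planting proto+NGG adds
# exactly one GG (the PAM) and no CC
safe_proto <- function(k = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p <- paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = "")
    if (!grepl("CC", p)) return(p)
  }
}

# genome string with elements planted left to right, padded by A/T background
plant_genome <- function(elements, pad = 50, seed = 1) {
  set.seed(seed)
  parts <- character(2 * length(elements) + 1)
  parts[1] <- safe_background(pad)
  for (i in seq_along(elements)) {
    parts[2 * i] <- elements[i]
    parts[2 * i + 1] <- safe_background(pad)
  }
  c(chr1 = paste(parts, collapse = ""))
}

# CFD table injected through the public file-based loader
write_cfd_table <- function(default = 0.5, overrides = NULL,
                            pams = c(AGG = 1, CGG = 1, GGG = 1, TGG = 1)) {
  bases <- c("A", "C", "G", "T")
  rows <- expand.grid(position = 1:20, guide_base = bases, site_base = bases,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$guide_base != rows$site_base, ]
  rows$penalty <- default
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- rows$position == overrides$position[i] &
        rows$guide_base == overrides$guide_base[i] &
        rows$site_base == overrides$site_base[i]
      rows$penalty[hit] <- overrides$penalty[i]
    }
  }
  mm_path <- tempfile(fileext = ".tsv")
  pam_path <- tempfile(fileext = ".tsv")
  write.table(rows, mm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pam = names(pams), penalty = unname(pams)),
              pam_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfd_penalty_table(mm_path, pam_path)
}

# canonical column view for comparing trie and brute-force outputs
site_key <- function(df) {
  df <- df[c("chrom", "start", "strand", "protospacer", "pam", "distance")]
  rownames(df) <- NULL
  df
}

# a small simulated screen shared by correction/benchmark tests
small_screen <- function(seed = 7, ...) {
  sim <- simulate_crispr_screen(seed = seed, n_genes = 60, guides_per_gene = 5,
                                genome_length = 2e5, ...)
  pre <- suppressMessages(prepare_screen(sim$counts))
  prof <- sim$profiles[match(pre$guide_id, sim$profiles$guide_id), ]
  rownames(prof) <- NULL
  list(sim = sim, pre = pre, prof = prof)
}
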