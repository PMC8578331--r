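#' Read a genome into a named character vector
#'
#' Accepts a FASTA path (gzip allowed), a [Biostrings::DNAStringSet], or an
#' already-loaded named character vector. Sequence names are truncated at the
#' first whitespace and sequences are uppercased.
#'
#' @param x FASTA file path, `DNAStringSet`, or named character vector.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ds <- tryCatch(Biostrings::readDNAStringSet(x),
                   error = function(e) stop("malformed FASTA '", x, "': ",
                                            conditionMessage(e), call. = FALSE))
    x <- setNames(as.character(ds), names(ds))
  } else if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  } else if (!is.character(x)) {
    stop("genome must be a FASTA path, DNAStringSet or named character vector")
  }
  if (length(x) == 0L) stop("empty genome")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all genome sequences must be named")
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- names(x)[duplicated(names(x))]
  if (length(dup)) stop("duplicate sequence record name(s): ",
                        paste(unique(dup), collapse = ", "))
  toupper(x)
}

.check_guide <- function(guide, k) {
  if (!is.character(guide) || length(guide) < 1L) stop("guide must be a character vector")
  guide <- toupper(guide)
  bad <- nchar(guide) != k
  if (any(bad)) stop("guide length must equal index k = ", k, " (offending: ",
                     paste(head(guide[bad], 3), collapse = ", "), ")")
  if (any(grepl("[^ACGT]", guide))) stop("guides must contain only A/C/G/T")
  guide
}

.check_pams <- function(pam_patterns) {
  pam_patterns <- toupper(pam_patterns)
  if (any(nchar(pam_patterns) != 3L) ||
      any(grepl("[^ACGTRYSWKMBDHVN]", pam_patterns)))
    stop("PAM patterns must be 3-letter IUPAC strings (e.g. 'NGG')")
  pam_patterns
}

#' Build an exact index of all Cas9 target sites in a genome
#'
#' Scans both strands of every sequence for k-mer protospacers immediately
#' 5' of a PAM match and stores them keyed on the protospacer sequence
#' (sorted keys; queries run a bounded-mismatch depth-first traversal over
#' the implied prefix tree). Reverse-strand sites are stored as the reverse
#' complement of the genomic window, so the stored protospacer always reads
#' 5'->3' on the cutting strand. Windows containing non-ACGT characters are
#' skipped entirely.
#'
#' @param genome FASTA path, `DNAStringSet` or named character vector.
#' @param k Protospacer length, 19 or 20.
#' @param pam_patterns Character vector of 3-letter IUPAC PAM patterns
#'   (default `"NGG"`, the SpCas9 motif).
#' @param exclude_alt Drop sequences whose name matches `alt_pattern`
#'   (alternative contigs would otherwise inflate off-target counts).
#' @param alt_pattern Regular expression identifying alternative contigs.
#' @param genome_id Provenance string stored with the index.
#' @return A `target_index` object: list with `k`, `pam_patterns`,
#'   `genome_id`, `chroms`, and a `sites` data frame (protospacer, chrom,
#'   start, strand, pam) sorted by protospacer key.
#' @examples
#' g <- c(chrA = paste0(strrep("A", 30), "ACGTACGTACGTACGTACGT", "TGG"))
#' idx <- build_target_index(g, k = 20)
#' @export
build_target_index <- function(genome, k = 20L, pam_patterns = "NGG",
                               exclude_alt = FALSE, alt_pattern = "_alt",
                               genome_id = NULL) {
  genome <- read_genome(genome)
  if (!k %in% c(19L, 20L)) stop("k must be 19 or 20")
  pam_patterns <- .check_pams(pam_patterns)
  if (exclude_alt) {
    keep <- !grepl(alt_pattern, names(genome))
    genome <- genome[keep]
    if (length(genome) == 0L) stop("all sequences excluded by alt_pattern")
  }
  sc <- cpp_scan_sites(unname(genome), as.integer(k), pam_patterns)
  sites <- data.frame(
    protospacer = as.character(sc$protospacer),
    chrom = names(genome)[sc$chrom_idx],
    start = as.integer(sc$start),
    strand = ifelse(sc$strand_plus == 1L, "+", "-"),
    pam = as.character(sc$pam),
    stringsAsFactors = FALSE
  )
  ord <- order(sites$protospacer, sites$chrom, sites$start, sites$strand,
               method = "radix")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(k = as.integer(k), pam_patterns = pam_patterns,
                 genome_id = genome_id %||% "unnamed_genome",
                 chroms = names(genome), sites = sites),
            class = "target_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.target_index <- function(x, ...) {
  cat("target_index:", nrow(x$sites), "sites |", length(unique(x$sites$protospacer)),
      "distinct protospacers | k =", x$k,
      "| PAM:", paste(x$pam_patterns, collapse = ","),
      "| genome:", x$genome_id, "\n")
  invisible(x)
}

# Batch bounded-Hamming query; returns a data.frame with a guide column.
.query_index <- function(index, guides, max_distance) {
  stopifnot(inherits(index, "target_index"))
  if (max_distance < 0 || max_distance > 3) stop("max_distance must be in 0..3")
  guides <- .check_guide(guides, index$k)
  hits <- cpp_trie_query(index$sites$protospacer, guides,
                         as.integer(max_distance))
  out <- index$sites[hits$site_idx, , drop = FALSE]
  out$distance <- hits$distance
  out$guide <- guides[hits$guide_idx]
  out$guide_idx <- hits$guide_idx
  ord <- order(out$guide_idx, out$chrom, out$start, out$strand, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate a guide's Hamming neighborhood
#'
#' Returns exactly the indexed target sites whose protospacer differs from
#' the guide at `max_distance` or fewer positions (substitutions only; the
#' PAM is not counted), each annotated with its Hamming distance, ordered by
#' (chrom, start, strand).
#'
#' @param index A `target_index`.
#' @param guide A single protospacer sequence of length `index$k`.
#' @param max_distance Maximum Hamming distance, 0..3 (default 3).
#' @return Data frame of target sites: chrom, start (0-based protospacer
#'   start on the + strand), strand, protospacer, pam, distance.
#' @export
hamming_neighbors <- function(index, guide, max_distance = 3L) {
  stopifnot(length(guide) == 1L)
  out <- .query_index(index, guide, max_distance)
  out[c("chrom", "start", "strand", "protospacer", "pam", "distance")]
}

#' Count a guide's neighbors at Hamming distance 0-3
#'
#' @inheritParams hamming_neighbors
#' @return Named integer vector `c(H0, H1, H2, H3)`.
#' @export
neighbor_counts <- function(index, guide) {
  nb <- hamming_neighbors(index, guide, max_distance = 3L)
  counts <- tabulate(nb$distance + 1L, nbins = 4L)
  setNames(as.integer(counts), c("H0", "H1", "H2", "H3"))
}

#' Brute-force sliding-window off-target scan (test oracle)
#'
#' Independent of the index: slides a window over both strands of the
#' genome, checks the PAM directly, and counts mismatches position by
#' position. Output contract is identical to [hamming_neighbors()]. Refuses
#' genomes over `max_genome_bp` unless `force = TRUE`.
#'
#' @inheritParams build_target_index
#' @param guide Single protospacer sequence (length inferred as k).
#' @param max_distance Maximum Hamming distance, 0..3.
#' @param max_genome_bp Size guard (default 50 Mb).
#' @param force Override the size guard.
#' @return Data frame as in [hamming_neighbors()].
#' @export
brute_force_site_scan <- function(genome, guide, max_distance = 3L,
                                  pam_patterns = "NGG", max_genome_bp = 5e7,
                                  force = FALSE) {
  genome <- read_genome(genome)
  if (sum(nchar(genome)) > max_genome_bp && !force)
    stop("genome exceeds ", max_genome_bp, " bp; pass force = TRUE to override")
  guide <- toupper(guide)
  k <- nchar(guide[1])
  guide <- .check_guide(guide, k)
  pam_patterns <- .check_pams(pam_patterns)
  hits <- cpp_brute_scan(unname(genome), guide, as.integer(k),
                         as.integer(max_distance), pam_patterns)
  out <- data.frame(
    chrom = names(genome)[hits$chrom_idx],
    start = as.integer(hits$start),
    strand = ifelse(hits$strand_plus == 1L, "+", "-"),
    protospacer = as.character(hits$protospacer),
    pam = as.character(hits$pam),
    distance = as.integer(hits$distance),
    guide_idx = hits$guide_idx,
    stringsAsFactors = FALSE
  )
  ord <- order(out$guide_idx, out$chrom, out$start, out$strand, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (length(guide) == 1L) out$guide_idx <- NULL
  out
}

#' Serialize a target index to a self-describing text file
#'
#' @param index A `target_index`.
#' @param path Output file path (plain TSV with `#` header lines).
#' @export
write_target_index <- function(index, path) {
  stopifnot(inherits(index, "target_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# speccorr_target_index\tv1",
               paste0("# k\t", index$k),
               paste0("# pams\t", paste(index$pam_patterns, collapse = ",")),
               paste0("# genome_id\t", index$genome_id),
               paste0("# chroms\t", paste(index$chroms, collapse = ","))), con)
  write.table(index$sites, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a serialized target index
#'
#' @param path File written by [write_target_index()].
#' @return A `target_index`.
#' @export
read_target_index <- function(path) {
  hdr <- readLines(path, n = 5L)
  if (!startsWith(hdr[1], "# speccorr_target_index"))
    stop("'", path, "' is not a speccorr target index file")
  field <- function(i) sub("^# [a-z_]+\t", "", hdr[i])
  sites <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sites$strand <- as.character(sites$strand)
  structure(list(k = as.integer(field(2)),
                 pam_patterns = strsplit(field(3), ",")[[1]],
                 genome_id = field(4),
                 chroms = strsplit(field(5), ",")[[1]],
                 sites = sites),
            class = "target_index")
}

#' Export enumerated target sites as BED6
#'
#' One record per site covering the protospacer (0-based, half-open);
#' name = query guide, score = Hamming distance.
#'
#' @param sites Data frame from [hamming_neighbors()] or
#'   [brute_force_site_scan()].
#' @param guide Guide name written into the BED name column.
#' @param k Protospacer length (interval width).
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, guide, k, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$start + k, name = guide,
                    score = sites$distance, strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
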