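#' Load a CFD penalty table
#'
#' The Cutting Frequency Determination (CFD) score models the likelihood
#' that Cas9 cuts a mismatched site as a product of per-position,
#' per-identity mismatch penalties and a PAM penalty. This loader reads a
#' mismatch table (columns `position` 1..20 counted from the PAM-distal end,
#' `guide_base`, `site_base`, `penalty`) and a PAM table (columns `pam`,
#' `penalty`). The tables shipped with the package
#' (`inst/extdata/cfd_*_penalties_synthetic.tsv`) are synthetic stand-ins
#' with the qualitative structure of empirical CFD constants (penalties
#' decrease toward the PAM; transitions are better tolerated than
#' transversions); substitute the published constants via `mismatch_path` /
#' `pam_path` for production use on real libraries.
#'
#' @param mismatch_path,pam_path Optional paths to user-supplied tables.
#' @return A `cfd_table`: list with a `[20 x 4 x 4]` penalty array
#'   (matching bases = 1) and a named PAM penalty vector.
#' @export
cfd_penalty_table <- function(mismatch_path = NULL, pam_path = NULL) {
  mismatch_path <- mismatch_path %||%
    system.file("extdata", "cfd_mismatch_penalties_synthetic.tsv",
                package = "speccorr", mustWork = TRUE)
  pam_path <- pam_path %||%
    system.file("extdata", "cfd_pam_penalties_synthetic.tsv",
                package = "speccorr", mustWork = TRUE)
  mm <- read.delim(mismatch_path, stringsAsFactors = FALSE)
  pam <- read.delim(pam_path, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  arr <- array(NA_real_, dim = c(20L, 4L, 4L),
               dimnames = list(NULL, bases, bases))
  for (b in bases) arr[, b, b] <- 1
  idx <- cbind(mm$position, match(mm$guide_base, bases), match(mm$site_base, bases))
  if (any(is.na(idx)) || any(mm$position < 1 | mm$position > 20))
    stop("invalid position or base in mismatch penalty table")
  arr[idx] <- mm$penalty
  if (any(mm$penalty < 0 | mm$penalty > 1)) stop("mismatch penalties must lie in [0,1]")
  if (any(pam$penalty < 0 | pam$penalty > 1)) stop("PAM penalties must lie in [0,1]")
  structure(list(mismatch = arr, pam = setNames(pam$penalty, toupper(pam$pam))),
            class = "cfd_table")
}

# Vectorised CFD for aligned guide/site pairs. 19-mers are anchored to the
# PAM-proximal positions of the 20-position table (positions 2..20).
.cfd_vec <- function(guides, sites, pams, table) {
  stopifnot(inherits(table, "cfd_table"))
  n <- length(guides)
  if (n == 0L) return(numeric(0))
  k <- nchar(guides[1])
  if (!k %in% c(19L, 20L)) stop("CFD table supports protospacer lengths 19 and 20")
  offset <- 20L - k
  gm <- matrix(unlist(strsplit(guides, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  sm <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  gi <- match(gm, bases)
  si <- match(sm, bases)
  pos <- matrix(rep(seq_len(k) + offset, each = n), nrow = n)
  pen <- table$mismatch[cbind(as.vector(pos), as.vector(gi), as.vector(si))]
  if (anyNA(pen)) stop("penalty missing from CFD table for some position/base pair")
  pen <- matrix(pen, nrow = n)
  pp <- table$pam[toupper(pams)]
  if (anyNA(pp)) stop("PAM penalty missing from CFD table for: ",
                      paste(unique(pams[is.na(pp)]), collapse = ", "))
  exp(rowSums(log(pen))) * unname(pp)
}

#' Score one target site with CFD
#'
#' Product over mismatched positions of the mismatch penalty, times the PAM
#' penalty. A perfect match with an NGG PAM scores 1.
#'
#' @param guide Protospacer sequence of the guide (19 or 20 nt).
#' @param site_protospacer Site protospacer, same length.
#' @param pam 3-mer PAM of the site.
#' @param table A [cfd_penalty_table()].
#' @return CFD value in \[0, 1\].
#' @export
cfd <- function(guide, site_protospacer, pam, table) {
  stopifnot(length(guide) == 1L, length(site_protospacer) == 1L)
  if (nchar(guide) != nchar(site_protospacer))
    stop("guide and site protospacer must have equal length")
  .cfd_vec(toupper(guide), toupper(site_protospacer), pam, table)
}

#' Aggregate a guide's CFD mass into its specificity score
#'
#' `s = 1 / sum(CFD over every enumerated site)`, the perfect site
#' contributing CFD 1. A guide whose only enumerated site is its single
#' perfect target scores 1; the score tends to 0 as off-target CFD mass
#' grows. Guides without a perfect (distance-0) site have no defined score
#' and return `NA` (never 0, which would fake maximal promiscuity).
#'
#' @param cfd_values CFD of every site in the guide's complete Hamming <= 3
#'   neighborhood.
#' @param distances Hamming distance of each site.
#' @return Specificity score in (0, 1\], or `NA` if no perfect target.
#' @export
specificity_score <- function(cfd_values, distances) {
  stopifnot(length(cfd_values) == length(distances))
  if (!any(distances == 0L)) return(NA_real_)
  1 / sum(cfd_values)
}

#' Annotate a guide library with off-target counts and specificity
#'
#' For each guide, enumerates its Hamming <= 3 neighborhood in the index,
#' scores every site with CFD, and reports the five covariates used by the
#' correction model: specificity score `s` plus neighbor counts H0-H3.
#' Guides absent from the genome are flagged (`not_in_index`), guides with
#' off-targets but no perfect site are flagged (`no_perfect_target`); both
#' get `NA` scores and are retained, never dropped.
#'
#' @param index A [build_target_index()] result.
#' @param guides Data frame with columns `guide_id`, `sequence` and
#'   optionally `gene`.
#' @param table A [cfd_penalty_table()].
#' @param max_distance Neighborhood radius (default 3).
#' @return Data frame: guide_id, sequence, gene, H0, H1, H2, H3,
#'   specificity, flags.
#' @export
annotate_library <- function(index, guides, table = cfd_penalty_table(),
                             max_distance = 3L) {
  stopifnot(is.data.frame(guides),
            all(c("guide_id", "sequence") %in% names(guides)))
  if (anyDuplicated(guides$guide_id))
    stop("duplicate guide IDs: ",
         paste(unique(guides$guide_id[duplicated(guides$guide_id)]), collapse = ", "))
  seqs <- .check_guide(guides$sequence, index$k)
  hits <- .query_index(index, seqs, max_distance)
  n <- nrow(guides)
  H <- matrix(0L, nrow = n, ncol = 4L,
              dimnames = list(NULL, c("H0", "H1", "H2", "H3")))
  spec <- rep(NA_real_, n)
  if (nrow(hits) > 0) {
    tab <- base::table(factor(hits$guide_idx, levels = seq_len(n)),
                       factor(hits$distance, levels = 0:3))
    H[] <- as.integer(tab)
    hits$cfd <- .cfd_vec(hits$guide, hits$protospacer, hits$pam, table)
    cfd_sum <- vapply(split(hits$cfd, factor(hits$guide_idx, levels = seq_len(n))),
                      sum, numeric(1))
    spec <- ifelse(H[, "H0"] > 0L, 1 / cfd_sum, NA_real_)
  }
  total <- rowSums(H)
  flags <- ifelse(total == 0L, "not_in_index",
                  ifelse(H[, "H0"] == 0L, "no_perfect_target", ""))
  out <- data.frame(guide_id = guides$guide_id, sequence = seqs,
                    gene = if ("gene" %in% names(guides)) guides$gene else NA_character_,
                    H, specificity = spec, flags = flags,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a library annotation table
#'
#' @param annot Result of [annotate_library()].
#' @param path Output TSV path.
#' @export
write_annotation <- function(annot, path) {
  write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
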