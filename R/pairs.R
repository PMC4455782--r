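# Hi-C read-pair ingestion and the restriction-site proximity filter.
#
# Internally every coordinate is a 0-based offset of a read's 5' alignment
# position; the ".pairs" interchange format is 1-based and is converted at
# the I/O boundary.

pairs_cols <- c("read_id", "contig1", "pos1", "strand1", "contig2", "pos2", "strand2")

#' Read a ".pairs" contact table
#'
#' Reads a 4DN-flavoured pairs file with tab-separated columns
#' `readID chrom1 pos1 chrom2 pos2 strand1 strand2` (positions 1-based) and
#' `#` header lines.
#'
#' @param path Path to the pairs file.
#' @return Tibble with columns `read_id`, `contig1`, `pos1`, `strand1`,
#'   `contig2`, `pos2`, `strand2`; positions converted to 0-based offsets.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) abort(paste0("pairs file not found: ", path))
  x <- readr::read_tsv(
    path,
    comment = "#",
    col_names = c("read_id", "contig1", "pos1", "contig2", "pos2", "strand1", "strand2"),
    col_types = readr::cols(
      read_id = "c", contig1 = "c", pos1 = "i",
      contig2 = "c", pos2 = "i", strand1 = "c", strand2 = "c"
    ),
    progress = FALSE
  )
  dplyr::select(
    dplyr::mutate(x, pos1 = .data$pos1 - 1L, pos2 = .data$pos2 - 1L),
    dplyr::all_of(pairs_cols)
  )
}

#' Write a ".pairs" contact table
#'
#' @param pairs Pairs tibble (0-based positions, see [read_pairs()]).
#' @param path Output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(pairs_cols %in% names(pairs)))
  out <- tibble(
    readID = pairs$read_id,
    chrom1 = pairs$contig1, pos1 = pairs$pos1 + 1L,
    chrom2 = pairs$contig2, pos2 = pairs$pos2 + 1L,
    strand1 = pairs$strand1, strand2 = pairs$strand2
  )
  write_atomic(path, function(tmp) {
    writeLines(c(
      "## pairs format v1.0",
      "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"
    ), tmp)
    readr::write_tsv(out, tmp, col_names = FALSE, append = TRUE, progress = FALSE)
  })
}

#' Convert name-grouped alignment records into Hi-C pairs
#'
#' Takes a table of per-read alignment records (one row per mate) and emits
#' one contact per read pair in which both mates are mapped. Pairs with an
#' unmapped mate are dropped and counted in the `"n_dropped_unmapped"`
#' attribute of the result.
#'
#' @param alignments Tibble with columns `read_id`, `contig`, `pos`
#'   (0-based 5' position), `strand` (`"+"`/`"-"`), `mapped` (logical).
#'   Records must be grouped by read id (all rows of a read adjacent) and
#'   each read id must have exactly two records.
#' @return Pairs tibble as in [read_pairs()], with attribute
#'   `"n_dropped_unmapped"`.
#' @export
pairs_from_alignments <- function(alignments) {
  need <- c("read_id", "contig", "pos", "strand", "mapped")
  stopifnot(all(need %in% names(alignments)))
  r <- rle(alignments$read_id)
  if (anyDuplicated(r$values) > 0L) {
    abort("alignment records are not name-grouped: a read id appears in non-adjacent blocks")
  }
  if (any(r$lengths != 2L)) {
    bad <- r$values[which(r$lengths != 2L)[1L]]
    abort(paste0("read id '", bad, "' has ", r$lengths[which(r$lengths != 2L)[1L]],
                 " alignment records; exactly 2 expected"))
  }
  first <- alignments[seq(1L, nrow(alignments), by = 2L), ]
  second <- alignments[seq(2L, nrow(alignments), by = 2L), ]
  both <- first$mapped & second$mapped
  out <- tibble(
    read_id = first$read_id[both],
    contig1 = first$contig[both], pos1 = as.integer(first$pos[both]),
    strand1 = first$strand[both],
    contig2 = second$contig[both], pos2 = as.integer(second$pos[both]),
    strand2 = second$strand[both]
  )
  attr(out, "n_dropped_unmapped") <- sum(!both)
  out
}

#' Read Hi-C pairs from a name-grouped SAM/BAM file
#'
#' Thin wrapper that loads alignment records with Rsamtools and delegates to
#' [pairs_from_alignments()]. The file must be name-grouped (both mates
#' adjacent), as produced by an aligner run in paired mode.
#'
#' @param path Path to a SAM or BAM file.
#' @return Pairs tibble (see [pairs_from_alignments()]).
#' @export
read_alignment_pairs <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required to read SAM/BAM input")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "strand"))
  )[[1L]]
  mapped <- bitwAnd(rec$flag, 4L) == 0L
  aln <- tibble(
    read_id = rec$qname,
    contig = as.character(rec$rname),
    pos = ifelse(is.na(rec$pos), 0L, rec$pos - 1L),
    strand = ifelse(as.character(rec$strand) == "-", "-", "+"),
    mapped = mapped
  )
  pairs_from_alignments(aln)
}

#' Filter Hi-C pairs by restriction-site proximity
#'
#' Keeps a read pair only if both 5' alignment positions lie within
#' `site_window` bp (inclusive) of the nearest restriction site on their
#' contig. Ligation junctions form at restriction sites, so informative Hi-C
#' reads start close to one; distant read starts are dominated by random
#' breaks and are discarded. Pairs with an endpoint on a contig carrying no
#' site at all can never pass and are counted separately.
#'
#' @param pairs Pairs tibble (see [read_pairs()]).
#' @param contigs Annotated contig tibble from [annotate_sites()].
#' @param site_window Maximum distance (bp) from a read's 5' position to the
#'   nearest site's first base; default 500.
#' @return The surviving pairs, with a `"filter_report"` attribute (tibble
#'   with `total`, `kept`, `dropped`, `dropped_zero_site`, `site_window`);
#'   see [filter_report()].
#' @export
filter_pairs <- function(pairs, contigs, site_window = 500) {
  stopifnot(all(pairs_cols %in% names(pairs)))
  if (!"sites" %in% names(contigs)) {
    abort("contigs must be annotated with restriction sites; run annotate_sites()")
  }
  if (length(site_window) != 1L || site_window < 0) {
    abort("site_window must be a single value >= 0")
  }
  unknown <- setdiff(unique(c(pairs$contig1, pairs$contig2)), contigs$id)
  if (length(unknown) > 0L) {
    abort(paste0("pair references unknown contig(s): ",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  site_index <- contigs$sites
  names(site_index) <- contigs$id
  endpoint_dist <- function(contig, pos) {
    d <- rep(Inf, length(pos))
    groups <- split(seq_along(pos), contig)
    for (cid in names(groups)) {
      sel <- groups[[cid]]
      d[sel] <- dist_to_nearest_site(pos[sel], site_index[[cid]])
    }
    d
  }
  d1 <- endpoint_dist(pairs$contig1, pairs$pos1)
  d2 <- endpoint_dist(pairs$contig2, pairs$pos2)
  keep <- d1 <= site_window & d2 <= site_window
  zero_site <- is.infinite(d1) | is.infinite(d2)
  out <- pairs[keep, ]
  attr(out, "filter_report") <- tibble(
    total = nrow(pairs),
    kept = sum(keep),
    dropped = sum(!keep),
    dropped_zero_site = sum(zero_site & !keep),
    site_window = site_window
  )
  out
}

#' Retrieve the filter report of a filtered pair set
#'
#' @param x Output of [filter_pairs()], or any object carrying a
#'   `"filter_report"` attribute (e.g. the result of [deconvolve()]).
#' @return One-row tibble with kept/dropped counts.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) abort("no filter report attached; was filter_pairs() used?")
  rep
}

#' Deduplicate pairs at coordinate level
#'
#' Removes read pairs with identical coordinates and strands (PCR duplicate
#' proxy). Off by default in the pipeline.
#'
#' @param pairs Pairs tibble.
#' @return Deduplicated pairs tibble.
#' @export
dedup_pairs <- function(pairs) {
  dplyr::distinct(pairs, .data$contig1, .data$pos1, .data$strand1,
                  .data$contig2, .data$pos2, .data$strand2, .keep_all = TRUE)
}
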