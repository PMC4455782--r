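#' Read a draft assembly from FASTA
#'
#' Loads a (meta)genome assembly into a contig table. Sequences are retained
#' so restriction sites can be located with [annotate_sites()]. Record ids are
#' the first whitespace-delimited token of each FASTA header.
#'
#' @param path Path to a multi-record FASTA file.
#' @return A tibble with one row per contig and columns `id`, `length` (bp)
#'   and `seq` (uppercase character; IUPAC ambiguity codes preserved).
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) abort(paste0("assembly file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort(paste0("assembly file is empty: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate contig id(s) in assembly: ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, length = Biostrings::width(seqs),
         seq = unname(as.character(seqs)))
}

#' Write contigs to FASTA
#'
#' @param contigs Contig tibble with `id` and `seq` columns.
#' @param path Output FASTA path (written atomically).
#' @return `path`, invisibly.
#' @export
write_assembly <- function(contigs, path) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  seqs <- Biostrings::DNAStringSet(contigs$seq)
  names(seqs) <- contigs$id
  write_atomic(path, function(tmp) Biostrings::writeXStringSet(seqs, tmp))
}

#' Locate restriction sites in a sequence
#'
#' Finds every exact, possibly overlapping occurrence of a restriction
#' enzyme's recognition motif (e.g. HindIII `AAGCTT`, NcoI `CCATGG`).
#' Matching is case-insensitive; positions containing IUPAC ambiguity codes
#' never match. If the motif is not its own reverse complement, occurrences
#' of the reverse complement are merged in (deduplicated, sorted), so site
#' positions always refer to the forward strand.
#'
#' @param sequence A nucleotide string.
#' @param motif The recognition motif (A/C/G/T only).
#' @return Sorted integer vector of 0-based offsets of the motif's first base.
#' @examples
#' find_restriction_sites("GGAAGCTTCCAAGCTT", "AAGCTT")
#' @export
find_restriction_sites <- function(sequence, motif) {
  motif <- check_motif(motif)
  subject <- Biostrings::DNAString(sequence)
  hits <- Biostrings::start(Biostrings::matchPattern(motif, subject, fixed = TRUE))
  rc <- revcomp(motif)
  if (!identical(rc, motif)) {
    hits <- c(hits, Biostrings::start(Biostrings::matchPattern(rc, subject, fixed = TRUE)))
  }
  sort(unique(as.integer(hits))) - 1L
}

#' Annotate contigs with restriction sites
#'
#' Adds a `sites` list-column (0-based offsets of the motif's first base on
#' each contig) and a `site_count` column. Site counts are the normalisation
#' denominators of the contact graph, and site positions drive the read-pair
#' proximity filter.
#'
#' @param contigs Contig tibble from [read_assembly()] (must retain `seq`).
#' @param motif Restriction motif, e.g. `"AAGCTT"`.
#' @return The contig tibble with `sites` and `site_count` columns added, and
#'   the motif recorded in attribute `"motif"`.
#' @export
annotate_sites <- function(contigs, motif) {
  motif <- check_motif(motif)
  if (!"seq" %in% names(contigs)) {
    abort("contigs must retain a 'seq' column for site annotation")
  }
  out <- dplyr::mutate(
    contigs,
    sites = purrr::map(.data$seq, find_restriction_sites, motif = motif),
    site_count = lengths(.data$sites)
  )
  attr(out, "motif") <- motif
  out
}

#' Write a restriction-site annotation table
#'
#' Emits `contig_id<TAB>length<TAB>site_count<TAB>comma-joined positions`.
#'
#' @param contigs Annotated contig tibble from [annotate_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(contigs, path) {
  stopifnot(all(c("id", "length", "site_count", "sites") %in% names(contigs)))
  out <- tibble(
    contig_id = contigs$id,
    length = contigs$length,
    site_count = contigs$site_count,
    positions = purrr::map_chr(contigs$sites, paste, collapse = ",")
  )
  write_tsv_atomic(out, path)
}

#' Read a contig-to-species truth table
#'
#' Parses a two-column, headerless TSV of `(contig id, species label)` rows,
#' one row per membership; contigs listed under several species become
#' multi-label entries. A contig is considered to belong to every species it
#' aligns to, so multi-membership is expected for conserved or shared
#' sequence. Lines starting with `#` are comments.
#'
#' @param path Path to the truth TSV.
#' @param contigs Optional contig tibble; ids present in the truth table but
#'   absent from the assembly trigger a warning (rows are kept, to support
#'   partial assemblies).
#' @return A tibble with columns `contig_id` and `species`, one row per
#'   distinct membership.
#' @export
read_truth <- function(path, contigs = NULL) {
  if (!file.exists(path)) abort(paste0("truth file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warn(paste0("truth file has no data rows: ", path))
    return(tibble(contig_id = character(), species = character()))
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    abort(paste0("malformed truth row at line ", bad, ": expected 2 tab-separated columns"))
  }
  out <- dplyr::distinct(tibble(
    contig_id = purrr::map_chr(fields, 1L),
    species = purrr::map_chr(fields, 2L)
  ))
  if (!is.null(contigs)) {
    missing <- setdiff(out$contig_id, contigs$id)
    if (length(missing) > 0L) {
      warn(paste0(
        length(missing), " truth contig id(s) absent from the assembly (kept): ",
        paste(utils::head(missing, 5L), collapse = ", "),
        if (length(missing) > 5L) ", ..." else ""
      ))
    }
  }
  out
}

#' Write a truth table
#'
#' @param truth Tibble with `contig_id` and `species` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write_tsv_atomic(truth[, c("contig_id", "species")], path, col_names = FALSE)
}
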