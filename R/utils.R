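# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Atomic write: emit to a sibling temp file, then rename into place so that
# partially written outputs are never observed.
write_atomic <- function(path, writer) {
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(paste0("failed to move temporary file into place at ", path))
  }
  invisible(path)
}

write_tsv_atomic <- function(x, path, col_names = TRUE) {
  write_atomic(path, function(tmp) {
    readr::write_tsv(x, tmp, col_names = col_names, progress = FALSE)
  })
}

# Reverse complement of an unambiguous DNA motif.
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

check_motif <- function(motif) {
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif)) {
    abort("restriction motif must be a non-empty string")
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    abort(paste0("restriction motif must contain only A/C/G/T, got '", motif, "'"))
  }
  motif
}

# Distance from each 5' position to the nearest annotated site (first base),
# vectorised over positions. `sites` is a sorted 0-based integer vector.
dist_to_nearest_site <- function(pos, sites) {
  if (length(sites) == 0L) {
    return(rep(Inf, length(pos)))
  }
  i <- findInterval(pos, sites)
  d_left <- ifelse(i >= 1L, pos - sites[pmax(i, 1L)], Inf)
  d_right <- ifelse(i < length(sites), sites[pmin(i + 1L, length(sites))] - pos, Inf)
  pmin(d_left, d_right)
}

`%const%` <- function(x, y) isTRUE(all.equal(x, y))
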